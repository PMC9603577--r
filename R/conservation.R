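# Cross-species identity over the catalytic domain and its sub-regions.

#' Read a pre-aligned multi-species protein FASTA
#'
#' Consumes an existing alignment (gap character `-`); the package does not
#' align. All rows must have equal (gapped) length and the designated
#' reference species must be present.
#'
#' @param path Aligned multi-FASTA path.
#' @param reference_id Identifier of the reference (human) row; defaults to
#'   the first record.
#' @return List of class `aligned_set`: `reference_id`, `rows` (named
#'   character vector of gapped sequences).
#' @export
read_alignment <- function(path, reference_id = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) < 2L) stop("alignment needs at least 2 sequences: ", path)
  rows <- toupper(as.character(aa))
  names(rows) <- names(aa)
  if (length(unique(nchar(rows))) != 1L) {
    stop("aligned sequences have unequal lengths in ", path)
  }
  if (is.null(reference_id)) reference_id <- names(rows)[1L]
  if (!reference_id %in% names(rows)) {
    stop("reference '", reference_id, "' not found in ", path)
  }
  structure(list(reference_id = reference_id, rows = rows),
            class = "aligned_set")
}

# Alignment column index of each reference (ungapped) position.
reference_columns <- function(aln) {
  ref <- strsplit(aln$rows[[aln$reference_id]], "")[[1L]]
  which(ref != "-")
}

#' Percent identity of one species to the reference over a region
#'
#' Regions are given in reference (ungapped, 1-based inclusive) coordinates.
#' Alignment columns where the reference is gapped are not reference
#' positions and do not enter the denominator; gaps in the other species
#' count as mismatches. Identity = 100 x matches / region length.
#'
#' @param aln An `aligned_set`.
#' @param other Species identifier to compare against the reference.
#' @param start,end Region bounds in reference coordinates; default the full
#'   reference length.
#' @return Percent identity (unrounded).
#' @export
pairwise_identity <- function(aln, other, start = 1L, end = NULL) {
  if (!other %in% names(aln$rows)) stop("unknown species: ", other)
  cols <- reference_columns(aln)
  if (is.null(end)) end <- length(cols)
  if (start < 1L || end > length(cols) || start > end) {
    stop("region ", start, "-", end, " outside reference length ",
         length(cols))
  }
  idx <- cols[start:end]
  ref <- strsplit(aln$rows[[aln$reference_id]], "")[[1L]][idx]
  oth <- strsplit(aln$rows[[other]], "")[[1L]][idx]
  100 * sum(oth == ref) / length(idx)
}

#' Mean cross-species conservation of a region
#'
#' Mean of [pairwise_identity()] to the reference over all non-reference
#' species in the alignment.
#'
#' @inheritParams pairwise_identity
#' @return Percent (unrounded; round with [round_half_up()] for reports).
#' @export
region_conservation <- function(aln, start = 1L, end = NULL) {
  others <- setdiff(names(aln$rows), aln$reference_id)
  mean(vapply(others, function(sp) pairwise_identity(aln, sp, start, end),
              numeric(1)))
}

#' Per-species, per-region conservation report
#'
#' @param aln An `aligned_set`.
#' @param regions Region data frame (see [default_regions()]).
#' @return Data frame: one row per (species, region) plus a `mean` species
#'   row, with one-decimal identities.
#' @export
conservation_report <- function(aln, regions = default_regions()) {
  others <- setdiff(names(aln$rows), aln$reference_id)
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    ids <- vapply(others, function(sp) {
      pairwise_identity(aln, sp, regions$start[i], regions$end[i])
    }, numeric(1))
    data.frame(region = regions$name[i],
               species = c(others, "mean"),
               identity = round_half_up(c(ids, mean(ids)), 1))
  })
  do.call(rbind, rows)
}

#' Functional regions of the CDKL5 catalytic domain
#'
#' The three critical sites — ATP-binding site (aa 19-43), S/T kinase active
#' site (aa 131-143), TEY motif (aa 169-171) — and two representative
#' non-critical windows (aa 144-168, between active site and TEY motif, and
#' aa 257-297). Coordinates are 1-based inclusive residue positions of the
#' human protein.
#'
#' @return Data frame: `name`, `start`, `end`, `critical`.
#' @export
default_regions <- function() {
  data.frame(
    name = c("ATP-binding site", "S/T kinase active site", "TEY motif",
             "non-critical 144-168", "non-critical 257-297"),
    start = c(19L, 131L, 169L, 144L, 257L),
    end = c(43L, 143L, 171L, 168L, 297L),
    critical = c(TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}
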