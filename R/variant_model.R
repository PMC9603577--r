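# Substitution representation, notation parsing, saturation enumeration.

#' Amino-acid row order used throughout the package
#'
#' The 20 standard one-letter codes grouped by physicochemical class —
#' non-polar, polar uncharged, acidic, basic — with a fixed alphabetical-free
#' internal order so that heatmap rows and enumeration output are
#' deterministic. This grouping matches the conventional presentation of
#' saturation heatmaps for kinase domains.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' amino_acid_order()
amino_acid_order <- function() {
  c(
    "G", "A", "V", "L", "I", "M", "P", "F", "W", # non-polar
    "S", "T", "C", "Y", "N", "Q",                # polar, uncharged
    "D", "E",                                    # acidic
    "K", "R", "H"                                # basic
  )
}

AA_STANDARD <- c(
  "G", "A", "V", "L", "I", "M", "P", "F", "W",
  "S", "T", "C", "Y", "N", "Q", "D", "E", "K", "R", "H"
)

#' Read a protein sequence from FASTA
#'
#' Reads the first record of a protein FASTA file and validates that every
#' residue is one of the 20 standard one-letter codes. Residue numbering is
#' 1-based: residue 1 is the first character.
#'
#' @param path Path to a FASTA file.
#' @return A list with `id` (record identifier) and `residues` (single
#'   uppercase string).
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("FASTA file contains no records: ", path)
  residues <- toupper(as.character(aa[[1L]]))
  bad <- setdiff(unique(strsplit(residues, "")[[1L]]), AA_STANDARD)
  if (length(bad) > 0L) {
    stop("non-standard residue code(s) in ", names(aa)[1L], ": ",
         paste(bad, collapse = ", "))
  }
  list(id = names(aa)[1L], residues = residues)
}

#' Parse protein substitution notation
#'
#' Parses one-letter substitution notation such as `"H145Y"` (wild-type
#' residue, 1-based position, mutant residue). Vectorised.
#'
#' @param text Character vector of substitution strings.
#' @return A data frame with columns `position`, `wt`, `mut`, `is_wildtype`.
#'   `is_wildtype` is `TRUE` when the two residues are equal (a self
#'   substitution such as `"M1M"`, used only to mark wild-type heatmap cells).
#' @export
#' @examples
#' parse_substitution(c("H145Y", "M1M"))
parse_substitution <- function(text) {
  if (length(text) == 0L) {
    return(data.frame(position = integer(), wt = character(),
                      mut = character(), is_wildtype = logical()))
  }
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", text)
  if (any(!ok)) {
    stop("malformed substitution notation: ",
         paste(text[!ok], collapse = ", "))
  }
  wt <- substr(text, 1L, 1L)
  mut <- substring(text, nchar(text))
  pos <- as.integer(substr(text, 2L, nchar(text) - 1L))
  bad_aa <- !(wt %in% AA_STANDARD) | !(mut %in% AA_STANDARD)
  if (any(bad_aa)) {
    stop("non-standard amino-acid code in: ",
         paste(text[bad_aa], collapse = ", "))
  }
  if (any(pos < 1L)) {
    stop("position must be >= 1 in: ", paste(text[pos < 1L], collapse = ", "))
  }
  data.frame(position = pos, wt = wt, mut = mut, is_wildtype = wt == mut)
}

#' Format substitutions as one-letter notation
#'
#' Inverse of [parse_substitution()]: `parse_substitution(format_substitution(x))`
#' reproduces `x`.
#'
#' @param subs Data frame with columns `position`, `wt`, `mut`.
#' @return Character vector like `"H145Y"`.
#' @export
format_substitution <- function(subs) {
  paste0(subs$wt, subs$position, subs$mut)
}

#' Enumerate the saturation substitution set over a region
#'
#' For every position in `start:end` emits the 19 non-wild-type replacements,
#' in the fixed order of [amino_acid_order()]. A 300-residue domain therefore
#' yields 19 x 300 = 5700 substitutions. The initiator methionine (position 1)
#' is substitutable like any other position.
#'
#' @param seq A protein sequence: either the list returned by
#'   [read_protein_fasta()] or a plain residue string.
#' @param start,end 1-based inclusive region bounds; default the whole
#'   sequence.
#' @return Data frame with columns `position`, `wt`, `mut`, `is_wildtype`
#'   (all `FALSE`), ordered by position then amino-acid order.
#' @export
#' @examples
#' enumerate_saturation("MKI", 1, 3)
enumerate_saturation <- function(seq, start = 1L, end = NULL) {
  residues <- if (is.list(seq)) seq$residues else seq
  stopifnot(is.character(residues), length(residues) == 1L, nzchar(residues))
  len <- nchar(residues)
  if (is.null(end)) end <- len
  start <- as.integer(start); end <- as.integer(end)
  if (start < 1L || end > len || start > end) {
    stop("region ", start, "-", end, " outside sequence of length ", len)
  }
  chars <- strsplit(residues, "")[[1L]]
  bad <- setdiff(unique(chars), AA_STANDARD)
  if (length(bad) > 0L) {
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "))
  }
  order20 <- amino_acid_order()
  pos <- start:end
  wt <- chars[pos]
  # 19 rows per position: the 20 standard codes minus the wild-type residue
  res <- do.call(rbind, lapply(seq_along(pos), function(i) {
    muts <- order20[order20 != wt[i]]
    data.frame(position = pos[i], wt = wt[i], mut = muts)
  }))
  res$is_wildtype <- FALSE
  rownames(res) <- NULL
  res
}

#' Write prediction-server batch input files
#'
#' Serialises a substitution set in the batch-submission dialect of one of
#' the three prediction servers. The pipeline only writes these inputs (and
#' parses the servers' reports, see [read_native_report()]); it never queries
#' the services itself.
#'
#' @param subs Data frame of substitutions (`position`, `wt`, `mut`).
#' @param accession Sequence accession string placed in dialects that need it.
#' @param dialect One of `"polyphen2"` (lines `accession pos wt mut`),
#'   `"provean"` (one `WTposMUT` line per substitution) or `"sift"`
#'   (comma-separated substitution list, one line).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tool_batch_inputs <- function(subs, accession, dialect, path) {
  if (nrow(subs) == 0L) stop("empty substitution collection")
  dialect <- match.arg(dialect, c("polyphen2", "provean", "sift"))
  lines <- switch(dialect,
    polyphen2 = paste(accession, subs$position, subs$wt, subs$mut),
    provean = format_substitution(subs),
    sift = paste(format_substitution(subs), collapse = ",")
  )
  writeLines(lines, path)
  invisible(path)
}
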