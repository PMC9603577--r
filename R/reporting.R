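# Heatmap-matrix export of consensus tiers over the saturation set.

#' Build the 20 x L tier heatmap matrix
#'
#' Rows are the 20 amino acids in the fixed group order of
#' [amino_acid_order()]; columns are positions. Each column has exactly one
#' wild-type cell (marked `"."`, at the row of the wild-type residue) and 19
#' tier cells (P3/P2/B2/B3).
#'
#' @param tiers Complete tier table for the range (see [tier_table()]).
#' @param sequence Residue string of the reference protein.
#' @param start,end 1-based inclusive position range; default the full
#'   sequence.
#' @return Character matrix with amino-acid rownames and position colnames.
#' @export
build_heatmap <- function(tiers, sequence, start = 1L, end = NULL) {
  if (is.null(end)) end <- nchar(sequence)
  positions <- start:end
  chars <- strsplit(sequence, "")[[1L]]
  order20 <- amino_acid_order()
  mat <- matrix(NA_character_, nrow = 20L, ncol = length(positions),
                dimnames = list(order20, positions))
  mat[cbind(match(chars[positions], order20), seq_along(positions))] <- "."
  in_range <- tiers$position %in% positions
  t_sub <- tiers[in_range, , drop = FALSE]
  mat[cbind(match(t_sub$mut, order20),
            match(t_sub$position, positions))] <- as.character(t_sub$tier)
  if (anyNA(mat)) {
    holes <- which(is.na(mat), arr.ind = TRUE)
    miss <- paste0(chars[positions[holes[, 2L]]], positions[holes[, 2L]],
                   order20[holes[, 1L]])
    stop("incomplete tiers; missing cell(s): ",
         paste(utils::head(miss, 10L), collapse = ", "),
         if (length(miss) > 10L) sprintf(" (and %d more)", length(miss) - 10L))
  }
  mat
}

#' Write a heatmap matrix as TSV
#'
#' First column `aa` holds the amino-acid row labels; remaining columns are
#' positions. Wild-type cells serialise as `"."`.
#'
#' @param mat Matrix from [build_heatmap()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(mat, path) {
  df <- data.frame(aa = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a heatmap matrix TSV
#'
#' Inverse of [write_heatmap_tsv()].
#'
#' @param path TSV path.
#' @return Character matrix with amino-acid rownames and position colnames.
#' @export
read_heatmap_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$aa
  mat
}

#' Plot a tier heatmap
#'
#' Renders the matrix with ggplot2 (tiers coloured on a damaging-to-benign
#' scale, wild-type cells white). The TSV matrix, not the image, is the
#' contract surface; plotting is a convenience.
#'
#' @param mat Matrix from [build_heatmap()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(mat) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_heatmap needs the ggplot2 package")
  }
  df <- expand.grid(aa = rownames(mat), position = as.integer(colnames(mat)),
                    stringsAsFactors = FALSE)
  df$cell <- as.vector(mat)
  df$aa <- factor(df$aa, levels = rev(amino_acid_order()))
  df$cell <- factor(df$cell, levels = c("P3", "P2", "B2", "B3", "."))
  ggplot2::ggplot(df, ggplot2::aes(x = position, y = aa, fill = cell)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      P3 = "#b2182b", P2 = "#ef8a62", B2 = "#67a9cf", B3 = "#2166ac",
      "." = "white"), name = "tier") +
    ggplot2::labs(x = "position", y = "mutant residue") +
    ggplot2::theme_minimal(base_size = 8)
}
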