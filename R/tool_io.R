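# Readers/writers: canonical score table, native tool reports, reference sets.

TOOLS <- c("humdiv", "humvar", "provean", "sift")

score_range <- function(tool) {
  # humdiv/humvar/sift scores live in [0,1]; provean is an unbounded delta
  if (tool %in% c("humdiv", "humvar", "sift")) c(0, 1) else c(-Inf, Inf)
}

validate_scores <- function(tab, context = "score table") {
  needed <- c("position", "wt", "mut", "tool", "score")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop(context, " missing column(s): ", paste(missing, collapse = ", "))
  }
  bad_tool <- setdiff(unique(tab$tool), TOOLS)
  if (length(bad_tool) > 0L) {
    stop(context, " has unknown tool(s): ", paste(bad_tool, collapse = ", "))
  }
  if (any(!is.finite(tab$score))) stop(context, " has non-finite score(s)")
  for (t in unique(tab$tool)) {
    rng <- score_range(t)
    s <- tab$score[tab$tool == t]
    if (any(s < rng[1] | s > rng[2])) {
      stop(context, ": ", t, " score out of [", rng[1], ",", rng[2], "]")
    }
  }
  key <- paste(tab$tool, tab$position, tab$wt, tab$mut)
  if (anyDuplicated(key)) {
    stop(context, " has duplicate (tool, substitution) rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  invisible(tab)
}

#' Read the canonical score-table TSV
#'
#' The canonical interchange format for prediction scores: a UTF-8
#' tab-delimited file with header columns `position`, `wt`, `mut`, `tool`,
#' `score` (extra columns are tolerated and dropped). Scores are validated
#' against each tool's range and duplicate (tool, substitution) rows are
#' rejected.
#'
#' @param path Path to the TSV file.
#' @return Data frame with the five canonical columns.
#' @export
read_score_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  needed <- c("position", "wt", "mut", "tool", "score")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    stop("score table ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[needed]
  if (nrow(tab) == 0L) {
    tab$position <- integer(); tab$score <- numeric()
    return(tab)
  }
  tab$position <- as.integer(tab$position)
  tab$score <- suppressWarnings(as.numeric(tab$score))
  if (any(is.na(tab$score))) stop("unparseable score value(s) in ", path)
  validate_scores(tab, context = paste0("score table ", path))
  tab
}

#' Write the canonical score-table TSV
#'
#' @param tab Data frame of scores (canonical columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(tab, path) {
  validate_scores(tab)
  utils::write.table(tab[c("position", "wt", "mut", "tool", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction server's native report
#'
#' Parses the batch-output dialect of one of the three servers into canonical
#' score rows. Server-assigned class labels present in the reports are
#' deliberately ignored: classification is always recomputed locally from
#' thresholds (see [classify_scores()]), which keeps the pipeline auditable.
#' Lines starting with `#` are skipped; extra columns are tolerated.
#'
#' Dialects:
#' \describe{
#'   \item{polyphen2}{Tab-delimited with columns `pos`, `aa1`, `aa2` and a
#'     probability column `pph2_prob` (plus a prediction column, ignored).
#'     `tool` selects which mode (`"humdiv"` or `"humvar"`) the report came
#'     from, since PolyPhen-2 emits the same layout for both.}
#'   \item{provean}{Tab- or comma-delimited with columns `VARIATION`
#'     (one-letter notation) and `SCORE`.}
#'   \item{sift}{Tab-delimited with columns `substitution` and `score`.}
#' }
#'
#' @param path Path to the report file.
#' @param tool One of `"humdiv"`, `"humvar"`, `"provean"`, `"sift"`.
#' @return Canonical score data frame.
#' @export
read_native_report <- function(path, tool) {
  tool <- match.arg(tool, TOOLS)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("native report ", path, " has no data rows")
  sep <- if (tool == "provean" && grepl(",", lines[1L])) "," else "\t"
  tab <- utils::read.table(text = lines, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, strip.white = TRUE,
                           check.names = TRUE)
  get_col <- function(tab, candidates, what) {
    hit <- intersect(candidates, names(tab))
    if (length(hit) == 0L) {
      stop("native ", tool, " report ", path, " lacks a ", what,
           " column (looked for: ", paste(candidates, collapse = ", "), ")")
    }
    tab[[hit[1L]]]
  }
  if (tool %in% c("humdiv", "humvar")) {
    pos <- as.integer(get_col(tab, c("pos", "o_pos", "position"), "position"))
    wt <- trimws(get_col(tab, c("aa1", "o_aa1", "wt"), "wild-type residue"))
    mut <- trimws(get_col(tab, c("aa2", "o_aa2", "mut"), "mutant residue"))
    score <- suppressWarnings(
      as.numeric(get_col(tab, c("pph2_prob", "prob"), "probability")))
    out <- data.frame(position = pos, wt = wt, mut = mut,
                      tool = tool, score = score)
  } else if (tool == "provean") {
    variation <- trimws(get_col(tab, c("VARIATION", "variation"), "variation"))
    score <- suppressWarnings(
      as.numeric(get_col(tab, c("SCORE", "score"), "score")))
    sub <- parse_substitution(variation)
    out <- data.frame(position = sub$position, wt = sub$wt, mut = sub$mut,
                      tool = tool, score = score)
  } else {
    variation <- trimws(get_col(tab, c("substitution", "SUBSTITUTION"),
                                "substitution"))
    score <- suppressWarnings(
      as.numeric(get_col(tab, c("score", "SCORE", "sift_score"), "score")))
    sub <- parse_substitution(variation)
    out <- data.frame(position = sub$position, wt = sub$wt, mut = sub$mut,
                      tool = tool, score = score)
  }
  if (any(is.na(out$score))) {
    stop("native report ", path, ": unparseable score at data row(s) ",
         paste(which(is.na(out$score)), collapse = ", "))
  }
  validate_scores(out, context = paste0("native report ", path))
  out
}

#' Read a labelled reference variant set
#'
#' Reads a CSV with columns `notation` (one-letter substitution) and `label`.
#' Labels are normalised: `"benign"` and `"likely benign"` map to `benign`;
#' `"pathogenic"` and `"likely pathogenic"` map to `pathogenic`. This mirrors
#' how expert-reviewed ClinVar classes collapse onto the binary evaluation
#' axis. Duplicate substitutions are rejected.
#'
#' @param path Path to the CSV file.
#' @return Data frame with columns `position`, `wt`, `mut`, `label` and
#'   optional `source_note` (copied through when present in the input).
#' @export
read_reference_set <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("notation", "label"), names(tab))
  if (length(missing) > 0L) {
    stop("reference set ", path, " missing column(s): ",
         paste(missing, collapse = ", "))
  }
  sub <- parse_substitution(trimws(tab$notation))
  label_raw <- tolower(trimws(tab$label))
  label <- ifelse(label_raw %in% c("pathogenic", "likely pathogenic"),
                  "pathogenic",
           ifelse(label_raw %in% c("benign", "likely benign"), "benign", NA))
  if (any(is.na(label))) {
    stop("unknown label token(s): ",
         paste(unique(label_raw[is.na(label)]), collapse = ", "))
  }
  out <- data.frame(position = sub$position, wt = sub$wt, mut = sub$mut,
                    label = label)
  if ("source_note" %in% names(tab)) out$source_note <- tab$source_note
  if (anyDuplicated(format_substitution(out))) {
    stop("duplicate substitutions in reference set ", path)
  }
  out
}

#' Write a reference variant set CSV
#'
#' @param ref Reference data frame (`position`, `wt`, `mut`, `label`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_set <- function(ref, path) {
  out <- data.frame(notation = format_substitution(ref), label = ref$label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
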