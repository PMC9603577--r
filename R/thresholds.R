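# Per-tool categorical classification from raw scores and binarisation.

#' Default classification thresholds
#'
#' The published operating thresholds of the four predictors:
#' \itemize{
#'   \item PolyPhen-2 HumDiv: score > 0.957 is "probably damaging",
#'     score < 0.450 is "benign", the closed middle interval is
#'     "possibly damaging".
#'   \item PolyPhen-2 HumVar: boundaries 0.909 and 0.447, same scheme.
#'   \item PROVEAN: delta score <= -2.5 is "deleterious", otherwise
#'     "neutral". The boundary value itself is deleterious, following the
#'     tool's own convention.
#'   \item SIFT: score >= 0.05 is "tolerated", below 0.05 "deleterious".
#' }
#' All thresholds are overridable, which makes the exact-boundary conventions
#' and sensitivity analyses configurable without code change.
#'
#' @return Nested list of per-tool thresholds.
#' @export
default_thresholds <- function() {
  list(
    humdiv = list(probably = 0.957, benign = 0.450),
    humvar = list(probably = 0.909, benign = 0.447),
    provean = list(cutoff = -2.5),
    sift = list(cutoff = 0.05)
  )
}

#' Classify PolyPhen-2 scores into three-way categories
#'
#' @param score Numeric vector in \eqn{[0,1]}.
#' @param mode `"humdiv"` or `"humvar"`.
#' @param thresholds Threshold configuration, see [default_thresholds()].
#' @return Character vector over `probably_damaging`, `possibly_damaging`,
#'   `benign`. Scores exactly at either boundary fall in the closed middle
#'   interval (`possibly_damaging`): the named classes are "above" the upper
#'   and "below" the lower boundary, so the closed middle is the only
#'   exhaustive completion.
#' @export
classify_polyphen2 <- function(score, mode = c("humdiv", "humvar"),
                               thresholds = default_thresholds()) {
  mode <- match.arg(mode)
  if (any(!is.finite(score) | score < 0 | score > 1)) {
    stop("PolyPhen-2 score out of [0,1]")
  }
  th <- thresholds[[mode]]
  ifelse(score > th$probably, "probably_damaging",
         ifelse(score < th$benign, "benign", "possibly_damaging"))
}

#' Classify PROVEAN delta scores
#'
#' @param score Finite numeric vector (delta scores; more negative = more
#'   deleterious).
#' @inheritParams classify_polyphen2
#' @return Character vector over `deleterious`, `neutral`. Scores at the
#'   cutoff (-2.5 by default) are deleterious.
#' @export
classify_provean <- function(score, thresholds = default_thresholds()) {
  if (any(!is.finite(score))) stop("non-finite PROVEAN score")
  ifelse(score <= thresholds$provean$cutoff, "deleterious", "neutral")
}

#' Classify SIFT scores
#'
#' @param score Numeric vector in \eqn{[0,1]}.
#' @inheritParams classify_polyphen2
#' @return Character vector over `deleterious`, `tolerated`. A score at the
#'   cutoff (0.05 by default) or above is tolerated.
#' @export
classify_sift <- function(score, thresholds = default_thresholds()) {
  if (any(!is.finite(score) | score < 0 | score > 1)) {
    stop("SIFT score out of [0,1]")
  }
  ifelse(score >= thresholds$sift$cutoff, "tolerated", "deleterious")
}

#' Classify a score by tool
#'
#' Dispatch wrapper over the per-tool classifiers. Vectorised over `score`
#' for a single `tool`.
#'
#' @param tool One of `"humdiv"`, `"humvar"`, `"provean"`, `"sift"`.
#' @inheritParams classify_polyphen2
#' @return Character vector of tool-specific category labels.
#' @export
classify_score <- function(tool, score, thresholds = default_thresholds()) {
  tool <- match.arg(tool, TOOLS)
  switch(tool,
    humdiv = classify_polyphen2(score, "humdiv", thresholds),
    humvar = classify_polyphen2(score, "humvar", thresholds),
    provean = classify_provean(score, thresholds),
    sift = classify_sift(score, thresholds)
  )
}

#' Binarise tool categories to pathogenic/benign
#'
#' The damaging-side categories (`probably_damaging`, `possibly_damaging`,
#' `deleterious`) map to `pathogenic`; the tolerated side (`benign`,
#' `neutral`, `tolerated`) maps to `benign`. This unification is what makes
#' tools with different native vocabularies combinable.
#'
#' @param category Character vector of tool categories.
#' @return Character vector over `pathogenic`, `benign`.
#' @export
binarize_category <- function(category) {
  path <- c("probably_damaging", "possibly_damaging", "deleterious")
  ben <- c("benign", "neutral", "tolerated")
  bad <- setdiff(unique(category), c(path, ben))
  if (length(bad) > 0L) {
    stop("unknown category label(s): ", paste(bad, collapse = ", "))
  }
  ifelse(category %in% path, "pathogenic", "benign")
}

#' Classify a whole score table
#'
#' Adds `category` (tool-specific label) and `call` (binary
#' pathogenic/benign) columns to a canonical score table.
#'
#' @param scores Canonical score data frame.
#' @inheritParams classify_polyphen2
#' @return The input with `category` and `call` columns appended.
#' @export
classify_scores <- function(scores, thresholds = default_thresholds()) {
  validate_scores(scores)
  scores$category <- NA_character_
  for (t in unique(scores$tool)) {
    idx <- scores$tool == t
    scores$category[idx] <- classify_score(t, scores$score[idx], thresholds)
  }
  scores$call <- binarize_category(scores$category)
  scores
}

#' Per-tool binary call frequencies and rates
#'
#' Summarises a classified score table into, for each tool, the frequency and
#' percentage of benign and pathogenic calls (percentages to one decimal,
#' half-up). Class counts sum to each tool's total by construction.
#'
#' @param scores Canonical score table; classified on the fly if it lacks a
#'   `call` column.
#' @inheritParams classify_polyphen2
#' @return Data frame with one row per tool: `tool`, `n_benign`,
#'   `n_pathogenic`, `total`, `pct_benign`, `pct_pathogenic`.
#' @export
tabulate_categories <- function(scores, thresholds = default_thresholds()) {
  if (!"call" %in% names(scores)) scores <- classify_scores(scores, thresholds)
  tools <- intersect(TOOLS, unique(scores$tool))
  rows <- lapply(tools, function(t) {
    calls <- scores$call[scores$tool == t]
    n_path <- sum(calls == "pathogenic")
    n_ben <- sum(calls == "benign")
    total <- length(calls)
    data.frame(tool = t, n_benign = n_ben, n_pathogenic = n_path,
               total = total,
               pct_benign = round_half_up(100 * n_ben / total, 1),
               pct_pathogenic = round_half_up(100 * n_path / total, 1))
  })
  do.call(rbind, rows)
}
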