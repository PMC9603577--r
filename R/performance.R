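# Confusion counts, accuracy/sensitivity/specificity/MCC, combination sweep.

#' Confusion counts of binary predictions against a labelled reference
#'
#' TP = pathogenic reference predicted pathogenic, TN = benign predicted
#' benign, FP = benign predicted pathogenic, FN = pathogenic predicted
#' benign. Every reference variant must have a prediction.
#'
#' @param predictions Data frame with `position`, `wt`, `mut`, `call`.
#' @param reference Data frame with `position`, `wt`, `mut`, `label`.
#' @return List of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predictions, reference) {
  pred_key <- format_substitution(predictions)
  ref_key <- format_substitution(reference)
  missing <- setdiff(ref_key, pred_key)
  if (length(missing) > 0L) {
    stop("no prediction for reference variant(s): ",
         paste(missing, collapse = ", "))
  }
  call <- predictions$call[match(ref_key, pred_key)]
  confusion(
    tp = sum(reference$label == "pathogenic" & call == "pathogenic"),
    tn = sum(reference$label == "benign" & call == "benign"),
    fp = sum(reference$label == "benign" & call == "pathogenic"),
    fn = sum(reference$label == "pathogenic" & call == "benign")
  )
}

#' Construct confusion counts directly
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return List of class `confusion_counts`.
#' @export
confusion <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  counts <- as.list(stats::setNames(as.integer(counts), names(counts)))
  structure(counts, class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' Computes
#' \deqn{accuracy = 100 (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{sensitivity = 100\, TP/(TP+FN)}
#' \deqn{specificity = 100\, TN/(TN+FP)}
#' \deqn{MCC = (TP\cdot TN - FP\cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' MCC ranges over \eqn{[-1, 1]} (+1 always correct, 0 random, -1 always
#' wrong) and is undefined — held as `NA`, never coerced to 0 — when any of
#' the four marginal sums is zero. Sensitivity and specificity are likewise
#' `NA` when their denominator is zero. Values are kept unrounded; use
#' [round_metrics()] / [format_mcc()] for presentation.
#'
#' @param cc A `confusion_counts` object (or list with `tp`, `tn`, `fp`,
#'   `fn`).
#' @return List of class `performance_metrics`: `accuracy`, `sensitivity`,
#'   `specificity`, `mcc` plus the input counts.
#' @export
performance_metrics <- function(cc) {
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  total <- tp + tn + fp + fn
  if (total == 0L) stop("empty confusion: all counts are zero")
  sens <- if (tp + fn > 0L) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) 100 * tn / (tn + fp) else NA_real_
  marg <- as.numeric(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (any(marg == 0)) NA_real_ else {
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(prod(marg))
  }
  structure(list(accuracy = 100 * (tp + tn) / total, sensitivity = sens,
                 specificity = spec, mcc = mcc,
                 tp = tp, tn = tn, fp = fp, fn = fn),
            class = "performance_metrics")
}

#' Presentation rounding of performance metrics
#'
#' Percentages to one decimal, MCC to three decimals, both half-up.
#'
#' @param m A `performance_metrics` object.
#' @return List with rounded `accuracy`, `sensitivity`, `specificity`,
#'   `mcc` (still `NA` when undefined).
#' @export
round_metrics <- function(m) {
  list(accuracy = round_half_up(m$accuracy, 1),
       sensitivity = round_half_up(m$sensitivity, 1),
       specificity = round_half_up(m$specificity, 1),
       mcc = round_half_up(m$mcc, 3))
}

#' Render an MCC value for reports
#'
#' Undefined MCCs print as a horizontal bar, the convention used in
#' benchmark tables for combinations whose confusion matrix has an empty
#' marginal.
#'
#' @param mcc Numeric (possibly `NA`) MCC value(s).
#' @return Character vector: three-decimal number or `"―"`.
#' @export
format_mcc <- function(mcc) {
  ifelse(is.na(mcc), "―", sprintf("%.3f", round_half_up(mcc, 3)))
}

#' @export
print.performance_metrics <- function(x, ...) {
  r <- round_metrics(x)
  cat(sprintf(
    "accuracy %.1f%%  sensitivity %s  specificity %s  MCC %s\n",
    r$accuracy,
    ifelse(is.na(r$sensitivity), "―", sprintf("%.1f%%", r$sensitivity)),
    ifelse(is.na(r$specificity), "―", sprintf("%.1f%%", r$specificity)),
    format_mcc(x$mcc)))
  invisible(x)
}

#' Reconstruct confusion counts from printed marginals
#'
#' Given a reference composition and a predictor's printed sensitivity and
#' specificity, reconstructs the integer confusion counts by nearest-integer
#' (half-up) inversion: `tp = round(n_pathogenic * sens/100)`,
#' `tn = round(n_benign * spec/100)`. The reconstruction is validated by a
#' round trip: recomputed sensitivity/specificity must match the inputs at
#' one-decimal rounding.
#'
#' @param n_pathogenic,n_benign Positive reference class sizes.
#' @param sensitivity,specificity Percentages in \eqn{[0, 100]}.
#' @return A `confusion_counts` object.
#' @export
derive_confusion <- function(n_pathogenic, n_benign, sensitivity, specificity) {
  stopifnot(n_pathogenic > 0, n_benign > 0,
            sensitivity >= 0, sensitivity <= 100,
            specificity >= 0, specificity <= 100)
  tp <- as.integer(round_half_up(n_pathogenic * sensitivity / 100))
  tn <- as.integer(round_half_up(n_benign * specificity / 100))
  cc <- confusion(tp = tp, tn = tn, fp = n_benign - tn, fn = n_pathogenic - tp)
  m <- performance_metrics(cc)
  if (abs(round_half_up(m$sensitivity, 1) - round_half_up(sensitivity, 1)) > 0.05 ||
      abs(round_half_up(m$specificity, 1) - round_half_up(specificity, 1)) > 0.05) {
    stop("inconsistent marginals: reconstruction does not round-trip ",
         "(sens ", sensitivity, ", spec ", specificity, ")")
  }
  cc
}

# All non-empty subsets of `tools`, ordered singles, pairs, triples, ...
tool_subsets <- function(tools) {
  out <- list()
  for (k in seq_along(tools)) {
    combs <- utils::combn(tools, k, simplify = FALSE)
    out <- c(out, combs)
  }
  out
}

#' Benchmark every tool combination against a reference set
#'
#' Emits one row per non-empty subset of the supplied tools (15 rows for the
#' standard 4-tool panel: 4 singles, 6 pairs, 4 triples, 1 quadruple).
#' Singles pass their call through; larger subsets are combined with
#' [combine_calls()]. Each row carries the confusion counts and the
#' unrounded metrics; `mcc` is `NA` where undefined.
#'
#' @param calls Long data frame with `position`, `wt`, `mut`, `tool`,
#'   `call` covering every reference variant for every tool.
#' @param reference Labelled reference data frame.
#' @param tools Tools to sweep, in canonical order.
#' @return Data frame with columns `combination`, `n_tools`, `tp`, `tn`,
#'   `fp`, `fn`, `accuracy`, `sensitivity`, `specificity`, `mcc`.
#' @export
sweep_combinations <- function(calls, reference,
                               tools = intersect(TOOLS, unique(calls$tool))) {
  ref_key <- format_substitution(reference)
  per_tool <- lapply(tools, function(t) {
    sub <- calls[calls$tool == t, , drop = FALSE]
    hit <- match(ref_key, format_substitution(sub))
    if (anyNA(hit)) {
      stop("tool ", t, " lacks calls for: ",
           paste(ref_key[is.na(hit)], collapse = ", "))
    }
    sub$call[hit]
  })
  names(per_tool) <- tools
  rows <- lapply(tool_subsets(tools), function(subset) {
    mat <- do.call(cbind, per_tool[subset])
    consensus <- if (length(subset) == 1L) mat[, 1L] else {
      apply(mat, 1L, combine_calls)
    }
    cc <- confusion_counts(
      data.frame(position = reference$position, wt = reference$wt,
                 mut = reference$mut, call = consensus),
      reference)
    m <- performance_metrics(cc)
    data.frame(combination = paste(subset, collapse = "+"),
               n_tools = length(subset),
               tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, mcc = m$mcc)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published benchmark marginals for the 15 tool combinations
#'
#' Sensitivity/specificity percentages reported for each single tool and
#' combination evaluated on the 36-variant CDKL5 ClinVar reference set
#' (33 pathogenic, 3 benign). These printed marginals are inputs to
#' [derive_confusion()]-based reconstructions of the benchmark. The source
#' table prints one pair row with a duplicated "HumDiv & HumDiv" label; it is
#' encoded here as the humdiv+humvar subset, whose metrics it carries, so
#' each distinct subset appears exactly once.
#'
#' @return Data frame: `combination`, `n_tools`, `sensitivity`,
#'   `specificity`.
#' @export
benchmark_marginals <- function() {
  rows <- list(
    list("humdiv",                      100, 33.3),
    list("humvar",                      97.0, 66.7),
    list("provean",                     97.0, 66.7),
    list("sift",                        97.0, 0.0),
    list("humdiv+humvar",               100, 33.3),
    list("humdiv+provean",              100, 33.3),
    list("humdiv+sift",                 100, 0.0),
    list("humvar+provean",              100, 66.7),
    list("humvar+sift",                 100, 0.0),
    list("provean+sift",                97.0, 0.0),
    list("humdiv+humvar+provean",       100, 66.7),
    list("humdiv+humvar+sift",          100, 33.3),
    list("humdiv+provean+sift",         97.0, 33.3),
    list("humvar+provean+sift",         97.0, 66.7),
    list("humdiv+humvar+provean+sift",  100, 33.3)
  )
  out <- data.frame(
    combination = vapply(rows, `[[`, "", 1L),
    sensitivity = vapply(rows, `[[`, 0, 2L),
    specificity = vapply(rows, `[[`, 0, 3L)
  )
  out$n_tools <- lengths(strsplit(out$combination, "+", fixed = TRUE))
  out[c("combination", "n_tools", "sensitivity", "specificity")]
}

#' Count combinations whose MCC exceeds a threshold
#'
#' Reconstructs each row's confusion counts from its printed marginals and
#' counts rows with a defined MCC strictly above `threshold`. Undefined MCCs
#' are excluded from the count, never treated as 0.
#'
#' @param marginals Data frame as returned by [benchmark_marginals()].
#' @param n_pathogenic,n_benign Reference class sizes.
#' @param threshold MCC cutoff (default 0.5, the conventional bar for a
#'   classifier regarded as accurate).
#' @return List with `mcc` (named numeric vector per combination) and
#'   `n_above` (integer count).
#' @export
count_mcc_above <- function(marginals = benchmark_marginals(),
                            n_pathogenic = 33L, n_benign = 3L,
                            threshold = 0.5) {
  mcc <- vapply(seq_len(nrow(marginals)), function(i) {
    cc <- derive_confusion(n_pathogenic, n_benign,
                           marginals$sensitivity[i], marginals$specificity[i])
    performance_metrics(cc)$mcc
  }, numeric(1))
  names(mcc) <- marginals$combination
  list(mcc = mcc, n_above = sum(!is.na(mcc) & mcc > threshold))
}
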