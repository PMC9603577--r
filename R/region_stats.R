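# Tier counts per region and the critical vs non-critical test of proportion.

#' Count consensus tiers within each region
#'
#' @param tiers Tier table (see [tier_table()]).
#' @param regions Region data frame (see [default_regions()]). Substitutions
#'   whose position falls outside every region are reported under `"other"`.
#' @return Data frame: one row per region (plus `"other"`): `region`,
#'   `critical`, `P3`, `P2`, `B2`, `B3`, `total` and one-decimal percentage
#'   columns `pct_P3` ... `pct_B3`.
#' @export
count_tiers_by_region <- function(tiers, regions = default_regions()) {
  assign_region <- function(pos) {
    hit <- which(pos >= regions$start & pos <= regions$end)
    if (length(hit) == 0L) "other" else regions$name[hit[1L]]
  }
  where <- vapply(tiers$position, assign_region, "")
  all_names <- c(regions$name, "other")
  rows <- lapply(all_names, function(rn) {
    sub <- tiers$tier[where == rn]
    counts <- table(factor(sub, levels = TIER_LEVELS))
    total <- length(sub)
    pct <- if (total > 0) round_half_up(100 * as.integer(counts) / total, 1)
           else rep(NA_real_, 4L)
    data.frame(region = rn,
               critical = if (rn == "other") NA else
                 regions$critical[regions$name == rn],
               P3 = as.integer(counts[["P3"]]), P2 = as.integer(counts[["P2"]]),
               B2 = as.integer(counts[["B2"]]), B3 = as.integer(counts[["B3"]]),
               total = total,
               pct_P3 = pct[1L], pct_P2 = pct[2L],
               pct_B2 = pct[3L], pct_B3 = pct[4L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample test of proportion
#'
#' Pooled two-sample z test without continuity correction:
#' \deqn{z = (p_1 - p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{\hat p} the pooled proportion; two-sided p-value from the
#' standard normal (so \eqn{z^2} equals the 2x2 chi-square statistic without
#' continuity correction). The confidence interval for \eqn{p_1 - p_2} uses
#' the unpooled standard error. When the pooled proportion is degenerate
#' (0 or 1) both sample proportions are equal; z is undefined (`NA`) and the
#' p-value is reported as 1.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return List of class `prop_test_result`: `p1`, `p2`, `z`, `p_value`,
#'   `ci` (length-2 vector for `p1 - p2`), `significant` (interval excludes
#'   0 at `conf_level`).
#' @export
two_proportion_test <- function(x1, n1, x2, n2, conf_level = 0.95) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    res <- list(p1 = p1, p2 = p2, z = NA_real_, p_value = 1,
                ci = c(0, 0), significant = FALSE)
    return(structure(res, class = "prop_test_result"))
  }
  z <- (p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  p_value <- 2 * stats::pnorm(-abs(z))
  se_unpooled <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  crit <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- (p1 - p2) + c(-1, 1) * crit * se_unpooled
  structure(list(p1 = p1, p2 = p2, z = z, p_value = p_value, ci = ci,
                 significant = p_value < (1 - conf_level)),
            class = "prop_test_result")
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf("p1 = %.4f, p2 = %.4f, z = %s, p = %.4g, 95%% CI [%.4f, %.4f]%s\n",
              x$p1, x$p2,
              if (is.na(x$z)) "undefined" else sprintf("%.3f", x$z),
              x$p_value, x$ci[1], x$ci[2],
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Critical vs non-critical pathogenic-call enrichment
#'
#' Pools the critical regions into one group and the non-critical regions
#' into the other, then tests (a) the pathogenic-tier proportion (P3+P2) and
#' (b) the benign-tier proportion (B3+B2) between the groups. The two tests
#' are complementary (proportions sum to 1, so the z statistics are equal in
#' magnitude with opposite sign); both are reported for transparency, along
#' with per-window tests of the pathogenic proportion.
#'
#' @param region_counts Output of [count_tiers_by_region()].
#' @param conf_level Confidence level (default 0.95).
#' @return List with `pathogenic` and `benign` (`prop_test_result` for the
#'   pooled comparison), `per_window` (data frame of per-non-critical-window
#'   pathogenic-proportion tests vs the pooled critical group), and the
#'   pooled counts.
#' @export
critical_vs_noncritical <- function(region_counts, conf_level = 0.95) {
  rc <- region_counts[region_counts$region != "other", , drop = FALSE]
  if (!any(rc$critical) || !any(!rc$critical)) {
    stop("need counts for both critical and non-critical regions")
  }
  crit <- rc[rc$critical, , drop = FALSE]
  ncrit <- rc[!rc$critical, , drop = FALSE]
  p_crit <- sum(crit$P3 + crit$P2); n_crit <- sum(crit$total)
  p_ncrit <- sum(ncrit$P3 + ncrit$P2); n_ncrit <- sum(ncrit$total)
  path_test <- two_proportion_test(p_crit, n_crit, p_ncrit, n_ncrit,
                                   conf_level)
  ben_test <- two_proportion_test(n_crit - p_crit, n_crit,
                                  n_ncrit - p_ncrit, n_ncrit, conf_level)
  per_window <- do.call(rbind, lapply(seq_len(nrow(ncrit)), function(i) {
    tw <- two_proportion_test(p_crit, n_crit,
                              ncrit$P3[i] + ncrit$P2[i], ncrit$total[i],
                              conf_level)
    data.frame(window = ncrit$region[i], z = tw$z, p_value = tw$p_value,
               significant = tw$significant)
  }))
  list(pathogenic = path_test, benign = ben_test, per_window = per_window,
       counts = data.frame(
         group = c("critical", "non-critical"),
         pathogenic_tiers = c(p_crit, p_ncrit),
         total = c(n_crit, n_ncrit)))
}
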