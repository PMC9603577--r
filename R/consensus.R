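# Multi-tool combination and P3/P2/B2/B3 consensus tiering.

#' Combine binary calls from several tools into one consensus call
#'
#' Combination rules for panels of 2-4 tools:
#' \itemize{
#'   \item 2 tools: benign only when unanimously benign; a single damaging
#'     output makes the consensus pathogenic.
#'   \item 3 tools: simple majority (>= 2 votes) wins.
#'   \item 4 tools: pathogenic when two or more outputs are damaging; benign
#'     when three or more are benign. A 2-2 tie therefore resolves to
#'     pathogenic.
#' }
#'
#' @param calls Character vector of 2-4 values in
#'   `c("pathogenic", "benign")`.
#' @return `"pathogenic"` or `"benign"`.
#' @export
combine_calls <- function(calls) {
  n <- length(calls)
  if (n < 2L || n > 4L) stop("combine_calls needs 2-4 calls, got ", n)
  bad <- setdiff(unique(calls), c("pathogenic", "benign"))
  if (length(bad) > 0L) stop("unknown call value(s): ",
                             paste(bad, collapse = ", "))
  n_path <- sum(calls == "pathogenic")
  need <- if (n == 2L) 1L else 2L
  if (n_path >= need) "pathogenic" else "benign"
}

#' Consensus tier from the designated three-tool panel
#'
#' Tiers count pathogenic votes among exactly three panel calls (by default
#' PolyPhen-2 HumDiv, PolyPhen-2 HumVar and PROVEAN): P3 = 3 pathogenic,
#' P2 = 2, B2 = 1 (i.e. 2 benign), B3 = 0 (3 benign). P tiers binarise to
#' pathogenic, B tiers to benign, so the tier is a refinement of
#' [combine_calls()] on the same three calls.
#'
#' @param calls Character vector of exactly 3 binary calls.
#' @return List with `pathogenic_votes`, `benign_votes`, `tier`.
#' @export
consensus_tier <- function(calls) {
  if (length(calls) != 3L) {
    stop("consensus tier needs exactly 3 panel calls, got ", length(calls))
  }
  bad <- setdiff(unique(calls), c("pathogenic", "benign"))
  if (length(bad) > 0L) stop("unknown call value(s): ",
                             paste(bad, collapse = ", "))
  votes <- sum(calls == "pathogenic")
  tier <- c("B3", "B2", "P2", "P3")[votes + 1L]
  list(pathogenic_votes = votes, benign_votes = 3L - votes, tier = tier)
}

TIER_LEVELS <- c("P3", "P2", "B2", "B3")

#' Tier every substitution of a saturation score table
#'
#' Classifies the panel tools' scores, checks the panel is complete for every
#' substitution, and assigns one P3/P2/B2/B3 tier per substitution.
#'
#' @param scores Canonical score table covering the panel tools.
#' @param panel Character vector of exactly 3 tool names; defaults to the
#'   best-performing panel `humdiv`, `humvar`, `provean`.
#' @param thresholds Threshold configuration.
#' @return Data frame with columns `position`, `wt`, `mut`,
#'   `pathogenic_votes`, `tier` (factor over P3, P2, B2, B3), ordered by
#'   position then mutant residue order.
#' @export
tier_table <- function(scores, panel = c("humdiv", "humvar", "provean"),
                       thresholds = default_thresholds()) {
  if (length(panel) != 3L) stop("panel must name exactly 3 tools")
  panel <- vapply(panel, match.arg, "", choices = TOOLS)
  classified <- classify_scores(scores[scores$tool %in% panel, , drop = FALSE],
                                thresholds)
  key <- paste0(classified$wt, classified$position, classified$mut)
  subs <- unique(data.frame(position = classified$position,
                            wt = classified$wt, mut = classified$mut,
                            key = key))
  # completeness: every substitution needs all three panel tools
  have <- tapply(classified$tool, key, function(x) length(unique(x)))
  gaps <- names(have)[have < 3L]
  if (length(gaps) > 0L) {
    stop("missing panel score(s) for: ",
         paste(utils::head(sort(gaps), 10L), collapse = ", "),
         if (length(gaps) > 10L) sprintf(" (and %d more)", length(gaps) - 10L))
  }
  votes <- tapply(classified$call == "pathogenic", key, sum)
  subs$pathogenic_votes <- as.integer(votes[subs$key])
  subs$tier <- factor(c("B3", "B2", "P2", "P3")[subs$pathogenic_votes + 1L],
                      levels = TIER_LEVELS)
  subs$key <- NULL
  mut_rank <- match(subs$mut, amino_acid_order())
  subs <- subs[order(subs$position, mut_rank), , drop = FALSE]
  rownames(subs) <- NULL
  subs
}

#' Summarise a tier table into class counts and percentages
#'
#' @param tiers Output of [tier_table()].
#' @return Data frame with one row per tier (P3, P2, B2, B3): `tier`, `n`,
#'   `pct` (one decimal, half-up). Counts partition the table; percentages
#'   sum to 100 up to rounding.
#' @export
tier_summary <- function(tiers) {
  counts <- table(factor(tiers$tier, levels = TIER_LEVELS))
  data.frame(tier = TIER_LEVELS, n = as.integer(counts),
             pct = round_half_up(100 * as.integer(counts) / nrow(tiers), 1))
}
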