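# Seeded generators: score tables with calibrated marginal call rates and
# reference sets realising exact per-tool confusion counts. These stand in
# for live prediction-server output so every pipeline stage runs headless.

#' Generate a random protein sequence
#'
#' Uniform over the 20 standard residues. Used to build synthetic catalytic
#' domains for simulation and tests; it does not model real residue
#' composition.
#'
#' @param length Sequence length (default 300, a kinase catalytic domain).
#' @param seed Optional RNG seed (caller's RNG state is restored).
#' @return Single residue string.
#' @export
random_protein <- function(length = 300L, seed = NULL) {
  with_seed(seed, paste(sample(AA_STANDARD, length, replace = TRUE),
                        collapse = ""))
}

#' Synthetic score-table configuration
#'
#' Bundles the study conditions for [simulate_scores()]:
#' \itemize{
#'   \item `p_pathogenic`: latent probability that a substitution is truly
#'     damaging. Default 0.9 — saturation of a conserved kinase domain is
#'     dominated by damaging substitutions.
#'   \item `target_rates`: per-tool marginal pathogenic-call rates the
#'     generator is calibrated to; defaults are the observed saturation
#'     call rates of the four tools on the CDKL5 catalytic domain
#'     (95.8 / 92.3 / 82.6 / 88.0%).
#'   \item `benign_call_rate`: probability that a latent-benign substitution
#'     is still called pathogenic by a tool (over-calling). Default 0.65 for
#'     every tool.
#'   \item `components`: per-tool two-component score families (Beta for
#'     the [0,1]-scaled tools, Normal for the unbounded PROVEAN delta), one
#'     component per side of the tool's decision threshold.
#' }
#' Calibration solves, per tool, the pathogenic-call probability for
#' latent-pathogenic substitutions `a` from
#' `target = p_pathogenic * a + (1 - p_pathogenic) * benign_call_rate`, so
#' the expected post-threshold call rate equals the target exactly; an
#' unachievable target (`a` outside \eqn{[0,1]}) is a calibration error.
#'
#' @param seed Integer RNG seed.
#' @param sequence Residue string; generated with [random_protein()] from
#'   `seed` when `NULL`.
#' @param sequence_length Length of the generated sequence when `sequence`
#'   is `NULL`.
#' @param p_pathogenic Latent pathogenic probability: a scalar, or a vector
#'   with one entry per residue position for region-dependent structure
#'   (e.g. higher damage probability inside critical sites). Marginal call
#'   rates depend only on its mean.
#' @param target_rates Named vector of per-tool target pathogenic-call
#'   rates (proportions in \eqn{[0,1]}).
#' @param benign_call_rate Named vector (or scalar) of per-tool
#'   pathogenic-call probabilities for latent-benign substitutions.
#' @param thresholds Threshold configuration the calibration is relative to.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             sequence = NULL,
                             sequence_length = 300L,
                             p_pathogenic = 0.9,
                             target_rates = c(humdiv = 0.958, humvar = 0.923,
                                              provean = 0.826, sift = 0.880),
                             benign_call_rate = 0.65,
                             thresholds = default_thresholds()) {
  stopifnot(all(p_pathogenic >= 0), all(p_pathogenic <= 1),
            all(target_rates >= 0), all(target_rates <= 1))
  if (length(p_pathogenic) > 1L && length(p_pathogenic) != sequence_length) {
    stop("per-position p_pathogenic must have one entry per residue")
  }
  tools <- names(target_rates)
  if (is.null(tools) || !all(tools %in% TOOLS)) {
    stop("target_rates must be named with known tools")
  }
  if (length(benign_call_rate) == 1L) {
    benign_call_rate <- stats::setNames(rep(benign_call_rate, length(tools)),
                                        tools)
  }
  # pathogenic-call probability for latent-pathogenic substitutions, per
  # tool; with a per-position latent profile the marginal rate depends only
  # on its mean, so calibration uses the mean latent rate
  w <- mean(p_pathogenic)
  if (w == 0) {
    # no latent-pathogenic mass: the benign-side rate must carry the target
    a <- stats::setNames(rep(0, length(tools)), tools)
    bad <- abs(target_rates - benign_call_rate[tools]) > 1e-12
  } else {
    a <- (target_rates - (1 - w) * benign_call_rate[tools]) / w
    bad <- a < 0 | a > 1
  }
  if (any(bad)) {
    stop("unachievable target rate(s) for: ",
         paste(tools[bad], collapse = ", "),
         " (solved call probability outside [0,1])")
  }
  structure(list(seed = as.integer(seed), sequence = sequence,
                 sequence_length = as.integer(sequence_length),
                 p_pathogenic = p_pathogenic,
                 target_rates = target_rates,
                 benign_call_rate = benign_call_rate[tools],
                 pathogenic_call_rate = a,
                 thresholds = thresholds,
                 components = default_score_components()),
            class = "synthetic_config")
}

# Two-component score families per tool: one component per side of the
# decision threshold. Beta on [0,1] scales, Normal for the PROVEAN delta.
default_score_components <- function() {
  list(
    humdiv = list(family = "beta",
                  pathogenic = c(8, 1), benign = c(1, 8)),
    humvar = list(family = "beta",
                  pathogenic = c(8, 1), benign = c(1, 8)),
    provean = list(family = "normal",
                   pathogenic = c(-6, 2.5), benign = c(0, 1.5)),
    sift = list(family = "beta",
                pathogenic = c(1, 20), benign = c(2, 2))
  )
}

# Inverse-CDF draws truncated to (lo, hi) on the component's support.
rbeta_trunc <- function(n, shape, lo, hi) {
  u <- stats::runif(n, stats::pbeta(lo, shape[1], shape[2]),
                    stats::pbeta(hi, shape[1], shape[2]))
  stats::qbeta(u, shape[1], shape[2])
}

rnorm_trunc <- function(n, par, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, par[1], par[2]),
                    stats::pnorm(hi, par[1], par[2]))
  stats::qnorm(u, par[1], par[2])
}

# The score interval on which a tool's binary call is pathogenic / benign.
call_interval <- function(tool, call, thresholds) {
  if (tool %in% c("humdiv", "humvar")) {
    thr <- thresholds[[tool]]$benign  # pathogenic call iff score >= thr
    if (call == "pathogenic") c(thr, 1) else c(0, thr)
  } else if (tool == "provean") {
    thr <- thresholds$provean$cutoff  # pathogenic iff score <= thr
    if (call == "pathogenic") c(-Inf, thr) else c(thr, Inf)
  } else {
    thr <- thresholds$sift$cutoff     # pathogenic iff score < thr
    if (call == "pathogenic") c(0, thr) else c(thr, 1)
  }
}

draw_scores <- function(tool, call, components, thresholds) {
  n <- length(call)
  comp <- components[[tool]]
  out <- numeric(n)
  for (cl in c("pathogenic", "benign")) {
    idx <- call == cl
    if (!any(idx)) next
    iv <- call_interval(tool, cl, thresholds)
    par <- comp[[cl]]
    out[idx] <- if (comp$family == "beta") {
      rbeta_trunc(sum(idx), par, iv[1], iv[2])
    } else {
      rnorm_trunc(sum(idx), par, iv[1], iv[2])
    }
  }
  out
}

#' Simulate a calibrated saturation score table
#'
#' For every substitution of the saturation set over the configured
#' sequence, draws one score per tool: a latent pathogenic/benign label per
#' substitution, a per-tool binary call with the calibrated conditional
#' probabilities, and a score from the tool's component distribution
#' truncated to the side of the threshold matching the call. The expected
#' per-tool pathogenic-call rate after thresholding therefore equals the
#' configured target exactly; the empirical rate fluctuates binomially.
#' Fully reproducible from `cfg$seed` (the caller's RNG state is restored).
#'
#' @param cfg A `synthetic_config`.
#' @return List: `sequence` (residue string), `substitutions` (saturation
#'   set with a `latent` label column), `scores` (canonical score table).
#' @export
simulate_scores <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    sequence <- cfg$sequence
    if (is.null(sequence)) {
      sequence <- paste(sample(AA_STANDARD, cfg$sequence_length,
                               replace = TRUE), collapse = "")
    }
    subs <- enumerate_saturation(sequence)
    n <- nrow(subs)
    p_lat <- if (length(cfg$p_pathogenic) == 1L) cfg$p_pathogenic else {
      if (length(cfg$p_pathogenic) != nchar(sequence)) {
        stop("per-position p_pathogenic must have one entry per residue")
      }
      cfg$p_pathogenic[subs$position]
    }
    subs$latent <- ifelse(stats::runif(n) < p_lat, "pathogenic", "benign")
    tools <- names(cfg$target_rates)
    scores <- do.call(rbind, lapply(tools, function(t) {
      p_call <- ifelse(subs$latent == "pathogenic",
                       cfg$pathogenic_call_rate[[t]],
                       cfg$benign_call_rate[[t]])
      call <- ifelse(stats::runif(n) < p_call, "pathogenic", "benign")
      data.frame(position = subs$position, wt = subs$wt, mut = subs$mut,
                 tool = t,
                 score = draw_scores(t, call, cfg$components, cfg$thresholds))
    }))
    rownames(scores) <- NULL
    list(sequence = sequence, substitutions = subs, scores = scores)
  })
}

#' Simulate a labelled reference set with exact per-tool confusion counts
#'
#' Builds a reference of `n_pathogenic` + `n_benign` distinct substitutions
#' drawn reproducibly from the saturation set of `sequence`, plus per-tool
#' binary calls constructed so that each tool's confusion counts against the
#' reference exactly equal
#' `derive_confusion(n_pathogenic, n_benign, sens, spec)` for its configured
#' (sensitivity, specificity) pair — exactly, not in expectation.
#'
#' Because the printed marginals of the tools do not determine their joint
#' error pattern, the overlap of errors across tools is configurable:
#' `"maximal"` (all tools err on the same variants — the regime in which the
#' consensus confusion equals the shared single-tool confusion),
#' `"disjoint"` (errors on distinct variants where capacity allows) or
#' `"random"` (seeded random error placement per tool).
#'
#' @param sequence Residue string to draw variants from.
#' @param n_pathogenic,n_benign Reference class sizes (defaults 33 and 3,
#'   the expert-reviewed ClinVar composition for the CDKL5 catalytic
#'   domain).
#' @param tool_performance Named list of `c(sensitivity, specificity)`
#'   percentage pairs per tool; defaults to the published single-tool
#'   marginals on that reference.
#' @param overlap `"maximal"`, `"disjoint"` or `"random"`.
#' @param seed Integer RNG seed.
#' @return List: `reference` (labelled variants), `calls` (long per-tool
#'   binary-call table).
#' @export
simulate_reference <- function(sequence,
                               n_pathogenic = 33L, n_benign = 3L,
                               tool_performance = list(
                                 humdiv = c(100, 33.3),
                                 humvar = c(97.0, 66.7),
                                 provean = c(97.0, 66.7),
                                 sift = c(97.0, 0.0)),
                               overlap = c("maximal", "disjoint", "random"),
                               seed = 1L) {
  overlap <- match.arg(overlap)
  subs <- enumerate_saturation(sequence)
  n <- n_pathogenic + n_benign
  if (n > nrow(subs)) stop("reference larger than the saturation set")
  with_seed(seed, {
    pick <- subs[sample.int(nrow(subs), n), , drop = FALSE]
    reference <- data.frame(position = pick$position, wt = pick$wt,
                            mut = pick$mut,
                            label = rep(c("pathogenic", "benign"),
                                        c(n_pathogenic, n_benign)))
    tools <- names(tool_performance)
    fn_offset <- 0L; fp_offset <- 0L
    calls <- do.call(rbind, lapply(tools, function(t) {
      perf <- tool_performance[[t]]
      cc <- derive_confusion(n_pathogenic, n_benign, perf[1], perf[2])
      place_errors <- function(n_err, group_size, offset) {
        if (n_err == 0L) return(integer())
        switch(overlap,
          maximal = seq_len(n_err),
          disjoint = {
            if (offset + n_err > group_size) {
              stop("disjoint overlap infeasible: error budget exceeds ",
                   "group size for tool ", t)
            }
            offset + seq_len(n_err)
          },
          random = sample.int(group_size, n_err))
      }
      fn_idx <- place_errors(cc$fn, n_pathogenic, fn_offset)
      fp_idx <- place_errors(cc$fp, n_benign, fp_offset)
      if (overlap == "disjoint") {
        fn_offset <<- fn_offset + cc$fn
        fp_offset <<- fp_offset + cc$fp
      }
      call <- rep("pathogenic", n)
      call[fn_idx] <- "benign"                      # missed pathogenic
      ben_rows <- n_pathogenic + seq_len(n_benign)
      call[ben_rows] <- "benign"
      call[ben_rows[fp_idx]] <- "pathogenic"        # over-called benign
      data.frame(position = reference$position, wt = reference$wt,
                 mut = reference$mut, tool = t, call = call)
    }))
    rownames(calls) <- NULL
    list(reference = reference, calls = calls)
  })
}
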