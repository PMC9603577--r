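---
title: "Methods: saturation pathogenicity analysis of a kinase catalytic domain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saturation pathogenicity analysis of a kinase catalytic domain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdkl5sat)
```

## Overview

`cdkl5sat` analyses the mutational landscape of the CDKL5 catalytic domain
(residues 1–300) by exhaustive single amino-acid substitution: every
position is replaced by each of the 19 alternative residues, giving
19 × 300 = 5700 variants. Four predictor tools/modes — PolyPhen-2 HumDiv,
PolyPhen-2 HumVar, PROVEAN and SIFT — score each variant; local threshold
rules convert scores to categorical calls; a designated three-tool panel
produces consensus tiers; and a labelled reference set grounds a benchmark
of all 15 tool combinations. The package treats the predictors as external
oracles: it writes their batch inputs and parses their reports, but their
scoring algorithms are out of scope, and a seeded synthetic generator
substitutes for live server output wherever the pipeline needs scores.

## Substitution model

A substitution is `(position, wt, mut)` in 1-based residue coordinates with
one-letter codes (`H145Y`). One-letter notation is assumed throughout,
including in the server batch-input writers; three-letter notation is not
produced. The initiator methionine is substitutable like any other position
— the 5700 count includes positions 1–9 even though conservation-based
tools typically judge N-terminal substitutions neutral. Self-substitutions
(`M1M`) are representable because heatmap columns mark the wild-type cell,
but enumeration never emits them.

Enumeration order is fixed: positions ascending, and within a position the
19 mutants follow `amino_acid_order()` — non-polar (G A V L I M P F W),
polar uncharged (S T C Y N Q), acidic (D E), basic (K R H). The grouping is
the conventional physicochemical one used in saturation heatmaps; the order
*within* each group is a package decision (no external convention pins it)
and matters only for row layout, never for any statistic.

## Threshold classification

All thresholds live in one configuration object (`default_thresholds()`)
and are overridable for sensitivity analysis. Defaults, all on the tools'
native score scales:

| tool | rule |
|---|---|
| HumDiv | > 0.957 probably damaging; < 0.450 benign; else possibly damaging |
| HumVar | > 0.909 probably damaging; < 0.447 benign; else possibly damaging |
| PROVEAN | ≤ −2.5 deleterious; else neutral |
| SIFT | ≥ 0.05 tolerated; else deleterious |

Two boundary conventions needed a decision. PolyPhen-2's named classes are
"above" the upper and "below" the lower boundary, so scores exactly at
either boundary fall in the closed middle interval (possibly damaging) —
the only exhaustive completion of the stated rule. PROVEAN's cutoff is
stated as "below −2.5", but the tool's own published labelling treats −2.5
itself as deleterious; the package follows the tool (≤). Both choices move
only measure-zero boundary inputs and are configurable.

Binarisation maps probably/possibly damaging and deleterious to
*pathogenic*; benign, neutral and tolerated to *benign*. Server-assigned
class labels present in native reports are discarded and recomputed
locally, so a threshold override propagates consistently through the whole
pipeline.

## Consensus combination and tiers

For a panel of *k* tools' binary calls, the consensus is pathogenic when at
least ⌈criterion⌉ votes are damaging: 1 of 2, 2 of 3, 2 of 4. The 4-tool
2–2 tie therefore resolves to pathogenic ("two or more damaging"), which is
the stated rule, not a package invention. Tiers refine the 3-tool case by
vote count: P3/P2/B2/B3 for 3/2/1/0 pathogenic votes; P-tiers binarise to
pathogenic, making the tier a strict refinement of the combination rule.
The tier panel defaults to HumDiv + HumVar + PROVEAN — the combination the
benchmark ranks best — but any 3-tool subset can be passed.

## Performance metrics

From confusion counts (TP = damaging variant called pathogenic, TN = benign
called benign, FP, FN):

$$\mathrm{acc} = 100\frac{TP+TN}{N},\quad
\mathrm{sens} = 100\frac{TP}{TP+FN},\quad
\mathrm{spec} = 100\frac{TN}{TN+FP},$$

$$\mathrm{MCC} = \frac{TP\cdot TN - FP\cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.$$

MCC is **undefined** when any marginal factor is zero. It is held as `NA`
and rendered `―`; coercing it to 0 would corrupt the "MCC > 0.5" count,
since an undefined value is not evidence of random performance. A balanced
confusion with 75% of each class correct gives MCC exactly 0.5, the
conventional bar for an acceptable classifier.

Internal values are unrounded; presentation rounds percentages to one
decimal and MCC to three, half away from zero (`round_half_up()`), matching
how such benchmark tables are printed (base R's half-to-even would differ
on exact halves).

`derive_confusion()` inverts printed sensitivity/specificity marginals back
to integer counts by nearest-integer reconstruction and validates the round
trip at one-decimal precision — e.g. sensitivity 97.0% of 33 pathogenic
variants gives TP = round(32.01) = 32, and specificity 0.0% of 3 benign
gives TN = 0. Inconsistent marginals (those that cannot round-trip) are an
error rather than a silent approximation.

The benchmark sweep emits one row per non-empty subset of the four tools,
15 rows, ordered singles → pairs → triples → quadruple. The published
benchmark table contains a row labelled as a pair of HumDiv with itself;
its metrics equal the HumDiv + HumVar pair (which the table otherwise
lacks), so `benchmark_marginals()` encodes it as that subset and each
distinct subset appears exactly once.

## Region statistics

Critical regions are the ATP-binding site (19–43), S/T kinase active site
(131–143) and TEY motif (169–171); the non-critical comparison windows are
144–168 and 257–297. Tier counts are taken per region (a complete
saturation gives 19 × length substitutions per region; substitutions
outside all regions are tallied under "other").

The critical-versus-non-critical comparison pools the three critical
regions against the two non-critical windows — matching the single pooled
significance statement the analysis design calls for — and applies a
two-sample test of proportion to the pathogenic-tier (P3+P2) share and,
complementarily, the benign-tier share. The test is stated precisely since
"test of proportion" alone underdetermines it: pooled-variance z statistic
without continuity correction (so z² equals the 2×2 chi-square statistic),
two-sided normal p-value, with the 95% CI for the difference using the
unpooled standard error. Per-window tests are also emitted for
transparency. Only two planned comparisons are made, so no multiplicity
correction is applied by default. When the pooled proportion is degenerate
(0 or 1) both sample proportions coincide; z is undefined and p is
reported as 1.

## Conservation

The conservation module consumes a pre-aligned multi-species FASTA
(alignment computation is a solved external step and deliberately out of
scope). Percent identity of a species to the reference over a region is
computed on reference (ungapped) coordinates: columns where the reference
is gapped are not positions, and gaps in the other species count as
mismatches. Region conservation is the arithmetic mean of pairwise
identities over non-reference species. Exact-identity was chosen over
similarity-matrix scoring because reported 100% values for close orthologs
are consistent with identity; published decimals for diverged species
depend on an unspecified alignment and statistic and are not reproduced.

## Synthetic generator

The generator exists so that every pipeline stage is testable without
prediction-server access. Its defaults are the study conditions:

- **Latent damage probability** 0.9 per substitution (optionally a
  per-position profile, e.g. elevated inside critical sites). The consensus
  landscape of this domain is ~94% pathogenic, so a high latent rate is the
  realistic regime.
- **Target marginal call rates** per tool: HumDiv 0.958, HumVar 0.923,
  PROVEAN 0.826, SIFT 0.880 — the observed saturation call rates.
- **Benign-side call-through** 0.65: the probability that a latent-benign
  substitution is still called pathogenic, reflecting these predictors'
  well-known tendency to over-call damage (SIFT's benchmark specificity is
  0%). It is also the regime in which all four targets are jointly
  achievable given the latent rate.

Calibration solves the latent-pathogenic call probability *a* per tool from
`target = w·a + (1−w)·b` (mean latent rate *w*, call-through *b*); an *a*
outside [0, 1] is a calibration error. Scores are then drawn from
two-component families truncated to the side of the tool's threshold that
matches the sampled call — Beta components for the [0,1]-scaled tools,
Normal for the unbounded PROVEAN delta, via inverse-CDF sampling — so the
*expected* post-threshold call rate equals the target exactly and the
empirical rate fluctuates binomially (tests check within 3 binomial
standard errors at n = 5700). Draws are reproducible from the seed, and the
caller's RNG state is restored.

`simulate_reference()` builds a reference set (default 33 pathogenic + 3
benign, the expert-reviewed ClinVar composition) whose per-tool confusion
counts *exactly* equal the requested sensitivity/specificity pairs via
`derive_confusion()`. Because marginals do not determine the joint error
pattern across tools, the overlap is configurable: `maximal` (all tools err
on the same variants — the consensus then inherits the shared confusion),
`disjoint`, or seeded `random`.

What the generator does **not** emulate: score autocorrelation along the
sequence, position-specific score profiles (e.g. uniformly neutral
N-terminal substitutions), correlation between tools' scores beyond the
shared latent label, and real residue composition. Consequently, passing
tests demonstrate the correctness of the classification, consensus,
benchmark and region machinery under controlled conditions — not that any
particular full-scale published count (per-tool frequencies such as
241/5459, the 94.0%/6.0% tier split, per-region tier percentages) is
recovered, since those require the live scores of all 5700 variants.

## Problem sizes and determinism

The test suite and acceptance script run at the native scale of the
analysis — 5700-substitution saturation sets, 36-variant references — which
completes in seconds; smaller sequences (20–200 residues) are used where
only structural properties are exercised. All stochastic steps take
explicit seeds, and regeneration under a fixed seed is byte-identical.

## Known limitations

- Only 3 benign reference variants: specificity and MCC are extremely
  sensitive to single benign misclassifications (one flip moves specificity
  by 33.3 points), which is intrinsic to the reference composition, not to
  the implementation.
- The native-report readers accept a documented superset of the servers'
  2021–2022 column layouts and tolerate extra columns; exotic or future
  layouts may need the canonical TSV route instead.
- Conservation percentages for diverged species depend on the upstream
  alignment; the module reports identity on whatever alignment it is given.
- Nucleotide-level representation (codon reachability, HGVS `c.` notation)
  is out of scope; the analysis is protein-level throughout.
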