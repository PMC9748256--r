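---
title: "Calibrating computational variant-effect evidence with local likelihood ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating computational variant-effect evidence with local likelihood ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localLR)
```

## The problem

Clinical variant classification under the ACMG/AMP framework admits
computational (in silico) predictions as evidence for pathogenicity (PP3) or
benignity (BP4).  Historically that evidence was capped at "supporting"
strength and gated on the agreement of multiple tools, with score thresholds
chosen by each tool's developers rather than by any calibration against
clinical truth.  `localLR` implements a quantitative alternative: it converts
the continuous score of *any* predictor into interval-valued evidence whose
strength (supporting, moderate, strong, very strong; in either direction) is
justified by a measured likelihood ratio.

## The evidence model

Evidence combination follows the Bayesian rendering of the ACMG/AMP rules.
Posterior odds of pathogenicity are prior odds times a positive likelihood
ratio (LR+), and the four strength tiers correspond to exponentially spaced
LR+ values: a single line of supporting, moderate, strong, or very strong
evidence carries LR+ of $c^{1/8}$, $c^{1/4}$, $c^{1/2}$, $c$.  With the
reference prior probability of pathogenicity 0.0441 (prior odds 0.0461) and
scaling constant $c = 1124$, the pathogenic cutoffs are 2.406, 5.790, 33.53
and 1124, and the benign cutoffs are their exact reciprocals
(`evidenceConfig()` / `strengthCutoffTable()`).  Benign posterior cutoffs
are reported as probability of benignity.  The mapping to the points-based
system is $\log_2$ of the exponent weights: supporting $\pm 1$, moderate
$\pm 2$, strong $\pm 4$, very strong $\pm 8$ (`pointsValue()`), with the
recommended cap of 4 points on the sum of computational and hotspot
evidence.

`c` is treated as a configuration constant.  `solveC()` ships a
reconstructed constraint set (the classical combining rules with posterior
floors 0.9 for likely pathogenic and 0.99 for pathogenic), but the solved
value depends strongly on which combinations are included — the
two-strong-lines rule alone would force $c \ge 2146$ at this prior — so
reproducing any particular published constant from the solver is not a
design goal and the cutoff table never depends on it.

## Local calibration

For a tool with score $s$ (oriented so higher means more pathogenic;
lower-is-pathogenic tools are negated, and thresholds are mapped back to the
native scale on output), the local positive likelihood ratio is the density
ratio of pathogenic to benign score distributions at $s$.  It is estimated
by an adaptive sliding window: at every unique score of the labeled
calibration set, the half-width $\epsilon$ is the smallest value such that
$[s - \epsilon, s + \epsilon]$ holds at least `minLabeled` (default 100)
labeled variants and at least `minUnlabeledFrac` (default 3%) of an
unlabeled population reference.  Benign counts are weighted by
$w = (n_P / n_B) / \text{prior odds}$ so that a window whose composition
matches the full labeled set returns exactly the configured prior; $w$ is
recomputed per tool because missing scores change the usable counts.  The
local posterior is $P / (P + wB)$, interchangeable with the local LR+ at
fixed prior.

Numerical choices worth knowing:

* **Candidate half-widths are observed distances.**  The "smallest
  $\epsilon$" is selected from $\{|x - s|\}$ over labeled and unlabeled
  scores.  Under proportional edge scaling the continuously shrinking
  requirement could be met strictly between two observed distances;
  snapping up to the next observed distance captures the identical window
  content and makes the estimator exactly reproducible by definition-level
  code (`windowHalfwidth()` is that reference implementation; the compiled
  path in `calibrateScores()` is tested to agree exactly).
* **Edge scaling.**  Near the ends of the observed score range both window
  requirements are multiplied by the fraction of the window lying inside
  the range, preserving smaller windows at the extremes.  The requirements
  are never scaled below what the largest observed window can satisfy; if
  even the full range fails them, calibration stops with an error naming
  the constraint.
* **Pure windows.**  A window with zero weighted benign count yields
  posterior 1 and a `+Inf` LR+ sentinel, never `NaN`.
* **Ties.**  The curve is indexed by unique scores; tied variants share one
  estimate.  Missing scores are excluded from estimation and counted as
  indeterminate downstream.

## Bootstrap bounds and threshold selection

Thresholds are selected from one-sided 95% confidence bounds, not point
estimates.  The bounds come from a stratified bootstrap (default 10,000
replicates; labeled variants resampled with replacement within class; the
unlabeled set and $w$ held fixed; window half-widths re-estimated in each
replicate).  Quantiles are taken on the posterior scale — monotonically
equivalent to the LR+ scale at fixed prior and numerically safer near 0 and
1 — and clamped to the conservative side of the point estimate.  Memory for
the bootstrap grows as replicates times unique scores (roughly 3 GB at
10,000 replicates on a 40,000-score curve; the analyses in this package use
1,000 replicates, which changes thresholds negligibly).

The pathogenic supporting threshold is the smallest observed score $\tau$
such that the *lower* bound meets the supporting cutoff at every observed
score at or above $\tau$; stronger tiers repeat the rule at their cutoffs,
and the benign side mirrors it with upper bounds and reciprocal cutoffs.
The suffix/prefix construction makes the threshold nesting invariant hold
automatically.  Between observed scores the bound is treated as undefined
rather than interpolated: the quantifier is evaluated on prediction data.

The resulting up-to-nine intervals are half-open — pathogenic intervals
closed on the left, benign on the right, the indeterminate region open on
both sides — so every score (and every missing score) maps to exactly one
strength label (`assignStrength()`).

### Conservatism of the strong thresholds

The bound-based rule is intentionally stringent, and users should expect
estimated thresholds to sit *above* the scores where the true local LR+
first crosses a cutoff.  On synthetic equal-variance Gaussian classes
(N(2,1) vs N(0,1), 20,000 per class, $w = 1$, unlabeled drawn from the
50/50 mixture matching the implied prior), the supporting threshold is
recovered within about +0.10 of the analytic value across seeds, while the
strong threshold runs +0.1 to +0.3 high.  Two mechanisms contribute roughly
equally: windows near the analytic strong threshold contain only a few
dozen benign variants, so the pointwise suffix-minimum dips upward-bias the
crossing; and the one-sided margin shifts it further.  This bias is the
price of the "for all scores above" quantifier and one-sided bounds; it
errs exclusively toward weaker claimed evidence.  A related small-count
caveat applies in the extreme tail: windows with near-zero benign counts
have unreliable bootstrap bounds, and with small labeled sets a spurious
very-strong interval can appear.  Larger benign samples (or inspection of
per-window benign counts, exposed on the curve object) guard against this.

## Validation of intervals

On an independent labeled set, each interval is checked with the
interval-based likelihood ratio — the unweighted ratio of the fraction of
pathogenic variants inside the interval to the fraction of benign variants
inside it.  Pathogenic intervals should meet or exceed their cutoff, benign
intervals stay at or below the reciprocal cutoff.  On the calibration data
itself this holds *exactly* for the weighted version by the mediant
inequality: every window in a selected interval has weighted posterior at
or above the cutoff, and a ratio of summed counts cannot fall below the
smallest of its constituents.  On fresh data it holds up to sampling noise.
A population score set is audited by the fraction of variants falling in
each interval (missing scores in indeterminate; fractions sum to one):
strong-or-stronger pathogenic fractions materially above the prior indicate
overprediction.

Fixed developer-recommended thresholds are assessed by reading the curve at
the nearest observed score, reporting the LR+ point estimate with a
two-sided 95% bootstrap interval, and grading strength on the point
estimate.  Multi-tool consensus is evaluated by the same window-count
posterior in the joint score space, with axis-aligned neighbourhoods grown
isotropically in per-tool rank space (ranks remove scale differences; the
construction is otherwise the univariate rule).

## Prior estimation

The prior probability of pathogenicity is estimated from a labeled-positive
sample and an unlabeled reference by a nearest-neighbour removal curve:
repeatedly sample a positive, remove its closest remaining unlabeled
neighbour, and record the distance.  Distances stay small while
positive-like unlabeled scores remain and rise sharply once they are
exhausted, so the knee of the curve (fraction removed vs distance)
estimates the positive fraction.  The detector smooths the averaged curve
(origin prepended) with a centred moving average 5% of the grid wide and
returns the fraction of steepest ascent.  A centred moving average turns a
step into a ramp centred on the step, so the steepest slope sits at the
step location itself; the discrete second difference — available as
`detector = "curvature"` — peaks at the ramp corner half a window early and
is also more easily distracted by end-of-curve depletion, which is why
slope is the default.  Flat curves return `NA` (not estimable).  The
estimator assumes the two mixture components are separated relative to the
sample size; heavily overlapping components bias any knee detector, and the
benchmark in the test-suite uses components eight standard deviations apart
for that reason.  Estimates are scale invariant.

## Filtering engine

`filterLabeledSet()` and `filterPopulationSet()` implement the
data-assembly rules for clinical-archive and population variant tables:
missense consequence, allele frequency below 0.01 (exomes first, genomes
fallback, absent-from-both treated as rare), genes with at least one
pathogenic variant, removal of VUS / zero-star / conflicting records,
`PASS` filter status, median genotype quality above 20, median depth at
least 30 when the allele count is below 3 and at least 10 otherwise,
exclusion regions supplied as 0-based half-open BED (any overlap with the
1-based closed variant span excludes), tool-training-set and
labeled-overlap removal, and exome/genome union deduplicated by variant
key.  Each run returns the per-step waterfall of surviving counts; filters
are idempotent, and a `trainingLast` switch reproduces the ordering used
for held-out validation snapshots.  Records missing a field a step needs
are dropped with a warning.

## The synthetic-data generator

`scoreModel()` describes two class-conditional score distributions (Beta by
default, mimicking bounded posterior-style tool outputs; Gaussian for
closed-form checks), labeled class sizes, an unlabeled mixture with
pathogenic weight `alpha`, and a missing-score rate.  The defaults emulate
the structure of a clinical-archive calibration set paired with a
population reference: 4,000 pathogenic and 7,834 benign labeled variants, a
40,000-score unlabeled set with `alpha = 0.0441` (the reference prior), and
5% missing scores.  In the threshold-recovery analyses the unlabeled
mixture is set to the prior implied by the weighting (50/50 when $w = 1$
with equal classes), mirroring the correspondence between the population
reference and the configured prior in real use.  The truth bundle carries
the analytic density-ratio function and `analyticThreshold()` inverts it
for any cutoff, giving ground truth for recovery tests.

What the generator does *not* emulate: discretized or heaped score
distributions (many real tools emit few unique values), covariation of
missingness with score, gene-level clustering of variants, and label noise
in the underlying archives.  Passing recovery tests on these smooth
synthetic families therefore demonstrates correctness of the estimator and
its conservatism properties, not performance guarantees on any real tool.

## Problem sizes used in the shipped analyses

The test-suite and the reproduction script run the Gaussian recovery
condition at 20,000 variants per class with 1,000 bootstrap replicates,
interval validation over 50 fresh draws of 3,000 per class, prior-estimator
benchmarks at 20,000 scores per set, and a 100-record filtering fixture —
sizes chosen so the full suite completes in a few minutes on one core while
keeping window counts in the regime the method is designed for.
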