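# localLR

Calibration of computational variant-effect predictors into ACMG/AMP
PP3/BP4 evidence strengths via local positive likelihood ratios.

## The problem

Clinical laboratories use in silico missense predictors (REVEL, CADD, SIFT,
PolyPhen-2, ...) as evidence for pathogenicity (PP3) or benignity (BP4)
when classifying sequence variants.  The score thresholds in common use
come from tool developers, not from calibration against clinical truth, and
the historical rules cap computational evidence at "supporting" strength.
`localLR` implements a quantitative framework that converts any continuous
prediction score into interval-valued evidence with a measured strength —
supporting, moderate, strong or very strong, in either direction — and
validates those intervals on independent data.

The core quantities: prior odds of pathogenicity are updated by a positive
likelihood ratio, `posterior odds = LR+ × prior odds`, and the four ACMG/AMP
strength tiers correspond to exponentially spaced LR+ cutoffs
`c^(1/8) < c^(1/4) < c^(1/2) < c` (2.406, 5.790, 33.53 and 1124 at the
reference prior 0.0441 with `c = 1124`; benign cutoffs are the exact
reciprocals).  For a continuous score `s`, the *local* positive likelihood
ratio `lr+(s) = p(s | pathogenic) / p(s | benign)` is estimated with an
adaptive sliding window over labeled variants (at least 100 labeled and 3%
of an unlabeled population reference per window, benign counts weighted to
match the prior), bounded below/above by one-sided 95% bootstrap confidence
limits, and thresholded: the supporting pathogenic threshold is the
smallest score above which the lower bound never falls under 2.406, and so
on for every tier and direction.  The package also ships interval
validation via interval-based likelihood ratios, a positive–unlabeled
estimator of the prior (nearest-neighbour removal distance curves), the
variant-filtering engine used to assemble calibration data sets, and a
synthetic score generator with analytic ground truth.

See the methods vignette
(`vignettes/calibrating-insilico-evidence.Rmd`) for the model, the
numerical choices and the estimator's conservatism properties.

## Worked example

Calibrate a synthetic bounded-score tool (Beta-distributed classes, an
archive-sized labeled set of 4,000 pathogenic / 7,834 benign variants, and
a 40,000-score population reference containing 4.41% pathogenic-like
variants):

```r
library(localLR)

cfg <- evidenceConfig(prior = 0.0441, c = 1124)
cfg
#> EvidenceConfig: prior = 0.0441 (odds 0.04613), c = 1124
#>  criterion    strength  direction lr_cutoff lr_reciprocal posterior_cutoff
#>        PP3  supporting pathogenic 2.406e+00     4.156e-01          0.09992
#>        PP3    moderate pathogenic 5.790e+00     1.727e-01          0.21080
#>        PP3      strong pathogenic 3.353e+01     2.983e-02          0.60730
#>        PP3 very_strong pathogenic 1.124e+03     8.897e-04          0.98110
#>        BP4  supporting     benign 4.156e-01     2.406e+00          0.98120
#>        BP4    moderate     benign 1.727e-01     5.790e+00          0.99210
#>        BP4      strong     benign 2.983e-02     3.353e+01          0.99860
#>        BP4 very_strong     benign 8.897e-04     1.124e+03          1.00000

sim <- simulateScores(scoreModel(), seed = 1)
curve <- calibrateScores(sim$labeled[, c("variant_key", "score")],
                         sim$labeled[, c("variant_key", "label")],
                         sim$unlabeled$score, config = cfg,
                         settings = calibrationSettings(nBootstrap = 1000),
                         seed = 1)
curve
#> CalibrationCurve 'tool': 11253 unique scores in [0.002219, 0.9982]
#>   prior 0.0441, benign weight 11.07, 1000 bootstrap replicates

ths <- buildThresholdSets(curve, cfg)
ths$pathogenic
#> ThresholdSet (pathogenic):
#>   supporting   lr+ 2.406    tau = 0.5649
#>   moderate     lr+ 5.79     tau = 0.6270
#>   strong       lr+ 33.53    tau = 0.7346
#>   very_strong  lr+ 1124     tau = -
```

Scores at or above 0.5649 earn supporting pathogenic evidence, at or above
0.6270 moderate, at or above 0.7346 strong; this tool never reaches very
strong ("-"), matching the behaviour of well-performing real predictors.
The benign side mirrors this with thresholds 0.4028 (supporting) down to
0.1784 (very strong), and scores between 0.4028 and 0.5649 are
indeterminate — they contribute no evidence.  Validating the intervals on
an independent labeled draw and auditing the population reference:

```r
intervals <- evidenceIntervals(ths, cfg)
test <- simulateScores(scoreModel(), seed = 2)
validateThresholds(intervals, test$labeled$score, test$labeled$label,
                   population = test$unlabeled$score, config = cfg)
#> ValidationReport: 4000 pathogenic, 7834 benign labeled variants, 40000 population variants
#>       strength  direction     lower     upper ... interval_lr pass population_fraction
#>    very_strong     benign      -Inf 0.1784449 ...   7.216e-04 TRUE             0.33000
#>         strong     benign 0.1784449 0.1833919 ...   0.000e+00 TRUE             0.01215
#>       moderate     benign 0.1833919 0.3493062 ...   2.313e-02 TRUE             0.34930
#>     supporting     benign 0.3493062 0.4027579 ...   1.453e-01 TRUE             0.07220
#>  indeterminate       none 0.4027579 0.5649155 ...   9.125e-01   NA             0.16970
#>     supporting pathogenic 0.5649155 0.6270426 ...   4.456e+00 TRUE             0.01850
#>       moderate pathogenic 0.6270426 0.7345836 ...   2.082e+01 TRUE             0.01943
#>         strong pathogenic 0.7345836       Inf ...   3.026e+02 TRUE             0.02875
```

Every interval's likelihood ratio on the held-out set meets its cutoff
(`pass`), and only 2.9% of the population lands in the strong pathogenic
interval — below the 4.41% prior, i.e. no overprediction at high strength.

A command-line front end over the same functions ships in
`inst/scripts/locallr.R` (subcommands `table1`, `calibrate`, `thresholds`,
`validate`, `prior`, `filter`, `simulate`).

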