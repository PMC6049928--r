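---
title: "Methods: bucket-based NMR biomarker screening in metabscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bucket-based NMR biomarker screening in metabscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabscreen)
```

# Overview

`metabscreen` screens bucketed 1D ¹H NMR spectra for metabolic biomarkers
that separate a control from a study population. The screen triangulates
three kinds of evidence per bucket — a Welch p-value, a PLS-DA VIP score
and a rank-based AUROC — and fuses significance and importance into a
single signed shading score for longitudinal heat maps across age, sex and
sample-matrix strata. Because real raw-spectrum cohorts of this kind are
rarely public, the package ships a synthetic cohort generator with known
ground truth, so that every stage can be tested for calibration (false
positive rates at their nominal levels) and power (planted effects
recovered) rather than merely for code coverage.

# The statistical model

## Univariate screen

Each bucket is tested with Welch's unequal-variance *t*:
$t = (\bar y - \bar x)/\sqrt{s_x^2/n_x + s_y^2/n_y}$, with
Welch–Satterthwaite degrees of freedom and a two-sided p-value. The
orientation is study minus control throughout. Multiplicity is handled by
Bonferroni division of the critical alpha by the number of buckets — and
only Bonferroni: resonances of one metabolite are strongly dependent, so
the correction is already conservative, and layering an FDR procedure on
top would suggest a precision the bucket-level dependence structure cannot
support.

Fold changes use the signed convention common in metabolic profiling: the
study/control ratio of means $r$ is reported as $r$ when $r \ge 1$ and as
$-1/r$ otherwise, so magnitude is always at least 1 and sign encodes
direction. The accompanying error is first-order (delta-method)
propagation of a ratio of means,
$|FC|\sqrt{(s_x/\bar x)^2/n_x + (s_y/\bar y)^2/n_y}$ — chosen because it is
reproducible, documented, and monotone in the group CVs. Buckets with zero
variance in both groups are degenerate rather than erroneous: equal
constants give $p = 1$, unequal constants $p = 0$, each with a warning.
The Welch formulas are written out explicitly (with `stats::pt`) so these
cases are handled deterministically; `stats::t.test` serves as the
independent oracle in the test suite.

Volcano classification follows the usual display thresholds: significant
buckets with more than a two-fold change (|log₂ FC| > 1) are "green",
significant sub-two-fold buckets "red", the rest "grey"; the significance
axis threshold is $-\log_{10}(0.05) = 1.3$.

## Multivariate models

PCA is a deterministic SVD after column scaling. The default scaling is
mean-centering only, because bucket areas share one physical unit
(intensity·ppm) and centring preserves the dominance of high-concentration
metabolites that practitioners expect in scores plots; unit-variance and
Pareto scaling are selectable. A fixed sign convention (the
largest-magnitude element of each loading column is positive) makes
repeated fits bit-identical.

PLS-DA regresses a centred 0/1 group indicator on the scaled buckets by
NIPALS with deflation of X. With a single response the NIPALS weight
vector is exactly $w = X^\top y / \lVert X^\top y\rVert$, so no iteration
or random initialisation is involved and the fit is deterministic. Three
latent variables are the default. Cumulative R²Y is $1 - RSS/TSS$ of the
indicator. VIP is the standard
$\mathrm{VIP}_j = \sqrt{k \sum_a SSY_a (w_{aj}/\lVert w_a \rVert)^2 / \sum_a SSY_a}$,
whose mean square is 1 by construction — the VIP > 1 rule therefore flags
buckets of above-average importance.

Q² uses stratified 7-fold cross-validation (the conventional default of
the commercial PLS software family), with the fold partition drawn from a
recorded seed. Held-out predictions come from the trained model's
regression coefficients $B = W(P^\top W)^{-1}q$;
$Q^2(A) = 1 - \mathrm{PRESS}_A/TSS$ cumulatively over components. If a
training split ever loses a class the partition is re-drawn (at most 100
attempts) before failing.

## The separation F-test

Group separation in a scores plot is tested with the two-sample Hotelling
T² on the first two score dimensions:
$D^2 = \Delta^\top S_{pooled}^{-1} \Delta$,
$T^2 = \frac{n_1 n_2}{n_1+n_2} D^2$, and
$F = \frac{n_1+n_2-p-1}{p(n_1+n_2-2)} T^2$ with $df = (p,\; n_1+n_2-p-1)$,
compared against the upper-α F quantile. This reconstruction reproduces
the (Mahalanobis distance, F, F-critical) triple format used in published
scores-plot analyses, including the F-critical ≈ 3.1–3.25 values typical
of 20–50 sample comparisons. Two score dimensions are the default because
separation is conventionally judged on the 2-D scores plot; the test
errors out with advice if the pooled covariance is singular.

A deliberate asymmetry, worth stating: on null data the test holds its
nominal level on **PCA** scores (the projection ignores the labels), but
**not** on PLS-DA scores, which are chosen to separate the classes —
supervised projections of pure noise still separate visibly. The test
suite asserts the former and the package reports both, mirroring how such
studies interpret a significant PLS-DA separation alongside an
unseparated PCA.

## Evidence fusion

Per bucket, the rank AUROC is the Mann–Whitney U (midrank ties) divided by
$n_1 n_2$. Published screens of this kind report all accuracies ≥ 0.5
regardless of effect direction, so the package reports
$\max(\mathrm{AUC}, 1-\mathrm{AUC})$ with an explicit direction flag tied
to the sign of the mean difference; the raw orientation is also returned.

The combined heat-map score is $-\log_{10}(p) + \mathrm{VIP}$ when the
fold change is positive (> +1) and $+\log_{10}(p) - \mathrm{VIP}$ when
negative, shaded when its magnitude reaches
$2.3 = -\log_{10}(0.05) + 1.0$ — the score at exactly the significance and
VIP thresholds. The boundary is inclusive (the threshold is the *minimum*
of the shading gradient), a fold of exactly +1 scores 0 and never shades,
and log base 10 is forced by the 1.3 significance axis. Heat-map rows are
metabolites that are significant by p or by VIP > 1 in at least one
stratum; when several buckets map to one metabolite, the bucket with the
largest score magnitude represents it (configurable), since the
alternative — averaging — would let weak buckets dilute a strong one.
Shade fractions are normalised to the map-wide maximum. Ranking of merged
records is by |score| descending, ties broken by AUC, then |log₂ FC|, then
bucket id, making the order total and deterministic.

# The synthetic cohort generator

## What it emulates

- **Template libraries** for urine, serum, fecal-extract and
  pancreatic-tissue matrices: each metabolite is a set of resonance
  positions (ppm) with a control-group concentration scale (mM) and a
  log-normal coefficient of variation derived from tabulated control
  mean/StDev pairs, capped at 1.5. Relative areas split equally across a
  metabolite's resonances, since per-peak intensity ratios are not
  tabulated; they are configurable per template. The serum library carries
  three unassigned resonances (1.173, 1.183, 3.205 ppm) as synthetic
  stand-ins at a nominal 1 mM scale so every matrix offers at least eight
  templates.
- **Biology:** concentrations are log-normal (positive support, and
  control StDevs comparable to their means make a normal model
  untenable), with the arithmetic mean anchored to the template scale.
  Study-group effects are planted multiplicatively using the signed fold
  convention: × fold when positive, ÷ |fold| when negative.
- **Acquisition:** 600 MHz, a 20.0 ppm spectral window ([−2, 18] ppm),
  65536 grid points matching the 65 K points of the emulated experiment,
  Lorentzian lines of 0.8 Hz FWHM (under the 0.9 Hz shimming
  acceptability bound), a TSP reference at 0.0 ppm rendered with nine
  proton equivalents at 1.0 mM (urine/fecal) or 0.58 mM (serum/tissue),
  per-resonance chemical-shift jitter of SD 0.002 ppm (small enough that
  peaks stay within their 0.01 ppm buckets, emulating per-sample manual
  bucket tracking), and additive Gaussian noise (default SD 5 intensity
  units, giving single-proton millimolar peaks an SNR in the tens).

Lineshapes are rendered **cell-averaged**: each grid point carries the
mean of the analytic Lorentzian over its grid cell, computed from the
arctan antiderivative. Point-sampling a line whose width is comparable to
the grid spacing makes trapezoidal bucket areas misestimate true line
areas by several percent; cell averaging makes integrated areas grid-exact
(the area-linearity test demands relative error < 10⁻⁶), at the cost of a
slight (~5%) apparent broadening of the rendered line — still comfortably
below the 0.9 Hz bound, as the acceptance suite measures.

## What it does not emulate

No J-coupling fine structure, water suppression artefacts, baseline roll,
phase errors, or relaxation editing; no peak-position drift larger than
the jitter SD, so no alignment/warping step is needed or provided. Passing
tests therefore demonstrate the statistical machinery under the generative
assumptions (log-normal biology, additive noise, known bucket positions) —
not robustness to the spectral pathologies of real data, which the
out-of-scope preprocessing (phasing, baseline correction) would handle
upstream.

A direct bucket-table route (`simulate_bucket_table()`) skips rendering
and produces areas as concentration × relative area with optional
multiplicative measurement noise. It shares the biological model with the
rendered route and is used for replicate-heavy calibration experiments;
the rendered route is exercised end to end in the round-trip and heat-map
tests.

## Bucketing conventions

Spectra are referenced by shifting the axis so the tallest peak in
[−0.3, 0.3] ppm sits at exactly 0.0 ppm (erroring if nothing rises above
the window's noise floor, estimated as median + 5 MAD). Buckets are
half-open windows integrated trapezoidally with linear interpolation at
the exact boundaries, so adjacent buckets tile the axis without double
counting. Auto-generated definitions place a ±0.005 ppm window around
each template resonance, shrunk at midpoints between close neighbours so
windows never overlap; bucket ids are the centre ppm printed to 3–4
decimals. No normalization is the default (peak areas exported as-is);
TSP-ratio and total-area (TSP-excluded) normalizations are selectable,
with TSP recommended for urine where dilution varies. Absolute
quantification follows the nine-proton TSP ratio rule:
(area/TSP area) × (9/n_protons) × TSP mM.

# Defaults and study conditions

| Parameter | Default | Why |
|---|---|---|
| group size | 24/group | cohort sizing of the emulated breeding design |
| alpha | 0.05 | conventional screen level (the 1.3 volcano axis) |
| fold threshold | 2 | volcano two-fold convention |
| PLS-DA components | 3 | standard for these cohort sizes; cross-validated |
| CV folds | 7 | convention of the PLS software family |
| scaling | center | buckets share units; UV/Pareto selectable |
| linewidth | 0.8 Hz | below the 0.9 Hz shimming acceptability bound |
| grid | 65536 pts / 20 ppm | the emulated 65 K acquisition |
| jitter SD | 0.002 ppm | keeps peaks inside manual buckets |
| NIPALS tolerance | — | closed-form weights; no iteration needed |

Calibration suites fix their own conditions once: null calibration uses
200 independent single-resonance features at 24 vs 24 (expected 10
uncorrected hits at α = 0.05) and 200 replicate cohorts of 50 features for
the PCA-scores rejection rate; recovery plants the persistently decreased
urinary metabolites (3-indoxylsulfate −1.80, benzoate −2.38, citrate
−1.98) at a log-scale SD of 0.4 with 24 per group across 100 replicates,
and renders three full 24 vs 24 cohorts (ages 5/11/15 months) for the
longitudinal heat map; AUC calibration compares against
$\Phi(\delta/(\sigma\sqrt2))$ at 100 per group. These sizes keep the whole
suite under a minute while leaving Monte-Carlo error well inside the
asserted tolerances.

# Numerical and degenerate-input decisions

- Ties in AUROC are midranked (½ per tied pair); two identical constant
  groups give exactly 0.5.
- `separation_test` requires at least 3 per group and an invertible pooled
  covariance; identical centroids give D = 0, F = 0.
- PLS-DA stops early (with the fitted components kept) if X is exhausted
  before the requested number of latent variables; a single-bucket model
  has VIP ≡ 1.
- Constant buckets are refused by name under unit-variance scaling, and
  handled via the degenerate Welch rules in the univariate screen.
- Ascending input axes are flipped to descending on load; non-numeric
  rows are rejected with their line number.
- All randomness flows through explicit seeds (cohort design, CV folds),
  and identical seeds reproduce outputs byte for byte.

# Known limitations

- The delta-method fold error is first-order and understates uncertainty
  for CVs near or above 1 (common in urine); it is a display quantity,
  not an inferential one.
- The Bonferroni divisor counts all buckets although same-metabolite
  buckets are dependent; corrected significance is therefore conservative
  by design.
- Q² conventions differ between implementations (per-component versus
  cumulative PRESS ratios); this package reports the cumulative form and
  records the fold seed, so numbers are comparable only within this
  convention.
- Heat-map collapsing by best bucket slightly favours metabolites with
  many resonances under multiplicity; the `collapse = "none"` option
  keeps buckets as rows when that matters.
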