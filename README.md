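# metabscreen

Case-control biomarker screening for bucketed 1D ¹H NMR metabolomics, with a
ground-truth-known synthetic cohort generator so that every stage of the
screen can be validated end to end without access to raw spectrometer data.

## The problem

NMR metabolic profiling compares biofluid or tissue-extract spectra between a
control and a study population (for example healthy mice versus mice
developing precancerous pancreatic lesions). Each "bucket" — a small ppm
window around one resonance — is integrated to a peak area, and the
samples × buckets area matrix is screened for metabolites whose levels
separate the groups. A candidate biomarker is credible when several
independent lines of evidence agree: a small Welch p-value, a high
PLS-DA importance score, and good single-feature classification accuracy.

`metabscreen` implements that triangulation screen:

- **Univariate:** Welch's *t* per bucket,
  *t* = (ȳ − x̄)/√(s²ₓ/nₓ + s²ᵧ/nᵧ), with Bonferroni-corrected
  significance (α/n_buckets) and signed fold changes (study/control ratio
  reported as −1/r when r < 1) with first-order error propagation.
- **Multivariate:** centered PCA, and PLS-DA fit by deterministic NIPALS
  against the 0/1 group indicator, with per-bucket VIP scores
  (VIP²_j averages to 1), cumulative R²Y, and stratified k-fold
  cross-validated Q².
- **Scores-plot separation:** two-sample Hotelling T² on the first two score
  dimensions, reported as the familiar (Mahalanobis D, F, F-critical)
  triple: T² = (n₁n₂/(n₁+n₂))·D², F = ((n₁+n₂−p−1)/(p(n₁+n₂−2)))·T².
- **Classification accuracy:** tie-corrected rank AUROC per bucket
  (Mann-Whitney U/(n₁n₂), oriented ≥ 0.5 with a direction flag).
- **Combined evidence:** the heat-map shading score, −log₁₀(p) + VIP for
  positive fold changes and +log₁₀(p) − VIP for negative ones, shaded when
  its magnitude reaches 2.3 (= −log₁₀(0.05) + 1.0, i.e. both thresholds met),
  plus volcano classification (|log₂ FC| > 1, −log₁₀ p > 1.3).
- **Simulator:** metabolite multiplet templates for urine, serum, fecal and
  tissue matrices (tabulated resonance positions and control concentration
  scales), log-normal inter-individual variation, planted study/control
  folds, cell-averaged Lorentzian lineshapes (0.8 Hz FWHM at 600 MHz over a
  20 ppm window), a TSP reference line at 0.0 ppm, chemical-shift jitter and
  additive noise — or a direct bucket-table route for cheap replicate
  studies.

## Worked example

Simulate a 24 vs 24 urine cohort with 3-indoxylsulfate planted at a −1.80
study/control fold (moderate biological spread, cv 0.42), then run the full
per-stratum battery:

```r
library(metabscreen)

lib <- template_library("urine")
lib <- lapply(lib, function(tm) { tm$cv <- 0.42; tm })
names(lib) <- vapply(lib, `[[`, "", "name")

tb  <- simulate_bucket_table(lib, n_per_group = 24,
                             planted_effects = c(`3-indoxylsulfate` = -1.80),
                             measurement_cv = 0.15, seed = 42)
res <- analyze_stratum(tb, metabolite = attr(tb, "bucket_metabolite"))
head(rank_biomarkers(res$records), 5)
```

```
  rank bucket_id       metabolite  p_value   vip fold_change   auc heatmap_score
1    1     7.197 3-indoxylsulfate 1.00e-05 0.609       -2.05 0.868         -5.61
2    2     7.207 3-indoxylsulfate 1.30e-05 0.559       -2.07 0.882         -5.44
3    3     7.282 3-indoxylsulfate 1.57e-05 0.605       -2.16 0.875         -5.41
4    4     7.271 3-indoxylsulfate 3.20e-05 0.600       -2.11 0.854         -5.10
5    5     7.699 3-indoxylsulfate 3.21e-05 0.572       -2.09 0.863         -5.07
```

All six resonances of the planted metabolite rank at the top: p-values
around 10⁻⁵, fold changes ≈ −2 (study lower), AUROC ≈ 0.87, and strongly
negative combined scores (|score| ≥ 2.3 would shade these cells blue in a
heat map). The separation test shows the characteristic pattern of
supervised versus unsupervised projections on subtle effects:

```r
res$plsda_separation
#> <separation_test> Mahalanobis distance = 0.775, F-statistic = 3.52,
#>   F-critical = 3.2 (df 2, 45): significant
res$pca_separation
#> F-statistic = 1.18, F-critical = 3.2: not significant
```

The same screen runs from rendered spectra on disk (`generate_cohort()`
writes ppm/intensity files plus a manifest and ground-truth table;
`reference_to_tsp()` and `build_bucket_table()` take it from there), and
`run_pipeline()` orchestrates multi-age designs into a longitudinal heat map
— see the vignette in `vignettes/` for the full tour and the reasoning
behind each default.

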