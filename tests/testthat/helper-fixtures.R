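# shared fixture builders for the test suite

# cv that yields a given log-scale standard deviation for the log-normal
# concentration model
cv_for_sdlog <- function(sdlog) sqrt(exp(sdlog^2) - 1)

# a template library with every cv replaced
with_uniform_cv <- function(library, cv) {
  out <- lapply(library, function(tm) { tm$cv <- cv; tm })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

# tiny deterministic bucket table: rows samples, cols buckets
toy_bucket_table <- function(areas, groups) {
  n <- nrow(areas)
  if (is.null(colnames(areas)))
    colnames(areas) <- sprintf("b%02d", seq_len(ncol(areas)))
  ids <- sprintf("S%03d", seq_len(n))
  rownames(areas) <- ids
  structure(list(
    areas = areas,
    samples = data.frame(sample_id = ids, group = groups,
                         stringsAsFactors = FALSE),
    buckets = data.frame(bucket_id = colnames(areas),
                         ppm_low = seq_len(ncol(areas)),
                         ppm_high = seq_len(ncol(areas)) + 0.01),
    normalization = "none"), class = "bucket_table")
}

# analytic fraction of a unit-area Lorentzian inside [lo, hi]
lorentz_fraction <- function(lo, hi, center, fwhm) {
  g <- fwhm / 2
  (atan((hi - center) / g) - atan((lo - center) / g)) / pi
}

# small noiseless acquisition for fast rendering tests
quiet_acq <- function(points = 16384L, ...) {
  acquisition_model(points = points, noise_sd = 0, shift_jitter_sd = 0, ...)
}
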