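# Synthetic NMR cohort generation: study designs, acquisition parameters,
# per-sample concentration draws, Lorentzian spectrum rendering and
# on-disk cohort materialisation with a ground-truth table.

#' Describe a case-control cohort design
#'
#' @param n_per_group Mice per group within each stratum (>= 3).
#' @param strata Data frame with columns `matrix`, `age_months`, `sex`.
#'   `age_months` is one of `"5"`, `"11"`, `"15"`, `"tumor"`; tumor strata
#'   pool both sexes against gender-matched controls and may use
#'   `sex = "MF"`.
#' @param planted_effects Named numeric vector mapping metabolite names to
#'   signed study/control fold changes (the ratio when >= 1, minus the
#'   reciprocal when the metabolite goes down).
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 24,
                          strata = data.frame(matrix = "urine",
                                              age_months = "15",
                                              sex = "M"),
                          planted_effects = numeric(),
                          seed = 1L) {
  stopifnot(is.numeric(n_per_group), n_per_group >= 3)
  strata <- as.data.frame(strata, stringsAsFactors = FALSE)
  if (!all(c("matrix", "age_months", "sex") %in% names(strata)))
    stop("strata must have columns matrix, age_months, sex")
  strata$matrix <- as.character(strata$matrix)
  strata$age_months <- as.character(strata$age_months)
  strata$sex <- as.character(strata$sex)
  bad <- setdiff(strata$matrix, c("urine", "serum", "fecal", "tissue"))
  if (length(bad)) stop("unknown sample matrix in strata: ", bad[1])
  if (length(planted_effects)) {
    if (is.null(names(planted_effects)) || any(!nzchar(names(planted_effects))))
      stop("planted_effects must be a named vector")
    if (any(abs(planted_effects) < 1))
      stop("planted fold changes use the signed convention; |fold| must be >= 1")
  }
  structure(list(n_per_group = as.integer(n_per_group), strata = strata,
                 planted_effects = planted_effects, seed = as.integer(seed)),
            class = "cohort_design")
}

#' Describe the simulated NMR acquisition
#'
#' Defaults emulate a 600 MHz acquisition over a 20.0 ppm spectral width
#' with a TSP chemical-shift reference at 0.0 ppm and line widths kept
#' under the 0.9 Hz shimming acceptability bound.
#'
#' @param spectrometer_frequency Proton frequency in MHz.
#' @param spectral_window ppm interval covered by the spectrum.
#' @param points Number of grid points (>= 4096); the default matches the
#'   65 K points of the emulated acquisition so that sub-Hz line widths
#'   are well sampled.
#' @param linewidth_fwhm Lorentzian full width at half maximum, in Hz.
#' @param shift_jitter_sd Per-resonance chemical-shift jitter SD (ppm).
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param tsp_concentration TSP concentration in mM (1.0 for urine/fecal
#'   preparations, 0.58 for serum/tissue).
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(spectrometer_frequency = 600,
                              spectral_window = c(-2, 18),
                              points = 65536L,
                              linewidth_fwhm = 0.8,
                              shift_jitter_sd = 0.002,
                              noise_sd = 5,
                              tsp_concentration = 1.0) {
  stopifnot(linewidth_fwhm > 0, points >= 4096, noise_sd >= 0,
            shift_jitter_sd >= 0, tsp_concentration >= 0,
            length(spectral_window) == 2)
  spectral_window <- sort(as.numeric(spectral_window))
  structure(list(spectrometer_frequency = spectrometer_frequency,
                 spectral_window = spectral_window,
                 points = as.integer(points),
                 linewidth_fwhm = linewidth_fwhm,
                 shift_jitter_sd = shift_jitter_sd,
                 noise_sd = noise_sd,
                 tsp_concentration = tsp_concentration),
            class = "acquisition_model")
}

# TSP concentration convention per sample matrix
.tsp_for_matrix <- function(matrix) {
  if (matrix %in% c("serum", "tissue")) 0.58 else 1.0
}

#' Draw per-sample metabolite concentrations
#'
#' Concentrations are log-normal with arithmetic mean equal to each
#' template's `base_concentration` and coefficient of variation `cv`
#' (`cv = 0` returns the base concentration exactly).  For the study
#' group, metabolites named in `planted_effects` are multiplied by the
#' fold when it is positive and divided by its magnitude when negative.
#'
#' @param library A list of [metabolite_template] objects.
#' @param n Number of samples to draw.
#' @param group `"control"` or `"study"`.
#' @param planted_effects Named signed fold-change vector (study group only).
#' @return Matrix `n` x `length(library)` of concentrations (mM).
#' @export
sample_concentrations <- function(library, n, group = c("control", "study"),
                                  planted_effects = numeric()) {
  group <- match.arg(group)
  if (length(planted_effects)) {
    missing <- setdiff(names(planted_effects), names(library))
    if (length(missing))
      stop("planted metabolite not in template library: ",
           paste(missing, collapse = ", "))
  }
  conc <- vapply(library, function(tm) {
    if (tm$cv == 0) {
      rep(tm$base_concentration, n)
    } else {
      sdlog <- sqrt(log(1 + tm$cv^2))
      meanlog <- log(tm$base_concentration) - sdlog^2 / 2
      stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
    }
  }, numeric(n))
  conc <- matrix(conc, nrow = n,
                 dimnames = list(NULL, vapply(library, `[[`, "", "name")))
  if (group == "study" && length(planted_effects)) {
    for (nm in names(planted_effects)) {
      f <- planted_effects[[nm]]
      conc[, nm] <- if (f > 0) conc[, nm] * f else conc[, nm] / abs(f)
    }
  }
  conc
}

# unit-area Lorentzian, cell-averaged over the grid spacing `h`: each grid
# point carries the mean of the analytic line over its cell (arctan
# antiderivative), so trapezoidal bucket integrals recover line areas
# essentially exactly even when the linewidth approaches the grid spacing
.lorentzian <- function(ppm, center, fwhm_ppm, h) {
  gamma <- fwhm_ppm / 2
  (atan((ppm + h / 2 - center) / gamma) -
   atan((ppm - h / 2 - center) / gamma)) / (pi * h)
}

#' Render a 1D NMR spectrum from a concentration map
#'
#' Each resonance contributes a unit-area Lorentzian scaled by
#' `concentration x relative_area`, so the integral of an isolated line is
#' proportional to the metabolite concentration.  A TSP reference line
#' (nine equivalent protons, area `9 x tsp_concentration`) is added at
#' 0.0 ppm, chemical-shift jitter is applied per resonance, and Gaussian
#' noise is superimposed.  The ppm axis is strictly descending.
#'
#' @param concentrations Named numeric vector of metabolite concentrations
#'   (mM); names must match templates in `library`.
#' @param library List of [metabolite_template] objects.
#' @param acq An [acquisition_model].
#' @return An object of class `nmr_spectrum` with fields `ppm`,
#'   `intensity` and `meta`.
#' @export
render_spectrum <- function(concentrations, library, acq = acquisition_model()) {
  stopifnot(inherits(acq, "acquisition_model"))
  win <- acq$spectral_window
  ppm <- seq(win[2], win[1], length.out = acq$points)  # descending
  h <- (win[2] - win[1]) / (acq$points - 1)
  fwhm_ppm <- acq$linewidth_fwhm / acq$spectrometer_frequency
  intensity <- numeric(acq$points)
  for (nm in names(concentrations)) {
    tm <- library[[nm]]
    if (is.null(tm)) stop("no template for metabolite '", nm, "'")
    for (k in seq_len(nrow(tm$peaks))) {
      centre <- tm$peaks$ppm_center[k]
      if (acq$shift_jitter_sd > 0)
        centre <- centre + stats::rnorm(1, sd = acq$shift_jitter_sd)
      if (centre < win[1] || centre > win[2]) {
        warning("resonance of '", nm, "' at ", format(centre),
                " ppm falls outside the spectral window; skipped")
        next
      }
      intensity <- intensity + concentrations[[nm]] * tm$peaks$relative_area[k] *
        .lorentzian(ppm, centre, fwhm_ppm, h)
    }
  }
  if (acq$tsp_concentration > 0) {
    tsp_centre <- 0
    if (acq$shift_jitter_sd > 0)
      tsp_centre <- stats::rnorm(1, sd = acq$shift_jitter_sd)
    intensity <- intensity + 9 * acq$tsp_concentration *
      .lorentzian(ppm, tsp_centre, fwhm_ppm, h)
  }
  if (acq$noise_sd > 0)
    intensity <- intensity + stats::rnorm(acq$points, sd = acq$noise_sd)
  new_spectrum(ppm, intensity)
}

#' Generate a synthetic cohort on disk
#'
#' Writes one two-column (`ppm`, `intensity`) tab-separated spectrum file
#' per sample, a comma-separated manifest (`sample_id`, `matrix`, `group`,
#' `age_months`, `sex`, `file`) and a ground-truth table listing every
#' planted (metabolite, resonance, fold) triple.  Re-running with the same
#' design seed reproduces the files byte for byte.
#'
#' @param design A [cohort_design].
#' @param acq An [acquisition_model]; its `tsp_concentration` is overridden
#'   per stratum by the matrix convention (1.0 mM urine/fecal, 0.58 mM
#'   serum/tissue).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest`, `ground_truth` and the paths
#'   written.
#' @export
generate_cohort <- function(design, acq = acquisition_model(),
                            out_dir = tempfile("cohort")) {
  stopifnot(inherits(design, "cohort_design"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  set.seed(design$seed)
  manifest <- list(); gt <- list(); idx <- 0L
  for (s in seq_len(nrow(design$strata))) {
    st <- design$strata[s, ]
    lib <- template_library(st$matrix)
    acq_s <- acq
    acq_s$tsp_concentration <- .tsp_for_matrix(st$matrix)
    for (group in c("control", "study")) {
      eff <- if (group == "study") design$planted_effects else numeric()
      conc <- sample_concentrations(lib, design$n_per_group, group, eff)
      for (i in seq_len(design$n_per_group)) {
        idx <- idx + 1L
        sid <- sprintf("S%04d", idx)
        sp <- render_spectrum(conc[i, ], lib, acq_s)
        file <- file.path(out_dir, paste0(sid, ".tsv"))
        write_spectrum(sp, file)
        manifest[[idx]] <- data.frame(
          sample_id = sid, matrix = st$matrix, group = group,
          age_months = st$age_months, sex = st$sex,
          file = basename(file), stringsAsFactors = FALSE)
      }
    }
    if (length(design$planted_effects)) {
      planted <- intersect(names(design$planted_effects), names(lib))
      for (nm in planted) {
        gt[[length(gt) + 1L]] <- data.frame(
          metabolite = nm, ppm = lib[[nm]]$peaks$ppm_center,
          planted_fold = design$planted_effects[[nm]],
          matrix = st$matrix, age_months = st$age_months,
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  ground_truth <- if (length(gt)) unique(do.call(rbind, gt)) else
    data.frame(metabolite = character(), ppm = numeric(),
               planted_fold = numeric(), matrix = character(),
               age_months = character())
  mpath <- file.path(out_dir, "manifest.csv")
  gpath <- file.path(out_dir, "ground_truth.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  utils::write.csv(ground_truth, gpath, row.names = FALSE, quote = FALSE)
  invisible(list(manifest = manifest, ground_truth = ground_truth,
                 dir = out_dir, manifest_file = mpath,
                 ground_truth_file = gpath))
}

#' Simulate a bucket table directly (no spectrum rendering)
#'
#' Skips the spectral forward model: each template resonance becomes one
#' bucket whose area equals `concentration x relative_area`, optionally
#' perturbed by multiplicative log-normal measurement noise.  Useful for
#' calibration experiments that need many replicate cohorts cheaply; the
#' statistical structure (log-normal biology, planted folds) is identical
#' to the rendered route.
#'
#' @param library List of [metabolite_template] objects.
#' @param n_per_group Samples per group.
#' @param planted_effects Named signed fold-change vector for the study group.
#' @param measurement_cv Multiplicative log-normal noise CV per bucket
#'   (0 disables).
#' @param seed Optional integer seed.
#' @return A `bucket_table` (see [build_bucket_table]) whose metadata
#'   carries `group`, plus attribute `bucket_metabolite` mapping bucket ids
#'   to metabolite names.
#' @export
simulate_bucket_table <- function(library, n_per_group = 24,
                                  planted_effects = numeric(),
                                  measurement_cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conc_c <- sample_concentrations(library, n_per_group, "control")
  conc_s <- sample_concentrations(library, n_per_group, "study", planted_effects)
  conc <- rbind(conc_c, conc_s)
  peaks <- do.call(rbind, lapply(library, function(tm)
    data.frame(metabolite = tm$name, ppm = tm$peaks$ppm_center,
               rel = tm$peaks$relative_area, stringsAsFactors = FALSE)))
  areas <- conc[, peaks$metabolite, drop = FALSE] *
    matrix(peaks$rel, nrow(conc), nrow(peaks), byrow = TRUE)
  if (measurement_cv > 0) {
    sdlog <- sqrt(log(1 + measurement_cv^2))
    areas <- areas * matrix(
      stats::rlnorm(length(areas), -sdlog^2 / 2, sdlog),
      nrow(areas), ncol(areas))
  }
  bucket_id <- format_bucket_id(peaks$ppm)
  # disambiguate coincident centres across metabolites, if any
  bucket_id <- make.unique(bucket_id, sep = "_")
  colnames(areas) <- bucket_id
  n <- n_per_group
  meta <- data.frame(
    sample_id = sprintf("S%04d", seq_len(2 * n)),
    group = rep(c("control", "study"), each = n),
    stringsAsFactors = FALSE)
  rownames(areas) <- meta$sample_id
  defs <- data.frame(bucket_id = bucket_id,
                     ppm_low = peaks$ppm - 0.005,
                     ppm_high = peaks$ppm + 0.005,
                     stringsAsFactors = FALSE)
  tb <- structure(list(areas = areas, samples = meta, buckets = defs,
                       normalization = "none"),
                  class = "bucket_table")
  attr(tb, "bucket_metabolite") <- stats::setNames(peaks$metabolite, bucket_id)
  tb
}
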