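# Metabolite multiplet templates for the four sample matrices.
#
# Peak positions (ppm) and control-group concentration means / standard
# deviations follow published 600 MHz reference profiles of mouse urine,
# serum, fecal extract and pancreatic tissue extract.  Relative areas
# default to an equal split across a metabolite's listed resonances; no
# per-peak intensity ratios are modelled.

#' Construct a metabolite multiplet template
#'
#' A template describes one metabolite as a set of resonance positions with
#' relative areas, a typical (control-group) concentration and a log-normal
#' coefficient of variation for inter-individual biological spread.
#'
#' @param name Metabolite name.
#' @param ppm Numeric vector of resonance centres (ppm).
#' @param base_concentration Mean control-group concentration in mM (> 0).
#' @param cv Coefficient of variation of the log-normal concentration
#'   distribution (>= 0).
#' @param relative_area Relative area of each resonance; must sum to 1.
#'   Defaults to an equal split across `ppm`.
#' @param spectral_window Allowed ppm interval for resonance centres.
#' @return An object of class `metabolite_template`.
#' @export
metabolite_template <- function(name, ppm, base_concentration, cv,
                                relative_area = NULL,
                                spectral_window = c(-2, 18)) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ppm <- as.numeric(ppm)
  if (length(ppm) == 0L || anyNA(ppm))
    stop("template '", name, "': ppm centres must be non-empty and finite")
  if (any(ppm < min(spectral_window)) || any(ppm > max(spectral_window)))
    stop("template '", name, "': resonance outside the spectral window")
  if (is.null(relative_area))
    relative_area <- rep(1 / length(ppm), length(ppm))
  relative_area <- as.numeric(relative_area)
  if (length(relative_area) != length(ppm))
    stop("template '", name, "': relative_area length mismatch")
  if (abs(sum(relative_area) - 1) > 1e-9)
    stop("template '", name, "': relative areas must sum to 1")
  if (!is.numeric(base_concentration) || base_concentration <= 0)
    stop("template '", name, "': base_concentration must be > 0")
  if (!is.numeric(cv) || cv < 0)
    stop("template '", name, "': cv must be >= 0")
  structure(
    list(name = name,
         peaks = data.frame(ppm_center = ppm, relative_area = relative_area),
         base_concentration = as.numeric(base_concentration),
         cv = as.numeric(cv)),
    class = "metabolite_template")
}

#' @export
print.metabolite_template <- function(x, ...) {
  cat(sprintf("<metabolite_template> %s: %d peak(s), %.3g mM (cv %.2f)\n",
              x$name, nrow(x$peaks), x$base_concentration, x$cv))
  invisible(x)
}

# concentration mean/sd pairs -> capped coefficient of variation
.cv_from_moments <- function(mean, sd, cap = 1.5) {
  min(sd / mean, cap)
}

.template_tables <- function() {
  # name = list(ppm..., mean, sd) per matrix
  list(
    urine = list(
      `3-indoxylsulfate` = list(ppm = c(7.699, 7.282, 7.271, 7.207, 7.197, 7.352),
                                mean = 4.65, sd = 3.69),
      creatine          = list(ppm = 3.023, mean = 9.42, sd = 7.25),
      benzoate          = list(ppm = c(7.464, 7.477), mean = 3.02, sd = 4.20),
      trigonelline      = list(ppm = 8.831, mean = 0.96, sd = 0.76),
      `2-oxoglutarate`  = list(ppm = c(2.446, 2.435, 2.426, 2.982, 2.420),
                               mean = 19.69, sd = 24.74),
      fructose          = list(ppm = c(3.543, 4.124, 3.814, 3.554, 3.896,
                                       3.789, 3.779, 3.549, 4.107),
                               mean = 60.31, sd = 105.51),
      glucose           = list(ppm = c(3.411, 3.5005, 3.240, 3.731, 3.517,
                                       3.537, 3.396, 3.703, 3.824, 3.833,
                                       3.691, 4.632, 3.531, 5.217, 3.451),
                               mean = 30.71, sd = 102.30),
      creatinine        = list(ppm = 4.041, mean = 8.19, sd = 6.38),
      taurine           = list(ppm = c(3.474, 3.254), mean = 62.69, sd = 45.49),
      `trans-aconitate` = list(ppm = 6.577, mean = 6.68, sd = 7.54),
      lactate           = list(ppm = 1.329, mean = 1.85, sd = 1.10),
      `hippuric acid`   = list(ppm = c(3.954, 3.961), mean = 24.56, sd = 19.22),
      `L-methylamine`   = list(ppm = 2.596, mean = 0.13, sd = 0.11),
      citrate           = list(ppm = c(2.563, 2.535, 2.684), mean = 19.28, sd = 23.22)
    ),
    serum = list(
      glucose                = list(ppm = c(3.522, 3.380, 3.398), mean = 88.33, sd = 19.58),
      choline                = list(ppm = c(4.073, 4.065), mean = 5.44, sd = 2.30),
      lactate                = list(ppm = c(4.077, 4.081), mean = 182.09, sd = 32.99),
      citrate                = list(ppm = 2.555, mean = 2.12, sd = 0.36),
      `1,3-dihydroxyacetone` = list(ppm = 4.426, mean = 0.43, sd = 0.45),
      pyruvate               = list(ppm = 2.359, mean = 4.06, sd = 0.99),
      glycerol               = list(ppm = 3.572, mean = 23.01, sd = 4.78),
      # unassigned serum resonances carried as synthetic stand-ins; their
      # concentrations are not reported, a nominal 1 mM scale is assumed
      `unknown_1.173`        = list(ppm = 1.173, mean = 1.00, sd = 0.50),
      `unknown_1.183`        = list(ppm = 1.183, mean = 1.00, sd = 0.50),
      `unknown_3.205`        = list(ppm = 3.205, mean = 1.00, sd = 0.50)
    ),
    fecal = list(
      acetoin           = list(ppm = 4.429, mean = 2.04, sd = 1.62),
      taurine           = list(ppm = 3.262, mean = 6.03, sd = 7.72),
      glucose           = list(ppm = c(3.418, 3.249, 3.424, 3.409, 3.392,
                                       3.480, 4.644, 3.465, 3.469, 3.438),
                               mean = 9.51, sd = 11.23),
      phenylalanine     = list(ppm = c(7.352, 7.323, 7.381, 7.310, 7.420,
                                       7.368, 7.433),
                               mean = 2.24, sd = 1.13),
      benzoate          = list(ppm = c(7.476, 7.489, 7.869, 7.558, 7.545),
                               mean = 2.63, sd = 1.84),
      `propionic acid`  = list(ppm = 2.152, mean = 4.47, sd = 2.79),
      acetate           = list(ppm = 1.904, mean = 74.29, sd = 35.81),
      valine            = list(ppm = c(0.975, 1.037, 0.987, 2.261, 2.269),
                               mean = 6.41, sd = 4.10),
      `L-alanine`       = list(ppm = 3.779, mean = 9.75, sd = 5.10),
      glutamate         = list(ppm = c(2.346, 2.118, 2.141, 2.038, 2.130,
                                       2.330, 2.359, 2.369),
                               mean = 17.84, sd = 9.94),
      butyrate          = list(ppm = 0.869, mean = 2.55, sd = 2.03),
      `L-methionine`    = list(ppm = c(2.622, 2.647), mean = 0.39, sd = 0.23),
      `2-oxoisocaproate` = list(ppm = c(0.932, 2.593, 2.608), mean = 0.98, sd = 0.35),
      lactate           = list(ppm = c(1.311, 4.089), mean = 10.10, sd = 5.61)
    ),
    tissue = list(
      tyrosine           = list(ppm = c(3.041, 3.934, 3.058), mean = 2.16, sd = 3.41),
      taurine            = list(ppm = c(3.237, 3.391), mean = 21.35, sd = 20.00),
      glucose            = list(ppm = c(3.465, 3.479, 3.493, 4.643), mean = 3.58, sd = 2.93),
      `o-phosphocholine` = list(ppm = 3.201, mean = 1.80, sd = 1.56),
      cytidine           = list(ppm = 7.838, mean = 1.23, sd = 1.49),
      niacinamide        = list(ppm = 8.231, mean = 0.70, sd = 0.48),
      aspartate          = list(ppm = c(2.677, 2.661), mean = 9.93, sd = 11.26),
      asparagine         = list(ppm = 2.834, mean = 2.65, sd = 2.82),
      xanthine           = list(ppm = 7.849, mean = 2.06, sd = 4.50),
      phenylalanine      = list(ppm = 7.301, mean = 2.04, sd = 3.10),
      lactate            = list(ppm = 4.100, mean = 10.00, sd = 11.18)
    )
  )
}

#' Built-in metabolite template library for a sample matrix
#'
#' Returns the multiplet templates for one of the four supported sample
#' matrices (`"urine"`, `"serum"`, `"fecal"`, `"tissue"`).  Peak positions
#' are the tabulated resonance ppm values for that matrix; base
#' concentrations and coefficients of variation come from the control-group
#' concentration mean/StDev columns (cv capped at 1.5).
#'
#' @param matrix One of `"urine"`, `"serum"`, `"fecal"`, `"tissue"`.
#' @return A named list of [metabolite_template] objects.
#' @examples
#' lib <- template_library("urine")
#' lib[["3-indoxylsulfate"]]
#' @export
template_library <- function(matrix = c("urine", "serum", "fecal", "tissue")) {
  if (!is.character(matrix) || length(matrix) != 1L ||
      !matrix %in% c("urine", "serum", "fecal", "tissue"))
    stop("unknown sample matrix: ", paste(matrix, collapse = ", "),
         " (expected one of urine, serum, fecal, tissue)")
  tab <- .template_tables()[[matrix]]
  out <- lapply(names(tab), function(nm) {
    e <- tab[[nm]]
    metabolite_template(nm, e$ppm, e$mean, .cv_from_moments(e$mean, e$sd))
  })
  names(out) <- names(tab)
  out
}

#' Default planted study/control fold-change map for a matrix
#'
#' One representative signed fold change per metabolite, taken from the
#' most significant 15-month resonance of that metabolite (tumor-group
#' values for `"tissue"`).  Signs follow the reporting convention: the
#' study/control ratio when >= 1, otherwise minus its reciprocal.
#'
#' @inheritParams template_library
#' @return Named numeric vector of signed fold changes.
#' @export
default_fold_map <- function(matrix = c("urine", "serum", "fecal", "tissue")) {
  matrix <- match.arg(matrix)
  switch(matrix,
    urine = c(`3-indoxylsulfate` = -1.80, benzoate = -2.38,
              `trans-aconitate` = -1.96, `L-methylamine` = -1.44,
              citrate = -1.98, `2-oxoglutarate` = -1.43,
              fructose = 4.98, glucose = 6.46, creatinine = 4.47,
              taurine = 5.61),
    serum = c(glucose = -1.54, choline = -1.52, lactate = -1.54,
              citrate = 1.33, `1,3-dihydroxyacetone` = -2.18,
              pyruvate = -1.31, glycerol = -1.15),
    fecal = c(phenylalanine = -1.80, benzoate = -1.81, valine = -1.46,
              glutamate = -1.50, butyrate = -1.42, `L-methionine` = -1.44,
              `2-oxoisocaproate` = -1.36, lactate = -1.50, acetoin = 1.30),
    tissue = c(tyrosine = 2.465, taurine = 2.20, glucose = 2.07))
}

#' Library of featureless single-peak templates
#'
#' Generates `n` synthetic single-resonance metabolites evenly spread over a
#' ppm range, all with the same concentration scale and coefficient of
#' variation.  Used for null-calibration experiments where many independent
#' buckets with no group effect are needed.
#'
#' @param n Number of templates.
#' @param ppm_range Interval over which peak centres are placed.
#' @param base_concentration Common concentration (mM).
#' @param cv Common coefficient of variation.
#' @return A named list of [metabolite_template] objects.
#' @export
null_template_library <- function(n, ppm_range = c(0.5, 9.5),
                                  base_concentration = 1, cv = 0.3) {
  stopifnot(n >= 1)
  centres <- seq(ppm_range[1], ppm_range[2], length.out = n)
  out <- lapply(seq_len(n), function(i)
    metabolite_template(sprintf("feature_%03d", i), centres[i],
                        base_concentration, cv))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
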