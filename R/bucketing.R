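# Spectrum I/O, TSP referencing, bucket-window integration and assembly
# of the samples x buckets area matrix.

#' Construct a spectrum object
#'
#' @param ppm Numeric ppm axis; ascending input is flipped to descending.
#' @param intensity Numeric intensities, same length as `ppm`.
#' @param meta Optional named list/row of sample metadata.
#' @return An object of class `nmr_spectrum`.
#' @export
new_spectrum <- function(ppm, intensity, meta = list()) {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop("ppm and intensity lengths differ (",
         length(ppm), " vs ", length(intensity), ")")
  if (anyNA(ppm) || any(!is.finite(intensity)))
    stop("non-finite values in spectrum")
  if (is.unsorted(rev(ppm), strictly = TRUE)) {
    if (is.unsorted(ppm, strictly = TRUE))
      stop("ppm axis must be strictly monotone")
    ppm <- rev(ppm); intensity <- rev(intensity)
  }
  structure(list(ppm = ppm, intensity = intensity, meta = meta),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, %.3f .. %.3f ppm\n",
              length(x$ppm), max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' Write a spectrum to a two-column tab-separated file
#'
#' Header line `ppm\\tintensity`, ppm descending.
#'
#' @param s An `nmr_spectrum`.
#' @param path Output file path.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "nmr_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("ppm\tintensity", con)
  writeLines(sprintf("%.6f\t%.8g", s$ppm, s$intensity), con)
  invisible(path)
}

#' Read a spectrum from a two-column text file
#'
#' Accepts tab- or whitespace-separated `ppm` / `intensity` columns with an
#' optional header.  Ascending axes are flipped to descending.
#'
#' @param path File path.
#' @param meta Optional metadata attached to the spectrum.
#' @return An `nmr_spectrum`.
#' @export
read_spectrum <- function(path, meta = list()) {
  if (!file.exists(path)) stop("spectrum file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty spectrum file: ", path)
  start <- 1L
  if (grepl("[A-DF-Za-df-z]", lines[1])) start <- 2L  # header (not sci notation)
  body <- lines[start:length(lines)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "[\t ,]+")
  nf <- lengths(parts)
  if (any(nf != 2))
    stop("line ", which(nf != 2)[1] + start - 1L,
         " of ", path, ": expected two columns")
  vals <- suppressWarnings(vapply(parts, function(p) as.numeric(p), numeric(2)))
  if (anyNA(vals)) {
    bad <- which(colSums(is.na(vals)) > 0)[1]
    stop("line ", bad + start - 1L, " of ", path, ": non-numeric value")
  }
  new_spectrum(vals[1, ], vals[2, ], meta = meta)
}

#' Reference the ppm axis to the TSP line
#'
#' Shifts the axis so the apex of the tallest peak inside `search_window`
#' sits at exactly 0.0 ppm.  Intensities are unchanged.
#'
#' @param s An `nmr_spectrum`.
#' @param search_window ppm interval searched for the TSP apex.
#' @return The referenced spectrum.
#' @export
reference_to_tsp <- function(s, search_window = c(-0.3, 0.3)) {
  stopifnot(inherits(s, "nmr_spectrum"))
  in_win <- s$ppm >= min(search_window) & s$ppm <= max(search_window)
  if (!any(in_win)) stop("TSP not found: search window outside spectrum")
  y <- s$intensity[in_win]
  floor_level <- stats::median(y) + 5 * stats::mad(y)
  if (max(y) <= floor_level || max(y) <= 0)
    stop("TSP not found: no peak above noise floor in search window")
  apex <- s$ppm[in_win][which.max(y)]
  s$ppm <- s$ppm - apex
  s
}

#' Measure a peak's full width at half maximum
#'
#' Finds the tallest peak inside `window`, refines the apex height by a
#' parabolic fit through the three grid points around the maximum, and
#' locates the two half-height crossings by linear interpolation.
#'
#' @param s An `nmr_spectrum`.
#' @param window ppm interval containing the peak (default the TSP region).
#' @param frequency Spectrometer frequency in MHz; when given, the width
#'   is returned in Hz instead of ppm.
#' @return Full width at half maximum (ppm, or Hz when `frequency` is set).
#' @export
measure_fwhm <- function(s, window = c(-0.3, 0.3), frequency = NULL) {
  stopifnot(inherits(s, "nmr_spectrum"))
  keep <- s$ppm >= min(window) & s$ppm <= max(window)
  if (sum(keep) < 5) stop("window contains too few points")
  x <- rev(s$ppm[keep]); y <- rev(s$intensity[keep])
  i <- which.max(y)
  if (i <= 1 || i >= length(y)) stop("peak apex on the window boundary")
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  apex_y <- if (denom < 0) {
    d <- (y[i - 1] - y[i + 1]) / (2 * denom)
    y[i] - 0.25 * (y[i - 1] - y[i + 1]) * d
  } else y[i]
  half <- apex_y / 2
  above <- which(y > half)
  lo <- above[1]; hi <- above[length(above)]
  if (lo <= 1 || hi >= length(y)) stop("half-height crossing outside window")
  xl <- stats::approx(y[c(lo - 1, lo)], x[c(lo - 1, lo)], xout = half)$y
  xr <- stats::approx(y[c(hi, hi + 1)], x[c(hi, hi + 1)], xout = half)$y
  width <- xr - xl
  if (!is.null(frequency)) width * frequency else width
}

#' Canonical bucket id from a centre ppm
#'
#' Centres are printed to three to four decimals, trailing zeros trimmed to
#' a minimum of three decimals (`7.699`, `3.5005`).
#' @param ppm Numeric vector of window centres.
#' @return Character ids.
#' @export
format_bucket_id <- function(ppm) {
  id4 <- sprintf("%.4f", ppm)
  ifelse(substr(id4, nchar(id4), nchar(id4)) == "0",
         sprintf("%.3f", ppm), id4)
}

#' Bucket definitions centred on template-library resonances
#'
#' One window per resonance, half-width `half_width`, shrunk at the
#' midpoint between adjacent centres so windows never overlap.
#'
#' @param library List of [metabolite_template] objects.
#' @param half_width Half-width of each window (ppm).
#' @return Data frame `bucket_id`, `ppm_low`, `ppm_high` plus a
#'   `metabolite` column mapping windows to template names.
#' @export
bucket_definitions <- function(library, half_width = 0.005) {
  peaks <- do.call(rbind, lapply(library, function(tm)
    data.frame(metabolite = tm$name, ppm = tm$peaks$ppm_center,
               stringsAsFactors = FALSE)))
  peaks <- peaks[order(peaks$ppm), ]
  n <- nrow(peaks)
  lo <- peaks$ppm - half_width
  hi <- peaks$ppm + half_width
  if (n > 1) {
    mid <- (peaks$ppm[-n] + peaks$ppm[-1]) / 2
    hi[-n] <- pmin(hi[-n], mid)
    lo[-1] <- pmax(lo[-1], mid)
  }
  data.frame(bucket_id = make.unique(format_bucket_id(peaks$ppm), sep = "_"),
             ppm_low = lo, ppm_high = hi, metabolite = peaks$metabolite,
             stringsAsFactors = FALSE, row.names = NULL)
}

# trapezoidal integral between exact ppm bounds on an ascending axis, with
# linear interpolation at the bounds so adjacent windows tile without
# overlap or double counting
.integrate_xy <- function(x, y, lo, hi) {
  n <- length(x)
  lo <- max(lo, x[1]); hi <- min(hi, x[n])
  if (hi <= lo) return(NA_real_)
  interp <- function(x0) {
    i <- findInterval(x0, x, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    y[i] + (y[i + 1] - y[i]) * (x0 - x[i]) / (x[i + 1] - x[i])
  }
  i1 <- findInterval(lo, x) + 1L          # first grid point > lo
  i2 <- findInterval(hi, x)               # last grid point <= hi
  if (i2 >= 1L && x[i2] == hi) i2 <- i2 - 1L  # half-open: hi interpolated
  inside <- if (i2 >= i1) i1:i2 else integer(0)
  xs <- c(lo, x[inside], hi)
  ys <- c(interp(lo), y[inside], interp(hi))
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

.integrate_window <- function(s, lo, hi) {
  .integrate_xy(rev(s$ppm), rev(s$intensity), lo, hi)
}

#' Integrate one bucket window
#'
#' Trapezoidal integral of intensity over `[ppm_low, ppm_high)`; the
#' boundaries are interpolated so adjacent buckets never double-count.
#'
#' @param s An `nmr_spectrum`.
#' @param ppm_low,ppm_high Window bounds (`ppm_low < ppm_high`).
#' @return Integrated area (intensity x ppm units).
#' @export
integrate_bucket <- function(s, ppm_low, ppm_high) {
  stopifnot(inherits(s, "nmr_spectrum"), ppm_low < ppm_high)
  a <- .integrate_window(s, ppm_low, ppm_high)
  if (is.na(a))
    stop(sprintf("bucket [%.4f, %.4f] does not overlap the spectral window",
                 ppm_low, ppm_high))
  a
}

#' Assemble the samples x buckets area matrix
#'
#' @param spectra Named list of referenced `nmr_spectrum` objects (names
#'   are sample ids), or a character vector of file paths.
#' @param defs Bucket definition data frame (`bucket_id`, `ppm_low`,
#'   `ppm_high`), e.g. from [bucket_definitions].
#' @param manifest Optional data frame with a `sample_id` column and group
#'   metadata, joined onto the table rows.
#' @param normalization `"none"` (raw areas), `"tsp"` (each row divided by
#'   that sample's TSP-region integral) or `"total_area"` (divided by the
#'   row total excluding the TSP region).
#' @param tsp_region ppm interval treated as the TSP reference region.
#' @return An object of class `bucket_table` with fields `areas`
#'   (matrix), `samples` (metadata), `buckets` (definitions) and
#'   `normalization`.
#' @export
build_bucket_table <- function(spectra, defs, manifest = NULL,
                               normalization = c("none", "tsp", "total_area"),
                               tsp_region = c(-0.05, 0.05)) {
  normalization <- match.arg(normalization)
  if (is.character(spectra)) {
    paths <- spectra
    spectra <- lapply(paths, read_spectrum)
    names(spectra) <- if (!is.null(names(paths)) && all(nzchar(names(paths))))
      names(paths) else sub("\\.[^.]*$", "", basename(paths))
  }
  if (!length(spectra)) stop("no spectra supplied")
  if (!nrow(defs)) stop("no bucket definitions supplied")
  ids <- names(spectra)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_along(spectra))
  areas <- matrix(NA_real_, length(spectra), nrow(defs),
                  dimnames = list(ids, defs$bucket_id))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    x <- rev(s$ppm); y <- rev(s$intensity)  # ascending, once per sample
    for (j in seq_len(nrow(defs))) {
      a <- .integrate_xy(x, y, defs$ppm_low[j], defs$ppm_high[j])
      if (is.na(a))
        stop("sample ", ids[i], ": bucket ", defs$bucket_id[j],
             " does not overlap the spectral window")
      areas[i, j] <- a
    }
  }
  if (normalization == "tsp") {
    denom <- vapply(spectra, .integrate_window,
                    numeric(1), lo = tsp_region[1], hi = tsp_region[2])
    if (any(!is.finite(denom)) || any(denom <= 0))
      stop("TSP-region integral non-positive; cannot normalize")
    areas <- areas / denom
  } else if (normalization == "total_area") {
    denom <- vapply(spectra, function(s) {
      tot <- .integrate_window(s, min(s$ppm), max(s$ppm))
      tsp <- .integrate_window(s, tsp_region[1], tsp_region[2])
      tot - ifelse(is.na(tsp), 0, tsp)
    }, numeric(1))
    if (any(!is.finite(denom)) || any(denom <= 0))
      stop("total-area integral non-positive; cannot normalize")
    areas <- areas / denom
  }
  meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if (!is.null(manifest)) {
    missing <- setdiff(ids, manifest$sample_id)
    if (length(missing))
      stop("sample id missing from manifest: ", paste(missing, collapse = ", "))
    meta <- merge(meta, manifest, by = "sample_id", sort = FALSE)
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(list(areas = areas, samples = meta,
                 buckets = defs[, c("bucket_id", "ppm_low", "ppm_high")],
                 normalization = normalization),
            class = "bucket_table")
}

#' @export
print.bucket_table <- function(x, ...) {
  cat(sprintf("<bucket_table> %d samples x %d buckets (normalization: %s)\n",
              nrow(x$areas), ncol(x$areas), x$normalization))
  invisible(x)
}

#' Absolute quantification against the TSP reference
#'
#' TSP contributes nine equivalent protons, so a metabolite resonance of
#' `n_protons` protons with area `area` corresponds to
#' `(area / tsp_area) * (9 / n_protons) * tsp_conc` mM.
#'
#' @param area Bucket area of the metabolite resonance.
#' @param tsp_area Area of the TSP reference region (> 0).
#' @param n_protons Number of protons giving rise to the resonance (>= 1).
#' @param tsp_conc TSP concentration in mM.
#' @return Estimated concentration in mM.
#' @export
quantify_via_tsp <- function(area, tsp_area, n_protons, tsp_conc) {
  if (!is.numeric(tsp_area) || tsp_area <= 0)
    stop("tsp_area must be > 0")
  stopifnot(n_protons >= 1, tsp_conc > 0)
  (area / tsp_area) * (9 / n_protons) * tsp_conc
}
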