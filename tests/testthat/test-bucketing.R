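test_that("spectrum files round-trip and malformed files are rejected", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("ppm\tintensity", "1.0\t5", "0.0\t10", "-1.0\t5"), f)
  s <- read_spectrum(f)
  expect_length(s$ppm, 3)
  expect_equal(s$ppm, c(1, 0, -1))

  # ascending input is flipped to descending
  writeLines(c("ppm\tintensity", "-1.0\t5", "0.0\t10", "1.0\t5"), f)
  s2 <- read_spectrum(f)
  expect_equal(s2$ppm, c(1, 0, -1))
  expect_equal(s2$intensity, c(5, 10, 5))

  # non-numeric intensity names the offending line
  writeLines(c("ppm\tintensity", "1.0\t5", "0.0\tNA"), f)
  expect_error(read_spectrum(f), "line 3")

  writeLines(c("ppm\tintensity", "1.0\t5\t9"), f)
  expect_error(read_spectrum(f), "two columns")

  expect_error(read_spectrum(tempfile()), "not found")
  expect_error(new_spectrum(c(1, 0), c(1, 2, 3)), "lengths differ")

  # writer/reader round trip preserves values
  sp <- new_spectrum(seq(2, -2, length.out = 101),
                     dnorm(seq(2, -2, length.out = 101)))
  write_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(back$intensity, sp$intensity, tolerance = 1e-6)
  unlink(f)
})

test_that("TSP referencing moves the apex to exactly 0 ppm", {
  acq <- quiet_acq()
  lib <- list(probe = metabolite_template("probe", 5, 1, 0))
  sp <- render_spectrum(c(probe = 1), lib, acq)
  shifted <- sp
  shifted$ppm <- shifted$ppm + 0.013  # mis-referenced axis
  ref <- reference_to_tsp(shifted)
  step <- abs(diff(ref$ppm[1:2]))
  apex <- ref$ppm[abs(ref$ppm) < 0.3][which.max(ref$intensity[abs(ref$ppm) < 0.3])]
  expect_lte(abs(apex), step)
  # idempotence: re-referencing shifts by at most one grid step
  ref2 <- reference_to_tsp(ref)
  expect_lte(max(abs(ref2$ppm - ref$ppm)), step + 1e-12)
  # intensities untouched
  expect_identical(ref$intensity, shifted$intensity)
  # flat window: no reference peak
  flat <- new_spectrum(seq(1, -1, length.out = 101), rep(1, 101))
  expect_error(reference_to_tsp(flat), "TSP not found")
})

test_that("bucket integration matches rectangles and the analytic Lorentzian", {
  x <- seq(1, 0, length.out = 1001)
  s <- new_spectrum(x, rep(1, 1001))
  expect_lt(abs(integrate_bucket(s, 0.40, 0.41) - 0.0100), 1e-9)

  acq <- quiet_acq()
  lib <- list(probe = metabolite_template("probe", 5, 1, 0))
  sp <- render_spectrum(c(probe = 1), lib, acq)
  fwhm_ppm <- acq$linewidth_fwhm / acq$spectrometer_frequency
  a <- integrate_bucket(sp, 5 - 20 * fwhm_ppm, 5 + 20 * fwhm_ppm)
  expect_gte(a, 0.98)  # unit-area line, +/-20 FWHM captures >= 98%

  expect_error(integrate_bucket(sp, 30, 31), "does not overlap")
  expect_error(integrate_bucket(sp, 5, 4))
})

test_that("adjacent buckets tile the axis without double counting", {
  acq <- quiet_acq()
  lib <- list(probe = metabolite_template("probe", 5, 1, 0))
  sp <- render_spectrum(c(probe = 2), lib, acq)
  whole <- integrate_bucket(sp, 4.9, 5.1)
  halves <- integrate_bucket(sp, 4.9, 5.0) + integrate_bucket(sp, 5.0, 5.1)
  expect_lt(abs(whole - halves), 1e-12)
})

test_that("grid refinement changes bucket areas by less than 0.5%", {
  lib <- list(probe = metabolite_template("probe", 5, 1, 0))
  a1 <- integrate_bucket(render_spectrum(c(probe = 1), lib,
                                         quiet_acq(points = 16384L)),
                         4.99, 5.01)
  a2 <- integrate_bucket(render_spectrum(c(probe = 1), lib,
                                         quiet_acq(points = 32768L)),
                         4.99, 5.01)
  expect_lt(abs(a2 - a1) / a1, 0.005)
})

test_that("auto-generated bucket windows are disjoint and labelled by centre", {
  lib <- template_library("urine")
  defs <- bucket_definitions(lib)
  expect_equal(nrow(defs),
               sum(vapply(lib, function(tm) nrow(tm$peaks), 1L)))
  expect_true(all(defs$ppm_low < defs$ppm_high))
  o <- order(defs$ppm_low)
  expect_true(all(defs$ppm_high[o][-nrow(defs)] <=
                  defs$ppm_low[o][-1] + 1e-12))
  expect_true("7.699" %in% defs$bucket_id)
  expect_true("3.5005" %in% defs$bucket_id)
})

test_that("bucket tables fill every cell and normalizations behave", {
  acq <- quiet_acq(points = 8192L)
  lib <- list(a = metabolite_template("a", 3, 1, 0),
              b = metabolite_template("b", 6, 2, 0))
  defs <- bucket_definitions(lib, half_width = 0.02)
  s1 <- render_spectrum(c(a = 1, b = 2), lib, acq)
  s2 <- render_spectrum(c(a = 2, b = 4), lib, acq)  # x2 dilution mirror
  tb_none <- build_bucket_table(list(S1 = s1, S2 = s2), defs,
                                normalization = "none")
  expect_true(all(is.finite(tb_none$areas)))
  expect_equal(dim(tb_none$areas), c(2L, 2L))
  expect_true(all(tb_none$areas >= 0))

  # tsp normalization cancels a global intensity scaling (receiver gain)
  s1x2 <- s1; s1x2$intensity <- 2 * s1$intensity
  tb_tsp <- build_bucket_table(list(S1 = s1, S2 = s1x2), defs,
                               normalization = "tsp")
  expect_equal(unname(tb_tsp$areas["S1", ]), unname(tb_tsp$areas["S2", ]),
               tolerance = 1e-12)

  # with constant TSP, tsp-normalized areas are proportional to raw areas
  tb_tsp2 <- build_bucket_table(list(S1 = s1, S2 = s2), defs,
                                normalization = "tsp")
  ratio <- tb_none$areas / tb_tsp2$areas
  expect_lt(diff(range(ratio[1, ])) / mean(ratio[1, ]), 1e-6)

  # total-area normalization equalises a doubled-concentration pair
  # (reference-free spectra: the fixed TSP line would not rescale)
  acq0 <- quiet_acq(points = 8192L, tsp_concentration = 0)
  t1 <- render_spectrum(c(a = 1, b = 2), lib, acq0)
  t2 <- render_spectrum(c(a = 2, b = 4), lib, acq0)
  tb_tot <- build_bucket_table(list(S1 = t1, S2 = t2), defs,
                               normalization = "total_area")
  expect_equal(unname(tb_tot$areas["S1", ]), unname(tb_tot$areas["S2", ]),
               tolerance = 1e-6)

  # manifest join and missing-id error
  man <- data.frame(sample_id = c("S1", "S2"), group = c("control", "study"))
  tb_m <- build_bucket_table(list(S1 = s1, S2 = s2), defs, manifest = man)
  expect_equal(tb_m$samples$group, c("control", "study"))
  expect_error(build_bucket_table(list(S1 = s1, SX = s2), defs,
                                  manifest = man), "SX")
})

test_that("disjoint bucket areas never exceed the total spectrum integral", {
  acq <- quiet_acq(points = 8192L)
  lib <- template_library("tissue")
  lib0 <- with_uniform_cv(lib, 0)
  conc <- vapply(lib0, `[[`, numeric(1), "base_concentration")
  sp <- render_spectrum(conc, lib0, acq)
  defs <- bucket_definitions(lib0)
  total <- integrate_bucket(sp, min(sp$ppm), max(sp$ppm))
  areas <- vapply(seq_len(nrow(defs)), function(j)
    integrate_bucket(sp, defs$ppm_low[j], defs$ppm_high[j]), numeric(1))
  expect_lte(sum(areas), total)
})

test_that("cohort round trip recovers planted concentrations (noise off)", {
  lib <- with_uniform_cv(template_library("urine"), cv_for_sdlog(0.4))
  design <- cohort_design(n_per_group = 6, planted_effects = numeric(),
                          seed = 17)
  acq <- quiet_acq(points = 32768L)
  dir <- tempfile("rt")
  set.seed(design$seed)
  conc <- sample_concentrations(lib, 12, "control")
  spectra <- lapply(seq_len(12), function(i)
    render_spectrum(conc[i, ], lib, acq))
  names(spectra) <- sprintf("S%02d", 1:12)
  defs <- bucket_definitions(lib)
  tb <- build_bucket_table(spectra, defs)
  # per-bucket area vs its metabolite's planted concentration across samples
  r2 <- vapply(seq_len(nrow(defs)), function(j) {
    stats::cor(tb$areas[, defs$bucket_id[j]], conc[, defs$metabolite[j]])^2
  }, numeric(1))
  # isolated lines (nearest foreign resonance > 0.1 ppm away) are exact;
  # closer neighbours pick up Lorentzian tail leakage, as in real spectra
  ppm <- defs$ppm_low / 2 + defs$ppm_high / 2
  iso <- vapply(seq_len(nrow(defs)), function(j) {
    other <- abs(ppm[-j] - ppm[j])
    foreign <- defs$metabolite[-j] != defs$metabolite[j]
    all(other[foreign] > 0.1)
  }, logical(1))
  expect_gte(sum(iso), 5)
  expect_gt(min(r2[iso]), 0.999)
  expect_gt(stats::median(r2), 0.99)
})

test_that("TSP quantification follows the nine-proton ratio rule", {
  expect_equal(quantify_via_tsp(1, 1, 9, 1.0), 1.0)
  expect_equal(quantify_via_tsp(1, 1, 1, 0.58), 5.22)
  expect_equal(quantify_via_tsp(0, 2, 3, 1.0), 0)
  expect_error(quantify_via_tsp(1, 0, 9, 1.0), "tsp_area")
})
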