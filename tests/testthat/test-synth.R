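test_that("identical seeds reproduce identical outputs", {
  a <- simulate_batch_set(seed = 5)
  b <- simulate_batch_set(seed = 5)
  expect_identical(a$table$areas, b$table$areas)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_ms2("rutin", "negative", 0.1, seed = 3),
                   simulate_ms2("rutin", "negative", 0.1, seed = 3))
  expect_identical(simulate_calibration("eupatilin", noise_cv = 0.05,
                                        seed = 2),
                   simulate_calibration("eupatilin", noise_cv = 0.05,
                                        seed = 2))
  c1 <- simulate_chromatogram(a$truth[a$truth$batch == "HN1", ],
                              chrom_template(), noise_sd = 1, seed = 9)
  c2 <- simulate_chromatogram(a$truth[a$truth$batch == "HN1", ],
                              chrom_template(), noise_sd = 1, seed = 9)
  expect_identical(c1$intensities, c2$intensities)
})

test_that("noise-free batch sets hit the configured region means exactly", {
  sim <- simulate_batch_set(default_region_effects(cv = 0), noise_cv = 0,
                            seed = 1)
  info <- default_peak_info()
  ext <- extraction_spec()
  for (p in c("17", "2", "11")) {
    i <- match(p, info$peak_id)
    rf_eff <- info$response_factor[i] * ext$sample_mass_g /
      ext$extract_volume_ml
    hn <- sim$table$areas[sim$table$regions == "HN", p]
    expect_equal(mean(hn), info$mean_HN[i] * rf_eff, tolerance = 1e-12)
    hb <- sim$table$areas[sim$table$regions == "HB", p]
    expect_equal(mean(hb), info$mean_HB[i] * rf_eff, tolerance = 1e-12)
  }
  # the planted eupatilin means are the published 1.053 / 1.997 mg/g
  expect_equal(info$mean_HN[info$compound == "eupatilin"], 1.053)
  expect_equal(info$mean_HB[info$compound == "eupatilin"], 1.997)
})

test_that("sampled means converge to the configured lognormal mean", {
  sim <- simulate_batch_set(default_region_effects(cv = 0),
                            n_per_region = 200, noise_cv = 0.2, seed = 1)
  info <- default_peak_info()
  ext <- extraction_spec()
  i <- match("17", info$peak_id)
  rf_eff <- info$response_factor[i] * ext$sample_mass_g / ext$extract_volume_ml
  target <- info$mean_HN[i] * rf_eff
  x <- sim$table$areas[sim$table$regions == "HN", "17"]
  se <- target * 0.2 / sqrt(200)   # lognormal mean-one noise, cv 0.2
  expect_lt(abs(mean(x) - target), 3 * se)
})

test_that("region contrasts are planted at the marker peaks only", {
  spec <- default_region_effects()
  info <- default_peak_info()
  for (p in names(spec)) {
    rm <- spec[[p]]$region_means
    if (info$marker[match(p, info$peak_id)]) {
      expect_false(rm[["HN"]] == rm[["HB"]])
    } else {
      expect_identical(rm[["HN"]], rm[["HB"]])
    }
  }
  expect_identical(info$peak_id[info$marker],
                   c("2", "8", "9", "10", "11", "12", "17"))
})

test_that("simulated chromatogram peaks integrate to the configured area", {
  tmpl <- chrom_template(peak_ids = "11", retention_times = 12,
                         reference_peak = "11", baseline_level = 0)
  truth <- data.frame(batch = "b", peak_id = "11", true_mg_g = 100 * 125 / 1000)
  ch <- simulate_chromatogram(truth, tmpl)
  pk <- detect_peaks(ch, min_height = 1, baseline = 0)
  expect_identical(nrow(pk), 1L)
  expect_gt(pk$area, 99)   # analytic Gaussian area 100
  expect_lt(pk$area, 101)
})

test_that("an empty ground truth yields a flat baseline", {
  tmpl <- chrom_template()
  ch <- simulate_chromatogram(data.frame(batch = character(0),
                                         peak_id = character(0),
                                         true_mg_g = numeric(0)), tmpl)
  expect_equal(stats::sd(ch$intensities), 0)
  expect_identical(nrow(detect_peaks(ch, min_height = 1)), 0L)
})

test_that("peaks just over six sigma apart resolve beyond 1.5", {
  # Rs = 2 * dt / (8 sigma): exactly 1.5 at 6 sigma, 1.6 at 6.4 sigma
  ch <- gaussian_chrom(c(5, 5 + 6.4 * 0.05), c(100, 80), sigma = 0.05)
  pk <- detect_peaks(ch, min_height = 1, baseline = 0)
  expect_identical(nrow(pk), 2L)
  expect_gt(resolution(pk[1, ], pk[2, ]), 1.5)
})

test_that("a too-coarse sampling grid is rejected", {
  tmpl <- chrom_template(peak_width_sigma = 0.05)
  truth <- data.frame(batch = "b", peak_id = "11", true_mg_g = 1)
  expect_error(simulate_chromatogram(truth, tmpl, step = 0.02),
               "sigma/5")
})

test_that("noise-free calibration series are perfectly linear", {
  cal <- simulate_calibration("eupatilin", noise_cv = 0)
  fit <- fit_calibration(cal$concentration, cal$area)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(fit$slope, attr(cal, "response_factor"))
  # doubling the concentrations doubles the areas
  cal2 <- simulate_calibration("eupatilin",
                               levels = cal$concentration * 2, noise_cv = 0)
  expect_equal(cal2$area, cal$area * 2)
  expect_error(simulate_calibration("eupatilin", levels = c(0.1, 0.2)),
               "levels")
})

test_that("small calibration noise keeps the fit nearly perfect", {
  r2 <- vapply(1:200, function(s) {
    cal <- simulate_calibration("chlorogenic_acid", noise_cv = 0.02,
                                seed = s)
    fit_calibration(cal$concentration, cal$area)$r_squared
  }, numeric(1))
  expect_gt(stats::median(r2), 0.99)
})

test_that("the full noise-free pipeline recovers the planted contents", {
  sim <- simulate_batch_set(default_region_effects(cv = 0), noise_cv = 0,
                            seed = 2)
  tmpl <- chrom_template()
  peaks <- list()
  for (b in c("HN1", "HB1")) {
    tb <- sim$truth[sim$truth$batch == b, ]
    peaks[[b]] <- detect_peaks(simulate_chromatogram(tb, tmpl),
                               min_height = 1)
  }
  matched <- match_peaks(peaks, default_match_template(),
                         regions = c(HN1 = "HN", HB1 = "HB"))
  q <- qams_analysis(matched, seed = 1)
  truth <- sim$truth
  for (r in seq_len(nrow(q$results))) {
    tv <- truth$true_mg_g[truth$batch == q$results$batch[r] &
                            truth$compound == q$results$compound[r]]
    expect_equal(q$results$esm_mg_g[r], tv, tolerance = 0.01)
    expect_equal(q$results$qams_mg_g[r], tv, tolerance = 0.01)
  }
})
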