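test_that("correction factors follow their defining ratio", {
  expect_equal(correction_factor(100, 0.1, 100, 0.1), 1)
  # (200/0.1) / (150/0.09) = 2000 / 1666.67 = 1.2
  expect_equal(correction_factor(200, 0.1, 150, 0.09), 1.2)
  expect_error(correction_factor(0, 0.1, 150, 0.09), "positive")
})

test_that("condition aggregation reproduces the printed table averages", {
  f <- aaf_correction_factors()
  expect_equal(round(aggregate_conditions(f$neochlorogenic_acid)$mean, 3),
               1.222)
  expect_equal(round(aggregate_conditions(f$caffeic_acid)$mean, 3), 0.667)
  rrt <- aaf_relative_retention()
  expect_equal(round(aggregate_conditions(rrt$neochlorogenic_acid)$mean, 3),
               0.219)
  expect_identical(aggregate_conditions(rep(2, 5))$rsd_pct, 0)
  expect_error(aggregate_conditions(NA_real_), "no values")
})

test_that("calibration fitting matches a normal-equation oracle", {
  cal <- simulate_calibration("caffeic_acid", noise_cv = 0)
  fit <- fit_calibration(cal$concentration, cal$area)
  expect_equal(fit$r_squared, 1)
  # two points interpolate exactly
  f2 <- fit_calibration(c(1, 2), c(10, 30))
  expect_equal(f2$intercept + f2$slope * c(1, 2), c(10, 30))
  set.seed(14)
  x <- stats::runif(7, 0.01, 0.5)
  y <- 800 * x + 3 + stats::rnorm(7, sd = 2)
  mine <- fit_calibration(x, y)
  oracle <- ols_oracle(x, y)
  expect_equal(c(mine$intercept, mine$slope), unname(oracle),
               tolerance = 1e-10)
  expect_error(fit_calibration(c(1, 1), c(2, 3)), "distinct")
})

test_that("external-standard quantification applies the stoichiometry", {
  curve <- fit_calibration(c(0.01, 0.1), c(10, 100))  # area = 1000 * conc
  # 0.05 mg/mL in 25 mL from 0.2 g -> 6.25 mg/g
  expect_equal(quantify_esm(50, curve), 6.25)
  # an area at a calibration point returns its known concentration
  expect_equal(quantify_esm(100, curve), 0.1 * 125)
  # halving the sample mass doubles the content
  expect_equal(quantify_esm(50, curve, extraction_spec(0.1, 25)), 12.5)
  expect_warning(quantify_esm(1000, curve), "range")
})

test_that("QAMS inverts the correction factor consistently", {
  ext <- extraction_spec()
  expect_equal(quantify_qams(200, 200, 0.08, 1, ext), 0.08 * 125)
  # the correction_factor example run backwards
  f <- correction_factor(200, 0.1, 150, 0.09)
  expect_equal(quantify_qams(150, 200, 0.1, f, ext), 0.09 * 125)
  # reciprocity on random consistent observations
  set.seed(3)
  for (k in 1:20) {
    a_s <- stats::runif(1, 50, 500); c_s <- stats::runif(1, 0.01, 0.3)
    a_i <- stats::runif(1, 50, 500); c_i <- stats::runif(1, 0.01, 0.3)
    f <- correction_factor(a_s, c_s, a_i, c_i)
    expect_equal(quantify_qams(a_i, a_s, c_s, f), c_i * 125,
                 tolerance = 1e-12)
  }
  expect_error(quantify_qams(10, 0, 0.1, 1), "positive")
})

test_that("QAMS equals ESM on noise-free synthetic batches", {
  sim <- simulate_batch_set(default_region_effects(cv = 0), noise_cv = 0,
                            seed = 5)
  q <- qams_analysis(sim$table, seed = 1)
  rel <- abs(q$results$qams_mg_g - q$results$esm_mg_g) / q$results$esm_mg_g
  expect_lt(max(rel), 1e-9)
  expect_lt(max(q$results$rd_pct), 1e-7)
})

test_that("RRT templates assign the published analytes", {
  rrt_tab <- aaf_relative_retention()
  template <- vapply(setdiff(names(rrt_tab), c("factor", "level")),
                     function(a) mean(rrt_tab[[a]]), numeric(1))
  template <- c(template, isochlorogenic_acid_C = 1)
  observed <- stats::setNames(template * (1 + 0.002), paste0("pk", seq_along(template)))
  out <- identify_by_rrt(observed, template)
  expect_false(anyNA(out$peak))
  # nearest template wins; far-off observations stay unassigned
  expect_identical(identify_by_rrt(c(a = 0.219), c(x = 0.219, y = 0.348))$analyte[1], "x")
  far <- identify_by_rrt(c(a = 0.30), c(x = 0.219, y = 0.348))
  expect_true(all(is.na(far$peak)))
  expect_error(identify_by_rrt(c(a = 0.219), c(x = 0.219, y = 0.2195)),
               "ambiguous")
})

test_that("relative deviation matches the printed method-agreement values", {
  expect_equal(relative_deviation(5, 5), 0)
  expect_equal(relative_deviation(0.556, 0.559), 0.269, tolerance = 0.002)
  expect_equal(round(relative_deviation(6.975, 6.960), 3), 0.108)
  # the conventional definition gives about twice the printed values
  expect_equal(relative_deviation(0.556, 0.559, method = "reference") /
                 relative_deviation(0.556, 0.559), 2, tolerance = 0.01)
  expect_error(relative_deviation(0, 0), "zero")
})

test_that("region summaries and totals reproduce the printed table", {
  tab <- aaf_batch_quantification(include_totals = FALSE)
  sm <- summarize_by_region(tab)
  eup <- sm[sm$compound == "eupatilin", ]
  expect_equal(round(eup$mean_mg_g[eup$region == "HN"], 3), 1.053)
  expect_equal(round(eup$mean_mg_g[eup$region == "HB"], 3), 1.997)
  tot <- total_content(tab)
  expect_equal(tot$total[tot$batch == "HN2"], 7.574)
})

test_that("spike recovery is exact on closed-loop synthetic data", {
  expect_equal(spike_recovery(1.5, 0.5, 1.0), 100)
  expect_error(spike_recovery(1, 0.5, 0), "positive")
  # noise-free pipeline: spiking at 100% of base doubles the estimate
  sim <- simulate_batch_set(default_region_effects(cv = 0), noise_cv = 0,
                            seed = 6)
  q <- qams_analysis(sim$table, seed = 1)
  base <- q$results$esm_mg_g[q$results$batch == "HN1" &
                               q$results$compound == "eupatilin"]
  spiked_table <- sim$table
  spiked_table$areas["HN1", "17"] <- 2 * spiked_table$areas["HN1", "17"]
  q2 <- qams_analysis(spiked_table, seed = 1)
  spiked <- q2$results$esm_mg_g[q2$results$batch == "HN1" &
                                  q2$results$compound == "eupatilin"]
  expect_equal(spike_recovery(spiked, base, base), 100, tolerance = 0.1)
})

test_that("f and RRT stay robust under condition perturbations", {
  # condition effects are mostly common-mode (instrument sensitivity,
  # flow): both peaks drift together, with a small analyte-specific
  # residual; QAMS robustness rests on this cancellation
  set.seed(8)
  n_cond <- 19
  common <- stats::runif(n_cond, 0.95, 1.05)
  resid_s <- stats::runif(n_cond, 0.98, 1.02)
  resid_i <- stats::runif(n_cond, 0.98, 1.02)
  k_s <- 1000; k_i <- 820; c_s <- 0.05; c_i <- 0.04
  f_vals <- vapply(seq_len(n_cond), function(c) {
    correction_factor(k_s * c_s * common[c] * resid_s[c], c_s,
                      k_i * c_i * common[c] * resid_i[c], c_i)
  }, numeric(1))
  expect_lt(aggregate_conditions(f_vals)$rsd_pct, 3)
  # retention drifts cancel in the ratio the same way
  t_common <- stats::runif(n_cond, 0.98, 1.02)
  rrt_vals <- (2.628 * t_common * stats::runif(n_cond, 0.995, 1.005)) /
    (12.0 * t_common)
  expect_lt(aggregate_conditions(rrt_vals)$rsd_pct, 3)
})
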