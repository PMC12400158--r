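test_that("well-separated Gaussians integrate to their configured areas", {
  ch <- gaussian_chrom(c(3, 6, 9), c(100, 50, 200), sigma = 0.05)
  pk <- detect_peaks(ch, min_height = 1, baseline = 0)
  expect_identical(nrow(pk), 3L)
  expect_equal(pk$area, c(100, 50, 200), tolerance = 0.01)
  expect_false(any(pk$unresolved))
})

test_that("a flat trace yields no peaks", {
  ch <- chromatogram(seq(0, 10, 0.01), rep(7, 1001))
  expect_identical(nrow(detect_peaks(ch, min_height = 1)), 0L)
})

test_that("strongly overlapping peaks are flagged unresolved", {
  # 1 sigma apart: the valley stays far above half the lower apex
  ch <- gaussian_chrom(c(5, 5.05), c(100, 80), sigma = 0.05)
  pk <- detect_peaks(ch, min_height = 1, baseline = 0)
  expect_true(nrow(pk) %in% c(1L, 2L))
  if (nrow(pk) == 2L) expect_true(all(pk$unresolved))
})

test_that("asymmetry is 1 for symmetric peaks and inverts under mirroring", {
  ch <- gaussian_chrom(5, 100, sigma = 0.05)
  pk <- detect_peaks(ch, min_height = 1, baseline = 0)
  as1 <- asymmetry_factor(ch, pk[1, ], baseline = 0)
  expect_equal(as1, 1, tolerance = 0.02)
  # tailing generator peak
  tmpl <- chrom_template(peak_ids = "11", retention_times = 12,
                         reference_peak = "11", baseline_level = 0,
                         tailing = 0.3)
  truth <- data.frame(batch = "b", peak_id = "11", true_mg_g = 10)
  cht <- simulate_chromatogram(truth, tmpl)
  pkt <- detect_peaks(cht, min_height = 1, baseline = 0)
  as_t <- asymmetry_factor(cht, pkt[1, ], baseline = 0)
  expect_gt(as_t, 1)
  # mirroring the time axis turns tailing into fronting: As -> 1/As
  mir <- chromatogram(rev(max(cht$times) - cht$times),
                      rev(cht$intensities))
  pkm <- detect_peaks(mir, min_height = 1, baseline = 0)
  as_m <- asymmetry_factor(mir, pkm[1, ], baseline = 0)
  expect_equal(as_m, 1 / as_t, tolerance = 0.02)
})

test_that("resolution follows the Gaussian closed form", {
  ch <- gaussian_chrom(c(5, 5.6), c(100, 100), sigma = 0.05)
  pk <- detect_peaks(ch, min_height = 1, baseline = 0)
  # Rs = 2 * 0.6 / (8 * 0.05) = 3.0
  expect_equal(resolution(pk[1, ], pk[2, ]), 3.0, tolerance = 0.02)
  # co-eluting identical peaks
  same <- pk[1, ]
  expect_equal(resolution(same, same), 0)
  # linear in the apex separation at fixed widths
  ch2 <- gaussian_chrom(c(5, 6.2), c(100, 100), sigma = 0.05)
  pk2 <- detect_peaks(ch2, min_height = 1, baseline = 0)
  expect_equal(resolution(pk2[1, ], pk2[2, ]), 6.0, tolerance = 0.05)
  expect_error(resolution(pk[2, ], pk[1, ]), "elute")
})

test_that("relative retention times are ratios to the reference peak", {
  pk <- data.frame(apex_time = c(2.628, 12.0, 18.648),
                   assigned_id = c("1", "11", "17"),
                   stringsAsFactors = FALSE)
  rrt <- compute_rrt(pk, "11")
  expect_identical(rrt[["11"]], 1)
  expect_equal(rrt[["1"]], 0.219, tolerance = 1e-4)
  # uniform time rescaling leaves every RRT unchanged
  pk2 <- pk
  pk2$apex_time <- pk$apex_time * 1.37
  expect_equal(compute_rrt(pk2, "11"), rrt)
  expect_error(compute_rrt(pk[1:2, ][-2, ], "11"), "reference")
})

test_that("template matching is a closed loop on generated batches", {
  sim <- simulate_batch_set(seed = 4)
  tmpl <- chrom_template()
  peaks <- list()
  for (b in c("HN1", "HN2", "HB1")) {
    tb <- sim$truth[sim$truth$batch == b, ]
    peaks[[b]] <- detect_peaks(simulate_chromatogram(tb, tmpl),
                               min_height = 1)
  }
  matched <- match_peaks(peaks, default_match_template())
  expect_false(anyNA(matched$areas))
  expect_identical(nrow(attr(matched, "unmatched")), 0L)
})

test_that("a deleted peak is reported missing, not mismatched", {
  sim <- simulate_batch_set(seed = 4)
  tb <- sim$truth[sim$truth$batch == "HN1" & sim$truth$peak_id != "7", ]
  pk <- detect_peaks(simulate_chromatogram(tb, chrom_template()),
                     min_height = 1)
  matched <- match_peaks(list(HN1 = pk), default_match_template())
  expect_identical(sum(!is.na(matched$areas)), 17L)
  um <- attr(matched, "unmatched")
  expect_identical(um$peak, "7")
})

test_that("a uniform retention shift cancels out in RRT matching", {
  sim <- simulate_batch_set(seed = 4)
  tmpl <- chrom_template()
  tmpl_shift <- chrom_template(retention_times = tmpl$retention_times * 1.03)
  tb <- sim$truth[sim$truth$batch == "HB2", ]
  pk <- detect_peaks(simulate_chromatogram(tb, tmpl_shift), min_height = 1)
  # reference window is relative, so the +3% shift still finds peak 11
  matched <- match_peaks(list(HB2 = pk), default_match_template())
  expect_false(anyNA(matched$areas))
})

test_that("cosine similarity has the expected fixed points", {
  x <- c(1, 2, 3, 4)
  expect_equal(similarity(x, x), 1)
  expect_equal(similarity(x, 3 * x), 1)
  expect_equal(similarity(c(1, 0), c(0, 1)), 0)
  expect_error(similarity(c(0, 0), x[1:2]), "zero")
  expect_error(similarity(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("fingerprints stay close to their region's mean profile", {
  sim <- simulate_batch_set(default_region_effects(cv = 0), noise_cv = 0,
                            seed = 3)
  areas <- sim$table$areas
  for (r in c("HN", "HB")) {
    rows <- areas[sim$table$regions == r, , drop = FALSE]
    ref <- colMeans(rows)
    sims <- apply(rows, 1L, similarity, reference = ref)
    expect_true(all(sims >= 0.99))
  }
  # under the default noise the all-batch similarity stays high even
  # though the two region profiles genuinely differ
  noisy <- simulate_batch_set(seed = 3)
  expect_true(all(similarity_to_mean(noisy$table) >= 0.95))
})
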