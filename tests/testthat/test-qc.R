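test_that("timing deviations are measured intervals minus the nominal cycle", {
  expect_equal(timing_deviations(c(0, 1200, 2400))$deviation_s, c(0, 0))
  expect_equal(timing_deviations(c(0, 1215))$deviation_s, 15)
  drift <- generate_timestamps(100, cumulative_drift_per_cycle = 0.05,
                               per_cycle_jitter_sd = 0.2, seed = 4)
  td <- timing_deviations(drift[drift$well == 1 & drift$channel == "trans", ])
  expect_equal(mean(td$deviation_s), 0.05, tolerance = 0.02)
})

test_that("noise is the population SD outside the ROI", {
  f <- matrix(5, 20, 20)
  expect_equal(noise_level(f), 0)
  set.seed(33)
  g <- matrix(rnorm(1e4, 50, 2), 100, 100)
  expect_equal(noise_level(g), 2, tolerance = 0.03)
  full <- matrix(TRUE, 4, 4)
  expect_error(noise_level(matrix(1, 4, 4), full), "empty outside")
})

test_that("signal and S/N follow the k-times-noise extraction rule", {
  out <- signal_and_snr(c(0.5, 0.5, 4, 6), noise = 1, k = 3)
  expect_equal(out$signal, 5)
  expect_equal(out$snr, 5)
  none <- signal_and_snr(c(0.5, 1, 2), noise = 1, k = 3)
  expect_true(is.na(none$signal))
  expect_error(signal_and_snr(c(1, 2), noise = 0), "undefined S/N")
  # min_run drops isolated excursions but keeps contiguous regions
  prof <- c(0, 9, 0, 0, 8, 8, 8, 0)
  expect_equal(signal_and_snr(prof, 1, k = 3, min_run = 3)$signal, 8)
})

test_that("snr crossing matches the rendered amplitude crossing within one cycle", {
  sim <- ideal_scene(
    width = 192, height = 160, n_cycles = 16, r_max = 45, growth_rate = 0.4,
    channels = c("trans", "green"), seed = 17,
    reporters = reporter_model(noise_sd = 2, vignette_strength = 0,
                               jitter_sd = 0, green_amplitude = 30,
                               green_decline_onset = 99,
                               fluor_background = 0))
  green <- subtract_reference(scene_stack(sim, 1, "green"))
  mid <- (160 + 1) / 2
  snr <- vapply(green$frames, function(f) {
    p <- line_profile(f, c(mid, 64), c(mid, 192))
    signal_and_snr(p, noise = 2, k = 3, min_run = 3)$snr
  }, numeric(1))
  crossing <- which(!is.na(snr) & snr >= 3)[1]
  gt_cross <- which(sim$ground_truth$green_level > 6)[1]
  expect_lte(abs(crossing - gt_cross), 1)
})

test_that("coefficients of variation use the population SD in percent", {
  expect_equal(cv_stats(rep(7, 10))$temporal, 0)
  expect_equal(cv_stats(c(90, 110))$temporal, 10)
  expect_warning(out <- cv_stats(c(-1, 1))$temporal, "mean is zero")
  expect_true(is.na(out))
  m <- rbind(c(90, 5), c(110, 5))
  cs <- cv_stats(m)
  expect_equal(cs$temporal, c(10, 0))   # per position over time
  expect_equal(length(cs$spatial), 2)   # per time point across positions
})

test_that("LOD follows factor x blank SD over the calibration slope", {
  cal <- tibble::tibble(
    concentration = rep(c(0, 1e-6, 2e-6, 4e-6), each = 3),
    intensity = c(9.8, 10.0, 10.2, rep(0, 9)))
  cal$intensity[4:12] <- 10 + 1e6 * cal$concentration[4:12]
  out <- lod_estimate(cal)
  expect_equal(out$slope, 1e6, tolerance = 1e-6)
  expect_equal(out$lod, 5 * pop_sd_oracle(c(9.8, 10, 10.2)) / 1e6)
  exact <- generate_calibration_series(blank_sd = 0, slope = 1e6)
  expect_equal(lod_estimate(exact)$lod, 0)
})

test_that("Monte-Carlo LOD recovers the closed form 5 sigma / m within 15%", {
  true_lod <- 5 * 2 / 8.3e8
  lods <- vapply(1:100, function(s) {
    cal <- generate_calibration_series(blank_sd = 2, slope = 8.3e8,
                                       replicates = 12, seed = s)
    lod_estimate(cal)$lod
  }, numeric(1))
  expect_lt(abs(mean(lods) - true_lod) / true_lod, 0.15)
})

test_that("Laplacian focus variance ranks sharpness and vanishes on flat frames", {
  expect_equal(focus_metric(matrix(100, 20, 20)), 0)
  fm <- vapply(c(0, 1, 2, 4), function(s)
    focus_metric(generate_usaf_target(groups = 0, pixel_size = 0.05,
                                      blur_sd = s)$frame),
    numeric(1))
  expect_true(all(diff(fm) < 0))   # strictly decreasing with blur
})

test_that("Michelson contrast handles the limiting cases", {
  prof <- rep(c(100, 200), 5)[-1]
  expect_equal(michelson_contrast(c(150, prof, 150)), 1 / 3)
  expect_equal(michelson_contrast(rep(80, 10)), 0)
  expect_equal(michelson_contrast(c(100, rep(c(0, 200), 4), 100)), 1)
})

test_that("usaf element frequencies follow 2^(group + (element-1)/6)", {
  expect_equal(usaf_frequency(0, 1), 1)
  expect_equal(round(usaf_frequency(2, 6), 2), 7.13)
  expect_equal(usaf_frequency(1, 2), 2^(7 / 6))
  grid <- expand.grid(g = -2:7, e = 1:6)
  f <- usaf_frequency(grid$g, grid$e)
  expect_true(all(diff(sort(f)) > 0))   # all 60 frequencies distinct, ordered
})

test_that("resolution scan returns the coarser neighbour of the contrast crossing", {
  t <- generate_usaf_target(groups = 0:2, pixel_size = 0.02, blur_sd = 5)
  res <- resolution_estimate(t$frame, t$elements)
  ct <- dplyr::arrange(res$contrasts, freq_lp_mm)
  first_fail <- which(ct$contrast < 0.10)[1]
  expect_equal(res$freq_lp_mm, ct$freq_lp_mm[first_fail - 1])
  expect_equal(res$spacing_um, 1000 / res$freq_lp_mm)
  sharp <- generate_usaf_target(groups = 0:2, pixel_size = 0.02, blur_sd = 0)
  res0 <- resolution_estimate(sharp$frame, sharp$elements)
  expect_equal(res0$group, 2)
  expect_equal(res0$element, 6)   # finest rendered element passes unblurred
})

test_that("uniformity CV matches the direct formula on a linear vignette ramp", {
  d <- generate_alignment_disk(vignette_strength = 0.2, intensity = 180,
                               disk_radius = 150, hole_radius = 15)
  cv <- uniformity_cv(d$frame, d$center, d$hole_radius, d$disk_radius,
                      window = 55)
  dist <- seq(15 + 5, 15 + 5 + 54)
  expected <- round(180 * (1 - 0.2 * dist / 150))
  oracle <- 100 * pop_sd_oracle(expected) / mean(expected)
  for (v in cv$cv_pct) expect_equal(v, oracle, tolerance = 0.05)
  expect_error(
    uniformity_cv(d$frame, d$center, d$hole_radius, d$disk_radius,
                  window = 200),
    "not clear of hole/edge")
})
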