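test_that("biomass proxy and fluorescence intensity follow the inner-outer arithmetic", {
  mask <- matrix(FALSE, 30, 30); mask[1:25, 1:20] <- TRUE
  roi <- roi_result(mask, 500, 100, 0)
  expect_equal(biomass_proxy(roi), 50000)
  flat <- roi_result(mask, 500, 42, 42)
  expect_equal(biomass_proxy(flat), 0)
  fl <- roi_result(mask[1:10, 1:10] | TRUE, 100, 30, 10)
  expect_equal(fluorescence_intensity(fl), 2000)
  eq <- roi_result(mask[1:10, 1:10] | TRUE, 100, 5, 5)
  expect_equal(fluorescence_intensity(eq), 0)
  expect_warning(neg <- fluorescence_intensity(
    roi_result(mask[1:10, 1:10] | TRUE, 100, 5, 9)), "negative")
  expect_equal(neg, -400)
})

test_that("biomass proxy is invariant to a constant frame offset", {
  mask <- disc_frame(40, 40, 8, 1) > 0
  f <- disc_frame(40, 40, 8, 60, background = 10)
  r1 <- extract_roi(mask, f)
  r2 <- extract_roi(mask, f + 37)
  expect_equal(biomass_proxy(r1), biomass_proxy(r2))
})

test_that("normalized fluorescence handles zero and missing biomass", {
  expect_equal(normalized_fluorescence(5000, 50000), 0.1)
  expect_equal(normalized_fluorescence(0, 50000), 0)
  expect_true(is.na(normalized_fluorescence(5000, 0)))
  expect_equal(normalized_fluorescence(c(10, 0, 5), c(100, 100, 0)),
               c(0.1, 0, NA))
})

test_that("growth onset finds the first stable increase after the minimum", {
  # hand enumeration: minimum at position 3 (first 5); from position 4 the
  # run 5 -> 7 -> 9 -> 12 gives three strict increases
  expect_equal(growth_onset(c(10, 8, 5, 5, 7, 9, 12, 15), k = 3), 4)
  expect_equal(growth_onset(c(1, 2, 3, 4, 5), k = 3), 1)
  expect_warning(on <- growth_onset(c(9, 7, 5, 3, 1), k = 3), "no growth")
  expect_true(is.na(on))
})

test_that("series alignment shifts times so the onset is zero", {
  s <- tibble::tibble(cycle = 0:7, time_s = (0:7) * 1200,
                      area_px = c(10, 8, 5, 5, 7, 9, 12, 15))
  onset <- growth_onset(s$area_px, k = 3)
  al <- align_series(s, onset)
  expect_equal(al$time_s[onset], 0)
  expect_equal(al$time_s[onset + 1], 1200)
  expect_true(all(al$time_s[seq_len(onset - 1)] < 0))
  expect_identical(align_series(s, 1)$time_s, s$time_s)
})

test_that("auc integrates from first detection by the trapezoid rule", {
  # hand trapezoid on the detected span [1, 2] of y = [0, 1, 2]: 1.5
  expect_equal(auc(c(0, 1, 2), 0:2), 1.5)
  expect_equal(auc(rep(1, 11), 0:10), 10)
  expect_equal(auc(rep(0, 5), 0:4), 0)
  expect_equal(auc(c(NA, NA, 2, 4), 0:3), 3)
})

test_that("fold-change matrix is the ratio of per-bin means", {
  base <- tidyr::expand_grid(strain = c("a", "b"), time_s = (0:5) * 1200) |>
    dplyr::mutate(value = 1 + time_s / 6000)
  fc <- fold_change_matrix(dplyr::mutate(base, value = value * 2), base)
  expect_true(all(fc == 2))
  fc1 <- fold_change_matrix(base, base)
  expect_true(all(fc1 == 1))
  zero <- dplyr::mutate(base, value = 0)
  fcz <- fold_change_matrix(base, zero)
  expect_true(all(is.na(fcz)))
})

test_that("noiseless scene recovers amplitude x area and reporter dynamics", {
  sim <- generate_stack(
    scene_config(frame_width = 256, frame_height = 192, wells = 1,
                 channels = c("trans", "green", "red"), n_cycles = 24,
                 seed = 11),
    growth_model(r_max = 60, growth_rate = 0.25, lag_cycles = 2,
                 edge_softness = 1),
    reporter_model(noise_sd = 0, vignette_strength = 0, jitter_sd = 0,
                   green_decline_onset = 10, green_rise_cycles = 4,
                   fluor_background = 0))
  s <- quantify_stacks(scene_stack(sim, 1, "trans"),
                       list(green = scene_stack(sim, 1, "green"),
                            red = scene_stack(sim, 1, "red")))
  n <- nrow(s)
  # biomass ~ inner_density x area at the mature disc
  expect_equal(s$biomass[n], 120 * s$area_px[n], tolerance = 0.02)
  # green integrated intensity peaks strictly before the endpoint...
  expect_lt(which.max(s$fluor_green), n)
  # ...while red never drops below 98% of its running maximum
  red <- s$fluor_red[!is.na(s$fluor_red)]
  expect_true(all(red >= cummax(red) * 0.98))
})

test_that("normalized green fluorescence recovers the programmed amplitude ratio", {
  amps <- c(20, 40, 60, 80, 100)
  norm_end <- vapply(amps, function(a) {
    sim <- ideal_scene(
      width = 192, height = 160, n_cycles = 14, r_max = 45,
      growth_rate = 0.35, seed = 7,
      reporters = reporter_model(noise_sd = 2, vignette_strength = 0,
                                 jitter_sd = 0, green_amplitude = a,
                                 green_decline_onset = 99,
                                 green_rise_cycles = 2,
                                 fluor_background = 0))
    s <- quantify_stacks(scene_stack(sim, 1, "trans"),
                         list(green = scene_stack(sim, 1, "green")))
    s$norm_green[nrow(s)]
  }, numeric(1))
  fit <- stats::lm(norm_end ~ I(amps / 120))
  expect_gte(summary(fit)$r.squared, 0.95)
})
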