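test_that("generators are bit-reproducible for a fixed seed", {
  a <- ideal_scene(width = 96, height = 80, n_cycles = 4, seed = 42,
                   reporters = reporter_model(noise_sd = 2, jitter_sd = 1))
  b <- ideal_scene(width = 96, height = 80, n_cycles = 4, seed = 42,
                   reporters = reporter_model(noise_sd = 2, jitter_sd = 1))
  expect_identical(a$stacks[["well1.trans"]]$frames,
                   b$stacks[["well1.trans"]]$frames)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(generate_timestamps(10, seed = 3, per_cycle_jitter_sd = 1),
                   generate_timestamps(10, seed = 3, per_cycle_jitter_sd = 1))
  expect_identical(generate_calibration_series(seed = 3),
                   generate_calibration_series(seed = 3))
})

test_that("a static noiseless scene renders identical frames at every cycle", {
  sim <- generate_stack(
    scene_config(frame_width = 96, frame_height = 80, wells = 1,
                 channels = c("trans", "green"), n_cycles = 5, seed = 1),
    growth_model(r0 = 20, r_max = 20, growth_rate = 0, lag_cycles = 0),
    reporter_model(noise_sd = 0, jitter_sd = 0, crosstalk_green_to_red = 0,
                   green_amplitude = 0, red_amplitude = 0))
  for (key in names(sim$stacks)) {
    frames <- sim$stacks[[key]]$frames
    for (f in frames[-1]) expect_identical(f, frames[[1]])
  }
})

test_that("rendered transillumination disc area matches pi r^2 (pixel-count oracle)", {
  # small pixel size puts the dish edge outside the frame, so the disc is
  # the only dark feature the raw pixel count can see
  sim <- ideal_scene(n_cycles = 16, r_max = 55, growth_rate = 0.25,
                     pixel_size = 0.05)
  gt <- sim$ground_truth
  frames <- sim$stacks[["well1.trans"]]$frames
  for (i in which(gt$radius_px >= 10)) {
    count <- sum(frames[[i]] < 200 - 120 / 2)   # background - density/2
    expect_lt(abs(count - pi * gt$radius_px[i]^2) / (pi * gt$radius_px[i]^2),
              0.05)
  }
})

test_that("red channel carries the configured green crosstalk fraction", {
  sim <- ideal_scene(
    n_cycles = 12, r_max = 50, growth_rate = 0.3,
    reporters = reporter_model(noise_sd = 0, vignette_strength = 0,
                               jitter_sd = 0, red_amplitude = 0,
                               crosstalk_green_to_red = 0.2,
                               green_decline_onset = 99,
                               fluor_background = 0))
  gt <- sim$ground_truth
  i <- which.max(gt$radius_px)
  g <- sim$stacks[["well1.green"]]$frames[[i]]
  r <- sim$stacks[["well1.red"]]$frames[[i]]
  inside <- disc_frame(192, 256, gt$radius_px[i] - 5, 1) > 0
  expect_lt(abs(mean(r[inside]) / mean(g[inside]) - 0.2), 0.02)
})

test_that("an over-large disc radius is rejected naming the cycle", {
  expect_error(
    generate_stack(
      scene_config(frame_width = 64, frame_height = 64, wells = 1,
                   channels = "trans", n_cycles = 5, seed = 1),
      growth_model(r_max = 200, growth_rate = 2, lag_cycles = 0),
      reporter_model(noise_sd = 0, jitter_sd = 0)),
    "cycle")
})

test_that("usaf target renders the nominal frequencies and blur kills fine contrast", {
  t0 <- generate_usaf_target(groups = 0, pixel_size = 0.05, blur_sd = 0)
  e1 <- t0$elements[t0$elements$element == 1, ]
  expect_equal(e1$freq_lp_mm, 1)            # 2^0
  expect_equal(e1$period_px, 20)            # 1 lp/mm at 0.05 mm/px
  prof <- colMeans(t0$frame[e1$row0:e1$row1, e1$col0:e1$col1])
  expect_equal(michelson_contrast(prof), 1) # bars at 0, field at 200
  blurred <- generate_usaf_target(groups = 0:2, pixel_size = 0.02,
                                  blur_sd = 10)
  res <- resolution_estimate(blurred$frame, blurred$elements)
  finest <- dplyr::slice_max(res$contrasts, freq_lp_mm)
  expect_lt(finest$contrast, 0.10)
  expect_error(generate_usaf_target(groups = 5, pixel_size = 0.05),
               "resolvable")
})

test_that("alignment disk gives a flat annulus without vignette", {
  d <- generate_alignment_disk(vignette_strength = 0, intensity = 180)
  cv <- uniformity_cv(d$frame, d$center, d$hole_radius, d$disk_radius)
  expect_equal(cv$cv_pct, rep(0, 4))
  # annulus pixels (clear of both rims) all equal the nominal intensity
  dd <- sqrt(outer((seq_len(384) - d$center[1])^2,
                   (seq_len(512) - d$center[2])^2, `+`))
  ann <- dd > d$hole_radius + 3 & dd < d$disk_radius - 3
  expect_true(all(d$frame[ann] == 180))
})

test_that("timestamp log obeys the schedule arithmetic", {
  ts <- generate_timestamps(5, interval = 1200)
  one <- ts[ts$well == 1 & ts$channel == "trans", ]
  expect_equal(diff(one$epoch_s), rep(1200, 4))
  drift <- generate_timestamps(289, interval = 1200,
                               cumulative_drift_per_cycle = 0.05)
  # 0.05 s/cycle accumulates to 14.4 s at cycle 288
  expect_equal(drift$epoch_s[drift$cycle == 288][1] - 288 * 1200, 14.4)
  expect_equal(nrow(generate_timestamps(0)), 0)
})

test_that("calibration series is linear in concentration with exact blanks", {
  cal <- generate_calibration_series(blank_sd = 0, blank_mean = 10,
                                     slope = 1e6)
  expect_equal(cal$intensity, 10 + 1e6 * cal$concentration)
  noisy <- generate_calibration_series(blank_sd = 2, blank_mean = 10,
                                       replicates = 50, seed = 9)
  blanks <- noisy$intensity[noisy$concentration == 0]
  se <- 2 / sqrt(length(blanks))
  expect_lt(abs(mean(blanks) - 10), 3 * se)
})
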