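test_that("line profiles interpolate bilinearly and are linear in the frame", {
  f <- matrix(seq(0, 255, length.out = 20 * 30), 20, 30)
  row10 <- line_profile(f, c(10, 1), c(10, 30), n_samples = 30)
  expect_equal(row10, f[10, ])
  const <- line_profile(matrix(42, 10, 10), c(2, 2), c(9, 9))
  expect_equal(const, rep(42, length(const)))
  p <- line_profile(f, c(3.3, 2.1), c(17.8, 28.4), n_samples = 50)
  q <- line_profile(255 - f, c(3.3, 2.1), c(17.8, 28.4), n_samples = 50)
  expect_equal(p + q, rep(255, 50))
  expect_error(line_profile(f, c(0, 1), c(5, 5)), "outside")
})

test_that("a static stack yields an all-zero kymograph", {
  f <- matrix(runif(300, 0, 255), 15, 20)
  st <- lapse_stack(rep(list(f), 6), well = 1, channel = "trans")
  km <- build_kymograph(st, c(8, 1), c(8, 20),
                        mode = "inverted_transillumination")
  expect_true(all(km$values == 0))
  expect_equal(nrow(km$values), 6)
  expect_true(all(km$values[1, ] == 0))
})

test_that("kymograph edge column advances with the ground-truth radius", {
  sim <- ideal_scene(n_cycles = 14, r_max = 55, growth_rate = 0.3,
                     channels = "trans")
  st <- scene_stack(sim, 1, "trans")
  mid <- (192 + 1) / 2
  km <- build_kymograph(st, c(mid, 1), c(mid, 128),
                        mode = "inverted_transillumination")
  gt <- sim$ground_truth
  centre_col <- (256 + 1) / 2
  for (i in which(gt$radius_px >= 15)) {
    # left disc boundary along the row: centre minus radius
    edge <- detect_edge(km$values[i, ])
    expect_lt(abs(edge - (centre_col - gt$radius_px[i])), 4,
              label = sprintf("cycle %d edge", gt$cycle[i]))
  }
})

test_that("detect_edge finds the step with the rising-index convention", {
  prof <- c(rep(0, 119), rep(200, 30))
  expect_equal(detect_edge(prof), 120)
  expect_error(detect_edge(rep(5, 50)), "no edge")
})

test_that("detect_edge locates a noisy step within one pixel in >= 95% of trials", {
  set.seed(202)
  hits <- 0
  for (i in 1:200) {
    true_pos <- sample(40:80, 1)
    prof <- c(rep(0, true_pos - 1), rep(200, 120 - true_pos + 1)) +
      rnorm(120, sd = 2)
    if (abs(detect_edge(prof) - true_pos) <= 1) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("injected rigid shifts are recovered as positional deviations", {
  shifts <- cbind(0, c(0, 2, -3, 7, 0, -10))   # lateral drift along the line
  sim <- generate_stack(
    scene_config(frame_width = 512, frame_height = 384, wells = 1,
                 channels = "epi", n_cycles = 6, seed = 5),
    growth_model(r0 = 0, r_max = 0, inner_density = 0),
    reporter_model(noise_sd = 0, vignette_strength = 0, jitter_sd = 0),
    jitter_offsets = shifts)
  st <- scene_stack(sim, 1, "epi")
  mid <- (384 + 1) / 2
  km <- build_kymograph(st, c(mid, 5), c(mid, 150),
                        mode = "inverted_transillumination")
  pd <- positional_deviation(km, pixel_size = 0.043)
  expect_equal(pd$deviation_px, shifts[, 2])
  # px -> mm conversion: 7 px at 0.043 mm/px is 0.301 mm
  expect_equal(pd$deviation_mm[4], 0.301)
})

test_that("kymograph CSV export is value-preserving", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- matrix(rnorm(60), 6, 10)
  write_kymograph_csv(m, path)
  expect_equal(read_kymograph_csv(path), m, ignore_attr = TRUE)
})

test_that("display normalization maps to [0, 1] without touching raw values", {
  m <- matrix(c(10, 20, 30, 40), 2, 2)
  n <- normalize_kymograph(m)
  expect_equal(range(n), c(0, 1))
  expect_equal(normalize_kymograph(matrix(5, 3, 3)), matrix(0, 3, 3))
})
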