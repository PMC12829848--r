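# shared fixture builders: everything is generated in code at test time

# a small ideal-optics growth scene (no noise, vignette or jitter)
ideal_scene <- function(width = 256, height = 192, n_cycles = 20,
                        channels = c("trans", "green", "red"), seed = 11,
                        r_max = 60, growth_rate = 0.2, lag = 2,
                        reporters = NULL, pixel_size = NULL) {
  generate_stack(
    scene_config(frame_width = width, frame_height = height, wells = 1,
                 channels = channels, n_cycles = n_cycles, seed = seed,
                 pixel_size = pixel_size),
    growth_model(r_max = r_max, growth_rate = growth_rate, lag_cycles = lag),
    reporters %||% reporter_model(noise_sd = 0, vignette_strength = 0,
                                  jitter_sd = 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hard-edged disc frame: `amplitude` inside radius r, `background` outside
disc_frame <- function(h, w, r, amplitude, background = 0,
                       center = c((h + 1) / 2, (w + 1) / 2)) {
  d <- sqrt(outer((seq_len(h) - center[1])^2,
                  (seq_len(w) - center[2])^2, `+`))
  matrix(background + (d <= r) * amplitude, h, w)
}

pop_sd_oracle <- function(x) sqrt(mean((x - mean(x))^2))

# brute-force Otsu oracle: exhaustive search over all 255 cut points,
# maximizing between-class variance; ties resolve to the lowest threshold
otsu_brute_force <- function(frame) {
  v <- floor(as.numeric(frame))
  n <- length(v)
  best_t <- NA_integer_; best_bcv <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best_bcv + 1e-9) { best_bcv <- bcv; best_t <- t }
  }
  best_t
}
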