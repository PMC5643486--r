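# Independent oracle for the dye-transit curve model and its indices.
# Written from the model definition, not via the package's own code
# paths: a 1 ms fine-grid evaluation with linear-interpolation crossing
# detection.

oracle_curve <- function(t, t0, alpha, beta, amplitude, leak_frac = 0,
                         tau_leak = 10, baseline = 0) {
  s <- t - t0
  g <- ifelse(s > 0, (s / (alpha * beta))^alpha * exp(alpha - s / beta), 0)
  lk <- ifelse(s > 0, leak_frac * amplitude * (1 - exp(-s / tau_leak)), 0)
  baseline + amplitude * g + lk
}

# Fine-grid (1 ms) oracle for half-rise, half-fall, offset of the
# noiseless continuous curve, normalized to % of peak-above-baseline.
oracle_dynamics <- function(t0, alpha, beta, amplitude = 100, leak_frac = 0,
                            tau_leak = 10, baseline = 0, t_end = 55,
                            plateau_window = c(50, 55)) {
  tg <- seq(0, t_end, by = 0.001)
  y <- oracle_curve(tg, t0, alpha, beta, amplitude, leak_frac, tau_leak,
                    baseline)
  ipk <- which.max(y)
  peak <- y[ipk]
  v <- 100 * (y - baseline) / (peak - baseline)
  cross_up <- which(v[seq_len(ipk)] >= 50)[1]
  half_rise <- if (cross_up == 1) tg[1] else {
    tg[cross_up - 1] + (50 - v[cross_up - 1]) /
      (v[cross_up] - v[cross_up - 1]) * 0.001
  }
  below <- which(v[(ipk + 1):length(v)] < 50)
  half_fall <- if (!length(below)) NA_real_ else {
    j <- ipk + below[1]
    tg[j - 1] + (v[j - 1] - 50) / (v[j - 1] - v[j]) * 0.001
  }
  pidx <- tg >= plateau_window[1] & tg <= plateau_window[2]
  list(half_rise = half_rise, half_fall = half_fall,
       offset = mean(v[pidx]), peak_time = tg[ipk])
}

# Small, fast scene configurations reused across tests.
tiny_scene <- function(...) {
  scene_config(layout = "retina", size = 32, duration = 20, ...)
}

# Sampled raw curve on the standard 30 fps clock (times relative to
# bolus onset, 5 s pre-bolus baseline).
sampled_curve <- function(params, duration = 60, frame_rate = 30,
                          bolus_onset = 5) {
  tt <- (seq_len(duration * frame_rate) - 1) / frame_rate - bolus_onset
  list(times = tt, raw = simulate_pixel_curve(params, tt))
}
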