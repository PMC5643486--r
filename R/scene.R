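#' Per-class curve-parameter distribution
#'
#' Describes how [curve_params()] are drawn for the pixels of one vessel
#' compartment: independent Gaussian draws for arrival time and leak
#' fraction, multiplicative Gaussian jitter for time scale, amplitude and
#' baseline. Values are clipped to their valid ranges.
#'
#' @param t0_mean,t0_sd arrival-time mean and sd (s after infusion onset).
#' @param alpha gamma-variate shape (shared by the class).
#' @param beta_mean,beta_rsd time-scale mean (s) and relative sd.
#' @param amplitude_mean,amplitude_rsd amplitude mean and relative sd.
#' @param leak_mean,leak_sd leakage-fraction mean and sd.
#' @param tau_leak leakage time constant (s).
#' @param baseline_mean,baseline_rsd baseline mean and relative sd.
#' @return A list of class `class_curve_dist`.
#' @export
class_curve_dist <- function(t0_mean, t0_sd = 0.2, alpha = 3,
                             beta_mean = 1, beta_rsd = 0.05,
                             amplitude_mean = 100, amplitude_rsd = 0.10,
                             leak_mean = 0, leak_sd = 0.02, tau_leak = 10,
                             baseline_mean = 20, baseline_rsd = 0.05) {
  structure(list(t0_mean = t0_mean, t0_sd = t0_sd, alpha = alpha,
                 beta_mean = beta_mean, beta_rsd = beta_rsd,
                 amplitude_mean = amplitude_mean, amplitude_rsd = amplitude_rsd,
                 leak_mean = leak_mean, leak_sd = leak_sd, tau_leak = tau_leak,
                 baseline_mean = baseline_mean, baseline_rsd = baseline_rsd),
            class = "class_curve_dist")
}

#' Default per-class curve distributions for a layout
#'
#' @param layout `"retina"` or `"cortex"`.
#' @return Named list of [class_curve_dist()] for `artery`, `vein`,
#'   `capillary` and `background`.
#' @export
# Default class distributions. Arrival times, time scales and leak
# fractions are calibrated so the noiseless class medians approximate the
# normal in-vivo values (retinal artery/capillary/vein half-rise near
# 6.5/6.7/7.4 s, cortical near 5.6/5.8/6.2 s; cortical offsets ~35-41%,
# retinal ~10-16%): arteries fill first, veins last, cortical transit is
# faster than retinal, and the cortical extravascular compartment is
# bright and leaky while retinal pigment keeps the background dim.
default_scene_classes <- function(layout) {
  if (layout == "retina") {
    list(
      artery = class_curve_dist(t0_mean = 5.16, beta_mean = 1.00,
                                amplitude_mean = 150, leak_mean = 0.131,
                                baseline_mean = 40),
      vein = class_curve_dist(t0_mean = 5.68, t0_sd = 0.25, beta_mean = 1.27,
                              amplitude_mean = 140, leak_mean = 0.168,
                              baseline_mean = 40),
      capillary = class_curve_dist(t0_mean = 5.38, beta_mean = 0.95,
                                   amplitude_mean = 60, leak_mean = 0.105,
                                   baseline_mean = 24),
      background = class_curve_dist(t0_mean = 5.5, beta_mean = 1.2,
                                    amplitude_mean = 3, leak_mean = 0,
                                    leak_sd = 0, baseline_mean = 12)
    )
  } else {
    list(
      artery = class_curve_dist(t0_mean = 4.21, beta_mean = 0.99,
                                amplitude_mean = 150, leak_mean = 0.385,
                                baseline_mean = 45),
      vein = class_curve_dist(t0_mean = 4.73, t0_sd = 0.25, beta_mean = 1.06,
                              amplitude_mean = 140, leak_mean = 0.374,
                              baseline_mean = 45),
      capillary = class_curve_dist(t0_mean = 4.43, beta_mean = 0.98,
                                   amplitude_mean = 80, leak_mean = 0.468,
                                   baseline_mean = 30),
      background = class_curve_dist(t0_mean = 5.0, beta_mean = 1.0,
                                    amplitude_mean = 0.5, leak_mean = 0,
                                    leak_sd = 0, baseline_mean = 5)
    )
  }
}

#' Configuration of a synthetic angiography scene
#'
#' Defines the geometry, acquisition parameters, per-class curve
#' distributions, noise, motion and seed of a synthetic dye-transit video.
#' The acquisition defaults mirror a standard rodent video angiography
#' protocol: 30 frames/s for 60 s with the fluorescein bolus delivered 5 s
#' after recording onset.
#'
#' @param layout `"retina"` (spoke pattern of alternating artery/vein
#'   radial vessels around a central disc, dim pigment-blocked background)
#'   or `"cortex"` (fewer, larger curvilinear vessels over a bright
#'   diffuse extravascular compartment).
#' @param size image side length in pixels (square frames).
#' @param frame_rate frames per second.
#' @param duration recording length (s).
#' @param bolus_onset infusion onset, seconds after recording start.
#' @param classes named list of [class_curve_dist()] for `artery`, `vein`,
#'   `capillary` and `background`; defaults depend on `layout`.
#' @param noise_sigma additive Gaussian noise sd (intensity units).
#' @param noise_prop signal-proportional noise coefficient (sd =
#'   `noise_prop` times the noiseless intensity).
#' @param motion_amplitude maximum rigid translation (pixels) of the
#'   smooth random-walk motion; 0 disables motion.
#' @param bit_depth 8 or 16 for camera quantization with saturation, or
#'   `NA` for an unquantized floating-point video.
#' @param seed integer seed; all randomness in [render_video()] flows
#'   from it.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(layout = c("retina", "cortex"), size = 64,
                         frame_rate = 30, duration = 60, bolus_onset = 5,
                         classes = NULL, noise_sigma = 2, noise_prop = 0.01,
                         motion_amplitude = 0, bit_depth = 8, seed = 1) {
  layout <- match.arg(layout)
  if (is.null(classes)) classes <- default_scene_classes(layout)
  stopifnot(setequal(names(classes), c("artery", "vein", "capillary", "background")),
            size >= 16, frame_rate > 0, duration > 0, bolus_onset >= 0)
  if (!(classes$artery$t0_mean < classes$capillary$t0_mean &&
        classes$capillary$t0_mean < classes$vein$t0_mean))
    stop("class arrival times must be ordered artery < capillary < vein",
         call. = FALSE)
  if (!is.na(bit_depth) && !bit_depth %in% c(8, 16))
    stop("`bit_depth` must be 8, 16 or NA", call. = FALSE)
  structure(list(layout = layout, size = as.integer(size),
                 frame_rate = frame_rate, duration = duration,
                 bolus_onset = bolus_onset, classes = classes,
                 noise_sigma = noise_sigma, noise_prop = noise_prop,
                 motion_amplitude = motion_amplitude, bit_depth = bit_depth,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("Synthetic angiography scene: %s, %dx%d px, %g fps, %g s (bolus at %g s)\n",
              x$layout, x$size, x$size, x$frame_rate, x$duration, x$bolus_onset))
  cat(sprintf("  noise sigma %g (+%g propor.), motion %g px, bit depth %s, seed %d\n",
              x$noise_sigma, x$noise_prop, x$motion_amplitude,
              ifelse(is.na(x$bit_depth), "float", x$bit_depth), x$seed))
  invisible(x)
}

# Label codes used throughout: 0 background, 1 artery, 2 vein,
# 3 capillary/extravascular.
label_levels <- function() {
  c(background = 0L, artery = 1L, vein = 2L, capillary_extravascular = 3L)
}

# Retina: central disc, 8 alternating artery/vein spokes, capillary bed
# elsewhere inside the circular field of view.
layout_labels_retina <- function(n) {
  c0 <- (n + 1) / 2
  rr <- matrix(rep(seq_len(n), n), n, n)
  cc <- t(rr)
  r <- sqrt((rr - c0)^2 + (cc - c0)^2)
  theta <- atan2(rr - c0, cc - c0)
  fov <- 0.48 * n; disc <- 0.10 * n
  w <- max(2, round(n / 20))
  lab <- matrix(0L, n, n)
  inside <- r > disc & r <= fov
  lab[inside] <- 3L
  for (k in 0:7) {
    ang <- k * pi / 4
    d <- abs(atan2(sin(theta - ang), cos(theta - ang)))
    on_spoke <- inside & (r * d <= w / 2)
    lab[on_spoke] <- if (k %% 2 == 0) 1L else 2L
  }
  lab
}

# Cortex: two large curvilinear vessels through a circular cranial
# window whose interior is diffuse extravascular tissue.
layout_labels_cortex <- function(n) {
  c0 <- (n + 1) / 2
  rr <- matrix(rep(seq_len(n), n), n, n)
  cc <- t(rr)
  r <- sqrt((rr - c0)^2 + (cc - c0)^2)
  inside <- r <= 0.49 * n
  lab <- matrix(0L, n, n)
  lab[inside] <- 3L
  w <- max(3, round(n / 10))
  art <- n / 3 + 0.08 * n * sin(2 * pi * rr / n)
  ven <- 2 * n / 3 + 0.08 * n * cos(2 * pi * rr / n)
  lab[inside & abs(cc - art) <= w / 2] <- 1L
  lab[inside & abs(cc - ven) <= w / 2] <- 2L
  lab
}

#' Vessel label map of a scene layout
#'
#' @param config a [scene_config()].
#' @return Integer matrix of labels (0 background, 1 artery, 2 vein,
#'   3 capillary/extravascular).
#' @export
scene_labels <- function(config) {
  switch(config$layout,
         retina = layout_labels_retina(config$size),
         cortex = layout_labels_cortex(config$size))
}

# Draw per-pixel curve parameters given a label map; returns a list of
# size x size matrices, one per curve_params field.
draw_pixel_params <- function(config, labels) {
  n <- config$size
  fields <- c("t0", "alpha", "beta", "amplitude", "leak_frac", "tau_leak",
              "baseline")
  out <- stats::setNames(lapply(fields, function(f) matrix(NA_real_, n, n)),
                         fields)
  codes <- label_levels()
  for (cls in names(codes)) {
    idx <- which(labels == codes[[cls]])
    if (!length(idx)) next
    d <- config$classes[[switch(cls, capillary_extravascular = "capillary", cls)]]
    m <- length(idx)
    out$t0[idx] <- stats::rnorm(m, d$t0_mean, d$t0_sd)
    out$alpha[idx] <- d$alpha
    out$beta[idx] <- pmax(0.1, d$beta_mean * stats::rnorm(m, 1, d$beta_rsd))
    out$amplitude[idx] <- pmax(1e-3, d$amplitude_mean * stats::rnorm(m, 1, d$amplitude_rsd))
    out$leak_frac[idx] <- pmin(0.95, pmax(0, stats::rnorm(m, d$leak_mean, d$leak_sd)))
    out$tau_leak[idx] <- d$tau_leak
    out$baseline[idx] <- pmax(0, d$baseline_mean * stats::rnorm(m, 1, d$baseline_rsd))
  }
  # arrival cannot precede the infusion
  out$t0 <- pmax(out$t0, 0.1)
  out
}

# Smooth random-walk translation with max |shift| scaled to `amplitude`.
motion_path <- function(n_frames, amplitude, frame_rate) {
  if (amplitude <= 0) return(data.frame(frame = seq_len(n_frames), dx = 0, dy = 0))
  smooth_walk <- function() {
    steps <- stats::rnorm(n_frames)
    w <- max(3, round(frame_rate / 2))
    walk <- stats::filter(cumsum(steps), rep(1 / w, w), sides = 2)
    walk[is.na(walk)] <- 0
    walk <- walk - walk[1]
    m <- max(abs(walk))
    if (m > 0) walk * amplitude / m else walk
  }
  data.frame(frame = seq_len(n_frames), dx = as.numeric(smooth_walk()),
             dy = as.numeric(smooth_walk()))
}

# Translate a matrix by (dx, dy) pixels via the Fourier shift theorem
# (exact for the discrete spectrum, cyclic boundary). Used by the
# renderer so simulated motion introduces no interpolation blur; the
# scene layouts keep their borders dark so wrap-around is invisible.
translate_fourier <- function(m, dx, dy) {
  if (dx == 0 && dy == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  kr <- fft_freqs(nr); kc <- fft_freqs(nc)
  ph <- exp(-2i * pi * (outer(kr, rep(1, nc)) * dy / nr +
                          outer(rep(1, nr), kc) * dx / nc))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (nr * nc)
}

# Translate a matrix by (dx, dy) pixels (content moves +dx columns,
# +dy rows) with bilinear interpolation and edge replication.
translate_bilinear <- function(m, dx, dy) {
  if (dx == 0 && dy == 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  src_r <- seq_len(nr) - dy
  src_c <- seq_len(nc) - dx
  r0 <- pmin(pmax(floor(src_r), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(src_c), 1), nc); c1 <- pmin(c0 + 1, nc)
  fr <- pmin(pmax(src_r - floor(src_r), 0), 1)
  fc <- pmin(pmax(src_c - floor(src_c), 0), 1)
  fr[src_r < 1 | src_r > nr] <- 0
  fc[src_c < 1 | src_c > nc] <- 0
  a <- m[r0, c0, drop = FALSE]; b <- m[r1, c0, drop = FALSE]
  d <- m[r0, c1, drop = FALSE]; e <- m[r1, c1, drop = FALSE]
  FR <- matrix(fr, nr, nc)
  FC <- matrix(fc, nr, nc, byrow = TRUE)
  (a * (1 - FR) + b * FR) * (1 - FC) + (d * (1 - FR) + e * FR) * FC
}

#' Render a synthetic angiography video with ground truth
#'
#' Draws per-pixel transit-curve parameters from the scene's class
#' distributions, evaluates the noiseless curves on the frame clock,
#' applies rigid motion, camera noise and optional quantization, and
#' returns both the video and the complete ground truth (label map,
#' per-pixel parameters, applied shifts, and the analytic half-rise /
#' half-fall / offset of every non-background pixel's noiseless curve).
#'
#' @param config a [scene_config()].
#' @param animal_id identifier stored in the resulting stack.
#' @param analytic_truth if `TRUE` (default), compute the analytic
#'   dynamics maps of the noiseless curves (root finding per pixel).
#' @return A list with elements `stack` (a [video_stack()]) and `truth`
#'   (class `ground_truth`: `labels`, `params`, `shifts`, `dynamics`,
#'   `saturated`).
#' @export
render_video <- function(config, animal_id = "sim", analytic_truth = TRUE) {
  stopifnot(inherits(config, "scene_config"))
  if (config$duration <= config$bolus_onset)
    stop("`duration` must exceed `bolus_onset`", call. = FALSE)
  set.seed(config$seed)
  n <- config$size
  n_frames <- round(config$duration * config$frame_rate)
  labels <- scene_labels(config)
  par_maps <- draw_pixel_params(config, labels)
  shifts <- motion_path(n_frames, config$motion_amplitude, config$frame_rate)

  t_rel <- (seq_len(n_frames) - 1) / config$frame_rate - config$bolus_onset
  P <- n * n
  S <- outer(t_rel, as.vector(par_maps$t0), "-")
  alpha <- matrix(as.vector(par_maps$alpha), n_frames, P, byrow = TRUE)
  beta <- matrix(as.vector(par_maps$beta), n_frames, P, byrow = TRUE)
  amp <- matrix(as.vector(par_maps$amplitude), n_frames, P, byrow = TRUE)
  leak <- matrix(as.vector(par_maps$leak_frac), n_frames, P, byrow = TRUE)
  tau <- matrix(as.vector(par_maps$tau_leak), n_frames, P, byrow = TRUE)
  base <- matrix(as.vector(par_maps$baseline), n_frames, P, byrow = TRUE)
  pos <- S > 0
  G <- matrix(0, n_frames, P)
  G[pos] <- exp(alpha[pos] * (log(S[pos]) - log(alpha[pos] * beta[pos])) +
                alpha[pos] - S[pos] / beta[pos])
  L <- matrix(0, n_frames, P)
  L[pos] <- leak[pos] * amp[pos] * (1 - exp(-S[pos] / tau[pos]))
  M <- base + amp * G + L
  rm(S, alpha, beta, leak, tau, base, G, L)

  frames <- array(M, dim = c(n_frames, n, n))
  rm(M)
  if (config$motion_amplitude > 0) {
    for (t in seq_len(n_frames)) {
      frames[t, , ] <- pmax(translate_fourier(frames[t, , ],
                                              shifts$dx[t], shifts$dy[t]), 0)
    }
  }
  if (config$noise_sigma > 0 || config$noise_prop > 0) {
    noise <- stats::rnorm(length(frames), 0, config$noise_sigma)
    if (config$noise_prop > 0)
      noise <- noise + stats::rnorm(length(frames), 0,
                                    config$noise_prop * pmax(frames, 0))
    frames <- frames + noise
  }
  saturated <- matrix(FALSE, n, n)
  if (!is.na(config$bit_depth)) {
    maxval <- 2^config$bit_depth - 1
    over <- apply(frames > maxval, c(2, 3), any)
    saturated <- saturated | over
    frames <- round(pmin(pmax(frames, 0), maxval))
  }

  stack <- video_stack(frames, frame_rate = config$frame_rate,
                       bolus_onset_s = config$bolus_onset,
                       animal_id = animal_id,
                       site = ifelse(config$layout == "retina", "retina", "brain"))

  dynamics <- NULL
  if (analytic_truth) {
    t_end <- config$duration - config$bolus_onset
    pw <- c(t_end - 5, t_end)
    hr <- hf <- off <- matrix(NA_real_, n, n)
    for (idx in which(labels != 0L)) {
      p <- curve_params(t0 = par_maps$t0[idx], alpha = par_maps$alpha[idx],
                        beta = par_maps$beta[idx],
                        amplitude = par_maps$amplitude[idx],
                        leak_frac = par_maps$leak_frac[idx],
                        tau_leak = par_maps$tau_leak[idx],
                        baseline = par_maps$baseline[idx])
      d <- curve_dynamics(p, t_end = t_end, plateau_window = pw)
      hr[idx] <- d$half_rise; hf[idx] <- d$half_fall; off[idx] <- d$offset
    }
    dynamics <- list(half_rise = hr, half_fall = hf, offset = off)
  }

  truth <- structure(list(labels = labels, params = par_maps, shifts = shifts,
                          dynamics = dynamics, saturated = saturated,
                          config = config),
                     class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Derive a barrier-disruption scenario from a control scene
#'
#' Returns a scene configuration identical to `base` except that the
#' mean leakage fraction of the artery, vein and capillary/extravascular
#' compartments is shifted upward by `offset_shift`, emulating increased
#' dye leakage after blood-neural-barrier disruption. All transit-timing
#' parameters are untouched, so the disrupted scene differs from control
#' only in its residual-fluorescence plateau.
#'
#' @param base a [scene_config()].
#' @param offset_shift additive shift of the per-class mean leak fraction.
#' @return A modified [scene_config()].
#' @export
make_disruption_scenario <- function(base, offset_shift) {
  stopifnot(inherits(base, "scene_config"), is.numeric(offset_shift),
            length(offset_shift) == 1)
  out <- base
  for (cls in c("artery", "vein", "capillary")) {
    lf <- out$classes[[cls]]$leak_mean + offset_shift
    if (lf < 0 || lf >= 1)
      stop(sprintf("shifted leak fraction for %s (%.3g) out of [0, 1)", cls, lf),
           call. = FALSE)
    out$classes[[cls]]$leak_mean <- lf
  }
  out
}
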