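#' Parameters of a single-pixel dye-transit curve
#'
#' Describes the noiseless fluorescence time course of one pixel as a
#' gamma-variate first-pass bolus plus a saturating leakage term:
#' \deqn{I(t) = b + A\,g(t - t_0) + A\,\ell\,(1 - e^{-(t - t_0)/\tau}),\quad t \ge t_0,}
#' with \eqn{I(t) = b} before arrival, where
#' \eqn{g(s) = (s/\alpha\beta)^\alpha e^{\alpha - s/\beta}} is the
#' gamma-variate normalised to peak 1 at \eqn{s = \alpha\beta}.
#' The gamma-variate is the standard indicator-dilution model for
#' first-pass dye transit; the leakage term raises the late plateau to a
#' fraction \eqn{\ell} of the transit peak, the signature of
#' blood-neural-barrier breakdown.
#'
#' @param t0 bolus-arrival delay in seconds, relative to infusion onset.
#' @param alpha gamma-variate shape (dimensionless, > 0).
#' @param beta gamma-variate time scale in seconds (> 0).
#' @param amplitude peak fluorescence above baseline (arbitrary units, > 0).
#' @param leak_frac leakage plateau as a fraction of peak, in \[0, 1).
#' @param tau_leak leakage rise time constant in seconds (> 0).
#' @param baseline pre-bolus intensity (arbitrary units, >= 0).
#' @return An object of class `curve_params`.
#' @seealso [simulate_pixel_curve()], [curve_dynamics()]
#' @export
#' @examples
#' p <- curve_params(t0 = 4, alpha = 3, beta = 1.5, amplitude = 100)
#' simulate_pixel_curve(p, c(0, 4.5, 8.5, 20))
curve_params <- function(t0 = 5, alpha = 3, beta = 1.5, amplitude = 100,
                         leak_frac = 0, tau_leak = 10, baseline = 0) {
  stopifnot(is.numeric(t0), is.numeric(alpha), is.numeric(beta),
            is.numeric(amplitude), is.numeric(leak_frac),
            is.numeric(tau_leak), is.numeric(baseline))
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (tau_leak <= 0) stop("`tau_leak` must be > 0", call. = FALSE)
  if (amplitude <= 0) stop("`amplitude` must be > 0", call. = FALSE)
  if (leak_frac < 0 || leak_frac >= 1)
    stop("`leak_frac` must be in [0, 1)", call. = FALSE)
  if (baseline < 0) stop("`baseline` must be >= 0", call. = FALSE)
  structure(list(t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude,
                 leak_frac = leak_frac, tau_leak = tau_leak,
                 baseline = baseline),
            class = "curve_params")
}

#' @export
print.curve_params <- function(x, ...) {
  cat("Dye-transit curve parameters\n")
  cat(sprintf("  arrival t0 = %.3g s, gamma-variate alpha = %.3g, beta = %.3g s\n",
              x$t0, x$alpha, x$beta))
  cat(sprintf("  amplitude = %.3g, baseline = %.3g, leak fraction = %.3g (tau = %.3g s)\n",
              x$amplitude, x$baseline, x$leak_frac, x$tau_leak))
  invisible(x)
}

# Normalised gamma-variate, peak 1 at s = alpha*beta; 0 for s <= 0.
gamma_variate <- function(s, alpha, beta) {
  out <- numeric(length(s))
  pos <- s > 0
  sp <- s[pos]
  out[pos] <- exp(alpha * (log(sp) - log(alpha * beta)) + alpha - sp / beta)
  out
}

#' Evaluate the noiseless transit curve of one pixel
#'
#' @param params a [curve_params()] object.
#' @param times numeric vector of times (s, relative to infusion onset),
#'   strictly increasing.
#' @return Numeric vector of intensities, one per time point. Deterministic
#'   and noiseless; equals `baseline` for all `times < t0`.
#' @export
simulate_pixel_curve <- function(params, times) {
  if (!inherits(params, "curve_params")) params <- do.call(curve_params, params)
  stopifnot(is.numeric(times), length(times) >= 1)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  s <- times - params$t0
  y <- params$baseline + params$amplitude * gamma_variate(s, params$alpha, params$beta)
  lk <- s > 0
  y[lk] <- y[lk] + params$leak_frac * params$amplitude * (1 - exp(-s[lk] / params$tau_leak))
  y
}

# Continuous-time curve as a closure (used by the analytic dynamics below).
curve_fun <- function(params) {
  force(params)
  function(t) simulate_pixel_curve(params, sort(t))[rank(t)]
}

#' Analytic dynamics indices of a noiseless transit curve
#'
#' Computes the half-rise, half-fall and offset of the continuous,
#' noiseless curve defined by `params`, using the same definitions as
#' the map pipeline: normalise peak-above-baseline to 100%, take the
#' first 50% crossing before the peak (half-rise), the first 50% crossing
#' after the peak (half-fall, `NA` if censored by the end of the
#' recording), and the mean normalised value over the plateau window
#' (offset, %). Crossings are located by root finding on the continuous
#' curve, the peak by golden-section refinement of a dense grid.
#'
#' @param params a [curve_params()] object.
#' @param t_end end of the recording, seconds after infusion onset.
#' @param plateau_window length-2 numeric, window (s after onset) over
#'   which the offset plateau is averaged.
#' @return A list with elements `half_rise`, `half_fall` (s after
#'   infusion onset; `half_fall` is `NA_real_` when censored), `offset`
#'   (%), `peak_time` (s) and `peak` (raw intensity).
#' @export
curve_dynamics <- function(params, t_end = 55, plateau_window = c(50, 55)) {
  if (!inherits(params, "curve_params")) params <- do.call(curve_params, params)
  f <- function(t) simulate_pixel_curve(params, t)
  # locate the global peak: coarse grid then local refinement
  grid <- seq(params$t0, min(t_end, params$t0 + 12 * params$alpha * params$beta),
              length.out = 512)
  vals <- f(grid)
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  peak_time <- opt$maximum
  peak <- opt$objective
  b <- params$baseline
  if (peak <= b) {
    return(list(half_rise = NA_real_, half_fall = NA_real_,
                offset = NA_real_, peak_time = NA_real_, peak = peak))
  }
  half <- b + 0.5 * (peak - b)
  g <- function(t) f(t) - half
  half_rise <- stats::uniroot(g, c(params$t0, peak_time), tol = 1e-9)$root
  half_fall <- NA_real_
  tgrid <- seq(peak_time, t_end, length.out = 2048)
  below <- (f(tgrid) - half) < 0
  if (any(below)) {
    j <- which(below)[1]
    half_fall <- stats::uniroot(g, c(tgrid[max(1, j - 1)], tgrid[j]), tol = 1e-9)$root
  }
  pw <- seq(plateau_window[1], plateau_window[2], length.out = 101)
  offset <- mean((f(pw) - b) / (peak - b)) * 100
  offset <- min(max(offset, 0), 100)
  list(half_rise = half_rise, half_fall = half_fall, offset = offset,
       peak_time = peak_time, peak = peak)
}
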