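#' Analysis configuration for the dynamics pipeline
#'
#' @param frame_rate frames per second of the recordings.
#' @param bolus_onset_s infusion onset, seconds after recording start.
#' @param baseline_window length-2 numeric (s, relative to bolus onset)
#'   for the baseline average; default the whole pre-bolus segment.
#' @param smoothing_width_s width (s) of the centered moving average used
#'   for peak location and 50% crossing detection (raw normalized values
#'   are used for the offset average).
#' @param plateau_window_s length-2 numeric (s after bolus onset) over
#'   which the offset plateau is averaged; default the final 5 s of the
#'   recording.
#' @param snr_k exclusion threshold: pixels whose smoothed peak does not
#'   exceed `baseline_mean + snr_k * baseline_sd` carry no usable transit
#'   signal.
#' @param saturation_value digitizer maximum; samples at this value flag
#'   the pixel as saturated. `NA` disables the check.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(frame_rate = 30, bolus_onset_s = 5,
                            baseline_window = NULL, smoothing_width_s = 0.5,
                            plateau_window_s = NULL, snr_k = 3,
                            saturation_value = NA_real_) {
  structure(list(frame_rate = frame_rate, bolus_onset_s = bolus_onset_s,
                 baseline_window = baseline_window,
                 smoothing_width_s = smoothing_width_s,
                 plateau_window_s = plateau_window_s, snr_k = snr_k,
                 saturation_value = saturation_value),
            class = "analysis_config")
}

# Reason codes for per-pixel validity; every invalid pixel carries
# exactly one code.
#' Validity reason codes used in dynamics maps
#' @return Named integer vector of reason codes.
#' @export
reason_codes <- function() {
  c(ok = 0L, background = 1L, saturated = 2L, no_peak = 3L,
    censored_half_fall = 4L, low_snr = 5L, out_of_frame = 6L)
}

# Centered moving average with replicate padding; works on vectors and
# on matrices (column-wise). Width forced odd.
smooth_ma <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2 == 0) width <- width + 1L
  if (width == 1L) return(x)
  h <- width %/% 2
  if (is.matrix(x)) {
    xp <- rbind(x[rep(1, h), , drop = FALSE], x,
                x[rep(nrow(x), h), , drop = FALSE])
    sm <- stats::filter(xp, rep(1 / width, width), sides = 2)
    out <- sm[(h + 1):(h + nrow(x)), , drop = FALSE]
    dimnames(out) <- dimnames(x)
    matrix(out, nrow(x), ncol(x))
  } else {
    xp <- c(rep(x[1], h), x, rep(x[length(x)], h))
    as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[(h + 1):(h + length(x))]
  }
}

#' Normalize a raw pixel time course
#'
#' Subtracts the baseline mean (taken over the pre-bolus window, which
#' also neutralizes any constant pseudofluorescence), locates the peak on
#' the smoothed curve over post-onset times, and scales peak-above-
#' baseline to 100%. The smoothed normalized values drive crossing
#' detection; the raw normalized values are kept for the offset average.
#'
#' @param raw numeric vector of raw intensities.
#' @param times numeric vector (s, relative to bolus onset; pre-bolus
#'   samples have negative times), strictly increasing.
#' @param baseline_window length-2 numeric wholly pre-bolus (upper bound
#'   at most 0); default the whole pre-bolus segment.
#' @param smoothing_width moving-average width in samples (>= 1).
#' @param snr_k signal threshold multiplier (see [analysis_config()]).
#' @param saturation_value digitizer maximum or `NA`.
#' @return An object of class `normalized_curve`: `times`, `values`
#'   (smoothed, % of peak-above-baseline), `raw_values`, `peak_time`,
#'   `peak_index`, `baseline_mean`, `baseline_sd`, `saturated`, `reason`
#'   (`"ok"`, `"no_peak"` or `"low_snr"`).
#' @export
normalize_curve <- function(raw, times, baseline_window = NULL,
                            smoothing_width = 1, snr_k = 3,
                            saturation_value = NA_real_) {
  stopifnot(length(raw) == length(times), length(raw) >= 2)
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (is.null(baseline_window)) baseline_window <- c(min(times), 0)
  if (baseline_window[2] > 0)
    stop("baseline window must be wholly pre-bolus", call. = FALSE)
  if (smoothing_width < 1) stop("smoothing width must be >= 1 sample", call. = FALSE)
  bidx <- times >= baseline_window[1] & times <= baseline_window[2]
  if (!any(bidx)) stop("baseline window contains no samples", call. = FALSE)
  b <- mean(raw[bidx])
  bsd <- if (sum(bidx) > 1) stats::sd(raw[bidx]) else 0
  saturated <- !is.na(saturation_value) && any(raw >= saturation_value)
  sm <- smooth_ma(raw, smoothing_width)
  post <- which(times >= 0)
  if (!length(post)) stop("no post-bolus samples", call. = FALSE)
  ipk <- post[which.max(sm[post])]
  smax <- sm[ipk]
  reason <- "ok"
  if (smax <= b + snr_k * bsd) reason <- if (bsd == 0) "no_peak" else "low_snr"
  denom <- smax - b
  values <- raw_values <- rep(NA_real_, length(raw))
  peak_time <- NA_real_
  if (reason == "ok") {
    values <- 100 * (sm - b) / denom
    raw_values <- 100 * (raw - b) / denom
    peak_time <- times[ipk]
  }
  structure(list(times = times, values = values, raw_values = raw_values,
                 peak_time = peak_time, peak_index = if (reason == "ok") ipk else NA_integer_,
                 baseline_mean = b, baseline_sd = bsd, saturated = saturated,
                 reason = reason),
            class = "normalized_curve")
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("Normalized curve: %d samples, baseline %.3g +/- %.3g, reason '%s'",
              length(x$times), x$baseline_mean, x$baseline_sd, x$reason))
  if (x$reason == "ok") cat(sprintf(", peak at %.3f s", x$peak_time))
  if (x$saturated) cat(" [saturated]")
  cat("\n")
  invisible(x)
}

check_curve_ok <- function(curve) {
  if (!inherits(curve, "normalized_curve"))
    stop("expected a `normalized_curve`", call. = FALSE)
  if (curve$reason != "ok")
    stop(sprintf("curve is not valid (reason '%s')", curve$reason), call. = FALSE)
}

#' Half-rise time of a normalized curve
#'
#' First time at or before the peak where the smoothed curve crosses 50%
#' of peak-above-baseline rising, with linear interpolation between
#' samples. Reported relative to bolus onset.
#'
#' @param curve a valid [normalize_curve()] result.
#' @return Half-rise time in seconds.
#' @export
compute_half_rise <- function(curve) {
  check_curve_ok(curve)
  v <- curve$values; tt <- curve$times; ipk <- curve$peak_index
  above <- which(v[seq_len(ipk)] >= 50)
  if (!length(above))
    stop("curve never reaches 50% before its peak", call. = FALSE)
  i <- above[1]
  if (i == 1) return(tt[1])
  tt[i - 1] + (50 - v[i - 1]) / (v[i] - v[i - 1]) * (tt[i] - tt[i - 1])
}

#' Half-fall time of a normalized curve
#'
#' First time after the peak where the smoothed curve crosses 50%
#' falling (linear interpolation). If the curve never falls below 50%
#' before the recording ends the value is censored: `NA_real_` with
#' attribute `censored = TRUE`.
#'
#' @param curve a valid [normalize_curve()] result.
#' @return Half-fall time in seconds, or censored `NA`.
#' @export
compute_half_fall <- function(curve) {
  check_curve_ok(curve)
  v <- curve$values; tt <- curve$times; ipk <- curve$peak_index
  n <- length(v)
  if (ipk >= n) return(structure(NA_real_, censored = TRUE))
  below <- which(v[(ipk + 1):n] < 50)
  if (!length(below)) return(structure(NA_real_, censored = TRUE))
  i <- ipk + below[1]
  tt[i - 1] + (v[i - 1] - 50) / (v[i - 1] - v[i]) * (tt[i] - tt[i - 1])
}

#' Offset (remnant fluorescence) of a normalized curve
#'
#' Mean of the raw normalized values over the late plateau window,
#' clamped to \[0, 100\]; the leakage indicator.
#'
#' @param curve a valid [normalize_curve()] result.
#' @param plateau_window length-2 numeric (s after bolus onset), after
#'   the peak and within the recording.
#' @return Offset in percent of peak-above-baseline.
#' @export
compute_offset <- function(curve, plateau_window) {
  check_curve_ok(curve)
  tt <- curve$times
  if (plateau_window[1] <= curve$peak_time)
    stop("plateau window must lie after the peak", call. = FALSE)
  idx <- tt >= plateau_window[1] & tt <= plateau_window[2]
  if (!any(idx)) stop("plateau window contains no samples", call. = FALSE)
  min(max(mean(curve$raw_values[idx]), 0), 100)
}

#' Per-pixel dynamics maps of a registered stack
#'
#' Applies [normalize_curve()], [compute_half_rise()],
#' [compute_half_fall()] and [compute_offset()] to every pixel of a
#' (registered) video stack, producing the half-rise (s), half-fall (s)
#' and offset (%) maps plus a per-pixel validity reason map. Background
#' (mask label 0), saturated, signal-free and registration-uncovered
#' pixels are flagged, never zero-filled; censored half-fall pixels keep
#' their half-rise and offset values.
#'
#' @param stack a [video_stack()], ideally after [register_stack()].
#' @param mask optional vessel label map (matrix, 0..3); label 0 marks
#'   background pixels that are skipped.
#' @param config an [analysis_config()]; its `frame_rate` and
#'   `bolus_onset_s` default to the stack's own values.
#' @return An object of class `dynamics_maps` with matrices `half_rise`,
#'   `half_fall`, `offset`, integer `reason` (see [reason_codes()]) and
#'   the analysis `config`.
#' @export
compute_maps <- function(stack, mask = NULL, config = NULL) {
  stopifnot(inherits(stack, "video_stack"))
  if (is.null(config)) config <- analysis_config()
  stopifnot(inherits(config, "analysis_config"))
  config$frame_rate <- stack$frame_rate
  config$bolus_onset_s <- stack$bolus_onset_s
  d <- dim(stack$frames)
  nr <- d[2]; nc <- d[3]; P <- nr * nc
  codes <- reason_codes()

  keep <- if (!is.null(stack$frame_valid)) stack$frame_valid else rep(TRUE, d[1])
  tt <- frame_times(stack)[keep] - stack$bolus_onset_s
  M <- matrix(stack$frames[keep, , ], nrow = sum(keep))

  bw <- config$baseline_window
  if (is.null(bw)) bw <- c(min(tt), 0)
  pw <- config$plateau_window_s
  if (is.null(pw)) pw <- c(max(tt) - 5, max(tt))
  w <- max(1L, round(config$smoothing_width_s * stack$frame_rate))

  bidx <- tt >= bw[1] & tt <= bw[2]
  if (!any(bidx)) stop("baseline window contains no frames", call. = FALSE)
  bmean <- colMeans(M[bidx, , drop = FALSE])
  bsd <- if (sum(bidx) > 1) {
    sqrt(pmax(colMeans(M[bidx, , drop = FALSE]^2) - bmean^2, 0) *
           sum(bidx) / (sum(bidx) - 1))
  } else rep(0, P)

  SM <- smooth_ma(M, w)
  post <- which(tt >= 0)
  ipk <- post[max.col(t(SM[post, , drop = FALSE]), ties.method = "first")]
  smax <- SM[cbind(ipk, seq_len(P))]

  sat <- if (!is.na(config$saturation_value)) {
    colSums(M >= config$saturation_value) > 0
  } else rep(FALSE, P)

  reason <- rep(codes[["ok"]], P)
  no_sig <- smax <= bmean + config$snr_k * bsd
  reason[no_sig & bsd > 0] <- codes[["low_snr"]]
  reason[no_sig & bsd == 0] <- codes[["no_peak"]]
  reason[sat] <- codes[["saturated"]]
  if (!is.null(stack$coverage)) reason[!as.vector(stack$coverage)] <- codes[["out_of_frame"]]
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == c(nr, nc)))
    reason[as.vector(mask) == 0L] <- codes[["background"]]
  }

  half_rise <- half_fall <- offset <- rep(NA_real_, P)
  pidx <- tt >= pw[1] & tt <= pw[2]
  if (!any(pidx)) stop("plateau window contains no frames", call. = FALSE)
  nT <- length(tt)
  for (p in which(reason == codes[["ok"]])) {
    denom <- smax[p] - bmean[p]
    v <- 100 * (SM[, p] - bmean[p]) / denom
    i <- ipk[p]
    above <- which(v[seq_len(i)] >= 50)
    a <- above[1]
    half_rise[p] <- if (a == 1) tt[1] else
      tt[a - 1] + (50 - v[a - 1]) / (v[a] - v[a - 1]) * (tt[a] - tt[a - 1])
    if (i < nT) {
      below <- which(v[(i + 1):nT] < 50)
      if (length(below)) {
        j <- i + below[1]
        half_fall[p] <- tt[j - 1] + (v[j - 1] - 50) / (v[j - 1] - v[j]) *
          (tt[j] - tt[j - 1])
      } else {
        reason[p] <- codes[["censored_half_fall"]]
      }
    } else {
      reason[p] <- codes[["censored_half_fall"]]
    }
    rawv <- 100 * (M[pidx, p] - bmean[p]) / denom
    offset[p] <- min(max(mean(rawv), 0), 100)
  }

  structure(list(half_rise = matrix(half_rise, nr, nc),
                 half_fall = matrix(half_fall, nr, nc),
                 offset = matrix(offset, nr, nc),
                 reason = matrix(as.integer(reason), nr, nc),
                 config = config),
            class = "dynamics_maps")
}

#' @export
print.dynamics_maps <- function(x, ...) {
  codes <- reason_codes()
  tab <- table(factor(x$reason, levels = codes, labels = names(codes)))
  d <- dim(x$half_rise)
  cat(sprintf("Dynamics maps %dx%d px\n", d[1], d[2]))
  valid <- x$reason %in% c(codes[["ok"]], codes[["censored_half_fall"]])
  if (any(valid)) {
    cat(sprintf("  half-rise median %.2f s, half-fall median %.2f s, offset median %.1f%%\n",
                stats::median(x$half_rise[valid], na.rm = TRUE),
                stats::median(x$half_fall[valid], na.rm = TRUE),
                stats::median(x$offset[valid], na.rm = TRUE)))
  }
  cat("  pixel validity: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' Plot dynamics maps as color images
#'
#' One panel per parameter, in the conventional cool-to-warm palette
#' (early/low = blue, late/high = red); invalid pixels are left blank.
#'
#' @param x a `dynamics_maps` object.
#' @param ... unused.
#' @export
plot.dynamics_maps <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  pal <- grDevices::hcl.colors(64, "Blue-Red")
  for (p in c("half_rise", "half_fall", "offset")) {
    m <- x[[p]]
    graphics::image(t(m[nrow(m):1, ]), col = pal, axes = FALSE,
                    main = sub("_", "-", p))
  }
  invisible(x)
}

#' Extract per-class valid pixel values from dynamics maps
#'
#' @param maps a `dynamics_maps` object.
#' @param labels vessel label map (matrix, 0..3).
#' @param parameter `"half_rise"`, `"half_fall"` or `"offset"`.
#' @param class_label integer class label (1 artery, 2 vein, 3
#'   capillary/extravascular).
#' @return Numeric vector of valid (finite) pixel values.
#' @export
map_values <- function(maps, labels, parameter, class_label) {
  stopifnot(inherits(maps, "dynamics_maps"),
            parameter %in% c("half_rise", "half_fall", "offset"))
  v <- maps[[parameter]][labels == class_label]
  v[is.finite(v)]
}
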