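#' Reference image for registration
#'
#' The registration reference is the mean of the pre-bolus baseline
#' frames: they show the (motion-representative) anatomy without any
#' dye-dependent intensity change. Because the baseline frames may
#' themselves be moving, each one is first aligned to the first frame
#' (whose shift defines the zero of the shift estimates) before
#' averaging; a plain average of moving frames would be blurred and
#' anchored at the mean baseline displacement rather than at zero.
#'
#' @param stack a [video_stack()].
#' @param align align baseline frames to the first frame before
#'   averaging (default); `FALSE` gives the plain mean.
#' @return A matrix, the mean baseline frame.
#' @export
baseline_reference <- function(stack, align = TRUE) {
  tt <- frame_times(stack)
  idx <- which(tt < stack$bolus_onset_s)
  if (!length(idx)) stop("stack has no pre-bolus frames", call. = FALSE)
  if (!align || length(idx) == 1)
    return(apply(stack$frames[idx, , , drop = FALSE], c(2, 3), mean))
  f1 <- stack$frames[idx[1], , ]
  acc <- f1
  if (stats::sd(f1) == 0) return(apply(stack$frames[idx, , , drop = FALSE], c(2, 3), mean))
  for (t in idx[-1]) {
    fr <- stack$frames[t, , ]
    if (stats::sd(fr) == 0) { acc <- acc + fr; next }
    s <- phase_correlate(f1, fr)
    acc <- acc + translate_bilinear(fr, -s[["dx"]], -s[["dy"]])
  }
  acc / length(idx)
}

# fft frequency index vector 0, 1, ..., -1 (length n)
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# FFT cross-correlation of `frame` against `ref`; returns the
# translation (dx, dy) such that frame(x) ~= ref(x - shift), with
# sub-pixel refinement by locally upsampled inverse DFT of the
# cross-power spectrum. Means are removed before the FFT; the raw
# (matched-filter) cross-power is used rather than the whitened phase
# spectrum, which is markedly more robust to frame noise.
phase_correlate <- function(ref, frame, upsample = 32) {
  nr <- nrow(ref); nc <- ncol(ref)
  Fr <- stats::fft(ref - mean(ref))
  Ff <- stats::fft(frame - mean(frame))
  R <- Fr * Conj(Ff)
  corr <- Re(stats::fft(R, inverse = TRUE)) / (nr * nc)
  i <- which.max(corr)
  pr <- (i - 1) %% nr
  pc <- (i - 1) %/% nr
  if (pr > nr / 2) pr <- pr - nr
  if (pc > nc / 2) pc <- pc - nc
  # refine around the integer peak with a local matrix-product DFT,
  # then a parabolic sub-grid step along each axis
  kr <- fft_freqs(nr); kc <- fft_freqs(nc)
  ur <- pr + seq(-1, 1, by = 1 / upsample)
  uc <- pc + seq(-1, 1, by = 1 / upsample)
  Er <- exp(2i * pi * outer(ur, kr) / nr)     # |ur| x nr
  Ec <- exp(2i * pi * outer(kc, uc) / nc)     # nc x |uc|
  C <- Re(Er %*% R %*% Ec) / (nr * nc)
  j <- which(C == max(C), arr.ind = TRUE)[1, ]
  peak_r <- ur[j[1]]; peak_c <- uc[j[2]]
  h <- 1 / upsample
  if (j[1] > 1 && j[1] < length(ur)) {
    y <- C[(j[1] - 1):(j[1] + 1), j[2]]
    d <- (y[1] - y[3]) / (2 * (y[1] - 2 * y[2] + y[3]))
    if (is.finite(d) && abs(d) <= 0.5) peak_r <- peak_r + d * h
  }
  if (j[2] > 1 && j[2] < length(uc)) {
    y <- C[j[1], (j[2] - 1):(j[2] + 1)]
    d <- (y[1] - y[3]) / (2 * (y[1] - 2 * y[2] + y[3]))
    if (is.finite(d) && abs(d) <= 0.5) peak_c <- peak_c + d * h
  }
  # the correlation peak sits at minus the applied shift
  c(dy = -peak_r, dx = -peak_c)
}

#' Estimate per-frame rigid shifts of a video stack
#'
#' Translation-only registration by phase correlation of every frame
#' against a reference (by default the mean pre-bolus baseline frame,
#' [baseline_reference()]), with sub-pixel refinement by locally
#' upsampled inverse DFT. The per-frame quality score is the Pearson
#' correlation between the reference and the integer-aligned frame,
#' clamped to \[0, 1\]; frames scoring below `drop_threshold`, or frames
#' with no spatial structure (all-constant), are flagged unusable rather
#' than force-aligned.
#'
#' @param stack a [video_stack()].
#' @param reference optional reference matrix (same size as the frames).
#' @param upsample sub-pixel refinement factor (shift resolution
#'   `1/upsample` px).
#' @param drop_threshold minimum usable correlation score.
#' @return A data.frame of class `shift_estimate` with columns `frame`,
#'   `dx`, `dy`, `score`, `use`.
#' @export
estimate_shifts <- function(stack, reference = NULL, upsample = 32,
                            drop_threshold = 0.2) {
  stopifnot(inherits(stack, "video_stack"))
  if (is.null(reference)) reference <- baseline_reference(stack)
  d <- dim(stack$frames)
  if (!all(dim(reference) == d[2:3]))
    stop("reference dimensions must match the frames", call. = FALSE)
  n_frames <- d[1]
  out <- data.frame(frame = seq_len(n_frames), dx = NA_real_, dy = NA_real_,
                    score = 0, use = FALSE)
  ref_sd <- stats::sd(reference)
  for (t in seq_len(n_frames)) {
    fr <- stack$frames[t, , ]
    if (stats::sd(fr) == 0 || ref_sd == 0) next  # undefined shift, flagged
    s <- phase_correlate(reference, fr, upsample = upsample)
    out$dx[t] <- s[["dx"]]
    out$dy[t] <- s[["dy"]]
    out$score[t] <- shift_score(reference, fr, s[["dx"]], s[["dy"]])
  }
  out$use <- !is.na(out$dx) & out$score >= drop_threshold
  structure(out, class = c("shift_estimate", "data.frame"),
            upsample = upsample, drop_threshold = drop_threshold)
}

# Pearson correlation between reference and frame aligned by the rounded
# shift, on the overlap region; clamped to [0, 1].
shift_score <- function(ref, frame, dx, dy) {
  dxi <- round(dx); dyi <- round(dy)
  nr <- nrow(ref); nc <- ncol(ref)
  rs <- max(1, 1 + dyi):min(nr, nr + dyi)   # rows of frame overlapping ref
  cs <- max(1, 1 + dxi):min(nc, nc + dxi)
  if (length(rs) < 4 || length(cs) < 4) return(0)
  a <- frame[rs, cs]
  b <- ref[rs - dyi, cs - dxi]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  max(0, min(1, stats::cor(as.vector(a), as.vector(b))))
}

#' Apply estimated shifts to align a stack
#'
#' Each usable frame is resampled by its negated shift (bilinear
#' interpolation, edge replication). Pixels whose aligned value would
#' come from outside the frame for any used frame are recorded in the
#' stack's `coverage` mask and flagged invalid downstream; frames
#' flagged unusable by [estimate_shifts()] are left in place but marked
#' in `frame_valid` so the dynamics module skips them.
#'
#' @param stack a [video_stack()].
#' @param shifts a `shift_estimate` from [estimate_shifts()].
#' @return The aligned [video_stack()], with `coverage` (logical matrix)
#'   and `frame_valid` (logical vector) fields added.
#' @export
apply_shifts <- function(stack, shifts) {
  stopifnot(inherits(stack, "video_stack"), inherits(shifts, "shift_estimate"))
  d <- dim(stack$frames)
  if (nrow(shifts) != d[1])
    stop("one shift per frame required", call. = FALSE)
  out <- stack
  coverage <- matrix(TRUE, d[2], d[3])
  rowidx <- seq_len(d[2]); colidx <- seq_len(d[3])
  for (t in seq_len(d[1])) {
    if (!shifts$use[t]) next
    dx <- shifts$dx[t]; dy <- shifts$dy[t]
    if (dx == 0 && dy == 0) next
    out$frames[t, , ] <- translate_bilinear(stack$frames[t, , ], -dx, -dy)
    # aligned pixel (r, c) samples source (r + dy, c + dx)
    ok_r <- rowidx + dy >= 1 & rowidx + dy <= d[2]
    ok_c <- colidx + dx >= 1 & colidx + dx <= d[3]
    coverage <- coverage & outer(ok_r, ok_c, "&")
  }
  out$coverage <- coverage
  out$frame_valid <- shifts$use
  out
}

#' Register a stack in one step
#'
#' Convenience wrapper: [estimate_shifts()] then [apply_shifts()].
#'
#' @inheritParams estimate_shifts
#' @return The aligned stack, with the `shift_estimate` attached as the
#'   `shifts` field.
#' @export
register_stack <- function(stack, reference = NULL, upsample = 32,
                           drop_threshold = 0.2) {
  sh <- estimate_shifts(stack, reference = reference, upsample = upsample,
                        drop_threshold = drop_threshold)
  out <- apply_shifts(stack, sh)
  out$shifts <- sh
  out
}

#' Write shift estimates as CSV
#'
#' @param shifts a `shift_estimate`.
#' @param path output CSV path.
#' @export
write_shifts_csv <- function(shifts, path) {
  utils::write.csv(as.data.frame(shifts), path, row.names = FALSE)
  invisible(path)
}
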