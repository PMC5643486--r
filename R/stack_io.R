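#' Video stack container
#'
#' An ordered set of grayscale frames with its acquisition metadata. The
#' frame array is indexed `[time, row, column]`; intensities are raw
#' camera units (never rescaled on read). Frame times are 0-based at
#' recording start; analysis times reported by the dynamics module are
#' relative to the bolus-onset instant at `bolus_onset_s`.
#'
#' @param frames 3-d numeric array `(time, row, column)`, non-negative.
#' @param frame_rate frames per second.
#' @param bolus_onset_s infusion onset, seconds after recording start.
#' @param animal_id animal identifier.
#' @param site `"retina"` or `"brain"`.
#' @param saturation_value digitizer maximum (e.g. 255), or `NA` for
#'   unquantized data.
#' @return An object of class `video_stack`.
#' @export
video_stack <- function(frames, frame_rate, bolus_onset_s, animal_id = "unknown",
                        site = c("retina", "brain"), saturation_value = NA_real_) {
  site <- match.arg(site)
  stopifnot(is.array(frames), length(dim(frames)) == 3, frame_rate > 0,
            bolus_onset_s >= 0)
  if (any(frames < 0, na.rm = TRUE))
    stop("frame intensities must be non-negative", call. = FALSE)
  if (dim(frames)[1] <= frame_rate * bolus_onset_s)
    stop("stack has no post-bolus frames", call. = FALSE)
  structure(list(frames = frames, frame_rate = frame_rate,
                 bolus_onset_s = bolus_onset_s, animal_id = animal_id,
                 site = site, saturation_value = saturation_value),
            class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Video stack '%s' (%s): %d frames of %dx%d px, %g fps (%.1f s), bolus at %g s\n",
              x$animal_id, x$site, d[1], d[2], d[3], x$frame_rate,
              d[1] / x$frame_rate, x$bolus_onset_s))
  invisible(x)
}

#' @export
dim.video_stack <- function(x) dim(x$frames)

#' Frame times of a stack
#'
#' @param stack a [video_stack()].
#' @return Numeric vector of frame times (s) relative to recording
#'   start (subtract `bolus_onset_s` for analysis times).
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$frames)[1]) - 1) / stack$frame_rate
}

#' Write a video stack as multi-page TIFF plus JSON metadata
#'
#' Integer-valued stacks are stored losslessly at 8 or 16 bits; other
#' stacks are stored as 32-bit float pages scaled into \[0, 1\] with the
#' scale recorded in the metadata sidecar.
#'
#' @param stack a [video_stack()].
#' @param video_path output TIFF path.
#' @param metadata_path output JSON path.
#' @return Invisibly, the metadata list.
#' @export
write_stack <- function(stack, video_path, metadata_path) {
  stopifnot(inherits(stack, "video_stack"))
  fr <- stack$frames
  n_frames <- dim(fr)[1]
  mx <- max(fr)
  is_int <- all(fr == round(fr))
  if (is_int && mx <= 255) {
    bits <- 8L; scale <- 255
  } else if (is_int && mx <= 65535) {
    bits <- 16L; scale <- 65535
  } else {
    bits <- 32L; scale <- ifelse(mx > 0, mx, 1)
  }
  pages <- lapply(seq_len(n_frames), function(t) fr[t, , ] / scale)
  tiff::writeTIFF(pages, video_path, bits.per.sample = bits)
  meta <- list(frame_rate = stack$frame_rate,
               bolus_onset_s = stack$bolus_onset_s,
               animal_id = stack$animal_id, site = stack$site,
               n_frames = n_frames, bits_per_sample = bits,
               intensity_scale = scale,
               saturation_value = stack$saturation_value)
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(meta)
}

#' Read a video stack from multi-page TIFF plus JSON metadata
#'
#' @param video_path TIFF path.
#' @param metadata_path JSON sidecar; must contain `frame_rate` and
#'   `bolus_onset_s`.
#' @return A [video_stack()]. Raw intensities are restored on their
#'   original scale, never renormalized.
#' @export
read_stack <- function(video_path, metadata_path) {
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  for (key in c("frame_rate", "bolus_onset_s")) {
    if (is.null(meta[[key]]))
      stop(sprintf("metadata is missing required key '%s'", key), call. = FALSE)
  }
  pages <- tiff::readTIFF(video_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1)
    stop("frame size differs across TIFF pages", call. = FALSE)
  if (!is.null(meta$n_frames) && length(pages) != meta$n_frames)
    stop(sprintf("truncated stack: %d pages, metadata says %d",
                 length(pages), meta$n_frames), call. = FALSE)
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  d <- dims[[1]]
  frames <- array(NA_real_, c(length(pages), d[1], d[2]))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]] * scale
  if (!is.null(meta$bits_per_sample) && meta$bits_per_sample %in% c(8, 16))
    frames <- round(frames)
  video_stack(frames, frame_rate = meta$frame_rate,
              bolus_onset_s = meta$bolus_onset_s,
              animal_id = ifelse(is.null(meta$animal_id), "unknown", meta$animal_id),
              site = ifelse(is.null(meta$site), "retina", meta$site),
              saturation_value = ifelse(is.null(meta$saturation_value) ||
                                          is.na(meta$saturation_value),
                                        NA_real_, meta$saturation_value))
}

#' Write a vessel label map
#'
#' Labels are stored as a single-page 8-bit image with the convention
#' 0 = background, 1 = artery, 2 = vein, 3 = capillary/extravascular.
#'
#' @param labels integer matrix of labels in 0..3.
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @export
write_label_map <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels %in% 0:3))
  img <- labels / 255
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' Read a vessel label map
#'
#' @param path single-page integer TIFF or PNG.
#' @return Integer matrix with labels 0..3 (0 = background, 1 = artery,
#'   2 = vein, 3 = capillary/extravascular). Any pixel value above 3 is a
#'   format error.
#' @export
read_label_map <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  lab <- round(img * 255)
  if (any(lab > 3))
    stop("label map contains values > 3", call. = FALSE)
  storage.mode(lab) <- "integer"
  lab
}

# FNV-1a 32-bit hash of a string; used to stamp configuration provenance.
# 32-bit modular multiply done in 16-bit halves to stay within exact doubles.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(x))
  mul32 <- function(h, p) {
    h1 <- floor(h / 65536); h0 <- h %% 65536
    (((h1 * p) %% 65536) * 65536 + h0 * p) %% 2^32
  }
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 10,
                              force = TRUE))
}

#' Write dynamics maps to a directory
#'
#' Writes one 32-bit float TIFF per parameter (`half_rise.tif`,
#' `half_fall.tif`, `offset.tif`; values scaled into \[0, 1\] with scales
#' recorded in the sidecar), the validity/reason map (`validity.tif`),
#' and a `provenance.json` sidecar carrying the scales, reason-code
#' table, analysis-config hash and seed.
#'
#' @param maps a `dynamics_maps` object (see [compute_maps()]).
#' @param out_dir output directory (created if needed).
#' @param seed optional seed to record in the provenance.
#' @return Invisibly, the vector of files written.
#' @export
write_maps <- function(maps, out_dir, seed = NULL) {
  stopifnot(inherits(maps, "dynamics_maps"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scales <- list()
  files <- character()
  for (p in c("half_rise", "half_fall", "offset")) {
    m <- maps[[p]]
    finite <- is.finite(m)
    sc <- if (any(finite)) max(abs(m[finite]), 1e-12) else 1
    img <- m / sc
    img[!finite] <- 0
    f <- file.path(out_dir, paste0(p, ".tif"))
    tiff::writeTIFF(img, f, bits.per.sample = 32L)
    scales[[p]] <- sc
    files <- c(files, f)
  }
  vf <- file.path(out_dir, "validity.tif")
  tiff::writeTIFF(maps$reason / 255, vf, bits.per.sample = 8L)
  files <- c(files, vf)
  prov <- list(scales = scales, reason_codes = as.list(reason_codes()),
               config = unclass(maps$config),
               config_hash = config_hash(maps$config),
               seed = seed)
  pf <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(prov, pf, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(files, pf))
}

#' Read dynamics maps written by [write_maps()]
#'
#' Invalid pixels (validity reason other than `ok` or
#' `censored_half_fall`) are restored as `NaN` in the parameter maps.
#'
#' @param dir directory written by [write_maps()].
#' @return A `dynamics_maps` object.
#' @export
read_maps <- function(dir) {
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  reason <- round(tiff::readTIFF(file.path(dir, "validity.tif")) * 255)
  storage.mode(reason) <- "integer"
  codes <- reason_codes()
  out <- list()
  for (p in c("half_rise", "half_fall", "offset")) {
    m <- tiff::readTIFF(file.path(dir, paste0(p, ".tif"))) * prov$scales[[p]]
    bad <- !(reason %in% c(codes[["ok"]], codes[["censored_half_fall"]]))
    m[bad] <- NaN
    if (p == "half_fall") m[reason == codes[["censored_half_fall"]]] <- NaN
    out[[p]] <- m
  }
  structure(list(half_rise = out$half_rise, half_fall = out$half_fall,
                 offset = out$offset, reason = reason,
                 config = prov$config),
            class = "dynamics_maps")
}

#' Read a group manifest
#'
#' Manifests are CSV files with the fixed header
#' `animal_id,site,group,time_point,video,meta,mask` assigning each
#' animal's files to a site, experimental group and time point.
#'
#' @param path CSV path.
#' @param check_paths verify that every referenced file exists.
#' @return A data.frame with the manifest columns.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("animal_id", "site", "group", "time_point", "video", "meta", "mask")
  if (!all(required %in% names(m)))
    stop("manifest must have columns ", paste(required, collapse = ", "),
         call. = FALSE)
  key <- paste(m$site, m$time_point, m$animal_id)
  if (anyDuplicated(key))
    stop("animal_ids must be unique within (site, time_point)", call. = FALSE)
  if (check_paths) {
    base <- dirname(path)
    for (col in c("video", "meta", "mask")) {
      p <- m[[col]]
      p <- ifelse(file.exists(p), p, file.path(base, p))
      if (!all(file.exists(p)))
        stop(sprintf("unresolvable %s path(s): %s", col,
                     paste(m[[col]][!file.exists(p)], collapse = ", ")),
             call. = FALSE)
      m[[col]] <- p
    }
  }
  m
}

#' Write a group manifest
#'
#' @param manifest data.frame with the manifest columns.
#' @param path output CSV path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}
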