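#' Peak-intensity image of a stack
#'
#' Per-pixel maximum over time of a (registered) stack; vessels carrying
#' dye are bright in this image, which drives segmentation.
#'
#' @param stack a [video_stack()].
#' @return A matrix.
#' @export
peak_image <- function(stack) {
  stopifnot(inherits(stack, "video_stack"))
  apply(stack$frames, c(2, 3), max)
}

# Merge 4-connected component labels that touch diagonally, yielding
# 8-connected components (EBImage::bwlabel is 4-connected).
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  parent <- seq_len(max(lab) + 1L)  # 1-based union-find over labels
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  diag_pairs <- list(
    list(a = lab[seq_len(nr - 1), seq_len(nc - 1)], b = lab[2:nr, 2:nc]),
    list(a = lab[seq_len(nr - 1), 2:nc], b = lab[2:nr, seq_len(nc - 1)])
  )
  for (dp in diag_pairs) {
    touching <- which(dp$a > 0 & dp$b > 0 & dp$a != dp$b)
    for (i in touching) union2(dp$a[i] + 1L, dp$b[i] + 1L)
  }
  roots <- vapply(seq_along(parent), find, integer(1))
  out <- lab
  out[lab > 0] <- roots[lab[lab > 0] + 1L] - 1L
  # relabel compactly
  u <- sort(unique(out[out > 0]))
  out[out > 0] <- match(out[out > 0], u)
  out
}

#' Segment large vessels from a peak image
#'
#' Otsu threshold on the peak-intensity image followed by removal of
#' 8-connected components smaller than `min_size` pixels. The remaining
#' foreground with a valid transit signal is treated as the
#' capillary/extravascular compartment by [classify_by_timing()].
#'
#' @param peak matrix, per-pixel maximum of the registered stack (see
#'   [peak_image()]).
#' @param min_size minimum component size in pixels.
#' @return Logical matrix: large-vessel mask.
#' @export
segment_vessels <- function(peak, min_size = 20) {
  stopifnot(is.matrix(peak))
  rng <- range(peak)
  if (diff(rng) == 0)
    stop("peak image is uniform; nothing to segment", call. = FALSE)
  img <- (peak - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(img))
  mask <- img > thr
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- merge_diagonal_labels(matrix(as.integer(lab), nrow(peak), ncol(peak)))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  out <- matrix(lab %in% keep & lab > 0, nrow(peak), ncol(peak))
  if (!any(out))
    stop("segmentation found no vessel components", call. = FALSE)
  out
}

# Mean silhouette width of a 1-d two-group split, computed on up to
# `max_n` evenly spaced order statistics for determinism and speed.
silhouette_1d <- function(values, cluster, max_n = 1000) {
  n <- length(values)
  if (n > max_n) {
    o <- order(values)
    pick <- o[round(seq(1, n, length.out = max_n))]
    values <- values[pick]; cluster <- cluster[pick]
  }
  s <- vapply(seq_along(values), function(i) {
    same <- values[cluster == cluster[i]]
    other <- values[cluster != cluster[i]]
    if (length(same) <= 1 || !length(other)) return(0)
    a <- sum(abs(values[i] - same)) / (length(same) - 1)  # exclude self

    b <- mean(abs(values[i] - other))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Classify vessel pixels into arteries and veins by fill timing
#'
#' Splits the half-rise values of the large-vessel pixels into two
#' clusters with 1-d k-means (deterministic initialization at the 10th
#' and 90th percentiles); the earlier-filling cluster becomes the artery
#' class, the later the vein class (arteries fill first). Foreground
#' pixels with a valid transit signal outside the large-vessel mask
#' become the capillary/extravascular compartment.
#'
#' @param maps a `dynamics_maps` object (supplies half-rise values and
#'   validity).
#' @param vessel_mask logical matrix from [segment_vessels()].
#' @return An object of class `classification_result`: `labels` (0..3
#'   label map), `counts` (per-class pixel counts), `method`
#'   (`"auto_timing"`), `quality` (silhouette-style separation of the
#'   two half-rise clusters).
#' @export
classify_by_timing <- function(maps, vessel_mask) {
  stopifnot(inherits(maps, "dynamics_maps"), is.matrix(vessel_mask))
  codes <- reason_codes()
  valid <- maps$reason == codes[["ok"]] | maps$reason == codes[["censored_half_fall"]]
  hr <- maps$half_rise
  vess <- which(vessel_mask)
  vess_valid <- vess[valid[vess] & is.finite(hr[vess])]
  if (length(vess_valid) < 0.5 * length(vess))
    stop("half-rise is valid on fewer than 50% of vessel pixels", call. = FALSE)
  v <- hr[vess_valid]
  if (diff(range(v)) == 0)
    stop("all vessel half-rise values are identical; cannot classify", call. = FALSE)
  centers <- matrix(stats::quantile(v, c(0.1, 0.9), type = 7, names = FALSE), 2, 1)
  if (centers[1] == centers[2]) centers[2] <- centers[2] + 1e-9
  km <- stats::kmeans(matrix(v, ncol = 1), centers = centers, iter.max = 100)
  means <- as.vector(km$centers)
  artery_cluster <- which.min(means)
  labels <- matrix(0L, nrow(hr), ncol(hr))
  labels[vess_valid] <- ifelse(km$cluster == artery_cluster, 1L, 2L)
  # remaining foreground with valid transit -> capillary/extravascular
  labels[valid & labels == 0L] <- 3L
  counts <- c(artery = sum(labels == 1L), vein = sum(labels == 2L),
              capillary_extravascular = sum(labels == 3L))
  quality <- silhouette_1d(v, km$cluster)
  structure(list(labels = labels, counts = counts, method = "auto_timing",
                 quality = quality),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Vessel classification (%s): artery %d px, vein %d px, capillary/extravascular %d px\n",
              x$method, x$counts[["artery"]], x$counts[["vein"]],
              x$counts[["capillary_extravascular"]]))
  cat(sprintf("  half-rise cluster separation (silhouette): %.3f\n", x$quality))
  invisible(x)
}

#' Wrap a manually drawn label map as a classification result
#'
#' Manual label maps always take precedence over automatic timing-based
#' classification when supplied to the pipeline.
#'
#' @param labels integer label map (0..3).
#' @return A `classification_result` with method `"manual"`.
#' @export
manual_classification <- function(labels) {
  stopifnot(is.matrix(labels), all(labels %in% 0:3))
  counts <- c(artery = sum(labels == 1L), vein = sum(labels == 2L),
              capillary_extravascular = sum(labels == 3L))
  structure(list(labels = labels, counts = counts, method = "manual",
                 quality = NA_real_),
            class = "classification_result")
}
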