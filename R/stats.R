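#' Frequency histogram normalized to percent of pixels
#'
#' Counts in half-open bins `[edge, edge + width)`, expressed as percent
#' of the total number of pixels contributing, as used to summarize the
#' per-class distribution of each dynamics parameter.
#'
#' @param values finite numeric vector (censored pixels are excluded by
#'   the caller and reported via `n_censored`).
#' @param bin_width bin width (default 0.1 s for times, 1 for percent
#'   parameters).
#' @param range optional length-2 numeric covering all values; defaults
#'   to the data range.
#' @param n_censored number of censored pixels excluded from the
#'   histogram (bookkeeping only).
#' @return An object of class `class_histogram`: `breaks`, `counts_pct`,
#'   `n_pixels`, `n_censored`.
#' @export
build_histogram <- function(values, bin_width = 0.1, range = NULL,
                            n_censored = 0) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to histogram", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  if (bin_width <= 0) stop("`bin_width` must be > 0", call. = FALSE)
  if (is.null(range)) range <- base::range(values)
  lo <- floor(range[1] / bin_width + 1e-9) * bin_width
  hi <- lo + ceiling((range[2] - lo) / bin_width - 1e-9) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  if (any(values >= hi)) hi <- hi + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (any(values < breaks[1]) || any(values >= breaks[length(breaks)]))
    stop("`range` does not cover all values", call. = FALSE)
  idx <- findInterval(values, breaks, rightmost.closed = FALSE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  structure(list(breaks = breaks, counts_pct = 100 * counts / length(values),
                 n_pixels = length(values), n_censored = n_censored),
            class = "class_histogram")
}

#' @export
print.class_histogram <- function(x, ...) {
  cat(sprintf("Histogram: %d pixels (%d censored excluded), %d bins of width %g\n",
              x$n_pixels, x$n_censored, length(x$counts_pct),
              diff(x$breaks[1:2])))
  invisible(x)
}

#' Plot a normalized frequency histogram
#' @param x a `class_histogram`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.class_histogram <- function(x, ...) {
  mids <- x$breaks[-length(x$breaks)] + diff(x$breaks) / 2
  graphics::plot(mids, x$counts_pct, type = "h", xlab = "value",
                 ylab = "normalized count (% of pixels)", ...)
  invisible(x)
}

#' Median and interquartile range
#'
#' Quantiles use linear interpolation (type 7) throughout the package;
#' the IQR is the range between the lower 25% and upper 75% quartiles.
#'
#' @param values numeric vector with at least one finite value.
#' @return Named numeric vector `c(median, iqr)`.
#' @export
median_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], iqr = q[3] - q[1])
}

#' Bootstrap confidence limits of the group mean of per-animal medians
#'
#' Animals (their medians), not pixels, are the resampling unit: pixels
#' within an animal are not independent. The group is resampled with
#' replacement `n_boot` times; the statistic is the mean of the
#' resampled medians and the confidence limits are the 2.5th and 97.5th
#' percentiles of the bootstrap distribution, taken as `(R+1)*alpha`
#' order statistics (quantile type 6), the convention of the canonical
#' percentile bootstrap.
#'
#' @param per_animal_medians numeric vector, one median per animal
#'   (>= 2 animals).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed for reproducibility.
#' @param conf confidence level.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
bootstrap_cl <- function(per_animal_medians, n_boot = 1000, seed = 1,
                         conf = 0.95) {
  x <- per_animal_medians
  if (length(x) < 2) stop("need at least 2 animals to bootstrap", call. = FALSE)
  if (any(!is.finite(x))) stop("medians must be finite", call. = FALSE)
  set.seed(seed)
  n <- length(x)
  draws <- matrix(sample(x, n * n_boot, replace = TRUE), n_boot, n)
  stat <- rowMeans(draws)
  a <- (1 - conf) / 2
  q <- stats::quantile(stat, c(a, 1 - a), type = 6, names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Flag a value falling outside confidence limits
#'
#' The interval is inclusive: values exactly on a limit are inside.
#'
#' @param value numeric scalar.
#' @param cl length-2 numeric `(lower, upper)`.
#' @return Logical.
#' @export
flag_outside_cl <- function(value, cl) {
  stopifnot(length(cl) == 2, cl[1] <= cl[2])
  value < cl[1] || value > cl[2]
}

#' Control cutoff: pooled 75th percentile
#'
#' The upper quartile of the pixel values pooled across all control
#' animals of a site/class/parameter, chosen to be indicative of a
#' larger area of injury.
#'
#' @param control_pixel_values pooled numeric vector (>= 100 pixels).
#' @param min_n minimum pool size.
#' @return The 75th percentile (linear interpolation).
#' @export
control_cutoff <- function(control_pixel_values, min_n = 100) {
  v <- control_pixel_values[is.finite(control_pixel_values)]
  if (length(v) < min_n)
    stop(sprintf("need >= %d pooled control pixels, got %d", min_n, length(v)),
         call. = FALSE)
  stats::quantile(v, 0.75, type = 7, names = FALSE)
}

#' Index of injury
#'
#' Percentage of an animal's valid pixels whose value lies strictly
#' above the control cutoff. When the animal is drawn from the control
#' distribution itself the expectation is the 25% reference level.
#'
#' @param treated_pixel_values numeric vector of pixel values (>= 1
#'   valid pixel).
#' @param cutoff control cutoff from [control_cutoff()].
#' @return Percentage in \[0, 100\].
#' @export
injury_index <- function(treated_pixel_values, cutoff) {
  v <- treated_pixel_values[is.finite(treated_pixel_values)]
  if (!length(v)) stop("no valid pixels", call. = FALSE)
  100 * sum(v > cutoff) / length(v)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U: exact enumeration when the combined sample
#' size is at most 12 and there are no ties, normal approximation with
#' tie correction otherwise (the standard [stats::wilcox.test()]
#' machinery).
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @return List with `U` (statistic for `group_a`) and `p` (two-sided).
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  if (length(unique(c(group_a, group_b))) == 1)
    return(list(U = length(group_a) * length(group_b) / 2, p = 1))
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (length(group_a) + length(group_b)) <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = FALSE)
  )
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Per-animal group summary of medians and IQRs
#'
#' @param values_by_animal named list, one numeric vector of pixel
#'   values per animal.
#' @return A list with the per-animal `medians`, `iqrs`, and group
#'   `mean_median`, `sem_median`, `mean_iqr`, `sem_iqr` (SEM = sd/sqrt(n)
#'   with n = number of animals).
#' @export
group_summary <- function(values_by_animal) {
  stopifnot(is.list(values_by_animal), length(values_by_animal) >= 1)
  mi <- vapply(values_by_animal, median_iqr, numeric(2))
  n <- ncol(mi)
  sem <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
  list(medians = mi["median", ], iqrs = mi["iqr", ],
       mean_median = mean(mi["median", ]), sem_median = sem(mi["median", ]),
       mean_iqr = mean(mi["iqr", ]), sem_iqr = sem(mi["iqr", ]))
}

#' Build a control reference for one site
#'
#' For each (class, parameter) pair: the pooled 75th-percentile cutoff
#' across the control animals' pixels and the bootstrap 95% confidence
#' limits of the group mean of per-animal medians.
#'
#' @param control_values nested list:
#'   `control_values[[class]][[parameter]]` is a list of per-animal
#'   pixel-value vectors.
#' @param site `"retina"` or `"brain"`.
#' @param n_boot bootstrap resamples.
#' @param seed bootstrap seed.
#' @param min_pool minimum pooled pixel count for the cutoff.
#' @return A data.frame of class `control_reference` with columns
#'   `site`, `class`, `parameter`, `cutoff`, `cl_low`, `cl_high`,
#'   `n_boot`, `seed`.
#' @export
build_control_reference <- function(control_values, site = "retina",
                                    n_boot = 1000, seed = 1, min_pool = 100) {
  rows <- list()
  for (cls in names(control_values)) {
    for (par in names(control_values[[cls]])) {
      per_animal <- control_values[[cls]][[par]]
      pooled <- unlist(per_animal, use.names = FALSE)
      cutoff <- control_cutoff(pooled, min_n = min_pool)
      meds <- vapply(per_animal, function(v) median_iqr(v)[["median"]],
                     numeric(1))
      cl <- bootstrap_cl(meds, n_boot = n_boot, seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        site = site, class = cls, parameter = par, cutoff = cutoff,
        cl_low = cl[["lower"]], cl_high = cl[["upper"]],
        n_boot = n_boot, seed = seed, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("control_reference", "data.frame"))
}

#' Write / read a control reference as JSON
#'
#' @param ref a `control_reference`.
#' @param path JSON path.
#' @export
write_reference <- function(ref, path) {
  jsonlite::write_json(as.data.frame(ref), path, digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(df, class = c("control_reference", "data.frame"))
}

#' Injury indices for a group of animals against a reference
#'
#' @param values_by_animal named list of per-animal pixel-value vectors
#'   for one (site, class, parameter).
#' @param cutoff control cutoff.
#' @return A list with per-animal `index`, group `mean`, `sem`, and
#'   `flag_25` (TRUE when the group mean lies more than 2 SEM away from
#'   the 25% null reference level).
#' @export
injury_group <- function(values_by_animal, cutoff) {
  idx <- vapply(values_by_animal, injury_index, numeric(1), cutoff = cutoff)
  n <- length(idx)
  sem <- if (n > 1) stats::sd(idx) / sqrt(n) else NA_real_
  m <- mean(idx)
  list(index = idx, mean = m, sem = sem,
       flag_25 = if (is.na(sem) || sem == 0) NA else abs(m - 25) > 2 * sem)
}
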