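#' Configuration of a simulated angiography study
#'
#' Bundles every stage's configuration for [run_experiment()]: the
#' control scene, group sizes, the leakage shift applied to the treated
#' group, classification mode, statistics settings and the global seed.
#' Unknown fields passed through `from_list` are rejected.
#'
#' @param scene control-group [scene_config()].
#' @param n_control,n_treated animals per group.
#' @param offset_shift upward shift of the treated group's mean leak
#'   fraction (see [make_disruption_scenario()]).
#' @param classification `"manual"` (use the simulator's ground-truth
#'   label map, standing in for hand-drawn masks) or `"auto"`
#'   (segmentation + timing-based classification).
#' @param n_boot bootstrap resamples for the control reference.
#' @param bin_width_time histogram bin width (s) for half-rise/half-fall.
#' @param bin_width_offset histogram bin width (%) for offset.
#' @param register run rigid registration on every stack (recommended
#'   whenever motion is simulated).
#' @param seed global seed; all per-animal seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scene = scene_config(), n_control = 10, n_treated = 10,
                       offset_shift = 0.3,
                       classification = c("manual", "auto"),
                       n_boot = 1000, bin_width_time = 0.1,
                       bin_width_offset = 1, register = TRUE, seed = 1) {
  classification <- match.arg(classification)
  stopifnot(inherits(scene, "scene_config"), n_control >= 1, n_treated >= 0)
  structure(list(scene = scene, n_control = n_control, n_treated = n_treated,
                 offset_shift = offset_shift, classification = classification,
                 n_boot = n_boot, bin_width_time = bin_width_time,
                 bin_width_offset = bin_width_offset, register = register,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Build a run configuration from a plain list (e.g. parsed JSON)
#'
#' Unknown fields are rejected; absent fields take the documented
#' defaults.
#'
#' @param x named list.
#' @return A [run_config()].
#' @export
run_config_from_list <- function(x) {
  known <- names(formals(run_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(x$scene) && !inherits(x$scene, "scene_config")) {
    sknown <- names(formals(scene_config))
    sunknown <- setdiff(names(x$scene), sknown)
    if (length(sunknown))
      stop("unknown scene fields: ", paste(sunknown, collapse = ", "),
           call. = FALSE)
    x$scene <- do.call(scene_config, x$scene)
  }
  do.call(run_config, x)
}

# Deterministic per-animal seed derived from the global seed.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 100003 + k * 7919) %% 2147483647)
}

# label code -> class name used in summaries
class_names <- function() c(artery = 1L, vein = 2L, capillary = 3L)
param_names <- function() c("half_rise", "half_fall", "offset")

# Analyze one simulated animal: render, register, map, label.
# Returns per-(class, parameter) pixel values plus bookkeeping.
analyze_animal <- function(scene, animal_id, classification = "manual",
                           register = TRUE) {
  sim <- render_video(scene, animal_id = animal_id, analytic_truth = FALSE)
  stack <- sim$stack
  if (register) stack <- register_stack(stack)
  sat_val <- if (is.na(scene$bit_depth)) NA_real_ else 2^scene$bit_depth - 1
  cfg <- analysis_config(saturation_value = sat_val)
  if (classification == "manual") {
    labels <- sim$truth$labels
    maps <- compute_maps(stack, mask = labels, config = cfg)
  } else {
    maps <- compute_maps(stack, mask = NULL, config = cfg)
    vessels <- segment_vessels(peak_image(stack))
    labels <- classify_by_timing(maps, vessels)$labels
  }
  values <- list()
  for (cls in names(class_names())) {
    values[[cls]] <- list()
    for (par in param_names()) {
      values[[cls]][[par]] <- map_values(maps, labels, par, class_names()[[cls]])
    }
  }
  codes <- reason_codes()
  list(values = values, maps = maps, labels = labels,
       n_censored = sum(maps$reason == codes[["censored_half_fall"]]))
}

#' Run a simulated control-vs-disruption angiography study
#'
#' Simulates `n_control` control animals from the configured scene and
#' `n_treated` animals from the leakage-shifted disruption scenario,
#' runs the full pipeline on every stack (registration, per-pixel
#' dynamics maps, vessel labels), builds the control reference (pooled
#' 75th-percentile cutoffs and bootstrap confidence limits), computes
#' every animal's index of injury for each class and parameter, and
#' compares groups with the Mann-Whitney rank-sum test. Per-animal
#' failures are caught and reported; the pipeline continues with the
#' remaining animals. Identical configuration and seed reproduce the
#' bundle exactly.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory: writes `reference.json`,
#'   `results.csv` and `provenance.json`.
#' @return An object of class `angio_experiment`.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  treated_scene <- if (config$n_treated > 0)
    make_disruption_scenario(config$scene, config$offset_shift) else NULL

  groups <- list(control = list(scene = config$scene, n = config$n_control),
                 treated = list(scene = treated_scene, n = config$n_treated))
  values <- list(); errors <- list(); censored <- list()
  for (g in names(groups)) {
    if (groups[[g]]$n == 0) next
    for (i in seq_len(groups[[g]]$n)) {
      id <- sprintf("%s_%02d", g, i)
      sc <- groups[[g]]$scene
      sc$seed <- sub_seed(config$seed, (if (g == "treated") 1000 else 0) + i)
      res <- tryCatch(
        analyze_animal(sc, id, classification = config$classification,
                       register = config$register),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[id]] <- conditionMessage(res)
        next
      }
      values[[g]][[id]] <- res$values
      censored[[id]] <- res$n_censored
    }
  }
  if (is.null(values$control) || length(values$control) < 2)
    stop("fewer than 2 control animals analyzed successfully", call. = FALSE)

  # reorganize to class -> parameter -> animal
  nest <- function(group_vals) {
    out <- list()
    for (cls in names(class_names())) {
      out[[cls]] <- list()
      for (par in param_names()) {
        out[[cls]][[par]] <- lapply(group_vals, function(a) a[[cls]][[par]])
      }
    }
    out
  }
  control_nested <- nest(values$control)
  site <- ifelse(config$scene$layout == "retina", "retina", "brain")
  reference <- build_control_reference(control_nested, site = site,
                                       n_boot = config$n_boot,
                                       seed = config$seed)

  injury <- list(); summaries <- list(); hists <- list(); tests <- list()
  treated_nested <- if (!is.null(values$treated)) nest(values$treated) else NULL
  for (cls in names(class_names())) {
    for (par in param_names()) {
      key <- paste(cls, par, sep = ".")
      cut <- reference$cutoff[reference$class == cls & reference$parameter == par]
      ctl <- injury_group(control_nested[[cls]][[par]], cut)
      injury[[key]] <- list(control = ctl)
      summaries[[key]] <- list(control = group_summary(control_nested[[cls]][[par]]))
      bw <- if (par == "offset") config$bin_width_offset else config$bin_width_time
      hists[[key]] <- list(control = build_histogram(
        unlist(control_nested[[cls]][[par]], use.names = FALSE), bin_width = bw))
      if (!is.null(treated_nested)) {
        trt <- injury_group(treated_nested[[cls]][[par]], cut)
        injury[[key]]$treated <- trt
        summaries[[key]]$treated <- group_summary(treated_nested[[cls]][[par]])
        hists[[key]]$treated <- build_histogram(
          unlist(treated_nested[[cls]][[par]], use.names = FALSE), bin_width = bw)
        tests[[key]] <- rank_sum_test(trt$index, ctl$index)
      }
    }
  }

  summary_df <- do.call(rbind, lapply(names(injury), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    ref_row <- reference[reference$class == parts[1] &
                           reference$parameter == parts[2], ]
    data.frame(class = parts[1], parameter = parts[2],
               cutoff = ref_row$cutoff,
               cl_low = ref_row$cl_low, cl_high = ref_row$cl_high,
               control_mean_median = summaries[[key]]$control$mean_median,
               control_sem_median = summaries[[key]]$control$sem_median,
               control_injury_mean = injury[[key]]$control$mean,
               control_injury_sem = injury[[key]]$control$sem,
               treated_mean_median = if (!is.null(summaries[[key]]$treated))
                 summaries[[key]]$treated$mean_median else NA_real_,
               treated_outside_cl = if (!is.null(summaries[[key]]$treated))
                 flag_outside_cl(summaries[[key]]$treated$mean_median,
                                 c(ref_row$cl_low, ref_row$cl_high)) else NA,
               treated_injury_mean = if (!is.null(injury[[key]]$treated))
                 injury[[key]]$treated$mean else NA_real_,
               treated_injury_sem = if (!is.null(injury[[key]]$treated))
                 injury[[key]]$treated$sem else NA_real_,
               p_rank_sum = if (!is.null(tests[[key]])) tests[[key]]$p else NA_real_,
               stringsAsFactors = FALSE)
  }))

  prov <- list(config_hash = config_hash(config), seed = config$seed,
               package_version = as.character(utils::packageVersion("angiodyn")),
               n_control = config$n_control, n_treated = config$n_treated,
               errors = errors)
  out <- structure(list(reference = reference, injury = injury,
                        summaries = summaries, histograms = hists,
                        rank_sum = tests, summary = summary_df,
                        errors = errors, censored = censored,
                        provenance = prov, config = config),
                   class = "angio_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_reference(reference, file.path(out_dir, "reference.json"))
    utils::write.csv(summary_df, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' @export
print.angio_experiment <- function(x, ...) {
  cat(sprintf("Simulated angiography study (%s): %d control, %d treated animals\n",
              x$config$scene$layout, x$config$n_control, x$config$n_treated))
  if (length(x$errors))
    cat(sprintf("  %d animal(s) failed: %s\n", length(x$errors),
                paste(names(x$errors), collapse = ", ")))
  df <- x$summary
  cat("\nIndex of injury (% pixels beyond control 75% cutoff; null = 25%):\n")
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-10s %-10s control %5.1f +/- %4.1f  treated %5.1f +/- %4.1f  p = %.3g\n",
                df$class[i], df$parameter[i],
                df$control_injury_mean[i], df$control_injury_sem[i],
                df$treated_injury_mean[i], df$treated_injury_sem[i],
                df$p_rank_sum[i]))
  }
  invisible(x)
}

#' Summarize a simulated study
#'
#' @param object an `angio_experiment`.
#' @param ... unused.
#' @return The summary data.frame (one row per class and parameter).
#' @export
summary.angio_experiment <- function(object, ...) object$summary

#' Plot injury indices of a simulated study
#'
#' Group-mean index of injury with 2 SEM error bars per class and
#' parameter, against the 25% null reference line.
#'
#' @param x an `angio_experiment`.
#' @param ... unused.
#' @export
plot.angio_experiment <- function(x, ...) {
  df <- x$summary
  n <- nrow(df)
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(0, 100), xaxt = "n",
                 xlab = "", ylab = "index of injury (% pixels)",
                 main = "Index of injury vs 25% null")
  graphics::axis(1, at = seq_len(n),
                 labels = paste(df$class, df$parameter, sep = "\n"),
                 cex.axis = 0.6, las = 2)
  graphics::abline(h = 25, lty = 2)
  graphics::points(seq_len(n) - 0.1, df$control_injury_mean, pch = 16, col = "grey40")
  graphics::arrows(seq_len(n) - 0.1, df$control_injury_mean - 2 * df$control_injury_sem,
                   seq_len(n) - 0.1, df$control_injury_mean + 2 * df$control_injury_sem,
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  if (!all(is.na(df$treated_injury_mean))) {
    graphics::points(seq_len(n) + 0.1, df$treated_injury_mean, pch = 16, col = "firebrick")
    graphics::arrows(seq_len(n) + 0.1, df$treated_injury_mean - 2 * df$treated_injury_sem,
                     seq_len(n) + 0.1, df$treated_injury_mean + 2 * df$treated_injury_sem,
                     angle = 90, code = 3, length = 0.03, col = "firebrick")
  }
  invisible(x)
}
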