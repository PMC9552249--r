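#' Pipeline configuration
#'
#' Collects every tunable of the whole-slide pipeline in one serializable
#' object: pixel scale, HPF geometry, scan and patch strides, the area
#' counting rule, the activity cutoff, thresholds and conventions. The
#' defaults are the pipeline's reference operating point. Round-trips
#' unchanged through JSON ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param microns_per_pixel Scanner scale, um/px.
#' @param hpf_area_mm2 HPF area. Default 0.3.
#' @param scan_stride HPF scan stride in px. Default 500.
#' @param patch,patch_stride Patch grid inside a window. Defaults 448 / 424.
#' @param min_area,one_cell_max,increment,increment_mode Counting rule, see
#'   [counting_rule()].
#' @param activity_threshold Active-EoE cutoff in eosinophils/HPF. Default 15.
#' @param prob_threshold Softmax threshold. Default 0.5.
#' @param connectivity Component connectivity, 8 or 4.
#' @param empty_metric Zero-denominator convention for [mean_metric()].
#' @param background_filter_mode See [filter_patches()].
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(microns_per_pixel = unclass(pixel_scale()),
                            hpf_area_mm2 = 0.3, scan_stride = 500,
                            patch = 448, patch_stride = 424,
                            min_area = 1800, one_cell_max = 3000,
                            increment = 2000, increment_mode = "floor",
                            activity_threshold = 15, prob_threshold = 0.5,
                            connectivity = 8, empty_metric = "score",
                            background_filter_mode = "drop_below", seed = 0L) {
  cfg <- list(microns_per_pixel = microns_per_pixel, hpf_area_mm2 = hpf_area_mm2,
              scan_stride = as.integer(scan_stride), patch = as.integer(patch),
              patch_stride = as.integer(patch_stride),
              min_area = min_area, one_cell_max = one_cell_max,
              increment = increment, increment_mode = increment_mode,
              activity_threshold = activity_threshold,
              prob_threshold = prob_threshold,
              connectivity = as.integer(connectivity),
              empty_metric = empty_metric,
              background_filter_mode = background_filter_mode,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

config_rule <- function(config) {
  counting_rule(config$min_area, config$one_cell_max, config$increment,
                config$increment_mode)
}

#' Run the whole-slide pipeline over a set of slides
#'
#' For every slide: scan with the sliding high-power field
#' ([peak_eos_count()]), record the PEC and its window, classify activity at
#' the configured cutoff, and assemble the ranked slide list. When
#' pathologist PEC labels are supplied, the run is also scored: activity
#' [classification_metrics()] at the same cutoff and a [roc_sweep()] over
#' the predicted counts.
#'
#' @param slides Named list of slide inputs (anything [as_slide_source()]
#'   accepts). Names become slide ids.
#' @param segmenter One [new_segmenter()] shared by all slides, or a list of
#'   segmenters parallel to `slides` (required for per-slide oracles).
#' @param config A [pipeline_config()].
#' @param true_pecs Optional named numeric vector of pathologist PECs
#'   (names matching `slides`).
#' @return A list of class `pipeline_result`: `reports` (ranked tibble with
#'   `slide_id`, `pec`, `peak_row`, `peak_col`, `window_side`, `active`,
#'   `rank`), `metrics` (one-row tibble or `NULL`), `roc` (an `eos_roc` or
#'   `NULL`), `config`.
#' @export
run_pipeline <- function(slides, segmenter, config = pipeline_config(),
                         true_pecs = NULL) {
  if (!length(slides)) stop("empty slide list", call. = FALSE)
  if (is.null(names(slides)) || any(names(slides) == "")) {
    names(slides) <- sprintf("slide_%03d", seq_along(slides))
  }
  segs <- if (inherits(segmenter, "eos_segmenter")) {
    rep(list(segmenter), length(slides))
  } else {
    stopifnot(length(segmenter) == length(slides))
    segmenter
  }
  scale <- pixel_scale(config$microns_per_pixel)
  hpf_side <- hpf_side_pixels(config$hpf_area_mm2, scale)
  rule <- config_rule(config)
  reports <- purrr::map_dfr(seq_along(slides), function(i) {
    res <- peak_eos_count(slides[[i]], segs[[i]], hpf_side = hpf_side,
                          scan_stride = config$scan_stride,
                          patch = config$patch, patch_stride = config$patch_stride,
                          rule = rule, prob_threshold = config$prob_threshold,
                          connectivity = config$connectivity)
    tibble::tibble(slide_id = names(slides)[[i]], pec = res$pec,
                   peak_row = res$peak$row, peak_col = res$peak$col,
                   window_side = res$peak$height,
                   not_intact_at_peak = res$peak_not_intact,
                   active = classify_activity(res$pec, config$activity_threshold))
  })
  reports <- ranked_slide_list(reports)
  metrics <- NULL; roc <- NULL
  if (!is.null(true_pecs)) {
    truth <- true_pecs[reports$slide_id]
    true_active <- classify_activity(truth, config$activity_threshold) == "active"
    metrics <- classification_metrics(reports$active == "active", true_active)
    if (any(true_active) && !all(true_active)) {
      roc <- roc_sweep(reports$pec, true_active)
    }
  }
  structure(list(reports = reports, metrics = metrics, roc = roc, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d slides; %d active at threshold %g\n",
              nrow(x$reports), sum(x$reports$active == "active"),
              x$config$activity_threshold))
  print(x$reports)
  if (!is.null(x$metrics)) {
    cat(sprintf("accuracy %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
                x$metrics$accuracy, x$metrics$tpr, x$metrics$tnr))
  }
  invisible(x)
}

#' Write a slide report as JSON
#'
#' Persists the per-slide findings (PEC, peak window, activity call, rank)
#' plus the configuration, so every report field can be reconstructed from
#' the saved artifacts.
#'
#' @param result A `pipeline_result` from [run_pipeline()].
#' @param path JSON file path.
#' @export
write_slide_reports <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  payload <- list(reports = result$reports,
                  config = unclass(result$config))
  if (!is.null(result$metrics)) payload$metrics <- result$metrics
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Plot the scanned windows of a PEC result
#'
#' Shows every scanned high-power-field window as a tile colored by its
#' intact count, with the peak window outlined — a quick audit of where the
#' diagnostic count came from.
#'
#' @param object A `pec_result` from [peak_eos_count()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pec_result <- function(object, ...) {
  w <- object$windows
  peak <- object$peak
  ggplot2::ggplot(w, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$intact)) +
    ggplot2::geom_tile(width = object$scan_stride * 0.95,
                       height = object$scan_stride * 0.95) +
    ggplot2::annotate("rect", xmin = peak$col, xmax = peak$col + peak$width,
                      ymin = peak$row, ymax = peak$row + peak$height,
                      colour = "red", fill = NA, linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "intact count") +
    ggplot2::labs(x = "column (px)", y = "row (px)",
                  title = sprintf("PEC %d at (%d, %d)", object$pec,
                                  peak$row, peak$col)) +
    ggplot2::theme_minimal()
}
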