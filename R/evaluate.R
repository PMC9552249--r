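#' ROC threshold sweep over peak eosinophil counts
#'
#' Sweeps the activity-classification threshold over all midpoints between
#' distinct observed PEC values (plus sentinels below and above the range),
#' classifying a slide active when `pec >= threshold`. Returns the ROC
#' points, the trapezoidal area under the curve, and the threshold that
#' maximizes accuracy (smallest such threshold on ties). With truth labels
#' produced by the clinical >= 15 cutoff and counts near truth, the optimal
#' threshold lands at 14.5 — the midpoint just below 15.
#'
#' @param pecs Numeric PEC per slide.
#' @param true_labels Logical (`TRUE` = active) or `"active"`/`"not_active"`.
#' @return An `eos_roc` object: list with `points` (tibble `threshold`,
#'   `tpr`, `fpr`, `accuracy`), `auc`, `best_threshold`, `n`.
#' @examples
#' r <- roc_sweep(c(2, 9, 14, 16, 30, 40), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
#' r$auc; r$best_threshold
#' @export
roc_sweep <- function(pecs, true_labels) {
  g <- if (is.logical(true_labels)) true_labels else true_labels == "active"
  stopifnot(length(pecs) == length(g), length(g) > 0)
  if (all(g) || !any(g)) {
    stop("both classes must be present to sweep a ROC curve", call. = FALSE)
  }
  v <- sort(unique(pecs))
  mids <- if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2 else numeric(0)
  thr <- c(min(v) - 1, mids, max(v) + 1)   # below-range => all active; above => none
  pos <- sum(g); neg <- sum(!g)
  pts <- purrr::map_dfr(thr, function(t) {
    p <- pecs >= t
    tibble::tibble(threshold = t,
                   tpr = sum(p & g) / pos,
                   fpr = sum(p & !g) / neg,
                   accuracy = mean(p == g))
  })
  ord <- order(pts$fpr, pts$tpr)
  auc <- sum(diff(pts$fpr[ord]) * (pts$tpr[ord][-1L] + pts$tpr[ord][-nrow(pts)]) / 2)
  best <- min(pts$threshold[pts$accuracy == max(pts$accuracy)])
  structure(list(points = pts, auc = auc, best_threshold = best, n = length(g)),
            class = "eos_roc")
}

#' @export
print.eos_roc <- function(x, ...) {
  cat(sprintf("<eos_roc> n = %d, AUC = %.4f, best threshold = %g\n",
              x$n, x$auc, x$best_threshold))
  invisible(x)
}

#' @rdname roc_sweep
#' @param x An `eos_roc` object.
#' @param ... Unused.
#' @export
tidy.eos_roc <- function(x, ...) x$points

#' @rdname roc_sweep
#' @export
glance.eos_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, best_threshold = x$best_threshold, n = x$n)
}

#' @rdname roc_sweep
#' @param object An `eos_roc` object.
#' @export
autoplot.eos_roc <- function(object, ...) {
  pts <- dplyr::arrange(object$points, .data$fpr, .data$tpr)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Fall-out (FPR)", y = "Sensitivity (TPR)",
                  title = sprintf("PEC threshold sweep (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Calibration of predicted against true eosinophil counts
#'
#' Ordinary least squares of predicted counts on true counts, plus the mean
#' absolute counting error. An unbiased counter gives slope ~1 and
#' intercept ~0.
#'
#' @param pred_counts,true_counts Numeric vectors of equal length, `n >= 3`.
#' @return An `eos_calibration` object: list with `slope`, `intercept`,
#'   `r_squared`, `mean_abs_error`, `n` and the underlying `stats::lm` fit.
#' @examples
#' fit <- count_calibration(c(1, 2, 3, 5), c(1, 2, 3, 4))
#' glance(fit)
#' @export
count_calibration <- function(pred_counts, true_counts) {
  stopifnot(length(pred_counts) == length(true_counts))
  if (length(true_counts) < 3L) stop("need n >= 3 pairs", call. = FALSE)
  if (stats::var(true_counts) == 0) {
    stop("true counts are constant; the calibration slope is undefined", call. = FALSE)
  }
  fit <- stats::lm(pred ~ true,
                   data = data.frame(pred = pred_counts, true = true_counts))
  structure(list(
    slope = unname(stats::coef(fit)[["true"]]),
    intercept = unname(stats::coef(fit)[["(Intercept)"]]),
    # suppress the "essentially perfect fit" note: exact counters are expected
    r_squared = suppressWarnings(summary(fit)$r.squared),
    mean_abs_error = mean(abs(pred_counts - true_counts)),
    n = length(true_counts), fit = fit
  ), class = "eos_calibration")
}

#' @export
print.eos_calibration <- function(x, ...) {
  cat(sprintf("<eos_calibration> slope %.3f, intercept %.3f, R^2 %.4f, MAE %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$mean_abs_error, x$n))
  invisible(x)
}

#' @rdname count_calibration
#' @param x,object An `eos_calibration` object.
#' @param ... Unused.
#' @export
tidy.eos_calibration <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = unname(s[, "Estimate"]),
                 std_error = unname(s[, "Std. Error"]),
                 p_value = unname(s[, "Pr(>|t|)"]))
}

#' @rdname count_calibration
#' @export
glance.eos_calibration <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, mean_abs_error = x$mean_abs_error,
                 n = x$n)
}

#' @rdname count_calibration
#' @export
autoplot.eos_calibration <- function(object, ...) {
  df <- stats::model.frame(object$fit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = "True count", y = "Predicted count",
                  title = sprintf("Count calibration: slope %.3f, MAE %.3f",
                                  object$slope, object$mean_abs_error)) +
    ggplot2::theme_minimal()
}

#' Segment-level detection error statistics
#'
#' Matches predicted connected components against ground-truth components of
#' the same class. A predicted component is a true detection when it overlaps
#' at least one pixel of a still-unmatched true component (matching is greedy
#' by overlap size; each true component can absorb one prediction). Reports
#' the component false discovery rate (unmatched predictions over all
#' predictions; 0 when nothing is predicted) and the counting error rate
#' `|predicted count - true count| / max(true count, 1)`.
#'
#' @param pred,truth [label_masks()] of equal extent.
#' @param class `"intact"` or `"not_intact"`.
#' @param rule A [counting_rule()] used for both counts.
#' @param connectivity Component connectivity, 8 or 4.
#' @return A one-row tibble: `n_pred`, `n_true`, `n_matched`, `fdr`,
#'   `count_error_rate`, `pred_count`, `true_count`.
#' @export
segment_error_stats <- function(pred, truth, class = "intact",
                                rule = counting_rule(), connectivity = 8) {
  stopifnot(inherits(pred, "label_masks"), inherits(truth, "label_masks"))
  if (!identical(unname(mask_extent(pred)), unname(mask_extent(truth)))) {
    stop("prediction and truth extents differ", call. = FALSE)
  }
  pl <- label_components(pred[[class]], connectivity)
  tl <- label_components(truth[[class]], connectivity)
  np <- max(pl); nt <- max(tl)
  both <- pl > 0L & tl > 0L
  matched_p <- logical(np); matched_t <- logical(nt)
  if (any(both)) {
    ov <- table(p = pl[both], t = tl[both])
    df <- as.data.frame(ov, stringsAsFactors = FALSE)
    df$p <- as.integer(df$p); df$t <- as.integer(df$t)
    df <- df[df$Freq > 0, , drop = FALSE]
    # largest overlap first; ties broken by component ids for determinism
    df <- df[order(-df$Freq, df$p, df$t), , drop = FALSE]
    for (k in seq_len(nrow(df))) {
      pi <- df$p[[k]]; ti <- df$t[[k]]
      if (!matched_p[pi] && !matched_t[ti]) {
        matched_p[pi] <- TRUE; matched_t[ti] <- TRUE
      }
    }
  }
  pc <- count_eosinophils(pred, class, rule, connectivity)$count
  tc <- count_eosinophils(truth, class, rule, connectivity)$count
  tibble::tibble(
    n_pred = np, n_true = nt, n_matched = sum(matched_p),
    fdr = if (np > 0) (np - sum(matched_p)) / np else 0,
    count_error_rate = abs(pc - tc) / max(tc, 1),
    pred_count = pc, true_count = tc
  )
}
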