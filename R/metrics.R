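#' Per-class pixel confusion counts for one image
#'
#' Compares a predicted mask stack against ground truth and tallies, per
#' class, the pixel-level true positives, false positives, false negatives
#' and true negatives. These four counts are the raw material for every
#' segmentation metric in the package; keeping them per image (rather than
#' pooled over a batch) avoids bias from the many patches that contain no
#' eosinophils at all.
#'
#' @param pred,truth [label_masks()] of equal extent.
#' @param image_id Identifier recorded in the output. Default `"image"`.
#' @return A tibble with one row per class: `image`, `class`, `tp`, `fp`,
#'   `fn`, `tn`. Rows always satisfy `tp + fp + fn + tn = npixels`.
#' @examples
#' m <- label_masks(extent = extent(8, 8))
#' confusion_counts(m, m)
#' @export
confusion_counts <- function(pred, truth, image_id = "image") {
  stopifnot(inherits(pred, "label_masks"), inherits(truth, "label_masks"))
  if (!identical(unname(mask_extent(pred)), unname(mask_extent(truth)))) {
    stop("prediction and truth extents differ", call. = FALSE)
  }
  purrr::map_dfr(mask_classes(), function(cls) {
    p <- pred[[cls]]; g <- truth[[cls]]
    tp <- sum(p & g)
    fp <- sum(p & !g)
    fn <- sum(!p & g)
    tibble::tibble(image = image_id, class = cls,
                   tp = tp, fp = fp, fn = fn, tn = length(p) - tp - fp - fn)
  })
}

metric_kinds <- function() c("iou", "precision", "recall", "specificity")

#' Mean segmentation metric over images and classes
#'
#' Averages a per-(image, class) ratio over every row of a confusion-count
#' table: `mIoU = mean(TP / (TP + FP + FN))`, `mPrecision = mean(TP / (TP + FP))`,
#' `mRecall = mean(TP / (TP + FN))`, `mSpecificity = mean(TN / (TN + FP))`,
#' the mean running over all images and both eosinophil classes.
#'
#' A term with a zero denominator needs a convention (common here, since many
#' patches contain no eosinophils of a class). Under `empty = "score"`
#' (default) such a term scores 1 when the situation is vacuously perfect
#' (e.g. empty truth and empty prediction) and 0 otherwise (e.g. empty truth
#' but spurious prediction); under `empty = "skip"` the term is dropped from
#' the average.
#'
#' @param counts A confusion-count tibble from [confusion_counts()] (rows from
#'   several images can be combined with `dplyr::bind_rows()`).
#' @param kind One of `"iou"`, `"precision"`, `"recall"`, `"specificity"`.
#' @param empty Zero-denominator convention, `"score"` or `"skip"`.
#' @return A single score in `[0, 1]`.
#' @export
mean_metric <- function(counts, kind = metric_kinds(), empty = c("score", "skip")) {
  kind <- match.arg(kind)
  empty <- match.arg(empty)
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  num <- switch(kind, iou = tp, precision = tp, recall = tp, specificity = tn)
  den <- switch(kind,
                iou = tp + fp + fn,
                precision = tp + fp,
                recall = tp + fn,
                specificity = tn + fp)
  # when the denominator is empty, is the complementary side also empty?
  vacuous <- switch(kind,
                    iou = TRUE,                 # den 0 => truth and pred both empty
                    precision = fn == 0,        # no predictions; perfect iff no truth missed
                    recall = fp == 0,           # no truth; perfect iff nothing predicted
                    specificity = rep(TRUE, length(tp)))  # den 0 forces fp = 0
  term <- ifelse(den > 0, num / den, as.numeric(vacuous))
  if (empty == "skip") term <- term[den > 0]
  if (!length(term)) return(NA_real_)
  mean(term)
}

#' Precision/recall weighted-average selection metric
#'
#' The per-image selection metric `alpha * mPrecision + (1 - alpha) * mRecall`
#' used to steer checkpoint selection during training. Together with mIoU,
#' mRecall and mPrecision, the weights `alpha` in {0.3, 0.4, 0.5, 0.6, 0.7}
#' form the eight candidate selection metrics compared by [rank_models()].
#'
#' @inheritParams mean_metric
#' @param alpha Precision weight in `[0, 1]`.
#' @return A single score in `[0, 1]`.
#' @export
weighted_pr <- function(counts, alpha, empty = c("score", "skip")) {
  empty <- match.arg(empty)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single number in [0, 1]", call. = FALSE)
  }
  alpha * mean_metric(counts, "precision", empty) +
    (1 - alpha) * mean_metric(counts, "recall", empty)
}

#' Binary activity-classification metrics
#'
#' Scores predicted active/not-active labels against the truth with the
#' standard confusion-matrix ratios, reported as percentages: Accuracy,
#' F1-score (harmonic mean of precision and recall of the active class),
#' Miss-rate (FNR), Fall-out (FPR), Specificity (TNR) and Sensitivity (TPR).
#'
#' @param pred_labels,true_labels Equal-length logical vectors (`TRUE` =
#'   active) or vectors coercible to logical via `== "active"`.
#' @return A one-row tibble with columns `accuracy`, `f1`, `fnr`, `fpr`,
#'   `tnr`, `tpr` (percent) and the raw counts `tp`, `fp`, `fn`, `tn`.
#' @examples
#' classification_metrics(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE))
#' @export
classification_metrics <- function(pred_labels, true_labels) {
  as_active <- function(x) if (is.logical(x)) x else x == "active"
  p <- as_active(pred_labels); g <- as_active(true_labels)
  if (!length(p) || length(p) != length(g)) {
    stop("label vectors must be non-empty and of equal length", call. = FALSE)
  }
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  pos <- tp + fn; neg <- tn + fp
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (pos > 0) tp / pos else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else NA_real_
  pct <- function(x) 100 * x
  tibble::tibble(
    accuracy = pct((tp + tn) / length(p)),
    f1 = pct(f1),
    fnr = pct(if (pos > 0) fn / pos else NA_real_),
    fpr = pct(if (neg > 0) fp / neg else NA_real_),
    tnr = pct(if (neg > 0) tn / neg else NA_real_),
    tpr = pct(if (pos > 0) tp / pos else NA_real_),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

# Standard competition ("1224") ranking: best score gets rank 1, tied scores
# share a rank, and the next distinct score skips by the tie count.
competition_rank <- function(x, higher_better = TRUE) {
  v <- if (higher_better) -x else x
  as.integer(rank(v, ties.method = "min"))
}

#' Rank candidate models across quantification and classification metrics
#'
#' Implements competition-rank model selection over a score table: each
#' metric column is ranked independently (competition ranking: ties share a
#' rank, the next rank skips by the tie count), with "better" meaning higher
#' for Accuracy, F1, Specificity and Sensitivity and lower for mean count
#' error, Miss-rate and Fall-out. The Mean Rank of a model is the arithmetic
#' mean of its six classification-metric ranks — the count-error rank is
#' reported alongside but kept out of the mean — and the Final Rank is the
#' competition rank of the Mean Rank (ascending).
#'
#' @param scores A tibble with a `model` column and numeric columns
#'   `count_error`, `accuracy`, `f1`, `fnr`, `fpr`, `tnr`, `tpr` (percent
#'   scales for the latter six). See [selection_scores()] for a worked table.
#' @return `scores` with added integer rank columns (`rank_count_error`,
#'   `rank_accuracy`, ..., `rank_tpr`), `mean_rank` (rounded to 2 decimals)
#'   and `final_rank`.
#' @examples
#' rank_models(selection_scores())
#' @export
rank_models <- function(scores) {
  needed <- c("model", "count_error", "accuracy", "f1", "fnr", "fpr", "tnr", "tpr")
  missing <- setdiff(needed, names(scores))
  if (length(missing)) {
    stop("score table is missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(scores) < 2L) stop("need at least 2 models to rank", call. = FALSE)
  higher <- c(count_error = FALSE, accuracy = TRUE, f1 = TRUE,
              fnr = FALSE, fpr = FALSE, tnr = TRUE, tpr = TRUE)
  out <- tibble::as_tibble(scores)
  for (m in names(higher)) {
    out[[paste0("rank_", m)]] <- competition_rank(out[[m]], higher[[m]])
  }
  class_ranks <- paste0("rank_", c("accuracy", "f1", "fnr", "fpr", "tnr", "tpr"))
  out$mean_rank <- round(rowMeans(as.matrix(out[class_ranks])), 2)
  out$final_rank <- competition_rank(out$mean_rank, higher_better = FALSE)
  out
}

#' Bundled model-selection score table
#'
#' The validation scores of eight segmentation models, each trained with a
#' different per-image checkpoint-selection metric (mIoU, mRecall,
#' mPrecision, and weighted precision/recall means `m(aP + (1-a)R)` for
#' `a` in 0.3..0.7): mean intact-eosinophil count error plus the six
#' activity-classification metrics. Used as the worked example for
#' [rank_models()]; the arithmetic precision/recall mean `m(0.5P + 0.5R)`
#' wins the final rank on this table.
#'
#' @return A tibble with columns `model`, `count_error`, `accuracy`, `f1`,
#'   `fnr`, `fpr`, `tnr`, `tpr`.
#' @export
selection_scores <- function() {
  path <- system.file("extdata", "selection_scores.csv", package = "eoescan",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = TRUE)
  tibble::as_tibble(df)
}
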