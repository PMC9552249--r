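#' Three-class probability map
#'
#' Per-pixel softmax probabilities for the classes `background`, `intact`
#' and `not_intact`. Values lie in `[0, 1]` and sum to 1 across classes at
#' every pixel.
#'
#' @param x A numeric array `height x width x 3`, third dimension ordered
#'   (or dim-named) `background`, `intact`, `not_intact`.
#' @param validate Check ranges and per-pixel sums (default). Internal
#'   producers that construct valid maps by design may skip this.
#' @return An object of class `prob_map`.
#' @export
prob_map <- function(x, validate = TRUE) {
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3L] == 3L)
  nm <- dimnames(x)[[3L]]
  if (!is.null(nm)) {
    stopifnot(setequal(nm, prob_classes()))
    x <- x[, , prob_classes(), drop = FALSE]
  } else {
    dimnames(x) <- list(NULL, NULL, prob_classes())
  }
  if (validate) {
    if (min(x) < -1e-6 || max(x) > 1 + 1e-6) {
      stop("probabilities must lie in [0, 1]", call. = FALSE)
    }
    sums <- x[, , 1L] + x[, , 2L] + x[, , 3L]
    if (max(abs(sums - 1)) > 1e-4) {
      stop("class probabilities must sum to 1 at every pixel", call. = FALSE)
    }
  }
  structure(x, class = "prob_map")
}

prob_classes <- function() c("background", "intact", "not_intact")

#' Threshold a probability map into label masks
#'
#' A pixel is assigned to the eosinophil class with the larger probability,
#' but only when that probability reaches the threshold; otherwise it is
#' background. At most one class can therefore be set at any pixel.
#'
#' @param probs A [prob_map()].
#' @param threshold Softmax probability threshold in `(0, 1)`. Default 0.5.
#' @return A [label_masks()].
#' @export
threshold_probabilities <- function(probs, threshold = 0.5) {
  stopifnot(inherits(probs, "prob_map"))
  p_int <- probs[, , "intact"]; p_not <- probs[, , "not_intact"]
  take_int <- p_int >= p_not    # intact wins exact ties
  hit <- pmax(p_int, p_not) >= threshold
  new_label_masks(hit & take_int, hit & !take_int)
}

#' Combined Dice + binary cross-entropy segmentation loss
#'
#' The training loss of the reference segmenter: a soft Dice loss and a
#' binary cross-entropy, each averaged over the two eosinophil classes and
#' combined with weights 1.0 (Dice) and 0.5 (BCE). Per class,
#' `dice = 1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)` on the soft
#' probabilities, with additive smoothing `eps` stabilising empty masks, and
#' `bce = -mean(g * log p + (1 - g) * log(1 - p))`.
#'
#' @param pred A [prob_map()].
#' @param truth A [label_masks()] of the same extent.
#' @param weights Named numeric `c(dice = 1, bce = 0.5)`.
#' @param eps Dice smoothing constant. Default 1.
#' @return Scalar loss (>= 0; 0 only for a perfect hard prediction, up to eps).
#' @export
combined_loss <- function(pred, truth, weights = c(dice = 1, bce = 0.5), eps = 1) {
  stopifnot(inherits(pred, "prob_map"), inherits(truth, "label_masks"))
  ext <- mask_extent(truth)
  if (!identical(unname(dim(pred)[1:2]), unname(c(ext[["height"]], ext[["width"]])))) {
    stop("prediction and truth extents differ", call. = FALSE)
  }
  dice <- bce <- numeric(0)
  for (cls in mask_classes()) {
    p <- pred[, , cls]
    g <- truth[[cls]] * 1
    dice <- c(dice, 1 - (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps))
    pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
    bce <- c(bce, -mean(g * log(pc) + (1 - g) * log(1 - pc)))
  }
  unname(weights[["dice"]] * mean(dice) + weights[["bce"]] * mean(bce))
}

#' Cosine-annealing learning-rate schedule
#'
#' `lr(t) = lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * t / T))`:
#' starts at `lr_max`, decays to `lr_min` at epoch `T` along a half cosine.
#'
#' @param t Current epoch, `0 <= t <= T`.
#' @param T Total epochs.
#' @param lr_max,lr_min Schedule endpoints.
#' @return Learning rate at epoch `t`.
#' @export
cosine_annealing_lr <- function(t, T, lr_max = 1e-3, lr_min = 0) {
  if (any(t < 0) || any(t > T)) stop("epoch `t` must satisfy 0 <= t <= T", call. = FALSE)
  lr_min + 0.5 * (lr_max - lr_min) * (1 + cos(pi * t / T))
}

#' Segmenter objects
#'
#' A segmenter is a callable contract: given an RGB tile and its absolute
#' top-left offset within the slide, it returns a [prob_map()] of the tile's
#' extent. Model-based segmenters use only the pixels; the ground-truth
#' oracle uses only the offset. `predict_tile()` invokes the contract.
#'
#' @param predict_fn `function(tile, offset, size)` returning a [prob_map()];
#'   `tile` may be `NULL` for segmenters that do not consume pixels, in which
#'   case `size` (an [extent()]) defines the output extent.
#' @param name Human-readable label.
#' @param meta Arbitrary metadata list (e.g. training config).
#' @return An object of class `eos_segmenter`.
#' @export
new_segmenter <- function(predict_fn, name = "segmenter", meta = list()) {
  stopifnot(is.function(predict_fn))
  structure(list(predict = predict_fn, name = name, meta = meta),
            class = "eos_segmenter")
}

#' @rdname new_segmenter
#' @param segmenter An `eos_segmenter`.
#' @param tile RGB array `h x w x 3` in `[0, 1]`, or `NULL`.
#' @param offset 0-based `c(row, col)` of the tile within the slide.
#' @param size Tile [extent()]; defaults to the tile's own dimensions.
#' @export
predict_tile <- function(segmenter, tile, offset = c(0L, 0L), size = NULL) {
  stopifnot(inherits(segmenter, "eos_segmenter"))
  if (is.null(size)) {
    if (is.null(tile)) stop("`size` is required when `tile` is NULL", call. = FALSE)
    size <- as_extent(tile)
  } else {
    size <- as_extent(size)
  }
  out <- segmenter$predict(tile, as.integer(offset), size)
  if (!inherits(out, "prob_map")) stop("segmenter did not return a prob_map", call. = FALSE)
  if (!identical(unname(dim(out)[1:2]), unname(c(size[["height"]], size[["width"]])))) {
    stop("segmenter output extent mismatch", call. = FALSE)
  }
  out
}

#' @export
print.eos_segmenter <- function(x, ...) {
  cat(sprintf("<eos_segmenter> %s\n", x$name))
  invisible(x)
}

masks_to_probs <- function(masks) {
  ext <- mask_extent(masks)
  i <- masks$intact * 1
  nn <- (!masks$intact & masks$not_intact) * 1
  arr <- array(c(1 - i - nn, i, nn), c(ext[["height"]], ext[["width"]], 3L),
               dimnames = list(NULL, NULL, prob_classes()))
  prob_map(arr, validate = FALSE)
}

#' Ground-truth oracle segmenter
#'
#' A test double for a trained network: it emits probability 1 for the true
#' class of every pixel, read from the supplied ground-truth masks at the
#' requested offset. With `flip_rate > 0` it corrupts the output — each
#' eosinophil pixel independently flips to background with that probability,
#' and each background pixel flips to a random eosinophil class — which lets
#' downstream robustness be exercised with a controlled error rate. Flips
#' are deterministic given `seed` and the tile offset.
#'
#' @param truth A [label_masks()] covering the whole slide.
#' @param flip_rate Per-pixel corruption probability in `[0, 1)`. Default 0.
#' @param seed Integer seed for the corruption noise.
#' @return An [new_segmenter()] honouring the segmenter contract.
#' @examples
#' truth <- rasterize_annotations(
#'   tibble::tibble(row = 32, col = 32, class = "intact"), extent(64, 64))
#' seg <- oracle_segmenter(truth)
#' pm <- predict_tile(seg, NULL, c(0, 0), size = extent(64, 64))
#' identical(threshold_probabilities(pm)$intact, truth$intact)
#' @export
oracle_segmenter <- function(truth, flip_rate = 0, seed = 0L) {
  stopifnot(inherits(truth, "label_masks"))
  if (flip_rate < 0 || flip_rate >= 1) stop("`flip_rate` must be in [0, 1)", call. = FALSE)
  predict_fn <- function(tile, offset, size) {
    m <- crop_masks(truth, offset[1L], offset[2L], size[["height"]], size[["width"]])
    if (flip_rate > 0) {
      h <- size[["height"]]; w <- size[["width"]]
      tile_seed <- (as.numeric(seed) * 2654435 + offset[1L] * 40503 + offset[2L] * 9973) %% 2^31
      m <- with_seed(as.integer(tile_seed), {
        flips <- matrix(stats::runif(h * w) < flip_rate, h, w)
        eos <- m$intact | m$not_intact
        new_int <- m$intact & !flips
        new_not <- m$not_intact & !flips
        promote <- flips & !eos
        if (any(promote)) {
          to_int <- matrix(stats::runif(h * w) < 0.5, h, w) & promote
          new_int <- new_int | to_int
          new_not <- new_not | (promote & !to_int)
        }
        label_masks(intact = new_int, not_intact = new_not)
      })
    }
    masks_to_probs(m)
  }
  new_segmenter(predict_fn, name = sprintf("oracle (flip_rate = %g)", flip_rate),
                meta = list(flip_rate = flip_rate, seed = seed))
}
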