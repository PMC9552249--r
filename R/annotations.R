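#' Read and write point annotations
#'
#' Expert annotations mark the center pixel of each eosinophil and its class.
#' The on-disk format is a UTF-8 CSV with header
#' `image_id,row,col,class`, coordinates 0-based pixels, and
#' `class` one of `intact`, `not_intact`.
#'
#' @param path CSV file path.
#' @return `read_annotations()` returns a tibble with columns `image_id`
#'   (character), `row`, `col` (integer) and `class` (character).
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("image_id", "row", "col", "class")
  if (!all(required %in% names(df))) {
    stop("annotation CSV must have columns image_id,row,col,class", call. = FALSE)
  }
  bad <- setdiff(unique(df$class), mask_classes())
  if (length(bad)) stop("unknown annotation class: ", paste(bad, collapse = ", "), call. = FALSE)
  tibble::tibble(image_id = as.character(df$image_id),
                 row = as.integer(df$row), col = as.integer(df$col),
                 class = df$class)
}

#' @rdname read_annotations
#' @param annotations A tibble with columns `image_id`, `row`, `col`, `class`.
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(c("image_id", "row", "col", "class") %in% names(annotations)))
  utils::write.csv(annotations[, c("image_id", "row", "col", "class")], path,
                   row.names = FALSE, fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Rasterize point annotations into label masks
#'
#' Expands each annotated center into a solid disk of the given diameter
#' (closed disk: pixels whose squared distance from the center is at most
#' `(diameter/2)^2`), clipped to the image extent, and unions the disks per
#' class. With the default 50 px diameter a disk in the open field covers
#' 1961 pixels, close to the area of a typical eosinophil (~2050 px) and
#' inside the 1800-3000 px one-cell counting band, so isolated annotations
#' round-trip to a count of one. Overlapping same-class disks merge; instance
#' identity is recovered downstream by connected components.
#'
#' @param points A tibble with columns `row`, `col` (0-based center pixels)
#'   and `class` in `c("intact", "not_intact")`; typically from
#'   [read_annotations()].
#' @param extent The image [extent()].
#' @param diameter Disk diameter in pixels (>= 1). Default 50.
#' @return A [label_masks()].
#' @examples
#' pts <- tibble::tibble(row = 50, col = 50, class = "intact")
#' m <- rasterize_annotations(pts, extent(100, 100))
#' sum(m$intact)   # ~pi * 25^2
#' @export
rasterize_annotations <- function(points, extent, diameter = 50) {
  ext <- as_extent(extent)
  if (diameter < 1) stop("`diameter` must be >= 1", call. = FALSE)
  h <- ext[["height"]]; w <- ext[["width"]]
  out <- list(intact = matrix(FALSE, h, w), not_intact = matrix(FALSE, h, w))
  if (nrow(points) == 0L) return(label_masks(out$intact, out$not_intact))
  outside <- points$row < 0 | points$row >= h | points$col < 0 | points$col >= w
  if (any(outside)) {
    p <- points[which(outside)[1L], ]
    stop(sprintf("annotation at (%d, %d) lies outside the %d x %d extent",
                 p$row, p$col, h, w), call. = FALSE)
  }
  r <- diameter / 2
  r2 <- r^2
  ri <- floor(r)   # integer reach of the disk
  for (k in seq_len(nrow(points))) {
    cls <- points$class[[k]]
    cr <- points$row[[k]]; cc <- points$col[[k]]
    rows <- max(0L, cr - ri):min(h - 1L, cr + ri)
    cols <- max(0L, cc - ri):min(w - 1L, cc + ri)
    dr2 <- (rows - cr)^2
    dc2 <- (cols - cc)^2
    disk <- outer(dr2, dc2, `+`) <= r2
    sub <- out[[cls]][rows + 1L, cols + 1L, drop = FALSE]
    out[[cls]][rows + 1L, cols + 1L] <- sub | disk
  }
  label_masks(out$intact, out$not_intact)
}

#' Fraction of background (glass) pixels in a patch
#'
#' A pixel counts as background when its mean channel intensity reaches the
#' white threshold; H&E tissue is darker and pinker than bare glass.
#'
#' @param patch An RGB array (height x width x 3) or grey matrix with values
#'   in `[0, 1]`.
#' @param white_threshold Intensity at or above which a pixel is background,
#'   as a fraction of full scale. Default 0.90.
#' @return Fraction of background pixels in `[0, 1]`.
#' @export
background_fraction <- function(patch, white_threshold = 0.90) {
  if (length(patch) == 0L) stop("`patch` is empty", call. = FALSE)
  grey <- if (is.matrix(patch)) patch else {
    stopifnot(length(dim(patch)) == 3L)
    (patch[, , 1L] + patch[, , 2L] + patch[, , 3L]) / 3
  }
  mean(grey >= white_threshold)
}

#' Filter patches by background fraction
#'
#' Training patches are filtered on how much bare glass they contain, to
#' balance how often tissue edges appear in the set. The rule direction is
#' ambiguous in common usage, so both readings are available:
#' `"drop_below"` (default, literal reading) removes patches whose background
#' fraction is below `threshold`; `"drop_above"` (tissue-poor reading) removes
#' patches whose background fraction exceeds `1 - threshold`.
#'
#' @param patches A tibble with a list-column `image` of RGB arrays, or a bare
#'   list of RGB arrays, or a tibble that already has a numeric
#'   `background_fraction` column.
#' @param threshold Background-fraction threshold in `[0, 1]`. Default 0.15.
#' @param mode `"drop_below"` or `"drop_above"`.
#' @param white_threshold Passed to [background_fraction()].
#' @return The kept patches as a tibble with a `background_fraction` column;
#'   the removed rows are attached as the `"removed"` attribute (so
#'   kept + removed always partition the input).
#' @export
filter_patches <- function(patches, threshold = 0.15,
                           mode = c("drop_below", "drop_above"),
                           white_threshold = 0.90) {
  mode <- match.arg(mode)
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]", call. = FALSE)
  if (!is.data.frame(patches)) patches <- tibble::tibble(image = patches)
  tbl <- tibble::as_tibble(patches)
  if (!"background_fraction" %in% names(tbl)) {
    tbl$background_fraction <- purrr::map_dbl(tbl$image, background_fraction,
                                              white_threshold = white_threshold)
  }
  drop <- if (mode == "drop_below") {
    tbl$background_fraction < threshold
  } else {
    tbl$background_fraction > 1 - threshold
  }
  kept <- tbl[!drop, , drop = FALSE]
  attr(kept, "removed") <- tbl[drop, , drop = FALSE]
  kept
}

#' Split ids into training and validation sets
#'
#' Deterministic random split given a seed; the training set takes
#' `round(train_fraction * N)` ids.
#'
#' @param ids Vector of at least two unique ids.
#' @param train_fraction Fraction assigned to training. Default 0.80.
#' @param seed Integer seed controlling the shuffle.
#' @return A list with `train` and `val` id vectors (disjoint, exhaustive),
#'   plus `train_fraction` and `seed`.
#' @examples
#' split_dataset(letters[1:10], seed = 1)
#' @export
split_dataset <- function(ids, train_fraction = 0.80, seed) {
  n <- length(ids)
  if (n < 2L) stop("need at least 2 ids to split", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be strictly between 0 and 1", call. = FALSE)
  }
  n_train <- as.integer(round(train_fraction * n))
  n_train <- max(1L, min(n - 1L, n_train))   # both sets non-empty
  shuffled <- with_seed(seed, sample(ids))
  list(train = shuffled[seq_len(n_train)],
       val = shuffled[(n_train + 1L):n],
       train_fraction = train_fraction, seed = seed)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
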