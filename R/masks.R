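#' Multi-label segmentation mask stack
#'
#' A `label_masks` object holds one logical matrix per eosinophil class over a
#' shared pixel grid. The two classes are `intact` (eosinophils with visible
#' red cytoplasmic granules and a nucleus — the only class that contributes to
#' the diagnostic count) and `not_intact` (granule fields or cells without a
#' visible nucleus). Pixels outside both masks are implicitly non-eosinophil
#' tissue or background.
#'
#' @param intact,not_intact Logical matrices of identical dimensions, or `NULL`
#'   to create empty (all-`FALSE`) masks over `extent`.
#' @param extent An [extent()]; required when both masks are `NULL`.
#' @return A `label_masks` object: a named list of logical matrices with an
#'   `extent` attribute.
#' @examples
#' m <- label_masks(extent = extent(64, 64))
#' mask_extent(m)
#' @export
label_masks <- function(intact = NULL, not_intact = NULL, extent = NULL) {
  if (is.null(intact) && is.null(not_intact)) {
    if (is.null(extent)) stop("supply masks or an extent", call. = FALSE)
    ext <- as_extent(extent)
    blank <- matrix(FALSE, ext[["height"]], ext[["width"]])
    intact <- blank
    not_intact <- blank
  } else {
    ref <- if (is.null(intact)) not_intact else intact
    ext <- as_extent(ref)
    blank <- matrix(FALSE, ext[["height"]], ext[["width"]])
    if (is.null(intact)) intact <- blank
    if (is.null(not_intact)) not_intact <- blank
  }
  coerce_mask <- function(m, what) {
    if (!is.matrix(m)) stop(sprintf("`%s` must be a matrix", what), call. = FALSE)
    if (!identical(dim(m), unname(c(ext[["height"]], ext[["width"]])))) {
      stop("mask dimensions disagree with the extent", call. = FALSE)
    }
    storage.mode(m) <- "logical"
    if (anyNA(m)) m[is.na(m)] <- FALSE
    m
  }
  structure(list(intact = coerce_mask(intact, "intact"),
                 not_intact = coerce_mask(not_intact, "not_intact")),
            extent = ext, class = "label_masks")
}

# Unchecked constructor for internal producers of known-good logical masks.
new_label_masks <- function(intact, not_intact) {
  structure(list(intact = intact, not_intact = not_intact),
            extent = extent(nrow(intact), ncol(intact)), class = "label_masks")
}

#' @rdname label_masks
#' @param x A `label_masks` object.
#' @export
mask_extent <- function(x) {
  stopifnot(inherits(x, "label_masks"))
  attr(x, "extent")
}

#' @export
print.label_masks <- function(x, ...) {
  ext <- mask_extent(x)
  cat(sprintf("<label_masks> %d x %d px; intact: %d px, not_intact: %d px\n",
              ext[["height"]], ext[["width"]],
              sum(x$intact), sum(x$not_intact)))
  invisible(x)
}

mask_classes <- function() c("intact", "not_intact")

# Crop a half-open [row, row+h) x [col, col+w) region (0-based offsets).
crop_masks <- function(masks, row, col, h, w) {
  ext <- mask_extent(masks)
  if (row < 0 || col < 0 || row + h > ext[["height"]] || col + w > ext[["width"]]) {
    stop(sprintf("crop at (%d, %d) extends beyond the extent", row, col), call. = FALSE)
  }
  ri <- (row + 1L):(row + h); ci <- (col + 1L):(col + w)
  new_label_masks(masks$intact[ri, ci, drop = FALSE],
                  masks$not_intact[ri, ci, drop = FALSE])
}

#' Fuse tile masks back into a full-extent mask by OR
#'
#' Reassembles per-tile mask stacks into one mask over the full extent: a
#' pixel is positive for a class iff any tile covering it marks it positive
#' (inclusive disjunction over overlapping regions). The result is invariant
#' to the order of the tiles, and fusing the same tile twice changes nothing.
#'
#' @param tiles A list of `list(offset = c(row, col), masks = label_masks)`
#'   entries; offsets are 0-based top-left corners.
#' @param extent The output [extent()].
#' @return A [label_masks()] over `extent`.
#' @examples
#' ext <- extent(8, 8)
#' tile <- label_masks(intact = matrix(TRUE, 4, 4))
#' fused <- fuse_masks(list(list(offset = c(0, 4), masks = tile)), ext)
#' sum(fused$intact)
#' @export
fuse_masks <- function(tiles, extent) {
  ext <- as_extent(extent)
  out <- lapply(mask_classes(), function(cls) matrix(FALSE, ext[["height"]], ext[["width"]]))
  names(out) <- mask_classes()
  for (t in tiles) {
    off <- as.integer(t$offset)
    m <- t$masks
    stopifnot(inherits(m, "label_masks"))
    text <- mask_extent(m)
    h <- text[["height"]]; w <- text[["width"]]
    if (off[1L] < 0L || off[2L] < 0L ||
        off[1L] + h > ext[["height"]] || off[2L] + w > ext[["width"]]) {
      stop(sprintf("tile at offset (%d, %d) extends beyond the extent", off[1L], off[2L]),
           call. = FALSE)
    }
    ri <- (off[1L] + 1L):(off[1L] + h); ci <- (off[2L] + 1L):(off[2L] + w)
    for (cls in mask_classes()) {
      out[[cls]][ri, ci] <- out[[cls]][ri, ci] | m[[cls]]
    }
  }
  new_label_masks(out$intact, out$not_intact)
}

#' Read and write label masks as PNG
#'
#' Masks persist as a single-channel 3-value label PNG: 0 = background,
#' 1 = intact, 2 = not-intact (stored as grey levels 0, 1/255, 2/255).
#'
#' @param masks A [label_masks()].
#' @param path PNG file path.
#' @return `write_label_png()` returns `path` invisibly; `read_label_png()`
#'   returns a [label_masks()].
#' @export
write_label_png <- function(masks, path) {
  stopifnot(inherits(masks, "label_masks"))
  lab <- matrix(0L, nrow(masks$intact), ncol(masks$intact))
  lab[masks$not_intact] <- 2L
  lab[masks$intact] <- 1L   # intact wins where both are set
  png::writePNG(lab / 255, target = path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  lab <- round(img * 255)
  label_masks(intact = lab == 1, not_intact = lab == 2)
}
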