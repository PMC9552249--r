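#' Read a slide image from disk
#'
#' Reads PNG or TIFF (level 0 of a multi-page/pyramidal file) into an RGB
#' array `height x width x 3` with values in `[0, 1]`. Alpha channels are
#' dropped; grey images are expanded to three channels.
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @return RGB array.
#' @export
read_slide <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = {
                  x <- tiff::readTIFF(path, all = FALSE)
                  if (is.list(x)) x[[1L]] else x
                },
                stop("unsupported slide format: .", ext, call. = FALSE))
  if (is.matrix(img)) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_slide
#' @param slide RGB array in `[0, 1]`.
#' @export
write_slide <- function(slide, path) {
  ext <- tolower(tools::file_ext(path))
  slide <- pmin(pmax(slide, 0), 1)
  switch(ext,
         png = png::writePNG(slide, target = path),
         tif = ,
         tiff = tiff::writeTIFF(slide, where = path),
         stop("unsupported slide format: .", ext, call. = FALSE))
  invisible(path)
}

#' Slide pixel sources with bounded-memory access
#'
#' The sliding high-power-field scan never needs the whole decoded slide at
#' once: it requests one patch-sized region at a time. A `slide_source` wraps
#' whatever holds the pixels behind a region accessor
#' `get(row, col, height, width)` (0-based, half-open), so peak memory during
#' a scan is bounded by one window plus one patch.
#'
#' Accepted inputs: an RGB array; a PNG/TIFF path (decoded on first access);
#' a `function(row, col, h, w)` with an `extent` supplied; a [label_masks()]
#' ground truth (a pixel-free source whose regions read as `NULL` — only
#' usable with segmenters that ignore pixels, such as [oracle_segmenter()]);
#' or an existing `slide_source`.
#'
#' @param x Slide input (see Details).
#' @param extent Required when `x` is a bare accessor function.
#' @return A `slide_source`: a list with `extent`, `get`, `has_pixels`.
#' @export
as_slide_source <- function(x, extent = NULL) {
  if (inherits(x, "slide_source")) return(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    ext <- as_extent(x)
    return(new_slide_source(ext, function(r, c, h, w) {
      x[(r + 1L):(r + h), (c + 1L):(c + w), , drop = FALSE]
    }, has_pixels = TRUE))
  }
  if (is.character(x) && length(x) == 1L) {
    img <- NULL
    force(x)
    getter <- function(r, c, h, w) {
      if (is.null(img)) img <<- read_slide(x)
      img[(r + 1L):(r + h), (c + 1L):(c + w), , drop = FALSE]
    }
    probe <- read_slide(x)   # extent must be known up front
    img <- probe
    return(new_slide_source(as_extent(probe), getter, has_pixels = TRUE))
  }
  if (inherits(x, "label_masks")) {
    return(new_slide_source(mask_extent(x), function(r, c, h, w) NULL,
                            has_pixels = FALSE))
  }
  if (is.function(x)) {
    if (is.null(extent)) stop("an accessor function needs an explicit `extent`", call. = FALSE)
    return(new_slide_source(as_extent(extent), x, has_pixels = TRUE))
  }
  stop("cannot interpret `x` as a slide source", call. = FALSE)
}

new_slide_source <- function(extent, get, has_pixels) {
  structure(list(extent = extent, get = get, has_pixels = has_pixels),
            class = "slide_source")
}

#' @export
print.slide_source <- function(x, ...) {
  cat(sprintf("<slide_source> %d x %d px (%s)\n",
              x$extent[["height"]], x$extent[["width"]],
              if (x$has_pixels) "pixel-backed" else "truth-only"))
  invisible(x)
}
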