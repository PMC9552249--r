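#' Pixel scale of a scanned slide
#'
#' The linear scale of the scanner, in microns per pixel. The default is
#' derived from the high-power-field geometry used throughout the pipeline:
#' the conventional 0.3 mm^2 counting field, scanned at 400X, spans
#' 2144 x 2144 px, so one pixel is sqrt(0.3) mm / 2144 ~= 0.25549 um
#' (equivalently, the field side of ~548 um maps to 2144 px).
#'
#' @param microns_per_pixel Strictly positive length of one pixel side, in um.
#' @return An object of class `pixel_scale` (a scalar double).
#' @examples
#' pixel_scale()                 # default 400X scale, ~0.2555 um/px
#' pixel_scale(0.5)              # a 200X-like scale
#' @export
pixel_scale <- function(microns_per_pixel = sqrt(0.3) * 1000 / 2144) {
  if (!is.numeric(microns_per_pixel) || length(microns_per_pixel) != 1L ||
      !is.finite(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("`microns_per_pixel` must be a single positive number", call. = FALSE)
  }
  structure(as.numeric(microns_per_pixel), class = "pixel_scale")
}

#' @export
print.pixel_scale <- function(x, ...) {
  cat(sprintf("<pixel_scale> %.5f um/px\n", unclass(x)))
  invisible(x)
}

#' Image extent in pixels
#'
#' @param height,width Positive integer pixel dimensions.
#' @return An integer vector `c(height = , width = )` of class `extent`.
#' @examples
#' extent(1200, 1200)
#' @export
extent <- function(height, width = height) {
  h <- as.integer(height); w <- as.integer(width)
  if (length(h) != 1L || length(w) != 1L || is.na(h) || is.na(w) || h < 1L || w < 1L) {
    stop("extent dimensions must be single integers >= 1", call. = FALSE)
  }
  structure(c(height = h, width = w), class = "extent")
}

as_extent <- function(x) {
  if (inherits(x, "extent")) return(x)
  if (is.matrix(x)) return(extent(nrow(x), ncol(x)))
  if (is.array(x) && length(dim(x)) == 3L) return(extent(dim(x)[1L], dim(x)[2L]))
  if (is.numeric(x) && length(x) == 2L) return(extent(x[1L], x[2L]))
  stop("cannot interpret as an extent", call. = FALSE)
}

# Offsets along one axis. 0-based, half-open: an offset o covers [o, o + tile).
axis_offsets <- function(len, tile, stride, policy) {
  if (tile > len) stop("tile exceeds extent", call. = FALSE)
  reach <- len - tile
  regular <- seq.int(0L, reach, by = stride)
  if (policy == "exact") {
    residue <- reach %% stride
    if (residue != 0L) {
      stop(sprintf("tiling residue of %d px: extent %d minus tile %d is not divisible by stride %d",
                   residue, len, tile, stride), call. = FALSE)
    }
    return(as.integer(regular))
  }
  # clamp: append a flush tile at the far edge if the grid stops short
  if (regular[length(regular)] < reach) regular <- c(regular, reach)
  as.integer(unique(regular))
}

#' Plan a grid of square tiles over an extent
#'
#' Computes the top-left corners of `tile` x `tile` pixel tiles covering an
#' extent at a fixed stride. Coordinates are 0-based; a tile at offset
#' `(row, col)` covers the half-open region `[row, row + tile) x [col, col + tile)`.
#'
#' Two edge policies are supported. Under `"exact"` the extent minus the tile
#' must be divisible by the stride on each axis (the regular grid ends flush
#' with the image); training and high-power-field grids in this pipeline are
#' constructed this way, e.g. a 1200 px axis with 448 px tiles at stride 376
#' gives offsets 0, 376, 752. Under `"clamp"` the regular grid is emitted and,
#' if it stops short of the edge, one extra flush-right/bottom offset is
#' appended per axis, so the union of tiles always covers the extent (the
#' duplicated coverage is harmless under OR fusion of masks).
#'
#' @param extent An [extent()] (or anything coercible: a matrix, an array, a
#'   length-2 numeric `c(height, width)`).
#' @param tile Square tile side in pixels; must fit inside the extent.
#' @param stride Step between consecutive tiles in pixels, >= 1.
#' @param policy `"exact"` or `"clamp"` (see Details).
#' @return A tibble of class `tile_grid` with integer columns `row`, `col`
#'   (0-based top-left corners, row-major order) and attributes `tile`,
#'   `stride`, `policy`, `extent`.
#' @examples
#' plan_tiles(extent(1200, 1200), tile = 448, stride = 376)          # 9 tiles
#' plan_tiles(extent(2144, 2144), tile = 448, stride = 424)          # 25 tiles
#' plan_tiles(extent(1000, 1000), tile = 448, stride = 376, "clamp") # flush edge
#' @export
plan_tiles <- function(extent, tile, stride, policy = c("exact", "clamp")) {
  policy <- match.arg(policy)
  ext <- as_extent(extent)
  tile <- as.integer(tile); stride <- as.integer(stride)
  if (is.na(tile) || tile < 1L) stop("`tile` must be a positive integer", call. = FALSE)
  if (is.na(stride) || stride < 1L) stop("`stride` must be a positive integer", call. = FALSE)
  rows <- axis_offsets(ext[["height"]], tile, stride, policy)
  cols <- axis_offsets(ext[["width"]], tile, stride, policy)
  grid <- tidyr::expand_grid(row = rows, col = cols)
  tibble::new_tibble(grid, tile = tile, stride = stride, policy = policy,
                     extent = ext, class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  ext <- attr(x, "extent")
  cat(sprintf("<tile_grid> %d tiles of %d px (stride %d, policy %s) over %d x %d\n",
              nrow(x), attr(x, "tile"), attr(x, "stride"), attr(x, "policy"),
              ext[["height"]], ext[["width"]]))
  NextMethod()
}

#' Side of a square high-power field, in pixels
#'
#' Converts a high-power-field (HPF) area in mm^2 into the side length of the
#' square scan window, rounded to whole pixels. At the default scale the
#' conventional 0.3 mm^2 field is a 548 um square, i.e. 2144 px.
#'
#' @param hpf_area_mm2 Field area in mm^2 (> 0). Default 0.3.
#' @param scale A [pixel_scale()].
#' @return Integer window side in pixels.
#' @examples
#' hpf_side_pixels()            # 2144
#' hpf_side_pixels(0.15)        # a half-area field
#' @export
hpf_side_pixels <- function(hpf_area_mm2 = 0.3, scale = pixel_scale()) {
  if (!is.numeric(hpf_area_mm2) || length(hpf_area_mm2) != 1L ||
      !is.finite(hpf_area_mm2) || hpf_area_mm2 <= 0) {
    stop("`hpf_area_mm2` must be a single positive number", call. = FALSE)
  }
  side_um <- hpf_side_microns(hpf_area_mm2)
  as.integer(round(side_um / unclass(pixel_scale(unclass(scale)))))
}

#' Side of a square high-power field, in microns
#'
#' @inheritParams hpf_side_pixels
#' @return Exact (unrounded) side length in um; `sqrt(0.3) mm` is ~547.7 um,
#'   i.e. 548 um to the nearest micron.
#' @examples
#' round(hpf_side_microns())    # 548
#' @export
hpf_side_microns <- function(hpf_area_mm2 = 0.3) {
  if (!is.numeric(hpf_area_mm2) || length(hpf_area_mm2) != 1L ||
      !is.finite(hpf_area_mm2) || hpf_area_mm2 <= 0) {
    stop("`hpf_area_mm2` must be a single positive number", call. = FALSE)
  }
  sqrt(hpf_area_mm2) * 1000
}
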