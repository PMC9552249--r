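#' Area-based eosinophil counting rule
#'
#' After segmentation, eosinophils are counted from connected-region areas:
#' a region must exceed `min_area` (1800 px, exclusive) to count at all; up
#' to `one_cell_max` (3000 px, inclusive) it counts as one eosinophil — the
#' typical eosinophil covers about 2050 px, comfortably inside this band —
#' and beyond 3000 px each additional `increment` (2000 px) adds one more
#' cell, merged neighbours being indistinguishable at mask level. Whether a
#' partial extra increment counts is set by `increment_mode`: `"floor"`
#' (default) requires the full additional 2000 px, `"ceil"` counts it as
#' soon as the region passes 3000 px by any margin.
#'
#' @param min_area Exclusive lower area bound in pixels. Default 1800.
#' @param one_cell_max Inclusive one-cell upper bound in pixels. Default 3000.
#' @param increment Additional pixels per extra cell. Default 2000.
#' @param increment_mode `"floor"` or `"ceil"`.
#' @return A `counting_rule` object.
#' @export
counting_rule <- function(min_area = 1800, one_cell_max = 3000, increment = 2000,
                          increment_mode = c("floor", "ceil")) {
  increment_mode <- match.arg(increment_mode)
  if (!(min_area > 0 && min_area < one_cell_max)) {
    stop("need 0 < min_area < one_cell_max", call. = FALSE)
  }
  if (increment <= 0) stop("`increment` must be positive", call. = FALSE)
  structure(list(min_area = min_area, one_cell_max = one_cell_max,
                 increment = increment, increment_mode = increment_mode),
            class = "counting_rule")
}

#' Count eosinophils in a connected region of given area
#'
#' @param area Region area(s) in pixels (vectorized, >= 0).
#' @param rule A [counting_rule()].
#' @return Integer count(s).
#' @examples
#' count_from_area(c(1800, 2050, 3000, 5000, 7001))
#' @export
count_from_area <- function(area, rule = counting_rule()) {
  stopifnot(inherits(rule, "counting_rule"), all(area >= 0))
  extra <- (area - rule$one_cell_max) / rule$increment
  extra <- if (rule$increment_mode == "floor") floor(extra) else ceiling(extra)
  out <- ifelse(area <= rule$min_area, 0L,
                ifelse(area <= rule$one_cell_max, 1L, 1L + pmax(0, extra)))
  as.integer(out)
}

# Connected-component labeling of a logical matrix. EBImage::bwlabel gives
# 4-connectivity; 8-connectivity is obtained by union-find merging of labels
# that touch diagonally.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  # label within the foreground bounding box only; sparse masks dominate here
  rows_any <- which(rowSums(mask) > 0)
  if (!length(rows_any)) return(matrix(0L, nrow(mask), ncol(mask)))
  cols_any <- which(colSums(mask) > 0)
  r0 <- rows_any[1L]; r1 <- rows_any[length(rows_any)]
  c0 <- cols_any[1L]; c1 <- cols_any[length(cols_any)]
  sub <- label_components_dense(mask[r0:r1, c0:c1, drop = FALSE], connectivity)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[r0:r1, c0:c1] <- sub
  out
}

label_components_dense <- function(mask, connectivity) {
  lab <- EBImage::imageData(EBImage::bwlabel(mask * 1))
  storage.mode(lab) <- "integer"
  if (!is.matrix(lab)) lab <- matrix(lab, nrow(mask), ncol(mask))
  n <- max(lab)
  if (connectivity == 8 && n > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a <- c(lab[-nr, -nc], lab[-nr, -1L])   # pixel vs down-right / down-left
    b <- c(lab[-1L, -1L], lab[-1L, -nc])
    keep <- a > 0L & b > 0L & a != b
    if (any(keep)) {
      pairs <- unique(cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep])))
      parent <- seq_len(n)
      find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(n), find, integer(1))
      dense <- match(roots, sort(unique(roots)))
      lab[lab > 0L] <- dense[lab[lab > 0L]]
    }
  }
  lab
}

# Per-component area, bounding box and centroid (0-based coordinates).
component_table <- function(lab, class = NA_character_) {
  n <- max(lab)
  if (n == 0L) {
    return(tibble::tibble(component = integer(), class = character(),
                          area = integer(), row_min = integer(), row_max = integer(),
                          col_min = integer(), col_max = integer(),
                          centroid_row = double(), centroid_col = double()))
  }
  idx <- which(lab > 0L)
  id <- lab[idx]
  r <- (idx - 1L) %% nrow(lab)          # 0-based row
  cc <- (idx - 1L) %/% nrow(lab)        # 0-based col
  area <- tabulate(id, n)
  tibble::tibble(
    component = seq_len(n), class = class, area = as.integer(area),
    row_min = as.integer(tapply(r, id, min)),
    row_max = as.integer(tapply(r, id, max)),
    col_min = as.integer(tapply(cc, id, min)),
    col_max = as.integer(tapply(cc, id, max)),
    centroid_row = as.numeric(tapply(r, id, mean)),
    centroid_col = as.numeric(tapply(cc, id, mean))
  )
}

#' Count eosinophils of one class in a mask stack
#'
#' Labels the class mask into connected components (8-connected by default)
#' and applies the area [counting_rule()] to each component; the total is
#' the sum over components.
#'
#' @param masks A [label_masks()].
#' @param class `"intact"` (default; the diagnostic class) or `"not_intact"`.
#' @param rule A [counting_rule()].
#' @param connectivity 8 (default) or 4.
#' @return A list with `count` (integer total) and `components` (a tibble of
#'   per-component geometry with a `count` column).
#' @export
count_eosinophils <- function(masks, class = "intact", rule = counting_rule(),
                              connectivity = 8) {
  stopifnot(inherits(masks, "label_masks"), class %in% mask_classes())
  lab <- label_components(masks[[class]], connectivity)
  comp <- component_table(lab, class)
  comp$count <- count_from_area(comp$area, rule)
  list(count = sum(comp$count), components = comp)
}

#' Eosinophil density per reference field area
#'
#' Normalizes a count observed over `window_area_px` pixels to the clinical
#' reference area (0.3 mm^2, the 400X high-power field).
#'
#' @param count Eosinophil count observed in the window.
#' @param window_area_px Window area in pixels.
#' @param scale A [pixel_scale()].
#' @param reference_area_mm2 Reference area. Default 0.3 mm^2.
#' @return Eosinophils per reference area.
#' @examples
#' eos_density(15, hpf_side_pixels()^2)   # 15 per 0.3 mm^2
#' @export
eos_density <- function(count, window_area_px, scale = pixel_scale(),
                        reference_area_mm2 = 0.3) {
  if (window_area_px <= 0) stop("`window_area_px` must be positive", call. = FALSE)
  area_mm2 <- window_area_px * (unclass(scale) / 1000)^2
  count * reference_area_mm2 / area_mm2
}

#' Classify disease activity from a peak eosinophil count
#'
#' Active EoE is called when the peak count reaches the clinical cutoff of
#' 15 intact eosinophils per high-power field; 14 is below the line, 15 on it.
#'
#' @param pec Peak eosinophil count(s), >= 0.
#' @param threshold Diagnostic cutoff. Default 15.
#' @return Character vector, `"active"` or `"not_active"`.
#' @export
classify_activity <- function(pec, threshold = 15) {
  stopifnot(all(pec >= 0))
  ifelse(pec >= threshold, "active", "not_active")
}

#' Sliding high-power-field peak eosinophil count
#'
#' Scans a slide with a square high-power-field (HPF) window (default side
#' 2144 px, i.e. 0.3 mm^2) advanced at `scan_stride` (default 500 px, clamp
#' policy so edge windows stay flush with the slide), and returns the window
#' with the maximum intact-eosinophil count — the slide's PEC. Each window is
#' processed lazily: only its own pixels are requested from the slide source,
#' cropped into `patch` x `patch` tiles at `patch_stride` (exact policy; the
#' default 448/424 grid tiles a 2144 px window into 25 patches), each tile is
#' segmented, the tile masks are OR-fused back over the window, and the fused
#' window mask is counted. Peak memory is therefore bounded by one window
#' plus one patch, never the whole decoded slide. Ties are broken by
#' row-major scan order. Slides smaller than one HPF are scanned with a
#' single window covering the whole slide.
#'
#' @param slide Anything [as_slide_source()] accepts.
#' @param segmenter An [new_segmenter()] (e.g. [oracle_segmenter()] or a
#'   trained [train_segmenter()] model).
#' @param hpf_side HPF window side in pixels. Default [hpf_side_pixels()].
#' @param scan_stride Window stride in pixels. Default 500.
#' @param patch,patch_stride Patch grid inside each window. Defaults 448/424.
#' @param rule A [counting_rule()].
#' @param prob_threshold Softmax threshold for
#'   [threshold_probabilities()]. Default 0.5.
#' @param connectivity Component connectivity, 8 or 4.
#' @param keep_slide_mask If `TRUE`, also OR-fuse every window's mask into a
#'   whole-slide [label_masks()] (costs full-slide memory; off by default).
#' @return An object of class `pec_result`: a list with `pec`, `peak`
#'   (`row`, `col`, `height`, `width` of the winning window, 0-based),
#'   `peak_not_intact` (the not-intact count inside the peak window, reported
#'   but never part of the PEC), `peak_mask` (the fused [label_masks()] of the
#'   peak window), `windows` (tibble of all window offsets with their `intact`
#'   counts), `hpf_side`, and optionally `slide_mask`.
#' @export
peak_eos_count <- function(slide, segmenter,
                           hpf_side = hpf_side_pixels(), scan_stride = 500,
                           patch = 448, patch_stride = 424,
                           rule = counting_rule(), prob_threshold = 0.5,
                           connectivity = 8, keep_slide_mask = FALSE) {
  src <- as_slide_source(slide)
  ext <- src$extent
  win_h <- min(hpf_side, ext[["height"]])
  win_w <- min(hpf_side, ext[["width"]])
  wins <- tidyr::expand_grid(
    row = axis_offsets(ext[["height"]], win_h, as.integer(scan_stride), "clamp"),
    col = axis_offsets(ext[["width"]], win_w, as.integer(scan_stride), "clamp"))
  patch <- min(patch, win_h, win_w)
  pgrid <- plan_tiles(extent(win_h, win_w), patch, patch_stride,
                      policy = if (win_h == win_w && win_h == hpf_side) "exact" else "clamp")
  slide_mask <- if (keep_slide_mask) label_masks(extent = ext) else NULL
  counts_int <- integer(nrow(wins))
  best_mask <- NULL; best_count <- -1L
  for (k in seq_len(nrow(wins))) {
    wr <- wins$row[[k]]; wc <- wins$col[[k]]
    tiles <- vector("list", nrow(pgrid))
    for (j in seq_len(nrow(pgrid))) {
      pr <- pgrid$row[[j]]; pc <- pgrid$col[[j]]
      pix <- src$get(wr + pr, wc + pc, patch, patch)
      pm <- predict_tile(segmenter, pix, offset = c(wr + pr, wc + pc),
                         size = extent(patch, patch))
      tiles[[j]] <- list(offset = c(pr, pc),
                         masks = threshold_probabilities(pm, prob_threshold))
    }
    wmask <- fuse_masks(tiles, extent(win_h, win_w))
    counts_int[[k]] <- count_eosinophils(wmask, "intact", rule, connectivity)$count
    if (counts_int[[k]] > best_count) {       # strict: first maximum wins ties
      best_count <- counts_int[[k]]; best_mask <- wmask
    }
    if (keep_slide_mask) {
      ri <- (wr + 1L):(wr + win_h); ci <- (wc + 1L):(wc + win_w)
      for (cls in mask_classes()) {
        slide_mask[[cls]][ri, ci] <- slide_mask[[cls]][ri, ci] | wmask[[cls]]
      }
    }
  }
  wins$intact <- counts_int
  best <- which.max(wins$intact)   # first maximum in row-major order
  structure(list(
    pec = wins$intact[[best]],
    peak = list(row = wins$row[[best]], col = wins$col[[best]],
                height = win_h, width = win_w),
    peak_not_intact = count_eosinophils(best_mask, "not_intact", rule,
                                        connectivity)$count,
    peak_mask = best_mask,
    windows = wins, hpf_side = hpf_side, scan_stride = scan_stride,
    slide_mask = slide_mask
  ), class = "pec_result")
}

#' @export
print.pec_result <- function(x, ...) {
  cat(sprintf("<pec_result> PEC %d at window (%d, %d) [%d x %d px]; %d windows scanned\n",
              x$pec, x$peak$row, x$peak$col, x$peak$height, x$peak$width,
              nrow(x$windows)))
  invisible(x)
}

#' Rank slides by peak eosinophil count
#'
#' Orders slide reports from most to least eosinophil-dense, so review can be
#' prioritized; ties are broken by slide id (ascending).
#'
#' @param reports A tibble/data frame with columns `slide_id` and `pec` (e.g.
#'   from [run_pipeline()]).
#' @return The same rows ordered by descending `pec`, with a `rank` column
#'   (competition ranking: tied PECs share a rank).
#' @export
ranked_slide_list <- function(reports) {
  stopifnot(all(c("slide_id", "pec") %in% names(reports)))
  out <- dplyr::arrange(tibble::as_tibble(reports),
                        dplyr::desc(.data$pec), .data$slide_id)
  out$rank <- competition_rank(out$pec, higher_better = TRUE)
  out
}
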