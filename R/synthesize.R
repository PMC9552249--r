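#' Specify a synthetic H&E-like slide
#'
#' Describes a slide to be generated by [generate_slide()]: its extent, how
#' many intact / not-intact eosinophils to scatter over the tissue, optional
#' dense clusters planted inside specific high-power-field windows (to set a
#' known PEC by construction), and the background appearance. The rendering
#' emulates the cues the real classes are recognised by — intact eosinophils
#' as red-granular disks with a visible nucleus blob, not-intact ones as
#' duller granule fields without a nucleus, on pale pink tissue with white
#' glass regions — without claiming histological realism; it exists so that
#' segmentation, counting and the whole-slide scan can be exercised against
#' exact ground truth.
#'
#' Ground-truth masks follow the annotation protocol: a 50 px diameter disk
#' at each planted center (area ~1961 px, inside the 1800-3000 px one-cell
#' band), so planted cell numbers and mask-derived counts agree exactly. The
#' `radius` jitter applies to the rendered granule core.
#'
#' @param extent Slide [extent()].
#' @param n_intact,n_not_intact Number of scattered cells per class.
#' @param clusters Optional list of `list(center = c(row, col), class,
#'   count)` entries; each plants `count` cells of `class` inside the
#'   HPF-sized window centered at `center` (the window is snapped onto the
#'   scan grid, so the planted count is exactly attainable by one scanned
#'   window). Scattered *intact* cells are kept
#'   one full HPF side away from every cluster window, so no scan window can
#'   mix cluster and stray intact cells and a planted intact cluster count is
#'   the window's exact count (not-intact cells roam freely — they never
#'   enter the PEC). On slides too small to hold that clearance, plant
#'   clusters with `n_intact = 0`.
#' @param radius Mean rendered granule-core radius in pixels. Default 25.
#' @param radius_jitter Relative jitter of the rendered radius. Default 0.2.
#' @param min_separation Minimum center-to-center distance between planted
#'   cells. Default 56 px (annotation disks stay disjoint).
#' @param glass_fraction Approximate fraction of the background covered by
#'   white glass patches. Default 0.1.
#' @param hpf_side,scan_stride The window grid ground truth is defined on —
#'   the same grid [peak_eos_count()] scans. Defaults 2144 / 500.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A `synthetic_slide_spec` list.
#' @export
synthetic_slide_spec <- function(extent, n_intact = 12, n_not_intact = 8,
                                 clusters = list(), radius = 25,
                                 radius_jitter = 0.2, min_separation = 56,
                                 glass_fraction = 0.1,
                                 hpf_side = hpf_side_pixels(), scan_stride = 500,
                                 seed = 1L) {
  ext <- as_extent(extent)
  for (cl in clusters) {
    stopifnot(length(cl$center) == 2L, cl$class %in% mask_classes(), cl$count >= 1)
  }
  structure(list(extent = ext, n_intact = n_intact, n_not_intact = n_not_intact,
                 clusters = clusters, radius = radius, radius_jitter = radius_jitter,
                 min_separation = min_separation, glass_fraction = glass_fraction,
                 hpf_side = hpf_side, scan_stride = scan_stride,
                 seed = as.integer(seed)),
            class = "synthetic_slide_spec")
}

# Clamp a square window of side `side` centered at `center` inside the extent;
# returns 0-based top-left c(row, col) and the (possibly reduced) sides.
clamp_window <- function(center, side, ext) {
  h <- min(side, ext[["height"]]); w <- min(side, ext[["width"]])
  r <- max(0L, min(ext[["height"]] - h, as.integer(round(center[1L] - h / 2))))
  c <- max(0L, min(ext[["width"]] - w, as.integer(round(center[2L] - w / 2))))
  list(row = r, col = c, height = h, width = w)
}

# Rejection-sample `n` points in [lo_r, hi_r] x [lo_c, hi_c] at pairwise
# distance >= sep from each other and from `existing` (2-col matrix).
place_points <- function(n, lo_r, hi_r, lo_c, hi_c, sep, existing,
                         forbid = NULL, max_tries = 400L) {
  pts <- matrix(numeric(0), 0L, 2L)
  if (n == 0L) return(pts)
  if (hi_r < lo_r || hi_c < lo_c) stop("placement region is empty", call. = FALSE)
  sep2 <- sep^2
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- c(stats::runif(1, lo_r, hi_r), stats::runif(1, lo_c, hi_c))
      all_pts <- rbind(existing, pts)
      ok <- !nrow(all_pts) ||
        min((all_pts[, 1L] - cand[1L])^2 + (all_pts[, 2L] - cand[2L])^2) >= sep2
      if (ok && !is.null(forbid)) ok <- !forbid(cand)
      if (ok) { pts <- rbind(pts, cand); placed <- TRUE; break }
    }
    if (!placed) {
      stop("overcrowding: could not place the requested cells at the minimum separation",
           call. = FALSE)
    }
  }
  pts
}

# Draw a disk-shaped blob into img (H x W x 3), mixing `col` in with weight
# `alpha` (matrix or scalar) over pixels within `radius` of (cr, cc), 0-based.
draw_blob <- function(img, cr, cc, radius, col, alpha = 1, speckle = 0) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  ri <- ceiling(radius)
  rows <- max(0L, floor(cr) - ri):min(h - 1L, ceiling(cr) + ri)
  cols <- max(0L, floor(cc) - ri):min(w - 1L, ceiling(cc) + ri)
  d2 <- outer((rows - cr)^2, (cols - cc)^2, `+`)
  inside <- d2 <= radius^2
  if (!any(inside)) return(img)
  a <- inside * alpha
  if (speckle > 0) {
    a <- a * matrix(stats::rbinom(length(a), 1L, 1 - speckle) * 0.4 + 0.6,
                    nrow(a), ncol(a))
  }
  for (ch in 1:3) {
    sub <- img[rows + 1L, cols + 1L, ch]
    img[rows + 1L, cols + 1L, ch] <- sub * (1 - a) + col[ch] * a
  }
  img
}

render_cell <- function(img, row, col, class, core_radius) {
  # pale cytoplasm out to the annotation radius, granule core, nucleus if intact
  img <- draw_blob(img, row, col, 25, c(0.97, 0.78, 0.82), alpha = 0.9)
  core_col <- if (class == "intact") c(0.86, 0.12, 0.25) else c(0.78, 0.38, 0.22)
  img <- draw_blob(img, row, col, core_radius, core_col, alpha = 0.95,
                   speckle = if (class == "intact") 0.25 else 0.5)
  if (class == "intact") {
    img <- draw_blob(img, row, col, 8, c(0.30, 0.18, 0.52), alpha = 0.95)
  }
  img
}

render_background <- function(ext, glass_fraction) {
  h <- ext[["height"]]; w <- ext[["width"]]
  img <- array(0, c(h, w, 3L))
  base <- c(0.91, 0.78, 0.86)   # pale H&E tissue
  noise <- matrix(stats::rnorm(h * w, 0, 0.03), h, w)
  for (ch in 1:3) img[, , ch] <- pmin(pmax(base[ch] + noise, 0), 1)
  # white glass patches
  target <- glass_fraction * h * w
  covered <- 0
  while (covered < target) {
    gr <- stats::runif(1, 0, h); gc <- stats::runif(1, 0, w)
    rad <- stats::runif(1, min(h, w) / 20, min(h, w) / 6)
    img <- draw_blob(img, gr, gc, rad, c(0.985, 0.98, 0.985), alpha = 1)
    covered <- covered + pi * rad^2 * 0.7   # rough, overlaps ignored
  }
  img
}

#' Generate a synthetic slide with exact ground truth
#'
#' Realizes a [synthetic_slide_spec()]: plants the requested cells (clusters
#' first, then scattered cells kept clear of all cluster windows), builds the
#' ground-truth [label_masks()] by rasterizing the planted centers with the
#' 50 px annotation disk, pre-computes the per-window intact counts on the
#' same clamped window grid that [peak_eos_count()] scans (a brute-force scan
#' that reads the whole truth at once), and optionally renders the RGB image.
#' Everything is deterministic given the spec's seed.
#'
#' @param spec A [synthetic_slide_spec()].
#' @param render If `FALSE`, skip RGB rendering (`image` is `NULL`); the
#'   ground truth is unaffected. Useful for oracle-driven scans of large
#'   slides.
#' @return A list with `image` (RGB array or `NULL`) and `truth`, itself a
#'   list: `masks` ([label_masks()]), `points` (annotation tibble),
#'   `window_counts` (tibble `row`, `col`, `intact`), `pec`, `peak`
#'   (0-based window), `active` (at the 15-cell cutoff).
#' @examples
#' spec <- synthetic_slide_spec(extent(600, 600), n_intact = 3,
#'                              n_not_intact = 2, hpf_side = 300,
#'                              scan_stride = 150, seed = 7)
#' s <- generate_slide(spec)
#' s$truth$pec
#' @export
generate_slide <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "synthetic_slide_spec"))
  ext <- spec$extent
  margin <- 26   # keep annotation disks unclipped
  with_seed(spec$seed, {
    centers <- matrix(numeric(0), 0L, 2L)
    classes <- character(0)
    # snap each cluster window onto the scan grid, so one scanned window
    # contains the full cluster and the planted count is attainable
    cluster_wins <- lapply(spec$clusters, function(cl) {
      win <- clamp_window(cl$center, spec$hpf_side, ext)
      rows <- axis_offsets(ext[["height"]], win$height,
                           as.integer(spec$scan_stride), "clamp")
      cols <- axis_offsets(ext[["width"]], win$width,
                           as.integer(spec$scan_stride), "clamp")
      win$row <- rows[which.min(abs(rows - win$row))]
      win$col <- cols[which.min(abs(cols - win$col))]
      win
    })
    for (k in seq_along(spec$clusters)) {
      cl <- spec$clusters[[k]]; win <- cluster_wins[[k]]
      pts <- place_points(cl$count,
                          lo_r = win$row + margin + 2,
                          hi_r = win$row + win$height - margin - 2,
                          lo_c = win$col + margin + 2,
                          hi_c = win$col + win$width - margin - 2,
                          sep = spec$min_separation, existing = centers)
      centers <- rbind(centers, pts)
      classes <- c(classes, rep(cl$class, cl$count))
    }
    # scattered cells stay a full HPF side clear of every cluster window
    forbid <- if (length(cluster_wins)) {
      function(p) any(vapply(cluster_wins, function(w) {
        p[1L] >= w$row - spec$hpf_side && p[1L] < w$row + w$height + spec$hpf_side &&
          p[2L] >= w$col - spec$hpf_side && p[2L] < w$col + w$width + spec$hpf_side
      }, logical(1)))
    } else NULL
    for (cls in mask_classes()) {
      n <- if (cls == "intact") spec$n_intact else spec$n_not_intact
      pts <- place_points(n, margin, ext[["height"]] - 1 - margin,
                          margin, ext[["width"]] - 1 - margin,
                          sep = spec$min_separation, existing = centers,
                          forbid = if (cls == "intact") forbid else NULL)
      centers <- rbind(centers, pts)
      classes <- c(classes, rep(cls, n))
    }
    points <- tibble::tibble(image_id = "synthetic",
                             row = as.integer(round(centers[, 1L])),
                             col = as.integer(round(centers[, 2L])),
                             class = classes)
    masks <- rasterize_annotations(points, ext)
    radii <- spec$radius * stats::runif(nrow(points),
                                        1 - spec$radius_jitter,
                                        1 + spec$radius_jitter)
    image <- NULL
    if (render) {
      image <- render_background(ext, spec$glass_fraction)
      for (i in seq_len(nrow(points))) {
        image <- render_cell(image, points$row[[i]], points$col[[i]],
                             points$class[[i]], radii[[i]])
      }
    }
    truth <- c(list(masks = masks, points = points),
               truth_window_scan(masks, spec$hpf_side, spec$scan_stride))
    list(image = image, truth = truth)
  })
}

# Brute-force scan: count intact eosinophils in every window of the clamped
# grid, reading the whole truth masks directly. Serves as the independent
# reference for the lazy windowed pipeline.
truth_window_scan <- function(masks, hpf_side, scan_stride,
                              rule = counting_rule(), connectivity = 8) {
  ext <- mask_extent(masks)
  win_h <- min(hpf_side, ext[["height"]])
  win_w <- min(hpf_side, ext[["width"]])
  wins <- tidyr::expand_grid(
    row = axis_offsets(ext[["height"]], win_h, as.integer(scan_stride), "clamp"),
    col = axis_offsets(ext[["width"]], win_w, as.integer(scan_stride), "clamp"))
  wins$intact <- vapply(seq_len(nrow(wins)), function(k) {
    m <- crop_masks(masks, wins$row[[k]], wins$col[[k]], win_h, win_w)
    count_eosinophils(m, "intact", rule, connectivity)$count
  }, integer(1))
  best <- which.max(wins$intact)
  list(window_counts = wins,
       pec = wins$intact[[best]],
       peak = list(row = wins$row[[best]], col = wins$col[[best]],
                   height = win_h, width = win_w),
       active = classify_activity(wins$intact[[best]]) == "active")
}

#' Generate a labeled patch dataset from synthetic slides
#'
#' Crops `n` tiles from a generated slide for segmenter training. A
#' configurable fraction of tiles is guaranteed to contain at least one cell
#' of each class (tiles are centered, with jitter, on planted cells); the
#' rest are sampled uniformly. Tile-local annotations are emitted alongside,
#' so masks can be re-rasterized from the CSV round-trip.
#'
#' @param spec A [synthetic_slide_spec()]; extents of a few thousand pixels
#'   are ample.
#' @param tile Tile side in pixels. Default 448.
#' @param n Number of tiles, >= 1.
#' @param class_fraction Minimum fraction of tiles containing each class.
#'   Default 0.4.
#' @param annotations_path Optional CSV path; when given, tile-local
#'   annotations are written with [write_annotations()].
#' @return A tibble with columns `image_id`, `row`, `col` (tile origin on the
#'   slide), list-columns `image` and `masks`, and the per-tile annotation
#'   tibble as attribute `"annotations"`.
#' @export
generate_patch_dataset <- function(spec, tile = 448, n, class_fraction = 0.4,
                                   annotations_path = NULL) {
  stopifnot(n >= 1)
  tile <- as.integer(tile)
  slide <- generate_slide(spec, render = TRUE)
  ext <- spec$extent
  if (tile > ext[["height"]] || tile > ext[["width"]]) {
    stop("tile exceeds the slide extent", call. = FALSE)
  }
  pts <- slide$truth$points
  with_seed(spec$seed + 1L, {
    n_each <- ceiling(class_fraction * n)
    origin_near <- function(p) {
      r <- as.integer(round(p$row - tile / 2 + stats::runif(1, -tile / 8, tile / 8)))
      c <- as.integer(round(p$col - tile / 2 + stats::runif(1, -tile / 8, tile / 8)))
      c(max(0L, min(ext[["height"]] - tile, r)), max(0L, min(ext[["width"]] - tile, c)))
    }
    origins <- list()
    for (cls in mask_classes()) {
      cand <- pts[pts$class == cls, , drop = FALSE]
      if (!nrow(cand)) stop("slide has no ", cls, " cells; class balance infeasible",
                            call. = FALSE)
      rows <- sample(seq_len(nrow(cand)), n_each, replace = TRUE)
      origins <- c(origins, lapply(rows, function(i) origin_near(cand[i, ])))
    }
    n_rand <- max(0L, n - length(origins))
    origins <- c(origins, lapply(seq_len(n_rand), function(i) {
      c(sample.int(ext[["height"]] - tile + 1L, 1L) - 1L,
        sample.int(ext[["width"]] - tile + 1L, 1L) - 1L)
    }))
    origins <- origins[seq_len(n)]   # class tiles first, trimmed to n
    out <- purrr::map_dfr(seq_along(origins), function(k) {
      o <- origins[[k]]
      tibble::tibble(image_id = sprintf("tile_%03d", k), row = o[1L], col = o[2L])
    })
    out$image <- purrr::map(origins, function(o) {
      slide$image[(o[1L] + 1L):(o[1L] + tile), (o[2L] + 1L):(o[2L] + tile), , drop = FALSE]
    })
    out$masks <- purrr::map(origins, function(o) {
      crop_masks(slide$truth$masks, o[1L], o[2L], tile, tile)
    })
    ann <- purrr::map_dfr(seq_along(origins), function(k) {
      o <- origins[[k]]
      inside <- pts$row >= o[1L] & pts$row < o[1L] + tile &
        pts$col >= o[2L] & pts$col < o[2L] + tile
      if (!any(inside)) return(tibble::tibble())
      tibble::tibble(image_id = out$image_id[[k]],
                     row = pts$row[inside] - o[1L],
                     col = pts$col[inside] - o[2L],
                     class = pts$class[inside])
    })
    attr(out, "annotations") <- ann
    if (!is.null(annotations_path)) write_annotations(ann, annotations_path)
    out
  })
}
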