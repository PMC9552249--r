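# Independent brute-force reference implementations. These deliberately use
# the dumbest possible algorithms (per-pixel loops, flood fill, exhaustive
# search) so they share no code with the package's vectorized paths.

random_masks <- function(h, w, p = 0.3) {
  label_masks(intact = matrix(runif(h * w) < p, h, w),
              not_intact = matrix(runif(h * w) < p, h, w))
}

# per-pixel OR fusion
bf_fuse <- function(tiles, ext) {
  out <- list(intact = matrix(FALSE, ext[["height"]], ext[["width"]]),
              not_intact = matrix(FALSE, ext[["height"]], ext[["width"]]))
  for (cls in c("intact", "not_intact")) {
    for (t in tiles) {
      m <- t$masks[[cls]]
      for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
        if (m[i, j]) {
          out[[cls]][t$offset[1] + i, t$offset[2] + j] <- TRUE
        }
      }
    }
  }
  out
}

# per-pixel confusion counts for one class
bf_confusion <- function(p, g) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] && g[i, j]) tp <- tp + 1L
    else if (p[i, j]) fp <- fp + 1L
    else if (g[i, j]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# flood-fill connected components
bf_components <- function(mask, connectivity = 8) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  moves <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  for (si in seq_len(nrow(mask))) for (sj in seq_len(ncol(mask))) {
    if (mask[si, sj] && lab[si, sj] == 0L) {
      nxt <- nxt + 1L
      queue <- list(c(si, sj)); lab[si, sj] <- nxt
      while (length(queue)) {
        cur <- queue[[1L]]; queue <- queue[-1L]
        for (k in seq_len(nrow(moves))) {
          ni <- cur[1] + moves[k, 1]; nj <- cur[2] + moves[k, 2]
          if (ni >= 1 && nj >= 1 && ni <= nrow(mask) && nj <= ncol(mask) &&
              mask[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- nxt
            queue <- c(queue, list(c(ni, nj)))
          }
        }
      }
    }
  }
  lab
}

# literal restatement of the area counting rule, one increment at a time
bf_count_from_area <- function(area, mode = "floor") {
  if (area <= 1800) return(0L)
  if (area <= 3000) return(1L)
  n <- 1L
  rest <- area - 3000
  while (rest >= 2000) { n <- n + 1L; rest <- rest - 2000 }
  if (mode == "ceil" && rest > 0) n <- n + 1L
  n
}

# exhaustive accuracy search over a fine threshold grid
bf_best_threshold <- function(pecs, labels) {
  cand <- sort(unique(c(pecs - 0.25, pecs + 0.25,
                        (rev(sort(pecs))[1] + 1),
                        (sort(pecs)[1] - 1),
                        (sort(unique(pecs))[-1] + sort(unique(pecs))[-length(unique(pecs))]) / 2)))
  acc <- vapply(cand, function(t) mean((pecs >= t) == labels), numeric(1))
  list(best_acc = max(acc), thresholds = cand[acc == max(acc)])
}

# tiny slide spec used across tests (small HPF so scans stay fast)
small_slide_spec <- function(seed, extent_px = 900, n_intact = 6,
                             n_not_intact = 4, clusters = list(),
                             hpf_side = 300, scan_stride = 150) {
  synthetic_slide_spec(extent(extent_px, extent_px), n_intact = n_intact,
                       n_not_intact = n_not_intact, clusters = clusters,
                       hpf_side = hpf_side, scan_stride = scan_stride,
                       seed = seed)
}
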