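test_that("count_from_area honours the band boundaries and both increment modes", {
  expect_equal(count_from_area(2050), 1L)   # the typical eosinophil area
  expect_equal(count_from_area(1800), 0L)
  expect_equal(count_from_area(1801), 1L)
  expect_equal(count_from_area(3000), 1L)
  expect_equal(count_from_area(c(5000, 7001)), c(2L, 3L))
  ceil_rule <- counting_rule(increment_mode = "ceil")
  expect_equal(count_from_area(3001, ceil_rule), 2L)
  expect_equal(count_from_area(3001), 1L)
  # non-decreasing in area
  areas <- sort(sample(0:20000, 200))
  expect_true(all(diff(count_from_area(areas)) >= 0))
})

test_that("count_from_area agrees with the stepwise rule enumeration on a grid", {
  areas <- seq(0, 20000, by = 37)   # dense spot-check; the full sweep is in acceptance
  for (mode in c("floor", "ceil")) {
    rule <- counting_rule(increment_mode = mode)
    ref <- vapply(areas, bf_count_from_area, integer(1), mode = mode)
    expect_equal(count_from_area(areas, rule), ref)
  }
})

test_that("connected-component labeling matches flood fill at both connectivities", {
  set.seed(23)
  for (rep in 1:15) {
    mask <- matrix(runif(12 * 14) < 0.35, 12, 14)
    for (conn in c(4, 8)) {
      lab <- eoescan:::label_components(mask, conn)
      ref <- bf_components(mask, conn)
      expect_equal(max(lab), max(ref))
      # same partition: label images must be identical up to renaming
      if (max(ref) > 0) {
        expect_equal(length(unique(paste(lab[mask], ref[mask]))), max(ref))
      }
      expect_true(all((lab > 0) == mask))
    }
  }
})

test_that("count_eosinophils counts disks and merged components correctly", {
  empty <- label_masks(extent = extent(100, 100))
  expect_equal(count_eosinophils(empty)$count, 0L)
  pts <- tibble::tibble(row = c(60L, 60L, 200L), col = c(60L, 200L, 60L),
                        class = "intact")
  m <- rasterize_annotations(pts, extent(260, 260))
  res <- count_eosinophils(m)
  expect_equal(res$count, 3L)
  expect_equal(nrow(res$components), 3L)
  expect_true(all(res$components$area > 1800 & res$components$area <= 3000))
  # a merged 3900 px component still counts one under floor mode
  blob <- label_masks(intact = matrix(c(rep(TRUE, 3900), rep(FALSE, 4100)), 80, 100))
  expect_equal(count_eosinophils(blob)$count, 1L)
  expect_equal(count_eosinophils(blob, rule = counting_rule(increment_mode = "ceil"))$count, 2L)
})

test_that("counting is invariant to mask translation", {
  set.seed(4)
  base <- rasterize_annotations(
    tibble::tibble(row = c(40L, 95L), col = c(40L, 95L), class = "intact"),
    extent(140, 140))
  shifted <- label_masks(extent = extent(200, 200))
  shifted$intact[31:170, 41:180] <- base$intact
  expect_equal(count_eosinophils(shifted)$count, count_eosinophils(base)$count)
})

test_that("density normalizes to the 0.3 mm^2 reference field", {
  hpf_px <- hpf_side_pixels()^2
  expect_equal(eos_density(15, hpf_px), 15)
  expect_equal(eos_density(0, hpf_px), 0)
  expect_equal(eos_density(5, hpf_px / 2), 10)
})

test_that("activity classification splits exactly at the cutoff", {
  expect_equal(classify_activity(c(0, 14, 15, 40)),
               c("not_active", "not_active", "active", "active"))
  expect_equal(classify_activity(10, threshold = 10), "active")
})

test_that("ranked slide list orders by PEC then id", {
  rep <- tibble::tibble(slide_id = c("s1", "s2", "s3"), pec = c(3L, 40L, 15L))
  out <- ranked_slide_list(rep)
  expect_equal(out$pec, c(40L, 15L, 3L))
  ties <- tibble::tibble(slide_id = c("b", "a", "c"), pec = c(7L, 7L, 7L))
  expect_equal(ranked_slide_list(ties)$slide_id, c("a", "b", "c"))
  expect_equal(ranked_slide_list(ties)$rank, c(1L, 1L, 1L))
})

test_that("roc_sweep matches exhaustive search and known geometry", {
  r <- roc_sweep(c(1, 2, 3, 20, 25, 30), c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(r$auc, 1)
  expect_equal(max(r$points$accuracy), 1)
  # constructed 6-slide fixture against the exhaustive-search oracle
  pecs <- c(2, 9, 14, 16, 13, 40); labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r2 <- roc_sweep(pecs, labels)
  ref <- bf_best_threshold(pecs, labels)
  expect_equal(max(r2$points$accuracy), ref$best_acc)
  expect_equal(mean((pecs >= r2$best_threshold) == labels), ref$best_acc)
  # smallest of the package's own candidates achieving the maximum
  expect_equal(r2$best_threshold,
               min(r2$points$threshold[r2$points$accuracy == ref$best_acc]))
  # label-independent counts give a chance-level AUC
  set.seed(77)
  n <- 600
  pecs3 <- rpois(n, 12); labels3 <- runif(n) < 0.5
  r3 <- roc_sweep(pecs3, labels3)
  expect_lt(abs(r3$auc - 0.5), 3 * sqrt(1 / (12 * n / 4)))
  expect_error(roc_sweep(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("roc_sweep agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  pecs <- c(rpois(40, 8), rpois(40, 20))
  labels <- rep(c(FALSE, TRUE), each = 40)
  ours <- roc_sweep(pecs, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, pecs, quiet = TRUE)))
  expect_equal(ours$auc, as.numeric(ref), tolerance = 1e-10)
})

test_that("count calibration recovers exact and shifted relationships", {
  truth <- c(0, 2, 5, 9, 14, 22)
  fit <- count_calibration(truth, truth)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$mean_abs_error, 0)
  fit2 <- count_calibration(truth + 1, truth)
  expect_equal(fit2$slope, 1)
  expect_equal(fit2$intercept, 1)
  expect_equal(fit2$mean_abs_error, 1)
  # noisy pairs against the closed-form least-squares solution
  set.seed(5)
  x <- rpois(50, 10); y <- x + rnorm(50, 0, 1.5)
  fit3 <- count_calibration(y, x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(fit3$slope, b)
  expect_equal(fit3$intercept, a)
  expect_equal(fit3$mean_abs_error, mean(abs(y - x)))
  expect_error(count_calibration(c(1, 2, 3), c(4, 4, 4)), "constant")
  g <- glance(fit3)
  expect_named(g, c("slope", "intercept", "r_squared", "mean_abs_error", "n"))
  td <- tidy(fit3)
  expect_equal(td$estimate, c(a, b))
})

test_that("segment error stats match a brute-force component matching", {
  # perfect prediction
  pts <- tibble::tibble(row = c(50L, 150L), col = c(50L, 150L), class = "intact")
  m <- rasterize_annotations(pts, extent(200, 200))
  s <- segment_error_stats(m, m)
  expect_equal(s$fdr, 0)
  expect_equal(s$count_error_rate, 0)
  # one spurious among four predictions
  truth <- rasterize_annotations(
    tibble::tibble(row = c(40L, 40L, 150L), col = c(40L, 150L, 40L), class = "intact"),
    extent(200, 200))
  pred <- rasterize_annotations(
    tibble::tibble(row = c(40L, 40L, 150L, 150L), col = c(40L, 150L, 40L, 150L),
                   class = "intact"), extent(200, 200))
  s2 <- segment_error_stats(pred, truth)
  expect_equal(s2$n_pred, 4L)
  expect_equal(s2$fdr, 0.25)
  expect_equal(s2$count_error_rate, abs(4 - 3) / 3)
  # nothing predicted: FDR defined as 0
  s3 <- segment_error_stats(label_masks(extent = extent(200, 200)), truth)
  expect_equal(s3$fdr, 0)
  # randomized masks: FDR equals the oracle count of overlap-free predictions
  set.seed(66)
  for (rep in 1:10) {
    p <- label_masks(intact = matrix(runif(400) < 0.2, 20, 20))
    g <- label_masks(intact = matrix(runif(400) < 0.2, 20, 20))
    s4 <- segment_error_stats(p, g)
    pl <- bf_components(p$intact, 8); gl <- bf_components(g$intact, 8)
    # independent greedy matching over the explicit overlap table
    overlaps <- list()
    for (pk in seq_len(max(pl))) for (tk in seq_len(max(gl))) {
      o <- sum(pl == pk & gl == tk)
      if (o > 0) overlaps[[length(overlaps) + 1]] <- c(pk, tk, o)
    }
    mp <- logical(max(pl)); mt <- logical(max(gl))
    if (length(overlaps)) {
      tab <- do.call(rbind, overlaps)
      tab <- tab[order(-tab[, 3], tab[, 1], tab[, 2]), , drop = FALSE]
      for (r in seq_len(nrow(tab))) {
        if (!mp[tab[r, 1]] && !mt[tab[r, 2]]) {
          mp[tab[r, 1]] <- TRUE; mt[tab[r, 2]] <- TRUE
        }
      }
    }
    expect_equal(s4$n_matched, sum(mp))
    expect_equal(s4$fdr, if (max(pl) > 0) (max(pl) - sum(mp)) / max(pl) else 0)
  }
})
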