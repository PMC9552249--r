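test_that("confusion counts match the per-pixel oracle", {
  set.seed(31)
  for (rep in 1:10) {
    pred <- random_masks(6, 6, 0.4)
    truth <- random_masks(6, 6, 0.4)
    cc <- confusion_counts(pred, truth, image_id = "x")
    for (cls in c("intact", "not_intact")) {
      ref <- bf_confusion(pred[[cls]], truth[[cls]])
      row <- cc[cc$class == cls, ]
      expect_equal(c(tp = row$tp, fp = row$fp, fn = row$fn, tn = row$tn), ref)
      expect_equal(row$tp + row$fp + row$fn + row$tn, 36L)
    }
  }
  m <- random_masks(5, 5)
  cc <- confusion_counts(m, m)
  expect_true(all(cc$fp == 0L & cc$fn == 0L))
  empty <- label_masks(extent = extent(5, 5))
  cc2 <- confusion_counts(empty, m)
  expect_equal(cc2$fn, c(sum(m$intact), sum(m$not_intact)))
  expect_true(all(cc2$tp == 0L))
})

test_that("mean metrics equal the brute-force summation over images and classes", {
  set.seed(7)
  counts <- dplyr::bind_rows(lapply(1:8, function(i) {
    confusion_counts(random_masks(6, 6), random_masks(6, 6), image_id = paste0("im", i))
  }))
  for (kind in c("iou", "precision", "recall", "specificity")) {
    ref <- mean(apply(counts, 1, function(r) {
      tp <- as.numeric(r[["tp"]]); fp <- as.numeric(r[["fp"]])
      fn <- as.numeric(r[["fn"]]); tn <- as.numeric(r[["tn"]])
      switch(kind, iou = tp / (tp + fp + fn), precision = tp / (tp + fp),
             recall = tp / (tp + fn), specificity = tn / (tn + fp))
    }))
    expect_equal(mean_metric(counts, kind), ref)
  }
  # identical masks: all four metrics are exactly 1
  m <- random_masks(6, 6)
  same <- confusion_counts(m, m)
  for (kind in c("iou", "precision", "recall", "specificity")) {
    expect_equal(mean_metric(same, kind), 1)
  }
  # disjoint non-empty masks: iou/precision/recall all 0
  a <- label_masks(intact = rbind(matrix(TRUE, 3, 6), matrix(FALSE, 3, 6)),
                   not_intact = rbind(matrix(TRUE, 3, 6), matrix(FALSE, 3, 6)))
  b <- label_masks(intact = rbind(matrix(FALSE, 3, 6), matrix(TRUE, 3, 6)),
                   not_intact = rbind(matrix(FALSE, 3, 6), matrix(TRUE, 3, 6)))
  disj <- confusion_counts(a, b)
  expect_equal(mean_metric(disj, "iou"), 0)
  expect_equal(mean_metric(disj, "precision"), 0)
  expect_equal(mean_metric(disj, "recall"), 0)
})

test_that("zero-denominator terms follow the configurable convention", {
  empty <- label_masks(extent = extent(4, 4))
  nonempty <- label_masks(intact = matrix(TRUE, 4, 4))
  # empty truth, empty prediction: vacuously perfect
  both <- confusion_counts(empty, empty)
  expect_equal(mean_metric(both, "iou"), 1)
  expect_equal(mean_metric(both, "recall"), 1)
  expect_true(is.na(mean_metric(both, "iou", empty = "skip")))
  # empty truth, spurious prediction: recall denominator is 0 but pred is not
  sp <- confusion_counts(nonempty, empty)
  expect_equal(mean_metric(sp, "recall"),
               mean(c(0, 1)))   # intact term 0, not_intact vacuous 1
  # empty prediction on non-empty truth: precision 0 for that class
  mp <- confusion_counts(empty, nonempty)
  expect_equal(mean_metric(mp, "precision"), mean(c(0, 1)))
})

test_that("weighted precision/recall metric is the stated affine combination", {
  counts <- tibble::tibble(image = "i", class = c("intact", "not_intact"),
                           tp = c(8L, 6L), fp = c(2L, 4L), fn = c(2L, 4L),
                           tn = c(24L, 22L))
  p <- mean_metric(counts, "precision"); r <- mean_metric(counts, "recall")
  expect_equal(weighted_pr(counts, 1), p)
  expect_equal(weighted_pr(counts, 0), r)
  expect_equal(weighted_pr(counts, 0.5), (p + r) / 2)
  # constructed P = 0.8, R = 0.6 case
  c2 <- tibble::tibble(image = "i", class = "intact",
                       tp = 12L, fp = 3L, fn = 8L, tn = 77L)
  expect_equal(mean_metric(c2, "precision"), 0.8)
  expect_equal(mean_metric(c2, "recall"), 0.6)
  expect_equal(weighted_pr(c2, 0.5), 0.7)
  expect_error(weighted_pr(counts, 1.2), "\\[0, 1\\]")
})

test_that("iou never exceeds precision or recall per term", {
  set.seed(12)
  for (rep in 1:30) {
    cc <- confusion_counts(random_masks(8, 8), random_masks(8, 8))
    expect_lte(mean_metric(cc, "iou"), mean_metric(cc, "precision") + 1e-12)
    expect_lte(mean_metric(cc, "iou"), mean_metric(cc, "recall") + 1e-12)
  }
})

test_that("classification metrics implement the confusion-matrix formulas", {
  perfect <- classification_metrics(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$fnr, 0)
  expect_equal(perfect$f1, 100)
  allneg <- classification_metrics(rep(FALSE, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(allneg$tnr, 100)
  expect_equal(allneg$tpr, 0)
  # hand-computed fixture: tp 40, fn 5, fp 3, tn 52
  pred <- c(rep(TRUE, 40), rep(FALSE, 5), rep(TRUE, 3), rep(FALSE, 52))
  true <- c(rep(TRUE, 45), rep(FALSE, 55))
  m <- classification_metrics(pred, true)
  expect_equal(m$accuracy, 92)
  expect_equal(m$fnr, 100 * 5 / 45)
  expect_equal(m$fpr, 100 * 3 / 55)
  expect_equal(m$tpr, 100 * 40 / 45)
  expect_equal(m$tnr, 100 * 52 / 55)
  prec <- 40 / 43; rec <- 40 / 45
  expect_equal(m$f1, 100 * 2 / (1 / prec + 1 / rec))
  expect_error(classification_metrics(logical(0), logical(0)), "non-empty")
})

test_that("competition ranking reproduces every printed rank annotation", {
  tbl <- selection_scores()
  ranked <- rank_models(tbl)
  expect_equal(ranked$rank_count_error, c(3L, 8L, 6L, 5L, 2L, 1L, 4L, 6L))
  expect_equal(ranked$rank_accuracy,    c(2L, 5L, 8L, 5L, 4L, 1L, 2L, 7L))
  expect_equal(ranked$rank_f1,          c(2L, 5L, 8L, 5L, 4L, 1L, 3L, 7L))
  expect_equal(ranked$rank_fnr,         c(5L, 3L, 8L, 3L, 1L, 2L, 6L, 7L))
  expect_equal(ranked$rank_fpr,         c(4L, 7L, 1L, 7L, 6L, 5L, 3L, 1L))
  expect_equal(ranked$rank_tnr,         c(4L, 7L, 1L, 7L, 6L, 5L, 3L, 1L))
  expect_equal(ranked$rank_tpr,         c(5L, 3L, 8L, 3L, 1L, 2L, 6L, 7L))
  expect_equal(ranked$mean_rank, c(3.67, 5, 5.67, 5, 3.67, 2.67, 3.83, 5))
  expect_equal(ranked$final_rank, c(2L, 5L, 8L, 5L, 2L, 1L, 4L, 5L))
  expect_equal(ranked$model[ranked$final_rank == 1L], "m(0.5P+0.5R)")
})

test_that("ranking is row-order invariant and handles ties lawfully", {
  tbl <- selection_scores()
  perm <- tbl[sample(nrow(tbl)), ]
  r1 <- rank_models(tbl); r2 <- rank_models(perm)
  joined <- dplyr::left_join(r1, r2, by = "model", suffix = c("", ".p"))
  expect_equal(joined$final_rank, joined$final_rank.p)
  expect_equal(joined$mean_rank, joined$mean_rank.p)
  # all-identical models all rank 1
  same <- tbl[rep(1, 4), ]
  same$model <- letters[1:4]
  rs <- rank_models(same)
  expect_true(all(rs$final_rank == 1L))
  expect_true(all(rs$rank_accuracy == 1L))
  # tied competition ranks share the minimum, so rank sums never exceed
  # k(k+1)/2, with equality exactly when all scores are distinct
  k <- nrow(tbl)
  expect_lte(sum(rank_models(tbl)$rank_fpr), k * (k + 1) / 2)
  expect_equal(sum(rank_models(tbl)$rank_count_error), k * (k + 1) / 2 - 1)
  expect_error(rank_models(tbl[, -2]), "missing columns")
})
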