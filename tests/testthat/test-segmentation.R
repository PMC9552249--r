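make_probs <- function(h, w, seed = 1) {
  set.seed(seed)
  z <- array(rexp(h * w * 3), c(h, w, 3))
  s <- z[, , 1] + z[, , 2] + z[, , 3]
  prob_map(array(c(z[, , 1] / s, z[, , 2] / s, z[, , 3] / s), c(h, w, 3)))
}

test_that("prob_map validates range and per-pixel sums", {
  bad <- array(0.6, c(4, 4, 3))
  expect_error(prob_map(bad), "sum to 1")
  ok <- array(1 / 3, c(4, 4, 3))
  expect_s3_class(prob_map(ok), "prob_map")
  neg <- array(c(rep(-0.2, 16), rep(0.6, 32)), c(4, 4, 3))
  expect_error(prob_map(neg), "\\[0, 1\\]")
})

test_that("thresholding matches the per-pixel argmax rule and is single-label", {
  for (seed in 1:20) {
    p <- make_probs(9, 7, seed)
    m <- threshold_probabilities(p, 0.5)
    for (i in 1:9) for (j in 1:7) {
      pi <- p[i, j, "intact"]; pn <- p[i, j, "not_intact"]
      want <- if (pi >= pn && pi >= 0.5) "intact"
              else if (pn > pi && pn >= 0.5) "not_intact" else "background"
      expect_identical(m$intact[i, j], want == "intact")
      expect_identical(m$not_intact[i, j], want == "not_intact")
    }
    expect_false(any(m$intact & m$not_intact))
  }
  # pure background and a confident disk
  bg <- prob_map(array(rep(c(1, 0, 0), each = 12), c(3, 4, 3)))
  mbg <- threshold_probabilities(bg)
  expect_equal(sum(mbg$intact) + sum(mbg$not_intact), 0L)
})

test_that("combined loss matches closed forms and a brute-force oracle", {
  truth <- random_masks(8, 8, p = 0.4)
  truth$not_intact <- truth$not_intact & !truth$intact   # single-label truth
  perfect <- eoescan:::masks_to_probs(truth)
  expect_lt(combined_loss(perfect, truth), 0.02)   # 0 up to the Dice eps
  # uniform 0.5 on each eosinophil channel: BCE term is exactly ln 2
  u <- prob_map(array(c(rep(0, 64), rep(0.5, 128)), c(8, 8, 3)))
  w_bce_only <- combined_loss(u, truth, weights = c(dice = 0, bce = 1))
  expect_equal(w_bce_only, log(2), tolerance = 1e-10)
  # random case against an independent per-pixel implementation
  set.seed(9)
  p <- make_probs(8, 8, seed = 99)
  eps <- 1
  ref <- 0
  for (cls in c("intact", "not_intact")) {
    pc <- p[, , cls]; g <- truth[[cls]] * 1
    dice <- 1 - (2 * sum(pc * g) + eps) / (sum(pc) + sum(g) + eps)
    pcc <- pmin(pmax(pc, 1e-7), 1 - 1e-7)
    bce <- -sum(g * log(pcc) + (1 - g) * log(1 - pcc)) / 64
    ref <- ref + dice / 2 + 0.5 * bce / 2
  }
  expect_equal(combined_loss(p, truth), ref, tolerance = 1e-12)
  expect_error(combined_loss(p, random_masks(4, 4)), "extents differ")
})

test_that("cosine annealing hits its endpoints and midpoint", {
  expect_equal(cosine_annealing_lr(0, 100, 1e-3, 0), 1e-3)
  expect_equal(cosine_annealing_lr(100, 100, 1e-3, 0), 0)
  expect_equal(cosine_annealing_lr(50, 100, 1e-3, 1e-5), (1e-3 + 1e-5) / 2)
  expect_error(cosine_annealing_lr(101, 100), "0 <= t <= T")
})

test_that("the uncorrupted oracle reproduces truth exactly", {
  truth <- rasterize_annotations(
    tibble::tibble(row = c(30L, 70L), col = c(30L, 70L),
                   class = c("intact", "not_intact")), extent(100, 100))
  seg <- oracle_segmenter(truth)
  pm <- predict_tile(seg, NULL, c(0, 0), size = extent(100, 100))
  out <- threshold_probabilities(pm)
  expect_identical(out$intact, truth$intact)
  expect_identical(out$not_intact, truth$not_intact)
  counts <- confusion_counts(out, truth)
  expect_equal(mean_metric(counts, "iou"), 1)
  # cropped prediction equals cropped truth
  pm2 <- predict_tile(seg, NULL, c(20, 60), size = extent(40, 40))
  expect_identical(threshold_probabilities(pm2)$not_intact,
                   truth$not_intact[21:60, 61:100])
})

test_that("oracle corruption realizes the requested flip rate", {
  truth <- label_masks(intact = matrix(TRUE, 200, 200))
  seg <- oracle_segmenter(truth, flip_rate = 0.3, seed = 5)
  out <- threshold_probabilities(predict_tile(seg, NULL, c(0, 0),
                                              size = extent(200, 200)))
  flipped <- sum(!out$intact)
  n <- 200 * 200
  sigma <- sqrt(n * 0.3 * 0.7)
  expect_lt(abs(flipped - 0.3 * n), 3 * sigma)
  # deterministic under the same seed
  out2 <- threshold_probabilities(predict_tile(seg, NULL, c(0, 0),
                                               size = extent(200, 200)))
  expect_identical(out$intact, out2$intact)
})
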