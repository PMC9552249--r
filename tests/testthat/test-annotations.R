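test_that("rasterized disks match the pixelwise distance oracle", {
  # open-field disk
  pts <- tibble::tibble(row = 50L, col = 50L, class = "intact")
  m <- rasterize_annotations(pts, extent(100, 100), diameter = 50)
  ref <- matrix(FALSE, 100, 100)
  for (i in 0:99) for (j in 0:99) ref[i + 1, j + 1] <- (i - 50)^2 + (j - 50)^2 <= 25^2
  expect_identical(m$intact, ref)
  expect_equal(sum(m$not_intact), 0L)
  # clipped quarter disk at the corner
  mc <- rasterize_annotations(tibble::tibble(row = 0L, col = 0L, class = "not_intact"),
                              extent(100, 100))
  refc <- matrix(FALSE, 100, 100)
  for (i in 0:99) for (j in 0:99) refc[i + 1, j + 1] <- i^2 + j^2 <= 625
  expect_identical(mc$not_intact, refc)
  # empty input
  e <- rasterize_annotations(tibble::tibble(row = integer(), col = integer(),
                                            class = character()), extent(10, 10))
  expect_equal(sum(e$intact) + sum(e$not_intact), 0L)
})

test_that("default disk area sits within 1.5% of pi r^2 and in the one-cell band", {
  m <- rasterize_annotations(tibble::tibble(row = 60L, col = 60L, class = "intact"),
                             extent(121, 121))
  area <- sum(m$intact)
  expect_lt(abs(area - pi * 25^2) / (pi * 25^2), 0.015)
  expect_equal(count_from_area(area), 1L)
})

test_that("annotations outside the extent are rejected with their location", {
  expect_error(rasterize_annotations(tibble::tibble(row = 200L, col = 5L,
                                                    class = "intact"),
                                     extent(100, 100)), "\\(200, 5\\)")
})

test_that("background_fraction measures white glass", {
  white <- array(1, c(10, 10, 3))
  dark <- array(0.3, c(10, 10, 3))
  expect_equal(background_fraction(white), 1)
  expect_equal(background_fraction(dark), 0)
  half <- array(0.3, c(10, 10, 3)); half[1:5, , ] <- 0.99
  expect_equal(background_fraction(half), 0.5)
})

test_that("filter_patches applies both rule directions and loses nothing", {
  fr <- c(0, 0.05, 0.15, 0.4, 0.5, 0.9, 1)
  tbl <- tibble::tibble(id = seq_along(fr), background_fraction = fr)
  kept <- filter_patches(tbl, threshold = 0.15, mode = "drop_below")
  expect_equal(kept$id, which(fr >= 0.15))
  expect_equal(attr(kept, "removed")$id, which(fr < 0.15))
  expect_equal(nrow(kept) + nrow(attr(kept, "removed")), length(fr))
  kept2 <- filter_patches(tbl, threshold = 0.15, mode = "drop_above")
  expect_equal(kept2$id, which(fr <= 0.85))
  # all-tissue patches vanish under the literal reading, survive the other
  tissue <- tibble::tibble(background_fraction = rep(0, 4))
  expect_equal(nrow(filter_patches(tissue, mode = "drop_below")), 0L)
  expect_equal(nrow(filter_patches(tissue, mode = "drop_above")), 4L)
  # half-background patches are kept under either mode
  hb <- tibble::tibble(background_fraction = rep(0.5, 3))
  expect_equal(nrow(filter_patches(hb, mode = "drop_below")), 3L)
  expect_equal(nrow(filter_patches(hb, mode = "drop_above")), 3L)
})

test_that("filter_patches computes fractions from images when needed", {
  imgs <- list(array(1, c(4, 4, 3)), array(0.2, c(4, 4, 3)))
  kept <- filter_patches(imgs, threshold = 0.15, mode = "drop_above")
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$background_fraction, 0)
})

test_that("split_dataset honours the 80/20 rule deterministically", {
  s10 <- split_dataset(letters[1:10], seed = 1)
  expect_length(s10$train, 8L)
  expect_length(s10$val, 2L)
  expect_setequal(c(s10$train, s10$val), letters[1:10])
  expect_length(intersect(s10$train, s10$val), 0L)
  expect_identical(split_dataset(letters[1:10], seed = 1), s10)
  expect_false(identical(split_dataset(letters[1:10], seed = 2)$train, s10$train))
  s5 <- split_dataset(1:5, seed = 3)
  expect_length(s5$train, 4L)
  expect_length(s5$val, 1L)
  expect_error(split_dataset("a", seed = 1), "at least 2")
})

test_that("annotation CSV round-trips", {
  ann <- tibble::tibble(image_id = c("a", "a", "b"),
                        row = c(10L, 20L, 5L), col = c(3L, 7L, 9L),
                        class = c("intact", "not_intact", "intact"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, path)
  expect_equal(read_annotations(path), ann)
})
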