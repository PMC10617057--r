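test_that("dice loss matches hand-evaluated cases", {
  m <- matrix(0, 25, 20)
  m[1:25, 1:20][seq_len(500)] <- 1
  expect_equal(dice_loss(m, m, xi = 100), 0)

  z <- matrix(0, 10, 10)
  expect_equal(dice_loss(z, z, xi = 100), 0)  # xi rescues 0/0

  # disjoint masks, |A| = |B| = 50: 1 - 100/200
  a <- matrix(0, 10, 10); a[1:50] <- 1
  b <- matrix(0, 10, 10); b[51:100] <- 1
  expect_equal(dice_loss(a, b, xi = 100), 0.5)

  # soft prediction: intersection is the sum of products
  p <- matrix(0.5, 4, 4)
  g <- matrix(c(rep(1, 8), rep(0, 8)), 4, 4)
  expect_equal(dice_loss(p, g, xi = 0), 1 - 2 * 4 / (8 + 8))
})

test_that("dice loss validates its contract", {
  m <- matrix(0, 4, 4)
  expect_error(dice_loss(m, matrix(0, 4, 5)), "dimensions")
  expect_error(dice_loss(m, m, xi = -1), "non-negative")
  expect_error(dice_loss(m + 2, m), "\\[0, 1\\]")
  expect_error(dice_loss(m, m + 0.5), "binary")
})

test_that("dsc and jaccard match pixel-counting on constructed overlap", {
  # |A| = |B| = 100, |A intersect B| = 50
  a <- matrix(0, 20, 20); a[1:100] <- 1
  b <- matrix(0, 20, 20); b[51:150] <- 1
  expect_equal(dsc(a, b), 0.5)
  expect_equal(jaccard(a, b), 1 / 3)
  expect_equal(dsc(a, a), 1)
  expect_equal(jaccard(a, a), 1)
  d <- matrix(0, 20, 20); d[151:200] <- 1
  expect_equal(dsc(a, d), 0)
  # both-empty convention
  z <- matrix(0, 5, 5)
  expect_equal(dsc(z, z), 1)
  expect_equal(jaccard(z, z), 1)
})

test_that("metric identities hold over random mask pairs", {
  withr::with_seed(11, {
    for (i in 1:200) {
      a <- random_mask(16, 16, runif(1, 0.05, 0.9))
      b <- random_mask(16, 16, runif(1, 0.05, 0.9))
      d <- dsc(a, b)
      j <- jaccard(a, b)
      expect_equal(j, d / (2 - d), tolerance = 1e-12)
      expect_lte(j, d)
      expect_equal(d, dsc(b, a))        # symmetry
      expect_equal(j, jaccard(b, a))
      # as xi -> 0 the loss approaches 1 - dsc
      expect_equal(dice_loss(a, b, xi = 1e-9), 1 - d, tolerance = 1e-6)
    }
  })
})

test_that("confusion counts agree with a nested-loop oracle", {
  withr::with_seed(22, {
    for (i in 1:50) {
      a <- random_mask(8, 8, runif(1, 0.1, 0.9))
      b <- random_mask(8, 8, runif(1, 0.1, 0.9))
      cc <- confusion_counts(a, b)
      oracle <- loop_confusion(a, b)
      expect_identical(unclass(cc)[c("tp", "tn", "fp", "fn")], oracle)
      expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 64)
    }
  })
  n <- 36
  ones <- matrix(1, 6, 6); zeros <- matrix(0, 6, 6)
  expect_equal(confusion_counts(ones, ones)$tp, n)
  expect_equal(confusion_counts(zeros, ones)$fn, n)
})

test_that("pixel accuracy follows (TP+TN)/(TP+TN+FN+FP)", {
  expect_equal(pixel_accuracy(list(tp = 10, tn = 90, fp = 0, fn = 0)), 1)
  expect_equal(pixel_accuracy(list(tp = 0, tn = 0, fp = 50, fn = 50)), 0)
  expect_equal(pixel_accuracy(list(tp = 30, tn = 50, fp = 10, fn = 10)), 0.8)
  expect_error(pixel_accuracy(list(tp = 0, tn = 0, fp = 0, fn = 0)), "empty")
})

test_that("score_masks reads mask files and reports all three metrics", {
  dir <- withr::local_tempdir()
  a <- random_mask(32, 32, 0.3)
  b <- random_mask(32, 32, 0.3)
  pa <- file.path(dir, "pred.png"); pb <- file.path(dir, "ref.png")
  png::writePNG(a, pa)
  png::writePNG(b, pb)
  sc <- score_masks(pa, pb)
  expect_equal(sc$dsc, dsc(a, b))
  expect_equal(sc$jaccard, jaccard(a, b))
  expect_equal(sc$accuracy, pixel_accuracy(confusion_counts(a, b)))
})
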