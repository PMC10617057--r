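test_that("model_config enforces the structural contract", {
  expect_error(model_config(input_size = c(250, 250, 3)), "not divisible")
  expect_error(model_config(encoder_widths = c(8, 16, 32)), "n_downsamples")
  cfg <- tiny_model_config()
  expect_equal(cfg$fused_channels, cfg$lateral_channels * cfg$n_downsamples)
})

test_that("encoder pyramid halves spatial size at every level", {
  for (hw in c(32L, 64L)) {
    cfg <- model_config(input_size = c(hw, hw, 3L),
                        encoder_widths = c(2L, 3L, 4L, 5L, 6L),
                        lateral_channels = 2L, seed = 1)
    m <- build_model(cfg, "improved_fpn")
    x <- array(runif(hw * hw * 3), c(hw, hw, 3, 1))
    fg <- fpnseg:::forward_graph(m, x)
    # fused tensor lives at the finest pyramid level (input / 2)
    expect_equal(dim(fg$fused$value)[1:2], c(hw / 2, hw / 2))
    expect_equal(dim(fg$prob$value), c(hw, hw, 1, 1))
  }
  # spec'd level sizes for 256 inputs are 128, 64, 32, 16; verify the
  # halving arithmetic cheaply via the config
  expect_equal(256 / 2^(1:4), c(128, 64, 32, 16))
})

test_that("fused tensor carries lateral_channels x n_levels channels", {
  cfg <- tiny_model_config(hw = 32L)
  m <- build_model(cfg, "improved_fpn")
  x <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  fg <- fpnseg:::forward_graph(m, x)
  expect_equal(dim(fg$fused$value)[3], cfg$lateral_channels * 4)
  expect_equal(glance(m)$fused_channels, cfg$lateral_channels * 4)
})

test_that("forward output is a valid probability map for both architectures", {
  cfg <- tiny_model_config(hw = 16L)
  for (arch in c("improved_fpn", "unet")) {
    m <- build_model(cfg, arch)
    x <- array(runif(16 * 16 * 3 * 3), c(16, 16, 3, 3))
    p <- predict(m, x)
    expect_equal(dim(p), c(16, 16, 1, 3))
    expect_true(all(p > 0 & p < 1))
    # constant-zero input: finite, no NaN
    p0 <- predict(m, array(0, c(16, 16, 3, 1)))
    expect_true(all(is.finite(p0)))
    # deterministic inference
    expect_identical(predict(m, x), p)
    # wrong channel count
    expect_error(predict(m, array(0.1, c(16, 16, 2, 1))), "channels")
  }
})

test_that("predict_mask thresholds per pixel", {
  expect_equal(predict_mask(matrix(0.9, 4, 4)), matrix(1, 4, 4))
  expect_equal(predict_mask(matrix(0.1, 4, 4)), matrix(0, 4, 4))
  withr::with_seed(2, {
    pm <- matrix(runif(64), 8, 8)
    expect_equal(predict_mask(pm, 0.3), matrix(as.numeric(pm > 0.3), 8, 8))
  })
  expect_error(predict_mask(matrix(0.5, 2, 2), 0), "strictly inside")
  expect_error(predict_mask(matrix(0.5, 2, 2), 1), "strictly inside")
})

test_that("tape gradients match finite differences through both networks", {
  withr::with_seed(99, {
    cfg <- tiny_model_config()
    xb <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
    yb <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 1, 2))
    for (arch in c("improved_fpn", "unet")) {
      m <- build_model(cfg, arch)
      loss_of <- function(model) {
        fg <- fpnseg:::forward_graph(model, xb, training = TRUE)
        fpnseg:::op_dice_loss(fg$tape, fg$prob, yb, xi = 100)$value
      }
      fg <- fpnseg:::forward_graph(m, xb, training = TRUE)
      l <- fpnseg:::op_dice_loss(fg$tape, fg$prob, yb, xi = 100)
      fpnseg:::tape_backward(fg$tape, l)
      check <- if (arch == "improved_fpn") {
        c("stem1_W", "enc3a_W", "lat2_W", "sm4b_W", "fuse_W",
          "fuse_bn_g", "head_W", "head_b")
      } else {
        c("stem1_W", "enc3a_W", "up2_W", "dec1a_W", "dec4b_bn_g", "head_W")
      }
      for (nm in check) {
        nd <- fg$pnodes[[nm]]
        expect_false(is.null(nd$grad), info = nm)
        ii <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
        for (i in ii) {
          mp <- m; mp$params[[nm]][i] <- mp$params[[nm]][i] + 1e-5
          mm <- m; mm$params[[nm]][i] <- mm$params[[nm]][i] - 1e-5
          fd <- (loss_of(mp) - loss_of(mm)) / 2e-5
          expect_equal(nd$grad[i], fd, tolerance = 1e-4,
                       info = sprintf("%s/%s[%d]", arch, nm, i))
        }
      }
      expect_true(all(vapply(names(m$params), function(nm) {
        nd <- fg$pnodes[[nm]]
        is.null(nd) || is.null(nd$grad) || all(is.finite(nd$grad))
      }, logical(1))))
    }
  })
})

test_that("architecture summaries count parameters consistently", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, "improved_fpn")
  tab <- tidy(m)
  expect_equal(sum(tab$n_params), glance(m)$n_params)
  expect_gt(glance(m)$n_params, 0)
  f <- tempfile(fileext = ".txt")
  write_model_summary(m, f)
  expect_true(any(grepl("total parameters", readLines(f))))
  unlink(f)
})

test_that("weights survive a save/load round trip", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, "unet")
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  p1 <- predict(m, x)
  ck <- tempfile(fileext = ".rds")
  save_model_weights(m, ck)
  m2 <- load_model_weights(ck)
  expect_identical(predict(m2, x), p1)
  unlink(ck)
})
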