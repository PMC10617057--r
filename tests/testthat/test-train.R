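tiny_split <- function(n = 12, seed = 50, hw = 16L) {
  pc <- phantom_config(image_size = c(hw, hw), tumor_probability = 1,
                       seed = seed)
  recs <- preprocess_records(generate_phantom_records(n, pc))
  split_dataset(recs, c(0.7, 0.2, 0.1), seed = seed)
}

test_that("training_config validates its invariants", {
  expect_error(training_config(batch_size = 0), "batch_size")
  expect_error(training_config(learning_rate = 0), "learning_rate")
  expect_error(training_config(patience = 0), "patience")
})

test_that("train requires non-empty partitions", {
  sp <- tiny_split()
  sp$validation <- list()
  m <- build_model(tiny_model_config(), "improved_fpn")
  expect_error(train(m, sp), "non-empty")
})

test_that("early stopping halts after `patience` non-improving epochs", {
  # min_delta = 1 makes every epoch count as non-improving after the
  # first, so patience = 1 must stop at epoch 2
  sp <- tiny_split()
  m <- build_model(tiny_model_config(), "improved_fpn")
  tc <- training_config(batch_size = 4, max_epochs = 10,
                        learning_rate = 1e-4, patience = 1, min_delta = 1,
                        seed = 1)
  fit <- train(m, sp, tc)
  expect_equal(fit$stopped_epoch, 2)
  expect_equal(fit$best_epoch, 1)
  expect_equal(nrow(fit$history), 2)
  # the restored monitor value is the best seen
  expect_equal(min(fit$history$val_loss[seq_len(fit$best_epoch)]),
               fit$history$val_loss[fit$best_epoch])
  expect_lte(fit$best_epoch, fit$stopped_epoch)
})

test_that("training is reproducible under a fixed seed", {
  sp <- tiny_split()
  tc <- training_config(batch_size = 4, max_epochs = 2,
                        learning_rate = 1e-4, seed = 3)
  ac <- augmentation_config()
  f1 <- train(build_model(tiny_model_config(), "improved_fpn"), sp, tc, ac)
  f2 <- train(build_model(tiny_model_config(), "improved_fpn"), sp, tc, ac)
  expect_equal(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("a training step reduces the loss it optimizes", {
  sp <- tiny_split()
  tc <- training_config(batch_size = 4, max_epochs = 3,
                        learning_rate = 1e-3, seed = 2)
  fit <- train(build_model(tiny_model_config(), "improved_fpn"), sp, tc)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_true(all(is.finite(fit$history$val_loss)))
})

test_that("evaluate reports per-image metrics and global accuracy", {
  sp <- tiny_split(n = 10)
  m <- build_model(tiny_model_config(), "improved_fpn")
  expect_error(evaluate(m, list()), "empty")
  rep <- evaluate(m, sp$test)
  expect_s3_class(rep$summary, "tbl_df")
  expect_equal(nrow(rep$per_image), length(sp$test))
  expect_true(all(rep$per_image$dsc >= 0 & rep$per_image$dsc <= 1))
  expect_equal(rep$summary$dsc, mean(rep$per_image$dsc))
  # tidy/glance accessors
  expect_identical(tidy(rep), rep$per_image)
  expect_identical(glance(rep), rep$summary)
})

test_that("an all-background predictor scores the phantom composition", {
  # untrained model forced to predict background via a huge threshold:
  # DSC near 0 on positive phantoms, accuracy = background fraction
  sp <- tiny_split(n = 10)
  recs <- sp$train
  bt <- fpnseg:::stack_records(recs)
  zero_pred <- array(0, dim(bt$y))
  d <- dsc(zero_pred[, , 1, 1], bt$y[, , 1, 1])
  expect_equal(d, 0)
  acc <- pixel_accuracy(confusion_counts(zero_pred[, , 1, 1],
                                         bt$y[, , 1, 1]))
  expect_equal(acc, mean(bt$y[, , 1, 1] == 0))
})

test_that("history plots and CSV export work", {
  sp <- tiny_split()
  tc <- training_config(batch_size = 4, max_epochs = 2, seed = 1)
  fit <- train(build_model(tiny_model_config(), "improved_fpn"), sp, tc)
  p <- autoplot(fit$history)
  expect_s3_class(p, "ggplot")
  f <- tempfile(fileext = ".csv")
  write_history(fit$history, f)
  expect_equal(nrow(utils::read.csv(f)), nrow(fit$history))
  unlink(f)
  expect_s3_class(autoplot(evaluate(fit, sp$test)), "ggplot")
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("compare_models trains both architectures under one setting", {
  sp <- tiny_split(n = 12)
  tc <- training_config(batch_size = 4, max_epochs = 1, seed = 1)
  cmp <- compare_models(sp, tiny_model_config(), tc,
                        archs = c("unet", "improved_fpn"))
  expect_equal(nrow(cmp$table), 2)
  expect_setequal(cmp$table$model, c("unet", "improved_fpn"))
  expect_true(all(c("dsc", "jaccard", "accuracy") %in% names(cmp$table)))
  expect_true(all(cmp$table$dsc >= 0 & cmp$table$dsc <= 1))
  expect_s3_class(cmp$fits$unet, "fpnseg_fit")
  expect_identical(tidy(cmp), cmp$table)
})

test_that("run configuration files round-trip through the constructors", {
  f <- tempfile(fileext = ".yml")
  writeLines(c("model:",
               "  input_size: [64, 64, 3]",
               "  encoder_widths: [8, 16, 32, 64, 128]",
               "  lateral_channels: 48",
               "training:",
               "  batch_size: 8",
               "  max_epochs: 150",
               "  learning_rate: 1.0e-4",
               "augmentation:",
               "  horizontal_shift: 0.25",
               "  transpose: 0.25",
               "  vertical_shift: 0.25",
               "  blur: 0.05",
               "  random_crop: 0.05",
               "  random_rotate: 0.5",
               "  random_resize: 0.25",
               "  random_flip: 0.5",
               "  random_brightness: 1.0"), f)
  rc <- read_run_config(f)
  expect_s3_class(rc$model, "model_config")
  expect_equal(rc$model$fused_channels, 192)
  expect_equal(rc$training$batch_size, 8)
  expect_equal(unname(rc$augmentation$params["random_brightness"]), 1.0)
  writeLines(c("training:", "  nonsense: 1"), f)
  expect_error(read_run_config(f), "unknown")
  unlink(f)
})
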