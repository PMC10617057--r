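# Training and evaluation harness: Adam on the smoothed Dice loss,
# early stopping on validation Dice loss with best-weights restoration,
# and the two-model comparison procedure.

#' Training configuration
#'
#' Defaults follow the study protocol: batch size 8, up to 150 epochs,
#' Adam at learning rate 1e-4, early stopping on the validation Dice
#' loss. Patience 10 and `min_delta` 1e-4 are this package's choices
#' (the protocol invokes early stopping without parameters).
#'
#' @param batch_size Images per optimization step.
#' @param max_epochs Upper bound on epochs.
#' @param learning_rate Adam step size.
#' @param patience Epochs without validation improvement before
#'   stopping.
#' @param min_delta Minimum decrease in validation Dice loss that
#'   counts as an improvement.
#' @param xi Dice-loss smoothing constant.
#' @param per_image_loss Average per-image Dice losses instead of
#'   pooling the batch (pooling is the default; see the vignette).
#' @param bce_weight Weight of an optional added binary cross-entropy
#'   term (0 = pure Dice loss, the default).
#' @param seed Seed controlling batch order and augmentation draws.
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 8L, max_epochs = 150L,
                            learning_rate = 1e-4, patience = 10L,
                            min_delta = 1e-4, xi = 100,
                            per_image_loss = FALSE, bce_weight = 0,
                            seed = 1L) {
  stopifnot(batch_size >= 1, max_epochs >= 1, learning_rate > 0,
            patience >= 1, min_delta >= 0, xi >= 0, bce_weight >= 0)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 min_delta = min_delta, xi = xi,
                 per_image_loss = per_image_loss,
                 bce_weight = bce_weight, seed = as.integer(seed)),
            class = "training_config")
}

adam_init <- function(params) {
  opt <- new.env(parent = emptyenv())
  opt$m <- lapply(params, function(p) p * 0)
  opt$v <- lapply(params, function(p) p * 0)
  opt$t <- 0L
  opt
}

adam_step <- function(params, pnodes, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    nd <- pnodes[[nm]]
    if (is.null(nd) || is.null(nd$grad)) next
    g <- nd$grad
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  params
}

validate_pass <- function(model, records, xi, batch_size, threshold = 0.5) {
  n <- length(records)
  I <- S <- 0
  dscs <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    bt <- stack_records(records[idx])
    fg <- forward_graph(model, bt$x, training = FALSE)
    p <- fg$prob$value
    I <- I + sum(p * bt$y)
    S <- S + sum(p) + sum(bt$y)
    hard <- (p > threshold) * 1
    for (j in seq_along(idx)) {
      dscs[idx[j]] <- dsc(hard[, , 1, j], bt$y[, , 1, j])
    }
  }
  list(loss = 1 - (2 * I + xi) / (S + xi), dsc = mean(dscs))
}

#' Train a segmentation model
#'
#' Minimizes the smoothed Dice loss with Adam. Augmentation (if a
#' config is supplied) is applied to training batches only; the
#' validation pass uses the raw records and inference-mode batch norm.
#' Early stopping monitors the validation Dice loss and the weights of
#' the best epoch are restored on return. Fixed `tconfig$seed` makes
#' the whole run reproducible (batch order, augmentation draws).
#'
#' @param model A [build_model()] result.
#' @param split A [split_dataset()] with non-empty train and validation
#'   partitions (preprocessed records).
#' @param tconfig A [training_config()].
#' @param aconfig An [augmentation_config()], or `NULL` for no
#'   augmentation.
#' @param verbose Print one line per epoch.
#' @return An object of class `fpnseg_fit`: a list with the trained
#'   `model` (best weights), the per-epoch `history` tibble
#'   (`training_history`), `best_epoch` and `stopped_epoch`.
#' @export
train <- function(model, split, tconfig = training_config(),
                  aconfig = NULL, verbose = FALSE) {
  n_train <- length(split$train)
  n_val <- length(split$validation)
  if (n_train == 0L || n_val == 0L)
    stop("train and validation partitions must both be non-empty",
         call. = FALSE)
  opt <- adam_init(model$params)
  best_loss <- Inf
  best_epoch <- 0L
  best <- NULL
  wait <- 0L
  stopped_epoch <- tconfig$max_epochs
  rows <- list()

  withr::with_seed(tconfig$seed, {
    for (epoch in seq_len(tconfig$max_epochs)) {
      ord <- sample.int(n_train)
      batch_losses <- numeric(0)
      for (start in seq(1L, n_train, by = tconfig$batch_size)) {
        idx <- ord[start:min(start + tconfig$batch_size - 1L, n_train)]
        recs <- split$train[idx]
        if (!is.null(aconfig) && aconfig$enabled)
          recs <- lapply(recs, augment_pair, config = aconfig)
        bt <- stack_records(recs)
        fg <- forward_graph(model, bt$x, training = TRUE)
        loss <- op_dice_loss(fg$tape, fg$prob, bt$y, xi = tconfig$xi,
                             per_image = tconfig$per_image_loss)
        if (tconfig$bce_weight > 0) {
          bce <- op_bce_loss(fg$tape, fg$prob, bt$y)
          loss <- op_scale_add(fg$tape, loss, bce, 1, tconfig$bce_weight)
        }
        if (!is.finite(loss$value))
          stop(sprintf(
            "non-finite training loss at epoch %d (step %d): %s",
            epoch, opt$t + 1L, format(loss$value)), call. = FALSE)
        tape_backward(fg$tape, loss)
        model$params <- adam_step(model$params, fg$pnodes, opt,
                                  tconfig$learning_rate)
        batch_losses <- c(batch_losses, loss$value)
      }
      val <- validate_pass(model, split$validation, tconfig$xi,
                           tconfig$batch_size)
      rows[[epoch]] <- tibble::tibble(epoch = epoch,
                                      train_loss = mean(batch_losses),
                                      val_loss = val$loss,
                                      val_dsc = val$dsc)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  val DSC %.4f",
                        epoch, mean(batch_losses), val$loss, val$dsc))
      if (val$loss < best_loss - tconfig$min_delta) {
        best_loss <- val$loss
        best_epoch <- epoch
        best <- list(params = model$params, state = as.list(model$state))
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tconfig$patience) {
          stopped_epoch <- epoch
          break
        }
      }
      stopped_epoch <- epoch
    }
  })

  if (!is.null(best)) {
    model$params <- best$params
    for (nm in names(best$state)) model$state[[nm]] <- best$state[[nm]]
  }
  history <- do.call(rbind, rows)
  class(history) <- c("training_history", class(history))
  attr(history, "best_epoch") <- best_epoch
  attr(history, "stopped_epoch") <- stopped_epoch
  structure(list(model = model, history = history,
                 best_epoch = best_epoch, stopped_epoch = stopped_epoch),
            class = "fpnseg_fit")
}

#' @export
print.fpnseg_fit <- function(x, ...) {
  cat(sprintf(
    "fpnseg_fit (%s): stopped at epoch %d, best epoch %d (val loss %.4f, val DSC %.4f)\n",
    x$model$arch, x$stopped_epoch, x$best_epoch,
    x$history$val_loss[x$best_epoch], x$history$val_dsc[x$best_epoch]))
  invisible(x)
}

#' @export
tidy.fpnseg_fit <- function(x, ...) {
  h <- x$history
  class(h) <- setdiff(class(h), "training_history")
  h
}

#' @export
glance.fpnseg_fit <- function(x, ...) {
  tibble::tibble(architecture = x$model$arch,
                 epochs_run = x$stopped_epoch,
                 best_epoch = x$best_epoch,
                 best_val_loss = x$history$val_loss[x$best_epoch],
                 best_val_dsc = x$history$val_dsc[x$best_epoch])
}

#' Evaluate a model on a record set
#'
#' Reports the test-set metrics: mean per-image DSC and Jaccard, global
#' pixel accuracy over all pixels, and (for reference) the pooled DSC
#' and Jaccard computed over all test pixels at once. A per-image table
#' is attached for inspection.
#'
#' @param model A trained `fpnseg_model` (or an `fpnseg_fit`).
#' @param records Non-empty list of preprocessed `image_record`s.
#' @param threshold Binarization threshold for predictions.
#' @param batch_size Images per forward pass.
#' @return An object of class `evaluation_report`: a list with
#'   `summary` (one-row tibble) and `per_image` (one row per record).
#' @export
evaluate <- function(model, records, threshold = 0.5, batch_size = 8L) {
  if (inherits(model, "fpnseg_fit")) model <- model$model
  n <- length(records)
  if (n == 0L) stop("`records` is empty", call. = FALSE)
  per <- vector("list", n)
  tp <- tn <- fp <- fn <- 0
  Ipool <- Spool <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    bt <- stack_records(records[idx])
    prob <- forward_graph(model, bt$x, training = FALSE)$prob$value
    hard <- predict_mask(prob, threshold)
    for (j in seq_along(idx)) {
      p <- hard[, , 1, j]
      g <- bt$y[, , 1, j]
      cc <- confusion_counts(p, g)
      tp <- tp + cc$tp; tn <- tn + cc$tn; fp <- fp + cc$fp; fn <- fn + cc$fn
      Ipool <- Ipool + sum(p * g)
      Spool <- Spool + sum(p) + sum(g)
      per[[idx[j]]] <- tibble::tibble(id = records[[idx[j]]]$id,
                                      dsc = dsc(p, g),
                                      jaccard = jaccard(p, g),
                                      accuracy = pixel_accuracy(cc))
    }
  }
  per_image <- do.call(rbind, per)
  dsc_pooled <- if (Spool == 0) 1 else 2 * Ipool / Spool
  summary <- tibble::tibble(
    model = model$arch,
    dsc = mean(per_image$dsc),
    jaccard = mean(per_image$jaccard),
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    dsc_pooled = dsc_pooled,
    jaccard_pooled = if (Spool == 0) 1 else Ipool / (Spool - Ipool),
    n_images = n)
  structure(list(summary = summary, per_image = per_image),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "evaluation (%s, %d images): DSC %.3f, Jaccard %.3f, accuracy %.4f\n",
    s$model, s$n_images, s$dsc, s$jaccard, s$accuracy))
  invisible(x)
}

#' @export
tidy.evaluation_report <- function(x, ...) x$per_image

#' @export
glance.evaluation_report <- function(x, ...) x$summary

#' Train and compare models under identical settings
#'
#' Trains each architecture with the same split, training configuration
#' and seed, evaluates on the test partition and returns a two-row
#' comparison table (DSC / Jaccard / accuracy per model).
#'
#' @param split A [split_dataset()] with all three partitions.
#' @param config A [model_config()] shared by the architectures.
#' @param tconfig A [training_config()].
#' @param aconfig Optional [augmentation_config()].
#' @param archs Architectures to compare.
#' @param verbose Passed to [train()].
#' @return An object of class `model_comparison`: list with `table`
#'   (tibble) and the underlying `fits`.
#' @export
compare_models <- function(split, config = model_config(),
                           tconfig = training_config(), aconfig = NULL,
                           archs = c("unet", "improved_fpn"),
                           verbose = FALSE) {
  if (length(archs) < 2L) stop("need at least two architectures",
                               call. = FALSE)
  if (length(split$test) == 0L) stop("test partition is empty",
                                     call. = FALSE)
  fits <- list()
  rows <- list()
  for (arch in archs) {
    model <- build_model(config, arch)
    fit <- train(model, split, tconfig, aconfig, verbose = verbose)
    rep <- evaluate(fit, split$test, batch_size = tconfig$batch_size)
    fits[[arch]] <- fit
    rows[[arch]] <- tibble::tibble(
      model = arch,
      dsc = rep$summary$dsc,
      jaccard = rep$summary$jaccard,
      accuracy = rep$summary$accuracy,
      n_params = n_parameters(fit$model),
      best_epoch = fit$best_epoch)
  }
  structure(list(table = do.call(rbind, rows), fits = fits),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model comparison (test partition):\n")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.model_comparison <- function(x, ...) x$table
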