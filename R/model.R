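# Segmentation architectures: the improved-FPN network (U-Net
# contracting path as the bottom-up pathway, FPN top-down decoder with
# multi-level fusion) and the classical U-Net baseline.

#' Model configuration
#'
#' Structural parameters shared by both architectures. The defaults are
#' the full-scale network: 256 x 256 x 3 inputs, U-Net channel doubling
#' 64..1024 over four downsamplings, 128 lateral channels so the four
#' pyramid levels concatenate to 512 fused channels. For CPU-scale
#' experiments pass smaller `input_size` and `encoder_widths`.
#'
#' @param input_size Integer `(H, W, channels)`. H and W must be
#'   divisible by `2^n_downsamples`.
#' @param encoder_widths Channel counts per encoder scale; length must
#'   be `n_downsamples + 1`.
#' @param lateral_channels Channels after each lateral 1x1 convolution;
#'   the fused tensor has `lateral_channels * n_downsamples` channels.
#' @param n_downsamples Number of 2x downsamplings (pyramid levels).
#' @param residual Add an identity shortcut around the second conv of
#'   each encoder scale (off by default).
#' @param seed Seed for weight initialization.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_size = c(256L, 256L, 3L),
                         encoder_widths = c(64L, 128L, 256L, 512L, 1024L),
                         lateral_channels = 128L,
                         n_downsamples = 4L,
                         residual = FALSE,
                         seed = 1L) {
  if (length(input_size) != 3L)
    stop("`input_size` must be (H, W, channels)", call. = FALSE)
  div <- 2^n_downsamples
  if (input_size[1] %% div != 0 || input_size[2] %% div != 0)
    stop(sprintf("input size %dx%d is not divisible by 2^%d = %d",
                 input_size[1], input_size[2], n_downsamples, div),
         call. = FALSE)
  if (length(encoder_widths) != n_downsamples + 1L)
    stop("`encoder_widths` must have n_downsamples + 1 entries", call. = FALSE)
  structure(list(input_size = as.integer(input_size),
                 encoder_widths = as.integer(encoder_widths),
                 lateral_channels = as.integer(lateral_channels),
                 n_downsamples = as.integer(n_downsamples),
                 fused_channels = as.integer(lateral_channels * n_downsamples),
                 residual = isTRUE(residual),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build a segmentation model
#'
#' `arch = "improved_fpn"` grafts an FPN decoder onto the U-Net
#' contracting path: the four post-downsampling encoder scales feed
#' lateral 1x1 convolutions (to `lateral_channels`), the top-down
#' pathway upsamples each coarser merged map nearest-neighbour and adds
#' it element-wise, two 3x3 convolutions smooth each merged level, all
#' levels are upsampled to the finest pyramid resolution and
#' concatenated, and a 3x3 convolution with batch normalization and
#' ReLU plus a 1x1 convolution produce the logit map, bilinearly
#' upsampled to input resolution and passed through a sigmoid.
#' `arch = "unet"` is the classical U-Net baseline with skip
#' concatenations and upsample+conv expansion.
#'
#' @param config A [model_config()].
#' @param arch `"improved_fpn"` or `"unet"`.
#' @return An object of class `fpnseg_model` holding the parameter set,
#'   batch-norm state, and layer table.
#' @export
build_model <- function(config = model_config(),
                        arch = c("improved_fpn", "unet")) {
  arch <- match.arg(arch)
  w <- config$encoder_widths
  L <- config$lateral_channels
  nd <- config$n_downsamples
  cin0 <- config$input_size[3]

  params <- list()
  layers <- list()
  bn_keys <- character(0)
  add_conv <- function(name, kh, cin, cout, bn = TRUE,
                       sd = sqrt(2 / (kh * kh * cin))) {
    params[[paste0(name, "_W")]] <<-
      matrix(rnorm(kh * kh * cin * cout, 0, sd), kh * kh * cin, cout)
    params[[paste0(name, "_b")]] <<- numeric(cout)
    layers[[length(layers) + 1L]] <<-
      list(layer = name, kernel = kh, in_ch = cin, out_ch = cout,
           batchnorm = bn)
    if (bn) {
      params[[paste0(name, "_bn_g")]] <<- rep(1, cout)
      params[[paste0(name, "_bn_be")]] <<- numeric(cout)
      bn_keys <<- c(bn_keys, paste0(name, "_bn"))
    }
  }

  withr::with_seed(config$seed, {
    add_conv("stem1", 3, cin0, w[1])
    add_conv("stem2", 3, w[1], w[1])
    for (k in seq_len(nd)) {
      add_conv(paste0("enc", k, "a"), 3, w[k], w[k + 1])
      add_conv(paste0("enc", k, "b"), 3, w[k + 1], w[k + 1])
    }
    if (arch == "improved_fpn") {
      for (k in seq_len(nd)) add_conv(paste0("lat", k), 1, w[k + 1], L,
                                      bn = FALSE, sd = sqrt(1 / w[k + 1]))
      for (k in seq_len(nd)) {
        add_conv(paste0("sm", k, "a"), 3, L, L, bn = FALSE)
        add_conv(paste0("sm", k, "b"), 3, L, L, bn = FALSE)
      }
      add_conv("fuse", 3, L * nd, L * nd)
      add_conv("head", 1, L * nd, 1L, bn = FALSE, sd = sqrt(1 / (L * nd)))
    } else {
      for (k in rev(seq_len(nd))) {
        add_conv(paste0("up", k), 3, w[k + 1], w[k])
        add_conv(paste0("dec", k, "a"), 3, 2L * w[k], w[k])
        add_conv(paste0("dec", k, "b"), 3, w[k], w[k])
      }
      add_conv("head", 1, w[1], 1L, bn = FALSE, sd = sqrt(1 / w[1]))
    }
  })

  state <- new.env(parent = emptyenv())
  for (key in bn_keys) {
    cout <- length(params[[paste0(key, "_g")]])
    state[[paste0(key, "_mean")]] <- numeric(cout)
    state[[paste0(key, "_var")]] <- rep(1, cout)
  }
  structure(list(arch = arch, config = config, params = params,
                 layers = layers, bn_keys = bn_keys, state = state),
            class = "fpnseg_model")
}

# Full forward pass on the tape. Returns the tape, the probability
# node, the pre-fusion concatenated node (improved FPN only) and the
# parameter-node environment used to collect gradients.
forward_graph <- function(model, x, training = FALSE) {
  d <- dim(x)
  cfg <- model$config
  if (is.null(d) || length(d) < 3L)
    stop("input must be an H x W x C (x N) array", call. = FALSE)
  x <- as_nhwc(x)
  d <- dim(x)
  if (d[3] != cfg$input_size[3])
    stop(sprintf("input has %d channels, model expects %d",
                 d[3], cfg$input_size[3]), call. = FALSE)
  div <- 2^cfg$n_downsamples
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop(sprintf("input size %dx%d is not divisible by 2^%d",
                 d[1], d[2], cfg$n_downsamples), call. = FALSE)

  tp <- new_tape()
  pn <- new.env(parent = emptyenv())
  P <- function(nm) {
    if (is.null(pn[[nm]])) pn[[nm]] <- add_node(tp, model$params[[nm]],
                                                name = nm)
    pn[[nm]]
  }
  cbr <- function(xn, name, kh = 3, bn = TRUE, act = TRUE) {
    y <- op_conv(tp, xn, P(paste0(name, "_W")), P(paste0(name, "_b")),
                 kh, kh)
    if (bn) y <- op_batchnorm(tp, y, P(paste0(name, "_bn_g")),
                              P(paste0(name, "_bn_be")),
                              model$state, paste0(name, "_bn"), training)
    if (act) y <- op_relu(tp, y)
    y
  }

  nd <- cfg$n_downsamples
  x0 <- op_leaf(tp, x, "input")
  s <- cbr(cbr(x0, "stem1"), "stem2")
  e <- s
  feats <- vector("list", nd)
  for (k in seq_len(nd)) {
    e <- op_maxpool2(tp, e)
    e1 <- cbr(e, paste0("enc", k, "a"))
    if (cfg$residual) {
      y <- cbr(e1, paste0("enc", k, "b"), act = FALSE)
      e2 <- op_relu(tp, op_add(tp, y, e1))
    } else {
      e2 <- cbr(e1, paste0("enc", k, "b"))
    }
    feats[[k]] <- e2
    e <- e2
  }

  fused <- NULL
  if (model$arch == "improved_fpn") {
    lat <- lapply(seq_len(nd), function(k)
      op_conv(tp, feats[[k]], P(paste0("lat", k, "_W")),
              P(paste0("lat", k, "_b")), 1, 1))
    pmaps <- vector("list", nd)
    pmaps[[nd]] <- lat[[nd]]
    for (k in rev(seq_len(nd - 1))) {
      pmaps[[k]] <- op_add(tp, lat[[k]],
                           op_upsample_nn(tp, pmaps[[k + 1]], 2L))
    }
    sm <- lapply(seq_len(nd), function(k) {
      y <- cbr(pmaps[[k]], paste0("sm", k, "a"), bn = FALSE)
      cbr(y, paste0("sm", k, "b"), bn = FALSE)
    })
    ups <- lapply(seq_len(nd), function(k)
      op_upsample_nn(tp, sm[[k]], 2L^(k - 1)))
    fused <- op_concat(tp, ups)
    f <- cbr(fused, "fuse")
    logit <- op_conv(tp, f, P("head_W"), P("head_b"), 1, 1)
    logit <- op_bilinear_resize(tp, logit, d[1], d[2])
  } else {
    dnode <- feats[[nd]]
    skips <- c(list(s), feats[seq_len(nd - 1)])
    for (k in rev(seq_len(nd))) {
      dnode <- op_upsample_nn(tp, dnode, 2L)
      dnode <- cbr(dnode, paste0("up", k))
      dnode <- op_concat(tp, list(skips[[k]], dnode))
      dnode <- cbr(dnode, paste0("dec", k, "a"))
      dnode <- cbr(dnode, paste0("dec", k, "b"))
    }
    logit <- op_conv(tp, dnode, P("head_W"), P("head_b"), 1, 1)
  }
  prob <- op_sigmoid(tp, logit)
  list(tape = tp, prob = prob, fused = fused, pnodes = pn)
}

#' Predict probability maps or masks
#'
#' Runs the network in inference mode (batch-norm running statistics;
#' fully deterministic for fixed weights).
#'
#' @param object A [build_model()] or trained model.
#' @param images An H x W x C (x N) array in `[0, 1]`, or a list of
#'   preprocessed `image_record`s.
#' @param type `"prob"` for sigmoid probability maps, `"mask"` for
#'   binarized masks.
#' @param threshold Binarization threshold when `type = "mask"`.
#' @param batch_size Images per forward pass.
#' @param ... Unused.
#' @return An H x W x 1 x N array of probabilities in `(0, 1)` (or a
#'   binary array for `type = "mask"`).
#' @export
predict.fpnseg_model <- function(object, images, type = c("prob", "mask"),
                                 threshold = 0.5, batch_size = 8L, ...) {
  type <- match.arg(type)
  if (is.list(images) && !is.array(images))
    images <- stack_records(images)$x
  x <- as_nhwc(images)
  d <- dim(x)
  n <- d[4]
  out <- array(0, c(d[1], d[2], 1L, n))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fg <- forward_graph(object, x[, , , idx, drop = FALSE],
                        training = FALSE)
    out[, , , idx] <- fg$prob$value
  }
  if (type == "mask") out <- predict_mask(out, threshold)
  out
}

#' Binarize a probability map
#'
#' @param probmap Numeric array with values in `[0, 1]`.
#' @param threshold Threshold strictly inside `(0, 1)`.
#' @return A strictly binary array of the same shape.
#' @export
predict_mask <- function(probmap, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie strictly inside (0, 1)", call. = FALSE)
  if (any(probmap < 0 | probmap > 1))
    stop("`probmap` must lie in [0, 1]", call. = FALSE)
  out <- (probmap > threshold) * 1
  dim(out) <- dim(probmap)
  out
}

# Stack a list of preprocessed records into batch arrays.
stack_records <- function(records) {
  d <- dim(records[[1]]$image)
  n <- length(records)
  x <- array(unlist(lapply(records, function(r) r$image), use.names = FALSE),
             c(d[1], d[2], d[3], n))
  y <- array(unlist(lapply(records, function(r) r$mask), use.names = FALSE),
             c(d[1], d[2], 1L, n))
  list(x = x, y = y)
}

n_parameters <- function(model) sum(lengths(model$params))

#' @export
print.fpnseg_model <- function(x, ...) {
  cat(sprintf("fpnseg_model '%s': input %s, widths %s, %s parameters\n",
              x$arch, paste(x$config$input_size, collapse = "x"),
              paste(x$config$encoder_widths, collapse = ","),
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-layer architecture table
#'
#' One row per convolution layer: kernel size, input/output channels,
#' parameter count (including the layer's batch-norm scale and shift,
#' when present). This is the plain-text architecture summary for
#' audit.
#'
#' @param x A `fpnseg_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.fpnseg_model <- function(x, ...) {
  rows <- lapply(x$layers, function(l) {
    np <- l$kernel^2 * l$in_ch * l$out_ch + l$out_ch +
      if (l$batchnorm) 2L * l$out_ch else 0L
    tibble::tibble(layer = l$layer, kernel = l$kernel, in_ch = l$in_ch,
                   out_ch = l$out_ch, batchnorm = l$batchnorm,
                   n_params = np)
  })
  do.call(rbind, rows)
}

#' One-row model summary
#'
#' @param x A `fpnseg_model`.
#' @param ... Unused.
#' @return A tibble with architecture, parameter count and the channel
#'   contract (pyramid levels, lateral and fused channels).
#' @export
glance.fpnseg_model <- function(x, ...) {
  tibble::tibble(architecture = x$arch,
                 n_params = n_parameters(x),
                 n_levels = x$config$n_downsamples,
                 lateral_channels = x$config$lateral_channels,
                 fused_channels = x$config$fused_channels,
                 input_h = x$config$input_size[1],
                 input_w = x$config$input_size[2])
}

#' Write a plain-text architecture summary
#'
#' @param model A `fpnseg_model`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_model_summary <- function(model, file) {
  tab <- tidy.fpnseg_model(model)
  lines <- c(sprintf("architecture: %s", model$arch),
             sprintf("input: %s",
                     paste(model$config$input_size, collapse = "x")),
             sprintf("total parameters: %d", n_parameters(model)),
             "",
             sprintf("%-10s %6s %6s %6s %10s", "layer", "kernel", "in",
                     "out", "params"),
             sprintf("%-10s %6d %6d %6d %10d", tab$layer, tab$kernel,
                     tab$in_ch, tab$out_ch, tab$n_params))
  writeLines(lines, file)
  invisible(file)
}

#' Save / load model weights
#'
#' Serializes the parameter set, batch-norm running statistics,
#' configuration and architecture tag as an RDS checkpoint.
#'
#' @param model A `fpnseg_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `path` invisibly (`save_model_weights`); the restored
#'   `fpnseg_model` (`load_model_weights`).
#' @export
save_model_weights <- function(model, path) {
  saveRDS(list(arch = model$arch, config = unclass(model$config),
               params = model$params,
               state = as.list(model$state)), path)
  invisible(path)
}

#' @rdname save_model_weights
#' @export
load_model_weights <- function(path) {
  ck <- readRDS(path)
  cfg <- structure(ck$config, class = "model_config")
  model <- build_model(cfg, ck$arch)
  model$params <- ck$params
  for (nm in names(ck$state)) model$state[[nm]] <- ck$state[[nm]]
  model
}
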