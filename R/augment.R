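# Paired image/mask augmentation: nine operations with reproducible
# randomness. Geometric transforms are applied identically to image and
# mask (mask resampled nearest-neighbour so it stays strictly binary);
# photometric transforms (blur, brightness) touch the image only.

#' Augmentation configuration
#'
#' The nine augmentation operations and their parameters. The bare
#' numbers are interpreted as follows (configurable): the shift
#' parameters are the maximum fractional offset of the image side;
#' `random_resize` is the maximum fractional zoom in/out;
#' `random_brightness` the maximum multiplicative jitter range; and
#' `transpose`, `blur`, `random_crop`, `random_rotate`, `random_flip`
#' are application probabilities. Each enabled operation is considered
#' independently per sample, in the order listed.
#'
#' @param horizontal_shift,vertical_shift Max offset as a fraction of
#'   the image side (the shift itself is drawn uniformly in `±` that).
#' @param transpose Probability of transposing the axes.
#' @param blur Probability of Gaussian blur (sigma `blur_sigma`).
#' @param random_crop Probability of cropping a random sub-window
#'   (side fraction drawn in `[crop_min, 1]`) and rescaling back.
#' @param random_rotate Probability of rotating by an angle drawn
#'   uniformly in `±rotate_max_deg` degrees.
#' @param random_resize Max fractional zoom; the scale is drawn in
#'   `1 ± random_resize` and the result is cropped/zero-padded back.
#' @param random_flip Probability of a flip (axis chosen at random).
#' @param random_brightness Max multiplicative brightness jitter `b`:
#'   factor drawn log-uniformly in `[1/(1+b), 1+b]`, image clipped to
#'   `[0, 1]`.
#' @param enabled Global on/off switch.
#' @param apply Named logical vector switching individual operations.
#' @param blur_sigma,rotate_max_deg,crop_min Magnitudes of the
#'   probability-gated operations.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(horizontal_shift = 0.25,
                                transpose = 0.25,
                                vertical_shift = 0.25,
                                blur = 0.05,
                                random_crop = 0.05,
                                random_rotate = 0.5,
                                random_resize = 0.25,
                                random_flip = 0.5,
                                random_brightness = 1.0,
                                enabled = TRUE,
                                apply = NULL,
                                blur_sigma = 1,
                                rotate_max_deg = 30,
                                crop_min = 0.8) {
  ops <- c("horizontal_shift", "transpose", "vertical_shift", "blur",
           "random_crop", "random_rotate", "random_resize", "random_flip",
           "random_brightness")
  pars <- c(horizontal_shift, transpose, vertical_shift, blur, random_crop,
            random_rotate, random_resize, random_flip, random_brightness)
  names(pars) <- ops
  if (any(pars < 0)) stop("augmentation parameters must be >= 0", call. = FALSE)
  probs <- c("transpose", "blur", "random_crop", "random_rotate", "random_flip")
  if (any(pars[probs] > 1))
    stop("probability-interpreted parameters must be <= 1", call. = FALSE)
  ap <- stats::setNames(rep(TRUE, length(ops)), ops)
  if (!is.null(apply)) ap[names(apply)] <- apply
  structure(list(params = pars, enabled = enabled, apply = ap,
                 blur_sigma = blur_sigma, rotate_max_deg = rotate_max_deg,
                 crop_min = crop_min),
            class = "augmentation_config")
}

# ---- geometric primitives ------------------------------------------------

# Integer-pixel translation with zero fill; exact for image and mask.
shift_int <- function(arr, dy, dx) {
  d <- dim(arr)
  H <- d[1]; W <- d[2]
  out <- array(0, d)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  ok_y <- ys >= 1 & ys <= H; ok_x <- xs >= 1 & xs <= W
  if (!any(ok_y) || !any(ok_x)) return(out)
  if (length(d) == 2L) {
    out[which(ok_y), which(ok_x)] <- arr[ys[ok_y], xs[ok_x]]
  } else {
    out[which(ok_y), which(ok_x), ] <- arr[ys[ok_y], xs[ok_x], , drop = FALSE]
  }
  out
}

# Affine resampling. A is a 2x3 matrix mapping output pixel centres
# (x = column, y = row, 1-based) to input coordinates:
#   x_in = A[1,1] x + A[1,2] y + A[1,3];  y_in = A[2,1] x + A[2,2] y + A[2,3]
# Out-of-frame samples are zero-filled. `interp` "nearest" keeps masks
# strictly binary; "bilinear" is used for images.
warp_affine <- function(arr, A, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  d <- dim(arr)
  H <- d[1]; W <- d[2]
  C <- if (length(d) == 3L) d[3] else 1L
  xo <- rep(seq_len(W), each = H)
  yo <- rep(seq_len(H), times = W)
  xi <- A[1, 1] * xo + A[1, 2] * yo + A[1, 3]
  yi <- A[2, 1] * xo + A[2, 2] * yo + A[2, 3]
  out <- array(0, d)
  am <- if (length(d) == 2L) matrix(arr, H, W) else arr
  if (interp == "nearest") {
    ri <- round(yi); ci <- round(xi)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    idx <- ri[ok] + (ci[ok] - 1) * H
    for (ch in seq_len(C)) {
      plane <- numeric(H * W)
      src <- if (length(d) == 2L) am else am[, , ch]
      plane[ok] <- src[idx]
      if (length(d) == 2L) out[] <- plane else out[, , ch] <- plane
    }
  } else {
    y0 <- floor(yi); x0 <- floor(xi)
    fy <- yi - y0; fx <- xi - x0
    corners <- list(list(y0, x0, (1 - fy) * (1 - fx)),
                    list(y0 + 1, x0, fy * (1 - fx)),
                    list(y0, x0 + 1, (1 - fy) * fx),
                    list(y0 + 1, x0 + 1, fy * fx))
    for (ch in seq_len(C)) {
      src <- if (length(d) == 2L) am else am[, , ch]
      plane <- numeric(H * W)
      for (cn in corners) {
        ok <- cn[[1]] >= 1 & cn[[1]] <= H & cn[[2]] >= 1 & cn[[2]] <= W
        idx <- cn[[1]][ok] + (cn[[2]][ok] - 1) * H
        plane[ok] <- plane[ok] + cn[[3]][ok] * src[idx]
      }
      if (length(d) == 2L) out[] <- plane else out[, , ch] <- plane
    }
  }
  out
}

# Rotation about the image centre by `deg` degrees (inverse mapping).
affine_rotation <- function(H, W, deg) {
  th <- -deg * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  matrix(c(cos(th), sin(th),
           -sin(th), cos(th),
           cx - cos(th) * cx + sin(th) * cy,
           cy - sin(th) * cx - cos(th) * cy),
         2, 3)
}

# Zoom about the centre by factor z (z > 1 enlarges the content).
affine_zoom <- function(H, W, z) {
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  matrix(c(1 / z, 0, 0, 1 / z, cx - cx / z, cy - cy / z), 2, 3)
}

# Map the full frame onto the window of fractional side f with top-left
# corner (x0, y0) (1-based input coordinates).
affine_crop <- function(H, W, f, x0, y0) {
  sx <- (f * W - 1) / (W - 1)
  sy <- (f * H - 1) / (H - 1)
  matrix(c(sx, 0, 0, sy, x0 - sx, y0 - sy), 2, 3)
}

apply_geometric <- function(image, mask, A) {
  list(image = warp_affine(image, A, "bilinear"),
       mask = warp_affine(mask, A, "nearest"))
}

# ---- augment_pair --------------------------------------------------------

#' Augment one image/mask pair
#'
#' Applies the nine operations of [augmentation_config()] in order.
#' Every geometric transform is applied identically to image and mask;
#' the mask is resampled nearest-neighbour so the output mask is
#' strictly binary; output shape equals input shape. Blur and
#' brightness leave the mask untouched. With all probabilities and
#' magnitudes at zero (or `enabled = FALSE`) the function is the
#' identity.
#'
#' @param record A preprocessed `image_record` (image in `[0, 1]`,
#'   binary mask).
#' @param config An [augmentation_config()].
#' @param seed Optional integer; if given, draws are made under this
#'   seed so the augmentation is reproducible in isolation. If `NULL`
#'   the ambient RNG stream is used (the training loop seeds it once).
#' @return The augmented `image_record`.
#' @export
augment_pair <- function(record, config = augmentation_config(), seed = NULL) {
  if (!is.null(seed))
    return(withr::with_seed(as.integer(seed),
                            augment_pair(record, config, seed = NULL)))
  if (!config$enabled) return(record)
  img <- record$image
  msk <- record$mask
  d <- dim(img)
  H <- d[1]; W <- d[2]
  p <- config$params
  on <- config$apply

  if (on[["horizontal_shift"]] && p[["horizontal_shift"]] > 0) {
    dx <- round(runif(1, -p[["horizontal_shift"]], p[["horizontal_shift"]]) * W)
    if (dx != 0) { img <- shift_int(img, 0, dx); msk <- shift_int(msk, 0, dx) }
  }
  if (on[["transpose"]] && p[["transpose"]] > 0 && H == W &&
      runif(1) < p[["transpose"]]) {
    img <- aperm(img, c(2, 1, 3))
    msk <- t(msk)
  }
  if (on[["vertical_shift"]] && p[["vertical_shift"]] > 0) {
    dy <- round(runif(1, -p[["vertical_shift"]], p[["vertical_shift"]]) * H)
    if (dy != 0) { img <- shift_int(img, dy, 0); msk <- shift_int(msk, dy, 0) }
  }
  if (on[["blur"]] && p[["blur"]] > 0 && runif(1) < p[["blur"]]) {
    img <- pmin(pmax(EBImage::gblur(img, sigma = config$blur_sigma), 0), 1)
  }
  if (on[["random_crop"]] && p[["random_crop"]] > 0 &&
      runif(1) < p[["random_crop"]]) {
    f <- runif(1, config$crop_min, 1)
    x0 <- 1 + runif(1) * (W - f * W)
    y0 <- 1 + runif(1) * (H - f * H)
    g <- apply_geometric(img, msk, affine_crop(H, W, f, x0, y0))
    img <- g$image; msk <- g$mask
  }
  if (on[["random_rotate"]] && p[["random_rotate"]] > 0 &&
      runif(1) < p[["random_rotate"]]) {
    ang <- runif(1, -config$rotate_max_deg, config$rotate_max_deg)
    g <- apply_geometric(img, msk, affine_rotation(H, W, ang))
    img <- g$image; msk <- g$mask
  }
  if (on[["random_resize"]] && p[["random_resize"]] > 0) {
    z <- 1 + runif(1, -p[["random_resize"]], p[["random_resize"]])
    g <- apply_geometric(img, msk, affine_zoom(H, W, z))
    img <- g$image; msk <- g$mask
  }
  if (on[["random_flip"]] && p[["random_flip"]] > 0 &&
      runif(1) < p[["random_flip"]]) {
    if (runif(1) < 0.5) {                      # horizontal
      img <- img[, W:1, , drop = FALSE]; msk <- msk[, W:1, drop = FALSE]
    } else {                                   # vertical
      img <- img[H:1, , , drop = FALSE]; msk <- msk[H:1, , drop = FALSE]
    }
  }
  if (on[["random_brightness"]] && p[["random_brightness"]] > 0) {
    b <- p[["random_brightness"]]
    fac <- exp(runif(1, log(1 / (1 + b)), log(1 + b)))
    img <- pmin(pmax(img * fac, 0), 1)
  }
  img <- pmin(pmax(img, 0), 1)
  dim(msk) <- c(H, W)
  record$image <- img
  record$mask <- msk
  record
}

#' Write a preview grid of augmented variants
#'
#' Produces a PNG panel of `n` augmented copies of one record with the
#' mask overlaid in red, for visual QC of the augmentation settings.
#'
#' @inheritParams augment_pair
#' @param n Number of variants (panels).
#' @param seed Integer seed; the same seed reproduces the same file.
#' @param file Output PNG path.
#' @return `file`, invisibly.
#' @export
preview_grid <- function(record, config = augmentation_config(), n = 9,
                         seed = 1L, file = tempfile(fileext = ".png")) {
  stopifnot(n >= 1)
  d <- dim(record$image)
  H <- d[1]; W <- d[2]
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  pad <- 2L
  canvas <- array(0, c(nrow_g * (H + pad) - pad, ncol_g * (W + pad) - pad, 3))
  withr::with_seed(as.integer(seed), {
    for (k in seq_len(n)) {
      aug <- augment_pair(record, config)
      panel <- aug$image
      fg <- aug$mask == 1
      for (ch in 1:3) {
        pl <- panel[, , ch]
        pl[fg] <- if (ch == 1) pmin(pl[fg] * 0.4 + 0.6, 1) else pl[fg] * 0.4
        panel[, , ch] <- pl
      }
      r0 <- (ceiling(k / ncol_g) - 1) * (H + pad)
      c0 <- ((k - 1) %% ncol_g) * (W + pad)
      canvas[r0 + seq_len(H), c0 + seq_len(W), ] <- panel
    }
  })
  ok <- tryCatch({ png::writePNG(canvas, file); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop(sprintf("cannot write preview grid to '%s'", file),
                call. = FALSE)
  invisible(file)
}
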