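#' Phantom generator configuration
#'
#' Parameters of the synthetic MRI-slice phantoms used for desk-scale
#' experiments: an elliptical "brain" with smooth texture on a dark
#' background, and (with probability `tumor_probability`) one to three
#' irregular hyperintense "tumor" blobs with an exact binary mask. The
#' default positive fraction 0.35 mirrors the class balance of the
#' public lower-grade-glioma slice collection this emulates (1373
#' tumor-bearing out of 3929 slices).
#'
#' @param image_size Integer `(H, W)`. 256 x 256 matches the study
#'   images; 64 x 64 is the fast-test size.
#' @param tumor_probability Fraction of images that carry a tumor.
#' @param tumor_radius_range Blob base radius as a fraction of the
#'   shorter image side, `(min, max)`.
#' @param blob_irregularity Amplitude of the low-frequency radial
#'   perturbation of the blob boundary (0 = perfect ellipse).
#' @param noise_sigma Additive Gaussian noise, on the 0-255 scale.
#' @param contrast Mean intensity excess of tumor over surrounding
#'   brain, 0-255 scale. The default keeps the task easily learnable on
#'   CPU; lower it for a harder benchmark.
#' @param brain_level,background_level Baseline intensities (0-255).
#' @param channel_gains Per-channel multipliers emulating the RGB
#'   appearance of the exported MRI slices.
#' @param seed Base seed for [generate_dataset()] /
#'   [generate_phantom_records()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = c(256L, 256L),
                           tumor_probability = 0.35,
                           tumor_radius_range = c(0.06, 0.18),
                           blob_irregularity = 0.35,
                           noise_sigma = 8,
                           contrast = 90,
                           brain_level = 100,
                           background_level = 15,
                           channel_gains = c(1, 0.85, 1.1),
                           seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16),
            tumor_probability >= 0, tumor_probability <= 1,
            length(tumor_radius_range) == 2L,
            all(tumor_radius_range > 0), all(tumor_radius_range < 0.5),
            blob_irregularity >= 0, noise_sigma >= 0, contrast >= 0)
  structure(list(image_size = as.integer(image_size),
                 tumor_probability = tumor_probability,
                 tumor_radius_range = tumor_radius_range,
                 blob_irregularity = blob_irregularity,
                 noise_sigma = noise_sigma,
                 contrast = contrast,
                 brain_level = brain_level,
                 background_level = background_level,
                 channel_gains = channel_gains,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Low-frequency 2D texture: a few random cosine waves.
phantom_texture <- function(H, W, amplitude) {
  yy <- matrix(seq_len(H) / H, H, W)
  xx <- matrix(rep(seq_len(W) / W, each = H), H, W)
  tex <- matrix(0, H, W)
  for (k in 1:4) {
    fx <- runif(1, 0.5, 3); fy <- runif(1, 0.5, 3)
    ph <- runif(1, 0, 2 * pi)
    tex <- tex + runif(1, 0.3, 1) * cos(2 * pi * (fx * xx + fy * yy) + ph)
  }
  amplitude * tex / 2
}

#' Generate one synthetic phantom
#'
#' Deterministic given `seed`: the same seed always reproduces the same
#' image and mask bit for bit.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed for this phantom.
#' @return An `image_record`: a list with `image` (H x W x 3, raw 0-255),
#'   `mask` (H x W, strictly `{0, 1}`), `id`, and `preprocessed = FALSE`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  withr::with_seed(as.integer(seed), {
    H <- config$image_size[1]; W <- config$image_size[2]
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(rep(seq_len(W), each = H), H, W)

    # brain ellipse with random pose
    cy <- H / 2 * (1 + runif(1, -0.05, 0.05))
    cx <- W / 2 * (1 + runif(1, -0.05, 0.05))
    a <- runif(1, 0.30, 0.40) * W
    b <- runif(1, 0.28, 0.38) * H
    th <- runif(1, 0, pi)
    xr <- (xx - cx) * cos(th) + (yy - cy) * sin(th)
    yr <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)
    brain <- (xr / a)^2 + (yr / b)^2 <= 1

    base <- matrix(config$background_level, H, W)
    base[brain] <- config$brain_level +
      phantom_texture(H, W, 0.15 * config$brain_level)[brain]

    mask <- matrix(0, H, W)
    if (runif(1) < config$tumor_probability) {
      n_blobs <- sample(1:3, 1)
      for (bl in seq_len(n_blobs)) {
        # blob centre well inside the brain ellipse
        r0 <- runif(1, config$tumor_radius_range[1],
                    config$tumor_radius_range[2]) * min(H, W)
        u <- sqrt(runif(1)) * 0.55
        ang <- runif(1, 0, 2 * pi)
        bx <- cx + u * a * cos(ang) * cos(th) - u * b * sin(ang) * sin(th)
        by <- cy + u * a * cos(ang) * sin(th) + u * b * sin(ang) * cos(th)
        # irregular boundary: radius modulated by low-order harmonics
        nh <- 3L
        cf <- runif(nh, -1, 1)
        cf <- cf / max(1, sum(abs(cf)))
        phs <- runif(nh, 0, 2 * pi)
        dx <- xx - bx; dy <- yy - by
        dist <- sqrt(dx^2 + dy^2)
        theta <- atan2(dy, dx)
        rtheta <- rep(r0, length(theta))
        for (m in seq_len(nh)) {
          rtheta <- rtheta + r0 * config$blob_irregularity *
            cf[m] * cos((m + 1) * theta + phs[m])
        }
        mask[dist <= rtheta & brain] <- 1
      }
    }

    intensity <- base + config$contrast * mask +
      matrix(rnorm(H * W, 0, config$noise_sigma), H, W)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      img[, , ch] <- pmin(pmax(config$channel_gains[ch] * intensity, 0), 255)
    }
    new_image_record(image = img, mask = mask,
                     id = sprintf("phantom_%06d", as.integer(seed)),
                     preprocessed = FALSE)
  })
}

#' Generate a list of phantom records in memory
#'
#' @inheritParams generate_phantom
#' @param n Number of phantoms.
#' @return A list of `image_record`s with seeds `config$seed + 0:(n-1)`.
#' @export
generate_phantom_records <- function(n, config = phantom_config()) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) generate_phantom(config, config$seed + i - 1L))
}

#' Write a synthetic dataset to disk
#'
#' Writes `n` phantom image/mask PNG pairs following the loader's naming
#' rule (`<stem>.png` / `<stem><mask_suffix>.png`) plus a plain-text
#' manifest (`manifest.tsv`: path, mask path, label per line).
#'
#' @inheritParams generate_phantom_records
#' @param out_dir Output directory (created if missing).
#' @param mask_suffix Mask filename suffix; must match what
#'   [load_pairs()] will be given.
#' @return The manifest as a tibble with columns `path`, `mask_path`,
#'   `label` (1 = tumor present), invisibly also written to
#'   `file.path(out_dir, "manifest.tsv")`.
#' @export
generate_dataset <- function(n, config = phantom_config(), out_dir,
                             mask_suffix = "_mask") {
  stopifnot(n >= 1)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", out_dir),
                  call. = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- generate_phantom(config, config$seed + i - 1L)
    stem <- rec$id
    img_path <- file.path(out_dir, paste0(stem, ".png"))
    msk_path <- file.path(out_dir, paste0(stem, mask_suffix, ".png"))
    png::writePNG(rec$image / 255, img_path)
    png::writePNG(rec$mask, msk_path)
    rows[[i]] <- tibble::tibble(path = img_path, mask_path = msk_path,
                                label = as.integer(sum(rec$mask) > 0))
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
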