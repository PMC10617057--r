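# Data pipeline: loading image/mask pairs, preprocessing, and the
# train/validation/test split.

new_image_record <- function(image, mask, id, patient_id = NULL,
                             path = NULL, preprocessed = FALSE) {
  structure(list(image = image, mask = mask, id = id,
                 patient_id = patient_id, path = path,
                 preprocessed = preprocessed),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("image_record '%s': %s image, %d mask pixels%s\n", x$id,
              paste(dim(x$image), collapse = "x"), sum(x$mask != 0),
              if (x$preprocessed) " (preprocessed)" else " (raw)"))
  invisible(x)
}

# Read a PNG or TIFF file to a numeric array on the raw 0-255 scale.
read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop(sprintf("unsupported image format '%s' (%s)", ext, path),
                   call. = FALSE))
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3]  # drop alpha
  x * 255
}

#' Load image/mask pairs from a directory
#'
#' Scans `image_dir` for PNG/TIFF images and pairs each with the mask
#' file sharing its stem plus `mask_suffix` (the public LGG collection
#' uses `"_mask"`). Images without a mask are reported with a warning
#' and skipped; an image whose mask has a different spatial shape is an
#' error naming the file.
#'
#' @param image_dir Directory containing images and masks.
#' @param mask_suffix Filename suffix identifying mask files.
#' @param patient_pattern Optional regular expression; if it matches an
#'   image stem, the first capture group becomes the record's
#'   `patient_id` (used by the patient-level split option).
#' @return A list of `image_record`s with raw `[0, 255]` images and raw
#'   grayscale masks; run [preprocess_records()] before training.
#' @export
load_pairs <- function(image_dir, mask_suffix = "_mask",
                       patient_pattern = NULL) {
  if (!dir.exists(image_dir))
    stop(sprintf("directory '%s' does not exist", image_dir), call. = FALSE)
  files <- list.files(image_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop(sprintf("no PNG/TIFF files found in '%s'", image_dir), call. = FALSE)
  stems <- tools::file_path_sans_ext(basename(files))
  is_mask <- endsWith(stems, mask_suffix)
  image_files <- files[!is_mask]
  if (length(image_files) == 0L)
    stop(sprintf("'%s' contains only mask files", image_dir), call. = FALSE)

  records <- list()
  orphans <- character(0)
  for (f in image_files) {
    stem <- tools::file_path_sans_ext(basename(f))
    candidates <- files[is_mask][
      tools::file_path_sans_ext(basename(files[is_mask])) ==
        paste0(stem, mask_suffix)]
    if (length(candidates) == 0L) {
      orphans <- c(orphans, basename(f))
      next
    }
    img <- read_image_file(f)
    msk <- read_image_file(candidates[1])
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    if (!identical(dim(img)[1:2], dim(msk)[1:2]))
      stop(sprintf("image '%s' (%s) and its mask (%s) differ in shape",
                   basename(f), paste(dim(img)[1:2], collapse = "x"),
                   paste(dim(msk)[1:2], collapse = "x")), call. = FALSE)
    pid <- NULL
    if (!is.null(patient_pattern) && grepl(patient_pattern, stem))
      pid <- sub(paste0(".*", patient_pattern, ".*"), "\\1", stem)
    records[[length(records) + 1L]] <-
      new_image_record(image = img, mask = msk, id = stem,
                       patient_id = pid, path = f)
  }
  if (length(orphans) > 0L)
    warning(sprintf("%d image(s) without a matching mask were skipped: %s",
                    length(orphans), paste(orphans, collapse = ", ")),
            call. = FALSE)
  records
}

#' Global pixel normalization
#'
#' Scales raw pixel values from `[0, 255]` to `[0, 1]` by elementwise
#' division by 255.
#'
#' @param image Numeric array with values in `[0, 255]`.
#' @return The array divided by 255.
#' @export
normalize_global <- function(image) {
  if (any(image < 0 | image > 255))
    stop("pixel values outside [0, 255]", call. = FALSE)
  image / 255
}

#' Binarize a grayscale mask
#'
#' Pixels strictly above `threshold` become 1 (tumor area), the rest 0
#' (tumor-free area).
#'
#' @param mask Numeric array normalized to `[0, 1]`.
#' @param threshold Threshold in `[0, 1)`.
#' @return A strictly binary array of the same shape.
#' @export
binarize_mask <- function(mask, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1)
    stop("`threshold` must be a single number in [0, 1)", call. = FALSE)
  if (any(mask < 0 | mask > 1))
    stop("`mask` must be normalized to [0, 1] before binarization",
         call. = FALSE)
  out <- (mask > threshold) * 1
  dim(out) <- dim(mask)
  out
}

#' Preprocess records: normalize images, binarize masks
#'
#' @param records List of `image_record`s (raw scale).
#' @param threshold Mask binarization threshold on the `[0, 1]` scale.
#' @return The records with images in `[0, 1]`, masks in `{0, 1}`, and
#'   `preprocessed = TRUE`.
#' @export
preprocess_records <- function(records, threshold = 0.5) {
  lapply(records, function(r) {
    if (!r$preprocessed) {
      r$image <- normalize_global(r$image)
      m <- r$mask
      if (max(m) > 1) m <- m / 255
      r$mask <- binarize_mask(m, threshold)
      r$preprocessed <- TRUE
    }
    r
  })
}

#' Drop records without any tumor pixels
#'
#' Keeps exactly the records whose (binarized) mask has at least one
#' foreground pixel, preserving order — the class-balance filtering
#' step applied before training.
#'
#' @param records List of `image_record`s with binary masks.
#' @return The positive records, in their original order.
#' @export
filter_positive <- function(records) {
  keep <- vapply(records, function(r) sum(r$mask != 0) > 0, logical(1))
  out <- records[keep]
  if (length(out) == 0L && length(records) > 0L)
    warning("no records with tumor pixels remain after filtering",
            call. = FALSE)
  out
}

#' Train/validation/test split
#'
#' Shuffles the records with `seed` and partitions them into
#' train/validation/test. Partition sizes are `round(n * fraction)` for
#' validation and test, with the remainder going to train (the largest
#' partition), so sizes are deterministic. With
#' `group_by_patient = TRUE` whole patients are assigned to a single
#' partition, preventing leakage of a patient's slices across splits.
#'
#' @param records List of `image_record`s.
#' @param fractions Numeric `(train, validation, test)` summing to 1.
#' @param seed Integer seed; the same seed always yields the same split.
#' @param group_by_patient Split at the patient level (requires
#'   `patient_id` on every record).
#' @return An object of class `dataset_split`: a list with elements
#'   `train`, `validation`, `test` (disjoint, exhaustive) and
#'   `fractions`.
#' @export
split_dataset <- function(records, fractions = c(0.7, 0.2, 0.1),
                          seed = 1L, group_by_patient = FALSE) {
  n <- length(records)
  if (n < 3L) stop("need at least 3 records to split", call. = FALSE)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    stop("`fractions` must be three non-negative numbers summing to 1",
         call. = FALSE)
  if (group_by_patient) {
    pids <- vapply(records, function(r) {
      if (is.null(r$patient_id)) NA_character_ else r$patient_id
    }, character(1))
    if (anyNA(pids))
      stop("group_by_patient = TRUE requires patient_id on every record",
           call. = FALSE)
    up <- unique(pids)
    gsplit <- split_indices(length(up), fractions, seed)
    part <- character(n)
    for (nm in names(gsplit)) part[pids %in% up[gsplit[[nm]]]] <- nm
    idx <- list(train = which(part == "train"),
                validation = which(part == "validation"),
                test = which(part == "test"))
  } else {
    idx <- split_indices(n, fractions, seed)
  }
  structure(list(train = records[idx$train],
                 validation = records[idx$validation],
                 test = records[idx$test],
                 fractions = fractions),
            class = "dataset_split")
}

split_indices <- function(n, fractions, seed) {
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  n_val <- round(n * fractions[2])
  n_test <- round(n * fractions[3])
  n_train <- n - n_val - n_test
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset_split: %d train / %d validation / %d test (fractions %s)\n",
              length(x$train), length(x$validation), length(x$test),
              paste(x$fractions, collapse = "/")))
  invisible(x)
}

#' Write a split manifest as plain-text file lists
#'
#' Writes `train.txt`, `validation.txt`, `test.txt` (one record id or
#' path per line) so a split is a reproducible artifact.
#'
#' @param split A [split_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_split_manifest <- function(split, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (part in c("train", "validation", "test")) {
    lines <- vapply(split[[part]],
                    function(r) if (!is.null(r$path)) r$path else r$id,
                    character(1))
    writeLines(lines, file.path(dir, paste0(part, ".txt")))
  }
  invisible(dir)
}

#' Rebuild a split from a manifest directory
#'
#' @param records The full record list the manifest refers to.
#' @param dir Directory holding `train.txt` / `validation.txt` /
#'   `test.txt` written by [write_split_manifest()].
#' @return A `dataset_split`.
#' @export
read_split_manifest <- function(records, dir) {
  keys <- vapply(records, function(r) if (!is.null(r$path)) r$path else r$id,
                 character(1))
  pick <- function(part) {
    wanted <- readLines(file.path(dir, paste0(part, ".txt")))
    records[match(wanted, keys)]
  }
  structure(list(train = pick("train"), validation = pick("validation"),
                 test = pick("test"), fractions = NA_real_),
            class = "dataset_split")
}
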