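#' Smoothed Dice loss
#'
#' Computes the smoothed Dice loss
#' \deqn{L = 1 - \frac{2|A \cap B| + \xi}{|A| + |B| + \xi}}
#' where \eqn{A} is the predicted segmentation and \eqn{B} the reference
#' mask. For soft predictions the intersection is the sum of elementwise
#' products \eqn{\sum p g} and \eqn{|A|} the sum of predicted
#' probabilities, the standard continuous relaxation that makes the loss
#' differentiable. The smoothing constant \eqn{\xi} (default 100)
#' prevents a zero denominator when both masks are empty, so the loss of
#' two empty masks is 0, not 0/0.
#'
#' @param predicted Numeric array with values in `[0, 1]`: soft
#'   probabilities or a hard mask. Any of H x W, H x W x C, or
#'   H x W x C x N.
#' @param reference Binary array (`{0, 1}`) of the same shape.
#' @param xi Non-negative smoothing constant. Default 100.
#' @param per_image If `TRUE` and the input has a batch dimension,
#'   returns the mean of per-image losses; otherwise the loss is pooled
#'   over all pixels.
#' @return A single number in `[0, 1]`.
#' @examples
#' m <- matrix(0, 10, 10); m[1:5, 1:10] <- 1
#' dice_loss(m, m)                 # identical masks -> 0
#' @export
dice_loss <- function(predicted, reference, xi = 100, per_image = FALSE) {
  check_same_shape(predicted, reference)
  if (!is.numeric(xi) || length(xi) != 1L || xi < 0)
    stop("`xi` must be a single non-negative number", call. = FALSE)
  if (any(predicted < 0 | predicted > 1))
    stop("`predicted` must lie in [0, 1]", call. = FALSE)
  if (!is_binary(reference))
    stop("`reference` must be strictly binary", call. = FALSE)
  p <- as_nhwc(predicted)
  g <- as_nhwc(reference)
  if (per_image) {
    n <- dim(p)[4]
    ls <- vapply(seq_len(n), function(k) {
      pk <- p[, , , k]; gk <- g[, , , k]
      1 - (2 * sum(pk * gk) + xi) / (sum(pk) + sum(gk) + xi)
    }, numeric(1))
    mean(ls)
  } else {
    1 - (2 * sum(p * g) + xi) / (sum(p) + sum(g) + xi)
  }
}

check_hard_pair <- function(predicted, reference) {
  check_same_shape(predicted, reference)
  if (!is_binary(predicted) || !is_binary(reference))
    stop("both masks must be strictly binary ({0, 1}); binarize soft maps first",
         call. = FALSE)
  invisible(TRUE)
}

#' Dice similarity coefficient (DSC)
#'
#' \eqn{DSC = 2|A \cap B| / (|A| + |B|)} for hard binary masks. When
#' both masks are empty the coefficient is defined as 1 (perfect
#' agreement on "no tumor").
#'
#' @inheritParams dice_loss
#' @return A single number in `[0, 1]`.
#' @seealso [jaccard()], [dice_loss()]
#' @export
dsc <- function(predicted, reference) {
  check_hard_pair(predicted, reference)
  s <- sum(predicted) + sum(reference)
  if (s == 0) return(1)
  2 * sum(predicted * reference) / s
}

#' Jaccard index (IoU)
#'
#' \eqn{Jac = |A \cap B| / (|A| + |B| - |A \cap B|)} for hard binary
#' masks; 1 when both masks are empty. Related to the Dice coefficient
#' by \eqn{J = D / (2 - D)}.
#'
#' @inheritParams dice_loss
#' @return A single number in `[0, 1]`.
#' @export
jaccard <- function(predicted, reference) {
  check_hard_pair(predicted, reference)
  i <- sum(predicted * reference)
  u <- sum(predicted) + sum(reference) - i
  if (u == 0) return(1)
  i / u
}

#' Pixel-wise confusion counts
#'
#' Tallies true positives (label 1, prediction 1), true negatives,
#' false positives (label 0, prediction 1) and false negatives over all
#' pixels of a hard binary pair.
#'
#' @inheritParams dice_loss
#' @return An object of class `confusion_counts`: a list with integer
#'   fields `tp`, `tn`, `fp`, `fn` summing to the pixel count.
#' @export
confusion_counts <- function(predicted, reference) {
  check_hard_pair(predicted, reference)
  tp <- sum(predicted == 1 & reference == 1)
  tn <- sum(predicted == 0 & reference == 0)
  fp <- sum(predicted == 1 & reference == 0)
  fn <- sum(predicted == 0 & reference == 1)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d TN=%d FP=%d FN=%d (total %d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Pixel accuracy
#'
#' \eqn{Acc = (TP + TN) / (TP + TN + FN + FP)}.
#'
#' @param counts A [confusion_counts()] object (or a list with fields
#'   `tp`, `tn`, `fp`, `fn`).
#' @return A single number in `[0, 1]`.
#' @export
pixel_accuracy <- function(counts) {
  tot <- counts$tp + counts$tn + counts$fp + counts$fn
  if (tot <= 0) stop("confusion counts are empty (total = 0)", call. = FALSE)
  (counts$tp + counts$tn) / tot
}

#' Score a predicted mask file against a reference mask file
#'
#' Standalone scoring entry point: reads two single-channel mask images
#' (PNG or TIFF), binarizes both at `threshold`, and reports the three
#' overlap metrics. Intended for scoring exported predictions without
#' touching the model code.
#'
#' @param predicted_path,reference_path Paths to single-channel images.
#'   Multi-channel inputs are collapsed by averaging.
#' @param threshold Binarization threshold on the `[0, 1]` scale.
#' @return A one-row tibble with columns `dsc`, `jaccard`, `accuracy`.
#' @export
score_masks <- function(predicted_path, reference_path, threshold = 0.5) {
  rd <- function(path) {
    x <- read_image_file(path)
    if (length(dim(x)) == 3L) x <- apply(x, c(1, 2), mean)
    x / 255
  }
  p <- binarize_mask(rd(predicted_path), threshold)
  g <- binarize_mask(rd(reference_path), threshold)
  cc <- confusion_counts(p, g)
  tibble::tibble(dsc = dsc(p, g), jaccard = jaccard(p, g),
                 accuracy = pixel_accuracy(cc))
}
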