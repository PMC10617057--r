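# Internal helpers shared across modules.

# Strict binary check: every element exactly 0 or 1.
is_binary <- function(x) all(x == 0 | x == 1)

# Promote an H x W or H x W x C array to H x W x C x N.
as_nhwc <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array, got a vector", call. = FALSE)
  if (length(d) == 2L) d <- c(d, 1L)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("expected an array with 2-4 dimensions", call. = FALSE)
  dim(x) <- d
  x
}

# Broadcast a per-channel vector over an H x W x C x N array.
bc_channel <- function(v, d) {
  out <- rep(rep(v, each = d[1] * d[2]), times = d[4])
  dim(out) <- d
  out
}

# Per-channel sums over H, W and N of an H x W x C x N array.
channel_sum <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  cs <- colSums(x)
  rowSums(matrix(cs, d[3], d[4]))
}

check_same_shape <- function(a, b, what = c("predicted", "reference")) {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s and %s must have identical dimensions (%s vs %s)",
                 what[1], what[2],
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}
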