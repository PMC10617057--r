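# Shared fixtures: all synthetic, built in code at test time.

# Desk-scale study conditions: 64x64 phantoms and the reduced-width
# model (1/8 of the full encoder widths, 48 lateral channels).
desk_phantom_config <- function(seed = 100L, tumor_probability = 1,
                                size = c(64L, 64L)) {
  phantom_config(image_size = size, tumor_probability = tumor_probability,
                 seed = seed)
}

desk_model_config <- function(seed = 1L) {
  model_config(input_size = c(64L, 64L, 3L),
               encoder_widths = c(8L, 16L, 32L, 64L, 128L),
               lateral_channels = 48L, seed = seed)
}

# Tiny config for gradient checks and fast structural tests.
tiny_model_config <- function(seed = 7L, hw = 16L) {
  model_config(input_size = c(hw, hw, 3L),
               encoder_widths = c(2L, 3L, 4L, 5L, 6L),
               lateral_channels = 2L, seed = seed)
}

# Random hard binary mask.
random_mask <- function(h, w, p = 0.3) {
  matrix(as.double(rbinom(h * w, 1, p)), h, w)
}

# A preprocessed record with constant image and given mask.
flat_record <- function(mask, id = "rec") {
  h <- nrow(mask); w <- ncol(mask)
  new_record(array(0.5, c(h, w, 3)), mask, id)
}

new_record <- function(image, mask, id = "rec") {
  structure(list(image = image, mask = mask, id = id, patient_id = NULL,
                 path = NULL, preprocessed = TRUE),
            class = "image_record")
}

# Brute-force per-pixel confusion tally (independent oracle).
loop_confusion <- function(pred, ref) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; g <- ref[i, j]
      if (p == 1 && g == 1) tp <- tp + 1L
      else if (p == 0 && g == 0) tn <- tn + 1L
      else if (p == 1 && g == 0) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}
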