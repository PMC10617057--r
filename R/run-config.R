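# Structured run configuration: one YAML file covering model, training
# and augmentation blocks. The augmentation block mirrors the nine
# operation names verbatim.

#' Read a run configuration file
#'
#' Parses a YAML file with optional `model`, `training` and
#' `augmentation` blocks into the corresponding config objects; keys
#' not present fall back to the package defaults. The augmentation keys
#' are the nine operation names (`horizontal_shift`, `transpose`,
#' `vertical_shift`, `blur`, `random_crop`, `random_rotate`,
#' `random_resize`, `random_flip`, `random_brightness`).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `model` ([model_config()]), `training`
#'   ([training_config()]) and `augmentation`
#'   ([augmentation_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' not found", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  build <- function(ctor, block) {
    args <- raw[[block]]
    if (is.null(args)) args <- list()
    known <- names(formals(ctor))
    unknown <- setdiff(names(args), known)
    if (length(unknown) > 0L)
      stop(sprintf("unknown %s config keys: %s", block,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    do.call(ctor, args)
  }
  list(model = build(model_config, "model"),
       training = build(training_config, "training"),
       augmentation = build(augmentation_config, "augmentation"))
}

#' Write a training history as CSV
#'
#' @param history A `training_history`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(as.data.frame(history), path, row.names = FALSE)
  invisible(path)
}
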