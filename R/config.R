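# YAML round-trip for model + training configuration, shared by the CLI.

#' Read / write a run configuration
#'
#' A flat YAML file mirroring [model_config()] and [train_config()]; keys
#' absent from the file keep their defaults.
#'
#' @param path YAML file path.
#' @return `read_run_config`: list with `model` ([model_config()]) and
#'   `train` ([train_config()]).
#' @export
read_run_config <- function(path) {
  y <- if (is.null(path)) list() else yaml::read_yaml(path)
  enc <- do.call(encoder_spec, y$encoder %||% list())
  mc_args <- y$model %||% list()
  mc_args$encoder <- enc
  mc <- do.call(model_config, mc_args)
  tc_args <- y$train %||% list()
  if (!is.null(tc_args$tversky)) tc_args$tversky <- do.call(tversky_params, tc_args$tversky)
  tc <- do.call(train_config, tc_args)
  list(model = mc, train = tc, synth = y$synth %||% list())
}

#' @param cfg list with `model`, `train` (and optionally `synth`) entries.
#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  strip <- function(x) { attributes(x) <- list(names = names(x)); x }
  y <- list(
    encoder = strip(cfg$model$encoder),
    model = strip(cfg$model[setdiff(names(cfg$model), "encoder")]),
    train = strip(cfg$train))
  y$train$tversky <- strip(cfg$train$tversky)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
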