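# YAML serialization of run configurations.

#' Write a LOSO run configuration to YAML
#'
#' @param config a [loso_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "loso_config"))
  lst <- unclass(config)
  lst$cnn <- unclass(lst$cnn)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Read a LOSO run configuration from YAML
#'
#' Missing keys fall back to the [loso_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `loso_config`.
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cnn_args <- lst$cnn %||% list()
  lst$cnn <- NULL
  cfg <- do.call(loso_config, lst)
  cfg$cnn <- do.call(cnn_config, cnn_args)
  cfg
}
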