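# YAML round-trip for the two configuration objects, mirroring their field
# names so runs are reproducible from a config file checked into a project.

#' Read / write model and training configurations as YAML
#'
#' The YAML schema mirrors the argument names of [model_config()] and
#' [training_config()]; unknown keys are an error so typos cannot silently
#' fall back to defaults.
#'
#' @param path YAML file path.
#' @return `model_config_from_yaml`: a [model_config()];
#'   `training_config_from_yaml`: a [training_config()].
#' @export
model_config_from_yaml <- function(path) {
  fields <- yaml::read_yaml(path)
  unknown <- setdiff(names(fields), names(formals(model_config)))
  if (length(unknown)) {
    stop("unknown model config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(fields$conv_kernel_sizes)) {
    fields$conv_kernel_sizes <- lapply(fields$conv_kernel_sizes, as.integer)
  }
  do.call(model_config, fields)
}

#' @rdname model_config_from_yaml
#' @export
training_config_from_yaml <- function(path) {
  fields <- yaml::read_yaml(path)
  unknown <- setdiff(names(fields), names(formals(training_config)))
  if (length(unknown)) {
    stop("unknown training config field(s): ",
         paste(unknown, collapse = ", "))
  }
  do.call(training_config, fields)
}

#' @param config A `subloc_model_config` or `subloc_training_config`.
#' @rdname model_config_from_yaml
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, c("subloc_model_config",
                               "subloc_training_config")))
  fields <- unclass(config)
  # training_config stores derived fields under the same names it accepts,
  # except early_stop_patience (0 encodes NULL)
  if (inherits(config, "subloc_training_config") &&
      identical(fields$early_stop_patience, 0L)) {
    fields$early_stop_patience <- NULL
  }
  yaml::write_yaml(fields, path)
  invisible(path)
}
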