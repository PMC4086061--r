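# Run configuration: hydrogen-bond criteria and base-library overrides,
# loadable from a YAML document so thresholds and modified-base definitions
# are editable without touching code.

#' Load a run configuration from YAML
#'
#' The document may contain a `params` section (`max_da_distance`,
#' `min_ada_angle`, `min_daa_angle`; missing fields take the defaults) and
#' a `library` section of base entries merged over the built-in library
#' (see [base_library()]).
#'
#' @param path YAML file path.
#' @return list with `params` (an `hbond_params`) and `library`.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  dflt <- default_params()
  p <- cfg$params %||% list()
  list(params = hbond_params(
         max_da_distance = p$max_da_distance %||% dflt$max_da_distance,
         min_ada_angle = p$min_ada_angle %||% dflt$min_ada_angle,
         min_daa_angle = p$min_daa_angle %||% dflt$min_daa_angle),
       library = base_library(cfg$library))
}

#' Save hydrogen-bond parameters to YAML
#'
#' Written parameters round-trip unchanged through [load_config()].
#'
#' @param params an `hbond_params`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  stopifnot(inherits(params, "hbond_params"))
  yaml::write_yaml(list(params = unclass(params)), path)
  invisible(path)
}
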