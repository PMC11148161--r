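#' Serialize a model configuration back to YAML
#'
#' Round-trips losslessly with [load_model_config()].
#'
#' @param cfg a `pbpkeo_config`.
#' @param path output YAML file.
#' @return `path`, invisibly.
#' @export
save_model_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 12)
  invisible(path)
}

#' Write a run manifest alongside outputs
#'
#' Records the package version, seed, scenario label, frozen calibration
#' factors and a content hash of the numeric configuration, so any artifact
#' set can be traced to the exact run that produced it.
#'
#' @param path output JSON file.
#' @param cfg a `pbpkeo_config`.
#' @param seed integer seed used by the run.
#' @param scenario free-text scenario label.
#' @return the manifest list, invisibly.
#' @export
write_run_manifest <- function(path, cfg, seed, scenario = "unnamed") {
  pt <- parameter_table(cfg)
  hash <- sum(pt$value[is.finite(pt$value)] *
                seq_along(pt$value)[is.finite(pt$value)]) %% 1e9
  manifest <- list(
    package = "pbpkeo",
    version = as.character(utils::packageVersion("pbpkeo")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    scenario = scenario,
    seed = seed,
    eo_mode = list(drive = cfg$eo$drive,
                   kon_time_base = cfg$eo$kon_time_base),
    calibration = cfg$calibration,
    config_hash = hash
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
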