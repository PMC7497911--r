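#' Read a commissioning configuration from YAML
#'
#' Builds a [commissioning_config()] from a YAML file with optional sections
#' `run` (periods_s, roms_cm, n_repeats, seed, in_plane_cm, slice_cm,
#' static_slice_cm, collimation_cm, station_dead_time_s,
#' integration_window_s, supersample), `traces` (the patient-like trace
#' spec, or `patient: no` to skip it), `phantom` (`rod:` and `spheres:`
#' specs, or `spheres: no`), `measurement`, `binning` and `recommendation`.
#' Unknown keys raise an error; omitted keys keep package defaults.
#'
#' @param path YAML file path.
#' @return a [commissioning_config()].
#' @export
read_commissioning_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("run", "traces", "phantom", "measurement", "binning",
             "recommendation")
  if (length(setdiff(names(cfg), known)))
    stop("unknown config section(s): ",
         paste(setdiff(names(cfg), known), collapse = ", "))
  build <- function(fun, args) {
    if (is.null(args)) return(fun())
    bad <- setdiff(names(args), names(formals(fun)))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    do.call(fun, args)
  }
  run <- cfg$run %||% list()
  patient <- if (identical(cfg$traces$patient, FALSE)) NULL else
    build(patient_trace_spec, cfg$traces$patient)
  spheres <- if (identical(cfg$phantom$spheres, FALSE)) NULL else
    build(sphere_phantom, cfg$phantom$spheres)
  args <- c(run,
            list(rod = build(rod_phantom, cfg$phantom$rod),
                 spheres = spheres, patient = patient,
                 settings = build(measurement_settings, cfg$measurement),
                 binning = build(binning_config, cfg$binning),
                 recommendation = build(recommendation_config, cfg$recommendation)))
  bad <- setdiff(names(args), names(formals(commissioning_config)))
  if (length(bad)) stop("unknown run key(s): ", paste(bad, collapse = ", "))
  do.call(commissioning_config, args)
}
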