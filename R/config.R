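#' Read a scenario configuration file
#'
#' Scenario presets ship as YAML (see
#' `system.file("extdata", "mouse_control.yaml", package = "omapr")`); a
#' config names a packaged scenario and may override its pacing,
#' geometry, duration, seed or noise. Every parameter is validated by
#' [scenario()] before anything runs.
#'
#' @param path YAML file with a `scenario` field plus optional
#'   `pcl`, `rows`, `cols`, `duration_ms`, `frame_rate`, `seed`,
#'   `noise_sd` overrides.
#' @return An `omr_scenario`.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop_argument(sprintf("Config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenario)) stop_argument("Config must name a `scenario`.")
  scenario(cfg$scenario,
           pcl = cfg$pcl %||% 150,
           shape = c(cfg$rows %||% 200, cfg$cols %||% 200),
           duration_ms = cfg$duration_ms %||% 2000,
           frame_rate = cfg$frame_rate %||% 977,
           seed = cfg$seed %||% 1L,
           noise_sd = cfg$noise_sd)
}
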