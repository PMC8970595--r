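#' Analyze a conditioned recording into maps and a summary
#'
#' Runs the mapping stage: activation map, APD80 map with IQR outlier
#' exclusion, local-polynomial conduction-velocity field and axis CV
#' extraction. Before the velocity fit the activation map is smoothed
#' with a mask-aware gaussian ([smooth_map()]): activation-marker jitter
#' enters `1 / |grad(T)|` with a convex, speed-inflating bias, and
#' isochrone smoothing suppresses it without touching the per-pixel
#' activation times used for APD.
#'
#' @param cond an `omr_conditioned` bundle.
#' @param axis_angle fiber long-axis direction in degrees (y up), used to
#'   split longitudinal from transversal vectors.
#' @param cv_window,cv_order,cv_residual_ms velocity-fit parameters, see
#'   [fit_cv_bayly()].
#' @param axis_tolerance_deg angular half-width of each axis sector.
#' @param cv_smooth_window isochrone smoothing window (pixels) applied
#'   before the velocity fit; 0 disables it.
#' @param sustain_ms repolarization sustain time, see [compute_apd80()].
#' @return An `omr_analysis` list: `activation`, `apd`, `velocity`,
#'   `axis_cv` and a one-row `summary` tibble (masked-pixel counts, mean
#'   APD80 after exclusion with SD, axis CVs, SNR statistics).
#' @export
analyze_conditioned <- function(cond, axis_angle = 0,
                                cv_window = 7L, cv_order = 2L,
                                cv_residual_ms = 2,
                                axis_tolerance_deg = 15,
                                cv_smooth_window = 5L,
                                sustain_ms = 2) {
  act <- activation_map(cond)
  apd <- apd_map(cond, act = act, sustain_ms = sustain_ms)
  act_cv <- if (cv_smooth_window >= 3L) {
    smooth_map(act, cv_smooth_window)
  } else act
  field <- fit_cv_bayly(act_cv, pixel_size = cond$pixel_size,
                        window = cv_window, order = cv_order,
                        residual_threshold_ms = cv_residual_ms)
  axis_cv <- extract_axis_cv(field, axis_angle,
                             tolerance_deg = axis_tolerance_deg)
  mask <- cond$mask$values
  apd_vals <- apd$values[!is.na(apd$values)]
  summary <- tibble::tibble(
    pcl = cond$params$pcl,
    n_beats_averaged = cond$beat$n_beats_averaged,
    n_masked = sum(mask),
    snr_raw_mean = mean(cond$snr_raw$values[mask], na.rm = TRUE),
    snr_conditioned_mean = mean(cond$snr_conditioned$values[mask], na.rm = TRUE),
    apd80_mean = mean(apd_vals),
    apd80_sd = stats::sd(apd_vals),
    n_apd = length(apd_vals),
    cv_long = axis_cv$cv_long,
    cv_trans = axis_cv$cv_trans,
    n_vectors_long = axis_cv$n_long,
    n_vectors_trans = axis_cv$n_trans,
    axis_angle = axis_angle
  )
  structure(list(activation = act, apd = apd, velocity = field,
                 axis_cv = axis_cv, summary = summary),
            class = "omr_analysis")
}

#' @export
print.omr_analysis <- function(x, ...) {
  s <- x$summary
  cat("<omr_analysis>\n")
  cat(sprintf("  APD80 %.1f +/- %.1f ms over %d px; CV long %.1f / trans %.1f cm/s\n",
              s$apd80_mean, s$apd80_sd, s$n_apd, s$cv_long, s$cv_trans))
  cat(sprintf("  SNR raw %.2f -> conditioned %.2f over %d masked px\n",
              s$snr_raw_mean, s$snr_conditioned_mean, s$n_masked))
  invisible(x)
}

#' One-row summary of an analysis
#'
#' @param x an `omr_analysis`.
#' @param ... unused.
#' @return The one-row summary tibble.
#' @method glance omr_analysis
#' @export
glance.omr_analysis <- function(x, ...) x$summary

#' Pipeline configuration
#'
#' Validates everything up front so a bad parameter fails before any
#' stage runs. A single global seed fans out to per-stage seeds as
#' `seed * 100 + stage_index` (stage 1 = simulate); it is echoed into
#' every output.
#'
#' @param scenario_name packaged scenario name, see [scenario()].
#' @param pcl pacing cycle length, ms.
#' @param shape `(rows, cols)` in pixels.
#' @param duration_ms movie length, ms.
#' @param seed global pipeline seed.
#' @param out_dir output directory (created if needed); `NULL` keeps all
#'   artifacts in memory only.
#' @param axis_angle fiber axis used for CV extraction; defaults to the
#'   scenario's true fiber angle.
#' @param ... overrides passed to [scenario()].
#' @return A `pipeline_config` list with the fully resolved scenario.
#' @export
pipeline_config <- function(scenario_name = "mouse_control", pcl = 150,
                            shape = c(200, 200), duration_ms = 2000,
                            seed = 1L, out_dir = NULL, axis_angle = NULL,
                            ...) {
  check_number(seed, "seed", integer = TRUE)
  sc <- scenario(scenario_name, pcl = pcl, shape = shape,
                 duration_ms = duration_ms, seed = as.integer(seed) * 100L + 1L,
                 ...)
  structure(list(scenario = sc, seed = as.integer(seed), out_dir = out_dir,
                 axis_angle = axis_angle %||% sc$wave$long_axis_angle),
            class = "pipeline_config")
}

#' Run the full simulate -> condition -> analyze pipeline
#'
#' Executes every stage, records per-stage wall times, and (when
#' `out_dir` is set) writes all artifacts: the OMR1 movie, the
#' ground-truth sidecar, the conditioned bundle (`conditioned.rds`),
#' activation/APD/SNR maps as CSV matrices and a JSON summary echoing
#' every parameter and the seed. Identical configurations and seeds
#' produce identical summaries.
#'
#' @param config a [pipeline_config()].
#' @return An `omr_run` list: `analysis`, `conditioned`, `truth`,
#'   `summary` (the analysis summary extended with seed and scenario
#'   metadata), `timings_s`, and `paths` of artifacts written.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_argument("`config` must come from pipeline_config().")
  }
  sc <- config$scenario
  paths <- character(0)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop_computation(sprintf("Pipeline stage `%s` failed: %s", name,
                               conditionMessage(e)))
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }
  sim <- stage("simulate", simulate_scenario(sc))
  cond <- stage("condition", condition_recording(sim$recording, sc$params))
  analysis <- stage("analyze",
                    analyze_conditioned(cond, axis_angle = config$axis_angle))
  summary <- analysis$summary
  summary$seed <- config$seed
  summary$scenario <- sc$name
  summary$true_apd80 <- sim$truth$apd80
  summary$true_cv_long <- sim$truth$v_long * 100
  summary$true_cv_trans <- sim$truth$v_trans * 100
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(config$out_dir, f)
    write_recording(sim$recording, p("movie.omr1"))
    write_truth(sim$truth, p("movie"))
    saveRDS(cond, p("conditioned.rds"))
    wmap <- function(m, f) {
      utils::write.table(m, p(f), sep = ",", row.names = FALSE,
                         col.names = FALSE)
      p(f)
    }
    paths <- c(p("movie.omr1"), p("movie_truth.json"), p("conditioned.rds"),
               wmap(analysis$activation$values, "activation_map.csv"),
               wmap(analysis$apd$values, "apd_map.csv"),
               wmap(cond$snr_raw$values, "snr_raw.csv"),
               wmap(cond$snr_conditioned$values, "snr_conditioned.csv"),
               wmap(analysis$velocity$speed, "cv_speed.csv"))
    report <- c(as.list(summary),
                list(scenario_parameters = list(
                  pcl = sc$wave$pcl, v_long = sc$wave$v_long,
                  v_trans = sc$wave$v_trans,
                  long_axis_angle = sc$wave$long_axis_angle,
                  noise_sd = sc$noise$noise_sd,
                  baseline_intensity = sc$noise$baseline_intensity,
                  vignette_strength = sc$noise$vignette_strength,
                  amplitude_fraction = sc$template$amplitude_fraction,
                  spatial_window = sc$params$spatial_window,
                  spatial_sigma = sc$params$spatial_sigma,
                  snr_cutoff = sc$params$snr_cutoff,
                  intensity_cutoff = sc$params$intensity_cutoff)))
    jsonlite::write_json(report, p("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    # wall-clock timings are run-specific; they live outside the
    # deterministic summary so equal seeds give byte-identical summaries
    jsonlite::write_json(as.list(timings), p("timings.json"),
                         auto_unbox = TRUE)
    paths <- c(paths, p("summary.json"), p("timings.json"))
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      stop_computation(sprintf("Declared outputs were not written: %s",
                               paste(missing, collapse = ", ")))
    }
  }
  structure(list(analysis = analysis, conditioned = cond, truth = sim$truth,
                 summary = summary, timings_s = timings, paths = paths),
            class = "omr_run")
}

#' @export
print.omr_run <- function(x, ...) {
  cat(sprintf("<omr_run> scenario %s, seed %d (%.1f s total)\n",
              x$summary$scenario, x$summary$seed, sum(unlist(x$timings_s))))
  print(x$analysis)
  invisible(x)
}

#' @method glance omr_run
#' @export
glance.omr_run <- function(x, ...) x$summary
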