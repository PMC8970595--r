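#' Anisotropic wave model for a paced heart surface
#'
#' Describes elliptical wavefront propagation away from a point pacing site
#' over a 2-D imaged surface: conduction is fastest along the fiber (long)
#' axis and slowest across it, so isochrones are ellipses centred on the
#' stimulus electrode.
#'
#' @param pacing_site 1-based `(row, col)` of the stimulus electrode.
#' @param v_long,v_trans longitudinal / transversal conduction velocity in
#'   m/s (numerically equal to mm/ms); `v_long >= v_trans > 0`.
#' @param long_axis_angle fiber long-axis direction, degrees
#'   counter-clockwise from the +x (column) image axis.
#' @param pcl pacing cycle length, ms.
#' @param duration_ms recording duration covered by pacing, ms.
#' @param stim_start_ms time of the first stimulus, ms; the default leaves
#'   a diastolic pre-stimulus window at the start of the movie.
#' @return A `wave_model` list.
#' @export
wave_model <- function(pacing_site, v_long, v_trans, long_axis_angle = 0,
                       pcl = 150, duration_ms = 2000, stim_start_ms = 10) {
  check_number(v_trans, "v_trans", lower = 1e-9)
  check_number(v_long, "v_long", lower = v_trans)
  check_number(pcl, "pcl", lower = 1e-9)
  check_number(duration_ms, "duration_ms", lower = 1e-9)
  check_number(stim_start_ms, "stim_start_ms", lower = 0)
  if (length(pacing_site) != 2L) stop_argument("`pacing_site` must be (row, col).")
  structure(list(pacing_site = as.numeric(pacing_site), v_long = v_long,
                 v_trans = v_trans, long_axis_angle = long_axis_angle,
                 pcl = pcl, duration_ms = duration_ms,
                 stim_start_ms = stim_start_ms),
            class = "wave_model")
}

#' Analytic activation-time field of an elliptical paced wave
#'
#' For a pixel at physical offset `(dx, dy)` mm from the pacing site the
#' offsets are rotated into the fiber frame, `u` along and `w` across the
#' long axis, and the activation delay is
#' `T = sqrt((u / v_long)^2 + (w / v_trans)^2)` ms. `T` is zero at the
#' pacing site. The +y image axis points down rows; angles are measured in
#' the conventional mathematical sense on the (x right, y up) plane.
#'
#' @param model a [wave_model()].
#' @param shape `(rows, cols)` of the imaged field.
#' @param pixel_size mm per pixel.
#' @return Numeric `rows x cols` matrix of activation delays (ms after the
#'   stimulus).
#' @examples
#' m <- wave_model(c(1, 1), v_long = 1, v_trans = 1)
#' # 3-4-5 triangle: 3 mm and 4 mm legs at 1 mm/ms arrive after 5 ms
#' compute_activation_field(m, shape = c(5, 4), pixel_size = 1)[5, 4]
#' @export
compute_activation_field <- function(model, shape, pixel_size) {
  check_number(pixel_size, "pixel_size", lower = 1e-12)
  rows <- shape[[1L]]; cols <- shape[[2L]]
  site <- model$pacing_site
  if (site[1L] < 1 || site[1L] > rows || site[2L] > cols || site[2L] < 1) {
    stop_argument("pacing site lies outside the field.")
  }
  dx <- (matrix(seq_len(cols), rows, cols, byrow = TRUE) - site[2L]) * pixel_size
  # image rows grow downward; flip sign so the fiber angle is standard math
  dy <- (site[1L] - matrix(seq_len(rows), rows, cols)) * pixel_size
  th <- model$long_axis_angle * pi / 180
  u <- dx * cos(th) + dy * sin(th)
  w <- -dx * sin(th) + dy * cos(th)
  sqrt((u / model$v_long)^2 + (w / model$v_trans)^2)
}

#' Action-potential waveform template
#'
#' A stylized optical action potential: rest at 0, a monotone smoothstep
#' upstroke of `upstroke_duration` ms rising to 1, then exponential
#' repolarization with time constant `tau = apd80_at_pcl / log(5)`, so the
#' fall to 20% of amplitude occurs `apd80` ms into the beat. Rate
#' dependence (restitution) is linear in pacing cycle length around the
#' reference PCL, and a drug mode adds a fixed APD increment (emulating a
#' transient-outward K+ current blocker such as 4-AP).
#'
#' @param apd80 action potential duration at 80% repolarization, ms, at
#'   `pcl_ref`.
#' @param upstroke_duration depolarization upstroke length, ms.
#' @param amplitude_fraction fractional fluorescence change of a full
#'   action potential (dF/F), in (0, 1).
#' @param restitution_slope APD80 change per ms of PCL change (ms/ms).
#' @param drug_apd_increment APD80 prolongation applied in drug mode, ms.
#' @param pcl_ref reference PCL at which `apd80` is stated, ms.
#' @return An `ap_template` list.
#' @export
ap_template <- function(apd80 = 40, upstroke_duration = 2,
                        amplitude_fraction = 0.08, restitution_slope = 0,
                        drug_apd_increment = 0, pcl_ref = 150) {
  check_number(upstroke_duration, "upstroke_duration", lower = 1e-9)
  check_number(apd80, "apd80", lower = upstroke_duration + 1e-9)
  check_number(amplitude_fraction, "amplitude_fraction", lower = 1e-9, upper = 1 - 1e-9)
  check_number(restitution_slope, "restitution_slope")
  check_number(drug_apd_increment, "drug_apd_increment", lower = 0)
  structure(list(apd80 = apd80, upstroke_duration = upstroke_duration,
                 amplitude_fraction = amplitude_fraction,
                 restitution_slope = restitution_slope,
                 drug_apd_increment = drug_apd_increment, pcl_ref = pcl_ref),
            class = "ap_template")
}

#' Rate-corrected APD80 of a template
#'
#' `apd80_at_pcl = apd80 - restitution_slope * (pcl_ref - pcl)` plus the
#' drug increment when `drug = TRUE`.
#'
#' @inheritParams make_ap_trace
#' @param drug apply the drug-mode APD increment?
#' @return APD80 in ms at the requested pacing cycle length.
#' @export
apd80_at_pcl <- function(template, pcl, drug = FALSE) {
  apd <- template$apd80 - template$restitution_slope * (template$pcl_ref - pcl) +
    if (isTRUE(drug)) template$drug_apd_increment else 0
  if (apd <= template$upstroke_duration) {
    stop_argument(sprintf(
      "APD80 at PCL %g ms is %.3g ms, not above the %g ms upstroke.",
      pcl, apd, template$upstroke_duration))
  }
  apd
}

# normalized AP value at phase p (ms since stimulus onset), vectorized;
# decay time constant chosen so the 20%-amplitude crossing sits at apd80
ap_shape <- function(p, upstroke, tau) {
  v <- numeric(length(p))
  up <- p >= 0 & p < upstroke
  s <- p[up] / upstroke
  v[up] <- 3 * s^2 - 2 * s^3
  de <- p >= upstroke
  v[de] <- exp(-(p[de] - upstroke) / tau)
  v
}

# periodic paced waveform: 0 before the first stimulus, then ap_shape on
# the phase within each cycle (each stimulus resets the trajectory)
ap_value <- function(t, pcl, upstroke, tau) {
  v <- numeric(length(t))
  on <- t >= 0
  v[on] <- ap_shape(t[on] %% pcl, upstroke, tau)
  v
}

#' Sample a normalized paced AP trace
#'
#' Evaluates the template waveform on the camera's frame grid for a train
#' of `n_beats` stimuli separated by `pcl` ms, the first at
#' `stim_start_ms`. Values are normalized fluorescence-voltage in `[0, 1]`
#' (upstroke positive; the simulator applies the dye's polarity inversion
#' separately).
#'
#' @param template an [ap_template()].
#' @param pcl pacing cycle length, ms; must exceed the rate-corrected APD.
#' @param frame_rate sampling rate, frames per second.
#' @param n_beats number of stimuli.
#' @param drug apply the drug-mode APD increment?
#' @param stim_start_ms time of the first stimulus, ms.
#' @return A tibble with `time_ms` and `v` covering
#'   `stim_start_ms + n_beats * pcl` ms.
#' @examples
#' tr <- make_ap_trace(ap_template(apd80 = 40), pcl = 150, frame_rate = 977,
#'                     n_beats = 2)
#' max(tr$v)
#' @export
make_ap_trace <- function(template, pcl, frame_rate, n_beats = 1L,
                          drug = FALSE, stim_start_ms = 10) {
  check_number(pcl, "pcl", lower = 1e-9)
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  check_number(n_beats, "n_beats", lower = 1, integer = TRUE)
  apd <- apd80_at_pcl(template, pcl, drug = drug)
  if (pcl <= apd) {
    stop_argument(sprintf("PCL %g ms must exceed the APD80 of %.3g ms.", pcl, apd))
  }
  tau <- apd / log(5)
  dt <- 1000 / frame_rate
  t <- seq(0, stim_start_ms + n_beats * pcl, by = dt)
  tibble::tibble(time_ms = t,
                 v = ap_value(t - stim_start_ms, pcl, template$upstroke_duration, tau))
}

#' Acquisition noise and illumination model
#'
#' Static baseline fluorescence with a radial cosine vignette
#' (`B = baseline * ((1 - strength) + strength * cos(pi/2 * r / r_max))`,
#' `r_max` the centre-to-corner distance), additive white gaussian sensor
#' noise, and an optional linear intensity drift.
#'
#' @param baseline_intensity mean diastolic intensity at the image centre,
#'   counts.
#' @param vignette_strength fractional fall-off at the frame corner, in
#'   `[0, 1)`.
#' @param noise_sd gaussian noise SD, counts; see [noise_sd_for_snr()] for
#'   the SNR-targeted calibration used by the shipped scenarios.
#' @param drift_per_second linear intensity drift, counts/s.
#' @param seed RNG seed making the simulated movie reproducible.
#' @return A `noise_model` list.
#' @export
noise_model <- function(baseline_intensity = 600, vignette_strength = 0.3,
                        noise_sd = 0, drift_per_second = 0, seed = 1L) {
  check_number(baseline_intensity, "baseline_intensity", lower = 1)
  check_number(vignette_strength, "vignette_strength", lower = 0, upper = 1 - 1e-9)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(drift_per_second, "drift_per_second")
  check_number(seed, "seed", integer = TRUE)
  structure(list(baseline_intensity = baseline_intensity,
                 vignette_strength = vignette_strength, noise_sd = noise_sd,
                 drift_per_second = drift_per_second, seed = as.integer(seed)),
            class = "noise_model")
}

#' Vignetted baseline image
#'
#' @inheritParams compute_activation_field
#' @param noise a [noise_model()].
#' @return `rows x cols` matrix of baseline intensities (counts).
#' @export
baseline_image <- function(noise, shape) {
  rows <- shape[[1L]]; cols <- shape[[2L]]
  cr <- (rows + 1) / 2; cc <- (cols + 1) / 2
  r <- sqrt(outer((seq_len(rows) - cr)^2, (seq_len(cols) - cc)^2, `+`))
  rmax <- sqrt((rows - cr)^2 + (cols - cc)^2)
  if (rmax == 0) rmax <- 1
  s <- noise$vignette_strength
  noise$baseline_intensity * ((1 - s) + s * cos(pi / 2 * r / rmax))
}

#' Solve the noise SD that yields a target raw SNR
#'
#' The raw per-pixel SNR under the package's definition (RMS signal
#' amplitude over RMS diastolic noise, see [compute_snr()]) is
#' `B * dF/F * RMS(V) / noise_sd` for a pixel of baseline `B`, where
#' `RMS(V)` is the root-mean-square of the normalized waveform over one
#' pacing cycle on the frame grid. Given a target masked-mean SNR the
#' noise SD follows in closed form from the mean baseline of the pixels
#' that survive the intensity cutoff.
#'
#' @inheritParams make_ap_trace
#' @param target_snr desired masked-mean raw SNR (e.g. 0.5 for the mouse
#'   scenario, 1.4 for the rat).
#' @param baseline_mean mean baseline intensity over the analysis mask,
#'   counts.
#' @return Noise SD in counts.
#' @export
noise_sd_for_snr <- function(target_snr, template, pcl, frame_rate,
                             baseline_mean, drug = FALSE) {
  check_number(target_snr, "target_snr", lower = 1e-9)
  apd <- apd80_at_pcl(template, pcl, drug = drug)
  tau <- apd / log(5)
  dt <- 1000 / frame_rate
  ph <- seq(0, pcl - dt / 2, by = dt)
  rms_v <- sqrt(mean(ap_shape(ph, template$upstroke_duration, tau)^2))
  baseline_mean * template$amplitude_fraction * rms_v / target_snr
}

#' Simulate an optical-mapping movie with known ground truth
#'
#' Emulates a voltage-dye recording of a paced rodent heart. The
#' fluorescence at pixel `(x, y)` and time `t` is
#' `F = B(x,y) * (1 - dF/F * V(t - T(x,y))) + drift * t + noise`, i.e. the
#' normalized AP `V`, delayed by the analytic activation field `T`,
#' modulates the vignetted baseline with inverted polarity (depolarization
#' darkens, as for di-4-ANEPPS at red wavelengths), then gaussian sensor
#' noise is added and samples are rounded to the camera's integer range.
#' Values falling outside the dynamic range are clipped with a warning.
#'
#' @param wave a [wave_model()].
#' @param template an [ap_template()].
#' @param noise a [noise_model()].
#' @param shape `(rows, cols)` in pixels.
#' @param frame_rate frames per second.
#' @param duration_ms movie length, ms.
#' @param bits_per_sample camera bit depth.
#' @param pixel_size mm per pixel.
#' @param drug simulate the drug (APD-prolonging) condition?
#' @return A list with `recording` (an `omr_recording`) and `truth`, an
#'   `omr_truth` list holding the exact activation field (ms after each
#'   stimulus), the true APD80 field (ms), the axis velocities (m/s) and
#'   the stimulus times (ms).
#' @export
simulate_recording <- function(wave, template, noise, shape = c(200, 200),
                               frame_rate = 977, duration_ms = wave$duration_ms,
                               bits_per_sample = 10L, pixel_size = 0.035,
                               drug = FALSE) {
  rows <- shape[[1L]]; cols <- shape[[2L]]
  if (duration_ms < wave$stim_start_ms + wave$pcl) {
    stop_argument("duration must cover at least one full beat.")
  }
  apd <- apd80_at_pcl(template, wave$pcl, drug = drug)
  tau <- apd / log(5)
  act <- compute_activation_field(wave, shape, pixel_size)
  B <- baseline_image(noise, shape)
  npix <- rows * cols
  nf <- as.integer(floor(duration_ms * frame_rate / 1000))
  dt <- 1000 / frame_rate
  t_frames <- (seq_len(nf) - 1) * dt
  onset <- as.vector(act) + wave$stim_start_ms
  bvec <- as.vector(B)
  alpha <- template$amplitude_fraction
  frames <- integer(npix * nf)
  dim(frames) <- c(npix, nf)
  vmax <- 2^bits_per_sample - 1
  n_clipped <- 0L
  set.seed(noise$seed)
  chunk <- max(1L, as.integer(2^21 %/% npix))
  for (start in seq(1L, nf, by = chunk)) {
    idx <- start:min(start + chunk - 1L, nf)
    tt <- matrix(t_frames[idx], npix, length(idx), byrow = TRUE) - onset
    v <- ap_value(tt, wave$pcl, template$upstroke_duration, tau)
    dim(v) <- dim(tt)
    f <- bvec * (1 - alpha * v) +
      noise$drift_per_second * rep(t_frames[idx] / 1000, each = npix)
    if (noise$noise_sd > 0) f <- f + stats::rnorm(length(f), sd = noise$noise_sd)
    f <- round(f)
    n_clipped <- n_clipped + sum(f < 0 | f > vmax)
    frames[, idx] <- as.integer(pmin(pmax(f, 0), vmax))
  }
  if (n_clipped > 0L) {
    rlang::warn(sprintf("%d samples clipped to the %d-bit range.",
                        n_clipped, bits_per_sample),
                class = "omapr_clipping_warning")
  }
  dim(frames) <- c(rows, cols, nf)
  rec <- recording(frames, frame_rate = frame_rate,
                   bits_per_sample = bits_per_sample, pixel_size = pixel_size)
  stim <- seq(wave$stim_start_ms, duration_ms, by = wave$pcl)
  truth <- structure(list(
    activation_field = act,
    apd_field = matrix(apd, rows, cols),
    v_long = wave$v_long, v_trans = wave$v_trans,
    long_axis_angle = wave$long_axis_angle,
    apd80 = apd, pcl = wave$pcl, stimulus_times = stim,
    baseline = B, noise_sd = noise$noise_sd,
    amplitude_fraction = alpha
  ), class = "omr_truth")
  list(recording = rec, truth = truth)
}

mouse_cv_anchors <- list(pcl = c(90, 150), v_long = c(0.47, 0.51),
                         v_trans = c(0.25, 0.29))

# linear interpolation/extrapolation of the packaged CV restitution anchors
scenario_cv <- function(pcl, anchors = mouse_cv_anchors) {
  lin <- function(y) {
    slope <- diff(y) / diff(anchors$pcl)
    y[1L] + slope * (pcl - anchors$pcl[1L])
  }
  list(v_long = lin(anchors$v_long), v_trans = lin(anchors$v_trans))
}

#' Packaged recording scenarios
#'
#' Bundles of wave, template, noise and conditioning parameters emulating
#' the study conditions the toolkit is validated on:
#'
#' * `mouse_control` — 200x200 px at 977 FPS, 2 s, PCL 150 ms; APD80
#'   40 ms at PCL 150 with restitution slope 19/70 ms/ms (so APD80 falls
#'   by 19 ms from PCL 150 to PCL 80); conduction velocities from linear
#'   anchors 0.51/0.29 m/s at PCL 150 and 0.47/0.25 m/s at PCL 90;
#'   noise calibrated to a raw masked-mean SNR of 0.5.
#' * `mouse_4ap` — mouse scenario with a +19 ms drug APD increment.
#' * `rat_control` — APD80 60 ms, velocities 0.60/0.35 m/s, noise
#'   calibrated to raw SNR 1.4.
#'
#' @param name scenario name.
#' @param pcl pacing cycle length, ms.
#' @param shape `(rows, cols)` in pixels.
#' @param duration_ms movie length, ms.
#' @param frame_rate frames per second.
#' @param seed RNG seed for the noise realization.
#' @param noise_sd override the calibrated noise SD (counts); `NULL` keeps
#'   the SNR-targeted calibration.
#' @return An `omr_scenario` list with components `wave`, `template`,
#'   `noise`, `drug`, `params` (a [conditioning_params()]) and scalar
#'   metadata (`name`, `shape`, `frame_rate`, `duration_ms`,
#'   `bits_per_sample`, `pixel_size`, `target_raw_snr`).
#' @examples
#' sc <- scenario("mouse_control", shape = c(40, 40), duration_ms = 500)
#' sc$wave$v_long
#' @export
scenario <- function(name = c("mouse_control", "mouse_4ap", "rat_control"),
                     pcl = 150, shape = c(200, 200), duration_ms = 2000,
                     frame_rate = 977, seed = 1L, noise_sd = NULL) {
  name <- match.arg(name)
  rows <- shape[[1L]]; cols <- shape[[2L]]
  site <- c(round(rows / 2), round(cols / 2))
  drug <- name == "mouse_4ap"
  if (name == "rat_control") {
    template <- ap_template(apd80 = 60, upstroke_duration = 2,
                            amplitude_fraction = 0.08,
                            restitution_slope = 19 / 70, pcl_ref = 150)
    v <- list(v_long = 0.60, v_trans = 0.35)
    target_snr <- 1.4
  } else {
    template <- ap_template(apd80 = 40, upstroke_duration = 2,
                            amplitude_fraction = 0.08,
                            restitution_slope = 19 / 70,
                            drug_apd_increment = 19, pcl_ref = 150)
    v <- scenario_cv(pcl)
    target_snr <- 0.5
  }
  wave <- wave_model(site, v_long = v$v_long, v_trans = v$v_trans,
                     long_axis_angle = 30, pcl = pcl,
                     duration_ms = duration_ms)
  noise <- noise_model(baseline_intensity = 600, vignette_strength = 0.3,
                       noise_sd = 0, drift_per_second = 0, seed = seed)
  params <- conditioning_params(pcl = pcl, intensity_cutoff = 0.8 * 600)
  if (is.null(noise_sd)) {
    B <- baseline_image(noise, shape)
    bmean <- mean(B[B >= params$intensity_cutoff])
    noise_sd <- noise_sd_for_snr(target_snr, template, pcl, frame_rate,
                                 baseline_mean = bmean, drug = drug)
  }
  noise$noise_sd <- noise_sd
  structure(list(name = name, wave = wave, template = template, noise = noise,
                 drug = drug, params = params, shape = c(rows, cols),
                 frame_rate = frame_rate, duration_ms = duration_ms,
                 bits_per_sample = 10L, pixel_size = 0.035,
                 target_raw_snr = target_snr),
            class = "omr_scenario")
}

#' Simulate a packaged scenario
#'
#' @param sc an [scenario()] object.
#' @return As [simulate_recording()]: `list(recording, truth)`.
#' @export
simulate_scenario <- function(sc) {
  if (!inherits(sc, "omr_scenario")) stop_argument("`sc` must be an `omr_scenario`.")
  simulate_recording(sc$wave, sc$template, sc$noise, shape = sc$shape,
                     frame_rate = sc$frame_rate, duration_ms = sc$duration_ms,
                     bits_per_sample = sc$bits_per_sample,
                     pixel_size = sc$pixel_size, drug = sc$drug)
}

#' @export
print.omr_scenario <- function(x, ...) {
  cat(sprintf("<omr_scenario> %s: %dx%d px @ %g FPS, %g ms, PCL %g ms\n",
              x$name, x$shape[1L], x$shape[2L], x$frame_rate, x$duration_ms,
              x$wave$pcl))
  cat(sprintf("  CV %g/%g m/s, APD80 %g ms, raw-SNR target %g (noise SD %.2f)\n",
              x$wave$v_long, x$wave$v_trans,
              apd80_at_pcl(x$template, x$wave$pcl, x$drug), x$target_raw_snr,
              x$noise$noise_sd))
  invisible(x)
}

#' Write the ground-truth sidecar for a simulated recording
#'
#' Scalars go to `<stem>_truth.json`; the activation and APD fields go to
#' `<stem>_activation.csv` / `<stem>_apd.csv` as plain numeric matrices.
#'
#' @param truth an `omr_truth` from [simulate_recording()].
#' @param stem output path stem (no extension).
#' @return Paths written, invisibly.
#' @export
write_truth <- function(truth, stem) {
  scal <- truth[c("v_long", "v_trans", "long_axis_angle", "apd80", "pcl",
                  "stimulus_times", "noise_sd", "amplitude_fraction")]
  pj <- paste0(stem, "_truth.json")
  jsonlite::write_json(scal, pj, auto_unbox = TRUE, digits = NA)
  pa <- paste0(stem, "_activation.csv")
  utils::write.table(truth$activation_field, pa, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  pd <- paste0(stem, "_apd.csv")
  utils::write.table(truth$apd_field, pd, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(pj, pa, pd))
}
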