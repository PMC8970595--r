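#' Conditioning parameters
#'
#' Tunable parameters of the signal-conditioning chain. The defaults are
#' the high-frame-rate CMOS settings used throughout the package: a 5x5
#' spatial gaussian (sigma `(window - 1) / 4` so the kernel truncates at
#' two sigma), ensemble averaging of every complete beat inside a 2 s
#' window, and a diastolic noise window covering the last 20% of each
#' pacing cycle.
#'
#' @param pcl pacing cycle length, ms.
#' @param spatial_window odd spatial gaussian window, pixels.
#' @param spatial_sigma spatial gaussian SD, pixels.
#' @param ensemble_window_ms length of recording over which beats are
#'   ensemble averaged, ms.
#' @param diastolic_fraction fraction of each cycle (its trailing end,
#'   just before the next upstroke) treated as diastole for noise and
#'   resting-level estimation.
#' @param snr_cutoff mask cutoff on conditioned SNR (dimensionless).
#' @param intensity_cutoff mask cutoff on mean intensity, counts.
#' @param pre_fraction fraction of a cycle included before the detected
#'   beat onset when windowing beats, so the earliest pixels keep their
#'   full upstroke.
#' @param saturation_guard fraction of the top of the dynamic range
#'   treated as oversaturated.
#' @return A `conditioning_params` list.
#' @export
conditioning_params <- function(pcl, spatial_window = 5L,
                                spatial_sigma = (spatial_window - 1) / 4,
                                ensemble_window_ms = 2000,
                                diastolic_fraction = 0.2,
                                snr_cutoff = 2, intensity_cutoff = 0,
                                pre_fraction = 0.1,
                                saturation_guard = 0.01) {
  check_number(pcl, "pcl", lower = 1e-9)
  check_number(spatial_window, "spatial_window", lower = 1, integer = TRUE)
  if (spatial_window %% 2L == 0L) stop_argument("`spatial_window` must be odd.")
  check_number(diastolic_fraction, "diastolic_fraction", lower = 1e-9, upper = 1 - 1e-9)
  check_number(pre_fraction, "pre_fraction", lower = 0, upper = 0.5)
  structure(list(pcl = pcl, spatial_window = as.integer(spatial_window),
                 spatial_sigma = spatial_sigma,
                 ensemble_window_ms = ensemble_window_ms,
                 diastolic_fraction = diastolic_fraction,
                 snr_cutoff = snr_cutoff, intensity_cutoff = intensity_cutoff,
                 pre_fraction = pre_fraction,
                 saturation_guard = saturation_guard),
            class = "conditioning_params")
}

# reflective-boundary band matrix applying a 1-D kernel along one axis
band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (o in seq_along(kernel)) {
    j <- reflect_index(seq_len(n) + o - r - 1L, n)
    K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + kernel[o]
  }
  K
}

#' Spatial gaussian binning of a movie
#'
#' Convolves every frame with a normalized, window-truncated, separable
#' 2-D gaussian (weights sum to one, so flat frames are unchanged) using
#' reflective boundaries.
#'
#' @param x an `omr_recording`, a `rows x cols x frames` array, or a
#'   single frame matrix.
#' @param window odd kernel size in pixels, at most `min(rows, cols)`.
#' @param sigma gaussian SD in pixels; the default truncates the kernel
#'   at two sigma.
#' @return A numeric array/matrix of the filtered intensities, same shape
#'   as the input frames.
#' @export
spatial_gaussian_filter <- function(x, window = 5L, sigma = (window - 1) / 4) {
  frames <- if (inherits(x, "omr_recording")) x$frames else x
  if (is.matrix(frames)) dim(frames) <- c(dim(frames), 1L)
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop_argument("`x` must be a recording, movie array or frame matrix.")
  }
  d <- dim(frames)
  if (window > min(d[1:2])) stop_argument("`window` exceeds the frame size.")
  k <- gaussian_kernel_1d(window, sigma)
  Kr <- band_matrix(d[1L], k)
  Kct <- t(band_matrix(d[2L], k))
  out <- array(0, d)
  for (f in seq_len(d[3L])) {
    out[, , f] <- Kr %*% frames[, , f] %*% Kct
  }
  if (d[3L] == 1L && (is.matrix(x) || (is.array(x) && length(dim(x)) == 2L))) {
    return(out[, , 1L])
  }
  out
}

# movie as a pixels x frames matrix (no copy beyond the dim change)
movie_matrix <- function(x) {
  frames <- if (inherits(x, "omr_recording")) x$frames else x
  d <- dim(frames)
  dim(frames) <- c(d[1L] * d[2L], d[3L])
  frames
}

# spatially averaged global signal
global_trace <- function(x) {
  colMeans(movie_matrix(x))
}

#' Locate stimulus-aligned beat windows
#'
#' Beat onsets are found on the spatially averaged global signal: the
#' strongest upstroke anywhere in the recording fixes the pacing phase
#' (the dye's polarity, inverted or not, is detected from its sign),
#' candidate onsets are laid out at strides of one pacing cycle, and each
#' is refined within +/- 2 frames to the local derivative extreme. Each
#' beat window spans one cycle (`frames_per_beat = round(pcl * frame_rate
#' / 1000)` frames) and starts `pre_fraction` of a cycle before the
#' detected onset so that early-activating pixels keep their full
#' upstroke. Only beats whose windows lie completely inside the ensemble
#' window are returned.
#'
#' @param x recording, movie array, or a single global trace vector.
#' @param pcl pacing cycle length, ms.
#' @param frame_rate frames per second.
#' @param ensemble_window_ms restrict beats to the first this-many ms.
#' @param pre_fraction cycle fraction included before each onset.
#' @return An `omr_beats` list: `onsets` (frame index of each steepest
#'   upstroke), `starts` (first frame of each beat window),
#'   `frames_per_beat`, `pre_frames`, `n_beats`, `frame_rate`, `pcl`.
#' @export
segment_beats <- function(x, pcl, frame_rate, ensemble_window_ms = NULL,
                          pre_fraction = 0.1) {
  g <- if (is.numeric(x) && is.null(dim(x))) x else global_trace(x)
  nt <- length(g)
  check_number(pcl, "pcl", lower = 1e-9)
  check_number(frame_rate, "frame_rate", lower = 1e-9)
  stride <- pcl * frame_rate / 1000
  if (nt < stride) {
    stop_segmentation(sprintf(
      "Recording of %d frames is shorter than one %g ms cycle (%.1f frames).",
      nt, pcl, stride))
  }
  if (diff(range(g)) == 0) {
    stop_segmentation("Flat global signal: no upstroke to segment on.")
  }
  d <- diff(g)
  i0 <- which.max(abs(d))
  sgn <- sign(d[i0])
  if (abs(d[i0]) == 0) stop_segmentation("No detectable upstroke in the global signal.")
  fpb <- as.integer(round(stride))
  pre <- as.integer(round(pre_fraction * fpb))
  limit <- nt
  if (!is.null(ensemble_window_ms)) {
    limit <- min(nt, as.integer(floor(ensemble_window_ms * frame_rate / 1000)))
  }
  ks <- seq(-ceiling(i0 / stride), ceiling((nt - i0) / stride))
  onsets <- integer(0)
  for (k in ks) {
    cand <- i0 + as.integer(round(k * stride))
    lo <- max(1L, cand - 2L); hi <- min(nt - 1L, cand + 2L)
    if (lo > hi) next
    seg <- d[lo:hi] * sgn
    onset <- lo + which.max(seg) - 1L
    if (seg[onset - lo + 1L] < 0.2 * abs(d[i0])) next   # no real upstroke here
    onsets <- c(onsets, onset)
  }
  onsets <- sort(unique(onsets))
  # keep the windows aligned but never lose the first beat to the pre-margin
  if (length(onsets) > 0L) pre <- min(pre, onsets[1L] - 1L)
  onsets <- onsets[onsets - pre >= 1L & onsets - pre + fpb - 1L <= limit]
  if (length(onsets) == 0L) {
    stop_segmentation("No complete beat fits inside the ensemble window.")
  }
  structure(list(onsets = onsets, starts = onsets - pre,
                 frames_per_beat = fpb, pre_frames = pre,
                 n_beats = length(onsets), frame_rate = frame_rate, pcl = pcl),
            class = "omr_beats")
}

#' @export
print.omr_beats <- function(x, ...) {
  cat(sprintf("<omr_beats> %d beats of %d frames (PCL %g ms @ %g FPS), onsets %s...\n",
              x$n_beats, x$frames_per_beat, x$pcl, x$frame_rate,
              paste(utils::head(x$onsets, 4L), collapse = ", ")))
  invisible(x)
}

#' Ensemble average of stimulus-aligned beats
#'
#' Averages the movie across the beat windows located by
#' [segment_beats()] (or across an explicit list of equally sized,
#' already-aligned beat matrices), suppressing uncorrelated noise by
#' roughly the square root of the number of beats.
#'
#' @param x recording or movie array (or, if `beats` is missing, a list
#'   of aligned `pixels x frames` beat matrices).
#' @param beats an `omr_beats` segmentation.
#' @return An `omr_beat`: `traces` (`rows x cols x frames_per_beat`
#'   numeric array, same orientation and polarity as the input),
#'   `n_beats_averaged`, `frame_rate`, `pcl`, `pre_frames`.
#' @export
ensemble_average <- function(x, beats) {
  if (missing(beats)) {
    if (!is.list(x) || length(x) == 0L) {
      stop_argument("Provide a movie plus `beats`, or a non-empty list of beat matrices.")
    }
    dims <- lapply(x, dim)
    if (length(unique(lapply(dims, identical, dims[[1L]]))) != 1L ||
        !all(vapply(dims, identical, logical(1L), dims[[1L]]))) {
      stop_argument("Ragged beat stack: all beats must have identical dimensions.")
    }
    avg <- Reduce(`+`, x) / length(x)
    return(structure(list(traces = avg, n_beats_averaged = length(x),
                          frame_rate = NA_real_, pcl = NA_real_,
                          pre_frames = NA_integer_),
                     class = "omr_beat"))
  }
  frames <- if (inherits(x, "omr_recording")) x$frames else x
  d <- dim(frames)
  M <- movie_matrix(frames)
  fpb <- beats$frames_per_beat
  acc <- matrix(0, nrow(M), fpb)
  for (s in beats$starts) {
    acc <- acc + M[, s:(s + fpb - 1L)]
  }
  avg <- acc / beats$n_beats
  dim(avg) <- c(d[1L], d[2L], fpb)
  structure(list(traces = avg, n_beats_averaged = beats$n_beats,
                 frame_rate = beats$frame_rate, pcl = beats$pcl,
                 pre_frames = beats$pre_frames),
            class = "omr_beat")
}

#' @export
print.omr_beat <- function(x, ...) {
  d <- dim(x$traces)
  cat(sprintf("<omr_beat> %dx%d px, %d frames/beat, %d beats averaged\n",
              d[1L], d[2L], d[3L], x$n_beats_averaged))
  invisible(x)
}

# 1-D gaussian smoothing along time (columns) with reflective boundary
smooth_gaussian_time <- function(x, frame_rate, sigma_ms = 7, truncate = 4) {
  vec <- is.null(dim(x))
  M <- if (vec) matrix(x, 1L) else x
  nt <- ncol(M)
  sigma <- sigma_ms * frame_rate / 1000
  r <- as.integer(ceiling(truncate * sigma))
  if (nt <= 2L * r) {
    stop_argument(sprintf(
      "Trace of %d samples is shorter than the %d-tap smoothing kernel.",
      nt, 2L * r + 1L))
  }
  k <- gaussian_kernel_1d(2L * r + 1L, sigma)
  out <- matrix(0, nrow(M), nt)
  for (o in seq_along(k)) {
    j <- reflect_index(seq_len(nt) + o - r - 1L, nt)
    out <- out + k[o] * M[, j, drop = FALSE]
  }
  if (vec) as.vector(out) else out
}

#' Estimate the per-pixel resting (diastolic) level
#'
#' The trace is smoothed with a 1-D gaussian of `sigma_ms` (default 7 ms,
#' kernel truncated at four sigma) and the resting level is the mean of
#' the smoothed trace over the diastolic window. Smoothing-then-averaging
#' is linear, so for many pixels the same number is obtained by one
#' weighted average of raw frames; the matrix method uses that identity.
#'
#' @param x numeric trace (vector) or `pixels x frames` matrix.
#' @param frame_rate frames per second.
#' @param diastole_idx integer frame indices of the diastolic window
#'   (default: the whole trace, appropriate for quiescent signals).
#' @param sigma_ms smoothing SD in ms.
#' @param truncate kernel truncation in units of sigma.
#' @return Scalar resting level, or one per matrix row.
#' @export
estimate_resting_level <- function(x, frame_rate, diastole_idx = NULL,
                                   sigma_ms = 7, truncate = 4) {
  vec <- is.null(dim(x))
  nt <- if (vec) length(x) else ncol(x)
  if (is.null(diastole_idx)) diastole_idx <- seq_len(nt)
  if (vec) {
    sm <- smooth_gaussian_time(x, frame_rate, sigma_ms, truncate)
    return(mean(sm[diastole_idx]))
  }
  sigma <- sigma_ms * frame_rate / 1000
  r <- as.integer(ceiling(truncate * sigma))
  if (nt <= 2L * r) {
    stop_argument(sprintf(
      "Trace of %d samples is shorter than the %d-tap smoothing kernel.",
      nt, 2L * r + 1L))
  }
  k <- gaussian_kernel_1d(2L * r + 1L, sigma)
  w <- numeric(nt)
  for (i in diastole_idx) {
    j <- reflect_index(i + seq.int(-r, r), nt)
    # reflected indices can repeat near the edges; accumulate, not overwrite
    agg <- rowsum(k, j)
    jj <- as.integer(rownames(agg))
    w[jj] <- w[jj] + agg[, 1L]
  }
  w <- w / length(diastole_idx)
  as.vector(x %*% w)
}

#' Normalize traces and correct dye polarity
#'
#' Flips the inverted voltage-dye signal so depolarization is
#' positive-going and rescales each pixel so its resting level maps to 0
#' and its peak to 1. Pixels with (near-)zero dynamic range are flagged
#' dead rather than raising an error, and their traces are set to `NA`.
#'
#' @param x an `omr_beat` or a numeric array/matrix/vector of traces
#'   (time along the last dimension).
#' @param resting per-pixel resting level (scalar or one per pixel).
#' @param inverted is the raw polarity inverted (depolarization darkens)?
#' @param dead_range absolute amplitude below which a pixel is dead.
#' @return List with `traces` (same shape, normalized), `amplitude` (the
#'   per-pixel scaling) and `dead` (logical per pixel).
#' @export
normalize_invert <- function(x, resting, inverted = TRUE, dead_range = 1e-8) {
  traces <- if (inherits(x, "omr_beat")) x$traces else x
  vec <- is.null(dim(traces))
  d <- dim(traces)
  M <- if (vec) matrix(traces, 1L)
  else if (length(d) == 3L) movie_matrix(traces)
  else traces
  if (length(resting) == 1L) resting <- rep(resting, nrow(M))
  w <- if (inverted) resting - M else M - resting
  amp <- apply(w, 1L, max)
  dead <- !is.finite(amp) | amp <= dead_range
  amp_safe <- ifelse(dead, 1, amp)
  out <- w / amp_safe
  out[dead, ] <- NA_real_
  if (vec) {
    out <- as.vector(out)
  } else {
    dim(out) <- d
  }
  list(traces = out, amplitude = ifelse(dead, NA_real_, amp), dead = dead)
}

# diastolic frame indices: the trailing fraction of each beat window
diastole_indices <- function(starts, fpb, diastolic_fraction) {
  ndia <- max(3L, as.integer(round(diastolic_fraction * fpb)))
  idx <- lapply(starts, function(s) (s + fpb - ndia):(s + fpb - 1L))
  sort(unique(unlist(idx)))
}

#' Signal-to-noise ratio of fluorescence traces
#'
#' SNR is the ratio of the root-mean-square signal amplitude to the
#' root-mean-square noise, the noise being evaluated at resting potential
#' (the diastolic interval). The RMS amplitude is the noise-power-
#' corrected deviation from rest over the beat,
#' `A = sqrt(max(mean((x - rest)^2 over beats) - mean((x - rest)^2 over
#' diastole), 0))`, so that the ratio measures the action potential
#' itself and not the noise it rides on; a noise-free trace returns
#' `Inf`.
#'
#' @param x numeric trace (vector) or `pixels x frames` matrix.
#' @param beat_idx frame indices covering the beats (signal window).
#' @param diastole_idx frame indices of the pooled diastolic windows
#'   (at least 3 samples).
#' @param resting resting level, scalar or one per pixel.
#' @return SNR, scalar or one per pixel.
#' @export
compute_snr <- function(x, beat_idx, diastole_idx, resting) {
  vec <- is.null(dim(x))
  M <- if (vec) matrix(x, 1L) else x
  if (length(diastole_idx) < 3L) {
    stop_computation("Need at least 3 diastolic samples to estimate noise.")
  }
  if (length(beat_idx) < 1L) stop_computation("Empty beat window.")
  dev <- M - resting
  msq_beat <- rowMeans(dev[, beat_idx, drop = FALSE]^2)
  msq_dia <- rowMeans(dev[, diastole_idx, drop = FALSE]^2)
  amp <- sqrt(pmax(msq_beat - msq_dia, 0))
  noise <- sqrt(msq_dia)
  snr <- ifelse(noise == 0, ifelse(amp > 0 | msq_beat > 0, Inf, NA_real_),
                amp / noise)
  if (vec) snr[1L] else snr
}

#' Per-pixel SNR map of a recording or conditioned beat
#'
#' For a raw recording the beats are segmented first and the diastolic
#' noise window pools the trailing `diastolic_fraction` of every cycle;
#' for an ensemble-averaged beat the single beat window is used. The
#' resting level is estimated per pixel with [estimate_resting_level()].
#'
#' @param x an `omr_recording` or `omr_beat`.
#' @param params a [conditioning_params()].
#' @param beats optional precomputed [segment_beats()] result (recordings
#'   only).
#' @return An `omr_map` of kind `"snr"` tagged `"raw"` or
#'   `"conditioned"`.
#' @export
snr_map <- function(x, params, beats = NULL) {
  if (inherits(x, "omr_recording")) {
    fr <- x$header$frame_rate
    M <- movie_matrix(x)
    if (is.null(beats)) {
      beats <- segment_beats(x, params$pcl, fr,
                             ensemble_window_ms = params$ensemble_window_ms,
                             pre_fraction = params$pre_fraction)
    }
    fpb <- beats$frames_per_beat
    beat_idx <- sort(unique(unlist(lapply(beats$starts,
                                          function(s) s:(s + fpb - 1L)))))
    dia_idx <- diastole_indices(beats$starts, fpb, params$diastolic_fraction)
    rest <- estimate_resting_level(M, fr, diastole_idx = dia_idx)
    snr <- compute_snr(M, beat_idx, dia_idx, rest)
    dims <- dim(x$frames)[1:2]
    tag <- "raw"
  } else if (inherits(x, "omr_beat")) {
    fr <- x$frame_rate
    M <- movie_matrix(x$traces)
    fpb <- dim(x$traces)[3L]
    dia_idx <- diastole_indices(1L, fpb, params$diastolic_fraction)
    rest <- estimate_resting_level(M, fr, diastole_idx = dia_idx)
    snr <- compute_snr(M, seq_len(fpb), dia_idx, rest)
    dims <- dim(x$traces)[1:2]
    tag <- "conditioned"
  } else {
    stop_argument("`x` must be an `omr_recording` or `omr_beat`.")
  }
  new_map(matrix(snr, dims[1L], dims[2L]), kind = "snr", units = "",
          definition = tag)
}

#' Build the pixel validity mask
#'
#' A pixel is kept iff its SNR reaches `snr_cutoff` and its mean
#' intensity lies between `intensity_cutoff` and the saturation bound
#' (the top `saturation_guard` fraction of the dynamic range counts as
#' oversaturated). An all-FALSE mask is allowed but warned about.
#'
#' @param snr an `omr_map` of SNR values (or a numeric matrix).
#' @param intensity matrix of per-pixel mean intensity, counts.
#' @param params a [conditioning_params()].
#' @param bits_per_sample camera bit depth defining the saturation bound.
#' @return An `omr_map` of kind `"mask"` (logical values) with a
#'   `provenance` record of the cutoffs applied.
#' @export
build_mask <- function(snr, intensity, params, bits_per_sample = 10L) {
  s <- if (inherits(snr, "omr_map")) snr$values else snr
  if (!identical(dim(s), dim(intensity))) {
    stop_argument("SNR and intensity maps must have the same shape.")
  }
  sat <- (2^bits_per_sample - 1) * (1 - params$saturation_guard)
  keep <- !is.na(s) & s >= params$snr_cutoff &
    intensity >= params$intensity_cutoff & intensity <= sat
  if (!any(keep)) {
    rlang::warn("All pixels excluded by the current cutoffs (empty mask).",
                class = "omapr_empty_mask_warning")
  }
  new_map(keep, kind = "mask", units = "",
          provenance = list(snr_cutoff = params$snr_cutoff,
                            intensity_cutoff = params$intensity_cutoff,
                            saturation_bound = sat))
}

#' Run the full signal-conditioning chain
#'
#' Applies, in order: spatial gaussian binning, beat segmentation on the
#' global signal, ensemble averaging of all complete beats in the
#' ensemble window, per-pixel resting-level estimation, polarity
#' correction and normalization, raw and conditioned SNR mapping, and
#' SNR/intensity masking.
#'
#' @param rec an `omr_recording`.
#' @param params a [conditioning_params()].
#' @return An `omr_conditioned` bundle: `beat` (normalized upstroke-
#'   positive `omr_beat`), `avg` (ensemble average before
#'   normalization), `resting`, `amplitude`, `dead`, `snr_raw`,
#'   `snr_conditioned`, `intensity`, `mask`, `beats`, `params`,
#'   `frame_rate`, `pixel_size`, `bits_per_sample`.
#' @export
condition_recording <- function(rec, params) {
  validate_recording(rec)
  fr <- rec$header$frame_rate
  beats <- segment_beats(rec, params$pcl, fr,
                         ensemble_window_ms = params$ensemble_window_ms,
                         pre_fraction = params$pre_fraction)
  raw_snr <- snr_map(rec, params, beats = beats)
  intensity <- matrix(rowMeans(movie_matrix(rec)),
                      rec$header$height, rec$header$width)
  filt <- spatial_gaussian_filter(rec$frames, params$spatial_window,
                                  params$spatial_sigma)
  avg <- ensemble_average(filt, beats)
  fpb <- dim(avg$traces)[3L]
  dia_idx <- diastole_indices(1L, fpb, params$diastolic_fraction)
  M <- movie_matrix(avg$traces)
  resting <- estimate_resting_level(M, fr, diastole_idx = dia_idx)
  norm <- normalize_invert(M, resting)
  beat <- avg
  beat$traces <- norm$traces
  dim(beat$traces) <- dim(avg$traces)
  cond_snr <- snr_map(avg, params)
  mask <- build_mask(cond_snr, intensity, params,
                     bits_per_sample = rec$header$bits_per_sample)
  mask$values <- mask$values & !matrix(norm$dead, nrow(intensity), ncol(intensity))
  structure(list(beat = beat, avg = avg,
                 resting = matrix(resting, nrow(intensity), ncol(intensity)),
                 amplitude = matrix(norm$amplitude, nrow(intensity), ncol(intensity)),
                 dead = matrix(norm$dead, nrow(intensity), ncol(intensity)),
                 snr_raw = raw_snr, snr_conditioned = cond_snr,
                 intensity = intensity, mask = mask, beats = beats,
                 params = params, frame_rate = fr,
                 pixel_size = rec$header$pixel_size,
                 bits_per_sample = rec$header$bits_per_sample),
            class = "omr_conditioned")
}

#' @export
print.omr_conditioned <- function(x, ...) {
  d <- dim(x$beat$traces)
  cat(sprintf("<omr_conditioned> %dx%d px, %d frames/beat, %d beats averaged\n",
              d[1L], d[2L], d[3L], x$beat$n_beats_averaged))
  cat(sprintf("  masked pixels: %d/%d; masked-mean SNR raw %.3g -> conditioned %.3g\n",
              sum(x$mask$values), length(x$mask$values),
              mean(x$snr_raw$values[x$mask$values], na.rm = TRUE),
              mean(x$snr_conditioned$values[x$mask$values], na.rm = TRUE)))
  invisible(x)
}
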