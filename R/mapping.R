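#' Activation time of a single beat trace
#'
#' The activation marker is the maximum first difference of the
#' (upstroke-positive) trace, refined by parabolic interpolation around
#' the discrete derivative peak; exact ties resolve to the earliest
#' sample. Flat traces return `NA` (the pixel is excluded, not an
#' error).
#'
#' @param trace numeric beat trace, upstroke positive-going.
#' @param frame_rate frames per second.
#' @return Activation time in ms relative to the start of the trace
#'   (frame 1 = 0 ms).
#' @export
detect_activation <- function(trace, frame_rate) {
  act <- activation_times(matrix(trace, 1L), frame_rate)
  act[1L]
}

# vectorized activation marker for pixels x frames matrices
activation_times <- function(M, frame_rate) {
  nt <- ncol(M)
  if (nt < 3L) stop_argument("Need at least 3 frames to detect activation.")
  D <- M[, 2:nt, drop = FALSE] - M[, 1:(nt - 1L), drop = FALSE]
  flat <- apply(D, 1L, function(r) all(!is.finite(r)) || diff(range(r)) == 0)
  idx <- max.col(D, ties.method = "first")
  delta <- numeric(nrow(M))
  inner <- idx > 1L & idx < ncol(D)
  if (any(inner)) {
    i <- which(inner)
    a <- D[cbind(i, idx[i] - 1L)]
    b <- D[cbind(i, idx[i])]
    cc <- D[cbind(i, idx[i] + 1L)]
    den <- a - 2 * b + cc
    delta[i] <- ifelse(den == 0, 0, 0.5 * (a - cc) / den)
    delta[i] <- pmin(pmax(delta[i], -0.5), 0.5)
  }
  act <- (idx - 0.5 + delta) * 1000 / frame_rate
  act[flat] <- NA_real_
  act
}

#' Per-pixel activation map of a conditioned beat
#'
#' @param cond an `omr_conditioned` bundle.
#' @return An `omr_map` of kind `"activation"` (ms relative to the beat
#'   window start), defined only on masked pixels.
#' @export
activation_map <- function(cond) {
  if (!inherits(cond, "omr_conditioned")) {
    stop_argument("`cond` must come from condition_recording().")
  }
  M <- movie_matrix(cond$beat$traces)
  act <- activation_times(M, cond$frame_rate)
  act[!as.vector(cond$mask$values)] <- NA_real_
  new_map(matrix(act, nrow(cond$mask$values), ncol(cond$mask$values)),
          kind = "activation", units = "ms", mask = cond$mask$values)
}

#' APD80 of a single beat trace
#'
#' Action potential duration at 80% repolarization: the amplitude is the
#' post-activation peak above the resting level (a 3-frame running mean
#' tames single-sample noise at the peak) and the APD is the time from
#' activation to the first sustained crossing below
#' `resting + 0.2 * amplitude`, with linear interpolation between the
#' bracketing samples. A crossing must persist below the threshold for
#' `sustain_ms` (about two frames at 977 FPS) to count, so isolated
#' noise dips during repolarization are not mistaken for it. Traces that never repolarize within the
#' window return `NA` (flagged, not an error).
#'
#' @param trace numeric beat trace, upstroke positive-going.
#' @param activation activation time in ms (see [detect_activation()]).
#' @param resting resting level of the trace.
#' @param frame_rate frames per second.
#' @param sustain_ms time the trace must remain below threshold, ms.
#' @return APD80 in ms, or `NA` if the pixel never repolarizes.
#' @export
compute_apd80 <- function(trace, activation, resting, frame_rate,
                          sustain_ms = 2) {
  apd80_times(matrix(trace, 1L), activation, resting, frame_rate,
              sustain_ms)[1L]
}

# vectorized APD80 for pixels x frames matrices
apd80_times <- function(M, activation, resting, frame_rate, sustain_ms = 2) {
  npix <- nrow(M); nt <- ncol(M)
  dt <- 1000 / frame_rate
  if (length(resting) == 1L) resting <- rep(resting, npix)
  act_idx <- pmax(1L, pmin(nt, as.integer(floor(activation / dt)) + 1L))
  # 3-frame running mean for a noise-robust peak estimate
  R <- M
  R[, 2:(nt - 1L)] <- (M[, 1:(nt - 2L)] + M[, 2:(nt - 1L)] + M[, 3:nt]) / 3
  colidx <- matrix(seq_len(nt), npix, nt, byrow = TRUE)
  Rmasked <- R
  Rmasked[colidx < act_idx] <- -Inf
  peak_idx <- max.col(Rmasked, ties.method = "first")
  peak_val <- Rmasked[cbind(seq_len(npix), peak_idx)]
  amp <- peak_val - resting
  thr <- resting + 0.2 * amp
  below <- M < thr
  s <- max(1L, as.integer(round(sustain_ms * frame_rate / 1000)))
  # sustained crossing: below the threshold for s consecutive frames
  # (windows running past the end only need to stay below until the end)
  cnt <- matrix(0L, npix, nt)
  for (k in 0:(s - 1L)) {
    j <- pmin(seq_len(nt) + k, nt)
    cnt <- cnt + below[, j, drop = FALSE]
  }
  ok <- cnt == s & colidx > peak_idx
  cross <- rep(NA_integer_, npix)
  for (t in 2:nt) {
    hit <- is.na(cross) & ok[, t]
    if (any(hit)) cross[hit] <- t
  }
  apd <- rep(NA_real_, npix)
  found <- !is.na(cross) & !is.na(amp) & amp > 0
  if (any(found)) {
    i <- which(found)
    t1 <- cross[i] - 1L
    y1 <- M[cbind(i, t1)]
    y2 <- M[cbind(i, cross[i])]
    frac <- ifelse(y1 == y2, 0, (y1 - thr[i]) / (y1 - y2))
    cross_ms <- (t1 - 1L + frac) * dt
    apd[i] <- cross_ms - activation[i]
  }
  apd[!is.finite(activation) | apd <= 0] <- NA_real_
  apd
}

#' Per-pixel APD80 map with IQR outlier exclusion
#'
#' Measures APD80 on every masked pixel of the conditioned beat, then
#' excludes pixels outside the Tukey fences `Q1 - 1.5 IQR` and
#' `Q3 + 1.5 IQR` (see [exclude_outliers_iqr()]).
#'
#' @param cond an `omr_conditioned` bundle.
#' @param act optional precomputed [activation_map()].
#' @param sustain_ms see [compute_apd80()].
#' @return An `omr_map` of kind `"apd80"` (ms) carrying
#'   `outlier_bounds`, with outliers and unrepolarized pixels set `NA`.
#' @export
apd_map <- function(cond, act = NULL, sustain_ms = 2) {
  if (is.null(act)) act <- activation_map(cond)
  M <- movie_matrix(cond$beat$traces)
  avec <- as.vector(act$values)
  # the normalized beat has resting ~0 by construction; measure it anyway
  fpb <- ncol(M)
  dia <- diastole_indices(1L, fpb, cond$params$diastolic_fraction)
  rest <- estimate_resting_level(M, cond$frame_rate, diastole_idx = dia)
  apd <- apd80_times(M, avec, rest, cond$frame_rate, sustain_ms)
  apd[!as.vector(cond$mask$values)] <- NA_real_
  keep <- exclude_outliers_iqr(apd[!is.na(apd)])
  bounds <- keep$bounds
  if (!is.null(bounds)) {
    apd[!is.na(apd) & (apd < bounds[1L] | apd > bounds[2L])] <- NA_real_
  }
  new_map(matrix(apd, nrow(act$values), ncol(act$values)),
          kind = "apd80", units = "ms", mask = cond$mask$values,
          outlier_bounds = bounds)
}

#' Interquartile-range outlier exclusion
#'
#' Computes the Tukey fences `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR` with
#' quartiles by linear interpolation between order statistics
#' (`stats::quantile` type 7) and removes, in a single pass, every value
#' outside them. Fewer than 4 values are returned unchanged with `NULL`
#' bounds, and a zero IQR excludes nothing.
#'
#' @param values numeric vector (ms in the APD use).
#' @return List with `retained`, `bounds` (`c(low, high)` or `NULL`) and
#'   `n_excluded`.
#' @examples
#' exclude_outliers_iqr(c(10, 11, 12, 12, 13, 50))
#' @export
exclude_outliers_iqr <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L) {
    return(list(retained = values, bounds = NULL, n_excluded = 0L))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  bounds <- c(q[1L] - 1.5 * iqr, q[2L] + 1.5 * iqr)
  keep <- values >= bounds[1L] & values <= bounds[2L]
  list(retained = values[keep], bounds = bounds,
       n_excluded = sum(!keep))
}

# design matrix of a full 2-D polynomial of given order at offsets (x, y)
poly_design <- function(x, y, order) {
  cols <- list()
  for (total in 0:order) {
    for (ix in total:0) {
      iy <- total - ix
      cols[[length(cols) + 1L]] <- x^ix * y^iy
    }
  }
  do.call(cbind, cols)
}

#' Conduction-velocity vector field by local polynomial surface fitting
#'
#' For every defined pixel of the activation map, a polynomial surface
#' `T(x, y)` (default order 2) is least-squares fitted to the activation
#' times in the surrounding `window x window` neighborhood, in physical
#' (mm) coordinates with y up. The local conduction velocity is
#' `v = grad(T) / |grad(T)|^2` evaluated at the centre -- the gradient
#' inverse, pointing along propagation -- scaled to cm/s. Fits whose
#' residual RMS exceeds `residual_threshold_ms`, or with too few or
#' degenerate neighbors, leave the pixel undefined.
#'
#' Activation-marker jitter propagates into `1 / |grad(T)|` with a
#' convex (speed-inflating) bias, so noisy maps should be smoothed with
#' [smooth_map()] before fitting; on noise-free polynomial fields the
#' fit is exact.
#'
#' @param act an [activation_map()] (or any `omr_map` of times in ms).
#' @param pixel_size mm per pixel.
#' @param window odd neighborhood size, pixels.
#' @param order polynomial order of the fitted surface.
#' @param residual_threshold_ms drop fits with residual RMS above this.
#' @param min_points minimum defined neighbors required for a fit
#'   (default: the number of polynomial coefficients).
#' @return An `omr_velocity_field`: matrices `vx`, `vy` (cm/s, y up),
#'   `speed`, `residual_ms`, plus `window`, `order`.
#' @export
fit_cv_bayly <- function(act, pixel_size, window = 7L, order = 2L,
                         residual_threshold_ms = 2,
                         min_points = NULL) {
  v <- if (inherits(act, "omr_map")) act$values else act
  check_number(pixel_size, "pixel_size", lower = 1e-12)
  check_number(window, "window", lower = 3, integer = TRUE)
  if (window %% 2L == 0L) stop_argument("`window` must be odd.")
  check_number(order, "order", lower = 1, integer = TRUE)
  p <- (order + 1) * (order + 2) / 2
  if (is.null(min_points)) min_points <- p
  rows <- nrow(v); cols <- ncol(v)
  r <- (window - 1L) %/% 2L
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  # physical offsets, y up (row offset negated)
  X <- poly_design(offs$dc * pixel_size, -offs$dr * pixel_size, order)
  # poly_design emits, for total = 0..order, the terms x^t y^0 ... x^0 y^t,
  # so column 2 is x and column 3 is y: the centre gradient coefficients
  vx <- vy <- speed <- resid <- matrix(NA_real_, rows, cols)
  valid <- is.finite(v)
  interior <- matrix(FALSE, rows, cols)
  if (rows > 2L * r && cols > 2L * r) {
    interior[(r + 1L):(rows - r), (r + 1L):(cols - r)] <- TRUE
  }
  # pixels whose full window is defined: one shared pseudo-inverse
  full <- interior
  shift_ok <- function(m, dr, dc) {
    out <- matrix(FALSE, rows, cols)
    rs <- max(1L, 1L - dr):min(rows, rows - dr)
    cs <- max(1L, 1L - dc):min(cols, cols - dc)
    out[rs, cs] <- m[rs + dr, cs + dc]
    out
  }
  for (i in seq_len(nrow(offs))) {
    full <- full & shift_ok(valid, offs$dr[i], offs$dc[i])
    if (!any(full)) break
  }
  n_off <- nrow(offs)
  XtXi <- solve(crossprod(X))
  if (any(full)) {
    idx_full <- which(full)
    W <- matrix(0, length(idx_full), n_off)
    rr <- ((idx_full - 1L) %% rows) + 1L
    cc <- ((idx_full - 1L) %/% rows) + 1L
    for (i in seq_len(n_off)) {
      W[, i] <- v[cbind(rr + offs$dr[i], cc + offs$dc[i])]
    }
    P <- XtXi %*% t(X)                      # p x n_off
    coef <- W %*% t(P)                      # npix x p
    res <- W - coef %*% t(X)
    rms <- sqrt(rowMeans(res^2))
    gx <- coef[, 2L]; gy <- coef[, 3L]      # ms/mm
    g2 <- gx^2 + gy^2
    okg <- g2 > 0
    vx[idx_full[okg]] <- 100 * gx[okg] / g2[okg]   # mm/ms -> cm/s
    vy[idx_full[okg]] <- 100 * gy[okg] / g2[okg]
    resid[idx_full] <- rms
  }
  # boundary-of-mask pixels: per-pixel fits on the defined neighbors
  partial <- valid & !full
  idx_part <- which(partial)
  if (length(idx_part) > 0L) {
    rr <- ((idx_part - 1L) %% rows) + 1L
    cc <- ((idx_part - 1L) %/% rows) + 1L
    for (j in seq_along(idx_part)) {
      nr <- rr[j] + offs$dr; nc <- cc[j] + offs$dc
      inb <- nr >= 1L & nr <= rows & nc >= 1L & nc <= cols
      ti <- rep(NA_real_, n_off)
      ti[inb] <- v[cbind(nr[inb], nc[inb])]
      use <- is.finite(ti)
      if (sum(use) < min_points) next
      Xi <- X[use, , drop = FALSE]
      qr_fit <- qr(Xi)
      if (qr_fit$rank < ncol(Xi)) next     # degenerate neighborhood
      beta <- qr.coef(qr_fit, ti[use])
      res <- ti[use] - Xi %*% beta
      g2 <- beta[2L]^2 + beta[3L]^2
      resid[idx_part[j]] <- sqrt(mean(res^2))
      if (g2 > 0) {
        vx[idx_part[j]] <- 100 * beta[2L] / g2
        vy[idx_part[j]] <- 100 * beta[3L] / g2
      }
    }
  }
  bad <- !is.na(resid) & resid > residual_threshold_ms
  vx[bad] <- NA_real_; vy[bad] <- NA_real_
  speed <- sqrt(vx^2 + vy^2)
  structure(list(vx = vx, vy = vy, speed = speed, residual_ms = resid,
                 window = as.integer(window), order = as.integer(order),
                 residual_threshold_ms = residual_threshold_ms,
                 pixel_size = pixel_size),
            class = "omr_velocity_field")
}

#' @export
print.omr_velocity_field <- function(x, ...) {
  n <- sum(is.finite(x$speed))
  cat(sprintf("<omr_velocity_field> order-%d fit, %dx%d px window, %d vectors\n",
              x$order, x$window, x$window, n))
  if (n > 0) {
    cat(sprintf("  speed median %.3g cm/s [%.3g, %.3g]\n",
                stats::median(x$speed[is.finite(x$speed)]),
                min(x$speed, na.rm = TRUE), max(x$speed, na.rm = TRUE)))
  }
  invisible(x)
}

#' Tidy a velocity field
#'
#' @param x an `omr_velocity_field`.
#' @param ... unused.
#' @return Tibble with `row`, `col`, `vx`, `vy`, `speed` (cm/s),
#'   `angle_deg` (direction of propagation, y up) and `residual_ms`.
#' @method tidy omr_velocity_field
#' @export
tidy.omr_velocity_field <- function(x, ...) {
  keep <- which(is.finite(x$speed))
  rows <- nrow(x$speed)
  tibble::tibble(
    row = ((keep - 1L) %% rows) + 1L,
    col = ((keep - 1L) %/% rows) + 1L,
    vx = x$vx[keep], vy = x$vy[keep], speed = x$speed[keep],
    angle_deg = atan2(x$vy[keep], x$vx[keep]) * 180 / pi,
    residual_ms = x$residual_ms[keep]
  )
}

#' Longitudinal and transversal conduction velocity
#'
#' Averages vector speeds whose propagation direction lies within
#' `tolerance_deg` of the fiber long axis (longitudinal CV) or of its
#' perpendicular (transversal CV). Vectors pointing opposite an axis
#' count toward it: a centrally paced wave propagates outward both ways.
#' The sector average is a trimmed mean: inverting a noisy gradient
#' produces a heavy right tail of spurious speeds, and trimming removes
#' its bias without the fragility of a plain mean.
#'
#' @param field an `omr_velocity_field`.
#' @param axis_angle fiber long-axis direction, degrees (y up).
#' @param tolerance_deg angular half-width of each axis sector.
#' @param trim fraction trimmed from each tail of the speed
#'   distribution before averaging.
#' @return List with `cv_long`, `cv_trans` (cm/s; `NA` with a warning if
#'   no vector falls in a sector), `n_long`, `n_trans`.
#' @export
extract_axis_cv <- function(field, axis_angle, tolerance_deg = 15,
                            trim = 0.2) {
  tv <- tidy(field)
  if (nrow(tv) == 0L) stop_argument("Empty velocity field.")
  axis_dist <- function(angles, axis) {
    d <- abs(((angles - axis) + 90) %% 180 - 90)
    d
  }
  sel_l <- axis_dist(tv$angle_deg, axis_angle) <= tolerance_deg
  sel_t <- axis_dist(tv$angle_deg, axis_angle + 90) <= tolerance_deg
  cv_l <- if (any(sel_l)) mean(tv$speed[sel_l], trim = trim) else NA_real_
  cv_t <- if (any(sel_t)) mean(tv$speed[sel_t], trim = trim) else NA_real_
  if (!any(sel_l) || !any(sel_t)) {
    rlang::warn("No vectors within tolerance of one or both axes.",
                class = "omapr_empty_axis_warning")
  }
  list(cv_long = cv_l, cv_trans = cv_t,
       n_long = sum(sel_l), n_trans = sum(sel_t))
}

#' Assemble a restitution curve
#'
#' Collects per-PCL summaries (as produced by [analyze_conditioned()] or
#' [run_pipeline()]) into a rate-dependence table of APD80 and axis
#' conduction velocities.
#'
#' @param summaries a list of per-PCL summary lists (each with at least
#'   `pcl` and `apd80_mean`; optionally `apd80_sd`, `cv_long`,
#'   `cv_trans`), or a data frame with those columns.
#' @return An `omr_restitution` tibble sorted by decreasing PCL.
#' @export
build_restitution <- function(summaries) {
  if (is.data.frame(summaries)) {
    df <- tibble::as_tibble(summaries)
  } else {
    if (length(summaries) < 1L) stop_argument("Need at least one per-PCL summary.")
    df <- dplyr::bind_rows(lapply(summaries, function(s) {
      tibble::tibble(pcl = s$pcl,
                     apd80_mean = s$apd80_mean,
                     apd80_sd = s$apd80_sd %||% NA_real_,
                     cv_long = s$cv_long %||% NA_real_,
                     cv_trans = s$cv_trans %||% NA_real_,
                     n_pixels = s$n_pixels %||% NA_integer_)
    }))
  }
  if (anyDuplicated(df$pcl)) stop_argument("Duplicate PCL entries in restitution input.")
  df <- dplyr::arrange(df, dplyr::desc(.data$pcl))
  class(df) <- c("omr_restitution", class(df))
  df
}

#' Plot a restitution curve
#'
#' @param object an `omr_restitution`.
#' @param ... unused.
#' @return A ggplot of APD80 against PCL (and CV where present).
#' @method autoplot omr_restitution
#' @export
autoplot.omr_restitution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$pcl, y = .data$apd80_mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "pacing cycle length (ms)", y = "mean APD80 (ms)")
}

#' Mask-aware gaussian smoothing of a per-pixel map
#'
#' Smooths a scalar map with a normalized, truncated 2-D gaussian while
#' respecting undefined pixels: values are averaged with weights
#' renormalized over the defined neighbors only (normalized
#' convolution), and undefined pixels stay undefined. Used to suppress
#' activation-marker jitter before conduction-velocity fitting; in the
#' interior, gaussian smoothing leaves the gradient of any quadratic
#' surface unchanged.
#'
#' @param map an `omr_map` or numeric matrix (NA = undefined).
#' @param window odd kernel size, pixels.
#' @param sigma gaussian SD, pixels.
#' @return Same type as the input, smoothed.
#' @export
smooth_map <- function(map, window = 5L, sigma = (window - 1) / 4) {
  v <- if (inherits(map, "omr_map")) map$values else map
  def <- is.finite(v)
  filled <- ifelse(def, v, 0)
  dim(filled) <- dim(v)
  wts <- matrix(as.numeric(def), nrow(v), ncol(v))
  num <- spatial_gaussian_filter(filled, window, sigma)
  den <- spatial_gaussian_filter(wts, window, sigma)
  out <- ifelse(def & den > 0, num / den, NA_real_)
  dim(out) <- dim(v)
  if (inherits(map, "omr_map")) {
    map$values <- out
    map
  } else out
}
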