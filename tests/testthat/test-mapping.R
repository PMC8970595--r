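test_that("activation detection follows the max-derivative marker", {
  dt <- 1000 / 977
  # ideal step at frame 30: activation between frames 29 and 30
  step <- c(rep(0, 29), rep(1, 70))
  expect_equal(detect_activation(step, 977), 28.5 * dt, tolerance = 1e-9)

  # constant-derivative ramp (exactly representable steps): earliest tie wins
  ramp <- c(rep(0, 10), (0:16) / 16, rep(1, 30))
  expect_equal(detect_activation(ramp, 977), 11 * dt, tolerance = dt)

  # flat trace: excluded, not an error
  expect_true(is.na(detect_activation(rep(2, 50), 977)))

  # parabolic refinement recovers sub-frame timing of a smooth upstroke
  t <- (0:120) * dt
  v <- 1 / (1 + exp(-(t - 40.3) / 1.2))
  act <- detect_activation(v, 977)
  expect_equal(act, 40.3, tolerance = 0.3)
})

test_that("APD80 matches closed forms on canonical traces", {
  fr <- 1000; dt <- 1
  # square pulse of duration 25 ms
  pulse <- c(rep(0, 20), rep(1, 25), rep(0, 60))
  act <- detect_activation(pulse, fr)
  apd <- compute_apd80(pulse, act, 0, fr)
  expect_equal(apd, 25, tolerance = 1 + 1e-9)

  # exponential repolarization, tau = 20 ms: crossing at tau ln 5 after peak
  tau <- 20
  tr <- c(rep(0, 15), exp(-(0:150) / tau))
  act2 <- detect_activation(tr, fr)
  apd2 <- compute_apd80(tr, act2, 0, fr)
  peak_to_cross <- tau * log(5)
  expect_equal(apd2, peak_to_cross + (15.5 - 14.5), tolerance = 1.2)

  # unrepolarized pixel flagged, not an error
  plateau <- c(rep(0, 10), rep(1, 60))
  expect_true(is.na(compute_apd80(plateau, detect_activation(plateau, fr), 0, fr)))
})

test_that("APD80 is invariant to affine intensity rescaling", {
  set.seed(81)
  fr <- 977
  tpl <- ap_template(apd80 = 35)
  tr <- make_ap_trace(tpl, pcl = 150, frame_rate = fr)$v
  act <- detect_activation(tr, fr)
  base <- compute_apd80(tr, act, 0, fr)
  for (i in 1:5) {
    gain <- runif(1, 0.1, 50); offset <- runif(1, -100, 100)
    scaled <- gain * tr + offset
    expect_equal(compute_apd80(scaled, detect_activation(scaled, fr),
                               offset, fr),
                 base, tolerance = 1e-9)
  }
})

test_that("IQR exclusion reproduces the worked example and edge rules", {
  out <- exclude_outliers_iqr(c(10, 11, 12, 12, 13, 50))
  expect_equal(out$bounds, c(9, 15))
  expect_identical(out$retained, c(10, 11, 12, 12, 13))
  expect_identical(out$n_excluded, 1L)
  # quartiles by linear interpolation between order statistics
  expect_equal(stats::quantile(c(10, 11, 12, 12, 13, 50), 0.25,
                               names = FALSE), 11.25)

  same <- exclude_outliers_iqr(rep(7, 10))
  expect_identical(same$n_excluded, 0L)
  expect_identical(same$retained, rep(7, 10))

  few <- exclude_outliers_iqr(c(1, 2, 100))
  expect_null(few$bounds)
  expect_identical(few$retained, c(1, 2, 100))

  # retained values always lie within the computed bounds (property)
  set.seed(91)
  for (i in 1:10) {
    x <- rnorm(50, sd = runif(1, 0.1, 30)) + rt(50, df = 2)
    o <- exclude_outliers_iqr(x)
    expect_true(all(o$retained >= o$bounds[1] & o$retained <= o$bounds[2]))
  }
})

test_that("the velocity fit is exact on polynomial activation surfaces", {
  px <- 0.1
  co <- outer(rep(1, 41), 1:41)   # column index
  ro <- outer(1:41, rep(1, 41))   # row index
  x <- (co - 21) * px; y <- -(ro - 21) * px

  # plane wave along +x at 0.5 mm/ms: T = x / 0.5
  plane <- x / 0.5
  f <- fit_cv_bayly(plane, px)
  inner <- 5:37
  expect_equal(max(abs(f$speed[inner, inner] - 50)), 0, tolerance = 1e-6)
  expect_equal(max(abs(f$vx[inner, inner] - 50)), 0, tolerance = 1e-6)
  expect_equal(max(abs(f$vy[inner, inner])), 0, tolerance = 1e-6)
  expect_lt(max(f$residual_ms, na.rm = TRUE), 1e-9)

  # generic quadratic surface: gradient reproduced exactly at every centre
  quad <- 2 + 0.3 * x - 0.8 * y + 0.1 * x^2 - 0.05 * x * y + 0.2 * y^2
  fq <- fit_cv_bayly(quad, px, residual_threshold_ms = Inf)
  gx <- 0.3 + 0.2 * x - 0.05 * y
  gy <- -0.8 - 0.05 * x + 0.4 * y
  g2 <- gx^2 + gy^2
  expect_equal(fq$vx[inner, inner], (100 * gx / g2)[inner, inner],
               tolerance = 1e-6)
  expect_equal(fq$vy[inner, inner], (100 * gy / g2)[inner, inner],
               tolerance = 1e-6)
})

test_that("the velocity fit recovers the elliptical wave away from the source", {
  m <- wave_model(c(61, 61), v_long = 0.51, v_trans = 0.29,
                  long_axis_angle = 0)
  act <- compute_activation_field(m, c(121, 121), pixel_size = 0.035)
  f <- fit_cv_bayly(act, 0.035)
  # on-axis pixels at least 22 px (0.77 mm) from the source
  long_cols <- c(10:39, 83:112)
  sp_long <- f$speed[61, long_cols]
  expect_lt(max(abs(sp_long - 51) / 51), 0.02)
  sp_trans <- f$speed[c(10:39, 83:112), 61]
  expect_lt(max(abs(sp_trans - 29) / 29), 0.02)
  axis <- extract_axis_cv(f, axis_angle = 0)
  expect_equal(axis$cv_long, 51, tolerance = 0.03)
  expect_equal(axis$cv_trans, 29, tolerance = 0.03)
})

test_that("activation noise leaves the median speed within 5%", {
  set.seed(101)
  px <- 0.5                       # coarse map: gradient well resolved
  co <- outer(rep(1, 41), 1:41); ro <- outer(1:41, rep(1, 41))
  x <- (co - 21) * px
  plane <- x / 0.5 + rnorm(41 * 41, sd = 0.5)
  dim(plane) <- c(41, 41)
  f <- fit_cv_bayly(plane, px, residual_threshold_ms = Inf)
  expect_lt(abs(median(f$speed, na.rm = TRUE) - 50) / 50, 0.05)
})

test_that("masked and degenerate neighborhoods are handled", {
  px <- 0.1
  co <- outer(rep(1, 21), 1:21); ro <- outer(1:21, rep(1, 21))
  plane <- ((co - 11) * px) / 0.5
  plane[, 14:21] <- NA            # mask edge
  f <- fit_cv_bayly(plane, px)
  expect_true(all(is.na(f$speed[, 14:21])))
  # boundary pixels near the mask edge still get partial-window fits
  expect_true(all(is.finite(f$speed[5:17, 12])))
  expect_equal(f$speed[10, 12], 50, tolerance = 1e-6)

  # too few defined neighbors: undefined, no error
  sparse <- matrix(NA_real_, 21, 21)
  sparse[11, 11] <- 1; sparse[11, 12] <- 2; sparse[12, 11] <- 3
  fs <- fit_cv_bayly(sparse, px)
  expect_true(all(is.na(fs$speed)))

  expect_error(fit_cv_bayly(plane, px, window = 4),
               class = "omapr_argument_error")
})

test_that("axis extraction splits longitudinal and transversal sectors", {
  field <- structure(list(
    vx = matrix(c(50, 0, 40, NA), 2, 2),
    vy = matrix(c(0, 30, 0.0001, NA), 2, 2),
    speed = matrix(c(50, 30, 40, NA), 2, 2),
    residual_ms = matrix(0, 2, 2), window = 7L, order = 2L,
    residual_threshold_ms = 2, pixel_size = 0.1),
    class = "omr_velocity_field")
  out <- extract_axis_cv(field, axis_angle = 0, trim = 0)
  expect_equal(out$cv_long, 45)         # the two +x vectors
  expect_equal(out$cv_trans, 30)        # the +y vector
  expect_identical(out$n_long, 2L)

  # opposite-pointing vectors fold onto the same axis
  field$vx <- matrix(c(-50, 0, -40, NA), 2, 2)
  out2 <- extract_axis_cv(field, axis_angle = 0, trim = 0)
  expect_equal(out2$cv_long, 45)

  empty <- field; empty$speed[] <- NA
  expect_error(extract_axis_cv(empty, 0), class = "omapr_argument_error")

  # no vector within tolerance of the transversal axis: NA with warning
  field$vy <- matrix(0, 2, 2); field$vx <- matrix(c(50, 40, 45, NA), 2, 2)
  field$speed <- abs(field$vx)
  expect_warning(out3 <- extract_axis_cv(field, 0, trim = 0),
                 class = "omapr_empty_axis_warning")
  expect_true(is.na(out3$cv_trans))
})

test_that("mask-aware smoothing preserves quadratic gradients inside the mask", {
  px <- 1
  co <- outer(rep(1, 31), 1:31); ro <- outer(1:31, rep(1, 31))
  x <- (co - 16) * px; y <- -(ro - 16) * px
  quad <- 1 + 0.5 * x - 0.2 * y + 0.03 * x^2
  sm <- smooth_map(quad, 5)
  # interior gradient unchanged (constant offset allowed)
  inner <- 6:26
  gx <- (sm[16, 7:27] - sm[16, 5:25]) / 2
  expect_equal(gx, 0.5 + 0.03 * 2 * x[16, 6:26], tolerance = 1e-6)
  # NA pixels stay NA; defined pixels stay defined
  quad[3, 3] <- NA
  sm2 <- smooth_map(quad, 5)
  expect_true(is.na(sm2[3, 3]))
  expect_false(anyNA(sm2[-3, ]))
})

test_that("restitution assembly sorts, validates and plots", {
  r <- build_restitution(list(
    list(pcl = 80, apd80_mean = 21, cv_long = 46, cv_trans = 24),
    list(pcl = 150, apd80_mean = 40, apd80_sd = 2, cv_long = 51, cv_trans = 29)
  ))
  expect_s3_class(r, "omr_restitution")
  expect_identical(r$pcl, c(150, 80))
  expect_equal(r$apd80_mean, c(40, 21))

  single <- build_restitution(list(list(pcl = 150, apd80_mean = 40)))
  expect_identical(nrow(single), 1L)

  expect_error(build_restitution(list(list(pcl = 150, apd80_mean = 40),
                                      list(pcl = 150, apd80_mean = 41))),
               class = "omapr_argument_error")

  p <- ggplot2::autoplot(r)
  expect_s3_class(p, "ggplot")
})
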