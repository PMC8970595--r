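test_that("the spatial gaussian kernel is normalized and matches closed form", {
  # constant frames are fixed points of a normalized kernel
  const <- matrix(7.5, 20, 20)
  expect_equal(spatial_gaussian_filter(const, 5, 1), const)

  # unit impulse: centre weight is the squared separable centre weight
  w1 <- exp(-(-2:2)^2 / 2); w1 <- w1 / sum(w1)   # 0.0545 0.2442 0.4026 ...
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  out <- spatial_gaussian_filter(imp, 5, 1)
  expect_equal(out[11, 11], w1[3]^2, tolerance = 1e-6)
  expect_equal(out[11, 11], 0.1621, tolerance = 1e-3)
  expect_equal(out[11, 13], w1[3] * w1[5], tolerance = 1e-6)
  expect_equal(sum(out), 1, tolerance = 1e-12)

  expect_error(spatial_gaussian_filter(imp, 4, 1), class = "omapr_argument_error")
  expect_error(spatial_gaussian_filter(imp, 23, 1), class = "omapr_argument_error")
})

test_that("5x5 binning reduces white-noise SD about 3.48-fold", {
  set.seed(21)
  noise <- matrix(rnorm(300 * 300), 300, 300)
  filt <- spatial_gaussian_filter(noise, 5, 1)
  w1 <- exp(-(-2:2)^2 / 2); w1 <- w1 / sum(w1)
  expected <- 1 / sum(w1^2)                     # per axis, squared for 2-D
  inner <- filt[11:290, 11:290]
  expect_equal(sd(noise) / sd(inner), expected^1, tolerance = 0.05)
  expect_equal(expected, 3.48, tolerance = 1e-2)
})

test_that("the spatial filter is linear and shift-equivariant", {
  set.seed(31)
  a <- matrix(rnorm(18 * 18), 18, 18)
  b <- matrix(rnorm(18 * 18), 18, 18)
  expect_equal(spatial_gaussian_filter(2 * a + 3 * b, 5, 1),
               2 * spatial_gaussian_filter(a, 5, 1) +
                 3 * spatial_gaussian_filter(b, 5, 1),
               tolerance = 1e-12)
  # interior response to a shifted image is the shifted response
  sh <- rbind(a[-1, ], a[1, ])
  f1 <- spatial_gaussian_filter(a, 3, 0.5)
  f2 <- spatial_gaussian_filter(sh, 3, 0.5)
  expect_equal(f2[3:14, 3:16], f1[4:15, 3:16], tolerance = 1e-12)
})

test_that("beat segmentation finds every complete cycle in the window", {
  # 2 s at PCL 150 holds 13 complete beats
  tpl <- ap_template(apd80 = 40)
  tr <- make_ap_trace(tpl, pcl = 150, frame_rate = 977, n_beats = 14)
  g <- 600 * (1 - 0.08 * tr$v[1:1954])          # inverted-polarity global signal
  beats <- segment_beats(g, pcl = 150, frame_rate = 977,
                         ensemble_window_ms = 2000)
  expect_identical(beats$n_beats, 13L)
  expect_identical(beats$frames_per_beat, 147L)
  # detected onsets sit on the stimulus grid (10 + k * 150 ms) within 3 frames
  stim_frames <- (10 + (0:12) * 150) / (1000 / 977) + 1
  expect_true(all(abs(beats$onsets - stim_frames) <= 3))

  expect_error(segment_beats(g[1:90], 150, 977),
               class = "omapr_segmentation_error")
  expect_error(segment_beats(rep(5, 2000), 150, 977),
               class = "omapr_segmentation_error")
})

test_that("segmentation locks onto the simulator's pacing grid", {
  sc <- small_scenario()
  sim <- simulate_scenario(sc)
  beats <- segment_beats(sim$recording, 150, 977)
  expect_gte(beats$n_beats, 3L)
  # onsets trail the stimuli by one constant delay: the phases agree to a frame
  onset_ms <- (beats$onsets - 1) * 1000 / 977
  expect_lt(diff(range(onset_ms %% 150)), 1000 / 977 + 1e-9)
})

test_that("ensemble averaging obeys its identities", {
  set.seed(41)
  beat <- matrix(rnorm(50 * 30), 50, 30)
  avg <- ensemble_average(list(beat, beat, beat))
  expect_equal(avg$traces, beat)
  expect_identical(avg$n_beats_averaged, 3L)

  one <- ensemble_average(list(beat))
  expect_equal(one$traces, beat)
  expect_identical(one$n_beats_averaged, 1L)

  expect_error(ensemble_average(list(beat, beat[, 1:10])),
               class = "omapr_argument_error")
  expect_error(ensemble_average(list()), class = "omapr_argument_error")
})

test_that("averaging 13 noisy beats shrinks noise like the square root", {
  set.seed(51)
  sigma <- 3
  npix <- 900; fpb <- 40; nb <- 13
  clean <- matrix(rep(sin(seq_len(fpb) / 5), each = npix), npix, fpb)
  movie <- matrix(0, npix, fpb * nb)
  for (b in seq_len(nb)) {
    movie[, (b - 1) * fpb + seq_len(fpb)] <- clean + rnorm(npix * fpb, sd = sigma)
  }
  dim(movie) <- c(30, 30, fpb * nb)
  beats <- structure(list(onsets = (0:(nb - 1)) * fpb + 1L,
                          starts = (0:(nb - 1)) * fpb + 1L,
                          frames_per_beat = fpb, pre_frames = 0L,
                          n_beats = nb, frame_rate = 1000, pcl = fpb),
                     class = "omr_beats")
  avg <- ensemble_average(movie, beats)
  resid <- movie_residual <- avg$traces - array(clean, c(30, 30, fpb))
  expect_equal(sd(resid), sigma / sqrt(nb), tolerance = 0.15)
})

test_that("normalization inverts polarity and is scale-invariant", {
  t <- seq(0, 1, length.out = 80)
  v <- exp(-((t - 0.4) / 0.1)^2)               # upstroke-positive shape
  inv <- 200 - 100 * v                          # dye-like inverted trace
  out <- normalize_invert(inv, resting = 200)
  expect_gte(min(out$traces), 0)
  expect_lt(min(out$traces), 1e-4)
  expect_equal(max(out$traces), 1, tolerance = 1e-9)
  expect_gt(out$traces[which.max(v)], 0.99)

  # amplitude 1 independent of baseline and fractional amplitude
  for (B in c(300, 900)) for (alpha in c(0.03, 0.2)) {
    tr2 <- B * (1 - alpha * v)
    o2 <- normalize_invert(tr2, resting = B)
    expect_equal(o2$traces, v / max(v), tolerance = 1e-12)
  }

  dead <- normalize_invert(rep(5, 30), resting = 5)
  expect_true(dead$dead)
  expect_true(all(is.na(dead$traces)))
})

test_that("SNR follows the RMS amplitude over RMS diastolic noise definition", {
  set.seed(61)
  n_beat <- 40000; n_dia <- 20000
  signal <- rep(c(2, -2), length.out = n_beat)   # clean RMS exactly 2
  trace <- c(signal, numeric(n_dia)) + rnorm(n_beat + n_dia, sd = 1)
  snr <- compute_snr(trace, seq_len(n_beat), n_beat + seq_len(n_dia),
                     resting = 0)
  expect_equal(snr, 2, tolerance = 0.03)

  # noiseless trace: the defined sentinel is infinite
  expect_identical(compute_snr(c(1, 2, 1, 0, 0, 0, 0), 1:4, 5:7, 0), Inf)

  expect_error(compute_snr(trace, 1:10, 1:2, 0),
               class = "omapr_computation_error")
})

test_that("resting-level estimation matches its definition and kernel size", {
  expect_equal(estimate_resting_level(rep(3.25, 200), 977), 3.25)

  # sigma = 7 ms at 977 FPS: radius ceil(4 * 6.839) = 28, 57 taps
  sigma <- 7 * 977 / 1000
  expect_identical(as.integer(ceiling(4 * sigma)), 28L)
  expect_error(estimate_resting_level(rnorm(56), 977),
               class = "omapr_argument_error")

  # matrix fast path is the smooth-then-average identity
  set.seed(71)
  M <- matrix(rnorm(6 * 300), 6, 300)
  dia <- 200:260
  fast <- estimate_resting_level(M, 977, diastole_idx = dia)
  slow <- vapply(seq_len(6), function(i) {
    sm <- omapr:::smooth_gaussian_time(M[i, ], 977)
    mean(sm[dia])
  }, numeric(1))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("masking applies SNR, intensity and saturation cutoffs", {
  params <- conditioning_params(pcl = 150, snr_cutoff = 2,
                                intensity_cutoff = 100)
  snr <- matrix(c(3, 1, 3, 3), 2, 2)
  intensity <- matrix(c(200, 200, 50, 1020), 2, 2)
  mask <- build_mask(snr, intensity, params, bits_per_sample = 10)
  expect_identical(mask$values, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_identical(mask$provenance$snr_cutoff, 2)

  expect_warning(
    build_mask(snr, intensity, conditioning_params(150, intensity_cutoff = 5000)),
    class = "omapr_empty_mask_warning"
  )
  expect_error(build_mask(snr, intensity[1, , drop = FALSE], params),
               class = "omapr_argument_error")
})

test_that("the mask recovers the analytic vignette disc", {
  noise <- noise_model(baseline_intensity = 600, vignette_strength = 0.3)
  B <- baseline_image(noise, c(80, 80))
  cutoff <- 520
  params <- conditioning_params(150, snr_cutoff = 0, intensity_cutoff = cutoff)
  mask <- build_mask(matrix(10, 80, 80), B, params)
  # analytic disc radius: (1-s) + s cos(pi/2 r/rmax) = cutoff/600
  rmax <- sqrt(2) * (80 - 81 / 2 + 0.5)
  r_disc <- rmax * 2 / pi * acos((cutoff / 600 - 0.7) / 0.3)
  cr <- (80 + 1) / 2
  d <- sqrt(outer((1:80 - cr)^2, (1:80 - cr)^2, `+`))
  expect_true(all(mask$values[d <= r_disc - 1]))
  expect_true(!any(mask$values[d >= r_disc + 1]))
})

test_that("conditioning raises SNR over the raw recording", {
  sc <- small_scenario()
  sim <- simulate_scenario(sc)
  cond <- condition_recording(sim$recording, sc$params)
  m <- cond$mask$values
  expect_gt(sum(m), 1000)
  raw_mean <- mean(cond$snr_raw$values[m])
  cond_mean <- mean(cond$snr_conditioned$values[m])
  expect_gt(cond_mean, raw_mean)
  # per-pixel paired comparison holds on average, not just in the mean
  expect_gt(mean(cond$snr_conditioned$values[m] > cond$snr_raw$values[m]), 0.95)
})

test_that("ensemble averaging a noiseless movie is idempotent", {
  # integer frames per cycle so every beat is sampled at the same phase
  sc <- small_scenario(shape = c(24, 24), duration_ms = 650, noise_sd = 0,
                       frame_rate = 1000)
  sim <- simulate_scenario(sc)
  beats <- segment_beats(sim$recording, 150, 1000)
  avg <- ensemble_average(sim$recording$frames, beats)
  first <- sim$recording$frames[, , beats$starts[1] + 0:(beats$frames_per_beat - 1)]
  # beats are identical up to integer quantization of the < 0.1-count
  # diastolic tail, so the ensemble average reproduces any single beat
  expect_lt(max(abs(avg$traces - first)), 1)
  expect_lt(mean(abs(avg$traces - first)), 0.05)
})
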