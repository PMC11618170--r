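test_that("ROI time curves average exactly over the membership mask", {
  fr <- array(0, dim = c(4, 16, 16))
  for (k in 1:4) fr[k, , ] <- k * 2
  ser <- image_series(fr, 1, (1:4) * 1.8)
  cur <- extract_time_curve(ser, roi_spec(c(8, 8), 3))
  expect_equal(cur$s_raw, c(2, 4, 6, 8))
  # radius below half a pixel: single-pixel trace
  fr[, 9, 9] <- 99
  ser1 <- image_series(fr, 1, (1:4) * 1.8)
  cur1 <- extract_time_curve(ser1, roi_spec(c(8, 8), 0.4))
  expect_equal(cur1$s_raw, rep(99, 4))
  expect_error(extract_time_curve(ser, roi_spec(c(1, 1), 3)), "bounds")
})

test_that("a noise-free phantom ROI curve reproduces the bolus model", {
  cfg <- phantom_config(matrix = c(32, 32), pixel_mm = 2, n_frames = 24,
                        frame_dt_s = 1.8,
                        vessels = list(vessel_spec("AA", c(0, 0), 16, 100,
                                                   400, bolus_params(9, 3, 7))),
                        noise_sigma = 0, edge_blur_sigma_mm = 0, seed = 1)
  ph <- generate_phantom(cfg)
  ser <- image_series(ph$movie, 2, ph$frame_times_s + 1e-9)
  ser$frame_times_s <- ph$frame_times_s
  cur <- extract_time_curve(ser, roi_spec(c(16, 16), 3))
  expected <- 100 + 400 * bolus_curve(ph$frame_times_s, bolus_params(9, 3, 7))
  expect_lt(max(abs(cur$s_raw - expected)), 1e-6)
})

test_that("preprocessing is the identity at factor 1 / window 1 and
           reduces noise variance otherwise", {
  tc <- time_curve((0:20) * 1.8, sin((0:20) / 3) + 2)
  pre <- preprocess_curve(tc, interp_factor = 1, window = 1)
  rng <- range(tc$s_raw)
  expect_equal(pre$s_norm, (tc$s_raw - rng[1]) / diff(rng))
  # peak location of an interpolated gamma variate within 0.2 s of truth
  ts <- (0:39) * 1.8
  cur <- time_curve(ts, gamma_variate(ts, 9, 3, 7))
  pre2 <- preprocess_curve(cur)
  expect_lt(abs(pre2$t_s[which.max(pre2$s_norm)] - 16), 0.2)
  # Monte Carlo: smoothing reduces variance of added noise
  set.seed(3)
  worse <- 0
  for (r in 1:100) {
    noisy <- time_curve(ts, gamma_variate(ts, 9, 3, 7) + rnorm(40, sd = 0.05))
    raw <- preprocess_curve(noisy, 10, 1)
    smo <- preprocess_curve(noisy, 10, 5)
    resid <- function(p) {
      clean <- gamma_variate(p$t_s, 9, 3, 7)
      clean <- (clean - min(clean)) / diff(range(clean))
      var(p$s_norm - clean)
    }
    if (resid(smo) >= resid(raw)) worse <- worse + 1
  }
  expect_lt(worse, 20)
  expect_error(preprocess_curve(time_curve(1:4, rep(1, 4)), 1, 1), "constant")
})

test_that("FWHM of canonical shapes matches closed forms", {
  tri <- preprocess_curve(time_curve(seq(0, 2, by = 0.01),
                                     1 - abs(seq(0, 2, by = 0.01) - 1)),
                          1, 1)
  expect_equal(curve_fwhm(tri), 1, tolerance = 1e-6)
  t <- seq(-10, 30, by = 0.2)
  gau <- preprocess_curve(time_curve(t, exp(-(t - 8)^2 / (2 * 4))), 10, 1)
  expect_equal(curve_fwhm(gau), 2 * sqrt(2 * log(2)) * 2, tolerance = 1e-3)
  # gamma variate sampled at 1.8 s recovers the dense-grid oracle within 1%
  ts <- seq(0, 70.2, by = 1.8)
  for (a in c(2, 3)) {
    cur <- preprocess_curve(time_curve(ts, gamma_variate(ts, 9, a, 7)))
    expect_equal(curve_fwhm(cur), oracle_gamma_fwhm(a, 7),
                 tolerance = 0.01)
  }
  flat <- preprocess_curve(time_curve(ts, pmin(ts / 10, 1)), 1, 1)
  expect_error(curve_fwhm(flat), "downward|half")
})

test_that("max upslope matches ramps and the dense-grid gamma oracle", {
  ramp <- preprocess_curve(time_curve(seq(0, 10, 0.5),
                                      seq(0, 10, 0.5) / 10), 1, 1)
  expect_equal(curve_maxslope(ramp), 0.1, tolerance = 1e-9)
  ramp5 <- preprocess_curve(time_curve(seq(0, 5, 0.25),
                                       seq(0, 5, 0.25) / 5), 1, 1)
  expect_equal(curve_maxslope(ramp5), 2 * curve_maxslope(ramp),
               tolerance = 1e-9)
  # frozen dense-grid analytic value for alpha = 3, tp = 6 (1 ms grid)
  ts <- seq(0, 60, by = 0.5)
  cur <- preprocess_curve(time_curve(ts, gamma_variate(ts, 0, 3, 6)), 10, 1)
  expect_equal(curve_maxslope(cur), 0.291468, tolerance = 0.02 * 0.291468)
})

test_that("vessel sharpness resolves step and Gaussian edges", {
  x <- seq(0, 10, by = 0.05)
  step <- profile_curve(x, as.numeric(x >= 5) * 80 + 10)
  vs_step <- vessel_sharpness(step)
  expect_lte(vs_step$d_mm, 0.05)
  expect_gte(vs_step$vs_per_mm, 20)
  gauss <- profile_curve(x, pnorm((x - 5) / 1.0))
  vs_g <- vessel_sharpness(gauss)
  expect_equal(vs_g$d_mm, 1.6832, tolerance = 0.02 * 1.6832)
  expect_equal(vs_g$vs_per_mm, 0.594, tolerance = 0.02 * 0.594)
  expect_equal(vs_g$d_mm, true_edge_width(1.0), tolerance = 0.02)
  # affine intensity transforms leave (vs, d) unchanged
  aff <- profile_curve(x, 3.7 * pnorm((x - 5) / 1.0) + 42)
  vs_a <- vessel_sharpness(aff)
  expect_equal(vs_a$d_mm, vs_g$d_mm)
  # falling edge is handled symmetrically
  fall <- profile_curve(x, pnorm((5 - x) / 1.0))
  expect_equal(vessel_sharpness(fall)$d_mm, vs_g$d_mm, tolerance = 1e-6)
  expect_error(vessel_sharpness(profile_curve(x, rep(1, length(x)))), "flat")
  expect_error(vessel_sharpness(profile_curve(c(0, 1), c(0, 1))), "short")
})

test_that("vs times d equals one for every successful measurement", {
  set.seed(5)
  x <- seq(0, 12, by = 0.05)
  for (r in 1:20) {
    sigma <- runif(1, 0.3, 3)
    prof <- profile_curve(x, pnorm((x - 6) / sigma) * runif(1, 50, 500))
    out <- vessel_sharpness(prof)
    expect_equal(out$vs_per_mm * out$d_mm, 1, tolerance = 1e-12)
  }
})

test_that("profiles extracted from images follow the pixel data", {
  img <- outer(rep(1, 32), pnorm(((0:31) - 16) / 2))   # x-direction edge
  pr <- extract_profile(img, from_px = c(16, 4), to_px = c(16, 28),
                        pixel_mm = 1.5)
  expect_true(all(diff(pr$positions_mm) > 0))
  expect_lte(max(diff(pr$positions_mm)), 0.5 * 1.5 + 1e-9)
  out <- vessel_sharpness(pr)
  expect_equal(out$d_mm, true_edge_width(2) * 1.5, tolerance = 0.05)
  expect_error(extract_profile(img, c(4, 4), c(4, 4), 1), "degenerate")
})

test_that("subtraction SNR recovers the true ratio and scales exactly", {
  set.seed(9)
  reps <- 200
  est <- numeric(reps)
  for (r in 1:reps) {
    fr <- array(rnorm(8 * 32 * 32, mean = 100, sd = 10), c(8, 32, 32))
    ser <- image_series(fr, 1, (1:8) * 1.8)
    est[r] <- snr_subtraction(ser, roi_spec(c(16, 16), 13), 5)
  }
  se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - 10), 3 * se)
  # doubling the analysed frame's intensity doubles SNR exactly (the
  # noise estimate comes from the unchanged pre-bolus frames)
  fr <- array(rnorm(8 * 32 * 32, 100, 10), c(8, 32, 32))
  fr2 <- fr; fr2[5, , ] <- 2 * fr2[5, , ]
  s1 <- snr_subtraction(image_series(fr, 1, (1:8) * 1.8),
                        roi_spec(c(16, 16), 10), 5)
  s2 <- snr_subtraction(image_series(fr2, 1, (1:8) * 1.8),
                        roi_spec(c(16, 16), 10), 5)
  expect_equal(s2, 2 * s1)
  # signal-free series: SNR near zero
  set.seed(10)
  noise_only <- array(rnorm(8 * 32 * 32, 0, 10), c(8, 32, 32))
  s0 <- snr_subtraction(image_series(noise_only, 1, (1:8) * 1.8),
                        roi_spec(c(16, 16), 13), 5)
  expect_lt(abs(s0), 0.2)
  # noiseless input is flagged, not infinite
  expect_error(snr_subtraction(image_series(array(7, c(5, 8, 8)), 1,
                                            (1:5) * 1.8),
                               roi_spec(c(4, 4), 2), 4), "noiseless")
})

test_that("compute_metrics assembles a per-ROI report", {
  cfg <- dynamic_config(noise_sigma = 2, n = 64, seed = 12)
  ph <- generate_phantom(cfg)
  ser <- image_series(ph$movie, cfg$pixel_mm, ph$frame_times_s + 0.9)
  rois <- list(AA = roi_spec(c(32, 32), 4))
  profiles <- list(AA = list(from_px = c(32 - 13, 32), to_px = c(32, 32),
                             wall_mm = 14))
  rep <- compute_metrics(ser, rois, profiles)
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep), 1)
  expect_equal(rep$vs_per_mm * rep$d_mm, 1, tolerance = 1e-12)
  # the default two-frame smoother broadens the measured width slightly
  expect_equal(rep$fwhm_s, true_bolus_fwhm(bolus_params(9, 3, 7)),
               tolerance = 0.05)
  expect_gte(rep$fwhm_s, true_bolus_fwhm(bolus_params(9, 3, 7)) * 0.99)
  expect_gt(rep$snr, 10)
})
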