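test_that("golden-angle spoke angles follow the 111.24611-degree increment", {
  expect_equal(golden_angle_spokes(3), c(0, 111.24611, 42.49222),
               tolerance = 1e-9)
  a <- golden_angle_spokes(1e4)
  expect_true(all(a >= 0 & a < 180))
  expect_gt(min(diff(sort(a))), 1e-6)   # all distinct to 1e-6 deg
  expect_error(golden_angle_spokes(0))
})

test_that("golden-angle windows keep near-uniform angular coverage", {
  a <- golden_angle_spokes(200)
  gap_stats <- function(w) {
    th <- sort(w)
    gaps <- diff(c(th, th[1] + 180))    # circular gaps, period 180
    c(ratio_minmax = max(gaps) / min(gaps),
      ratio_mean = max(gaps) / mean(gaps))
  }
  for (W in c(13, 21, 34)) {
    for (s in seq_len(200 - W + 1)) {
      g <- gap_stats(a[s:(s + W - 1)])
      expect_lte(g["ratio_minmax"], 2.62)
    }
  }
  # 13-spoke windows: max gap within 1.9x of the mean gap
  for (s in seq_len(200 - 12)) {
    expect_lte(gap_stats(a[s:(s + 12)])["ratio_mean"], 1.9)
  }
})

test_that("view-sharing schedule partitions lines per the 25%/33% rule", {
  sch <- build_twist_schedule(16, 7, frame_dt_s = 1.98)
  expect_length(sch$center_lines, 4)              # 25% of 16
  expect_equal(lengths(sch$periphery_subsets), c(4, 4, 4))
  all_lines <- sort(c(sch$center_lines, unlist(sch$periphery_subsets)))
  expect_identical(all_lines, 1:16)               # partition, no overlap
  # every frame acquires centre + one subset = 8 of 16 lines
  for (k in 1:7) {
    rows <- sch$frame_plan[sch$frame_plan$frame == k, ]
    expect_equal(nrow(rows), 8)
    expect_false(any(duplicated(rows$line)))
  }
  # three consecutive frames jointly acquire every line
  for (k0 in 1:5) {
    rows <- sch$frame_plan[sch$frame_plan$frame %in% k0:(k0 + 2), ]
    expect_setequal(unique(rows$line), 1:16)
  }
  # timestamps strictly increase in acquisition order
  expect_true(all(diff(sch$frame_plan$t_s) > 0))
  expect_error(build_twist_schedule(6, 2), "at least 8")
})

test_that("frame-duration arithmetic is exact and linear", {
  expect_equal(frame_duration(13, 53, 0.0026), 1.7914)
  expect_equal(round(frame_duration(13, 53, 0.0026), 1), 1.8)
  expect_equal(frame_duration(1, 1, 1), 1)
  expect_equal(frame_duration(26, 53, 0.0026),
               2 * frame_duration(13, 53, 0.0026))
  expect_error(frame_duration(0, 53, 0.0026))
})

test_that("Cartesian sampler reproduces DFT rows of a static scene", {
  ph <- generate_phantom(static_config())
  F <- stats::fft(ph$scene(0))
  sch <- build_twist_schedule(16, 3, frame_dt_s = 1.8)
  acq <- sample_cartesian(ph, sch)
  for (i in seq_len(nrow(acq$plan))) {
    u <- acq$plan$ky[i] %% 32
    expect_equal(acq$lines[i, ], F[u + 1, ], tolerance = 1e-12)
  }
})

test_that("a mid-frame enhancement step corrupts only post-step lines", {
  # step scene: vessel switches from baseline to enhanced at t = 4 s
  cfg <- phantom_config(matrix = c(16, 16), pixel_mm = 4, n_frames = 4,
                        frame_dt_s = 1.8,
                        vessels = list(vessel_spec("AA", c(0, 0), 16, 100,
                                                   300, bolus_params(50, 3, 7))),
                        noise_sigma = 0, edge_blur_sigma_mm = 3, seed = 1)
  ph <- generate_phantom(cfg)
  pre_img <- ph$scene(0); post_img <- ph$scene(60)
  step_t <- 4
  ph$scene <- function(t_s) if (t_s < step_t) pre_img else post_img
  sch <- build_twist_schedule(16, 3, frame_dt_s = 1.8)
  acq <- sample_cartesian(ph, sch)
  Fpre <- stats::fft(pre_img); Fpost <- stats::fft(post_img)
  for (i in seq_len(nrow(acq$plan))) {
    u <- acq$plan$ky[i] %% 16
    ref <- if (acq$plan$t_s[i] < step_t) Fpre else Fpost
    expect_equal(acq$lines[i, ], ref[u + 1, ], tolerance = 1e-12)
  }
})

test_that("radial sampler matches the direct-summation DFT oracle", {
  ph <- generate_phantom(static_config())
  img <- ph$scene(0)
  traj <- radial_trajectory(6, 32, spoke_dt_s = 0.01)
  acq <- sample_radial(ph, traj)
  r <- (0:31 - 16)   # n_readout = N: integer radii
  th <- traj$angles_deg * pi / 180
  for (i in 1:6) {
    o <- dft_direct(img, r * cos(th[i]), r * sin(th[i]))
    expect_lt(max(Mod(acq$samples[, i] - o)) / max(Mod(o)), 1e-6)
  }
  # spoke at 0 degrees equals the matching row of the full DFT
  F <- stats::fft(img)
  expect_equal(acq$samples[, 1], F[1, (r %% 32) + 1], tolerance = 1e-10)
  # real, centred scene: spoke magnitude symmetric about k = 0
  mag <- Mod(acq$samples[, 2])
  expect_equal(mag[2:16], rev(mag[18:32]), tolerance = 1e-6)
})

test_that("spokes with identical angle and timestamp are identical", {
  ph <- generate_phantom(static_config())
  traj <- radial_trajectory(2, 32, spoke_dt_s = 0.01)
  traj$angles_deg[2] <- traj$angles_deg[1]
  traj$timestamps_s[2] <- traj$timestamps_s[1]
  acq <- sample_radial(ph, traj)
  expect_identical(acq$samples[, 1], acq$samples[, 2])
})

test_that("sampling rejects timestamps beyond the movie duration", {
  ph <- generate_phantom(static_config())   # 4 frames x 1.8 s = 7.2 s
  expect_error(sample_cartesian(ph, build_twist_schedule(16, 10,
                                                         frame_dt_s = 1.98)),
               "duration")
  expect_error(sample_radial(ph, radial_trajectory(100, 32, spoke_dt_s = 1)),
               "duration")
})

test_that("acquisition parameter invariants are enforced", {
  expect_error(acquisition_params(tr_s = 0))
  expect_error(acquisition_params(center_fraction = 1))
  expect_error(acquisition_params(periphery_fraction = 0.6))
  expect_error(radial_trajectory(0, 32))
})
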