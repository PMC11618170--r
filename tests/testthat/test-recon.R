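test_that("view-shared recon of a static scene stabilises after 3 frames", {
  ph <- generate_phantom(static_config())
  sch <- build_twist_schedule(16, 4, frame_dt_s = 1.8)
  ser <- recon_twist(sample_cartesian(ph, sch))
  f3 <- ser$frames[3, , ]; f4 <- ser$frames[4, , ]
  expect_lt(max(abs(f4 - f3)) / max(f3), 1e-10)
  # frame 1 (centre + one subset only) carries less high-frequency energy
  cser <- recon_twist(sample_cartesian(ph, sch), magnitude = FALSE)
  hf <- function(img) {
    K <- stats::fft(img)
    sum(Mod(K[9:24, ])^2)   # outer half of ky
  }
  expect_lt(hf(cser[1, , ]), hf(cser[3, , ]))
})

test_that("complete view-shared sampling reproduces the static scene", {
  ph <- generate_phantom(static_config())
  img <- ph$scene(0)
  # schedule over all 32 lines: after 3 frames every line is acquired
  sch <- build_twist_schedule(32, 3, frame_dt_s = 1.8)
  ser <- recon_twist(sample_cartesian(ph, sch))
  expect_equal(ser$frames[3, , ], img, tolerance = 1e-10)
  # Parseval on the complete frame
  K <- stats::fft(img)
  expect_equal(sum(img^2), sum(Mod(K)^2) / 32^2, tolerance = 1e-10)
})

test_that("fully sampled radial gridding reconstructs the scene to <2% NRMSE", {
  ph <- generate_phantom(static_config())
  img <- ph$scene(0)
  traj <- radial_trajectory(51, 64, spoke_dt_s = 1e-4)   # >= pi/2 * 32
  ser <- recon_radial_gridding(sample_radial(ph, traj), spokes_per_frame = 51)
  nrmse <- sqrt(mean((ser$frames[1, , ] - img)^2)) / sqrt(mean(img^2))
  expect_lt(nrmse, 0.02)
})

test_that("undersampled radial frames of a point-like object show streaks", {
  cfg <- phantom_config(matrix = c(32, 32), pixel_mm = 2, n_frames = 4,
                        frame_dt_s = 1.8,
                        vessels = list(vessel_spec("AA", c(0, 0), 2.5, 200,
                                                   10, bolus_params(1e5, 3, 7))),
                        noise_sigma = 0, edge_blur_sigma_mm = 0.8, seed = 1)
  ph <- generate_phantom(cfg)
  traj <- radial_trajectory(51, 64, spoke_dt_s = 1e-4)
  acq <- sample_radial(ph, traj)
  full <- recon_radial_gridding(acq, spokes_per_frame = 51)$frames[1, , ]
  und <- recon_radial_gridding(acq, spokes_per_frame = 13)$frames[1, , ]
  d <- sqrt(outer((0:31 - 16)^2, (0:31 - 16)^2, "+"))
  outside <- d > 3 / 2 * 2   # beyond a 3-pixel disc around the point
  expect_gt(sum(und[outside]^2), 0)
  expect_gt(sum(und[outside]^2), sum(full[outside]^2))
})

test_that("all-zero k-space reconstructs to an all-zero image", {
  ph <- generate_phantom(static_config())
  traj <- radial_trajectory(13, 64, spoke_dt_s = 1e-4)
  acq <- sample_radial(ph, traj)
  acq$samples[] <- 0 + 0i
  ser <- recon_radial_gridding(acq, 13)
  expect_equal(max(abs(ser$frames)), 0)
})

test_that("both reconstructions are linear before the magnitude step", {
  ph1 <- generate_phantom(static_config(radius_mm = 10))
  ph2 <- generate_phantom(static_config(radius_mm = 20))
  sch <- build_twist_schedule(16, 3, frame_dt_s = 1.8)
  a1 <- sample_cartesian(ph1, sch); a2 <- sample_cartesian(ph2, sch)
  a12 <- a1; a12$lines <- a1$lines + a2$lines
  c1 <- recon_twist(a1, magnitude = FALSE)
  c2 <- recon_twist(a2, magnitude = FALSE)
  c12 <- recon_twist(a12, magnitude = FALSE)
  expect_equal(c12, c1 + c2, tolerance = 1e-8)
  traj <- radial_trajectory(13, 64, spoke_dt_s = 1e-4)
  r1 <- sample_radial(ph1, traj); r2 <- sample_radial(ph2, traj)
  r12 <- r1; r12$samples <- r1$samples + r2$samples
  g1 <- recon_radial_gridding(r1, 13, magnitude = FALSE)
  g2 <- recon_radial_gridding(r2, 13, magnitude = FALSE)
  g12 <- recon_radial_gridding(r12, 13, magnitude = FALSE)
  expect_equal(g12, g1 + g2, tolerance = 1e-8)
})

test_that("view sharing spreads one frame's data across following frames;
           radial frames stay independent", {
  ph <- generate_phantom(dynamic_config(n = 32, n_frames = 12))
  sch <- build_twist_schedule(16, 5, frame_dt_s = 1.8)
  acq <- sample_cartesian(ph, sch)
  base <- recon_twist(acq)$frames
  pert <- acq
  rows <- which(pert$plan$frame == 2 & pert$plan$block == "periphery")
  pert$lines[rows, ] <- pert$lines[rows, ] * 2
  out <- recon_twist(pert)$frames
  changed <- vapply(1:5, function(k) max(abs(out[k, , ] - base[k, , ])) > 1e-9,
                    TRUE)
  # frame 2's periphery subset is reused until re-acquired in frame 5
  expect_identical(changed, c(FALSE, TRUE, TRUE, TRUE, FALSE))
  traj <- radial_trajectory(39, 64, spoke_dt_s = 0.1)
  racq <- sample_radial(ph, traj)
  rbase <- recon_radial_gridding(racq, 13)$frames
  rpert <- racq
  rpert$samples[, 14:26] <- rpert$samples[, 14:26] * 2
  rout <- recon_radial_gridding(rpert, 13)$frames
  rchanged <- vapply(1:3, function(k)
    max(abs(rout[k, , ] - rbase[k, , ])) > 1e-9, TRUE)
  expect_identical(rchanged, c(FALSE, TRUE, FALSE))
})

test_that("streak energy is near zero for clean recons and ordered by
           undersampling", {
  ph <- generate_phantom(static_config())
  img <- ph$scene(0)
  d <- sqrt(outer((0:31 - 16)^2, (0:31 - 16)^2, "+")) * 2   # mm
  bg <- d > 10 + 8
  vessel <- d < 5
  traj <- radial_trajectory(52, 64, spoke_dt_s = 1e-4)
  acq <- sample_radial(ph, traj)
  full <- recon_radial_gridding(acq, 52)$frames[1, , ]
  expect_lt(streak_energy(full, bg, vessel), 1e-3)
  se <- vapply(c(13, 26, 52), function(spf)
    streak_energy(recon_radial_gridding(acq, spf)$frames[1, , ], bg, vessel),
    0)
  expect_true(all(diff(se) < 0))   # more spokes, fewer streaks
  expect_error(streak_energy(full, bg & FALSE, vessel), "empty")
})

test_that("image series invariants are enforced", {
  expect_error(image_series(array(0, c(2, 4, 4)), 1, c(2, 1)),
               "strictly increasing")
  expect_error(image_series(array(NA_real_, c(2, 4, 4)), 1, c(1, 2)),
               "finite")
})
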