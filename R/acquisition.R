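# golden angle in degrees, the 180/phi^2 convention
GOLDEN_ANGLE_DEG <- 111.24611

#' Acquisition parameters
#'
#' Timing and sampling-pattern parameters shared by the two simulated
#' schemes. Defaults follow a typical 1.5 T aortic CE-trMRA protocol:
#' radial TR 2.6 ms, 13 spokes per reconstructed frame, 53 partitions in
#' the (timing-only) slice direction, and a Cartesian view-sharing pattern
#' that re-acquires the central 25% of phase-encode lines every frame while
#' cycling through 33% of the periphery.
#'
#' @param tr_s repetition time per k-space line/spoke, seconds.
#' @param spokes_per_frame radial spokes grouped into one frame.
#' @param n_partitions 3D partition count; used only in the frame-duration
#'   arithmetic (the simulation itself is 2D+time, one star of the stack).
#' @param center_fraction fraction of phase-encode lines in the re-acquired
#'   central block (0 < f < 1).
#' @param periphery_fraction fraction of the remaining periphery acquired
#'   between consecutive centre acquisitions (0 < f <= 1/2).
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(tr_s = 0.0026, spokes_per_frame = 13L,
                               n_partitions = 53L, center_fraction = 0.25,
                               periphery_fraction = 0.33) {
  if (tr_s <= 0) stop("'tr_s' must be positive")
  if (spokes_per_frame < 1) stop("'spokes_per_frame' must be >= 1")
  if (center_fraction <= 0 || center_fraction >= 1)
    stop("'center_fraction' must lie in (0, 1)")
  if (periphery_fraction <= 0 || periphery_fraction > 0.5)
    stop("'periphery_fraction' must lie in (0, 1/2]")
  structure(list(tr_s = tr_s, spokes_per_frame = as.integer(spokes_per_frame),
                 n_partitions = as.integer(n_partitions),
                 center_fraction = center_fraction,
                 periphery_fraction = periphery_fraction),
            class = "acquisition_params")
}

#' Golden-angle spoke angles
#'
#' @param n number of spokes (>= 1).
#' @return numeric vector of angles in degrees,
#'   `angle[i] = ((i-1) * 111.24611) mod 180`; spokes are full diameters so
#'   angles live on `[0, 180)`.
#' @export
golden_angle_spokes <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be a positive integer")
  ((seq_len(n) - 1) * GOLDEN_ANGLE_DEG) %% 180
}

#' Frame duration arithmetic
#'
#' Temporal resolution of a stack-of-stars frame:
#' `spokes_per_frame * n_partitions * tr_s` seconds.
#'
#' @param spokes_per_frame spokes grouped into one frame.
#' @param n_partitions 3D partition count.
#' @param tr_s repetition time, seconds.
#' @return frame duration in seconds.
#' @export
frame_duration <- function(spokes_per_frame, n_partitions, tr_s) {
  if (any(c(spokes_per_frame, n_partitions, tr_s) <= 0))
    stop("all inputs must be positive")
  spokes_per_frame * n_partitions * tr_s
}

#' Golden-angle radial trajectory
#'
#' Spoke `i` (1-based) has angle `((i-1) * 111.24611) mod 180` degrees and
#' timestamp `(i-1) * spoke_dt_s`. Each spoke is a full diameter through
#' k = 0 with `n_readout` samples spanning `[-N/2, N/2)` in grid units,
#' i.e. a radial sample spacing of `N / n_readout` (2x readout
#' oversampling for `n_readout = 2N`).
#'
#' @param n_spokes number of spokes.
#' @param n_readout samples per spoke.
#' @param spoke_dt_s time between consecutive spokes, seconds. In a 2D
#'   simulation standing in for one star of a stack-of-stars this is the
#'   full in-plane repeat time `n_partitions * tr_s`; the default `tr_s`
#'   corresponds to a single-partition acquisition.
#' @param tr_s repetition time used for the default `spoke_dt_s`.
#' @return An object of class `radial_trajectory`.
#' @export
radial_trajectory <- function(n_spokes, n_readout, spoke_dt_s = NULL,
                              tr_s = 0.0026) {
  if (n_spokes < 1) stop("'n_spokes' must be >= 1")
  if (is.null(spoke_dt_s)) spoke_dt_s <- tr_s
  if (spoke_dt_s <= 0) stop("'spoke_dt_s' must be positive")
  structure(list(n_spokes = as.integer(n_spokes),
                 n_readout = as.integer(n_readout),
                 golden_angle_deg = GOLDEN_ANGLE_DEG,
                 angles_deg = golden_angle_spokes(n_spokes),
                 spoke_dt_s = spoke_dt_s,
                 timestamps_s = (seq_len(n_spokes) - 1) * spoke_dt_s),
            class = "radial_trajectory")
}

#' Number of acquired Cartesian phase-encode lines
#'
#' The Cartesian protocol acquires at anisotropic resolution (coarser in
#' the phase-encode direction); this is emulated by acquiring only the
#' central band of phase-encode lines and zero-filling the rest. The
#' returned count is even.
#'
#' @param ny full matrix size in the phase-encode direction.
#' @param resolution_ratio ratio of phase to read resolution
#'   (default 2.89 / 1.56).
#' @return even number of acquired lines, at most `ny`.
#' @export
twist_line_count <- function(ny, resolution_ratio = 2.89 / 1.56) {
  n <- 2L * as.integer(round(ny / resolution_ratio / 2))
  min(n, as.integer(ny))
}

#' Cartesian view-sharing (TWIST-style) schedule
#'
#' The innermost `center_fraction` of the acquired phase-encode lines forms
#' the centre block "A", re-acquired every frame. The remaining periphery
#' is split into three interleaved subsets (every third line), each holding
#' about `periphery_fraction` of the periphery; frame `k` acquires the
#' centre block followed by subset `((k-1) mod 3) + 1`, so the acquisition
#' order over frames reads A, B1, A, B2, A, B3, ... Per-line timestamps are
#' spread uniformly over the frame window.
#'
#' @param n_lines number of acquired phase-encode lines (even, >= 8).
#' @param n_frames number of reconstructed frames.
#' @param params an [acquisition_params()] object.
#' @param frame_dt_s duration of one frame window, seconds; per-line
#'   timestamps advance by `frame_dt_s / lines_per_frame` (the effective
#'   in-plane line repeat time of the 3D sequence).
#' @return An object of class `cartesian_schedule` with the line table
#'   (`ky` index per line), the centre block, the three periphery subsets
#'   and the per-frame acquisition plan with timestamps.
#' @export
build_twist_schedule <- function(n_lines, n_frames, params = acquisition_params(),
                                 frame_dt_s = 1.98) {
  stopifnot(inherits(params, "acquisition_params"))
  if (n_lines < 8) stop("'n_lines' must be at least 8")
  if (n_lines %% 2 != 0) stop("'n_lines' must be even")
  if (n_frames < 1) stop("'n_frames' must be >= 1")
  ky <- seq_len(n_lines) - 1L - n_lines %/% 2L   # -n/2 .. n/2-1
  n_center <- as.integer(round(params$center_fraction * n_lines))
  if (n_center < 1) stop("centre block is empty; increase 'n_lines'")
  ord <- order(abs(ky + 0.25))                    # innermost lines first
  center_idx <- sort(ord[seq_len(n_center)])
  periph_idx <- sort(ord[-seq_len(n_center)])
  if (length(periph_idx) < 3)
    stop("'n_lines' too small for three non-empty periphery subsets")
  subsets <- lapply(1:3, function(s) periph_idx[seq(s, length(periph_idx), by = 3)])
  lines_per_frame <- n_center + lengths(subsets)
  line_dt <- frame_dt_s / max(lines_per_frame)
  plan <- do.call(rbind, lapply(seq_len(n_frames), function(k) {
    sub <- subsets[[(k - 1L) %% 3L + 1L]]
    idx <- c(center_idx, sub)
    data.frame(frame = k, line = idx, ky = ky[idx],
               t_s = (k - 1L) * frame_dt_s +
                 (seq_along(idx) - 0.5) * line_dt,
               block = rep(c("center", "periphery"),
                           c(n_center, length(sub))))
  }))
  structure(list(n_lines = as.integer(n_lines), ky = ky,
                 center_lines = center_idx, periphery_subsets = subsets,
                 n_frames = as.integer(n_frames), frame_dt_s = frame_dt_s,
                 line_dt_s = line_dt, frame_plan = plan, params = params),
            class = "cartesian_schedule")
}

# 2D DFT with the R fft convention:
# F[u, v] = sum_{y, x} img[y, x] exp(-2 pi i (u y / Ny + v x / Nx)),
# u, v = 0 .. N-1
fft2 <- function(img) stats::fft(img)
ifft2 <- function(K) stats::fft(K, inverse = TRUE)

# complex i.i.d. Gaussian noise with per-component sd 'sd'
cplx_noise <- function(n, sd) complex(real = stats::rnorm(n, sd = sd),
                                      imaginary = stats::rnorm(n, sd = sd))

#' Sample Cartesian view-shared k-space from a dynamic phantom
#'
#' Each scheduled phase-encode line holds the corresponding row of the 2D
#' DFT of the continuous scene evaluated at that line's timestamp. This is
#' the mechanism by which motion and contrast enhancement during the
#' acquisition corrupt the reconstructed frames.
#'
#' @param phantom a [generate_phantom()] result.
#' @param schedule a [build_twist_schedule()] result; `n_lines` must not
#'   exceed the phantom's Ny.
#' @param noise_sigma image-domain-equivalent measurement noise standard
#'   deviation, a.u.; complex Gaussian noise of per-component sd
#'   `noise_sigma * sqrt(Ny*Nx)` is added per k-space sample so that a
#'   fully sampled reconstruction carries about `noise_sigma` of voxel
#'   noise per channel.
#' @param seed RNG seed for the measurement noise (ignored when
#'   `noise_sigma = 0`).
#' @return An object of class `kspace_acquisition` with
#'   `scheme = "cartesian_viewshare"`.
#' @export
sample_cartesian <- function(phantom, schedule, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(phantom, "dynamic_phantom"),
            inherits(schedule, "cartesian_schedule"))
  ny <- phantom$config$matrix[1]; nx <- phantom$config$matrix[2]
  if (schedule$n_lines > ny)
    stop("schedule has more lines than the phantom matrix")
  t_max <- phantom$config$n_frames * phantom$config$frame_dt_s
  plan <- schedule$frame_plan
  if (max(plan$t_s) > t_max)
    stop("schedule timestamps exceed the phantom movie duration")
  lines <- matrix(0 + 0i, nrow(plan), nx)
  for (i in seq_len(nrow(plan))) {
    img <- phantom$scene(plan$t_s[i])
    u <- plan$ky[i] %% ny
    lines[i, ] <- fft2(img)[u + 1L, ]
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    lines <- lines + matrix(cplx_noise(length(lines),
                                       noise_sigma * sqrt(ny * nx)),
                            nrow(plan), nx)
  }
  structure(list(scheme = "cartesian_viewshare", lines = lines,
                 plan = plan, schedule = schedule,
                 matrix = phantom$config$matrix,
                 pixel_mm = phantom$config$pixel_mm),
            class = "kspace_acquisition")
}

# evaluate the 2D DFT of a real image at arbitrary k-points along one spoke
# using the separable split  S_j = sum_y e_y[y,j] * (sum_x img[y,x] e_x[x,j]);
# the two inner sums are real GEMMs
dft_spoke <- function(img, kx, ky) {
  ny <- nrow(img); nx <- ncol(img)
  xs <- seq_len(nx) - 1; ys <- seq_len(ny) - 1
  ex <- exp(outer(xs, kx) * (-2i * pi / nx))   # nx x m
  m_r <- img %*% Re(ex)
  m_i <- img %*% Im(ex)
  ey <- exp(outer(ys, ky) * (-2i * pi / ny))   # ny x m
  colSums(Re(ey) * m_r - Im(ey) * m_i) +
    1i * colSums(Re(ey) * m_i + Im(ey) * m_r)
}

# k-space coordinates of one spoke: radii (N/n_readout) * (j - n_readout/2)
spoke_radii <- function(n_readout, n) (seq_len(n_readout) - 1 - n_readout %/% 2) * (n / n_readout)

#' Sample golden-angle radial k-space from a dynamic phantom
#'
#' Spoke `i` holds the 2D DFT of the scene at the spoke's timestamp,
#' evaluated by direct summation at `n_readout` points along `angle[i]`
#' through k = 0 (radii span `[-N/2, N/2)` grid units). The DFT convention
#' matches [sample_cartesian()], so a spoke at 0 degrees with integer radii
#' equals the corresponding row of the full 2D FFT.
#'
#' @inheritParams sample_cartesian
#' @param traj a [radial_trajectory()]; `n_readout` must be at least the
#'   matrix size.
#' @return An object of class `kspace_acquisition` with
#'   `scheme = "radial_golden"`; `samples` is `n_readout x n_spokes`.
#' @export
sample_radial <- function(phantom, traj, noise_sigma = 0, seed = NULL) {
  stopifnot(inherits(phantom, "dynamic_phantom"),
            inherits(traj, "radial_trajectory"))
  ny <- phantom$config$matrix[1]; nx <- phantom$config$matrix[2]
  if (ny != nx) stop("radial sampling requires a square matrix")
  if (traj$n_readout < ny)
    stop("'n_readout' must be at least the matrix size")
  t_max <- phantom$config$n_frames * phantom$config$frame_dt_s
  if (max(traj$timestamps_s) > t_max)
    stop("trajectory timestamps exceed the phantom movie duration")
  r <- spoke_radii(traj$n_readout, ny)
  th <- traj$angles_deg * pi / 180
  samples <- matrix(0 + 0i, traj$n_readout, traj$n_spokes)
  for (i in seq_len(traj$n_spokes)) {
    img <- phantom$scene(traj$timestamps_s[i])
    kx <- r * cos(th[i]); ky <- r * sin(th[i])
    samples[, i] <- dft_spoke(img, kx, ky)
  }
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    samples <- samples + matrix(cplx_noise(length(samples),
                                           noise_sigma * sqrt(ny * nx)),
                                traj$n_readout, traj$n_spokes)
  }
  structure(list(scheme = "radial_golden", samples = samples, traj = traj,
                 matrix = phantom$config$matrix,
                 pixel_mm = phantom$config$pixel_mm),
            class = "kspace_acquisition")
}

#' @export
print.kspace_acquisition <- function(x, ...) {
  n <- if (x$scheme == "radial_golden") ncol(x$samples) else nrow(x$lines)
  cat(sprintf("kspace_acquisition (%s): %d %s, matrix %d x %d\n", x$scheme, n,
              if (x$scheme == "radial_golden") "spokes" else "lines",
              x$matrix[1], x$matrix[2]))
  invisible(x)
}
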