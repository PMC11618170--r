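#' Reconstructed image series
#'
#' Container for a reconstructed magnitude frame series.
#'
#' @param frames real array `(n_frames, Ny, Nx)`.
#' @param pixel_mm pixel spacing, mm.
#' @param frame_times_s midpoint acquisition time of each frame, seconds
#'   (strictly increasing).
#' @param provenance list describing the scheme and recon settings.
#' @return An object of class `image_series`.
#' @export
image_series <- function(frames, pixel_mm, frame_times_s,
                         provenance = list()) {
  stopifnot(length(dim(frames)) == 3L,
            dim(frames)[1] == length(frame_times_s))
  if (any(diff(frame_times_s) <= 0))
    stop("'frame_times_s' must be strictly increasing")
  if (any(!is.finite(frames)))
    stop("'frames' must be finite")
  structure(list(frames = frames, pixel_mm = pixel_mm,
                 frame_times_s = frame_times_s, provenance = provenance),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("image_series: %d frames of %d x %d (%.2f mm px), scheme: %s\n",
              dim(x$frames)[1], dim(x$frames)[2], dim(x$frames)[3],
              x$pixel_mm, x$provenance$scheme %||% "unknown"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fftshift2 <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  m[c((ny %/% 2 + 1):ny, 1:(ny %/% 2)), c((nx %/% 2 + 1):nx, 1:(nx %/% 2))]
}
# for even sizes ifftshift == fftshift

#' Reconstruct a Cartesian view-shared series
#'
#' Frame `k`'s k-space combines the centre block acquired during frame `k`
#' with the most recently acquired copy of each periphery subset (from
#' frames `<= k`); subsets not yet acquired at the start of the sequence
#' remain zero-filled, as do phase-encode lines outside the acquired band.
#' The image is the magnitude of the inverse 2D FFT.
#'
#' @param acq a [sample_cartesian()] acquisition.
#' @param magnitude return magnitude images (default) or the complex
#'   reconstruction (for linearity checks).
#' @return An [image_series()] (or a complex array when
#'   `magnitude = FALSE`).
#' @export
recon_twist <- function(acq, magnitude = TRUE) {
  stopifnot(inherits(acq, "kspace_acquisition"),
            acq$scheme == "cartesian_viewshare")
  ny <- acq$matrix[1]; nx <- acq$matrix[2]
  sch <- acq$schedule
  plan <- acq$plan
  nt <- sch$n_frames
  # most recent acquisition row (in `lines`) of each line index, per frame
  frames <- array(if (magnitude) 0 else 0i, dim = c(nt, ny, nx))
  latest <- rep(NA_integer_, sch$n_lines)   # row of `lines` last acquiring line
  for (k in seq_len(nt)) {
    rows <- which(plan$frame == k)
    if (!any(plan$block[rows] == "center"))
      stop("frame without a centre block")
    latest[plan$line[rows]] <- rows
    K <- matrix(0 + 0i, ny, nx)
    have <- which(!is.na(latest))
    u <- sch$ky[have] %% ny
    K[u + 1L, ] <- acq$lines[latest[have], , drop = FALSE]
    img <- ifft2(K) / (ny * nx)
    frames[k, , ] <- if (magnitude) Mod(img) else img
  }
  ft <- (seq_len(nt) - 0.5) * sch$frame_dt_s
  if (!magnitude) return(frames)
  image_series(frames, acq$pixel_mm, ft,
               provenance = list(scheme = "cartesian_viewshare",
                                 n_lines = sch$n_lines,
                                 recon = "view-shared inverse FFT"))
}

# Kaiser-Bessel gridding kernel, width W in oversampled-grid cells, with
# the Beatty-style beta for the given oversampling factor
kb_beta <- function(width, osf) {
  pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
}
kb_kernel <- function(d, width, beta) {
  u <- 2 * d / width
  w <- numeric(length(d))
  ok <- abs(u) <= 1
  w[ok] <- besselI(beta * sqrt(1 - u[ok]^2), 0)
  w
}
# Fourier transform of the (continuous) KB kernel, for deapodization;
# x in centred image-pixel units of the oversampled grid of size G
kb_deapod <- function(x, width, beta, G) {
  z2 <- beta^2 - (pi * width * x / G)^2
  out <- numeric(length(x))
  pos <- z2 > 0
  out[pos] <- width * sinh(sqrt(z2[pos])) / sqrt(z2[pos])
  zn <- sqrt(-z2[!pos])
  out[!pos] <- width * ifelse(zn == 0, 1, sin(zn) / zn)
  out
}

# per-spoke azimuthal extent: half the sum of the circular gaps (period
# pi) to the two neighbouring spokes in the frame
spoke_dtheta <- function(angles_deg) {
  th <- sort(angles_deg %% 180) * pi / 180
  n <- length(th)
  if (n == 1) return(pi)
  gaps <- diff(c(th, th[1] + pi))            # circular gaps
  dth <- (gaps + c(gaps[n], gaps[-n])) / 2   # half of both adjacent gaps
  dth[order(order(angles_deg %% 180))]       # back to acquisition order
}

# ramp density compensation: per-sample polar area weights in grid units
# (annulus area r * dtheta * dkr; the centre sample gets the area of the
# innermost disc shared among the spokes crossing it). `dtheta` is the
# per-spoke azimuthal extent from spoke_dtheta().
radial_dcf <- function(radii, dtheta, dkr) {
  w <- abs(radii) * dtheta * dkr
  w[radii == 0] <- dtheta[radii == 0] * dkr^2 / 4
  w
}

# sparse sample-to-grid interpolation matrix (KB kernel weights); rows are
# samples, columns are cells of the G x G oversampled grid
kb_interp_matrix <- function(kx, ky, n, osf, width) {
  G <- as.integer(round(osf * n))
  beta <- kb_beta(width, osf)
  gx <- osf * kx; gy <- osf * ky
  fx <- floor(gx); fy <- floor(gy)
  half <- width / 2
  m <- length(kx)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  for (dy in seq_len(width) - half) {
    uy <- fy + dy
    wy <- kb_kernel(gy - uy, width, beta)
    iy <- (as.integer(uy) + G %/% 2L) %% G
    for (dx in seq_len(width) - half) {
      ux <- fx + dx
      wxy <- wy * kb_kernel(gx - ux, width, beta)
      ix <- (as.integer(ux) + G %/% 2L) %% G
      ii <- c(ii, seq_len(m)); jj <- c(jj, ix * G + iy + 1L)
      ww <- c(ww, wxy)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(m, G * G))
}

# gridded density of a fully sampled Cartesian k-space restricted to the
# sampled disk: the target the compensated radial density should reproduce
cartesian_density_target <- function(n, osf, width, k_max) {
  v <- (-(n %/% 2)):(n %/% 2 - 1)
  vg <- expand.grid(vy = v, vx = v)
  keep <- sqrt(vg$vy^2 + vg$vx^2) <= k_max
  Pc <- kb_interp_matrix(vg$vx[keep], vg$vy[keep], n, osf, width)
  as.numeric(Matrix::crossprod(Pc, rep(1, sum(keep))))
}

# Pipe-Menon-style iterative density compensation: multiplicatively update
# the weights until their gridded-then-resampled density matches that of a
# fully sampled Cartesian grid over the sampled disk. Only samples inside
# the Nyquist-sampled core (`mask`) are refined -- there the Cartesian
# density is reachable and the refinement removes the residual quadrature
# error of the ramp; beyond the core the azimuthal density is genuinely
# deficient and the ramp area weights are kept unchanged (matching the
# target there would apodize the frame and blur edges).
refine_dcf_pipe <- function(w0, P, target_resampled, mask, iters = 10) {
  w <- w0
  for (i in seq_len(iters)) {
    d <- as.numeric(P %*% Matrix::crossprod(P, w))
    d[d <= 0] <- min(d[d > 0])
    w[mask] <- w[mask] * target_resampled[mask] / d[mask]
  }
  w
}

# adjoint gridding of one frame of radial samples onto an N x N image;
# P is the kb_interp_matrix() of the frame's sample positions
grid_radial_frame <- function(vals, kx, ky, n, osf = 1.5, width = 4,
                              weights, P) {
  G <- as.integer(round(osf * n))
  beta <- kb_beta(width, osf)
  # modulate so the scene centre (pixel N/2) sits at the coordinate origin
  v <- vals * exp(2i * pi * (kx + ky) * (n / 2) / n) * weights
  Kr <- matrix(as.numeric(Matrix::crossprod(P, Re(v))), G, G)
  Ki <- matrix(as.numeric(Matrix::crossprod(P, Im(v))), G, G)
  K <- Kr + 1i * Ki                            # centred k arrangement
  img_os <- fftshift2(ifft2(fftshift2(K)))     # centred image, G x G
  xs <- seq_len(G) - 1 - G %/% 2
  deap <- outer(kb_deapod(xs, width, beta, G),
                kb_deapod(xs, width, beta, G))
  img_os <- img_os / deap / n^2
  keep <- (G %/% 2 - n %/% 2 + 1):(G %/% 2 + n %/% 2)
  img_os[keep, keep]
}

#' Reconstruct a golden-angle radial series by density-compensated gridding
#'
#' Consecutive non-overlapping blocks of `spokes_per_frame` spokes form one
#' frame. Each frame is reconstructed by ramp (`|k|`) density compensation
#' with a flat floor at the Nyquist-matched plateau radius
#' (`n_spokes / pi` grid units), convolution gridding onto a 1.5x
#' oversampled Cartesian grid with a width-4 Kaiser-Bessel kernel, inverse
#' FFT, deapodization, and magnitude. For a fully sampled static star
#' (>= pi/2 * N spokes) the result matches the scene with a normalised RMSE
#' below 2%.
#'
#' @param acq a [sample_radial()] acquisition.
#' @param spokes_per_frame spokes grouped into each reconstructed frame.
#' @param osf gridding oversampling factor.
#' @param kernel_width Kaiser-Bessel kernel width in oversampled grid cells.
#' @param dcf_iters Pipe-Menon refinement iterations applied to the ramp
#'   weights (0 disables refinement and uses the plain ramp-with-plateau).
#' @param magnitude return magnitude images (default) or complex frames.
#' @return An [image_series()] (or a complex array when
#'   `magnitude = FALSE`).
#' @export
recon_radial_gridding <- function(acq, spokes_per_frame = 13L, osf = 1.5,
                                  kernel_width = 4L, dcf_iters = 10L,
                                  magnitude = TRUE) {
  stopifnot(inherits(acq, "kspace_acquisition"),
            acq$scheme == "radial_golden")
  traj <- acq$traj
  if (spokes_per_frame < 1) stop("'spokes_per_frame' must be >= 1")
  nt <- traj$n_spokes %/% spokes_per_frame
  if (nt < 1) stop("fewer spokes than 'spokes_per_frame'")
  n <- acq$matrix[1]
  r <- spoke_radii(traj$n_readout, n)
  dkr <- n / traj$n_readout
  th <- traj$angles_deg * pi / 180
  frames <- array(if (magnitude) 0 else 0i, dim = c(nt, n, n))
  ft <- numeric(nt)
  tgt <- if (dcf_iters > 0)
    cartesian_density_target(n, osf, kernel_width, max(abs(r))) else NULL
  for (k in seq_len(nt)) {
    sp <- ((k - 1L) * spokes_per_frame + 1L):(k * spokes_per_frame)
    kx <- as.vector(outer(r, cos(th[sp])))
    ky <- as.vector(outer(r, sin(th[sp])))
    vals <- as.vector(acq$samples[, sp])
    dth <- spoke_dtheta(traj$angles_deg[sp])
    dth_s <- rep(dth, each = traj$n_readout)
    w <- radial_dcf(rep(r, times = length(sp)), dth_s, dkr)
    P <- kb_interp_matrix(kx, ky, n, osf, kernel_width)
    if (dcf_iters > 0) {
      core <- abs(rep(r, times = length(sp))) <= 1 / dth_s
      w <- refine_dcf_pipe(w, P, as.numeric(P %*% tgt), core, dcf_iters)
    }
    img <- grid_radial_frame(vals, kx, ky, n, osf, kernel_width, w, P)
    frames[k, , ] <- if (magnitude) Mod(img) else img
    ft[k] <- mean(traj$timestamps_s[sp]) + traj$spoke_dt_s / 2
  }
  if (!magnitude) return(frames)
  image_series(frames, acq$pixel_mm, ft,
               provenance = list(scheme = "radial_golden",
                                 spokes_per_frame = spokes_per_frame,
                                 recon = "KB gridding, ramp DCF",
                                 osf = osf, kernel_width = kernel_width))
}

#' Background streak/artefact energy
#'
#' Mean squared intensity within a background mask (which must exclude all
#' true vessel supports), normalised by the mean squared intensity within
#' the vessel mask. Used to quantify the radial streaking versus Cartesian
#' aliasing/ringing contrast between schemes.
#'
#' @param img a 2D image (one frame).
#' @param mask logical background mask, same size as `img`.
#' @param vessel_mask logical mask of the vessel interiors.
#' @return normalised background energy (unitless scalar).
#' @export
streak_energy <- function(img, mask, vessel_mask) {
  stopifnot(is.matrix(img), identical(dim(img), dim(mask)),
            identical(dim(img), dim(vessel_mask)))
  if (!any(mask)) stop("empty background mask")
  if (!any(vessel_mask)) stop("empty vessel mask")
  mean(img[mask]^2) / mean(img[vessel_mask]^2)
}
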