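# shared fixtures and independent oracles

# a small static scene: one centred vessel, bolus far outside the simulated
# window so every frame is baseline
static_config <- function(n = 32, pixel_mm = 2, radius_mm = 10,
                          blur_mm = 2, seed = 1) {
  phantom_config(matrix = c(n, n), pixel_mm = pixel_mm, n_frames = 4,
                 frame_dt_s = 1.8,
                 vessels = list(vessel_spec("AA", c(0, 0), radius_mm, 100,
                                            300, bolus_params(1e5, 3, 7))),
                 motion = motion_params(), noise_sigma = 0,
                 edge_blur_sigma_mm = blur_mm, seed = seed)
}

# single dynamic vessel, configurable noise/motion
dynamic_config <- function(noise_sigma = 0, amplitude_mm = c(0, 0),
                           n = 64, n_frames = 40, alpha = 3, tp = 7,
                           t0 = 9, recirc = 0, seed = 1) {
  phantom_config(matrix = c(n, n), pixel_mm = 2.5, n_frames = n_frames,
                 frame_dt_s = 1.8,
                 vessels = list(vessel_spec("AA", c(0, 0), 16, 100, 400,
                                            bolus_params(t0, alpha, tp,
                                                         recirc))),
                 motion = motion_params(amplitude_mm), noise_sigma = noise_sigma,
                 edge_blur_sigma_mm = 2, seed = seed)
}

# direct-summation 2D DFT oracle (slow; tiny images only), same convention
# as the samplers: F(k) = sum_{y,x} img[y+1,x+1] e^{-2pi i (ky y + kx x)/N}
dft_direct <- function(img, kx, ky) {
  ny <- nrow(img); nx <- ncol(img)
  out <- complex(length(kx))
  for (m in seq_along(kx)) {
    s <- 0 + 0i
    for (y in 0:(ny - 1)) for (x in 0:(nx - 1))
      s <- s + img[y + 1, x + 1] *
        exp(-2i * pi * (ky[m] * y / ny + kx[m] * x / nx))
    out[m] <- s
  }
  out
}

# dense-grid gamma-variate FWHM oracle (1 ms grid, linear interpolation),
# written independently of the package implementation
oracle_gamma_fwhm <- function(alpha, tp, dt = 1e-3) {
  t <- seq(0, 40 * tp, by = dt)
  s <- ifelse(t > 0, exp(alpha * (log(t / tp) + 1 - t / tp)), 0)
  im <- which.max(s); half <- s[im] / 2
  up <- which(s[-length(s)] < half & s[-1] >= half); up <- up[up < im][1]
  dn <- which(s[-length(s)] >= half & s[-1] < half)
  dn <- dn[dn >= im]; dn <- dn[length(dn)]
  tu <- t[up] + (half - s[up]) / (s[up + 1] - s[up]) * dt
  td <- t[dn] + (half - s[dn]) / (s[dn + 1] - s[dn]) * dt
  td - tu
}
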