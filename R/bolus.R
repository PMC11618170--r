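#' Gamma-variate bolus parameters
#'
#' Parameters of the first-pass contrast bolus model used by the dynamic
#' phantom. The enhancement curve is the unit-peak gamma variate
#' \deqn{g(t) = ((t-t_0)/t_p)^\alpha \exp(\alpha (1 - (t-t_0)/t_p))}
#' for \eqn{t > t_0} (0 before arrival), which attains its maximum of 1 at
#' \eqn{t_0 + t_p}. An optional recirculation plateau
#' \eqn{f_r (1 - e^{-(t-t_0)/\tau})} with \eqn{\tau = 3 t_p} models the
#' persistent late-frame signal seen after the first pass.
#'
#' @param t0_s bolus arrival delay in seconds (>= 0).
#' @param alpha dimensionless shape parameter (> 0); larger values give a
#'   narrower, more symmetric bolus.
#' @param tp_s time to peak after arrival, seconds (> 0).
#' @param recirculation_fraction late-plateau amplitude relative to the
#'   first-pass peak, in `[0, 1)`.
#' @return An object of class `bolus_params`.
#' @export
bolus_params <- function(t0_s, alpha, tp_s, recirculation_fraction = 0) {
  stopifnot(is.numeric(t0_s), length(t0_s) == 1L, t0_s >= 0)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a positive scalar")
  if (!is.numeric(tp_s) || length(tp_s) != 1L || tp_s <= 0)
    stop("'tp_s' must be a positive scalar")
  if (!is.numeric(recirculation_fraction) || recirculation_fraction < 0 ||
      recirculation_fraction >= 1)
    stop("'recirculation_fraction' must lie in [0, 1)")
  structure(list(t0_s = t0_s, alpha = alpha, tp_s = tp_s,
                 recirculation_fraction = recirculation_fraction),
            class = "bolus_params")
}

#' Unit-peak gamma-variate curve
#'
#' @param t time points, seconds (vectorised).
#' @param t0_s arrival delay, seconds.
#' @param alpha shape parameter (> 0).
#' @param tp_s time to peak after arrival, seconds.
#' @return `g(t)`, zero for `t <= t0_s`, maximum 1 at `t0_s + tp_s`.
#' @export
gamma_variate <- function(t, t0_s, alpha, tp_s) {
  x <- (t - t0_s) / tp_s
  g <- numeric(length(t))
  pos <- x > 0
  # evaluate in log space: alpha can be large (e.g. 500)
  g[pos] <- exp(alpha * (log(x[pos]) + 1 - x[pos]))
  g
}

#' Full bolus enhancement curve (first pass plus recirculation plateau)
#'
#' @param t time points, seconds.
#' @param bolus a [bolus_params()] object.
#' @return enhancement relative to the first-pass peak (unitless).
#' @export
bolus_curve <- function(t, bolus) {
  stopifnot(inherits(bolus, "bolus_params"))
  g <- gamma_variate(t, bolus$t0_s, bolus$alpha, bolus$tp_s)
  rf <- bolus$recirculation_fraction
  if (rf > 0) {
    tau <- 3 * bolus$tp_s
    dt <- t - bolus$t0_s
    g <- g + ifelse(dt > 0, rf * (1 - exp(-dt / tau)), 0)
  }
  g
}

#' Ground-truth FWHM of a bolus curve
#'
#' Evaluates the enhancement curve on a dense time grid (default 1 ms) and
#' returns the width between the first upward and the last downward
#' half-maximum crossing, each located by linear interpolation. This is the
#' reference against which FWHM measured on reconstructed frame series is
#' validated.
#'
#' @param bolus a [bolus_params()] object.
#' @param dt_s dense grid step, seconds.
#' @return FWHM in seconds.
#' @export
true_bolus_fwhm <- function(bolus, dt_s = 1e-3) {
  stopifnot(inherits(bolus, "bolus_params"))
  # horizon: the gamma variate has decayed to < 1e-6 long before 40*tp for
  # any alpha >= 0.5; the plateau asymptote is recirculation_fraction
  t <- seq(bolus$t0_s, bolus$t0_s + 40 * bolus$tp_s, by = dt_s)
  s <- bolus_curve(t, bolus)
  half_crossings(t, s)
}

# shared crossing finder: width between first upward and last downward
# half-maximum crossing of (t, s)
half_crossings <- function(t, s) {
  i_max <- which.max(s)
  half <- 0.5 * s[i_max]
  up <- which(s[-length(s)] < half & s[-1] >= half)
  up <- up[up < i_max]
  if (length(up) == 0L)
    stop("no upward half-maximum crossing before the peak")
  dn <- which(s[-length(s)] >= half & s[-1] < half)
  dn <- dn[dn >= i_max]
  if (length(dn) == 0L)
    stop("no downward half-maximum crossing after the peak ",
         "(curve never returns below half maximum; FWHM undefined)")
  i <- up[1]
  t_up <- t[i] + (half - s[i]) / (s[i + 1] - s[i]) * (t[i + 1] - t[i])
  j <- dn[length(dn)]
  t_dn <- t[j] + (half - s[j]) / (s[j + 1] - s[j]) * (t[j + 1] - t[j])
  t_dn - t_up
}

#' Ground-truth 20--80% edge rise width of a Gaussian-blurred edge
#'
#' The phantom renders vessel boundaries as a step edge blurred with an
#' isotropic Gaussian of standard deviation `sigma`, so the radial intensity
#' profile is \eqn{\Phi(x/\sigma)}. The distance over which the intensity
#' rises from 20% to 80% of the full step is then
#' \eqn{2 \sigma \Phi^{-1}(0.8) \approx 1.6832 \sigma}.
#'
#' @param edge_blur_sigma_mm Gaussian edge blur, mm (>= 0).
#' @return 20--80% rise distance in mm.
#' @export
true_edge_width <- function(edge_blur_sigma_mm) {
  if (!is.numeric(edge_blur_sigma_mm) || any(edge_blur_sigma_mm < 0))
    stop("'edge_blur_sigma_mm' must be non-negative")
  2 * edge_blur_sigma_mm * stats::qnorm(0.8)
}
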