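#' Circular region of interest
#'
#' @param center_px length-2 `(y, x)` centre in 0-based pixel units.
#' @param radius_px radius in pixels (> 0). A pixel belongs to the ROI when
#'   its centre lies within `radius_px` (Euclidean) of the ROI centre.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center_px, radius_px) {
  stopifnot(is.numeric(center_px), length(center_px) == 2L)
  if (radius_px <= 0) stop("'radius_px' must be positive")
  structure(list(center_px = as.numeric(center_px), radius_px = radius_px),
            class = "roi_spec")
}

#' Logical mask of an ROI on an image grid
#' @param roi an [roi_spec()].
#' @param dim length-2 `(Ny, Nx)` image dimensions.
#' @return logical `Ny x Nx` matrix.
#' @export
roi_mask <- function(roi, dim) {
  ys <- seq_len(dim[1]) - 1; xs <- seq_len(dim[2]) - 1
  d2 <- outer((ys - roi$center_px[1])^2, (xs - roi$center_px[2])^2, "+")
  m <- d2 <= roi$radius_px^2
  if (!any(m)) stop("ROI contains no pixels")
  m
}

check_roi_inside <- function(roi, dim) {
  if (roi$center_px[1] - roi$radius_px < 0 ||
      roi$center_px[2] - roi$radius_px < 0 ||
      roi$center_px[1] + roi$radius_px > dim[1] - 1 ||
      roi$center_px[2] + roi$radius_px > dim[2] - 1)
    stop("ROI extends outside the image bounds")
}

#' Extract the ROI time--intensity curve from an image series
#'
#' @param series an [image_series()] with at least 4 frames.
#' @param roi an [roi_spec()] fully inside the image.
#' @return An object of class `time_curve` with `t_s` (frame times) and
#'   `s_raw` (mean ROI intensity per frame).
#' @export
extract_time_curve <- function(series, roi) {
  stopifnot(inherits(series, "image_series"), inherits(roi, "roi_spec"))
  d <- dim(series$frames)
  if (d[1] < 4) stop("at least 4 frames are required")
  check_roi_inside(roi, d[2:3])
  m <- roi_mask(roi, d[2:3])
  s <- vapply(seq_len(d[1]), function(k) mean(series$frames[k, , ][m]), 0)
  structure(list(t_s = series$frame_times_s, s_raw = s, roi = roi,
                 preprocessed = FALSE),
            class = "time_curve")
}

#' Time curve from raw samples
#' @param t_s increasing sample times, seconds.
#' @param s_raw intensity samples.
#' @return a `time_curve` object.
#' @export
time_curve <- function(t_s, s_raw) {
  stopifnot(length(t_s) == length(s_raw), all(diff(t_s) > 0))
  structure(list(t_s = t_s, s_raw = s_raw, preprocessed = FALSE),
            class = "time_curve")
}

# centred moving average with partial windows at the edges
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  h <- (window - 1) %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - h, 1); hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Interpolate, smooth and normalise a time curve
#'
#' The raw ROI curve is interpolated onto a grid `interp_factor` times
#' denser, then smoothed with a centred moving average of `window`
#' interpolated samples, then min--max normalised to `[0, 1]`. The default
#' interpolant is the shape-preserving monotone cubic (Fritsch--Carlson,
#' the `pchip` of numerical practice): unlike a natural spline it cannot
#' ring below the pre-bolus baseline (which would inflate the min--max
#' range and bias the half-maximum level), and unlike linear interpolation
#' it does not clip the peak between frames.
#'
#' @param curve a [time_curve()].
#' @param interp_factor integer >= 1 temporal interpolation factor.
#' @param window odd moving-average length (in interpolated samples).
#' @param method interpolation method: `"pchip"` (monotone cubic),
#'   `"spline"` (natural cubic) or `"linear"`.
#' @return a preprocessed `time_curve` with elements `t_s`, `s_norm`.
#' @export
preprocess_curve <- function(curve, interp_factor = 10L, window = 5L,
                             method = c("pchip", "spline", "linear")) {
  stopifnot(inherits(curve, "time_curve"))
  method <- match.arg(method)
  if (interp_factor < 1) stop("'interp_factor' must be >= 1")
  if (window < 1 || window %% 2 == 0)
    stop("'window' must be an odd positive integer")
  n <- length(curve$t_s)
  ti <- seq(curve$t_s[1], curve$t_s[n],
            length.out = (n - 1) * interp_factor + 1)
  si <- if (interp_factor == 1) curve$s_raw
        else switch(method,
          linear = stats::approx(curve$t_s, curve$s_raw, xout = ti)$y,
          spline = stats::spline(curve$t_s, curve$s_raw, xout = ti,
                                 method = "natural")$y,
          pchip = stats::splinefun(curve$t_s, curve$s_raw,
                                   method = "monoH.FC")(ti))
  si <- moving_average(si, window)
  rng <- range(si)
  if (rng[1] == rng[2])
    stop("constant curve: min-max normalisation undefined")
  structure(list(t_s = ti, s_norm = (si - rng[1]) / (rng[2] - rng[1]),
                 s_raw = si, interp_factor = as.integer(interp_factor),
                 smoothing = sprintf("moving average, window %d", window),
                 method = method, preprocessed = TRUE),
            class = "time_curve")
}

#' Full width at half maximum of a preprocessed bolus curve
#'
#' The half level is 0.5 on the min--max normalised curve. The width is the
#' time between the first upward half crossing before the global peak and
#' the last downward half crossing after it, both located by linear
#' interpolation. A curve that never returns below half maximum (e.g. a
#' recirculation plateau at or above 0.5) is flagged as an error, not
#' silently truncated.
#'
#' @param curve a preprocessed [time_curve()].
#' @return FWHM in seconds.
#' @export
curve_fwhm <- function(curve) {
  stopifnot(inherits(curve, "time_curve"))
  if (!isTRUE(curve$preprocessed))
    stop("curve must be preprocessed (see preprocess_curve)")
  half_crossings(curve$t_s, curve$s_norm)
}

#' Maximum upslope of a preprocessed bolus curve
#'
#' Maximum forward finite difference of the normalised curve, restricted to
#' the upslope segment before the global peak; units 1/s.
#'
#' @param curve a preprocessed [time_curve()].
#' @return max slope in 1/s.
#' @export
curve_maxslope <- function(curve) {
  stopifnot(inherits(curve, "time_curve"))
  if (!isTRUE(curve$preprocessed))
    stop("curve must be preprocessed (see preprocess_curve)")
  s <- curve$s_norm; t <- curve$t_s
  if (length(s) < 2) stop("need at least two samples")
  ipk <- which.max(s)
  if (ipk < 2) stop("no upslope segment before the peak")
  d <- diff(s[seq_len(ipk)]) / diff(t[seq_len(ipk)])
  max(d)
}

#' Extract an intensity profile along a straight line
#'
#' Samples the image along the segment from `from_px` to `to_px` (0-based
#' `(y, x)` pixel coordinates) by bilinear interpolation at half-pixel
#' steps, then resamples with a cubic spline at `step_px` (default
#' 0.1 pixel) steps.
#'
#' @param img 2D image matrix.
#' @param from_px,to_px line endpoints, 0-based `(y, x)` pixels.
#' @param pixel_mm pixel spacing, mm.
#' @param step_px supersampling step along the line, pixels.
#' @return An object of class `profile_curve` with `positions_mm`
#'   (strictly increasing distances from `from_px`) and `intensities`.
#' @export
extract_profile <- function(img, from_px, to_px, pixel_mm, step_px = 0.1) {
  stopifnot(is.matrix(img), length(from_px) == 2L, length(to_px) == 2L)
  len <- sqrt(sum((to_px - from_px)^2))
  if (len <= 0) stop("degenerate profile line")
  bil <- function(frac) {
    y <- from_px[1] + frac * (to_px[1] - from_px[1])
    x <- from_px[2] + frac * (to_px[2] - from_px[2])
    y0 <- pmax(pmin(floor(y), nrow(img) - 2), 0)
    x0 <- pmax(pmin(floor(x), ncol(img) - 2), 0)
    wy <- y - y0; wx <- x - x0
    img[cbind(y0 + 1, x0 + 1)] * (1 - wy) * (1 - wx) +
      img[cbind(y0 + 2, x0 + 1)] * wy * (1 - wx) +
      img[cbind(y0 + 1, x0 + 2)] * (1 - wy) * wx +
      img[cbind(y0 + 2, x0 + 2)] * wy * wx
  }
  coarse <- seq(0, 1, by = min(0.5 / len, 1))
  vals <- bil(coarse)
  pos <- seq(0, len, by = step_px)
  fine <- stats::spline(coarse * len, vals, xout = pos,
                        method = "natural")$y
  structure(list(positions_mm = pos * pixel_mm, intensities = fine,
                 from_px = from_px, to_px = to_px),
            class = "profile_curve")
}

#' Profile from position/intensity samples
#' @param positions_mm strictly increasing positions, mm.
#' @param intensities intensity samples.
#' @return a `profile_curve` object.
#' @export
profile_curve <- function(positions_mm, intensities) {
  stopifnot(length(positions_mm) == length(intensities),
            all(diff(positions_mm) > 0))
  structure(list(positions_mm = positions_mm, intensities = intensities),
            class = "profile_curve")
}

#' Vessel sharpness from a 20--80% edge rise
#'
#' Thresholds are taken at 20% and 80% of the absolute intensity range of
#' the profile (its raw min and max, no normalisation). The edge of
#' interest is anchored at the steepest-gradient point; from there the
#' nearest 20% and 80% crossings on that edge are located by linear
#' interpolation. The rise distance is `d = |x80 - x20|` mm and vessel
#' sharpness is `vs = 1/d`. The construction is invariant under affine
#' intensity transforms with positive gain.
#'
#' @param profile a [profile_curve()] crossing one monotone vessel edge
#'   around its steepest gradient.
#' @param edge_search_mm optional length-2 window (positions in mm along
#'   the profile) restricting where the edge anchor is sought. When the
#'   profile was drawn across a known vessel wall (as in the pipeline),
#'   restricting the search to the expected wall neighbourhood keeps
#'   streaks and ghosts elsewhere on the line from hijacking the anchor.
#' @return list with `vs_per_mm`, `d_mm`, `x20_mm`, `x80_mm`.
#' @export
vessel_sharpness <- function(profile, edge_search_mm = NULL) {
  stopifnot(inherits(profile, "profile_curve"))
  x <- profile$positions_mm; s <- profile$intensities
  if (length(s) < 3) stop("profile too short")
  lo <- min(s); hi <- max(s)
  if (hi <= lo) stop("flat profile: no edge")
  l20 <- lo + 0.2 * (hi - lo)
  l80 <- lo + 0.8 * (hi - lo)
  g <- diff(s) / diff(x)
  cross_from <- function(ig, level, direction) {
    # walk from the gradient point in `direction` (-1 left, +1 right) to
    # the first segment crossing `level`
    idx <- if (direction < 0) seq(ig, 1) else seq(ig, length(s) - 1)
    for (i in idx) {
      s0 <- s[i]; s1 <- s[i + 1]
      if ((s0 - level) * (s1 - level) <= 0 && s0 != s1) {
        return(x[i] + (level - s0) / (s1 - s0) * (x[i + 1] - x[i]))
      }
    }
    NA_real_
  }
  # anchor at the steepest gradient; if that segment sits on an artefact
  # (e.g. a ghost edge) from which both thresholds cannot be reached, fall
  # back to the next-steepest candidates, with a warning
  cand <- seq_along(g)
  if (!is.null(edge_search_mm)) {
    mid <- (x[-1] + x[-length(x)]) / 2
    cand <- cand[mid >= edge_search_mm[1] & mid <= edge_search_mm[2]]
    if (length(cand) == 0) stop("empty edge search window")
  }
  g_cand <- g[cand]
  ord <- cand[order(abs(g_cand), decreasing = TRUE)]
  ord <- ord[seq_len(min(length(ord), 25L))]
  x20 <- x80 <- NA_real_
  used <- NA_integer_
  for (j in seq_along(ord)) {
    ig <- ord[j]
    if (g[ig] > 0) {
      c20 <- cross_from(ig, l20, -1); c80 <- cross_from(ig, l80, +1)
    } else {
      c80 <- cross_from(ig, l80, -1); c20 <- cross_from(ig, l20, +1)
    }
    if (!is.na(c20) && !is.na(c80)) {
      x20 <- c20; x80 <- c80; used <- j
      break
    }
  }
  if (is.na(x20) || is.na(x80))
    stop("profile does not reach both the 20% and 80% thresholds")
  if (used > 1L)
    warning("steepest gradient lies on an artefact edge; ",
            "sharpness anchored at the next-steepest vessel edge")
  d <- abs(x80 - x20)
  if (d == 0) stop("degenerate edge: zero rise distance")
  list(vs_per_mm = 1 / d, d_mm = d, x20_mm = x20, x80_mm = x80)
}

#' Subtraction-method SNR
#'
#' The noise level is estimated from the voxelwise difference of the second
#' and third frames (both pre-bolus; the first frame is not used):
#' `sigma = sd(frame3 - frame2 over the ROI) / sqrt(2)`, since the
#' difference of two i.i.d. noise realisations has twice the variance. SNR
#' is the mean ROI intensity of the peak frame divided by this estimate.
#'
#' @param series an [image_series()]; frames 2 and 3 (1-based) must be
#'   pre-bolus.
#' @param roi an [roi_spec()].
#' @param peak_frame 1-based index of the analysed frame (>= 4).
#' @return SNR (unitless).
#' @export
snr_subtraction <- function(series, roi, peak_frame) {
  stopifnot(inherits(series, "image_series"), inherits(roi, "roi_spec"))
  d <- dim(series$frames)
  if (d[1] < 4) stop("at least 4 frames are required")
  if (peak_frame < 4 || peak_frame > d[1])
    stop("'peak_frame' must be between 4 and the number of frames")
  check_roi_inside(roi, d[2:3])
  m <- roi_mask(roi, d[2:3])
  dif <- (series$frames[3, , ] - series$frames[2, , ])[m]
  sigma <- stats::sd(dif) / sqrt(2)
  if (sigma == 0)
    stop("zero noise estimate: subtraction SNR undefined on noiseless input")
  mean(series$frames[peak_frame, , ][m]) / sigma
}

#' Per-ROI image-quality metrics for one reconstructed series
#'
#' For each ROI: the smoothed/normalised time curve's FWHM and maximum
#' upslope, the 20--80% vessel sharpness measured on a profile running from
#' outside the vessel to its centre on the peak frame, and the
#' subtraction SNR at the peak frame. The peak frame is selected as the
#' frame maximising the smoothed ROI mean.
#'
#' @param series an [image_series()].
#' @param rois named list of [roi_spec()] objects.
#' @param profiles named list (same names) of lists with elements
#'   `from_px`, `to_px` defining the sharpness profile line (optionally
#'   `wall_mm`, the expected wall position along the line).
#' @param interp_factor forwarded to [preprocess_curve()].
#' @param window moving-average length in interpolated samples. The
#'   default spans two frame periods: undersampled radial frames carry a
#'   frame-to-frame fluctuation of the ROI mean (the streak pattern
#'   rotates with the golden angle), and a smoother shorter than one frame
#'   period cannot suppress it.
#' @return A `data.frame` (class `metrics_report`) with one row per ROI:
#'   `roi`, `fwhm_s`, `maxslope_per_s`, `vs_per_mm`, `d_mm`, `snr`,
#'   `peak_frame`.
#' @export
compute_metrics <- function(series, rois, profiles, interp_factor = 10L,
                            window = 2L * interp_factor + 1L) {
  stopifnot(inherits(series, "image_series"),
            identical(names(rois), names(profiles)))
  rows <- lapply(names(rois), function(nm) {
    roi <- rois[[nm]]
    curve <- extract_time_curve(series, roi)
    pre <- preprocess_curve(curve, interp_factor, window)
    fwhm <- tryCatch(curve_fwhm(pre), error = function(e) NA_real_)
    ms <- curve_maxslope(pre)
    # peak frame: original frame whose time is nearest the smoothed peak
    tpk <- pre$t_s[which.max(pre$s_norm)]
    peak_frame <- which.min(abs(series$frame_times_s - tpk))
    peak_frame <- max(peak_frame, 4L)
    # sharpness: median over the three frames centred on the peak, a robust
    # automated stand-in for a reader choosing the frame where the vessel
    # is best visible (a single frame can be ruined by a streak or ghost
    # crossing the wall)
    win <- if (!is.null(profiles[[nm]]$wall_mm))
      profiles[[nm]]$wall_mm + c(-9, 9) else NULL
    cand_frames <- unique(pmin(pmax(peak_frame + (-1:1), 4L),
                               dim(series$frames)[1]))
    ds <- vapply(cand_frames, function(f) {
      pr <- extract_profile(series$frames[f, , ],
                            profiles[[nm]]$from_px, profiles[[nm]]$to_px,
                            series$pixel_mm)
      tryCatch(suppressWarnings(
        vessel_sharpness(pr, edge_search_mm = win)$d_mm),
        error = function(e) NA_real_)
    }, 0)
    d_med <- stats::median(ds, na.rm = TRUE)
    if (is.na(d_med)) stop("vessel sharpness undefined for ROI ", nm)
    vs <- list(vs_per_mm = 1 / d_med, d_mm = d_med)
    snr <- tryCatch(snr_subtraction(series, roi, peak_frame),
                    error = function(e) NA_real_)
    data.frame(roi = nm, fwhm_s = fwhm, maxslope_per_s = ms,
               vs_per_mm = vs$vs_per_mm, d_mm = vs$d_mm, snr = snr,
               peak_frame = peak_frame)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_report", "data.frame")
  out
}
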