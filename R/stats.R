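#' Paired t test from first principles
#'
#' For paired vectors `a`, `b`, computes `d = a - b`,
#' `t = mean(d) / (sd(d)/sqrt(n))`, `df = n - 1`, and a two-sided p-value
#' from the Student-t distribution function (regularised incomplete beta).
#'
#' @param a,b equal-length numeric vectors with no missing values,
#'   length >= 2.
#' @return list with `t`, `df`, `p`, `mean_diff`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == length(b))
  if (length(a) < 2) stop("need at least 2 pairs")
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed")
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) stop("all pairwise differences identical: t undefined")
  t <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, mean_diff = mean(d))
}

#' Rating table for inter-rater agreement
#'
#' @param counts `n_subjects x n_categories` matrix of rating counts; each
#'   row must sum to the same number of raters.
#' @return An object of class `rating_table`.
#' @export
rating_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 subjects")
  if (ncol(counts) < 2) stop("need at least 2 categories")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  n_raters <- rowSums(counts)
  if (length(unique(n_raters)) != 1L)
    stop("every subject must be rated by the same number of raters")
  if (n_raters[1] < 2) stop("need at least 2 raters")
  structure(list(counts = counts, n_raters = as.integer(n_raters[1])),
            class = "rating_table")
}

#' Fleiss' kappa for multiple raters
#'
#' Chance-corrected agreement for `n` raters assigning `N` subjects to
#' categorical scores: per-subject agreement
#' \eqn{P_i = (\sum_j n_{ij}^2 - n) / (n(n-1))}, observed agreement
#' \eqn{\bar P = \mathrm{mean}(P_i)}, chance agreement
#' \eqn{\bar P_e = \sum_j p_j^2} with marginal proportions \eqn{p_j}, and
#' \eqn{\kappa = (\bar P - \bar P_e) / (1 - \bar P_e)}.
#'
#' @param r a [rating_table()].
#' @return kappa (scalar).
#' @export
fleiss_kappa <- function(r) {
  stopifnot(inherits(r, "rating_table"))
  counts <- r$counts
  n <- r$n_raters
  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / sum(counts)
  p_e <- sum(p_j^2)
  if (p_e >= 1)
    stop("all ratings fall in a single category: kappa undefined")
  (p_bar - p_e) / (1 - p_e)
}

#' Summarise a paired scheme comparison across subjects
#'
#' Given per-subject metric reports for two acquisition schemes, builds a
#' table with one row per ROI and metric: mean and SD under each scheme,
#' the paired t-test, and a direction flag indicating which scheme scored
#' higher (or `"equal"`; the t-test is flagged `NA` when all differences
#' vanish).
#'
#' @param reports_a,reports_b lists of [compute_metrics()] reports, one per
#'   subject, with identical ROI sets.
#' @param labels length-2 character names of the two schemes.
#' @param metrics metric columns to compare.
#' @return A `data.frame` with columns `roi`, `metric`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `t`, `df`, `p`, `higher`.
#' @export
summarize_comparison <- function(reports_a, reports_b,
                                 labels = c("A", "B"),
                                 metrics = c("fwhm_s", "maxslope_per_s",
                                             "vs_per_mm", "snr")) {
  if (length(reports_a) != length(reports_b) || length(reports_a) < 2)
    stop("need >= 2 paired subjects")
  rois <- reports_a[[1]]$roi
  for (r in c(reports_a, reports_b))
    if (!identical(r$roi, rois)) stop("mismatched ROI sets across subjects")
  rows <- list()
  for (roi in rois) for (m in metrics) {
    va <- vapply(reports_a, function(r) r[r$roi == roi, m], 0)
    vb <- vapply(reports_b, function(r) r[r$roi == roi, m], 0)
    tt <- tryCatch(paired_t_test(va, vb), error = function(e)
      list(t = NA_real_, df = length(va) - 1, p = NA_real_))
    higher <- if (isTRUE(all.equal(mean(va), mean(vb)))) "equal"
              else if (mean(va) > mean(vb)) labels[1] else labels[2]
    rows[[length(rows) + 1L]] <-
      data.frame(roi = roi, metric = m, mean_a = mean(va), sd_a = stats::sd(va),
                 mean_b = mean(vb), sd_b = stats::sd(vb),
                 t = tt$t, df = tt$df, p = tt$p, higher = higher)
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- labels
  out
}
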