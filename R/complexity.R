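# Nonlinear complexity measures for breath-to-breath series.
#
# All three estimators are implemented from their definitions: template
# matching with the Chebyshev (max-coordinate) distance for the entropies,
# and RMS fluctuation of the integrated, windowed, polynomial-detrended
# profile for DFA.

# Logical match matrix AND-ed across template offsets 0..(m-1).
# Returns the count matrix for templates 1..M where M = N - m_total.
template_match <- function(w, m, M) {
  cm <- w[seq_len(M), seq_len(M), drop = FALSE]
  k <- 1L
  while (k < m) {
    cm <- cm & w[seq_len(M) + k, seq_len(M) + k, drop = FALSE]
    k <- k + 1L
  }
  cm
}

#' Sample entropy
#'
#' SampEn is the negative natural logarithm of the conditional probability
#' that two template sequences that match within a tolerance for `m`
#' points also match at the next point, with self-matches excluded.
#' Lower values indicate a more regular (less complex) series.
#'
#' The tolerance is resolved as `r` times the sample standard deviation of
#' `x`, the established convention for physiological series, so the value
#' is invariant under affine rescaling of `x`.
#'
#' @param x numeric series of length at least `m + 2`.
#' @param m embedding dimension (template length), default 2.
#' @param r tolerance as a fraction of the sample SD of `x`, default 0.2.
#' @return SampEn in nats. A degenerate constant series returns 0 (every
#'   template matches). If no `(m+1)`-point matches exist the value is
#'   `Inf`, a distinguished "no matches" marker that downstream group
#'   statistics treat as missing.
#' @examples
#' sample_entropy(sin(1:300) + rnorm(300, sd = 0.1))
#' @export
sample_entropy <- function(x, m = 2, r = 0.2) {
  m <- as.integer(check_scalar_num(m, "m"))
  check_scalar_num(r, "r")
  if (m < 1) stopf("`m` must be >= 1", class = "invalid_parameter")
  if (r <= 0) stopf("`r` must be positive", class = "invalid_parameter")
  x <- as.numeric(x)
  n <- length(x)
  if (n < m + 2)
    stopf("series length %d is too short for m = %d (need >= m + 2)", n, m,
          class = "insufficient_data")
  if (anyNA(x) || any(!is.finite(x)))
    stopf("series contains non-finite values", class = "data_error")
  s <- stats::sd(x)
  if (s == 0) return(0)  # all templates match: -ln(1)
  r_abs <- r * s

  M <- n - m  # templates of length m and m+1 both start at 1..M
  w <- abs(outer(x, x, "-")) <= r_abs
  cm <- template_match(w, m, M)
  b <- (sum(cm) - M) / 2          # ordered pairs i < j
  cm1 <- cm & w[seq_len(M) + m, seq_len(M) + m, drop = FALSE]
  a <- (sum(cm1) - M) / 2
  if (b == 0 || a == 0) {
    warning("no template matches at m + 1; sample entropy undefined (Inf)",
            call. = FALSE)
    return(Inf)
  }
  -log(a / b)
}

#' Cross-sample entropy between two series
#'
#' Measures the asynchrony of two related series by counting template
#' matches *across* them: larger values mean fewer shared sub-patterns
#' (more asynchrony); smaller values mean stronger synchronization.
#' Both series are z-normalized independently before matching (IBI is in
#' seconds, RV in arbitrary units — the scales are incommensurate), so the
#' tolerance `r` is in SD units. The statistic is symmetric in `(x, y)`.
#'
#' @param x,y numeric series of equal length, at least `m + 2`.
#' @inheritParams sample_entropy
#' @return cross-SampEn in nats; `Inf` when no `(m+1)`-matches exist;
#'   0 when either series is constant (degenerate).
#' @export
cross_sample_entropy <- function(x, y, m = 2, r = 0.2) {
  m <- as.integer(check_scalar_num(m, "m"))
  check_scalar_num(r, "r")
  if (m < 1) stopf("`m` must be >= 1", class = "invalid_parameter")
  if (r <= 0) stopf("`r` must be positive", class = "invalid_parameter")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stopf("series lengths differ (%d vs %d)", length(x), length(y),
          class = "shape_error")
  n <- length(x)
  if (n < m + 2)
    stopf("series length %d too short for m = %d", n, m,
          class = "insufficient_data")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("series contain non-finite values", class = "data_error")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  zx <- (x - mean(x)) / sx
  zy <- (y - mean(y)) / sy

  M <- n - m
  w <- abs(outer(zx, zy, "-")) <= r
  cm <- template_match(w, m, M)
  b <- sum(cm)                    # all (i, j) cross pairs
  cm1 <- cm & w[seq_len(M) + m, seq_len(M) + m, drop = FALSE]
  a <- sum(cm1)
  if (b == 0 || a == 0) {
    warning("no cross-template matches at m + 1; cross-SampEn undefined (Inf)",
            call. = FALSE)
    return(Inf)
  }
  -log(a / b)
}

#' Detrended fluctuation analysis
#'
#' Estimates the scaling exponent of long-range correlation in a series.
#' The series is integrated (cumulative sum of deviations from the mean),
#' partitioned at each scale `s` into non-overlapping windows taken from
#' both the start and the end of the profile, each window is detrended
#' with an order-`detrend_order` polynomial least-squares fit, and the RMS
#' residual fluctuation `F(s)` is regressed on `s` in log-log coordinates.
#' The slope of that line is the scaling exponent alpha: 0.5 for
#' uncorrelated noise, > 0.5 for persistent correlation, ~1.5 for
#' integrated noise. For fractional Gaussian noise, alpha ~ H.
#'
#' @param x numeric series, length at least `4 * min_scale`.
#' @param min_scale smallest window size in samples (default 4).
#' @param max_scale largest window size (default `length(x) %/% 4`).
#' @param n_scales number of log-spaced scales (default 16; duplicate
#'   integer scales are collapsed, at least 6 must remain).
#' @param detrend_order polynomial order of the per-window detrend
#'   (default 1, i.e. DFA-1).
#' @return a list of class `"dfa_fit"` with `alpha` (the exponent),
#'   `scales`, and `fluctuations`.
#' @examples
#' fit <- dfa(rnorm(2048))
#' fit$alpha  # near 0.5 for white noise
#' @export
dfa <- function(x, min_scale = 4, max_scale = NULL, n_scales = 16,
                detrend_order = 1) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(max_scale)) max_scale <- n %/% 4L
  min_scale <- as.integer(check_scalar_num(min_scale, "min_scale"))
  max_scale <- as.integer(check_scalar_num(max_scale, "max_scale"))
  n_scales <- as.integer(check_scalar_num(n_scales, "n_scales"))
  detrend_order <- as.integer(check_scalar_num(detrend_order, "detrend_order"))
  if (min_scale < 4 || min_scale >= max_scale || max_scale > n %/% 4L)
    stopf("scales must satisfy 4 <= min_scale < max_scale <= n/4",
          class = "invalid_parameter")
  if (n < 4 * min_scale)
    stopf("series length %d too short for min_scale %d", n, min_scale,
          class = "insufficient_data")
  if (any(!is.finite(x)))
    stopf("series contains non-finite values", class = "data_error")
  if (stats::sd(x) == 0)
    stopf("zero-variance series: DFA undefined", class = "degenerate_series")

  scales <- unique(round(exp(seq(log(min_scale), log(max_scale),
                                 length.out = n_scales))))
  scales <- scales[scales >= min_scale & scales <= max_scale]
  if (length(scales) < 6)
    stopf("fewer than 6 usable scales between %d and %d", min_scale, max_scale,
          class = "insufficient_data")

  prof <- cumsum(x - mean(x))
  fl <- vapply(scales, function(s) {
    k <- n %/% s
    d <- stats::poly(seq_len(s), degree = detrend_order, raw = TRUE)
    qrd <- qr(cbind(1, d))
    fwd <- matrix(prof[seq_len(k * s)], nrow = s)
    bwd <- matrix(prof[(n - k * s + 1L):n], nrow = s)
    res <- cbind(qr.resid(qrd, fwd), qr.resid(qrd, bwd))
    sqrt(mean(res^2))
  }, numeric(1))

  fit <- stats::lm.fit(cbind(1, log(scales)), log(fl))
  structure(list(alpha = unname(fit$coefficients[2L]),
                 scales = scales, fluctuations = fl),
            class = "dfa_fit")
}

#' @export
print.dfa_fit <- function(x, ...) {
  cat(sprintf("DFA fit: alpha = %.3f over %d scales [%d, %d]\n",
              x$alpha, length(x$scales), min(x$scales), max(x$scales)))
  invisible(x)
}

#' Full complexity profile of one recording's breath series
#'
#' Computes every per-recording metric used in the group analysis: means
#' and coefficients of variation of IBI and RV, sample entropy of each,
#' DFA scaling exponents of each, and the cross-sample entropy between
#' them (RV truncated to the IBI length for alignment).
#'
#' @param series a [breath_series()] object.
#' @param m,r sample-entropy parameters (defaults 2 and 0.2).
#' @param min_scale,n_scales,detrend_order DFA parameters; the maximum
#'   scale is a quarter of each series length.
#' @return a one-row `data.frame` of class `"complexity_profile"` with
#'   columns `n_breaths`, `mean_ibi`, `cv_ibi`, `mean_rv`, `cv_rv`,
#'   `sampen_ibi`, `sampen_rv`, `alpha_ibi`, `alpha_rv`, `cross_sampen`.
#' @export
complexity_profile <- function(series, m = 2, r = 0.2, min_scale = 4,
                               n_scales = 16, detrend_order = 1) {
  stopifnot(inherits(series, "breath_series"))
  ibi <- series$ibi
  rv <- series$rv
  if (length(rv) < 100)
    warning(sprintf("only %d breaths; complexity metrics may be unstable below 100",
                    length(rv)), call. = FALSE)
  summ <- series_summary(series)
  prof <- data.frame(
    n_breaths = length(rv),
    mean_ibi = summ$mean_ibi, cv_ibi = summ$cv_ibi,
    mean_rv = summ$mean_rv, cv_rv = summ$cv_rv,
    sampen_ibi = sample_entropy(ibi, m, r),
    sampen_rv = sample_entropy(rv, m, r),
    alpha_ibi = dfa(ibi, min_scale = min_scale, n_scales = n_scales,
                    detrend_order = detrend_order)$alpha,
    alpha_rv = dfa(rv, min_scale = min_scale, n_scales = n_scales,
                   detrend_order = detrend_order)$alpha,
    cross_sampen = cross_sample_entropy(ibi, rv[seq_along(ibi)], m, r)
  )
  class(prof) <- c("complexity_profile", "data.frame")
  prof
}
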