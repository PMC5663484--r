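# Breath extraction: respiratory signal -> IBI / RV series.

#' Breath series container
#'
#' Paired inter-breath-interval (IBI) and respiratory-volume (RV)
#' sequences for one recording. For `n` detected peaks the IBI series has
#' length `n - 1` (consecutive peak-to-peak intervals in seconds) and the
#' RV series length `n` (peak amplitudes in arbitrary units, measured
#' from the local baseline).
#'
#' @param peak_times strictly increasing peak times in seconds.
#' @param rv positive peak amplitudes, one per peak.
#' @return an object of class `"breath_series"`: a list with `peak_times`,
#'   `rv` and `ibi = diff(peak_times)`.
#' @export
breath_series <- function(peak_times, rv) {
  peak_times <- as.numeric(peak_times)
  rv <- as.numeric(rv)
  if (length(peak_times) != length(rv))
    stopf("peak_times and rv lengths differ", class = "shape_error")
  if (length(peak_times) < 2)
    stopf("need at least 2 peaks for a breath series", class = "insufficient_data")
  if (any(!is.finite(peak_times)) || any(!is.finite(rv)))
    stopf("non-finite values in breath series", class = "data_error")
  if (any(diff(peak_times) <= 0))
    stopf("peak times must be strictly increasing", class = "data_error")
  if (any(rv <= 0))
    stopf("all RV amplitudes must be positive", class = "data_error")
  structure(list(peak_times = peak_times, rv = rv, ibi = diff(peak_times)),
            class = "breath_series")
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("Breath series: %d breaths over %.1f s (mean IBI %.3f s, mean RV %.3f)\n",
              length(x$rv), diff(range(x$peak_times)),
              mean(x$ibi), mean(x$rv)))
  invisible(x)
}

#' Breath-peak detection parameters
#'
#' @param highpass_cutoff high-pass corner in Hz for baseline removal
#'   (default 0.1). Implemented as subtraction of a centered moving
#'   average of width `1/highpass_cutoff` seconds (zero phase).
#' @param min_prominence peak prominence threshold as a fraction of the
#'   window's robust amplitude (median absolute deviation x 1.4826 x 4);
#'   default 0.3, must be in (0, 1).
#' @param refractory minimum spacing between accepted peaks in seconds
#'   (default 0.15); when two candidates are closer, the higher one wins
#'   and ties go to the earlier.
#' @param smoothing_width width of the centered moving-average smoother
#'   in seconds (default 0.02).
#' @return a list of class `"detection_params"`.
#' @export
detection_params <- function(highpass_cutoff = 0.1, min_prominence = 0.3,
                             refractory = 0.15, smoothing_width = 0.02) {
  check_scalar_num(highpass_cutoff, "highpass_cutoff")
  check_scalar_num(min_prominence, "min_prominence")
  check_scalar_num(refractory, "refractory")
  check_scalar_num(smoothing_width, "smoothing_width")
  if (refractory <= 0)
    stopf("`refractory` must be positive", class = "invalid_parameter")
  if (min_prominence <= 0 || min_prominence >= 1)
    stopf("`min_prominence` must be in (0, 1)", class = "invalid_parameter")
  if (highpass_cutoff <= 0 || smoothing_width < 0)
    stopf("invalid filter parameters", class = "invalid_parameter")
  structure(list(highpass_cutoff = highpass_cutoff,
                 min_prominence = min_prominence,
                 refractory = refractory,
                 smoothing_width = smoothing_width),
            class = "detection_params")
}

#' Preprocess a respiratory signal for peak detection
#'
#' Removes slow baseline drift by subtracting a triangular (twice-applied
#' centered moving average) baseline of width `1/highpass_cutoff`
#' seconds, then smooths with a centered moving average of
#' `smoothing_width` seconds. Both operations are symmetric (zero phase),
#' so peak times are not shifted, and the length is preserved.
#'
#' @param signal a [respiratory_signal()].
#' @param params a [detection_params()] list.
#' @return the filtered [respiratory_signal()].
#' @export
preprocess <- function(signal, params = detection_params()) {
  stopifnot(inherits(signal, "respiratory_signal"))
  fs <- signal$fs
  if (params$highpass_cutoff >= fs / 2)
    stopf("highpass_cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)",
          params$highpass_cutoff, fs / 2, class = "invalid_parameter")
  x <- signal$samples
  hp_width <- max(3L, round(fs / params$highpass_cutoff))
  # two passes = triangular kernel: suppresses the breath-band ripple of a
  # plain boxcar baseline (sidelobes squared) while still removing drift
  x <- x - runmean_centered(runmean_centered(x, hp_width), hp_width)
  sm_width <- round(params$smoothing_width * fs)
  if (sm_width > 1L) {
    if (sm_width %% 2L == 0L) sm_width <- sm_width + 1L  # keep symmetric
    x <- runmean_centered(x, sm_width)
  }
  signal$samples <- x
  signal
}

# Indices of strict local maxima; for plateaus the first sample of the
# plateau top is returned.
local_maxima <- function(x) {
  s <- sign(diff(x))
  nz <- which(s != 0)
  if (length(nz) < 2) return(integer(0))
  up_down <- s[nz[-length(nz)]] == 1 & s[nz[-1]] == -1
  nz[c(up_down, FALSE)] + 1L
}

# Topographic prominence of each candidate peak: height above the higher
# of the two key saddles toward the nearest strictly higher peak (or the
# record edge).
peak_prominence <- function(x, peaks) {
  k <- length(peaks)
  if (k == 0) return(numeric(0))
  h <- x[peaks]
  # valley minima between consecutive peaks, plus the two edge segments
  vals <- numeric(k + 1)
  vals[1] <- min(x[seq_len(peaks[1])])
  if (k > 1)
    for (i in seq_len(k - 1))
      vals[i + 1] <- min(x[peaks[i]:peaks[i + 1]])
  vals[k + 1] <- min(x[peaks[k]:length(x)])
  prom <- numeric(k)
  for (i in seq_len(k)) {
    lb <- vals[i]; j <- i - 1
    while (j >= 1 && h[j] <= h[i]) { lb <- min(lb, vals[j]); j <- j - 1 }
    rb <- vals[i + 1]; j <- i + 1
    while (j <= k && h[j] <= h[i]) { rb <- min(rb, vals[j + 1]); j <- j + 1 }
    prom[i] <- h[i] - max(lb, rb)
  }
  prom
}

#' Detect breath peaks in a preprocessed signal
#'
#' Finds local maxima whose topographic prominence reaches
#' `min_prominence` times the robust signal amplitude (median absolute
#' deviation scaled by 1.4826 and multiplied by 4 — an outlier-resistant
#' peak-to-trough estimate for uncalibrated plethysmograph units), then
#' enforces a minimum spacing of `refractory` seconds: when two candidates
#' are too close the higher is kept, ties resolved in favour of the
#' earlier one.
#'
#' @inheritParams preprocess
#' @return integer vector of peak sample indices (possibly empty; a flat
#'   signal yields no peaks and is not an error).
#' @export
detect_breath_peaks <- function(signal, params = detection_params()) {
  stopifnot(inherits(signal, "respiratory_signal"))
  x <- signal$samples
  fs <- signal$fs
  cand <- local_maxima(x)
  if (length(cand) == 0) return(integer(0))
  robust_amp <- stats::mad(x) * 4
  if (robust_amp == 0 && diff(range(x)) == 0) return(integer(0))
  prom <- peak_prominence(x, cand)
  # a sparse pulse train can have MAD 0; fall back to any real prominence
  thr <- if (robust_amp > 0) params$min_prominence * robust_amp else
    1e-8 * diff(range(x))
  cand <- cand[prom >= thr]
  if (length(cand) <= 1) return(cand)

  # greedy refractory enforcement: highest first, earlier wins ties
  min_gap <- params$refractory * fs
  ord <- order(-x[cand], cand)
  keep <- logical(length(cand))
  kept_idx <- numeric(0)
  for (i in ord) {
    if (!any(abs(kept_idx - cand[i]) < min_gap)) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, cand[i])
    }
  }
  sort(cand[keep])
}

#' Build a breath series from detected peaks
#'
#' Converts peak indices to a [breath_series()]: IBIs are consecutive
#' peak-to-peak intervals in seconds; each RV is the signal value at the
#' peak minus the minimum of the signal between its neighbouring peaks
#' (the adjacent troughs), which immunizes the amplitudes against residual
#' baseline drift. The first and last peaks use their single adjacent
#' trough.
#'
#' @inheritParams preprocess
#' @param peaks integer peak indices from [detect_breath_peaks()].
#' @param baseline `"trough"` (default) references each amplitude to the
#'   neighbouring minima; `"absolute"` uses the raw signal value at the
#'   peak.
#' @return a [breath_series()].
#' @export
build_breath_series <- function(signal, peaks, baseline = c("trough", "absolute")) {
  stopifnot(inherits(signal, "respiratory_signal"))
  baseline <- match.arg(baseline)
  peaks <- as.integer(peaks)
  if (length(peaks) < 3)
    stopf("need at least 3 peaks to form a breath series (got %d)",
          length(peaks), class = "insufficient_breaths")
  x <- signal$samples
  k <- length(peaks)
  if (baseline == "absolute") {
    rv <- x[peaks]
  } else {
    troughs <- vapply(seq_len(k - 1),
                      function(i) min(x[peaks[i]:peaks[i + 1]]), numeric(1))
    base <- numeric(k)
    base[1] <- troughs[1]
    base[k] <- troughs[k - 1]
    if (k > 2)
      base[2:(k - 1)] <- pmin(troughs[1:(k - 2)], troughs[2:(k - 1)])
    rv <- x[peaks] - base
  }
  breath_series((peaks - 1L) / signal$fs + signal$start_offset, rv)
}

#' Summary statistics of a breath series
#'
#' @param series a [breath_series()].
#' @return a list with `mean_ibi`, `cv_ibi`, `mean_rv`, `cv_rv`; the CV is
#'   the sample standard deviation (n - 1 denominator) over the mean.
#' @export
series_summary <- function(series) {
  stopifnot(inherits(series, "breath_series"))
  cv <- function(v) {
    m <- mean(v)
    if (m == 0) stopf("zero mean: CV undefined", class = "degenerate_series")
    stats::sd(v) / m
  }
  list(mean_ibi = mean(series$ibi), cv_ibi = cv(series$ibi),
       mean_rv = mean(series$rv), cv_rv = cv(series$rv))
}
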