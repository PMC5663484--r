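# Independent brute-force oracles and small fixture builders.

# Naive O(n^2 m) sample entropy: exhaustive template-pair loops with the
# Chebyshev distance, self-matches excluded by i < j. Tolerance given in
# absolute units.
sampen_naive <- function(x, m, r_abs) {
  n <- length(x)
  M <- n - m
  a <- 0L; b <- 0L
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r_abs) {
        b <- b + 1L
        if (abs(x[i + m] - x[j + m]) <= r_abs) a <- a + 1L
      }
    }
  }
  if (b == 0 || a == 0) return(Inf)
  -log(a / b)
}

# Naive cross-sample entropy: z-normalize both series, count matches over
# ALL ordered (i, j) template pairs across series.
cross_sampen_naive <- function(x, y, m, r) {
  zx <- (x - mean(x)) / sd(x)
  zy <- (y - mean(y)) / sd(y)
  M <- length(x) - m
  a <- 0L; b <- 0L
  for (i in seq_len(M)) {
    for (j in seq_len(M)) {
      if (max(abs(zx[i:(i + m - 1)] - zy[j:(j + m - 1)])) <= r) {
        b <- b + 1L
        if (abs(zx[i + m] - zy[j + m]) <= r) a <- a + 1L
      }
    }
  }
  if (b == 0 || a == 0) return(Inf)
  -log(a / b)
}

# Noise-free rendered breath train with known ground truth.
make_clean_recording <- function(n_breaths = 120, seed = 11, noise_sd = 0,
                                 drift_amplitude = 0, fs = 1000, ...) {
  spec <- breath_process_spec(n_breaths = n_breaths, seed = seed, ...)
  series <- generate_breath_series(spec)
  render_signal(series,
                render_spec(fs = fs, noise_sd = noise_sd,
                            drift_amplitude = drift_amplitude),
                seed = seed + 1)
}

# Match detected peak times to ground truth within a tolerance; returns
# precision/recall/F1.
detection_f1 <- function(detected_times, truth_times, tol = 0.05) {
  used <- rep(FALSE, length(truth_times))
  tp <- 0L
  for (t in detected_times) {
    d <- abs(truth_times - t)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      tp <- tp + 1L
      used[which.min(d)] <- TRUE
    }
  }
  precision <- tp / max(1L, length(detected_times))
  recall <- tp / max(1L, length(truth_times))
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}
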