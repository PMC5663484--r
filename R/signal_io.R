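# Reading, writing and windowing of respiratory pressure signals.
#
# CSV dialect: one header line `# fs=<Hz>` (optionally followed by further
# `# key=value` metadata lines), then one sample value per line or
# `time,value` pairs. Written files are lossless at 17 significant digits.

#' Respiratory signal container
#'
#' A uniformly sampled single-channel pressure trace with its sampling
#' rate, as recorded by whole-body plethysmography.
#'
#' @param samples numeric vector of pressure values (arbitrary units);
#'   all values must be finite.
#' @param fs sampling rate in Hz (the recordings this package targets are
#'   acquired at 1 kHz).
#' @param start_offset time of the first sample in seconds (default 0).
#' @param metadata named list of free-form annotations (subject id, group
#'   label, ...).
#' @return an object of class `"respiratory_signal"`.
#' @export
respiratory_signal <- function(samples, fs, start_offset = 0, metadata = list()) {
  check_scalar_num(fs, "fs")
  if (fs <= 0) stopf("`fs` must be positive", class = "invalid_parameter")
  samples <- as.numeric(samples)
  if (length(samples) == 0)
    stopf("empty sample vector", class = "format_error")
  bad <- which(!is.finite(samples))
  if (length(bad))
    stopf("non-finite sample at index %d (0-based)", bad[1] - 1L,
          class = "data_error")
  structure(list(samples = samples, fs = fs,
                 start_offset = check_scalar_num(start_offset, "start_offset"),
                 metadata = metadata),
            class = "respiratory_signal")
}

#' @export
print.respiratory_signal <- function(x, ...) {
  cat(sprintf("Respiratory signal: %d samples at %g Hz (%.1f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), unlist(x$metadata),
                             sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a respiratory signal
#'
#' @param path file to read.
#' @param format only `"csv"` (the dialect above) is implemented; WFDB
#'   records are not supported and raise an error.
#' @return a [respiratory_signal()]. Metadata lines (`# key=value` after
#'   the `fs` header) populate `metadata`.
#' @export
read_signal <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "wfdb")
    stopf("WFDB input is not supported; convert to the csv dialect",
          class = "format_error")
  if (!file.exists(path))
    stopf("file not found: %s", path, class = "io_error")
  con <- file(path, "r"); on.exit(close(con))
  meta <- list(); fs <- NULL; n_header <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0 || !startsWith(line, "#")) break
    n_header <- n_header + 1L
    kv <- strsplit(trimws(sub("^#", "", line)), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) {
      if (kv[1] == "fs") fs <- as.numeric(kv[2]) else meta[[kv[1]]] <- kv[2]
    }
  }
  if (is.null(fs) || !is.finite(fs))
    stopf("missing `# fs=<Hz>` header in %s", path, class = "format_error")
  close(con); on.exit()
  first_data <- line
  has_time <- grepl(",", first_data, fixed = TRUE)
  if (has_time) {
    m <- utils::read.csv(path, header = FALSE, skip = n_header,
                         colClasses = "numeric")
    samples <- m[[2]]
  } else {
    samples <- scan(path, what = double(), skip = n_header, quiet = TRUE)
  }
  bad <- which(!is.finite(samples))
  if (length(bad))
    stopf("non-finite sample at index %d (0-based) in %s", bad[1] - 1L, path,
          class = "data_error")
  respiratory_signal(samples, fs = fs, metadata = meta)
}

#' Write a respiratory signal
#'
#' Inverse of [read_signal()]; lossless for the csv dialect at 17
#' significant digits.
#'
#' @param signal a [respiratory_signal()].
#' @param path destination file.
#' @param format only `"csv"`.
#' @export
write_signal <- function(signal, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "wfdb")
    stopf("WFDB output is not supported", class = "format_error")
  stopifnot(inherits(signal, "respiratory_signal"))
  if (length(signal$samples) == 0)
    stopf("refusing to write an empty signal", class = "format_error")
  header <- sprintf("# fs=%s", format(signal$fs, digits = 17))
  meta <- vapply(names(signal$metadata),
                 function(k) sprintf("# %s=%s", k, signal$metadata[[k]]),
                 character(1))
  body <- formatC(signal$samples, digits = 17, format = "g")
  ok <- tryCatch({
    writeLines(c(header, meta, body), path)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write to %s", path, class = "io_error")
  invisible(path)
}

#' Write / read a breath series as TSV
#'
#' Two data columns `ibi_s` and `rv_au` plus `peak_time_s`, one header
#' line. The first row's `ibi_s` is `NA` (there is one fewer interval
#' than peaks).
#'
#' @param series a [breath_series()].
#' @param path destination / source file.
#' @return `read_breath_series` returns a [breath_series()].
#' @export
write_breath_series <- function(series, path) {
  stopifnot(inherits(series, "breath_series"))
  df <- data.frame(ibi_s = c(NA, series$ibi), rv_au = series$rv,
                   peak_time_s = series$peak_times)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_breath_series
#' @export
read_breath_series <- function(path) {
  df <- utils::read.delim(path)
  breath_series(df$peak_time_s, df$rv_au)
}

#' Select the lowest-artifact analysis window
#'
#' Slides a window of `duration` seconds over the signal in steps of
#' `hop` seconds and scores each position with a two-term artifact index:
#' `w1 *` (fraction of samples further than 5 robust SDs from the window
#' median — movement/pressure artifacts) `+ w2 *` (fraction of spectral
#' power outside the breathing band — sniffing bouts, still periods,
#' drift). The minimal-score window is returned; ties break to the
#' earliest start. Scoring runs on a ~50 Hz decimated copy of the signal
#' (block means), which preserves the breathing band while keeping the
#' per-window spectra cheap.
#'
#' @param signal a [respiratory_signal()].
#' @param duration window length in seconds (default 1200, i.e. the
#'   20-minute segment used for breathing-pattern analysis).
#' @param hop window step in seconds (default 30).
#' @param band breathing band in Hz (default `c(0.5, 5)`, matching
#'   guinea-pig respiratory rates of roughly 1-3 Hz).
#' @param weights the two score weights `c(w1, w2)` (default 0.5, 0.5).
#' @return a list of class `"analysis_window"` with `start_index`
#'   (1-based sample index into the signal), `duration` (s) and
#'   `artifact_score`.
#' @export
select_analysis_window <- function(signal, duration = 1200, hop = 30,
                                   band = c(0.5, 5), weights = c(0.5, 0.5)) {
  stopifnot(inherits(signal, "respiratory_signal"))
  fs <- signal$fs
  n <- length(signal$samples)
  len <- round(duration * fs)
  if (n < len)
    stopf("signal (%.1f s) shorter than the analysis window (%.1f s)",
          n / fs, duration, class = "insufficient_data")

  # decimate to ~50 Hz by block means for scoring
  dec <- max(1L, floor(fs / 50))
  nd <- n %/% dec
  xd <- colMeans(matrix(signal$samples[seq_len(nd * dec)], nrow = dec))
  fsd <- fs / dec
  len_d <- max(2L, round(duration * fsd))
  hop_d <- max(1L, round(hop * fsd))
  starts_d <- unique(c(seq(1L, nd - len_d + 1L, by = hop_d), nd - len_d + 1L))

  score_one <- function(s0) {
    w <- xd[s0:(s0 + len_d - 1L)]
    med <- stats::median(w)
    madv <- stats::mad(w)
    amp_frac <- if (madv > 0) mean(abs(w - med) > 5 * madv) else mean(w != med)
    wc <- w - mean(w)
    p <- Mod(stats::fft(wc))^2
    half <- seq_len(floor(length(wc) / 2))
    freqs <- (half) * fsd / length(wc)
    pw <- p[half + 1L]
    tot <- sum(pw)
    out_frac <- if (tot > 0) sum(pw[freqs < band[1] | freqs > band[2]]) / tot else 0
    weights[1] * amp_frac + weights[2] * out_frac
  }
  scores <- vapply(starts_d, score_one, numeric(1))
  best <- which.min(scores)  # which.min takes the earliest on ties
  start_index <- (starts_d[best] - 1L) * dec + 1L
  if (start_index + len - 1L > n) start_index <- n - len + 1L
  structure(list(start_index = start_index, duration = duration,
                 artifact_score = scores[best],
                 scores = scores,
                 starts = (starts_d - 1L) * dec + 1L),
            class = "analysis_window")
}

#' Extract the samples of an analysis window as a new signal
#'
#' @param signal a [respiratory_signal()].
#' @param window an `"analysis_window"` from [select_analysis_window()].
#' @return a [respiratory_signal()] restricted to the window, with
#'   `start_offset` advanced accordingly.
#' @export
crop_to_window <- function(signal, window) {
  stopifnot(inherits(signal, "respiratory_signal"),
            inherits(window, "analysis_window"))
  len <- round(window$duration * signal$fs)
  idx <- window$start_index:(window$start_index + len - 1L)
  respiratory_signal(signal$samples[idx], signal$fs,
                     start_offset = signal$start_offset +
                       (window$start_index - 1L) / signal$fs,
                     metadata = signal$metadata)
}
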