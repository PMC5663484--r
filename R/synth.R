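# Synthetic plethysmography: stochastic breath processes with known
# ground-truth complexity, rendered into realistic pressure signals.

#' Breath-process generative parameters
#'
#' Defines a stochastic process for one recording's breath-by-breath
#' dynamics. Interval and amplitude innovations are fractional Gaussian
#' noise with controllable Hurst exponents (long-range correlation), may
#' share a common fGn stream (interval-amplitude coupling), and can be
#' blended with a deterministic period-3 cycle that lowers entropy while
#' preserving the mean and CV (the `regularity` control). Occasional
#' deep inspirations (sighs) multiply the breath amplitude.
#'
#' @param n_breaths number of breaths to generate.
#' @param ibi_mean mean inter-breath interval in seconds.
#' @param ibi_cv coefficient of variation of the intervals.
#' @param ibi_hurst Hurst exponent of the interval innovations, in (0,1).
#' @param rv_mean mean breath amplitude (arbitrary units).
#' @param rv_cv coefficient of variation of the amplitudes.
#' @param rv_hurst Hurst exponent of the amplitude innovations.
#' @param coupling_rho fraction of innovation variance shared between
#'   intervals and amplitudes, in `[-1, 1]`; 1 makes the two z-series
#'   identical, negative values anticorrelate them. Also scales how much
#'   of the shared regular cycle (see `regularity`) the amplitudes carry.
#' @param regularity convex blend weight of the shared deterministic
#'   period-3 cycle in the interval innovations, in `[0, 1]` (the
#'   amplitude innovations receive it with weight
#'   `coupling_rho * regularity`): 0 is fully stochastic; 1 makes the
#'   interval sequence a strictly periodic cycle with (near-)zero sample
#'   entropy. The blend is rescaled to unit innovation SD so the CV is
#'   unchanged.
#' @param sigh_rate per-breath probability of a deep inspiration,
#'   in `[0, 0.2)`.
#' @param sigh_amplitude_factor amplitude multiplier of a sigh (> 1).
#' @param sigh_affects_ibi if TRUE the interval following a sigh is
#'   lengthened by the same factor (post-sigh pause); default FALSE.
#' @param seed integer seed for reproducibility.
#' @return a list of class `"breath_process_spec"`.
#' @export
breath_process_spec <- function(n_breaths = 1200, ibi_mean = 0.5,
                                ibi_cv = 0.08, ibi_hurst = 0.6,
                                rv_mean = 1, rv_cv = 0.1, rv_hurst = 0.6,
                                coupling_rho = 0.2, regularity = 0.1,
                                sigh_rate = 0.002, sigh_amplitude_factor = 2.5,
                                sigh_affects_ibi = FALSE, seed = 1L) {
  spec <- list(n_breaths = as.integer(check_scalar_num(n_breaths, "n_breaths")),
               ibi_mean = check_scalar_num(ibi_mean, "ibi_mean"),
               ibi_cv = check_scalar_num(ibi_cv, "ibi_cv"),
               ibi_hurst = check_scalar_num(ibi_hurst, "ibi_hurst"),
               rv_mean = check_scalar_num(rv_mean, "rv_mean"),
               rv_cv = check_scalar_num(rv_cv, "rv_cv"),
               rv_hurst = check_scalar_num(rv_hurst, "rv_hurst"),
               coupling_rho = check_scalar_num(coupling_rho, "coupling_rho"),
               regularity = check_scalar_num(regularity, "regularity"),
               sigh_rate = check_scalar_num(sigh_rate, "sigh_rate"),
               sigh_amplitude_factor = check_scalar_num(sigh_amplitude_factor,
                                                        "sigh_amplitude_factor"),
               sigh_affects_ibi = isTRUE(sigh_affects_ibi),
               seed = as.integer(check_scalar_num(seed, "seed")))
  if (spec$n_breaths < 16)
    stopf("`n_breaths` must be >= 16", class = "invalid_parameter")
  if (spec$ibi_mean <= 0 || spec$rv_mean <= 0)
    stopf("`ibi_mean` and `rv_mean` must be positive", class = "invalid_parameter")
  if (spec$ibi_cv < 0 || spec$rv_cv < 0)
    stopf("CVs must be non-negative", class = "invalid_parameter")
  if (spec$ibi_hurst <= 0 || spec$ibi_hurst >= 1 ||
      spec$rv_hurst <= 0 || spec$rv_hurst >= 1)
    stopf("Hurst exponents must lie in (0, 1)", class = "invalid_parameter")
  if (abs(spec$coupling_rho) > 1)
    stopf("`coupling_rho` must lie in [-1, 1]", class = "invalid_parameter")
  if (spec$regularity < 0 || spec$regularity > 1)
    stopf("`regularity` must lie in [0, 1]", class = "invalid_parameter")
  if (spec$sigh_rate < 0 || spec$sigh_rate >= 0.2)
    stopf("`sigh_rate` must lie in [0, 0.2)", class = "invalid_parameter")
  if (spec$sigh_rate > 0 && spec$sigh_amplitude_factor <= 1)
    stopf("`sigh_amplitude_factor` must exceed 1", class = "invalid_parameter")
  class(spec) <- "breath_process_spec"
  spec
}

#' Generate a stochastic breath series
#'
#' Realizes the process defined by a [breath_process_spec()]:
#' `gap_k = ibi_mean * (1 + ibi_cv * z_k)` and
#' `rv_k = rv_mean * (1 + rv_cv * y_k)`, where the z/y innovations are
#' fGn with the requested Hurst exponents, partially shared between the
#' two series according to `coupling_rho`, and additionally blended
#' (variance-preserving, so means and CVs are unchanged) with a shared
#' deterministic zero-mean unit-SD period-3 cycle: weight `regularity`
#' in the intervals, weight `coupling_rho * regularity` in the
#' amplitudes. The cycle lowers the entropy of the rhythm, and because
#' it is common to both series it synchronizes them (lower cross-sample
#' entropy) in proportion to the coupling. Gaps are floored at
#' `0.2 * ibi_mean`
#' (and amplitudes at `0.05 * rv_mean`) to keep them positive; truncation
#' events are counted in the `"truncations"` attribute. Sighs multiply
#' the amplitude (and optionally the following gap) by
#' `sigh_amplitude_factor`.
#'
#' Peak times are the cumulative sum of the gaps, so the ground-truth IBI
#' series analysed downstream is `diff(peak_times)`.
#'
#' @param spec a [breath_process_spec()].
#' @return a [breath_series()] with attribute `"truncations"` (count of
#'   floored values) and `"sighs"` (indices of sigh breaths).
#' @export
generate_breath_series <- function(spec) {
  stopifnot(inherits(spec, "breath_process_spec"))
  n <- spec$n_breaths
  rho <- spec$coupling_rho
  g <- spec$regularity

  draws <- with_seed(spec$seed, {
    e_x <- generate_fgn(max(n, 16), spec$ibi_hurst)
    e_y <- generate_fgn(max(n, 16), spec$rv_hurst)
    shared <- generate_fgn(max(n, 16), (spec$ibi_hurst + spec$rv_hurst) / 2)
    sighs <- stats::runif(n) < spec$sigh_rate
    list(e_x = e_x[seq_len(n)], e_y = e_y[seq_len(n)],
         shared = shared[seq_len(n)], sighs = sighs)
  })

  zx <- sqrt(1 - abs(rho)) * draws$e_x + sqrt(abs(rho)) * draws$shared
  zy <- sqrt(1 - abs(rho)) * draws$e_y + sign(rho + (rho == 0)) *
    sqrt(abs(rho)) * draws$shared

  # Deterministic period-3 cycle, zero mean and unit SD over a period.
  # The cycle is the *shared* regular rhythm: it enters the interval
  # innovations with weight `regularity` and the amplitude innovations
  # with weight `coupling_rho * regularity` (the amplitudes follow the
  # regular rhythm only to the extent they are coupled to it). Cross-
  # template matching responds to shared repeating sub-patterns, not to
  # instantaneous correlation, so this is what makes coupled recordings
  # measurably synchronized; keeping the amplitude cycle weight below the
  # interval one also preserves the amplitudes' Hurst structure, which a
  # dominant periodic component would mask.
  cyc <- rep_len(c(1, 0, -1) * sqrt(3 / 2), n)
  blend <- function(z, w) if (w == 0) z else
    ((1 - w) * z + w * cyc) / sqrt((1 - w)^2 + w^2)
  zx <- blend(zx, g)
  zy <- blend(zy, abs(rho) * g)

  gaps <- spec$ibi_mean * (1 + spec$ibi_cv * zx)
  rv <- spec$rv_mean * (1 + spec$rv_cv * zy)
  floor_ibi <- 0.2 * spec$ibi_mean
  floor_rv <- 0.05 * spec$rv_mean
  n_trunc <- sum(gaps < floor_ibi) + sum(rv < floor_rv)
  gaps <- pmax(gaps, floor_ibi)
  rv <- pmax(rv, floor_rv)

  sighs <- which(draws$sighs)
  if (length(sighs)) {
    rv[sighs] <- rv[sighs] * spec$sigh_amplitude_factor
    if (spec$sigh_affects_ibi) {
      after <- sighs[sighs < n] + 1L
      gaps[after] <- gaps[after] * spec$sigh_amplitude_factor
    }
  }

  out <- breath_series(cumsum(gaps), rv)
  attr(out, "truncations") <- n_trunc
  attr(out, "sighs") <- sighs
  out
}

#' Signal rendering parameters
#'
#' @param fs sampling rate in Hz (default 1000).
#' @param waveform breath pulse shape: `"raised_cosine"` (default) or
#'   `"gaussian_pulse"`.
#' @param noise_sd SD of additive Gaussian measurement noise (amplitude
#'   units).
#' @param drift_amplitude,drift_period sinusoidal baseline drift
#'   amplitude (units) and period (seconds); amplitude 0 disables it.
#' @param artifact_epochs list of `c(start_s, duration_s, gain)` triples;
#'   each epoch's samples are multiplied by `gain`. Epochs must not
#'   overlap and must lie within the record.
#' @return a list of class `"render_spec"`.
#' @export
render_spec <- function(fs = 1000, waveform = c("raised_cosine", "gaussian_pulse"),
                        noise_sd = 0.02, drift_amplitude = 0.1,
                        drift_period = 60, artifact_epochs = list()) {
  waveform <- match.arg(waveform)
  check_scalar_num(fs, "fs")
  if (fs <= 0) stopf("`fs` must be positive", class = "invalid_parameter")
  if (check_scalar_num(noise_sd, "noise_sd") < 0)
    stopf("`noise_sd` must be non-negative", class = "invalid_parameter")
  check_scalar_num(drift_amplitude, "drift_amplitude")
  if (check_scalar_num(drift_period, "drift_period") <= 0)
    stopf("`drift_period` must be positive", class = "invalid_parameter")
  if (length(artifact_epochs)) {
    ep <- do.call(rbind, lapply(artifact_epochs, function(e) {
      if (length(e) != 3) stopf("artifact epochs are (start, duration, gain) triples",
                                class = "invalid_parameter")
      as.numeric(e)
    }))
    ep <- ep[order(ep[, 1]), , drop = FALSE]
    if (any(ep[, 1] < 0) || any(ep[, 2] <= 0))
      stopf("artifact epochs must have non-negative start and positive duration",
            class = "invalid_parameter")
    if (nrow(ep) > 1 && any(ep[-nrow(ep), 1] + ep[-nrow(ep), 2] > ep[-1, 1]))
      stopf("artifact epochs overlap", class = "invalid_parameter")
  }
  structure(list(fs = fs, waveform = waveform, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude, drift_period = drift_period,
                 artifact_epochs = artifact_epochs),
            class = "render_spec")
}

#' Render a breath series into a plethysmography-like signal
#'
#' Each breath becomes one smooth unimodal pulse whose peak amplitude is
#' the breath's RV and whose peak time is the breath's ground-truth peak
#' time. Pulse width adapts to the local inter-peak gaps (90% of the
#' smaller neighbouring gap, capped at the mean gap) so pulses never
#' overlap and peak positions are exact. Additive Gaussian noise,
#' sinusoidal baseline drift, and gain-multiplied artifact epochs are
#' applied afterwards.
#'
#' @param series a [breath_series()] (e.g. from
#'   [generate_breath_series()]).
#' @param render a [render_spec()].
#' @param duration requested record length in seconds; defaults to the
#'   span of the series plus a half-second pad. If the series spans more
#'   than twice the requested duration a configuration error is raised;
#'   breaths beyond the duration are dropped.
#' @param seed seed for the additive noise.
#' @param metadata metadata list attached to the returned signal.
#' @return a [respiratory_signal()] with the rendered (and possibly
#'   truncated) ground-truth [breath_series()] in attribute `"truth"`,
#'   within which artifact epochs are recorded in attribute
#'   `"artifact_epochs"`.
#' @export
render_signal <- function(series, render = render_spec(), duration = NULL,
                          seed = NULL, metadata = list()) {
  stopifnot(inherits(series, "breath_series"), inherits(render, "render_spec"))
  fs <- render$fs
  span <- max(series$peak_times)
  if (is.null(duration)) duration <- span + 0.5
  if (span > 2 * duration)
    stopf("breath series spans %.1f s, more than twice the requested %.1f s record",
          span, duration, class = "configuration_error")
  keep <- series$peak_times < duration - 0.1
  if (sum(keep) < 2)
    stopf("fewer than 2 breaths fall inside the requested duration",
          class = "configuration_error")
  pt <- series$peak_times[keep]
  rv <- series$rv[keep]

  n <- round(duration * fs)
  x <- numeric(n)
  gaps <- diff(pt)
  mean_gap <- mean(gaps)
  left <- c(gaps[1], gaps)
  right <- c(gaps, gaps[length(gaps)])
  widths <- pmin(0.9 * pmin(left, right), mean_gap)

  for (k in seq_along(pt)) {
    w <- widths[k]
    i0 <- max(1L, ceiling((pt[k] - w / 2) * fs) + 1L)
    i1 <- min(n, floor((pt[k] + w / 2) * fs) + 1L)
    if (i1 < i0) next
    t_rel <- ((i0:i1) - 1L) / fs - pt[k]
    pulse <- if (render$waveform == "raised_cosine") {
      0.5 * (1 + cos(2 * pi * t_rel / w))
    } else {
      exp(-0.5 * (t_rel / (w / 6))^2)
    }
    x[i0:i1] <- x[i0:i1] + rv[k] * pulse
  }

  tt <- (seq_len(n) - 1L) / fs
  if (render$drift_amplitude != 0)
    x <- x + render$drift_amplitude * sin(2 * pi * tt / render$drift_period)
  if (render$noise_sd > 0)
    x <- x + with_seed(seed, stats::rnorm(n, sd = render$noise_sd))
  for (e in render$artifact_epochs) {
    if (e[1] + e[2] > duration)
      stopf("artifact epoch [%g, %g] extends beyond the %g s record",
            e[1], e[1] + e[2], duration, class = "invalid_parameter")
    idx <- (floor(e[1] * fs) + 1L):min(n, floor((e[1] + e[2]) * fs))
    x[idx] <- x[idx] * e[3]
  }

  sig <- respiratory_signal(x, fs = fs, metadata = metadata)
  attr(sig, "truth") <- breath_series(pt, rv)
  attr(sig, "artifact_epochs") <- render$artifact_epochs
  sig
}

#' Built-in cohort templates
#'
#' `control_like_spec()` emulates healthy respiratory dynamics: mostly
#' stochastic intervals with mild long-range correlation and weak
#' interval-amplitude coupling. `asthma_like_spec()` shifts every control
#' toward the pattern reported for allergen-exposed animals: a strong
#' regular (low-entropy) interval component, 1.5x the interval CV, a high
#' amplitude Hurst exponent (raised DFA alpha of RV), and strong
#' interval-amplitude coupling (lower cross-SampEn, i.e. increased
#' synchronization). Means are identical across templates.
#'
#' @param ... overrides passed on to [breath_process_spec()].
#' @return a [breath_process_spec()].
#' @export
control_like_spec <- function(...) {
  args <- utils::modifyList(
    list(ibi_mean = 0.5, ibi_cv = 0.08, ibi_hurst = 0.6,
         rv_mean = 1, rv_cv = 0.1, rv_hurst = 0.6,
         coupling_rho = 0.2, regularity = 0.1,
         sigh_rate = 0.002, sigh_amplitude_factor = 2.5),
    list(...))
  do.call(breath_process_spec, args)
}

#' @rdname control_like_spec
#' @export
asthma_like_spec <- function(...) {
  args <- utils::modifyList(
    list(ibi_mean = 0.5, ibi_cv = 0.12, ibi_hurst = 0.6,
         rv_mean = 1, rv_cv = 0.1, rv_hurst = 0.9,
         coupling_rho = 0.8, regularity = 0.6,
         sigh_rate = 0.002, sigh_amplitude_factor = 2.5),
    list(...))
  do.call(breath_process_spec, args)
}

#' Cohort-level generative configuration
#'
#' @param groups named list of [breath_process_spec()] templates, one per
#'   experimental group; names must be unique.
#' @param n_per_group recordings per group (at least 2 for downstream
#'   group comparison; 1 is allowed at generation time).
#' @param record_duration record length in seconds (default 3600, the
#'   60-minute main recording period).
#' @param render a [render_spec()].
#' @param master_seed integer; per-recording seeds are derived
#'   deterministically from `(master_seed, group, index)`.
#' @return a list of class `"synth_cohort_config"`.
#' @export
synth_cohort_config <- function(groups, n_per_group = 10,
                                record_duration = 3600,
                                render = render_spec(), master_seed = 1L) {
  if (is.null(names(groups)) || anyDuplicated(names(groups)) ||
      any(names(groups) == ""))
    stopf("`groups` must be a uniquely named list", class = "configuration_error")
  for (gspec in groups)
    if (!inherits(gspec, "breath_process_spec"))
      stopf("each group template must be a breath_process_spec",
            class = "configuration_error")
  n_per_group <- as.integer(check_scalar_num(n_per_group, "n_per_group"))
  if (n_per_group < 1)
    stopf("`n_per_group` must be >= 1", class = "configuration_error")
  check_scalar_num(record_duration, "record_duration")
  stopifnot(inherits(render, "render_spec"))
  structure(list(groups = groups, n_per_group = n_per_group,
                 record_duration = record_duration, render = render,
                 master_seed = as.integer(check_scalar_num(master_seed,
                                                           "master_seed"))),
            class = "synth_cohort_config")
}

#' Generate a labeled synthetic cohort
#'
#' Produces `n_per_group` rendered recordings per group, each with its
#' ground-truth breath series attached, fully reproducible from
#' `master_seed` (per-recording seeds are a deterministic hash of the
#' master seed, the group label and the recording index).
#'
#' @param cfg a [synth_cohort_config()].
#' @return a list of class `"synth_cohort"`: `signals` (named list of
#'   [respiratory_signal()]s, each with `"truth"` attribute and
#'   `metadata$group` / `metadata$subject`), plus the `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_cohort_config"))
  signals <- list()
  for (grp in names(cfg$groups)) {
    template <- cfg$groups[[grp]]
    n_breaths <- ceiling(cfg$record_duration / template$ibi_mean * 1.1) + 16
    for (i in seq_len(cfg$n_per_group)) {
      seed_i <- derive_seed(cfg$master_seed, grp, i)
      spec_i <- template
      spec_i$seed <- seed_i
      spec_i$n_breaths <- as.integer(n_breaths)
      series <- generate_breath_series(spec_i)
      subject <- sprintf("%s_%02d", grp, i)
      sig <- render_signal(series, cfg$render,
                           duration = cfg$record_duration,
                           seed = seed_i + 1L,
                           metadata = list(subject = subject, group = grp))
      signals[[subject]] <- sig
    }
  }
  structure(list(signals = signals, config = cfg), class = "synth_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Writes one signal csv and one ground-truth breath-series TSV per
#' recording, plus a YAML manifest of the generative configuration.
#'
#' @param cohort a `"synth_cohort"` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$signals)) {
    sig <- cohort$signals[[nm]]
    write_signal(sig, file.path(dir, paste0(nm, ".csv")))
    write_breath_series(attr(sig, "truth"),
                        file.path(dir, paste0(nm, "_truth.tsv")))
  }
  cfg <- cohort$config
  manifest <- list(
    n_per_group = cfg$n_per_group,
    record_duration = cfg$record_duration,
    master_seed = cfg$master_seed,
    render = unclass(cfg$render),
    groups = lapply(cfg$groups, unclass)
  )
  yaml::write_yaml(manifest, file.path(dir, "cohort.yaml"))
  invisible(dir)
}

#' Read a cohort configuration from a YAML manifest
#'
#' @param path YAML file with the fields of [synth_cohort_config()]
#'   (group templates as [breath_process_spec()] field lists).
#' @return a [synth_cohort_config()].
#' @export
read_cohort_config <- function(path) {
  m <- yaml::read_yaml(path)
  groups <- lapply(m$groups, function(g) do.call(breath_process_spec, g))
  render <- if (is.null(m$render)) render_spec() else {
    m$render$artifact_epochs <- m$render$artifact_epochs %||% list()
    do.call(render_spec, m$render)
  }
  synth_cohort_config(groups = groups,
                      n_per_group = m$n_per_group %||% 10,
                      record_duration = m$record_duration %||% 3600,
                      render = render,
                      master_seed = m$master_seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
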