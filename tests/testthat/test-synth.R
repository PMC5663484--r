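test_that("breath process spec validates its invariants", {
  expect_error(breath_process_spec(ibi_mean = -1), class = "invalid_parameter")
  expect_error(breath_process_spec(ibi_hurst = 1.1), class = "invalid_parameter")
  expect_error(breath_process_spec(regularity = 1.5), class = "invalid_parameter")
  expect_error(breath_process_spec(sigh_rate = 0.3), class = "invalid_parameter")
  expect_error(breath_process_spec(coupling_rho = 2), class = "invalid_parameter")
  expect_error(breath_process_spec(sigh_rate = 0.01, sigh_amplitude_factor = 0.9),
               class = "invalid_parameter")
})

test_that("regularity = 1 produces a strictly periodic, near-zero-entropy rhythm", {
  spec <- breath_process_spec(n_breaths = 300, regularity = 1, sigh_rate = 0,
                              seed = 3)
  s <- generate_breath_series(spec)
  # strict period-3 cycle in the intervals
  L <- length(s$ibi)
  expect_lt(max(abs(s$ibi[1:(L - 3)] - s$ibi[4:L])), 1e-12)
  expect_lt(sample_entropy(s$ibi), 0.05)
  # degenerate constant rhythm: zero interval CV
  s0 <- generate_breath_series(breath_process_spec(n_breaths = 300,
                                                   regularity = 1, ibi_cv = 0,
                                                   sigh_rate = 0, seed = 3))
  expect_equal(series_summary(s0)$cv_ibi, 0)
})

test_that("mean and CV are preserved across regularity levels", {
  for (g in c(0, 0.5, 0.9)) {
    s <- generate_breath_series(breath_process_spec(n_breaths = 3000,
                                                    regularity = g,
                                                    sigh_rate = 0, seed = 17))
    summ <- series_summary(s)
    expect_lt(abs(summ$mean_ibi - 0.5), 0.01)
    expect_lt(abs(summ$cv_ibi - 0.08), 0.015)
  }
})

test_that("full coupling makes interval and amplitude innovations identical", {
  spec <- breath_process_spec(n_breaths = 400, coupling_rho = 1,
                              ibi_hurst = 0.7, rv_hurst = 0.7,
                              ibi_cv = 0.1, rv_cv = 0.1,
                              sigh_rate = 0, seed = 9)
  s <- generate_breath_series(spec)
  # same z-series up to affine scale: gaps/ibi_mean - 1 proportional to rv/rv_mean - 1
  zx <- (c(s$peak_times[1], s$ibi) / 0.5 - 1) / 0.1
  zy <- (s$rv / 1 - 1) / 0.1
  expect_equal(zx, zy, tolerance = 1e-10)
  # and cross-SampEn then equals the self-match-allowed entropy of the
  # shared series, by the naive oracle
  ibi <- s$ibi[1:120]; rv <- s$rv[2:121]
  expect_equal(cross_sample_entropy(ibi, rv, m = 2, r = 0.2),
               cross_sampen_naive(ibi, rv, m = 2, r = 0.2))
})

test_that("sample entropy of the rhythm is non-increasing in regularity", {
  levels <- c(0, 0.3, 0.6, 0.9)
  means <- vapply(levels, function(g) {
    mean(vapply(1:20, function(s) {
      ser <- generate_breath_series(breath_process_spec(n_breaths = 400,
                                                        regularity = g,
                                                        sigh_rate = 0,
                                                        seed = 40 + s))
      sample_entropy(ser$ibi)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0.02))  # non-increasing up to MC noise
  expect_lt(means[4], means[1] - 0.5)    # and strongly decreasing overall
})

test_that("cross-sample entropy is non-increasing in coupling", {
  # measured where the shared regular component is appreciable
  levels <- c(0, 0.3, 0.6, 0.9)
  means <- vapply(levels, function(rho) {
    mean(vapply(1:20, function(s) {
      ser <- generate_breath_series(breath_process_spec(n_breaths = 400,
                                                        coupling_rho = rho,
                                                        regularity = 0.4,
                                                        sigh_rate = 0,
                                                        seed = 70 + s))
      cross_sample_entropy(ser$ibi, ser$rv[-1])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) <= 0.02))
  expect_lt(means[4], means[1])  # strictly lower at strong coupling
})

test_that("interval floor truncation is applied and counted", {
  spec <- breath_process_spec(n_breaths = 200, ibi_cv = 0.8, regularity = 0,
                              sigh_rate = 0, seed = 2)
  s <- generate_breath_series(spec)
  expect_true(all(s$ibi >= 0.2 * 0.5 - 1e-12))
  expect_gt(attr(s, "truncations"), 0)
})

test_that("rendering a noiseless train puts signal maxima on the true peaks", {
  sig <- make_clean_recording(n_breaths = 100, seed = 5)
  truth <- attr(sig, "truth")
  fs <- sig$fs
  for (k in seq_along(truth$peak_times)) {
    i0 <- round(truth$peak_times[k] * fs) + 1
    win <- sig$samples[(i0 - 50):(i0 + 50)]
    expect_lt(abs(which.max(win) - 51), 1.5)  # within one sample
    # amplitude exact up to the sub-sample offset of the true peak time
    expect_equal(max(win), truth$rv[k], tolerance = 1e-4)
  }
})

test_that("rendered signal length follows the requested duration", {
  spec <- breath_process_spec(n_breaths = 100, ibi_mean = 0.5, seed = 8)
  series <- generate_breath_series(spec)
  sig <- render_signal(series, render_spec(noise_sd = 0, drift_amplitude = 0))
  # ~100 breaths x 0.5 s at 1 kHz
  expect_lt(abs(length(sig$samples) - 50000), 1500)
})

test_that("render configuration errors are raised", {
  series <- generate_breath_series(breath_process_spec(n_breaths = 100, seed = 1))
  expect_error(render_signal(series, render_spec(), duration = 10),
               class = "configuration_error")
  expect_error(render_spec(artifact_epochs = list(c(0, 10, 5), c(5, 10, 2))),
               class = "invalid_parameter")
})

test_that("cohort generation is reproducible and validates labels", {
  cfg <- synth_cohort_config(
    groups = list(a = control_like_spec(), b = asthma_like_spec()),
    n_per_group = 2, record_duration = 60, master_seed = 12)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(lapply(c1$signals, `[[`, "samples"),
                   lapply(c2$signals, `[[`, "samples"))
  expect_error(synth_cohort_config(groups = list(control_like_spec()),
                                   master_seed = 1),
               class = "configuration_error")
  dup <- list(a = control_like_spec(), a = control_like_spec())
  expect_error(synth_cohort_config(groups = dup, master_seed = 1),
               class = "configuration_error")
})

test_that("cohort round-trips through disk with its manifest", {
  dir <- withr::local_tempdir()
  cfg <- synth_cohort_config(
    groups = list(ctl = control_like_spec(), case = asthma_like_spec()),
    n_per_group = 1, record_duration = 30, master_seed = 4)
  coh <- generate_cohort(cfg)
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "cohort.yaml")))
  cfg2 <- read_cohort_config(file.path(dir, "cohort.yaml"))
  expect_equal(cfg2$groups$case$regularity, cfg$groups$case$regularity)
  expect_equal(cfg2$master_seed, cfg$master_seed)
  sig <- read_signal(file.path(dir, "ctl_01.csv"))
  expect_identical(sig$samples, coh$signals$ctl_01$samples)
  tr <- read_breath_series(file.path(dir, "ctl_01_truth.tsv"))
  expect_equal(tr$peak_times, attr(coh$signals$ctl_01, "truth")$peak_times,
               tolerance = 1e-12)
})
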