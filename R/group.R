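# Cohort-level orchestration and group-comparison statistics.

#' Pipeline configuration
#'
#' Bundles the per-stage parameters of [run_pipeline()].
#'
#' @param window_duration,window_hop analysis-window length and step in
#'   seconds (defaults 1200 and 30).
#' @param detection a [detection_params()].
#' @param m,r sample-entropy parameters.
#' @param min_scale,n_scales,detrend_order DFA parameters.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(window_duration = 1200, window_hop = 30,
                            detection = detection_params(),
                            m = 2, r = 0.2,
                            min_scale = 4, n_scales = 16, detrend_order = 1) {
  structure(list(window_duration = window_duration, window_hop = window_hop,
                 detection = detection, m = m, r = r, min_scale = min_scale,
                 n_scales = n_scales, detrend_order = detrend_order),
            class = "pipeline_config")
}

#' Run the full breathing-pattern pipeline on a cohort
#'
#' For each recording: select the lowest-artifact analysis window,
#' preprocess, detect breath peaks, build the IBI/RV series, and compute
#' the complexity profile. Per-recording failures are recorded with their
#' reason and do not abort the cohort; the run is deterministic given the
#' inputs.
#'
#' @param recordings a `"synth_cohort"`, a named list of
#'   [respiratory_signal()] objects (each with `metadata$group` and
#'   `metadata$subject`), or a character vector of signal file paths
#'   readable by [read_signal()].
#' @param config a [pipeline_config()].
#' @return a list of class `"cohort_result"`: `table` (one row per
#'   successful recording: `subject`, `group`, then all complexity-profile
#'   columns) and `failures` (data frame of `subject`, `reason`).
#' @export
run_pipeline <- function(recordings, config = pipeline_config()) {
  if (inherits(recordings, "synth_cohort")) recordings <- recordings$signals
  if (is.character(recordings)) {
    paths <- recordings
    recordings <- stats::setNames(as.list(paths),
                                  sub("\\.[^.]*$", "", basename(paths)))
  }
  if (length(recordings) == 0)
    stopf("no recordings supplied", class = "pipeline_error")

  rows <- list(); fails <- list()
  for (nm in names(recordings)) {
    res <- tryCatch({
      sig <- recordings[[nm]]
      if (is.character(sig)) sig <- read_signal(sig)
      win <- select_analysis_window(sig, duration = config$window_duration,
                                    hop = config$window_hop)
      seg <- crop_to_window(sig, win)
      seg <- preprocess(seg, config$detection)
      peaks <- detect_breath_peaks(seg, config$detection)
      series <- build_breath_series(seg, peaks)
      prof <- suppressWarnings(
        complexity_profile(series, m = config$m, r = config$r,
                           min_scale = config$min_scale,
                           n_scales = config$n_scales,
                           detrend_order = config$detrend_order))
      grp <- sig$metadata$group %||% NA_character_
      subj <- sig$metadata$subject %||% nm
      cbind(data.frame(subject = subj, group = grp), prof)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[nm]] <- data.frame(subject = nm, reason = conditionMessage(res))
    } else {
      rows[[nm]] <- res
    }
  }
  if (length(rows) == 0) {
    msg <- paste(vapply(fails, function(f) paste0(f$subject, ": ", f$reason),
                        character(1)), collapse = "; ")
    stopf("all recordings failed: %s", msg, class = "pipeline_error")
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  class(table) <- "data.frame"
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(subject = character(0), reason = character(0))
  rownames(failures) <- NULL
  structure(list(table = table, failures = failures), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Cohort result: %d recordings (%d failed) in %d group(s)\n",
              nrow(x$table), nrow(x$failures),
              length(unique(x$table$group))))
  invisible(x)
}

# Shared validation for the group comparisons: drops non-finite metric
# values (warning with a count), checks group sizes.
prepare_groups <- function(table, metric, reference_group) {
  if (inherits(table, "cohort_result")) table <- table$table
  if (!metric %in% names(table))
    stopf("metric `%s` not found in cohort table", metric,
          class = "invalid_parameter")
  x <- table[[metric]]
  grp <- as.character(table$group)
  bad <- !is.finite(x)
  if (any(bad)) {
    warning(sprintf("excluding %d non-finite `%s` value(s) from the comparison",
                    sum(bad), metric), call. = FALSE)
    x <- x[!bad]; grp <- grp[!bad]
  }
  levels <- unique(grp)
  if (!reference_group %in% levels)
    stopf("reference group `%s` not present", reference_group,
          class = "invalid_parameter")
  if (length(levels) < 2)
    stopf("need at least 2 groups", class = "insufficient_data")
  sizes <- table(grp)
  if (any(sizes < 2))
    stopf("every group needs at least 2 finite values (smallest has %d)",
          min(sizes), class = "insufficient_data")
  list(x = x, grp = grp,
       levels = c(reference_group, setdiff(levels, reference_group)))
}

#' One-way ANOVA with Bonferroni-adjusted pairwise tests
#'
#' The omnibus F statistic is computed from the group sums of squares
#' (`F = MS_between / MS_within` with `k - 1` and `N - k` degrees of
#' freedom). Pairwise comparisons of the reference group against every
#' other group use two-sample t statistics with the pooled within-group
#' mean square and `N - k` degrees of freedom; raw p-values are
#' multiplied by the number of comparisons and capped at 1 (Bonferroni).
#'
#' @param table a cohort table (or [run_pipeline()] result) with columns
#'   `group` and the metric.
#' @param metric name of the metric column to compare.
#' @param reference_group label of the reference (control) group.
#' @return a list of class `"group_comparison"` with `metric`, `method`,
#'   `omnibus_stat`, `omnibus_p`, and a `pairwise` data frame
#'   (`group_a`, `group_b`, `estimate` = mean difference B - A, `raw_p`,
#'   `adjusted_p`).
#' @export
one_way_anova_bonferroni <- function(table, metric, reference_group) {
  pg <- prepare_groups(table, metric, reference_group)
  x <- pg$x; grp <- pg$grp
  k <- length(pg$levels); n_tot <- length(x)
  means <- tapply(x, grp, mean)
  ns <- tapply(x, grp, length)
  grand <- mean(x)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((x - means[grp])^2)
  if (ss_within == 0)
    stopf("zero within-group variance everywhere: F undefined",
          class = "degenerate_data")
  df1 <- k - 1; df2 <- n_tot - k
  f_stat <- (ss_between / df1) / (ss_within / df2)
  omnibus_p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)

  mse <- ss_within / df2
  others <- pg$levels[-1]
  pw <- do.call(rbind, lapply(others, function(g2) {
    se <- sqrt(mse * (1 / ns[[reference_group]] + 1 / ns[[g2]]))
    tval <- (means[[g2]] - means[[reference_group]]) / se
    raw <- 2 * stats::pt(-abs(tval), df2)
    data.frame(group_a = reference_group, group_b = g2,
               estimate = means[[g2]] - means[[reference_group]],
               statistic = tval, raw_p = raw, adjusted_p = NA_real_)
  }))
  pw$adjusted_p <- pmin(1, pw$raw_p * nrow(pw))
  structure(list(metric = metric, method = "anova_bonferroni",
                 omnibus_stat = f_stat, omnibus_p = omnibus_p, pairwise = pw),
            class = "group_comparison")
}

#' Kruskal-Wallis test with Dunn's pairwise post test
#'
#' The omnibus H statistic is computed from mid-ranks with the standard
#' tie correction `1 - sum(t^3 - t) / (N^3 - N)`. Dunn's pairwise z
#' statistics compare mean ranks using the ties-adjusted pooled variance
#' `(N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_a + 1/n_b)`; raw p-values
#' are Bonferroni-adjusted across the pairwise set.
#'
#' @inheritParams one_way_anova_bonferroni
#' @return a `"group_comparison"` (see [one_way_anova_bonferroni()];
#'   `estimate` is the mean-rank difference B - A).
#' @export
kruskal_dunn <- function(table, metric, reference_group) {
  pg <- prepare_groups(table, metric, reference_group)
  x <- pg$x; grp <- pg$grp
  n_tot <- length(x); k <- length(pg$levels)
  rk <- rank(x)  # mid-ranks
  tie_tab <- table(x)
  tie_sum <- sum(tie_tab^3 - tie_tab)
  if (tie_sum == n_tot^3 - n_tot)
    stopf("all values tied: rank tests undefined", class = "degenerate_data")
  mean_rk <- tapply(rk, grp, mean)
  ns <- tapply(rk, grp, length)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(ns * mean_rk^2) - 3 * (n_tot + 1)
  h <- h / (1 - tie_sum / (n_tot^3 - n_tot))
  omnibus_p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)

  sigma2 <- n_tot * (n_tot + 1) / 12 - tie_sum / (12 * (n_tot - 1))
  others <- pg$levels[-1]
  pw <- do.call(rbind, lapply(others, function(g2) {
    se <- sqrt(sigma2 * (1 / ns[[reference_group]] + 1 / ns[[g2]]))
    z <- (mean_rk[[g2]] - mean_rk[[reference_group]]) / se
    raw <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = reference_group, group_b = g2,
               estimate = mean_rk[[g2]] - mean_rk[[reference_group]],
               statistic = z, raw_p = raw, adjusted_p = NA_real_)
  }))
  pw$adjusted_p <- pmin(1, pw$raw_p * nrow(pw))
  structure(list(metric = metric, method = "kruskal_dunn",
                 omnibus_stat = h, omnibus_p = omnibus_p, pairwise = pw),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  stat_name <- if (x$method == "anova_bonferroni") "F" else "H"
  cat(sprintf("%s on `%s`: %s = %.4g, omnibus p = %.4g\n",
              x$method, x$metric, stat_name, x$omnibus_stat, x$omnibus_p))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Compare groups on one metric, choosing the test automatically
#'
#' `method = "auto"` applies a Shapiro-Wilk normality screen to the
#' within-group residuals: the parametric ANOVA/Bonferroni route is used
#' unless the screen rejects normality at the 0.05 level, in which case
#' the Kruskal-Wallis/Dunn route is used.
#'
#' @inheritParams one_way_anova_bonferroni
#' @param method `"auto"`, `"anova_bonferroni"` or `"kruskal_dunn"`.
#' @return a `"group_comparison"`.
#' @export
compare_groups <- function(table, metric, reference_group,
                           method = c("auto", "anova_bonferroni", "kruskal_dunn")) {
  method <- match.arg(method)
  if (method == "auto") {
    pg <- prepare_groups(table, metric, reference_group)
    resid <- pg$x - tapply(pg$x, pg$grp, mean)[pg$grp]
    method <- if (length(resid) >= 3 && length(resid) <= 5000 &&
                  stats::sd(resid) > 0 &&
                  stats::shapiro.test(resid)$p.value < 0.05)
      "kruskal_dunn" else "anova_bonferroni"
  }
  switch(method,
         anova_bonferroni = one_way_anova_bonferroni(table, metric, reference_group),
         kruskal_dunn = kruskal_dunn(table, metric, reference_group))
}

#' Check the asthma-versus-control effect pattern
#'
#' Evaluates, per case group against the control, the qualitative pattern
#' reported for allergen-exposed animals: lower sample entropy of IBI,
#' higher CV of IBI, higher DFA alpha of RV, and lower cross-sample
#' entropy (increased IBI-RV synchronization), with no significant shift
#' in mean IBI, mean RV, SampEn of RV, DFA alpha of IBI, or CV of RV.
#'
#' @param table a cohort table or [run_pipeline()] result.
#' @param control_label label of the control group.
#' @param case_labels case group labels (default: every other group).
#' @param method passed to [compare_groups()] (default the parametric
#'   route, matching how the complexity panels were analysed).
#' @param alpha significance level for the adjusted p-values.
#' @return a data frame of class `"effect_pattern"` with one row per
#'   (metric, case group): `metric`, `case_group`, `expected`
#'   (`"lower"`, `"higher"` or `"none"`), `estimate` (case minus
#'   control), `adjusted_p`, `significant`, and `consistent` (does the
#'   observed direction/significance match the expectation). Metrics
#'   missing from the table are reported with `consistent = NA`
#'   (untestable). Attribute `"low_power"` flags groups with fewer than
#'   5 recordings.
#' @export
reproduce_effect_pattern <- function(table, control_label, case_labels = NULL,
                                     method = "anova_bonferroni", alpha = 0.05) {
  if (inherits(table, "cohort_result")) table <- table$table
  expected <- c(sampen_ibi = "lower", cv_ibi = "higher", alpha_rv = "higher",
                cross_sampen = "lower", mean_ibi = "none", mean_rv = "none",
                sampen_rv = "none", alpha_ibi = "none", cv_rv = "none")
  if (is.null(case_labels))
    case_labels <- setdiff(unique(as.character(table$group)), control_label)

  rows <- list()
  for (metric in names(expected)) {
    exp_dir <- expected[[metric]]
    if (!metric %in% names(table)) {
      rows[[metric]] <- data.frame(metric = metric, case_group = case_labels,
                                   expected = exp_dir, estimate = NA_real_,
                                   adjusted_p = NA_real_, significant = NA,
                                   consistent = NA)
      next
    }
    cmp <- tryCatch(
      suppressWarnings(compare_groups(table, metric, control_label, method)),
      error = function(e) NULL)
    if (is.null(cmp)) {
      rows[[metric]] <- data.frame(metric = metric, case_group = case_labels,
                                   expected = exp_dir, estimate = NA_real_,
                                   adjusted_p = NA_real_, significant = NA,
                                   consistent = NA)
      next
    }
    pw <- cmp$pairwise[cmp$pairwise$group_b %in% case_labels, , drop = FALSE]
    sig <- pw$adjusted_p < alpha
    consistent <- switch(exp_dir,
                         lower = sig & pw$estimate < 0,
                         higher = sig & pw$estimate > 0,
                         none = !sig)
    rows[[metric]] <- data.frame(metric = metric, case_group = pw$group_b,
                                 expected = exp_dir, estimate = pw$estimate,
                                 adjusted_p = pw$adjusted_p,
                                 significant = sig, consistent = consistent)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  sizes <- table(as.character(table$group))
  attr(out, "low_power") <- any(sizes < 5)
  class(out) <- c("effect_pattern", "data.frame")
  out
}

#' @export
print.effect_pattern <- function(x, ...) {
  cat("Effect-pattern report (case vs control):\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (isTRUE(attr(x, "low_power")))
    cat("Note: some groups have fewer than 5 recordings; power is low.\n")
  invisible(x)
}
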