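make_table <- function(values, groups) data.frame(group = groups, metric = values)

test_that("identical groups give F = 0 and H = 0", {
  tab <- make_table(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  av <- one_way_anova_bonferroni(tab, "metric", "a")
  expect_equal(av$omnibus_stat, 0)
  expect_equal(av$omnibus_p, 1)
  kw <- kruskal_dunn(tab, "metric", "a")
  expect_equal(kw$omnibus_stat, 0)
})

test_that("ANOVA F matches the hand sums-of-squares computation and aov", {
  tab <- make_table(c(2, 4, 6, 8, 10, 12, 5, 7, 9),
                    rep(c("A", "B", "C"), each = 3))
  av <- one_way_anova_bonferroni(tab, "metric", "A")
  # SSB = 3[(4-7)^2+(10-7)^2+(7-7)^2] = 54; SSW = 3*8 = 24; F = 27/4
  expect_equal(av$omnibus_stat, 6.75)
  # independent cross-check against the standard linear-model route
  fit <- summary(aov(metric ~ group, data = tab))[[1]]
  expect_equal(av$omnibus_stat, fit[["F value"]][1])
  expect_equal(av$omnibus_p, fit[["Pr(>F)"]][1])
  # Bonferroni definition on the pairwise set
  expect_equal(av$pairwise$adjusted_p,
               pmin(1, av$pairwise$raw_p * nrow(av$pairwise)))
  expect_true(all(av$pairwise$adjusted_p >= av$pairwise$raw_p))
})

test_that("Kruskal-Wallis H and Dunn z match hand-computed references", {
  # untied data: ranks 1..6, mean ranks 2, 3, 5.5
  tab <- make_table(c(1, 3, 2, 4, 10, 12), rep(c("A", "B", "C"), each = 2))
  kw <- kruskal_dunn(tab, "metric", "A")
  expect_equal(kw$omnibus_stat, 26 / 7, tolerance = 1e-12)
  z <- kw$pairwise$statistic[match(c("B", "C"), kw$pairwise$group_b)]
  expect_equal(z, c(1 / sqrt(3.5), 3.5 / sqrt(3.5)), tolerance = 1e-12)
  # independent cross-check of the tie-corrected H
  tab2 <- make_table(c(1, 2, 2, 2, 3, 4, 5, 5, 6), rep(c("A", "B", "C"), each = 3))
  kw2 <- kruskal_dunn(tab2, "metric", "A")
  expect_equal(kw2$omnibus_stat,
               unname(kruskal.test(metric ~ group, data = tab2)$statistic))
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(11)
  tab <- make_table(rnorm(30), rep(c("a", "b", "c"), each = 10))
  kw1 <- kruskal_dunn(tab, "metric", "a")
  tab$metric <- exp(tab$metric)
  kw2 <- kruskal_dunn(tab, "metric", "a")
  expect_equal(kw1$omnibus_stat, kw2$omnibus_stat)
  expect_equal(kw1$pairwise$raw_p, kw2$pairwise$raw_p)
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(one_way_anova_bonferroni(
    make_table(c(1, 1, 2, 2), rep(c("a", "b"), each = 2)), "metric", "a"),
    class = "degenerate_data")
  expect_error(kruskal_dunn(
    make_table(rep(5, 6), rep(c("a", "b"), each = 3)), "metric", "a"),
    class = "degenerate_data")
  expect_error(one_way_anova_bonferroni(
    make_table(c(1, 2, 3), c("a", "a", "b")), "metric", "a"),
    class = "insufficient_data")
})

test_that("non-finite metric values are excluded with a warning", {
  tab <- make_table(c(1, 2, 3, Inf, 5, 6, 7), c(rep("a", 4), rep("b", 3)))
  expect_warning(av <- one_way_anova_bonferroni(tab, "metric", "a"),
                 "non-finite")
  expect_equal(av$omnibus_stat,
               summary(aov(metric ~ group,
                           data = tab[is.finite(tab$metric), ]))[[1]][["F value"]][1])
})

test_that("omnibus type-I error is calibrated at the nominal level", {
  n_rep <- 1000
  groups <- rep(c("a", "b", "c"), each = 10)
  set.seed(123)
  rejections <- vapply(seq_len(n_rep), function(i) {
    tab <- make_table(rnorm(30), groups)
    one_way_anova_bonferroni(tab, "metric", "a")$omnibus_p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("null omnibus p-values are approximately uniform", {
  set.seed(321)
  groups <- rep(c("a", "b", "c"), each = 10)
  ps <- vapply(seq_len(500), function(i)
    one_way_anova_bonferroni(make_table(rnorm(30), groups),
                             "metric", "a")$omnibus_p, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("auto method selection screens residual normality", {
  set.seed(15)
  normal_tab <- make_table(rnorm(30), rep(c("a", "b", "c"), each = 10))
  expect_equal(compare_groups(normal_tab, "metric", "a", "auto")$method,
               "anova_bonferroni")
  skewed_tab <- make_table(rlnorm(30, sdlog = 2.5),
                           rep(c("a", "b", "c"), each = 10))
  expect_equal(compare_groups(skewed_tab, "metric", "a", "auto")$method,
               "kruskal_dunn")
})

test_that("pipeline produces a complete table and tolerates corrupt inputs", {
  dir <- withr::local_tempdir()
  cfg <- synth_cohort_config(
    groups = list(ctl = control_like_spec(), case = asthma_like_spec()),
    n_per_group = 2, record_duration = 240, master_seed = 5)
  coh <- generate_cohort(cfg)
  write_cohort(coh, dir)
  paths <- file.path(dir, paste0(names(coh$signals), ".csv"))
  bad <- file.path(dir, "broken.csv")
  writeLines(c("# fs=1000", "1", "NaN", "2"), bad)
  res <- run_pipeline(c(paths, bad),
                      pipeline_config(window_duration = 200, window_hop = 30))
  expect_equal(nrow(res$table), 4)
  expect_equal(nrow(res$failures), 1)
  expect_match(res$failures$reason, "non-finite")
  expect_true(all(is.finite(as.matrix(
    res$table[, setdiff(names(res$table), c("subject", "group"))]))))
  # deterministic: rerunning reproduces the table bitwise
  res2 <- run_pipeline(c(paths, bad),
                       pipeline_config(window_duration = 200, window_hop = 30))
  expect_identical(res$table, res2$table)
  expect_error(run_pipeline(list()), class = "pipeline_error")
})

test_that("a null cohort shows no significant effect directions", {
  cfg <- synth_cohort_config(
    groups = list(ctl = control_like_spec(), sham = control_like_spec()),
    n_per_group = 4, record_duration = 240, master_seed = 99)
  res <- run_pipeline(generate_cohort(cfg),
                      pipeline_config(window_duration = 200, window_hop = 60))
  pat <- reproduce_effect_pattern(res, "ctl")
  # a null cohort must not reproduce the disease pattern (individual
  # metrics may trip the nominal type-I rate; the joint pattern cannot)
  primary <- pat[pat$expected != "none", ]
  expect_false(all(primary$consistent))
  expect_lt(sum(primary$significant, na.rm = TRUE), 3)
  expect_true(isTRUE(attr(pat, "low_power")))
})
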