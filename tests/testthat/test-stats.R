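test_that("inactive histograms bin reversals and report first-bin fractions", {
  pairs <- data.frame(
    pair_type = c("DK", "DK", "KD", "KK", "KD"),
    inactive_duration = c(0.1, 1.2, 0.3, 0.2, 1.2))
  h <- inactive_histogram(pairs)
  expect_equal(unname(h$first_bin_fraction["DK"]), 0.5)
  expect_equal(unname(h$first_bin_fraction["KD"]), 0.5)
  expect_equal(unname(h$first_bin_fraction["overall"]), 0.5)
  # all long gaps land in the third bin, none in the first
  all_long <- data.frame(pair_type = rep(c("DK", "KD"), 5),
                         inactive_duration = rep(1.2, 10))
  h2 <- inactive_histogram(all_long)
  expect_equal(unname(h2$first_bin_fraction["overall"]), 0)
  third <- h2$histogram[h2$histogram$bin_left == 1.0, ]
  expect_equal(sum(third$count), 10)
  expect_equal(sum(h2$histogram$count), 10)
  # no reversals: empty histogram, NA fractions
  h3 <- inactive_histogram(data.frame(pair_type = "KK",
                                      inactive_duration = 1))
  expect_equal(nrow(h3$histogram), 0)
  expect_true(all(is.na(h3$first_bin_fraction)))
})

test_that("force histograms use 0.5-pN bins and find low-force peaks", {
  h <- force_histogram(c(1.2, 1.2, 2.3))
  expect_equal(h$count[h$bin_left == 1.0], 2)
  expect_equal(h$count[h$bin_left == 2.0], 1)
  expect_equal(nrow(force_histogram(numeric(0))), 0)
  hn <- force_histogram(c(1.2, 1.2, 2.3), normalize = TRUE)
  expect_equal(max(hn$normalized), 1)

  # dynein single/pair periodicity after partial inhibition: modes near
  # 1.1 and 2.2 pN recovered by peak picking
  cfg <- synth_config(n_events = 60L, p_kinesin = 0, dynein_pairs = FALSE,
                      premature_rate = 0)
  sim <- generate_trace(cfg, seed = 55)
  an <- analyze_trace(sim$trace,
                      thresholds = stall_thresholds("low_force_minus"))
  expect_gt(nrow(an$stalls), 40)
  pk <- force_peaks(force_histogram(an$stalls$stall_force), min_count = 5)
  expect_true(any(pk > 0.75 & pk < 1.6))
  expect_true(any(pk > 1.75 & pk < 2.6))
})

test_that("two-Gaussian fits recover single/multi-motor mixtures", {
  set.seed(12)
  forces <- c(rnorm(200, 6, 1), rnorm(300, 12, 1.5))
  fit <- fit_two_gaussians(forces)
  expect_lt(abs(fit$means[1] - 6) / 6, 0.05)
  expect_lt(abs(fit$means[2] - 12) / 12, 0.05)
  expect_lt(abs(fit$weights[1] - 0.4), 0.05)
  expect_equal(fit$single_fraction, fit$weights[1])
  expect_false(fit$degenerate)

  expect_warning(fit_two_gaussians(rnorm(200, 6, 1)), "degenerate")
  expect_error(fit_two_gaussians(rnorm(10)), "at least 20")
})

test_that("group comparison is an unpaired two-tailed t test", {
  a <- c(1.1, 1.3, 1.2, 1.4, 1.25)
  same <- compare_groups(a, a)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(8)
  g1 <- rnorm(30, 0, 1)
  g2 <- rnorm(30, 3, 1)  # shifted by 3 SD
  expect_lt(compare_groups(g1, g2)$p_value, 0.001)
  degen <- compare_groups(rep(1, 5), rep(1, 4))
  expect_true(degen$degenerate_variance)
  expect_true(is.na(degen$p_value))
  # cross-check against stats::t.test with pooled variance
  ref <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(compare_groups(g1, g2)$t_statistic, unname(ref$statistic))
})

test_that("recovery reports handle perfect, empty and mismatched input", {
  run <- small_run()
  rep <- run$report
  expect_equal(rep$precision, 1)
  expect_equal(rep$recall, 1)
  expect_equal(sum(rep$pair_confusion), sum(diag(rep$pair_confusion)))

  # detection on an unrelated quiet trace finds nothing: recall 0
  empty_an <- analyze_trace(make_thermal_trace(20, seed = 2,
                                               trace_id = "t01"))
  rep0 <- recovery_report(list(empty_an), list(run$sims[[1]]))
  expect_equal(rep0$recall, 0)

  bad <- run$analyses[[2]] # trace id t02 against truth t01
  expect_error(recovery_report(list(bad), list(run$sims[[1]])),
               "do not match")
})
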