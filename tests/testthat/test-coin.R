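test_that("coin-toss sequences are deterministic and correctly biased", {
  expect_true(all(simulate_sequence(50, 1, seed = 1)$label == "K"))
  expect_true(all(simulate_sequence(50, 0, seed = 1)$label == "D"))
  expect_identical(simulate_sequence(1000, 0.5, seed = 5),
                   simulate_sequence(1000, 0.5, seed = 5))
  expect_error(simulate_sequence(10, 1.5), "0, 1")

  s <- simulate_sequence(1e5, 0.5, seed = 2)
  fk <- direction_fraction(s)$fraction_K
  expect_lt(abs(fk - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("pair fractions enumerate overlapping pairs within traces", {
  ps <- pair_fractions(c("K", "D", "K"))
  expect_equal(unname(ps$counts), c(0L, 1L, 1L, 0L))
  expect_equal(unname(ps$fractions[c("DK", "KD")]), c(0.5, 0.5))
  expect_equal(pair_fractions("KKKK")$counts[["KK"]], 3L)
  expect_equal(pair_fractions(character(0))$total_pairs, 0L)
  # no pair across a trace boundary: two traces of length 2 give 2 pairs
  es <- event_sequence(c("K", "D", "D", "K"), trace_id = c(1, 1, 2, 2))
  ps2 <- pair_fractions(es)
  expect_equal(ps2$total_pairs, 2L)
  expect_equal(ps2$counts[["KD"]], 1L)
  expect_equal(ps2$counts[["DK"]], 1L)
  expect_equal(ps2$counts[["DD"]], 0L)
})

test_that("i.i.d. pair fractions converge to q^2, q(1-q), (1-q)q, (1-q)^2", {
  for (q in c(0.5, 0.3)) {
    s <- simulate_sequence(1e5, q, seed = 31)
    fr <- pair_fractions(s)$fractions
    expected <- c(DD = (1 - q)^2, DK = (1 - q) * q,
                  KD = q * (1 - q), KK = q^2)
    # overlapping pairs share tosses, so allow a conservative 4x binomial
    # standard error
    for (ty in names(expected)) {
      se <- sqrt(expected[[ty]] * (1 - expected[[ty]]) / 1e5)
      expect_lt(abs(fr[[ty]] - expected[[ty]]), 4 * se)
    }
  }
})

test_that("direction fractions behave on edge cases", {
  expect_equal(direction_fraction(c("K", "K", "D"))$fraction_K, 2 / 3)
  expect_equal(direction_fraction(c("D", "D"))$fraction_K, 0)
  expect_error(direction_fraction(character(0)), "empty")
})

test_that("uniformity test quantifies closeness to the fair-coin 25%", {
  u <- uniformity_test(c(100, 100, 100, 100))
  expect_equal(u$statistic, 0)
  expect_equal(u$p_value, 1)
  # counts near 447/4 each
  u2 <- uniformity_test(c(112, 112, 112, 111))
  expect_lt(u2$statistic, 0.1)
  u3 <- uniformity_test(c(400, 0, 0, 47))
  expect_gt(u3$statistic, 7.81) # chi-square 0.95 quantile, df = 3
  expect_lt(u3$p_value, 0.05)
  expect_error(uniformity_test(c(0, 0, 0, 0)), "zero")
})

test_that("lag-1 independence flags memory and passes i.i.d. sequences", {
  alt <- rep(c("K", "D"), 250)
  r <- lag1_independence(alt)
  expect_gt(r$statistic, 100)
  expect_lt(r$p_value, 1e-10)

  fair <- simulate_sequence(1e5, 0.5, seed = 13)
  r2 <- lag1_independence(fair)
  expect_gt(r2$p_value, 0.001)

  expect_true(is.na(lag1_independence(c("K", "D"))$statistic))
  expect_match(lag1_independence(rep("K", 50))$reason, "degenerate")
})
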