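test_that("contact fraction is the area ratio and is validated", {
  expect_equal(contact_fraction(cargo_geometry(750, 0.08)), 0.04527074,
               tolerance = 1e-6)
  expect_equal(contact_fraction(cargo_geometry(750, 0)), 0)
  expect_error(cargo_geometry(750, 10), "exceeds")
})

test_that("motor counts scale with cargo surface area", {
  s <- scale_motor_count(3.5, 90, 750)
  expect_equal(s$raw, 243.0556, tolerance = 1e-6)
  expect_equal(s$rounded, 240)
  expect_equal(scale_motor_count(30, 250, 750)$raw, 270)
  expect_equal(scale_motor_count(7, 500, 500)$raw, 7)
  expect_error(scale_motor_count(3, -1, 750), "> 0")

  expect_equal(expected_in_contact(240, 0.04)$raw, 9.6)
  expect_equal(expected_in_contact(240, 0.04)$rounded, 10)
  expect_equal(expected_in_contact(40, 0.04)$rounded, 2)
  expect_equal(expected_in_contact(0, 0.5)$raw, 0)
})

test_that("binomial occupancy pmf and tail match the brute-force oracle", {
  expect_equal(occupancy_pmf(40, 0.04, 1), 0.3256103, tolerance = 1e-6)
  expect_equal(occupancy_tail(40, 0.04, 0), 1)
  expect_equal(occupancy_tail(40, 0.04, 1), 0.8046338, tolerance = 1e-6)
  expect_equal(occupancy_tail(240, 0.04, 6), 0.9204423, tolerance = 1e-6)
  expect_error(occupancy_pmf(10, 0.1, 11), "exceed")
  expect_error(occupancy_tail(10, 1.2, 1), "0, 1")

  # oracle equivalence and normalisation over randomized cases
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(0:500, 1)
    p <- runif(1)
    expect_equal(sum(vapply(0:n, occupancy_pmf, numeric(1), n = n, p = p)),
                 1, tolerance = 1e-12)
    k <- sample(0:n, 1)
    expect_equal(occupancy_pmf(n, p, k), brute_pmf(k, n, p),
                 tolerance = 1e-10)
  }
})

test_that("occupancy tail is monotone in threshold, p and n", {
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(5:100, 1)
    p <- runif(1, 0.01, 0.99)
    tails <- vapply(0:n, occupancy_tail, numeric(1), n = n, p = p)
    expect_true(all(diff(tails) <= 1e-12))
    m <- sample(1:n, 1)
    expect_gte(occupancy_tail(n, min(1, p * 1.2), m),
               occupancy_tail(n, p, m))
    expect_gte(occupancy_tail(n + 5, p, m), occupancy_tail(n, p, m))
  }
})

test_that("joint reversal probability reproduces the 74% prediction", {
  m <- occupancy_model()
  expect_equal(joint_reversal_probability(m), 0.740619, tolerance = 1e-6)

  # brute-force enumeration over all (i, j) occupancy pairs at small counts
  set.seed(3)
  for (rep in 1:5) {
    nd <- sample(2:12, 1); nk <- sample(1:12, 1)
    md <- sample(1:nd, 1); mk <- sample(1:nk, 1)
    p <- runif(1, 0.05, 0.6)
    mod <- occupancy_model(
      dynein = motor_population("dynein", "minus", 1.1, 1.6, 0.27, nd),
      kinesin = motor_population("kinesin", "plus", 6, 5, 1, nk),
      contact_fraction = p,
      team_threshold_dynein = md, team_threshold_kinesin = mk)
    brute <- 0
    for (i in md:nd) for (j in mk:nk) {
      brute <- brute + brute_pmf(i, nd, p) * brute_pmf(j, nk, p)
    }
    expect_equal(joint_reversal_probability(mod), brute, tolerance = 1e-10)
  }

  # degenerate limits
  expect_equal(joint_reversal_probability(
    occupancy_model(contact_fraction = 0)), 0)
  certain <- occupancy_model(
    dynein = motor_population("dynein", "minus", 1.1, 1.6, 0.27, 6),
    kinesin = motor_population("kinesin", "plus", 6, 5, 1, 1),
    contact_fraction = 1)
  expect_equal(joint_reversal_probability(certain), 1)
})

test_that("kinesin team probabilities split 20/33/48 and sum to one", {
  kt <- kinesin_team_probabilities(40, 0.04)
  expect_equal(kt$P_0K, 0.1953662, tolerance = 1e-6)
  expect_equal(kt$P_1K, 0.3256103, tolerance = 1e-6)
  expect_equal(kt$P_gt1K, 0.4790236, tolerance = 1e-6)
  expect_equal(kinesin_team_probabilities(25, 0),
               list(P_0K = 1, P_1K = 0, P_gt1K = 0))
  set.seed(11)
  for (rep in 1:10) {
    kt <- kinesin_team_probabilities(sample(1:200, 1), runif(1))
    expect_equal(kt$P_0K + kt$P_1K + kt$P_gt1K, 1, tolerance = 1e-12)
  }
})

test_that("membrane residence time follows A/(4D)", {
  expect_equal(lipid_residence_time(0.08, 10, "ms"), 2)
  expect_equal(lipid_residence_time(0.08, 1.4, "ms"), 14.28571,
               tolerance = 1e-6)
  expect_equal(lipid_residence_time(0, 5), 0)
  expect_error(lipid_residence_time(0.08, 0), "> 0")
})

test_that("rotational diffusion bounds the fly-back rotation near a degree", {
  # closed form recomputed independently: D_rot = kT / (8 pi eta R^3)
  d_rot <- kbt(295) / (8 * pi * 1e-3 * 1e-6 * 375^3)
  expect_equal(rotational_rms_angle(750, 1e-3, 295, 5e-5),
               sqrt(2 * d_rot * 5e-5) * 180 / pi)
  expect_equal(rotational_rms_angle(750, 1e-3, 295, 5e-5), 1.004,
               tolerance = 0.01)
  expect_equal(rotational_rms_angle(750, 1e-3, 295, 0), 0)
  expect_equal(rotational_rms_angle(750, 1e-3, 295, 4 * 0.01),
               2 * rotational_rms_angle(750, 1e-3, 295, 0.01))
})
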