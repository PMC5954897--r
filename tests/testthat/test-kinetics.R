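test_that("closed-form occupancy kinetics match their printed values", {
  expect_equal(equilibrium_occupancy(1.6, 0.27), 0.855615,
               tolerance = 1e-6)                       # printed as 0.85
  expect_equal(equilibrium_occupancy(5, 1), 0.8333333,
               tolerance = 1e-6)                       # printed as 0.83
  expect_equal(equilibrium_occupancy(2, 0), 1)
  expect_error(equilibrium_occupancy(0, 0), "zero")

  expect_equal(characteristic_time(1.6, 0.27), 0.5347594,
               tolerance = 1e-6)                       # printed as 0.53 s
  expect_equal(characteristic_time(5, 1), 1 / 6)       # printed as 0.16 s
  expect_equal(characteristic_time(0.5, 0.5), 1)
})

test_that("mean occupancy solves the attach/detach ODE", {
  expect_equal(mean_occupancy(0, 1.6, 0.27), 0)
  ceq <- equilibrium_occupancy(1.6, 0.27)
  tc <- characteristic_time(1.6, 0.27)
  expect_equal(mean_occupancy(tc, 1.6, 0.27), ceq * (1 - exp(-1)))
  expect_equal(mean_occupancy(50 * tc, 1.6, 0.27), ceq, tolerance = 1e-9)
  expect_error(mean_occupancy(-1, 1.6, 0.27), ">= 0")

  # finite-difference check of dC/dt = k_on (1 - C) - k_off C
  for (t in c(0.05, 0.2, 1, 3)) {
    h <- 1e-6
    lhs <- (mean_occupancy(t + h, 1.6, 0.27) -
              mean_occupancy(t - h, 1.6, 0.27)) / (2 * h)
    C <- mean_occupancy(t, 1.6, 0.27)
    expect_equal(lhs, 1.6 * (1 - C) - 0.27 * C, tolerance = 1e-5)
  }

  expect_equal(expected_bound(10, 1.6, 0.27, 0.535), 5.41, tolerance = 0.01)
  expect_equal(expected_bound(2, 5, 1, 1 / 6), 1.05, tolerance = 0.01)
  expect_equal(expected_bound(0, 5, 1, 1), 0)
})

test_that("the Gillespie trajectory has the right limits and statistics", {
  # no attachment: stays at zero
  tr0 <- simulate_binding(5, 0, 1, t_max = 10, seed = 1)
  expect_true(all(tr0$bound == 0))
  # no detachment: absorbs at n
  tr1 <- simulate_binding(5, 2, 0, t_max = 50, seed = 2)
  expect_equal(tr1$bound[nrow(tr1)], 5)
  expect_true(all(diff(tr1$time) > 0))
  # determinism
  expect_identical(simulate_binding(10, 1.6, 0.27, 5, seed = 7),
                   simulate_binding(10, 1.6, 0.27, 5, seed = 7))
  # long-run time average matches C_eq within 3 standard errors
  traj <- simulate_binding(10, 1.6, 0.27, t_max = 2000, seed = 3)
  ceq <- equilibrium_occupancy(1.6, 0.27)
  tau <- characteristic_time(1.6, 0.27)
  se <- sqrt(ceq * (1 - ceq) / 10 * 2 * tau / 2000)
  expect_lt(abs(mean_bound_fraction(traj) - ceq), 3 * se)
})

test_that("ensemble averages reproduce the mean-field solution", {
  n <- 10; t_q <- 0.3
  boots <- vapply(1:2000, function(i) {
    bound_at(simulate_binding(n, 1.6, 0.27, t_max = t_q, seed = 10000 + i),
             t_q)
  }, integer(1))
  expected <- n * mean_occupancy(t_q, 1.6, 0.27)
  se <- sd(boots) / sqrt(length(boots))
  expect_lt(abs(mean(boots) - expected), 3 * se)
})

test_that("analytic birth-death first-passage times are exact", {
  expect_equal(first_passage_analytic(10, 1.6, 0.27, 6), 0.5686274,
               tolerance = 1e-6)
  expect_equal(first_passage_analytic(2, 5, 1, 1), 0.1)
  expect_equal(first_passage_analytic(4, 2, 0, 4),
               sum(1 / ((4:1) * 2)))       # pure-birth sum
  expect_equal(first_passage_analytic(10, 1.6, 0.27, 0), 0)
  expect_error(first_passage_analytic(10, 0, 0.27, 6), "unreachable")
})

test_that("Monte-Carlo first passage agrees with the analytic oracle", {
  cases <- list(c(10, 6, 4000), c(10, 3, 4000), c(2, 1, 4000), c(5, 5, 2000))
  for (cs in cases) {
    mc <- first_passage_mc(cs[1], 1.6, 0.27, cs[2], replicates = cs[3],
                           seed = 21)
    exact <- first_passage_analytic(cs[1], 1.6, 0.27, cs[2])
    expect_lt(abs(mc$mean - exact), 3 * mc$sem)
  }
  expect_equal(first_passage_mc(5, 1, 1, 0, replicates = 10)$mean, 0)
  expect_error(first_passage_mc(5, 1, 1, 6), "exceed")
})
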