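test_that("thermal segments match the Ornstein-Uhlenbeck closed forms", {
  trap <- trap_config(detector_noise_sd = 0)
  x <- thermal_segment(trap, 50, seed = 4) # 1e5 samples
  sd_th <- thermal_sd(trap)
  expect_equal(sd_th, sqrt(kbt(295) / 0.02))
  expect_lt(abs(sd(x) - sd_th) / sd_th, 0.05)
  # lag-1 autocorrelation = exp(-dt/tau)
  a_expected <- exp(-(1 / 2000) / trap_relaxation_time(trap))
  a_obs <- cor(x[-1], x[-length(x)])
  expect_lt(abs(a_obs - a_expected), 0.02)
  # stiff-trap limit
  stiff <- trap_config(stiffness = 100, detector_noise_sd = 0)
  expect_lt(sd(thermal_segment(stiff, 5, seed = 1)), 0.5)
})

test_that("stall segments plateau at F/K_T with the programmed width", {
  trap <- trap_config()
  st <- stall_segment(trap, "plus", stall_force = 6,
                      unloaded_velocity = 1.5, t_stall = 0.8)
  expect_equal(st$plateau, 300) # 6 pN / 0.02 pN/nm
  expect_gt(st$realized_force, 0.95 * 6)
  # initial slope ~ unloaded velocity
  v_init <- st$positions[1] * trap$sampling_rate
  expect_equal(v_init, 1500, tolerance = 0.01)
  # noise-free half-max width equals the request within one sample period
  f <- trap$stiffness * abs(st$positions)
  width <- sum(f >= max(f) / 2) / trap$sampling_rate
  expect_lt(abs(width - 0.8), 1 / trap$sampling_rate + 1e-9)
  # premature detachment leaves the motor still moving
  pre <- stall_segment(trap, "plus", 6, 1.5, detach_fraction = 0.3)
  expect_equal(pre$realized_force, 0.3 * 6, tolerance = 0.05)
  expect_gt(pre$detach_velocity, 1000)
})

test_that("fly-back segments relax on the programmed time scales", {
  trap <- trap_config()
  sd0 <- thermal_sd(trap)
  fb <- flyback_segment(trap, 300, "free")
  t_out <- sum(abs(fb$positions) > 2 * sd0) / trap$sampling_rate
  expect_lt(t_out, 0.005)  # unopposed fly-backs complete within 5 ms
  tow <- flyback_segment(trap, 300, "tug_of_war", resist_time = 0.05)
  t_out_tow <- sum(abs(tow$positions) > 2 * sd0) / trap$sampling_rate
  expect_equal(t_out_tow, 0.05, tolerance = 0.05)
  expect_equal(tow$flyback_time, 0.05)
  # already at the centre: nothing to fly back
  expect_equal(flyback_segment(trap, 0.5 * sd0, "free")$duration, 0)
})

test_that("generated traces are deterministic with full ground truth", {
  cfg <- synth_config(n_events = 12L)
  a <- generate_trace(cfg, seed = 5, trace_id = "x")
  b <- generate_trace(cfg, seed = 5, trace_id = "x")
  expect_identical(a$trace$x_nm, b$trace$x_nm)
  expect_identical(a$events, b$events)
  expect_equal(nrow(a$events[!a$events$premature, ]), 12L)
  expect_equal(nrow(a$pairs), 11L)
  expect_true(all(a$events$t_release > a$events$t_start))
  # pair typing is consistent with the event labels
  lab <- a$events$label[!a$events$premature]
  expect_identical(a$pairs$pair_type, paste0(lab[-12], lab[-1]))
})

test_that("a reversal-certain configuration makes every pair rapid", {
  cfg <- synth_config(n_events = 25L, p_rr = 1)
  sim <- generate_trace(cfg, seed = 8)
  expect_true(all(sim$pairs$inactive < 0.5))
  expect_true(all(sim$pairs$is_rr))
})

test_that("datasets round-trip with reproducible manifests", {
  cfg <- synth_config(n_events = 6L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m0 <- generate_dataset(0L, cfg, seed = 1, out_dir = d1)
  expect_length(m0$files, 0)
  m1 <- generate_dataset(2L, cfg, seed = 3, out_dir = d1)
  m2 <- generate_dataset(2L, cfg, seed = 3, out_dir = d2)
  expect_identical(m1$checksums, m2$checksums)
  truth <- read.csv(file.path(d1, "truth_events.csv"))
  expect_equal(nrow(truth), m1$n_events)
  # written traces are readable and match the generator
  tr <- read_trace(file.path(d1, m1$files[1]))
  sim <- generate_trace(cfg, seed = m1$seeds[1], trace_id = "trace_001")
  expect_identical(tr$x_nm, sim$trace$x_nm)
})
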