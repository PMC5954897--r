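# Shared fixtures, built in code and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

# A quiet trace: pure thermal fluctuation in the trap.
make_thermal_trace <- function(duration = 10, seed = 1,
                               trap = trap_config(detector_noise_sd = 0),
                               trace_id = "thermal") {
  x <- thermal_segment(trap, duration, seed = seed)
  trap_trace((seq_along(x) - 1) / trap$sampling_rate, x,
             metadata = list(trap_stiffness = trap$stiffness,
                             sampling_rate = trap$sampling_rate,
                             temperature = trap$temperature,
                             trace_id = trace_id))
}

# A small analysed synthetic dataset reused by several pipeline tests.
small_run <- function() {
  if (is.null(.fixture_cache$small)) {
    cfg <- synth_config(n_events = 40L)
    res <- lapply(1:4, function(i) {
      sim <- generate_trace(cfg, seed = derive_seed(42L, i),
                            trace_id = sprintf("t%02d", i))
      list(sim = sim, an = analyze_trace(sim$trace))
    })
    .fixture_cache$small <- list(
      sims = lapply(res, `[[`, "sim"),
      analyses = lapply(res, `[[`, "an"),
      report = recovery_report(lapply(res, `[[`, "an"),
                               lapply(res, `[[`, "sim")))
  }
  .fixture_cache$small
}

# Independent brute-force binomial pmf (factorial form), used as the oracle
# for the occupancy layer.
brute_pmf <- function(k, n, p) {
  choose(n, k) * p^k * (1 - p)^(n - k)
}
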