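#' Optical-trap configuration for trace synthesis
#'
#' Physical parameters of the simulated trap and detection chain. The drag
#' coefficient defaults to Stokes' law on the cargo sphere,
#' `6 pi eta R`, with an effective viscosity `viscosity_factor` times water
#' to represent assay buffer near a surface; it can be overridden directly.
#'
#' @param stiffness Trap stiffness K_T, pN/nm.
#' @param sampling_rate Detector sampling rate, Hz (default 2000).
#' @param temperature Bath temperature, K.
#' @param cargo_diameter Cargo diameter, nm.
#' @param viscosity_factor Effective viscosity as a multiple of water
#'   (1e-3 Pa s).
#' @param drag Drag coefficient, pN s/nm; `NULL` derives it from Stokes'
#'   law.
#' @param detector_noise_sd Additive detector noise SD, nm.
#' @return Object of class `trap_config`.
#' @export
trap_config <- function(stiffness = 0.02, sampling_rate = 2000,
                        temperature = 295, cargo_diameter = 750,
                        viscosity_factor = 3, drag = NULL,
                        detector_noise_sd = 2) {
  .check_scalar(stiffness, "stiffness", positive = TRUE)
  .check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  .check_scalar(temperature, "temperature", positive = TRUE)
  .check_scalar(cargo_diameter, "cargo_diameter", positive = TRUE)
  .check_scalar(detector_noise_sd, "detector_noise_sd", nonneg = TRUE)
  if (is.null(drag)) {
    eta <- viscosity_factor * .eta_water * .pa_s_to_pn_s_nm2 # pN s / nm^2
    drag <- 6 * pi * eta * cargo_diameter / 2
  }
  .check_scalar(drag, "drag", positive = TRUE)
  structure(list(stiffness = stiffness, sampling_rate = sampling_rate,
                 temperature = temperature, cargo_diameter = cargo_diameter,
                 drag = drag, detector_noise_sd = detector_noise_sd),
            class = "trap_config")
}

#' Thermal position statistics of a trapped cargo
#'
#' `thermal_sd` is the stationary SD of a bead in a harmonic trap,
#' `sqrt(k_B T / K_T)`; `trap_relaxation_time` is the Ornstein-Uhlenbeck
#' relaxation time `gamma / K_T`.
#'
#' @param trap A [trap_config()].
#' @return SD in nm / time in seconds.
#' @export
thermal_sd <- function(trap) {
  stopifnot(inherits(trap, "trap_config"))
  sqrt(kbt(trap$temperature) / trap$stiffness)
}

#' @rdname thermal_sd
#' @export
trap_relaxation_time <- function(trap) {
  stopifnot(inherits(trap, "trap_config"))
  trap$drag / trap$stiffness
}

## Exact discrete-time OU noise around zero: stationary SD `sd`, relaxation
## time `tau`, sampled every `dt`. Uses the exact AR(1) transition (not an
## Euler step) so lag-1 autocorrelation is exp(-dt/tau) at any dt.
.ou_noise <- function(n, dt, tau, sd) {
  if (n == 0L) return(numeric(0))
  a <- exp(-dt / tau)
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  x0 <- stats::rnorm(1L, sd = sd)
  as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
}

#' Thermal (motor-free) trap segment
#'
#' Position fluctuations of a trapped cargo with no motor engaged: an exact
#' discrete Ornstein-Uhlenbeck process with stationary SD `sqrt(k_B T/K_T)`
#' and relaxation time `gamma/K_T`, plus additive detector noise.
#'
#' @param trap A [trap_config()].
#' @param duration Segment duration, s.
#' @param seed Integer seed.
#' @return Numeric vector of positions (nm).
#' @export
thermal_segment <- function(trap, duration, seed = 1L) {
  stopifnot(inherits(trap, "trap_config"))
  .check_scalar(duration, "duration", positive = TRUE)
  set.seed(seed)
  n <- round(duration * trap$sampling_rate)
  dt <- 1 / trap$sampling_rate
  .ou_noise(n, dt, trap_relaxation_time(trap), thermal_sd(trap)) +
    stats::rnorm(n, sd = trap$detector_noise_sd)
}

## --- analytic mean-path pieces -------------------------------------------

## Half-max crossing time of the rise x(t) = X (1 - exp(-t/tau)) truncated
## at t = T: the force is maximal at T, and half-max is crossed at
## t_half = -tau log(1 - (1 - exp(-T/tau)) / 2).
.rise_t_half <- function(T, tau) {
  -tau * log(1 - (1 - exp(-T / tau)) / 2)
}

## Total rise duration T such that the width at half-maximal force
## (T - t_half) equals the requested stall width.
.rise_duration <- function(t_stall, tau) {
  g <- function(T) (T - .rise_t_half(T, tau)) - t_stall
  stats::uniroot(g, c(t_stall, t_stall + tau), tol = 1e-12)$root
}

#' Motor-driven stall segment (noise-free mean path)
#'
#' Deterministic excursion of a cargo pulled against the trap by a motor
#' team with linear force-velocity relation `v(F) = v0 (1 - F/F_stall)`:
#' an exponential approach to the plateau `X = F_stall / K_T` with time
#' constant `X / v0`, held so that the width of the force record at
#' half-maximal force equals `t_stall` exactly, then instantaneous
#' detachment. Set `detach_fraction < 1` to emulate premature detachment
#' while the cargo is still moving.
#'
#' @param trap A [trap_config()].
#' @param direction `"plus"` or `"minus"`.
#' @param stall_force Programmed stall force, pN (> 0).
#' @param unloaded_velocity Unloaded motor velocity, um/s.
#' @param t_stall Programmed width at half-maximal force, s.
#' @param detach_fraction Fraction of `stall_force` reached at detachment
#'   (1 = full stall).
#' @return List with `positions` (mean path, nm, sampled at the trap rate),
#'   `duration` (s), `t_half` (s, half-max crossing), `tau` (s),
#'   `plateau` (nm) and `detach_velocity` (nm/s).
#' @export
stall_segment <- function(trap, direction = c("plus", "minus"), stall_force,
                          unloaded_velocity = 1.5, t_stall = 1,
                          detach_fraction = 1) {
  stopifnot(inherits(trap, "trap_config"))
  direction <- match.arg(direction)
  .check_scalar(stall_force, "stall_force", positive = TRUE)
  .check_scalar(unloaded_velocity, "unloaded_velocity", positive = TRUE)
  .check_prob(detach_fraction, "detach_fraction")
  X <- stall_force / trap$stiffness          # nm
  v0 <- unloaded_velocity * 1000             # nm/s
  tau <- X / v0
  if (detach_fraction < 1) {
    dur <- -tau * log(1 - detach_fraction)
  } else {
    .check_scalar(t_stall, "t_stall", positive = TRUE)
    dur <- .rise_duration(t_stall, tau)
  }
  dt <- 1 / trap$sampling_rate
  n <- max(1L, round(dur / dt))
  tt <- (1:n) * dt
  sgn <- if (direction == "plus") 1 else -1
  pos <- sgn * X * (1 - exp(-tt / tau))
  list(positions = pos,
       duration = n * dt,
       t_half = .rise_t_half(n * dt, tau),
       tau = tau, plateau = sgn * X,
       end_position = pos[n],
       realized_force = trap$stiffness * abs(pos[n]),
       detach_velocity = v0 * exp(-n * dt / tau))
}

#' Post-detachment fly-back segment (mean path)
#'
#' Return of the cargo to the trap centre after motor detachment. A
#' `"free"` fly-back is the trap relaxation `x0 exp(-t/tau)` with
#' `tau = gamma/K_T` (complete within a few ms). A `"tug_of_war"` fly-back
#' is resisted by a transient opposing-motor force, modelled as a linear
#' ramp timed so the cargo leaves the 2-SD band of centre fluctuations
#' exactly `resist_time` seconds after release.
#'
#' @param trap A [trap_config()].
#' @param start_position Position at detachment, nm.
#' @param kind `"free"` or `"tug_of_war"`.
#' @param resist_time Programmed fly-back time for `"tug_of_war"`, s
#'   (typically 0.01-0.1).
#' @return List with `positions` (mean path), `duration` (s),
#'   `band_entry_1sd` (s, crossing into the 1-SD band) and
#'   `flyback_time` (s, programmed dwell outside the 2-SD band).
#' @export
flyback_segment <- function(trap, start_position,
                            kind = c("free", "tug_of_war"),
                            resist_time = 0.05) {
  stopifnot(inherits(trap, "trap_config"))
  kind <- match.arg(kind)
  sd0 <- thermal_sd(trap)
  dt <- 1 / trap$sampling_rate
  x0 <- abs(start_position)
  sgn <- sign(start_position)
  if (x0 <= 2 * sd0) {
    return(list(positions = numeric(0), duration = 0,
                band_entry_1sd = 0, flyback_time = 0))
  }
  if (kind == "free") {
    tau <- trap_relaxation_time(trap)
    dur <- tau * log(x0 / 0.5)   # decay to 0.5 nm
    n <- max(1L, round(dur / dt))
    tt <- (1:n) * dt
    pos <- sgn * x0 * exp(-tt / tau)
    t1 <- tau * log(x0 / sd0)
    tf <- tau * log(x0 / (2 * sd0))
  } else {
    .check_scalar(resist_time, "resist_time", positive = TRUE)
    t_ramp <- resist_time / (1 - 2 * sd0 / x0)
    n <- max(1L, round(t_ramp / dt))
    tt <- (1:n) * dt
    pos <- sgn * x0 * pmax(0, 1 - tt / t_ramp)
    t1 <- t_ramp * (1 - sd0 / x0)
    tf <- resist_time
  }
  list(positions = pos, duration = n * dt, band_entry_1sd = t1,
       flyback_time = tf)
}

#' Synthetic-dataset configuration
#'
#' Study conditions of the synthetic optical-trap data: the trap, the
#' occupancy model supplying the rapid-reversal probability, the coin-toss
#' bias, and the event-level force/duration distributions.
#'
#' Defaults emulate a 750-nm early phagosome: fair coin between kinesin and
#' dynein stalls; kinesin teams of 1 or 2 motors (6 / 12 pN) in the ratio
#' implied by the occupancy model's team-size probabilities; dynein
#' recruited in pairs (force multiples of 2.2 pN, major weight at 6.6 pN)
#' unless `dynein_pairs = FALSE`, which yields single/pair forces of
#' 1.1 / 2.2 pN as after partial dynein inhibition; stall widths uniform on
#' 0.6-1.3 s; reversal-permissive (< 0.5 s) inactive gaps drawn with
#' probability `p_rr` (default: the occupancy model's joint reversal
#' probability, 0.7406 under the default model) from an exponential with
#' the dynein characteristic binding time as mean, truncated below 0.5 s,
#' and long gaps from 0.5 s plus an exponential of mean 1.5 s; a fraction
#' `p_tow` of rapid reversals carry a tug-of-war fly-back of 20-80 ms.
#'
#' @param trap A [trap_config()].
#' @param model An [occupancy_model()].
#' @param n_events Stalls per trace.
#' @param p_kinesin Coin bias towards plus-directed events.
#' @param p_rr Probability that the gap after an event is < 0.5 s;
#'   `NULL` uses [joint_reversal_probability()] of `model`.
#' @param p_tow Probability that a rapid reversal is resisted by a
#'   tug-of-war.
#' @param premature_rate Probability of a premature sub-stall detachment
#'   preceding a kinesin stall.
#' @param dynein_pairs Recruit dynein in pairs (multiples of 2.2 pN) or as
#'   single/pairs at 1.1/2.2 pN.
#' @param velocity Unloaded motor velocity, um/s (both classes).
#' @param t_stall_range Uniform range of programmed half-max widths, s.
#' @param inactive_long_mean Mean of the exponential tail added to 0.5 s
#'   for non-rapid gaps, s.
#' @param tow_resist_range Uniform range of tug-of-war fly-back times, s.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(trap = trap_config(), model = occupancy_model(),
                         n_events = 100L, p_kinesin = 0.5, p_rr = NULL,
                         p_tow = 0.3, premature_rate = 0.05,
                         dynein_pairs = TRUE, velocity = 1.5,
                         t_stall_range = c(0.6, 1.3),
                         inactive_long_mean = 1.5,
                         tow_resist_range = c(0.02, 0.08)) {
  stopifnot(inherits(trap, "trap_config"), inherits(model, "occupancy_model"))
  .check_scalar(n_events, "n_events", positive = TRUE, integerish = TRUE)
  .check_prob(p_kinesin, "p_kinesin")
  if (is.null(p_rr)) p_rr <- joint_reversal_probability(model)
  .check_prob(p_rr, "p_rr")
  .check_prob(p_tow, "p_tow")
  .check_prob(premature_rate, "premature_rate")
  .check_scalar(velocity, "velocity", positive = TRUE)
  structure(list(trap = trap, model = model, n_events = as.integer(n_events),
                 p_kinesin = p_kinesin, p_rr = p_rr, p_tow = p_tow,
                 premature_rate = premature_rate,
                 dynein_pairs = dynein_pairs, velocity = velocity,
                 t_stall_range = t_stall_range,
                 inactive_short_mean = characteristic_time(
                   model$dynein$k_on, model$dynein$k_off),
                 inactive_long_mean = inactive_long_mean,
                 tow_resist_range = tow_resist_range),
            class = "synth_config")
}

## Truncated exponential on [0, cap): inverse-CDF sampling.
.rexp_trunc <- function(n, mean, cap) {
  u <- stats::runif(n)
  -mean * log(1 - u * (1 - exp(-cap / mean)))
}

## Draw a team stall force for one event.
.draw_force <- function(config, label) {
  if (label == "K") {
    kp <- kinesin_team_probabilities(config$model$kinesin$total_count,
                                     config$model$contact_fraction)
    p_single <- kp$P_1K / (kp$P_1K + kp$P_gt1K)
    unit <- config$model$kinesin$single_motor_force
    n_mot <- if (stats::runif(1L) < p_single) 1L else 2L
    list(force = n_mot * unit, n_motors = n_mot)
  } else {
    unit <- config$model$dynein$single_motor_force
    if (config$dynein_pairs) {
      n_mot <- sample(c(4L, 6L, 8L, 10L), 1L,
                      prob = c(0.25, 0.45, 0.2, 0.1))
    } else {
      n_mot <- sample(c(1L, 2L), 1L, prob = c(0.55, 0.45))
    }
    list(force = n_mot * unit, n_motors = n_mot)
  }
}

#' Generate a synthetic optical-trap trace with ground truth
#'
#' Concatenates, following a coin-toss label sequence, the event anatomy of
#' a bidirectional trap record: stall rise and plateau, post-detachment
#' fly-back (free or tug-of-war), inactive dwell at the trap centre, next
#' stall. Inactive dwells are constructed so that the time the cargo spends
#' inside the centre-fluctuation band between consecutive stalls equals the
#' programmed gap. The parallel channel superposes the mean path with an
#' exact Ornstein-Uhlenbeck thermal bath plus detector noise; the
#' perpendicular channel is pure thermal noise. Every event and pair label
#' is recorded in the ground truth.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; the trace and truth are deterministic given it.
#' @param trace_id Identifier stored in the trace metadata.
#' @return List of class `synthetic_trace` with elements `trace` (a
#'   [trap_trace()]), `events` (ground-truth stall table) and `pairs`
#'   (ground-truth consecutive-pair table with RR / tug-of-war labels).
#' @export
generate_trace <- function(config = synth_config(), seed = 1L,
                           trace_id = "synthetic") {
  stopifnot(inherits(config, "synth_config"))
  set.seed(seed)
  trap <- config$trap
  dt <- 1 / trap$sampling_rate
  sd0 <- thermal_sd(trap)
  tau_t <- trap_relaxation_time(trap)

  n_ev <- config$n_events
  labels <- ifelse(stats::runif(n_ev) < config$p_kinesin, "K", "D")

  ## per-gap draws (gap i sits between event i and i+1)
  n_gap <- max(0L, n_ev - 1L)
  gap_rr <- stats::runif(n_gap) < config$p_rr
  gaps <- numeric(n_gap)
  if (n_gap > 0L) {
    gaps[gap_rr] <- .rexp_trunc(sum(gap_rr), config$inactive_short_mean, 0.5)
    gaps[!gap_rr] <- 0.5 + stats::rexp(sum(!gap_rr),
                                       1 / config$inactive_long_mean)
    reversal <- labels[-n_ev] != labels[-1L]
    tow <- reversal & gap_rr & stats::runif(n_gap) < config$p_tow
    gaps[tow] <- 0
  } else {
    tow <- logical(0)
  }

  segs <- list()
  scls <- list()
  si <- 0L
  n_total <- 0L
  ## noise_scale < 1 marks spans where engaged motors stiffen the linkage
  ## and damp the thermal fluctuation (tug-of-war fly-backs)
  push <- function(v, noise_scale = 1) {
    si <<- si + 1L
    segs[[si]] <<- v
    scls[[si]] <<- rep(noise_scale, length(v))
    n_total <<- n_total + length(v)
  }

  ## initial quiet period for centre calibration
  push(numeric(round(1.0 / dt)))

  ev <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    lab <- labels[i]
    dir <- if (lab == "K") "plus" else "minus"
    fd <- .draw_force(config, lab)
    t_stall <- stats::runif(1L, config$t_stall_range[1L],
                            config$t_stall_range[2L])
    premature <- lab == "K" && stats::runif(1L) < config$premature_rate

    if (premature) {
      f_pre <- stats::runif(1L, 1.2, 2.6)
      pre <- stall_segment(trap, dir, fd$force, config$velocity,
                           detach_fraction = f_pre / fd$force)
      t0_pre <- n_total * dt
      push(pre$positions)
      fb_pre <- flyback_segment(trap, pre$positions[length(pre$positions)],
                                "free")
      push(fb_pre$positions)
      push(numeric(round(stats::runif(1L, 0.06, 0.15) / dt)))
      pre_rec <- data.frame(
        trace_id = trace_id, event = i, label = lab, direction = dir,
        n_motors = fd$n_motors, force_pn = f_pre,
        force_realized = pre$realized_force,
        t_start = t0_pre, t_release = t0_pre + pre$duration,
        t_stall = NA_real_, premature = TRUE,
        flyback_kind = "free", flyback_time = fb_pre$flyback_time,
        inactive_after = NA_real_)
    } else {
      pre_rec <- NULL
    }

    st <- stall_segment(trap, dir, fd$force, config$velocity,
                        t_stall = t_stall)
    t0 <- n_total * dt
    push(st$positions)
    t_rel <- n_total * dt

    is_tow <- if (i < n_ev) tow[i] else FALSE
    fb <- flyback_segment(trap, st$end_position,
                          if (is_tow) "tug_of_war" else "free",
                          resist_time = if (is_tow)
                            stats::runif(1L, config$tow_resist_range[1L],
                                         config$tow_resist_range[2L])
                          else 0.05)
    push(fb$positions, noise_scale = if (is_tow) 0.5 else 1)

    if (i < n_ev) {
      ## dwell compensation: the detector measures the in-band time between
      ## stalls, which includes the fly-back tail inside the band and the
      ## next rise up to the band edge (~sd0/v0, independent of team force
      ## since the rise leaves the band at its unloaded velocity)
      t_exit_next <- sd0 / (config$velocity * 1000)
      extra <- (fb$duration - fb$band_entry_1sd) + t_exit_next
      dwell <- max(0, gaps[i] - extra)
      push(numeric(round(dwell / dt)))
    } else {
      push(numeric(round(0.5 / dt)))
    }

    rec <- data.frame(
      trace_id = trace_id, event = i, label = lab, direction = dir,
      n_motors = fd$n_motors, force_pn = fd$force,
      force_realized = st$realized_force,
      t_start = t0, t_release = t_rel, t_stall = t_stall,
      premature = FALSE,
      flyback_kind = if (is_tow) "tug_of_war" else "free",
      flyback_time = fb$flyback_time,
      inactive_after = if (i < n_ev) gaps[i] else NA_real_)
    ev[[i]] <- rbind(pre_rec, rec)
  }

  events <- do.call(rbind, ev)
  rownames(events) <- NULL

  mean_path <- unlist(segs, use.names = FALSE)
  n <- length(mean_path)
  x <- mean_path + unlist(scls, use.names = FALSE) *
    .ou_noise(n, dt, tau_t, sd0) +
    stats::rnorm(n, sd = trap$detector_noise_sd)
  y <- .ou_noise(n, dt, tau_t, sd0) +
    stats::rnorm(n, sd = trap$detector_noise_sd)

  trace <- trap_trace(
    time = (seq_len(n) - 1L) * dt, x = x, y = y,
    metadata = list(trap_stiffness = trap$stiffness,
                    sampling_rate = trap$sampling_rate,
                    temperature = trap$temperature,
                    cargo_diameter = trap$cargo_diameter,
                    trace_id = trace_id))

  real <- events[!events$premature, ]
  pairs <- NULL
  if (nrow(real) >= 2L) {
    i1 <- seq_len(nrow(real) - 1L)
    type <- paste0(real$label[i1], real$label[i1 + 1L])
    inact <- real$inactive_after[i1]
    is_rev <- type %in% c("DK", "KD")
    pairs <- data.frame(
      trace_id = trace_id,
      first = real$event[i1], second = real$event[i1 + 1L],
      pair_type = type, inactive = inact, is_rr = inact < 0.5,
      tow_class = ifelse(is_rev & inact < 0.5,
                         ifelse(real$flyback_kind[i1] == "tug_of_war",
                                "with_tow", "no_tow"),
                         NA_character_))
  }

  structure(list(trace = trace, events = events, pairs = pairs),
            class = "synthetic_trace")
}

#' @export
print.synthetic_trace <- function(x, ...) {
  cat("<synthetic_trace>", nrow(x$events), "programmed events,",
      if (is.null(x$pairs)) 0L else nrow(x$pairs), "pairs\n")
  print(x$trace)
  invisible(x)
}

#' Generate and write a dataset of synthetic traces
#'
#' Writes `n_traces` trace files (CSV, see [write_trace()]), pooled
#' ground-truth event and pair tables, and a JSON manifest with the derived
#' per-trace seeds and file checksums. Per-trace seeds come from
#' [derive_seed()] so the dataset is reproducible at any size.
#'
#' @param n_traces Number of traces.
#' @param config A [synth_config()].
#' @param seed Top-level integer seed.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly: list with `files`, `seeds`,
#'   `checksums`, `n_events`.
#' @export
generate_dataset <- function(n_traces, config = synth_config(), seed = 1L,
                             out_dir = ".") {
  .check_scalar(n_traces, "n_traces", nonneg = TRUE, integerish = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  seeds <- integer(0)
  all_events <- list()
  all_pairs <- list()
  for (i in seq_len(n_traces)) {
    id <- sprintf("trace_%03d", i)
    s <- derive_seed(seed, i)
    sim <- generate_trace(config, seed = s, trace_id = id)
    f <- file.path(out_dir, paste0(id, ".csv"))
    write_trace(sim$trace, f)
    files <- c(files, f)
    seeds <- c(seeds, s)
    all_events[[i]] <- sim$events
    all_pairs[[i]] <- sim$pairs
  }
  events <- if (length(all_events)) do.call(rbind, all_events) else NULL
  pairs <- if (length(all_pairs)) do.call(rbind, all_pairs) else NULL
  if (!is.null(events)) {
    utils::write.csv(events, file.path(out_dir, "truth_events.csv"),
                     row.names = FALSE)
  }
  if (!is.null(pairs)) {
    utils::write.csv(pairs, file.path(out_dir, "truth_pairs.csv"),
                     row.names = FALSE)
  }
  manifest <- list(files = basename(files), seeds = seeds,
                   checksums = unname(tools::md5sum(files)),
                   n_events = if (is.null(events)) 0L else nrow(events))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  invisible(manifest)
}
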