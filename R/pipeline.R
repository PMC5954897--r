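#' Trap-centre calibration
#'
#' Locates the trap centre and the motor-free ("inactive") position
#' fluctuation of a trace. The centre is found as the densest position
#' cluster of the median-filtered signal (motor-free dwells concentrate at
#' the trap centre while stall plateaus spread over many force levels); the
#' calibration segment is the longest contiguous dwell in that cluster and
#' must cover at least `min_duration` seconds. Supply `segment` to use an
#' explicitly chosen quiet interval, or construct a calibration directly
#' with `center_calibration()` when the fluctuation is known (e.g.
#' noise-free synthetic data).
#'
#' @param trace A [trap_trace()].
#' @param segment Optional `c(t0, t1)` quiet interval in seconds.
#' @param min_duration Minimum quiet dwell required, s.
#' @param filter_width Median pre-filter width, s.
#' @return Object of class `center_calibration`: list with
#'   `center_position` (nm), `center_sd` (nm), `perpendicular_sd` (nm or
#'   `NA`), and the `segment` used.
#' @export
calibrate_center <- function(trace, segment = NULL, min_duration = 0.5,
                             filter_width = 0.005) {
  stopifnot(inherits(trace, "trap_trace"))
  md <- trace_metadata(trace)
  dt <- 1 / md$sampling_rate
  x <- trace$x_nm
  if (!is.null(segment)) {
    idx <- which(trace$time_s >= segment[1L] & trace$time_s <= segment[2L])
    if (length(idx) < 2L) stop("empty calibration segment", call. = FALSE)
  } else {
    xs <- .medfilt(x, filter_width, md$sampling_rate)
    d <- stats::density(xs, n = 1024)
    pk <- which.max(d$y)
    c0 <- d$x[pk]
    ## filtered-noise SD from the half-width at half-maximum of the peak
    half <- d$y[pk] / 2
    lo <- which(d$y[seq_len(pk)] < half)
    hi <- which(d$y[pk:length(d$y)] < half)
    hwhm <- if (length(lo) && length(hi)) {
      min(c0 - d$x[max(lo)], d$x[pk + min(hi) - 1L] - c0)
    } else {
      stats::mad(xs - c0)
    }
    sf <- max(hwhm / 1.1774, 1e-3)
    inb <- abs(xs - c0) < 4 * sf
    r <- rle(inb)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= round(min_duration / dt))
    ## a genuine motor-free dwell is dominated by fast thermal noise, so
    ## the median filter removes most of its variance; slow motor-driven
    ## ramps or dwells keep theirs. Reject candidates that do not behave
    ## thermally or that drift between their halves.
    ok <- ok[order(r$lengths[ok], decreasing = TRUE)]
    idx <- NULL
    for (b in ok) {
      cand <- starts[b]:ends[b]
      seg_x <- x[cand]
      h <- length(seg_x) %/% 2
      drift <- abs(mean(seg_x[1:h]) - mean(seg_x[(h + 1):length(seg_x)]))
      if (stats::sd(xs[cand]) < 0.9 * stats::sd(seg_x) &&
          drift < 0.5 * stats::sd(seg_x)) {
        idx <- cand
        break
      }
    }
    if (is.null(idx)) {
      stop("no motor-free segment of at least ", min_duration,
           " s found; supply one explicitly", call. = FALSE)
    }
  }
  center_calibration(
    center_position = mean(x[idx]),
    center_sd = stats::sd(x[idx]),
    perpendicular_sd = if ("y_nm" %in% names(trace))
      stats::sd(trace$y_nm[idx]) else NA_real_,
    segment = range(trace$time_s[idx]))
}

#' @rdname calibrate_center
#' @param center_position,center_sd,perpendicular_sd Calibration values in
#'   nm.
#' @export
center_calibration <- function(center_position, center_sd,
                               perpendicular_sd = NA_real_,
                               segment = c(NA_real_, NA_real_)) {
  .check_scalar(center_position, "center_position")
  .check_scalar(center_sd, "center_sd", positive = TRUE)
  structure(list(center_position = center_position, center_sd = center_sd,
                 perpendicular_sd = perpendicular_sd, segment = segment),
            class = "center_calibration")
}

#' @export
print.center_calibration <- function(x, ...) {
  cat(sprintf("<center_calibration> centre %.2f nm, SD %.2f nm\n",
              x$center_position, x$center_sd))
  invisible(x)
}

## Running-median filter with width in seconds (odd window).
.medfilt <- function(x, width, fs) {
  k <- max(3L, round(width * fs))
  if (k %% 2L == 0L) k <- k + 1L
  if (k >= length(x)) return(x)
  as.numeric(stats::runmed(x, k))
}

#' Stall detection thresholds
#'
#' Per-direction gates on detected excursions: a candidate is a stall when
#' its maximal force exceeds `min_force` and its width at half-maximal
#' force exceeds `min_duration`. The `"default"` profile applies
#' 3 pN / 0.5 s in both directions; `"low_force_minus"` relaxes the minus
#' (dynein) direction to 0.7 pN / 0.3 s for datasets where single dyneins
#' (~1.1 pN) must be counted, as after partial dynein inhibition.
#'
#' @param profile `"default"` or `"low_force_minus"`.
#' @return Named list of per-direction thresholds.
#' @export
stall_thresholds <- function(profile = c("default", "low_force_minus")) {
  profile <- match.arg(profile)
  minus <- if (profile == "low_force_minus") {
    list(min_force = 0.7, min_duration = 0.3)
  } else {
    list(min_force = 3, min_duration = 0.5)
  }
  list(plus = list(min_force = 3, min_duration = 0.5), minus = minus)
}

#' Detect stalls in an optical-trap trace
#'
#' Segments the median-filtered trace into candidate motor events by
#' hysteresis around the trap centre — an event opens where the excursion
#' exceeds 2 centre-SDs and closes where it falls back below 1 SD — and
#' converts displacement to force via `F = K_T (x - centre)`. For each
#' candidate the maximal (filtered) force, the plateau force (median over
#' the last 100 ms of the force plateau; less biased by thermal noise
#' than the raw sample maximum, and reported as the stall force), the
#' width at half-maximal force `T_STALL`, the release time (last crossing
#' of 97% of the plateau, i.e. the end of the force plateau) and the
#' pre-detachment velocity over the `velocity_window`
#' before release are measured. Candidates pass as stalls when they satisfy
#' the per-direction thresholds; all candidates longer than
#' `min_candidate_duration` are returned so that premature detachments can
#' be flagged downstream by [flag_premature()].
#'
#' @param trace A [trap_trace()].
#' @param calibration A `center_calibration`; computed from the trace when
#'   `NULL`.
#' @param thresholds See [stall_thresholds()].
#' @param filter_width Median filter width, s (default 5 ms).
#' @param min_candidate_duration Shortest excursion considered an event, s.
#' @param velocity_window Pre-detachment velocity window, s (default 0.2).
#' @return Object of class `stall_events`: data frame with one row per
#'   candidate (`t_start`, `t_end`, `t_release`, `direction`, `label`,
#'   `peak_force`, `stall_force`, `t_stall`, `pre_detachment_velocity`,
#'   `passes`, `premature`), carrying the calibration as an attribute.
#' @export
detect_stalls <- function(trace, calibration = NULL,
                          thresholds = stall_thresholds(),
                          filter_width = 0.005,
                          min_candidate_duration = 0.01,
                          velocity_window = 0.2) {
  stopifnot(inherits(trace, "trap_trace"))
  md <- trace_metadata(trace)
  if (is.null(md$trap_stiffness)) {
    stop("trace metadata lacks trap_stiffness", call. = FALSE)
  }
  if (is.null(calibration)) calibration <- calibrate_center(trace)
  fs <- md$sampling_rate
  dt <- 1 / fs
  xs <- .medfilt(trace$x_nm, filter_width, fs)
  dev <- xs - calibration$center_position
  sdc <- calibration$center_sd

  ## filtered-noise SD, for the release threshold: measured over the
  ## calibration segment when known, otherwise approximated from the raw
  ## centre SD
  seg <- calibration$segment
  sf <- if (all(is.finite(seg))) {
    idx <- which(trace$time_s >= seg[1L] & trace$time_s <= seg[2L])
    stats::sd(xs[idx])
  } else {
    calibration$center_sd / 2
  }

  act <- abs(dev) > sdc
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= max(2L, round(min_candidate_duration * fs)))

  rows <- vector("list", length(keep))
  n_out <- 0L
  for (j in keep) {
    i0 <- starts[j]; i1 <- ends[j]
    seg <- dev[i0:i1]
    if (max(abs(seg)) <= 2 * sdc) next # never left the hysteresis band
    f <- md$trap_stiffness * seg
    af <- abs(f)
    pk <- max(af)
    ipk <- which.max(af)
    dir <- if (seg[ipk] > 0) "plus" else "minus"
    half_idx <- which(af >= pk / 2)
    t_stall <- (max(half_idx) - min(half_idx) + 1L) * dt
    ## plateau force, two passes: a rough plateau location keeps the
    ## trailing samples of a slow (tug-of-war) force decay out of the
    ## window; the final estimate is a median over the 100 ms before the
    ## end of the plateau — the sample maximum is biased upward by thermal
    ## noise, early rise samples downward
    rough <- stats::median(af[af >= 0.8 * pk])
    i_he <- max(which(af >= 0.95 * rough))
    plat_w <- min(i_he - min(half_idx), round(0.1 * fs))
    stall_force <- stats::median(af[(i_he - plat_w):i_he])
    ## release: last crossing of the plateau minus a 2-sigma noise margin
    ## (end of the force plateau, i.e. motor detachment)
    rel_thr <- max(stall_force - 2 * md$trap_stiffness * sf,
                   0.6 * stall_force)
    i_rel <- i0 + max(which(af >= rel_thr)) - 1L
    nw <- round(velocity_window * fs)
    w0 <- max(1L, i_rel - nw)
    vfit <- stats::coef(stats::lsfit(trace$time_s[w0:i_rel],
                                     xs[w0:i_rel]))[2L]
    thr <- thresholds[[dir]]
    n_out <- n_out + 1L
    rows[[n_out]] <- data.frame(
      trace_id = md$trace_id %||% NA_character_,
      i_start = i0, i_end = i1, i_release = i_rel,
      t_start = trace$time_s[i0], t_end = trace$time_s[i1],
      t_release = trace$time_s[i_rel],
      direction = dir, label = if (dir == "plus") "K" else "D",
      peak_force = pk, stall_force = stall_force, t_stall = t_stall,
      pre_detachment_velocity = abs(vfit),
      passes = pk > thr$min_force && t_stall > thr$min_duration,
      premature = FALSE)
  }
  out <- if (n_out) do.call(rbind, rows[seq_len(n_out)]) else
    data.frame(trace_id = character(), i_start = integer(),
               i_end = integer(), i_release = integer(),
               t_start = numeric(), t_end = numeric(),
               t_release = numeric(), direction = character(),
               label = character(), peak_force = numeric(),
               stall_force = numeric(), t_stall = numeric(),
               pre_detachment_velocity = numeric(), passes = logical(),
               premature = logical())
  rownames(out) <- NULL
  structure(out, calibration = calibration,
            class = c("stall_events", "data.frame"))
}

#' Flag and merge premature detachments
#'
#' Sub-threshold candidates (failing both the force and the duration gate)
#' whose pre-detachment velocity exceeds the median velocity of accepted
#' stalls by `speed_factor` (with an absolute floor `speed_floor`, nm/s)
#' are flagged as premature detachments of the following stall's team and
#' merged into the next accepted stall in the same direction (within
#' `merge_window` seconds), so the premature + full excursions count as one
#' event, not two.
#'
#' @param events A `stall_events` table from [detect_stalls()].
#' @param speed_factor Multiple of the median accepted plateau velocity.
#' @param speed_floor Absolute minimum flagging velocity, nm/s.
#' @param merge_window Maximum gap to the following stall, s.
#' @return The updated `stall_events` (premature rows flagged, following
#'   stalls extended to the premature start).
#' @export
flag_premature <- function(events, speed_factor = 3, speed_floor = 100,
                           merge_window = 1.0) {
  stopifnot(inherits(events, "stall_events"))
  if (!nrow(events)) return(events)
  acc <- which(events$passes)
  if (!length(acc)) return(events)
  med_v <- stats::median(events$pre_detachment_velocity[acc])
  thr <- max(speed_factor * med_v, speed_floor)
  cand <- which(!events$passes & events$pre_detachment_velocity > thr)
  for (i in cand) {
    nxt <- which(events$passes & !events$premature &
                   events$direction == events$direction[i] &
                   events$t_start > events$t_end[i] &
                   events$t_start - events$t_end[i] <= merge_window)
    if (length(nxt)) {
      nxt <- nxt[1L]
      events$premature[i] <- TRUE
      events$t_start[nxt] <- events$t_start[i]
      events$i_start[nxt] <- events$i_start[i]
    }
  }
  events
}

## Accepted, non-premature stalls in time order.
.kept_stalls <- function(events) {
  ev <- events[events$passes & !events$premature, , drop = FALSE]
  ev[order(ev$t_start), , drop = FALSE]
}

#' Detect inactive periods between stalls
#'
#' For each gap between consecutive accepted stalls, measures the dwell at
#' the trap centre: the span of median-filtered samples within 2 centre-SDs
#' of the centre, tolerating interior excursions of at most
#' `excursion_tolerance` seconds. A gap with no in-band samples (abutting
#' stalls) yields no interval. Each interval carries the SD of the raw
#' position inside it for the fluctuation comparison against the free
#' trap.
#'
#' @param trace A [trap_trace()].
#' @param calibration A `center_calibration`.
#' @param events A `stall_events` table.
#' @param filter_width Median filter width, s.
#' @param excursion_tolerance Longest tolerated interior excursion, s.
#' @return Data frame with one row per gap that contains an inactive
#'   interval: `after_event` (row index into the kept stalls), `t_start`,
#'   `t_end`, `duration`, `position_sd`.
#' @export
detect_inactive <- function(trace, calibration, events,
                            filter_width = 0.005,
                            excursion_tolerance = 0.010) {
  stopifnot(inherits(trace, "trap_trace"),
            inherits(calibration, "center_calibration"))
  md <- trace_metadata(trace)
  dt <- 1 / md$sampling_rate
  xs <- .medfilt(trace$x_nm, filter_width, md$sampling_rate)
  dev <- abs(xs - calibration$center_position)
  kept <- .kept_stalls(events)
  out <- list()
  if (nrow(kept) >= 2L) {
    for (i in seq_len(nrow(kept) - 1L)) {
      g0 <- kept$i_end[i] + 1L
      g1 <- kept$i_start[i + 1L] - 1L
      if (g1 < g0) next
      inb <- which(dev[g0:g1] < 2 * calibration$center_sd)
      if (!length(inb)) next
      i_first <- g0 + min(inb) - 1L
      i_last <- g0 + max(inb) - 1L
      ## interior excursions beyond the band longer than the tolerance
      ## terminate the interval at the excursion
      exc <- rle(dev[i_first:i_last] >= 2 * calibration$center_sd)
      if (any(exc$values & exc$lengths > round(excursion_tolerance / dt))) {
        ends <- cumsum(exc$lengths)
        bad <- which(exc$values &
                       exc$lengths > round(excursion_tolerance / dt))[1L]
        i_last <- i_first + (ends[bad] - exc$lengths[bad]) - 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        after_event = i,
        t_start = trace$time_s[i_first], t_end = trace$time_s[i_last],
        duration = (i_last - i_first + 1L) * dt,
        position_sd = stats::sd(trace$x_nm[i_first:i_last]))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(after_event = integer(), t_start = numeric(),
               t_end = numeric(), duration = numeric(),
               position_sd = numeric())
}

#' Pair consecutive stalls and call rapid reversals
#'
#' Types every overlapping pair of consecutive accepted stalls by their
#' directions (minus = D, plus = K; `DK` and `KD` are reversals), assigns
#' the intervening inactive duration (0 when no inactive interval was
#' detected — abutting stalls are rapid reversals by definition) and calls
#' rapid reversals against `rr_threshold`.
#'
#' @param events A `stall_events` table.
#' @param inactive Output of [detect_inactive()].
#' @param rr_threshold Rapid-reversal threshold on the inactive time, s
#'   (default 0.5).
#' @return Object of class `event_pairs`: data frame with `first`,
#'   `second` (row indices into the kept stalls), `pair_type`,
#'   `inactive_duration`, `is_rr`, and placeholders `flyback_time`,
#'   `tow_class` filled by [measure_flyback()] / [classify_tow()].
#' @export
pair_events <- function(events, inactive, rr_threshold = 0.5) {
  stopifnot(inherits(events, "stall_events"))
  kept <- .kept_stalls(events)
  n <- nrow(kept)
  if (n < 2L) {
    return(structure(
      data.frame(trace_id = character(), first = integer(),
                 second = integer(), pair_type = character(),
                 inactive_duration = numeric(), is_rr = logical(),
                 flyback_time = numeric(), tow_class = character()),
      class = c("event_pairs", "data.frame")))
  }
  i1 <- seq_len(n - 1L)
  dur <- numeric(n - 1L)
  if (nrow(inactive)) dur[inactive$after_event] <- inactive$duration
  out <- data.frame(
    trace_id = kept$trace_id[i1],
    first = i1, second = i1 + 1L,
    pair_type = paste0(kept$label[i1], kept$label[i1 + 1L]),
    inactive_duration = dur,
    is_rr = dur < rr_threshold,
    flyback_time = NA_real_,
    tow_class = NA_character_)
  structure(out, kept = kept, class = c("event_pairs", "data.frame"))
}

#' Measure the fly-back time of a reversal pair
#'
#' Dwell in the fly-back region: time from the first stall's release (end
#' of its force plateau) until the position first re-enters the 2-SD
#' band of centre fluctuations. Fast fly-backs (a few ms, the trap
#' relaxation) indicate an unopposed return; slow ones indicate a
#' tug-of-war with still-engaged opposing motors.
#'
#' @param trace A [trap_trace()].
#' @param calibration A `center_calibration`.
#' @param pairs An `event_pairs` table (from [pair_events()]).
#' @param which_pairs Row indices to measure; default all reversal pairs.
#' @return `pairs` with `flyback_time` filled in (s; `NA` when the trace is
#'   truncated before re-entry, 0 when the release point is already inside
#'   the band).
#' @export
measure_flyback <- function(trace, calibration, pairs,
                            which_pairs = which(pairs$pair_type %in%
                                                  c("DK", "KD"))) {
  stopifnot(inherits(trace, "trap_trace"),
            inherits(calibration, "center_calibration"),
            inherits(pairs, "event_pairs"))
  kept <- attr(pairs, "kept")
  md <- trace_metadata(trace)
  dt <- 1 / md$sampling_rate
  ## a light (2.5 ms) median filter suppresses single-sample noise
  ## crossings of the band without distorting millisecond fly-backs
  dev <- abs(.medfilt(trace$x_nm, 0.0025, md$sampling_rate) -
               calibration$center_position)
  band <- 2 * calibration$center_sd
  for (p in which_pairs) {
    i_rel <- kept$i_release[pairs$first[p]]
    i_next <- kept$i_start[pairs$second[p]]
    if (dev[i_rel] < band) {
      pairs$flyback_time[p] <- 0
      next
    }
    seg <- dev[(i_rel + 1L):max(i_rel + 1L, i_next)]
    hit <- which(seg < band)
    pairs$flyback_time[p] <- if (length(hit)) hit[1L] * dt else NA_real_
  }
  pairs
}

#' Classify reversal fly-backs as with / without tug-of-war
#'
#' Splits measured fly-back times into a fast (no tug-of-war) and a slow
#' (with tug-of-war) class, either by a fixed `cutoff` (default 5 ms, the
#' upper bound of unopposed fly-backs) or by a 1-D two-class split of the
#' log fly-back times maximising the between-class variance (Otsu's
#' criterion). The cluster method needs at least 4 values and falls back
#' to the threshold (with a message) otherwise.
#'
#' @param flyback_times Numeric vector of fly-back times, s (NAs dropped).
#' @param method `"threshold"` or `"cluster"`.
#' @param cutoff Threshold in seconds for the `"threshold"` method.
#' @return List with `classes` (`"with_tow"` / `"no_tow"` per input value,
#'   `NA` preserved), `fraction_with_tow`, `threshold_used` (s) and
#'   `method`.
#' @export
classify_tow <- function(flyback_times, method = c("threshold", "cluster"),
                         cutoff = 0.005) {
  method <- match.arg(method)
  ok <- !is.na(flyback_times)
  vals <- flyback_times[ok]
  if (!length(vals)) stop("no fly-back times to classify", call. = FALSE)
  if (method == "cluster") {
    if (length(vals) < 4L) {
      message("classify_tow: < 4 values, falling back to threshold method")
      method <- "threshold"
    } else {
      cutoff <- .otsu_split(log10(pmax(vals, 1e-5)))
      cutoff <- 10^cutoff
    }
  }
  classes <- rep(NA_character_, length(flyback_times))
  classes[ok] <- ifelse(vals > cutoff, "with_tow", "no_tow")
  list(classes = classes,
       fraction_with_tow = mean(vals > cutoff),
       threshold_used = cutoff, method = method)
}

## Otsu's 1-D two-class split: threshold maximising the between-class
## variance; returns the midpoint between the bracketing observations.
.otsu_split <- function(v) {
  v <- sort(v)
  n <- length(v)
  cs <- cumsum(v)
  tot <- cs[n]
  k <- seq_len(n - 1L)
  m1 <- cs[k] / k
  m2 <- (tot - cs[k]) / (n - k)
  between <- k * (n - k) * (m1 - m2)^2
  kbest <- which.max(between)
  (v[kbest] + v[kbest + 1L]) / 2
}

#' Run the full detection pipeline on one trace
#'
#' Convenience wrapper: centre calibration, stall detection, premature
#' flagging/merging, inactive-interval detection, pairing with
#' rapid-reversal calls, fly-back measurement for reversals, and
#' tug-of-war classification.
#'
#' @param trace A [trap_trace()].
#' @param thresholds See [stall_thresholds()].
#' @param calibration Optional precomputed `center_calibration`.
#' @param tow_method `"threshold"` or `"cluster"` (see [classify_tow()]).
#' @return Object of class `trace_analysis`: list with `calibration`,
#'   `events` (all candidates), `stalls` (accepted, merged), `inactive`,
#'   and `pairs`.
#' @export
analyze_trace <- function(trace, thresholds = stall_thresholds(),
                          calibration = NULL, tow_method = "threshold") {
  if (is.null(calibration)) calibration <- calibrate_center(trace)
  events <- detect_stalls(trace, calibration, thresholds)
  events <- flag_premature(events)
  inactive <- detect_inactive(trace, calibration, events)
  pairs <- pair_events(events, inactive)
  if (nrow(pairs)) {
    pairs <- measure_flyback(trace, calibration, pairs)
    rev_rr <- which(pairs$pair_type %in% c("DK", "KD") & pairs$is_rr &
                      !is.na(pairs$flyback_time))
    if (length(rev_rr)) {
      cls <- classify_tow(pairs$flyback_time[rev_rr], method = tow_method)
      pairs$tow_class[rev_rr] <- cls$classes
    }
  }
  structure(list(calibration = calibration, events = events,
                 stalls = .kept_stalls(events), inactive = inactive,
                 pairs = pairs),
            class = "trace_analysis")
}

#' @export
print.trace_analysis <- function(x, ...) {
  cat("<trace_analysis>", nrow(x$stalls), "stalls,",
      nrow(x$pairs), "pairs,",
      sum(x$pairs$is_rr & x$pairs$pair_type %in% c("DK", "KD")),
      "rapid reversals\n")
  invisible(x)
}
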