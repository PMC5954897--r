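#' Inactive-time histogram and first-bin fraction
#'
#' Bins the inactive durations of reversal pairs (DK and KD separately) in
#' `bin`-second bins. The first-bin fraction — reversals with inactive time
#' below `bin` (default 0.5 s), i.e. rapid reversals — is the observable
#' the binomial occupancy model predicts: under the default model 74% of
#' reversals should fall in the first bin.
#'
#' @param pairs An `event_pairs` data frame (or any data frame with
#'   `pair_type` and `inactive_duration`), possibly pooled over traces.
#' @param bin Bin width, s.
#' @return List with `histogram` (data frame: `pair_type`, `bin_left`,
#'   `bin_right`, `count`) and `first_bin_fraction` (named vector over
#'   `DK`, `KD`, `overall`). Empty input yields an empty histogram and
#'   `NA` fractions.
#' @export
inactive_histogram <- function(pairs, bin = 0.5) {
  .check_scalar(bin, "bin", positive = TRUE)
  rev <- pairs[pairs$pair_type %in% c("DK", "KD"), , drop = FALSE]
  if (!nrow(rev)) {
    return(list(histogram = data.frame(pair_type = character(),
                                       bin_left = numeric(),
                                       bin_right = numeric(),
                                       count = integer()),
                first_bin_fraction = c(DK = NA_real_, KD = NA_real_,
                                       overall = NA_real_)))
  }
  hist_one <- function(d, type) {
    if (!length(d)) return(NULL)
    top <- max(bin, bin * ceiling(max(d) / bin + 1e-9))
    br <- seq(0, top, by = bin)
    cnt <- as.integer(table(cut(d, br, right = FALSE,
                                include.lowest = TRUE)))
    data.frame(pair_type = type, bin_left = br[-length(br)],
               bin_right = br[-1L], count = cnt)
  }
  h <- rbind(hist_one(rev$inactive_duration[rev$pair_type == "DK"], "DK"),
             hist_one(rev$inactive_duration[rev$pair_type == "KD"], "KD"))
  frac <- function(d) if (length(d)) mean(d < bin) else NA_real_
  list(histogram = h,
       first_bin_fraction = c(
         DK = frac(rev$inactive_duration[rev$pair_type == "DK"]),
         KD = frac(rev$inactive_duration[rev$pair_type == "KD"]),
         overall = frac(rev$inactive_duration)))
}

#' Stall-force histogram
#'
#' Bins stall forces in `bin`-pN bins (default 0.5 pN) from zero. With
#' `normalize = TRUE` counts are scaled to the maximum bin, the form used
#' to overlay categories.
#'
#' @param forces Positive stall forces, pN.
#' @param bin Bin width, pN.
#' @param normalize Scale counts to the maximum bin.
#' @return Data frame with `bin_left`, `bin_right`, `mid`, `count` and,
#'   when requested, `normalized`.
#' @export
force_histogram <- function(forces, bin = 0.5, normalize = FALSE) {
  .check_scalar(bin, "bin", positive = TRUE)
  if (!length(forces)) {
    return(data.frame(bin_left = numeric(), bin_right = numeric(),
                      mid = numeric(), count = integer()))
  }
  stopifnot(all(forces > 0))
  br <- seq(0, bin * ceiling(max(forces) / bin + 1e-9), by = bin)
  cnt <- as.integer(table(cut(forces, br, right = FALSE)))
  out <- data.frame(bin_left = br[-length(br)], bin_right = br[-1L],
                    mid = br[-length(br)] + bin / 2, count = cnt)
  if (normalize) out$normalized <- out$count / max(out$count)
  out
}

#' Peaks of a force histogram
#'
#' Local maxima of the binned counts (strictly above the right neighbour,
#' at least the left), used to read off unitary-force periodicity, e.g.
#' the ~1.1 / ~2.2 pN dynein peaks.
#'
#' @param hist Output of [force_histogram()].
#' @param min_count Ignore maxima below this count.
#' @return Numeric vector of bin mid-points at the peaks.
#' @export
force_peaks <- function(hist, min_count = 1L) {
  cnt <- hist$count
  n <- length(cnt)
  if (n == 0L) return(numeric(0))
  left <- c(-Inf, cnt[-n])
  right <- c(cnt[-1L], -Inf)
  hist$mid[cnt >= left & cnt > right & cnt >= min_count]
}

#' Two-Gaussian mixture fit of a stall-force distribution
#'
#' Maximum-likelihood fit of a two-component Gaussian mixture with unequal
#' variances (EM, via \pkg{mclust}). Components are returned in order of
#' increasing mean; the weight of the low-force component is the
#' single-motor fraction when applied to a single/multi-motor force
#' distribution (e.g. the ~40%/60% single/multi-kinesin split at 6 and
#' 12 pN).
#'
#' @param forces Numeric vector of stall forces (at least 20).
#' @return List with `means`, `sds`, `weights` (low-force component
#'   first), `single_fraction` (weight of the low component),
#'   `degenerate` (TRUE when the two component means are separated by less
#'   than twice the mean component SD) and `loglik`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_two_gaussians <- function(forces) {
  if (length(forces) < 20L) {
    stop("need at least 20 values for a two-component fit", call. = FALSE)
  }
  fit <- Mclust(forces, G = 2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) {
    stop("two-Gaussian mixture fit did not converge", call. = FALSE)
  }
  ord <- order(fit$parameters$mean)
  means <- unname(fit$parameters$mean[ord])
  sds <- unname(sqrt(fit$parameters$variance$sigmasq[ord]))
  wts <- unname(fit$parameters$pro[ord])
  degenerate <- diff(means) < 2 * mean(sds)
  if (degenerate) {
    warning("two-Gaussian fit is degenerate: components overlap",
            call. = FALSE)
  }
  list(means = means, sds = sds, weights = wts,
       single_fraction = wts[1L], degenerate = degenerate,
       loglik = fit$loglik)
}

#' Compare two groups with an unpaired two-tailed t test
#'
#' Student's t test (unpaired, two-tailed, pooled variance), the comparison
#' used for mock- versus inhibitor-treated stall statistics.
#'
#' @param values_a,values_b Numeric vectors (each at least 2 values).
#' @return List with `t_statistic`, `p_value`, `means`, `sems`, `n` and
#'   `degenerate_variance` (TRUE when both groups have zero variance, in
#'   which case the statistic is `NA`).
#' @export
compare_groups <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 2L, length(values_b) >= 2L)
  sems <- c(stats::sd(values_a) / sqrt(length(values_a)),
            stats::sd(values_b) / sqrt(length(values_b)))
  means <- c(mean(values_a), mean(values_b))
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    return(list(t_statistic = NA_real_, p_value = NA_real_, means = means,
                sems = sems, n = c(length(values_a), length(values_b)),
                degenerate_variance = TRUE))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(t_statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       means = means, sems = sems,
       n = c(length(values_a), length(values_b)),
       degenerate_variance = FALSE)
}

#' Detection-versus-truth recovery report
#'
#' Scores a detection result against the generator's ground truth. Truth
#' stalls are matched to accepted detected stalls of the same trace by time
#' overlap (> 50% of the truth stall's rise-to-release interval); matched
#' pairs of consecutive stalls are compared by pair type, rapid-reversal
#' call and tug-of-war class.
#'
#' @param analyses A `trace_analysis` or list of them (one per trace).
#' @param truth A `synthetic_trace` or list of them (same traces).
#' @return List with `n_truth`, `n_detected`, `precision`, `recall`,
#'   `force_relative_error` (per matched stall), `pair_confusion` (4x4
#'   table), `pair_type_agreement`, `rr_agreement`, `tow_agreement`.
#' @export
recovery_report <- function(analyses, truth) {
  if (inherits(analyses, "trace_analysis")) analyses <- list(analyses)
  if (inherits(truth, "synthetic_trace")) truth <- list(truth)
  if (length(analyses) != length(truth)) {
    stop("'analyses' and 'truth' must describe the same traces",
         call. = FALSE)
  }
  types <- c("DD", "DK", "KD", "KK")
  conf <- matrix(0L, 4L, 4L, dimnames = list(truth = types,
                                             detected = types))
  n_truth <- 0L; n_det <- 0L; n_match <- 0L
  ferr <- numeric(0)
  rr_ok <- integer(0); tow_ok <- integer(0)
  for (k in seq_along(analyses)) {
    an <- analyses[[k]]
    tr <- truth[[k]]
    t_id_a <- unique(an$stalls$trace_id)
    t_id_t <- unique(tr$events$trace_id)
    if (length(t_id_a) && length(t_id_t) && !identical(t_id_a, t_id_t)) {
      stop("trace ids of detection and truth do not match: ",
           t_id_a[1L], " vs ", t_id_t[1L], call. = FALSE)
    }
    tru <- tr$events[!tr$events$premature, , drop = FALSE]
    det <- an$stalls
    n_truth <- n_truth + nrow(tru)
    n_det <- n_det + nrow(det)
    match_idx <- rep(NA_integer_, nrow(tru))
    used <- logical(nrow(det))
    for (i in seq_len(nrow(tru))) {
      dur <- tru$t_release[i] - tru$t_start[i]
      ov <- pmin(det$t_release, tru$t_release[i]) -
        pmax(det$t_start, tru$t_start[i])
      j <- which(!used & ov > 0.5 * dur)
      if (length(j)) {
        j <- j[which.max(ov[j])]
        match_idx[i] <- j
        used[j] <- TRUE
        f_ref <- if ("force_realized" %in% names(tru))
          tru$force_realized[i] else tru$force_pn[i]
        ferr <- c(ferr, abs(det$stall_force[j] - f_ref) / f_ref)
      }
    }
    n_match <- n_match + sum(!is.na(match_idx))
    ## pair-level comparison on consecutively matched stalls
    if (nrow(tru) >= 2L && nrow(an$pairs)) {
      for (i in seq_len(nrow(tru) - 1L)) {
        j1 <- match_idx[i]; j2 <- match_idx[i + 1L]
        if (is.na(j1) || is.na(j2) || j2 != j1 + 1L) next
        p <- which(an$pairs$first == j1)
        if (!length(p)) next
        p <- p[1L]
        t_type <- paste0(tru$label[i], tru$label[i + 1L])
        d_type <- an$pairs$pair_type[p]
        conf[t_type, d_type] <- conf[t_type, d_type] + 1L
        tp <- tr$pairs[tr$pairs$first == tru$event[i], , drop = FALSE]
        if (nrow(tp) == 1L && t_type == d_type) {
          rr_ok <- c(rr_ok, tp$is_rr == an$pairs$is_rr[p])
          if (!is.na(tp$tow_class) && !is.na(an$pairs$tow_class[p])) {
            tow_ok <- c(tow_ok, tp$tow_class == an$pairs$tow_class[p])
          }
        }
      }
    }
  }
  list(n_truth = n_truth, n_detected = n_det,
       precision = if (n_det) n_match / n_det else NA_real_,
       recall = if (n_truth) n_match / n_truth else NA_real_,
       force_relative_error = ferr,
       pair_confusion = conf,
       pair_type_agreement = if (sum(conf)) sum(diag(conf)) / sum(conf)
       else NA_real_,
       rr_agreement = if (length(rr_ok)) mean(rr_ok) else NA_real_,
       tow_agreement = if (length(tow_ok)) mean(tow_ok) else NA_real_)
}
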