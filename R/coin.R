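#' Event sequence of motor-class activations
#'
#' Successive stalls on a cargo are labelled `K` (plus-directed, kinesin) or
#' `D` (minus-directed, dynein). Under the coin-toss model the labels are
#' independent draws — a fair coin gives each of the four consecutive pair
#' types DD/DK/KD/KK a 25% share.
#'
#' @param labels Character vector of labels from a two-letter alphabet
#'   (default `K`/`D`).
#' @param trace_id Vector (recycled) grouping labels by trace; pairs are
#'   never formed across traces.
#' @return Object of class `event_sequence`.
#' @export
event_sequence <- function(labels, trace_id = 1L) {
  labels <- as.character(labels)
  if (length(labels) == 1L && nchar(labels) > 1L) {
    labels <- strsplit(labels, "")[[1L]] # "KDK" shorthand
  }
  if (length(unique(labels)) > 2L) {
    stop("an event sequence uses at most a two-letter alphabet",
         call. = FALSE)
  }
  structure(data.frame(label = labels,
                       trace_id = rep_len(trace_id, length(labels)),
                       stringsAsFactors = FALSE),
            class = c("event_sequence", "data.frame"))
}

#' Simulate a (possibly biased) coin-toss activation sequence
#'
#' @param n Number of events.
#' @param p_kinesin Probability of a `K` event; 0.5 is the fair coin.
#' @param seed Integer seed.
#' @param labels Two labels, success first (default `c("K", "D")`).
#' @return An [event_sequence()].
#' @export
simulate_sequence <- function(n, p_kinesin = 0.5, seed = 1L,
                              labels = c("K", "D")) {
  .check_scalar(n, "n", nonneg = TRUE, integerish = TRUE)
  .check_prob(p_kinesin, "p_kinesin")
  stopifnot(length(labels) == 2L)
  set.seed(seed)
  draws <- stats::runif(n) < p_kinesin
  event_sequence(ifelse(draws, labels[1L], labels[2L]))
}

.pair_types <- function(labels) c("DD", "DK", "KD", "KK")

#' Consecutive event-pair statistics
#'
#' Counts all overlapping consecutive pairs within each trace (a trace of
#' `s` events contributes `s - 1` pairs; pairs never span trace
#' boundaries) and their fractions of the total. Pair `XY` means an `X`
#' event followed by a `Y` event, so `DK` and `KD` are reversals.
#'
#' @param sequence An [event_sequence()] (or character vector of labels).
#' @return Object of class `pair_stats`: list with integer `counts` and
#'   numeric `fractions` over `DD`, `DK`, `KD`, `KK`, plus `total_pairs`.
#'   Empty input yields zero counts, not an error.
#' @export
pair_fractions <- function(sequence) {
  sequence <- .as_event_sequence(sequence)
  counts <- stats::setNames(integer(4L), .pair_types())
  for (id in unique(sequence$trace_id)) {
    lab <- sequence$label[sequence$trace_id == id]
    if (length(lab) >= 2L) {
      pr <- paste0(lab[-length(lab)], lab[-1L])
      tab <- table(factor(pr, levels = .pair_types()))
      counts <- counts + as.integer(tab)
    }
  }
  total <- sum(counts)
  structure(list(counts = counts,
                 fractions = if (total > 0) counts / total else
                   stats::setNames(rep(NA_real_, 4L), .pair_types()),
                 total_pairs = total),
            class = "pair_stats")
}

#' @export
print.pair_stats <- function(x, ...) {
  cat("<pair_stats>", x$total_pairs, "pairs\n")
  print(rbind(count = x$counts, fraction = round(x$fractions, 4)))
  invisible(x)
}

.as_event_sequence <- function(x) {
  if (inherits(x, "event_sequence")) x else event_sequence(x)
}

#' Fraction of plus- and minus-directed events
#'
#' @param sequence An [event_sequence()] or character vector.
#' @return Named list `fraction_K`, `fraction_D` (summing to 1).
#' @export
direction_fraction <- function(sequence) {
  sequence <- .as_event_sequence(sequence)
  if (nrow(sequence) == 0L) stop("empty sequence", call. = FALSE)
  fk <- mean(sequence$label == "K")
  list(fraction_K = fk, fraction_D = 1 - fk)
}

#' Chi-square test of pair-type uniformity
#'
#' Goodness of fit of the four pair-type counts against the fair-coin
#' expectation of 25% each (df = 3). Quantifies how closely an observed
#' pair spectrum matches independent, equally likely activations.
#'
#' @param pair_counts Either a `pair_stats` object or four non-negative
#'   counts (DD, DK, KD, KK).
#' @return List with `statistic` and `p_value`.
#' @export
uniformity_test <- function(pair_counts) {
  if (inherits(pair_counts, "pair_stats")) pair_counts <- pair_counts$counts
  stopifnot(length(pair_counts) == 4L, all(pair_counts >= 0))
  if (sum(pair_counts) == 0) {
    stop("cannot test uniformity of zero pairs", call. = FALSE)
  }
  ht <- suppressWarnings(
    stats::chisq.test(pair_counts, p = rep(0.25, 4L)))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value))
}

#' Lag-1 independence (memorylessness) test
#'
#' 2x2 contingency test of the current event label against the previous
#' one, within traces. Under the coin-toss (memoryless Markov) model the
#' two are independent; a long strictly alternating sequence is strongly
#' dependent.
#'
#' @param sequence An [event_sequence()] or character vector.
#' @return List with `statistic`, `p_value` and `table`; if a margin is
#'   degenerate (only one label present before or after) the test is
#'   refused and `statistic`/`p_value` are `NA` with a `reason`.
#' @export
lag1_independence <- function(sequence) {
  sequence <- .as_event_sequence(sequence)
  prev <- character(); curr <- character()
  for (id in unique(sequence$trace_id)) {
    lab <- sequence$label[sequence$trace_id == id]
    if (length(lab) >= 2L) {
      prev <- c(prev, lab[-length(lab)])
      curr <- c(curr, lab[-1L])
    }
  }
  if (length(prev) < 2L) {
    return(list(statistic = NA_real_, p_value = NA_real_, table = NULL,
                reason = "fewer than 2 pairs"))
  }
  tab <- table(prev, curr)
  if (any(dim(tab) < 2L)) {
    return(list(statistic = NA_real_, p_value = NA_real_, table = tab,
                reason = "degenerate margin: only one label observed"))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       table = tab, reason = NULL)
}
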