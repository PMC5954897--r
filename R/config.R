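#' Run configuration
#'
#' A `run_config` is a nested key-value document holding every tunable
#' parameter of a run plus a single top-level seed. Per-trace / per-replicate
#' seeds are derived from the top-level seed with [derive_seed()], so a
#' configuration fully determines all stochastic output.
#'
#' @param seed Integer top-level seed.
#' @param params Named (possibly nested) list of module parameters.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, params = list()) {
  .check_scalar(seed, "seed", integerish = TRUE)
  if (length(params) && is.null(names(params))) {
    stop("'params' must be a named list", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), params = params),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> seed =", x$seed, "\n")
  cat(yaml::as.yaml(x$params))
  invisible(x)
}

#' Read / write a run configuration (YAML)
#'
#' Configurations round-trip: `read_config(write_config(cfg, f))` is
#' identical to `cfg`.
#'
#' @param path File path.
#' @return `read_config` returns a [run_config()]; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$seed)) stop("config is missing 'seed'", call. = FALSE)
  run_config(doc$seed, doc$params %||% list())
}

#' @rdname read_config
#' @param config A [run_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(list(seed = config$seed, params = config$params), path,
                   precision = 15L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream seed from the top-level seed
#'
#' Deterministic counter scheme: stream `i` of top-level seed `s` receives
#' `(s * 48271 + i) mod (2^31 - 1)` (a Lehmer-style mix; all arithmetic is
#' exact in doubles). Identical `(seed, index)` pairs always map to the same
#' derived seed, and derived seeds stay below 2^31.
#'
#' @param seed Integer top-level seed.
#' @param index Non-negative integer stream index (e.g. trace number).
#' @return An integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(seed, index) {
  .check_scalar(seed, "seed", integerish = TRUE)
  .check_scalar(index, "index", nonneg = TRUE, integerish = TRUE)
  m <- 2147483647
  as.integer((((seed %% m) * 48271) %% m + index) %% m)
}
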