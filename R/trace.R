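#' Optical-trap position trace
#'
#' A `trap_trace` holds a uniformly sampled position-time record of a trapped
#' cargo together with the trap metadata needed to convert displacement into
#' force (F = K_T * x). Position along the microtubule axis is in nm with the
#' plus end positive; the perpendicular channel is optional.
#'
#' @param time Numeric vector of times in seconds, strictly increasing on a
#'   uniform grid with step `1/sampling_rate`.
#' @param x Numeric vector, position parallel to the microtubule axis (nm).
#' @param y Optional numeric vector, perpendicular position (nm). `NULL`
#'   marks an absent channel.
#' @param metadata Named list with at least `trap_stiffness` (pN/nm) and
#'   `sampling_rate` (Hz); `temperature` (K), `cargo_diameter` (nm) and
#'   `trace_id` are carried when present.
#' @return An object of class `trap_trace`: a data frame with columns
#'   `time_s`, `x_nm` and optionally `y_nm`, with the metadata attached as
#'   an attribute.
#' @seealso [read_trace()], [write_trace()]
#' @export
trap_trace <- function(time, x, y = NULL, metadata = list()) {
  if (length(time) < 2L) {
    stop("a trace needs at least 2 samples to establish a time grid",
         call. = FALSE)
  }
  if (length(x) != length(time)) {
    stop("'time' and 'x' must have equal length", call. = FALSE)
  }
  if (!is.null(y) && length(y) != length(time)) {
    stop("'y' must match the length of 'time'", call. = FALSE)
  }
  for (key in c("trap_stiffness", "sampling_rate")) {
    if (is.null(metadata[[key]])) {
      stop(sprintf("trace metadata is missing required key '%s'", key),
           call. = FALSE)
    }
  }
  .check_scalar(metadata$trap_stiffness, "trap_stiffness", positive = TRUE)
  .check_scalar(metadata$sampling_rate, "sampling_rate", positive = TRUE)
  dt <- 1 / metadata$sampling_rate
  steps <- diff(time)
  if (any(steps <= 0) || max(abs(steps - dt)) > 1e-6 * dt) {
    stop("time must increase on a uniform grid with step 1/sampling_rate",
         call. = FALSE)
  }
  df <- data.frame(time_s = as.numeric(time), x_nm = as.numeric(x))
  if (!is.null(y)) df$y_nm <- as.numeric(y)
  structure(df,
            metadata = metadata,
            class = c("trap_trace", "data.frame"))
}

#' @export
print.trap_trace <- function(x, ...) {
  md <- trace_metadata(x)
  n <- nrow(x)
  cat(sprintf("<trap_trace> %s: %d samples, %.3f s at %g Hz\n",
              if (is.null(md$trace_id)) "(unnamed)" else md$trace_id,
              n, n / md$sampling_rate, md$sampling_rate))
  cat(sprintf("  trap stiffness %g pN/nm; perpendicular channel: %s\n",
              md$trap_stiffness,
              if ("y_nm" %in% names(x)) "present" else "absent"))
  invisible(x)
}

#' @rdname trap_trace
#' @param trace A `trap_trace`.
#' @export
trace_metadata <- function(trace) {
  attr(trace, "metadata")
}

#' @export
plot.trap_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$x_nm, type = "l", xlab = "time (s)",
                 ylab = "position (nm)", ...)
  invisible(x)
}

## Metadata keys serialised into the commented file header.
.trace_meta_keys <- c("trap_stiffness", "sampling_rate", "temperature",
                      "cargo_diameter", "trace_id")

#' Read an optical-trap trace file
#'
#' Traces are stored as plain CSV with a commented header block: lines of the
#' form `# key: value` carrying the metadata, then a `time_s,x_nm[,y_nm]`
#' table. A missing `y_nm` column yields a trace without a perpendicular
#' channel (not zeros).
#'
#' @param path Path to a trace file written by [write_trace()].
#' @return A [trap_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- m[2]
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (is.na(num)) val else num
    }
  }
  for (key in c("trap_stiffness", "sampling_rate")) {
    if (is.null(meta[[key]])) {
      stop(sprintf("malformed trace header: missing key '%s'", key),
           call. = FALSE)
    }
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (!all(c("time_s", "x_nm") %in% names(tab))) {
    stop("malformed trace body: need columns time_s,x_nm", call. = FALSE)
  }
  trap_trace(tab$time_s, tab$x_nm,
             y = if ("y_nm" %in% names(tab)) tab$y_nm else NULL,
             metadata = meta)
}

#' Write an optical-trap trace file
#'
#' Numeric values are written with 17 significant digits so that
#' `read_trace(write_trace(tr, f))` reproduces them exactly.
#'
#' @param trace A [trap_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!inherits(trace, "trap_trace")) {
    stop("'trace' must be a trap_trace", call. = FALSE)
  }
  md <- trace_metadata(trace)
  hdr <- character()
  for (key in .trace_meta_keys) {
    if (!is.null(md[[key]])) {
      val <- md[[key]]
      val <- if (is.numeric(val)) sprintf("%.17g", val) else as.character(val)
      hdr <- c(hdr, sprintf("# %s: %s", key, val))
    }
  }
  has_y <- "y_nm" %in% names(trace)
  cols <- c("time_s", "x_nm", if (has_y) "y_nm")
  rows <- do.call(paste, c(lapply(cols, function(cl) {
    sprintf("%.17g", trace[[cl]])
  }), sep = ","))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, paste(cols, collapse = ","), rows), con)
  invisible(path)
}
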