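#' Multichannel uniformly sampled recording trace
#'
#' The common currency of stimuli, simulations and (synthetic) recordings:
#' a set of equally long channels sampled on one uniform time base, each
#' carrying a unit label (`"mV"`, `"nA"`, `"nS"`, ...). Dual-recording
#' experiments conventionally use channels `V_pre`, `V_post`, `I_pre`,
#' `I_post`.
#'
#' @param dt sample interval (s).
#' @param channels named list of equal-length numeric vectors.
#' @param units named character vector of units, one per channel.
#' @param t0 time of the first sample (s).
#' @return an object of class `"trace"`.
#' @export
trace <- function(dt, channels, units, t0 = 0) {
  if (!(is.finite(dt) && dt > 0)) stop("trace: dt must be positive")
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("trace: channels must be a named list")
  n <- lengths(channels)
  if (length(unique(n)) != 1L)
    stop("trace: all channels must have equal length")
  if (!setequal(names(units), names(channels)))
    stop("trace: units must name every channel")
  structure(list(t0 = t0, dt = dt, channels = channels,
                 units = units[names(channels)]),
            class = "trace")
}

#' @export
print.trace <- function(x, ...) {
  n <- length(x$channels[[1]])
  cat(sprintf("trace: %d samples, dt = %.3g s (%.4g s total), t0 = %.4g s\n",
              n, x$dt, n * x$dt, x$t0))
  cat("  channels:",
      paste(sprintf("%s [%s]", names(x$channels), x$units), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
as.data.frame.trace <- function(x, ...) {
  n <- length(x$channels[[1]])
  data.frame(time = x$t0 + (seq_len(n) - 1L) * x$dt,
             as.data.frame(x$channels, ...))
}

#' Time base of a trace
#' @param x a [trace()].
#' @return numeric vector of sample times (s).
#' @export
trace_time <- function(x) {
  stopifnot(inherits(x, "trace"))
  x$t0 + (seq_along(x$channels[[1]]) - 1L) * x$dt
}

#' @export
plot.trace <- function(x, channels = names(x$channels), ...) {
  tt <- trace_time(x)
  op <- graphics::par(mfrow = c(length(channels), 1),
                      mar = c(2.5, 4, 0.5, 0.5))
  on.exit(graphics::par(op))
  for (ch in channels)
    graphics::plot(tt, x$channels[[ch]], type = "l",
                   xlab = "time (s)", ylab = sprintf("%s (%s)", ch, x$units[ch]),
                   ...)
  invisible(x)
}

#' Read / write traces as CSV
#'
#' The CSV dialect has a first column `time` (seconds) and one column per
#' channel, headed `name:unit`. Channel order is immaterial on read. The
#' time base must be uniform; non-uniform timestamps are rejected.
#'
#' @param path file path.
#' @return `read_trace()` returns a [trace()]; `write_trace()` returns
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (ncol(d) < 2L || names(d)[1] != "time")
    stop("trace CSV: first column must be 'time'")
  hdr <- names(d)[-1]
  bad <- !grepl(":", hdr, fixed = TRUE)
  if (any(bad))
    stop(sprintf("trace CSV: column %d header '%s' lacks a ':unit' suffix",
                 which(bad)[1] + 1L, hdr[bad][1]))
  tt <- d[[1]]
  if (length(tt) < 2L) stop("trace CSV: need at least 2 samples")
  dts <- diff(tt)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * max(dt, 1e-12)))
    stop(sprintf("trace CSV: non-uniform time base near line %d",
                 which.max(abs(dts - dt)) + 2L))
  nm <- sub(":[^:]*$", "", hdr)
  un <- sub("^.*:", "", hdr)
  trace(dt = dt, t0 = tt[1],
        channels = stats::setNames(lapply(seq_along(hdr), function(i) d[[i + 1L]]), nm),
        units = stats::setNames(un, nm))
}

#' @param x a [trace()] to write.
#' @param digits significant digits for CSV output.
#' @rdname read_trace
#' @export
write_trace <- function(x, path, digits = 10) {
  stopifnot(inherits(x, "trace"))
  d <- as.data.frame(x)
  names(d) <- c("time", sprintf("%s:%s", names(x$channels), x$units))
  d[] <- lapply(d, signif, digits = digits)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# linear interpolation of a channel onto arbitrary times (used to resample
# clamp commands onto integrator half-steps)
trace_interp <- function(x, channel, tt) {
  stats::approx(trace_time(x), x$channels[[channel]], xout = tt,
                rule = 2)$y
}

#' Resample a trace to a new sampling interval
#'
#' Linear interpolation onto a uniform grid with interval `dt_new`,
#' spanning the original duration.
#'
#' @param x a [trace()].
#' @param dt_new new sample interval (s).
#' @return a [trace()].
#' @export
resample_trace <- function(x, dt_new) {
  stopifnot(inherits(x, "trace"))
  tt_old <- trace_time(x)
  tt <- seq(x$t0, tt_old[length(tt_old)], by = dt_new)
  ch <- lapply(names(x$channels), function(nm) trace_interp(x, nm, tt))
  names(ch) <- names(x$channels)
  out <- trace(dt = dt_new, channels = ch, units = x$units, t0 = x$t0)
  attr(out, "analysis_window") <- attr(x, "analysis_window")
  out
}
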