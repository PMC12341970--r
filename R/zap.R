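#' ZAP (chirp) stimulus parameters
#'
#' Describes an exponential chirp whose instantaneous frequency sweeps from
#' `f_lo` to `f_hi` over `t_max` seconds, optionally preceded by lead-in
#' sinusoid cycles at `f_lo` that splice continuously into the chirp. The
#' chirp is `offset + amplitude * cos(phi(t) + phase0)` with phase
#' `phi(t) = 2*pi*f_lo*(exp(L*t) - 1)/L` and sweep rate
#' `L = log(f_hi/f_lo)/t_max`, so the instantaneous frequency is
#' `f_lo * exp(L*t)`.
#'
#' @param f_lo,f_hi sweep limits (Hz), `0 < f_lo < f_hi`.
#' @param t_max chirp duration (s), excluding pre-cycles.
#' @param amplitude stimulus half-range (nA for current commands, mV for
#'   voltage commands).
#' @param offset baseline value (same units as `amplitude`).
#' @param n_precycles number of lead-in sinusoid cycles at `f_lo` (each of
#'   duration `1/f_lo` s) prepended to avoid onset transients.
#' @param dt sample interval (s); must satisfy `dt < 1/(2*f_hi)`.
#' @param phase one of `"peak"` (signal starts at `offset + amplitude`,
#'   the natural choice for injected current) or `"trough"` (starts at
#'   `offset - amplitude`, so a voltage command whose offset is the range
#'   midpoint starts at the holding potential).
#' @param sweep `"up"` (frequency rises from `f_lo` to `f_hi`) or
#'   `"down"` (the time-reversed frequency track, `f_hi` down to `f_lo`;
#'   pre-cycles then run at `f_hi`). Reversing the sweep direction is a
#'   control: frequency profiles of a linear system are unchanged.
#' @return an object of class `"zap_params"`.
#' @seealso [generate_zap()], [zap_frequency()]
#' @export
zap_params <- function(f_lo = 0.1, f_hi = 4, t_max = 100,
                       amplitude = 3, offset = 0, n_precycles = 2,
                       dt = 1e-4, phase = c("peak", "trough"),
                       sweep = c("up", "down")) {
  phase <- match.arg(phase)
  sweep <- match.arg(sweep)
  if (!(is.finite(f_lo) && f_lo > 0)) stop("invalid zap_params: need f_lo > 0")
  if (!(is.finite(f_hi) && f_hi > f_lo))
    stop("invalid zap_params: need f_lo < f_hi")
  if (!(is.finite(t_max) && t_max > 0)) stop("invalid zap_params: need t_max > 0")
  if (!(is.finite(dt) && dt > 0 && dt < 1 / (2 * f_hi)))
    stop("invalid zap_params: need 0 < dt < 1/(2*f_hi) (Nyquist)")
  if (n_precycles < 0 || n_precycles != round(n_precycles))
    stop("invalid zap_params: need integer n_precycles >= 0")
  structure(list(f_lo = f_lo, f_hi = f_hi, t_max = t_max,
                 amplitude = amplitude, offset = offset,
                 n_precycles = n_precycles, dt = dt, phase = phase,
                 sweep = sweep, L = log(f_hi / f_lo) / t_max),
            class = "zap_params")
}

# frequency of the pre-cycle sinusoid (= starting frequency of the chirp)
zap_f_start <- function(params)
  if (params$sweep == "up") params$f_lo else params$f_hi

# pre-cycle lead-in duration and total protocol duration (s)
zap_pre_duration <- function(params) params$n_precycles / zap_f_start(params)

#' Total duration of a ZAP protocol
#' @param params a [zap_params()].
#' @return duration in seconds, pre-cycles included.
#' @export
zap_duration <- function(params) zap_pre_duration(params) + params$t_max

#' ZAP protocol envelope for simulations
#'
#' Wraps a ZAP command in the full experimental envelope: a quiescent
#' lead-in at `baseline` (letting the simulated preparation settle at
#' rest), the pre-cycles + chirp, a short half-cosine ramp back to
#' `baseline`, and a quiescent tail. Analysing a record that starts and
#' ends at rest makes the spectral ratio of a linear system exact (no
#' window-boundary transient), so the simulation wrappers use this
#' envelope and analyse the whole record.
#'
#' @param params a [zap_params()].
#' @param baseline stimulus value outside the protocol (0 nA for a
#'   current command; the holding potential for a voltage command).
#' @param pre_settle quiescent lead-in (s).
#' @param ramp duration of the half-cosine return to baseline (s).
#' @return a function of time (s) returning stimulus values.
#' @export
zap_protocol <- function(params, baseline = params$offset, pre_settle = 0,
                         ramp = 0.5) {
  stopifnot(inherits(params, "zap_params"))
  dur <- zap_duration(params)
  v_end <- zap_value(params, dur)
  function(tt) {
    t2 <- tt - pre_settle
    out <- rep(baseline, length(tt))
    on <- t2 >= 0 & t2 <= dur
    out[on] <- zap_value(params, t2[on])
    rmp <- t2 > dur & t2 < dur + ramp
    if (any(rmp)) {
      s <- (t2[rmp] - dur) / ramp
      out[rmp] <- baseline + (v_end - baseline) * (1 + cos(pi * s)) / 2
    }
    out
  }
}

#' @export
print.zap_params <- function(x, ...) {
  cat(sprintf(
    "ZAP chirp: %.3g-%.3g Hz over %.4g s (L = %.4g /s), amplitude %.4g, offset %.4g,\n  %d pre-cycle(s) at %.3g Hz, dt = %.3g s, %s-start\n",
    x$f_lo, x$f_hi, x$t_max, x$L, x$amplitude, x$offset,
    x$n_precycles, x$f_lo, x$dt, x$phase))
  invisible(x)
}

# chirp phase (rad) at chirp-segment time t (s)
zap_phase <- function(params, t) {
  if (params$sweep == "up")
    2 * pi * params$f_lo * (exp(params$L * t) - 1) / params$L
  else
    2 * pi * params$f_hi * (1 - exp(-params$L * t)) / params$L
}

#' Instantaneous frequency of the chirp segment
#'
#' @param params a [zap_params()] object.
#' @param t time (s) on the chirp-segment clock (0 = end of pre-cycles);
#'   must lie in `[0, t_max]`.
#' @return frequency in Hz: `f_lo * exp(L*t)` for an up-sweep (strictly
#'   increasing), `f_hi * exp(-L*t)` for a down-sweep.
#' @export
zap_frequency <- function(params, t) {
  stopifnot(inherits(params, "zap_params"))
  if (any(t < 0 | t > params$t_max))
    stop("t outside the chirp segment [0, t_max]")
  if (params$sweep == "up") params$f_lo * exp(params$L * t)
  else params$f_hi * exp(-params$L * t)
}

# raw waveform values at absolute times tt (s), t = 0 at protocol start
zap_value <- function(params, tt) {
  p <- params
  f0 <- zap_f_start(p)
  t_pre <- zap_pre_duration(p)
  ph <- ifelse(tt < t_pre,
               2 * pi * f0 * tt,
               2 * pi * p$n_precycles + zap_phase(p, pmin(tt - t_pre, p$t_max)))
  ph0 <- if (p$phase == "trough") pi else 0
  p$offset + p$amplitude * cos(ph + ph0)
}

#' Generate a ZAP stimulus trace
#'
#' Samples the chirp (plus pre-cycles) on a uniform time base. Phase is
#' continuous at the pre-cycle/chirp splice because each pre-cycle ends at
#' phase `2*pi` and the chirp phase starts at 0.
#'
#' @param params a [zap_params()] object.
#' @param name channel name for the generated command.
#' @param unit channel unit (`"nA"` for current, `"mV"` for voltage).
#' @return a [trace()] with one channel of total duration
#'   `n_precycles/f_start + t_max`; the attribute `"chirp_window"`
#'   records the chirp segment `c(start, end)` in seconds.
#' @export
generate_zap <- function(params, name = "I", unit = "nA") {
  stopifnot(inherits(params, "zap_params"))
  t_pre <- zap_pre_duration(params)
  t_tot <- t_pre + params$t_max
  n <- floor(t_tot / params$dt) + 1L
  tt <- (seq_len(n) - 1L) * params$dt
  x <- zap_value(params, tt)
  tr <- trace(dt = params$dt, channels = stats::setNames(list(x), name),
              units = stats::setNames(unit, name))
  attr(tr, "chirp_window") <- c(t_pre, t_tot)
  attr(tr, "zap_params") <- params
  tr
}
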