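#' Frequency profile container
#'
#' Amplitude of a ratio quantity (impedance, coupling coefficient or
#' coupling conductance) on a frequency grid.
#'
#' @param f strictly increasing frequency grid (Hz).
#' @param amp nonnegative amplitudes (`NA` = masked point).
#' @param quantity tag: `"Zpre"`, `"Zpost"`, `"Z1"`, `"Z2"`, `"Zk"`,
#'   `"CC"` or `"Gc"`.
#' @param unit amplitude unit (`"MOhm"`, `""`, `"uS"`).
#' @param normalized has the profile been divided by its value at the
#'   lowest band frequency?
#' @return an object of class `"freq_profile"`.
#' @export
freq_profile <- function(f, amp, quantity = "Zpre", unit = "MOhm",
                         normalized = FALSE) {
  if (length(f) != length(amp)) stop("freq_profile: f and amp lengths differ")
  if (is.unsorted(f, strictly = TRUE)) stop("freq_profile: f must be increasing")
  if (any(amp < 0, na.rm = TRUE)) stop("freq_profile: amplitudes must be >= 0")
  structure(list(f = f, amp = amp, quantity = quantity, unit = unit,
                 normalized = normalized),
            class = "freq_profile")
}

#' @export
print.freq_profile <- function(x, ...) {
  cat(sprintf("%s frequency profile%s: %d points, %.3g-%.3g Hz%s\n",
              x$quantity, if (nzchar(x$unit)) sprintf(" (%s)", x$unit) else "",
              length(x$f), min(x$f), max(x$f),
              if (x$normalized) ", normalized to lowest-frequency value" else ""))
  if (anyNA(x$amp)) cat(sprintf("  %d masked point(s)\n", sum(is.na(x$amp))))
  invisible(x)
}

#' @export
as.data.frame.freq_profile <- function(x, ...) {
  data.frame(f = x$f, amp = x$amp, quantity = x$quantity,
             normalized = x$normalized)
}

#' @export
plot.freq_profile <- function(x, ...) {
  ylab <- if (x$normalized) sprintf("%s (normalized)", x$quantity)
          else sprintf("%s%s", x$quantity,
                       if (nzchar(x$unit)) sprintf(" (%s)", x$unit) else "")
  graphics::plot(x$f, x$amp, xlab = "frequency (Hz)", ylab = ylab, ...)
  invisible(x)
}

# centered moving average with shrinking windows at the edges
moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Spectral ratio of two trace channels
#'
#' Estimates the amplitude profile of `numerator/denominator` (e.g.
#' `V_pre/I_pre` for the prejunctional impedance, `V_post/V_pre` for the
#' coupling coefficient, `I_post/V_pre` for the coupling conductance) as
#' the magnitude of the ratio of discrete Fourier transforms of the
#' analysis window, after mean removal from both channels, restricted to
#' the swept band; optional light frequency-domain smoothing is
#' available for noisy recordings (the polynomial resonance fit supplies
#' most of the smoothing either way).
#'
#' Grid points where the denominator's spectral magnitude falls below
#' `1e-6` times its band maximum are masked (`NA`) with a warning.
#'
#' @param x a [trace()] holding both channels.
#' @param numerator,denominator channel names.
#' @param band `c(f_lo, f_hi)` (Hz); defaults to the trace's recorded
#'   chirp sweep limits when available.
#' @param quantity,unit labels for the resulting profile.
#' @param segment analysis window `c(start, end)` in seconds; defaults
#'   to the trace attribute `"analysis_window"` set by the simulation
#'   helpers, else the whole record. Records produced by the protocol
#'   helpers start and end at rest (quiescent lead-in and settle tail),
#'   which eliminates window-boundary transients from the ratio; a
#'   narrower window (e.g. the bare chirp) is admissible but leaves a
#'   small boundary bias at the weakly driven end of the band.
#' @param smooth_bw frequency-domain moving-average bandwidth (Hz);
#'   `0` disables smoothing.
#' @return a [freq_profile()].
#' @export
spectral_ratio <- function(x, numerator, denominator, band = NULL,
                           quantity = "Zpre", unit = "MOhm",
                           segment = attr(x, "analysis_window"),
                           smooth_bw = 0) {
  stopifnot(inherits(x, "trace"))
  for (ch in c(numerator, denominator))
    if (!ch %in% names(x$channels))
      stop(sprintf("spectral_ratio: no channel '%s' in trace", ch))
  tt <- trace_time(x)
  keep <- if (is.null(segment)) rep(TRUE, length(tt))
          else tt >= segment[1] - 1e-9 & tt <= segment[2] + 1e-9
  u <- x$channels[[numerator]][keep]
  v <- x$channels[[denominator]][keep]
  if (is.null(band)) {
    zp <- attr(x, "zap_params")
    if (is.null(zp)) stop("spectral_ratio: band must be given")
    band <- c(zp$f_lo, zp$f_hi)
  }
  n <- length(u)
  U <- stats::fft(u - mean(u))
  V <- stats::fft(v - mean(v))
  fgrid <- (seq_len(n) - 1L) / (n * x$dt)
  sel <- which(fgrid >= band[1] - 1e-12 & fgrid <= band[2] + 1e-12)
  if (!length(sel)) stop("spectral_ratio: no DFT bins inside the band")
  magV <- Mod(V[sel])
  floor_ <- 1e-6 * max(magV)
  amp <- Mod(U[sel]) / magV
  masked <- magV < floor_
  if (any(masked)) {
    warning(sprintf("spectral_ratio: %d grid point(s) masked (denominator below floor)",
                    sum(masked)))
    amp[masked] <- NA_real_
  }
  df <- 1 / (n * x$dt)
  w <- max(1L, round(smooth_bw / df))
  if (w > 1L && !any(masked)) amp <- moving_average(amp, w)
  freq_profile(fgrid[sel], amp, quantity = quantity, unit = unit)
}

#' Normalize a frequency profile to its lowest-frequency value
#'
#' Divides every amplitude by the amplitude at the lowest band frequency
#' (the proxy for the zero-frequency value), the convention used to
#' compare resonance power across quantities with different units.
#'
#' @param profile a [freq_profile()].
#' @return the normalized [freq_profile()] (value 1 at its lowest
#'   frequency).
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "freq_profile"))
  b <- profile$amp[1]
  if (is.na(b) || b <= 0)
    stop("normalize_profile: lowest-frequency amplitude is masked or zero")
  freq_profile(profile$f, profile$amp / b, quantity = profile$quantity,
               unit = "", normalized = TRUE)
}

#' Fit a resonance peak to a frequency profile
#'
#' Least-squares polynomial fit (degree 6 by default) of amplitude
#' against frequency in Hz on the profile's grid; the resonance is the
#' global maximum of the fitted polynomial on the closed band, located
#' via the real roots of the fitted polynomial's derivative (endpoints
#' admissible). A maximum at a band endpoint is flagged as "no interior
#' resonance". The fitted amplitude at the lowest band frequency is
#' recorded for normalization.
#'
#' @param profile a [freq_profile()] (or anything with `f` and `amp`).
#' @param degree polynomial degree; at least `degree + 2` unmasked grid
#'   points are required.
#' @return an object of class `"resonance_fit"` with components
#'   `f_res` (Hz), `peak` (profile units), `amp_flo` (fitted amplitude at
#'   the lowest band frequency), `coefficients` (ascending powers),
#'   `at_edge`, `band`, `sigma` (residual SD) and the data.
#' @export
fit_resonance <- function(profile, degree = 6) {
  f <- profile$f
  amp <- profile$amp
  ok <- !is.na(amp)
  if (sum(ok) < degree + 2)
    stop(sprintf("fit_resonance: need at least %d unmasked points, got %d",
                 degree + 2, sum(ok)))
  f0 <- f[ok]; a0 <- amp[ok]
  X <- outer(f0, 0:degree, `^`)
  fit <- stats::lm.fit(X, a0)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  poly_eval <- function(z) drop(outer(z, 0:degree, `^`) %*% beta)
  # critical points: real roots of the derivative inside the band
  dcoef <- beta[-1] * seq_len(degree)
  cand <- numeric(0)
  if (any(dcoef != 0)) {
    r <- polyroot(dcoef)
    r <- Re(r[abs(Im(r)) < 1e-8 * pmax(1, Mod(r))])
    cand <- r[r > min(f0) & r < max(f0)]
  }
  cand <- c(min(f0), sort(cand), max(f0))
  vals <- poly_eval(cand)
  i <- which.max(vals)   # ties -> lowest frequency (candidates sorted)
  at_edge <- i == 1L || i == length(cand)
  structure(list(f_res = cand[i], peak = vals[i],
                 amp_flo = poly_eval(min(f0)),
                 coefficients = beta, degree = degree,
                 band = range(f0), at_edge = at_edge,
                 sigma = sqrt(mean(fit$residuals^2)),
                 f = f0, amp = a0, fitted = fit$fitted.values,
                 quantity = profile$quantity,
                 unit = if (!is.null(profile$unit)) profile$unit else ""),
            class = "resonance_fit")
}

#' @export
print.resonance_fit <- function(x, ...) {
  cat(sprintf("resonance fit (%s, degree-%d polynomial):\n", x$quantity,
              x$degree))
  if (x$at_edge)
    cat(sprintf("  no interior resonance: maximum at band edge %.3g Hz (amplitude %.4g)\n",
                x$f_res, x$peak))
  else
    cat(sprintf("  resonance frequency %.4g Hz, peak amplitude %.4g %s\n",
                x$f_res, x$peak, x$unit))
  cat(sprintf("  amplitude at %.3g Hz: %.4g; residual SD %.3g\n",
              x$band[1], x$amp_flo, x$sigma))
  invisible(x)
}

#' @export
summary.resonance_fit <- function(object, ...) {
  out <- data.frame(quantity = object$quantity, f_res = object$f_res,
                    peak = object$peak, amp_flo = object$amp_flo,
                    q_factor = object$peak / object$amp_flo,
                    at_edge = object$at_edge, sigma = object$sigma)
  class(out) <- c("summary.resonance_fit", "data.frame")
  out
}

#' @export
coef.resonance_fit <- function(object, ...) {
  stats::setNames(object$coefficients, paste0("f^", 0:object$degree))
}

#' @export
predict.resonance_fit <- function(object, newdata = NULL, ...) {
  f <- if (is.null(newdata)) object$f
       else if (is.list(newdata)) newdata$f else newdata
  drop(outer(f, 0:object$degree, `^`) %*% object$coefficients)
}

#' @export
residuals.resonance_fit <- function(object, ...) object$amp - object$fitted

#' @export
plot.resonance_fit <- function(x, ...) {
  graphics::plot(x$f, x$amp, xlab = "frequency (Hz)",
                 ylab = sprintf("%s%s", x$quantity,
                                if (nzchar(x$unit)) sprintf(" (%s)", x$unit) else ""),
                 col = "grey50", ...)
  fg <- seq(x$band[1], x$band[2], length.out = 400)
  graphics::lines(fg, predict(x, fg), lwd = 2)
  if (!x$at_edge)
    graphics::points(x$f_res, x$peak, pch = 1, cex = 2, lwd = 2, col = 2)
  invisible(x)
}

#' Coupling estimates from voltage-step protocols
#'
#' Classical step-based coupling measurement: the prejunctional cell is
#' stepped through a series of holding potentials; the coupling
#' coefficient (current clamp) or coupling conductance (dual voltage
#' clamp) is the ordinary least-squares slope of the per-step mean
#' response against the per-step mean prejunctional voltage.
#'
#' @param x a [trace()] with the prejunctional voltage and the response
#'   channel.
#' @param pre prejunctional voltage channel name.
#' @param response response channel (`V_post` for current clamp,
#'   `I_post` for dual voltage clamp).
#' @param onsets step onset times (s); at least 3 steps.
#' @param duration step duration (s).
#' @param mode `"currentclamp"` (returns CC, dimensionless) or
#'   `"voltageclamp"` (returns Gc in uS, reported positive for
#'   conventional junctional current flow).
#' @param settle fraction of each step discarded before averaging
#'   (steady-state window is the remainder).
#' @return scalar estimate (CC or Gc).
#' @export
step_coupling_estimate <- function(x, pre = "V_pre", response = "V_post",
                                   onsets, duration,
                                   mode = c("currentclamp", "voltageclamp"),
                                   settle = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(x, "trace"))
  if (length(onsets) < 3) stop("step_coupling_estimate: need at least 3 steps")
  tt <- trace_time(x)
  mean_in_window <- function(ch, t1, t2) mean(x$channels[[ch]][tt >= t1 & tt < t2])
  vp <- rp <- numeric(length(onsets))
  for (i in seq_along(onsets)) {
    t1 <- onsets[i] + settle * duration
    t2 <- onsets[i] + duration
    vp[i] <- mean_in_window(pre, t1, t2)
    rp[i] <- mean_in_window(response, t1, t2)
  }
  slope <- stats::coef(stats::lm(rp ~ vp))[[2]]
  if (mode == "voltageclamp") -slope else slope
}
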