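#' Two-variable linear resonator cell
#'
#' The canonical linear resonator: a capacitive voltage equation plus one
#' slow restorative variable with first-order kinetics,
#' \deqn{C dV/dt = -g_L V - g_1 w + I, \quad \tau_1 dw/dt = V - w,}
#' with voltages measured from rest. Its impedance is
#' \deqn{Z(f) = 1 / (g_L + 2\pi i f C' + g_1/(1 + 2\pi i f \tau_1')),}
#' (primes: unit-consistent ms-based values), a band-pass (resonant)
#' profile when the restorative conductance `g1` and time constant `tau1`
#' are large enough relative to the membrane time constant.
#'
#' Units follow the field's convention: with C in nF, conductances in uS,
#' time constants in ms, voltages in mV and currents in nA, impedances
#' come out in megaohms.
#'
#' @param C membrane capacitance (nF).
#' @param gL leak conductance (uS).
#' @param g1 restorative-gate conductance (uS); `g1 = 0` gives a passive
#'   RC cell.
#' @param tau1 restorative time constant (ms).
#' @return an object of class `"linear_resonator"`.
#' @export
linear_resonator <- function(C = 2, gL = 0.0656, g1 = 0.0124, tau1 = 800) {
  if (!(C > 0)) stop("linear_resonator: C must be > 0")
  if (!(tau1 > 0)) stop("linear_resonator: tau1 must be > 0")
  if (!(gL > 0)) stop("linear_resonator: gL must be > 0")
  # stability of [[-gL/C, -g1/C], [1/tau1, -1/tau1]]:
  # trace < 0 automatic; det = (gL + g1)/(C tau1) must be > 0
  if (gL + g1 <= 0)
    stop("linear_resonator: unstable parameters (gL + g1 must be > 0)")
  structure(list(C = C, gL = gL, g1 = g1, tau1 = tau1),
            class = "linear_resonator")
}

#' @export
print.linear_resonator <- function(x, ...) {
  cat(sprintf(
    "linear resonator: C = %.4g nF, gL = %.4g uS, g1 = %.4g uS, tau1 = %.4g ms\n",
    x$C, x$gL, x$g1, x$tau1))
  rs <- profile_peak(function(f) Mod(uncoupled_impedance(x, f)), c(0.01, 10))
  cat(sprintf("  impedance peak |Z| = %.4g MOhm at %.3g Hz%s\n", rs$peak,
              rs$f_res, if (rs$at_edge) " (band edge; no interior resonance)" else ""))
  invisible(x)
}

#' Impedance of an isolated linear resonator
#'
#' @param params a [linear_resonator()].
#' @param f frequency (Hz), vectorized.
#' @return complex impedance (megaohms); `Mod()` of it is the impedance
#'   amplitude profile.
#' @export
uncoupled_impedance <- function(params, f) {
  stopifnot(inherits(params, "linear_resonator"))
  w <- 2 * pi * f / 1000  # rad/ms
  1 / (params$gL + 1i * w * params$C +
         params$g1 / (1 + 1i * w * params$tau1))
}

#' Impedance profiles of two electrically coupled linear resonators
#'
#' Closed forms for the coupled pre- and postjunctional impedances in
#' terms of the isolated complex impedances `Z1`, `Z2` and the junctional
#' conductance `Gc`:
#' \deqn{Z_{pre} = (Z_2^{-1} + G_c) / D, \quad Z_{post} = G_c / D,}
#' \deqn{D = (Z_1^{-1} + G_c)(Z_2^{-1} + G_c) - G_c^2.}
#' Current is injected into the prejunctional cell (cell 1).
#'
#' `Gc` may be a scalar (ohmic junction) or a vector along `f`
#' (frequency-dependent junction, as used for inverted-U scaled coupling).
#'
#' @param p1,p2 [linear_resonator()] parameters of the pre- and
#'   postjunctional cells.
#' @param Gc junctional conductance (uS), scalar or vector along `f`.
#' @param f frequency (Hz), vectorized.
#' @return list with complex vectors `Zpre` and `Zpost` (megaohms).
#' @export
coupled_impedances <- function(p1, p2, Gc, f) {
  if (any(Gc < 0)) stop("coupled_impedances: Gc must be >= 0")
  Z1 <- uncoupled_impedance(p1, f)
  Z2 <- uncoupled_impedance(p2, f)
  D <- (1 / Z1 + Gc) * (1 / Z2 + Gc) - Gc^2
  list(Zpre = (1 / Z2 + Gc) / D, Zpost = Gc / D)
}

#' Coupling coefficient of coupled linear resonators
#'
#' The coupling-coefficient amplitude profile
#' \deqn{CC(f) = \| G_c / (Z_2^{-1}(f) + G_c) \|,}
#' which equals `|Zpost|/|Zpre|` of [coupled_impedances()] identically and
#' depends only on the *postjunctional* cell's isolated impedance, not on
#' the prejunctional cell.
#'
#' @param p2 postjunctional [linear_resonator()].
#' @param Gc junctional conductance (uS), scalar or vector along `f`.
#' @param f frequency (Hz), vectorized.
#' @return numeric vector of dimensionless CC amplitudes in `[0, 1)`.
#' @export
coupling_coefficient <- function(p2, Gc, f) {
  if (any(Gc < 0)) stop("coupling_coefficient: Gc must be >= 0")
  Z2 <- uncoupled_impedance(p2, f)
  Mod(Gc / (1 / Z2 + Gc))
}

#' Locate the peak of an amplitude profile
#'
#' Dense log-spaced grid search over the band followed by golden-section
#' refinement ([stats::optimize()]); ties broken toward the lower
#' frequency. Used for closed-form profiles; measured profiles go through
#' [fit_resonance()] instead.
#'
#' @param fun vectorized function of frequency returning amplitudes.
#' @param band `c(f_lo, f_hi)` (Hz).
#' @param n grid size.
#' @return list with `f_res`, `peak`, and `at_edge` (TRUE when the maximum
#'   sits at a band endpoint, i.e. no interior resonance).
#' @export
profile_peak <- function(fun, band = c(0.1, 4), n = 1000) {
  fg <- exp(seq(log(band[1]), log(band[2]), length.out = n))
  a <- fun(fg)
  i <- which.max(a)                 # which.max takes the first (lowest f) tie
  if (i == 1L || i == n) {
    return(list(f_res = fg[i], peak = a[i], at_edge = TRUE))
  }
  o <- stats::optimize(fun, lower = fg[i - 1L], upper = fg[i + 1L],
                       maximum = TRUE, tol = 1e-8)
  list(f_res = o$maximum, peak = o$objective, at_edge = FALSE)
}

#' Resonance of coupled profiles as the coupling conductance grows
#'
#' For each conductance in `Gc_grid`, locates the peak frequency and peak
#' amplitude of the coupled prejunctional impedance, postjunctional
#' impedance and coupling coefficient. With strong coupling the pre- and
#' postjunctional resonances converge; the CC resonance tracks the
#' postjunctional cell at weak coupling and moves up monotonically with
#' `Gc` when current is injected into the lower-frequency cell.
#'
#' @param p1,p2 [linear_resonator()] cells (1 = prejunctional).
#' @param Gc_grid nondecreasing nonnegative conductances (uS).
#' @param band frequency band `c(f_lo, f_hi)` (Hz).
#' @return data frame with one row per `Gc`: peak frequency (`f_*`), peak
#'   amplitude (`peak_*`) and band-edge flag (`edge_*`) for `Zpre`,
#'   `Zpost` and `CC`.
#' @export
resonance_vs_gc <- function(p1, p2, Gc_grid, band = c(0.1, 4)) {
  if (is.unsorted(Gc_grid) || any(Gc_grid < 0))
    stop("resonance_vs_gc: Gc_grid must be nonnegative and increasing")
  rows <- lapply(Gc_grid, function(gc) {
    pk_pre <- profile_peak(function(f) Mod(coupled_impedances(p1, p2, gc, f)$Zpre), band)
    pk_post <- profile_peak(function(f) Mod(coupled_impedances(p1, p2, gc, f)$Zpost), band)
    pk_cc <- profile_peak(function(f) coupling_coefficient(p2, gc, f), band)
    data.frame(Gc = gc,
               f_Zpre = pk_pre$f_res, peak_Zpre = pk_pre$peak, edge_Zpre = pk_pre$at_edge,
               f_Zpost = pk_post$f_res, peak_Zpost = pk_post$peak, edge_Zpost = pk_post$at_edge,
               f_CC = pk_cc$f_res, peak_CC = pk_cc$peak, edge_CC = pk_cc$at_edge)
  })
  do.call(rbind, rows)
}

#' Coupled profiles under a frequency-scaled coupling conductance
#'
#' Evaluates the coupled closed forms with `Gc(f) = Gc_base * scale(f)`
#' pointwise in frequency — the construction used to ask how an
#' inverted-U (resonant) junctional conductance reshapes and amplifies
#' the coupling coefficient relative to a constant junction.
#'
#' @param p1,p2 [linear_resonator()] cells.
#' @param Gc_base base junctional conductance (uS).
#' @param scale_fun positive vectorized function of frequency (Hz); the
#'   default is the bandpass junctional-conductance shape
#'   [gc_frequency_profile()] normalized to 1 at its own peak.
#' @param f frequency grid (Hz).
#' @return data frame with columns `f`, `Zpre`, `Zpost`, `CC` (amplitudes)
#'   and `Gc` (the scaled conductance used at each frequency).
#' @export
scaled_gc_cc <- function(p1, p2, Gc_base, f, scale_fun = NULL) {
  if (is.null(scale_fun)) {
    pk <- profile_peak(function(g) gc_frequency_profile(g, Gbar = 1),
                       c(0.01, 10))
    scale_fun <- function(g) gc_frequency_profile(g, Gbar = 1) / pk$peak
  }
  s <- scale_fun(f)
  if (any(s <= 0)) stop("scaled_gc_cc: scale function must be positive on the band")
  gc <- Gc_base * s
  zz <- coupled_impedances(p1, p2, gc, f)
  data.frame(f = f, Zpre = Mod(zz$Zpre), Zpost = Mod(zz$Zpost),
             CC = coupling_coefficient(p2, gc, f), Gc = gc)
}

#' Calibrate a linear resonator to a target resonance
#'
#' Numerically inverts the closed-form impedance: finds `gL` and `g1`
#' (for fixed `C`, `tau1`) such that the impedance amplitude profile
#' peaks at `f_res` with peak value `z_peak`.
#'
#' @param f_res target resonance frequency (Hz).
#' @param z_peak target peak impedance (megaohms).
#' @param C capacitance (nF).
#' @param tau1 restorative time constant (ms).
#' @return a [linear_resonator()] whose profile meets the target (checked
#'   to 0.1%); errors if the target is unattainable in this family.
#' @export
linear_resonator_calibrate <- function(f_res, z_peak, C = 2, tau1 = 300) {
  obj <- function(par) {
    gL <- exp(par[1]); g1 <- exp(par[2])
    p <- linear_resonator(C = C, gL = gL, g1 = g1, tau1 = tau1)
    pk <- profile_peak(function(f) Mod(uncoupled_impedance(p, f)),
                       c(max(f_res / 20, 1e-3), f_res * 20), n = 400)
    if (pk$at_edge) return(1e3 + abs(log(pk$peak / z_peak)))
    log(pk$f_res / f_res)^2 + log(pk$peak / z_peak)^2
  }
  fit <- stats::optim(c(log(1 / z_peak), log(1 / z_peak)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  p <- linear_resonator(C = C, gL = exp(fit$par[1]), g1 = exp(fit$par[2]),
                        tau1 = tau1)
  pk <- profile_peak(function(f) Mod(uncoupled_impedance(p, f)),
                     c(max(f_res / 20, 1e-3), f_res * 20))
  if (abs(pk$f_res / f_res - 1) > 1e-3 || abs(pk$peak / z_peak - 1) > 1e-3)
    stop(sprintf(
      "linear_resonator_calibrate: target (%.3g Hz, %.3g MOhm) not attainable with C = %.3g nF, tau1 = %.3g ms",
      f_res, z_peak, C, tau1))
  p
}
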