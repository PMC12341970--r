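#' Gating-variable specification
#'
#' First-order Hodgkin-Huxley gate `dx/dt = (x_inf(V) - x)/tau(V)` with a
#' logistic steady state `x_inf(V) = 1/(1 + exp((V - vh)/k))` (activation
#' gates have `k < 0`, inactivation gates `k > 0`) and a voltage-dependent
#' time constant in one of four forms:
#' \describe{
#'   \item{`"instant"`}{`x = x_inf(V)` at every instant (used for fast Na
#'     activation).}
#'   \item{`"constant"`}{`tau(V) = a` ms.}
#'   \item{`"xinf"`}{`tau(V) = a + b * x_inf(V)` ms, a self-referential
#'     form whose `x_inf` is this gate's own steady state.}
#'   \item{`"sigmoid"`}{`tau(V) = a + b / (1 + exp((V - c)/d))` ms.}
#' }
#'
#' @param vh half-activation voltage (mV).
#' @param k slope factor (mV); negative for activation.
#' @param p integer exponent on the gate in the channel current.
#' @param tau_form one of `"instant"`, `"constant"`, `"xinf"`, `"sigmoid"`.
#' @param a,b,c,d time-constant parameters (ms / mV as above).
#' @param tau_scale multiplicative scale on `tau(V)` (dimensionless);
#'   used to retune kinetics without touching the printed form.
#' @return an object of class `"gate_spec"`.
#' @export
gate_spec <- function(vh, k, p = 1,
                      tau_form = c("constant", "instant", "xinf", "sigmoid"),
                      a = 0, b = 0, c = 0, d = 1, tau_scale = 1) {
  tau_form <- match.arg(tau_form)
  if (p < 1 || p != round(p)) stop("gate_spec: p must be a positive integer")
  g <- structure(list(vh = vh, k = k, p = as.integer(p),
                      tau_form = tau_form, a = a, b = b, c = c, d = d,
                      tau_scale = tau_scale),
                 class = "gate_spec")
  vv <- seq(-120, 60, by = 1)
  if (tau_form != "instant" && any(gate_tau(g, vv) <= 0))
    stop("gate_spec: tau(V) must be positive on [-120, 60] mV")
  g
}

#' Evaluate a gate's steady state / time constant
#' @param gate a [gate_spec()].
#' @param v voltage (mV), vectorized.
#' @return numeric vector.
#' @export
gate_inf <- function(gate, v) 1 / (1 + exp((v - gate$vh) / gate$k))

#' @rdname gate_inf
#' @export
gate_tau <- function(gate, v) {
  tau <- switch(gate$tau_form,
                instant = rep(0, length(v)),
                constant = rep(gate$a, length(v)),
                xinf = gate$a + gate$b * gate_inf(gate, v),
                sigmoid = gate$a + gate$b / (1 + exp((v - gate$c) / gate$d)))
  gate$tau_scale * tau
}

#' Ionic-channel specification
#'
#' Current `I = g_max * m^p * h^q * (V - E_rev)` with optional activation
#' and inactivation gates. A channel with no gates is an ohmic leak.
#'
#' @param name channel label.
#' @param g_max maximal conductance (uS).
#' @param E_rev reversal potential (mV).
#' @param m activation [gate_spec()] or `NULL`.
#' @param h inactivation [gate_spec()] or `NULL`.
#' @return an object of class `"channel_spec"`.
#' @export
channel_spec <- function(name, g_max, E_rev, m = NULL, h = NULL) {
  if (g_max < 0) stop("channel_spec: g_max must be >= 0")
  structure(list(name = name, g_max = g_max, E_rev = E_rev, m = m, h = h),
            class = "channel_spec")
}

#' Single-compartment conductance-based cell
#'
#' @param C membrane capacitance (nF).
#' @param channels list of [channel_spec()]s.
#' @param name cell label.
#' @return an object of class `"cell_spec"`.
#' @export
cell_spec <- function(C, channels, name = "cell") {
  if (!(C > 0)) stop("cell_spec: C must be > 0")
  stopifnot(all(vapply(channels, inherits, TRUE, "channel_spec")))
  structure(list(C = C, channels = channels, name = name),
            class = "cell_spec")
}

#' @export
print.cell_spec <- function(x, ...) {
  cat(sprintf("cell '%s': C = %.4g nF, %d channel(s): %s\n", x$name, x$C,
              length(x$channels),
              paste(vapply(x$channels, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

tau_code <- c(instant = 0, constant = 1, xinf = 2, sigmoid = 3)

# flatten a gate into the 9 numeric columns the C++ integrator expects
gate_row <- function(g) {
  if (is.null(g)) return(c(NA, NA, NA, NA, NA, NA, NA, NA, NA))
  c(g$vh, g$k, g$p, tau_code[[g$tau_form]], g$a, g$b, g$c, g$d, g$tau_scale)
}

# channel matrix for a list of cells (0-based cell index in column 1)
channel_matrix <- function(cells) {
  rows <- list()
  for (i in seq_along(cells)) {
    for (ch in cells[[i]]$channels) {
      rows[[length(rows) + 1L]] <-
        c(i - 1, ch$g_max, ch$E_rev, gate_row(ch$m),
          as.numeric(!is.null(ch$h)), gate_row(ch$h))
    }
  }
  do.call(rbind, rows)
}

#' Pyloric-dilator-type resonant model cell
#'
#' Single-compartment cell with leak, a slow inactivating Ca current and
#' a hyperpolarization-activated inward (h) current, tuned to show
#' subthreshold membrane-potential resonance in the 0.1-4 Hz band near a
#' holding potential of -60 mV. The `"low_freq"` variant raises the leak,
#' slows Ca inactivation and slows h-current activation, lowering the
#' resonance frequency while keeping a similar peak amplitude.
#'
#' @param variant `"standard"` or `"low_freq"`.
#' @param name cell label.
#' @return a [cell_spec()].
#' @export
resonator_cell <- function(variant = c("standard", "low_freq"),
                           name = "PD") {
  variant <- match.arg(variant)
  std <- variant == "standard"
  cell_spec(
    C = 2, name = name,
    channels = list(
      channel_spec("leak", g_max = if (std) 0.098 else 0.1078, E_rev = -60),
      channel_spec("Ca", g_max = 0.1, E_rev = 120,
                   m = gate_spec(vh = -52, k = -7.2, p = 3,
                                 tau_form = "constant", a = 40),
                   # tau_h = 220 + 400*h_inf, x1.8 in the low-frequency variant
                   h = gate_spec(vh = -60, k = 5, p = 1, tau_form = "xinf",
                                 a = 220, b = 400,
                                 tau_scale = if (std) 1 else 1.8)),
      # h current: tau_m = 1500 - 1400*(1 - m_inf) = 100 + 1400*m_inf
      # low-freq variant: 2400 - 1600*(1 - m_inf) = 800 + 1600*m_inf
      channel_spec("h", g_max = 0.06, E_rev = -20,
                   m = if (std)
                     gate_spec(vh = -65, k = 4, p = 2, tau_form = "xinf",
                               a = 100, b = 1400)
                   else
                     gate_spec(vh = -65, k = 4, p = 2, tau_form = "xinf",
                               a = 800, b = 1600))))
}

#' Free-running follower model cell
#'
#' Resonant cell used as the third, unclamped neuron in the
#' coupling-current experiments: leak, an inactivating Ca current, a slow
#' K current and a modulatory inward current.
#'
#' @param name cell label.
#' @return a [cell_spec()].
#' @export
follower_cell <- function(name = "AB") {
  cell_spec(
    C = 2, name = name,
    channels = list(
      channel_spec("leak", g_max = 0.03, E_rev = -58),
      channel_spec("Ca", g_max = 0.012, E_rev = 120,
                   m = gate_spec(vh = -55.56, k = -3, p = 3,
                                 tau_form = "sigmoid",
                                 a = 8.95, b = 58.37, c = -54.5, d = 3),
                   h = gate_spec(vh = -60.12, k = 2, p = 1,
                                 tau_form = "constant", a = 3155.4)),
      channel_spec("KS", g_max = 0.03, E_rev = -80,
                   m = gate_spec(vh = -56, k = -2, p = 2,
                                 tau_form = "sigmoid",
                                 a = 2000, b = -1500, c = -55, d = -1)),
      channel_spec("MI", g_max = 0.011, E_rev = -10,
                   m = gate_spec(vh = -55, k = -5, p = 1,
                                 tau_form = "constant", a = 20))))
}
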