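# Independent oracles used across tests. These deliberately avoid the
# package's own integrators: small linear systems are solved with
# deSolve's adaptive lsoda so that closed forms and the package's RK4
# path are checked against a third route.

# steady-state response amplitude of the two-variable linear resonator
# (deviations from rest) driven by a unit sinusoidal current at f Hz
ode_impedance_amp <- function(p, f, n_settle_cycles = 8, n_measure_cycles = 4) {
  w <- 2 * pi * f / 1000  # rad/ms
  rhs <- function(t, y, parms) {
    list(c((-p$gL * y[1] - p$g1 * y[2] + sin(w * t)) / p$C,
           (y[1] - y[2]) / p$tau1))
  }
  period <- 1000 / f
  t_end <- (n_settle_cycles + n_measure_cycles) * period
  tt <- seq(0, t_end, by = period / 200)
  out <- deSolve::lsoda(c(0, 0), tt, rhs, NULL, rtol = 1e-10, atol = 1e-10)
  v <- out[out[, 1] >= n_settle_cycles * period, 2]
  (max(v) - min(v)) / 2
}

# same, for the coupled 4-variable pair; returns amplitudes of both cells
ode_coupled_amp <- function(p1, p2, gc, f, n_settle_cycles = 8,
                            n_measure_cycles = 4) {
  w <- 2 * pi * f / 1000
  rhs <- function(t, y, parms) {
    list(c((-p1$gL * y[1] - p1$g1 * y[2] - gc * (y[1] - y[3]) + sin(w * t)) / p1$C,
           (y[1] - y[2]) / p1$tau1,
           (-p2$gL * y[3] - p2$g1 * y[4] - gc * (y[3] - y[1])) / p2$C,
           (y[3] - y[4]) / p2$tau1))
  }
  period <- 1000 / f
  t_end <- (n_settle_cycles + n_measure_cycles) * period
  tt <- seq(0, t_end, by = period / 200)
  out <- deSolve::lsoda(c(0, 0, 0, 0), tt, rhs, NULL, rtol = 1e-10, atol = 1e-10)
  keep <- out[, 1] >= n_settle_cycles * period
  c(pre = (max(out[keep, 2]) - min(out[keep, 2])) / 2,
    post = (max(out[keep, 4]) - min(out[keep, 4])) / 2)
}

# a small calibrated resonator pair used in several tests: distinct
# resonance frequencies (0.8 / 1.2 Hz), equal peak impedance 15 MOhm
pair_lo <- function() linear_resonator(C = 2, gL = 0.06556, g1 = 0.01241,
                                       tau1 = 800)
pair_hi <- function() linear_resonator(C = 2, gL = 0.06498, g1 = 0.04779,
                                       tau1 = 800)

# bursting pair with the calibrated cell-2 scaling
burst_cell1 <- function(kappa = 1) bursting_cell(kappa = kappa, name = "B1")
burst_cell2 <- function(kappa = 1) bursting_cell(b1 = -0.0282679,
                                                 tau_scale = 1.167,
                                                 kappa = kappa, name = "B2")
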