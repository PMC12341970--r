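test_that("gate specifications validate their steady states and time constants", {
  g <- gate_spec(vh = -52, k = -7.2, p = 3, tau_form = "constant", a = 40)
  vv <- seq(-120, 60, by = 1)
  expect_true(all(gate_inf(g, vv) >= 0 & gate_inf(g, vv) <= 1))
  expect_true(all(gate_tau(g, vv) == 40))
  expect_error(gate_spec(vh = 0, k = 1, tau_form = "xinf", a = 1, b = -5),
               "positive")
  expect_error(gate_spec(vh = 0, k = 1, p = 0), "positive integer")
  expect_error(channel_spec("x", g_max = -1, E_rev = 0), "g_max")
  expect_error(cell_spec(C = 0, channels = list()), "C")
})

test_that("self-referential time-constant forms are positive across cell library", {
  vv <- seq(-120, 60, by = 0.5)
  for (cell in list(resonator_cell(), resonator_cell("low_freq"),
                    follower_cell(),
                    burst_cell1()$SN, burst_cell1()$A, burst_cell2()$SN)) {
    for (ch in cell$channels) {
      for (gate in list(ch$m, ch$h)) {
        if (is.null(gate) || gate$tau_form == "instant") next
        expect_true(all(gate_tau(gate, vv) > 0),
                    info = sprintf("%s/%s", cell$name, ch$name))
      }
    }
  }
})

test_that("a leak-only cell relaxes to the RC closed form", {
  cellf <- cell_spec(C = 2, name = "rc", channels = list(
    channel_spec("leak", g_max = 0.1, E_rev = -60)))
  tr <- simulate_network(list(cellf), inj = list("1" = 0.5),
                         duration = 0.5, dt = 0.05, record_dt = 1e-3,
                         v0 = -60)
  tt <- trace_time(tr) * 1000  # ms
  v_closed <- -60 + 0.5 / 0.1 * (1 - exp(-tt * 0.1 / 2))
  expect_lt(max(abs(tr$channels$V_rc - v_closed)), 1e-3)
})

test_that("integration converges: halving the step moves voltages < 0.01 mV", {
  cells <- list(resonator_cell(name = "a"), resonator_cell(name = "b"))
  stim <- function(t) sin(2 * pi * 1 * t)
  run <- function(dt) simulate_network(cells, edges = cbind(1, 2, 0.02),
                                       inj = list("1" = stim), duration = 2,
                                       dt = dt, record_dt = 1e-2)
  v1 <- run(0.05)$channels$V_a
  v2 <- run(0.025)$channels$V_a
  expect_lt(max(abs(v1 - v2)), 0.01)
})

test_that("gating variables stay within [0, 1]", {
  tr <- simulate_bursting_pair(burst_cell1(), burst_cell2(), 0.02,
                               duration = 2)
  g <- attr(tr, "gates_final")
  expect_true(all(g >= 0 & g <= 1))
})

test_that("clamp current equals the cell's current balance (passive audit)", {
  cellf <- function(nm) cell_spec(C = 2, name = nm, channels = list(
    channel_spec("leak", g_max = 0.1, E_rev = -60)))
  cmd <- function(t) -60 + 5 * sin(2 * pi * 2 * t)
  tr <- simulate_network(list(cellf("c"), cellf("f")),
                         edges = cbind(1, 2, 0.03),
                         clamp = list("1" = cmd),
                         duration = 2, dt = 0.05, record_dt = 1e-3)
  tt <- trace_time(tr)
  v <- tr$channels$V_c
  dvdt <- 5 * 2 * pi * 2 * cos(2 * pi * 2 * tt) / 1000  # mV/ms
  balance <- 2 * dvdt + 0.1 * (v + 60) + 0.03 * (v - tr$channels$V_f)
  i <- seq(10, length(tt) - 10)
  expect_lt(max(abs(tr$channels$I_c[i] - balance[i])), 1e-3)
})

test_that("dual-clamp coupling current recovers the configured conductance", {
  zv <- zap_params(amplitude = 7.5, offset = -52.5, t_max = 20,
                   phase = "trough")
  run <- coupled_zap_voltageclamp(resonator_cell(), resonator_cell(), zv,
                                  gc = 0.02)
  g <- run$profiles$Gc
  expect_lt(max(abs(g$amp - 0.02) / 0.02), 0.01)
})

test_that("identical isolated cells have identical impedance profiles", {
  zp <- zap_params(amplitude = 0.25, t_max = 20)
  run <- coupled_zap_currentclamp(resonator_cell(), resonator_cell(), 0.02,
                                  zp)
  expect_equal(run$profiles$Z1$amp, run$profiles$Z2$amp, tolerance = 1e-10)
  # coupling shifts the resonance only modestly, and the CC resonance
  # sits near that of the coupled cells
  expect_equal(run$fits$Zpre$f_res, run$fits$Z1$f_res, tolerance = 0.15)
  expect_equal(run$fits$CC$f_res, run$fits$Zpre$f_res, tolerance = 0.15)
  expect_false(run$fits$Zpre$at_edge)
})

test_that("divergent integrations report the offending time", {
  bad <- cell_spec(C = 1e-7, name = "bad", channels = list(
    channel_spec("leak", g_max = 10, E_rev = -60)))
  expect_error(
    simulate_network(list(bad), inj = list("1" = 100), duration = 0.1,
                     dt = 0.5, record_dt = 5e-3),
    "diverged")
})
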