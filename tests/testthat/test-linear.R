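test_that("passive cell impedance is the RC closed form and vanishes at high f", {
  p <- linear_resonator(C = 1, gL = 0.1, g1 = 0)
  f <- c(0.1, 0.5, 1, 2, 4)
  rc <- (1 / p$gL) / sqrt(1 + (2 * pi * f / 1000 * p$C / p$gL)^2)
  expect_equal(Mod(uncoupled_impedance(p, f)), rc, tolerance = 1e-12)
  expect_true(all(diff(Mod(uncoupled_impedance(p, seq(0.1, 4, 0.1)))) < 0))
  expect_lt(Mod(uncoupled_impedance(p, 1e6)), 1e-3)
})

test_that("closed-form resonance peak matches sinusoid-driven ODE simulation", {
  p <- pair_hi()  # resonates near 1.2 Hz
  fg <- seq(0.9, 1.5, by = 0.05)
  amp_ode <- vapply(fg, function(f) ode_impedance_amp(p, f), 0)
  amp_cf <- Mod(uncoupled_impedance(p, fg))
  # amplitudes agree (unit drive) and the argmax agrees to the grid step
  expect_equal(amp_ode, amp_cf, tolerance = 1e-3)
  expect_equal(fg[which.max(amp_ode)], fg[which.max(amp_cf)])
})

test_that("coupled closed forms reduce to the uncoupled limit and bound Zpost", {
  p1 <- pair_lo(); p2 <- pair_hi()
  f <- seq(0.1, 4, by = 0.05)
  z0 <- coupled_impedances(p1, p2, 0, f)
  expect_equal(z0$Zpre, uncoupled_impedance(p1, f), tolerance = 1e-12)
  expect_true(all(Mod(z0$Zpost) == 0))
  zz <- coupled_impedances(p1, p2, 0.02, f)
  expect_true(all(Mod(zz$Zpost) < Mod(zz$Zpre)))
})

test_that("coupled closed forms match the coupled ODE oracle within 1%", {
  p1 <- pair_lo(); p2 <- pair_hi()
  for (f in c(0.2, 0.8, 1.5, 3)) {
    amp <- ode_coupled_amp(p1, p2, 0.02, f)
    zz <- coupled_impedances(p1, p2, 0.02, f)
    expect_equal(unname(amp["pre"]), Mod(zz$Zpre), tolerance = 0.01)
    expect_equal(unname(amp["post"]), Mod(zz$Zpost), tolerance = 0.01)
  }
})

test_that("swapping the two cells swaps the pre/post roles exactly", {
  p1 <- pair_lo(); p2 <- pair_hi()
  f <- seq(0.1, 4, by = 0.1)
  a <- coupled_impedances(p1, p2, 0.02, f)
  b <- coupled_impedances(p2, p1, 0.02, f)
  expect_equal(a$Zpost, b$Zpost, tolerance = 1e-12)  # denominator symmetric
  Z1 <- uncoupled_impedance(p1, f)
  expect_equal(b$Zpre, (1 / Z1 + 0.02) / ((1 / Z1 + 0.02) *
                 (1 / uncoupled_impedance(p2, f) + 0.02) - 0.02^2),
               tolerance = 1e-12)
})

test_that("coupling coefficient limits and passive-postjunctional reduction hold", {
  p2 <- pair_hi()
  f <- seq(0.1, 4, by = 0.1)
  expect_true(all(coupling_coefficient(p2, 0, f) == 0))
  expect_equal(coupling_coefficient(p2, 1e6, f), rep(1, length(f)),
               tolerance = 1e-4)
  # near-zero capacitance, no restorative gate: pure resistance R2
  pr <- linear_resonator(C = 1e-6, gL = 0.05, g1 = 0)
  r2 <- 1 / pr$gL
  cc <- coupling_coefficient(pr, 0.02, f)
  expect_equal(cc, rep(0.02 * r2 / (1 + 0.02 * r2), length(f)),
               tolerance = 1e-6)
})

test_that("CC equals |Zpost|/|Zpre| and ignores the prejunctional cell", {
  p2 <- pair_hi()
  f <- seq(0.1, 4, by = 0.02)
  cc_direct <- coupling_coefficient(p2, 0.02, f)
  others <- list(pair_lo(),
                 linear_resonator(C = 1, gL = 0.2, g1 = 0),
                 linear_resonator(C = 3, gL = 0.03, g1 = 0.09, tau1 = 300))
  for (p1 in others) {
    zz <- coupled_impedances(p1, p2, 0.02, f)
    expect_lt(max(abs(Mod(zz$Zpost) / Mod(zz$Zpre) - cc_direct) / cc_direct),
              1e-9)
  }
})

test_that("peak localization flags flat profiles at the band edge", {
  pk <- profile_peak(function(f) 1 / f, c(0.1, 4))
  expect_true(pk$at_edge)
  expect_equal(pk$f_res, 0.1)
  pk2 <- profile_peak(function(f) exp(-(f - 1)^2), c(0.1, 4))
  expect_false(pk2$at_edge)
  expect_equal(pk2$f_res, 1, tolerance = 1e-5)
})

test_that("frequency-scaled coupling reproduces the constant case and amplifies CC", {
  p1 <- pair_lo(); p2 <- pair_hi()
  f <- seq(0.1, 4, by = 0.01)
  const <- scaled_gc_cc(p1, p2, 0.02, f, scale_fun = function(g) rep(1, length(g)))
  zz <- coupled_impedances(p1, p2, 0.02, f)
  expect_equal(const$Zpre, Mod(zz$Zpre), tolerance = 1e-12)
  expect_equal(const$CC, coupling_coefficient(p2, 0.02, f), tolerance = 1e-12)
  # inverted U equal to 1 at the band edges, peaked at 1 Hz
  bump <- function(g) 1 + 2 * (exp(-(g - 1)^2 / 0.5) -
                                 max(exp(-(0.1 - 1)^2 / 0.5),
                                     exp(-(4 - 1)^2 / 0.5)))
  sc <- scaled_gc_cc(p1, p2, 0.02, f, scale_fun = bump)
  expect_gt(max(sc$CC), max(const$CC))
  f_sc <- f[which.max(sc$CC)]
  f_const <- f[which.max(const$CC)]
  expect_lt(abs(f_sc - 1), abs(f_const - 1))  # shifted toward the scale peak
})

test_that("resonator calibration hits a requested frequency/amplitude target", {
  p <- linear_resonator_calibrate(0.9, 12, C = 2, tau1 = 600)
  pk <- profile_peak(function(f) Mod(uncoupled_impedance(p, f)), c(0.1, 4))
  expect_equal(pk$f_res, 0.9, tolerance = 1e-3)
  expect_equal(pk$peak, 12, tolerance = 1e-3)
})

test_that("unstable or degenerate parameters are rejected", {
  expect_error(linear_resonator(C = -1), "C")
  expect_error(linear_resonator(tau1 = 0), "tau1")
  expect_error(linear_resonator(gL = 0.1, g1 = -0.2), "unstable")
  expect_error(coupled_impedances(pair_lo(), pair_hi(), -0.01, 1), "Gc")
})
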