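test_that("spectral ratio of a channel with itself is one across the band", {
  tr <- generate_zap(zap_params(amplitude = 2, t_max = 20))
  tr$channels$J <- tr$channels$I
  tr$units <- c(tr$units, J = "nA")
  pr <- spectral_ratio(tr, "J", "I", band = c(0.1, 4), quantity = "CC",
                       unit = "")
  expect_equal(pr$amp, rep(1, length(pr$amp)), tolerance = 1e-9)
})

test_that("ZAP-driven passive RC cell recovers the analytic impedance within 2%", {
  # R = 10 MOhm, C = 1 nF
  p <- linear_resonator(C = 1, gL = 0.1, g1 = 0)
  tr <- simulate_linear_pair(p, p, 0, zap_params(amplitude = 1))
  pr <- spectral_ratio(tr, "V_pre", "I_pre", c(0.1, 4))
  rc <- (1 / p$gL) / sqrt(1 + (2 * pi * pr$f / 1000 * p$C / p$gL)^2)
  expect_lt(max(abs(pr$amp - rc) / rc), 0.02)
})

test_that("ZAP-driven coupled resonators recover the CC closed form within 2%", {
  p1 <- pair_lo(); p2 <- pair_hi()
  tr <- simulate_linear_pair(p1, p2, 0.02, zap_params(amplitude = 1))
  cc <- spectral_ratio(tr, "V_post", "V_pre", c(0.1, 4), quantity = "CC",
                       unit = "")
  cca <- coupling_coefficient(p2, 0.02, cc$f)
  expect_lt(max(abs(cc$amp - cca) / cca), 0.02)
})

test_that("CC profile equals the ratio of Zpost and Zpre profiles pointwise", {
  p1 <- pair_lo(); p2 <- pair_hi()
  tr <- simulate_linear_pair(p1, p2, 0.02, zap_params(amplitude = 1, t_max = 50))
  zpre <- spectral_ratio(tr, "V_pre", "I_pre", c(0.1, 4))
  zpost <- spectral_ratio(tr, "V_post", "I_pre", c(0.1, 4))
  cc <- spectral_ratio(tr, "V_post", "V_pre", c(0.1, 4))
  expect_equal(cc$amp, zpost$amp / zpre$amp, tolerance = 1e-9)
})

test_that("profiles are invariant to the sweep direction on a linear system", {
  p1 <- pair_lo(); p2 <- pair_hi()
  up <- simulate_linear_pair(p1, p2, 0.02, zap_params(amplitude = 1))
  dn <- simulate_linear_pair(p1, p2, 0.02, zap_params(amplitude = 1,
                                                      sweep = "down"))
  pu <- spectral_ratio(up, "V_pre", "I_pre", c(0.1, 4))
  pd <- spectral_ratio(dn, "V_pre", "I_pre", c(0.1, 4))
  # the two records differ in length (pre-cycles at different rates), so
  # compare on a common frequency grid
  fg <- seq(0.15, 3.95, by = 0.05)
  au <- stats::approx(pu$f, pu$amp, fg)$y
  ad <- stats::approx(pd$f, pd$amp, fg)$y
  expect_lt(max(abs(au - ad) / au), 0.01)
})

test_that("weak denominator bins are masked with a warning", {
  n <- 20000
  dt <- 1e-3
  tt <- (0:(n - 1)) * dt
  tr <- trace(dt, channels = list(num = rnorm(n),
                                  den = sin(2 * pi * 1 * tt)),
              units = c(num = "mV", den = "mV"))
  expect_warning(pr <- spectral_ratio(tr, "num", "den", c(0.1, 4)),
                 "masked")
  expect_true(anyNA(pr$amp))
  expect_error(spectral_ratio(tr, "num", "nope", c(0.1, 4)), "nope")
})

test_that("polynomial fit recovers interior peaks and flags monotone profiles", {
  f <- seq(0.1, 4, by = 0.01)
  # curve inside the polynomial family: exact recovery expected
  prof <- freq_profile(f, 8 - (f - 1.5)^2, quantity = "Zpre", unit = "MOhm")
  fit <- fit_resonance(prof)
  expect_false(fit$at_edge)
  expect_equal(fit$f_res, 1.5, tolerance = 1e-6)
  expect_equal(fit$peak, 8, tolerance = 1e-6)
  expect_equal(fit$amp_flo, 8 - (0.1 - 1.5)^2, tolerance = 1e-6)
  # peak amplitude dominates the fitted curve everywhere on the grid
  expect_true(all(predict(fit, f) <= fit$peak + 1e-9))

  dec <- freq_profile(f, 10 / (1 + f), quantity = "Zpre", unit = "MOhm")
  fit2 <- fit_resonance(dec)
  expect_true(fit2$at_edge)
  expect_equal(fit2$f_res, 0.1, tolerance = 1e-9)

  expect_error(fit_resonance(freq_profile(f[1:6], (6:1) / 6)), "at least")
})

test_that("resonance-fit methods expose coefficients, predictions, residuals", {
  f <- seq(0.1, 4, by = 0.01)
  set.seed(42)
  prof <- freq_profile(f, pmax(8 - (f - 1.5)^2 + rnorm(length(f), 0, 0.05), 0))
  fit <- fit_resonance(prof)
  expect_length(coef(fit), 7)
  expect_equal(unname(predict(fit, 1.5)), fit$peak, tolerance = 1e-2)
  expect_equal(length(residuals(fit)), length(f))
  expect_lt(fit$sigma, 0.08)
  s <- summary(fit)
  expect_equal(s$f_res, fit$f_res)
  expect_output(print(fit), "resonance")
})

test_that("normalization pins the lowest-frequency value to 1 and is idempotent", {
  f <- seq(0.1, 4, by = 0.05)
  prof <- freq_profile(f, 4 + 3 * exp(-(f - 1)^2), quantity = "Zpre",
                       unit = "MOhm")
  np <- normalize_profile(prof)
  expect_equal(np$amp[1], 1)
  expect_true(np$normalized)
  expect_equal(max(np$amp), max(prof$amp) / prof$amp[1], tolerance = 1e-12)
  expect_equal(normalize_profile(np)$amp, np$amp, tolerance = 1e-12)
  bad <- freq_profile(f, c(0, (4 + f)[-1]))
  expect_error(normalize_profile(bad), "zero")
})

test_that("step protocols recover CC and the configured junctional conductance", {
  # exact proportional response
  n <- 5000
  v_pre <- rep(c(-80, -70, -60, -50, -40), each = 1000)
  tr <- trace(1e-3, channels = list(V_pre = v_pre, V_post = 0.3 * v_pre),
              units = c(V_pre = "mV", V_post = "mV"))
  onsets <- (0:4)
  cc <- step_coupling_estimate(tr, onsets = onsets, duration = 1)
  expect_equal(cc, 0.3, tolerance = 1e-9)

  # two passive coupled cells in dual clamp: slope of I_post vs V_pre
  leak_cell <- function(nm) cell_spec(C = 1, name = nm, channels = list(
    channel_spec("leak", g_max = 0.1, E_rev = -60)))
  cmd <- function(t) v_pre_steps(t)
  v_pre_steps <- stats::approxfun(seq(0, 5, by = 1), c(-80, -70, -60, -50, -40, -40),
                                  method = "constant", rule = 2)
  sim <- simulate_network(list(leak_cell("pre"), leak_cell("post")),
                          edges = cbind(1, 2, 0.05),
                          clamp = list("1" = cmd, "2" = -60),
                          duration = 5, dt = 0.05)
  gc_hat <- step_coupling_estimate(sim, pre = "V_pre", response = "I_post",
                                   onsets = 0:4, duration = 1,
                                   mode = "voltageclamp")
  expect_equal(gc_hat, 0.05, tolerance = 0.01)

  # zero coupling: slope vanishes
  sim0 <- simulate_network(list(leak_cell("pre"), leak_cell("post")),
                           clamp = list("1" = cmd, "2" = -60),
                           duration = 5, dt = 0.05)
  expect_lt(abs(step_coupling_estimate(sim0, pre = "V_pre",
                                       response = "I_post", onsets = 0:4,
                                       duration = 1, mode = "voltageclamp")),
            1e-6)
  expect_error(step_coupling_estimate(tr, onsets = 0:1, duration = 1),
               "3 steps")
})
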