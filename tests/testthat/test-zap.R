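test_that("zap_params rejects invalid parameter sets with a named reason", {
  expect_error(zap_params(f_lo = 0), "f_lo")
  expect_error(zap_params(f_lo = 4, f_hi = 0.1), "f_hi")
  expect_error(zap_params(t_max = -1), "t_max")
  expect_error(zap_params(dt = 0.2), "Nyquist")
  expect_error(zap_params(n_precycles = -1), "n_precycles")
  expect_error(zap_params(n_precycles = 1.5), "n_precycles")
})

test_that("instantaneous frequency runs from f_lo to f_hi with geometric-mean midpoint", {
  z <- zap_params(f_lo = 0.1, f_hi = 4, t_max = 100)
  expect_equal(zap_frequency(z, 0), 0.1)
  expect_equal(zap_frequency(z, 100), 4)
  # midpoint of the exponential sweep is the geometric mean
  expect_equal(zap_frequency(z, 50), sqrt(0.1 * 4), tolerance = 1e-12)
  expect_error(zap_frequency(z, 101), "chirp segment")
  # strictly increasing
  tt <- seq(0, 100, by = 0.5)
  expect_true(all(diff(zap_frequency(z, tt)) > 0))
})

test_that("chirp cycle count matches numerical integration of the frequency track", {
  z <- zap_params(f_lo = 0.1, f_hi = 4, t_max = 100)
  cycles_phase <- gapres:::zap_phase(z, z$t_max) / (2 * pi)
  cycles_closed <- (z$f_hi - z$f_lo) / z$L
  cycles_numeric <- stats::integrate(function(t) zap_frequency(z, t), 0, 100,
                                     rel.tol = 1e-10)$value
  expect_equal(cycles_phase, cycles_closed, tolerance = 1e-10)
  expect_equal(cycles_phase, cycles_numeric, tolerance = 1e-8)
})

test_that("generated ZAP starts at the commanded phase and has the right duration", {
  z <- zap_params(amplitude = 3, offset = 0)
  tr <- generate_zap(z)
  x <- tr$channels$I
  expect_equal(x[1], 3)                      # cos(0) = 1 at protocol start
  expect_equal(length(x) * tr$dt, 2 / 0.1 + 100, tolerance = 1e-3)
  zt <- zap_params(amplitude = 15, offset = -45, phase = "trough")
  xt <- generate_zap(zt, name = "V", unit = "mV")$channels$V
  expect_equal(xt[1], -60)                   # voltage command starts at hold
})

test_that("phase is continuous across the pre-cycle/chirp splice", {
  z <- zap_params(amplitude = 1, t_max = 20)
  tr <- generate_zap(z)
  x <- tr$channels$I
  tt <- trace_time(tr)
  splice <- 2 / z$f_lo
  near <- which(abs(tt - splice) < 0.5)
  # jump bounded by the largest slope at f_lo: 2*pi*f_lo*amp*dt (with margin)
  expect_lt(max(abs(diff(x[near]))), 2 * pi * z$f_lo * z$dt * 1.1)
})

test_that("amplitude envelope is constant and attained", {
  z <- zap_params(amplitude = 2, offset = 0.5, t_max = 50)
  x <- generate_zap(z)$channels$I
  expect_true(all(abs(x - 0.5) <= 2 + 1e-12))
  expect_equal(max(abs(x - 0.5)), 2, tolerance = 1e-4)
})

test_that("down-sweep is the time-reversal of the up-sweep frequency track", {
  zu <- zap_params()
  zd <- zap_params(sweep = "down")
  tt <- seq(0, 100, by = 1)
  expect_equal(zap_frequency(zd, tt), zap_frequency(zu, 100 - tt),
               tolerance = 1e-12)
  expect_equal(zap_frequency(zd, 0), 4)
  expect_equal(zap_frequency(zd, 100), 0.1)
})

test_that("protocol envelope returns to baseline and inserts the lead-in", {
  z <- zap_params(amplitude = 1, t_max = 10, n_precycles = 1)
  f <- zap_protocol(z, baseline = 0, pre_settle = 5)
  expect_equal(f(c(0, 2.5, 4.99)), c(0, 0, 0))
  expect_equal(f(5), 1)                       # chirp starts (cos from peak)
  dur <- 5 + zap_duration(z)
  expect_equal(f(dur + 0.5 + 1e-6), 0, tolerance = 1e-9) # after the ramp
  # half-cosine ramp: distance to baseline decreases monotonically
  rmp <- f(seq(dur + 1e-9, dur + 0.5, length.out = 50))
  expect_true(all(diff(abs(rmp)) <= 1e-12))
})
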