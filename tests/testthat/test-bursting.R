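test_that("the junctional conductance profile is a band-pass with one peak", {
  f <- seq(0.01, 20, by = 0.01)
  g <- gc_frequency_profile(f, Gbar = 0.01)
  expect_true(all(g > 0))
  expect_lt(gc_frequency_profile(1e-6, 0.01), 1e-6)
  expect_lt(gc_frequency_profile(1000, 0.01), 1e-8)
  # single interior maximum at log(50)/4.9
  i <- which.max(g)
  expect_equal(f[i], log(50) / 4.9, tolerance = 0.01)
  expect_true(all(diff(g[1:i]) > 0))
  expect_true(all(diff(g[i:length(g)]) < 0))
  # printed scale factor leaves the peak above Gbar ...
  expect_equal(max(g) / 0.01, 2.3746, tolerance = 1e-3)
  # ... unless renormalized so the peak equals Gbar
  gr <- gc_frequency_profile(f, 0.01, renormalize = TRUE)
  expect_equal(max(gr), 0.01, tolerance = 1e-6)
})

test_that("waveform decomposition is exact and separates time scales", {
  n <- 20000
  tt <- (0:(n - 1)) * 1e-3
  const <- trace(1e-3, channels = list(V_SN1 = rep(3.5, n)),
                 units = c(V_SN1 = "mV"))
  d <- decompose_waveform(const)
  expect_equal(d$slow, rep(3.5, n))
  expect_true(all(d$fast == 0))

  slow_sine <- trace(1e-3, channels = list(V_SN1 = sin(2 * pi * 0.5 * tt)),
                     units = c(V_SN1 = "mV"))
  d2 <- decompose_waveform(slow_sine)
  mid <- seq(200, n - 200)
  expect_lt(max(abs(d2$fast[mid])), 0.01 * max(abs(d2$full)))
  # closure at every sample
  expect_equal(d2$full, d2$slow + d2$fast, tolerance = 1e-12)
  short <- trace(1e-3, channels = list(V_SN1 = 1:10), units = c(V_SN1 = "mV"))
  expect_error(decompose_waveform(short), "window")
})

test_that("synchrony metrics behave on constructed waveform pairs", {
  set.seed(1)
  n <- 20000
  tt <- (0:(n - 1)) * 1e-3
  burst <- function(phase, spike_phase = 0) {
    env <- pmax(sin(2 * pi * 0.8 * tt + phase), 0)
    -55 + 20 * env + 2 * (env > 0.3) * sin(2 * pi * 40 * tt + spike_phase)
  }
  tr <- trace(1e-3, channels = list(V_SN1 = burst(0), V_SN2 = burst(0)),
              units = c(V_SN1 = "mV", V_SN2 = "mV"))
  syn <- burst_synchrony(tr)
  expect_equal(syn$R2_full, 1, tolerance = 1e-12)
  expect_equal(syn$R2_slow, 1, tolerance = 1e-12)
  expect_equal(syn$f_network, 0.8, tolerance = 0.05)

  # half-cycle shift destroys slow-wave synchrony (R^2 falls far from 1;
  # squared correlation keeps part of the anti-phase correlation)
  tr2 <- trace(1e-3, channels = list(V_SN1 = burst(0), V_SN2 = burst(pi)),
               units = c(V_SN1 = "mV", V_SN2 = "mV"))
  expect_lt(burst_synchrony(tr2)$R2_slow, 0.6)

  # independent fast-band activity decorrelates the fast component
  tr3 <- trace(1e-3,
               channels = list(V_SN1 = burst(0) + rnorm(n),
                               V_SN2 = burst(0, spike_phase = 2) + rnorm(n)),
               units = c(V_SN1 = "mV", V_SN2 = "mV"))
  expect_lt(burst_synchrony(tr3)$R2_fast, 0.1)
})

test_that("identical cells with identical initial conditions stay identical", {
  tr <- simulate_bursting_pair(burst_cell1(), burst_cell1(), 0.02,
                               duration = 5)
  expect_lt(max(abs(tr$channels$V_SN1 - tr$channels$V_SN2)), 1e-9)
  syn <- burst_synchrony(tr)
  expect_equal(syn$R2_slow, 1, tolerance = 1e-9)
})

test_that("the calibrated pair bursts ~10% apart when uncoupled and locks when coupled", {
  tr0 <- simulate_bursting_pair(burst_cell1(), burst_cell2(), 0)
  f1 <- burst_frequency(tr0, "V_SN1")
  f2 <- burst_frequency(tr0, "V_SN2")
  expect_gt(f1, f2)  # cell 2 is the slowed variant
  expect_equal(100 * (f1 - f2) / f1, 10, tolerance = 0.15)

  syn <- burst_synchrony(simulate_bursting_pair(burst_cell1(), burst_cell2(),
                                                0.02))
  expect_lt(abs(syn$f_network - syn$f_network2) / syn$f_network, 0.005)
})

test_that("synchrony grows with coupling strength", {
  res <- gc_sweep(c(0.005, 0.02, 0.08))
  expect_true(all(diff(res$R2_slow) > 0))
  expect_true(all(res$R2_slow >= 0 & res$R2_slow <= 1))
  expect_gt(res$R2_slow[3], 0.98)  # strong coupling approaches full synchrony
})
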