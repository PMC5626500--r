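test_that("synthetic ensembles have the declared first-order statistics", {
  tr <- generate_poisson_trains(100, 10000, 12, seed = 1)
  expect_equal(nrow(tr) / 100 / 10, 12, tolerance = 0.05)
  expect_true(all(tr$t_ms >= 0 & tr$t_ms <= 10000))
  expect_true(!is.unsorted(tr$t_ms))
})

test_that("pairwise correlation follows the analytic Poisson-mixture value", {
  dur <- 30000; base <- 40; n <- 2
  for (frac in c(0, 0.5, 1)) {
    a <- generate_correlated_trains(n, dur, base, shared_frac = frac,
                                    osc_hz = 10, seed = 20 + frac * 10)
    y1 <- bin_population(a, 1, dur)
    y2 <- bin_population(a, 2, dur)
    got <- ccf_population(y1, y2, 5)[6]
    # analytic: cov = var of the shared rate; var = rate var + Poisson noise
    lam <- base / 1000
    var_rate <- (lam * frac)^2 / 2
    rho <- var_rate / (var_rate + lam)
    se <- 3 / sqrt(dur)
    expect_lt(abs(got - rho), 3 * se + 0.01)
  }
})

test_that("fully shared sinusoidal drive gives rate-level correlation 1", {
  dur <- 20000
  a <- generate_correlated_trains(400, dur, 30, shared_frac = 1,
                                  osc_hz = 8, seed = 31)
  b <- generate_correlated_trains(400, dur, 30, shared_frac = 1,
                                  osc_hz = 8, seed = 32)
  yA <- lowpass_activity(bin_population(a, 1:400, dur), 15)
  yB <- lowpass_activity(bin_population(b, 1:400, dur), 15)
  expect_gt(ccf_population(yA, yB, 5)[6], 0.95)
})
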