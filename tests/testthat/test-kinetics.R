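test_that("double exponential conductance is normalized and peaks at the
           closed-form argmax", {
  expect_equal(double_exp_g(0, 1, 1, 5), 0)
  tg <- seq(0, 60, by = 1e-3)
  g <- double_exp_g(tg, 2.5, 1, 5)
  expect_equal(max(g), 2.5, tolerance = 1e-6)
  t_star <- 5 * 1 / 4 * log(5)
  expect_equal(tg[which.max(g)], t_star, tolerance = 1e-2)
  expect_true(all(g >= 0))
  expect_error(double_exp_g(1, 1, 5, 5), "tau_rise")
})

test_that("GABA waveform mixes transient and spillover components", {
  p <- granular_config()$synapses$gaba_grc
  expect_equal(gaba_g(0, p), 0)
  tg <- seq(0, 400, by = 0.01)
  g <- gaba_g(tg, p)
  expect_lte(max(g), p$gmax_ns)
  expect_gte(max(g), 0.9 * p$gmax_ns)
  # late tail is dominated by the slow spillover component (peak-normalized
  # amplitude 0.1 * gmax * N_slow decaying at tau_slow)
  n_slow <- 1 / (exp(-8.064 / 35) - exp(-8.064 / 3))
  expect_equal(gaba_g(200, p), 0.1 * p$gmax_ns * n_slow * exp(-200 / 35),
               tolerance = 1e-3)
  expect_true(all(g >= 0))
})

test_that("NMDA magnesium block follows the Boltzmann voltage dependence", {
  expect_equal(nmda_voltage_factor(0), 1 / (1 + 1 / 1.77), tolerance = 1e-12)
  expect_equal(nmda_voltage_factor(-70),
               1 / (1 + (1 / 1.77) * exp(70 / 22.4)), tolerance = 1e-12)
  expect_equal(nmda_voltage_factor(1e4), 1, tolerance = 1e-6)
  v <- seq(-120, 60, by = 0.5)
  expect_true(all(diff(nmda_voltage_factor(v)) > 0))
  expect_equal(nmda_voltage_factor(v, mg_mm = 0), rep(1, length(v)))
})

test_that("gap junction currents are Ohmic and conserve charge pairwise", {
  expect_equal(gap_junction_current(-60, -60, 1.2), 0)
  expect_equal(gap_junction_current(-65, -55, 1.659), 16.59)
  expect_equal(gap_junction_current(-55, -65, 1.659),
               -gap_junction_current(-65, -55, 1.659))
  expect_equal(gap_junction_g(0), 1.659)
  expect_equal(gap_junction_g(100), 1.659 * exp(-1.259), tolerance = 1e-12)
  d <- seq(0, 300, by = 10)
  expect_true(all(diff(gap_junction_g(d)) < 0))
})

test_that("cascade is stable, superposable and matches a dense ODE solver", {
  skip_if_not_installed("deSolve")
  A <- cascade_matrix()
  # zero input stays zero; a single release decays back to zero
  s <- cascade_step(rep(0, 5), 0.1)
  expect_equal(s, setNames(rep(0, 5), c("P", "T", "I1", "I2", "I3")))
  E <- cascade_propagator(A, 1)
  s <- cascade_step(rep(0, 5), 1, spike = TRUE, y = 1, E = E)
  for (k in 1:600) s <- cascade_step(s, 1, E = E)
  expect_true(all(s < 1e-6))

  # trajectory of T vs deSolve at tight tolerance
  ts <- seq(0, 80, by = 0.25)
  sol <- deSolve::ode(y = c(1, 0, 0, 0, 0), times = ts,
                      func = function(t, y, p) list(A %*% y),
                      rtol = 1e-10, atol = 1e-12)
  T_ref <- sol[, 3]
  T_mine <- cascade_transmitter(ts)
  expect_lt(max(abs(T_mine - T_ref)) / max(T_ref), 1e-6)
  # stepping solution agrees too
  E <- cascade_propagator(A, 0.25)
  s <- c(1, 0, 0, 0, 0); T_step <- numeric(length(ts)); T_step[1] <- 0
  for (i in 2:length(ts)) { s <- cascade_step(s, 0.25, E = E); T_step[i] <- s[2] }
  expect_lt(max(abs(T_step - T_ref)) / max(T_ref), 1e-6)

  # linearity: k releases = k times one release
  s1 <- cascade_step(rep(0, 5), 0.5, spike = TRUE, y = 1)
  s3 <- cascade_step(rep(0, 5), 0.5, spike = TRUE, y = 3)
  expect_equal(3 * s1, s3, tolerance = 1e-12)
})

test_that("release depression scales the diffusing fraction and recovers", {
  rel <- list(y0 = 1, depression_frac = 0.6, recovery_ms = 50)
  y <- release_fractions(c(0, 1, 2), rel)
  expect_equal(y[1], 1)
  expect_true(all(diff(y) < 0))
  # long gaps recover the resource
  y2 <- release_fractions(c(0, 1000), rel)
  expect_gt(y2[2], 0.99)
})

test_that("surrogate neuron reproduces the closed-form LIF f-I curve", {
  p <- granular_config()$neurons$grc
  p$adapt_b_pa <- 0
  # below rheobase: silent
  st <- neuron_state(p)
  for (k in 1:4000) {
    out <- step_neuron(st, p, i_syn_pa = 0, dt_ms = 0.025)
    st <- out$state
    expect_false(out$spike)
  }
  expect_equal(st$v_mv, p$e_leak_mv, tolerance = 1e-6)
  # suprathreshold constant current: rate within 2 % of the analytic value
  for (i_pa in c(20, 40)) {
    f_ref <- lif_fi_rate(i_pa, p)
    expect_gt(f_ref, 0)
    st <- neuron_state(p); n_sp <- 0
    for (k in 1:40000) {   # 1 s at 0.025 ms
      out <- step_neuron(st, p, i_syn_pa = i_pa, dt_ms = 0.025)
      st <- out$state
      n_sp <- n_sp + out$spike
    }
    expect_equal(n_sp, f_ref, tolerance = 0.02)
  }
})
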