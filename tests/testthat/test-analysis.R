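test_that("population binning normalizes by the cell count", {
  sp <- data.frame(cell = c(1, 1, 2), t_ms = c(0.4, 5.2, 5.7))
  y <- bin_population(sp, cells = 1:2, duration_ms = 10)
  expect_equal(length(y), 10)
  expect_equal(y[1], 0.5)
  expect_equal(y[6], 1)       # both cells spike in bin 6
  expect_equal(sum(y) * 2, 3) # total mass = spike count
  expect_error(bin_population(sp, integer(), 10), "empty patch")
  # Poisson trains against a direct count oracle
  trains <- generate_poisson_trains(20, 500, 40, seed = 2)
  y2 <- bin_population(trains, 1:20, 500)
  expect_equal(sum(y2) * 20, nrow(trains))
})

test_that("CCF matches the brute-force double loop to 1e-12", {
  set.seed(3)
  for (L in c(61, 400)) {
    yA <- rpois(L, 2) + 0.1 * seq_len(L)
    yB <- rev(yA) + rnorm(L)
    nlag <- 25
    expect_equal(as.numeric(ccf_population(yA, yB, nlag)),
                 ccf_bruteforce(yA, yB, nlag), tolerance = 1e-12)
  }
  # identical inputs give (L-1)/L at zero lag
  y <- rnorm(500)
  expect_equal(ccf_population(y, y, 10)[11], 499 / 500, tolerance = 1e-12)
  # independent white noise decorrelates
  a <- rnorm(20000); b <- rnorm(20000)
  expect_lt(abs(ccf_population(a, b, 1)[2]), 0.03)
  expect_error(ccf_population(rep(1, 100), rnorm(100), 10), "zero-variance")
  # three-point worked example against a hand summation
  yA <- c(1, 2, 4); yB <- c(0, 1, 1)
  got <- ccf_population(yA, yB, 1)
  expect_equal(as.numeric(got), ccf_bruteforce(yA, yB, 1), tolerance = 1e-12)
})

test_that("rate-modulation discounting separates slow co-modulation from
           fast synchrony", {
  dur <- 8000
  # identical slow sinusoidal rates, independent spikes (disjoint halves
  # of one ensemble share the rate but not the spikes): c ~ 0, b ~ a
  slow <- generate_correlated_trains(300, dur, 30, shared_frac = 0.8,
                                     osc_hz = 2, seed = 4)
  yA <- bin_population(slow, 1:150, dur)
  yB <- bin_population(slow, 151:300, dur)
  r <- discounted_correlation(yA, yB)
  expect_gt(r$a, 0.2)
  expect_lt(abs(r$c), 0.1 * r$a)
  # common fast 40-Hz drive: the low-pass discount removes almost nothing
  fast <- generate_correlated_trains(300, dur, 30, shared_frac = 0.8,
                                      osc_hz = 40, seed = 5)
  y1 <- bin_population(fast, 1:150, dur)
  y2 <- bin_population(fast, 151:300, dur)
  r2 <- discounted_correlation(y1, y2)
  expect_gt(r2$a, 0.2)
  expect_equal(r2$c, r2$a, tolerance = 0.15)
  # b of white noise is negligible
  r3 <- discounted_correlation(rnorm(5000), rnorm(5000))
  expect_lt(abs(r3$b), 0.02)
})

test_that("shuffle significance flags synchrony and calibrates under the null", {
  dur <- 4000
  ens <- generate_correlated_trains(240, dur, 25, shared_frac = 0.9,
                                    osc_hz = 35, seed = 6)
  yA <- bin_population(ens, 1:120, dur)
  yB <- bin_population(ens, 121:240, dur)
  sig <- shuffle_significance(yA, yB, seed = 1)
  expect_lt(sig$p, 0.01)
  # n_out = 0 gives p = 0 by construction
  expect_equal(shuffle_significance(yA, yB, n_shuffle = 5, seed = 2)$p *
                 5 * 601 %% 1, 0)
  expect_warning(shuffle_significance(rnorm(80) + 10, rnorm(80) + 10,
                                      nlag = 30, seed = 3), "sub-epochs")
})

test_that("shuffle test type-I error stays at or below nominal on
           independent Poisson pairs", {
  hits <- 0; reps <- 60
  for (k in seq_len(reps)) {
    a <- generate_poisson_trains(60, 2500, 20, seed = 100 + k)
    b <- generate_poisson_trains(60, 2500, 20, seed = 900 + k)
    yA <- bin_population(a, 1:60, 2500); yB <- bin_population(b, 1:60, 2500)
    p <- shuffle_significance(yA, yB, n_shuffle = 20, seed = k)$p
    hits <- hits + (p < 0.01)
  }
  expect_lte(hits / reps, 0.05)
})

test_that("oscillation metrics recover frequency and the index limits", {
  dur <- 6000
  tr <- generate_correlated_trains(300, dur, 30, shared_frac = 0.9,
                                   osc_hz = 40, seed = 7)
  y <- bin_population(tr, 1:300, dur)
  m <- oscillation_metrics(y)
  expect_equal(m$peak_freq_hz, 40, tolerance = 0.025)
  expect_gt(m$n_cycles, 100)
  # perfectly synchronous population, one spike per cell per cycle
  n <- 50; cyc <- 25
  sp <- data.frame(cell = rep(1:n, cyc),
                   t_ms = rep(seq(10, by = 20, length.out = cyc), each = n))
  ys <- bin_population(sp, 1:n, 520)
  ms <- oscillation_metrics(ys, band = c(30, 100))
  expect_equal(ms$sync_index, 1, tolerance = 0.05)
  expect_equal(ms$peak_freq_hz, 50, tolerance = 2)
  # silence
  m0 <- oscillation_metrics(rep(0, 1000))
  expect_true(is.na(m0$peak_freq_hz))
  expect_equal(m0$sync_index, 0)
})

test_that("windowed rates count spikes per cell per second", {
  sp <- data.frame(cell = c(1, 2, 2), t_ms = c(10, 11, 40))
  expect_equal(windowed_rate(sp, 1:2, c(0, 30)), 2 / 2 / 0.03)
  expect_equal(windowed_rate(sp, 1:2, c(100, 120)), 0)
  tr <- generate_poisson_trains(200, 5000, 10, seed = 8)
  expect_equal(windowed_rate(tr, 1:200, c(0, 5000)), 10, tolerance = 0.05)
})

test_that("dynamic range divides extreme activation fractions", {
  # synthetic records with known active fractions 5 % and 50 % per 1-ms bin
  mk <- function(frac, n = 200, dur = 400) {
    on <- seq_len(n * frac)
    data.frame(cell = rep(on, dur),
               t_ms = rep(seq_len(dur) - 0.5, each = length(on)))
  }
  rec <- list(lo = mk(0.05), hi = mk(0.5))
  dr <- dynamic_range(rec, 1:200, 400, windows_ms = 1)
  expect_equal(unname(dr$range), 10, tolerance = 1e-9)
  # constant activity: range 1
  dr1 <- dynamic_range(list(a = mk(0.2), b = mk(0.2)), 1:200, 400, 1)
  expect_equal(unname(dr1$range), 1)
  # invariance under relabeling; monotonicity in window length
  tr <- generate_poisson_trains(100, 2000, 15, seed = 9)
  tr2 <- tr; tr2$cell <- 101 - tr2$cell
  p1 <- percent_active(tr, 1:100, 2000, 10)
  expect_equal(percent_active(tr2, 1:100, 2000, 10), p1)
  pcts <- vapply(c(1, 10, 100), percent_active, numeric(1),
                 spikes = tr, cells = 1:100, duration_ms = 2000)
  expect_true(all(diff(pcts) > 0))
  # zero minimum is floored and flagged
  silent <- data.frame(cell = 1, t_ms = 0.5)[0, ]
  dr0 <- dynamic_range(list(a = silent, b = mk(0.5)), 1:200, 400, 1)
  expect_true(dr0$floored)
  expect_true(is.finite(dr0$range))
})

test_that("volumetric maps conserve spike mass and blur as requested", {
  cfg <- granular_config(geometry = list(transverse_um = 100,
                                         sagittal_um = 100,
                                         granular_um = 100))
  pos <- matrix(c(55, 45, 35, 15, 85, 95), 2, 3, byrow = TRUE)
  sp <- data.frame(cell = c(1, 2, 2), t_ms = c(0.1, 0.5, 3))
  raw <- volumetric_map(sp, pos, 0, cfg, kernel_sigma_um = 0)
  expect_equal(sum(raw), 2)           # mass = in-frame spike count
  expect_equal(attr(raw, "raw_total"), 2)
  one <- volumetric_map(sp[1, ], pos, 0, cfg, kernel_sigma_um = 15)
  peak <- which(one == max(one), arr.ind = TRUE)
  expect_equal(as.numeric(peak), c(6, 5, 4))   # blob centered at (55,45,35)
  expect_equal(max(one), 1, tolerance = 1e-6)  # max-normalized kernel
})

test_that("bootstrap errors behave on degenerate and analytic cases", {
  expect_error(bootstrap_error(1:10, function(cs) 1, resamples = 1),
               "insufficient resamples")
  expect_equal(bootstrap_error(rep(1, 20), function(cs) mean(cs),
                               resamples = 50), 0)
  # mean of n iid values: bootstrap SE within 20 % of sigma/sqrt(n)
  set.seed(10)
  x <- rnorm(400, sd = 2)
  se <- bootstrap_error(seq_along(x), function(cs) mean(x[cs]),
                        resamples = 400)
  expect_equal(se, 2 / sqrt(400), tolerance = 0.2)
})
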