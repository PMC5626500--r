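test_that("mossy-fiber LIF respects refractoriness and hits target rates", {
  sch <- make_constant_schedule(5, 60000)
  sp <- lif_mf_spikes(sch, n_fibers = 25, seed = 5)
  rate <- nrow(sp) / 25 / 60
  expect_lt(abs(rate - 5), 0.5)
  isi <- unlist(tapply(sp$t_ms, sp$fiber, function(t) diff(sort(t))))
  expect_true(all(isi >= 1.1))
  # a range of targets comes back within 10 %
  for (target in c(2, 20, 120, 500)) {
    spk <- lif_mf_spikes(make_constant_schedule(target, 20000),
                         n_fibers = 10, seed = target)
    expect_lt(abs(nrow(spk) / 10 / 20 / target - 1), 0.1)
  }
})

test_that("nu-to-rate table is monotone and inverts by interpolation", {
  tab <- calibrate_rate_table(dur_ms = 8000, n_fibers = 8,
                              nu_grid = c(0, 1, 1.5, 2, 3, 5, 10, 30, 100))
  expect_true(all(diff(tab$rate_hz) >= 0))
  expect_lt(tab$rate_hz[1], 0.2)               # nu = 0 is silent
  nu <- nu_for_rate(c(5, 60), tab)
  expect_true(all(diff(nu) > 0))
  expect_warning(nu_for_rate(1e5, tab), "clamping")
})

test_that("firing is fluctuation-driven: without noise the fiber is silent", {
  p <- mf_lif_params(sigma_form = "none")
  nu5 <- nu_for_rate(5, default_rate_table())
  sp <- cpp_mf_lif(matrix(nu5, 1, 5000), 1L, p, 0.1, 1)
  expect_equal(length(sp$fiber), 0)
  # the alternative shot-noise reading is also selectable and much weaker
  p2 <- mf_lif_params(sigma_form = "g_sqrt_Nnu")
  sp2 <- cpp_mf_lif(matrix(nu5, 1, 5000), 1L, p2, 0.1, 1)
  expect_lt(length(sp2$fiber), 3)
})

test_that("slow rate schedules alternate smoothed 300-ms plateaus", {
  sch <- make_slow_rate_schedule(60)
  expect_equal(length(sch$rate_hz), 3000)
  # plateau midpoints keep the target rates within 1 %
  mids_lo <- c(150, 750, 1350); mids_hi <- c(450, 1050, 1650)
  expect_true(all(abs(sch$rate_hz[mids_lo] - 10) < 0.1))
  expect_true(all(abs(sch$rate_hz[mids_hi] - 60) < 0.6))
  raw <- make_slow_rate_schedule(60, sigma_ms = 0)
  expect_true(all(raw$rate_hz %in% c(10, 60)))
  expect_error(make_slow_rate_schedule(5, lower_hz = 10), "upper_hz > lower")
})

test_that("burst schedules deliver about five spikes per fiber per burst", {
  sch <- make_burst_schedule(n_bursts = 1, rest_hz = 0)
  expect_equal(sum(sch$rate_hz) / 1000, 5)     # 500 Hz x 10 ms
  sch9 <- make_burst_schedule(rest_hz = 0, lead_ms = 50)
  on <- attr(sch9, "onsets_ms")
  expect_equal(length(on), 9)
  sp <- lif_mf_spikes(sch9, n_fibers = 40, seed = 6)
  # count bursts visible in the output trains
  per_burst <- vapply(on, function(t0)
    sum(sp$t_ms >= t0 & sp$t_ms < t0 + 12) / 40, numeric(1))
  expect_gte(sum(per_burst > 2), 8)
  expect_equal(mean(per_burst), 5, tolerance = 0.25)
})

test_that("probes are weak asynchronous epochs of the stated mass", {
  pr <- make_probe(rate_hz = 20, duration_ms = 20, delay_ms = 2)
  expect_equal(length(pr$rate_hz), 22)
  expect_equal(sum(pr$rate_hz) / 1000, 0.4)    # expected spikes per fiber
  expect_equal(sum(make_probe(rate_hz = 0)$rate_hz), 0)
})

test_that("patch selection follows rosette membership", {
  net <- tiny_net()
  p1 <- select_patch(net$mossy, c(80, 75), 60)
  expect_gt(length(p1$fibers), 0)
  r <- net$mossy$rosettes
  for (f in p1$fibers) {
    d2 <- (r$x[r$fiber == f] - 80)^2 + (r$y[r$fiber == f] - 75)^2
    expect_true(any(d2 <= 60^2))
  }
  expect_warning(select_patch(net$mossy, c(-5000, -5000), 1), "empty patch")
})

test_that("protocols give every fiber exactly one schedule", {
  net <- tiny_net()
  patch <- select_patch(net$mossy, c(80, 75), 60)
  prot <- stimulus_protocol(net$mossy, duration_ms = 500, patches = list(
    list(patch = patch, schedule = make_constant_schedule(60, 400),
         onset_ms = 100)))
  expect_equal(length(prot$group_of_fiber), nrow(net$mossy$fiber_origin))
  expect_true(all(prot$group_of_fiber[patch$fibers] == 2))
  expect_true(all(prot$rate_hz[1, ] == 5))
  expect_equal(unname(prot$rate_hz[2, c(50, 300)]), c(5, 60))
})

test_that("temporal-structure equalization clones mossy afferents", {
  net <- tiny_net()
  goc_pos <- net$somata$goc$pos
  p1 <- list(center = c(75, 75), radius_um = 70)
  p2 <- list(center = c(225, 75), radius_um = 70)
  g1 <- cells_in_patch(goc_pos, p1); g2 <- cells_in_patch(goc_pos, p2)
  expect_gt(length(g1), 0); expect_gt(length(g2), 0)
  eq <- suppressWarnings(equalize_temporal_structure(net, p1, p2, seed = 9))
  pairs <- attr(eq, "equalized_pairs")
  aff <- function(net, cell) sort(net$edges$mf_goc$pre[
    net$edges$mf_goc$post == cell])
  for (k in seq_len(nrow(pairs)))
    expect_identical(aff(eq, pairs[k, "dst"]), aff(eq, pairs[k, "src"]))
  # untouched cells keep their afferents
  untouched <- setdiff(seq_len(nrow(goc_pos)), pairs[, "dst"])
  for (cell in untouched[seq_len(min(5, length(untouched)))])
    expect_identical(aff(eq, cell), aff(net, cell))
  # equalizing a patch with itself permutes but preserves the afferent pool
  eqs <- suppressWarnings(equalize_temporal_structure(net, p1, p1, seed = 10))
  pool <- sort(unlist(lapply(g1, aff, net = net)))
  expect_identical(sort(unlist(lapply(g1, aff, net = eqs))), pool)
})
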