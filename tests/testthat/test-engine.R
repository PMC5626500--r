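# Engine contracts on hand-made micro circuits and the tiny fixture network.

mfspk <- function(t_ms, fiber = 1L) data.frame(fiber = fiber, t_ms = t_ms)

test_that("without mossy input granule cells stay silent", {
  net <- micro_net(n_grc = 3, n_goc = 1,
                   mf_grc = edge_df(1, 1:3))
  plan <- simulation_plan(200, dt_ms = 0.05, seed = 1)
  rec <- run_simulation(net, mfspk(numeric(0), integer(0)), plan,
                        disable = "extra_goc")
  expect_equal(nrow(rec$grc), 0)
})

test_that("identical seeds give identical records, and spike counts are
           invariant under cell relabeling", {
  net <- tiny_net()
  mf <- tiny_mf(400)
  plan <- simulation_plan(400, dt_ms = 0.05, seed = 3)
  r1 <- suppressWarnings(run_simulation(net, mf, plan))
  r2 <- suppressWarnings(run_simulation(net, mf, plan))
  expect_identical(r1$grc, r2$grc)
  expect_identical(r1$goc, r2$goc)
  r3 <- suppressWarnings(run_simulation(net, mf,
                                        simulation_plan(400, dt_ms = 0.05,
                                                        seed = 4)))
  expect_false(identical(r1$goc, r3$goc))   # engine noise differs
  expect_identical(nrow(r1$grc), nrow(r2$grc))
})

test_that("event delivery honours the per-edge conduction delay", {
  # one fiber driving one GrC through a known delay; the excitatory
  # conductance must not move the membrane before t_spike + delay
  for (delay in c(0.5, 2.5)) {
    net <- micro_net(n_grc = 1, n_goc = 1,
                     mf_grc = edge_df(1, 1, w = 5, delay_ms = delay))
    plan <- simulation_plan(20, dt_ms = 0.05, seed = 1,
                            record_voltage_grc = 1L)
    rec <- run_simulation(net, mfspk(5), plan, disable = "extra_goc")
    v <- rec$v_grc[, 1]
    t <- (seq_along(v)) * 0.05
    el <- net$cfg$neurons$grc$e_leak_mv
    moved <- which(abs(v - el) > 1e-4)
    expect_gt(t[min(moved)], 5 + delay - 0.11)
    expect_lt(t[min(moved)], 5 + delay + 0.5)
  }
})

test_that("gap-junction-coupled Golgi cells converge in potential", {
  cfg <- tiny_cfg()
  net <- micro_net(n_goc = 2, v_init_goc = c(-70, -52), cfg = cfg,
                   gaps = data.frame(i = 1, j = 2, dist_um = 10, g_ns = 2))
  # passive cells: no drive, no adaptation, threshold out of reach
  net$cfg$neurons$goc$i_drive_pa <- 0
  net$cfg$neurons$goc$v_thresh_mv <- 100
  plan <- simulation_plan(150, dt_ms = 0.05, seed = 1,
                          record_voltage_goc = c(1L, 2L))
  rec <- run_simulation(net, mfspk(numeric(0), integer(0)), plan,
                        disable = "extra_goc")
  dv <- abs(rec$v_goc[, 1] - rec$v_goc[, 2])
  expect_gt(dv[1], 10)
  expect_lt(dv[length(dv)], 0.5)
  expect_true(all(diff(dv) <= 1e-6))
})

test_that("a single mossy spike produces the calibrated conductance peaks", {
  # passive granule cell: the voltage deflection must reflect an AMPA
  # conductance peaking at gmax (weight 1, no depression on first release)
  net <- micro_net(n_grc = 1, n_goc = 1,
                   mf_grc = edge_df(1, 1, w = 1, delay_ms = 0.1))
  net$cfg$neurons$grc$v_thresh_mv <- 100    # keep it passive
  plan <- simulation_plan(400, dt_ms = 0.05, seed = 1,
                          record_voltage_grc = 1L)
  rec <- run_simulation(net, mfspk(5), plan, disable = "extra_goc")
  v <- rec$v_grc[, 1]
  expect_gt(max(v) - v[1], 1)     # clearly visible EPSP
  expect_lt(max(v), 0)            # bounded by the excitatory reversal
  # late NMDA/spillover tail decays back towards rest
  expect_lt(abs(v[length(v)] - v[1]), 0.5)
})

test_that("halving dt changes population rates by less than 2 %", {
  net <- tiny_net()
  mf <- tiny_mf(1000)
  r1 <- suppressWarnings(run_simulation(net, mf,
        simulation_plan(1000, dt_ms = 0.05, seed = 5)))
  r2 <- suppressWarnings(run_simulation(net, mf,
        simulation_plan(1000, dt_ms = 0.025, seed = 5)))
  expect_equal(mean_rate(r1, "grc", window = c(200, 1000)),
               mean_rate(r2, "grc", window = c(200, 1000)),
               tolerance = 0.02)
  goc1 <- mean_rate(r1, "goc", window = c(200, 1000))
  goc2 <- mean_rate(r2, "goc", window = c(200, 1000))
  expect_equal(goc1, goc2, tolerance = 0.05)
})

test_that("run records carry consistent metadata and export round-trips", {
  net <- tiny_net()
  mf <- tiny_mf(400)
  rec <- suppressWarnings(run_simulation(net, mf,
         simulation_plan(400, dt_ms = 0.05, seed = 3)))
  expect_true(all(rec$grc$t_ms >= 0 & rec$grc$t_ms <= 400 + 1e-6))
  expect_true(all(rec$goc$cell >= 1 & rec$goc$cell <= rec$n_goc))
  d <- tempfile()
  export_spikes(rec, d)
  back <- utils::read.table(file.path(d, "spikes_goc.txt"), header = TRUE)
  expect_equal(nrow(back), nrow(rec$goc))
  d2 <- tempfile()
  export_connectome(net, d2)
  man <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_equal(man$seed, 7)
  edges <- utils::read.csv(file.path(d2, "edges_mf_grc.csv"))
  expect_equal(nrow(edges), nrow(net$edges$mf_grc))
  expect_true(all(edges$weight_ns > 0))
  # manifest hashes are reproducible
  m1 <- run_manifest(net, rec)
  m2 <- run_manifest(net, rec)
  expect_identical(m1$connectome_hash, m2$connectome_hash)
  expect_identical(m1$spikes_hash, m2$spikes_hash)
})
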