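test_that("cell counts follow density times volume exactly", {
  cfg <- granular_config()
  som <- place_somata(cfg)
  expect_equal(nrow(som$goc$pos), 1995)
  expect_equal(nrow(som$grc$pos), 798000)
  g <- cfg$geometry
  for (pop in c("grc", "goc")) {
    p <- som[[pop]]$pos
    expect_true(all(p[, 1] >= 0 & p[, 1] <= g$transverse_um))
    expect_true(all(p[, 3] >= 0 & p[, 3] <= g$granular_um))
    expect_true(all(som[[pop]]$v_init_mv >= -75 & som[[pop]]$v_init_mv <= -60))
  }
  expect_true(all(abs(som$goc$soma_um / cfg$cells$goc_soma_um - 1) <= 0.2))
  expect_error(place_somata(granular_config(geometry =
    list(granular_um = 1e-9))), "volume")
})

test_that("mossy-fiber generator hits the printed fiber and rosette totals", {
  mf <- generate_mossy_fibers(granular_config())
  expect_lt(abs(nrow(mf$fiber_origin) / 2109 - 1), 0.15)
  expect_lt(abs(nrow(mf$rosettes) / 29519 - 1), 0.15)
  # strips are sagittally elongated
  spread <- aggregate(cbind(x, y) ~ fiber, mf$rosettes,
                      function(v) diff(range(v)))
  many <- table(mf$rosettes$fiber) >= 5
  expect_gt(mean(spread$y[many]), 3 * mean(spread$x[many]))
})

test_that("degenerate spread gives one rosette per fiber at its origin", {
  cfg <- granular_config(mossy = list(center_sd_sag_um = 0,
                                      n_clusters_mean = 1,
                                      rosettes_per_cluster_mean = 1,
                                      cluster_sd_sag_um = 0,
                                      rosette_sd_sag_um = 0,
                                      rosette_sd_trans_um = 0,
                                      margin_um = 1),
                         geometry = list(transverse_um = 300,
                                         sagittal_um = 300))
  mf <- suppressWarnings(generate_mossy_fibers(cfg))
  expect_equal(nrow(mf$rosettes), nrow(mf$fiber_origin))
  expect_equal(mf$rosettes$x, unname(mf$fiber_origin[mf$rosettes$fiber, "x"]))
  expect_equal(mf$rosettes$y, unname(mf$fiber_origin[mf$rosettes$fiber, "y"]))
})

test_that("overlap histogram counts distinct fibers per cube", {
  mk <- function(df) structure(list(rosettes = df), class = "gl_mossy")
  cfg <- granular_config(geometry = list(transverse_um = 100,
                                         sagittal_um = 100,
                                         granular_um = 100))
  one <- mk(data.frame(fiber = 1, x = 5, y = 5, z = 5))
  h1 <- overlap_histogram(one, 50, cfg)
  expect_equal(sum(h1), 1)
  expect_equal(unname(h1["1"] * 8), 1)   # one of eight cubes holds one fiber
  two <- mk(data.frame(fiber = c(1, 2), x = 5, y = 5, z = 5))
  h2 <- overlap_histogram(two, 50, cfg)
  expect_equal(unname(h2["2"] * 8), 1)
  expect_equal(unname(h2["1"]), 0)
  # uniform random rosettes match Poisson occupancy within sampling error
  set.seed(1)
  n <- 4000
  uni <- mk(data.frame(fiber = seq_len(n), x = runif(n, 0, 100),
                       y = runif(n, 0, 100), z = runif(n, 0, 100)))
  h <- overlap_histogram(uni, 25, cfg)
  lam <- n / 64
  pois <- stats::dpois(0:3, lam)
  expect_equal(unname(h[c("0", "1", "2", "3")]), pois, tolerance = 0.15)
})

test_that("point clouds have the prescribed geometry", {
  cfg <- tiny_cfg()
  som <- place_somata(cfg, seed = 3)
  cl <- build_point_clouds(som, cfg,
                           structures = c("ascending_axon", "parallel_fiber"),
                           cells = 1:5, seed = 3)
  aa <- cl$ascending_axon
  expect_equal(nrow(aa[aa$cell == 1, ]), 5)       # 200/50 + origin
  expect_equal(sort(unique(aa$path_um)), seq(0, 200, by = 50))
  pf <- cl$parallel_fiber
  expect_equal(nrow(pf[pf$cell == 1, ]), 267)     # 2 x 1000/7.5 arms + origin
  # parallel fibers run at the ascending-axon top
  expect_equal(mean(pf$z[pf$cell == 2]),
               unname(som$grc$pos[2, 3]) + 200, tolerance = 1)
  # zero jitter puts ascending-axon points exactly on the vertical axis
  cfg0 <- granular_config(clouds = list(jitter_sd_um = 0))
  som1 <- list(grc = list(pos = matrix(c(0, 0, 0), 1)), goc = som$goc)
  aa0 <- build_point_clouds(som1, cfg0, structures = "ascending_axon",
                            cells = 1)$ascending_axon
  expect_equal(aa0$x, rep(0, 5))
  expect_equal(aa0$y, rep(0, 5))
  expect_equal(aa0$z, seq(0, 200, by = 50))
})

test_that("dendritic cones have the stated heights and radii", {
  cfg <- granular_config()
  som <- place_somata(scale_network(cfg, "mini"), seed = 4)
  cl <- build_point_clouds(som, cfg, structures = c("apical_dendrite",
                                                    "basolateral_dendrite"),
                           seed = 4)
  api <- cl$apical_dendrite[cl$apical_dendrite$cell == 1, ]
  rel_z <- api$z - som$goc$pos[1, 3]
  expect_equal(max(rel_z), 332, tolerance = 2)
  horiz <- sqrt((api$x - som$goc$pos[1, 1])^2 + (api$y - som$goc$pos[1, 2])^2)
  expect_equal(max(horiz), 100, tolerance = 2)
  bas <- cl$basolateral_dendrite[cl$basolateral_dendrite$cell == 1, ]
  expect_equal(min(bas$z - som$goc$pos[1, 3]), -6, tolerance = 0.5)
})

test_that("grid-based radius search equals brute force on random points", {
  set.seed(42)
  pre <- matrix(runif(3000, 0, 100), ncol = 3)
  post <- matrix(runif(300, 0, 100), ncol = 3)
  pre_cell <- sample.int(200, 1000, replace = TRUE)
  r <- 12
  got <- connect_by_radius(pre, pre_cell, post, r)
  got <- got[order(got$post, got$pre), ]
  # brute-force all-pairs oracle
  ref <- do.call(rbind, lapply(seq_len(nrow(post)), function(j) {
    d <- sqrt(colSums((t(pre) - post[j, ])^2))
    hit <- d <= r
    if (!any(hit)) return(NULL)
    agg <- tapply(d[hit], pre_cell[hit], min)
    data.frame(pre = as.integer(names(agg)), post = j,
               dist_um = as.numeric(agg))
  }))
  ref <- ref[order(ref$post, ref$pre), ]
  expect_equal(got$pre, ref$pre)
  expect_equal(got$post, ref$post)
  expect_equal(got$dist_um, ref$dist_um, tolerance = 1e-12)
  # trivial geometry cases
  expect_equal(nrow(connect_by_radius(matrix(c(0, 0, 0), 1), 1L,
                                      matrix(c(3, 0, 0), 1), 1)), 0)
  expect_equal(nrow(connect_by_radius(matrix(0, 1, 3), 1L,
                                      matrix(0, 1, 3), 1e-6)), 1)
})

test_that("probability calibration hits the target or fails loudly", {
  expect_equal(calibrate_probability(rep(10, 100), 5), 0.5)
  expect_equal(calibrate_probability(rep(3, 10), 3), 1)
  expect_error(calibrate_probability(rep(4, 10), 8), "calibration error")
})

test_that("gap junctions are symmetric, unique and distance-decaying", {
  net <- tiny_net()
  gp <- net$gaps
  expect_true(all(gp$i < gp$j))
  expect_false(any(duplicated(gp[, c("i", "j")])))
  expect_true(all(gp$g_ns > 0))
  expect_equal(gp$g_ns, gap_junction_g(gp$dist_um), tolerance = 1e-12)
  inh <- net$edges$goc_goc
  expect_true(all(inh$pre != inh$post))
})

test_that("a built connectome satisfies its structural invariants", {
  net <- tiny_net()
  for (nm in names(net$edges)) {
    e <- net$edges[[nm]]
    expect_true(all(e$delay_ms >= 0), info = nm)
    expect_true(all(e$w > 0), info = nm)
    expect_false(any(duplicated(e[, c("pre", "post")])), info = nm)
  }
  # weight heterogeneity close to the configured CV
  w <- unlist(lapply(net$edges, `[[`, "w"))
  expect_equal(sd(w) / mean(w), 0.25, tolerance = 0.05)
  # parallel-fiber delays reflect path length at 0.3 m/s
  pf <- net$edges$pf_goc
  expect_equal(pf$delay_ms, pf$path_um / 300, tolerance = 1e-12)
  expect_true(all(pf$path_um >= 200))
})

test_that("builds are bit-identical under a fixed master seed", {
  cfg <- tiny_cfg()
  a <- build_network(cfg, seed = 123)
  b <- build_network(cfg, seed = 123)
  expect_identical(a$edges, b$edges)
  expect_identical(a$gaps, b$gaps)
  expect_identical(a$somata, b$somata)
  c2 <- build_network(cfg, seed = 124)
  expect_false(identical(a$edges$mf_grc, c2$edges$mf_grc))
})

test_that("convergence summary reports per-type statistics", {
  net <- tiny_net()
  s <- network_summary(net)
  expect_true(all(s$min <= s$mean & s$mean <= s$max))
  tc <- tiny_cfg()$connect$target_convergence
  got <- setNames(s$mean, s$type)
  for (nm in c("mf_grc", "mf_goc", "goc_grc"))
    expect_lt(abs(got[[nm]] / tc[[nm]] - 1), 0.2)
})
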