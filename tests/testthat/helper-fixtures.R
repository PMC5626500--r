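# Shared fixtures, built lazily once per test run.
#
# `tiny` is a mechanics-scale network (reduced GrC:GoC ratio and reduced
# parallel-fiber/ascending-axon convergence targets so the small candidate
# pools can reach them); it exercises every code path cheaply and is used
# for engine contracts (determinism, delays, coupling), not for the
# biological property checks, which run on study-condition volumes.

.fixtures <- new.env(parent = emptyenv())

tiny_cfg <- function() {
  granular_config(
    geometry = list(transverse_um = 300, sagittal_um = 150),
    cells = list(grc_per_goc = 50),
    connect = list(target_convergence = list(
      mf_grc = 4.5, mf_goc = 13.7, goc_grc = 8.4,
      aa_goc = 60, pf_goc = 150, goc_goc = 2.2, gap = 13.7)))
}

tiny_net <- function() {
  if (is.null(.fixtures$tiny_net))
    .fixtures$tiny_net <- build_network(tiny_cfg(), seed = 7L)
  .fixtures$tiny_net
}

tiny_mf <- function(duration_ms = 1000) {
  key <- paste0("tiny_mf_", duration_ms)
  if (is.null(.fixtures[[key]])) {
    prot <- stimulus_protocol(tiny_net()$mossy, duration_ms = duration_ms)
    .fixtures[[key]] <- mf_spikes(prot, seed = 11L)
  }
  .fixtures[[key]]
}

# a hand-made micro connectome (1 fiber, n_grc GrCs, n_goc GoCs) whose every
# edge is explicit; used to test event delivery and coupling contracts
micro_net <- function(n_grc = 1, n_goc = 2,
                      mf_grc = NULL, goc_grc = NULL, gaps = NULL,
                      v_init_goc = NULL, cfg = tiny_cfg()) {
  empty <- data.frame(pre = integer(), post = integer(),
                      dist_um = numeric(), w = numeric(),
                      delay_ms = numeric())
  ed <- function(e) if (is.null(e)) empty else e
  somata <- list(
    grc = list(pos = matrix(50, n_grc, 3), soma_um = rep(6, n_grc),
               v_init_mv = rep(cfg$neurons$grc$e_leak_mv, n_grc)),
    goc = list(pos = matrix(60, n_goc, 3), soma_um = rep(16, n_goc),
               v_init_mv = v_init_goc %||%
                 rep(cfg$neurons$goc$e_leak_mv, n_goc)))
  structure(list(
    cfg = cfg, seed = 1L, somata = somata,
    mossy = list(fiber_origin = matrix(0, 1, 2),
                 rosettes = data.frame(fiber = 1, x = 50, y = 50, z = 50)),
    edges = list(mf_grc = ed(mf_grc), mf_goc = empty, goc_grc = ed(goc_grc),
                 aa_goc = empty, pf_goc = empty, goc_goc = empty),
    gaps = if (is.null(gaps))
      data.frame(i = integer(), j = integer(), dist_um = numeric(),
                 g_ns = numeric()) else gaps,
    probs = list()), class = c("gl_connectome", "list"))
}

edge_df <- function(pre, post, w = 1, delay_ms = 0.1) {
  data.frame(pre = pre, post = post, dist_um = 0, w = w, delay_ms = delay_ms)
}
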