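## Network simulation front-end: kinetic precomputation (cascade eigenmodes,
## receptor normalization at the integration step), connectome-to-engine
## conversion, and the clock-driven run.

## modal decomposition of the cascade: injection and output coefficients
cascade_modes <- function(cas) {
  A <- cascade_matrix(cas)
  eg <- eigen(A)
  if (any(abs(Im(eg$values)) > 1e-10))
    stop("cascade matrix has complex eigenvalues; modal engine path invalid",
         call. = FALSE)
  V <- Re(eg$vectors)
  list(lambda = Re(eg$values), inj = solve(V)[, 1], out = V[2, ])
}

## peak of the discrete receptor-stage response to a unit release at the
## engine step dt (matches the engine update order exactly)
receptor_peak <- function(modes, tau_rise, tau_decay, dt_ms,
                          horizon_ms = 600) {
  z <- modes$inj
  dec <- exp(modes$lambda * dt_ms)
  c1r <- exp(-dt_ms / tau_rise); c2r <- tau_rise * (1 - c1r)
  c1d <- exp(-dt_ms / tau_decay); c2d <- tau_decay * (1 - c1d)
  r <- d <- 0
  gmax <- 0
  for (s in seq_len(ceiling(horizon_ms / dt_ms))) {
    z <- z * dec
    Tt <- sum(modes$out * z)
    r <- r * c1r + c2r * Tt
    d <- d * c1d + c2d * Tt
    g <- d - r
    if (g > gmax) gmax <- g
  }
  gmax
}

## all kinetic constants the engine needs, for a given dt
engine_kinetics <- function(cfg, dt_ms) {
  syn <- cfg$synapses
  modes <- cascade_modes(syn$cascade)
  nm <- syn$nmda_grc
  tau_nd_eff <- 1 / (1 / nm$tau_decay_ms + nm$desensitization_per_ms)
  a_pk <- receptor_peak(modes, syn$ampa_grc$tau_rise_ms,
                        syn$ampa_grc$tau_decay_ms, dt_ms)
  n_pk <- receptor_peak(modes, nm$tau_rise_ms, tau_nd_eff, dt_ms)
  vgrid <- seq(-120, 20, by = 0.25)
  gb <- syn$gaba_grc
  gq <- syn$gaba_goc
  list(
    cascade_lambda = modes$lambda, cascade_inj = modes$inj,
    cascade_out = modes$out,
    ampa_grc = list(tau_rise_ms = syn$ampa_grc$tau_rise_ms,
                    tau_decay_ms = syn$ampa_grc$tau_decay_ms,
                    norm = syn$ampa_grc$gmax_ns / a_pk),
    nmda_grc = list(tau_rise_ms = nm$tau_rise_ms, tau_decay_eff_ms = tau_nd_eff,
                    norm = nm$gmax_ns / n_pk),
    gaba_grc = list(tau_fast_ms = gb$tau_fast_ms, tau_slow_ms = gb$tau_slow_ms,
                    tau_rise_ms = gb$tau_rise_ms,
                    amp_fast = gb$gmax_ns * (1 - gb$slow_frac) *
                      double_exp_norm(gb$tau_rise_ms, gb$tau_fast_ms),
                    amp_slow = if (gb$slow_frac > 0)
                      gb$gmax_ns * gb$slow_frac *
                        double_exp_norm(gb$tau_rise_ms, gb$tau_slow_ms) else 0,
                    e_rev_mv = gb$e_rev_mv),
    ampa_mf_goc = list(tau_rise_ms = syn$ampa_mf_goc$tau_rise_ms,
                       tau_decay_ms = syn$ampa_mf_goc$tau_decay_ms,
                       norm = syn$ampa_mf_goc$gmax_ns *
                         double_exp_norm(syn$ampa_mf_goc$tau_rise_ms,
                                         syn$ampa_mf_goc$tau_decay_ms)),
    ## ascending-axon and parallel-fiber synapses share receptor kinetics;
    ## their different peak conductances are folded into the edge weights
    ampa_grc_goc = list(tau_rise_ms = syn$ampa_pf_goc$tau_rise_ms,
                        tau_decay_ms = syn$ampa_pf_goc$tau_decay_ms,
                        norm = double_exp_norm(syn$ampa_pf_goc$tau_rise_ms,
                                               syn$ampa_pf_goc$tau_decay_ms)),
    gaba_goc = list(tau_rise_ms = gq$tau_rise_ms, tau_fast_ms = gq$tau_fast_ms,
                    norm = gq$gmax_ns *
                      double_exp_norm(gq$tau_rise_ms, gq$tau_fast_ms),
                    e_rev_mv = gq$e_rev_mv),
    extra_goc = list(enabled = isTRUE(syn$extra_goc$enabled),
                     tau_decay_ms = syn$extra_goc$tau_decay_ms,
                     peak_g_ns = syn$extra_goc$peak_g_ns,
                     rate_per_ms = syn$extra_goc$n_synapses *
                       syn$extra_goc$rate_hz / 1000,
                     e_rev_mv = syn$extra_goc$e_rev_mv),
    tonic_grc = list(enabled = isTRUE(syn$tonic_grc$enabled),
                     g_ns = syn$tonic_grc$g_ns,
                     e_rev_mv = syn$tonic_grc$e_rev_mv),
    mg_table = nmda_voltage_factor(vgrid, nm$mg_mm, nm$k_mg_mm, nm$delta_v_mv),
    mg_v0 = -120, mg_dv = 0.25,
    release = syn$release,
    grc = cfg$neurons$grc, goc = cfg$neurons$goc
  )
}

edge_for_engine <- function(e, dt_ms, w_scale = 1) {
  list(pre = as.integer(e$pre), post = as.integer(e$post),
       dstep = pmax(1L, as.integer(round(e$delay_ms / dt_ms))),
       w = e$w * w_scale)
}

#' Run a network simulation
#'
#' Advances the full circuit with the clock-driven engine: mossy-fiber
#' spikes drive the glutamate-diffusion cascade onto granule cells (AMPA +
#' voltage-dependent NMDA) and double-exponential AMPA onto Golgi cells;
#' granule-cell spikes travel along ascending axons and parallel fibers to
#' Golgi cells; Golgi cells inhibit granule cells (fast + spillover GABA)
#' and each other, are coupled by gap junctions, and receive Poissonian
#' extracortical inhibition. Identical seeds, connectome and plan give
#' bit-identical spike records.
#'
#' @param net a `gl_connectome`.
#' @param mf data.frame of mossy-fiber spikes (`fiber`, `t_ms`, sorted).
#' @param plan a `gl_plan` from [simulation_plan()].
#' @param synapses optional overrides merged into `net$cfg$synapses` (e.g.
#'   `list(nmda_grc = list(gmax_ns = 0.1))`).
#' @param neurons optional overrides merged into `net$cfg$neurons`.
#' @param disable character vector of connection groups to silence:
#'   subsets of `c("goc_grc", "goc_goc", "gap", "aa_goc", "pf_goc",
#'   "mf_goc", "extra_goc")`.
#' @return a `gl_record`: `grc` and `goc` spike data.frames (`cell`,
#'   `t_ms`), the input `mf` spikes, voltage traces if requested, and run
#'   metadata.
#' @export
run_simulation <- function(net, mf, plan, synapses = list(),
                           neurons = list(), disable = character()) {
  cfg <- net$cfg
  if (length(synapses))
    cfg$synapses <- modify_config(cfg$synapses, synapses)
  if (length(neurons))
    cfg$neurons <- modify_config(cfg$neurons, neurons)
  dt <- plan$dt_ms
  kin <- engine_kinetics(cfg, dt)
  if ("extra_goc" %in% disable) kin$extra_goc$enabled <- FALSE

  n_grc <- nrow(net$somata$grc$pos)
  n_goc <- nrow(net$somata$goc$pos)
  n_fiber <- nrow(net$mossy$fiber_origin)
  syn <- cfg$synapses

  empty <- data.frame(pre = integer(), post = integer(), delay_ms = numeric(),
                      w = numeric())
  pick <- function(nm) if (nm %in% disable) empty else net$edges[[nm]]
  e_net <- list(
    n_grc = n_grc, n_goc = n_goc, n_fiber = n_fiber,
    mf_grc = edge_for_engine(net$edges$mf_grc, dt),
    mf_goc = edge_for_engine(pick("mf_goc"), dt),
    goc_grc = edge_for_engine(pick("goc_grc"), dt),
    aa_goc = edge_for_engine(pick("aa_goc"), dt,
                             syn$ampa_aa_goc$gmax_ns),
    pf_goc = edge_for_engine(pick("pf_goc"), dt,
                             syn$ampa_pf_goc$gmax_ns),
    goc_goc = edge_for_engine(pick("goc_goc"), dt),
    gap_i = if ("gap" %in% disable) integer() else as.integer(net$gaps$i),
    gap_j = if ("gap" %in% disable) integer() else as.integer(net$gaps$j),
    gap_g = if ("gap" %in% disable) numeric() else net$gaps$g_ns,
    v_init_grc = net$somata$grc$v_init_mv,
    v_init_goc = net$somata$goc$v_init_mv,
    mf_spike_t = mf$t_ms, mf_spike_f = as.integer(mf$fiber)
  )
  n_steps <- as.integer(ceiling(plan$duration_ms / dt))
  res <- cpp_run_network(e_net, kin, list(
    dt_ms = dt, n_steps = n_steps, seed = child_seed(plan$seed, 55),
    record_voltage_grc = plan$record_voltage_grc,
    record_voltage_goc = plan$record_voltage_goc))
  structure(list(
    grc = data.frame(cell = res$grc_cell, t_ms = res$grc_t),
    goc = data.frame(cell = res$goc_cell, t_ms = res$goc_t),
    mf = mf,
    v_grc = res$v_grc, v_goc = res$v_goc,
    duration_ms = plan$duration_ms, dt_ms = dt, seed = plan$seed,
    n_grc = n_grc, n_goc = n_goc, n_fiber = n_fiber),
    class = c("gl_record", "list"))
}

#' Mean population firing rate of a record
#'
#' @param record a `gl_record`.
#' @param pop `"grc"`, `"goc"` or `"mf"`.
#' @param cells optional subset of cell/fiber ids (all by default).
#' @param window optional `c(t0, t1)` ms window (whole record by default).
#' @return mean rate in Hz per cell.
#' @export
mean_rate <- function(record, pop = c("grc", "goc", "mf"), cells = NULL,
                      window = NULL) {
  pop <- match.arg(pop)
  sp <- record[[pop]]
  n <- switch(pop, grc = record$n_grc, goc = record$n_goc,
              mf = record$n_fiber)
  if (is.null(cells)) cells <- seq_len(n)
  if (is.null(window)) window <- c(0, record$duration_ms)
  key <- if (pop == "mf") sp$fiber else sp$cell
  cnt <- sum(key %in% cells & sp$t_ms >= window[1] & sp$t_ms < window[2])
  cnt / length(cells) / ((window[2] - window[1]) / 1000)
}
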