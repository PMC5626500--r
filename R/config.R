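#' Default network configuration
#'
#' Returns the full configuration of the granular-layer model: layer
#' geometry, cell densities, mossy-fiber rosette field parameters, point-cloud
#' geometry of axons and dendrites, connection radii and target convergences,
#' synaptic and gap-junction kinetics, surrogate neuron parameters, and the
#' master seed. Every physical quantity carries its unit in the key name
#' (`_um`, `_ms`, `_hz`, `_ns`, `_mv`, `_pa`, `_pf`).
#'
#' The defaults describe a cerebellar granular-layer volume of
#' 1500 x 700 um (transverse x sagittal) with a 200-um-thick granular layer,
#' a 30-um Purkinje-cell layer and a 200-um molecular layer. Golgi cells
#' (GoCs) are placed at 9500 cells/mm^3 and granule cells (GrCs) at 400 GrCs
#' per GoC, which yields 1995 GoCs and 798,000 GrCs at full scale. Mossy
#' fibers enter at 5000 fibers/mm^2 and deposit sagittally elongated strips
#' of rosettes.
#'
#' @param ... named overrides, e.g. `granular_config(geometry =
#'   list(sagittal_um = 300))`. Overrides are merged recursively into the
#'   defaults; unknown keys are an error.
#' @return an object of class `gl_config` (a nested named list).
#' @export
granular_config <- function(...) {
  cfg <- list(
    geometry = list(
      transverse_um = 1500,
      sagittal_um   = 700,
      granular_um   = 200,
      pc_layer_um   = 30,
      molecular_um  = 200
    ),
    cells = list(
      goc_density_per_mm3 = 9500,
      grc_per_goc         = 400,
      grc_soma_um         = 6,
      goc_soma_um         = 16,
      soma_jitter_frac    = 0.20,   # diameters varied by up to +/- 20 %
      v_init_range_mv     = c(-75, -60)
    ),
    mossy = list(
      areal_density_per_mm2 = 5000,
      margin_um             = 750,   # boundary band of external fibers
      # parametric rosette-cluster model (sagittal strips): only a fraction
      # of passing fibers arborize locally; the rest traverse without
      # synapsing, which reconciles the areal fiber density with the
      # instantiated fiber and rosette totals at uniform rosette density
      rosette_bearing_frac  = 0.311,
      center_sd_sag_um      = 250,   # displacement of strip center along fiber
      n_clusters_mean       = 2.0,   # clusters ~ 1 + Poisson(mean - 1)
      rosettes_per_cluster_mean = 9, # rosettes ~ 1 + Poisson(mean - 1)
      cluster_sd_sag_um     = 110,   # cluster centers along the strip
      rosette_sd_sag_um     = 30,
      rosette_sd_trans_um   = 9
    ),
    clouds = list(
      aa_length_um        = 200,
      aa_spacing_um       = 50,
      pf_half_length_um   = 1000,
      pf_spacing_um       = 7.5,
      jitter_sd_um        = 1,
      apical_cone_height_um      = 332,
      basolateral_cone_height_um = 6,
      dendrite_circle_radius_um  = 100,
      dendrite_spacing_um        = 5,
      apical_angles_deg      = c(30, 120),
      basolateral_angles_deg = c(-20, -240),
      dendrite_angle_sd_deg  = 10,
      goc_axon_half_extent_um = c(45, 160, 75),  # transverse, sagittal, vertical
      goc_axon_n_points       = 512
    ),
    connect = list(
      mf_grc_radius_um  = 30,
      mf_goc_radius_um  = 100,
      goc_grc_radius_um = 15,
      aa_goc_radius_um  = 30,
      pf_goc_radius_um  = 5,
      target_convergence = list(
        mf_grc  = 4.5,
        mf_goc  = 13.7,
        goc_grc = 8.4,
        aa_goc  = 554,
        pf_goc  = 4759,
        goc_goc = 2.2,
        gap     = 13.7
      ),
      # GoC-GoC coupling: Boltzmann probability p(x) = pmax / (1 + exp((x - x0)/k)).
      # Gap-junction curve fitted so the mean in a 200-um-thick layer at
      # 9500 GoC/mm^3 is 13.7 junctions/GoC; the inhibition curve is
      # anchored at p(50 um) = 0.20 with its midpoint fitted so the layer
      # mean is 2.2 inputs/GoC.
      gap_boltzmann = list(pmax = 0.90, x0_um = 53.61, k_um = 25),
      inh_boltzmann = list(pmax = 0.5038, x0_um = 47.91, k_um = 5),
      goc_inh_p50   = 0.20,          # experimental anchor, used in validation
      gap_beta_ns   = 1.659,
      gap_lambda_per_um = 0.01259,
      weight_cv     = 0.25,
      velocity_pf_m_per_s = 0.3,
      velocity_mf_m_per_s = 2,
      velocity_goc_m_per_s = 2
    ),
    synapses = list(
      # cascade approximation of glutamate diffusion at the MF-GrC relay
      cascade = list(
        rd_um = 1.03, d_um2_per_ms = 4,
        r_fast = 4, r_t = 6.2, r_t1 = 20, r_1t = 9.09,
        r_12 = 4.9, r_21 = 1.71, r_23 = 0.55, r_32 = 0.333
      ),
      release = list(y0 = 1, depression_frac = 0.25, recovery_ms = 50),
      ampa_grc = list(tau_rise_ms = 0.6, tau_decay_ms = 1.8,
                      gmax_ns = 0.32, e_rev_mv = 0),
      nmda_grc = list(tau_rise_ms = 8, tau_decay_ms = 52,
                      gmax_ns = 0.90, e_rev_mv = 0,
                      mg_mm = 1, k_mg_mm = 1.77, delta_v_mv = 22.4,
                      desensitization_per_ms = 12e-4),
      gaba_grc = list(tau_rise_ms = 3, tau_fast_ms = 5, tau_slow_ms = 35,
                      slow_frac = 0.10, gmax_ns = 0.42, e_rev_mv = -75),
      tonic_grc = list(g_ns = 0.088, e_rev_mv = -73, enabled = FALSE),
      ampa_mf_goc = list(tau_rise_ms = 0.5, tau_decay_ms = 1.5,
                         gmax_ns = 0.35, e_rev_mv = 0),
      ampa_aa_goc = list(tau_rise_ms = 0.5, tau_decay_ms = 1.2,
                         gmax_ns = 0.012, e_rev_mv = 0),
      ampa_pf_goc = list(tau_rise_ms = 0.5, tau_decay_ms = 1.2,
                         gmax_ns = 0.006, e_rev_mv = 0),
      gaba_goc = list(tau_rise_ms = 1, tau_fast_ms = 5, tau_slow_ms = 35,
                      slow_frac = 0, gmax_ns = 0.3, e_rev_mv = -75),
      extra_goc = list(n_synapses = 150, peak_g_ns = 0.180,
                       tau_decay_ms = 5, rate_hz = 16, e_rev_mv = -75,
                       enabled = TRUE)
    ),
    neurons = list(
      grc = list(c_pf = 3.1, g_leak_ns = 0.43, e_leak_mv = -74,
                 v_thresh_mv = -42, v_reset_mv = -63, refractory_ms = 1.5,
                 adapt_b_pa = 0, adapt_tau_ms = 100, i_drive_pa = 0,
                 block_v_mv = 1e9),
      goc = list(c_pf = 76, g_leak_ns = 3.6, e_leak_mv = -62,
                 v_thresh_mv = -50, v_reset_mv = -60, refractory_ms = 2,
                 adapt_b_pa = 90, adapt_tau_ms = 120, i_drive_pa = 105,
                 block_v_mv = -8,
                 # voltage-time area of the presynaptic action potential
                 # transmitted through a gap junction (spikelet), mV*ms
                 gap_spikelet_mv_ms = 30)
    ),
    master_seed = 42L
  )
  class(cfg) <- c("gl_config", "list")
  overrides <- list(...)
  if (length(overrides)) cfg <- modify_config(cfg, overrides)
  validate_config(cfg)
  cfg
}

## recursive merge with key checking
modify_config <- function(cfg, overrides) {
  stopifnot(is.list(overrides))
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg))
      stop("unknown configuration key: '", nm, "'", call. = FALSE)
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(overrides[[nm]]))) {
      cfg[[nm]] <- modify_config(cfg[[nm]], overrides[[nm]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  cfg
}

#' Validate a network configuration
#'
#' Checks the physical invariants of a configuration: positive extents,
#' densities, radii and velocities, probabilities in \[0, 1\], and kinetic
#' time constants ordered `tau_rise < tau_decay`.
#'
#' @param cfg a `gl_config` object.
#' @return `cfg`, invisibly; stops with an informative error otherwise.
#' @export
validate_config <- function(cfg) {
  geo <- cfg$geometry
  if (any(unlist(geo) <= 0))
    stop("configuration error: all layer extents must be > 0", call. = FALSE)
  if (cfg$cells$goc_density_per_mm3 <= 0 || cfg$cells$grc_per_goc <= 0)
    stop("configuration error: cell densities must be > 0", call. = FALSE)
  if (cfg$mossy$areal_density_per_mm2 <= 0)
    stop("configuration error: mossy-fiber density must be > 0", call. = FALSE)
  radii <- unlist(cfg$connect[grep("_radius_um$", names(cfg$connect))])
  if (any(radii <= 0))
    stop("configuration error: connection radii must be > 0", call. = FALSE)
  vel <- unlist(cfg$connect[grep("^velocity_", names(cfg$connect))])
  if (any(vel <= 0))
    stop("configuration error: conduction velocities must be > 0", call. = FALSE)
  for (nm in names(cfg$synapses)) {
    s <- cfg$synapses[[nm]]
    if (!is.null(s$tau_rise_ms) && !is.null(s$tau_decay_ms) &&
        s$tau_rise_ms >= s$tau_decay_ms)
      stop("parameter error: tau_rise must be < tau_decay in synapses$", nm,
           call. = FALSE)
  }
  p50 <- cfg$connect$goc_inh_p50
  if (p50 < 0 || p50 > 1)
    stop("configuration error: goc_inh_p50 must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' Granular-layer volume in mm^3
#' @param cfg a `gl_config`.
#' @return volume of the granular layer (not the full slice) in mm^3.
#' @export
granular_volume_mm3 <- function(cfg) {
  g <- cfg$geometry
  g$transverse_um * g$sagittal_um * g$granular_um * 1e-9
}

#' Rescale a configuration to a named preset
#'
#' Presets shrink the tissue footprint while leaving densities, radii,
#' kinetics and per-cell statistics untouched, so that per-cell convergence
#' and firing statistics of interior cells are preserved:
#' \describe{
#'   \item{full}{1500 x 700 um, the complete model (1995 GoCs).}
#'   \item{slab}{1500 x 300 um sagittal slab; keeps the full
#'     parallel-fiber axis.}
#'   \item{strip}{1500 x 100 um sagittal strip; full transverse axis at
#'     a fraction of the cell count, used for long simulations.}
#'   \item{mini}{600 x 200 um; small volume for quick runs and tests.}
#' }
#'
#' @param cfg a `gl_config`.
#' @param preset one of `"full"`, `"slab"`, `"strip"`, `"mini"`.
#' @return the rescaled `gl_config`.
#' @export
scale_network <- function(cfg, preset = c("full", "slab", "strip", "mini")) {
  preset <- match.arg(preset)
  dims <- switch(preset,
    full = c(1500, 700),
    slab = c(1500, 300),
    strip = c(1500, 100),
    mini = c(600, 200))
  modify_config(cfg, list(geometry = list(transverse_um = dims[1],
                                          sagittal_um = dims[2])))
}

#' Load a configuration from YAML
#'
#' Reads a YAML document of (possibly partial) configuration overrides and
#' merges it into the package defaults. An empty document yields the full
#' default configuration. Unknown keys and out-of-range values raise errors
#' naming the offending key.
#'
#' @param path path to a YAML file.
#' @return a validated `gl_config`.
#' @export
load_config <- function(path) {
  doc <- yaml::read_yaml(path)
  cfg <- granular_config()
  if (!is.null(doc) && length(doc)) cfg <- modify_config(cfg, doc)
  validate_config(cfg)
  cfg
}

#' Save a configuration to YAML
#' @param cfg a `gl_config`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Simulation plan
#'
#' @param duration_ms biological time to simulate.
#' @param dt_ms integration step. The default 0.025 ms resolves the fastest
#'   synaptic rise constant (0.5 ms) twentyfold; steps above one tenth of the
#'   fastest rise constant trigger a warning.
#' @param seed integer seed controlling initial conditions and input noise.
#' @param record_voltage_grc,record_voltage_goc cell indices (1-based) whose
#'   membrane potential is recorded at every step.
#' @param cfg configuration (used only to check `dt_ms` against the fastest
#'   synaptic rise constant).
#' @return an object of class `gl_plan`.
#' @export
simulation_plan <- function(duration_ms, dt_ms = 0.025, seed = 1L,
                            record_voltage_grc = integer(),
                            record_voltage_goc = integer(),
                            cfg = NULL) {
  stopifnot(duration_ms > 0, dt_ms > 0)
  if (!is.null(cfg)) {
    rises <- unlist(lapply(cfg$synapses, `[[`, "tau_rise_ms"))
    if (length(rises) && dt_ms > min(rises) / 10)
      warning("dt_ms = ", dt_ms, " exceeds one tenth of the fastest synaptic ",
              "rise constant (", min(rises), " ms)")
  }
  structure(list(duration_ms = duration_ms, dt_ms = dt_ms,
                 seed = as.integer(seed),
                 record_voltage_grc = as.integer(record_voltage_grc),
                 record_voltage_goc = as.integer(record_voltage_goc)),
            class = c("gl_plan", "list"))
}

## diffusion time constant of the cascade, tau_D = 100 R_d^2 / (4 D)  [ms]
cascade_tau_d <- function(cas) 100 * cas$rd_um^2 / (4 * cas$d_um2_per_ms)

## derive a child seed from a master seed; kept below 2^31
child_seed <- function(master, k) {
  (as.numeric(master) * 48271 + 11 * k) %% 2147483629
}
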