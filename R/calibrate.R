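## Calibration of the surrogate point-neuron circuit: synaptic peak
## conductances are scaled until the network reproduces the target baseline
## rates under 5-Hz mossy-fiber drive (GrC ~1 Hz; ~6-fold GrC increase
## without inhibition; GoC ~8.2 Hz with the 16-Hz extracortical dendritic
## inhibition).

#' Calibrate surrogate neuron/synapse conductances
#'
#' Multiplicative coordinate search over three conductance scales on a
#' reduced-network harness:
#' \enumerate{
#'   \item `s_exc` (mossy-fiber AMPA + NMDA onto GrCs), tuned so the GrC
#'     rate with Golgi inhibition disabled hits `grc_noinh_hz`;
#'   \item `s_goc` (all excitation onto GoCs), tuned to `goc_hz`;
#'   \item `s_inh` (GoC GABA onto GrCs), tuned to `grc_hz`;
#' }
#' steps 2 and 3 are alternated because Golgi rate and granule rate are
#' mutually coupled through the feedback loop. Each evaluation is a full
#' network simulation; rates are measured after a settling transient.
#'
#' @param net a `gl_connectome` (the calibration harness; per-cell
#'   statistics transfer to other volumes because convergences are
#'   calibrated per build).
#' @param mf mossy-fiber spikes for the harness at 5-Hz background.
#' @param plan a `gl_plan`; `duration_ms` is the evaluation window plus
#'   `settle_ms`.
#' @param targets list `grc_hz`, `grc_noinh_hz`, `goc_hz`.
#' @param settle_ms discarded transient.
#' @param max_inner bisection iterations per coordinate.
#' @param max_outer alternations of steps 2-3.
#' @param tol relative tolerance on each target.
#' @param init starting scales (warm start for refinement runs); a named
#'   vector `c(s_exc =, s_inh =, s_goc =)`.
#' @param skip_exc skip step 1 and keep `init[["s_exc"]]` (for warm-started
#'   refinements of the feedback loop only).
#' @param quiet suppress progress output.
#' @return list `scales` (`s_exc`, `s_inh`, `s_goc`), `cfg` (configuration
#'   with calibrated peak conductances baked in), `achieved` rates,
#'   `residuals` (relative errors), `history` (all evaluations).
#' @export
calibrate_surrogates <- function(net, mf, plan,
                                 targets = list(grc_hz = 1.01,
                                                grc_noinh_hz = 6.06,
                                                goc_hz = 8.18),
                                 settle_ms = 500, max_inner = 6,
                                 max_outer = 2, tol = 0.04,
                                 init = c(s_exc = 1, s_inh = 1, s_goc = 1),
                                 skip_exc = FALSE, quiet = TRUE) {
  base <- net$cfg$synapses
  win <- c(settle_ms, plan$duration_ms)
  history <- list()
  say <- function(...) if (!quiet) message(...)

  overrides <- function(s) list(
    ampa_grc = list(gmax_ns = base$ampa_grc$gmax_ns * s[["s_exc"]]),
    nmda_grc = list(gmax_ns = base$nmda_grc$gmax_ns * s[["s_exc"]]),
    gaba_grc = list(gmax_ns = base$gaba_grc$gmax_ns * s[["s_inh"]]),
    ampa_mf_goc = list(gmax_ns = base$ampa_mf_goc$gmax_ns * s[["s_goc"]]),
    ampa_aa_goc = list(gmax_ns = base$ampa_aa_goc$gmax_ns * s[["s_goc"]]),
    ampa_pf_goc = list(gmax_ns = base$ampa_pf_goc$gmax_ns * s[["s_goc"]]))

  evaluate <- function(s, disable = character()) {
    rec <- suppressWarnings(run_simulation(net, mf, plan,
                                           synapses = overrides(s),
                                           disable = disable))
    out <- c(grc = mean_rate(rec, "grc", window = win),
             goc = mean_rate(rec, "goc", window = win))
    history[[length(history) + 1]] <<- c(s, out,
                                         noinh = as.numeric("goc_grc" %in% disable))
    out
  }

  s <- init

  ## robust monotone search in log-space: expand a bracket around the
  ## target, then bisect; the rate response to each scale is steep and
  ## threshold-like, so proportional updates overshoot
  bisect_scale <- function(name, rate_of, target, s0, increasing = TRUE,
                           label = name) {
    f <- function(sv) {
      s[[name]] <<- sv
      r <- rate_of()
      say(sprintf("%s %.4g -> %.2f Hz", label, sv, r))
      r
    }
    lo <- hi <- s0
    r0 <- f(s0)
    if (abs(r0 / target - 1) < tol) return(s0)
    go_up <- xor(r0 < target, !increasing)
    for (k in seq_len(8)) {
      if (go_up) { lo <- hi; hi <- hi * 4 } else { hi <- lo; lo <- lo / 4 }
      r <- f(if (go_up) hi else lo)
      if (abs(r / target - 1) < tol) return(if (go_up) hi else lo)
      if ((r0 < target) != (r < target)) break   # target bracketed
      if (k == 8) warning("calibration bracket not found for ", name)
    }
    best <- if (go_up) hi else lo
    for (it in seq_len(max_inner)) {
      mid <- sqrt(lo * hi)
      r <- f(mid)
      best <- mid
      if (abs(r / target - 1) < tol) break
      if (xor(r < target, !increasing)) lo <- mid else hi <- mid
    }
    best
  }

  ## step 1: GrC excitation against the disinhibited target
  if (!skip_exc) s[["s_exc"]] <- bisect_scale("s_exc",
    function() evaluate(s, disable = "goc_grc")[["grc"]],
    targets$grc_noinh_hz, s[["s_exc"]], increasing = TRUE,
    label = "s_exc (GrC, no inhibition)")

  ## steps 2-3: Golgi excitation and granule inhibition, alternated
  for (outer in seq_len(max_outer)) {
    s[["s_goc"]] <- bisect_scale("s_goc",
      function() evaluate(s)[["goc"]], targets$goc_hz, s[["s_goc"]],
      increasing = TRUE, label = "s_goc (GoC)")
    s[["s_inh"]] <- bisect_scale("s_inh",
      function() evaluate(s)[["grc"]], targets$grc_hz, s[["s_inh"]],
      increasing = FALSE, label = "s_inh (GrC)")
  }

  ## the two feedback-coupled targets are alternated, so the last iterate
  ## can sit off the joint fixed point; keep the evaluated (s_inh, s_goc)
  ## pair with the smallest worst-case residual instead
  full <- Filter(function(h) h[["noinh"]] == 0 &&
                   h[["s_exc"]] == s[["s_exc"]], history)
  worst <- vapply(full, function(h)
    max(abs(h[["grc"]] / targets$grc_hz - 1),
        abs(h[["goc"]] / targets$goc_hz - 1)), numeric(1))
  best <- full[[which.min(worst)]]
  s[["s_inh"]] <- best[["s_inh"]]; s[["s_goc"]] <- best[["s_goc"]]
  noinh <- evaluate(s, disable = "goc_grc")[["grc"]]
  achieved <- list(grc_hz = best[["grc"]], goc_hz = best[["goc"]],
                   grc_noinh_hz = noinh)
  residuals <- list(
    grc = achieved$grc_hz / targets$grc_hz - 1,
    goc = achieved$goc_hz / targets$goc_hz - 1,
    grc_noinh = achieved$grc_noinh_hz / targets$grc_noinh_hz - 1)
  cfg <- net$cfg
  cfg$synapses <- modify_config(cfg$synapses, overrides(s))
  list(scales = as.list(s), cfg = cfg, achieved = achieved,
       residuals = residuals, history = history)
}

#' Save a calibration result as a JSON parameter manifest
#' @param cal result of [calibrate_surrogates()].
#' @param path destination JSON file.
#' @param seed the seed used for the harness (stored in the manifest).
#' @return `path`, invisibly.
#' @export
save_calibration <- function(cal, path, seed = NA_integer_) {
  jsonlite::write_json(list(scales = cal$scales, achieved = cal$achieved,
                            residuals = cal$residuals, seed = seed,
                            gmax_ns = list(
                              ampa_grc = cal$cfg$synapses$ampa_grc$gmax_ns,
                              nmda_grc = cal$cfg$synapses$nmda_grc$gmax_ns,
                              gaba_grc = cal$cfg$synapses$gaba_grc$gmax_ns,
                              ampa_mf_goc = cal$cfg$synapses$ampa_mf_goc$gmax_ns,
                              ampa_aa_goc = cal$cfg$synapses$ampa_aa_goc$gmax_ns,
                              ampa_pf_goc = cal$cfg$synapses$ampa_pf_goc$gmax_ns)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Apply a saved calibration manifest to a configuration
#' @param cfg a `gl_config`.
#' @param path JSON manifest from [save_calibration()], or the packaged
#'   default manifest when `NULL`.
#' @return the configuration with calibrated peak conductances.
#' @export
apply_calibration <- function(cfg, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "calibration.json", package = "granet")
  if (!nzchar(path) || !file.exists(path))
    stop("calibration manifest not found", call. = FALSE)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in names(man$gmax_ns))
    cfg$synapses[[nm]]$gmax_ns <- as.numeric(man$gmax_ns[[nm]])
  cfg
}
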