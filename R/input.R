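## Mossy-fiber input generation: noisy-LIF rate coder, rate-table
## calibration, stimulation paradigms (background / patches / slow rate
## modulation / bursts / probes) and temporal-structure equalization.

#' Mossy-fiber LIF parameters
#'
#' The noisy leaky integrate-and-fire rate coder that converts a target rate
#' `nu(t)` into spike trains: `dV/dt = -(V - E)/tau + beta*mu(t) +
#' sigma(t)*xi(t)` with `mu = g*N*nu`, Gaussian noise `xi` redrawn every
#' `noise_update_ms`, threshold -60 mV, reset to E after a 1.1-ms refractory
#' period. With the default `sigma_form = "gN_sqrt_nu"`
#' (`sigma = g*N*sqrt(nu)`) and `beta = 0.01` the drift stays far below
#' threshold and the fiber fires on noise fluctuations; the alternative
#' shot-noise reading `"g_sqrt_Nnu"` (`sigma = g*sqrt(N*nu)`) is selectable
#' for comparison.
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
mf_lif_params <- function(...) {
  p <- list(tau_ms = 1, e_mv = -70, threshold_mv = -60, refractory_ms = 1.1,
            n = 1000, g_uv_per_ms = 5, beta = 0.01, noise_update_ms = 1,
            sigma_form = "gN_sqrt_nu")
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  p
}

#' Calibrate the nu-to-rate table of the mossy-fiber LIF
#'
#' Simulates fibers at constant `nu` over a grid and tabulates the realized
#' output rate. The table is required to be monotone increasing (calibration
#' failure otherwise) and is inverted by linear interpolation to drive
#' fibers at target firing rates.
#'
#' @param p parameters from [mf_lif_params()].
#' @param nu_grid grid of constant `nu` values.
#' @param dur_ms simulated duration per grid point.
#' @param n_fibers independent fibers averaged per grid point.
#' @param seed integer seed.
#' @return data.frame `nu`, `rate_hz`, strictly increasing in `nu`.
#' @export
calibrate_rate_table <- function(p = mf_lif_params(),
                                 nu_grid = c(0, 0.25, 0.5, 0.75, 1, 1.125,
                                             1.25, 1.375, 1.5, 1.625, 1.75,
                                             2, 2.25, 2.5, 2.75, 3, 3.5, 4,
                                             4.5, 5, 6, 7, 8.5, 10, 12, 14,
                                             17, 20, 25, 30, 37, 45, 55, 70,
                                             85, 100, 125, 150, 185, 220,
                                             270, 330, 400, 500, 650, 850,
                                             1100, 1500, 2000),
                                 dur_ms = 20000, n_fibers = 16, seed = 1L) {
  nu_grid <- sort(nu_grid)
  nms <- as.integer(dur_ms)
  nu_mat <- matrix(rep(nu_grid, each = nms), nrow = length(nu_grid),
                   byrow = TRUE)
  grp <- rep(seq_along(nu_grid), each = n_fibers)
  sp <- cpp_mf_lif(nu_mat, as.integer(grp), p, 0.1, child_seed(seed, 7))
  counts <- tabulate(grp[sp$fiber], nbins = length(nu_grid))
  rate <- counts / n_fibers / (dur_ms / 1000)
  ok <- diff(rate) >= 0
  if (!all(ok | diff(nu_grid) == 0))
    stop("calibration failure: nu-to-rate table is not monotone", call. = FALSE)
  data.frame(nu = nu_grid, rate_hz = rate)
}

## package-level cache for the default rate table
.granet_cache <- new.env(parent = emptyenv())

default_rate_table <- function(p = mf_lif_params()) {
  key <- paste0("rate_table_", substr(rlang_hash(p), 1, 12))
  if (is.null(.granet_cache[[key]]))
    .granet_cache[[key]] <- calibrate_rate_table(p)
  .granet_cache[[key]]
}

rlang_hash <- function(x) paste(deparse(x), collapse = "")

#' Invert the rate table
#'
#' Linear interpolation of `nu` for a vector of target output rates; rates
#' outside the calibrated range trigger an extrapolation warning and are
#' clamped to the table ends.
#'
#' @param rate_hz target rates.
#' @param table calibration table from [calibrate_rate_table()].
#' @return `nu` values.
#' @export
nu_for_rate <- function(rate_hz, table) {
  if (any(rate_hz > max(table$rate_hz) | rate_hz < min(table$rate_hz)))
    warning("target rate outside the calibrated table range; clamping")
  stats::approx(table$rate_hz, table$nu, xout = rate_hz, rule = 2,
                ties = "ordered")$y
}

# --------------------------------------------------------------------------
# Rate schedules (1-ms grid)

#' Constant-rate schedule
#' @param rate_hz rate.
#' @param duration_ms duration.
#' @return a `gl_schedule`: list with `rate_hz` per 1-ms bin and `kind`.
#' @export
make_constant_schedule <- function(rate_hz, duration_ms) {
  structure(list(rate_hz = rep(rate_hz, as.integer(duration_ms)),
                 kind = "constant"), class = c("gl_schedule", "list"))
}

#' Slow rate-modulated schedule
#'
#' Alternating plateaus of the lower and upper bound rates, each lasting
#' `epoch_half_ms`; one lower+upper combination is a 600-ms epoch and the
#' stimulus consists of `n_epochs` epochs, smoothed with a Gaussian kernel.
#'
#' @param upper_hz upper bound rate (varied 50-60 Hz in the stimulation
#'   protocols).
#' @param lower_hz lower bound rate (constant 10 Hz).
#' @param epoch_half_ms plateau duration (300 ms).
#' @param n_epochs number of epochs (5).
#' @param sigma_ms Gaussian smoothing kernel width (50 ms); 0 disables
#'   smoothing.
#' @return a `gl_schedule` of length `n_epochs * 2 * epoch_half_ms` ms.
#' @export
make_slow_rate_schedule <- function(upper_hz, lower_hz = 10,
                                    epoch_half_ms = 300, n_epochs = 5,
                                    sigma_ms = 50) {
  stopifnot(upper_hz > lower_hz)
  one <- c(rep(lower_hz, epoch_half_ms), rep(upper_hz, epoch_half_ms))
  r <- rep(one, n_epochs)
  if (sigma_ms > 0) r <- gaussian_smooth(r, sigma_ms)
  structure(list(rate_hz = r, kind = "slow_modulated"),
            class = c("gl_schedule", "list"))
}

## Gaussian smoothing with edge replication, 1-ms grid
gaussian_smooth <- function(x, sigma_ms) {
  half <- max(1L, ceiling(3 * sigma_ms))
  k <- stats::dnorm(seq(-half, half), sd = sigma_ms)
  k <- k / sum(k)
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  stats::filter(xp, k, sides = 2)[(half + 1):(half + length(x))]
}

#' Burst schedule
#'
#' Short high-frequency bursts: `n_bursts` bursts of `burst_ms` at
#' `rate_hz`, separated by `inter_burst_ms` at the resting rate. At the
#' default 500 Hz x 10 ms each fiber emits 5 expected spikes per burst.
#'
#' @param n_bursts number of bursts.
#' @param burst_ms burst duration.
#' @param rate_hz within-burst target rate.
#' @param inter_burst_ms gap between burst onsets is `burst_ms +
#'   inter_burst_ms`.
#' @param rest_hz rate between bursts.
#' @param lead_ms quiet lead-in before the first burst.
#' @return a `gl_schedule`; burst onset times in attribute `onsets_ms`.
#' @export
make_burst_schedule <- function(n_bursts = 9, burst_ms = 10, rate_hz = 500,
                                inter_burst_ms = 300, rest_hz = 5,
                                lead_ms = 0) {
  stopifnot(inter_burst_ms > 0)
  r <- rep(rest_hz, lead_ms)
  onsets <- numeric(n_bursts)
  for (b in seq_len(n_bursts)) {
    onsets[b] <- length(r)
    r <- c(r, rep(rate_hz, burst_ms))
    if (b < n_bursts) r <- c(r, rep(rest_hz, inter_burst_ms))
  }
  structure(list(rate_hz = r, kind = "burst"),
            class = c("gl_schedule", "list"), onsets_ms = onsets)
}

#' Probe fragment
#'
#' A weak asynchronous mossy-fiber input epoch (independent across fibers):
#' `rate_hz` for `duration_ms`, placed `delay_ms` after the end of the
#' schedule it is appended to.
#'
#' @param rate_hz probe rate (20 Hz).
#' @param duration_ms probe duration (20 ms).
#' @param delay_ms delay after the preceding schedule end.
#' @param rest_hz rate during the delay.
#' @return a `gl_schedule` fragment.
#' @export
make_probe <- function(rate_hz = 20, duration_ms = 20, delay_ms = 0,
                       rest_hz = 0) {
  stopifnot(delay_ms >= 0)
  structure(list(rate_hz = c(rep(rest_hz, delay_ms),
                             rep(rate_hz, duration_ms)),
                 kind = "probe"), class = c("gl_schedule", "list"))
}

#' Concatenate schedules
#' @param ... `gl_schedule` objects.
#' @return combined `gl_schedule`.
#' @export
append_schedule <- function(...) {
  parts <- list(...)
  structure(list(rate_hz = unlist(lapply(parts, `[[`, "rate_hz")),
                 kind = paste(vapply(parts, `[[`, "", "kind"),
                              collapse = "+")),
            class = c("gl_schedule", "list"))
}

# --------------------------------------------------------------------------
# Patches and protocols

#' Select the mossy fibers of a stimulation patch
#'
#' A fiber belongs to a patch if at least one of its rosettes falls inside
#' the vertical cylinder of radius `radius_um` about `center` (rosettes are
#' the synaptic elements, so membership follows them rather than the fiber
#' entry point).
#'
#' @param mfset a `gl_mossy`.
#' @param center length-2 (x, y) center in um.
#' @param radius_um patch radius (100 or 200 um in the standard paradigms).
#' @return a `gl_patch`: `center`, `radius_um`, `fibers` (ids).
#' @export
select_patch <- function(mfset, center, radius_um) {
  stopifnot(radius_um > 0, length(center) >= 2)
  r <- mfset$rosettes
  d2 <- (r$x - center[1])^2 + (r$y - center[2])^2
  fibers <- sort(unique(r$fiber[d2 <= radius_um^2]))
  if (!length(fibers)) warning("empty patch: no rosettes within the cylinder")
  structure(list(center = center[1:2], radius_um = radius_um,
                 fibers = fibers), class = c("gl_patch", "list"))
}

#' Cells inside a patch cylinder
#' @param pos n x 3 position matrix.
#' @param patch a `gl_patch` (or list with `center`, `radius_um`).
#' @return integer indices.
#' @export
cells_in_patch <- function(pos, patch) {
  which((pos[, 1] - patch$center[1])^2 +
          (pos[, 2] - patch$center[2])^2 <= patch$radius_um^2)
}

#' Assemble a stimulus protocol
#'
#' Every mossy fiber follows exactly one rate schedule: the 5-Hz background
#' by default, or the schedule of the patch it belongs to (patch membership
#' replaces the background; fibers in several patches follow the first
#' listed). Schedules shorter than the protocol duration are padded with the
#' background rate.
#'
#' @param mfset a `gl_mossy`.
#' @param duration_ms protocol duration.
#' @param background_hz background rate (5 Hz).
#' @param patches list of entries `list(patch =, schedule =, onset_ms =)`.
#' @return a `gl_protocol`: `rate_hz` matrix (groups x ms), `group_of_fiber`,
#'   `duration_ms`, `patches`.
#' @export
stimulus_protocol <- function(mfset, duration_ms, background_hz = 5,
                              patches = list()) {
  n_fib <- nrow(mfset$fiber_origin)
  nms <- as.integer(duration_ms)
  n_grp <- 1L + length(patches)
  rate <- matrix(background_hz, nrow = n_grp, ncol = nms)
  grp <- rep(1L, n_fib)
  for (k in seq_along(patches)) {
    en <- patches[[k]]
    onset <- as.integer(en$onset_ms %||% 0)
    sched <- en$schedule$rate_hz
    i0 <- onset + 1L
    i1 <- min(nms, onset + length(sched))
    if (i1 >= i0) rate[k + 1L, i0:i1] <- sched[seq_len(i1 - i0 + 1L)]
    newly <- en$patch$fibers[grp[en$patch$fibers] == 1L]
    grp[newly] <- k + 1L
  }
  structure(list(rate_hz = rate, group_of_fiber = grp,
                 duration_ms = nms, patches = patches),
            class = c("gl_protocol", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate mossy-fiber spikes for a protocol
#'
#' Converts the target rates of every schedule group to `nu` by inverting
#' the calibration table, then runs the noisy-LIF coder for each fiber.
#'
#' @param protocol a `gl_protocol`.
#' @param p LIF parameters.
#' @param table calibration table; computed (and cached) if missing.
#' @param dt_ms integration step of the LIF coder.
#' @param seed integer seed.
#' @return data.frame `fiber`, `t_ms`, sorted by time, with the fiber count
#'   in attribute `n_fiber`.
#' @export
mf_spikes <- function(protocol, p = mf_lif_params(), table = NULL,
                      dt_ms = 0.1, seed = 1L) {
  if (is.null(table)) table <- default_rate_table(p)
  nu <- matrix(nu_for_rate(as.numeric(protocol$rate_hz), table),
               nrow = nrow(protocol$rate_hz))
  sp <- cpp_mf_lif(nu, as.integer(protocol$group_of_fiber), p, dt_ms,
                   child_seed(seed, 8))
  ord <- order(sp$t_ms)
  out <- data.frame(fiber = sp$fiber[ord], t_ms = sp$t_ms[ord])
  attr(out, "n_fiber") <- length(protocol$group_of_fiber)
  out
}

#' Spikes of independent fibers following one schedule
#'
#' Direct interface to the LIF coder: `n_fibers` independent fibers all
#' following `schedule`.
#'
#' @param schedule a `gl_schedule`.
#' @param n_fibers number of independent fibers.
#' @param p LIF parameters.
#' @param table calibration table (cached default if `NULL`).
#' @param dt_ms integration step.
#' @param seed integer seed.
#' @return data.frame `fiber`, `t_ms` with attribute `n_fiber`.
#' @export
lif_mf_spikes <- function(schedule, n_fibers = 1, p = mf_lif_params(),
                          table = NULL, dt_ms = 0.1, seed = 1L) {
  if (is.null(table)) table <- default_rate_table(p)
  nu <- matrix(nu_for_rate(schedule$rate_hz, table), nrow = 1)
  sp <- cpp_mf_lif(nu, rep(1L, n_fibers), p, dt_ms, child_seed(seed, 9))
  ord <- order(sp$t_ms)
  out <- data.frame(fiber = sp$fiber[ord], t_ms = sp$t_ms[ord])
  attr(out, "n_fiber") <- n_fibers
  out
}

#' Equalize mossy-fiber temporal structure between two patches
#'
#' For each Golgi cell in patch 1, a Golgi cell is picked at random (without
#' replacement) from patch 2 and its mossy-fiber afferents are replaced by
#' clones of the patch-1 cell's afferents (same fiber identities, weights
#' and delays), so matched cells receive identical mossy-fiber spike trains.
#' All other edges are untouched.
#'
#' @param net a `gl_connectome`.
#' @param patch1,patch2 `gl_patch` objects (GoC membership by soma position).
#' @param seed integer seed for the random pairing.
#' @return the modified `gl_connectome`, with the pairing in attribute
#'   `equalized_pairs`.
#' @export
equalize_temporal_structure <- function(net, patch1, patch2,
                                        seed = net$seed) {
  goc_pos <- net$somata$goc$pos
  g1 <- cells_in_patch(goc_pos, patch1)
  g2 <- cells_in_patch(goc_pos, patch2)
  if (!length(g1) || !length(g2))
    stop("both patches must contain GoCs", call. = FALSE)
  n <- min(length(g1), length(g2))
  if (length(g1) != length(g2))
    warning("unequal GoC counts (", length(g1), " vs ", length(g2),
            "); pairing the first ", n)
  pairs <- with_seed(child_seed(seed, 31),
                     cbind(src = sample(g1, n), dst = sample(g2, n)))
  e <- net$edges$mf_goc
  keep <- !(e$post %in% pairs[, "dst"])
  clones <- lapply(seq_len(n), function(k) {
    rows <- e[e$post == pairs[k, "src"], , drop = FALSE]
    rows$post <- pairs[k, "dst"]
    rows
  })
  net$edges$mf_goc <- rbind(e[keep, , drop = FALSE], do.call(rbind, clones))
  attr(net, "equalized_pairs") <- pairs
  net
}
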