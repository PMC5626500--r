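#' Double-exponential synaptic conductance
#'
#' Standard two-time-constant conductance waveform
#' `G(t) = gmax * N * (exp(-t/tau_decay) - exp(-t/tau_rise))`, where `N`
#' normalizes the peak to `gmax`. Used for all AMPAergic synapses onto Golgi
#' cells and, componentwise, for the GABAergic waveforms.
#'
#' @param t_ms time since the presynaptic spike (ms), vectorized; values
#'   before the spike (`t < 0`) return 0.
#' @param gmax_ns peak conductance (nS).
#' @param tau_rise_ms,tau_decay_ms rise and decay time constants (ms);
#'   `tau_rise < tau_decay` is required.
#' @return conductance in nS, same length as `t_ms`.
#' @export
double_exp_g <- function(t_ms, gmax_ns, tau_rise_ms, tau_decay_ms) {
  if (tau_rise_ms >= tau_decay_ms)
    stop("parameter error: tau_rise must be < tau_decay", call. = FALSE)
  n <- double_exp_norm(tau_rise_ms, tau_decay_ms)
  g <- gmax_ns * n * (exp(-t_ms / tau_decay_ms) - exp(-t_ms / tau_rise_ms))
  g[t_ms < 0] <- 0
  g
}

## peak time and normalization of the double exponential
double_exp_peak_time <- function(tau_rise_ms, tau_decay_ms) {
  tau_decay_ms * tau_rise_ms / (tau_decay_ms - tau_rise_ms) *
    log(tau_decay_ms / tau_rise_ms)
}

double_exp_norm <- function(tau_rise_ms, tau_decay_ms) {
  tp <- double_exp_peak_time(tau_rise_ms, tau_decay_ms)
  1 / (exp(-tp / tau_decay_ms) - exp(-tp / tau_rise_ms))
}

#' GABA-A conductance with spillover component
#'
#' The granule-cell IPSC waveform: a transient component (decay
#' `tau_fast_ms`) plus an indirect spillover component (decay `tau_slow_ms`)
#' contributing `slow_frac` of the peak amplitude, both sharing the same rise
#' time constant. Each component is peak-normalized before mixing, so the
#' combined peak lies between `(1 - slow_frac) * gmax` and `gmax`.
#'
#' @param t_ms time since spike (ms), vectorized.
#' @param p a list with `gmax_ns`, `tau_rise_ms`, `tau_fast_ms`,
#'   `tau_slow_ms`, `slow_frac` (see `granular_config()$synapses$gaba_grc`).
#' @return conductance in nS.
#' @export
gaba_g <- function(t_ms, p) {
  fast <- double_exp_g(t_ms, 1, p$tau_rise_ms, p$tau_fast_ms)
  if (p$slow_frac > 0) {
    slow <- double_exp_g(t_ms, 1, p$tau_rise_ms, p$tau_slow_ms)
  } else slow <- 0
  p$gmax_ns * ((1 - p$slow_frac) * fast + p$slow_frac * slow)
}

#' NMDA receptor voltage dependence (magnesium block)
#'
#' `f(V) = 1 / (1 + ([Mg]_o / K_Mg) * exp(-V / delta_V))`. Strictly
#' increasing in V; tends to 1 as the block is relieved at depolarized
#' potentials, and to 1 everywhere in the zero-magnesium limit.
#'
#' @param v_mv membrane potential (mV), vectorized.
#' @param mg_mm extracellular magnesium concentration (mM).
#' @param k_mg_mm magnesium affinity constant (mM).
#' @param delta_v_mv voltage sensitivity (mV).
#' @return unblocked fraction in (0, 1\].
#' @export
nmda_voltage_factor <- function(v_mv, mg_mm = 1, k_mg_mm = 1.77,
                                delta_v_mv = 22.4) {
  1 / (1 + (mg_mm / k_mg_mm) * exp(-v_mv / delta_v_mv))
}

#' Gap-junction current
#'
#' Ohmic electrical coupling: the current into cell i is
#' `I_i = g * (V_j - V_i)` (pA for g in nS and V in mV). Pairwise
#' antisymmetric, so the summed current of a coupled pair is zero.
#'
#' @param v_i_mv,v_j_mv membrane potentials of the two coupled cells (mV).
#' @param g_ns junctional conductance (nS).
#' @return current into cell i, pA.
#' @export
gap_junction_current <- function(v_i_mv, v_j_mv, g_ns) {
  stopifnot(all(g_ns >= 0))
  g_ns * (v_j_mv - v_i_mv)
}

#' Gap-junction conductance as a function of distance
#'
#' `g(x) = beta * exp(-lambda * x)`: strictly decreasing with somatic
#' distance.
#'
#' @param distance_um intersomatic distance (um), vectorized.
#' @param beta_ns conductance at zero distance (nS).
#' @param lambda_per_um decay constant (1/um).
#' @return conductance in nS.
#' @export
gap_junction_g <- function(distance_um, beta_ns = 1.659,
                           lambda_per_um = 0.01259) {
  beta_ns * exp(-lambda_per_um * distance_um)
}

# ---------------------------------------------------------------------------
# Cascade approximation of glutamate diffusion at the mossy fiber-GrC relay.
#
# State (P, T, I1, I2, I3): P is the fast-releasing pool incremented by y at
# each presynaptic spike, T the diffused transmitter concentration sensed by
# the receptors, I1..I3 progressively remote spillover compartments.

#' Cascade system matrix
#'
#' Builds the 5x5 linear system matrix (units 1/ms) of the glutamate
#' diffusion cascade. Rates are the configured multipliers divided by the
#' diffusion time constant `tau_D = 100 * R_d^2 / (4 D)`.
#'
#' @param cas the `synapses$cascade` block of a configuration.
#' @return a 5x5 matrix acting on the state `c(P, T, I1, I2, I3)`.
#' @export
cascade_matrix <- function(cas = granular_config()$synapses$cascade) {
  td <- cascade_tau_d(cas)
  r <- lapply(cas[c("r_fast", "r_t", "r_t1", "r_1t",
                    "r_12", "r_21", "r_23", "r_32")], function(x) x / td)
  A <- matrix(0, 5, 5,
              dimnames = list(c("P", "T", "I1", "I2", "I3"),
                              c("P", "T", "I1", "I2", "I3")))
  A["P", "P"] <- -r$r_fast
  A["T", "P"] <- 1
  A["T", "T"] <- -(r$r_t + r$r_t1)
  A["T", "I1"] <- r$r_t1
  A["I1", "T"] <- r$r_1t
  A["I1", "I1"] <- -(r$r_1t + r$r_12)
  A["I1", "I2"] <- r$r_12
  A["I2", "I1"] <- r$r_21
  A["I2", "I2"] <- -(r$r_21 + r$r_23)
  A["I2", "I3"] <- r$r_23
  A["I3", "I2"] <- r$r_32
  A["I3", "I3"] <- -r$r_32
  A
}

#' Exact one-step propagator of the cascade
#'
#' Matrix exponential `expm(A * dt)` computed by eigendecomposition (the
#' cascade matrix has distinct real negative eigenvalues for the default
#' rates; this is checked and a series fallback used otherwise).
#'
#' @param A cascade matrix from [cascade_matrix()].
#' @param dt_ms step (ms).
#' @return the 5x5 propagator matrix.
#' @export
cascade_propagator <- function(A, dt_ms) {
  eg <- eigen(A)
  if (all(abs(Im(eg$values)) < 1e-12) &&
      min(abs(outer(Re(eg$values), Re(eg$values), "-")
              [upper.tri(diag(5))])) > 1e-10) {
    V <- Re(eg$vectors)
    E <- V %*% diag(exp(Re(eg$values) * dt_ms)) %*% solve(V)
  } else {
    # scaling-and-squaring Taylor fallback
    k <- max(0, ceiling(log2(max(1, norm(A, "F") * dt_ms))) + 6)
    B <- A * dt_ms / 2^k
    E <- diag(5); term <- diag(5)
    for (i in 1:12) { term <- term %*% B / i; E <- E + term }
    for (i in seq_len(k)) E <- E %*% E
  }
  dimnames(E) <- dimnames(A)
  E
}

#' Advance the cascade by one time step
#'
#' On a presynaptic spike the releasable pool is incremented, `P -> P + y`;
#' the linear system is then advanced exactly by the matrix-exponential
#' propagator.
#'
#' @param state numeric 5-vector `c(P, T, I1, I2, I3)`.
#' @param dt_ms step (ms).
#' @param spike logical; was there a presynaptic spike at the start of the
#'   step?
#' @param y release fraction added to P on a spike.
#' @param A cascade matrix; defaults to the configured rates.
#' @param E optional precomputed propagator for `dt_ms` (avoids the matrix
#'   exponential in loops).
#' @return the updated 5-vector.
#' @export
cascade_step <- function(state, dt_ms, spike = FALSE, y = 1,
                         A = cascade_matrix(), E = NULL) {
  stopifnot(dt_ms > 0, length(state) == 5)
  if (spike) state[1] <- state[1] + y
  if (is.null(E)) E <- cascade_propagator(A, dt_ms)
  out <- drop(E %*% state)
  if (any(out < -1e-9))
    stop("numerical-scheme failure: cascade state went negative", call. = FALSE)
  pmax(out, 0)
}

#' Transmitter time course after a single release event
#'
#' Convenience closed-form evaluation of `T(t)` for a unit release at t = 0,
#' via the eigendecomposition of the cascade matrix.
#'
#' @param t_ms times (ms) at which to evaluate.
#' @param y release fraction.
#' @param A cascade matrix.
#' @return `T(t)` at the requested times.
#' @export
cascade_transmitter <- function(t_ms, y = 1, A = cascade_matrix()) {
  eg <- eigen(A)
  V <- eg$vectors
  c0 <- solve(V, c(y, 0, 0, 0, 0))
  out <- vapply(t_ms, function(t) {
    Re(sum(V[2, ] * c0 * exp(eg$values * t)))
  }, numeric(1))
  out[t_ms < 0] <- 0
  out
}

#' Presynaptic release depression
#'
#' The diffusing fraction `y` released per spike is `y0` scaled by a
#' depression resource R: after each spike `R -> R * (1 - d)`, and R
#' recovers towards 1 with time constant `recovery_ms`.
#'
#' @param spike_times_ms sorted spike times of one fiber.
#' @param rel the `synapses$release` block (`y0`, `depression_frac`,
#'   `recovery_ms`).
#' @return the release fraction y used at each spike (same length).
#' @export
release_fractions <- function(spike_times_ms, rel) {
  n <- length(spike_times_ms)
  y <- numeric(n)
  r <- 1
  t_prev <- -Inf
  for (i in seq_len(n)) {
    if (is.finite(t_prev))
      r <- 1 - (1 - r) * exp(-(spike_times_ms[i] - t_prev) / rel$recovery_ms)
    y[i] <- rel$y0 * r
    r <- r * (1 - rel$depression_frac)
    t_prev <- spike_times_ms[i]
  }
  y
}

# ---------------------------------------------------------------------------
# Surrogate point neurons

#' Surrogate neuron state
#'
#' Creates the initial state for the adaptive leaky integrate-and-fire
#' surrogate used for both cell types (granule cells: one compartment, no
#' adaptation by default; Golgi cells: adaptation plus a constant pacemaker
#' drive and a depolarization-block threshold on a slow shadow potential).
#'
#' @param p a `neurons$grc` or `neurons$goc` parameter block.
#' @param v0_mv initial membrane potential.
#' @return list state: `v_mv`, `w_pa` (adaptation), `refrac_ms` (time left),
#'   `shadow_mv` (slow unreset potential used for depolarization block).
#' @export
neuron_state <- function(p, v0_mv = p$e_leak_mv) {
  list(v_mv = v0_mv, w_pa = 0, refrac_ms = 0, shadow_mv = v0_mv)
}

#' Advance a surrogate neuron one step
#'
#' Exponential-Euler update of a conductance/current-driven leaky
#' integrate-and-fire neuron with spike-triggered adaptation, absolute
#' refractoriness and an optional depolarization block: when the slow shadow
#' potential (a 20-ms low-pass of the unreset voltage) exceeds `block_v_mv`,
#' spiking is suppressed, reproducing the silencing of Golgi cells under
#' sustained strong mossy-fiber drive.
#'
#' @param state from [neuron_state()].
#' @param p neuron parameter block.
#' @param i_syn_pa total synaptic + gap-junction + tonic current (pA,
#'   positive = depolarizing) evaluated at the current potential.
#' @param g_syn_ns total synaptic conductance (nS) entering the effective
#'   membrane time constant (0 for a current-based approximation).
#' @param dt_ms step (ms).
#' @return list `(state, spike)`.
#' @export
step_neuron <- function(state, p, i_syn_pa, g_syn_ns = 0, dt_ms = 0.025) {
  if (dt_ms > 0.1)
    warning("dt_ms > 0.1 ms: surrogate neuron update may be inaccurate")
  g_tot <- p$g_leak_ns + g_syn_ns
  v_inf <- (p$g_leak_ns * p$e_leak_mv + i_syn_pa - state$w_pa + p$i_drive_pa) /
    g_tot
  tau_eff <- p$c_pf / g_tot
  decay <- exp(-dt_ms / tau_eff)
  state$shadow_mv <- state$shadow_mv + dt_ms / 20 * (v_inf - state$shadow_mv)
  state$w_pa <- state$w_pa * exp(-dt_ms / p$adapt_tau_ms)
  spike <- FALSE
  if (state$refrac_ms > 0) {
    state$refrac_ms <- state$refrac_ms - dt_ms
    state$v_mv <- p$v_reset_mv
  } else {
    v_new <- v_inf + (state$v_mv - v_inf) * decay
    if (is.na(v_new) || abs(v_new) > 200)
      stop("numerical blow-up: |V| > 200 mV", call. = FALSE)
    if (v_new >= p$v_thresh_mv && state$shadow_mv < p$block_v_mv) {
      spike <- TRUE
      state$w_pa <- state$w_pa + p$adapt_b_pa
      state$refrac_ms <- p$refractory_ms
      v_new <- p$v_reset_mv
    } else if (v_new >= p$v_thresh_mv) {
      v_new <- p$v_thresh_mv   # depolarization block: clamp, no spike
    }
    state$v_mv <- v_new
  }
  list(state = state, spike = spike)
}

#' Closed-form firing rate of the LIF neuron under constant current
#'
#' With adaptation off, a leaky integrate-and-fire neuron driven by constant
#' current I fires periodically at
#' `f = 1 / (t_ref + tau_m * log((V_inf - V_reset) / (V_inf - V_thresh)))`
#' when the asymptotic potential `V_inf = E_L + (I + I_drive)/g_L` exceeds
#' threshold, and not at all otherwise.
#'
#' @param i_pa injected current (pA).
#' @param p neuron parameter block.
#' @return firing rate in Hz.
#' @export
lif_fi_rate <- function(i_pa, p) {
  v_inf <- p$e_leak_mv + (i_pa + p$i_drive_pa) / p$g_leak_ns
  if (v_inf <= p$v_thresh_mv) return(0)
  tau_m <- p$c_pf / p$g_leak_ns
  t_isi <- p$refractory_ms +
    tau_m * log((v_inf - p$v_reset_mv) / (v_inf - p$v_thresh_mv))
  1000 / t_isi
}
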