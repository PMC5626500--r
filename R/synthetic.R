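## Synthetic spike-train ensembles with known first- and second-order
## statistics; these serve as oracles for the analysis statistics.

#' Generate an ensemble of rate-correlated Poisson spike trains
#'
#' Every cell fires as an inhomogeneous Poisson process with the common
#' rate `r(t) = base_hz * (1 + shared_frac * sin(2*pi*osc_hz*t))`; spikes
#' are conditionally independent across cells given the rate. With
#' `shared_frac = 0` the trains are homogeneous and independent; with
#' larger values the pairwise correlation of the binned activities grows by
#' a closed-form amount (rate variance over rate variance plus Poisson
#' noise), which the tests compute analytically.
#'
#' @param n_cells number of cells.
#' @param duration_ms record duration.
#' @param base_hz base firing rate.
#' @param shared_frac modulation depth of the shared sinusoidal drive in
#'   \[0, 1\].
#' @param osc_hz frequency of the shared drive.
#' @param seed integer seed.
#' @return data.frame `cell`, `t_ms`, sorted by time.
#' @export
generate_correlated_trains <- function(n_cells, duration_ms, base_hz,
                                       shared_frac = 0, osc_hz = 40,
                                       seed = 1L) {
  stopifnot(base_hz >= 0, shared_frac >= 0, shared_frac <= 1)
  with_seed(child_seed(seed, 41), {
    tgrid <- seq_len(as.integer(duration_ms)) - 0.5     # bin centers, ms
    rate <- base_hz * (1 + shared_frac * sin(2 * pi * osc_hz * tgrid / 1000))
    lam <- rate / 1000                                   # per 1-ms bin
    counts <- stats::rpois(n_cells * length(lam), rep(lam, n_cells))
    cell <- rep(seq_len(n_cells), each = length(lam))
    bin <- rep(seq_along(lam), n_cells)
    keep <- counts > 0
    cell <- rep.int(cell[keep], counts[keep])
    t_ms <- rep.int(bin[keep] - 1, counts[keep]) +
      runif(sum(counts[keep]))
    ord <- order(t_ms)
    data.frame(cell = cell[ord], t_ms = t_ms[ord])
  })
}

#' Generate independent homogeneous Poisson trains
#'
#' @inheritParams generate_correlated_trains
#' @return data.frame `cell`, `t_ms`.
#' @export
generate_poisson_trains <- function(n_cells, duration_ms, base_hz,
                                    seed = 1L) {
  generate_correlated_trains(n_cells, duration_ms, base_hz,
                             shared_frac = 0, seed = seed)
}
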