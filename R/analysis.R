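## Population statistics: activity binning, cross-correlation with
## rate-modulation discounting and shuffle significance, oscillation
## spectra and synchronization index, windowed rates, dynamic range,
## volumetric maps, bootstrap errors.

#' Average population activity
#'
#' Bins the spikes of the selected cells into 1-ms bins and divides by the
#' cell count: `y(t)` is the average spike count per bin per cell.
#'
#' @param spikes data.frame `cell`, `t_ms` (one population of a spike
#'   record).
#' @param cells integer cell ids forming the patch/population.
#' @param duration_ms record duration (defines the bin grid).
#' @param bin_ms bin width (1 ms in all standard analyses).
#' @return numeric vector of length `duration_ms / bin_ms` with attribute
#'   `n_cells`.
#' @export
bin_population <- function(spikes, cells, duration_ms, bin_ms = 1) {
  if (!length(cells)) stop("empty patch: no cells to bin", call. = FALSE)
  n_bins <- ceiling(duration_ms / bin_ms)
  sel <- spikes$cell %in% cells
  idx <- pmin(n_bins, floor(spikes$t_ms[sel] / bin_ms) + 1L)
  y <- tabulate(idx, nbins = n_bins) / length(cells)
  attr(y, "n_cells") <- length(cells)
  attr(y, "bin_ms") <- bin_ms
  y
}

#' Cross-correlation function of two population activities
#'
#' The lagged, mean-subtracted product estimator
#' `CCF(t) = sum_s (yA(s+t) - mean(yA)) (yB(s) - mean(yB)) / (L * Z)` with
#' `Z = sqrt(Var(yA) * Var(yB))`, evaluated for lags `-nlag .. +nlag`.
#' Note the `1/L` convention: for `yA == yB` the zero-lag value is
#' `(L-1)/L`, slightly below 1.
#'
#' @param yA,yB equal-length activity vectors (length `L > 2 * nlag`).
#' @param nlag maximal lag in bins (300).
#' @param z_from optional pair of vectors from which the normalization
#'   variance is computed instead of `yA`, `yB` (used by the
#'   rate-modulation discounting, where filtered activities are normalized
#'   by the unfiltered variances).
#' @return numeric vector of length `2 * nlag + 1`, lags in attribute
#'   `lag_ms`.
#' @export
ccf_population <- function(yA, yB, nlag = 300, z_from = NULL) {
  L <- length(yA)
  stopifnot(length(yB) == L, L > 2 * nlag)
  za <- if (is.null(z_from)) yA else z_from[[1]]
  zb <- if (is.null(z_from)) yB else z_from[[2]]
  Z <- sqrt(stats::var(as.numeric(za)) * stats::var(as.numeric(zb)))
  if (!is.finite(Z) || Z == 0)
    stop("zero-variance input: CCF normalization undefined", call. = FALSE)
  a <- as.numeric(yA) - mean(yA)
  b <- as.numeric(yB) - mean(yB)
  out <- numeric(2 * nlag + 1)
  for (t in -nlag:nlag) {
    s <- if (t >= 0) seq_len(L - t) else seq(1 - t, L)
    out[t + nlag + 1] <- sum(a[s + t] * b[s]) / (L * Z)
  }
  attr(out, "lag_ms") <- -nlag:nlag
  out
}

#' Low-pass filter an activity vector below 10 Hz
#'
#' Zero-phase 4th-order Butterworth, applied forwards and backwards
#' (`signal::filtfilt`), on the 1-ms grid (1 kHz sampling).
#'
#' @param y activity vector.
#' @param cutoff_hz cutoff frequency.
#' @param fs_hz sampling rate.
#' @return filtered vector.
#' @export
lowpass_activity <- function(y, cutoff_hz = 10, fs_hz = 1000) {
  bf <- signal::butter(4, cutoff_hz / (fs_hz / 2), type = "low")
  signal::filtfilt(bf, as.numeric(y))
}

#' Cross-correlation with rate-modulation discounting
#'
#' Computes `a` = CCF(0) of the raw activities, `b` = CCF(0) of the
#' low-pass-filtered (< 10 Hz) activities still normalized by the
#' unfiltered variances, and the discounted oscillatory synchrony
#' `c = a - b`.
#'
#' @param yA,yB activity vectors from [bin_population()].
#' @param nlag maximal lag (300).
#' @param cutoff_hz rate-modulation cutoff (10 Hz).
#' @return object of class `gl_ccf`: list with `ccf`, `ccf_rate` (both full
#'   lag curves), `a`, `b`, `c`.
#' @export
discounted_correlation <- function(yA, yB, nlag = 300, cutoff_hz = 10) {
  raw <- ccf_population(yA, yB, nlag)
  fA <- lowpass_activity(yA, cutoff_hz)
  fB <- lowpass_activity(yB, cutoff_hz)
  flt <- ccf_population(fA, fB, nlag, z_from = list(yA, yB))
  a <- raw[nlag + 1]; b <- flt[nlag + 1]
  structure(list(ccf = raw, ccf_rate = flt, a = a, b = b, c = a - b),
            class = c("gl_ccf", "list"))
}

#' Shuffle significance of the zero-lag cross-correlation
#'
#' Divides both activities into sub-epochs of `sub_epoch_ms`, permutes the
#' sub-epoch order independently per population, recomputes the CCF over
#' all `+/- nlag` lags for each of `n_shuffle` shuffles, and reports the
#' empirical type-I rate `p = n_out / (n_shuffle * (2*nlag + 1))`, where
#' `n_out` counts shuffled CCF values whose magnitude exceeds the observed
#' |CCF(0)|. `p < 0.01` is the conventional significance level.
#'
#' @param yA,yB activity vectors.
#' @param sub_epoch_ms shuffle segment length (10 ms).
#' @param n_shuffle number of shuffles (50).
#' @param nlag maximal lag (300).
#' @param seed integer seed for the permutations.
#' @return list `p`, `observed` (CCF(0)), `n_out`, `n_total`.
#' @export
shuffle_significance <- function(yA, yB, sub_epoch_ms = 10, n_shuffle = 50,
                                 nlag = 300, seed = 1L) {
  L <- length(yA)
  n_sub <- floor(L / sub_epoch_ms)
  if (n_sub < 10)
    warning("fewer than 10 sub-epochs: shuffle test has little power")
  Luse <- n_sub * sub_epoch_ms
  yA <- as.numeric(yA)[seq_len(Luse)]; yB <- as.numeric(yB)[seq_len(Luse)]
  obs <- ccf_population(yA, yB, nlag)[nlag + 1]
  seg <- function(y, perm) {
    m <- matrix(y, nrow = sub_epoch_ms)
    as.numeric(m[, perm])
  }
  n_out <- 0L
  with_seed(child_seed(seed, 77), {
    for (k in seq_len(n_shuffle)) {
      zA <- seg(yA, sample.int(n_sub))
      zB <- seg(yB, sample.int(n_sub))
      cs <- ccf_population(zA, zB, nlag)
      n_out <- n_out + sum(abs(cs) > abs(obs))
    }
  })
  n_total <- n_shuffle * (2L * nlag + 1L)
  list(p = n_out / n_total, observed = obs, n_out = n_out, n_total = n_total)
}

#' Welch power spectral density of a population activity
#'
#' Averaged modified periodograms (Hann window, 50% overlap) of the
#' mean-subtracted 1-ms binned activity.
#'
#' @param y activity vector (1-ms bins).
#' @param segment_ms segment length (1000 ms).
#' @param fs_hz sampling rate (1000).
#' @return data.frame `freq_hz`, `power`.
#' @export
welch_psd <- function(y, segment_ms = 1000, fs_hz = 1000) {
  y <- as.numeric(y) - mean(y)
  L <- length(y)
  seg <- min(segment_ms, L)
  step <- max(1, floor(seg / 2))
  starts <- seq(1, L - seg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg) / (seg + 1))  # Hann
  acc <- numeric(floor(seg / 2) + 1)
  for (s0 in starts) {
    x <- y[s0:(s0 + seg - 1)] * w
    sp <- abs(stats::fft(x))^2 / (sum(w^2) * fs_hz)
    acc <- acc + sp[seq_along(acc)]
  }
  p <- acc / length(starts)
  data.frame(freq_hz = (seq_along(p) - 1) * fs_hz / seg, power = p)
}

#' Oscillation metrics of a population activity
#'
#' Peak frequency and power of the Welch PSD within `band`, plus the
#' synchronization index: the population PSTH is smoothed with a short
#' Gaussian, cycles are delimited by successive local minima, and the index
#' is the mean over cycles of the per-cell spike mass per cycle (the
#' integral of `y`), clamped to 1 -- i.e. the fraction of the population
#' taking part in each oscillatory cycle.
#'
#' @param y activity vector from [bin_population()].
#' @param band frequency band (Hz) searched for the peak.
#' @param segment_ms Welch segment length.
#' @param smooth_sigma_ms Gaussian smoothing for cycle detection (3 ms).
#' @param min_cycle_ms minimal cycle length considered (discards spurious
#'   minima; acts as the prominence criterion).
#' @return list `psd`, `peak_freq_hz`, `peak_power`, `sync_index`,
#'   `n_cycles`. Flat or silent signals report `NA` peak and index 0.
#' @export
oscillation_metrics <- function(y, band = c(5, 250), segment_ms = 1000,
                                smooth_sigma_ms = 3, min_cycle_ms = 4) {
  y <- as.numeric(y)
  if (all(y == 0) || stats::var(y) == 0)
    return(list(psd = NULL, peak_freq_hz = NA_real_, peak_power = NA_real_,
                sync_index = 0, n_cycles = 0L))
  psd <- welch_psd(y, segment_ms)
  inband <- psd$freq_hz >= band[1] & psd$freq_hz <= band[2]
  pk <- which.max(psd$power[inband])
  peak_freq <- psd$freq_hz[inband][pk]
  peak_pow <- psd$power[inband][pk]
  ys <- gaussian_smooth(y, smooth_sigma_ms)
  n <- length(ys)
  is_min <- c(FALSE, ys[2:(n - 1)] <= ys[1:(n - 2)] &
                ys[2:(n - 1)] < ys[3:n], FALSE)
  mins <- which(is_min)
  if (length(mins) >= 2) {
    keep <- c(TRUE, diff(mins) >= min_cycle_ms)
    mins <- mins[keep]
  }
  if (length(mins) < 2) {
    sync <- min(1, sum(y))
    ncyc <- 1L
  } else {
    cyc <- vapply(seq_len(length(mins) - 1),
                  function(k) sum(y[mins[k]:(mins[k + 1] - 1)]), numeric(1))
    sync <- mean(pmin(cyc, 1))
    ncyc <- length(cyc)
  }
  list(psd = psd, peak_freq_hz = peak_freq, peak_power = peak_pow,
       sync_index = sync, n_cycles = ncyc)
}

#' Mean per-cell firing rate in a time window
#'
#' @param spikes data.frame `cell`, `t_ms`.
#' @param cells cell ids of the population.
#' @param window length-2 `c(t0, t1)` in ms (half-open `[t0, t1)`).
#' @return rate in Hz.
#' @export
windowed_rate <- function(spikes, cells, window) {
  stopifnot(length(window) == 2, window[2] >= window[1])
  if (!length(cells) || window[2] == window[1]) return(0)
  n <- sum(spikes$cell %in% cells & spikes$t_ms >= window[1] &
             spikes$t_ms < window[2])
  n / length(cells) / ((window[2] - window[1]) / 1000)
}

#' Percentage of active cells per counting window
#'
#' Fraction of the population with at least one spike per window of length
#' `window_ms`, averaged over all windows of the record, in percent.
#'
#' @param spikes data.frame `cell`, `t_ms`.
#' @param cells population cell ids.
#' @param duration_ms record duration.
#' @param window_ms counting window (1, 10 or 100 ms).
#' @return percentage in \[0, 100\].
#' @export
percent_active <- function(spikes, cells, duration_ms, window_ms) {
  n_win <- floor(duration_ms / window_ms)
  if (n_win < 1 || !length(cells)) return(0)
  sel <- spikes$cell %in% cells & spikes$t_ms < n_win * window_ms
  win <- floor(spikes$t_ms[sel] / window_ms)
  cellwin <- unique(paste(spikes$cell[sel], win))
  100 * length(cellwin) / (length(cells) * n_win)
}

#' Dynamic range of granule-cell activation
#'
#' For a set of records obtained at different mossy-fiber input rates,
#' computes the percentage of active cells per counting window and the
#' dynamic range `max / min` across input rates for each window size. A
#' zero minimum is flagged and floored at one active cell per window.
#'
#' @param records named list of spike data.frames (one per input rate).
#' @param cells population cell ids.
#' @param duration_ms record duration.
#' @param windows_ms counting windows.
#' @return list `percent` (matrix rates x windows), `range` (per window),
#'   `floored` (logical per window).
#' @export
dynamic_range <- function(records, cells, duration_ms,
                          windows_ms = c(1, 10, 100)) {
  stopifnot(length(records) >= 2)
  pct <- sapply(windows_ms, function(w)
    vapply(records, percent_active, numeric(1), cells = cells,
           duration_ms = duration_ms, window_ms = w))
  pct <- matrix(pct, nrow = length(records),
                dimnames = list(names(records), paste0(windows_ms, "ms")))
  floor_pct <- 100 / length(cells)
  floored <- apply(pct, 2, min) <= 0
  lo <- pmax(apply(pct, 2, min), floor_pct)
  list(percent = pct, range = apply(pct, 2, max) / lo, floored = floored)
}

#' Volumetric activity map of one millisecond frame
#'
#' Bins the cells spiking within the given millisecond into voxels of
#' `voxel_um` and convolves with a 3D Gaussian kernel normalized by its
#' maximum, so the voxel value is proportional to the number of
#' simultaneously active cells in the neighbourhood.
#'
#' @param spikes data.frame `cell`, `t_ms`.
#' @param pos n x 3 cell position matrix (um).
#' @param t_ms frame start (counts spikes in `[t, t+1)` ms).
#' @param cfg a `gl_config` for the volume bounds.
#' @param voxel_um voxel edge (10 um).
#' @param kernel_sigma_um Gaussian width; 0 returns the raw count grid.
#' @return 3D array; raw (unconvolved) counts in attribute `raw_total`.
#' @export
volumetric_map <- function(spikes, pos, t_ms, cfg = granular_config(),
                           voxel_um = 10, kernel_sigma_um = 10) {
  g <- cfg$geometry
  dims <- c(ceiling(g$transverse_um / voxel_um),
            ceiling(g$sagittal_um / voxel_um),
            ceiling((g$granular_um + g$pc_layer_um + g$molecular_um) /
                      voxel_um))
  cells <- spikes$cell[spikes$t_ms >= t_ms & spikes$t_ms < t_ms + 1]
  arr <- array(0, dims)
  if (length(cells)) {
    vi <- cbind(pmin(dims[1], pmax(1, floor(pos[cells, 1] / voxel_um) + 1)),
                pmin(dims[2], pmax(1, floor(pos[cells, 2] / voxel_um) + 1)),
                pmin(dims[3], pmax(1, floor(pos[cells, 3] / voxel_um) + 1)))
    for (r in seq_len(nrow(vi))) arr[vi[r, 1], vi[r, 2], vi[r, 3]] <-
        arr[vi[r, 1], vi[r, 2], vi[r, 3]] + 1
  }
  raw_total <- sum(arr)
  if (kernel_sigma_um > 0) {
    sv <- kernel_sigma_um / voxel_um
    half <- max(1L, ceiling(3 * sv))
    k1 <- stats::dnorm(seq(-half, half), sd = sv)
    k1 <- k1 / max(k1)   # kernel normalized by its maximum
    arr <- conv_sep(arr, k1)
  }
  attr(arr, "raw_total") <- raw_total
  arr
}

## separable 3D convolution by shift-and-add (same size, zero padding)
conv_sep <- function(arr, k) {
  pad <- (length(k) - 1) / 2
  dm <- dim(arr)
  for (d in 1:3) {
    out <- array(0, dm)
    for (o in -pad:pad) {
      w <- k[o + pad + 1]
      if (w == 0) next
      src <- list(seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]))
      dst <- src
      keep <- src[[d]] + o >= 1 & src[[d]] + o <= dm[d]
      src[[d]] <- src[[d]][keep]
      dst[[d]] <- src[[d]] + o
      out[dst[[1]], dst[[2]], dst[[3]]] <-
        out[dst[[1]], dst[[2]], dst[[3]]] +
        w * arr[src[[1]], src[[2]], src[[3]]]
    }
    arr <- out
  }
  arr
}

#' Bootstrap standard error of a cell-resampled statistic
#'
#' Resamples cells with replacement and reports the standard deviation of
#' the recomputed statistic.
#'
#' @param cells vector of cell ids in the patch.
#' @param statistic function taking a vector of (possibly repeated) cell
#'   ids and returning a scalar.
#' @param resamples number of bootstrap resamples (>= 2; default 1000).
#' @param seed integer seed.
#' @return standard deviation of the bootstrap distribution.
#' @export
bootstrap_error <- function(cells, statistic, resamples = 1000, seed = 1L) {
  if (resamples < 2)
    stop("insufficient resamples: need at least 2", call. = FALSE)
  vals <- with_seed(child_seed(seed, 91), {
    vapply(seq_len(resamples), function(k)
      statistic(sample(cells, length(cells), replace = TRUE)), numeric(1))
  })
  stats::sd(vals)
}
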