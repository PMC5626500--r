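## Anatomical network construction: soma placement, mossy-fiber rosette
## fields, axonal/dendritic point clouds, proximity-based connectivity with
## probability calibration, gap junctions and conduction delays.

#' Evaluate code with a private RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state,
#' so builds are bit-identical for a fixed master seed regardless of the
#' surrounding RNG usage.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

#' Place granule- and Golgi-cell somata
#'
#' Computes the Golgi-cell count from the anatomical density and the granular
#' layer volume, the granule-cell count from the GrC:GoC ratio, and places
#' all somata uniformly at random in the granular layer. Soma diameters are
#' jittered by up to +/-20% of the nominal value and initial membrane
#' potentials drawn uniformly from the configured range.
#'
#' @param cfg a `gl_config`.
#' @param seed integer; defaults to the config master seed.
#' @return a `gl_somata` object: per population a list with `pos` (n x 3
#'   matrix, um; x transverse, y sagittal, z vertical from the granular-layer
#'   floor), `soma_um`, `v_init_mv`.
#' @export
place_somata <- function(cfg, seed = cfg$master_seed) {
  vol <- granular_volume_mm3(cfg)
  if (vol <= 0) stop("configuration error: granular layer volume is zero",
                     call. = FALSE)
  n_goc <- round(cfg$cells$goc_density_per_mm3 * vol)
  n_grc <- round(n_goc * cfg$cells$grc_per_goc)
  if (n_goc < 1) stop("configuration error: volume too small for one GoC",
                      call. = FALSE)
  g <- cfg$geometry
  jit <- cfg$cells$soma_jitter_frac
  vr <- cfg$cells$v_init_range_mv
  draw <- function(n, nominal_um) {
    list(pos = cbind(x = runif(n, 0, g$transverse_um),
                     y = runif(n, 0, g$sagittal_um),
                     z = runif(n, 0, g$granular_um)),
         soma_um = nominal_um * runif(n, 1 - jit, 1 + jit),
         v_init_mv = runif(n, min(vr), max(vr)))
  }
  out <- with_seed(child_seed(seed, 1), {
    list(grc = draw(n_grc, cfg$cells$grc_soma_um),
         goc = draw(n_goc, cfg$cells$goc_soma_um))
  })
  structure(out, class = c("gl_somata", "list"))
}

#' Generate mossy fibers and their rosette fields
#'
#' Candidate fibers are seeded at the areal density over the horizontal
#' footprint extended by a boundary margin, so that edge cells receive full
#' rosette density from fibers whose entry point lies outside the modelled
#' volume. Each fiber carries a sagittally elongated strip of rosette
#' clusters: the strip center is displaced along the sagittal (parasagittal)
#' axis from the fiber entry point, clusters scatter around the strip
#' center, and rosettes scatter tightly around each cluster (sagittal spread
#' larger than transverse, giving the parasagittal strip arrangement).
#' Fibers without a single rosette inside the granular-layer volume are
#' discarded; the remainder are the instantiated fiber set.
#'
#' @param cfg a `gl_config`.
#' @param seed integer seed.
#' @return a `gl_mossy` object: `fiber_origin` (n x 2, um), `rosettes`
#'   data.frame (`fiber`, `x`, `y`, `z`), `n_candidates`.
#' @export
generate_mossy_fibers <- function(cfg, seed = cfg$master_seed) {
  g <- cfg$geometry; m <- cfg$mossy
  marg <- m$margin_um
  max_spread <- m$cluster_sd_sag_um + 3 * m$rosette_sd_sag_um
  if (marg < max_spread)
    warning("mossy-fiber margin (", marg, " um) is below the maximum rosette ",
            "spread (", round(max_spread), " um): expect boundary effects")
  wx <- g$transverse_um + 2 * marg
  wy <- g$sagittal_um + 2 * marg
  n_all <- round(m$areal_density_per_mm2 * wx * wy * 1e-6)
  out <- with_seed(child_seed(seed, 2), {
    bearing <- runif(n_all) < (m$rosette_bearing_frac %||% 1)
    n_cand <- sum(bearing)
    x0 <- runif(n_cand, -marg, g$transverse_um + marg)
    y0 <- runif(n_cand, -marg, g$sagittal_um + marg)
    cy <- y0 + rnorm(n_cand, 0, m$center_sd_sag_um)
    ncl <- 1L + stats::rpois(n_cand, pmax(m$n_clusters_mean - 1, 0))
    fiber_of_cluster <- rep.int(seq_len(n_cand), ncl)
    cl_y <- cy[fiber_of_cluster] +
      rnorm(length(fiber_of_cluster), 0, m$cluster_sd_sag_um)
    nro <- 1L + stats::rpois(length(fiber_of_cluster),
                             pmax(m$rosettes_per_cluster_mean - 1, 0))
    fib <- fiber_of_cluster[rep.int(seq_along(fiber_of_cluster), nro)]
    ros_y <- rep.int(cl_y, nro) + rnorm(sum(nro), 0, m$rosette_sd_sag_um)
    ros_x <- x0[fib] + rnorm(sum(nro), 0, m$rosette_sd_trans_um)
    ros_z <- runif(sum(nro), 0, g$granular_um)
    inside <- ros_x >= 0 & ros_x <= g$transverse_um &
      ros_y >= 0 & ros_y <= g$sagittal_um
    keep_fibers <- sort(unique(fib[inside]))
    relabel <- integer(n_cand); relabel[keep_fibers] <- seq_along(keep_fibers)
    list(fiber_origin = cbind(x = x0[keep_fibers], y = y0[keep_fibers]),
         rosettes = data.frame(fiber = relabel[fib[inside]],
                               x = ros_x[inside], y = ros_y[inside],
                               z = ros_z[inside]),
         n_candidates = n_cand)
  })
  structure(out, class = c("gl_mossy", "list"))
}

#' Mossy-fiber overlap histogram
#'
#' Divides the volume into cubes of the given size and counts the number of
#' distinct mossy fibers with at least one rosette in each cube; returns the
#' relative frequency of cubes representing 0, 1, 2, 3 and 4-or-more
#' distinct fibers. This is the calibration objective for the rosette
#' spread parameters.
#'
#' @param mfset a `gl_mossy` object.
#' @param cube_um cube edge length (um).
#' @param cfg configuration providing the volume bounds.
#' @return named numeric vector over `c("0","1","2","3","4+")` summing to 1.
#' @export
overlap_histogram <- function(mfset, cube_um, cfg = granular_config()) {
  stopifnot(cube_um > 0)
  g <- cfg$geometry
  r <- mfset$rosettes
  nx <- ceiling(g$transverse_um / cube_um)
  ny <- ceiling(g$sagittal_um / cube_um)
  nz <- ceiling(g$granular_um / cube_um)
  cube <- (pmin(floor(r$x / cube_um), nx - 1) * ny +
           pmin(floor(r$y / cube_um), ny - 1)) * nz +
    pmin(floor(r$z / cube_um), nz - 1)
  pairs <- unique(data.frame(cube = cube, fiber = r$fiber))
  per_cube <- table(pairs$cube)
  n_total <- nx * ny * nz
  counts <- c(`0` = n_total - length(per_cube),
              `1` = sum(per_cube == 1), `2` = sum(per_cube == 2),
              `3` = sum(per_cube == 3), `4+` = sum(per_cube >= 4))
  counts / n_total
}

#' Build axonal and dendritic point clouds
#'
#' Generates the geometric point representations used for touch detection:
#' \describe{
#'   \item{ascending_axon}{per GrC a vertical line of `aa_length_um` with
#'     points every `aa_spacing_um` (origin included).}
#'   \item{parallel_fiber}{two transverse arms of `pf_half_length_um` at the
#'     ascending-axon top, points every `pf_spacing_um`.}
#'   \item{apical_dendrite / basolateral_dendrite}{per GoC, lines on the
#'     surface of an inverted cone (heights 332 and 6 um) reaching the
#'     circumference of a 100-um circle, at normally distributed angles.}
#'   \item{goc_axon}{uniform random points in a box of half-extents
#'     (45, 160, 75) um around the GoC soma.}
#' }
#' Gaussian jitter of `jitter_sd_um` is applied to axonal points.
#'
#' @param somata a `gl_somata`.
#' @param cfg a `gl_config`.
#' @param structures subset of structures to generate.
#' @param cells optional cell indices (for the GrC structures; all by default).
#' @param seed integer seed.
#' @return named list of data.frames with `cell`, `x`, `y`, `z`, `path_um`
#'   (path length from the soma along the structure; NA for goc_axon).
#' @export
build_point_clouds <- function(somata, cfg,
                               structures = c("apical_dendrite",
                                              "basolateral_dendrite",
                                              "goc_axon"),
                               cells = NULL, seed = cfg$master_seed) {
  cl <- cfg$clouds
  out <- list()
  with_seed(child_seed(seed, 3), {
    for (st in structures) {
      out[[st]] <- switch(st,
        ascending_axon = {
          idx <- if (is.null(cells)) seq_len(nrow(somata$grc$pos)) else cells
          offs <- seq(0, cl$aa_length_um, by = cl$aa_spacing_um)
          n <- length(idx) * length(offs)
          cell <- rep(idx, each = length(offs))
          path <- rep(offs, length(idx))
          data.frame(cell = cell,
                     x = somata$grc$pos[cell, 1] + rnorm(n, 0, cl$jitter_sd_um),
                     y = somata$grc$pos[cell, 2] + rnorm(n, 0, cl$jitter_sd_um),
                     z = somata$grc$pos[cell, 3] + path +
                       rnorm(n, 0, cl$jitter_sd_um),
                     path_um = path)
        },
        parallel_fiber = {
          idx <- if (is.null(cells)) seq_len(nrow(somata$grc$pos)) else cells
          arm <- seq(cl$pf_spacing_um, cl$pf_half_length_um,
                     by = cl$pf_spacing_um)
          offs <- c(0, -arm, arm)
          n <- length(idx) * length(offs)
          cell <- rep(idx, each = length(offs))
          along <- rep(offs, length(idx))
          data.frame(cell = cell,
                     x = somata$grc$pos[cell, 1] + along +
                       rnorm(n, 0, cl$jitter_sd_um),
                     y = somata$grc$pos[cell, 2] + rnorm(n, 0, cl$jitter_sd_um),
                     z = somata$grc$pos[cell, 3] + cl$aa_length_um +
                       rnorm(n, 0, cl$jitter_sd_um),
                     path_um = cl$aa_length_um + abs(along))
        },
        apical_dendrite = dendrite_cloud(somata$goc$pos, cl,
                                         cl$apical_angles_deg,
                                         cl$apical_cone_height_um),
        basolateral_dendrite = dendrite_cloud(somata$goc$pos, cl,
                                              cl$basolateral_angles_deg,
                                              -cl$basolateral_cone_height_um),
        goc_axon = {
          n_goc <- nrow(somata$goc$pos)
          he <- cl$goc_axon_half_extent_um
          np <- cl$goc_axon_n_points
          cell <- rep(seq_len(n_goc), each = np)
          data.frame(cell = cell,
                     x = somata$goc$pos[cell, 1] + runif(n_goc * np, -he[1], he[1]),
                     y = somata$goc$pos[cell, 2] + runif(n_goc * np, -he[2], he[2]),
                     z = somata$goc$pos[cell, 3] + runif(n_goc * np, -he[3], he[3]),
                     path_um = NA_real_)
        },
        stop("unknown structure kind: ", st))
    }
  })
  out
}

## points along cone-surface dendrites: one line per configured mean angle,
## from the soma to the circumference of the 100-um circle at the cone tip
dendrite_cloud <- function(goc_pos, cl, mean_angles_deg, height_um) {
  n_goc <- nrow(goc_pos)
  r <- cl$dendrite_circle_radius_um
  len <- sqrt(r^2 + height_um^2)
  frac <- seq(cl$dendrite_spacing_um, len, by = cl$dendrite_spacing_um) / len
  pieces <- lapply(mean_angles_deg, function(a0) {
    ang <- rnorm(n_goc, a0, cl$dendrite_angle_sd_deg) * pi / 180
    cell <- rep(seq_len(n_goc), each = length(frac))
    fr <- rep(frac, n_goc)
    data.frame(cell = cell,
               x = goc_pos[cell, 1] + fr * r * cos(ang[cell]),
               y = goc_pos[cell, 2] + fr * r * sin(ang[cell]),
               z = goc_pos[cell, 3] + fr * height_um,
               path_um = fr * len)
  })
  do.call(rbind, pieces)
}

#' Proximity-based connectivity between point clouds and cells
#'
#' Finds all (pre-cell, post-cell) pairs with at least one pre point within
#' `radius_um` of the post position (fast uniform-grid neighbour search,
#' equivalent to a k-d-tree query), collapses them to distinct cell pairs,
#' and accepts each candidate pair independently with the given probability.
#'
#' @param pre_points n x 3 matrix of pre-synaptic structure points (um).
#' @param pre_cell integer cell/fiber id per point.
#' @param post_pos m x 3 matrix of post-synaptic cell positions.
#' @param radius_um connection radius.
#' @param probability acceptance probability in \[0, 1\].
#' @param seed integer seed for the acceptance draws.
#' @return data.frame `pre`, `post`, `dist_um` (minimal point distance of
#'   the accepted pair).
#' @export
connect_by_radius <- function(pre_points, pre_cell, post_pos, radius_um,
                              probability = 1, seed = 1L) {
  stopifnot(radius_um > 0, probability >= 0, probability <= 1)
  if (NROW(pre_points) == 0 || NROW(post_pos) == 0)
    return(data.frame(pre = integer(), post = integer(), dist_um = numeric()))
  cand <- cpp_pairs_points_cells(as.matrix(pre_points), as.integer(pre_cell),
                                 as.matrix(post_pos), radius_um)
  keep <- if (probability >= 1) rep(TRUE, length(cand$pre)) else
    with_seed(seed, runif(length(cand$pre)) < probability)
  data.frame(pre = cand$pre[keep], post = cand$post[keep],
             dist_um = cand$dist_um[keep])
}

#' Calibrate a connection probability against a target convergence
#'
#' The acceptance probability that turns a candidate-pair pool into the
#' target mean convergence: `p = target / mean(candidates)`, clamped to 1.
#' Errors when the candidate pool cannot reach the target.
#'
#' @param candidate_counts candidate pairs per post-synaptic cell (the cells
#'   over which the target mean is defined, typically interior cells).
#' @param target_mean target mean convergence.
#' @return probability in (0, 1\].
#' @export
calibrate_probability <- function(candidate_counts, target_mean) {
  m <- mean(candidate_counts)
  if (m < target_mean)
    stop("calibration error: mean candidate count (", round(m, 2),
         ") is below the target convergence (", target_mean, ")",
         call. = FALSE)
  min(1, target_mean / m)
}

#' Boltzmann distance-dependent connection probability
#' @param distance_um distance (um), vectorized.
#' @param b list with `pmax`, `x0_um`, `k_um`.
#' @return probability.
#' @export
boltzmann_p <- function(distance_um, b) {
  b$pmax / (1 + exp((distance_um - b$x0_um) / b$k_um))
}

#' Build gap junctions between Golgi cells
#'
#' Connects GoC pairs with a Boltzmann distance-dependent probability and
#' assigns each junction the conductance `g = beta * exp(-lambda * x)`.
#' Junctions are symmetric, unique, self-free pairs.
#'
#' @param goc_pos m x 3 matrix of GoC positions.
#' @param cfg a `gl_config`.
#' @param seed integer seed.
#' @return data.frame `i`, `j` (i < j), `dist_um`, `g_ns`.
#' @export
build_gap_junctions <- function(goc_pos, cfg, seed = cfg$master_seed) {
  n <- nrow(goc_pos)
  pr <- upper_pairs(goc_pos)
  p <- boltzmann_p(pr$d, cfg$connect$gap_boltzmann)
  keep <- with_seed(child_seed(seed, 4), runif(length(p)) < p)
  data.frame(i = pr$i[keep], j = pr$j[keep], dist_um = pr$d[keep],
             g_ns = gap_junction_g(pr$d[keep], cfg$connect$gap_beta_ns,
                                   cfg$connect$gap_lambda_per_um))
}

#' Build inhibitory GoC-to-GoC connections
#'
#' Directed synaptic inhibition between Golgi cells with a Boltzmann
#' distance-dependent probability anchored at 20% at 50 um.
#'
#' @inheritParams build_gap_junctions
#' @return data.frame `pre`, `post`, `dist_um`, `w`, `delay_ms`.
#' @export
build_goc_inhibition <- function(goc_pos, cfg, seed = cfg$master_seed) {
  pr <- upper_pairs(goc_pos)
  p <- boltzmann_p(pr$d, cfg$connect$inh_boltzmann)
  with_seed(child_seed(seed, 5), {
    k1 <- runif(length(p)) < p        # i -> j
    k2 <- runif(length(p)) < p        # j -> i
    pre <- c(pr$i[k1], pr$j[k2]); post <- c(pr$j[k1], pr$i[k2])
    d <- c(pr$d[k1], pr$d[k2])
    data.frame(pre = pre, post = post, dist_um = d,
               w = weight_factors(length(pre), cfg$connect$weight_cv),
               delay_ms = d / (cfg$connect$velocity_goc_m_per_s * 1000))
  })
}

## all unordered pairs with distances (vectorized; fine up to a few 1e3 cells)
upper_pairs <- function(pos) {
  n <- nrow(pos)
  dm <- as.matrix(stats::dist(pos))
  iu <- which(upper.tri(dm), arr.ind = TRUE)
  list(i = iu[, 1], j = iu[, 2], d = dm[iu])
}

## multiplicative synaptic weight heterogeneity, CV around 1, strictly > 0
weight_factors <- function(n, cv) pmax(rnorm(n, 1, cv), 0.05)

#' Interior-cell mask
#'
#' Cells at least `margin_um` from the transverse and sagittal faces of the
#' volume (the vertical faces are genuine tissue boundaries of the granular
#' layer and are not excluded). `margin_um` may be length 2 (transverse,
#' sagittal); margins are capped at a third of the extent so the mask is
#' never empty.
#' @param pos n x 3 position matrix.
#' @param cfg a `gl_config`.
#' @param margin_um margin (um), length 1 or 2.
#' @return logical vector.
#' @export
interior_mask <- function(pos, cfg, margin_um) {
  g <- cfg$geometry
  m <- rep_len(margin_um, 2)
  mx <- min(m[1], g$transverse_um / 3)
  my <- min(m[2], g$sagittal_um / 3)
  pos[, 1] >= mx & pos[, 1] <= g$transverse_um - mx &
    pos[, 2] >= my & pos[, 2] <= g$sagittal_um - my
}

#' Interior margin for convergence statistics of an edge type
#'
#' The printed convergence figures refer to the full 1500 x 700 um model,
#' whose own tissue boundaries are part of the statistic. Reduced volumes
#' therefore apply an interior margin equal to the anatomical reach of the
#' connection only along dimensions that were shrunk below the full
#' anatomy; dimensions kept at full size reproduce the full model's
#' boundary profile and get no margin.
#'
#' @param type edge type name (or `"gap"`).
#' @param cfg a `gl_config`.
#' @return length-2 margin (transverse, sagittal) in um.
#' @export
edge_interior_margin <- function(type, cfg) {
  cl <- cfg$clouds; cn <- cfg$connect
  reach <- switch(type,
    mf_grc = c(0, 0),          # rosette field is margin-compensated
    mf_goc = c(0, 0),
    goc_grc = cl$goc_axon_half_extent_um[1:2] + cn$goc_grc_radius_um,
    aa_goc = rep(cl$dendrite_circle_radius_um + cn$aa_goc_radius_um, 2),
    pf_goc = c(cl$pf_half_length_um / 2,
               cl$dendrite_circle_radius_um + cn$pf_goc_radius_um),
    goc_goc = rep(cn$inh_boltzmann$x0_um + 3 * cn$inh_boltzmann$k_um, 2),
    gap = rep(cn$gap_boltzmann$x0_um + 3 * cn$gap_boltzmann$k_um, 2),
    stop("unknown edge type: ", type))
  full <- c(1500, 700)
  extent <- c(cfg$geometry$transverse_um, cfg$geometry$sagittal_um)
  ifelse(extent < full, pmin(reach, extent / 3), 0)
}

#' Build the complete granular-layer connectome
#'
#' Runs the full anatomical pipeline: soma placement, mossy-fiber rosette
#' fields, point-cloud generation, proximity-based candidate detection for
#' every connection type, probability calibration against the target
#' convergences (computed over interior cells so tissue-boundary deficits do
#' not bias the calibration), Bernoulli acceptance, synaptic weight
#' heterogeneity (CV 0.25), conduction delays from path lengths, gap
#' junctions and GoC-GoC inhibition.
#'
#' @param cfg a `gl_config`.
#' @param seed master seed; defaults to `cfg$master_seed`.
#' @param quiet suppress progress messages.
#' @return a `gl_connectome`: `cfg`, `seed`, `somata`, `mossy`, `edges`
#'   (named list of data.frames `pre`, `post`, `w`, `delay_ms`, ...),
#'   `gaps`, `probs` (calibrated acceptance probabilities).
#' @export
build_network <- function(cfg, seed = cfg$master_seed, quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  tc <- cfg$connect$target_convergence
  say("placing somata ...")
  somata <- place_somata(cfg, seed)
  grc_pos <- somata$grc$pos; goc_pos <- somata$goc$pos
  say("  ", nrow(goc_pos), " GoCs, ", nrow(grc_pos), " GrCs")
  say("generating mossy fibers ...")
  mossy <- generate_mossy_fibers(cfg, seed)
  ros <- as.matrix(mossy$rosettes[, c("x", "y", "z")])
  say("  ", nrow(mossy$fiber_origin), " fibers, ", nrow(ros), " rosettes")

  probs <- list()
  mf_v <- cfg$connect$velocity_mf_m_per_s * 1000   # um/ms
  goc_v <- cfg$connect$velocity_goc_m_per_s * 1000
  pf_v <- cfg$connect$velocity_pf_m_per_s * 1000

  ## --- MF -> GrC / MF -> GoC -------------------------------------------
  mf_edge <- function(post_pos, radius, target, k, type) {
    cand <- cpp_pairs_points_cells(ros, as.integer(mossy$rosettes$fiber),
                                   post_pos, radius)
    counts <- tabulate(cand$post, nbins = nrow(post_pos))
    int <- interior_mask(post_pos, cfg, edge_interior_margin(type, cfg))
    p <- calibrate_probability(counts[int], target)
    keep <- with_seed(child_seed(seed, 10 + k), runif(length(cand$pre)) < p)
    n <- sum(keep)
    w <- with_seed(child_seed(seed, 20 + k),
                   weight_factors(n, cfg$connect$weight_cv))
    list(p = p,
         edges = data.frame(pre = cand$pre[keep], post = cand$post[keep],
                            dist_um = cand$dist_um[keep], w = w,
                            delay_ms = cand$dist_um[keep] / mf_v))
  }
  say("connecting mossy fibers ...")
  r1 <- mf_edge(grc_pos, cfg$connect$mf_grc_radius_um, tc$mf_grc, 1, "mf_grc")
  r2 <- mf_edge(goc_pos, cfg$connect$mf_goc_radius_um, tc$mf_goc, 2, "mf_goc")
  probs$mf_grc <- r1$p; probs$mf_goc <- r2$p

  ## --- GoC -> GrC via axonal point cloud ---------------------------------
  say("connecting GoC axons to GrCs ...")
  clouds <- build_point_clouds(somata, cfg,
                               structures = c("apical_dendrite",
                                              "basolateral_dendrite",
                                              "goc_axon"), seed = seed)
  ax <- clouds$goc_axon
  cand <- cpp_pairs_points_cells(as.matrix(ax[, c("x", "y", "z")]),
                                 as.integer(ax$cell), grc_pos,
                                 cfg$connect$goc_grc_radius_um)
  counts <- tabulate(cand$post, nbins = nrow(grc_pos))
  int <- interior_mask(grc_pos, cfg, edge_interior_margin("goc_grc", cfg))
  probs$goc_grc <- calibrate_probability(counts[int], tc$goc_grc)
  keep <- with_seed(child_seed(seed, 13),
                    runif(length(cand$pre)) < probs$goc_grc)
  d_soma <- sqrt(rowSums((goc_pos[cand$pre[keep], , drop = FALSE] -
                          grc_pos[cand$post[keep], , drop = FALSE])^2))
  goc_grc <- data.frame(pre = cand$pre[keep], post = cand$post[keep],
                        dist_um = d_soma,
                        w = with_seed(child_seed(seed, 23),
                                      weight_factors(sum(keep),
                                                     cfg$connect$weight_cv)),
                        delay_ms = d_soma / goc_v)

  ## --- AA / PF -> GoC (streaming two-pass) -------------------------------
  say("connecting ascending axons and parallel fibers to GoCs ...")
  api <- clouds$apical_dendrite; bas <- clouds$basolateral_dendrite
  geom <- cfg$clouds
  s_aapf <- child_seed(seed, 6)
  ph1 <- cpp_aa_pf_connect(grc_pos, as.matrix(api[, c("x", "y", "z")]),
                           as.integer(api$cell),
                           as.matrix(bas[, c("x", "y", "z")]),
                           as.integer(bas$cell),
                           geom, cfg$connect$aa_goc_radius_um,
                           cfg$connect$pf_goc_radius_um, 0, 0,
                           s_aapf, 1L, nrow(goc_pos))
  int_aa <- interior_mask(goc_pos, cfg, edge_interior_margin("aa_goc", cfg))
  int_pf <- interior_mask(goc_pos, cfg, edge_interior_margin("pf_goc", cfg))
  probs$aa_goc <- calibrate_probability(ph1$aa_counts[int_aa], tc$aa_goc)
  probs$pf_goc <- calibrate_probability(ph1$pf_counts[int_pf], tc$pf_goc)
  ph2 <- cpp_aa_pf_connect(grc_pos, as.matrix(api[, c("x", "y", "z")]),
                           as.integer(api$cell),
                           as.matrix(bas[, c("x", "y", "z")]),
                           as.integer(bas$cell),
                           geom, cfg$connect$aa_goc_radius_um,
                           cfg$connect$pf_goc_radius_um,
                           probs$aa_goc, probs$pf_goc,
                           s_aapf, 2L, nrow(goc_pos))
  aa_goc <- data.frame(pre = ph2$aa$pre, post = ph2$aa$post,
                       path_um = ph2$aa$path_um,
                       w = with_seed(child_seed(seed, 24),
                                     weight_factors(length(ph2$aa$pre),
                                                    cfg$connect$weight_cv)),
                       delay_ms = ph2$aa$path_um / pf_v)
  pf_goc <- data.frame(pre = ph2$pf$pre, post = ph2$pf$post,
                       path_um = ph2$pf$path_um,
                       w = with_seed(child_seed(seed, 25),
                                     weight_factors(length(ph2$pf$pre),
                                                    cfg$connect$weight_cv)),
                       delay_ms = ph2$pf$path_um / pf_v)

  ## --- GoC <-> GoC -------------------------------------------------------
  say("gap junctions and GoC inhibition ...")
  gaps <- build_gap_junctions(goc_pos, cfg, seed)
  goc_goc <- build_goc_inhibition(goc_pos, cfg, seed)

  structure(list(
    cfg = cfg, seed = seed, somata = somata, mossy = mossy,
    edges = list(mf_grc = r1$edges, mf_goc = r2$edges, goc_grc = goc_grc,
                 aa_goc = aa_goc, pf_goc = pf_goc, goc_goc = goc_goc),
    gaps = gaps, probs = probs),
    class = c("gl_connectome", "list"))
}

#' Connectivity statistics of a built network
#'
#' Per-edge-type convergence (distinct presynaptic partners per
#' postsynaptic cell): mean, SD, min, max and edge totals. Optionally
#' restricted to interior postsynaptic cells.
#'
#' @param net a `gl_connectome`.
#' @param interior_margin_um if not `NULL`, statistics are computed over
#'   cells at least this far from the transverse/sagittal faces; the string
#'   `"per-type"` applies the per-edge-type margins of
#'   [edge_interior_margin()] (the same cells the probability calibration
#'   used).
#' @return data.frame with one row per edge type (plus gap junctions).
#' @export
network_summary <- function(net, interior_margin_um = NULL) {
  n_grc <- nrow(net$somata$grc$pos); n_goc <- nrow(net$somata$goc$pos)
  post_n <- c(mf_grc = n_grc, mf_goc = n_goc, goc_grc = n_grc,
              aa_goc = n_goc, pf_goc = n_goc, goc_goc = n_goc)
  mask_for <- function(type) {
    if (is.null(interior_margin_um)) return(NULL)
    pos <- if (type %in% c("mf_grc", "goc_grc")) net$somata$grc$pos
           else net$somata$goc$pos
    m <- if (identical(interior_margin_um, "per-type"))
      edge_interior_margin(type, net$cfg) else interior_margin_um
    interior_mask(pos, net$cfg, m)
  }
  one <- function(type) {
    e <- net$edges[[type]]
    conv <- tabulate(e$post, nbins = post_n[[type]])
    m <- mask_for(type)
    if (!is.null(m)) conv <- conv[m]
    data.frame(type = type, n_edges = nrow(e),
               mean = mean(conv), sd = stats::sd(conv),
               min = if (length(conv)) min(conv) else 0,
               max = if (length(conv)) max(conv) else 0)
  }
  out <- do.call(rbind, lapply(names(net$edges), one))
  gp <- tabulate(c(net$gaps$i, net$gaps$j), nbins = n_goc)
  m <- if (is.null(interior_margin_um)) NULL
       else interior_mask(net$somata$goc$pos, net$cfg,
                          if (identical(interior_margin_um, "per-type"))
                            edge_interior_margin("gap", net$cfg)
                          else interior_margin_um)
  if (!is.null(m)) gp <- gp[m]
  rbind(out, data.frame(type = "gap", n_edges = nrow(net$gaps),
                        mean = mean(gp), sd = stats::sd(gp),
                        min = if (length(gp)) min(gp) else 0,
                        max = if (length(gp)) max(gp) else 0))
}
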