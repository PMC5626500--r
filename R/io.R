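## Plain-text export/import of connectomes and spike records, and the
## reproducibility manifest.

#' Export a connectome to a directory of CSV tables
#'
#' One CSV per edge type (`pre`, `post`, `weight_ns`, `delay_ms`), the gap
#' junction table, position tables per population, the rosette table, and a
#' JSON manifest with the configuration, seed and calibrated probabilities.
#'
#' @param net a `gl_connectome`.
#' @param dir destination directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_connectome <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gmax <- c(mf_grc = net$cfg$synapses$ampa_grc$gmax_ns,
            mf_goc = net$cfg$synapses$ampa_mf_goc$gmax_ns,
            goc_grc = net$cfg$synapses$gaba_grc$gmax_ns,
            aa_goc = net$cfg$synapses$ampa_aa_goc$gmax_ns,
            pf_goc = net$cfg$synapses$ampa_pf_goc$gmax_ns,
            goc_goc = net$cfg$synapses$gaba_goc$gmax_ns)
  for (nm in names(net$edges)) {
    e <- net$edges[[nm]]
    utils::write.csv(data.frame(pre = e$pre, post = e$post,
                                weight_ns = e$w * gmax[[nm]],
                                delay_ms = e$delay_ms),
                     file.path(dir, paste0("edges_", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(net$gaps, file.path(dir, "gap_junctions.csv"),
                   row.names = FALSE)
  for (pop in c("grc", "goc")) {
    p <- net$somata[[pop]]
    utils::write.csv(data.frame(x = p$pos[, 1], y = p$pos[, 2],
                                z = p$pos[, 3], soma_um = p$soma_um,
                                v_init_mv = p$v_init_mv),
                     file.path(dir, paste0("positions_", pop, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(net$mossy$rosettes, file.path(dir, "rosettes.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = net$seed, probs = net$probs,
                            config = unclass(net$cfg)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Export spikes as two-column text
#'
#' @param record a `gl_record`.
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
export_spikes <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (pop in c("grc", "goc", "mf")) {
    sp <- record[[pop]]
    if (is.null(sp)) next
    nm <- if (pop == "mf") c("fiber", "t_ms") else c("cell", "t_ms")
    utils::write.table(sp[, nm], file.path(dir, paste0("spikes_", pop, ".txt")),
                       row.names = FALSE, col.names = TRUE, quote = FALSE)
  }
  invisible(dir)
}

#' Run manifest
#'
#' Hashes of the configuration and outputs plus the seeds used, sufficient
#' to check that a rerun reproduced a result bit-for-bit.
#'
#' @param net a `gl_connectome`.
#' @param record a `gl_record` (optional).
#' @param wall_times named numeric seconds per stage (optional).
#' @return list of class `gl_manifest`.
#' @export
run_manifest <- function(net, record = NULL, wall_times = NULL) {
  structure(list(
    package_version = as.character(utils::packageVersion("granet")),
    master_seed = net$seed,
    config_hash = object_hash(unclass(net$cfg)),
    connectome_hash = object_hash(lapply(net$edges, function(e)
      list(e$pre, e$post, round(e$w, 10)))),
    spikes_hash = if (is.null(record)) NA_character_ else
      object_hash(list(record$grc, record$goc)),
    wall_times_s = wall_times),
    class = c("gl_manifest", "list"))
}

## md5 of a serialized R object (via a temporary file; no extra deps)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
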