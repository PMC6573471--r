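#' Write / read a trajectory TSV
#'
#' Serialises a `te_trajectory` to a plain TSV: `#`-prefixed key/value
#' metadata header lines (parameter echo, status, replicate id), one row
#' per recorded generation.  Long runs are thinned on write: every
#' generation up to `dense_until`, every `thin`-th generation afterwards
#' (the final generation is always kept).
#'
#' @param traj a `te_trajectory`.
#' @param file output path.
#' @param replicate replicate id written to the header.
#' @param dense_until,thin recording-interval rule (see above).
#' @return `write_trajectory()` returns `file` invisibly;
#'   `read_trajectory()` returns a `te_trajectory` (records and metadata;
#'   the final population is not serialised here, see
#'   [write_population()]).
#' @export
write_trajectory <- function(traj, file, replicate = 1L,
                             dense_until = 1000L, thin = 10L) {
  rec <- traj$records
  keep <- rec$generation <= dense_until |
    rec$generation %% thin == 0 |
    rec$generation == rec$generation[nrow(rec)]
  rec <- rec[keep, , drop = FALSE]
  p <- traj$params
  con <- file(file, "w")
  on.exit(close(con))
  hdr <- c(replicate = replicate, status = traj$status, u = p$u, v = p$v,
           x = p$x, t = p$t, model = p$model, N = p$N, n_seed = p$n_seed,
           generations = p$generations,
           seed = if (is.null(traj$seed)) NA else traj$seed)
  writeLines(sprintf("# %s\t%s", names(hdr), as.character(hdr)), con)
  writeLines(paste(names(rec), collapse = "\t"), con)
  utils::write.table(rec, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  lines <- readLines(file)
  meta_lines <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", meta_lines), "\t")
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2),
                          vapply(kv, `[`, character(1), 1))
  body <- lines[!grepl("^# ", lines)]
  rec <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  params <- simulation_params(
    u = as.numeric(meta[["u"]]), v = as.numeric(meta[["v"]]),
    x = as.numeric(meta[["x"]]), t = as.numeric(meta[["t"]]),
    model = meta[["model"]], N = as.integer(meta[["N"]]),
    n_seed = as.integer(meta[["n_seed"]]),
    generations = as.integer(meta[["generations"]]))
  traj <- list(records = rec, status = meta[["status"]], params = params,
               seed = if (is.na(meta[["seed"]])) NULL
                      else as.integer(meta[["seed"]]),
               replicate = as.integer(meta[["replicate"]]))
  class(traj) <- "te_trajectory"
  traj
}

#' Write a run manifest
#'
#' Records everything needed to reproduce an experiment byte-for-byte:
#' the full parameter set, the genome architecture, the package version,
#' the master seed and all derived per-replicate seeds, and a timestamp.
#'
#' @param arch a [build_architecture()] object.
#' @param params a [simulation_params()] object.
#' @param replicates replicate count.
#' @param seed master seed.
#' @param file output path (JSON).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(arch, params, replicates, seed, file) {
  manifest <- list(
    package = "pirnatrap",
    version = as.character(utils::packageVersion("pirnatrap")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    master_seed = seed,
    replicate_seeds = replicate_seed(seed, seq_len(replicates)),
    parameters = unclass(params)[c("u", "v", "x", "t", "model", "N",
                                   "n_seed", "generations")],
    architecture = list(
      chrom_mb = arch$length_bp / 1e6,
      rr_cm_mb = arch$recomb_rate,
      cluster_kb = arch$cluster_len_bp / 1e3,
      ref_kb = arch$ref_len_bp / 1e3,
      cluster_recombining = arch$cluster_recombining))
  jsonlite::write_json(manifest, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
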