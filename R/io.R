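#' Spike, snapshot, and run output files
#'
#' Spike records are written as two-column whitespace-delimited text
#' (`neuron_id time_s`). Connectivity snapshots are written in Matrix
#' Market coordinate integer format together with a population-partition
#' sidecar CSV (`neuron_id, group`).
#'
#' @param spikes Data frame with `id`, `time_s`.
#' @param path Output file path.
#' @export
write_spikes <- function(spikes, path) {
  utils::write.table(spikes[, c("id", "time_s")], path,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- utils::read.table(path, col.names = c("id", "time_s"))
  df$id <- as.integer(df$id)
  df
}

#' @rdname write_spikes
#' @param A Sparse synapse-count matrix (integer counts).
#' @export
write_snapshot_mtx <- function(A, path) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  tr <- Matrix::summary(A)
  tr <- tr[tr$x != 0, , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(A), ncol(A), nrow(tr)), con)
  if (nrow(tr) > 0) {
    writeLines(sprintf("%d %d %d", tr$i, tr$j, as.integer(tr$x)), con)
  }
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_snapshot_mtx <- function(path) {
  methods::as(Matrix::readMM(path), "CsparseMatrix")
}

#' @rdname write_spikes
#' @param partition Partition as returned by [montage_partition()].
#' @param n_I Number of inhibitory neurons (labelled `I` in the sidecar).
#' @export
write_partition_csv <- function(partition, n_I, path) {
  n_E <- length(partition$labels)
  df <- data.frame(
    neuron_id = seq_len(n_E + n_I),
    group = c(partition_group_names[partition$labels],
              rep.int("I", n_I)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a complete run directory
#'
#' Persists everything needed to re-run the analysis without the simulator:
#' the configuration echo (YAML), the seed and package version, tidy CSVs of
#' the rate and connectivity time series, connectivity snapshots (Matrix
#' Market + partition sidecar), and the spike record if it was kept.
#'
#' @param result An `hsp_result` from [run_experiment()].
#' @param cfg The configuration the run used.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_run <- function(result, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_config(cfg, file.path(dir, "config.yaml"))
  meta <- list(seed = result$seed,
               version = as.character(utils::packageVersion("hspsim")),
               montage = result$montage$kind,
               timing = result$plan$timing,
               delta_vm_mv = result$plan$delta_vm_mv)
  yaml::write_yaml(meta, file.path(dir, "run.yaml"))
  utils::write.csv(result$rates, file.path(dir, "rates.csv"),
                   row.names = FALSE)
  utils::write.csv(result$gamma, file.path(dir, "gamma.csv"),
                   row.names = FALSE)
  utils::write.csv(result$gamma_engram, file.path(dir, "gamma_engram.csv"),
                   row.names = FALSE)
  write_partition_csv(result$partition, result$net$n_I,
                      file.path(dir, "partition.csv"))
  for (sn in result$snapshots) {
    write_snapshot_mtx(sn$A, file.path(dir, sprintf("A_t%07.1f.mtx", sn$t)))
  }
  if (!is.null(result$spikes)) {
    write_spikes(result$spikes, file.path(dir, "spikes.txt"))
  }
  invisible(dir)
}
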