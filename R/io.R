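# Plain-text readers and writers for the pipeline's external interfaces:
# time-series TSV (volumes x nodes), BIDS-style events and confounds TSV,
# phenotype CSV, node metadata TSV, adjacency TSV, JSON reports.

#' Write one run's ROI time series as TSV
#' @param run an [roi_run()].
#' @param path output file.
#' @export
write_timeseries_tsv <- function(run, path) {
  utils::write.table(run$data, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a run's ROI time series from TSV
#' @param path TSV with a header of node ids.
#' @param tr_seconds,run_id passed to [roi_run()].
#' @return an [roi_run()].
#' @export
read_timeseries_tsv <- function(path, tr_seconds = 2, run_id = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  roi_run(as.matrix(d), tr_seconds = tr_seconds,
          run_id = run_id %||% sub("\\.tsv$", "", basename(path)))
}

#' Read a BIDS-style confounds TSV
#'
#' Expects fMRIPrep-named columns `framewise_displacement` and `std_dvars`;
#' "n/a" and NaN entries (the conventional first row) are treated as 0.
#'
#' @param path TSV path.
#' @return data.frame with numeric framewise_displacement and std_dvars.
#' @export
read_confounds_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         na.strings = c("n/a", "NA", "NaN"))
  need <- c("framewise_displacement", "std_dvars")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_field("confounds", paste("missing columns:",
                                  paste(miss, collapse = ", ")))
  }
  d$framewise_displacement[is.na(d$framewise_displacement)] <- 0
  d$std_dvars[is.na(d$std_dvars)] <- 0
  d[, need]
}

#' Read a BIDS-style events TSV
#' @param path TSV with onset, duration, trial_type.
#' @return data.frame.
#' @export
read_events_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_field("events", paste("missing columns:",
                               paste(miss, collapse = ", ")))
  }
  d
}

#' Write a symmetric adjacency matrix as TSV with node ids
#' @param m matrix with dimnames.
#' @param path output file.
#' @export
write_adjacency_tsv <- function(m, path) {
  utils::write.table(cbind(node_id = rownames(m), as.data.frame(m)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an adjacency TSV written by [write_adjacency_tsv()]
#' @param path TSV path.
#' @return symmetric numeric matrix with dimnames.
#' @export
read_adjacency_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$node_id
  m
}

#' Write a full synthetic cohort to a BIDS-flavoured directory tree
#'
#' Per participant: one time-series, events and confounds TSV per run; one
#' phenotype CSV row (participants.csv at the top level); the latent truth
#' as JSON.
#'
#' @param cohort a `synthetic_cohort` from [simulate_cohort()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    pid <- p$phenotype$participant_id
    pd <- file.path(dir, pid)
    dir.create(pd, showWarnings = FALSE)
    for (r in seq_along(p$runs)) {
      run <- p$runs[[r]]
      write_timeseries_tsv(run, file.path(pd, sprintf("%s_%s_timeseries.tsv",
                                                      pid, run$run_id)))
      utils::write.table(p$events[[r]],
                         file.path(pd, sprintf("%s_%s_events.tsv", pid,
                                               run$run_id)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      conf <- p$confounds[[r]]
      conf_out <- data.frame(
        framewise_displacement = c("n/a",
                                   conf$framewise_displacement[-1]),
        std_dvars = c("n/a", conf$std_dvars[-1]))
      utils::write.table(conf_out,
                         file.path(pd, sprintf("%s_%s_confounds.tsv", pid,
                                               run$run_id)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    truth <- p$truth
    truth$planted_edges <- if (is.null(truth$planted_edges)) NULL else
      as.data.frame(truth$planted_edges)
    jsonlite::write_json(truth, file.path(pd, sprintf("%s_truth.json", pid)),
                         auto_unbox = TRUE, digits = NA)
  }
  utils::write.csv(cohort_phenotypes(cohort),
                   file.path(dir, "participants.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir cohort directory.
#' @param tr_seconds repetition time for the runs.
#' @return list of participants (runs, events, confounds, phenotype).
#' @export
read_cohort <- function(dir, tr_seconds = 2) {
  pheno <- utils::read.csv(file.path(dir, "participants.csv"),
                           stringsAsFactors = FALSE)
  lapply(seq_len(nrow(pheno)), function(i) {
    pid <- pheno$participant_id[i]
    pd <- file.path(dir, pid)
    ts_files <- sort(list.files(pd, pattern = "_timeseries\\.tsv$",
                                full.names = TRUE))
    if (!length(ts_files)) {
      stop_field("dir", paste("no time-series files under", pd))
    }
    runs <- lapply(ts_files, function(f) {
      rid <- sub(".*_(run-\\d+)_timeseries\\.tsv$", "\\1", f)
      read_timeseries_tsv(f, tr_seconds = tr_seconds, run_id = rid)
    })
    events <- lapply(sort(list.files(pd, pattern = "_events\\.tsv$",
                                     full.names = TRUE)), read_events_tsv)
    confounds <- lapply(sort(list.files(pd, pattern = "_confounds\\.tsv$",
                                        full.names = TRUE)),
                        read_confounds_tsv)
    list(runs = runs, events = events, confounds = confounds,
         phenotype = pheno[i, , drop = FALSE])
  })
}

#' Dump a multilayer partition as TSV (window, node_id, community)
#' @param partition a `multilayer_partition`.
#' @param path output file.
#' @export
write_partition_tsv <- function(partition, path) {
  lab <- partition$labels
  d <- data.frame(window = rep(seq_len(nrow(lab)), each = ncol(lab)),
                  node_id = rep(colnames(lab), nrow(lab)),
                  community = as.integer(t(lab)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
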