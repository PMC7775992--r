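# Participant- and cohort-level quality control, plus task-event regression.

#' Summarise motion traces for one participant
#'
#' @param fd per-volume framewise displacement (mm); concatenated across runs.
#' @param dvars per-volume standardized DVARS (%), aligned with `fd`.
#' @return object of class `motion_summary` with mean FD and the proportions
#'   of volumes exceeding the FD and DVARS spike thresholds.
#' @param fd_volume FD spike threshold in mm (default 0.25).
#' @param dvars_volume DVARS spike threshold in percent (default 4).
#' @export
motion_summary <- function(fd, dvars, fd_volume = 0.25, dvars_volume = 4) {
  if (length(fd) != length(dvars)) {
    stop_field("dvars", "fd and dvars must align volume-for-volume")
  }
  fd[is.na(fd)] <- 0
  dvars[is.na(dvars)] <- 0
  assert_that(all(fd >= 0), "fd", "must be non-negative")
  assert_that(all(dvars >= 0), "dvars", "must be non-negative")
  structure(
    list(fd = fd, dvars = dvars,
         mean_fd = mean(fd),
         frac_fd_gt = mean(fd > fd_volume),
         frac_dvars_gt = mean(dvars > dvars_volume),
         fd_volume = fd_volume, dvars_volume = dvars_volume),
    class = "motion_summary"
  )
}

#' Motion-based participant exclusion
#'
#' A participant is excluded if more than `fd_frac` of volumes have
#' FD > `fd_volume` mm, or more than `fd_frac` of volumes have
#' DVARS > `dvars_volume` %, or mean FD exceeds `mean_fd_max` mm. Every
#' triggered rule is listed in the decision.
#'
#' @param ms a [motion_summary()].
#' @param fd_frac maximal tolerated proportion of FD/DVARS spike volumes
#'   (default 0.25).
#' @param mean_fd_max maximal tolerated mean FD in mm (default 0.2).
#' @return list with `keep` (logical) and `reasons` (character vector of
#'   triggered rules, empty if kept).
#' @export
motion_exclude <- function(ms, fd_frac = 0.25, mean_fd_max = 0.2) {
  stopifnot(inherits(ms, "motion_summary"))
  reasons <- character(0)
  if (ms$frac_fd_gt > fd_frac) {
    reasons <- c(reasons, sprintf("frac(FD > %g mm) = %.3f > %g",
                                  ms$fd_volume, ms$frac_fd_gt, fd_frac))
  }
  if (ms$frac_dvars_gt > fd_frac) {
    reasons <- c(reasons, sprintf("frac(DVARS > %g%%) = %.3f > %g",
                                  ms$dvars_volume, ms$frac_dvars_gt, fd_frac))
  }
  if (ms$mean_fd > mean_fd_max) {
    reasons <- c(reasons, sprintf("mean FD = %.3f > %g mm",
                                  ms$mean_fd, mean_fd_max))
  }
  list(keep = length(reasons) == 0L, reasons = reasons)
}

#' Cohort-wide signal-dropout node mask
#'
#' Within each participant, mean node signal intensities are z-scored across
#' nodes (sample SD); a node is dropped from the whole cohort if its z falls
#' at or below `z_threshold` in any participant.
#'
#' @param mean_signals participants x nodes matrix of mean node signal
#'   intensities (runs already averaged per node).
#' @param z_threshold inclusive dropout threshold (default -1.64, the 5th
#'   percentile of a standard normal).
#' @return object of class `node_mask` with `kept` ids and a `dropped`
#'   data.frame (node_id, reason).
#' @export
flag_dropout_nodes <- function(mean_signals, z_threshold = -1.64) {
  mean_signals <- as.matrix(mean_signals)
  node_ids <- colnames(mean_signals) %||%
    paste0("node_", seq_len(ncol(mean_signals)))
  dropped <- character(0)
  reasons <- character(0)
  for (p in seq_len(nrow(mean_signals))) {
    x <- mean_signals[p, ]
    s <- stats::sd(x)
    if (is.na(s) || s == 0) {
      stop_field("mean_signals",
                 sprintf("participant %d has zero variance across nodes", p))
    }
    z <- (x - mean(x)) / s
    hit <- which(z <= z_threshold)
    for (h in hit) {
      if (!(node_ids[h] %in% dropped)) {
        dropped <- c(dropped, node_ids[h])
        reasons <- c(reasons,
                     sprintf("z = %.3f <= %g in participant %d", z[h],
                             z_threshold, p))
      }
    }
  }
  keep_order <- node_ids[!(node_ids %in% dropped)]
  drop_df <- data.frame(node_id = dropped, reason = reasons,
                        stringsAsFactors = FALSE)
  structure(list(kept = keep_order, dropped = drop_df),
            class = "node_mask")
}

#' Apply a node mask to a run
#'
#' @param run an [roi_run()].
#' @param mask a `node_mask` from [flag_dropout_nodes()].
#' @return the run restricted to the kept nodes.
#' @export
apply_node_mask <- function(run, mask) {
  stopifnot(inherits(run, "roi_run"), inherits(mask, "node_mask"))
  keep <- intersect(run$node_ids, mask$kept)
  roi_run(run$data[, keep, drop = FALSE], tr_seconds = run$tr_seconds,
          run_id = run$run_id, node_ids = keep)
}

#' Regress task-event regressors out of every node's time series
#'
#' Per node, ordinary least squares of the series on an intercept plus the
#' supplied HRF-convolved regressors; the residuals replace the series.
#' Residualising is idempotent and leaves residuals orthogonal to every
#' regressor column. Collinear regressor columns are dropped with a warning.
#'
#' @param run an [roi_run()].
#' @param regressors volumes x k numeric matrix (no intercept column).
#' @return residualised [roi_run()] with node order and shape preserved.
#' @export
regress_task_events <- function(run, regressors) {
  stopifnot(inherits(run, "roi_run"))
  regressors <- as.matrix(regressors)
  assert_that(nrow(regressors) == nrow(run$data), "regressors",
              "rows must equal volumes")
  X <- cbind(1, regressors)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- setdiff(seq_len(ncol(X)), keep)
    warning(sprintf("dropping %d collinear regressor column(s)",
                    length(dropped)))
    X <- X[, sort(keep), drop = FALSE]
    qrx <- qr(X)
  }
  resid <- qr.resid(qrx, run$data)
  colnames(resid) <- run$node_ids
  roi_run(resid, tr_seconds = run$tr_seconds, run_id = run$run_id,
          node_ids = run$node_ids)
}

#' Cohort QC report
#'
#' Runs motion exclusion for every participant and assembles a
#' machine-readable report.
#'
#' @param cohort list of synthetic participants (see [simulate_cohort()]) or
#'   any list whose elements carry `confounds` (per run: data.frame with
#'   framewise_displacement, std_dvars) and `phenotype$participant_id`.
#' @param fd_volume,fd_frac,dvars_volume,mean_fd_max thresholds, see
#'   [motion_summary()] and [motion_exclude()].
#' @return data.frame, one row per participant: id, keep, reasons (collapsed),
#'   mean_fd, frac_fd_gt, frac_dvars_gt.
#' @export
qc_report <- function(cohort, fd_volume = 0.25, fd_frac = 0.25,
                      dvars_volume = 4, mean_fd_max = 0.2) {
  rows <- lapply(cohort, function(p) {
    fd <- unlist(lapply(p$confounds, `[[`, "framewise_displacement"))
    dv <- unlist(lapply(p$confounds, `[[`, "std_dvars"))
    ms <- motion_summary(fd, dv, fd_volume = fd_volume,
                         dvars_volume = dvars_volume)
    dec <- motion_exclude(ms, fd_frac = fd_frac, mean_fd_max = mean_fd_max)
    data.frame(participant_id = p$phenotype$participant_id,
               keep = dec$keep,
               reasons = paste(dec$reasons, collapse = "; "),
               mean_fd = ms$mean_fd,
               frac_fd_gt = ms$frac_fd_gt,
               frac_dvars_gt = ms$frac_dvars_gt,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
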