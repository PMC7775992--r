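# Cartographic profiles and metastate labelling.
#
# Each time window gets a 2-D histogram (the cartographic profile, CP) of
# node-wise participation coefficient (between-community connectivity) and
# module degree z-score (within-community connectivity), computed against
# that window's multilayer community labels. k-means (k = 2) over a
# participant's CPs separates integrated from segregated windows; the
# cluster whose centroid carries more mass at high participation
# coefficients is the integrated one.

#' Participation coefficient
#'
#' `PC_i = 1 - sum_s (kappa_is / k_i)^2` where `kappa_is` is node i's strength
#' into community s and `k_i` its total strength. Isolated nodes get 0.
#'
#' @param w symmetric non-negative weight matrix (diagonal ignored).
#' @param labels integer community label per node.
#' @return numeric vector of per-node participation coefficients in \[0, 1\].
#' @export
participation_coefficient <- function(w, labels) {
  w <- as.matrix(w)
  if (any(w < 0)) stop_field("w", "negative weights; apply the signed-weight policy first")
  diag(w) <- 0
  assert_that(length(labels) == nrow(w), "labels", "one label per node")
  k <- rowSums(w)
  memb <- outer(labels, sort(unique(labels)), "==") + 0
  kappa <- w %*% memb
  pc <- 1 - rowSums((kappa / ifelse(k == 0, 1, k))^2)
  pc[k == 0] <- 0
  as.numeric(pc)
}

#' Module degree z-score
#'
#' Within-module strength of each node, z-scored against the other members of
#' its module (sample SD, n - 1). Modules with fewer than 2 nodes or zero
#' spread give z = 0.
#'
#' @inheritParams participation_coefficient
#' @return numeric vector of per-node module degree z-scores.
#' @export
module_degree_zscore <- function(w, labels) {
  w <- as.matrix(w)
  if (any(w < 0)) stop_field("w", "negative weights; apply the signed-weight policy first")
  diag(w) <- 0
  assert_that(length(labels) == nrow(w), "labels", "one label per node")
  z <- numeric(nrow(w))
  for (c in unique(labels)) {
    idx <- which(labels == c)
    if (length(idx) < 2) next
    kin <- rowSums(w[idx, idx, drop = FALSE])
    s <- stats::sd(kin)
    if (is.na(s) || s == 0) next
    z[idx] <- (kin - mean(kin)) / s
  }
  z
}

#' Cartographic profile of one window
#'
#' 2-D histogram over fixed bin edges: participation coefficient on \[0, 1\]
#' and module degree z-score clipped to \[-3, 3\], each in `bins` equal bins,
#' normalised to sum to 1. Fixed edges keep profiles comparable across
#' windows and participants.
#'
#' @param pc per-node participation coefficients.
#' @param mdz per-node module degree z-scores.
#' @param bins bins per axis (default 10).
#' @param window_ref optional (run, window) identifier carried through.
#' @return object of class `cartographic_profile` with field `histogram`
#'   (bins x bins matrix, PC rows x MDZ columns).
#' @export
cartographic_profile <- function(pc, mdz, bins = 10L, window_ref = NULL) {
  assert_that(length(pc) == length(mdz), "pc", "pc and mdz lengths differ")
  assert_that(all(pc >= -1e-9 & pc <= 1 + 1e-9), "pc", "must lie in [0, 1]")
  pc_bin <- pmin(pmax(floor(pc * bins) + 1L, 1L), bins)
  mdz_c <- pmin(pmax(mdz, -3), 3)
  mdz_bin <- pmin(pmax(floor((mdz_c + 3) / 6 * bins) + 1L, 1L), bins)
  h <- matrix(0, bins, bins)
  for (i in seq_along(pc)) h[pc_bin[i], mdz_bin[i]] <- h[pc_bin[i], mdz_bin[i]] + 1
  h <- h / length(pc)
  structure(list(histogram = h, bins = bins, window_ref = window_ref),
            class = "cartographic_profile")
}

# Flatten CPs (column-major: PC index varies fastest) into a feature matrix
cp_features <- function(profiles) {
  t(vapply(profiles, function(p) as.vector(p$histogram),
           numeric(profiles[[1L]]$bins^2)))
}

# Mass-weighted expected PC of a flattened centroid
centroid_expected_pc <- function(centroid, bins) {
  pc_centers <- (seq_len(bins) - 0.5) / bins
  w <- rep(pc_centers, times = bins)
  sum(centroid * w) / sum(centroid)
}

#' k-means metastate labelling of window profiles
#'
#' Clusters a participant's cartographic profiles (pooled across runs, one
#' repetition) into k = 2 states by Euclidean k-means on the flattened
#' histograms, then names the cluster with the higher mass-weighted mean PC
#' "integrated" and the other "segregated".
#'
#' @param profiles list of `cartographic_profile`, one per window, pooled
#'   across runs in run order.
#' @param run_ids character vector aligning each profile to its run.
#' @param k number of states (default 2; only 2 receives semantic labels).
#' @param seed integer seed for k-means restarts.
#' @param repetition repetition index carried through.
#' @return object of class `metastate_labeling`: `labels` (character vector
#'   "integrated"/"segregated"), `run_ids`, `frac_integrated`,
#'   `n_switches_per_run`, `repetition`.
#' @export
kmeans_metastates <- function(profiles, run_ids = NULL, k = 2L, seed = 1L,
                              repetition = 1L) {
  assert_that(length(profiles) >= 2, "profiles", "need at least 2 windows")
  X <- cp_features(profiles)
  if (nrow(unique(X)) < k) {
    stop_field("profiles", "fewer distinct profiles than clusters; no clustering possible")
  }
  if (is.null(run_ids)) run_ids <- rep("run-1", length(profiles))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = 10L, iter.max = 100L)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  bins <- profiles[[1L]]$bins
  epc <- apply(km$centers, 1L, centroid_expected_pc, bins = bins)
  integrated_cluster <- which.max(epc)
  labels <- ifelse(km$cluster == integrated_cluster, "integrated", "segregated")
  switches <- vapply(split(labels, factor(run_ids, levels = unique(run_ids))),
                     function(l) sum(l[-1L] != l[-length(l)]), numeric(1))
  structure(
    list(labels = labels, run_ids = run_ids,
         frac_integrated = mean(labels == "integrated"),
         n_switches_per_run = switches,
         repetition = as.integer(repetition), k = k, seed = as.integer(seed)),
    class = "metastate_labeling"
  )
}

#' Mean integrated connectivity network for one participant
#'
#' Per repetition, the signed window coupling matrices labelled "integrated"
#' (pooled over runs) are averaged; the final network is the unweighted mean
#' over repetitions. Repetitions with no integrated window are skipped with a
#' warning.
#'
#' @param stacks list of `window_stack` (one per run, in order).
#' @param labelings list of `metastate_labeling`, one per repetition, each
#'   covering all windows of all runs in the same pooled order.
#' @return object of class `integrated_network` with `mean_fc` (symmetric
#'   matrix), `n_windows_used` (per repetition), `n_repetitions`, `n_runs`.
#' @export
integrated_network <- function(stacks, labelings) {
  if (inherits(labelings, "metastate_labeling")) labelings <- list(labelings)
  all_windows <- do.call(c, lapply(stacks, `[[`, "windows"))
  n_win <- length(all_windows)
  N <- length(stacks[[1L]]$node_ids)
  acc <- matrix(0, N, N)
  used <- integer(0)
  n_used_reps <- 0L
  for (lab in labelings) {
    assert_that(length(lab$labels) == n_win, "labelings",
                "every window needs a label in every repetition")
    sel <- which(lab$labels == "integrated")
    if (!length(sel)) {
      warning(sprintf("repetition %d has no integrated window; skipped",
                      lab$repetition))
      used <- c(used, 0L)
      next
    }
    rep_mean <- Reduce(`+`, all_windows[sel]) / length(sel)
    acc <- acc + rep_mean
    used <- c(used, length(sel))
    n_used_reps <- n_used_reps + 1L
  }
  if (n_used_reps == 0L) stop_field("labelings", "no repetition had integrated windows")
  mean_fc <- acc / n_used_reps
  dimnames(mean_fc) <- list(stacks[[1L]]$node_ids, stacks[[1L]]$node_ids)
  structure(
    list(mean_fc = mean_fc, n_windows_used = used,
         n_repetitions = length(labelings), n_runs = length(stacks),
         node_ids = stacks[[1L]]$node_ids),
    class = "integrated_network"
  )
}

#' Participant metastate summary
#'
#' Percent time integrated (all windows pooled) and metastate switches per
#' run (consecutive-window label changes within a run, not across run
#' boundaries), each averaged across runs and repetitions.
#'
#' @param labelings a `metastate_labeling` or list of them (repetitions).
#' @return list with `pct_integrated` and `mean_switches`.
#' @export
metastate_stats <- function(labelings) {
  if (inherits(labelings, "metastate_labeling")) labelings <- list(labelings)
  pct <- vapply(labelings, function(l) 100 * l$frac_integrated, numeric(1))
  sw <- vapply(labelings, function(l) mean(l$n_switches_per_run), numeric(1))
  list(pct_integrated = mean(pct), mean_switches = mean(sw))
}
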