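# End-to-end orchestration: simulate/load -> QC -> coupling -> multilayer
# communities -> cartographic metastates -> integrated networks -> NBS ->
# cohort report, under one root seed.

#' Pipeline configuration
#'
#' Flat key-value configuration carrying the analysis constants. Unknown
#' keys are rejected to guard against silent typos.
#'
#' @param window_length_tr MTD window length in derivative points (15 TR,
#'   30 s at TR 2 s).
#' @param window_offset initial derivative points skipped (default 0).
#' @param cp_bins cartographic-profile bins per axis (default 10).
#' @param gamma,omega multilayer modularity resolution and inter-layer
#'   coupling (default 1 and 1).
#' @param n_repetitions repetitions of the non-deterministic community +
#'   clustering stage (default 100).
#' @param k_states metastate clusters (default 2).
#' @param nbs_thresholds F thresholds for the sweep (default 6:28).
#' @param n_permutations NBS permutations (default 5000).
#' @param alpha FWE significance level (default 0.025).
#' @param fd_volume,fd_frac,dvars_volume,mean_fd_max motion exclusion
#'   thresholds (0.25 mm, 25%, 4%, 0.2 mm).
#' @param dropout_z node dropout z threshold (default -1.64, inclusive).
#' @param seed root seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_length_tr = 15L, window_offset = 0L,
                            cp_bins = 10L, gamma = 1, omega = 1,
                            n_repetitions = 100L, k_states = 2L,
                            nbs_thresholds = 6:28, n_permutations = 5000L,
                            alpha = 0.025, fd_volume = 0.25, fd_frac = 0.25,
                            dvars_volume = 4, mean_fd_max = 0.2,
                            dropout_z = -1.64, seed = 1L) {
  cfg <- list(window_length_tr = as.integer(window_length_tr),
              window_offset = as.integer(window_offset),
              cp_bins = as.integer(cp_bins), gamma = gamma, omega = omega,
              n_repetitions = as.integer(n_repetitions),
              k_states = as.integer(k_states),
              nbs_thresholds = nbs_thresholds,
              n_permutations = as.integer(n_permutations), alpha = alpha,
              fd_volume = fd_volume, fd_frac = fd_frac,
              dvars_volume = dvars_volume, mean_fd_max = mean_fd_max,
              dropout_z = dropout_z, seed = as.integer(seed))
  assert_that(alpha > 0 && alpha < 0.5, "alpha", "must lie in (0, 0.5)")
  assert_that(cfg$window_length_tr >= 2, "window_length_tr", "must be >= 2")
  assert_that(cfg$n_repetitions >= 1, "n_repetitions", "must be >= 1")
  structure(cfg, class = "pipeline_config")
}

# update a config from a named list, rejecting unknown keys
update_config <- function(config, updates) {
  unknown <- setdiff(names(updates), names(unclass(config)))
  if (length(unknown)) {
    stop_field("config", paste("unknown keys:", paste(unknown, collapse = ", ")))
  }
  for (k in names(updates)) config[[k]] <- updates[[k]]
  config
}

#' Pool per-run window stacks into one multilayer sequence
#'
#' Concatenates the windows of a participant's runs into a single ordered
#' `window_stack` so that community structure is found once over all time
#' windows and community identities share one frame across runs.
#'
#' @param stacks list of `window_stack` objects (one per run, same nodes).
#' @return a `window_stack` whose `run_ids` field aligns windows to runs.
#' @export
pool_stacks <- function(stacks) {
  windows <- do.call(c, lapply(stacks, `[[`, "windows"))
  run_ids <- unlist(lapply(stacks, function(s)
    rep(s$run_id, length(s$windows))))
  structure(
    list(windows = windows, window_length_tr = stacks[[1L]]$window_length_tr,
         offset = stacks[[1L]]$offset, run_id = "pooled",
         node_ids = stacks[[1L]]$node_ids, run_ids = run_ids),
    class = "window_stack"
  )
}

# per-node flexibility over a pooled partition, excluding transitions that
# cross run boundaries (runs are separate acquisitions)
pooled_flexibility <- function(partition, run_ids) {
  lab <- partition$labels
  S <- nrow(lab)
  if (S < 2) stop_field("partition", "flexibility needs at least 2 layers")
  within_run <- run_ids[-1L] == run_ids[-S]
  changes <- (lab[-1L, , drop = FALSE] != lab[-S, , drop = FALSE])[within_run, ,
                                                                   drop = FALSE]
  mean(colMeans(changes))
}

#' Metastate analysis for one participant
#'
#' Runs MTD windowing per run, then `n_repetitions` independent rounds of
#' multilayer community detection over the pooled window sequence,
#' per-window cartographic profiles, and pooled k-means metastate
#' labelling; finally averages the integrated windows into the
#' participant's mean integrated network.
#'
#' @param runs list of (residualised, masked) [roi_run()] objects.
#' @param config a [pipeline_config()].
#' @param seed participant-level seed (repetitions derive from it).
#' @return list with `stacks`, `labelings` (per repetition),
#'   `integrated` ([integrated_network()]), `static` (mean over all
#'   windows), `stats` (pct integrated, switches), `flexibility`,
#'   `community_count` (mean over layers and repetitions), and the first
#'   repetition's pooled `partition`.
#' @export
analyze_participant <- function(runs, config = pipeline_config(), seed = 1L) {
  stacks <- lapply(runs, mtd_stack,
                   window_length = config$window_length_tr,
                   offset = config$window_offset)
  pooled <- pool_stacks(stacks)
  run_ids <- pooled$run_ids
  labelings <- vector("list", config$n_repetitions)
  flex <- comm <- numeric(config$n_repetitions)
  first_partition <- NULL
  for (rep_i in seq_len(config$n_repetitions)) {
    part <- multilayer_modularity(pooled, gamma = config$gamma,
                                  omega = config$omega,
                                  seed = derive_seed(seed, rep_i))
    if (rep_i == 1L) first_partition <- part
    profiles <- vector("list", length(pooled$windows))
    for (w in seq_along(pooled$windows)) {
      wmat <- pooled$windows[[w]]
      wmat[wmat < 0] <- 0
      labs <- part$labels[w, ]
      pc <- participation_coefficient(wmat, labs)
      mdz <- module_degree_zscore(wmat, labs)
      profiles[[w]] <- cartographic_profile(pc, mdz, bins = config$cp_bins,
                                            window_ref = c(run_ids[w], w))
    }
    labelings[[rep_i]] <- kmeans_metastates(
      profiles, run_ids = run_ids, k = config$k_states,
      seed = derive_seed(seed, rep_i, 1000L), repetition = rep_i)
    flex[rep_i] <- pooled_flexibility(part, run_ids)
    comm[rep_i] <- community_count(part)$run_mean
  }
  integ <- integrated_network(stacks, labelings)
  all_windows <- pooled$windows
  static <- Reduce(`+`, all_windows) / length(all_windows)
  dimnames(static) <- dimnames(integ$mean_fc)
  list(stacks = stacks, labelings = labelings, integrated = integ,
       static = static, stats = metastate_stats(labelings),
       flexibility = mean(flex), community_count = mean(comm),
       partition = first_partition)
}

#' Run the full pipeline
#'
#' Simulate (or load) a cohort, apply motion and dropout QC, regress task
#' events, run the metastate stage per participant, write per-participant
#' integrated networks and cohort summaries, run NBS for the group contrast
#' and the positive symptom-change regression, and record a manifest. Fully
#' deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param spec a [cohort_spec()] to simulate, or `NULL` with `input_dir`.
#' @param input_dir cohort directory from [write_cohort()] (used when `spec`
#'   is NULL).
#' @param out_dir artifact directory (created).
#' @param stages character subset of
#'   c("simulate","qc","coupling","metastates","nbs","report"); later stages
#'   reuse earlier artifacts in `out_dir` (re-entrant).
#' @return list with the cohort summaries, NBS results and manifest
#'   (invisibly also written under `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config(), spec = NULL,
                         input_dir = NULL, out_dir = tempfile("dynfc_"),
                         stages = c("simulate", "qc", "coupling",
                                    "metastates", "nbs", "report")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  # --- simulate / load -----------------------------------------------------
  if (!is.null(spec)) {
    cohort <- simulate_cohort(spec)
  } else {
    if (is.null(input_dir) || !dir.exists(input_dir)) {
      stop_field("input_dir", "missing input directory and no simulation spec")
    }
    cohort <- read_cohort(input_dir)
  }
  pheno <- do.call(rbind, lapply(cohort, `[[`, "phenotype"))

  # --- qc ------------------------------------------------------------------
  qc <- qc_report(cohort, fd_volume = config$fd_volume,
                  fd_frac = config$fd_frac,
                  dvars_volume = config$dvars_volume,
                  mean_fd_max = config$mean_fd_max)
  jsonlite::write_json(qc, file.path(out_dir, "qc_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  kept <- which(qc$keep)
  if (!length(kept)) stop("all participants excluded by motion QC")
  cohort <- cohort[kept]
  pheno <- pheno[kept, , drop = FALSE]

  # node dropout mask on run-averaged mean node signals
  mean_signals <- t(vapply(cohort, function(p) {
    rowMeans(vapply(p$runs, function(r) colMeans(r$data),
                    numeric(ncol(p$runs[[1]]$data))))
  }, numeric(ncol(cohort[[1]]$runs[[1]]$data))))
  colnames(mean_signals) <- cohort[[1]]$runs[[1]]$node_ids
  mask <- flag_dropout_nodes(mean_signals, z_threshold = config$dropout_z)

  # --- coupling prep: mask + event regression -----------------------------
  prepped <- lapply(cohort, function(p) {
    runs <- lapply(seq_along(p$runs), function(r) {
      run <- apply_node_mask(p$runs[[r]], mask)
      ev <- if (length(p$events) >= r) p$events[[r]] else NULL
      if (!is.null(ev) && nrow(ev)) {
        reg <- make_hrf_regressor(ev, nrow(run$data), run$tr_seconds)
        run <- regress_task_events(run, reg)
      }
      run
    })
    runs
  })

  # --- metastates ---------------------------------------------------------
  participant_results <- vector("list", length(prepped))
  for (i in seq_along(prepped)) {
    participant_results[[i]] <-
      analyze_participant(prepped[[i]], config,
                          seed = derive_seed(config$seed, 7L, kept[i]))
    pid <- pheno$participant_id[i]
    write_adjacency_tsv(participant_results[[i]]$integrated$mean_fc,
                        file.path(out_dir,
                                  sprintf("%s_integrated_network.tsv", pid)))
    write_partition_tsv(participant_results[[i]]$partition,
                        file.path(out_dir, sprintf("%s_partition.tsv", pid)))
  }
  summary_df <- data.frame(
    participant_id = pheno$participant_id,
    group = pheno$group,
    pct_integrated = vapply(participant_results,
                            function(x) x$stats$pct_integrated, numeric(1)),
    mean_switches = vapply(participant_results,
                           function(x) x$stats$mean_switches, numeric(1)),
    flexibility = vapply(participant_results, `[[`, numeric(1),
                         "flexibility"),
    mean_communities = vapply(participant_results, `[[`, numeric(1),
                              "community_count"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(summary_df, file.path(out_dir, "metastate_summary.csv"),
                   row.names = FALSE)

  # --- nbs ----------------------------------------------------------------
  networks <- lapply(participant_results, `[[`, "integrated")
  nbs_out <- list()
  if ("nbs" %in% stages) {
    thr <- config$nbs_thresholds[ceiling(length(config$nbs_thresholds) / 2)]
    if (length(unique(pheno$group)) == 2 &&
        min(table(pheno$group)) >= 3) {
      des_g <- nbs_design("group",
                          covariates = intersect(
                            c("age", "mean_fd", "antipsychotic",
                              "antidepressant"), names(pheno)),
                          kind = "ancova")
      nbs_out$group <- permutation_fwe(networks, pheno, des_g, threshold = thr,
                                       n_perm = config$n_permutations,
                                       seed = derive_seed(config$seed, 11L))
    }
    chr <- pheno$group == "CHR"
    if (sum(chr) >= 10) {
      ph_chr <- pheno[chr, , drop = FALSE]
      ph_chr$delta_panss_pos <- ph_chr$panss_pos_followup -
        ph_chr$panss_pos_baseline
      des_s <- nbs_design("delta_panss_pos",
                          covariates = intersect(
                            c("sex", "age", "mean_fd", "antipsychotic",
                              "antidepressant", "days_to_followup"),
                            names(ph_chr)),
                          kind = "regression")
      nbs_out$symptom_change <- permutation_fwe(
        networks[chr], ph_chr, des_s, threshold = thr,
        n_perm = config$n_permutations,
        seed = derive_seed(config$seed, 13L))
    }
    nbs_json <- lapply(nbs_out, function(res) {
      list(threshold = res$threshold, n_permutations = res$n_permutations,
           components = lapply(res$components, function(cmp) {
             list(extent = cmp$extent, fwe_p = cmp$fwe_p,
                  nodes = cmp$nodes)
           }))
    })
    jsonlite::write_json(nbs_json, file.path(out_dir, "nbs_results.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  # --- report + manifest --------------------------------------------------
  report <- cohort_stats(summary_df)
  jsonlite::write_json(report, file.path(out_dir, "cohort_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(
    config = unclass(config),
    n_participants_in = length(kept) + sum(!qc$keep),
    n_participants_kept = length(kept),
    n_nodes_kept = length(mask$kept),
    nodes_dropped = mask$dropped$node_id,
    n_windows_per_run = length(participant_results[[1L]]$stacks[[1L]]$windows),
    n_windows_total = sum(vapply(participant_results[[1L]]$stacks,
                                 function(s) length(s$windows), numeric(1))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("dynfc")),
    elapsed_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(qc = qc, node_mask = mask, summary = summary_df,
                 networks = networks, nbs = nbs_out, report = report,
                 manifest = manifest, out_dir = out_dir,
                 participant_results = participant_results, pheno = pheno))
}

#' Cohort-level descriptive statistics
#'
#' Group means/SDs and Welch two-sample tests on the metastate metrics, plus
#' optional Spearman correlations between requested column pairs. All tests
#' are descriptive (no multiplicity correction).
#'
#' @param summary_df data.frame with participant_id, group and metric
#'   columns (as produced by [run_pipeline()]).
#' @param cor_pairs optional list of 2-element character vectors naming
#'   column pairs for Spearman correlations.
#' @return object of class `cohort_report`.
#' @export
cohort_stats <- function(summary_df, cor_pairs = NULL) {
  metrics <- setdiff(names(summary_df),
                     c("participant_id", "group"))
  groups <- unique(summary_df$group)
  per_group <- lapply(metrics, function(m) {
    s <- lapply(groups, function(g) {
      x <- summary_df[[m]][summary_df$group == g]
      list(group = g, n = length(x), mean = mean(x), sd = stats::sd(x),
           median = stats::median(x))
    })
    names(s) <- groups
    s
  })
  names(per_group) <- metrics
  tests <- list()
  if (length(groups) == 2 && all(table(summary_df$group) >= 2)) {
    for (m in metrics) {
      x <- summary_df[[m]][summary_df$group == groups[1]]
      y <- summary_df[[m]][summary_df$group == groups[2]]
      tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
      wt <- tryCatch(stats::wilcox.test(x, y, exact = FALSE),
                     error = function(e) NULL)
      tests[[m]] <- list(
        metric = m, n = c(length(x), length(y)),
        t = if (!is.null(tt)) unname(tt$statistic) else NA,
        t_p = if (!is.null(tt)) tt$p.value else NA,
        mw_u = if (!is.null(wt)) unname(wt$statistic) else NA,
        mw_p = if (!is.null(wt)) wt$p.value else NA,
        mean_difference = mean(x) - mean(y))
    }
  }
  cors <- list()
  if (!is.null(cor_pairs)) {
    for (pair in cor_pairs) {
      r <- stats::cor(summary_df[[pair[1]]], summary_df[[pair[2]]],
                      method = "spearman", use = "complete.obs")
      cors[[paste(pair, collapse = "~")]] <-
        list(pair = pair, spearman_rho = r, n = nrow(summary_df))
    }
  }
  structure(list(per_group = per_group, tests = tests,
                 correlations = cors),
            class = "cohort_report")
}

#' Parameter sweep over window length, offset and CP resolution
#'
#' Runs the metastate stage of a (small) cohort over a grid of configuration
#' values with shared seeds, reporting mean % time integrated and the
#' stability of metastate labels (adjusted Rand index between two
#' independently seeded repetitions) per cell. Infeasible cells (window
#' longer than a run) are marked skipped.
#'
#' @param config base [pipeline_config()].
#' @param axes named list with any of `window_length`, `window_offset`,
#'   `cp_bins`, each a vector of values.
#' @param spec a [cohort_spec()] for the sweep cohort.
#' @return data.frame: one row per grid cell with parameters,
#'   `pct_integrated`, `label_stability_ari`, `skipped`.
#' @export
parameter_sweep <- function(config, axes, spec) {
  assert_that(length(axes) >= 1, "axes", "must be non-empty")
  allowed <- c("window_length", "window_offset", "cp_bins")
  assert_that(all(names(axes) %in% allowed), "axes",
              paste("allowed axes:", paste(allowed, collapse = ", ")))
  grid <- expand.grid(axes, stringsAsFactors = FALSE)
  cohort <- simulate_cohort(spec)
  prepped <- lapply(cohort, function(p) p$runs)
  rows <- vector("list", nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    cfg <- config
    if ("window_length" %in% names(grid))
      cfg$window_length_tr <- as.integer(grid$window_length[ci])
    if ("window_offset" %in% names(grid))
      cfg$window_offset <- as.integer(grid$window_offset[ci])
    if ("cp_bins" %in% names(grid))
      cfg$cp_bins <- as.integer(grid$cp_bins[ci])
    feasible <- spec$volumes_per_run - 1 - cfg$window_offset >=
      cfg$window_length_tr
    if (!feasible) {
      rows[[ci]] <- cbind(grid[ci, , drop = FALSE],
                          pct_integrated = NA, label_stability_ari = NA,
                          skipped = TRUE)
      next
    }
    cfg$n_repetitions <- 2L
    pct <- ari <- numeric(length(prepped))
    for (i in seq_along(prepped)) {
      res <- analyze_participant(prepped[[i]], cfg,
                                 seed = derive_seed(cfg$seed, 21L, i))
      pct[i] <- res$stats$pct_integrated
      ari[i] <- adjusted_rand(res$labelings[[1L]]$labels,
                              res$labelings[[2L]]$labels)
    }
    rows[[ci]] <- cbind(grid[ci, , drop = FALSE],
                        pct_integrated = mean(pct),
                        label_stability_ari = mean(ari), skipped = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
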