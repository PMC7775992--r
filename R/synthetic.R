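# Synthetic multi-run BOLD cohort generator.
#
# The generator emulates the statistical structure the downstream pipeline
# assumes: multi-run ROI time series whose latent regime alternates between
# a segregated state (correlation only within a-priori systems) and an
# integrated state (added cross-system correlation), task events convolved
# with a canonical HRF on designated task nodes, log-normal motion traces,
# and a phenotype table in which the change in positive symptom scores is,
# by construction, a linear function of the participant's mean coupling on a
# planted edge set during integrated windows. Every downstream stage is
# therefore testable against recorded ground truth without any real data.

#' Cohort specification
#'
#' @param n_participants number of participants.
#' @param n_nodes number of ROI nodes (default 20).
#' @param n_runs runs per participant (default 3).
#' @param volumes_per_run volumes per run (default 179).
#' @param tr_seconds repetition time (default 2).
#' @param n_systems number of a-priori resting-state systems (default 4);
#'   nodes are split evenly across systems.
#' @param dwell_integrated,dwell_segregated probability of staying in the
#'   integrated / segregated regime from one 15-TR window to the next.
#'   Length 1, or length 2 for group-specific (HC, CHR) dwell. Defaults 0.8
#'   and 0.7 give a stationary 60% of time integrated, in line with task
#'   cohorts spending the majority of windows integrated.
#' @param coupling_within within-system correlation in both regimes
#'   (default 0.8; deliberately strong so regimes are identifiable from
#'   15-TR coupling windows at modest node counts).
#' @param coupling_between cross-system correlation added in the integrated
#'   regime (default 0.65; 0 in the segregated regime). Kept below
#'   `coupling_within` so community structure never collapses during
#'   integration.
#' @param planted_edges two-column matrix of node index pairs carrying the
#'   planted symptom-change association; default: the 10 edges of the
#'   complete graph over five nodes spread across systems (cross-system
#'   edges have coupling headroom below `coupling_within`) when
#'   `planted_beta != 0`.
#' @param planted_beta signed coefficient linking mean planted-edge
#'   integrated coupling to the change in positive symptom scores
#'   (default -4).
#' @param planted_coupling_spread width of the per-participant uniform extra
#'   coupling on planted edges during integrated windows (default 0.2);
#'   this is what makes planted-edge coupling vary across participants.
#' @param change_noise_sd residual SD of the symptom-change model (default 1).
#' @param noise_sd observation (white) noise SD added to the BOLD signal
#'   (default 0.2), relative to unit signal variance.
#' @param task_amplitude amplitude of the HRF-convolved event response added
#'   to the task nodes, the first 3 nodes (default 0.5).
#' @param fd_meanlog,fd_sdlog,dvars_meanlog,dvars_sdlog log-normal parameters
#'   of the framewise-displacement (mm) and standardized DVARS (%) traces;
#'   defaults centre FD near 0.10 mm, matching a well-behaved cohort.
#' @param group_fraction_chr fraction of participants labelled CHR
#'   (default 0.7, roughly a 24/57 split).
#' @param window_length_tr latent regime granularity in TR (default 15),
#'   aligned with the analysis windows.
#' @param seed integer root seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants,
                        n_nodes = 20L,
                        n_runs = 3L,
                        volumes_per_run = 179L,
                        tr_seconds = 2,
                        n_systems = 4L,
                        dwell_integrated = 0.8,
                        dwell_segregated = 0.7,
                        coupling_within = 0.8,
                        coupling_between = 0.65,
                        planted_edges = NULL,
                        planted_beta = -4,
                        planted_coupling_spread = 0.2,
                        change_noise_sd = 1,
                        noise_sd = 0.2,
                        task_amplitude = 0.5,
                        fd_meanlog = log(0.10), fd_sdlog = 0.35,
                        dvars_meanlog = log(1.2), dvars_sdlog = 0.3,
                        group_fraction_chr = 0.7,
                        window_length_tr = 15L,
                        seed = 1L) {
  assert_that(n_participants >= 1, "n_participants", "must be >= 1")
  assert_that(n_systems >= 1, "n_systems", "must be >= 1")
  assert_that(n_nodes >= 2 * n_systems, "n_nodes",
              "must be at least twice n_systems")
  assert_that(volumes_per_run >= window_length_tr + 1, "volumes_per_run",
              "must cover at least one window")
  assert_that(length(dwell_integrated) <= 2 &&
                all(dwell_integrated > 0) && all(dwell_integrated < 1),
              "dwell_integrated", "must lie in (0, 1)")
  assert_that(length(dwell_segregated) <= 2 &&
                all(dwell_segregated > 0) && all(dwell_segregated < 1),
              "dwell_segregated", "must lie in (0, 1)")
  assert_that(n_runs >= 1, "n_runs", "must be >= 1")
  if (is.null(planted_edges) && planted_beta != 0) {
    # five nodes spread across systems; their complete graph (10 edges)
    anchors <- unique(round(seq(1, n_nodes, length.out = 5)))
    planted_edges <- t(utils::combn(anchors, 2L))
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    assert_that(ncol(planted_edges) == 2, "planted_edges",
                "must be a two-column matrix of node pairs")
    assert_that(all(planted_edges >= 1 & planted_edges <= n_nodes),
                "planted_edges", "node indices out of range")
    assert_that(all(planted_edges[, 1] != planted_edges[, 2]),
                "planted_edges", "self-edges not allowed")
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_nodes = as.integer(n_nodes), n_runs = as.integer(n_runs),
         volumes_per_run = as.integer(volumes_per_run),
         tr_seconds = tr_seconds, n_systems = as.integer(n_systems),
         dwell_integrated = dwell_integrated,
         dwell_segregated = dwell_segregated,
         coupling_within = coupling_within,
         coupling_between = coupling_between,
         planted_edges = planted_edges, planted_beta = planted_beta,
         planted_coupling_spread = planted_coupling_spread,
         change_noise_sd = change_noise_sd, noise_sd = noise_sd,
         task_amplitude = task_amplitude,
         fd_meanlog = fd_meanlog, fd_sdlog = fd_sdlog,
         dvars_meanlog = dvars_meanlog, dvars_sdlog = dvars_sdlog,
         group_fraction_chr = group_fraction_chr,
         window_length_tr = as.integer(window_length_tr),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# fixed small covariate coefficients of the symptom-change model; kept
# modest so the planted edge effect dominates but adjustment is testable
change_covariate_beta <- c(age = 0.02, sexM = 0.3, antipsychotic = 0.5,
                           antidepressant = 0.3, days = 0.001, mean_fd = 2)

#' System membership of nodes under a cohort spec
#' @param spec a [cohort_spec()].
#' @return integer vector of system ids, one per node.
#' @export
node_systems <- function(spec) {
  sort(rep_len(seq_len(spec$n_systems), spec$n_nodes))
}

#' Canonical double-gamma HRF, sampled at `t` seconds post-onset
#' @param t time in seconds.
#' @return HRF value(s). Peak near 5-6 s, undershoot near 15-16 s, peak to
#'   undershoot ratio 6.
#' @export
canonical_hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  h
}

#' HRF-convolved task regressors
#'
#' One column per trial type: a boxcar (onset to onset + duration) sampled on
#' the volume grid, convolved with the canonical double-gamma HRF. Events
#' starting beyond the run end are dropped with a warning.
#'
#' @param events data.frame with BIDS-style columns onset, duration,
#'   trial_type (seconds).
#' @param n_volumes volumes in the run.
#' @param tr repetition time in seconds.
#' @return n_volumes x n_trial_types matrix (zero columns for no events).
#' @export
make_hrf_regressor <- function(events, n_volumes, tr = 2) {
  run_end <- n_volumes * tr
  if (is.null(events) || nrow(events) == 0) {
    return(matrix(0, n_volumes, 1, dimnames = list(NULL, "task")))
  }
  bad <- events$onset >= run_end
  if (any(bad)) {
    warning(sprintf("%d event(s) beyond run end dropped", sum(bad)))
    events <- events[!bad, , drop = FALSE]
    if (nrow(events) == 0) {
      return(matrix(0, n_volumes, 1, dimnames = list(NULL, "task")))
    }
  }
  types <- unique(as.character(events$trial_type))
  grid <- (seq_len(n_volumes) - 1) * tr
  hrf_kernel <- canonical_hrf(seq(0, 32, by = tr))
  out <- matrix(0, n_volumes, length(types), dimnames = list(NULL, types))
  for (ti in seq_along(types)) {
    ev <- events[events$trial_type == types[ti], , drop = FALSE]
    stick <- numeric(n_volumes)
    for (e in seq_len(nrow(ev))) {
      on <- ev$onset[e]
      dur <- max(ev$duration[e], 1e-9)
      hit <- which(grid >= on - tr / 2 & grid < on + dur + tr / 2)
      if (!length(hit)) hit <- which.min(abs(grid - on))
      stick[hit] <- stick[hit] + 1
    }
    conv <- stats::convolve(stick, rev(hrf_kernel), type = "open")
    out[, ti] <- conv[seq_len(n_volumes)]
  }
  out
}

# regime covariance matrices for one participant; delta is the participant's
# extra planted-edge coupling (integrated regime only)
regime_covariances <- function(spec, delta) {
  sys <- node_systems(spec)
  same <- outer(sys, sys, "==")
  N <- spec$n_nodes
  sigma_seg <- matrix(0, N, N)
  sigma_seg[same] <- spec$coupling_within
  diag(sigma_seg) <- 1
  sigma_int <- matrix(spec$coupling_between, N, N)
  sigma_int[same] <- spec$coupling_within
  diag(sigma_int) <- 1
  if (!is.null(spec$planted_edges) && delta != 0) {
    d <- delta
    repeat {
      s <- sigma_int
      for (e in seq_len(nrow(spec$planted_edges))) {
        i <- spec$planted_edges[e, 1]; j <- spec$planted_edges[e, 2]
        s[i, j] <- s[i, j] + d
        s[j, i] <- s[i, j]
      }
      ok <- tryCatch({ chol(s); TRUE }, error = function(e) FALSE)
      if (ok) { sigma_int <- s; break }
      d <- d / 2
      if (d < 1e-6) break
    }
  }
  list(segregated = sigma_seg, integrated = sigma_int)
}

# latent regime sequence of one run at window granularity
simulate_regimes <- function(n_windows, p_stay_int, p_stay_seg) {
  states <- character(n_windows)
  p_int <- (1 - p_stay_seg) / ((1 - p_stay_int) + (1 - p_stay_seg))
  states[1] <- if (stats::runif(1) < p_int) "integrated" else "segregated"
  for (w in seq_len(n_windows - 1L)) {
    stay <- if (states[w] == "integrated") p_stay_int else p_stay_seg
    states[w + 1L] <- if (stats::runif(1) < stay) states[w] else
      setdiff(c("integrated", "segregated"), states[w])
  }
  states
}

default_events <- function(spec) {
  run_end <- spec$volumes_per_run * spec$tr_seconds
  onsets <- seq(6, run_end - 20, by = 18)
  data.frame(onset = onsets, duration = 0.1,
             trial_type = rep_len(c("standard", "target"), length(onsets)),
             stringsAsFactors = FALSE)
}

#' Simulate a cohort
#'
#' @param spec a [cohort_spec()].
#' @return list of participants; each participant is a list with `runs`
#'   (list of [roi_run()]), `events` (per-run data.frame), `confounds`
#'   (per-run data.frame with framewise_displacement, std_dvars),
#'   `phenotype` (one-row data.frame) and `truth` (latent regimes, true
#'   community labels per regime, planted-edge coupling and the exact
#'   symptom-change decomposition).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  hc_n <- round(n * (1 - spec$group_fraction_chr))
  groups <- c(rep("HC", hc_n), rep("CHR", n - hc_n))
  dwell_int <- rep_len(spec$dwell_integrated, 2)   # (HC, CHR)
  dwell_seg <- rep_len(spec$dwell_segregated, 2)
  sys <- node_systems(spec)
  n_win <- n_windows(spec$volumes_per_run, spec$window_length_tr)
  wl <- spec$window_length_tr
  task_nodes <- seq_len(min(3L, spec$n_nodes))

  cohort <- vector("list", n)
  for (p in seq_len(n)) {
    set.seed(derive_seed(spec$seed, p, 1L))
    grp <- groups[p]
    gi <- if (grp == "HC") 1L else 2L

    # phenotype draws (order fixed for reproducibility)
    age <- round(stats::runif(1, 18, 35), 1)
    sex <- sample(c("M", "F"), 1)
    antipsychotic <- if (grp == "CHR") stats::rbinom(1, 1, 0.2) else 0L
    antidepressant <- if (grp == "CHR") stats::rbinom(1, 1, 0.4) else
      stats::rbinom(1, 1, 0.05)
    days <- round(stats::rlnorm(1, log(500), 0.4))
    panss_pos_base <- max(7, round(stats::rnorm(1, 14, 4)))
    panss_neg_base <- max(7, round(stats::rnorm(1, 12, 4)))
    gaf_base <- round(stats::rnorm(1, if (grp == "CHR") 57 else 91, 10))
    delta <- if (!is.null(spec$planted_edges))
      stats::runif(1, 0, spec$planted_coupling_spread) else 0

    cov_mats <- regime_covariances(spec, delta)
    chol_seg <- chol(cov_mats$segregated)
    chol_int <- chol(cov_mats$integrated)

    runs <- vector("list", spec$n_runs)
    events <- vector("list", spec$n_runs)
    confounds <- vector("list", spec$n_runs)
    regimes <- vector("list", spec$n_runs)
    for (r in seq_len(spec$n_runs)) {
      set.seed(derive_seed(spec$seed, p, 2L, r))
      reg <- simulate_regimes(n_win, dwell_int[gi], dwell_seg[gi])
      regimes[[r]] <- reg
      # volumes: window blocks of wl TR; trailing volumes keep last regime
      vol_regime <- c(rep(reg, each = wl),
                      rep(reg[n_win], spec$volumes_per_run - n_win * wl))
      z <- matrix(stats::rnorm(spec$volumes_per_run * spec$n_nodes),
                  spec$volumes_per_run, spec$n_nodes)
      dat <- matrix(0, spec$volumes_per_run, spec$n_nodes)
      is_int <- vol_regime == "integrated"
      if (any(is_int)) dat[is_int, ] <- z[is_int, , drop = FALSE] %*% chol_int
      if (any(!is_int)) dat[!is_int, ] <- z[!is_int, , drop = FALSE] %*% chol_seg
      dat <- dat + spec$noise_sd *
        matrix(stats::rnorm(length(dat)), nrow(dat), ncol(dat))
      ev <- default_events(spec)
      if (spec$task_amplitude != 0) {
        reg_mat <- make_hrf_regressor(ev, spec$volumes_per_run,
                                      spec$tr_seconds)
        task_sig <- rowSums(reg_mat) * spec$task_amplitude
        dat[, task_nodes] <- dat[, task_nodes] + task_sig
      }
      # give nodes distinct mean intensities so dropout z-scoring is exercisable
      node_means <- 100 + 2 * seq_len(spec$n_nodes) %% 7
      dat <- sweep(dat, 2L, node_means, "+")
      runs[[r]] <- roi_run(dat, tr_seconds = spec$tr_seconds,
                           run_id = sprintf("run-%d", r),
                           node_ids = paste0("node_", seq_len(spec$n_nodes)))
      events[[r]] <- ev
      fd <- stats::rlnorm(spec$volumes_per_run, spec$fd_meanlog, spec$fd_sdlog)
      dv <- stats::rlnorm(spec$volumes_per_run, spec$dvars_meanlog,
                          spec$dvars_sdlog)
      fd[1] <- 0; dv[1] <- 0
      confounds[[r]] <- data.frame(framewise_displacement = fd,
                                   std_dvars = dv)
    }
    mean_fd <- mean(unlist(lapply(confounds, `[[`, "framewise_displacement")))

    # truth mean planted-edge coupling over truly integrated windows,
    # computed with the same MTD windowing the pipeline applies
    mfc <- 0
    if (!is.null(spec$planted_edges)) {
      vals <- c()
      for (r in seq_len(spec$n_runs)) {
        st <- mtd_stack(runs[[r]], window_length = wl, offset = 0L)
        sel <- which(regimes[[r]] == "integrated")
        for (w in sel) {
          vals <- c(vals, st$windows[[w]][spec$planted_edges])
        }
      }
      mfc <- if (length(vals)) mean(vals) else 0
    }

    set.seed(derive_seed(spec$seed, p, 3L))
    cb <- change_covariate_beta
    cov_term <- cb["age"] * (age - 25) + cb["sexM"] * (sex == "M") +
      cb["antipsychotic"] * antipsychotic +
      cb["antidepressant"] * antidepressant +
      cb["days"] * (days - 500) + cb["mean_fd"] * (mean_fd - 0.1)
    change_pos <- spec$planted_beta * mfc + cov_term +
      stats::rnorm(1, 0, spec$change_noise_sd)
    change_neg <- cov_term + stats::rnorm(1, 0, spec$change_noise_sd)
    change_gaf <- -cov_term + stats::rnorm(1, 0, spec$change_noise_sd)

    phenotype <- data.frame(
      participant_id = sprintf("sub-%03d", p),
      group = grp, age = age, sex = sex,
      antipsychotic = antipsychotic, antidepressant = antidepressant,
      days_to_followup = days, mean_fd = mean_fd,
      panss_pos_baseline = panss_pos_base,
      panss_pos_followup = panss_pos_base + change_pos,
      panss_neg_baseline = panss_neg_base,
      panss_neg_followup = panss_neg_base + change_neg,
      gaf_baseline = gaf_base,
      gaf_followup = gaf_base + change_gaf,
      stringsAsFactors = FALSE
    )
    truth <- list(
      regimes = regimes,
      community_labels = list(segregated = sys,
                              integrated = rep(1L, spec$n_nodes)),
      delta = delta, mean_planted_fc = mfc,
      planted_edges = spec$planted_edges,
      change_components = list(planted = spec$planted_beta * mfc,
                               covariates = unname(cov_term))
    )
    cohort[[p]] <- list(runs = runs, events = events, confounds = confounds,
                        phenotype = phenotype, truth = truth)
  }
  class(cohort) <- c("synthetic_cohort", "list")
  cohort
}

#' Phenotype table of a cohort
#' @param cohort a `synthetic_cohort`.
#' @return data.frame, one row per participant.
#' @export
cohort_phenotypes <- function(cohort) {
  do.call(rbind, lapply(cohort, `[[`, "phenotype"))
}

#' Synthetic node metadata table
#'
#' MNI-style coordinates on a deterministic grid plus system labels; a
#' stand-in for an a-priori node atlas, clearly synthetic.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with node_id, x, y, z, system.
#' @export
node_metadata <- function(spec) {
  sys <- node_systems(spec)
  sys_names <- c("Visual", "Default mode", "Somatomotor",
                 "Cingulo-opercular", "Fronto-parietal", "Salience",
                 "Subcortical", "Auditory")
  n <- spec$n_nodes
  data.frame(
    node_id = paste0("node_", seq_len(n)),
    x = round(70 * cos(seq_len(n)), 1),
    y = round(80 * sin(seq_len(n) * 2), 1),
    z = round(60 * sin(seq_len(n) * 3) - 10, 1),
    system = sys_names[(sys - 1L) %% length(sys_names) + 1L],
    stringsAsFactors = FALSE
  )
}
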