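# Multilayer (time-linked) community detection and partition dynamics.
#
# The quality function is the multislice modularity of Mucha et al.:
#   Q = (1/2mu) * sum_{ijsr} [ (A_ijs - gamma * k_is k_js / (2 m_s)) d_sr
#                              + d_ij * omega * C_sr ] * d(g_is, g_jr)
# with ordinal coupling C_sr = 1 for |s - r| = 1 (windows are time-ordered,
# so each node is linked to itself in adjacent layers only).

#' Multislice modularity score matrix
#'
#' Assembles the dense (nodes x layers) quality matrix B whose within-block
#' entries carry intra-layer modularity terms and whose off-blocks carry the
#' ordinal inter-layer coupling. Negative window weights are set to zero
#' first (graph metrics downstream assume non-negative weights); the signed
#' values are retained elsewhere for network averaging.
#'
#' @param stack a `window_stack` (layers = windows).
#' @param gamma resolution parameter (default 1).
#' @param omega inter-layer coupling (default 1).
#' @return list with `B` (NS x NS matrix, node index varying fastest),
#'   `twomu` (normalisation 2*mu), `n_nodes`, `n_layers`.
#' @export
modularity_matrix <- function(stack, gamma = 1, omega = 1) {
  stopifnot(inherits(stack, "window_stack"))
  S <- length(stack$windows)
  assert_that(S >= 1, "stack", "needs at least one window")
  N <- length(stack$node_ids)
  B <- matrix(0, N * S, N * S)
  twomu <- 0
  for (s in seq_len(S)) {
    A <- stack$windows[[s]]
    A[A < 0] <- 0
    diag(A) <- 0
    k <- rowSums(A)
    m2 <- sum(k)
    idx <- (s - 1L) * N + seq_len(N)
    if (m2 > 0) {
      B[idx, idx] <- A - gamma * tcrossprod(k) / m2
    } else {
      warning(sprintf("window %d is all-zero; kept with null modularity term", s))
      B[idx, idx] <- A
    }
    twomu <- twomu + m2
  }
  if (S > 1 && omega != 0) {
    for (s in seq_len(S - 1L)) {
      a <- (s - 1L) * N + seq_len(N)
      b <- s * N + seq_len(N)
      B[cbind(a, b)] <- B[cbind(a, b)] + omega
      B[cbind(b, a)] <- B[cbind(b, a)] + omega
    }
    twomu <- twomu + 2 * omega * N * (S - 1L)
  }
  list(B = B, twomu = twomu, n_nodes = N, n_layers = S)
}

#' Multilayer modularity maximisation
#'
#' Greedy Louvain-style maximisation of the multislice quality over a run's
#' window stack, with stochastic sweep order controlled by `seed`. The
#' returned quality is guarded from below by the two trivial partitions
#' (all-singleton and single-community): whichever of the three scores
#' highest is returned, so Q is never worse than either baseline.
#'
#' @inheritParams modularity_matrix
#' @param seed integer seed for the stochastic sweep order.
#' @return object of class `multilayer_partition`: `labels` (windows x nodes
#'   integer matrix, dense-coded), `gamma`, `omega`, `quality`, `seed`.
#' @export
multilayer_modularity <- function(stack, gamma = 1, omega = 1, seed = 1L) {
  mm <- modularity_matrix(stack, gamma = gamma, omega = omega)
  N <- mm$n_nodes
  S <- mm$n_layers
  res <- cpp_louvain_dense(mm$B, as.integer(seed))
  labels <- res$labels
  score <- res$score

  # second start: static mean-network communities replicated across layers.
  # Greedy moves on node-slices cannot coordinate a split of a spuriously
  # merged community across a stretch of layers; seeding from the static
  # partition reaches the temporally coherent optimum when it scores higher.
  if (S > 1) {
    mean_adj <- Reduce(`+`, lapply(stack$windows, function(w) {
      w[w < 0] <- 0
      w
    })) / S
    diag(mean_adj) <- 0
    k <- rowSums(mean_adj)
    m2 <- sum(k)
    if (m2 > 0) {
      B_static <- mean_adj - gamma * tcrossprod(k) / m2
      st_res <- cpp_louvain_dense(B_static, as.integer(seed))
      init <- rep.int(st_res$labels, S)
      res2 <- cpp_louvain_dense(mm$B, as.integer(seed), init = init)
      if (res2$score > score) {
        labels <- res2$labels
        score <- res2$score
      }
    }
  }

  # baseline guard: singleton and one-community partitions
  sing <- sum(diag(mm$B))
  one <- sum(mm$B)
  if (sing > score) {
    labels <- seq_len(N * S)
    score <- sing
  }
  if (one > score) {
    labels <- rep(1L, N * S)
    score <- one
  }
  lab <- matrix(dense_labels(labels), nrow = S, ncol = N, byrow = TRUE)
  colnames(lab) <- stack$node_ids
  q <- if (mm$twomu > 0) score / mm$twomu else 0
  structure(
    list(labels = lab, gamma = gamma, omega = omega, quality = q,
         raw_score = score, twomu = mm$twomu, seed = as.integer(seed),
         node_ids = stack$node_ids, run_id = stack$run_id),
    class = "multilayer_partition"
  )
}

#' @export
print.multilayer_partition <- function(x, ...) {
  cat(sprintf("<multilayer_partition: %d layers x %d nodes, Q = %.4f>\n",
              nrow(x$labels), ncol(x$labels), x$quality))
  invisible(x)
}

#' Node flexibility
#'
#' Per node, the proportion of consecutive layer transitions at which the
#' node changes community: switches / (layers - 1).
#'
#' @param partition a `multilayer_partition`.
#' @return list with `per_node` (named vector) and `mean`.
#' @export
flexibility <- function(partition) {
  stopifnot(inherits(partition, "multilayer_partition"))
  lab <- partition$labels
  S <- nrow(lab)
  assert_that(S >= 2, "partition", "flexibility needs at least 2 layers")
  changes <- lab[-1L, , drop = FALSE] != lab[-S, , drop = FALSE]
  per_node <- colMeans(changes)
  list(per_node = per_node, mean = mean(per_node))
}

#' Module allegiance matrix
#'
#' Fraction of (layer, repetition) observations in which each pair of nodes
#' shares a community.
#'
#' @param partitions list of `multilayer_partition` objects over the same
#'   node set (repetitions).
#' @return object of class `allegiance_matrix` wrapping the nodes x nodes
#'   co-assignment probability matrix `p`.
#' @export
allegiance <- function(partitions) {
  if (inherits(partitions, "multilayer_partition")) partitions <- list(partitions)
  stopifnot(length(partitions) >= 1)
  ids <- partitions[[1L]]$node_ids
  N <- length(ids)
  acc <- matrix(0, N, N)
  total <- 0L
  for (p in partitions) {
    stopifnot(inherits(p, "multilayer_partition"))
    if (!identical(p$node_ids, ids)) {
      stop_field("partitions", "node sets differ across partitions")
    }
    for (s in seq_len(nrow(p$labels))) {
      g <- p$labels[s, ]
      acc <- acc + outer(g, g, "==")
      total <- total + 1L
    }
  }
  p <- acc / total
  dimnames(p) <- list(ids, ids)
  structure(list(p = p, n_observations = total, node_ids = ids),
            class = "allegiance_matrix")
}

#' Recruitment and integration coefficients
#'
#' Recruitment R_i is a node's mean allegiance with the other nodes of its
#' own a-priori system; integration I_i is its mean allegiance with nodes of
#' all other systems. Nodes in singleton systems have undefined recruitment
#' (returned as NA).
#'
#' @param am an `allegiance_matrix`.
#' @param systems named character/factor vector mapping node id to system.
#' @return data.frame with columns node_id, system, recruitment, integration,
#'   plus attributes `mean_recruitment`, `mean_integration`.
#' @export
recruitment_integration <- function(am, systems) {
  stopifnot(inherits(am, "allegiance_matrix"))
  ids <- am$node_ids
  assert_that(all(ids %in% names(systems)), "systems",
              "every node must be mapped to a system")
  sys <- as.character(systems[ids])
  N <- length(ids)
  rec <- int <- numeric(N)
  for (i in seq_len(N)) {
    same <- sys == sys[i]
    same[i] <- FALSE
    other <- sys != sys[i]
    rec[i] <- if (any(same)) mean(am$p[i, same]) else NA_real_
    int[i] <- if (any(other)) mean(am$p[i, other]) else NA_real_
  }
  out <- data.frame(node_id = ids, system = sys, recruitment = rec,
                    integration = int, stringsAsFactors = FALSE)
  attr(out, "mean_recruitment") <- mean(rec, na.rm = TRUE)
  attr(out, "mean_integration") <- mean(int, na.rm = TRUE)
  out
}

#' Community counts per layer and run summary
#'
#' @param partition a `multilayer_partition`.
#' @return list with `per_layer` (integer vector of distinct labels per
#'   layer) and `run_mean` (mean over layers; cohort summaries take the
#'   median of these participant-level means).
#' @export
community_count <- function(partition) {
  stopifnot(inherits(partition, "multilayer_partition"))
  per_layer <- apply(partition$labels, 1L, function(g) length(unique(g)))
  list(per_layer = as.integer(per_layer), run_mean = mean(per_layer))
}

#' Exhaustive-search maximum of a dense partition score
#'
#' Enumerates every set partition (restricted growth strings) of up to 14
#' elements and returns the maximum of `sum(B[same block])`. Intended as an
#' independent optimality check for [multilayer_modularity()] on tiny
#' instances; the score shares only the definition of B, not the search.
#'
#' @param B symmetric score matrix (e.g. from [modularity_matrix()]).
#' @return list with `labels` (1-based) and `score`.
#' @export
brute_force_partition <- function(B) {
  cpp_exhaustive_best(as.matrix(B))
}
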