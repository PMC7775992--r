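# Network Based Statistics.
#
# Edge-wise GLM over participant networks, supra-threshold connected
# components, and permutation inference on the maximal component extent
# (family-wise error control). Covariates are handled with Freedman-Lane
# permutation: residuals of the reduced (covariate-only) model are permuted
# and added back to the reduced fit before refitting the full model.

#' NBS design specification
#'
#' @param response the phenotype variable of interest: a grouping factor for
#'   an ANCOVA-style contrast, or a numeric change score for a regression
#'   design. The edge-wise model always regresses edge FC on
#'   `[intercept | response | covariates]`.
#' @param covariates character vector of covariate column names.
#' @param contrast variable tested (defaults to `response`).
#' @param kind "ancova" (group contrast) or "regression" (continuous).
#' @return object of class `nbs_design`.
#' @export
nbs_design <- function(response, covariates = character(0),
                       contrast = response,
                       kind = c("regression", "ancova")) {
  kind <- match.arg(kind)
  vars <- c(response, covariates)
  assert_that(!anyDuplicated(vars), "covariates", "duplicated variables")
  assert_that(contrast %in% vars, "contrast", "must be part of the design")
  structure(list(response = response, covariates = covariates,
                 contrast = contrast, kind = kind),
            class = "nbs_design")
}

# Build response/covariate design matrices from the phenotype table.
# Returns X_full, X_red (reduced = without the contrast column), kept row idx.
nbs_design_matrices <- function(pheno, design) {
  vars <- c(design$response, design$covariates)
  missing_vars <- setdiff(vars, names(pheno))
  if (length(missing_vars)) {
    stop_field("pheno", paste("missing columns:",
                              paste(missing_vars, collapse = ", ")))
  }
  keep <- stats::complete.cases(pheno[, vars, drop = FALSE])
  if (any(!keep)) {
    warning(sprintf("%d participant(s) dropped for missing phenotype",
                    sum(!keep)))
  }
  ph <- pheno[keep, , drop = FALSE]
  one_col <- function(v) {
    x <- ph[[v]]
    if (is.character(x)) x <- factor(x)
    if (is.factor(x)) {
      if (nlevels(droplevels(x)) != 2) {
        stop_field(v, "factor contrasts must have exactly 2 levels")
      }
      x <- as.numeric(droplevels(x)) - 1
    }
    as.numeric(x)
  }
  cols <- lapply(vars, one_col)
  names(cols) <- vars
  X_full <- cbind(`(Intercept)` = 1, do.call(cbind, cols))
  colnames(X_full) <- c("(Intercept)", vars)
  qrf <- qr(X_full)
  if (qrf$rank < ncol(X_full)) {
    bad <- colnames(X_full)[setdiff(seq_len(ncol(X_full)),
                                    qrf$pivot[seq_len(qrf$rank)])]
    stop_field("design", paste("collinear columns:",
                               paste(bad, collapse = ", ")))
  }
  red_cols <- setdiff(colnames(X_full), design$contrast)
  X_red <- X_full[, red_cols, drop = FALSE]
  list(X_full = X_full, X_red = X_red, keep = which(keep),
       contrast_col = match(design$contrast, colnames(X_full)))
}

# Stack participant networks into an n x E matrix of upper-triangle edges
networks_to_edges <- function(networks) {
  mats <- lapply(networks, function(x) {
    if (inherits(x, "integrated_network")) x$mean_fc else as.matrix(x)
  })
  N <- nrow(mats[[1L]])
  node_ids <- rownames(mats[[1L]]) %||% paste0("node_", seq_len(N))
  Y <- t(vapply(mats, ut_vec, numeric(N * (N - 1) / 2)))
  list(Y = Y, n_nodes = N, node_ids = node_ids, edges = edge_index(N, node_ids))
}

# F and t per edge given design QRs; Y is n x E
edge_f_stats <- function(Y, qr_full, qr_red, contrast_col, eps = 1e-12) {
  n <- nrow(Y)
  p_full <- qr_full$rank
  df <- n - p_full
  rss_full <- colSums(qr.resid(qr_full, Y)^2)
  rss_red <- colSums(qr.resid(qr_red, Y)^2)
  num <- rss_red - rss_full
  f <- ifelse(rss_full < eps & num < eps, 0,
              pmax(num, 0) / (rss_full / df))
  f[!is.finite(f)] <- Inf
  list(f = f, df = df, rss_full = rss_full, rss_red = rss_red)
}

#' Edge-wise GLM statistics
#'
#' For every upper-triangle edge, ordinary least squares of edge FC on
#' `[intercept | contrast | covariates]`. F is the 1-df partial F for the
#' contrast; t is its signed square root (sign of the contrast coefficient).
#' For a binary group contrast without covariates this F equals the squared
#' equal-variance two-sample t.
#'
#' @param networks list of participant networks (symmetric matrices or
#'   `integrated_network` objects), shared node order.
#' @param pheno phenotype data.frame, one row per participant, same order.
#' @param design an [nbs_design()].
#' @return list with symmetric `f_matrix` and `t_matrix`, per-edge table
#'   `edges` (node_a, node_b, f, t), residual `df`, and the participant rows
#'   used.
#' @export
edgewise_glm <- function(networks, pheno, design) {
  stopifnot(inherits(design, "nbs_design"))
  ne <- networks_to_edges(networks)
  dm <- nbs_design_matrices(pheno, design)
  Y <- ne$Y[dm$keep, , drop = FALSE]
  qr_full <- qr(dm$X_full)
  qr_red <- qr(dm$X_red)
  st <- edge_f_stats(Y, qr_full, qr_red, dm$contrast_col)
  beta <- qr.coef(qr_full, Y)[dm$contrast_col, ]
  tval <- sign(beta) * sqrt(st$f)
  f_matrix <- ut_mat(st$f, ne$n_nodes)
  t_matrix <- ut_mat(tval, ne$n_nodes)
  dimnames(f_matrix) <- dimnames(t_matrix) <- list(ne$node_ids, ne$node_ids)
  edges <- ne$edges
  edges$f <- st$f
  edges$t <- tval
  list(f_matrix = f_matrix, t_matrix = t_matrix, edges = edges,
       df = st$df, participants_used = dm$keep)
}

#' Supra-threshold connected components
#'
#' Edges with statistic at or above `threshold` form a graph; connected
#' components are returned with their extent (edge count).
#'
#' @param stat_matrix symmetric per-edge statistic matrix.
#' @param threshold test-statistic threshold.
#' @return list of components, each a list with `edges` (data.frame node_a,
#'   node_b, stat), `extent`, `nodes`; ordered by decreasing extent.
#' @export
supra_components <- function(stat_matrix, threshold) {
  stat_matrix <- as.matrix(stat_matrix)
  N <- nrow(stat_matrix)
  ids <- rownames(stat_matrix) %||% paste0("node_", seq_len(N))
  ei <- edge_index(N, ids)
  v <- ut_vec(stat_matrix)
  sel <- which(v >= threshold)
  if (!length(sel)) return(list())
  sub <- ei[sel, , drop = FALSE]
  g <- igraph::graph_from_data_frame(sub[, c("node_a", "node_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  out <- lapply(seq_len(comp$no), function(ci) {
    nodes <- names(comp$membership)[comp$membership == ci]
    in_comp <- sub$node_a %in% nodes & sub$node_b %in% nodes
    edges <- sub[in_comp, c("node_a", "node_b"), drop = FALSE]
    edges$stat <- v[sel][in_comp]
    rownames(edges) <- NULL
    list(edges = edges, extent = nrow(edges), nodes = nodes)
  })
  out[order(vapply(out, `[[`, numeric(1), "extent"), decreasing = TRUE)]
}

# maximal component extent of a thresholded edge statistic vector,
# via union-find on the edge list (fast path for the permutation loop)
max_component_extent <- function(fvec, threshold, ei) {
  sel <- which(fvec >= threshold)
  if (!length(sel)) return(0L)
  a <- ei$i[sel]; b <- ei$j[sel]
  parent <- seq_len(max(c(a, b)))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(a, find, integer(1))
  max(tabulate(roots))
}

# Core permutation engine shared by permutation_fwe and threshold_sweep:
# returns observed F vector plus the n_perm x n_thresholds matrix of maximal
# null component extents under Freedman-Lane permutation.
nbs_permute <- function(networks, pheno, design, thresholds, n_perm, seed) {
  ne <- networks_to_edges(networks)
  dm <- nbs_design_matrices(pheno, design)
  Y <- ne$Y[dm$keep, , drop = FALSE]
  n <- nrow(Y)
  qr_full <- qr(dm$X_full)
  qr_red <- qr(dm$X_red)
  obs <- edge_f_stats(Y, qr_full, qr_red, dm$contrast_col)
  fitted_red <- qr.fitted(qr_red, Y)
  resid_red <- qr.resid(qr_red, Y)

  null_max <- matrix(0L, n_perm, length(thresholds))
  set.seed(derive_seed(seed, 104729L))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    Ystar <- fitted_red + resid_red[perm, , drop = FALSE]
    st <- edge_f_stats(Ystar, qr_full, qr_red, dm$contrast_col)
    for (ti in seq_along(thresholds)) {
      null_max[b, ti] <- max_component_extent(st$f, thresholds[ti], ne$edges)
    }
  }
  list(obs_f = obs$f, df = obs$df, null_max = null_max, ne = ne, dm = dm,
       Y = Y, qr_full = qr_full, qr_red = qr_red)
}

#' Permutation FWE inference on supra-threshold components
#'
#' Freedman-Lane permutation of reduced-model residuals; for each
#' permutation the maximal supra-threshold component extent is recorded, and
#' each observed component receives
#' `fwe_p = (1 + #\{perm max >= extent\}) / (1 + n_perm)`.
#'
#' @inheritParams edgewise_glm
#' @param threshold F threshold.
#' @param n_perm number of permutations (default 5000; a warning is issued
#'   below 100).
#' @param seed integer seed.
#' @return object of class `nbs_result`: `threshold`, `components` (each
#'   with edges, extent, fwe_p), `n_permutations`, `stat_matrix` (F),
#'   `edge_t` (signed t), `null_max` extents.
#' @export
permutation_fwe <- function(networks, pheno, design, threshold,
                            n_perm = 5000L, seed = 1L) {
  if (n_perm < 100) warning("fewer than 100 permutations: p-values unstable")
  eg <- edgewise_glm(networks, pheno, design)
  pm <- nbs_permute(networks, pheno, design, thresholds = threshold,
                    n_perm = n_perm, seed = seed)
  comps <- supra_components(eg$f_matrix, threshold)
  null_max <- pm$null_max[, 1L]
  comps <- lapply(comps, function(cmp) {
    cmp$fwe_p <- (1 + sum(null_max >= cmp$extent)) / (1 + n_perm)
    cmp
  })
  structure(
    list(threshold = threshold, components = comps,
         n_permutations = as.integer(n_perm),
         stat_matrix = eg$f_matrix, edge_t = eg$t_matrix,
         df = eg$df, null_max = null_max, design = design,
         seed = as.integer(seed)),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result F >= %g: %d component(s), %d permutations>\n",
              x$threshold, length(x$components), x$n_permutations))
  for (cmp in x$components) {
    cat(sprintf("  extent %d, FWE p = %.4f\n", cmp$extent, cmp$fwe_p))
  }
  invisible(x)
}

#' F-threshold sweep
#'
#' Runs the permutation procedure over an ascending range of F thresholds
#' with a shared permutation stream, and marks thresholds yielding any
#' component at FWE p <= `alpha`.
#'
#' @inheritParams permutation_fwe
#' @param thresholds ascending numeric thresholds (default 6:28).
#' @param alpha significance level (default 0.025).
#' @return list with `results` (one `nbs_result` per threshold) and
#'   `significant` (logical per threshold).
#' @export
threshold_sweep <- function(networks, pheno, design, thresholds = 6:28,
                            n_perm = 5000L, seed = 1L, alpha = 0.025) {
  assert_that(!is.unsorted(thresholds), "thresholds", "must be ascending")
  eg <- edgewise_glm(networks, pheno, design)
  pm <- nbs_permute(networks, pheno, design, thresholds = thresholds,
                    n_perm = n_perm, seed = seed)
  results <- vector("list", length(thresholds))
  signif <- logical(length(thresholds))
  for (ti in seq_along(thresholds)) {
    comps <- supra_components(eg$f_matrix, thresholds[ti])
    null_max <- pm$null_max[, ti]
    comps <- lapply(comps, function(cmp) {
      cmp$fwe_p <- (1 + sum(null_max >= cmp$extent)) / (1 + n_perm)
      cmp
    })
    signif[ti] <- any(vapply(comps, `[[`, numeric(1), "fwe_p") <= alpha)
    results[[ti]] <- structure(
      list(threshold = thresholds[ti], components = comps,
           n_permutations = as.integer(n_perm),
           stat_matrix = eg$f_matrix, edge_t = eg$t_matrix,
           df = eg$df, null_max = null_max, design = design,
           seed = as.integer(seed)),
      class = "nbs_result")
  }
  list(results = results, thresholds = thresholds, significant = signif,
       alpha = alpha)
}

#' Cohen's f-squared per edge
#'
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)` with the reduced model
#' holding covariates only. Summarised over all upper-triangle edges and,
#' optionally, over an edge subset. Edges with `R2_full = 1` are flagged
#' infinite.
#'
#' @inheritParams edgewise_glm
#' @param edge_subset optional data.frame with node_a, node_b columns.
#' @return list with per-edge table and mean/sd summaries.
#' @export
cohens_f2 <- function(networks, pheno, design, edge_subset = NULL) {
  ne <- networks_to_edges(networks)
  dm <- nbs_design_matrices(pheno, design)
  Y <- ne$Y[dm$keep, , drop = FALSE]
  qr_full <- qr(dm$X_full)
  qr_red <- qr(dm$X_red)
  st <- edge_f_stats(Y, qr_full, qr_red, dm$contrast_col)
  tss <- colSums(sweep(Y, 2L, colMeans(Y))^2)
  r2_full <- 1 - st$rss_full / tss
  r2_red <- 1 - st$rss_red / tss
  f2 <- ifelse(r2_full >= 1 - 1e-12, Inf, (r2_full - r2_red) / (1 - r2_full))
  edges <- ne$edges
  edges$r2_full <- r2_full
  edges$r2_reduced <- r2_red
  edges$f2 <- f2
  finite <- is.finite(f2)
  out <- list(edges = edges,
              mean_f2 = mean(f2[finite]), sd_f2 = stats::sd(f2[finite]),
              n_infinite = sum(!finite))
  if (!is.null(edge_subset)) {
    key <- paste(edges$node_a, edges$node_b)
    skey <- c(paste(edge_subset$node_a, edge_subset$node_b),
              paste(edge_subset$node_b, edge_subset$node_a))
    inset <- key %in% skey
    fs <- f2[inset & finite]
    out$subset_mean_f2 <- mean(fs)
    out$subset_sd_f2 <- stats::sd(fs)
    out$subset_n <- sum(inset)
  }
  out
}

#' Annotated sub-network report
#'
#' Per component node: coordinates, system affiliation and within-component
#' degree; per component, optionally the Pearson correlation of mean
#' component FC with the design's response across participants.
#'
#' @param result an `nbs_result`.
#' @param nodes node metadata data.frame (node_id, x, y, z, system).
#' @param networks,pheno optional; when supplied, the mean-FC-vs-response
#'   correlation is computed for each component.
#' @return list of per-component reports: `nodes` data.frame and
#'   `mean_fc_response_cor` (NA when networks/pheno absent).
#' @export
subnetwork_report <- function(result, nodes, networks = NULL, pheno = NULL) {
  stopifnot(inherits(result, "nbs_result"))
  lapply(result$components, function(cmp) {
    unknown <- setdiff(cmp$nodes, nodes$node_id)
    if (length(unknown)) {
      stop_field("nodes", paste("unknown node id(s):",
                                paste(unknown, collapse = ", ")))
    }
    deg <- table(c(cmp$edges$node_a, cmp$edges$node_b))
    nt <- nodes[match(cmp$nodes, nodes$node_id), , drop = FALSE]
    nt$degree <- as.integer(deg[nt$node_id])
    rownames(nt) <- NULL
    r <- NA_real_
    if (!is.null(networks) && !is.null(pheno)) {
      ne <- networks_to_edges(networks)
      key <- paste(ne$edges$node_a, ne$edges$node_b)
      skey <- c(paste(cmp$edges$node_a, cmp$edges$node_b),
                paste(cmp$edges$node_b, cmp$edges$node_a))
      mfc <- rowMeans(ne$Y[, key %in% skey, drop = FALSE])
      resp <- pheno[[result$design$response]]
      r <- stats::cor(mfc, as.numeric(resp), use = "complete.obs")
    }
    list(nodes = nt[order(-nt$degree), ], extent = cmp$extent,
         fwe_p = cmp$fwe_p, mean_fc_response_cor = r)
  })
}
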