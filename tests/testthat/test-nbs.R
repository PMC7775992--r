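# Edge-wise GLM, components, permutation FWE, effect sizes, reports.

make_pheno <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    participant_id = sprintf("sub-%03d", seq_len(n)),
    group = rep(c("HC", "CHR"), length.out = n),
    score = rnorm(n),
    age = runif(n, 18, 35),
    mean_fd = rlnorm(n, log(0.1), 0.3),
    stringsAsFactors = FALSE
  )
}

test_that("binary-contrast F equals the squared equal-variance two-sample t", {
  nets <- random_networks(16, 6, seed = 2)
  ph <- make_pheno(16, seed = 3)
  des <- nbs_design("group", kind = "ancova")
  eg <- edgewise_glm(nets, ph, des)
  g <- factor(ph$group)
  for (e in sample(nrow(eg$edges), 5)) {
    y <- vapply(nets, function(m) m[eg$edges$i[e], eg$edges$j[e]], numeric(1))
    tt <- t.test(y ~ g, var.equal = TRUE)
    expect_equal(eg$edges$f[e], unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("edge-wise partial F matches per-edge lm() refits with covariates", {
  nets <- random_networks(20, 7, seed = 4)
  ph <- make_pheno(20, seed = 5)
  des <- nbs_design("score", covariates = c("age", "mean_fd"))
  eg <- edgewise_glm(nets, ph, des)
  covars <- cbind(ph$age, ph$mean_fd)
  for (e in sample(nrow(eg$edges), 8)) {
    y <- vapply(nets, function(m) m[eg$edges$i[e], eg$edges$j[e]], numeric(1))
    expect_equal(eg$edges$f[e], oracle_edge_f(y, ph$score, covars),
                 tolerance = 1e-10)
  }
  # t carries the contrast sign and t^2 = F
  expect_equal(eg$edges$t^2, eg$edges$f, tolerance = 1e-9)
})

test_that("constant edges give F = 0 and null edges give calibrated p-values", {
  nets <- random_networks(30, 5, seed = 6)
  for (i in seq_along(nets)) nets[[i]][1, 2] <- nets[[i]][2, 1] <- 0.7
  ph <- make_pheno(30, seed = 7)
  eg <- edgewise_glm(nets, ph, nbs_design("score"))
  expect_equal(eg$f_matrix["node_1", "node_2"], 0)
  # per-edge p under the null is uniform: rejection rate near 0.05
  set.seed(8)
  n_sub <- 40
  reps <- 60
  hits <- 0L
  total <- 0L
  for (r in seq_len(reps)) {
    nets_r <- random_networks(n_sub, 6, seed = 100 + r)
    ph_r <- make_pheno(n_sub, seed = 200 + r)
    eg_r <- edgewise_glm(nets_r, ph_r, nbs_design("score"))
    p <- pf(eg_r$edges$f, 1, eg_r$df, lower.tail = FALSE)
    hits <- hits + sum(p < 0.05)
    total <- total + length(p)
  }
  rate <- hits / total
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("design validation catches collinearity and missing phenotype", {
  nets <- random_networks(10, 5, seed = 9)
  ph <- make_pheno(10, seed = 10)
  ph$age2 <- ph$age * 2
  expect_error(edgewise_glm(nets, ph, nbs_design("score", c("age", "age2"))),
               "collinear")
  ph$score[3] <- NA
  expect_warning(eg <- edgewise_glm(nets, ph, nbs_design("score")), "dropped")
  expect_length(eg$participants_used, 9L)
  expect_error(nbs_design("score", contrast = "other"), "contrast")
})

test_that("supra-threshold components have correct extents and nesting", {
  f <- matrix(0, 6, 6)
  rownames(f) <- colnames(f) <- paste0("node_", 1:6)
  # chain 1-2-3-4 of supra edges plus a disjoint edge 5-6
  f[1, 2] <- f[2, 1] <- 10
  f[2, 3] <- f[3, 2] <- 11
  f[3, 4] <- f[4, 3] <- 12
  f[5, 6] <- f[6, 5] <- 9
  comps <- supra_components(f, 9.5)
  expect_length(comps, 1L)
  expect_equal(comps[[1]]$extent, 3L)
  comps2 <- supra_components(f, 8)
  expect_length(comps2, 2L)
  expect_equal(sort(vapply(comps2, `[[`, numeric(1), "extent")), c(1, 3))
  expect_length(supra_components(f, 100), 0L)
  # raising the threshold never increases any extent
  set.seed(11)
  fm <- random_adjacency(10) * 30
  rownames(fm) <- colnames(fm) <- paste0("node_", 1:10)
  prev <- Inf
  for (thr in c(5, 10, 15, 20, 25)) {
    cs <- supra_components(fm, thr)
    ext <- if (length(cs)) max(vapply(cs, `[[`, numeric(1), "extent")) else 0
    expect_lte(ext, prev)
    prev <- ext
  }
})

test_that("permutation FWE inference is deterministic and monotone in extent", {
  nets <- random_networks(18, 6, seed = 12)
  ph <- make_pheno(18, seed = 13)
  des <- nbs_design("score", covariates = "age")
  expect_warning(r1 <- permutation_fwe(nets, ph, des, threshold = 4,
                                       n_perm = 50, seed = 3), "unstable")
  suppressWarnings({
    r2 <- permutation_fwe(nets, ph, des, threshold = 4, n_perm = 50, seed = 3)
  })
  expect_identical(vapply(r1$components, `[[`, numeric(1), "fwe_p"),
                   vapply(r2$components, `[[`, numeric(1), "fwe_p"))
  # for a fixed null distribution the p-value is non-increasing in extent
  nm <- r1$null_max
  p_of <- function(ext) (1 + sum(nm >= ext)) / (1 + length(nm))
  expect_true(all(diff(vapply(1:6, p_of, numeric(1))) <= 0))
})

test_that("threshold sweep shares permutations and flags significance", {
  nets <- random_networks(16, 6, seed = 14)
  ph <- make_pheno(16, seed = 15)
  des <- nbs_design("score")
  sw <- suppressWarnings(
    threshold_sweep(nets, ph, des, thresholds = c(6, 19, 28), n_perm = 60,
                    seed = 4))
  expect_length(sw$results, 3L)
  expect_equal(vapply(sw$results, `[[`, numeric(1), "threshold"), c(6, 19, 28))
  # thresholds above the max observed F give empty component lists
  top <- max(sw$results[[1]]$stat_matrix)
  sw2 <- suppressWarnings(
    threshold_sweep(nets, ph, des, thresholds = top + 1, n_perm = 60, seed = 4))
  expect_length(sw2$results[[1]]$components, 0L)
})

test_that("Cohen's f2 reproduces the R-squared identity per edge", {
  nets <- random_networks(22, 5, seed = 16)
  ph <- make_pheno(22, seed = 17)
  des <- nbs_design("score", covariates = "age")
  f2 <- cohens_f2(nets, ph, des)
  for (e in sample(nrow(f2$edges), 5)) {
    y <- vapply(nets, function(m) m[f2$edges$i[e], f2$edges$j[e]], numeric(1))
    r2f <- summary(lm(y ~ ph$score + ph$age))$r.squared
    r2r <- summary(lm(y ~ ph$age))$r.squared
    expect_equal(f2$edges$f2[e], (r2f - r2r) / (1 - r2f), tolerance = 1e-10)
  }
  # subset summaries
  sub <- f2$edges[1:3, c("node_a", "node_b")]
  f2s <- cohens_f2(nets, ph, des, edge_subset = sub)
  expect_equal(f2s$subset_n, 3L)
})

test_that("sub-network reports annotate nodes and obey the handshake lemma", {
  f <- matrix(0, 5, 5)
  rownames(f) <- colnames(f) <- paste0("node_", 1:5)
  # hub node_1 with three spokes
  f[1, 2] <- f[2, 1] <- 20
  f[1, 3] <- f[3, 1] <- 21
  f[1, 4] <- f[4, 1] <- 22
  res <- structure(list(threshold = 10,
                        components = supra_components(f, 10),
                        n_permutations = 0L, stat_matrix = f, edge_t = f,
                        df = 1, null_max = integer(0),
                        design = nbs_design("score"), seed = 1L),
                   class = "nbs_result")
  res$components[[1]]$fwe_p <- 0.01
  nodes <- data.frame(node_id = paste0("node_", 1:5), x = 1:5, y = 1:5,
                      z = 1:5, system = "Visual")
  rep <- subnetwork_report(res, nodes)
  expect_equal(rep[[1]]$nodes$degree[rep[[1]]$nodes$node_id == "node_1"], 3L)
  expect_equal(sum(rep[[1]]$nodes$degree), 2L * rep[[1]]$extent)
  expect_error(subnetwork_report(res, nodes[-1, ]), "unknown")
  empty <- res
  empty$components <- list()
  expect_length(subnetwork_report(empty, nodes), 0L)
})
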