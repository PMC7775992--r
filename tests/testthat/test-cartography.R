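# Participation coefficient, module degree z-score, cartographic profiles,
# k-means metastates, integrated network averaging.

test_that("participation coefficient matches closed forms and the brute-force oracle", {
  # all strength within own community -> 0
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1
  w[3, 4] <- w[4, 3] <- 1
  expect_equal(participation_coefficient(w, c(1, 1, 2, 2)), rep(0, 4))
  # strength split equally across 2 communities -> 0.5
  w2 <- matrix(0, 3, 3)
  w2[1, 2] <- w2[2, 1] <- 1
  w2[1, 3] <- w2[3, 1] <- 1
  expect_equal(participation_coefficient(w2, c(1, 1, 2))[1], 0.5)
  # isolated node -> 0
  w3 <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0))
  expect_equal(participation_coefficient(w3, c(1, 2, 2))[1], 0)
  expect_error(participation_coefficient(-w2, c(1, 1, 2)), "negative")

  set.seed(61)
  for (k in 1:10) {
    n <- sample(5:20, 1)
    w <- random_adjacency(n)
    labels <- sample(1:4, n, replace = TRUE)
    expect_equal(participation_coefficient(w, labels), oracle_pc(w, labels),
                 tolerance = 1e-12)
  }
})

test_that("module degree z-score matches hand computation and the oracle", {
  # identical within-strengths -> all zero
  ww <- matrix(1, 3, 3)
  diag(ww) <- 0
  expect_equal(module_degree_zscore(ww, rep(1, 3)), rep(0, 3))
  # within-strengths 1, 2, 3 (edges chosen so a+c=1, a+b=2, b+c=3)
  # give exactly z = (-1, 0, 1) with the n-1 SD; an outside singleton gets 0
  w3 <- matrix(0, 4, 4)
  w3[1, 2] <- w3[2, 1] <- 0    # a
  w3[2, 3] <- w3[3, 2] <- 2    # b
  w3[1, 3] <- w3[3, 1] <- 1    # c
  labels <- c(1, 1, 1, 2)
  z <- module_degree_zscore(w3, labels)
  expect_equal(z, c(-1, 0, 1, 0))
  expect_equal(z, oracle_mdz(w3, labels), tolerance = 1e-12)
  set.seed(62)
  for (k in 1:10) {
    n <- sample(5:20, 1)
    w <- random_adjacency(n)
    labels <- sample(1:3, n, replace = TRUE)
    expect_equal(module_degree_zscore(w, labels), oracle_mdz(w, labels),
                 tolerance = 1e-12)
  }
})

test_that("cartographic profiles bin correctly and normalise to one", {
  cp <- cartographic_profile(rep(0.05, 7), rep(0, 7))
  expect_equal(sum(cp$histogram), 1)
  expect_equal(cp$histogram[1, 6], 1)  # PC bin 1, MDZ bin for z = 0 is 6
  set.seed(63)
  pc <- runif(204)
  mdz <- rnorm(204, sd = 2)
  cp2 <- cartographic_profile(pc, mdz)
  expect_equal(sum(cp2$histogram), 1, tolerance = 1e-9)
  # independent binning oracle
  h <- matrix(0, 10, 10)
  for (i in seq_along(pc)) {
    pb <- min(floor(pc[i] * 10) + 1, 10)
    mb <- min(max(floor((min(max(mdz[i], -3), 3) + 3) / 0.6) + 1, 1), 10)
    h[pb, mb] <- h[pb, mb] + 1
  }
  expect_equal(cp2$histogram, h / 204, tolerance = 1e-12)
  # clipping keeps extreme MDZ in the outer bins
  cp3 <- cartographic_profile(c(0.5, 0.5), c(-10, 10))
  expect_equal(cp3$histogram[6, 1] + cp3$histogram[6, 10], 1)
})

test_that("k-means metastate labels carry PC-based semantics and window counts", {
  set.seed(64)
  mk_prof <- function(mu) {
    cartographic_profile(pmin(pmax(rnorm(50, mu, 0.04), 0), 1), rnorm(50))
  }
  profiles <- c(lapply(1:20, function(i) mk_prof(0.75)),
                lapply(1:13, function(i) mk_prof(0.25)))
  lab <- kmeans_metastates(profiles, seed = 5)
  expect_length(lab$labels, 33L)
  expect_true(all(lab$labels[1:20] == "integrated"))
  expect_true(all(lab$labels[21:33] == "segregated"))
  # semantics are invariant to which cluster index k-means happens to pick
  lab2 <- kmeans_metastates(rev(profiles), seed = 11)
  expect_true(all(lab2$labels[1:13] == "segregated"))
  expect_true(all(lab2$labels[14:33] == "integrated"))
  # identical profiles cannot be clustered
  same <- lapply(1:5, function(i) cartographic_profile(rep(0.5, 4), rep(0, 4)))
  expect_error(kmeans_metastates(same, seed = 1), "distinct")
})

test_that("integrated network averaging matches order-of-averaging oracles", {
  set.seed(65)
  windows1 <- replicate(4, random_adjacency(5, negatives = TRUE),
                        simplify = FALSE)
  windows2 <- replicate(3, random_adjacency(5, negatives = TRUE),
                        simplify = FALSE)
  stacks <- list(make_stack(windows1, run_id = "run-1"),
                 make_stack(windows2, run_id = "run-2"))
  mk_lab <- function(labels, rep_i) {
    structure(list(labels = labels,
                   run_ids = c(rep("run-1", 4), rep("run-2", 3)),
                   frac_integrated = mean(labels == "integrated"),
                   n_switches_per_run = c(0, 0), repetition = rep_i,
                   k = 2, seed = 1L),
              class = "metastate_labeling")
  }
  all_int <- mk_lab(rep("integrated", 7), 1L)
  net <- integrated_network(stacks, list(all_int))
  grand <- Reduce(`+`, c(windows1, windows2)) / 7
  expect_equal(net$mean_fc, grand, ignore_attr = TRUE, tolerance = 1e-12)

  # identical labels across repetitions equal the single-repetition mean
  sel_lab <- mk_lab(c("integrated", "segregated", "integrated", "segregated",
                      "integrated", "segregated", "integrated"), 1L)
  net1 <- integrated_network(stacks, list(sel_lab))
  net3 <- integrated_network(stacks, list(sel_lab, mk_lab(sel_lab$labels, 2L),
                                          mk_lab(sel_lab$labels, 3L)))
  expect_equal(net3$mean_fc, net1$mean_fc, tolerance = 1e-12)
  # equal window counts per repetition: mean of means equals pooled mean
  labA <- mk_lab(c(rep("integrated", 3), rep("segregated", 4)), 1L)
  labB <- mk_lab(c(rep("segregated", 4), rep("integrated", 3)), 2L)
  netAB <- integrated_network(stacks, list(labA, labB))
  pooled <- Reduce(`+`, c(c(windows1, windows2)[1:3],
                          c(windows1, windows2)[5:7])) / 6
  expect_equal(netAB$mean_fc, pooled, ignore_attr = TRUE, tolerance = 1e-12)
  # a repetition with no integrated window is skipped with a warning
  none <- mk_lab(rep("segregated", 7), 2L)
  expect_warning(net_skip <- integrated_network(stacks, list(sel_lab, none)),
                 "skipped")
  expect_equal(net_skip$mean_fc, net1$mean_fc, tolerance = 1e-12)
})

test_that("metastate statistics count switches within runs only", {
  mk_lab <- function(labels, run_ids) {
    switches <- vapply(split(labels, factor(run_ids, levels = unique(run_ids))),
                       function(l) sum(l[-1] != l[-length(l)]), numeric(1))
    structure(list(labels = labels, run_ids = run_ids,
                   frac_integrated = mean(labels == "integrated"),
                   n_switches_per_run = switches, repetition = 1L,
                   k = 2, seed = 1L),
              class = "metastate_labeling")
  }
  all_int <- mk_lab(rep("integrated", 8), rep(c("r1", "r2"), each = 4))
  st <- metastate_stats(all_int)
  expect_equal(st$pct_integrated, 100)
  expect_equal(st$mean_switches, 0)
  isis <- mk_lab(rep(c("integrated", "segregated"), 2), rep("r1", 4))
  expect_equal(metastate_stats(isis)$mean_switches, 3)
  alt11 <- mk_lab(rep_len(c("integrated", "segregated"), 11), rep("r1", 11))
  expect_equal(metastate_stats(alt11)$mean_switches, 10)
  # run boundary does not create a switch
  two_runs <- mk_lab(c(rep("integrated", 4), rep("segregated", 4)),
                     rep(c("r1", "r2"), each = 4))
  expect_equal(metastate_stats(two_runs)$mean_switches, 0)
})
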