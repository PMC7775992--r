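# Multilayer modularity and partition dynamics metrics.

test_that("the multislice quality matrix matches a literal construction", {
  set.seed(51)
  windows <- list(random_adjacency(5, negatives = TRUE),
                  random_adjacency(5), random_adjacency(5))
  st <- make_stack(windows)
  mm <- modularity_matrix(st, gamma = 0.9, omega = 1.3)
  expect_equal(mm$B, oracle_multislice_B(windows, gamma = 0.9, omega = 1.3),
               tolerance = 1e-12)
})

test_that("two persistent cliques are recovered exactly with the optimal Q", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1
  A[4:6, 4:6] <- 1
  diag(A) <- 0
  st <- make_stack(list(A, A))
  p <- multilayer_modularity(st, seed = 3)
  # two communities, matching the cliques, persistent across layers
  expect_equal(p$labels[1, ], p$labels[2, ], ignore_attr = TRUE)
  expect_length(unique(p$labels[1, ]), 2L)
  expect_equal(length(unique(p$labels[1, 1:3])), 1L)
  expect_equal(length(unique(p$labels[1, 4:6])), 1L)
  # Q equals the exhaustive maximum over all partitions of the 12 node-slices
  best <- brute_force_partition(oracle_multislice_B(st$windows))
  expect_equal(p$raw_score, best$score, tolerance = 1e-9)
})

test_that("a single complete layer collapses to one community", {
  A <- matrix(1, 5, 5)
  diag(A) <- 0
  p <- multilayer_modularity(make_stack(list(A)), seed = 1)
  expect_length(unique(p$labels[1, ]), 1L)
})

test_that("seeded runs are deterministic and reach the exhaustive optimum", {
  set.seed(77)
  hits <- 0L
  total <- 0L
  for (inst in 1:6) {
    windows <- if (inst %% 2 == 0) {
      list(random_adjacency(5), random_adjacency(5))
    } else {
      list(random_adjacency(4), random_adjacency(4), random_adjacency(4))
    }
    st <- make_stack(windows)
    best <- brute_force_partition(oracle_multislice_B(windows))$score
    for (s in 1:5) {
      p <- multilayer_modularity(st, seed = s)
      total <- total + 1L
      if (p$raw_score >= best - 1e-9) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
  A <- random_adjacency(6)
  p1 <- multilayer_modularity(make_stack(list(A)), seed = 9)
  p2 <- multilayer_modularity(make_stack(list(A)), seed = 9)
  expect_identical(p1$labels, p2$labels)
  expect_identical(p1$quality, p2$quality)
})

test_that("Q never falls below the trivial baseline partitions", {
  set.seed(99)
  for (k in 1:8) {
    n <- sample(4:8, 1)
    windows <- replicate(sample(1:3, 1), random_adjacency(n, negatives = TRUE),
                         simplify = FALSE)
    st <- make_stack(windows)
    mm <- modularity_matrix(st)
    p <- multilayer_modularity(st, seed = k)
    expect_gte(p$raw_score, sum(diag(mm$B)) - 1e-9)
    expect_gte(p$raw_score, sum(mm$B) - 1e-9)
  }
})

test_that("an all-zero layer is kept with a warning", {
  windows <- list(random_adjacency(4), matrix(0, 4, 4))
  expect_warning(p <- multilayer_modularity(make_stack(windows), seed = 1),
                 "all-zero")
  expect_equal(nrow(p$labels), 2L)
})

test_that("flexibility counts consecutive-layer switches", {
  mk_part <- function(lab) {
    structure(list(labels = lab, node_ids = paste0("node_", seq_len(ncol(lab))),
                   gamma = 1, omega = 1, quality = 0, seed = 1L),
              class = "multilayer_partition")
  }
  const <- mk_part(matrix(1L, 4, 3))
  expect_equal(flexibility(const)$per_node, rep(0, 3), ignore_attr = TRUE)
  alt <- mk_part(cbind(rep(c(1L, 2L), 3), rep(1L, 6)))
  f <- flexibility(alt)
  expect_equal(unname(f$per_node), c(1, 0))
  two_sw <- mk_part(cbind(c(1L, 1L, 2L, 2L, 1L)))
  expect_equal(unname(flexibility(two_sw)$per_node), 0.5)  # 2 of 4 transitions
  expect_error(flexibility(mk_part(matrix(1L, 1, 3))), "2 layers")
})

test_that("allegiance and recruitment/integration behave on closed-form cases", {
  mk_part <- function(lab) {
    structure(list(labels = lab, node_ids = paste0("node_", seq_len(ncol(lab))),
                   gamma = 1, omega = 1, quality = 0, seed = 1L),
              class = "multilayer_partition")
  }
  together <- mk_part(matrix(1L, 3, 4))
  am <- allegiance(list(together, together))
  expect_true(all(am$p == 1))
  apart <- mk_part(matrix(rep(1:4, each = 3), 3, 4))
  am2 <- allegiance(apart)
  expect_equal(sum(am2$p) - sum(diag(am2$p)), 0)
  # co-assigned in 3 of 4 layer-repetition observations -> 0.75
  l1 <- mk_part(rbind(c(1L, 1L), c(1L, 1L)))
  l2 <- mk_part(rbind(c(1L, 1L), c(1L, 2L)))
  am3 <- allegiance(list(l1, l2))
  expect_equal(am3$p[1, 2], 0.75)

  systems <- setNames(rep(c("A", "B"), each = 2), paste0("node_", 1:4))
  ri <- recruitment_integration(am, systems)
  expect_equal(ri$recruitment, rep(1, 4))
  expect_equal(ri$integration, rep(1, 4))
  # partition always equal to the system map: R = 1, I = 0
  sys_part <- mk_part(matrix(rep(c(1L, 1L, 2L, 2L), each = 3), 3, 4))
  ri2 <- recruitment_integration(allegiance(sys_part), systems)
  expect_equal(ri2$recruitment, rep(1, 4))
  expect_equal(ri2$integration, rep(0, 4))
  # singleton system -> recruitment NA
  systems3 <- setNames(c("A", "B", "B", "B"), paste0("node_", 1:4))
  ri3 <- recruitment_integration(allegiance(sys_part), systems3)
  expect_true(is.na(ri3$recruitment[1]))
})

test_that("random labels give matching recruitment and integration", {
  set.seed(303)
  # 2 equal systems, many layers of uniformly random labels: co-assignment
  # probability is system-independent, so R and I coincide up to MC error
  n_layers <- 400
  labs <- matrix(sample(1:3, n_layers * 8, replace = TRUE), n_layers, 8)
  part <- structure(list(labels = labs, node_ids = paste0("node_", 1:8),
                         gamma = 1, omega = 1, quality = 0, seed = 1L),
                    class = "multilayer_partition")
  systems <- setNames(rep(c("A", "B"), each = 4), paste0("node_", 1:8))
  ri <- recruitment_integration(allegiance(part), systems)
  se <- sqrt(1 / 3 * 2 / 3 / n_layers)
  expect_lt(max(abs(ri$recruitment - ri$integration)), 6 * se)
})

test_that("community counts summarise per layer and per run", {
  mk_part <- function(lab) {
    structure(list(labels = lab, node_ids = paste0("node_", seq_len(ncol(lab))),
                   gamma = 1, omega = 1, quality = 0, seed = 1L),
              class = "multilayer_partition")
  }
  singles <- mk_part(matrix(rep(1:5, each = 2), 2, 5, byrow = FALSE))
  expect_equal(community_count(mk_part(matrix(1:5, 2, 5, byrow = TRUE)))$per_layer,
               c(5L, 5L))
  expect_equal(community_count(mk_part(matrix(1L, 3, 4)))$per_layer, rep(1L, 3))
  mixed <- mk_part(rbind(c(1L, 2L, 3L, 3L), c(1L, 2L, 3L, 1L), c(1L, 2L, 3L, 4L)))
  expect_equal(community_count(mixed)$run_mean, mean(c(3, 3, 4)))
})
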