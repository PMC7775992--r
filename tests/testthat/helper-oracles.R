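# Independent oracle implementations and small fixture builders.
# These deliberately re-derive quantities by the most literal route
# (explicit loops, lm() refits, direct formula evaluation) so they share no
# code path with the package implementations they check.

# wrap a list of symmetric matrices as a window_stack
make_stack <- function(windows, node_ids = NULL, run_id = "run-1",
                       window_length = 15L) {
  n <- nrow(windows[[1L]])
  if (is.null(node_ids)) node_ids <- paste0("node_", seq_len(n))
  structure(
    list(windows = windows, window_length_tr = window_length, offset = 0L,
         run_id = run_id, node_ids = node_ids),
    class = "window_stack"
  )
}

random_adjacency <- function(n, negatives = FALSE) {
  a <- matrix(stats::runif(n * n), n, n)
  if (negatives) a <- a - 0.3
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

# literal multislice quality matrix: quadruple loop over the formula with
# ordinal inter-layer coupling
oracle_multislice_B <- function(windows, gamma = 1, omega = 1) {
  S <- length(windows)
  N <- nrow(windows[[1L]])
  B <- matrix(0, N * S, N * S)
  for (s in seq_len(S)) {
    A <- windows[[s]]
    A[A < 0] <- 0
    diag(A) <- 0
    k <- rowSums(A)
    m2 <- sum(A)
    for (i in seq_len(N)) {
      for (j in seq_len(N)) {
        null_term <- if (m2 > 0) gamma * k[i] * k[j] / m2 else 0
        B[(s - 1) * N + i, (s - 1) * N + j] <- A[i, j] - null_term
      }
    }
  }
  for (s in seq_len(S)) {
    for (r in seq_len(S)) {
      if (abs(s - r) == 1) {
        for (i in seq_len(N)) {
          B[(s - 1) * N + i, (r - 1) * N + i] <-
            B[(s - 1) * N + i, (r - 1) * N + i] + omega
        }
      }
    }
  }
  B
}

# brute-force participation coefficient via explicit per-community loops
oracle_pc <- function(w, labels) {
  n <- nrow(w)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- 0
    for (j in seq_len(n)) if (j != i) k <- k + w[i, j]
    if (k == 0) {
      out[i] <- 0
      next
    }
    acc <- 0
    for (s in unique(labels)) {
      kis <- 0
      for (j in seq_len(n)) if (j != i && labels[j] == s) kis <- kis + w[i, j]
      acc <- acc + (kis / k)^2
    }
    out[i] <- 1 - acc
  }
  out
}

# brute-force module degree z-score
oracle_mdz <- function(w, labels) {
  n <- nrow(w)
  kin <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j != i && labels[j] == labels[i]) kin[i] <- kin[i] + w[i, j]
    }
  }
  out <- numeric(n)
  for (s in unique(labels)) {
    idx <- which(labels == s)
    if (length(idx) < 2) next
    m <- mean(kin[idx])
    sdv <- stats::sd(kin[idx])
    if (is.na(sdv) || sdv == 0) next
    out[idx] <- (kin[idx] - m) / sdv
  }
  out
}

# per-edge partial F via lm() refits
oracle_edge_f <- function(y, contrast, covars = NULL) {
  dat <- data.frame(y = y, x = contrast)
  full_fml <- "y ~ x"
  red_fml <- "y ~ 1"
  if (!is.null(covars)) {
    for (k in seq_len(ncol(covars))) dat[[paste0("c", k)]] <- covars[, k]
    cs <- paste(paste0("c", seq_len(ncol(covars))), collapse = " + ")
    full_fml <- paste("y ~ x +", cs)
    red_fml <- paste("y ~", cs)
  }
  full <- stats::lm(stats::as.formula(full_fml), dat)
  red <- stats::lm(stats::as.formula(red_fml), dat)
  rss_f <- sum(stats::resid(full)^2)
  rss_r <- sum(stats::resid(red)^2)
  df <- stats::df.residual(full)
  (rss_r - rss_f) / (rss_f / df)
}

# synthetic participant networks with an optional planted association
random_networks <- function(n_subjects, n_nodes, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_subjects), function(i) {
    m <- matrix(stats::rnorm(n_nodes^2, sd = 0.3), n_nodes, n_nodes)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(paste0("node_", seq_len(n_nodes)),
                        paste0("node_", seq_len(n_nodes)))
    m
  })
}
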