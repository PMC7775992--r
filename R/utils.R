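# Internal helpers shared across modules.

#' Derive a child seed from a root seed and a path of integer indices
#'
#' All stochastic stages expand one root seed through this counter scheme so
#' that any sub-result (a participant, a repetition, a permutation block) can
#' be reproduced in isolation. The result is always a positive integer below
#' 2^31 - 1.
#'
#' @param root integer root seed.
#' @param ... integer indices identifying the consumer (e.g. participant,
#'   repetition).
#' @return a single integer seed.
#' @export
derive_seed <- function(root, ...) {
  idx <- c(...)
  s <- as.numeric(root) %% 2147483647
  for (k in idx) {
    # LCG-style mixing, kept in double precision below 2^53 before reduction
    s <- (s * 48271 + as.numeric(k) * 2246822519 + 374761393) %% 2147483647
  }
  as.integer(s %% 2147483646 + 1)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

assert_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop_field(field, msg)
  invisible(TRUE)
}

# Upper-triangle edge index table for n nodes (i < j), fixed column-major order
edge_index <- function(n, node_ids = NULL) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ut <- ut[order(ut[, 2L], ut[, 1L]), , drop = FALSE]
  out <- data.frame(i = ut[, 1L], j = ut[, 2L])
  if (!is.null(node_ids)) {
    out$node_a <- node_ids[out$i]
    out$node_b <- node_ids[out$j]
  }
  out
}

# Extract the upper triangle of a symmetric matrix as a vector in
# edge_index() order.
ut_vec <- function(m) m[upper.tri(m)]

# Rebuild a symmetric matrix (zero diagonal) from an upper-triangle vector.
ut_mat <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

#' Adjusted Rand index between two labelings
#'
#' Used to quantify stability of metastate labels across repeated runs in the
#' parameter sweep. Standard permutation-model correction.
#'
#' @param a,b label vectors of equal length.
#' @return adjusted Rand index in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop_field("labels", "length mismatch")
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Dense re-coding of labels to 1..K in order of first appearance
dense_labels <- function(x) {
  match(x, unique(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
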