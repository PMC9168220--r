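# Brute-force reference implementations, independent of the package's
# vectorized/incremental code paths, plus small random-graph factories.

# Pearson correlation of two vectors from first principles
brute_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# entry-wise correlation matrix between columns of M1 and M2
brute_cor_matrix <- function(M1, M2 = M1) {
  P1 <- ncol(M1); P2 <- ncol(M2)
  W <- matrix(NA_real_, P1, P2)
  for (i in seq_len(P1))
    for (j in seq_len(P2))
      W[i, j] <- brute_pearson(M1[, i], M2[, j])
  W
}

# top-k thresholding by exhaustive sort of the full edge table
brute_threshold <- function(W, k, directed) {
  P <- nrow(W)
  edges <- NULL
  for (i in seq_len(P))
    for (j in seq_len(P)) {
      if (i == j) next
      if (!directed && i > j) next
      if (W[i, j] > 0) edges <- rbind(edges, c(i, j, W[i, j]))
    }
  o <- order(-edges[, 3], edges[, 1], edges[, 2])
  keep <- edges[o[seq_len(k)], , drop = FALSE]
  A <- matrix(0, P, P)
  for (r in seq_len(nrow(keep))) {
    A[keep[r, 1], keep[r, 2]] <- keep[r, 3]
    if (!directed) A[keep[r, 2], keep[r, 1]] <- keep[r, 3]
  }
  A
}

# reachability by Boolean matrix powering
brute_connected <- function(A) {
  P <- nrow(A)
  B <- (A != 0) | (t(A) != 0)
  diag(B) <- TRUE
  R <- B
  for (s in seq_len(P)) R <- (R %*% B) > 0
  all(R)
}

brute_degree <- function(A) {
  P <- nrow(A)
  d <- numeric(P)
  for (p in seq_len(P)) for (i in seq_len(P)) d[p] <- d[p] + A[p, i]
  d
}

brute_in_out <- function(A) {
  P <- nrow(A)
  ind <- outd <- numeric(P)
  for (j in seq_len(P)) for (i in seq_len(P)) {
    ind[j] <- ind[j] + A[i, j]
    outd[j] <- outd[j] + A[j, i]
  }
  list(in_degree = ind, out_degree = outd)
}

# Onnela weighted clustering by exhaustive triangle enumeration
brute_clustering <- function(A) {
  P <- nrow(A)
  mx <- max(A)
  W <- if (mx > 0) A / mx else A
  C <- numeric(P)
  for (i in seq_len(P)) {
    k <- sum(A[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(P)) for (h in seq_len(P)) {
      if (j == i || h == i || h == j) next
      acc <- acc + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    }
    C[i] <- acc / (k * (k - 1))
  }
  C
}

# random connected-ish weighted symmetric adjacency
rand_sym_graph <- function(P, density = 0.5, zero_diag = TRUE) {
  W <- matrix(0, P, P)
  up <- which(upper.tri(W))
  on <- sample(up, max(1L, round(density * length(up))))
  W[on] <- runif(length(on), 0.1, 1)
  W <- W + t(W)
  if (zero_diag) diag(W) <- 0
  W
}

rand_dir_graph <- function(P, density = 0.5) {
  W <- matrix(runif(P * P), P, P)
  W[W > density] <- 0
  diag(W) <- 0
  W
}

# small cohort configurations used across test files
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_hc = 12L, n_et = 14L, n_cortical = 10L,
                   n_noncortical = 0L, seed = 42L)
  do.call(cohort_config, utils::modifyList(defaults, args))
}
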