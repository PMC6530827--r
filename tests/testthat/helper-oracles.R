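# Independent oracles used to freeze expected values. These deliberately do
# not reuse the package's computational paths.

# All set partitions of n elements as membership vectors (restricted growth).
all_set_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_set_partitions(n - 1)) {
    for (j in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, j)
  }
  out
}

# Exhaustive maximum Newman modularity over every partition of the node set.
max_q_exhaustive <- function(net) {
  genes <- net$genes
  ef <- match(net$edges$from, genes)
  et <- match(net$edges$to, genes)
  m <- net$n_e
  best <- -Inf
  for (p in all_set_partitions(length(genes))) {
    k <- max(p)
    intra <- p[ef] == p[et]
    ec <- tabulate(p[ef][intra], k)
    dc <- tabulate(c(p[ef], p[et]), k)
    best <- max(best, sum(ec / m - (dc / (2 * m))^2))
  }
  best
}

# Exhaustive hypergeometric upper tail from binomial coefficients.
hyper_tail_enum <- function(k, K, n, N) {
  if (k == 0) return(1)
  xs <- seq.int(k, min(n, K))
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Inverse-CDF sampler for a discrete power law on {k_min, ..., k_max}.
rpowerlaw_discrete <- function(n, gamma, k_min, k_max = 1e5) {
  ks <- seq.int(k_min, k_max)
  pmf <- ks^(-gamma)
  sample(ks, n, replace = TRUE, prob = pmf / sum(pmf))
}

degree_dist_from_degrees <- function(d) {
  tab <- table(d)
  out <- data.frame(k = as.integer(names(tab)), count = as.integer(tab),
                    pk = as.integer(tab) / length(d))
  out[order(out$k), ]
}

# Random sparse precision matrix with unit diagonal and known support;
# partial correlations equal minus the off-diagonal entries.
rand_sparse_precision <- function(p, n_edges, lo = 0.3, hi = 0.6) {
  repeat {
    pairs <- t(utils::combn(p, 2))[sample(choose(p, 2), n_edges), , drop = FALSE]
    Om <- diag(p)
    pc <- stats::runif(n_edges, lo, hi) * sample(c(-1, 1), n_edges, TRUE)
    for (e in seq_len(n_edges)) {
      Om[pairs[e, 1], pairs[e, 2]] <- Om[pairs[e, 2], pairs[e, 1]] <- -pc[e]
    }
    if (min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values) > 0.05) {
      return(list(Omega = Om, pairs = pairs, pcor = pc))
    }
  }
}

# Draw n observations from N(0, solve(Omega)) as a genes x samples matrix.
expr_from_precision <- function(n, Omega, gene_prefix = "g") {
  p <- nrow(Omega)
  R <- chol(solve(Omega))
  X <- matrix(stats::rnorm(n * p), n, p) %*% R
  m <- t(X)
  dimnames(m) <- list(sprintf("%s%02d", gene_prefix, seq_len(p)),
                      sprintf("s%03d", seq_len(n)))
  m
}

# The 3-gene chain precision matrix used across partial-correlation tests:
# true pcor(1,2) = pcor(2,3) = -0.4, pcor(1,3) = 0.
chain3_precision <- function() {
  matrix(c(1, 0.4, 0, 0.4, 1, 0.4, 0, 0.4, 1), 3, 3)
}
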