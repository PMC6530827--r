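# Small graph and expression fixtures built in code.

# Two triangles joined by one bridge edge; the max-modularity split is the
# natural 3+3 partition with Q = 2 (3/7 - (7/14)^2) = 5/14.
two_triangle_net <- function() {
  gcn(data.frame(from = c("a", "a", "b", "c", "d", "d", "e"),
                 to   = c("b", "c", "c", "d", "e", "f", "f")))
}

complete_net <- function(n, prefix = "v") {
  cmb <- utils::combn(sprintf("%s%d", prefix, seq_len(n)), 2)
  gcn(data.frame(from = cmb[1, ], to = cmb[2, ]))
}

ring_net <- function(n) {
  v <- sprintf("r%02d", seq_len(n))
  gcn(data.frame(from = v, to = v[c(2:n, 1)]))
}

star_net <- function(n_leaves) {
  gcn(data.frame(from = "hub", to = sprintf("leaf%d", seq_len(n_leaves))))
}

random_small_net <- function(n, p_edge = 0.4) {
  repeat {
    cmb <- utils::combn(sprintf("n%d", seq_len(n)), 2)
    keep <- stats::runif(ncol(cmb)) < p_edge
    if (any(keep)) {
      return(gcn(data.frame(from = cmb[1, keep], to = cmb[2, keep])))
    }
  }
}

# Planted compendium for module-recovery checks (reference configuration:
# 4 modules x 25 genes, within-module correlation 0.8, 60 conditions).
planted_sim <- function(seed, n_conditions = 60L) {
  simulate_expression(sim_config(
    n_modules = 4L, genes_per_module = 25L, n_background = 0L,
    n_conditions = n_conditions, n_replicates = 1L,
    within_module_cor = 0.8, seed = seed))
}
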