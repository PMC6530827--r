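test_that("perfect linear dependence gives a Pearson edge at any threshold", {
  set.seed(1)
  m <- matrix(rnorm(30), 3, 10,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:10)))
  m["b", ] <- 2 * m["a", ]
  net <- correlation_network(m, "pearson", r_threshold = 1)
  expect_true("a\rb" %in% edge_key(net$edges$from, net$edges$to))
  w <- net$edges$weight[net$edges$from == "a" & net$edges$to == "b"]
  expect_equal(w, 1, tolerance = 1e-12)
})

test_that("Spearman is invariant to monotone transforms where Pearson is not", {
  set.seed(2)
  m <- matrix(rnorm(20), 2, 10,
              dimnames = list(c("a", "b"), paste0("s", 1:10)))
  m["b", ] <- exp(m["a", ])
  sp <- correlation_network(m, "spearman", r_threshold = 0.999)
  expect_equal(sp$n_e, 1)
  expect_equal(sp$edges$weight, 1, tolerance = 1e-12)
  pe_r <- stats::cor(m["a", ], m["b", ])
  expect_lt(pe_r, 1 - 1e-6)
})

test_that("raising any threshold never adds an edge (monotone pruning)", {
  sim <- simulate_expression(sim_config(n_modules = 3, genes_per_module = 6,
                                        n_background = 6, n_conditions = 30,
                                        seed = 7))
  prev <- NULL
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    net <- correlation_network(sim$expr, "pearson", r_threshold = th)
    keys <- edge_key(net$edges$from, net$edges$to)
    if (!is.null(prev)) expect_true(all(keys %in% prev))
    prev <- keys
  }
  w <- wgcna_network(sim$expr, beta = 3, tau = 0.2)$network
  w2 <- wgcna_network(sim$expr, beta = 3, tau = 0.5)$network
  expect_true(all(edge_key(w2$edges$from, w2$edges$to) %in%
                    edge_key(w$edges$from, w$edges$to)))
})

test_that("networks are simple: no self-loops, no duplicates, isolated genes dropped", {
  sim <- simulate_expression(sim_config(n_modules = 2, genes_per_module = 5,
                                        n_background = 20, n_conditions = 30,
                                        seed = 3))
  net <- correlation_network(sim$expr, "pearson", r_threshold = 0.7)
  expect_true(all(net$edges$from != net$edges$to))
  expect_identical(anyDuplicated(edge_key(net$edges$from, net$edges$to)), 0L)
  expect_setequal(net$genes, unique(c(net$edges$from, net$edges$to)))
  expect_lt(net$n_g, nrow(sim$expr))   # background genes fail the threshold
})

test_that("edge recovery on planted modules reaches F1 >= 0.7", {
  f1 <- vapply(1:10, function(s) {
    sim <- planted_sim(seed = s)
    net <- correlation_network(sim$expr, "pearson", r_threshold = 0.6)
    edge_recovery(net, sim$truth)$f1
  }, numeric(1))
  expect_true(all(f1 >= 0.7))
})

test_that("within-module edges are more likely than between-module edges", {
  sim <- simulate_expression(sim_config(n_modules = 4, genes_per_module = 10,
                                        n_background = 0, n_conditions = 200,
                                        n_replicates = 1,
                                        within_module_cor = 0.5, seed = 13))
  truth_keys <- edge_key(sim$truth$true_edges$from, sim$truth$true_edges$to)
  for (th in c(0.2, 0.4, 0.6)) {
    net <- correlation_network(sim$expr, "pearson", r_threshold = th)
    keys <- edge_key(net$edges$from, net$edges$to)
    n_within <- sum(keys %in% truth_keys)
    n_total_within <- length(truth_keys)
    n_total_between <- choose(40, 2) - n_total_within
    p_within <- n_within / n_total_within
    p_between <- (length(keys) - n_within) / n_total_between
    expect_gt(p_within, p_between)
  }
})

test_that("zero-variance genes are skipped with a warning, not NaN edges", {
  set.seed(4)
  m <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  m[2, ] <- 3
  expect_warning(net <- correlation_network(m, "pearson", r_threshold = 0.1),
                 "zero-variance")
  expect_false("g2" %in% net$genes)
  expect_false(any(is.na(net$edges$weight)))
})

test_that("exact top-k edge selection matches the threshold ranking", {
  sim <- simulate_expression(sim_config(n_modules = 2, genes_per_module = 6,
                                        n_background = 4, n_conditions = 30,
                                        seed = 15))
  net <- correlation_network(sim$expr, "pearson", n_edges = 25)
  expect_equal(net$n_e, 25)
  full <- correlation_network(sim$expr, "pearson", r_threshold = 1e-6)
  top <- full$edges[order(-abs(full$edges$weight)), ][1:25, ]
  expect_setequal(edge_key(net$edges$from, net$edges$to),
                  edge_key(top$from, top$to))
})

test_that("soft-threshold adjacency at beta 1 equals correlation thresholding", {
  sim <- simulate_expression(sim_config(n_modules = 2, genes_per_module = 6,
                                        n_background = 4, n_conditions = 25,
                                        seed = 6))
  w <- wgcna_network(sim$expr, beta = 1, tau = 0.5)$network
  r <- correlation_network(sim$expr, "pearson", r_threshold = 0.5)
  expect_setequal(edge_key(w$edges$from, w$edges$to),
                  edge_key(r$edges$from, r$edges$to))
})

test_that("the topological overlap of a perfect triangle is 1 everywhere", {
  # Three genes with pairwise |r| = 1: a_ij = 1, so
  # TOM_ij = (1 + 1) / (2 + 1 - 1) = 1 for every pair.
  base <- c(1.2, -0.5, 3.1, 0.4, -1.8, 2.2)
  m <- rbind(a = base, b = 2 * base, c = -0.5 * base)
  colnames(m) <- paste0("s", 1:6)
  w <- wgcna_network(m, beta = 1, tau = 0.5)
  expect_equal(unname(w$tom[upper.tri(w$tom)]), rep(1, 3), tolerance = 1e-12)
})

test_that("wgcna default soft power is 5 and module recovery survives beta 5", {
  expect_identical(eval(formals(wgcna_network)$beta), 5L)
  aris <- vapply(1:10, function(s) {
    sim <- planted_sim(seed = 100 + s)
    net <- wgcna_network(sim$expr, beta = 5, tau = 0.8^5)$network
    part <- detect_modules(net, "walktrap")
    partition_similarity(part, truth_partition(sim$truth))
  }, numeric(1))
  expect_gte(mean(aris >= 0.8), 0.9)
})

test_that("soft-power selection returns the lowest qualifying power", {
  sim <- simulate_expression(sim_config(n_modules = 3, genes_per_module = 8,
                                        n_background = 10, n_conditions = 40,
                                        seed = 5))
  sel <- select_soft_power(sim$expr, betas = 1:6, r2_target = 0)
  expect_identical(as.integer(sel), 1L)
  tab <- attr(sel, "fit_table")
  expect_equal(tab$beta, 1:6)
})

test_that("pure noise never reaches the scale-free target and falls back with a warning", {
  set.seed(9)
  noise <- matrix(rnorm(600), 30, 20,
                  dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
  expect_warning(sel <- select_soft_power(noise, betas = 1:4,
                                          r2_target = 0.999),
                 "argmax")
  expect_true(sel %in% 1:4)
})
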