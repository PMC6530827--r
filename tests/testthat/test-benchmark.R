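test_that("undirecting a regulatory network collapses reciprocal pairs", {
  rn <- structure(list(edges = data.frame(
    regulator = c("A", "B", "A", "C"),
    target = c("B", "A", "C", "D"), stringsAsFactors = FALSE),
    genes = c("A", "B", "C", "D")), class = "regnet")
  net <- undirect_network(rn)
  expect_equal(net$n_e, 3)              # A-B collapsed
  expect_lte(net$n_e, nrow(rn$edges))
  # idempotent through a write -> read -> undirect round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  expect_identical(read_network(path)$edges, net$edges)
})

test_that("a star regulator keeps its full degree after undirecting", {
  rn <- structure(list(edges = data.frame(
    regulator = "TF1", target = sprintf("t%03d", 1:100)),
    genes = c("TF1", sprintf("t%03d", 1:100))), class = "regnet")
  net <- undirect_network(rn)
  expect_equal(unname(gcn_degrees(net)["TF1"]), 100L)
})

test_that("random edge addition adds exactly ceil(phi n_e) fresh edges", {
  net <- undirect_network(simulate_regulatory_network(100, 1, seed = 2))
  expect_identical(add_random_edges(net, phi = 0), net)
  for (phi in c(0.25, 0.5, 1)) {
    aug <- add_random_edges(net, phi = phi, seed = 11)
    expect_equal(aug$n_e, net$n_e + ceiling(phi * net$n_e))
    # original edges untouched
    expect_true(all(edge_key(net$edges$from, net$edges$to) %in%
                      edge_key(aug$edges$from, aug$edges$to)))
  }
  a1 <- add_random_edges(net, 0.5, seed = 7)
  a2 <- add_random_edges(net, 0.5, seed = 7)
  expect_identical(a1$edges, a2$edges)
  expect_error(add_random_edges(complete_net(4), phi = 2), "non-adjacent")
})

test_that("degree-weighted addition shifts the degree CDF to the right", {
  for (s in 1:3) {
    net <- undirect_network(simulate_regulatory_network(500, 2, seed = s))
    aug <- add_random_edges(net, 0.5, seed = 100 + s)
    d0 <- degree_distribution(net); d1 <- degree_distribution(aug)
    support <- sort(unique(c(d0$k, d1$k)))
    cdf <- function(d) stats::stepfun(d$k, c(0, cumsum(d$pk)))(support)
    expect_true(all(cdf(d1) <= cdf(d0) + 1e-12))
  }
})

test_that("the KS degree distance behaves like a metric on distributions", {
  net <- star_net(5)
  d <- degree_distribution(net)
  expect_equal(ks_degree_distance(d, d), 0)
  single <- function(k) data.frame(k = k, count = 5L, pk = 1)
  expect_equal(ks_degree_distance(single(1), single(10)), 1)
  other <- degree_distribution(ring_net(6))
  expect_equal(ks_degree_distance(d, other), ks_degree_distance(other, d))
})

test_that("screening applies the discard rules and keeps the rest ordered", {
  mknet <- function(n, extra = 0) {
    v <- sprintf("g%03d", seq_len(n))
    edges <- data.frame(from = v[-n], to = v[-1])
    if (extra > 0) {
      cmb <- utils::combn(v, 2)
      pool <- data.frame(from = cmb[1, ], to = cmb[2, ])
      pool <- pool[!(edge_key(pool$from, pool$to) %in%
                       edge_key(edges$from, edges$to)), ]
      edges <- rbind(edges, pool[seq_len(extra), ])
    }
    gcn(edges)
  }
  cand <- function(net, q, label) {
    list(network = net,
         partition = structure(list(q = q), class = "gcn_partition"),
         label = label)
  }
  crit <- screening_criteria(q_min = 0.5, g_min = 500, ratio_max = 10,
                             gold_ratios = c(2.6, 3.3))
  sparse <- cand(mknet(300), q = 0.8, label = "sparse")
  screened <- screen_candidates(list(sparse), crit)
  expect_equal(screened$discarded$reason, "very sparse connectivity")

  good1 <- cand(mknet(600, extra = 1000), q = 0.8, label = "good1")  # ratio 2.66
  good2 <- cand(mknet(600, extra = 3500), q = 0.7, label = "good2")  # ratio 6.8
  lowq <- cand(mknet(600, extra = 1000), q = 0.2, label = "lowq")
  out <- screen_candidates(list(good2, lowq, good1),
                           screening_criteria(q_min = 0.5, g_min = 500,
                                              ratio_max = 10,
                                              gold_ratios = c(2.6, 3.3)))
  expect_setequal(c(out$kept$label, out$discarded$label),
                  c("good1", "good2", "lowq"))
  expect_identical(out$kept$label, c("good1", "good2"))  # nearest gold first
  # the reported SPACE lower-bound regime n_e/n_g ~ 6.5 passes ratio_max 10
  expect_lte(6.5, 10)
  expect_true("good2" %in% out$kept$label)
  all_pass <- screen_candidates(list(good1, good2), crit)
  expect_equal(nrow(all_pass$discarded), 0)
  expect_error(screen_candidates(list(), crit), "empty")
})

test_that("method ranking is order-invariant and errors on missing fields", {
  mkrep <- function(method, sig, psi1, psi2, q, r2) {
    list(method = method,
         summary = list(total_significant_terms = sig, psi1 = psi1,
                        psi2 = psi2),
         q = q,
         power_law = list(r2_loglog = r2, ks_stat = NA_real_))
  }
  reps <- list(mkrep("alpha", 10, 2, 1.5, 0.8, 0.9),
               mkrep("beta", 4, 1, 0.5, 0.6, 0.5),
               mkrep("gamma", 7, 1.5, 1.0, 0.7, 0.7))
  r1 <- rank_methods(reps)
  r2 <- rank_methods(rev(reps))
  expect_identical(r1, r2)
  expect_identical(r1$method[r1$overall_rank == 1], "alpha")
  broken <- reps
  broken[[2]]$summary <- NULL
  expect_error(rank_methods(broken), "summary")
  expect_error(rank_methods(reps[1]), "at least 2")
})

test_that("edge recovery metrics follow their arithmetic identities", {
  truth <- list(true_edges = data.frame(from = c("a", "c"), to = c("b", "d")))
  exact <- gcn(data.frame(from = c("a", "c"), to = c("b", "d")))
  expect_equal(edge_recovery(exact, truth)$f1, 1)
  # prediction = truth plus an equal number of false edges among the same
  # genes: precision 1/2, recall 1, F1 = 2/3
  padded <- gcn(data.frame(from = c("a", "c", "a", "b"),
                           to = c("b", "d", "c", "d")))
  r2 <- edge_recovery(padded, truth)
  expect_equal(r2$precision, 0.5)
  expect_equal(r2$recall, 1)
  expect_equal(r2$f1, 2 / 3)
  # an empty (non-overlapping) prediction has zero recall and is flagged
  r3 <- edge_recovery(gcn(data.frame(from = "x", to = "y")), truth)
  expect_equal(r3$recall, 0)
  expect_true(r3$empty_prediction)
})

test_that("the adjusted Rand index is exact, symmetric and centred at chance", {
  sim <- simulate_expression(sim_config(n_modules = 4, genes_per_module = 25,
                                        n_background = 0, n_conditions = 5,
                                        seed = 3))
  tp <- truth_partition(sim$truth)
  expect_equal(partition_similarity(tp, tp), 1)
  set.seed(6)
  other <- stats::setNames(sample(1:4, 100, replace = TRUE),
                           names(tp$module_of))
  expect_equal(partition_similarity(tp, other),
               partition_similarity(other, tp))
  # chance level: random labels against the planted truth
  aris <- vapply(1:100, function(i) {
    set.seed(i)
    partition_similarity(tp, stats::setNames(sample(rep(1:4, 25)),
                                             names(tp$module_of)))
  }, numeric(1))
  expect_lte(abs(mean(aris)), 0.05)
  # cross-check against an independent implementation
  if (requireNamespace("e1071", quietly = TRUE)) {
    for (i in 1:10) {
      set.seed(i)
      a <- sample(1:3, 60, replace = TRUE)
      b <- sample(1:4, 60, replace = TRUE)
      names(a) <- names(b) <- paste0("g", 1:60)
      expect_equal(partition_similarity(a, b),
                   e1071::classAgreement(table(a, b))$crand,
                   tolerance = 1e-12)
    }
  }
})

test_that("regulon projection reports coverage and cohesion correctly", {
  sim <- planted_sim(seed = 4)
  net <- correlation_network(sim$expr, "pearson", r_threshold = 0.6)
  part <- detect_modules(net, "walktrap")
  mods <- sim$truth$modules
  sets <- list(pure = mods$M1,
               absent = paste0("zz", 1:5),
               diluted = c(mods$M2, paste0("zz", 1:20)))
  proj <- project_gene_sets(part, net, sets)
  expect_equal(proj$cohesion[proj$set == "pure"], 1)
  expect_equal(proj$coverage[proj$set == "absent"], 0)
  expect_true(is.na(proj$cohesion[proj$set == "absent"]))
  expect_equal(proj$cohesion[proj$set == "diluted"], 1)  # absent genes drop out
  diluted_in <- c(mods$M2, mods$M3[1:10])
  proj2 <- project_gene_sets(part, net, list(mix = diluted_in))
  expect_lt(proj2$cohesion, 1)
  expect_error(project_gene_sets(part, net, list()), "non-empty")
})
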