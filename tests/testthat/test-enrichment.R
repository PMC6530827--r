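test_that("the hypergeometric tail matches exhaustive enumeration", {
  # Hand-checkable fixture: N = 20, K = 5, n = 5, k = 3 -> 1126/15504.
  expect_equal(fisher_overrepresentation(3, 5, 5, 20), 1126 / 15504,
               tolerance = 1e-12)
  expect_equal(hyper_tail_enum(3, 5, 5, 20), 1126 / 15504, tolerance = 1e-14)
  # k = 0 spans the whole tail; k = n = K is the single most extreme table.
  expect_equal(fisher_overrepresentation(0, 5, 5, 20), 1)
  expect_equal(fisher_overrepresentation(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  set.seed(8)
  for (i in 1:200) {
    N <- sample(2:50, 1)
    n <- sample(1:N, 1)
    K <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(fisher_overrepresentation(k, K, n, N),
                 hyper_tail_enum(k, K, n, N), tolerance = 1e-12)
    expect_equal(fisher_overrepresentation(k, K, n, N),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(fisher_overrepresentation(6, 5, 5, 20), "inconsistent")
})

test_that("the tail probability is non-increasing in k", {
  p <- vapply(0:5, fisher_overrepresentation, numeric(1), K = 8, n = 5, N = 30)
  expect_true(all(diff(p) <= 0))
})

test_that("planted annotations make every dedicated term significant", {
  sim <- simulate_expression(sim_config(n_modules = 4, genes_per_module = 8,
                                        n_background = 20, n_conditions = 10,
                                        seed = 31))
  ann <- simulate_annotations(sim$truth, n_terms = 10, frac_correct = 1,
                              seed = 3)
  part <- truth_partition(sim$truth)
  res <- enrich_modules(part, ann, alpha = 0.05, min_module_size = 5)
  planted <- attr(ann, "planted_terms")
  for (m in names(planted)) {
    row <- res[res$module == m & res$term == planted[m], ]
    expect_equal(nrow(row), 1)
    expect_true(row$significant)
    # oracle bound: the p-value can never beat the most extreme table
    expect_gte(row$p, 1 / choose(row$N, row$n) - 1e-15)
  }
  expect_true(all(res$q >= res$p))
  expect_true(all(res$k <= pmin(res$n, res$K)))
})

test_that("unannotated modules produce no rows and sub-size modules are skipped", {
  sim <- simulate_expression(sim_config(n_modules = 2, genes_per_module = 8,
                                        n_background = 3, n_conditions = 10,
                                        seed = 7))
  ann <- simulate_annotations(sim$truth, n_terms = 4, frac_correct = 1, seed = 1)
  part <- truth_partition(sim$truth)   # background genes: singleton modules
  res <- enrich_modules(part, ann, min_module_size = 5)
  expect_true(all(res$module %in% c("M1", "M2")))
})

test_that("at frac_correct 0 enrichment of the true modules is at chance", {
  # With frac_correct = 0 no term is informative about any module, so the
  # raw one-sided FET significance rate across all tested module-term pairs
  # must stay near the nominal level.
  hits <- 0L; tests <- 0L
  for (s in 1:20) {
    sim <- simulate_expression(sim_config(n_modules = 4, genes_per_module = 6,
                                          n_background = 0, n_conditions = 10,
                                          seed = 400 + s))
    ann <- simulate_annotations(sim$truth, n_terms = 8, frac_correct = 0,
                                seed = s, extra_rate = 0.3)
    res <- enrich_modules(truth_partition(sim$truth), ann, alpha = 0.05,
                          correction = "none", min_module_size = 5)
    tests <- tests + nrow(res)
    hits <- hits + sum(res$significant)
  }
  expect_gt(tests, 100)
  # discrete one-sided FETs are conservative; allow sampling slack upward
  expect_lte(hits / tests, 0.05 + 3 * sqrt(0.05 * 0.95 / tests))
})

test_that("psi statistics match the hand-evaluated fixture", {
  # Three annotated modules with 4, 1 and 0 significant terms:
  # psi1 = (4+1)/2 = 2.5, psi2 = 5/3, psi2 (literal reading) = 5/2.
  res <- data.frame(
    module = c(rep("0", 5), rep("1", 3), rep("2", 2)),
    term = paste0("T", 1:10), k = 2, n = 6, K = 4, N = 40,
    p = 0.01, q = 0.01,
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE,
                    TRUE, FALSE, FALSE,
                    FALSE, FALSE))
  class(res) <- c("enrichment_result", "data.frame")
  attr(res, "alpha") <- 0.05
  part <- structure(list(module_of = character(), modules = list(),
                         q = NA, method = "fixture", params = list()),
                    class = "gcn_partition")
  ps <- psi_summary(res, part)
  expect_equal(ps$psi1, 2.5)
  expect_equal(ps$psi2, 5 / 3)
  expect_equal(ps$psi2_literal, 2.5)
  expect_equal(ps$total_significant_terms, 5L)
  expect_equal(ps$n_enriched_modules, 2L)

  # relabelling the modules changes nothing
  res2 <- res
  res2$module <- c(rep("B", 5), rep("C", 3), rep("A", 2))
  class(res2) <- class(res); attr(res2, "alpha") <- 0.05
  ps2 <- psi_summary(res2, part)
  expect_equal(ps2$psi1, ps$psi1)
  expect_equal(ps2$psi2, ps$psi2)

  # no significant results at all
  res3 <- res; res3$significant <- FALSE
  class(res3) <- class(res); attr(res3, "alpha") <- 0.05
  ps3 <- psi_summary(res3, part)
  expect_equal(ps3$psi1, 0)
  expect_equal(ps3$psi2, 0)

  # a single module with one significant term
  res4 <- res[res$module == "1", ]
  class(res4) <- class(res); attr(res4, "alpha") <- 0.05
  ps4 <- psi_summary(res4, part)
  expect_equal(ps4$psi1, 1)
  expect_equal(ps4$psi2, 1)
})

test_that("the true partition is at least as enriched as a size-matched shuffle", {
  wins <- vapply(1:20, function(s) {
    sim <- simulate_expression(sim_config(n_modules = 5, genes_per_module = 6,
                                          n_background = 0, n_conditions = 10,
                                          seed = 500 + s))
    ann <- simulate_annotations(sim$truth, n_terms = 10, frac_correct = 0.9,
                                seed = s)
    tp <- truth_partition(sim$truth)
    psi_true <- psi_summary(enrich_modules(tp, ann), tp)$psi2
    set.seed(s)
    shuffled <- tp
    names(shuffled$module_of) <- sample(names(shuffled$module_of))
    shuffled$modules <- split(names(shuffled$module_of), shuffled$module_of)
    psi_rand <- psi_summary(enrich_modules(shuffled, ann), shuffled)$psi2
    psi_true >= psi_rand
  }, logical(1))
  expect_gte(sum(wins), 18)
})
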