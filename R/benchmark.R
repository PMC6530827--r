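#' Collapse a directed regulatory network to an undirected gold standard
#'
#' Directed TF-to-target edges are represented as a co-expression-style
#' network by ignoring direction; reciprocal pairs collapse to one edge and
#' weights are set to 1.
#'
#' @param regnet a `regnet` (see [simulate_regulatory_network()] or
#'   [read_regnet()]), or a data.frame with columns `regulator`, `target`.
#' @return A [gcn()] network.
#' @export
undirect_network <- function(regnet) {
  edges <- if (inherits(regnet, "regnet")) regnet$edges else regnet
  stopifnot(is.data.frame(edges), all(c("regulator", "target") %in% names(edges)))
  a <- pmin(edges$regulator, edges$target)
  b <- pmax(edges$regulator, edges$target)
  keep <- !duplicated(paste(a, b, sep = "\r")) & a != b
  gcn(data.frame(from = a[keep], to = b[keep], weight = 1,
                 stringsAsFactors = FALSE),
      method = "gold_standard")
}

#' Probabilistic random edge addition
#'
#' Adds exactly `ceiling(phi * n_e)` new edges among currently non-adjacent
#' gene pairs, sampled with probability proportional to the product of the
#' endpoint degrees (rejection sampling over self-pairs, duplicates and
#' existing edges). Degree-proportional addition preserves the heavy tail of
#' the degree distribution while shifting it to the right, which is the
#' robustness probe used when comparing reconstructed networks to
#' gold standards. Original edges are untouched; deterministic under `seed`.
#'
#' @param network a [gcn()] object.
#' @param phi fraction of the current edge count to add (>= 0).
#' @param seed integer seed.
#' @return A [gcn()] network with `n_e + ceiling(phi * n_e)` edges; added
#'   edges carry weight 1.
#' @export
add_random_edges <- function(network, phi, seed = 1L) {
  stopifnot(inherits(network, "gcn"))
  if (phi < 0) stop("`phi` must be >= 0")
  n_add <- ceiling(phi * network$n_e)
  if (n_add == 0) return(network)
  max_pairs <- choose(network$n_g, 2)
  if (network$n_e + n_add > max_pairs) {
    stop("not enough non-adjacent gene pairs to add ", n_add, " edges")
  }
  deg <- gcn_degrees(network)
  genes <- network$genes
  existing <- edge_key(network$edges$from, network$edges$to)
  with_seed(seed, {
    new_keys <- character(0)
    new_from <- character(0); new_to <- character(0)
    while (length(new_keys) < n_add) {
      todo <- n_add - length(new_keys)
      i <- sample(genes, 2 * todo + 10, replace = TRUE, prob = deg)
      j <- sample(genes, 2 * todo + 10, replace = TRUE, prob = deg)
      ok <- i != j
      key <- edge_key(i[ok], j[ok])
      fresh <- !(key %in% existing) & !(key %in% new_keys) & !duplicated(key)
      take <- which(fresh)[seq_len(min(todo, sum(fresh)))]
      new_keys <- c(new_keys, key[take])
      new_from <- c(new_from, pmin(i[ok], j[ok])[take])
      new_to <- c(new_to, pmax(i[ok], j[ok])[take])
    }
    out <- gcn(rbind(network$edges,
                     data.frame(from = new_from, to = new_to, weight = 1,
                                stringsAsFactors = FALSE)),
               method = network$method,
               params = c(network$params, list(phi = phi)))
    out
  })
}

#' Kolmogorov-Smirnov distance between two degree distributions
#'
#' Quantifies the visual comparison of degree distributions between a
#' reconstructed network and a gold standard: the maximum absolute
#' difference between the two empirical degree CDFs, in \[0, 1\].
#'
#' @param a,b [degree_distribution()] results.
#' @return The KS distance.
#' @export
ks_degree_distance <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b), nrow(a) > 0, nrow(b) > 0)
  support <- sort(unique(c(a$k, b$k)))
  cdf <- function(d) {
    cs <- cumsum(d$pk)
    idx <- findInterval(support, d$k)
    c(0, cs)[idx + 1L]
  }
  max(abs(cdf(a) - cdf(b)))
}

#' Screening criteria for candidate networks
#'
#' Operationalizes the discard rules for candidate GCNs: very high
#' connectivity (`n_e/n_g > ratio_max`), low modularity (`Q < q_min`) and
#' very sparse connectivity (`n_g < g_min`, "only a few hundred genes").
#' Survivors are ordered by closeness of `n_e/n_g` to the nearest
#' gold-standard ratio.
#'
#' @param q_min minimum best-partition modularity (default 0.5).
#' @param g_min minimum gene count (default 500).
#' @param ratio_max maximum edges-to-genes ratio (default 10).
#' @param gold_ratios reference `n_e/n_g` values of the gold-standard
#'   networks.
#' @return list of class `screening_criteria`.
#' @export
screening_criteria <- function(q_min = 0.5, g_min = 500L, ratio_max = 10,
                               gold_ratios = numeric()) {
  if (q_min <= 0 || g_min <= 0 || ratio_max <= 0) {
    stop("all screening thresholds must be positive")
  }
  structure(list(q_min = q_min, g_min = as.integer(g_min),
                 ratio_max = ratio_max, gold_ratios = gold_ratios),
            class = "screening_criteria")
}

#' Screen candidate networks against the discard rules
#'
#' @param candidates list of candidates, each a list with elements `network`
#'   (a [gcn()]), `partition` (its best `gcn_partition`, carrying `q`) and
#'   optionally `label`.
#' @param criteria a [screening_criteria()] object.
#' @return list with data.frames `kept` (columns `label`, `n_g`, `n_e`,
#'   `ratio`, `q`, `gold_distance`; ordered by `gold_distance`) and
#'   `discarded` (same plus `reason`).
#' @export
screen_candidates <- function(candidates, criteria) {
  stopifnot(inherits(criteria, "screening_criteria"))
  if (!length(candidates)) stop("empty candidate list")
  rows <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    net <- cand$network
    data.frame(label = cand$label %||% net$method %||% as.character(i),
               n_g = net$n_g, n_e = net$n_e,
               ratio = net$n_e / net$n_g,
               q = cand$partition$q,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  reason <- character(nrow(tab))
  reason[tab$ratio > criteria$ratio_max] <- "very high connectivity"
  reason[tab$q < criteria$q_min] <- "low modularity"
  reason[tab$n_g < criteria$g_min] <- "very sparse connectivity"
  tab$gold_distance <- if (length(criteria$gold_ratios)) {
    vapply(tab$ratio, function(r) min(abs(r - criteria$gold_ratios)),
           numeric(1))
  } else NA_real_
  kept <- tab[reason == "", , drop = FALSE]
  if (nrow(kept) && !all(is.na(kept$gold_distance))) {
    kept <- kept[order(kept$gold_distance), , drop = FALSE]
  }
  discarded <- tab[reason != "", , drop = FALSE]
  discarded$reason <- reason[reason != ""]
  rownames(kept) <- rownames(discarded) <- NULL
  list(kept = kept, discarded = discarded)
}

#' Rank reconstruction methods by structure and enrichment
#'
#' Per-criterion ranks (1 = best) on: total significant enrichment tests,
#' psi1, psi2, best-partition modularity Q, and power-law fit quality
#' (log-log R-squared when available, otherwise 1 - KS). Overall rank is the
#' rank-sum order, ties broken by psi2. Input order does not matter.
#'
#' @param reports list of method reports, each a list with `method`,
#'   `summary` (an `enrichment_summary`), `q` (modularity) and `power_law`
#'   (a `power_law_fit`).
#' @return data.frame of class `method_ranking`, one row per method with the
#'   criterion values, per-criterion ranks and `overall_rank`.
#' @export
rank_methods <- function(reports) {
  if (length(reports) < 2) stop("need at least 2 method reports to rank")
  rows <- lapply(reports, function(rep) {
    for (f in c("method", "summary", "q", "power_law")) {
      if (is.null(rep[[f]])) stop("missing report field: ", f)
    }
    fitq <- if (!is.na(rep$power_law$r2_loglog)) rep$power_law$r2_loglog
            else 1 - rep$power_law$ks_stat
    data.frame(method = rep$method,
               total_significant = rep$summary$total_significant_terms,
               psi1 = rep$summary$psi1, psi2 = rep$summary$psi2,
               q = rep$q, fit_quality = fitq, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$method), , drop = FALSE]      # order invariance
  crit <- c("total_significant", "psi1", "psi2", "q", "fit_quality")
  for (cr in crit) {
    tab[[paste0("rank_", cr)]] <- rank(-tab[[cr]], ties.method = "average")
  }
  tab$rank_sum <- rowSums(tab[paste0("rank_", crit)])
  ord <- order(tab$rank_sum, -tab$psi2, tab$method)
  tab$overall_rank <- NA_integer_
  tab$overall_rank[ord] <- seq_len(nrow(tab))
  tab <- tab[order(tab$overall_rank), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("method_ranking", "data.frame")
  tab
}

#' Edge-recovery metrics against a planted ground truth
#'
#' Precision, recall and F1 of the predicted edge set against the true
#' within-module pairs, restricted to genes shared by both.
#'
#' @param predicted a [gcn()] network.
#' @param truth a `ground_truth` object (or any list with a `true_edges`
#'   data.frame of columns `from`, `to`).
#' @return list: `precision`, `recall`, `f1`, `tp`, `n_predicted`, `n_true`,
#'   `empty_prediction` flag (precision is defined as 0 when nothing was
#'   predicted).
#' @export
edge_recovery <- function(predicted, truth) {
  stopifnot(inherits(predicted, "gcn"))
  te <- truth$true_edges
  shared <- intersect(predicted$genes, unique(c(te$from, te$to)))
  pk <- edge_key(predicted$edges$from, predicted$edges$to)
  pk <- pk[predicted$edges$from %in% shared & predicted$edges$to %in% shared]
  tk <- edge_key(te$from, te$to)
  tk <- tk[te$from %in% shared & te$to %in% shared]
  tp <- length(intersect(pk, tk))
  precision <- if (length(pk)) tp / length(pk) else 0
  recall <- if (length(tk)) tp / length(tk) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, tp = tp,
       n_predicted = length(pk), n_true = length(tk),
       empty_prediction = length(pk) == 0)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two gene partitions (standard
#' expected-index correction), computed on the genes present in both.
#'
#' @param a,b `gcn_partition` objects or named membership vectors.
#' @return The ARI (1 for identical partitions, ~0 at chance).
#' @export
partition_similarity <- function(a, b) {
  ma <- membership_vector(a); mb <- membership_vector(b)
  shared <- intersect(names(ma), names(mb))
  if (!length(shared)) stop("partitions share no genes")
  ct <- table(ma[shared], mb[shared])
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  n2 <- choose(length(shared), 2)
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}

#' Project gene sets (regulons, operons) onto network modules
#'
#' For each named gene set, reports coverage (fraction of the set present in
#' the network) and cohesion (largest fraction of the covered genes falling
#' in a single module), with the per-module membership breakdown — the
#' guilt-by-association check that genes of the same regulon land in the
#' same module.
#'
#' @param partition a `gcn_partition`.
#' @param network the [gcn()] the partition was computed on.
#' @param gene_sets named list of character gene vectors.
#' @return data.frame with columns `set`, `size`, `n_in_network`, `coverage`,
#'   `cohesion`, `top_module`; the per-module breakdown is attached as the
#'   `breakdown` attribute (list of tables).
#' @export
project_gene_sets <- function(partition, network, gene_sets) {
  stopifnot(inherits(partition, "gcn_partition"), inherits(network, "gcn"))
  if (!length(gene_sets)) stop("`gene_sets` must be non-empty")
  if (is.null(names(gene_sets))) stop("`gene_sets` must be named")
  mem <- partition$module_of
  breakdown <- list()
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(gene_sets[[nm]])
    inside <- intersect(set, network$genes)
    coverage <- length(inside) / length(set)
    if (!length(inside)) {
      breakdown[[nm]] <<- table(character())
      return(data.frame(set = nm, size = length(set), n_in_network = 0L,
                        coverage = 0, cohesion = NA_real_,
                        top_module = NA_character_, stringsAsFactors = FALSE))
    }
    tab <- sort(table(mem[inside]), decreasing = TRUE)
    breakdown[[nm]] <<- tab
    data.frame(set = nm, size = length(set), n_in_network = length(inside),
               coverage = coverage, cohesion = as.numeric(tab[1]) / length(inside),
               top_module = names(tab)[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "breakdown") <- breakdown
  out
}
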