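#' Build an annotation table from gene-term pairs
#'
#' Flat gene-to-term annotations (no ontology-graph propagation), stored with
#' both the forward map and the inverted term index.
#'
#' @param pairs data.frame with columns `gene` and `term`.
#' @param universe optional gene universe; defaults to the annotated genes.
#' @param all_terms optional complete term list (terms may annotate no gene).
#' @return list of class `annotation_table`: `gene2term`, `term2gene`,
#'   `universe`, `terms`.
#' @export
annotation_table <- function(pairs, universe = NULL, all_terms = NULL) {
  stopifnot(is.data.frame(pairs), all(c("gene", "term") %in% names(pairs)))
  pairs <- unique(data.frame(gene = as.character(pairs$gene),
                             term = as.character(pairs$term),
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$gene, pairs$term), , drop = FALSE]
  universe <- sort(unique(c(universe, pairs$gene)))
  terms <- sort(unique(c(all_terms, pairs$term)))
  structure(list(
    gene2term = split(pairs$term, factor(pairs$gene, levels = universe)),
    term2gene = split(pairs$gene, factor(pairs$term, levels = terms)),
    universe = universe,
    terms = terms),
    class = "annotation_table")
}

#' @export
print.annotation_table <- function(x, ...) {
  cat(sprintf("Annotation table: %d genes (universe), %d terms, %d pairs\n",
              length(x$universe), length(x$terms),
              sum(lengths(x$gene2term))))
  invisible(x)
}

#' One-sided Fisher overrepresentation p-value
#'
#' Upper-tail hypergeometric probability
#' \deqn{p = \sum_{x \ge k} \binom{K}{x}\binom{N-K}{n-x}/\binom{N}{n}}
#' of observing at least `k` term genes in a module of `n` genes, given `K`
#' term genes in a universe of `N`. Accumulated in log space for stability.
#'
#' @param k term genes observed in the module.
#' @param K term genes in the universe.
#' @param n module genes in the universe.
#' @param N universe size.
#' @return The one-sided p-value in (0, 1\].
#' @examples
#' fisher_overrepresentation(3, 5, 5, 20)  # 1126/15504
#' @export
fisher_overrepresentation <- function(k, K, n, N) {
  for (v in c(k, K, n, N)) assert_count(v, "count", min = 0L)
  if (k > min(n, K) || n > N || K > N) {
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N")
  }
  if (k == 0) return(1)
  xs <- seq.int(k, min(n, K))
  exp(log_sum_exp(stats::dhyper(xs, K, N - K, n, log = TRUE)))
}

#' Per-module Fisher's-exact-test gene-set enrichment
#'
#' For every module with at least `min_module_size` genes and every term
#' with at least one gene in the module, computes the one-sided FET
#' p-value against the shared gene universe (genes present in both the
#' partition and the annotation table), adjusts p-values within each module,
#' and flags significance at `alpha`.
#'
#' @param partition a `gcn_partition` (see [detect_modules()]).
#' @param annotations an [annotation_table()].
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param correction a [stats::p.adjust()] method (default `"BH"`); use
#'   `"none"` for raw p-values.
#' @param min_module_size enrichment eligibility threshold (default 5).
#' @return data.frame of class `enrichment_result` with columns `module`,
#'   `term`, `k`, `n`, `K`, `N`, `p`, `q`, `significant`.
#' @export
enrich_modules <- function(partition, annotations, alpha = 0.05,
                           correction = "BH", min_module_size = 5L) {
  stopifnot(inherits(partition, "gcn_partition"),
            inherits(annotations, "annotation_table"))
  assert_fraction(alpha, "alpha", lo = 1e-12)
  assert_count(min_module_size, "min_module_size")
  universe <- intersect(names(partition$module_of), annotations$universe)
  N <- length(universe)
  if (N == 0) stop("partition and annotation gene universes do not intersect")
  term_genes <- lapply(annotations$term2gene, intersect, universe)
  Ks <- lengths(term_genes)

  rows <- list()
  for (mod in names(partition$modules)) {
    mg <- intersect(partition$modules[[mod]], universe)
    if (length(partition$modules[[mod]]) < min_module_size) next
    n <- length(mg)
    if (n == 0) next
    for (term in names(term_genes)[Ks > 0]) {
      k <- length(intersect(term_genes[[term]], mg))
      if (k == 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, term = term, k = k, n = n, K = Ks[[term]], N = N,
        p = fisher_overrepresentation(k, Ks[[term]], n, N),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(module = character(), term = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q = numeric(),
                      significant = logical())
  } else {
    out <- do.call(rbind, rows)
    out$q <- stats::ave(out$p, out$module,
                        FUN = function(p) stats::p.adjust(p, method = correction))
    out$significant <- out$q <= alpha
  }
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "universe_size") <- N
  out
}

#' Enrichment summary statistics psi-1 and psi-2
#'
#' `psi1` is the average number of significantly enriched terms per enriched
#' module (modules with at least one significant term). The verbal
#' definition of `psi2` found in the literature is ambiguous between two
#' denominators, so both readings are computed: `psi2` (default reading)
#' divides the total significant-test count by the number of modules with
#' at least one *annotated* (tested) term, keeping it a per-module rate;
#' `psi2_literal` divides by the enriched-module count and therefore
#' coincides with `psi1`.
#'
#' @param results an [enrich_modules()] result.
#' @param partition the partition the results were computed on.
#' @return list of class `enrichment_summary`: `psi1`, `psi2`,
#'   `psi2_literal`, `total_significant_terms`, `n_enriched_modules`,
#'   `n_annotated_modules`, `alpha`.
#' @export
psi_summary <- function(results, partition) {
  stopifnot(inherits(results, "enrichment_result"),
            inherits(partition, "gcn_partition"))
  alpha <- attr(results, "alpha") %||% NA_real_
  sig_by_module <- tapply(results$significant, results$module, sum)
  n_annotated <- length(unique(results$module))
  total_sig <- sum(results$significant)
  enriched <- sum(sig_by_module >= 1)
  if (enriched == 0 || n_annotated == 0) {
    if (n_annotated == 0) warning("no eligible annotated modules; psi1 = psi2 = 0")
    out <- list(psi1 = 0, psi2 = 0, psi2_literal = 0,
                total_significant_terms = total_sig,
                n_enriched_modules = 0L,
                n_annotated_modules = n_annotated, alpha = alpha)
  } else {
    out <- list(psi1 = total_sig / enriched,
                psi2 = total_sig / n_annotated,
                psi2_literal = total_sig / enriched,
                total_significant_terms = total_sig,
                n_enriched_modules = as.integer(enriched),
                n_annotated_modules = as.integer(n_annotated), alpha = alpha)
  }
  class(out) <- "enrichment_summary"
  out
}

#' @export
print.enrichment_summary <- function(x, ...) {
  cat(sprintf(
    "Enrichment summary: %d significant FETs in %d/%d annotated modules\n",
    x$total_significant_terms, x$n_enriched_modules, x$n_annotated_modules))
  cat(sprintf("  psi1 = %.3f   psi2 = %.3f (literal reading: %.3f)\n",
              x$psi1, x$psi2, x$psi2_literal))
  invisible(x)
}
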