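#' Newman modularity of a partition
#'
#' Computes \deqn{Q = \sum_c \left[\frac{e_c}{m} -
#' \left(\frac{d_c}{2m}\right)^2\right]} over modules `c`, with `e_c` the
#' intra-module edge count, `d_c` the total degree inside the module and `m`
#' the edge count. Unweighted by default; set `weighted = TRUE` to use edge
#' weights.
#'
#' @param network a [gcn()] object.
#' @param partition a `gcn_partition` or a named membership vector covering
#'   the network's genes.
#' @param weighted use edge weights instead of counts.
#' @return Modularity Q, a number in \[-0.5, 1\].
#' @export
modularity_q <- function(network, partition, weighted = FALSE) {
  stopifnot(inherits(network, "gcn"))
  if (network$n_e < 1) stop("cannot compute modularity of an empty network")
  mem <- membership_vector(partition)
  if (!all(network$genes %in% names(mem))) {
    stop("partition does not cover all network genes")
  }
  w <- if (weighted) abs(network$edges$weight) else rep(1, network$n_e)
  m <- sum(w)
  cf <- mem[network$edges$from]
  ct <- mem[network$edges$to]
  deg <- tapply(c(w, w), c(cf, ct), sum)          # total degree per module
  e_c <- stats::setNames(rep(0, length(deg)), names(deg))
  if (any(cf == ct)) {
    intra <- tapply(w[cf == ct], cf[cf == ct], sum)
    e_c[names(intra)] <- intra
  }
  sum(e_c / m - (deg / (2 * m))^2)
}

# Accept either a gcn_partition or a named vector.
membership_vector <- function(partition) {
  if (inherits(partition, "gcn_partition")) return(partition$module_of)
  if (is.null(names(partition))) stop("membership vector must be named by gene")
  partition
}

# Wrap an igraph communities object into the package's partition container.
as_partition <- function(network, membership, method, params = list()) {
  mem <- stats::setNames(as.character(membership), names(membership))
  mem <- mem[network$genes]
  q <- modularity_q(network, mem)
  modules <- split(names(mem), mem)
  structure(list(module_of = mem, modules = modules, q = q,
                 method = method, params = params),
            class = "gcn_partition")
}

#' @export
print.gcn_partition <- function(x, ...) {
  sizes <- lengths(x$modules)
  cat(sprintf("Partition (%s): %d modules over %d genes, Q = %.4f\n",
              x$method, length(x$modules), length(x$module_of), x$q))
  cat("  module sizes: ", paste(utils::head(sort(sizes, decreasing = TRUE), 10),
                                collapse = " "),
      if (length(sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Walktrap community detection
#'
#' Short random walks of length `t` define vertex distances; communities are
#' merged agglomeratively and the cut maximizing modularity over the merge
#' sequence is returned. Walks never cross components, so disconnected
#' components are partitioned independently. Deterministic.
#'
#' @param network a [gcn()] object.
#' @param t walk length (default 4, the algorithm's canonical default).
#' @return A `gcn_partition` (with `q` recomputed by [modularity_q()]).
#' @export
walktrap_partition <- function(network, t = 4L) {
  stopifnot(inherits(network, "gcn"))
  assert_count(t, "t")
  g <- as_igraph(network)
  cl <- igraph::cluster_walktrap(g, steps = t, weights = NA)
  as_partition(network, igraph::membership(cl), "walktrap", list(t = t))
}

#' Fast-greedy modularity maximization
#'
#' Agglomerative greedy modularity optimization: starting from singleton
#' communities, repeatedly merges the community pair with the largest
#' modularity gain and returns the maximum-modularity state. Deterministic.
#'
#' @param network a [gcn()] object.
#' @return A `gcn_partition`.
#' @export
fastgreedy_partition <- function(network) {
  stopifnot(inherits(network, "gcn"))
  g <- as_igraph(network)
  cl <- igraph::cluster_fast_greedy(g, weights = NA)
  as_partition(network, igraph::membership(cl), "fastgreedy")
}

#' Label propagation community detection
#'
#' Every gene starts with a unique label; asynchronous updates in random
#' order let each gene adopt its neighbours' most frequent label (uniform
#' random tie-breaking) until every label is a neighbourhood plurality.
#' Deterministic under a fixed seed.
#'
#' @param network a [gcn()] object.
#' @param seed integer seed controlling update order and tie-breaks.
#' @return A `gcn_partition`.
#' @export
label_propagation_partition <- function(network, seed = 1L) {
  stopifnot(inherits(network, "gcn"))
  g <- as_igraph(network)
  cl <- with_seed(seed, igraph::cluster_label_prop(g, weights = NA))
  as_partition(network, igraph::membership(cl), "label_propagation",
               list(seed = seed))
}

#' Detect modules and label them by decreasing size
#'
#' Dispatches to the chosen partitioner (or accepts an externally supplied
#' partition), then relabels modules in decreasing size order so that
#' "module 0" is always the largest — making module identities reproducible
#' across runs. Modules below `min_module_size` are retained but flagged
#' ineligible for enrichment testing.
#'
#' @param network a [gcn()] object.
#' @param method `"walktrap"`, `"fastgreedy"` or `"label_propagation"`; use
#'   `partition` to supply an external membership instead.
#' @param min_module_size minimum module size for enrichment eligibility
#'   (default 5 genes per module).
#' @param t walktrap walk length.
#' @param seed label-propagation seed.
#' @param partition optional external named membership vector (the escape
#'   hatch for partitioners not implemented here).
#' @return A `gcn_partition` with module ids `"0"`, `"1"`, ... in decreasing
#'   size order (ties broken by smallest member gene id) and an `eligible`
#'   element flagging modules of at least `min_module_size` genes.
#' @export
detect_modules <- function(network,
                           method = c("walktrap", "fastgreedy",
                                      "label_propagation"),
                           min_module_size = 5L, t = 4L, seed = 1L,
                           partition = NULL) {
  stopifnot(inherits(network, "gcn"))
  assert_count(min_module_size, "min_module_size")
  if (!is.null(partition)) {
    part <- as_partition(network, partition, method = "external")
  } else {
    method <- tryCatch(match.arg(method), error = function(e) {
      stop("unknown partitioner; available: walktrap, fastgreedy, ",
           "label_propagation, or supply `partition` with an external ",
           "membership vector", call. = FALSE)
    })
    part <- switch(method,
      walktrap = walktrap_partition(network, t = t),
      fastgreedy = fastgreedy_partition(network),
      label_propagation = label_propagation_partition(network, seed = seed))
  }
  # Relabel by decreasing size; deterministic tie-break by smallest gene id.
  mods <- part$modules
  anchor <- vapply(mods, min, "")
  ord <- order(-lengths(mods), anchor)
  mods <- mods[ord]
  names(mods) <- as.character(seq_along(mods) - 1L)
  mem <- stats::setNames(rep(names(mods), lengths(mods)),
                         unlist(mods, use.names = FALSE))
  part$modules <- mods
  part$module_of <- mem[network$genes]
  part$eligible <- stats::setNames(lengths(mods) >= min_module_size,
                                   names(mods))
  part$params$min_module_size <- as.integer(min_module_size)
  part
}
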