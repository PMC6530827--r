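#' Construct a gene co-expression network object
#'
#' A `gcn` is a simple, undirected, weighted graph over genes: the central
#' container of the package. Edges are stored as a canonical edge list
#' (lexicographically ordered endpoints, sorted rows) so that identical
#' networks are byte-identical on disk. Genes with no surviving edge are not
#' part of the network: only genes meeting the association threshold for
#' inclusion in the adjacency matrix appear.
#'
#' @param edges data.frame with columns `from`, `to` (character gene ids) and
#'   optionally `weight` (association score, defaults to 1).
#' @param method character tag recording the reconstruction method.
#' @param params named list of reconstruction parameters, kept for reporting.
#'
#' @return An object of class `gcn` with elements `genes` (sorted character
#'   vector), `edges` (canonical data.frame `from`, `to`, `weight`), `n_g`,
#'   `n_e`, `method`, `params`.
#' @examples
#' net <- gcn(data.frame(from = c("a", "b"), to = c("b", "c"), weight = 0.9))
#' net$n_g
#' @export
gcn <- function(edges, method = "manual", params = list()) {
  if (!is.data.frame(edges) || !all(c("from", "to") %in% names(edges))) {
    stop("`edges` must be a data.frame with columns `from` and `to`")
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, length(from))
  if (any(from == to)) {
    stop("self-loops are not allowed (first at row ",
         which(from == to)[1L], ")")
  }
  a <- pmin(from, to)
  b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate edges are not allowed (first duplicate at row ",
         which(duplicated(key))[1L], ")")
  }
  ord <- order(a, b)
  edges <- data.frame(from = a[ord], to = b[ord], weight = weight[ord],
                      stringsAsFactors = FALSE)
  genes <- sort(unique(c(a, b)))
  structure(
    list(genes = genes, edges = edges,
         n_g = length(genes), n_e = nrow(edges),
         method = method, params = params),
    class = "gcn")
}

#' Convert a gcn to an igraph graph
#'
#' @param net a `gcn` object.
#' @return An undirected `igraph` graph with a `weight` edge attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "gcn"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$genes))
}

#' @export
print.gcn <- function(x, ...) {
  cat(sprintf("Gene co-expression network (method: %s)\n", x$method))
  cat(sprintf("  genes (n_g): %d\n  edges (n_e): %d\n  n_e/n_g:     %.3f\n",
              x$n_g, x$n_e, if (x$n_g > 0) x$n_e / x$n_g else NA_real_))
  if (length(x$params)) {
    p <- paste(names(x$params),
               vapply(x$params, function(v) paste(format(v), collapse = ","), ""),
               sep = "=", collapse = ", ")
    cat("  params:     ", p, "\n")
  }
  invisible(x)
}

#' @export
summary.gcn <- function(object, k_min_hub = 5L, ...) {
  summarize_structure(object, k_min_hub = k_min_hub)
}

#' Plot the degree distribution of a network on log-log axes
#'
#' @param x a `gcn` object.
#' @param ... passed on to [plot()].
#' @export
plot.gcn <- function(x, ...) {
  dd <- degree_distribution(x)
  plot(dd$k, dd$pk, log = "xy", xlab = "degree k", ylab = "P(k)",
       main = sprintf("Degree distribution (%s)", x$method), ...)
  invisible(x)
}

# Degree of every gene in the network (named integer vector, network order).
gcn_degrees <- function(net) {
  stopifnot(inherits(net, "gcn"))
  d <- table(factor(c(net$edges$from, net$edges$to), levels = net$genes))
  stats::setNames(as.integer(d), net$genes)
}
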