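#' Structural summary of a network
#'
#' Computes the screening metrics used to compare candidate networks:
#' density, edges-to-genes ratio `n_e/n_g`, unweighted average shortest path
#' length and diameter (both on the largest connected component), component
#' count, and hub genes — genes connected to at least `k_min_hub` others
#' (default 5).
#'
#' @param network a [gcn()] object.
#' @param k_min_hub minimum degree for hub status (default 5).
#' @return list of class `gcn_structure`: `n_g`, `n_e`, `density`,
#'   `edge_gene_ratio`, `avg_path_length`, `diameter`, `n_components`,
#'   `hub_genes`, `k_min_hub`.
#' @export
summarize_structure <- function(network, k_min_hub = 5L) {
  stopifnot(inherits(network, "gcn"))
  if (network$n_e < 1) stop("cannot summarize an empty network")
  assert_count(k_min_hub, "k_min_hub")
  g <- as_igraph(network)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(g, which(comp$membership ==
                                               which.max(comp$csize)))
  deg <- gcn_degrees(network)
  structure(list(
    n_g = network$n_g,
    n_e = network$n_e,
    density = 2 * network$n_e / (network$n_g * (network$n_g - 1)),
    edge_gene_ratio = network$n_e / network$n_g,
    avg_path_length = igraph::mean_distance(giant, weights = NA),
    diameter = igraph::diameter(giant, weights = NA),
    n_components = comp$no,
    hub_genes = names(deg)[deg >= k_min_hub],
    k_min_hub = as.integer(k_min_hub)),
    class = "gcn_structure")
}

#' @export
print.gcn_structure <- function(x, ...) {
  cat("Network structure\n")
  cat(sprintf("  n_g: %d  n_e: %d  n_e/n_g: %.3f  density: %.4f\n",
              x$n_g, x$n_e, x$edge_gene_ratio, x$density))
  cat(sprintf("  components: %d  avg path length: %.3f  diameter: %d\n",
              x$n_components, x$avg_path_length, x$diameter))
  cat(sprintf("  hubs (degree >= %d): %d\n", x$k_min_hub, length(x$hub_genes)))
  invisible(x)
}

#' Empirical degree distribution of a network
#'
#' @param network a [gcn()] object.
#' @return data.frame of class `degree_dist` with columns `k` (ascending
#'   observed degrees), `count`, `pk` (empirical probability mass, summing
#'   to 1). Isolated genes cannot occur (they are excluded from networks
#'   upstream), so `min(k) >= 1`.
#' @export
degree_distribution <- function(network) {
  stopifnot(inherits(network, "gcn"))
  if (network$n_g < 1) stop("cannot compute the degree distribution of an empty network")
  deg <- gcn_degrees(network)
  tab <- table(deg)
  out <- data.frame(k = as.integer(names(tab)),
                    count = as.integer(tab),
                    pk = as.numeric(tab) / length(deg))
  out <- out[order(out$k), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("degree_dist", "data.frame")
  out
}

#' Fit a discrete power law to a degree distribution
#'
#' Two estimators are provided and reported side by side across the package:
#' the discrete maximum-likelihood estimator with the continuity correction,
#' \deqn{\hat\gamma = 1 + n \left[\sum_i \ln \frac{k_i}{k_{min} - 1/2}\right]^{-1}}
#' over degrees `k_i >= k_min`, with the Kolmogorov-Smirnov distance between
#' the empirical and fitted discrete CDFs; and a log-log regression of the
#' empirical probability mass on degree (slope = `-gamma`, with R-squared).
#'
#' @param dist a [degree_distribution()] result (or any data.frame with
#'   columns `k`, `count`).
#' @param method `"mle"` or `"loglog_regression"`.
#' @param k_min lower degree cutoff for the fit (default 1).
#' @return list of class `power_law_fit`: `gamma`, `k_min`, `r2_loglog`
#'   (regression method), `ks_stat` (mle method), `method`, `n`.
#' @export
fit_power_law <- function(dist, method = c("mle", "loglog_regression"),
                          k_min = 1L) {
  method <- match.arg(method)
  assert_count(k_min, "k_min")
  stopifnot(is.data.frame(dist), all(c("k", "count") %in% names(dist)))
  dist <- dist[dist$k >= k_min, , drop = FALSE]
  n <- sum(dist$count)
  if (nrow(dist) < 1L || n < 1L) stop("no degree observations at k >= k_min")
  if (nrow(dist) == 1L) stop("all degrees equal: power-law fit undefined")
  if (n < 10L) {
    warning("fewer than 10 degree observations at k >= k_min; low support")
  }

  if (method == "mle") {
    # Discrete power-law MLE: the closed-form continuity-correction estimate
    # seeds a numerical maximization of the zeta-normalized likelihood
    # (the closed form alone is visibly biased at small k_min).
    slog <- sum(dist$count * log(dist$k / (k_min - 0.5)))
    gamma0 <- 1 + n / slog
    sum_log_k <- sum(dist$count * log(dist$k))
    nloglik <- function(g) g * sum_log_k + n * log(hurwitz_zeta(g, k_min))
    gamma <- stats::optimize(nloglik,
                             c(1.01, max(3 * gamma0, 20)))$minimum
    # KS distance between empirical and fitted discrete CDFs on the
    # observed support, fitted tail normalized by a truncated zeta sum.
    kmax <- max(dist$k)
    support <- seq.int(k_min, kmax)
    pmf <- support^(-gamma) / hurwitz_zeta(gamma, k_min)
    fit_cdf <- cumsum(pmf)[match(dist$k, support)]
    emp_cdf <- cumsum(dist$count) / n
    ks <- max(abs(emp_cdf - fit_cdf))
    out <- list(gamma = gamma, k_min = as.integer(k_min),
                r2_loglog = NA_real_, ks_stat = ks, method = "mle", n = n)
  } else {
    pk <- dist$count / n
    fit <- stats::lm(log(pk) ~ log(dist$k))
    gamma <- -unname(stats::coef(fit)[2])
    out <- list(gamma = gamma, k_min = as.integer(k_min),
                r2_loglog = summary(fit)$r.squared, ks_stat = NA_real_,
                method = "loglog_regression", n = n)
  }
  class(out) <- "power_law_fit"
  out
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Discrete power-law fit (%s): gamma = %.3f (k_min = %d, n = %d)\n",
              x$method, x$gamma, x$k_min, x$n))
  if (x$method == "mle") cat(sprintf("  KS distance: %.4f\n", x$ks_stat))
  else cat(sprintf("  log-log R^2: %.4f\n", x$r2_loglog))
  invisible(x)
}

# Truncated Hurwitz zeta sum_{k >= k_min} k^-gamma with an integral tail
# correction; adequate for normalizing discrete power-law PMFs.
hurwitz_zeta <- function(gamma, k_min, n_terms = 10000L) {
  ks <- seq.int(k_min, k_min + n_terms)
  sum(ks^(-gamma)) + (k_min + n_terms + 0.5)^(1 - gamma) / (gamma - 1)
}
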