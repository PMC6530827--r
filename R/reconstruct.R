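#' Build a co-expression network by correlation thresholding
#'
#' Computes the pairwise Pearson or Spearman correlation matrix across
#' samples and keeps an edge (i, j) when `|r_ij| >= r_threshold` (unsigned
#' mode, the default) or `r_ij >= r_threshold` (signed mode). Edge weight is
#' the signed correlation. Genes with no surviving edge are dropped, per the
#' adjacency-inclusion rule.
#'
#' @param matrix genes x samples numeric matrix.
#' @param method `"pearson"` or `"spearman"` (ranks are taken first).
#' @param r_threshold absolute correlation cutoff in (0, 1].
#' @param unsigned threshold on `|r|` (default) or on signed `r`.
#' @param n_edges optional edge budget: ignore `r_threshold` and keep exactly
#'   the `n_edges` strongest pairs (matched edge-count mode, used when
#'   comparing methods at equal network size).
#' @return A [gcn()] network.
#' @examples
#' m <- matrix(rnorm(40), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' m[2, ] <- 2 * m[1, ]
#' correlation_network(m, "pearson", r_threshold = 0.99)
#' @export
correlation_network <- function(matrix, method = c("pearson", "spearman"),
                                r_threshold = 0.8, unsigned = TRUE,
                                n_edges = NULL) {
  method <- match.arg(method)
  check_expression(matrix)
  if (is.null(n_edges)) assert_fraction(r_threshold, "r_threshold", lo = 1e-12)
  if (ncol(matrix) < 3) stop("need at least 3 samples")
  if (nrow(matrix) < 2) stop("need at least 2 genes")
  matrix <- drop_constant_genes(matrix)
  cm <- stats::cor(t(matrix), method = method)
  edges_from_scores(cm, threshold = r_threshold, unsigned = unsigned,
                    n_edges = n_edges, method = method,
                    params = list(r_threshold = r_threshold,
                                  unsigned = unsigned))
}

#' Shrinkage partial-correlation network with empirical-Bayes edge calling
#'
#' Estimates partial correlations from the analytically shrunk correlation
#' matrix `R* = lambda* I + (1 - lambda*) R`, where the shrinkage intensity
#' `lambda*` is the ratio of the summed estimated variances of the empirical
#' correlations to their summed squares (clipped to \[0, 1\]). Observed
#' partial correlations are then modelled as a two-component mixture of the
#' null correlation density `f0(r; kappa) \propto (1 - r^2)^((kappa - 3)/2)`
#' (null fraction `eta0` and `kappa` fitted by maximum likelihood, with a
#' uniform alternative) and an edge is reported when the posterior
#' probability of the alternative reaches `omega`.
#'
#' @param matrix genes x samples numeric matrix.
#' @param omega posterior edge-probability cutoff (default 0.9).
#' @param omega_on_pcor if `TRUE`, threshold `|pcor| >= omega` directly
#'   instead of the posterior probability.
#' @param lambda optional forced shrinkage intensity (overrides the analytic
#'   estimate; `lambda = 1` gives the identity and hence an empty network).
#' @param shrink_floor lower bound on the shrinkage intensity.
#' @return A [gcn()] network (weights = partial correlations) with attributes
#'   `pcor` (full matrix), `posterior` (alternative-component posterior per
#'   pair, same layout), and `fit` (list: `lambda_star`, `eta0`, `kappa`).
#' @export
genenet_network <- function(matrix, omega = 0.9, omega_on_pcor = FALSE,
                            lambda = NULL, shrink_floor = 0) {
  check_expression(matrix)
  assert_fraction(omega, "omega", lo = 1e-12)
  n <- ncol(matrix)
  if (n < 4) stop("need at least 4 samples")
  matrix <- drop_constant_genes(matrix)
  p <- nrow(matrix)
  xs <- scale(t(matrix))                       # n x p, unit variance (n - 1)
  R <- crossprod(xs) / (n - 1)

  if (is.null(lambda)) {
    # Analytic shrinkage intensity: sum Var-hat(r_ij) / sum r_ij^2, i != j.
    w_bar <- crossprod(xs) / n
    sw2 <- crossprod(xs^2)                     # sum_k w_kij^2
    var_r <- n / (n - 1)^3 * (sw2 - n * w_bar^2)
    off <- upper.tri(R)
    lambda <- sum(var_r[off]) / sum(R[off]^2)
    lambda <- min(1, max(shrink_floor, lambda, 0))
  } else {
    assert_fraction(lambda, "lambda")
  }

  Rs <- lambda * diag(p) + (1 - lambda) * R
  ch <- tryCatch(chol(Rs), error = function(e) NULL)
  if (is.null(ch)) {
    stop("shrunk correlation matrix is singular; increase `shrink_floor`")
  }
  Om <- chol2inv(ch)
  d <- sqrt(diag(Om))
  pcor <- -Om / tcrossprod(d)
  diag(pcor) <- 1
  dimnames(pcor) <- list(rownames(matrix), rownames(matrix))

  r <- pcor[upper.tri(pcor)]
  if (omega_on_pcor) {
    post <- NULL
    fit <- list(lambda_star = lambda, eta0 = NA_real_, kappa = NA_real_)
    keep <- abs(r) >= omega
  } else {
    fit <- fit_null_mixture(r, kappa_max = 2 * n, kappa_min = n - p + 1)
    fit$lambda_star <- lambda
    post <- posterior_alt(r, fit)
    keep <- post >= omega
  }

  idx <- which(upper.tri(pcor), arr.ind = TRUE)
  edges <- data.frame(from = rownames(pcor)[idx[keep, 1]],
                      to = rownames(pcor)[idx[keep, 2]],
                      weight = r[keep], stringsAsFactors = FALSE)
  net <- gcn(edges, method = "genenet",
             params = list(omega = omega, omega_on_pcor = omega_on_pcor))
  attr(net, "pcor") <- pcor
  if (!is.null(post)) {
    pm <- base::matrix(NA_real_, p, p, dimnames = dimnames(pcor))
    pm[upper.tri(pm)] <- post
    attr(net, "posterior") <- pm
  }
  attr(net, "fit") <- fit
  net
}

# Log null density of a correlation coefficient with concentration kappa.
log_f0 <- function(r, kappa) {
  ((kappa - 3) / 2) * log1p(-pmin(r^2, 1 - 1e-12)) -
    lbeta(0.5, (kappa - 1) / 2)
}

# Two-component mixture fit: eta0 * f0(r; kappa) + (1 - eta0) * Unif(-1, 1).
# kappa is bounded below by the theoretical null degrees of freedom
# (shrinkage can only narrow the null beyond n - p + 1) and capped above
# (default 2n upstream) to avoid the degenerate kappa -> Inf maximum on
# short pcor vectors.
fit_null_mixture <- function(r, kappa_max, kappa_min = 4) {
  kappa_min <- max(kappa_min, 4)
  kappa_max <- max(kappa_max, kappa_min + 10)
  v <- stats::var(r)
  k0 <- min(max(if (is.finite(v) && v > 0) 1 / v else 10, 1.01 * kappa_min),
            0.9 * kappa_max)
  to_par <- function(eta0, kappa) {
    c(stats::qlogis((eta0 - 0.001) / 0.998),
      stats::qlogis((kappa - kappa_min) / (kappa_max - kappa_min)))
  }
  from_par <- function(par) {
    list(eta0 = 0.001 + 0.998 * stats::plogis(par[1]),
         kappa = kappa_min + (kappa_max - kappa_min) * stats::plogis(par[2]))
  }
  # MAP with a weak Beta(2, 1) prior on eta0: the empirical-null framework
  # assumes most pairs are null, and the prior (one extra log eta0 term)
  # stabilizes the fit on short pcor vectors without moving it for long ones.
  nll <- function(par) {
    th <- from_par(par)
    -sum(log(th$eta0 * exp(log_f0(r, th$kappa)) + (1 - th$eta0) * 0.5)) -
      log(th$eta0)
  }
  opt <- stats::optim(to_par(0.9, k0), nll, method = "Nelder-Mead",
                      control = list(maxit = 1000))
  out <- from_par(opt$par)
  out$converged <- opt$convergence == 0
  out
}

posterior_alt <- function(r, fit) {
  f0 <- exp(log_f0(r, fit$kappa))
  fa <- 0.5
  (1 - fit$eta0) * fa / (fit$eta0 * f0 + (1 - fit$eta0) * fa)
}

#' Sparse partial-correlation network by joint lasso regression
#'
#' Estimates the symmetric partial-correlation matrix by minimizing the
#' joint penalized regression loss
#' \deqn{\frac12 \sum_i \|X_i - \sum_{j \ne i} \rho_{ij}
#'   \sqrt{\sigma_{jj}/\sigma_{ii}} X_j\|^2 + \lambda \sum_{i<j} |\rho_{ij}|}
#' by cyclic coordinate descent with soft-thresholding, each update of
#' `rho_ij` pooling the two regression rows it appears in. Outer iterations
#' alternate coordinate-descent sweeps with residual-variance updates of the
#' precision diagonals `sigma_ii`. `lambda = lambda_scale * sqrt(n log p)`.
#' An edge is kept when `|rho_ij| >= rho_threshold`.
#'
#' @param matrix genes x samples numeric matrix (genes are standardized to
#'   zero mean, unit variance internally).
#' @param rho_threshold partial-correlation magnitude cutoff in (0, 1].
#' @param lambda_scale multiplier on the `sqrt(n log p)` penalty scale.
#' @param max_outer outer iterations (rho sweeps alternated with variance
#'   updates), default 3.
#' @param max_sweeps coordinate-descent sweeps allowed per outer iteration.
#' @param tol convergence tolerance on the largest single-coordinate change.
#' @return A [gcn()] network (weights = estimated partial correlations) with
#'   attributes `rho` (full estimated matrix) and `lambda`.
#' @export
space_network <- function(matrix, rho_threshold = 0.7, lambda_scale = 1,
                          max_outer = 3L, max_sweeps = 200L, tol = 1e-4) {
  check_expression(matrix)
  assert_fraction(rho_threshold, "rho_threshold", lo = 1e-12)
  if (lambda_scale <= 0) stop("`lambda_scale` must be positive")
  n <- ncol(matrix)
  if (n < 4) stop("need at least 4 samples")
  matrix <- drop_constant_genes(matrix)
  p <- nrow(matrix)
  X <- scale(t(matrix))                        # n x p
  G <- crossprod(X)
  lambda <- lambda_scale * sqrt(n * log(p))

  rho <- base::matrix(0, p, p)
  B <- base::matrix(0, p, p)                   # B[i, j]: coef of X_j for X_i
  C <- base::matrix(0, p, p)                   # C = B G
  om <- rep(1, p)                              # precision diagonals sigma_ii
  gd <- diag(G)
  pairs <- which(upper.tri(rho), arr.ind = TRUE)

  objective <- function() {
    rss <- gd - 2 * diag(C) + rowSums(C * B)
    0.5 * sum(rss) + lambda * sum(abs(rho[upper.tri(rho)]))
  }

  for (outer in seq_len(max_outer)) {
    prev_obj <- objective()
    converged <- FALSE
    last_delta <- NA_real_
    for (sweep in seq_len(max_sweeps)) {
      max_delta <- 0
      for (e in seq_len(nrow(pairs))) {
        i <- pairs[e, 1]; j <- pairs[e, 2]
        a_ij <- sqrt(om[j] / om[i]); a_ji <- 1 / a_ij
        num <- a_ij * (G[i, j] - C[i, j] + B[i, j] * gd[j]) +
               a_ji * (G[i, j] - C[j, i] + B[j, i] * gd[i])
        den <- a_ij^2 * gd[j] + a_ji^2 * gd[i]
        r_new <- sign(num) * max(abs(num) - lambda, 0) / den
        if (r_new != rho[i, j]) {
          max_delta <- max(max_delta, abs(r_new - rho[i, j]))
          b_ij <- r_new * a_ij; b_ji <- r_new * a_ji
          C[i, ] <- C[i, ] + (b_ij - B[i, j]) * G[j, ]
          C[j, ] <- C[j, ] + (b_ji - B[j, i]) * G[i, ]
          B[i, j] <- b_ij; B[j, i] <- b_ji
          rho[i, j] <- rho[j, i] <- r_new
        }
      }
      obj <- objective()
      if (obj > prev_obj + 1e-8 * (1 + abs(prev_obj))) {
        stop("internal error: coordinate-descent objective increased")
      }
      prev_obj <- obj
      last_delta <- max_delta
      if (max_delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop(sprintf(
        "sparse partial-correlation fit did not converge in %d sweeps (last max coordinate change %.3g)",
        max_sweeps, last_delta))
    }
    if (outer < max_outer) {
      rss <- pmax(gd - 2 * diag(C) + rowSums(C * B), 1e-8)
      om <- n / rss
      # Coefficients depend on the variance ratios: rebuild B (and C) from
      # rho under the updated precision diagonals.
      B <- rho * sqrt(outer(1 / om, om))
      C <- B %*% G
    }
  }

  dimnames(rho) <- list(rownames(matrix), rownames(matrix))
  net <- edges_from_scores(rho, threshold = rho_threshold, unsigned = TRUE,
                           n_edges = NULL, method = "space",
                           params = list(rho_threshold = rho_threshold,
                                         lambda_scale = lambda_scale))
  attr(net, "rho") <- rho
  attr(net, "lambda") <- lambda
  net
}

#' Soft-threshold adjacency network with topological overlap
#'
#' Raises absolute correlations to the soft power `beta` to form the
#' adjacency `a_ij = |r_ij|^beta` (unsigned mode), computes the topological
#' overlap matrix
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu`, and keeps an edge when `a_ij >= tau`.
#'
#' @param matrix genes x samples numeric matrix.
#' @param beta integer soft power (>= 1), default 5 — the lowest power at
#'   which typical compendia reach an adequate scale-free fit (see
#'   [select_soft_power()]).
#' @param tau adjacency cutoff in (0, 1].
#' @param unsigned use `|r|` (default); otherwise the signed variant
#'   `((1 + r)/2)^beta`.
#' @return list with `network` (a [gcn()], weights = adjacency) and `tom`
#'   (the full TOM matrix, for robustness analyses).
#' @export
wgcna_network <- function(matrix, beta = 5L, tau = 0.33, unsigned = TRUE) {
  check_expression(matrix)
  assert_count(beta, "beta")
  assert_fraction(tau, "tau", lo = 1e-12)
  if (ncol(matrix) < 3) stop("need at least 3 samples")
  matrix <- drop_constant_genes(matrix)
  r <- stats::cor(t(matrix))
  a <- if (unsigned) abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a) <- list(rownames(matrix), rownames(matrix))
  net <- edges_from_scores(a, threshold = tau, unsigned = TRUE,
                           n_edges = NULL, method = "wgcna",
                           params = list(beta = beta, tau = tau,
                                         unsigned = unsigned))
  list(network = net, tom = tom)
}

#' Select the soft power by the scale-free fit criterion
#'
#' For each candidate power, forms the weighted degrees `k_i = sum_j a_ij`
#' of the soft-threshold adjacency, bins `k`, and regresses log frequency on
#' log mean degree per bin. Returns the lowest power whose fit reaches
#' `r2_target`; if none qualifies, the argmax-R2 power with a warning.
#'
#' @param matrix genes x samples numeric matrix.
#' @param betas ascending candidate integer powers.
#' @param r2_target target scale-free fit R-squared (default 0.8).
#' @param n_bins number of degree bins for the log-log regression.
#' @return The selected power (integer) with attribute `fit_table`, a
#'   data.frame of `beta`, `r2`, `slope`.
#' @export
select_soft_power <- function(matrix, betas = 1:10, r2_target = 0.8,
                              n_bins = 10L) {
  check_expression(matrix)
  if (!length(betas) || is.unsorted(betas)) {
    stop("`betas` must be a non-empty ascending vector")
  }
  matrix <- drop_constant_genes(matrix)
  r <- abs(stats::cor(t(matrix)))
  diag(r) <- 0
  fits <- lapply(betas, function(b) {
    k <- rowSums(r^b)
    sf <- scale_free_fit(k, n_bins)
    data.frame(beta = b, r2 = sf["r2"], slope = sf["slope"])
  })
  tab <- do.call(rbind, fits)
  rownames(tab) <- NULL
  ok <- which(!is.na(tab$r2) & tab$r2 >= r2_target)
  if (length(ok)) {
    sel <- as.integer(tab$beta[ok[1]])
  } else {
    if (all(is.na(tab$r2))) stop("scale-free fit undefined for every power")
    sel <- as.integer(tab$beta[which.max(tab$r2)])
    warning(sprintf(
      "no power reached the scale-free fit target R^2 = %.2f; returning argmax beta = %d (R^2 = %.2f)",
      r2_target, sel, max(tab$r2, na.rm = TRUE)))
  }
  attr(sel, "fit_table") <- tab
  sel
}

# Log-log regression of binned weighted-degree frequency; returns r2 signed
# to 0 when the slope is non-negative (not scale-free-like).
scale_free_fit <- function(k, n_bins = 10L) {
  if (diff(range(k)) < 1e-12) return(c(r2 = NA_real_, slope = NA_real_))
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  keep <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(keep) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[keep] / sum(freq[keep])) ~ log10(mean_k[keep]))
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  c(r2 = if (slope < 0) r2 else 0, slope = slope)
}

#' Reconstruct a network by any of the five methods
#'
#' Thin dispatcher over [correlation_network()], [genenet_network()],
#' [space_network()] and [wgcna_network()] keyed by method tag; the WGCNA
#' route returns the network with the TOM attached as attribute `tom`.
#'
#' @param matrix genes x samples numeric matrix.
#' @param method one of `"pearson"`, `"spearman"`, `"genenet"`, `"space"`,
#'   `"wgcna"`.
#' @param ... method-specific parameters, passed through.
#' @return A [gcn()] network.
#' @export
gcn_reconstruct <- function(matrix,
                            method = c("pearson", "spearman", "genenet",
                                       "space", "wgcna"),
                            ...) {
  method <- match.arg(method)
  switch(method,
    pearson = correlation_network(matrix, "pearson", ...),
    spearman = correlation_network(matrix, "spearman", ...),
    genenet = genenet_network(matrix, ...),
    space = space_network(matrix, ...),
    wgcna = {
      w <- wgcna_network(matrix, ...)
      net <- w$network
      attr(net, "tom") <- w$tom
      net
    })
}

# Remove zero-variance genes (correlation undefined) with a warning.
drop_constant_genes <- function(matrix) {
  v <- apply(matrix, 1, stats::var)
  bad <- v < .Machine$double.eps
  if (any(bad)) {
    warning("skipping ", sum(bad), " zero-variance gene(s): ",
            paste(utils::head(rownames(matrix)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ..." else "")
    matrix <- matrix[!bad, , drop = FALSE]
  }
  matrix
}

# Shared edge extraction from a symmetric score matrix: threshold mode or
# exact top-n_edges mode (deterministic tie-break by gene pair order).
edges_from_scores <- function(scores, threshold, unsigned, n_edges,
                              method, params) {
  idx <- which(upper.tri(scores), arr.ind = TRUE)
  s <- scores[upper.tri(scores)]
  crit <- if (unsigned) abs(s) else s
  if (!is.null(n_edges)) {
    assert_count(n_edges, "n_edges", min = 0L)
    ord <- order(-crit, rownames(scores)[idx[, 1]], rownames(scores)[idx[, 2]])
    keep_rows <- ord[seq_len(min(n_edges, length(ord)))]
    params$n_edges <- n_edges
  } else {
    keep_rows <- which(crit >= threshold)
  }
  edges <- data.frame(from = rownames(scores)[idx[keep_rows, 1]],
                      to = rownames(scores)[idx[keep_rows, 2]],
                      weight = s[keep_rows], stringsAsFactors = FALSE)
  gcn(edges, method = method, params = params)
}
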