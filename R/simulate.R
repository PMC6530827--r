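#' Configuration for the synthetic expression compendium
#'
#' The generator emulates the structure of a normalized (log-scale) microarray
#' compendium driven by transcriptional regulators: each planted module is a
#' set of genes that follow one latent regulator profile, scaled by per-gene
#' loadings, plus independent noise; background genes are pure noise; a
#' fraction of genes get inflated replicate variance ("noisy") or a signal
#' shifted below a detection floor ("low signal"). Replicate samples of a
#' condition share the latent profile value and differ only by replicate
#' noise.
#'
#' The per-gene noise scale is calibrated so that the *expected* within-module
#' Pearson correlation across samples equals `within_module_cor`. A shared
#' global condition factor with weight `between_module_cor` correlates the
#' module regulator profiles, emulating compendium-wide condition effects
#' (growth phase, medium) that induce moderate correlation between genes of
#' different regulons.
#'
#' @param n_modules number of planted modules.
#' @param genes_per_module module size; either a single count or a
#'   `c(min, max)` range sampled per module.
#' @param n_background number of unregulated background genes.
#' @param n_conditions number of experimental conditions.
#' @param n_replicates replicate samples per condition.
#' @param within_module_cor target expected within-module Pearson correlation,
#'   in \[0, 1).
#' @param between_module_cor central value of the per-module shared-variance
#'   fraction with a global condition factor, in \[0, 1\] (0 = independent
#'   regulators). Per-module fractions are drawn uniformly within 0.3 of this
#'   value (clipped to \[0, 0.98\]), so pairs of regulator profiles show
#'   heterogeneous correlations around it.
#' @param noise_sd overall dynamic-range scale of the simulated signal
#'   (standard deviation of a background gene).
#' @param frac_noisy_genes fraction of genes given replicate variance
#'   inflated by `noisy_var_factor`.
#' @param frac_low_signal fraction of genes shifted below the detection
#'   floor (the 5th percentile of the global signal distribution).
#' @param noisy_var_factor variance inflation factor for noisy genes.
#' @param loading_range range of per-gene factor loadings (uniform draw);
#'   wider ranges give more heterogeneous within-module correlations.
#' @param signed_loadings if `TRUE`, loadings get random signs, producing
#'   negatively co-expressed module members; default keeps planted modules
#'   positively co-expressed.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_modules = 4L, genes_per_module = 25L,
                       n_background = 20L, n_conditions = 60L,
                       n_replicates = 2L, within_module_cor = 0.8,
                       between_module_cor = 0, noise_sd = 1,
                       frac_noisy_genes = 0, frac_low_signal = 0,
                       noisy_var_factor = 10, loading_range = c(0.7, 1.0),
                       signed_loadings = FALSE, seed = 1L) {
  assert_count(n_modules, "n_modules")
  if (!length(genes_per_module) %in% 1:2) {
    stop("`genes_per_module` must be a count or a c(min, max) range")
  }
  assert_count(min(genes_per_module), "genes_per_module", min = 2L)
  assert_count(n_background, "n_background", min = 0L)
  assert_count(n_conditions, "n_conditions")
  assert_count(n_replicates, "n_replicates")
  assert_fraction(within_module_cor, "within_module_cor")
  if (within_module_cor >= 1) stop("`within_module_cor` must be < 1")
  assert_fraction(between_module_cor, "between_module_cor")
  assert_fraction(frac_noisy_genes, "frac_noisy_genes")
  assert_fraction(frac_low_signal, "frac_low_signal")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  if (noisy_var_factor < 1) stop("`noisy_var_factor` must be >= 1")
  if (length(loading_range) != 2 || any(loading_range <= 0) ||
      diff(loading_range) < 0) {
    stop("`loading_range` must be an increasing positive pair")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Noise-to-loading scale s such that E over loadings of the pairwise
# within-module correlation sqrt(h_i h_j), h = l^2 / (l^2 + s^2), hits the
# target. Exact in expectation for any loading range.
calibrate_noise_scale <- function(target, loading_range) {
  if (target == 0) return(Inf)
  grid <- seq(loading_range[1], loading_range[2], length.out = 201L)
  mean_sqrt_h <- function(s) mean(sqrt(grid^2 / (grid^2 + s^2)))
  stats::uniroot(function(s) mean_sqrt_h(s) - sqrt(target),
                 lower = 1e-9, upper = 1e3, tol = 1e-10)$root
}

#' Simulate an expression compendium with planted co-expression modules
#'
#' @param config a [sim_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{expr}{`expression_matrix`: genes x samples numeric matrix of
#'       log-scale signal, with gene ids as rownames and sample ids as
#'       colnames.}
#'     \item{design}{data.frame `sample_id`, `condition_id`, `replicate`.}
#'     \item{truth}{`ground_truth` list: `module_of` (named vector; background
#'       genes carry their own singleton label), `modules` (list of gene
#'       vectors), `true_edges` (data.frame of all within-module pairs),
#'       `regulators` (one designated driver gene per module),
#'       `noisy_genes`, `low_signal_genes`, `loadings`.}
#'   }
#' @examples
#' sim <- simulate_expression(sim_config(n_modules = 2, genes_per_module = 5,
#'                                       n_conditions = 10, seed = 42))
#' dim(sim$expr)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    sizes <- if (length(cfg$genes_per_module) == 2L) {
      sample(cfg$genes_per_module[1]:cfg$genes_per_module[2],
             cfg$n_modules, replace = TRUE)
    } else rep(cfg$genes_per_module, cfg$n_modules)
    n_mod_genes <- sum(sizes)
    n_genes <- n_mod_genes + cfg$n_background
    genes <- sprintf("g%04d", seq_len(n_genes))
    module_ids <- sprintf("M%d", seq_len(cfg$n_modules))
    bg_labels <- if (cfg$n_background > 0) {
      paste0("bg_", genes[n_mod_genes + seq_len(cfg$n_background)])
    } else character(0)
    module_of <- c(rep(module_ids, sizes), bg_labels)
    names(module_of) <- genes
    modules <- split(genes[seq_len(n_mod_genes)],
                     factor(module_of[seq_len(n_mod_genes)], levels = module_ids))

    n_samp <- cfg$n_conditions * cfg$n_replicates
    cond <- rep(seq_len(cfg$n_conditions), each = cfg$n_replicates)
    repl <- rep(seq_len(cfg$n_replicates), cfg$n_conditions)
    sample_id <- sprintf("c%03d_r%d", cond, repl)
    design <- data.frame(sample_id = sample_id,
                         condition_id = sprintf("c%03d", cond),
                         replicate = repl, stringsAsFactors = FALSE)

    # Latent regulator profiles: shared global condition factor + a
    # module-specific part. The shared-variance fraction is drawn per module
    # around between_module_cor, so regulon pairs range from nearly
    # independent to strongly co-regulated — heterogeneous condition-driven
    # correlation, as in real compendia, rather than one uniform level.
    bc <- cfg$between_module_cor
    share <- if (bc == 0) rep(0, cfg$n_modules) else {
      stats::runif(cfg$n_modules, max(0, bc - 0.3), min(0.98, bc + 0.3))
    }
    global <- stats::rnorm(cfg$n_conditions)
    z <- sapply(seq_len(cfg$n_modules), function(m) {
      sqrt(share[m]) * global + sqrt(1 - share[m]) * stats::rnorm(cfg$n_conditions)
    })
    z <- matrix(z, nrow = cfg$n_conditions)

    loadings <- stats::runif(n_genes, cfg$loading_range[1], cfg$loading_range[2])
    # Designated regulator gene: first gene of each module, maximal loading.
    reg_idx <- cumsum(c(1, sizes[-length(sizes)]))
    regulators <- genes[reg_idx[seq_len(cfg$n_modules)]]
    loadings[reg_idx] <- cfg$loading_range[2]
    if (cfg$signed_loadings) {
      loadings <- loadings * sample(c(-1, 1), n_genes, replace = TRUE)
    }
    names(loadings) <- genes

    s_noise <- calibrate_noise_scale(cfg$within_module_cor, cfg$loading_range)
    mu <- stats::runif(n_genes, 7, 10)

    noisy <- sort(sample(genes, round(cfg$frac_noisy_genes * n_genes)))
    low <- sort(sample(genes, round(cfg$frac_low_signal * n_genes)))

    values <- matrix(0, nrow = n_genes, ncol = n_samp,
                     dimnames = list(genes, sample_id))
    mod_index <- match(module_of, module_ids)   # NA for background
    noise_fac <- ifelse(genes %in% noisy, sqrt(cfg$noisy_var_factor), 1)
    for (g in seq_len(n_genes)) {
      eps <- stats::rnorm(n_samp)
      if (is.na(mod_index[g])) {
        values[g, ] <- mu[g] + cfg$noise_sd * noise_fac[g] * eps
      } else {
        # Noise is on an absolute scale while the signal scales with the
        # loading, so the communality l^2/(l^2 + s^2) — and with it the
        # pairwise correlation — varies across genes; the calibration makes
        # the module-wide expectation hit within_module_cor exactly.
        zz <- z[cond, mod_index[g]]
        sg <- if (is.finite(s_noise)) s_noise else 1
        sig <- if (is.finite(s_noise)) loadings[g] * zz else 0
        values[g, ] <- mu[g] + cfg$noise_sd * (sig + sg * noise_fac[g] * eps)
      }
    }

    # Low-signal genes: shift the whole profile below the detection floor
    # (5th percentile of the global signal distribution).
    if (length(low)) {
      floor_q <- stats::quantile(values, 0.05, names = FALSE)
      for (g in low) {
        values[g, ] <- values[g, ] - (max(values[g, ]) - floor_q) - 2
      }
    }

    true_edges <- do.call(rbind, lapply(modules, function(gs) {
      if (length(gs) < 2) return(NULL)
      cmb <- utils::combn(sort(gs), 2)
      data.frame(from = cmb[1, ], to = cmb[2, ], stringsAsFactors = FALSE)
    }))
    rownames(true_edges) <- NULL

    truth <- structure(
      list(module_of = module_of, modules = modules, true_edges = true_edges,
           regulators = regulators, noisy_genes = noisy,
           low_signal_genes = low, loadings = loadings,
           true_annotations = NULL),
      class = "ground_truth")
    list(expr = structure(values, class = c("expression_matrix", "matrix", "array")),
         design = design, truth = truth)
  })
}

#' Simulate GO-style annotations concentrated in the planted modules
#'
#' Each planted module receives one dedicated term annotating `frac_correct`
#' of its genes (plus sparse random extras); the remaining terms annotate
#' uniform random gene subsets.
#'
#' @param truth a `ground_truth` object from [simulate_expression()].
#' @param n_terms total number of terms (must be >= number of modules).
#' @param frac_correct fraction of each module's genes annotated by its
#'   dedicated term, in \[0, 1\].
#' @param seed integer seed.
#' @param extra_rate probability that a dedicated term also annotates any
#'   given outside gene.
#' @return An `annotation_table` (see [annotation_table()]); its
#'   `planted_terms` attribute maps module id to its dedicated term.
#' @export
simulate_annotations <- function(truth, n_terms, frac_correct, seed = 1L,
                                 extra_rate = 0.02) {
  stopifnot(inherits(truth, "ground_truth"))
  assert_fraction(frac_correct, "frac_correct")
  n_modules <- length(truth$modules)
  if (n_terms < n_modules) stop("`n_terms` must be >= the number of modules")
  universe <- names(truth$module_of)
  with_seed(seed, {
    terms <- sprintf("T%03d", seq_len(n_terms))
    planted <- stats::setNames(terms[seq_len(n_modules)], names(truth$modules))
    pairs <- list()
    for (m in seq_len(n_modules)) {
      gs <- truth$modules[[m]]
      n_hit <- round(frac_correct * length(gs))
      hit <- if (n_hit > 0) sample(gs, n_hit) else character()
      outside <- setdiff(universe, gs)
      extras <- outside[stats::runif(length(outside)) < extra_rate]
      ann <- unique(c(hit, extras))
      if (length(ann)) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(gene = ann, term = terms[m], stringsAsFactors = FALSE)
      }
    }
    max_size <- max(4L, round(0.1 * length(universe)))
    for (t in seq.int(n_modules + 1L, length.out = n_terms - n_modules)) {
      size <- sample(3:max_size, 1L)
      pairs[[length(pairs) + 1L]] <-
        data.frame(gene = sample(universe, min(size, length(universe))),
                   term = terms[t], stringsAsFactors = FALSE)
    }
    tab <- annotation_table(do.call(rbind, pairs), universe = universe,
                            all_terms = terms)
    attr(tab, "planted_terms") <- planted
    tab
  })
}

#' Simulate a scale-free directed regulatory gold-standard network
#'
#' Grows a directed TF-to-target edge list by degree-proportional attachment
#' (each new gene is attached to existing regulators chosen with probability
#' proportional to `(out-degree + 1)^attachment_exponent`), then forces
#' `n_hub_regulators` nodes to a high out-degree, emulating sigma-factor-like
#' global regulators with long-tailed out-degree distributions.
#'
#' @param n_genes number of genes (nodes).
#' @param n_hub_regulators number of forced high-out-degree regulators.
#' @param attachment_exponent positive attachment exponent.
#' @param seed integer seed.
#' @param hub_out_degree out-degree forced on each hub (capped at
#'   `n_genes - 1`).
#' @param edges_per_gene attachment edges added per new gene.
#' @return A list of class `regnet`: `edges` (data.frame `regulator`,
#'   `target`), `genes`.
#' @export
simulate_regulatory_network <- function(n_genes, n_hub_regulators = 0L,
                                        attachment_exponent = 1,
                                        seed = 1L, hub_out_degree = 120L,
                                        edges_per_gene = 1L) {
  assert_count(n_genes, "n_genes", min = 2L)
  assert_count(n_hub_regulators, "n_hub_regulators", min = 0L)
  if (n_hub_regulators >= n_genes) stop("`n_genes` must exceed `n_hub_regulators`")
  if (attachment_exponent <= 0) stop("`attachment_exponent` must be positive")
  assert_count(edges_per_gene, "edges_per_gene")
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    out_deg <- integer(n_genes)
    reg <- integer(0); tgt <- integer(0)
    reg <- 1L; tgt <- 2L; out_deg[1L] <- 1L
    for (v in seq.int(3L, length.out = max(0L, n_genes - 2L))) {
      avail <- seq_len(v - 1L)
      w <- (out_deg[avail] + 1)^attachment_exponent
      k <- min(edges_per_gene, length(avail))
      src <- sample(avail, k, prob = w)
      reg <- c(reg, src); tgt <- c(tgt, rep(v, k))
      out_deg[src] <- out_deg[src] + 1L
    }
    key <- paste(reg, tgt)
    hubs <- seq_len(n_hub_regulators)
    want <- min(hub_out_degree, n_genes - 1L)
    for (h in hubs) {
      have <- tgt[reg == h]
      need <- want - length(unique(have))
      if (need > 0) {
        cand <- setdiff(seq_len(n_genes), c(h, have))
        new_t <- sample(cand, min(need, length(cand)))
        reg <- c(reg, rep(h, length(new_t))); tgt <- c(tgt, new_t)
      }
    }
    key <- paste(reg, tgt)
    keep <- !duplicated(key)
    edges <- data.frame(regulator = genes[reg[keep]], target = genes[tgt[keep]],
                        stringsAsFactors = FALSE)
    structure(list(edges = edges, genes = genes), class = "regnet")
  })
}

#' Ground-truth partition object
#'
#' Wraps the planted module memberships (background genes as singleton
#' modules) as a `gcn_partition`, usable wherever a detected partition is —
#' e.g. as the reference in [partition_similarity()] or to test enrichment
#' on the true modules.
#'
#' @param truth a `ground_truth` object.
#' @return A `gcn_partition` (with `q = NA`, as it is not tied to a network).
#' @export
truth_partition <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  mem <- truth$module_of
  structure(list(module_of = mem, modules = split(names(mem), mem),
                 q = NA_real_, method = "ground_truth", params = list()),
            class = "gcn_partition")
}

#' @export
print.regnet <- function(x, ...) {
  cat(sprintf("Directed regulatory network: %d genes, %d TF->target edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic compendium configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  invisible(x)
}
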