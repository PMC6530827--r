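#' Default configuration of the synthetic benchmark pipeline
#'
#' One nested list drives [run_pipeline()]: the synthetic compendium, the
#' preprocessing filters, the per-method reconstruction parameters, module
#' detection, enrichment, and candidate screening. The defaults define the
#' package's reference benchmark: a compendium of 8 planted modules of 6
#' genes plus 20 background genes over 100 conditions in duplicate, with
#' heterogeneous loadings and a shared global condition factor
#' (`between_module_cor = 0.6`) that induces moderate between-regulon
#' correlation — the regime in which marginal-correlation networks become
#' dense and less modular while partial-correlation methods stay sparse.
#' Method thresholds are scaled to the latent-factor partial-correlation
#' dilution (a module of size m with within-correlation r implies pairwise
#' partial correlations near `r / (1 + (m - 2) r)`); see the methods
#' vignette.
#'
#' @param seed global integer seed; per-stage seeds are derived from it by
#'   stable hashing of the stage names.
#' @return A nested list of class `pipeline_config`.
#' @export
benchmark_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    sim = list(n_modules = 8L, genes_per_module = 6L, n_background = 20L,
               n_conditions = 100L, n_replicates = 2L,
               within_module_cor = 0.7, between_module_cor = 0.6,
               noise_sd = 1, frac_noisy_genes = 0.05, frac_low_signal = 0.05,
               noisy_var_factor = 10, loading_range = c(0.4, 1)),
    annotations = list(n_terms = 25L, frac_correct = 0.9),
    preprocess = list(cv_quantile = 0.9, low_quantile = 0.05),
    methods = list(pearson = list(r_threshold = 0.6),
                   spearman = list(r_threshold = 0.6),
                   genenet = list(omega = 0.9),
                   space = list(rho_threshold = 0.12, lambda_scale = 0.5),
                   wgcna = list(beta = 5L, tau = 0.1)),
    modules = list(method = "walktrap", t = 4L, min_module_size = 5L),
    enrichment = list(alpha = 0.05, correction = "BH"),
    screening = list(q_min = 0.3, g_min = 20L, ratio_max = 10),
    powerlaw = list(k_min = 1L)),
    class = "pipeline_config")
}

check_pipeline_config <- function(config) {
  known <- c("seed", "sim", "annotations", "preprocess", "methods",
             "modules", "enrichment", "screening", "powerlaw")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "))
  }
  invisible(config)
}

#' Run the full synthetic benchmark pipeline
#'
#' Executes simulate -> preprocess -> reconstruct (per method) -> module
#' detection -> structural metrics and power-law fit -> enrichment and psi
#' statistics -> candidate screening -> method ranking, entirely driven by
#' `config` and deterministic under its seed. Recovery metrics against the
#' planted ground truth (edge F1, partition ARI) are attached per method,
#' plus a Pearson network rebuilt at the SPACE edge count (the
#' equal-network-size comparison).
#'
#' @param config a [benchmark_config()] list.
#' @param outdir optional directory; when given, every intermediate artifact
#'   (expression, design, networks, partitions, enrichment tables, ranking,
#'   summary) is written there as headered TSV.
#' @return list of class `gcn_pipeline`: `config`, `truth`, `methods` (per
#'   method: `network`, `partition`, `structure`, `power_law`, `enrichment`,
#'   `summary`, `recovery`, `ari`), `matched_pearson` (network + `q` at the
#'   SPACE edge count), `screening`, `ranking`, `summary` (one row per
#'   method).
#' @export
run_pipeline <- function(config = benchmark_config(), outdir = NULL) {
  check_pipeline_config(config)
  seed <- config$seed

  sim_args <- c(config$sim, list(seed = stage_seed(seed, "simulate")))
  sim <- simulate_expression(do.call(sim_config, sim_args))
  ann <- simulate_annotations(sim$truth,
                              n_terms = config$annotations$n_terms,
                              frac_correct = config$annotations$frac_correct,
                              seed = stage_seed(seed, "annotations"))

  filt <- filter_genes(sim$expr, sim$design,
                       cv_quantile = config$preprocess$cv_quantile,
                       low_quantile = config$preprocess$low_quantile)
  expr <- aggregate_replicates(filt$matrix, sim$design)

  truth_membership <- sim$truth$module_of
  results <- list()
  failed <- character()
  for (m in names(config$methods)) {
    pars <- config$methods[[m]]
    net <- do.call(gcn_reconstruct, c(list(matrix = expr, method = m), pars))
    if (net$n_e < 1) { failed <- c(failed, m); next }
    part <- detect_modules(net, method = config$modules$method,
                           min_module_size = config$modules$min_module_size,
                           t = config$modules$t,
                           seed = stage_seed(seed, paste0("modules_", m)))
    struct <- summarize_structure(net)
    pl <- tryCatch(fit_power_law(degree_distribution(net),
                                 method = "loglog_regression",
                                 k_min = config$powerlaw$k_min),
                   error = function(e) list(gamma = NA_real_, r2_loglog = 0,
                                            ks_stat = NA_real_,
                                            method = "loglog_regression"))
    enr <- enrich_modules(part, ann, alpha = config$enrichment$alpha,
                          correction = config$enrichment$correction,
                          min_module_size = config$modules$min_module_size)
    psis <- psi_summary(enr, part)
    results[[m]] <- list(
      method = m, network = net, partition = part, structure = struct,
      power_law = pl, enrichment = enr, summary = psis,
      q = part$q,
      recovery = edge_recovery(net, sim$truth),
      ari = partition_similarity(part,
                                 truth_membership[names(truth_membership) %in% net$genes]))
  }
  if (!length(results)) stop("pipeline stage failure: no method produced edges")

  matched <- NULL
  if (!is.null(results$space) && results$space$network$n_e >= 1) {
    mp_net <- correlation_network(expr, "pearson",
                                  n_edges = results$space$network$n_e)
    mp_part <- detect_modules(mp_net, method = config$modules$method,
                              min_module_size = config$modules$min_module_size,
                              t = config$modules$t,
                              seed = stage_seed(seed, "modules_matched"))
    matched <- list(network = mp_net, partition = mp_part, q = mp_part$q)
  }

  candidates <- lapply(results, function(r) {
    list(network = r$network, partition = r$partition, label = r$method)
  })
  crit <- do.call(screening_criteria, config$screening)
  screening <- screen_candidates(unname(candidates), crit)

  ranking <- if (length(results) >= 2) rank_methods(unname(results)) else NULL

  summary_tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(method = r$method, n_g = r$network$n_g, n_e = r$network$n_e,
               ratio = r$structure$edge_gene_ratio, q = r$q,
               n_modules = length(r$partition$modules),
               n_enriched = r$summary$n_enriched_modules,
               total_significant = r$summary$total_significant_terms,
               psi1 = r$summary$psi1, psi2 = r$summary$psi2,
               edge_f1 = r$recovery$f1, ari = r$ari,
               stringsAsFactors = FALSE)
  }))
  rownames(summary_tab) <- NULL

  out <- structure(list(config = config, truth = sim$truth, design = sim$design,
                        annotations = ann, expr = expr, methods = results,
                        failed = failed, matched_pearson = matched,
                        screening = screening, ranking = ranking,
                        summary = summary_tab),
                   class = "gcn_pipeline")
  if (!is.null(outdir)) write_pipeline_artifacts(out, sim, outdir)
  out
}

#' @export
print.gcn_pipeline <- function(x, ...) {
  cat("Synthetic GCN benchmark run (seed ", x$config$seed, ")\n\n", sep = "")
  print(x$summary, digits = 3)
  if (length(x$failed)) {
    cat("\nmethods with empty networks: ", paste(x$failed, collapse = ", "), "\n")
  }
  invisible(x)
}

write_pipeline_artifacts <- function(run, sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- run$config$seed
  cfg <- run$config
  write_expression(sim$expr, file.path(outdir, "expression.tsv"),
                   seed = seed, config = cfg)
  write_design(sim$design, file.path(outdir, "design.tsv"), seed = seed)
  write_annotations(run$annotations, file.path(outdir, "annotations.tsv"),
                    seed = seed)
  write_tsv_with_header(
    data.frame(gene = names(run$truth$module_of),
               module = unname(run$truth$module_of)),
    file.path(outdir, "truth_modules.tsv"), seed = seed)
  for (m in names(run$methods)) {
    write_network(run$methods[[m]]$network,
                  file.path(outdir, paste0("network_", m, ".tsv")),
                  seed = seed, config = cfg)
    write_partition(run$methods[[m]]$partition,
                    file.path(outdir, paste0("partition_", m, ".tsv")),
                    seed = seed)
    write_tsv_with_header(run$methods[[m]]$enrichment,
                          file.path(outdir, paste0("enrichment_", m, ".tsv")),
                          seed = seed)
  }
  if (!is.null(run$ranking)) {
    write_tsv_with_header(run$ranking, file.path(outdir, "ranking.tsv"),
                          seed = seed)
  }
  write_tsv_with_header(run$summary, file.path(outdir, "summary.tsv"),
                        seed = seed, config = cfg)
  invisible(outdir)
}
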