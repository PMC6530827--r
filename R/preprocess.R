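#' Collapse replicate samples to per-condition medians
#'
#' Mirrors the compendium preprocessing step of computing the median
#' expression value per replicate group before network reconstruction.
#' Idempotent on already-aggregated matrices (one sample per condition).
#'
#' @param matrix genes x samples numeric matrix (log-scale signal) with gene
#'   rownames and sample colnames.
#' @param design data.frame with columns `sample_id`, `condition_id` mapping
#'   every sample column to its condition.
#' @return genes x conditions matrix of per-condition medians; gene order
#'   preserved, conditions in first-appearance order of `design`.
#' @export
aggregate_replicates <- function(matrix, design) {
  check_expression(matrix)
  if (!all(c("sample_id", "condition_id") %in% names(design))) {
    stop("`design` needs columns `sample_id` and `condition_id`")
  }
  missing <- setdiff(colnames(matrix), design$sample_id)
  if (length(missing)) {
    stop("samples not mapped in design: ", paste(missing, collapse = ", "))
  }
  design <- design[design$sample_id %in% colnames(matrix), , drop = FALSE]
  conds <- unique(design$condition_id)
  out <- vapply(conds, function(cd) {
    cols <- design$sample_id[design$condition_id == cd]
    if (!length(cols)) stop("condition with zero samples: ", cd)
    block <- matrix[, cols, drop = FALSE]
    apply(block, 1, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) stop("all replicate values missing for condition ", cd)
      stats::median(v)
    })
  }, numeric(nrow(matrix)))
  out <- base::matrix(out, nrow = nrow(matrix),
                      dimnames = list(rownames(matrix), conds))
  structure(out, class = c("expression_matrix", "matrix", "array"))
}

#' Remove noisy and low-signal genes
#'
#' Operationalizes the exclusion of genes with noisy expression: a gene is
#' "noisy" when its median replicate coefficient of variation (CV, replicate
#' sd over replicate mean, per condition) exceeds `cv_max`, and "low signal"
#' when its median signal falls below the `low_quantile` quantile of the
#' global signal distribution. Apply before [aggregate_replicates()] so the
#' replicate structure is visible.
#'
#' @param matrix genes x samples matrix with replicate structure.
#' @param design data.frame `sample_id`, `condition_id` (and optionally
#'   `replicate`).
#' @param cv_max maximum tolerated median replicate CV (default 0.5).
#' @param low_quantile global signal quantile below which a gene's median
#'   signal marks it low-signal (default 0.05).
#' @param cv_quantile optional; if given, overrides `cv_max` with the
#'   corresponding quantile of the observed per-gene CV distribution.
#' @return list with `matrix` (survivors), `removed` (data.frame `gene`,
#'   `reason` in "noisy"/"low_signal"/"noisy;low_signal"), and `cv` (the
#'   per-gene median replicate CV used).
#' @export
filter_genes <- function(matrix, design, cv_max = 0.5, low_quantile = 0.05,
                         cv_quantile = NULL) {
  check_expression(matrix)
  if (cv_max <= 0) stop("`cv_max` must be positive")
  assert_fraction(low_quantile, "low_quantile")
  design <- design[match(colnames(matrix), design$sample_id), , drop = FALSE]
  cond <- factor(design$condition_id)
  multi <- names(which(table(cond) >= 2))

  gene_cv <- apply(matrix, 1, function(v) {
    if (!length(multi)) return(0)
    cvs <- vapply(multi, function(cd) {
      x <- v[cond == cd]
      m <- mean(x, na.rm = TRUE)
      if (abs(m) < .Machine$double.eps) return(NA_real_)
      stats::sd(x, na.rm = TRUE) / abs(m)
    }, numeric(1))
    stats::median(cvs, na.rm = TRUE)
  })
  gene_cv[is.na(gene_cv)] <- 0
  if (!is.null(cv_quantile)) {
    assert_fraction(cv_quantile, "cv_quantile")
    cv_max <- stats::quantile(gene_cv, cv_quantile, names = FALSE)
  }
  noisy <- gene_cv > cv_max

  floor_val <- stats::quantile(matrix, low_quantile, names = FALSE)
  med_sig <- apply(matrix, 1, stats::median, na.rm = TRUE)
  low <- if (low_quantile > 0) med_sig < floor_val else rep(FALSE, nrow(matrix))

  reason <- ifelse(noisy & low, "noisy;low_signal",
                   ifelse(noisy, "noisy", ifelse(low, "low_signal", NA)))
  removed <- data.frame(gene = rownames(matrix)[noisy | low],
                        reason = reason[noisy | low],
                        stringsAsFactors = FALSE)
  kept <- matrix[!(noisy | low), , drop = FALSE]
  list(matrix = structure(kept, class = c("expression_matrix", "matrix", "array")),
       removed = removed,
       cv = stats::setNames(gene_cv, rownames(matrix)))
}

# Shared validation of the genes x samples container.
check_expression <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expression matrix must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(matrix))) stop("duplicate gene ids in matrix")
  if (anyDuplicated(colnames(matrix))) stop("duplicate sample ids in matrix")
  invisible(matrix)
}
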