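#' Residualize predicted expression on genotype principal components
#'
#' Per gene, returns the residuals of predicted expression regressed (with
#' intercept) on the supplied population-structure covariates. With zero
#' covariate columns this reduces to centering.
#'
#' @param pred gene x sample predicted expression.
#' @param genotype_pcs sample x k score matrix (k may be 0).
#' @return gene x sample residual matrix.
#' @export
adjust_predicted <- function(pred, genotype_pcs) {
  n <- ncol(pred)
  if (is.null(genotype_pcs)) genotype_pcs <- matrix(0, n, 0)
  if (nrow(genotype_pcs) != n) stop2("genotype_pcs rows must match prediction samples")
  if (ncol(genotype_pcs) >= n) stop2("more covariates than samples")
  if (ncol(genotype_pcs) == 0) {
    out <- pred - rowMeans(pred)
  } else {
    X <- cbind(1, genotype_pcs)
    out <- t(lm.fit(X, t(pred))$residuals)
  }
  dimnames(out) <- dimnames(pred)
  out
}

#' Association test between one gene's predicted expression and a phenotype
#'
#' Ordinary least squares of the phenotype on predicted expression with
#' intercept; two-sided t p-value on n - 2 degrees of freedom. Constant
#' expression yields an untestable result (flagged, excluded from family
#' counts downstream).
#'
#' @param expr_g per-sample (residualized) predicted expression.
#' @param pheno per-sample (rank-normalized) phenotype, same order.
#' @return One-row data.frame: `beta`, `se`, `t_stat`, `p_value`, `n`,
#'   `untestable`.
#' @export
associate <- function(expr_g, pheno) {
  keep <- !is.na(expr_g) & !is.na(pheno)
  x <- expr_g[keep]; y <- pheno[keep]
  n <- length(x)
  if (n < 10) stop2("association needs n >= 10")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) {
    return(data.frame(beta = NA_real_, se = NA_real_, t_stat = NA_real_,
                      p_value = NA_real_, n = n, untestable = TRUE))
  }
  beta <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - mean(y) - beta * (x - mean(x))
  sigma2 <- sum(resid^2) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  t_stat <- beta / se
  p <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
  data.frame(beta = beta, se = se, t_stat = t_stat,
             p_value = max(p, .Machine$double.xmin), n = n,
             untestable = FALSE)
}

#' Bonferroni threshold over the union of tested genes
#'
#' The family-wise level divided by the total number of genes tested across
#' all algorithms (their per-algorithm counts summed).
#'
#' @param per_algorithm_gene_counts positive per-algorithm tested-gene
#'   counts.
#' @param alpha family-wise level.
#' @return p-value threshold (scalar).
#' @export
bonferroni_threshold <- function(per_algorithm_gene_counts, alpha = 0.05) {
  if (length(per_algorithm_gene_counts) == 0) stop2("empty gene counts")
  if (any(per_algorithm_gene_counts <= 0)) stop2("gene counts must be > 0")
  alpha / sum(per_algorithm_gene_counts)
}

#' Transcriptome-wide association study from a model collection
#'
#' Predicts expression in the association cohort (models filtered at
#' `min_cv_r2`), residualizes predictions on the cohort's own genotype
#' principal components, rank-normalizes the phenotype, regresses the
#' phenotype on each gene's adjusted predicted expression, and flags genes
#' below the Bonferroni threshold computed over the union family (all
#' algorithms; per-algorithm thresholds are also reported).
#'
#' @param db a `model_db`.
#' @param genotypes [geno_matrix()] of the association cohort (disjoint from
#'   training samples; caller-asserted).
#' @param phenotype named numeric vector (sample -> value).
#' @param pcs_k genotype PCs used for structure adjustment.
#' @param min_cv_r2 model inclusion threshold.
#' @param alpha family-wise level.
#' @param algorithms optional algorithm subset.
#' @return List with `results` (gene x algorithm association table),
#'   `threshold` (union Bonferroni threshold), `per_algorithm_thresholds`,
#'   `significant` (subset passing), and `t_comparison` (wide table of
#'   t-statistics per algorithm, with NA for genes an algorithm lacks).
#' @export
run_twas <- function(db, genotypes, phenotype, pcs_k = 3, min_cv_r2 = 0.01,
                     alpha = 0.05, algorithms = NULL) {
  common <- intersect(genotypes$samples, names(phenotype))
  pheno_all <- phenotype[common]
  if (sum(!is.na(pheno_all)) < 0.5 * length(genotypes$samples)) {
    stop2("phenotype missing for more than half of the cohort")
  }
  g <- genotypes[match(common, genotypes$samples), ]
  pr <- predict_cohort(db, g, min_cv_r2 = min_cv_r2, algorithms = algorithms)
  pcs <- genotype_pcs(g, pcs_k)
  pheno_n <- rank_inverse_normal(pheno_all)
  rows <- list()
  for (alg in names(pr$predictions)) {
    pred <- pr$predictions[[alg]]
    adj <- adjust_predicted(pred[, common, drop = FALSE], pcs)
    for (gene in rownames(adj)) {
      a <- associate(adj[gene, ], pheno_n)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(gene_id = gene, algorithm = alg, stringsAsFactors = FALSE), a)
    }
  }
  results <- do.call(rbind, rows)
  tested <- results[!results$untestable, ]
  counts <- table(tested$algorithm)
  thr <- bonferroni_threshold(as.numeric(counts), alpha)
  per_alg <- setNames(alpha / as.numeric(counts), names(counts))
  results$significant <- !results$untestable & results$p_value < thr
  tw <- stats::reshape(
    tested[, c("gene_id", "algorithm", "t_stat")],
    idvar = "gene_id", timevar = "algorithm", direction = "wide")
  names(tw) <- sub("^t_stat\\.", "t_", names(tw))
  list(results = results, threshold = thr,
       per_algorithm_thresholds = per_alg,
       significant = results[results$significant, , drop = FALSE],
       t_comparison = tw)
}
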