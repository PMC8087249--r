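#' Adjustment specification for expression preparation
#'
#' @param n_hidden_factors number of hidden confounding factors to estimate
#'   and remove (expression-PC stand-in for PEER-type factors; default 10).
#' @param n_genotype_pcs number of genotype principal components to include
#'   as covariates.
#' @param quantile_reference reference distribution for quantile
#'   normalization: `"average-empirical"` (mean of sorted samples) or
#'   `"normal-scores"`.
#' @param final one of `"quantile"` (training convention) or `"rank-normal"`
#'   (test convention): how residuals are renormalized after adjustment.
#' @return An object of class `adjustment_spec`.
#' @export
adjustment_spec <- function(n_hidden_factors = 10, n_genotype_pcs = 3,
                            quantile_reference = c("average-empirical",
                                                   "normal-scores"),
                            final = c("quantile", "rank-normal")) {
  quantile_reference <- match.arg(quantile_reference)
  final <- match.arg(final)
  stopifnot(n_hidden_factors >= 0, n_genotype_pcs >= 0)
  structure(list(n_hidden_factors = n_hidden_factors,
                 n_genotype_pcs = n_genotype_pcs,
                 quantile_reference = quantile_reference, final = final),
            class = "adjustment_spec")
}

#' Collapse probe-level values to gene level by averaging
#'
#' Each gene's value is the arithmetic mean over the probes mapping to it;
#' probes absent from the mapping are dropped and counted.
#'
#' @param values probe x sample numeric matrix (probe ids as row names).
#' @param mapping data.frame with columns `probe` and `gene` (each probe maps
#'   to at most one gene).
#' @return List with `values` (gene x sample matrix) and `n_unmapped`.
#' @export
collapse_ids <- function(values, mapping) {
  if (nrow(mapping) == 0) stop2("empty probe-to-gene mapping")
  if (anyDuplicated(mapping$probe)) stop2("a probe maps to more than one gene")
  idx <- match(rownames(values), mapping$probe)
  unmapped <- sum(is.na(idx))
  keep <- !is.na(idx)
  gene <- mapping$gene[idx[keep]]
  v <- values[keep, , drop = FALSE]
  sums <- rowsum(v, group = gene)           # rows ordered by sorted gene id
  counts <- as.vector(rowsum(rep(1, nrow(v)), group = gene))
  out <- sums / counts
  list(values = out, n_unmapped = unmapped)
}

#' Remove low-abundance genes
#'
#' Genes whose row mean abundance is strictly below `min_mean` are removed.
#'
#' @param values gene x sample abundance matrix (non-negative).
#' @param min_mean mean-abundance bound.
#' @return Filtered matrix.
#' @export
abundance_filter <- function(values, min_mean = 0.01) {
  if (any(values < 0, na.rm = TRUE)) stop2("abundances must be non-negative")
  values[rowMeans(values, na.rm = TRUE) >= min_mean, , drop = FALSE]
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share one reference distribution: the
#' mean of the sorted columns (`"average-empirical"`, ties averaged) or
#' standard normal scores (`"normal-scores"`).
#'
#' @param e gene x sample numeric matrix (>= 2 samples).
#' @param reference reference distribution.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(e, reference = c("average-empirical",
                                                "normal-scores")) {
  reference <- match.arg(reference)
  if (ncol(e) < 2) stop2("quantile normalization needs >= 2 samples")
  const <- apply(e, 2, function(x) length(unique(x[!is.na(x)])) <= 1)
  if (any(const)) warn2(sum(const), " constant sample(s): all values map to the reference median")
  if (reference == "average-empirical") {
    out <- limma::normalizeQuantiles(e, ties = TRUE)
  } else {
    n <- nrow(e)
    ref <- qnorm((seq_len(n) - 0.5) / n)
    out <- apply(e, 2, function(x) {
      r <- rank(x, ties.method = "average", na.last = "keep")
      approx_ref <- stats::approx(seq_len(n), ref, xout = r)$y
      approx_ref
    })
  }
  dimnames(out) <- dimnames(e)
  out
}

#' Rank-based inverse normal transform
#'
#' `x_i -> qnorm((rank_i - 0.5) / n)` with average ranks for ties.
#'
#' @param x numeric vector of length >= 2, not constant.
#' @return Transformed vector (names preserved).
#' @export
rank_inverse_normal <- function(x) {
  if (length(x) < 2) stop2("need at least 2 values")
  if (length(unique(x[!is.na(x)])) <= 1) stop2("constant vector cannot be rank-normalized")
  r <- rank(x, ties.method = "average", na.last = "keep")
  out <- qnorm((r - 0.5) / sum(!is.na(x)))
  names(out) <- names(x)
  out
}

#' Estimate hidden factors and residualize expression
#'
#' Estimates `n_hidden_factors` confounding factors as the top principal
#' components of the gene-centered expression matrix (a documented stand-in
#' for PEER-type factor models), regresses each gene on the factors plus the
#' supplied genotype PCs (with intercept) and returns the residuals, finally
#' renormalized per the spec (`quantile` or `rank-normal`).
#'
#' @param e gene x sample matrix.
#' @param spec an [adjustment_spec()].
#' @param genotype_pcs sample x k score matrix (k may be 0).
#' @return List with `values` (adjusted gene x sample matrix), `factors`
#'   (sample x f matrix) and `covariates` (the full design used).
#' @export
hidden_factor_adjust <- function(e, spec = adjustment_spec(),
                                 genotype_pcs = NULL) {
  n <- ncol(e)
  f <- spec$n_hidden_factors
  if (f >= n) stop2("n_hidden_factors must be < number of samples")
  if (is.null(genotype_pcs)) genotype_pcs <- matrix(0, n, 0)
  if (nrow(genotype_pcs) != n) stop2("genotype_pcs rows must match samples")
  centered <- e - rowMeans(e)
  factors <- if (f > 0) {
    sv <- svd(t(centered), nu = f, nv = 0)
    fs <- sv$u[, seq_len(f), drop = FALSE] %*% diag(sv$d[seq_len(f)], f, f)
    colnames(fs) <- paste0("HF", seq_len(f))
    fs
  } else {
    matrix(0, n, 0)
  }
  covs <- cbind(factors, genotype_pcs)
  if (ncol(covs) > 0) {
    X <- cbind(1, covs)
    fit <- lm.fit(X, t(e))
    resid <- t(fit$residuals)
  } else {
    resid <- centered
  }
  dimnames(resid) <- dimnames(e)
  out <- if (ncol(resid) >= 2 && spec$final == "quantile") {
    quantile_normalize(resid, spec$quantile_reference)
  } else if (spec$final == "rank-normal") {
    t(apply(resid, 1, rank_inverse_normal))
  } else {
    resid
  }
  dimnames(out) <- dimnames(e)
  list(values = out, factors = factors, covariates = covs)
}

#' Full expression preparation pipeline
#'
#' collapse -> abundance filter -> quantile normalize -> hidden-factor + PC
#' residualize (which renormalizes per `spec$final`). Returns the processed
#' matrix plus a manifest recording every step and parameter.
#'
#' @param values probe or gene x sample matrix.
#' @param mapping optional probe-to-gene mapping (skip collapse when NULL).
#' @param min_mean abundance bound; `NULL` skips the filter (array data).
#' @param spec an [adjustment_spec()].
#' @param genotype_pcs sample x k matrix or NULL.
#' @return List with `values` and `manifest` (data.frame of steps).
#' @export
prepare_expression <- function(values, mapping = NULL, min_mean = NULL,
                               spec = adjustment_spec(), genotype_pcs = NULL) {
  manifest <- list()
  if (!is.null(mapping)) {
    cl <- collapse_ids(values, mapping)
    values <- cl$values
    manifest[[length(manifest) + 1]] <-
      data.frame(step = "collapse_ids", detail = paste0("unmapped=", cl$n_unmapped))
  }
  if (!is.null(min_mean)) {
    before <- nrow(values)
    values <- abundance_filter(values, min_mean)
    manifest[[length(manifest) + 1]] <-
      data.frame(step = "abundance_filter",
                 detail = paste0("min_mean=", min_mean, ";removed=", before - nrow(values)))
  }
  values <- quantile_normalize(values, spec$quantile_reference)
  manifest[[length(manifest) + 1]] <-
    data.frame(step = "quantile_normalize", detail = spec$quantile_reference)
  adj <- hidden_factor_adjust(values, spec, genotype_pcs)
  manifest[[length(manifest) + 1]] <-
    data.frame(step = "hidden_factor_adjust",
               detail = sprintf("factors=%d;pcs=%d;final=%s", spec$n_hidden_factors,
                                if (is.null(genotype_pcs)) 0 else ncol(genotype_pcs),
                                spec$final))
  list(values = adj$values, manifest = do.call(rbind, manifest))
}
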