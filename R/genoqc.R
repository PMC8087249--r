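#' Quality-control thresholds for genotype data
#'
#' Bundles the per-variant and per-sample filters: call rate, Hardy-Weinberg
#' exact-test handling, minor allele frequency, strand-ambiguity removal,
#' sliding-window LD pruning and a relatedness bound. Two Hardy-Weinberg
#' conventions are supported because training and test cohorts typically use
#' different ones: `"reject-below"` removes variants with p < `hwe_alpha`
#' (a genotyping-error screen at a tiny alpha), `"retain-above"` keeps only
#' variants with p > `hwe_alpha` (a stricter post-imputation screen).
#'
#' @param min_call_rate minimum non-missing fraction per variant.
#' @param hwe_alpha Hardy-Weinberg p-value bound.
#' @param hwe_mode `"reject-below"` or `"retain-above"`.
#' @param maf_min minor-allele-frequency bound; variants with MAF <= this are
#'   removed (strict inequality retained).
#' @param ld_window,ld_step,ld_r2_max sliding-window pruning parameters
#'   (window size in variants, step, r-squared bound).
#' @param drop_ambiguous remove palindromic (A/T, C/G) variants.
#' @param relatedness_max kinship/IBD bound above which one of a sample pair
#'   is removed.
#' @param imputation_r2_min accepted for provenance parity with pipelines
#'   that filter on imputation quality; no imputation stage exists here, so
#'   it is ignored with a warning when set.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.99, hwe_alpha = 1e-5,
                          hwe_mode = c("reject-below", "retain-above"),
                          maf_min = 0.01, ld_window = 50, ld_step = 5,
                          ld_r2_max = 0.3, drop_ambiguous = TRUE,
                          relatedness_max = 0.05, imputation_r2_min = NULL) {
  hwe_mode <- match.arg(hwe_mode)
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, maf_min >= 0, maf_min <= 1,
            ld_window >= ld_step, ld_step >= 1)
  if (!is.null(imputation_r2_min)) {
    warn2("imputation_r2_min is accepted for provenance parity but ignored: ",
          "no imputation stage exists in this pipeline")
  }
  structure(list(min_call_rate = min_call_rate, hwe_alpha = hwe_alpha,
                 hwe_mode = hwe_mode, maf_min = maf_min, ld_window = ld_window,
                 ld_step = ld_step, ld_r2_max = ld_r2_max,
                 drop_ambiguous = drop_ambiguous,
                 relatedness_max = relatedness_max),
            class = "qc_thresholds")
}

#' Remove variants below a call-rate threshold
#' @param g a [geno_matrix()].
#' @param min_call_rate minimum non-missing fraction; variants strictly below
#'   it are removed, order otherwise preserved.
#' @return Filtered [geno_matrix()].
#' @export
call_rate_filter <- function(g, min_call_rate = 0.99) {
  cr <- colMeans(!is.na(g$dosages))
  g[, cr >= min_call_rate]
}

#' Hardy-Weinberg exact test (Levene-Haldane)
#'
#' Two-sided exact p-value from the conditional distribution of the
#' heterozygote count given the allele counts: the sum of the probabilities
#' of every attainable heterozygote count whose probability does not exceed
#' that of the observed count. Probabilities are computed on the log scale
#' from `P(n_het | n, n_minor) = C * 2^n_het / (n_hom_major! n_het! n_hom_minor!)`.
#'
#' @param n_hom_major,n_het,n_hom_minor genotype counts (non-negative, not
#'   all zero).
#' @return Exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop2("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop2("all genotype counts are zero")
  n_minor <- min(2 * n_hom_minor + n_het, 2 * n_hom_major + n_het)
  # attainable heterozygote counts share the parity of the minor allele count
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  logp <- vapply(hets, function(h) {
    a <- (n_minor - h) / 2          # minor homozygotes
    b <- n - a - h                  # major homozygotes
    h * log(2) - lfactorial(a) - lfactorial(h) - lfactorial(b)
  }, numeric(1))
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_het, hets)]
  p <- sum(prob[prob <= obs * (1 + 1e-12)])
  min(p, 1)
}

# Vectorized HWE p-values from hard-calls of a dosage matrix. Dosages farther
# than `tol` from an integer are treated as missing for the test only (the
# exact test needs genotype counts; array data are hard calls anyway).
hwe_pvalues <- function(g, tol = 0.1) {
  apply(g$dosages, 2, function(d) {
    hc <- round(d)
    hc[is.na(d) | abs(d - hc) > tol] <- NA
    tab <- c(sum(hc == 0, na.rm = TRUE), sum(hc == 1, na.rm = TRUE),
             sum(hc == 2, na.rm = TRUE))
    if (sum(tab) == 0) return(NA_real_)
    hwe_exact_test(tab[1], tab[2], tab[3])
  })
}

#' Filter variants by Hardy-Weinberg exact-test p-value
#' @param g a [geno_matrix()].
#' @param alpha p-value bound.
#' @param mode `"reject-below"` removes p < alpha; `"retain-above"` keeps
#'   p > alpha.
#' @return Filtered [geno_matrix()].
#' @export
hwe_filter <- function(g, alpha = 1e-5, mode = c("reject-below", "retain-above")) {
  mode <- match.arg(mode)
  p <- hwe_pvalues(g)
  keep <- if (mode == "reject-below") is.na(p) | p >= alpha else !is.na(p) & p > alpha
  g[, keep]
}

#' Remove variants at or below a minor-allele-frequency bound
#'
#' Allele frequency is the mean non-missing dosage over 2; the minor allele
#' frequency is `min(f, 1 - f)`. Variants with MAF <= `maf_min` are removed
#' (strict inequality is retained). Variants with all entries missing are
#' removed with a warning.
#'
#' @param g a [geno_matrix()].
#' @param maf_min MAF bound.
#' @return Filtered [geno_matrix()].
#' @export
maf_filter <- function(g, maf_min = 0.01) {
  f <- alt_freq(g)
  if (anyNA(f)) warn2(sum(is.na(f)), " variant(s) with all dosages missing removed")
  maf <- pmin(f, 1 - f)
  g[, !is.na(maf) & maf > maf_min]
}

#' Remove strand-ambiguous (palindromic) variants
#'
#' Variants whose allele pair is A/T or C/G cannot be strand-reconciled
#' across platforms and are removed. Non-SNP alleles (length > 1) are also
#' removed, with a warning.
#'
#' @param g a [geno_matrix()].
#' @return Filtered [geno_matrix()].
#' @export
remove_ambiguous <- function(g) {
  long <- nchar(g$variants$ref) > 1 | nchar(g$variants$alt) > 1
  if (any(long)) warn2(sum(long), " non-SNP variant(s) removed")
  amb <- is_ambiguous_pair(g$variants$ref, g$variants$alt)
  g[, !long & !amb]
}

#' Greedy sliding-window LD pruning
#'
#' Within each window of `window` consecutive retained variants, every pair
#' with squared Pearson correlation of dosages above `r2_max` loses its later
#' member (by position); the window then advances by `step` retained
#' variants. Deterministic given the input order. Zero-variance variants are
#' treated as uncorrelated with everything.
#'
#' @param g a [geno_matrix()].
#' @param window window size in variants (>= 2).
#' @param step advance in retained variants.
#' @param r2_max squared-correlation bound.
#' @return Character vector of retained variant ids.
#' @export
ld_prune <- function(g, window = 50, step = 5, r2_max = 0.3) {
  if (window < 2) stop2("window must be >= 2")
  ids <- g$variants$id
  m <- length(ids)
  keep <- rep(TRUE, m)
  dos <- g$dosages
  sds <- apply(dos, 2, stats::sd, na.rm = TRUE)
  start <- 1L
  repeat {
    alive <- which(keep)
    alive <- alive[alive >= start]
    if (length(alive) < 2) break
    win <- head(alive, window)
    for (a in seq_along(win)) {
      i <- win[a]
      if (!keep[i]) next
      for (b in seq_along(win)) {
        if (b <= a) next
        j <- win[b]
        if (!keep[j]) next
        if (is.na(sds[i]) || is.na(sds[j]) || sds[i] == 0 || sds[j] == 0) next
        r <- suppressWarnings(cor(dos[, i], dos[, j], use = "complete.obs"))
        if (!is.na(r) && r^2 > r2_max) keep[j] <- FALSE
      }
    }
    # advance past `step` retained variants from the window start
    surv <- which(keep)
    surv <- surv[surv >= start]
    if (length(surv) <= step) break
    start <- surv[step + 1L]
    if (start > m) break
    if (length(win) == length(alive)) break  # window already covered the tail
  }
  ids[keep]
}

#' Genetic relationship matrix and relatedness-based sample removal
#'
#' Computes `GRM = Z Z' / m` with Z the column-standardized (mean-imputed)
#' dosage matrix, then for every pair whose off-diagonal entry exceeds
#' `relatedness_max` removes the member with the lower genotype call rate
#' (ties: the later sample in input order).
#'
#' @param g a [geno_matrix()] with >= 2 samples (a single sample passes
#'   through untouched).
#' @param relatedness_max kinship/IBD bound.
#' @return List with `kinship` (n x n matrix) and `retained` (sample labels).
#' @export
kinship_and_remove <- function(g, relatedness_max = 0.05) {
  n <- length(g$samples)
  Z <- standardize_dosages(g$dosages)
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(g$samples, g$samples)
  if (n < 2) return(list(kinship = K, retained = g$samples))
  call_rate <- rowMeans(!is.na(g$dosages))
  drop <- rep(FALSE, n)
  pairs <- which(upper.tri(K) & K > relatedness_max, arr.ind = TRUE)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (drop[i] || drop[j]) next
      if (call_rate[i] < call_rate[j]) drop[i] <- TRUE else drop[j] <- TRUE
    }
  }
  list(kinship = K, retained = g$samples[!drop])
}

# Mean-impute missing entries and column-standardize; zero-variance columns
# become all-zero rather than NaN.
standardize_dosages <- function(dos) {
  mu <- colMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(idx)) dos[idx] <- mu[idx[, 2]]
  s <- apply(dos, 2, stats::sd)
  s[is.na(s) | s == 0] <- Inf
  scale(dos, center = mu, scale = s)
}

#' Genotype principal components
#'
#' Top-k left singular vectors (scaled by their singular values) of the
#' column-standardized, mean-imputed dosage matrix. Sign convention: within
#' each component the largest-magnitude variant loading is made positive, so
#' scores are reproducible across equivalent runs.
#'
#' @param g a [geno_matrix()].
#' @param k number of components; `k <= 0` returns a zero-column matrix.
#' @return sample x k score matrix.
#' @export
genotype_pcs <- function(g, k = 3) {
  n <- length(g$samples)
  if (k <= 0) {
    return(matrix(0, n, 0, dimnames = list(g$samples, NULL)))
  }
  Z <- standardize_dosages(g$dosages)
  k <- min(k, n - 1, ncol(Z) - 1)
  sv <- svd(Z, nu = k, nv = k)
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$v[, j]))
    if (sv$v[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(g$samples, paste0("PC", seq_len(k)))
  scores
}

#' Run the variant-level QC pipeline
#'
#' Applies, in order: call-rate filter, Hardy-Weinberg filter, MAF filter,
#' strand-ambiguity removal. LD pruning and relatedness screening are kept
#' separate ([ld_prune()], [kinship_and_remove()]) because they feed the
#' PCA/kinship stage rather than the model-training feature set.
#'
#' @param g a [geno_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return List with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (data.frame of per-step variant removal counts).
#' @export
geno_qc <- function(g, thresholds = qc_thresholds()) {
  steps <- character(0); removed <- integer(0); left <- integer(0)
  note <- function(name, before, after) {
    steps <<- c(steps, name)
    removed <<- c(removed, before - after)
    left <<- c(left, after)
  }
  m0 <- nrow(g$variants)
  g1 <- call_rate_filter(g, thresholds$min_call_rate)
  note("call_rate", m0, nrow(g1$variants))
  g2 <- hwe_filter(g1, thresholds$hwe_alpha, thresholds$hwe_mode)
  note("hwe", nrow(g1$variants), nrow(g2$variants))
  g3 <- maf_filter(g2, thresholds$maf_min)
  note("maf", nrow(g2$variants), nrow(g3$variants))
  g4 <- if (thresholds$drop_ambiguous) remove_ambiguous(g3) else g3
  note("ambiguous", nrow(g3$variants), nrow(g4$variants))
  report <- data.frame(step = steps, removed = removed, remaining = left,
                       stringsAsFactors = FALSE)
  list(genotypes = g4, report = report)
}
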