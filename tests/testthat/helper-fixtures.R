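# Shared in-code fixtures. Everything is generated programmatically; sizes
# are kept small so the default run stays fast.

# A tiny geno_matrix with hand-chosen dosages.
tiny_geno <- function(dosages, chrom = "1", pos = NULL, ref = NULL, alt = NULL) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  geno_matrix(dosages,
              data.frame(chrom = chrom, pos = pos,
                         id = paste0("v", seq_len(m)), ref = ref, alt = alt,
                         stringsAsFactors = FALSE))
}

# Independent enumeration oracle for the Hardy-Weinberg exact test: walks
# every attainable heterozygote count explicitly with exact factorials.
hwe_oracle <- function(aa, ab, bb) {
  n <- aa + ab + bb
  na <- min(2 * aa + ab, 2 * bb + ab)
  hets <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  num <- vapply(hets, function(h) {
    n_min_hom <- (na - h) / 2
    n_maj_hom <- n - n_min_hom - h
    exp(lgamma(n + 1) - lgamma(n_min_hom + 1) - lgamma(h + 1) -
          lgamma(n_maj_hom + 1) + h * log(2))
  }, numeric(1))
  prob <- num / sum(num)
  obs <- prob[match(ab, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# Independent re-implementation of the greedy sliding-window LD pruner.
ld_prune_oracle <- function(g, window, step, r2_max) {
  keep <- rep(TRUE, ncol(g$dosages))
  dos <- g$dosages
  start <- 1L
  repeat {
    alive <- which(keep)
    alive <- alive[alive >= start]
    if (length(alive) < 2) break
    win <- utils::head(alive, window)
    for (a in seq_along(win)) for (b in seq_along(win)) {
      if (b <= a) next
      i <- win[a]; j <- win[b]
      if (!keep[i] || !keep[j]) next
      si <- stats::sd(dos[, i]); sj <- stats::sd(dos[, j])
      if (is.na(si) || is.na(sj) || si == 0 || sj == 0) next
      r <- stats::cor(dos[, i], dos[, j], use = "complete.obs")
      if (!is.na(r) && r^2 > r2_max) keep[j] <- FALSE
    }
    surv <- which(keep); surv <- surv[surv >= start]
    if (length(surv) <= step) break
    start <- surv[step + 1L]
    if (length(win) == length(alive)) break
  }
  g$variants$id[keep]
}

# A small single-population cohort reused by several tests.
small_cohort <- function(n = 120, n_genes = 6, seed = 7, ...) {
  simulate_cohort(list(population_spec("POP", n, 0)),
                  n_genes = n_genes, n_variants_per_gene = 10,
                  seed = seed, ...)
}
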