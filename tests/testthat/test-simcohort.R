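test_that("Balding-Nichols frequency draws have the stated mean and variance", {
  pop0 <- population_spec("P0", 10, fst = 0)
  pop <- population_spec("P", 10, fst = 0.15)
  fr <- draw_population_freqs(50000, c(0.499, 0.501), list(pop0, pop), seed = 2)
  # fst = 0: population frequency equals the ancestral draw exactly
  expect_identical(fr$freqs$P0, fr$ancestral)
  # fst = 0.15 around p ~ 0.5: Beta mean p, variance fst * p * (1 - p)
  expect_lt(abs(mean(fr$freqs$P) - 0.5), 0.01)
  expect_lt(abs(var(fr$freqs$P) / (0.15 * 0.25) - 1), 0.1)
  expect_error(draw_population_freqs(10, c(0.1, 0.9), list(), 1), "non-empty")
  expect_error(population_spec("x", 5, fst = 1), "fst")
})

test_that("genotype draws follow Hardy-Weinberg binomial sampling", {
  g0 <- simulate_genotypes(c(0, 1), 50, seed = 3)
  expect_true(all(g0$dosages[, g0$variants$pos == 1000] == 0))
  expect_true(all(g0$dosages[, g0$variants$pos == 2000] == 2))

  n <- 20000
  g <- simulate_genotypes(0.3, n, seed = 4, ambiguous_frac = 0)
  counts <- tabulate(g$dosages[, 1] + 1, 3)
  expected <- c(0.49, 0.42, 0.09) * n
  sds <- sqrt(expected * (1 - c(0.49, 0.42, 0.09)))
  expect_true(all(abs(counts - expected) < 3 * sds))
})

test_that("simulated populations sit in Hardy-Weinberg equilibrium", {
  g <- simulate_genotypes(runif(400, 0.05, 0.95), 2000, seed = 6)
  p <- alt_freq(g)
  chi <- vapply(seq_len(400), function(j) {
    obs <- tabulate(g$dosages[, j] + 1, 3)
    exp_ <- 2000 * c((1 - p[j])^2, 2 * p[j] * (1 - p[j]), p[j]^2)
    sum((obs - exp_)^2 / pmax(exp_, 1e-12))
  }, numeric(1))
  frac_ok <- mean(chi < qchisq(0.999, df = 1))
  expect_gte(frac_ok, 0.99)
})

test_that("Hudson FST between two simulated populations recovers the configured fst", {
  for (fst in c(0.05, 0.15)) {
    pops <- list(population_spec("A", 300, fst), population_spec("B", 300, fst))
    fr <- draw_population_freqs(10000, c(0.1, 0.9), pops, seed = 8)
    gA <- simulate_genotypes(fr$freqs$A, 300, seed = 9)
    gB <- simulate_genotypes(fr$freqs$B, 300, seed = 10)
    est <- hudson_fst(gA, gB)
    expect_lt(abs(est / fst - 1), 0.2)
  }
})

test_that("expression heritability control is exact in its limits and calibrated otherwise", {
  g <- simulate_genotypes(runif(4, 0.3, 0.7), 5000, seed = 21, ambiguous_frac = 0)
  ids <- g$variants$id
  mk_truth <- function(h2, form = "additive-linear") {
    archs <- list(gene_A = eqtl_architecture("gene_A", ids[1:2], c(0.8, -0.5),
                                             form, h2))
    structure(list(architectures = archs, trait_gene = "gene_A",
                   trait_effect = -0.5,
                   hidden_factor_loadings = matrix(0, 1, 1,
                     dimnames = list("gene_A", NULL))),
              class = "sim_truth")
  }
  # h2 = 1, no factors: expression is an exact rescaling of the genetic value
  s1 <- simulate_expression(g, mk_truth(1), n_hidden_factors = 0, seed = 5)
  expect_equal(cor(s1$expression[1, ], s1$genetic[1, ]), 1)
  # h2 = 0: no genotype dependence (regression slope compatible with zero)
  s0 <- simulate_expression(g, mk_truth(0), n_hidden_factors = 0, seed = 5)
  fit <- lm(s0$expression[1, ] ~ g$dosages[, ids[1]])
  expect_lt(abs(coef(fit)[2] / summary(fit)$coefficients[2, 2]), 3)
  # h2 = 0.4: realized variance ratio close to target
  s4 <- simulate_expression(g, mk_truth(0.4), n_hidden_factors = 0, seed = 5)
  ratio <- var(s4$genetic[1, ]) / var(s4$expression[1, ])
  expect_lt(abs(ratio - 0.4), 0.05)
})

test_that("phenotype simulation recovers the configured trait effect", {
  gv <- rnorm(2000)
  y <- simulate_phenotype(gv, trait_effect = -0.5, noise_sd = 1, seed = 31)
  fit <- summary(lm(y ~ gv))
  expect_lt(abs(coef(fit)[2, 1] - (-0.5)), 3 * coef(fit)[2, 2])
  # null trait: slope compatible with zero
  y0 <- simulate_phenotype(gv, trait_effect = 0, noise_sd = 1, seed = 32)
  f0 <- summary(lm(y0 ~ gv))
  expect_lt(abs(coef(f0)[2, 1] / coef(f0)[2, 2]), 3)
  expect_error(simulate_phenotype(gv, 1, noise_sd = 0, seed = 1), "noise_sd")
})

test_that("cohort generation is bit-reproducible from its seed", {
  pops <- list(population_spec("A", 40, 0.05), population_spec("B", 30, 0.1))
  c1 <- simulate_cohort(pops, n_genes = 4, n_variants_per_gene = 8, seed = 77,
                        missing_rate = 0.02)
  c2 <- simulate_cohort(pops, n_genes = 4, n_variants_per_gene = 8, seed = 77,
                        missing_rate = 0.02)
  expect_identical(c1$genotypes$A$dosages, c2$genotypes$A$dosages)
  expect_identical(c1$expression$B, c2$expression$B)
  expect_identical(c1$phenotype$A, c2$phenotype$A)
  expect_identical(c1$truth$architectures, c2$truth$architectures)
  # different seed changes the data
  c3 <- simulate_cohort(pops, n_genes = 4, n_variants_per_gene = 8, seed = 78,
                        missing_rate = 0.02)
  expect_false(identical(c1$genotypes$A$dosages, c3$genotypes$A$dosages))
})

test_that("cohort variants lie inside their gene's cis window", {
  co <- small_cohort(n = 30, n_genes = 5)
  for (gene in names(co$truth$architectures)) {
    a <- co$truth$architectures[[gene]]
    ann <- co$annotation[co$annotation$gene_id == gene, ]
    pos <- co$genotypes$POP$variants$pos[
      match(a$causal_variant_ids, co$genotypes$POP$variants$id)]
    expect_true(all(pos >= ann$start - 1e6 & pos <= ann$end + 1e6))
  }
})

test_that("LD blocks keep exact marginals while correlating block-mates", {
  f <- withr::with_seed(1, runif(20, 0.2, 0.8))
  g <- simulate_ld_genotypes(f, 8000, seed = 5, block_size = 5,
                             fidelity = 0.92, ambiguous_frac = 0)
  # marginal allele frequencies are the per-variant inputs
  expect_lt(max(abs(alt_freq(g) - f[order(seq_len(20) * 1000)])), 0.02)
  C <- cor(g$dosages)
  within <- C[1:5, 1:5][upper.tri(diag(5))]
  across <- C[1:5, 6:10]
  expect_gt(mean(within), 0.3)
  expect_lt(mean(abs(across)), 0.05)
  # Hardy-Weinberg still holds per variant
  pv <- apply(g$dosages[, 1:5], 2, function(d) {
    tb <- tabulate(d + 1, 3)
    hwe_exact_test(tb[1], tb[2], tb[3])
  })
  expect_true(all(pv > 1e-4))
  # a shifted block phase changes who correlates with whom
  g2 <- simulate_ld_genotypes(f, 8000, seed = 5, block_size = 5,
                              fidelity = 0.92, block_offset = 2,
                              ambiguous_frac = 0)
  C2 <- cor(g2$dosages)
  expect_lt(mean(C2[1:3, 4:5]), mean(C2[4:5, 4:5][upper.tri(diag(2))]) )
})

test_that("hidden-causal cohorts exclude causal variants but keep informative tags", {
  co <- simulate_cohort(list(population_spec("P", 50, 0)),
                        n_genes = 3, n_variants_per_gene = 10,
                        ld_block_size = 5, ld_fidelity = 0.92,
                        hide_causal = TRUE, seed = 21)
  causal <- unique(unlist(lapply(co$truth$architectures, `[[`,
                                 "causal_variant_ids")))
  expect_false(any(causal %in% co$genotypes$P$variants$id))
  expect_gt(nrow(co$genotypes$P$variants), 0)
  expect_error(simulate_cohort(list(population_spec("P", 20, 0)),
                               n_genes = 2, hide_causal = TRUE, seed = 1),
               "ld_block_size")
})
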