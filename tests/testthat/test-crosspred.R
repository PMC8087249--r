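# A hand-built linear gene model for harmonization/prediction tests.
linear_model <- function(weights, intercept, variants, mean_dosage = NULL,
                         cv_r2 = 0.5) {
  if (is.null(mean_dosage)) mean_dosage <- rep(1, nrow(variants))
  structure(list(gene_id = "gX", algorithm = "en",
                 hyperparameters = list(alpha = 0.5),
                 cv = list(fold_r2 = rep(cv_r2, 5), mean_r2 = cv_r2, seed = 1),
                 variants = data.frame(id = variants$id, ref = variants$ref,
                                       alt = variants$alt,
                                       mean_dosage = mean_dosage,
                                       chrom = variants$chrom,
                                       pos = variants$pos,
                                       stringsAsFactors = FALSE),
                 payload = list(type = "linear", weights = weights,
                                intercept = intercept),
                 failed = FALSE), class = "gene_model")
}

test_that("harmonization matches, flips, and mean-imputes as stated", {
  mvars <- data.frame(chrom = "1", pos = c(100L, 200L, 300L, 400L),
                      id = paste0("m", 1:4),
                      ref = c("A", "A", "C", "A"), alt = c("G", "C", "T", "G"),
                      stringsAsFactors = FALSE)
  m <- linear_model(weights = c(1, 1, 1, 1), intercept = 0, mvars,
                    mean_dosage = c(0.5, 0.6, 0.7, 0.8))
  # test cohort: m1 matches; m2 has swapped alleles; m3 allele mismatch;
  # m4 absent entirely
  tvars <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                      id = paste0("t", 1:3),
                      ref = c("A", "C", "C"), alt = c("G", "A", "G"),
                      stringsAsFactors = FALSE)
  tg <- geno_matrix(cbind(c(0, 1), c(0.4, 2), c(1, 1)), tvars,
                    samples = c("s1", "s2"))
  h <- harmonize(m, tg)
  expect_equal(h$report$status,
               c("match", "allele-swap", "mismatch-dropped", "missing-imputed"))
  expect_equal(unname(h$X[, "m1"]), c(0, 1))
  expect_equal(unname(h$X[, "m2"]), c(2 - 0.4, 0))   # dosage flipped
  expect_equal(unname(h$X[, "m3"]), c(0.7, 0.7))     # training mean
  expect_equal(unname(h$X[, "m4"]), c(0.8, 0.8))
})

test_that("ambiguous model variants are dropped and majority-missing models skipped", {
  mvars <- data.frame(chrom = "1", pos = c(100L, 200L, 300L),
                      id = c("m1", "m2", "m3"),
                      ref = c("A", "C", "A"), alt = c("T", "G", "G"),
                      stringsAsFactors = FALSE)
  m <- linear_model(c(1, 1, 1), 0, mvars)
  tg <- geno_matrix(cbind(c(1, 1), c(0, 2), c(1, 0)), mvars,
                    samples = c("s1", "s2"))
  # two of three variants ambiguous: above the 50% skip bound
  expect_warning(h <- harmonize(m, tg), "skipped")
  expect_null(h)
  h2 <- harmonize(m, tg, max_missing_frac = 0.7)
  expect_equal(h2$report$status,
               c("ambiguous-dropped", "ambiguous-dropped", "match"))
  # exactly half unusable is not "more than half": the model is kept
  pvars <- data.frame(chrom = "1", pos = c(300L, 400L), id = c("p1", "p2"),
                      ref = c("A", "A"), alt = c("G", "C"),
                      stringsAsFactors = FALSE)
  m2 <- linear_model(c(1, 1), 0, pvars)
  tvars2 <- pvars
  tvars2$ref[1] <- "T"; tvars2$alt[1] <- "C"  # irreconcilable alleles at p1
  tg2 <- geno_matrix(cbind(c(0, 2), c(1, 0)), tvars2, samples = c("s1", "s2"))
  expect_silent(h3 <- harmonize(m2, tg2))
  expect_equal(h3$report$status, c("mismatch-dropped", "match"))
})

test_that("allele-flip round trip leaves predictions bit-identical", {
  co <- small_cohort(n = 60, n_genes = 4, ambiguous_frac = 0)
  db <- train_cohort(co$genotypes$POP, co$expression$POP, co$annotation,
                     algorithms = "en", seed = 13)
  tg <- co$genotypes$POP
  pr1 <- predict_cohort(db, tg, min_cv_r2 = -Inf)
  flipped <- geno_matrix(2 - tg$dosages,
                         transform(tg$variants, ref = alt, alt = ref),
                         samples = tg$samples)
  pr2 <- predict_cohort(db, flipped, min_cv_r2 = -Inf)
  expect_identical(pr1$predictions, pr2$predictions)
})

test_that("cohort prediction applies the cv R2 inclusion rule and linear payloads", {
  vars <- data.frame(chrom = "1", pos = 100L, id = "m1", ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  m <- linear_model(1.2, 0.5, vars, mean_dosage = 1, cv_r2 = 0.4)
  db <- structure(list(models = list(gX = list(en = m)),
                       results = data.frame(gene_id = "gX", algorithm = "en",
                                            mean_cv_r2 = 0.4, n_features = 1,
                                            failed = FALSE)),
                  class = "model_db")
  tg <- geno_matrix(matrix(c(0, 1, 2), 3, 1), vars,
                    samples = c("s1", "s2", "s3"))
  pr <- predict_cohort(db, tg, min_cv_r2 = 0.01)
  expect_equal(unname(pr$predictions$en["gX", ]), c(0.5, 1.7, 2.9))
  expect_error(predict_cohort(db, tg, min_cv_r2 = Inf), "no models")
})

test_that("Spearman evaluation is tie-corrected with the 0.1 significance heuristic", {
  pred <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4), g3 = c(4, 3, 2, 1),
                g4 = c(1, 1, 1, 1))
  obs <- rbind(g1 = c(1, 2, 3, 4), g2 = c(1, 3, 2, 4), g3 = c(1, 2, 3, 4),
               g4 = c(1, 2, 3, 4))
  colnames(pred) <- colnames(obs) <- paste0("s", 1:4)
  ev <- spearman_eval(pred, obs, "en", "POP")
  expect_equal(ev$rho[ev$gene_id == "g1"], 1)
  expect_equal(ev$rho[ev$gene_id == "g2"], 0.8)
  expect_equal(ev$rho[ev$gene_id == "g3"], -1)
  expect_equal(ev$rho[ev$gene_id == "g4"], 0)     # constant prediction
  expect_true(ev$degenerate[ev$gene_id == "g4"])
  expect_equal(ev$significant, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("performance comparison restricts means to the gene intersection", {
  ev <- rbind(
    data.frame(gene_id = c("a", "b", "c"), algorithm = "en", population = "P1",
               rho = c(0.3, 0.2, 0.5), significant = TRUE, degenerate = FALSE),
    data.frame(gene_id = c("a", "b"), algorithm = "rf", population = "P1",
               rho = c(0.25, 0.4), significant = TRUE, degenerate = FALSE))
  cmp <- compare_performance(ev)
  # paired algorithm comparison restricts to the genes the pair shares
  pa <- cmp$paired_algorithms
  expect_equal(pa$n_genes, 2)                       # gene c drops out
  expect_equal(pa$mean_1, mean(c(0.3, 0.2)))        # en over shared genes
  expect_equal(pa$mean_2, mean(c(0.25, 0.4)))
  expect_equal(pa$mean_diff, pa$mean_1 - pa$mean_2)
  # identical sets give mean difference 0 and a zero-variance flag
  ev2 <- rbind(ev[1:3, ], transform(ev[1:3, ], algorithm = "rf"))
  cmp2 <- compare_performance(ev2)
  expect_equal(cmp2$paired_algorithms$mean_diff, 0)
  expect_true(cmp2$paired_algorithms$zero_variance)
  # overlap counts at the rho > 0.1 heuristic
  expect_equal(cmp$overlap$overlap, 2)
  expect_equal(cmp$overlap$unique_1, 1)

  # population contrast: per-method intersection across populations
  ev3 <- rbind(
    data.frame(gene_id = c("a", "b", "c"), algorithm = "en",
               population = "NEAR", rho = c(0.5, 0.4, 0.3),
               significant = TRUE, degenerate = FALSE),
    data.frame(gene_id = c("b", "c", "d"), algorithm = "en",
               population = "FAR", rho = c(0.2, 0.1, 0.6),
               significant = TRUE, degenerate = FALSE))
  cmp3 <- compare_performance(ev3)
  mr <- cmp3$mean_rho_by_population
  expect_equal(mr$n_genes, rep(2, 2))               # genes b, c
  expect_equal(mr$mean_rho[mr$population == "NEAR"], mean(c(0.4, 0.3)))
  expect_equal(mr$mean_rho[mr$population == "FAR"], mean(c(0.2, 0.1)))
  expect_equal(cmp3$welch_populations$p_value,
               t.test(c(0.4, 0.3), c(0.2, 0.1))$p.value)
})

test_that("pooling a diverged population into training adds little over the matched population alone", {
  pops <- list(population_spec("NEAR", 60, 0), population_spec("FAR", 60, 0.32),
               population_spec("TEST", 200, 0))
  co <- simulate_cohort(pops, n_genes = 40, n_variants_per_gene = 12,
                        h2_range = c(0.2, 0.5), seed = 91)
  obs <- hidden_factor_adjust(co$expression$TEST,
          adjustment_spec(n_hidden_factors = 10, final = "rank-normal"))$values
  near <- co$genotypes$NEAR
  pooled_g <- bind_samples(near[1:30, ], co$genotypes$FAR[1:30, ])
  pooled_e <- cbind(co$expression$NEAR[, 1:30], co$expression$FAR[, 1:30])
  eval_one <- function(g, e, label) {
    db <- train_cohort(g, e, co$annotation, algorithms = "en", seed = 5)
    pr <- predict_cohort(db, co$genotypes$TEST, min_cv_r2 = 0.01)
    spearman_eval(pr$predictions$en, obs, "en", label)
  }
  evn <- eval_one(near, co$expression$NEAR, "NEARONLY")
  evp <- eval_one(pooled_g, pooled_e, "POOLED")
  # equal-size pooled training performs the same as matched-only training
  expect_gt(t.test(evn$rho, evp$rho)$p.value, 0.05)
  expect_lt(abs(mean(evn$rho) - mean(evp$rho)), 0.1)
})

test_that("mean test rho decreases as the training population diverges", {
  pops <- list(population_spec("T0", 100, 0, ld_offset = 0),
               population_spec("T1", 100, 0.16, ld_offset = 1),
               population_spec("T2", 100, 0.32, ld_offset = 2),
               population_spec("TEST", 300, 0, ld_offset = 0))
  co <- simulate_cohort(pops, n_genes = 50, n_variants_per_gene = 20,
                        h2_range = c(0.25, 0.6), ld_block_size = 5,
                        ld_fidelity = 0.95, hide_causal = TRUE, seed = 92)
  obs <- hidden_factor_adjust(co$expression$TEST,
          adjustment_spec(n_hidden_factors = 10, final = "rank-normal"))$values
  ms <- vapply(c("T0", "T1", "T2"), function(p) {
    db <- train_cohort(co$genotypes[[p]], co$expression[[p]], co$annotation,
                       algorithms = "en", seed = 5)
    pr <- predict_cohort(db, co$genotypes$TEST, min_cv_r2 = 0.01)
    mean(spearman_eval(pr$predictions$en, obs, "en", p)$rho)
  }, numeric(1))
  expect_true(all(diff(ms) <= 0))
})
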