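#' Harmonize a test cohort's genotypes to a trained model's variant set
#'
#' Variants are matched by chromosome and 1-based position. Matching ref/alt
#' alleles use the test dosage directly; swapped ref/alt use `2 - dosage`;
#' strand-ambiguous (A/T, C/G) model variants are dropped; variants absent
#' from the test cohort or with irreconcilable alleles are filled with the
#' model's stored training mean dosage (so their contribution sits at the
#' training average). Sporadic missing dosages are likewise mean-filled.
#'
#' @param model a `gene_model`.
#' @param test_g a [geno_matrix()] for the test cohort.
#' @param max_missing_frac skip the model (with a warning, returning `NULL`)
#'   when more than this fraction of its variants is missing from the test
#'   cohort.
#' @return List with `X` (test-sample x model-variant feature matrix, columns
#'   in model order) and `report` (per-variant status data.frame with
#'   statuses `match`, `allele-swap`, `ambiguous-dropped`, `mismatch-dropped`,
#'   `missing-imputed`), or `NULL` when skipped.
#' @export
harmonize <- function(model, test_g, max_missing_frac = 0.5) {
  mv <- model$variants
  key_m <- paste(mv$chrom, mv$pos)
  key_t <- paste(test_g$variants$chrom, test_g$variants$pos)
  hit <- match(key_m, key_t)
  n <- length(test_g$samples)
  X <- matrix(rep(mv$mean_dosage, each = n), nrow = n,
              dimnames = list(test_g$samples, mv$id))
  status <- rep("missing-imputed", nrow(mv))
  for (i in seq_len(nrow(mv))) {
    j <- hit[i]
    if (is.na(j)) next
    if (is_ambiguous_pair(mv$ref[i], mv$alt[i])) {
      status[i] <- "ambiguous-dropped"
      next
    }
    tr <- test_g$variants$ref[j]; ta <- test_g$variants$alt[j]
    d <- test_g$dosages[, j]
    if (tr == mv$ref[i] && ta == mv$alt[i]) {
      status[i] <- "match"
    } else if (tr == mv$alt[i] && ta == mv$ref[i]) {
      status[i] <- "allele-swap"
      d <- 2 - d
    } else {
      status[i] <- "mismatch-dropped"
      next
    }
    d[is.na(d)] <- mv$mean_dosage[i]
    X[, i] <- d
  }
  n_missing <- sum(status %in% c("missing-imputed", "mismatch-dropped",
                                 "ambiguous-dropped"))
  if (n_missing > max_missing_frac * nrow(mv)) {
    warn2("model ", model$gene_id, " [", model$algorithm, "]: ",
          n_missing, "/", nrow(mv), " variants unusable in test cohort; skipped")
    return(NULL)
  }
  list(X = X,
       report = data.frame(id = mv$id, status = status,
                           stringsAsFactors = FALSE))
}

#' Predict expression for a test cohort from a model collection
#'
#' Applies only models whose cross-validated mean R-squared exceeds
#' `min_cv_r2` (the inclusion rule used for independent-cohort prediction),
#' harmonizing each model's variant set to the test genotypes first.
#'
#' @param db a `model_db`.
#' @param test_g a [geno_matrix()].
#' @param min_cv_r2 inclusion threshold on cv mean R-squared (strict).
#' @param algorithms optional subset of algorithms.
#' @return List with `predictions` (named list per algorithm of gene x
#'   sample matrices) and `harmonization` (per gene/algorithm status counts).
#' @export
predict_cohort <- function(db, test_g, min_cv_r2 = 0.01, algorithms = NULL) {
  res <- db$results[!db$results$failed & db$results$mean_cv_r2 > min_cv_r2, ]
  if (!is.null(algorithms)) res <- res[res$algorithm %in% algorithms, ]
  if (nrow(res) == 0) stop2("no models exceed min_cv_r2 = ", min_cv_r2)
  out <- list(); hrows <- list()
  for (alg in unique(res$algorithm)) {
    genes <- res$gene_id[res$algorithm == alg]
    preds <- matrix(NA_real_, length(genes), length(test_g$samples),
                    dimnames = list(genes, test_g$samples))
    keep <- logical(length(genes))
    for (i in seq_along(genes)) {
      m <- db$models[[genes[i]]][[alg]]
      h <- harmonize(m, test_g)
      if (is.null(h)) next
      preds[i, ] <- predict(m, h$X)
      keep[i] <- TRUE
      tab <- table(factor(h$report$status,
                          levels = c("match", "allele-swap", "ambiguous-dropped",
                                     "mismatch-dropped", "missing-imputed")))
      hrows[[length(hrows) + 1]] <-
        data.frame(gene_id = genes[i], algorithm = alg, t(as.matrix(tab)),
                   check.names = FALSE, stringsAsFactors = FALSE)
    }
    out[[alg]] <- preds[keep, , drop = FALSE]
  }
  list(predictions = out,
       harmonization = if (length(hrows)) do.call(rbind, hrows) else NULL)
}

#' Evaluate predictions against observed expression by Spearman correlation
#'
#' Tie-corrected Spearman rho per gene between predicted and observed test
#' expression, with a significance flag at `rho > 0.1` (a conventional
#' heuristic, not a formal test). Constant predictions get rho 0 and a
#' degenerate flag.
#'
#' @param pred gene x sample predicted expression.
#' @param obs gene x sample observed (adjusted) expression.
#' @param algorithm,population labels attached to the result rows.
#' @param rho_sig significance heuristic threshold.
#' @return data.frame with `gene_id`, `algorithm`, `population`, `rho`,
#'   `significant`, `degenerate`.
#' @export
spearman_eval <- function(pred, obs, algorithm = NA_character_,
                          population = NA_character_, rho_sig = 0.1) {
  common_s <- intersect(colnames(pred), colnames(obs))
  if (length(common_s) < 3) stop2("need >= 3 common samples")
  genes <- intersect(rownames(pred), rownames(obs))
  rho <- vapply(genes, function(g) {
    p <- pred[g, common_s]
    if (stats::sd(p) == 0) return(NA_real_)
    cor(p, obs[g, common_s], method = "spearman")
  }, numeric(1))
  degenerate <- is.na(rho)
  rho[degenerate] <- 0
  data.frame(gene_id = genes, algorithm = algorithm, population = population,
             rho = rho, significant = rho > rho_sig, degenerate = degenerate,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare prediction performance across algorithms and training populations
#'
#' From a stacked set of [spearman_eval()] results, computes the four
#' comparison tables of a cross-population evaluation:
#' * `mean_rho_by_population`: per algorithm, mean rho per training
#'   population over the genes that algorithm predicted in every population
#'   (per-method intersection across populations).
#' * `welch_populations`: Welch two-sample t tests between training
#'   populations within each algorithm, on the same per-method intersection.
#' * `paired_algorithms`: paired t tests between algorithm pairs within each
#'   population, on the genes the pair shares there.
#' * `overlap`: overlap/unique gene counts between algorithm pairs among
#'   genes with rho above the significance heuristic.
#'
#' @param evals data.frame of stacked evaluation rows.
#' @param rho_sig threshold used for the overlap counts.
#' @return List with `mean_rho_by_population`, `welch_populations`,
#'   `paired_algorithms` and `overlap`.
#' @export
compare_performance <- function(evals, rho_sig = 0.1) {
  conds <- unique(evals[, c("algorithm", "population")])
  if (nrow(conds) < 2) stop2("need >= 2 algorithm or population conditions")
  algs <- unique(evals$algorithm)
  pops <- unique(evals$population)

  sub_rho <- function(alg, popn, genes) {
    s <- evals[evals$algorithm == alg & evals$population == popn, ]
    s <- s[match(genes, s$gene_id), ]
    s$rho
  }

  # per-method intersection across populations (Table-3 protocol)
  mean_rows <- list(); welch <- list()
  for (alg in algs) {
    sets <- lapply(pops, function(popn)
      evals$gene_id[evals$algorithm == alg & evals$population == popn])
    inter <- Reduce(intersect, sets)
    if (length(inter) == 0) {
      stop2("empty gene intersection across populations for algorithm ", alg)
    }
    for (popn in pops) {
      mean_rows[[length(mean_rows) + 1]] <- data.frame(
        algorithm = alg, population = popn,
        mean_rho = mean(sub_rho(alg, popn, inter)),
        n_genes = length(inter), stringsAsFactors = FALSE)
    }
    if (length(pops) >= 2) {
      for (a in seq_along(pops)) for (b in seq_along(pops)) {
        if (b <= a) next
        x <- sub_rho(alg, pops[a], inter); y <- sub_rho(alg, pops[b], inter)
        welch[[length(welch) + 1]] <- data.frame(
          algorithm = alg, population_1 = pops[a], population_2 = pops[b],
          mean_1 = mean(x), mean_2 = mean(y), n_genes = length(inter),
          p_value = t.test(x, y)$p.value, stringsAsFactors = FALSE)
      }
    }
  }

  # pairwise algorithm comparisons within population (Table-4/5 protocol)
  paired <- list(); overlap <- list()
  for (popn in pops) {
    pop_algs <- unique(evals$algorithm[evals$population == popn])
    if (length(pop_algs) < 2) next
    for (a in seq_along(pop_algs)) for (b in seq_along(pop_algs)) {
      if (b <= a) next
      s1 <- evals$gene_id[evals$algorithm == pop_algs[a] &
                            evals$population == popn]
      s2 <- evals$gene_id[evals$algorithm == pop_algs[b] &
                            evals$population == popn]
      shared <- intersect(s1, s2)
      if (length(shared) >= 2) {
        x <- sub_rho(pop_algs[a], popn, shared)
        y <- sub_rho(pop_algs[b], popn, shared)
        d <- x - y
        pv <- if (stats::sd(d) == 0) NA_real_
              else t.test(x, y, paired = TRUE)$p.value
        paired[[length(paired) + 1]] <- data.frame(
          population = popn, algorithm_1 = pop_algs[a],
          algorithm_2 = pop_algs[b], mean_1 = mean(x), mean_2 = mean(y),
          mean_diff = mean(d), n_genes = length(shared), p_value = pv,
          zero_variance = stats::sd(d) == 0, stringsAsFactors = FALSE)
      }
      sig <- evals[evals$population == popn & evals$rho > rho_sig, ]
      g1 <- sig$gene_id[sig$algorithm == pop_algs[a]]
      g2 <- sig$gene_id[sig$algorithm == pop_algs[b]]
      overlap[[length(overlap) + 1]] <- data.frame(
        population = popn, algorithm_1 = pop_algs[a],
        algorithm_2 = pop_algs[b], overlap = length(intersect(g1, g2)),
        unique_1 = length(setdiff(g1, g2)),
        unique_2 = length(setdiff(g2, g1)), stringsAsFactors = FALSE)
    }
  }

  list(mean_rho_by_population = do.call(rbind, mean_rows),
       welch_populations = if (length(welch)) do.call(rbind, welch) else NULL,
       paired_algorithms = if (length(paired)) do.call(rbind, paired) else NULL,
       overlap = if (length(overlap)) do.call(rbind, overlap) else NULL)
}
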