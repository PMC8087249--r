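#' Population specification for the cohort simulator
#'
#' Describes one simulated population: its label, sample size and its
#' Balding-Nichols divergence parameter F (often written FST) from the shared
#' ancestral population. F = 0 means the population's allele frequencies
#' equal the ancestral frequencies exactly; larger F means stronger drift.
#'
#' @param name population label.
#' @param n_samples number of individuals (>= 1).
#' @param fst divergence parameter in `[0, 1)`.
#' @param ld_offset shift (in variants) of this population's
#'   linkage-disequilibrium block boundaries relative to the shared layout.
#'   Populations with equal offsets share one tagging structure; a non-zero
#'   offset emulates the differing haplotype structure of a diverged
#'   population. Only meaningful when the cohort simulates LD blocks.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, n_samples, fst = 0, ld_offset = 0) {
  if (n_samples < 1) stop2("n_samples must be >= 1")
  if (fst < 0 || fst >= 1) stop2("fst must lie in [0, 1)")
  structure(list(name = as.character(name), n_samples = as.integer(n_samples),
                 fst = as.numeric(fst), ld_offset = as.integer(ld_offset)),
            class = "population_spec")
}

#' Draw per-population allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies p are drawn uniformly on `ancestral_range`; each
#' population's frequency is drawn from a Beta distribution with mean p and
#' variance `fst * p * (1 - p)` (shape parameters `p (1 - F) / F` and
#' `(1 - p)(1 - F) / F`). Populations with `fst = 0` copy the ancestral
#' frequency exactly.
#'
#' @param n_variants number of variants.
#' @param ancestral_range length-2 numeric interval strictly inside (0, 1).
#' @param pops list of [population_spec()] objects.
#' @param seed integer seed.
#' @return A list with `ancestral` (numeric vector) and `freqs` (named list
#'   of per-population frequency vectors).
#' @export
draw_population_freqs <- function(n_variants, ancestral_range = c(0.05, 0.95),
                                  pops, seed) {
  if (length(pops) == 0) stop2("pops must be non-empty")
  if (ancestral_range[1] <= 0 || ancestral_range[2] >= 1 ||
      ancestral_range[1] >= ancestral_range[2]) {
    stop2("ancestral_range must be an interval within (0, 1)")
  }
  fsts <- vapply(pops, `[[`, numeric(1), "fst")
  if (any(fsts < 0 | fsts >= 1)) stop2("fst must lie in [0, 1)")
  with_seed(seed, {
    p <- runif(n_variants, ancestral_range[1], ancestral_range[2])
    freqs <- lapply(pops, function(pop) {
      if (pop$fst == 0) return(p)
      f <- pop$fst
      q <- rbeta(n_variants, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      # guard against numerical under/overflow at extreme ancestral p
      pmin(pmax(q, 0), 1)
    })
    names(freqs) <- vapply(pops, `[[`, character(1), "name")
    list(ancestral = p, freqs = freqs)
  })
}

#' Simulate unlinked genotypes from allele frequencies
#'
#' Each dosage is the sum of two independent Bernoulli draws at the variant's
#' allele frequency (Hardy-Weinberg sampling), so dosages lie in {0, 1, 2}.
#' Variant metadata is synthesized on one chromosome with 1-based positions;
#' a configurable fraction of variants receives a strand-ambiguous (A/T or
#' C/G) allele pair so downstream ambiguity filters have work to do.
#'
#' @param freqs allele-frequency vector, all in `[0, 1]`.
#' @param n_samples number of individuals.
#' @param seed integer seed.
#' @param positions optional 1-based positions (default: evenly spaced).
#' @param chrom chromosome label.
#' @param ambiguous_frac fraction of variants given a palindromic allele pair.
#' @param missing_rate optional fraction of dosages set missing (NA), to
#'   exercise call-rate filtering.
#' @param sample_prefix prefix for synthesized sample labels.
#' @param alleles optional data.frame with columns `ref`, `alt` (one row per
#'   variant); supplied when several populations must share one allele
#'   labeling, drawn at random otherwise.
#' @return A [geno_matrix()].
#' @export
simulate_genotypes <- function(freqs, n_samples, seed, positions = NULL,
                               chrom = "1", ambiguous_frac = 0.1,
                               missing_rate = 0, sample_prefix = "S",
                               alleles = NULL) {
  if (any(freqs < 0 | freqs > 1)) stop2("freqs must lie in [0, 1]")
  m <- length(freqs)
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  with_seed(seed, {
    dos <- matrix(rbinom(n_samples * m, 2L, rep(freqs, each = n_samples)),
                  nrow = n_samples, ncol = m)
    pick <- if (is.null(alleles)) draw_allele_pairs(m, ambiguous_frac)
            else cbind(alleles$ref, alleles$alt)
    if (missing_rate > 0) {
      dos[runif(length(dos)) < missing_rate] <- NA_real_
    }
    variants <- data.frame(chrom = chrom, pos = as.integer(positions),
                           id = paste0("var_", chrom, "_", positions),
                           ref = pick[, 1], alt = pick[, 2],
                           stringsAsFactors = FALSE)
    ord <- order(variants$pos)
    geno_matrix(dos[, ord, drop = FALSE] * 1.0, variants[ord, ],
                samples = sprintf("%s%04d", sample_prefix, seq_len(n_samples)))
  })
}

# Allele pairs: non-ambiguous by default, palindromic (A/T, C/G) for a
# chosen fraction. Uses the current RNG stream.
draw_allele_pairs <- function(m, ambiguous_frac) {
  non_amb <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"))
  amb <- rbind(c("A", "T"), c("C", "G"), c("T", "A"), c("G", "C"))
  pick <- non_amb[sample.int(nrow(non_amb), m, replace = TRUE), , drop = FALSE]
  n_amb <- round(ambiguous_frac * m)
  if (n_amb > 0) {
    idx <- sample.int(m, n_amb)
    pick[idx, ] <- amb[sample.int(nrow(amb), n_amb, replace = TRUE), , drop = FALSE]
  }
  pick
}

#' Simulate genotypes in linkage-disequilibrium blocks
#'
#' Variants are grouped into consecutive blocks of `block_size`. For each
#' block and sample, one shared uniform draw per haplotype is made; each
#' variant's allele uses the shared draw with probability `fidelity` (a
#' fresh uniform otherwise) and codes the allele as `u < f_j` at the
#' variant's own frequency. Each variant therefore keeps its exact marginal
#' Binomial(2, f_j) Hardy-Weinberg distribution — so allele-frequency
#' divergence between populations is untouched by the block structure —
#' while block-mates correlate at r approximately `fidelity^2`, giving the
#' tag-redundancy structure of real cis windows.
#'
#' @param freqs per-block (recycled to per-variant) allele frequencies.
#' @param n_samples individuals.
#' @param seed integer seed.
#' @param block_size variants per LD block; 1 gives independent variants.
#' @param fidelity per-allele copy probability within a block, in `[0, 1]`.
#' @param block_offset shift of the block boundaries in variants; two
#'   populations simulated with different offsets have different tagging
#'   (who correlates with whom), emulating population-specific haplotype
#'   structure.
#' @inheritParams simulate_genotypes
#' @return A [geno_matrix()].
#' @export
simulate_ld_genotypes <- function(freqs, n_samples, seed, block_size = 1,
                                  fidelity = 0.9, block_offset = 0,
                                  positions = NULL,
                                  chrom = "1", ambiguous_frac = 0.1,
                                  missing_rate = 0, sample_prefix = "S",
                                  alleles = NULL) {
  if (block_size <= 1) {
    return(simulate_genotypes(freqs, n_samples, seed, positions, chrom,
                              ambiguous_frac, missing_rate, sample_prefix,
                              alleles))
  }
  m <- length(freqs)
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  blocks <- (seq_len(m) + block_offset - 1L) %/% block_size
  with_seed(seed, {
    dos <- matrix(0, n_samples, m)
    for (b in unique(blocks)) {
      idx <- which(blocks == b)
      u1 <- runif(n_samples)
      u2 <- runif(n_samples)
      for (j in idx) {
        use1 <- runif(n_samples) < fidelity
        use2 <- runif(n_samples) < fidelity
        a1 <- ifelse(use1, u1, runif(n_samples)) < freqs[j]
        a2 <- ifelse(use2, u2, runif(n_samples)) < freqs[j]
        dos[, j] <- as.numeric(a1) + as.numeric(a2)
      }
    }
    pick <- if (is.null(alleles)) draw_allele_pairs(m, ambiguous_frac)
            else cbind(alleles$ref, alleles$alt)
    if (missing_rate > 0) dos[runif(length(dos)) < missing_rate] <- NA_real_
    variants <- data.frame(chrom = chrom, pos = as.integer(positions),
                           id = paste0("var_", chrom, "_", positions),
                           ref = pick[, 1], alt = pick[, 2],
                           stringsAsFactors = FALSE)
    ord <- order(variants$pos)
    geno_matrix(dos[, ord, drop = FALSE] * 1.0, variants[ord, ],
                samples = sprintf("%s%04d", sample_prefix, seq_len(n_samples)))
  })
}

#' cis-eQTL architecture of one gene
#'
#' @param gene_id gene label.
#' @param causal_variant_ids variant ids carrying effects.
#' @param effect_sizes per-causal effect weights (same length).
#' @param model_form one of `"additive-linear"`, `"pairwise-interaction"`,
#'   `"threshold-nonlinear"`.
#' @param h2 proportion of expression variance explained by the genetic
#'   value, in `[0, 1]`.
#' @return An object of class `eqtl_architecture`.
#' @export
eqtl_architecture <- function(gene_id, causal_variant_ids, effect_sizes,
                              model_form = c("additive-linear",
                                             "pairwise-interaction",
                                             "threshold-nonlinear"),
                              h2) {
  model_form <- match.arg(model_form)
  if (length(causal_variant_ids) != length(effect_sizes)) {
    stop2("causal_variant_ids and effect_sizes must have equal length")
  }
  if (h2 < 0 || h2 > 1) stop2("h2 must lie in [0, 1]")
  structure(list(gene_id = as.character(gene_id),
                 causal_variant_ids = as.character(causal_variant_ids),
                 effect_sizes = as.numeric(effect_sizes),
                 model_form = model_form, h2 = as.numeric(h2)),
            class = "eqtl_architecture")
}

# Genetic value of one gene given causal dosages (samples x causals matrix).
# The pairwise-interaction form is a weak additive backbone plus products of
# mean-centered causal dosage pairs: centering removes the marginal (linear)
# component of the product, so the interaction is genuinely epistatic rather
# than additivity in disguise.
genetic_value <- function(arch, X) {
  b <- arch$effect_sizes
  if (arch$model_form == "pairwise-interaction" && ncol(X) >= 2) {
    Xc <- sweep(X, 2, colMeans(X))
    g <- rep(0, nrow(X))
    for (j in seq_len(ncol(X) - 1)) {
      g <- g + b[j] * Xc[, j] * Xc[, j + 1]
    }
  } else if (arch$model_form == "threshold-nonlinear") {
    # indicator-thresholded (carrier) coding replaces the additive dose
    g <- as.vector((X >= 1) %*% b)
  } else {
    g <- as.vector(X %*% b)
  }
  g
}

#' Simulate expression from genotypes under known architectures
#'
#' Per gene, a genetic value g is computed from the causal dosages under the
#' gene's architecture; Gaussian noise is added with variance scaled so the
#' realized `Var(g) / Var(g + noise)` equals the architecture's h2; the
#' genetic-plus-noise core is then standardized to unit variance, and shared
#' hidden-factor contributions (per-sample Gaussian scores times per-gene
#' loadings, a stand-in for the batch/confounder structure PEER-type factors
#' absorb in real data) are added on top.
#'
#' @param genotypes a [geno_matrix()] holding all causal variants.
#' @param truth a `sim_truth` object (see [simulate_cohort()]).
#' @param n_hidden_factors number of shared hidden factors to add.
#' @param seed integer seed.
#' @return A list with `expression` (gene x sample matrix), `genetic`
#'   (gene x sample matrix of scaled genetic components) and `factor_scores`
#'   (sample x factor matrix).
#' @export
simulate_expression <- function(genotypes, truth, n_hidden_factors, seed) {
  archs <- truth$architectures
  n <- length(genotypes$samples)
  G <- length(archs)
  with_seed(seed, {
    scores <- if (n_hidden_factors > 0) {
      matrix(rnorm(n * n_hidden_factors), n, n_hidden_factors)
    } else {
      matrix(0, n, 0)
    }
    expr <- matrix(0, G, n, dimnames = list(names(archs), genotypes$samples))
    gen <- expr
    for (i in seq_len(G)) {
      arch <- archs[[i]]
      miss <- setdiff(arch$causal_variant_ids, genotypes$variants$id)
      if (length(miss)) stop2("causal variants absent from genotypes: ",
                              paste(miss, collapse = ", "))
      X <- genotypes$dosages[, arch$causal_variant_ids, drop = FALSE]
      g <- genetic_value(arch, X)
      vg <- var(g)
      h2 <- arch$h2
      if (h2 == 1 && vg == 0) stop2("h2 = 1 with zero-variance genetic value for ",
                                    arch$gene_id)
      if (h2 == 0 || vg == 0) {
        core <- rnorm(n)
        gshare <- rep(0, n)
      } else if (h2 == 1) {
        core <- g / sd(g)
        gshare <- core
      } else {
        noise <- rnorm(n, sd = sqrt(vg * (1 - h2) / h2))
        core <- g + noise
        s <- sd(core)
        core <- core / s
        gshare <- g / s
      }
      contrib <- if (n_hidden_factors > 0) {
        as.vector(scores %*% truth$hidden_factor_loadings[i, seq_len(n_hidden_factors)])
      } else {
        0
      }
      expr[i, ] <- core + contrib
      gen[i, ] <- gshare
    }
    list(expression = expr, genetic = gen, factor_scores = scores)
  })
}

#' Simulate a quantitative trait from one gene's genetic expression component
#'
#' `phenotype = trait_effect * genetic_value + N(0, noise_sd^2)`. A negative
#' `trait_effect` reproduces the decreased-trait-with-increased-expression
#' direction seen for lipid-gene associations.
#'
#' @param expression_genetic_values per-sample genetic component of the trait
#'   gene's expression.
#' @param trait_effect regression effect of the genetic value on the trait.
#' @param noise_sd positive residual standard deviation.
#' @param seed integer seed.
#' @return Named numeric vector of phenotypes.
#' @export
simulate_phenotype <- function(expression_genetic_values, trait_effect,
                               noise_sd, seed) {
  if (noise_sd <= 0) stop2("noise_sd must be > 0")
  with_seed(seed, {
    y <- trait_effect * expression_genetic_values +
      rnorm(length(expression_genetic_values), sd = noise_sd)
    names(y) <- names(expression_genetic_values)
    y
  })
}

#' Simulate a multi-population cohort with known truth
#'
#' Lays `n_genes` genes along one chromosome, places `n_variants_per_gene`
#' variants inside each gene's cis window (gene span +/- `window_bp`), draws
#' per-population allele frequencies under the Balding-Nichols model, assigns
#' each gene a sparse cis-eQTL architecture (mixture of additive-linear,
#' pairwise-interaction and threshold-nonlinear forms) at a heritability
#' drawn from `h2_range`, simulates expression with shared hidden factors,
#' and derives a quantitative trait from one causal gene's genetic expression
#' component.
#'
#' Defaults emulate the structure of a multi-ancestry monocyte eQTL training
#' design: a few populations at graded divergence, sparse large-effect cis
#' signals, moderate heritability, ten hidden confounding factors, and a
#' negative trait effect.
#'
#' @param pops list of [population_spec()] objects.
#' @param n_genes number of genes.
#' @param n_variants_per_gene cis variants placed per gene.
#' @param n_causal_range integer range of causal variants per gene.
#' @param h2_range heritability range (drawn uniformly per gene).
#' @param architecture_mix named proportions for the three model forms.
#' @param n_hidden_factors shared hidden confounders.
#' @param loading_sd standard deviation of per-gene factor loadings (relative
#'   to the unit-variance expression core).
#' @param trait_gene gene carrying the trait effect (default: first
#'   additive-linear gene).
#' @param trait_effect effect of that gene's genetic value on the trait.
#' @param trait_noise_sd residual SD of the trait.
#' @param ld_block_size variants per linkage-disequilibrium block (1 =
#'   independent variants); see [simulate_ld_genotypes()].
#' @param ld_fidelity within-block allele copy probability.
#' @param hide_causal when `TRUE`, causal variants drive expression but are
#'   excluded from the returned genotype matrices, so prediction models must
#'   rely on linked tag variants — the situation of real cis windows, where
#'   the causal regulatory variant is rarely genotyped directly. Requires
#'   `ld_block_size > 1` to leave informative tags behind.
#' @param ambiguous_frac fraction of strand-ambiguous variants.
#' @param missing_rate fraction of dosages set missing.
#' @param gene_length gene span in bp.
#' @param gene_spacing distance between gene starts in bp.
#' @param window_bp cis window half-width.
#' @param ancestral_range ancestral allele-frequency interval.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return An object of class `sim_cohort`: list with `genotypes` (named list
#'   of [geno_matrix()] per population), `expression`, `genetic` (gene x
#'   sample matrices per population), `phenotype` (per population),
#'   `annotation` (gene spans), `truth` (class `sim_truth`) and `seed`.
#' @export
simulate_cohort <- function(pops,
                            n_genes = 50,
                            n_variants_per_gene = 45,
                            n_causal_range = c(1L, 4L),
                            h2_range = c(0.05, 0.3),
                            architecture_mix = c("additive-linear" = 0.7,
                                                 "pairwise-interaction" = 0.2,
                                                 "threshold-nonlinear" = 0.1),
                            n_hidden_factors = 10,
                            loading_sd = 0.2,
                            trait_gene = NULL,
                            trait_effect = -0.5,
                            trait_noise_sd = 1,
                            ld_block_size = 1,
                            ld_fidelity = 0.9,
                            hide_causal = FALSE,
                            ambiguous_frac = 0.1,
                            missing_rate = 0,
                            gene_length = 1e4,
                            gene_spacing = 2.5e6,
                            window_bp = 1e6,
                            ancestral_range = c(0.05, 0.95),
                            seed = 1L) {
  if (length(pops) == 0) stop2("at least one population required")
  pop_names <- vapply(pops, `[[`, character(1), "name")

  # gene layout: spaced so cis windows may overlap but stay at positive bp
  starts <- window_bp + 1 + (seq_len(n_genes) - 1) * gene_spacing
  annotation <- data.frame(gene_id = sprintf("gene_%03d", seq_len(n_genes)),
                           chrom = "1", start = starts,
                           end = starts + gene_length - 1,
                           stringsAsFactors = FALSE)

  layout <- with_seed(derive_seed(seed, 1L), {
    pos <- unlist(lapply(seq_len(n_genes), function(i) {
      lo <- max(1, annotation$start[i] - window_bp)
      hi <- annotation$end[i] + window_bp
      sort(sample(seq(lo, hi), n_variants_per_gene))
    }))
    unique(sort(pos))
  })
  m <- length(layout)

  fr <- draw_population_freqs(m, ancestral_range, pops, derive_seed(seed, 2L))
  # one allele labeling shared by every population
  shared_alleles <- with_seed(derive_seed(seed, 4L), {
    pk <- draw_allele_pairs(m, ambiguous_frac)
    data.frame(ref = pk[, 1], alt = pk[, 2], stringsAsFactors = FALSE)
  })
  genotypes <- list()
  for (k in seq_along(pops)) {
    genotypes[[pop_names[k]]] <- simulate_ld_genotypes(
      fr$freqs[[k]], pops[[k]]$n_samples, derive_seed(seed, 10L + k),
      block_size = ld_block_size, fidelity = ld_fidelity,
      block_offset = pops[[k]]$ld_offset %||% 0L,
      positions = layout, chrom = "1", ambiguous_frac = ambiguous_frac,
      missing_rate = missing_rate,
      sample_prefix = paste0(pop_names[k], "_"), alleles = shared_alleles)
  }
  variants <- genotypes[[1]]$variants

  # architectures: causal variants drawn from each gene's own cis window
  truth <- with_seed(derive_seed(seed, 3L), {
    forms <- sample(names(architecture_mix), n_genes, replace = TRUE,
                    prob = architecture_mix)
    archs <- lapply(seq_len(n_genes), function(i) {
      lo <- max(1, annotation$start[i] - window_bp)
      hi <- annotation$end[i] + window_bp
      cis_ids <- variants$id[variants$pos >= lo & variants$pos <= hi]
      nc_choices <- seq(n_causal_range[1], n_causal_range[2])
      nc <- nc_choices[sample.int(length(nc_choices), 1)]
      nc <- min(nc, length(cis_ids))
      ids <- sample(cis_ids, nc)
      eqtl_architecture(annotation$gene_id[i], ids, rnorm(nc),
                        model_form = forms[i],
                        h2 = runif(1, h2_range[1], h2_range[2]))
    })
    names(archs) <- annotation$gene_id
    loadings <- matrix(rnorm(n_genes * max(1, n_hidden_factors), sd = loading_sd),
                       nrow = n_genes,
                       dimnames = list(annotation$gene_id, NULL))
    tg <- trait_gene
    if (is.null(tg)) {
      lin <- names(archs)[vapply(archs, function(a)
        a$model_form == "additive-linear" && a$h2 > 0, logical(1))]
      tg <- if (length(lin)) lin[1] else names(archs)[1]
    }
    structure(list(architectures = archs, trait_gene = tg,
                   trait_effect = trait_effect,
                   hidden_factor_loadings = loadings),
              class = "sim_truth")
  })
  if (!truth$trait_gene %in% names(truth$architectures)) {
    stop2("trait_gene not among simulated genes")
  }

  expression <- list(); genetic <- list(); phenotype <- list()
  for (k in seq_along(pops)) {
    # expression simulation needs complete causal dosages; fill sporadic
    # missing entries with the variant mean for the generative step only
    gk <- genotypes[[pop_names[k]]]
    if (missing_rate > 0) {
      dd <- gk$dosages
      mu <- colMeans(dd, na.rm = TRUE)
      idx <- which(is.na(dd), arr.ind = TRUE)
      if (nrow(idx)) dd[idx] <- mu[idx[, 2]]
      gk <- geno_matrix(dd, gk$variants, gk$samples)
    }
    sim <- simulate_expression(gk, truth, n_hidden_factors,
                               derive_seed(seed, 20L + k))
    expression[[pop_names[k]]] <- sim$expression
    genetic[[pop_names[k]]] <- sim$genetic
    phenotype[[pop_names[k]]] <- simulate_phenotype(
      sim$genetic[truth$trait_gene, ], trait_effect, trait_noise_sd,
      derive_seed(seed, 30L + k))
  }

  if (hide_causal) {
    if (ld_block_size <= 1) {
      stop2("hide_causal requires ld_block_size > 1 (otherwise no tags remain)")
    }
    causal <- unique(unlist(lapply(truth$architectures, `[[`,
                                   "causal_variant_ids")))
    for (popn in pop_names) {
      keep <- !(genotypes[[popn]]$variants$id %in% causal)
      genotypes[[popn]] <- genotypes[[popn]][, keep]
    }
  }

  structure(list(genotypes = genotypes, expression = expression,
                 genetic = genetic, phenotype = phenotype,
                 annotation = annotation, truth = truth, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  ns <- vapply(x$genotypes, function(g) length(g$samples), integer(1))
  cat(sprintf("sim_cohort: %d genes, %d variants, populations: %s\n",
              nrow(x$annotation), nrow(x$genotypes[[1]]$variants),
              paste(sprintf("%s (n=%d)", names(ns), ns), collapse = ", ")))
  cat("trait gene:", x$truth$trait_gene, "\n")
  invisible(x)
}

#' Inject duplicated samples into a genotype matrix
#'
#' Appends copies of randomly chosen samples (relabelled with a `_dup`
#' suffix), giving the relatedness screen known positives to find.
#'
#' @param g a [geno_matrix()].
#' @param n_pairs number of duplicates to inject.
#' @param seed integer seed.
#' @return A [geno_matrix()] with `n_pairs` extra samples.
#' @export
inject_duplicates <- function(g, n_pairs = 1, seed = 1L) {
  with_seed(seed, {
    idx <- sample.int(length(g$samples), n_pairs)
    geno_matrix(rbind(g$dosages, g$dosages[idx, , drop = FALSE]),
                g$variants,
                samples = c(g$samples, paste0(g$samples[idx], "_dup")))
  })
}

#' Hudson-type FST estimate between two populations
#'
#' Ratio-of-averages Hudson estimator from sample allele frequencies:
#' per-variant numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`,
#' denominator `p1(1-p2) + p2(1-p1)`; the estimate is the summed numerator
#' over the summed denominator.
#'
#' @param g1,g2 [geno_matrix()] objects over the same variants.
#' @return FST estimate (scalar).
#' @export
hudson_fst <- function(g1, g2) {
  p1 <- alt_freq(g1); p2 <- alt_freq(g2)
  n1 <- length(g1$samples) * 2; n2 <- length(g2$samples) * 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}
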