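test_that("r2_score implements the prediction coefficient of determination", {
  y <- c(0, 1, 2)
  expect_equal(r2_score(y, y), 1)
  expect_equal(r2_score(y, rep(mean(y), 3)), 0)
  expect_equal(r2_score(y, c(2, 1, 0)), -3)  # 1 - 8/2
  expect_error(r2_score(c(1, 1, 1), y), "constant")

  # matches an independent re-implementation on random vectors
  set.seed(2)
  for (i in 1:20) {
    yo <- rnorm(50); yp <- rnorm(50)
    ref <- 1 - sum((yo - yp)^2) / sum((yo - mean(yo))^2)
    expect_equal(r2_score(yo, yp), ref, tolerance = 1e-12)
  }
})

test_that("fold assignment balances sizes and is seed-deterministic", {
  expect_equal(as.integer(table(make_folds(10, 5, 1))), rep(2L, 5))
  sizes <- sort(as.integer(table(make_folds(233, 5, 3))), decreasing = TRUE)
  expect_equal(sizes, c(47L, 47L, 47L, 46L, 46L))
  expect_identical(make_folds(100, 5, 7), make_folds(100, 5, 7))
  expect_false(identical(make_folds(100, 5, 7), make_folds(100, 5, 8)))
  expect_error(make_folds(4, 5, 1), ">= k")
})

test_that("cis-window extraction uses a closed 1 Mb interval around the gene span", {
  ann <- data.frame(gene_id = "g1", chrom = "1", start = 2e6, end = 2.01e6)
  pos <- c(1e6,        # exactly start - 1 Mb: included
           1e6 - 1,    # one bp outside: excluded
           3.01e6,     # exactly end + 1 Mb: included
           3.01e6 + 1, # excluded
           2.005e6)    # inside the gene
  g <- tiny_geno(matrix(1, 3, 5), pos = as.integer(pos))
  cis <- extract_cis(g, ann, "g1", window_bp = 1e6)
  expect_setequal(cis$variant_ids, g$variants$id[c(1, 3, 5)])
  expect_error(extract_cis(g, ann, "nope"), "unknown gene")

  # random layout equals brute-force interval membership
  set.seed(12)
  pos2 <- sort(sample(1:6e6, 300))
  g2 <- tiny_geno(matrix(1, 3, 300), pos = pos2)
  cis2 <- extract_cis(g2, ann, "g1")
  expect_setequal(cis2$variant_ids,
                  g2$variants$id[pos2 >= 1e6 & pos2 <= 3.01e6])
})

test_that("elastic net recovers a strong single-SNP signal and names it dominant", {
  set.seed(6)
  n <- 200; p <- 11
  X <- matrix(rbinom(n * p, 2, 0.5), n, p)
  colnames(X) <- paste0("v", 1:p)
  y <- 1.5 * X[, 1] + rnorm(n, sd = 0.3)
  m <- train_en(X, y, seed = 4)
  expect_gt(m$cv$mean_r2, 0.9)
  expect_equal(which.max(abs(m$payload$weights)), 1L)
  # in-sample R2 at least the cv estimate for a well-fit gene
  expect_gte(r2_score(y, predict(m, X)) + 1e-8, m$cv$mean_r2)
})

test_that("elastic net shows no cross-validation optimism on pure noise", {
  set.seed(61)
  r2s <- replicate(30, {
    X <- matrix(rbinom(60 * 8, 2, 0.4), 60, 8)
    colnames(X) <- paste0("v", 1:8)
    train_en(X, rnorm(60), seed = sample.int(1e6, 1))$cv$mean_r2
  })
  expect_lte(mean(r2s), 0.01)
})

test_that("degenerate feature matrices fall back to an intercept-only model", {
  X <- matrix(0, 30, 3); colnames(X) <- paste0("v", 1:3)
  y <- rnorm(30)
  m <- train_en(X, y, seed = 1)
  expect_true(all(m$payload$weights == 0))
  expect_lte(m$cv$mean_r2, 0)
})

test_that("a single-point grid equals plain 5-fold cross-validation", {
  set.seed(9)
  X <- matrix(rbinom(80 * 5, 2, 0.5), 80, 5); colnames(X) <- paste0("v", 1:5)
  y <- 0.8 * X[, 2] + rnorm(80)
  grid <- hyper_grid("rf", n_trees = 200L)
  m <- train_gridsearch(X, y, grid, seed = 11)
  folds <- make_folds(80, 5, 11)
  # oracle: same per-fold forests via the same derived seeds
  ref <- mean(sapply(1:5, function(f) {
    tr <- folds != f
    df <- as.data.frame(X[tr, ]); names(df) <- paste0("f", 1:5)
    fit <- ranger::ranger(y = y[tr], x = df, num.trees = 200, mtry = 5,
                          num.threads = 1,
                          seed = grexml:::derive_seed(11, 100 + f))
    dfte <- as.data.frame(X[!tr, ]); names(dfte) <- names(df)
    r2_score(y[!tr], predict(fit, dfte, num.threads = 1)$predictions)
  }))
  expect_equal(m$cv$mean_r2, ref, tolerance = 1e-10)
  expect_equal(m$hyperparameters$n_trees, 200L)
})

test_that("grid-search selection equals exhaustive re-evaluation for SVR and KNN", {
  set.seed(14)
  n <- 60; p <- 5
  X <- matrix(rbinom(n * p, 2, 0.4), n, p); colnames(X) <- paste0("v", 1:p)
  y <- 0.7 * X[, 1] - 0.4 * X[, 3] + rnorm(n, sd = 0.8)
  grids <- list(
    hyper_grid("svr", kernel = c("linear", "radial"), cost = c(0.01, 0.5, 2)),
    hyper_grid("knn", k = c(3L, 7L, 15L)))
  for (grid in grids) {
    m <- train_gridsearch(X, y, grid, seed = 21)
    folds <- make_folds(n, 5, 21)
    oracle <- vapply(seq_len(nrow(grid$configs)), function(ci) {
      mean(sapply(1:5, function(f) {
        tr <- folds != f
        fitted <- grexml:::fit_config(grid$algorithm, grid$configs[ci, ],
                                      X[tr, , drop = FALSE], y[tr], 21)
        r2_score(y[!tr],
                 grexml:::predict_config(fitted, X[!tr, , drop = FALSE]))
      }))
    }, numeric(1))
    expect_equal(m$cv$grid_r2$mean_r2, oracle, tolerance = 1e-10)
    expect_equal(unlist(m$hyperparameters),
                 unlist(as.list(grid$configs[which.max(oracle), ])))
  }
})

test_that("grid-search cv estimates stay honest on pure noise", {
  set.seed(15)
  reps <- 12
  for (alg in c("svr", "knn")) {
    grid <- if (alg == "svr") {
      hyper_grid("svr", kernel = c("linear", "radial"), cost = c(0.01, 1))
    } else {
      hyper_grid("knn", k = c(5L, 15L, 25L))
    }
    r2s <- replicate(reps, {
      X <- matrix(rbinom(60 * 6, 2, 0.4), 60, 6)
      colnames(X) <- paste0("v", 1:6)
      train_gridsearch(X, rnorm(60), grid,
                       seed = sample.int(1e6, 1))$cv$mean_r2
    })
    expect_lte(mean(r2s), 0.05)
  }
})

test_that("cohort training is deterministic and its summary is monotone", {
  co <- small_cohort(n = 80, n_genes = 5)
  db1 <- train_cohort(co$genotypes$POP, co$expression$POP, co$annotation,
                      algorithms = c("en", "knn"), seed = 33)
  db2 <- train_cohort(co$genotypes$POP, co$expression$POP, co$annotation,
                      algorithms = c("en", "knn"), seed = 33)
  expect_equal(db1$results, db2$results)
  w1 <- db1$models[[1]]$en$payload$weights
  expect_identical(w1, db2$models[[1]]$en$payload$weights)

  tab <- model_summary_table(db1)
  counts <- as.matrix(tab[, -1])
  expect_true(all(counts[, -1] <= counts[, -ncol(counts)]))
})

test_that("mean cv R2 is invariant to gene order and sample relabeling", {
  co <- small_cohort(n = 70, n_genes = 4)
  g <- co$genotypes$POP; e <- co$expression$POP
  db <- train_cohort(g, e, co$annotation, algorithms = "en", seed = 5)
  # permute annotation rows (gene order)
  dbp <- train_cohort(g, e, co$annotation[rev(seq_len(nrow(co$annotation))), ],
                      algorithms = "en", seed = 5)
  expect_equal(sort(db$results$mean_cv_r2), sort(dbp$results$mean_cv_r2))
  # relabel samples consistently in genotypes and expression
  new <- paste0("X", g$samples)
  g2 <- geno_matrix(g$dosages, g$variants, samples = new)
  e2 <- e; colnames(e2) <- new
  db2 <- train_cohort(g2, e2, co$annotation, algorithms = "en", seed = 5)
  expect_equal(db$results$mean_cv_r2, db2$results$mean_cv_r2)
})
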