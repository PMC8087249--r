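#' Extract the cis-window feature matrix for one gene
#'
#' Selects variants with position in `[gene_start - window_bp,
#' gene_end + window_bp]` (closed interval) on the gene's chromosome and
#' returns their dosages as the model feature matrix.
#'
#' @param g a [geno_matrix()].
#' @param annotation data.frame with columns `gene_id`, `chrom`, `start`,
#'   `end`.
#' @param gene_id gene to extract.
#' @param window_bp window half-width in bp (default 1 Mb).
#' @return List with `gene_id`, `chrom`, `window_start`, `window_end`,
#'   `variant_ids` (ordered by position), and `X` (sample x variant dosage
#'   matrix; zero columns when the window is empty).
#' @export
extract_cis <- function(g, annotation, gene_id, window_bp = 1e6) {
  row <- annotation[annotation$gene_id == gene_id, , drop = FALSE]
  if (nrow(row) == 0) stop2("unknown gene: ", gene_id)
  lo <- max(1, row$start[1] - window_bp)
  hi <- row$end[1] + window_bp
  sel <- which(g$variants$chrom == row$chrom[1] &
                 g$variants$pos >= lo & g$variants$pos <= hi)
  sel <- sel[order(g$variants$pos[sel])]
  list(gene_id = gene_id, chrom = row$chrom[1], window_start = lo,
       window_end = hi, variant_ids = g$variants$id[sel],
       X = g$dosages[, sel, drop = FALSE])
}

#' Coefficient of determination (prediction R-squared)
#'
#' `1 - sum((y_obs - y_pred)^2) / sum((y_obs - mean(y_obs))^2)`. This is the
#' out-of-sample coefficient of determination, not a squared correlation: it
#' is unbounded below, and negative values flag models predicting worse than
#' the observed mean.
#'
#' @param y_obs observed values (non-constant, length >= 2).
#' @param y_pred predicted values (same length).
#' @return R-squared (scalar, <= 1).
#' @export
r2_score <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred)) stop2("lengths differ")
  if (length(y_obs) < 2) stop2("need at least 2 observations")
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  if (ss_tot == 0) stop2("y_obs is constant; R2 undefined")
  1 - sum((y_obs - y_pred)^2) / ss_tot
}

#' Seeded k-fold assignment
#'
#' Random partition into k folds whose sizes differ by at most one;
#' deterministic for a given seed.
#'
#' @param n number of observations (>= k).
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold labels in `1..k`.
#' @export
make_folds <- function(n, k = 5, seed = 1L) {
  if (n < k) stop2("n must be >= k")
  base <- rep(seq_len(k), length.out = n)
  with_seed(seed, sample(base))
}

# --- hyperparameter grids -------------------------------------------------

#' Hyperparameter grid for one algorithm
#'
#' Encodes the search space and its enumeration order (ties in the grid
#' search go to the first configuration in this order):
#' * `en`: no grid here; the mixing parameter is fixed at `alpha = 0.5` and
#'   the penalty strength lambda is chosen by inner cross-validation.
#' * `rf`: number of trees 50 to 500 in steps of 50, ascending.
#' * `knn`: neighbors k in odd numbers 3..31 (fastest-varying), then
#'   weighting (`uniform`, `distance`), then Minkowski power (1, 2, 3).
#' * `svr`: kernel in (`linear`, `polynomial`, `radial`, `sigmoid`), degree
#'   2..7 for the polynomial kernel, penalty C in (1e-4, 5e-4, 1e-3, 5e-3,
#'   0.01, 0.05, 0.1, 0.5, 1.0, 1.5, 2.0) fastest-varying; the kernel width
#'   gamma follows the "scale" contract `1 / (n_features * Var(X))`.
#'
#' @param algorithm one of `"rf"`, `"knn"`, `"svr"`.
#' @param n_trees optional override of the RF tree grid.
#' @param k,weights,power optional overrides of the KNN grid.
#' @param kernel,degree,cost optional overrides of the SVR grid.
#' @return An object of class `hyper_grid` with elements `algorithm` and
#'   `configs` (data.frame in enumeration order).
#' @export
hyper_grid <- function(algorithm = c("rf", "knn", "svr"),
                       n_trees = seq(50L, 500L, by = 50L),
                       k = seq(3L, 31L, by = 2L),
                       weights = c("uniform", "distance"),
                       power = c(1, 2, 3),
                       kernel = c("linear", "polynomial", "radial", "sigmoid"),
                       degree = 2:7,
                       cost = c(1e-4, 5e-4, 1e-3, 5e-3, 0.01, 0.05, 0.1,
                                0.5, 1.0, 1.5, 2.0)) {
  algorithm <- match.arg(algorithm)
  configs <- switch(algorithm,
    rf = data.frame(n_trees = sort(as.integer(n_trees))),
    knn = expand.grid(k = as.integer(k), weights = weights, power = power,
                      stringsAsFactors = FALSE),
    svr = {
      rows <- list()
      for (kn in kernel) {
        degs <- if (kn == "polynomial") degree else NA_integer_
        for (dg in degs) {
          rows[[length(rows) + 1]] <-
            data.frame(kernel = kn, degree = dg, cost = cost,
                       stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
  rownames(configs) <- NULL
  structure(list(algorithm = algorithm, configs = configs),
            class = "hyper_grid")
}

# sklearn-style "scale" gamma: 1 / (p * population variance of the whole
# feature matrix), with a unit fallback for degenerate matrices.
scale_gamma <- function(X) {
  v <- mean((X - mean(X))^2)
  if (!is.finite(v) || v <= 0) return(1)
  1 / (ncol(X) * v)
}

# Center/scale by training statistics; zero-variance columns collapse to 0.
fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}
apply_scaler <- function(X, sc) {
  sweep(sweep(X, 2, sc$center, "-"), 2, sc$scale, "/")
}

# --- KNN regression engine ------------------------------------------------

# Minkowski distance matrix between rows of A (queries) and B (references).
minkowski_dist <- function(A, B, power) {
  D <- matrix(0, nrow(A), nrow(B))
  for (j in seq_len(ncol(A))) {
    D <- D + abs(outer(A[, j], B[, j], "-"))^power
  }
  D^(1 / power)
}

# Predict queries from k nearest training points. Neighbor ties in distance
# break by training-row order. With inverse-distance weighting, queries that
# coincide exactly with training points take the mean of their zero-distance
# neighbors.
knn_predict <- function(D, y_train, k, weights) {
  apply(D, 1, function(d) {
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    if (weights == "uniform") {
      mean(y_train[nn])
    } else if (any(dn == 0)) {
      mean(y_train[nn[dn == 0]])
    } else {
      w <- 1 / dn
      sum(w * y_train[nn]) / sum(w)
    }
  })
}

# --- single-config fit/predict used by grid CV and deployment -------------

fit_config <- function(algorithm, config, X, y, seed) {
  if (algorithm == "rf") {
    df <- as.data.frame(X)
    names(df) <- paste0("f", seq_len(ncol(X)))
    # all features eligible per split (the reference regressor's default);
    # node size at the engine's own regression default
    fit <- ranger::ranger(y = y, x = df, num.trees = config$n_trees,
                          mtry = ncol(X), min.node.size = 5,
                          num.threads = 1L, seed = seed)
    list(type = "ranger", fit = fit)
  } else if (algorithm == "svr") {
    sc <- fit_scaler(X)
    Xs <- apply_scaler(X, sc)
    fit <- e1071::svm(Xs, y, kernel = config$kernel, cost = config$cost,
                      degree = if (is.na(config$degree)) 3 else config$degree,
                      gamma = scale_gamma(Xs), scale = FALSE)
    list(type = "svm", fit = fit, scaler = sc)
  } else if (algorithm == "knn") {
    sc <- fit_scaler(X)
    list(type = "knn", X = apply_scaler(X, sc), y = y, scaler = sc,
         k = config$k, weights = config$weights, power = config$power)
  } else {
    stop2("unknown algorithm: ", algorithm)
  }
}

predict_config <- function(fitted, X_new) {
  if (fitted$type == "ranger") {
    df <- as.data.frame(X_new)
    names(df) <- paste0("f", seq_len(ncol(X_new)))
    predict(fitted$fit, df, num.threads = 1L)$predictions
  } else if (fitted$type == "svm") {
    as.vector(predict(fitted$fit, apply_scaler(X_new, fitted$scaler)))
  } else if (fitted$type == "knn") {
    D <- minkowski_dist(apply_scaler(X_new, fitted$scaler), fitted$X,
                        fitted$power)
    knn_predict(D, fitted$y, fitted$k, fitted$weights)
  } else {
    stop2("unknown payload type")
  }
}

# --- elastic net ----------------------------------------------------------

# glmnet needs >= 2 columns; pad single-feature matrices with a zero column
# that can never earn weight.
pad_features <- function(X) {
  if (ncol(X) >= 2) return(X)
  cbind(X, `.pad` = 0)
}

#' Train an elastic net gene model under nested cross-validation
#'
#' Outer loop: 5 seeded folds. For each held-out fold, 10-fold
#' cross-validation on the remaining four folds selects the lambda minimizing
#' mean squared error along the glmnet path at mixing `alpha = 0.5`; the
#' model refit at that lambda predicts the held-out fold and contributes one
#' R-squared. The reported performance is the mean of the five held-out
#' R-squared values. The deployed model is refit on all samples at the lambda
#' chosen by a fresh 10-fold cross-validation on all data; its payload is the
#' sparse weight vector plus intercept. Degenerate inputs (all-constant
#' features) fall back to an intercept-only model whose cross-validated
#' R-squared cannot exceed 0.
#'
#' @param X sample x variant dosage matrix (no missing values).
#' @param y expression vector.
#' @param seed integer seed (controls all fold assignments).
#' @param alpha elastic-net mixing parameter (fixed default 0.5).
#' @return A `gene_model` object.
#' @export
train_en <- function(X, y, seed = 1L, alpha = 0.5) {
  n <- length(y)
  if (n < 15) stop2("elastic net training needs n >= 15")
  if (ncol(X) < 1) stop2("need at least one feature")
  folds <- make_folds(n, 5, seed)
  Xp <- pad_features(X)
  fold_r2 <- numeric(5)
  for (f in 1:5) {
    tr <- folds != f
    fit <- tryCatch(
      glmnet::cv.glmnet(Xp[tr, , drop = FALSE], y[tr], alpha = alpha,
                        foldid = make_folds(sum(tr), 10, derive_seed(seed, f))),
      error = function(e) NULL)
    pred <- if (is.null(fit)) {
      rep(mean(y[tr]), sum(!tr))
    } else {
      as.vector(predict(fit, Xp[!tr, , drop = FALSE], s = "lambda.min"))
    }
    fold_r2[f] <- r2_score(y[!tr], pred)
  }
  final <- tryCatch(
    glmnet::cv.glmnet(Xp, y, alpha = alpha,
                      foldid = make_folds(n, 10, derive_seed(seed, 99L))),
    error = function(e) NULL)
  if (is.null(final)) {
    weights <- rep(0, ncol(X))
    intercept <- mean(y)
    lambda <- Inf
  } else {
    cf <- as.vector(coef(final, s = "lambda.min"))
    intercept <- cf[1]
    weights <- cf[-1][seq_len(ncol(X))]
    lambda <- final$lambda.min
  }
  new_gene_model(
    gene_id = NA_character_, algorithm = "en",
    hyperparameters = list(alpha = alpha, lambda = lambda),
    cv = list(fold_r2 = fold_r2, mean_r2 = mean(fold_r2), seed = seed),
    payload = list(type = "linear", weights = weights, intercept = intercept),
    X = X)
}

#' Train a gene model by exhaustive grid-search cross-validation
#'
#' Every grid configuration is scored by 5-fold cross-validation (one shared
#' seeded fold assignment across all configurations) using [r2_score()] on
#' each held-out fold; the configuration with the highest mean R-squared wins
#' (ties: first in the grid's enumeration order), and the deployed model is
#' refit on all samples at the winning configuration.
#'
#' The random-forest tree grid is evaluated incrementally: one forest of
#' `max(n_trees)` trees is grown per fold and the cross-validated R-squared
#' of each smaller tree count is computed from the cumulative means of its
#' first trees (the first N trees of a forest are themselves an N-tree
#' forest). KNN configurations whose k reaches the training-fold size are
#' skipped with a warning.
#'
#' @param X sample x variant dosage matrix (no missing values).
#' @param y expression vector.
#' @param grid a [hyper_grid()].
#' @param seed integer seed.
#' @return A `gene_model` whose `cv$grid_r2` records the mean cross-validated
#'   R-squared of every configuration.
#' @export
train_gridsearch <- function(X, y, grid, seed = 1L) {
  stopifnot(inherits(grid, "hyper_grid"))
  n <- length(y)
  if (n < 5) stop2("grid-search training needs n >= 5")
  folds <- make_folds(n, 5, seed)
  configs <- grid$configs
  nc <- nrow(configs)
  fold_r2 <- matrix(NA_real_, nc, 5)

  if (grid$algorithm == "rf") {
    max_trees <- max(configs$n_trees)
    for (f in 1:5) {
      tr <- folds != f
      df <- as.data.frame(X[tr, , drop = FALSE])
      names(df) <- paste0("f", seq_len(ncol(X)))
      fit <- ranger::ranger(y = y[tr], x = df, num.trees = max_trees,
                            mtry = ncol(X), min.node.size = 5,
                            num.threads = 1L,
                            seed = derive_seed(seed, 100L + f))
      dfte <- as.data.frame(X[!tr, , drop = FALSE])
      names(dfte) <- names(df)
      per_tree <- predict(fit, dfte, predict.all = TRUE,
                          num.threads = 1L)$predictions
      cums <- t(apply(per_tree, 1, cumsum))
      for (ci in seq_len(nc)) {
        N <- configs$n_trees[ci]
        fold_r2[ci, f] <- r2_score(y[!tr], cums[, N] / N)
      }
    }
  } else if (grid$algorithm == "knn") {
    # neighbor order depends only on fold x power, so sort once and read all
    # (k, weighting) predictions off cumulative sums over the sorted labels
    skipped <- FALSE
    for (f in 1:5) {
      tr <- folds != f
      ntr <- sum(tr)
      sc <- fit_scaler(X[tr, , drop = FALSE])
      Xtr <- apply_scaler(X[tr, , drop = FALSE], sc)
      Xte <- apply_scaler(X[!tr, , drop = FALSE], sc)
      ytr <- y[tr]
      for (pw in unique(configs$power)) {
        D <- minkowski_dist(Xte, Xtr, pw)
        ord <- t(apply(D, 1, order))
        sy <- matrix(ytr[t(ord)], nrow(D), ntr, byrow = TRUE)
        sd_ <- matrix(D[cbind(rep(seq_len(nrow(D)), each = ntr),
                              as.vector(t(ord)))],
                      nrow(D), ntr, byrow = TRUE)
        cum_y <- t(apply(sy, 1, cumsum))
        w <- 1 / sd_
        w[!is.finite(w)] <- 0
        cum_wy <- t(apply(w * sy, 1, cumsum))
        cum_w <- t(apply(w, 1, cumsum))
        n_zero <- rowSums(sd_ == 0)
        for (ci in which(configs$power == pw)) {
          k <- configs$k[ci]
          if (k >= ntr) { skipped <- TRUE; next }
          pred <- if (configs$weights[ci] == "uniform") {
            cum_y[, k] / k
          } else {
            p <- cum_wy[, k] / cum_w[, k]
            # exact-match rule: zero-distance neighbors take over
            hit <- n_zero > 0
            if (any(hit)) {
              kz <- pmin(n_zero[hit], k)
              p[hit] <- cum_y[hit, , drop = FALSE][cbind(seq_along(kz), kz)] / kz
            }
            p
          }
          fold_r2[ci, f] <- r2_score(y[!tr], pred)
        }
      }
    }
    if (skipped) warn2("KNN grid points with k >= training-fold size skipped")
  } else { # svr
    for (f in 1:5) {
      tr <- folds != f
      for (ci in seq_len(nc)) {
        fitted <- fit_config("svr", configs[ci, ], X[tr, , drop = FALSE],
                             y[tr], seed)
        pred <- predict_config(fitted, X[!tr, , drop = FALSE])
        fold_r2[ci, f] <- r2_score(y[!tr], pred)
      }
    }
  }

  mean_r2 <- rowMeans(fold_r2)
  if (all(is.na(mean_r2))) stop2("no evaluable grid configuration")
  best <- which.max(replace(mean_r2, is.na(mean_r2), -Inf))
  best_cfg <- configs[best, , drop = FALSE]
  deployed <- fit_config(grid$algorithm, best_cfg, X, y,
                         derive_seed(seed, 199L))
  new_gene_model(
    gene_id = NA_character_, algorithm = grid$algorithm,
    hyperparameters = as.list(best_cfg),
    cv = list(fold_r2 = fold_r2[best, ], mean_r2 = mean_r2[best],
              grid_r2 = cbind(configs, mean_r2 = mean_r2), seed = seed),
    payload = deployed, X = X)
}

# --- gene model object ----------------------------------------------------

new_gene_model <- function(gene_id, algorithm, hyperparameters, cv, payload,
                           X, variants = NULL, failed = FALSE) {
  if (is.null(variants)) {
    variants <- data.frame(id = colnames(X) %||% paste0("f", seq_len(ncol(X))),
                           ref = NA_character_, alt = NA_character_,
                           mean_dosage = colMeans(X), stringsAsFactors = FALSE)
  }
  structure(list(gene_id = gene_id, algorithm = algorithm,
                 hyperparameters = hyperparameters, cv = cv,
                 variants = variants, payload = payload, failed = failed),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s [%s]: %d variants, cv mean R2 = %.4f\n",
              x$gene_id, x$algorithm, nrow(x$variants), x$cv$mean_r2))
  invisible(x)
}

#' Predict expression from a trained gene model
#'
#' @param object a `gene_model`.
#' @param X sample x variant dosage matrix whose columns match
#'   `object$variants$id` (already harmonized).
#' @param ... unused.
#' @return Numeric prediction vector (one value per row of `X`).
#' @export
predict.gene_model <- function(object, X, ...) {
  if (object$failed) stop2("cannot predict from a failed model")
  X <- X[, object$variants$id, drop = FALSE]
  p <- object$payload
  if (p$type == "linear") {
    as.vector(p$intercept + X %*% p$weights)
  } else {
    predict_config(p, X)
  }
}

# --- cohort training ------------------------------------------------------

#' Train gene models for a whole cohort
#'
#' For each gene in the annotation with expression data, extracts the cis
#' window, mean-imputes sporadic missing dosages, and trains one model per
#' requested algorithm with a shared per-gene fold seed (so algorithm
#' comparisons are paired). Genes with empty cis windows are skipped and
#' reported; genes whose training fails are recorded as failed models with a
#' `-Inf` sentinel rather than silently dropped.
#'
#' @param genotypes a [geno_matrix()] for the training cohort.
#' @param expression gene x sample matrix (adjusted expression).
#' @param annotation gene span data.frame (`gene_id`, `chrom`, `start`,
#'   `end`).
#' @param algorithms subset of `c("en", "rf", "svr", "knn")`.
#' @param window_bp cis window half-width.
#' @param grids optional named list of [hyper_grid()] overrides.
#' @param seed integer seed.
#' @return An object of class `model_db`: list with `models` (nested list
#'   gene -> algorithm -> `gene_model`), `results` (data.frame of gene,
#'   algorithm, mean cv R-squared, n features, failed flag) and `skipped`
#'   (genes without cis variants).
#' @export
train_cohort <- function(genotypes, expression, annotation,
                         algorithms = c("en", "rf", "svr", "knn"),
                         window_bp = 1e6, grids = NULL, seed = 1L) {
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  common <- intersect(genotypes$samples, colnames(expression))
  if (length(common) == 0) stop2("no common samples between genotypes and expression")
  g <- genotypes[match(common, genotypes$samples), ]
  genes <- intersect(annotation$gene_id, rownames(expression))
  models <- list(); skipped <- character(0); rows <- list()
  for (gi in seq_along(genes)) {
    gene <- genes[gi]
    cis <- extract_cis(g, annotation, gene, window_bp)
    if (length(cis$variant_ids) == 0) {
      skipped <- c(skipped, gene)
      next
    }
    X <- cis$X[common, , drop = FALSE]
    all_na <- colSums(!is.na(X)) == 0
    X <- X[, !all_na, drop = FALSE]
    if (ncol(X) == 0) { skipped <- c(skipped, gene); next }
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    if (nrow(idx)) X[idx] <- mu[idx[, 2]]
    y <- expression[gene, common]
    # seed keyed by gene id so results do not depend on gene ordering
    gene_seed <- derive_seed(seed, string_hash(gene))
    vmeta <- g$variants[match(colnames(X), g$variants$id), ]
    for (alg in algorithms) {
      mdl <- tryCatch({
        m <- if (alg == "en") {
          train_en(X, y, seed = gene_seed)
        } else {
          grid <- grids[[alg]] %||% hyper_grid(alg)
          train_gridsearch(X, y, grid, seed = gene_seed)
        }
        m$gene_id <- gene
        m$variants$ref <- vmeta$ref
        m$variants$alt <- vmeta$alt
        m$variants <- cbind(m$variants[, c("id", "ref", "alt", "mean_dosage")],
                            chrom = vmeta$chrom, pos = vmeta$pos)
        m
      }, error = function(e) {
        new_gene_model(gene, alg, list(error = conditionMessage(e)),
                       cv = list(fold_r2 = rep(NA_real_, 5), mean_r2 = -Inf,
                                 seed = gene_seed),
                       payload = list(type = "failed"), X = X,
                       failed = TRUE)
      })
      models[[gene]][[alg]] <- mdl
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gene, algorithm = alg, mean_cv_r2 = mdl$cv$mean_r2,
        n_features = nrow(mdl$variants), failed = mdl$failed,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(models = models, results = do.call(rbind, rows),
                 skipped = skipped, seed = seed),
            class = "model_db")
}

#' @export
print.model_db <- function(x, ...) {
  cat(sprintf("model_db: %d genes x {%s}, %d skipped\n",
              length(x$models),
              paste(unique(x$results$algorithm), collapse = ", "),
              length(x$skipped)))
  invisible(x)
}

#' Count gene models exceeding cross-validated R-squared thresholds
#'
#' One row per algorithm, one column per threshold (counts of genes with
#' mean cv R-squared strictly above it); failed models are excluded.
#'
#' @param db a `model_db` (or its `results` data.frame).
#' @param thresholds numeric thresholds.
#' @return data.frame of counts.
#' @export
model_summary_table <- function(db, thresholds = c(-0.1, -0.01, 0, 0.01,
                                                   0.05, 0.1, 0.5)) {
  res <- if (inherits(db, "model_db")) db$results else db
  res <- res[!res$failed & is.finite(res$mean_cv_r2), ]
  algs <- unique(res$algorithm)
  out <- data.frame(algorithm = algs, stringsAsFactors = FALSE)
  for (th in thresholds) {
    out[[paste0("r2_gt_", th)]] <- vapply(algs, function(a)
      sum(res$mean_cv_r2[res$algorithm == a] > th), integer(1))
  }
  out
}

#' Persist a model collection
#'
#' Writes (a) `weights.tsv` for linear payloads (gene, variant, ref, alt,
#' weight, training mean dosage) in the PrediXcan-compatible layout, (b)
#' `model_info.tsv` (gene, algorithm, hyperparameters as JSON, per-fold and
#' mean cv R-squared, feature count) and (c) `model_db.rds` holding the full
#' collection including non-linear fitted payloads.
#'
#' @param db a `model_db`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
save_model_db <- function(db, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wrows <- list(); irows <- list()
  for (gene in names(db$models)) for (alg in names(db$models[[gene]])) {
    m <- db$models[[gene]][[alg]]
    if (!m$failed && m$payload$type == "linear") {
      nz <- which(m$payload$weights != 0)
      if (length(nz)) {
        wrows[[length(wrows) + 1]] <- data.frame(
          gene = gene, rsid = m$variants$id[nz], ref = m$variants$ref[nz],
          alt = m$variants$alt[nz],
          weight = format_num(m$payload$weights[nz]),
          mean_dosage = format_num(m$variants$mean_dosage[nz]),
          stringsAsFactors = FALSE)
      }
    }
    irows[[length(irows) + 1]] <- data.frame(
      gene = gene, algorithm = alg,
      hyperparameters = as.character(jsonlite::toJSON(
        m$hyperparameters[setdiff(names(m$hyperparameters), "error")],
        auto_unbox = TRUE, digits = NA)),
      fold_r2 = paste(format_num(m$cv$fold_r2), collapse = ","),
      mean_cv_r2 = format_num(m$cv$mean_r2),
      n_features = nrow(m$variants), failed = m$failed,
      stringsAsFactors = FALSE)
  }
  if (length(wrows)) {
    data.table::fwrite(do.call(rbind, wrows), file.path(dir, "weights.tsv"),
                       sep = "\t", quote = FALSE)
  }
  data.table::fwrite(do.call(rbind, irows), file.path(dir, "model_info.tsv"),
                     sep = "\t", quote = FALSE)
  saveRDS(db, file.path(dir, "model_db.rds"))
  invisible(dir)
}

#' @rdname save_model_db
#' @param dir directory written by [save_model_db()].
#' @export
load_model_db <- function(dir) {
  readRDS(file.path(dir, "model_db.rds"))
}
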