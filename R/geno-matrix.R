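#' Genotype matrix container
#'
#' Holds alternate-allele dosages as a sample x variant numeric matrix in
#' `[0, 2]` (missing entries `NA`) together with per-variant metadata
#' (chromosome, 1-based position, id, ref and alt alleles). This is the
#' exchange container for every genotype-consuming stage: quality control,
#' cis-window extraction, harmonization and prediction.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`; one row per column of `dosages`.
#' @param samples character vector of sample labels; defaults to the row
#'   names of `dosages`.
#' @return An object of class `geno_matrix`: a list with elements `dosages`,
#'   `variants` and `samples`.
#' @export
geno_matrix <- function(dosages, variants, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(dosages)))
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop2("variants must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(variants) != ncol(dosages)) {
    stop2("variants rows (", nrow(variants), ") != dosage columns (", ncol(dosages), ")")
  }
  if (anyDuplicated(variants$id)) stop2("variant ids must be unique")
  if (length(dosages) && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop2("dosages must lie in [0, 2]")
  }
  rownames(dosages) <- samples
  colnames(dosages) <- variants$id
  rownames(variants) <- NULL
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  cat("chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("missing dosages: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosages)

# Subset a geno_matrix by sample and/or variant index (logical, integer or
# name vectors), keeping metadata aligned.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(j)) j <- match(j, x$variants$id)
  geno_matrix(x$dosages[i, j, drop = FALSE],
              x$variants[j, , drop = FALSE],
              samples = x$samples[i])
}

#' Row-bind genotype matrices over samples
#'
#' Combines populations that share an identical variant set (same ids,
#' positions and alleles) into one cohort, e.g. to build a pooled training
#' set from several populations.
#'
#' @param ... `geno_matrix` objects with identical variant tables.
#' @return A single `geno_matrix`.
#' @export
bind_samples <- function(...) {
  gs <- list(...)
  if (length(gs) == 1 && is.list(gs[[1]]) && !inherits(gs[[1]], "geno_matrix")) {
    gs <- gs[[1]]
  }
  v0 <- gs[[1]]$variants
  for (g in gs[-1]) {
    if (!identical(g$variants$id, v0$id)) stop2("variant sets differ; cannot bind samples")
  }
  geno_matrix(do.call(rbind, lapply(gs, `[[`, "dosages")), v0,
              samples = unlist(lapply(gs, `[[`, "samples"), use.names = FALSE))
}

#' Per-variant alternate-allele frequency
#'
#' Mean non-missing dosage over 2, per variant.
#' @param g a [geno_matrix()].
#' @return Named numeric vector of alternate-allele frequencies.
#' @export
alt_freq <- function(g) colMeans(g$dosages, na.rm = TRUE) / 2

# Strand-ambiguous (palindromic) allele pair: A/T or C/G in either order.
is_ambiguous_pair <- function(ref, alt) {
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}
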