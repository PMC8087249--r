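#' Write genotypes as VCF with GT and DS fields
#'
#' Emits a minimal VCFv4.2 file: hard-call `GT` derived from the rounded
#' dosage (`./.` for missing) plus the dosage itself in `DS`. Paths ending in
#' `.gz` are gzip-compressed.
#'
#' @param g a [geno_matrix()].
#' @param path output path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  v <- g$variants
  n <- length(g$samples)
  gt_of <- function(d) {
    out <- rep("./.", length(d))
    hc <- round(d)
    out[!is.na(d) & hc == 0] <- "0/0"
    out[!is.na(d) & hc == 1] <- "0/1"
    out[!is.na(d) & hc == 2] <- "1/1"
    out
  }
  ds_of <- function(d) ifelse(is.na(d), ".", format_num(d))
  body <- vapply(seq_len(nrow(v)), function(j) {
    d <- g$dosages[, j]
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS", ".",
            "GT:DS", paste(gt_of(d), ds_of(d), sep = ":")), collapse = "\t")
  }, character(1))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alt allele dosage\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", g$samples), collapse = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a VCF written with GT/DS fields into a genotype matrix
#'
#' Dosages are taken from the `DS` field when present, otherwise from the
#' `GT` hard call; `./.` and `.` become missing.
#'
#' @param path `.vcf` or `.vcf.gz` file.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  dt <- data.table::fread(text = lines[-1], header = FALSE, sep = "\t",
                          colClasses = "character")
  data.table::setnames(dt, hdr)
  samples <- hdr[-(1:9)]
  variants <- data.frame(chrom = dt$CHROM, pos = as.integer(dt$POS), id = dt$ID,
                         ref = dt$REF, alt = dt$ALT, stringsAsFactors = FALSE)
  fmt <- strsplit(dt$FORMAT, ":")
  cells <- as.matrix(dt[, samples, with = FALSE])
  dos <- matrix(NA_real_, nrow = length(samples), ncol = nrow(dt))
  for (j in seq_len(nrow(dt))) {
    parts <- strsplit(cells[j, ], ":", fixed = TRUE)
    ds_i <- match("DS", fmt[[j]])
    gt_i <- match("GT", fmt[[j]])
    val <- vapply(parts, function(p) {
      if (!is.na(ds_i) && p[ds_i] != ".") return(suppressWarnings(as.numeric(p[ds_i])))
      gt <- p[gt_i]
      if (gt %in% c("./.", ".", ".|.")) return(NA_real_)
      sum(as.numeric(strsplit(gt, "[/|]")[[1]]))
    }, numeric(1))
    dos[, j] <- val
  }
  geno_matrix(dos, variants, samples = samples)
}

#' Write genotypes as a dosage text table
#'
#' One row per variant: `chrom rsid pos ref alt MAF` followed by one dosage
#' column per sample (header row carries the sample labels). This mirrors the
#' dosage format consumed by transcriptome-imputation tools. Paths ending in
#' `.gz` are gzip-compressed.
#'
#' @param g a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dosage <- function(g, path) {
  f <- alt_freq(g)
  maf <- pmin(f, 1 - f)
  dt <- data.table::data.table(chrom = g$variants$chrom, rsid = g$variants$id,
                               pos = g$variants$pos, ref = g$variants$ref,
                               alt = g$variants$alt, MAF = format_num(maf))
  dosc <- t(g$dosages)
  for (k in seq_along(g$samples)) {
    data.table::set(dt, j = g$samples[k], value = format_num(dosc[, k]))
  }
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a dosage text table written by [write_dosage()]
#' @param path dosage file.
#' @return A [geno_matrix()].
#' @export
read_dosage <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  samples <- setdiff(names(dt), c("chrom", "rsid", "pos", "ref", "alt", "MAF"))
  variants <- data.frame(chrom = as.character(dt$chrom), pos = as.integer(dt$pos),
                         id = dt$rsid, ref = dt$ref, alt = dt$alt,
                         stringsAsFactors = FALSE)
  dos <- t(as.matrix(dt[, samples, with = FALSE]))
  mode(dos) <- "double"
  geno_matrix(dos, variants, samples = samples)
}

#' Write / read a gene x sample matrix as TSV
#'
#' First column `gene_id`, remaining columns one per sample. Values are
#' written at full precision so read-back is bit-exact.
#'
#' @param x numeric matrix with gene row names and sample column names.
#' @param path output path (`.gz` supported).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  dt <- data.table::data.table(gene_id = rownames(x))
  for (k in seq_len(ncol(x))) {
    data.table::set(dt, j = colnames(x)[k], value = format_num(x[, k]))
  }
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  m <- as.matrix(dt[, -1])
  mode(m) <- "double"
  rownames(m) <- dt[[1]]
  m
}

#' Write / read a phenotype table (sample, value)
#' @param pheno named numeric vector.
#' @param path output path.
#' @return `path` invisibly (writer); named numeric vector (reader).
#' @export
write_phenotype <- function(pheno, path) {
  dt <- data.table::data.table(sample = names(pheno), value = format_num(pheno))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  setNames(as.numeric(dt$value), dt$sample)
}

#' Write / read the simulation truth sidecar as JSON
#'
#' Serializes causal variants, effect sizes, architecture forms,
#' heritabilities, the trait gene/effect and hidden-factor loadings at full
#' numeric precision.
#'
#' @param truth a `sim_truth` object.
#' @param path output `.json` path.
#' @return `path` invisibly (writer); `sim_truth` (reader).
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    trait_gene = truth$trait_gene,
    trait_effect = truth$trait_effect,
    architectures = lapply(truth$architectures, function(a) {
      list(gene_id = a$gene_id, causal_variant_ids = a$causal_variant_ids,
           effect_sizes = a$effect_sizes, model_form = a$model_form, h2 = a$h2)
    }),
    loading_genes = rownames(truth$hidden_factor_loadings),
    hidden_factor_loadings = unname(truth$hidden_factor_loadings)
  )
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  archs <- lapply(obj$architectures, function(a) {
    eqtl_architecture(a$gene_id, a$causal_variant_ids, a$effect_sizes,
                      a$model_form, a$h2)
  })
  loadings <- obj$hidden_factor_loadings
  rownames(loadings) <- obj$loading_genes
  structure(list(architectures = archs, trait_gene = obj$trait_gene,
                 trait_effect = obj$trait_effect,
                 hidden_factor_loadings = loadings),
            class = "sim_truth")
}

#' Write a simulated cohort to a directory
#'
#' Per population: genotypes as VCF and dosage text, expression/genetic TSV,
#' phenotype TSV; gene annotation TSV and a truth JSON sidecar at top level.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if absent).
#' @param gzip compress the larger files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, gzip = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  z <- if (gzip) ".gz" else ""
  for (pop in names(cohort$genotypes)) {
    write_vcf(cohort$genotypes[[pop]], file.path(dir, paste0(pop, ".vcf", z)))
    write_dosage(cohort$genotypes[[pop]], file.path(dir, paste0(pop, ".dosage.txt", z)))
    write_matrix_tsv(cohort$expression[[pop]],
                     file.path(dir, paste0(pop, ".expression.tsv", z)))
    write_phenotype(cohort$phenotype[[pop]],
                    file.path(dir, paste0(pop, ".phenotype.tsv")))
  }
  data.table::fwrite(cohort$annotation, file.path(dir, "annotation.tsv"), sep = "\t")
  write_truth(cohort$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
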