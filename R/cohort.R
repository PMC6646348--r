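#' Construct a genotyped cohort
#'
#' The central exchange object of the package: per-sample metadata, per-SNP
#' metadata and a sample-by-SNP genotype matrix counting copies of the A1
#' (minor) allele. Males at non-pseudoautosomal X loci are hemizygous, so
#' their entries are 0 or 2 (one allele copy stored on the diploid scale);
#' a male entry of 1 is a heterozygote call, retained on input but flagged
#' by [male_het_scan()] and removed by [sanitize_male_hets()].
#'
#' @param samples data.frame with columns `fid`, `iid`, `pat`, `mat`,
#'   `sex` (1 = male, 2 = female) and `phenotype` (1 = control, 2 = case,
#'   -9 = missing; 0 is accepted on input and normalised to -9).
#' @param snps data.frame with columns `chr` (23 = X; "X" is accepted and
#'   recoded), `snp`, `dist` (genetic distance in morgans, 0 for all markers
#'   here), `bp` (1-based position), `a1`, `a2` (single-character alleles,
#'   A1 = counted/minor allele).
#' @param genotypes integer matrix, `nrow(samples)` x `nrow(snps)`, entries
#'   in {0, 1, 2, NA}; NA is a missing call.
#' @param qt optional data.frame of quantitative phenotypes (one row per
#'   sample, e.g. HOMA-IR, glucose, BMI z-score), NA allowed.
#' @return An object of class `x_cohort`.
#' @export
x_cohort <- function(samples, snps, genotypes, qt = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need_s <- c("fid", "iid", "pat", "mat", "sex", "phenotype")
  need_m <- c("chr", "snp", "dist", "bp", "a1", "a2")
  if (!all(need_s %in% names(samples)))
    stop("samples must have columns: ", paste(need_s, collapse = ", "))
  if (!all(need_m %in% names(snps)))
    stop("snps must have columns: ", paste(need_m, collapse = ", "))
  samples$sex <- as.integer(samples$sex)
  if (!all(samples$sex %in% c(1L, 2L)))
    stop("sex codes must be 1 (male) or 2 (female)")
  samples$phenotype <- as.numeric(samples$phenotype)
  samples$phenotype[samples$phenotype == 0] <- -9
  if (!all(samples$phenotype %in% c(1, 2, -9)))
    stop("phenotype codes must be 1 (control), 2 (case) or -9/0 (missing)")
  snps$chr <- normalize_chr(snps$chr)
  snps$bp <- as.integer(snps$bp)
  if (nrow(snps) && any(snps$bp <= 0L)) stop("bp positions must be positive")
  if (nrow(snps) && any(snps$a1 == snps$a2)) stop("a1 and a2 must differ")
  if (anyDuplicated(samples$iid)) stop("sample ids must be unique")
  if (anyDuplicated(snps$snp)) stop("snp ids must be unique")
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(samples) || ncol(genotypes) != nrow(snps))
    stop("genotype matrix must be n_samples x n_snps")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && !all(bad %in% 0:2)) stop("genotype codes must be 0, 1, 2 or NA")
  dimnames(genotypes) <- list(samples$iid, snps$snp)
  if (!is.null(qt)) {
    qt <- as.data.frame(qt, stringsAsFactors = FALSE)
    if (nrow(qt) != nrow(samples))
      stop("qt must have one row per sample")
    rownames(qt) <- samples$iid
  }
  structure(list(samples = samples, snps = snps, genotypes = genotypes, qt = qt),
            class = "x_cohort")
}

normalize_chr <- function(chr) {
  chr <- as.character(chr)
  chr[chr %in% c("X", "x", "chrX")] <- "23"
  suppressWarnings(out <- as.integer(chr))
  if (length(out) && anyNA(out)) stop("unrecognised chromosome code")
  out
}

#' @export
print.x_cohort <- function(x, ...) {
  cat("<x_cohort> ", n_samples(x), " samples (",
      sum(x$samples$sex == 2L), " F / ", sum(x$samples$sex == 1L), " M), ",
      n_snps(x), " SNPs\n", sep = "")
  ph <- x$samples$phenotype
  cat("  affection: ", sum(ph == 2), " cases, ", sum(ph == 1), " controls, ",
      sum(ph == -9), " missing\n", sep = "")
  if (!is.null(x$qt))
    cat("  quantitative phenotypes: ", paste(names(x$qt), collapse = ", "), "\n", sep = "")
  if (n_snps(x)) {
    miss <- mean(is.na(x$genotypes))
    cat(sprintf("  missing call rate: %.3f\n", miss))
  }
  invisible(x)
}

#' @export
summary.x_cohort <- function(object, ...) {
  maf <- if (n_snps(object)) cohort_maf(object) else numeric(0)
  out <- list(
    n_samples = n_samples(object), n_snps = n_snps(object),
    n_female = sum(object$samples$sex == 2L),
    n_male = sum(object$samples$sex == 1L),
    snps = cbind(object$snps,
                 maf = maf,
                 miss = if (n_snps(object)) colMeans(is.na(object$genotypes)) else numeric(0)))
  class(out) <- "summary.x_cohort"
  out
}

#' @export
print.summary.x_cohort <- function(x, ...) {
  cat("x_cohort: ", x$n_samples, " samples (", x$n_female, " F / ",
      x$n_male, " M), ", x$n_snps, " SNPs\n", sep = "")
  print(x$snps, row.names = FALSE)
  invisible(x)
}

#' Subset a cohort by samples and/or SNPs
#'
#' @param x an `x_cohort`.
#' @param i sample index (logical, integer or iid character).
#' @param j SNP index (logical, integer or snp-id character).
#' @param ... unused.
#' @export
`[.x_cohort` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_samples(x))
  if (missing(j)) j <- seq_len(n_snps(x))
  if (is.character(i)) i <- match(i, x$samples$iid)
  if (is.character(j)) j <- match(j, x$snps$snp)
  x_cohort(x$samples[i, , drop = FALSE],
           x$snps[j, , drop = FALSE],
           x$genotypes[i, j, drop = FALSE],
           qt = if (is.null(x$qt)) NULL else x$qt[i, , drop = FALSE])
}

#' Number of samples in a cohort
#' @param cohort an `x_cohort`.
#' @export
n_samples <- function(cohort) nrow(cohort$samples)

#' Number of SNPs in a cohort
#' @param cohort an `x_cohort`.
#' @export
n_snps <- function(cohort) nrow(cohort$snps)

is_male <- function(cohort) cohort$samples$sex == 1L
is_female <- function(cohort) cohort$samples$sex == 2L

# X-chromosome allele counting: females contribute two alleles, males one.
# Male codes are on the diploid 0/2 scale, so a male's minor-allele count is
# code/2; male heterozygote calls (code 1) are excluded with a warning.
allele_counts_by_sex <- function(cohort, j) {
  g <- cohort$genotypes[, j]
  male <- is_male(cohort)
  gm <- g[male]
  if (any(!is.na(gm) & gm == 1L)) {
    warning("male heterozygote call(s) excluded from allele counting; run sanitize_male_hets()")
    gm[!is.na(gm) & gm == 1L] <- NA_integer_
  }
  gf <- g[!male]
  list(minor_f = sum(gf, na.rm = TRUE), total_f = 2L * sum(!is.na(gf)),
       minor_m = sum(gm, na.rm = TRUE) %/% 2L, total_m = sum(!is.na(gm)))
}

cohort_maf <- function(cohort) {
  vapply(seq_len(n_snps(cohort)), function(j) {
    ac <- suppressWarnings(allele_counts_by_sex(cohort, j))
    tot <- ac$total_f + ac$total_m
    if (tot == 0L) NA_real_ else (ac$minor_f + ac$minor_m) / tot
  }, numeric(1))
}

#' Relabel A1 so that it is the empirical minor allele
#'
#' Recomputes the counted allele per SNP from the data (females weighted
#' twice, males once) and swaps `a1`/`a2` — complementing genotype codes —
#' wherever the stored A1 is not the minor allele. Ties are broken
#' alphabetically. The PLINK text fileset cannot carry allele roles, so
#' readers infer them with this same rule; canonicalising first makes
#' binary/text round trips lossless.
#'
#' @param cohort an `x_cohort`.
#' @return The cohort with A1 = minor allele at every SNP.
#' @export
set_minor_first <- function(cohort) {
  for (j in seq_len(n_snps(cohort))) {
    ac <- suppressWarnings(allele_counts_by_sex(cohort, j))
    minor <- ac$minor_f + ac$minor_m
    total <- ac$total_f + ac$total_m
    a1 <- cohort$snps$a1[j]; a2 <- cohort$snps$a2[j]
    swap <- if (total == 0L) FALSE
            else if (2L * minor > total) TRUE
            else if (2L * minor == total) a2 < a1
            else FALSE
    if (swap) {
      cohort$snps$a1[j] <- a2; cohort$snps$a2[j] <- a1
      cohort$genotypes[, j] <- 2L - cohort$genotypes[, j]
    }
  }
  cohort
}
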