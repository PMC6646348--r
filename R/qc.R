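#' Per-sex missing call frequency
#'
#' @param cohort an `x_cohort` with at least one sample of each sex.
#' @return data.frame per SNP: `snp`, `miss_m`, `miss_f`, `miss_diff`
#'   (males minus females).
#' @export
missing_by_sex <- function(cohort) {
  male <- is_male(cohort)
  if (!any(male) || all(male)) stop("both sexes must be present")
  gm <- cohort$genotypes[male, , drop = FALSE]
  gf <- cohort$genotypes[!male, , drop = FALSE]
  data.frame(snp = cohort$snps$snp,
             miss_m = colMeans(is.na(gm)),
             miss_f = colMeans(is.na(gf)),
             miss_diff = colMeans(is.na(gm)) - colMeans(is.na(gf)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential missingness between sexes
#'
#' The PLINK `--test-missing` check with sex in the phenotype slot: per
#' SNP, a two-sided Fisher exact test of the 2x2 table of missing/called
#' status against sex.
#'
#' @param cohort an `x_cohort` with both sexes present.
#' @return the [missing_by_sex()] data.frame with an extra `p_diff` column.
#' @export
diff_missing_test <- function(cohort) {
  out <- missing_by_sex(cohort)
  male <- is_male(cohort)
  nm <- sum(male); nf <- sum(!male)
  out$p_diff <- vapply(seq_len(n_snps(cohort)), function(j) {
    mm <- sum(is.na(cohort$genotypes[male, j]))
    mf <- sum(is.na(cohort$genotypes[!male, j]))
    stats::fisher.test(matrix(c(mm, nm - mm, mf, nf - mf), 2))$p.value
  }, numeric(1))
  out
}

#' Sex-specific allele frequency comparison
#'
#' Minor-allele frequencies per sex (females contributing two alleles,
#' males one), with the female-vs-male minor-allele odds ratio (sample
#' cross-product ratio) and a two-sided Fisher exact p-value on the 2x2
#' allele-by-sex count table. A significant result warns that the marker
#' may misbehave in pooled-sex tests if the design is sex-unbalanced.
#'
#' @param cohort an `x_cohort` with called genotypes in both sexes.
#' @return data.frame per SNP: `snp`, `a1`, `maf_all`, `maf_f`, `maf_m`,
#'   `odds_ratio`, `p`.
#' @export
sex_allele_freq_test <- function(cohort) {
  rows <- lapply(seq_len(n_snps(cohort)), function(j) {
    ac <- allele_counts_by_sex(cohort, j)
    if (ac$total_f == 0L || ac$total_m == 0L)
      stop("SNP ", cohort$snps$snp[j], ": no called alleles in one sex")
    min_f <- ac$minor_f; maj_f <- ac$total_f - min_f
    min_m <- ac$minor_m; maj_m <- ac$total_m - min_m
    or <- (min_f / maj_f) / (min_m / maj_m)
    p <- stats::fisher.test(matrix(c(min_f, maj_f, min_m, maj_m), 2))$p.value
    data.frame(snp = cohort$snps$snp[j], a1 = cohort$snps$a1[j],
               maf_all = (min_f + min_m) / (ac$total_f + ac$total_m),
               maf_f = min_f / ac$total_f, maf_m = min_m / ac$total_m,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Minor-allele frequency by sample group
#'
#' Sex-weighted minor-allele frequency per SNP within arbitrary sample
#' groups (e.g. normal-BMI / overweight / obesity). The counted allele is
#' the cohort-wide A1, not re-estimated per group.
#'
#' @param cohort an `x_cohort`.
#' @param grouping vector of group labels, one per sample.
#' @return data.frame: `snp`, `group`, `a1`, `maf`.
#' @export
maf_by_group <- function(cohort, grouping) {
  grouping <- as.character(grouping)
  if (length(grouping) != n_samples(cohort))
    stop("grouping must have one label per sample")
  groups <- unique(grouping)
  rows <- list()
  for (g in groups) {
    sub <- cohort[grouping == g, ]
    if (n_samples(sub) == 0L) stop("empty group: ", g)
    for (j in seq_len(n_snps(sub))) {
      ac <- allele_counts_by_sex(sub, j)
      tot <- ac$total_f + ac$total_m
      rows[[length(rows) + 1L]] <- data.frame(
        snp = sub$snps$snp[j], group = g, a1 = sub$snps$a1[j],
        maf = if (tot == 0L) NA_real_ else (ac$minor_f + ac$minor_m) / tot,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Scan for male heterozygote calls
#'
#' Genotype calling run separately by sex should produce no heterozygote
#' calls in hemizygous males; any such call indicates an upstream error.
#'
#' @param cohort an `x_cohort`.
#' @return data.frame of incidents: `iid`, `snp`.
#' @export
male_het_scan <- function(cohort) {
  idx <- which(is_male(cohort) & !is.na(cohort$genotypes) & cohort$genotypes == 1L,
               arr.ind = TRUE)
  data.frame(iid = cohort$samples$iid[idx[, 1]],
             snp = cohort$snps$snp[idx[, 2]],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Set male heterozygote calls to missing
#'
#' @param cohort an `x_cohort`.
#' @param quiet suppress the message.
#' @return list with `cohort` (sanitized) and `incidents` (the
#'   [male_het_scan()] table of calls that were blanked).
#' @export
sanitize_male_hets <- function(cohort, quiet = FALSE) {
  inc <- male_het_scan(cohort)
  if (nrow(inc)) {
    bad <- is_male(cohort) & !is.na(cohort$genotypes) & cohort$genotypes == 1L
    cohort$genotypes[bad] <- NA_integer_
    if (!quiet)
      message("sanitized ", nrow(inc), " male heterozygote call(s) to missing")
  }
  list(cohort = cohort, incidents = inc)
}

#' Default QC thresholds
#'
#' The recommended X-chromosome SNP filters: female missing frequency at
#' most 2\%, differential-missingness Fisher p at least 1e-7, minor allele
#' frequency above 1\% in each sex, and female exact-HWE p (evaluated in
#' control females) at least 1e-4. Set any threshold to `NA` to disable
#' that criterion.
#'
#' @param female_miss_max maximum female missing call frequency.
#' @param diff_miss_p_min minimum differential-missingness p-value.
#' @param maf_min minimum per-sex minor allele frequency.
#' @param hwe_p_min minimum exact-HWE p-value in control females.
#' @export
qc_thresholds <- function(female_miss_max = 0.02, diff_miss_p_min = 1e-7,
                          maf_min = 0.01, hwe_p_min = 1e-4) {
  list(female_miss_max = female_miss_max, diff_miss_p_min = diff_miss_p_min,
       maf_min = maf_min, hwe_p_min = hwe_p_min)
}

#' Apply the X-specific SNP quality-control battery
#'
#' Evaluates the enabled criteria of [qc_thresholds()] per SNP and removes
#' any SNP failing at least one. A SNP fails the female-missingness
#' criterion when its female missing frequency strictly exceeds the
#' threshold; the HWE criterion is evaluated in control (phenotype 1)
#' females only.
#'
#' @param cohort an `x_cohort`.
#' @param thresholds list as returned by [qc_thresholds()].
#' @return list with `cohort` (filtered) and `report` (class `xqc_report`):
#'   per-SNP statistics, per-criterion pass flags, excluded SNP ids,
#'   male-heterozygote incident list and the thresholds used.
#' @export
apply_qc <- function(cohort, thresholds = qc_thresholds()) {
  th <- thresholds
  m <- n_snps(cohort)
  tab <- data.frame(snp = cohort$snps$snp, stringsAsFactors = FALSE)
  pass <- matrix(TRUE, m, 4, dimnames = list(cohort$snps$snp,
    c("female_miss", "diff_miss", "maf", "hwe")))
  miss <- diff_missing_test(cohort)
  tab$miss_f <- miss$miss_f; tab$miss_m <- miss$miss_m; tab$p_diff <- miss$p_diff
  if (!is.na(th$female_miss_max))
    pass[, "female_miss"] <- miss$miss_f <= th$female_miss_max
  if (!is.na(th$diff_miss_p_min))
    pass[, "diff_miss"] <- miss$p_diff >= th$diff_miss_p_min
  freq <- sex_allele_freq_test(cohort)
  tab$maf_f <- freq$maf_f; tab$maf_m <- freq$maf_m
  if (!is.na(th$maf_min))
    pass[, "maf"] <- pmin(freq$maf_f, freq$maf_m) >= th$maf_min
  tab$hwe_p <- NA_real_
  if (!is.na(th$hwe_p_min)) {
    ctrl_f <- is_female(cohort) & cohort$samples$phenotype == 1
    if (!any(ctrl_f)) stop("HWE criterion enabled but no control females present")
    for (j in seq_len(m)) {
      g <- cohort$genotypes[ctrl_f, j]
      cnt <- c(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
               sum(g == 0L, na.rm = TRUE))
      tab$hwe_p[j] <- if (sum(cnt)) hwe_exact(cnt[1], cnt[2], cnt[3])$p else NA_real_
    }
    pass[, "hwe"] <- !is.na(tab$hwe_p) & tab$hwe_p >= th$hwe_p_min
  }
  keep <- apply(pass, 1, all)
  report <- structure(list(table = tab, pass = pass,
                           excluded = cohort$snps$snp[!keep],
                           male_hets = male_het_scan(cohort),
                           thresholds = th),
                      class = "xqc_report")
  list(cohort = cohort[, keep], report = report)
}

#' @export
print.xqc_report <- function(x, ...) {
  cat("X-chromosome SNP QC report\n")
  en <- !vapply(x$thresholds, is.na, logical(1))
  cat("  enabled criteria:", paste(names(x$thresholds)[en], collapse = ", "), "\n")
  cat("  SNPs excluded:", length(x$excluded),
      if (length(x$excluded)) paste0("(", paste(x$excluded, collapse = ", "), ")") else "",
      "\n")
  cat("  male heterozygote incidents:", nrow(x$male_hets), "\n")
  df <- cbind(x$table, pass = apply(x$pass, 1, all))
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write PLINK-dialect QC report files
#'
#' Emits TSV reports in the dialects of PLINK's `.hwe`, `.frq` and
#' `.missing` outputs plus the per-criterion QC decision table.
#'
#' @param cohort an `x_cohort`.
#' @param dir output directory (created if absent).
#' @param prefix file name prefix.
#' @param report optional `xqc_report` from [apply_qc()].
#' @return character vector of file paths, invisibly.
#' @export
write_qc_reports <- function(cohort, dir, prefix = "xchrom", report = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  hwe <- hwe_female_table(cohort)
  chr <- cohort$snps$chr[match(hwe$snp, cohort$snps$snp)]
  hwetab <- data.frame(CHR = chr, SNP = hwe$snp, TEST = hwe$test, A1 = hwe$a1,
                       GENO = hwe$geno, `O.HET.` = round(hwe$o_het, 4),
                       `E.HET.` = round(hwe$e_het, 4), P = signif(hwe$p, 4),
                       check.names = FALSE)
  p <- file.path(dir, paste0(prefix, ".hwe")); paths <- c(paths, p)
  utils::write.table(hwetab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  freq <- sex_allele_freq_test(cohort)
  frqtab <- data.frame(CHR = cohort$snps$chr, SNP = freq$snp, A1 = freq$a1,
                       A2 = cohort$snps$a2, MAF = round(freq$maf_all, 4),
                       MAF_F = round(freq$maf_f, 4), MAF_M = round(freq$maf_m, 4),
                       OR = round(freq$odds_ratio, 4), P = signif(freq$p, 4))
  p <- file.path(dir, paste0(prefix, ".frq")); paths <- c(paths, p)
  utils::write.table(frqtab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  miss <- diff_missing_test(cohort)
  misstab <- data.frame(CHR = cohort$snps$chr, SNP = miss$snp,
                        F_MISS_M = round(miss$miss_m, 4),
                        F_MISS_F = round(miss$miss_f, 4),
                        DIFF = round(miss$miss_diff, 4), P = signif(miss$p_diff, 4))
  p <- file.path(dir, paste0(prefix, ".missing")); paths <- c(paths, p)
  utils::write.table(misstab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report)) {
    dec <- cbind(report$table, report$pass, overall = apply(report$pass, 1, all))
    p <- file.path(dir, paste0(prefix, ".qc_decisions.tsv")); paths <- c(paths, p)
    utils::write.table(dec, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
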