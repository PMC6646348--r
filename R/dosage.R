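#' XCI-aware dosage coding of X-chromosome genotypes
#'
#' Converts minor-allele genotype codes into the numeric dosages used by
#' regressions and score tests. Females are coded 0/1/2 by allele count
#' under either model. Hemizygous males depend on the X-inactivation model
#' assumed for the locus: under `"inactivation"` a male carrier is
#' equivalent to a homozygous female (codes 0/2); under `"escape"` both
#' female alleles are expressed and a male carries one dose (codes 0/1).
#' The dominance component `h` indicates female heterozygotes and is 0 for
#' every male.
#'
#' @param genotypes integer vector or matrix of codes {0,1,2,NA}; male
#'   entries on the hemizygous 0/2 scale.
#' @param sexes integer vector (1 = male, 2 = female), recycled along rows
#'   for a matrix.
#' @param xci_model `"inactivation"` or `"escape"`.
#' @return list with components `x` (additive dosage) and `h` (female
#'   heterozygosity indicator), each shaped like `genotypes`.
#' @export
xci_code <- function(genotypes, sexes, xci_model = c("inactivation", "escape")) {
  xci_model <- match.arg(xci_model)
  g <- genotypes
  mat <- is.matrix(g)
  sex <- as.integer(sexes)
  if (!all(sex %in% c(1L, 2L))) stop("sex codes must be 1 or 2")
  nrep <- if (mat) nrow(g) else length(g)
  if (length(sex) != nrep) stop("sexes length must match genotypes")
  male <- sex == 1L
  gm <- if (mat) g[male, , drop = FALSE] else g[male]
  if (any(!is.na(gm) & gm == 1L))
    stop("male heterozygote call encountered; run sanitize_male_hets() first")
  x <- g * 1.0
  if (xci_model == "escape") {
    if (mat) x[male, ] <- x[male, , drop = FALSE] / 2 else x[male] <- x[male] / 2
  }
  h <- (g == 1L) * 1.0
  if (mat) h[male, ] <- ifelse(is.na(gm), NA_real_, 0) else
    h[male] <- ifelse(is.na(gm), NA_real_, 0)
  list(x = x, h = h)
}

#' Export a per-sample, per-SNP dosage table
#'
#' @param cohort an `x_cohort`, sanitized of male heterozygote calls.
#' @param xci_model X-inactivation model for male coding (see [xci_code()]).
#' @return numeric matrix of additive dosages (samples x SNPs).
#' @export
export_dosage <- function(cohort, xci_model = c("inactivation", "escape")) {
  xci_model <- match.arg(xci_model)
  xci_code(cohort$genotypes, cohort$samples$sex, xci_model)$x
}
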