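# Sex-stratified score machinery shared by the Clayton tests.
#
# Within each sex stratum s, with phenotype y centred at the stratum mean,
#   U_s = sum_i (y_i - ybar_s) z_i            (z = dosage columns)
#   V_s = [sum_i (y_i - ybar_s)^2] * S_s
# where S_s is the within-stratum covariance matrix of z with the n/(n-1)
# finite-sample factor (i.e. the sample covariance). The statistic is
# U' V^- U on df = rank(V). For a single additive column in one stratum
# this reduces to (n-1) * cor(z, y)^2, the linear-by-linear form of the
# Cochran-Armitage trend test.
stratified_score <- function(z, y, stratum) {
  z <- as.matrix(z)
  ok <- stats::complete.cases(z, y, stratum)
  z <- z[ok, , drop = FALSE]; y <- y[ok]; stratum <- stratum[ok]
  n <- length(y)
  k <- ncol(z)
  if (n < 2L || length(unique(y)) < 2L)
    return(list(ok = FALSE, reason = "fewer than two distinct phenotype values", n = n))
  U <- numeric(k); V <- matrix(0, k, k)
  for (s in unique(stratum)) {
    i <- stratum == s
    ns <- sum(i)
    if (ns < 2L) next
    yc <- y[i] - mean(y[i])
    zc <- sweep(z[i, , drop = FALSE], 2, colMeans(z[i, , drop = FALSE]))
    U <- U + drop(crossprod(zc, yc))
    V <- V + sum(yc^2) * crossprod(zc) / (ns - 1)
  }
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  rank <- sum(ev > max(1e-12, max(ev, 0) * 1e-10))
  if (rank == 0L)
    return(list(ok = FALSE, reason = "zero score variance (constant dosage or phenotype within strata)",
                n = n))
  stat <- drop(t(U) %*% MASS::ginv(V) %*% U)
  list(ok = TRUE, statistic = stat, df = rank,
       p = stats::pchisq(stat, rank, lower.tail = FALSE), n = n)
}

score_htest <- function(res, method, data_name) {
  if (!res$ok)
    return(structure(list(statistic = c("X-squared" = NA_real_),
                          parameter = c(df = NA_real_), p.value = NA_real_,
                          method = method, data.name = data_name,
                          n = res$n, reason = res$reason), class = "htest"))
  structure(list(statistic = c("X-squared" = res$statistic),
                 parameter = c(df = res$df), p.value = res$p,
                 method = method, data.name = data_name, n = res$n),
            class = "htest")
}

# Phenotypes arrive either as 1/2 affection codes or as quantitative
# values; affection is mapped to 0/1 so both flow through the same score.
as_score_phenotype <- function(y) {
  y <- as.numeric(y)
  y[y == -9] <- NA_real_
  if (all(y %in% c(1, 2, NA_real_)) && any(!is.na(y))) y <- y - 1
  y
}

#' Clayton 1-df X-chromosome score test (S1)
#'
#' Sex-stratified score test of the additive XCI-aware dosage against a
#' binary or quantitative phenotype; the X-chromosome analogue of the
#' Cochran-Armitage trend test on the combined male and female genotype
#' table. Restricted to females it equals the (n-1) r-squared form of the
#' classical trend statistic. Chi-squared on 1 df under the null.
#'
#' @param dosage numeric additive dosage vector under an XCI model
#'   (see [xci_code()]).
#' @param phenotype numeric vector; affection codes 1/2 are mapped to 0/1,
#'   -9 to missing. Pairs with missing dosage or phenotype are excluded.
#' @param sexes integer vector (1 = male, 2 = female), the strata.
#' @return An `htest` with `statistic`, `parameter` (df), `p.value` and
#'   `n`; statistic `NA` with a `reason` when undefined.
#' @export
clayton_s1 <- function(dosage, phenotype, sexes) {
  y <- as_score_phenotype(phenotype)
  score_htest(stratified_score(cbind(x = dosage), y, sexes),
              "Clayton S1 (sex-stratified 1-df score / trend test)",
              deparse(substitute(dosage)))
}

#' Clayton 2-df X-chromosome score test (S2)
#'
#' Bivariate extension of [clayton_s1()] adding a female-heterozygote
#' dominance component; the X analogue of the 2-df Pearson test of the
#' combined genotype table. The variance matrix is inverted generalised;
#' the degrees of freedom equal its rank (2 in regular data, 1 when the
#' dominance column is degenerate, e.g. males only).
#'
#' @param dosage additive dosage vector (see [xci_code()]).
#' @param het female-heterozygote indicator (`h` from [xci_code()]); if
#'   `NULL`, derived as `dosage == 1` for females.
#' @param phenotype,sexes as in [clayton_s1()].
#' @return An `htest` (see [clayton_s1()]); `parameter` carries the rank.
#' @export
clayton_s2 <- function(dosage, phenotype, sexes, het = NULL) {
  if (is.null(het)) {
    het <- ifelse(is.na(dosage), NA_real_, as.numeric(dosage == 1 & sexes == 2L))
  }
  y <- as_score_phenotype(phenotype)
  score_htest(stratified_score(cbind(x = dosage, h = het), y, sexes),
              "Clayton S2 (sex-stratified 2-df score test)",
              deparse(substitute(dosage)))
}

#' Female-only Cochran-Armitage trend test
#'
#' Ignores males entirely and tests the female genotype codes for trend
#' in the (n-1) r-squared convention; for a quantitative phenotype this is
#' the female-stratum score test.
#'
#' @param cohort an `x_cohort`.
#' @param snp SNP id or column index.
#' @param phenotype `"affection"` or the name of a quantitative phenotype
#'   column; alternatively a numeric vector, one value per sample.
#' @return An `htest`.
#' @export
female_trend_test <- function(cohort, snp, phenotype = "affection") {
  j <- resolve_snp(cohort, snp)
  y <- resolve_phenotype(cohort, phenotype)
  fem <- is_female(cohort)
  res <- stratified_score(cbind(x = as.numeric(cohort$genotypes[fem, j])),
                          as_score_phenotype(y[fem]),
                          rep(2L, sum(fem)))
  score_htest(res, "Cochran-Armitage trend test (females only)",
              cohort$snps$snp[j])
}

#' Male-only allelic association test
#'
#' Fisher exact test of the 2x2 table of male A1/A2 allele counts against
#' case-control status, the allele-based test appropriate to hemizygous
#' males.
#'
#' @param cohort an `x_cohort` sanitized of male heterozygote calls.
#' @param snp SNP id or column index.
#' @param phenotype binary phenotype (defaults to affection status 1/2).
#' @return An `htest` with the sample odds ratio (cases vs controls) in
#'   `estimate` and the Fisher exact p-value.
#' @export
male_allelic_test <- function(cohort, snp, phenotype = "affection") {
  j <- resolve_snp(cohort, snp)
  y <- as_score_phenotype(resolve_phenotype(cohort, phenotype))
  if (!all(y %in% c(0, 1, NA_real_))) stop("male allelic test needs a binary phenotype")
  male <- is_male(cohort)
  g <- cohort$genotypes[male, j]
  if (any(!is.na(g) & g == 1L)) stop("male heterozygote call encountered")
  ym <- y[male]
  ok <- !is.na(g) & !is.na(ym)
  a_case <- sum(g[ok & ym == 1] == 2L); b_case <- sum(g[ok & ym == 1] == 0L)
  a_ctrl <- sum(g[ok & ym == 0] == 2L); b_ctrl <- sum(g[ok & ym == 0] == 0L)
  p <- stats::fisher.test(matrix(c(a_case, b_case, a_ctrl, b_ctrl), 2))$p.value
  or <- (a_case / b_case) / (a_ctrl / b_ctrl)
  structure(list(statistic = NULL, estimate = c("odds ratio" = or),
                 p.value = p, method = "Male allelic Fisher exact test",
                 data.name = cohort$snps$snp[j], n = sum(ok)),
            class = "htest")
}

#' Unstratified (naive) trend test on pooled sexes
#'
#' The pooled-sample trend statistic `(n-1) r^2` with no sex
#' stratification. Provided as the comparator whose type-I error inflates
#' under sex-specific allele frequencies combined with a sex-unbalanced
#' case-control design; the stratified [clayton_s1()] is the protected
#' alternative.
#'
#' @param dosage,phenotype numeric vectors.
#' @return An `htest`.
#' @export
pooled_trend_test <- function(dosage, phenotype) {
  y <- as_score_phenotype(phenotype)
  res <- stratified_score(cbind(x = dosage), y, rep(1L, length(y)))
  score_htest(res, "Unstratified trend test (pooled sexes)",
              deparse(substitute(dosage)))
}

resolve_snp <- function(cohort, snp) {
  j <- if (is.character(snp)) match(snp, cohort$snps$snp) else as.integer(snp)
  if (is.na(j) || j < 1L || j > n_snps(cohort)) stop("unknown SNP: ", snp)
  j
}

resolve_phenotype <- function(cohort, phenotype) {
  if (is.numeric(phenotype) && length(phenotype) == n_samples(cohort))
    return(phenotype)
  if (identical(phenotype, "affection")) return(cohort$samples$phenotype)
  if (!is.null(cohort$qt) && phenotype %in% names(cohort$qt))
    return(cohort$qt[[phenotype]])
  stop("unknown phenotype: ", phenotype)
}

#' Clayton X-chromosome association test for one SNP
#'
#' The high-level fitting interface: codes the genotypes under the chosen
#' X-inactivation model and runs both Clayton score statistics (S1, 1 df;
#' S2, 2 df) of dosage against phenotype, stratified by sex.
#'
#' @param cohort an `x_cohort` sanitized of male heterozygote calls.
#' @param snp SNP id or column index.
#' @param phenotype `"affection"`, a quantitative phenotype name, or a
#'   numeric vector per sample.
#' @param xci_model X-inactivation model for male dosage coding.
#' @return An object of class `clayton_test`: list with `snp`,
#'   `phenotype`, `xci_model`, `n`, `chi2_1df`, `p_1df`, `chi2_2df`,
#'   `p_2df`, `df_2df` and the two underlying `htest` objects.
#' @export
clayton_test <- function(cohort, snp, phenotype = "affection",
                         xci_model = c("inactivation", "escape")) {
  xci_model <- match.arg(xci_model)
  j <- resolve_snp(cohort, snp)
  y <- resolve_phenotype(cohort, phenotype)
  d <- xci_code(cohort$genotypes[, j], cohort$samples$sex, xci_model)
  s1 <- clayton_s1(d$x, y, cohort$samples$sex)
  s2 <- clayton_s2(d$x, y, cohort$samples$sex, het = d$h)
  structure(list(snp = cohort$snps$snp[j],
                 phenotype = if (is.character(phenotype)) phenotype else "phenotype",
                 xci_model = xci_model,
                 n = s1$n,
                 chi2_1df = unname(s1$statistic), p_1df = s1$p.value,
                 chi2_2df = unname(s2$statistic), p_2df = s2$p.value,
                 df_2df = unname(s2$parameter),
                 s1 = s1, s2 = s2),
            class = "clayton_test")
}

#' @export
print.clayton_test <- function(x, ...) {
  cat("Clayton X-chromosome score tests (", x$xci_model, " model)\n", sep = "")
  cat("  SNP ", x$snp, ", phenotype ", x$phenotype, ", n = ", x$n, "\n", sep = "")
  cat(sprintf("  S1: chi2 = %.3f on 1 df, p = %.4g\n", x$chi2_1df, x$p_1df))
  cat(sprintf("  S2: chi2 = %.3f on %s df, p = %.4g\n", x$chi2_2df,
              format(x$df_2df), x$p_2df))
  invisible(x)
}

#' Association table across SNPs and phenotypes
#'
#' Runs [clayton_test()] for every (SNP, phenotype) pair with
#' pairwise-complete samples, producing the standard report layout
#' (SNP, N, chi-squared 1 df, chi-squared 2 df, p 1 df, p 2 df, grouped by
#' phenotype).
#'
#' @param cohort an `x_cohort` sanitized of male heterozygote calls.
#' @param phenotypes character vector of phenotype names (`"affection"`
#'   and/or quantitative column names).
#' @param xci_model X-inactivation model for male dosage coding.
#' @return data.frame of class `xassoc_table`.
#' @export
assoc_table <- function(cohort, phenotypes = "affection",
                        xci_model = c("inactivation", "escape")) {
  xci_model <- match.arg(xci_model)
  rows <- list()
  for (ph in phenotypes) {
    for (j in seq_len(n_snps(cohort))) {
      ct <- clayton_test(cohort, j, ph, xci_model)
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype = ph, snp = ct$snp, n = ct$n,
        chi2_1df = ct$chi2_1df, chi2_2df = ct$chi2_2df,
        p_1df = ct$p_1df, p_2df = ct$p_2df, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("xassoc_table", "data.frame")
  attr(out, "xci_model") <- xci_model
  out
}

#' @export
print.xassoc_table <- function(x, ...) {
  cat("X-chromosome association results (", attr(x, "xci_model"),
      " model)\n", sep = "")
  df <- as.data.frame(x)
  df$chi2_1df <- round(df$chi2_1df, 3); df$chi2_2df <- round(df$chi2_2df, 3)
  df$p_1df <- signif(df$p_1df, 3); df$p_2df <- signif(df$p_2df, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an association table as TSV
#'
#' @param table an `xassoc_table`.
#' @param path output file.
#' @export
write_assoc_table <- function(table, path) {
  df <- as.data.frame(table)
  names(df) <- c("Phenotype", "SNP", "N", "Chi.squared.1.df", "Chi.squared.2.df",
                 "P.1df", "P.2df")[seq_along(names(df))]
  df <- df[, c("Phenotype", "SNP", "N", "Chi.squared.1.df", "Chi.squared.2.df",
               "P.1df", "P.2df")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' XCI-aware regression on dosage
#'
#' Thin convenience wrapping [stats::glm()]: regresses a phenotype on the
#' XCI-coded additive dosage with a sex adjustment and optional covariates.
#' Binary phenotypes (affection 1/2) use a logistic link, quantitative
#' phenotypes a Gaussian one.
#'
#' @param cohort an `x_cohort` sanitized of male heterozygote calls.
#' @param snp SNP id or column index.
#' @param phenotype phenotype name or numeric vector (see [clayton_test()]).
#' @param xci_model X-inactivation model for male dosage coding.
#' @param covariates optional data.frame of covariates, one row per sample.
#' @return The fitted `glm` object.
#' @export
xci_glm <- function(cohort, snp, phenotype = "affection",
                    xci_model = c("inactivation", "escape"), covariates = NULL) {
  xci_model <- match.arg(xci_model)
  j <- resolve_snp(cohort, snp)
  y <- as_score_phenotype(resolve_phenotype(cohort, phenotype))
  dosage <- xci_code(cohort$genotypes[, j], cohort$samples$sex, xci_model)$x
  dat <- data.frame(y = y, dosage = dosage,
                    sex = factor(cohort$samples$sex, levels = c(1, 2),
                                 labels = c("male", "female")))
  form <- y ~ dosage + sex
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(c("dosage", "sex", names(covariates)), "y")
  }
  fam <- if (all(y %in% c(0, 1, NA_real_))) stats::binomial() else stats::gaussian()
  stats::glm(form, family = fam, data = dat)
}
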