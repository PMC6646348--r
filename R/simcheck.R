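#' Monte-Carlo operating characteristics of the X-chromosome tests
#'
#' Simulates `n_reps` cohorts from a configuration, applies the requested
#' tests to a designated SNP, and records empirical rejection rates at each
#' nominal alpha. Under a null configuration the rate estimates type-I
#' error; under an effect configuration, power. Tests undefined on a
#' replicate (degenerate data) are excluded from the denominator; a test
#' undefined on more than 10\% of replicates is flagged.
#'
#' @param config a [sim_config()].
#' @param tests subset of `c("s1", "s2", "trendF", "alleleM", "pooled")`.
#'   `"pooled"` is the unstratified naive trend comparator.
#' @param alphas nominal significance levels.
#' @param n_reps number of replicates (at least 100).
#' @param seed integer seed for the whole experiment.
#' @param snp index of the SNP tested (default: the first).
#' @return Object of class `scenario_result`: data.frame of rejection
#'   rates (`test`, `alpha`, `rate`, `n_defined`, `band_lo`, `band_hi`
#'   where the band is the 99\% binomial interval around alpha), with the
#'   replicate p-values in `attr(, "pvals")`.
#' @export
run_scenario <- function(config, tests = c("s1", "s2"),
                         alphas = c(0.05, 0.01), n_reps = 2000L,
                         seed = config$seed, snp = 1L) {
  tests <- match.arg(tests, c("s1", "s2", "trendF", "alleleM", "pooled"),
                     several.ok = TRUE)
  if (n_reps < 100L) stop("n_reps must be at least 100")
  pheno_name <- if (config$effect == "quantitative_linear") config$qt_name else "affection"
  pv <- matrix(NA_real_, n_reps, length(tests), dimnames = list(NULL, tests))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      sim <- simulate_cohort(config, seed = NULL)
      ch <- sim$cohort
      y <- resolve_phenotype(ch, pheno_name)
      d <- xci_code(ch$genotypes[, snp], ch$samples$sex, config$xci_model)
      for (t in tests) {
        pv[r, t] <- switch(t,
          s1 = clayton_s1(d$x, y, ch$samples$sex)$p.value,
          s2 = clayton_s2(d$x, y, ch$samples$sex, het = d$h)$p.value,
          trendF = female_trend_test(ch, snp, pheno_name)$p.value,
          alleleM = male_allelic_test(ch, snp, pheno_name)$p.value,
          pooled = pooled_trend_test(d$x, y)$p.value)
      }
    }
  })
  rows <- list()
  for (t in tests) {
    defined <- sum(!is.na(pv[, t]))
    if (defined < 0.9 * n_reps)
      warning("test ", t, " undefined on more than 10% of replicates")
    for (a in alphas) {
      band <- stats::qbinom(c(0.005, 0.995), defined, a) / max(defined, 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        test = t, alpha = a,
        rate = mean(pv[, t] < a, na.rm = TRUE),
        n_defined = defined, band_lo = band[1], band_hi = band[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("scenario_result", "data.frame")
  attr(out, "n_reps") <- n_reps
  attr(out, "seed") <- seed
  attr(out, "pvals") <- pv
  out
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Monte-Carlo scenario (", attr(x, "n_reps"), " reps, seed ",
      format(attr(x, "seed")), ")\n", sep = "")
  df <- as.data.frame(x)
  df$rate <- round(df$rate, 4)
  df$band <- sprintf("[%.3f, %.3f]", df$band_lo, df$band_hi)
  print(df[, c("test", "alpha", "rate", "n_defined", "band")], row.names = FALSE)
  invisible(x)
}

#' Bundled study-design scenarios
#'
#' Five single-SNP configurations spanning the situations that drive
#' X-chromosome test selection:
#' \describe{
#'   \item{balanced_null}{the study margins (roughly balanced sex ratio in
#'     both groups), equal allele frequencies in the sexes, no effect.}
#'   \item{unbalanced_null}{sex-specific allele frequencies (0.37 female /
#'     0.30 male) with a strongly sex-unbalanced design (controls 80\%
#'     female, cases 30\% female), no effect — the situation in which a
#'     pooled test's type-I error inflates.}
#'   \item{xci_additive}{additive risk effect under complete inactivation.}
#'   \item{escape_additive}{additive risk effect under escape from
#'     inactivation.}
#'   \item{dominance_only}{a female-heterozygote-only quantitative effect,
#'     where the 2-df S2 outpowers the 1-df S1.}
#' }
#'
#' @param n_total total sample size of each scenario (study size by
#'   default).
#' @param beta effect size used by the effect scenarios.
#' @return named list of `sim_config` objects with fixed seeds.
#' @export
paper_scenarios <- function(n_total = 915L, beta = 0.35) {
  one_snp <- function(p_f, p_m, f = 0, beta. = 0, beta_dom = 0)
    data.frame(snp = "snp1", a1 = "A", a2 = "G", p_f = p_f, p_m = p_m, f = f,
               miss_f = 0, miss_m = 0, beta = beta., beta_dom = beta_dom,
               stringsAsFactors = FALSE)
  nf <- round(n_total * 477 / 915); nm <- n_total - nf
  balanced <- c(round(nf * 122 / 477), round(nm * 136 / 438), NA, NA)
  ctrl <- round(n_total * 258 / 915)
  unbal <- c(round(0.8 * ctrl), ctrl - round(0.8 * ctrl), NA, NA)
  nf_unbal <- round(0.8 * ctrl) + round(0.3 * (n_total - ctrl))
  list(
    balanced_null = sim_config(one_snp(0.3, 0.3), nf, nm,
                               group_counts = balanced, effect = "null",
                               seed = 101L),
    unbalanced_null = sim_config(one_snp(0.37, 0.30), nf_unbal,
                                 n_total - nf_unbal, group_counts = unbal,
                                 effect = "null", seed = 102L),
    xci_additive = sim_config(one_snp(0.3, 0.3, beta. = beta), nf, nm,
                              group_counts = balanced,
                              effect = "binary_logistic",
                              xci_model = "inactivation", seed = 103L),
    escape_additive = sim_config(one_snp(0.3, 0.3, beta. = beta), nf, nm,
                                 group_counts = balanced,
                                 effect = "binary_logistic",
                                 xci_model = "escape", seed = 104L),
    dominance_only = sim_config(one_snp(0.3, 0.3, beta_dom = 2 * beta), nf, nm,
                                group_counts = balanced,
                                effect = "quantitative_linear", seed = 105L))
}

#' Write a scenario result as TSV
#'
#' @param result a `scenario_result`.
#' @param path output file.
#' @export
write_scenario_result <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
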