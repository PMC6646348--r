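# run expr under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration for a synthetic X-chromosome cohort
#'
#' Defines the generative model behind [simulate_cohort()]: sex-specific
#' minor-allele frequencies per SNP, a female Hardy-Weinberg-disequilibrium
#' coefficient `f` (heterozygote frequency `2pq(1-f)`, so `f > 0` is a
#' heterozygote deficit), per-sex missing-call probabilities, the
#' case-control sex margins, and an optional phenotype effect model.
#'
#' @param snps data.frame with one row per SNP: `snp`, `a1`, `a2`, `p_f`,
#'   `p_m` (female/male minor-allele frequencies in (0,1)), `f`
#'   (HWD coefficient, `[-1,1]`), `miss_f`, `miss_m` (per-sex missing
#'   probabilities), optional `bp`, `chr`, `beta`, `beta_dom`.
#' @param n_females,n_males sample counts.
#' @param group_counts named or positional vector
#'   (control females, control males, case females, case males); must sum
#'   to the sex totals.
#' @param effect `"null"` (affection independent of genotype),
#'   `"binary_logistic"` (affection from a logistic dosage model, margins
#'   then matched by stratified rejection sampling) or
#'   `"quantitative_linear"` (Gaussian trait on dosage).
#' @param xci_model X-inactivation model used to build the latent dosage
#'   that drives effects.
#' @param alpha logistic intercept (default: logit of the configured case
#'   fraction).
#' @param gamma additive sex effect (on males) in either effect model.
#' @param sigma residual standard deviation of the quantitative trait.
#' @param qt_name name of the generated quantitative phenotype column.
#' @param seed default seed used by [simulate_cohort()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(snps, n_females, n_males,
                       group_counts = NULL,
                       effect = c("null", "binary_logistic", "quantitative_linear"),
                       xci_model = c("inactivation", "escape"),
                       alpha = NULL, gamma = 0, sigma = 1,
                       qt_name = "trait", seed = 20190722L) {
  effect <- match.arg(effect)
  xci_model <- match.arg(xci_model)
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("snp", "a1", "a2", "p_f", "p_m", "f", "miss_f", "miss_m")
  if (!all(need %in% names(snps)))
    stop("snps must have columns: ", paste(need, collapse = ", "))
  if (is.null(snps$bp)) snps$bp <- seq_len(nrow(snps))
  if (is.null(snps$chr)) snps$chr <- 23L
  if (is.null(snps$beta)) snps$beta <- 0
  if (is.null(snps$beta_dom)) snps$beta_dom <- 0
  stopifnot(all(snps$p_f > 0 & snps$p_f < 1), all(snps$p_m > 0 & snps$p_m < 1),
            all(snps$f >= -1 & snps$f <= 1),
            all(snps$miss_f >= 0 & snps$miss_f < 1),
            all(snps$miss_m >= 0 & snps$miss_m < 1))
  for (j in seq_len(nrow(snps))) {
    pr <- female_geno_probs(snps$p_f[j], snps$f[j])
    if (any(pr < -1e-12))
      stop("negative female genotype probability at SNP ", snps$snp[j],
           " (f too negative for this frequency)")
  }
  if (is.null(group_counts))
    group_counts <- c(ctrl_f = round(n_females * 0.28), ctrl_m = round(n_males * 0.31),
                      case_f = NA, case_m = NA)
  group_counts <- as.integer(group_counts)
  if (anyNA(group_counts[3:4]))
    group_counts[3:4] <- c(n_females - group_counts[1], n_males - group_counts[2])
  names(group_counts) <- c("ctrl_f", "ctrl_m", "case_f", "case_m")
  if (group_counts["ctrl_f"] + group_counts["case_f"] != n_females ||
      group_counts["ctrl_m"] + group_counts["case_m"] != n_males)
    stop("group_counts must sum to the per-sex totals")
  if (is.null(alpha)) {
    pcase <- (group_counts["case_f"] + group_counts["case_m"]) / (n_females + n_males)
    alpha <- log(pcase / (1 - pcase))
  }
  structure(list(snps = snps, n_females = as.integer(n_females),
                 n_males = as.integer(n_males), group_counts = group_counts,
                 effect = effect, xci_model = xci_model, alpha = unname(alpha),
                 gamma = gamma, sigma = sigma, qt_name = qt_name,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# P(genotype code 2, 1, 0) for a female under the f-adjusted trinomial
female_geno_probs <- function(p, f) {
  q <- 1 - p
  c(p2 = p^2 + f * p * q, p1 = 2 * p * q * (1 - f), p0 = q^2 + f * p * q)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_females, " F / ", x$n_males, " M, ",
      nrow(x$snps), " SNPs, effect = ", x$effect,
      " (", x$xci_model, "), seed = ", x$seed, "\n", sep = "")
  cat("  groups: controls ", x$group_counts["ctrl_f"], "F/",
      x$group_counts["ctrl_m"], "M, cases ", x$group_counts["case_f"], "F/",
      x$group_counts["case_m"], "M\n", sep = "")
  print(x$snps, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Default configuration emulating the study cohort
#'
#' Eight X-linked SNPs (seven in TNMD, one in SLC6A14) with the published
#' sex-specific minor-allele frequencies, per-sex missing-call rates, and a
#' female heterozygote-deficit coefficient per SNP calibrated from the
#' published observed/expected female heterozygosities
#' (`f = 1 - O(HET)/E(HET)`). Margins: 915 children, 477 females / 438
#' males; 258 controls (122 F / 136 M) and 657 cases (355 F / 302 M).
#' Effect model: null.
#'
#' @param ... overrides passed to [sim_config()] (e.g. `effect`, `seed`).
#' @return A `sim_config`.
#' @export
default_sim_config <- function(...) {
  snps <- data.frame(
    snp = c("rs11798018", "rs5966709", "rs4828037", "rs2073162",
            "rs2073163", "rs4828038", "rs1155974", "rs2011162"),
    chr = 23L,
    bp = c(100584572L, 100589508L, 100590686L, 100594019L,
           100594053L, 100596678L, 100598283L, 116459132L),
    a1 = c("A", "T", "C", "A", "C", "T", "T", "C"),
    a2 = c("C", "G", "T", "G", "T", "C", "C", "G"),
    p_f = c(0.26, 0.32, 0.34, 0.45, 0.46, 0.45, 0.44, 0.37),
    p_m = c(0.27, 0.31, 0.33, 0.42, 0.43, 0.42, 0.42, 0.30),
    # heterozygote deficit from printed O(HET)/E(HET) in all females
    f = 1 - c(0.38 / 0.39, 0.37 / 0.44, 0.38 / 0.45, 0.36 / 0.50,
              0.34 / 0.50, 0.36 / 0.50, 0.36 / 0.49, 0.38 / 0.47),
    miss_f = c(0.04, 0.004, 0.01, 0.008, 0.09, 0.002, 0.002, 0.02),
    miss_m = c(0.11, 0.06, 0.06, 0.08, 0.14, 0.07, 0.08, 0.07),
    stringsAsFactors = FALSE)
  args <- list(...)
  defaults <- list(snps = snps, n_females = 477L, n_males = 438L,
                   group_counts = c(122L, 136L, 355L, 302L))
  do.call(sim_config, utils::modifyList(defaults, args))
}

#' Simulate a cohort from a configuration
#'
#' Female genotypes are drawn from the f-adjusted trinomial, male
#' genotypes as Bernoulli(p_m) hemizygotes on the 0/2 scale. Phenotypes
#' follow the configured effect model; under `binary_logistic` the
#' case-control sex margins are matched to the configuration by per-sex
#' rejection sampling (the study fixes margins by recruitment). Missing
#' calls are applied last, independently per (sample, SNP) within sex.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; `config$seed` by default, `NULL` to draw from
#'   the current RNG stream.
#' @param max_tries rejection-sampling cap for margin matching.
#' @return list of class `x_sim` with `cohort` (an `x_cohort`) and `truth`
#'   (the config, the realized per-SNP allele frequencies, the latent
#'   dosage matrix before missingness and the seed used).
#' @export
simulate_cohort <- function(config, seed = config$seed, max_tries = 10000L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    nf <- config$n_females; nm <- config$n_males
    n <- nf + nm
    m <- nrow(config$snps)
    sex <- c(rep(2L, nf), rep(1L, nm))
    geno <- matrix(NA_integer_, n, m)
    for (j in seq_len(m)) {
      pr <- pmax(female_geno_probs(config$snps$p_f[j], config$snps$f[j]), 0)
      geno[seq_len(nf), j] <- sample(c(2L, 1L, 0L), nf, replace = TRUE, prob = pr)
      geno[nf + seq_len(nm), j] <- 2L * stats::rbinom(nm, 1L, config$snps$p_m[j])
    }
    dosage <- xci_code(geno, sex, config$xci_model)$x
    hdom <- (geno == 1L & sex == 2L) * 1.0
    gc <- config$group_counts
    phenotype <- integer(n)
    if (config$effect == "binary_logistic") {
      eta <- drop(dosage %*% config$snps$beta + hdom %*% config$snps$beta_dom +
                    config$gamma * (sex == 1L))
      for (s in c(2L, 1L)) {
        target <- if (s == 2L) gc["case_f"] else gc["case_m"]
        idx <- which(sex == s)
        # calibrate the stratum intercept so the expected case count hits the
        # target; the configured alpha is the starting point, margins are
        # design constants fixed by recruitment
        a_s <- tryCatch(
          stats::uniroot(function(a) mean(stats::plogis(a + eta[idx])) -
                           target / length(idx),
                         c(-30, 30))$root,
          error = function(e) config$alpha)
        pcase <- stats::plogis(a_s + eta[idx])
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          y <- stats::rbinom(length(idx), 1L, pcase)
          if (sum(y) == target) { ok <- TRUE; break }
        }
        if (!ok) stop("could not match group sex counts in ", max_tries,
                      " attempts; margins unattainable under this model")
        phenotype[idx] <- y + 1L
      }
    } else {
      # affection independent of genotype: assign the configured counts at random
      fidx <- which(sex == 2L); midx <- which(sex == 1L)
      phenotype[fidx] <- 1L
      phenotype[sample(fidx, gc["case_f"])] <- 2L
      phenotype[midx] <- 1L
      phenotype[sample(midx, gc["case_m"])] <- 2L
    }
    qt <- NULL
    if (config$effect == "quantitative_linear") {
      y <- drop(dosage %*% config$snps$beta) + drop(hdom %*% config$snps$beta_dom) +
        config$gamma * (sex == 1L) + stats::rnorm(n, 0, config$sigma)
      qt <- stats::setNames(data.frame(y), config$qt_name)
    }
    for (j in seq_len(m)) {
      rate <- ifelse(sex == 2L, config$snps$miss_f[j], config$snps$miss_m[j])
      drop_call <- stats::runif(n) < rate
      geno[drop_call, j] <- NA_integer_
    }
    iid <- sprintf("S%04d", seq_len(n))
    samples <- data.frame(fid = iid, iid = iid, pat = "0", mat = "0",
                          sex = sex, phenotype = phenotype,
                          stringsAsFactors = FALSE)
    snpmeta <- data.frame(chr = config$snps$chr, snp = config$snps$snp,
                          dist = 0, bp = config$snps$bp,
                          a1 = config$snps$a1, a2 = config$snps$a2,
                          stringsAsFactors = FALSE)
    cohort <- x_cohort(samples, snpmeta, geno, qt = qt)
    freq_f <- colSums(dosage[sex == 2L, , drop = FALSE]) / (2 * nf)
    freq_m <- colSums(dosage[sex == 1L, , drop = FALSE] > 0) / nm
    truth <- list(config = config, seed = seed,
                  realized_p_f = freq_f, realized_p_m = freq_m,
                  latent_dosage = dosage)
    structure(list(cohort = cohort, truth = truth), class = "x_sim")
  })
}

#' @export
print.x_sim <- function(x, ...) {
  cat("<x_sim> synthetic cohort (seed ", format(x$truth$seed), ")\n", sep = "")
  print(x$cohort)
  invisible(x)
}

#' Impose an exact per-sex missingness pattern
#'
#' Replaces the genotype calls of the first `floor(rate * n_sex)` samples
#' of each sex with missing at every SNP, so the realized per-sex missing
#' frequencies equal the requested rates deterministically (up to the
#' floor). Used to build QC fixtures whose missingness table is exact
#' rather than sampled.
#'
#' @param cohort an `x_cohort`.
#' @param rates_f,rates_m numeric vectors of per-SNP target rates.
#' @return The modified cohort.
#' @export
deterministic_missingness <- function(cohort, rates_f, rates_m) {
  stopifnot(length(rates_f) == n_snps(cohort), length(rates_m) == n_snps(cohort))
  fidx <- which(is_female(cohort)); midx <- which(is_male(cohort))
  for (j in seq_len(n_snps(cohort))) {
    g <- cohort$genotypes[, j]
    g[fidx] <- ifelse(seq_along(fidx) <= floor(rates_f[j] * length(fidx)),
                      NA_integer_, g[fidx])
    g[midx] <- ifelse(seq_along(midx) <= floor(rates_m[j] * length(midx)),
                      NA_integer_, g[midx])
    cohort$genotypes[, j] <- g
  }
  cohort
}
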