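test_that("the default configuration encodes the study margins", {
  cfg <- default_sim_config()
  expect_identical(cfg$n_females, 477L)
  expect_identical(cfg$n_males, 438L)
  expect_identical(unname(cfg$group_counts), c(122L, 136L, 355L, 302L))
  expect_identical(nrow(cfg$snps), 8L)
  expect_identical(cfg$effect, "null")
  expect_true(all(cfg$snps$f > 0))
  expect_identical(cfg$seed, 20190722L)
})

test_that("simulation is deterministic given (config, seed)", {
  cfg <- default_sim_config()
  a <- simulate_cohort(cfg, seed = 99)
  b <- simulate_cohort(cfg, seed = 99)
  expect_identical(a$cohort$genotypes, b$cohort$genotypes)
  expect_identical(a$cohort$samples, b$cohort$samples)
  c <- simulate_cohort(cfg, seed = 100)
  expect_false(identical(a$cohort$genotypes, c$cohort$genotypes))
})

test_that("simulated sex/affection margins match the configuration exactly", {
  for (eff in c("null", "binary_logistic")) {
    cfg <- default_sim_config(effect = eff)
    ch <- simulate_cohort(cfg, seed = 5)$cohort
    s <- ch$samples
    expect_identical(sum(s$sex == 2L), 477L)
    expect_identical(sum(s$sex == 1L), 438L)
    expect_identical(sum(s$sex == 2L & s$phenotype == 1), 122L)
    expect_identical(sum(s$sex == 1L & s$phenotype == 1), 136L)
    expect_identical(sum(s$sex == 2L & s$phenotype == 2), 355L)
    expect_identical(sum(s$sex == 1L & s$phenotype == 2), 302L)
  }
})

test_that("female genotypes meet HWE expectations when f = 0", {
  snp <- data.frame(snp = "s", a1 = "A", a2 = "G", p_f = 0.3, p_m = 0.3,
                    f = 0, miss_f = 0, miss_m = 0)
  cfg <- sim_config(snp, 50000, 10, group_counts = c(25000, 5, NA, NA))
  ch <- simulate_cohort(cfg, seed = 6)$cohort
  g <- ch$genotypes[ch$samples$sex == 2L, 1]
  n <- length(g)
  exp_p <- c(0.49, 0.42, 0.09)  # codes 0,1,2 at p=0.3
  for (k in 0:2) {
    se <- sqrt(exp_p[k + 1] * (1 - exp_p[k + 1]) / n)
    expect_lt(abs(mean(g == k) - exp_p[k + 1]), 3 * se)
  }
})

test_that("configured allele frequencies are recovered at large n", {
  snps <- data.frame(snp = c("s1", "s2"), a1 = "A", a2 = "G",
                     p_f = c(0.26, 0.45), p_m = c(0.27, 0.42),
                     f = c(0.1, 0.2), miss_f = 0, miss_m = 0)
  cfg <- sim_config(snps, 20000, 20000, group_counts = c(10000, 10000, NA, NA))
  sim <- simulate_cohort(cfg, seed = 7)
  ch <- sim$cohort
  fem <- ch$samples$sex == 2L
  for (j in 1:2) {
    p_f_hat <- mean(ch$genotypes[fem, j]) / 2
    p_m_hat <- mean(ch$genotypes[!fem, j]) / 2
    expect_lt(abs(p_f_hat - cfg$snps$p_f[j]), 0.01)
    expect_lt(abs(p_m_hat - cfg$snps$p_m[j]), 0.01)
    expect_equal(sim$truth$realized_p_f[j], p_f_hat, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("a positive f produces the intended heterozygote deficit", {
  snp <- data.frame(snp = "s", a1 = "A", a2 = "G", p_f = 0.45, p_m = 0.42,
                    f = 0.28, miss_f = 0, miss_m = 0)
  cfg <- sim_config(snp, 30000, 10, group_counts = c(15000, 5, NA, NA))
  ch <- simulate_cohort(cfg, seed = 8)$cohort
  g <- ch$genotypes[ch$samples$sex == 2L, 1]
  target <- 2 * 0.45 * 0.55 * (1 - 0.28)
  se <- sqrt(target * (1 - target) / length(g))
  expect_lt(abs(mean(g == 1L) - target), 3 * se)
})

test_that("per-sex missingness rates are honoured", {
  cfg <- default_sim_config()
  big <- sim_config(cfg$snps[1:2, ], 20000, 20000,
                    group_counts = c(10000, 10000, NA, NA))
  ch <- simulate_cohort(big, seed = 9)$cohort
  fem <- ch$samples$sex == 2L
  for (j in 1:2) {
    for (sexsel in list(fem, !fem)) {
      rate <- if (identical(sexsel, fem)) big$snps$miss_f[j] else big$snps$miss_m[j]
      got <- mean(is.na(ch$genotypes[sexsel, j]))
      se <- sqrt(max(rate, 1e-6) * (1 - rate) / sum(sexsel))
      expect_lt(abs(got - rate), 4 * se + 1e-4)
    }
  }
})

test_that("invalid configurations are rejected", {
  snp <- data.frame(snp = "s", a1 = "A", a2 = "G", p_f = 0.05, p_m = 0.3,
                    f = -0.9, miss_f = 0, miss_m = 0)
  expect_error(sim_config(snp, 10, 10, group_counts = c(5, 5, NA, NA)),
               "negative female genotype probability")
  snp$f <- 0
  expect_error(sim_config(snp, 10, 10, group_counts = c(9, 5, 2, 5)),
               "sum to the per-sex totals")
})

test_that("binary effects shift case genotype frequencies in the right direction", {
  snp <- data.frame(snp = "s", a1 = "A", a2 = "G", p_f = 0.3, p_m = 0.3,
                    f = 0, miss_f = 0, miss_m = 0, beta = 0.5)
  cfg <- sim_config(snp, 2000, 2000, group_counts = c(1000, 1000, NA, NA),
                    effect = "binary_logistic")
  ch <- simulate_cohort(cfg, seed = 10)$cohort
  d <- export_dosage(ch, "inactivation")
  cases <- ch$samples$phenotype == 2
  expect_gt(mean(d[cases, 1]), mean(d[!cases, 1]))
})

test_that("quantitative traits carry the configured dosage effect", {
  snp <- data.frame(snp = "s", a1 = "A", a2 = "G", p_f = 0.3, p_m = 0.3,
                    f = 0, miss_f = 0, miss_m = 0, beta = 0.8)
  cfg <- sim_config(snp, 3000, 3000, group_counts = c(1500, 1500, NA, NA),
                    effect = "quantitative_linear", sigma = 1, qt_name = "y")
  sim <- simulate_cohort(cfg, seed = 11)
  ch <- sim$cohort
  fit <- lm(ch$qt$y ~ sim$truth$latent_dosage[, 1] + I(ch$samples$sex == 1L))
  expect_equal(unname(coef(fit)[2]), 0.8, tolerance = 0.1)
})

test_that("deterministic missingness sets exact floor counts per sex", {
  cfg <- default_sim_config()
  nomiss <- cfg
  nomiss$snps$miss_f <- 0; nomiss$snps$miss_m <- 0
  ch <- simulate_cohort(nomiss, seed = 12)$cohort
  ch2 <- deterministic_missingness(ch, cfg$snps$miss_f, cfg$snps$miss_m)
  fem <- ch2$samples$sex == 2L
  for (j in seq_len(n_snps(ch2))) {
    expect_identical(sum(is.na(ch2$genotypes[fem, j])),
                     as.integer(floor(cfg$snps$miss_f[j] * 477)))
    expect_identical(sum(is.na(ch2$genotypes[!fem, j])),
                     as.integer(floor(cfg$snps$miss_m[j] * 438)))
  }
})
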