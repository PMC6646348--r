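test_that("female-only S1 equals the closed-form trend statistic", {
  withr::with_seed(21, {
    for (i in 1:25) {
      counts <- matrix(rpois(6, lambda = sample(5:40, 1)) + 1L, nrow = 2)
      x <- rep(rep(0:2, 2), as.vector(t(counts)))
      y <- rep(c(1, 0), each = 3)[rep(1:6, as.vector(t(counts)))]
      s1 <- clayton_s1(x, y, rep(2L, length(x)))
      expect_equal(unname(s1$statistic), ca_trend_oracle(counts),
                   tolerance = 1e-10)
      expect_equal(s1$p.value,
                   pchisq(ca_trend_oracle(counts), 1, lower.tail = FALSE),
                   tolerance = 1e-10)
    }
  })
})

test_that("the worked 2x3 table matches the textbook trend statistic", {
  counts <- matrix(c(10, 20, 10, 5, 20, 25), nrow = 2, byrow = TRUE)
  x <- rep(rep(0:2, 2), as.vector(t(counts)))
  y <- rep(c(1, 0), each = 3)[rep(1:6, as.vector(t(counts)))]
  expect_equal(unname(clayton_s1(x, y, rep(2L, 90))$statistic),
               ca_trend_oracle(counts), tolerance = 1e-10)
})

test_that("degenerate inputs yield an undefined result with a reason", {
  s <- clayton_s1(c(0, 1, 2, 0), c(1, 1, 1, 1), c(2L, 2L, 1L, 1L))
  expect_true(is.na(s$p.value))
  expect_match(s$reason, "phenotype")
  # phenotype varies only between strata: score variance is zero
  s2 <- clayton_s1(c(0, 1, 2, 0, 2, 0), c(1, 1, 1, 0, 0, 0),
                   c(2L, 2L, 2L, 1L, 1L, 1L))
  expect_true(is.na(s2$p.value))
  s3 <- clayton_s1(rep(1, 10), rep(c(0, 1), 5), rep(2L, 10))
  expect_true(is.na(s3$p.value))
})

test_that("S2 on males only collapses to the 1-df statistic", {
  withr::with_seed(22, {
    x <- 2 * rbinom(80, 1, 0.4)
    y <- rbinom(80, 1, 0.5)
    sex <- rep(1L, 80)
    s1 <- clayton_s1(x, y, sex)
    s2 <- clayton_s2(x, y, sex)
    expect_equal(unname(s2$parameter), 1)
    expect_equal(unname(s2$statistic), unname(s1$statistic), tolerance = 1e-10)
  })
})

test_that("statistics are invariant to allele relabelling", {
  withr::with_seed(23, {
    ch <- make_random_cohort(60, 50, 2, seed = 23)
    ch <- sanitize_male_hets(ch, quiet = TRUE)$cohort
    y <- rnorm(n_samples(ch)) + ch$samples$phenotype
    for (model in c("inactivation", "escape")) {
      d <- xci_code(ch$genotypes[, 1], ch$samples$sex, model)
      flip_g <- 2L - ch$genotypes[, 1]
      df <- xci_code(flip_g, ch$samples$sex, model)
      a <- clayton_s1(d$x, y, ch$samples$sex)
      b <- clayton_s1(df$x, y, ch$samples$sex)
      expect_equal(unname(a$statistic), unname(b$statistic), tolerance = 1e-10)
      a2 <- clayton_s2(d$x, y, ch$samples$sex, het = d$h)
      b2 <- clayton_s2(df$x, y, ch$samples$sex, het = df$h)
      expect_equal(unname(a2$statistic), unname(b2$statistic), tolerance = 1e-9)
    }
  })
})

test_that("statistics are invariant to affine phenotype transforms", {
  withr::with_seed(24, {
    ch <- make_random_cohort(50, 40, 1, seed = 24)
    y <- rnorm(n_samples(ch))
    d <- xci_code(ch$genotypes[, 1], ch$samples$sex, "inactivation")
    a <- clayton_s1(d$x, y, ch$samples$sex)
    b <- clayton_s1(d$x, -3.2 * y + 40, ch$samples$sex)
    expect_equal(unname(a$statistic), unname(b$statistic), tolerance = 1e-10)
    a2 <- clayton_s2(d$x, y, ch$samples$sex, het = d$h)
    b2 <- clayton_s2(d$x, -3.2 * y + 40, ch$samples$sex, het = d$h)
    expect_equal(unname(a2$statistic), unname(b2$statistic), tolerance = 1e-9)
  })
})

test_that("chi-square p agrees with the stratified permutation distribution", {
  withr::with_seed(25, {
    n <- 60
    sex <- rep(c(1L, 2L), c(24, 36))
    g <- ifelse(sex == 1L, 2L * rbinom(n, 1, 0.4), rbinom(n, 2, 0.4))
    y <- rbinom(n, 1, 0.5)
    d <- xci_code(g, sex, "inactivation")
    obs <- clayton_s1(d$x, y, sex)
    # permuting y within sex leaves each stratum's mean, total sum of
    # squares and V unchanged; only U varies, so T is a function of the
    # stratum-wise inner products x'y
    B <- 1e5
    perm_T <- numeric(B)
    idx_m <- which(sex == 1L); idx_f <- which(sex == 2L)
    ybar <- ave(y, sex)
    V <- sum(sapply(split(seq_len(n), sex), function(i) {
      ni <- length(i)
      sum((y[i] - mean(y[i]))^2) * var(d$x[i])
    }))
    Ym <- replicate(B, y[idx_m][sample.int(length(idx_m))])
    Yf <- replicate(B, y[idx_f][sample.int(length(idx_f))])
    Um <- drop((d$x[idx_m] - mean(d$x[idx_m])) %*% (Ym - mean(y[idx_m])))
    Uf <- drop((d$x[idx_f] - mean(d$x[idx_f])) %*% (Yf - mean(y[idx_f])))
    perm_T <- (Um + Uf)^2 / V
    p_perm <- mean(perm_T >= unname(obs$statistic) - 1e-12)
    # the chi-square reference is an asymptotic approximation to the exact
    # (discrete) permutation law; at n = 60 they agree to a few percent
    expect_lt(abs(p_perm - obs$p.value), 0.05)
  })
})

test_that("female trend test is consistent with S1 on a female-only cohort", {
  ch <- make_random_cohort(80, 1, 2, seed = 26)
  fem <- ch[ch$samples$sex == 2L, ]
  ft <- female_trend_test(ch, 1, "affection")
  s1 <- clayton_s1(as.numeric(fem$genotypes[, 1]), fem$samples$phenotype,
                   fem$samples$sex)
  expect_equal(unname(ft$statistic), unname(s1$statistic), tolerance = 1e-12)
})

test_that("male allelic test matches the hypergeometric oracle", {
  iid <- sprintf("M%02d", 1:80)
  g <- matrix(c(rep(2L, 30), rep(0L, 10), rep(2L, 10), rep(0L, 30)), ncol = 1)
  ch <- x_cohort(data.frame(fid = iid, iid = iid, pat = "0", mat = "0",
                            sex = 1L,
                            phenotype = rep(c(2, 1), each = 40)),
                 data.frame(chr = 23L, snp = "rs1", dist = 0, bp = 1L,
                            a1 = "A", a2 = "G"), g)
  mt <- male_allelic_test(ch, 1)
  expect_equal(unname(mt$estimate), 9)
  expect_equal(mt$p.value, fisher_oracle(30, 10, 10, 30), tolerance = 1e-10)
  # label swap inverts the odds ratio
  ch2 <- ch
  ch2$genotypes <- 2L - ch$genotypes
  expect_equal(unname(male_allelic_test(ch2, 1)$estimate), 1 / 9,
               tolerance = 1e-12)
  # identical distributions: p = 1
  ch3 <- ch
  ch3$genotypes <- matrix(rep(c(2L, 0L), 40), ncol = 1)
  expect_equal(male_allelic_test(ch3, 1)$p.value, 1)
})

test_that("assoc_table does pairwise-complete bookkeeping per cell", {
  sim <- simulate_cohort(default_sim_config(effect = "quantitative_linear"),
                         seed = 31)
  ch <- sanitize_male_hets(sim$cohort, quiet = TRUE)$cohort
  ch$qt$trait[1:40] <- NA
  tab <- assoc_table(ch, c("affection", "trait"))
  expect_identical(nrow(tab), 16L)
  aff <- tab[tab$phenotype == "affection", ]
  trt <- tab[tab$phenotype == "trait", ]
  called <- colSums(!is.na(ch$genotypes))
  expect_equal(aff$n, unname(called))
  miss_trait <- is.na(ch$qt$trait)
  expect_equal(trt$n, unname(colSums(!is.na(ch$genotypes) & !miss_trait)))
  one <- assoc_table(ch[, 1], "affection")
  expect_identical(nrow(one), 1L)
})

test_that("xci_glm fits the matching family and dosage coding", {
  sim <- simulate_cohort(default_sim_config(), seed = 32)
  ch <- sanitize_male_hets(sim$cohort, quiet = TRUE)$cohort
  fit <- xci_glm(ch, "rs2011162")
  expect_s3_class(fit, "glm")
  expect_identical(fit$family$family, "binomial")
  expect_true("dosage" %in% names(coef(fit)))
  sim2 <- simulate_cohort(default_sim_config(effect = "quantitative_linear"),
                          seed = 33)
  ch2 <- sanitize_male_hets(sim2$cohort, quiet = TRUE)$cohort
  fit2 <- xci_glm(ch2, 1, "trait")
  expect_identical(fit2$family$family, "gaussian")
})
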