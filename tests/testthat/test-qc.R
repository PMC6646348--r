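test_that("per-sex missing frequencies count what they should", {
  ch <- make_random_cohort(30, 25, 3, seed = 4, miss = 0)
  expect_true(all(missing_by_sex(ch)$miss_m == 0))
  expect_true(all(missing_by_sex(ch)$miss_f == 0))
  male_rows <- which(ch$samples$sex == 1L)
  ch$genotypes[male_rows[1:5], 2] <- NA_integer_
  mb <- missing_by_sex(ch)
  expect_equal(mb$miss_m[2], 5 / 25)
  expect_equal(mb$miss_diff[2], 5 / 25)
})

test_that("differential missingness p equals the hypergeometric tail sum", {
  # males 5 missing / 45 called, females 1 missing / 49 called
  iid <- sprintf("I%03d", 1:100)
  sex <- c(rep(1L, 50), rep(2L, 50))
  g <- matrix(0L, 100, 1)
  g[c(1:5, 51), 1] <- NA_integer_
  ch <- x_cohort(data.frame(fid = iid, iid = iid, pat = "0", mat = "0",
                            sex = sex, phenotype = 1),
                 data.frame(chr = 23L, snp = "rs1", dist = 0, bp = 1L,
                            a1 = "A", a2 = "G"), g)
  expect_equal(diff_missing_test(ch)$p_diff, fisher_oracle(5, 45, 1, 49),
               tolerance = 1e-12)
  # identical per-sex patterns: p = 1
  g2 <- matrix(0L, 100, 1); g2[c(1:3, 51:53), 1] <- NA_integer_
  ch$genotypes <- g2
  dimnames(ch$genotypes) <- list(iid, "rs1")
  expect_equal(diff_missing_test(ch)$p_diff, 1)
})

test_that("doubling all cells of a 2x2 never increases the exact p", {
  for (a in 0:3) for (b in c(1, 4)) for (cc in 0:3) for (d in c(2, 5)) {
    if (a + b == 0 || cc + d == 0) next
    expect_lte(fisher_oracle(2 * a, 2 * b, 2 * cc, 2 * d),
               fisher_oracle(a, b, cc, d) + 1e-12)
  }
})

test_that("sex allele frequencies weight females twice and males once", {
  iid <- c("F1", "F2", "M1", "M2", "M3")
  ch <- x_cohort(data.frame(fid = iid, iid = iid, pat = "0", mat = "0",
                            sex = c(2L, 2L, 1L, 1L, 1L), phenotype = 1),
                 data.frame(chr = 23L, snp = "rs1", dist = 0, bp = 1L,
                            a1 = "A", a2 = "G"),
                 matrix(c(1L, 2L, 2L, 0L, 0L), ncol = 1))
  sf <- sex_allele_freq_test(ch)
  expect_equal(sf$maf_f, 3 / 4)   # 2 females: 3 of 4 alleles
  expect_equal(sf$maf_m, 1 / 3)   # 3 males: 1 of 3 alleles
  expect_equal(sf$maf_all, 4 / 7)
})

test_that("equal allele distributions give OR 1, p 1; label swap inverts OR", {
  iid <- sprintf("I%02d", 1:20)
  sex <- rep(c(1L, 2L), each = 10)
  g <- matrix(c(rep(c(0L, 2L), 5), rep(c(0L, 2L), 5)), ncol = 1)
  ch <- x_cohort(data.frame(fid = iid, iid = iid, pat = "0", mat = "0",
                            sex = sex, phenotype = 1),
                 data.frame(chr = 23L, snp = "rs1", dist = 0, bp = 1L,
                            a1 = "A", a2 = "G"), g)
  sf <- sex_allele_freq_test(ch)
  expect_equal(sf$odds_ratio, 1)
  expect_equal(sf$p, 1)
  ch2 <- make_random_cohort(25, 25, 2, seed = 6, miss = 0)
  flip2 <- ch2
  flip2$genotypes <- 2L - ch2$genotypes
  sf1 <- sex_allele_freq_test(ch2)
  sf2 <- sex_allele_freq_test(flip2)
  expect_equal(sf2$odds_ratio, 1 / sf1$odds_ratio, tolerance = 1e-12)
  expect_equal(sf2$p, sf1$p, tolerance = 1e-12)
})

test_that("sex-stratified Fisher p matches the enumeration oracle", {
  ch <- make_random_cohort(30, 30, 4, seed = 12)
  sf <- sex_allele_freq_test(ch)
  for (j in 1:4) {
    ac <- xchrom:::allele_counts_by_sex(ch, j)
    expect_equal(sf$p[j],
                 fisher_oracle(ac$minor_f, ac$total_f - ac$minor_f,
                               ac$minor_m, ac$total_m - ac$minor_m),
                 tolerance = 1e-9)
  }
})

test_that("group frequencies agree with the pooled frequency on one group", {
  ch <- make_random_cohort(40, 40, 3, seed = 8)
  one <- maf_by_group(ch, rep("all", n_samples(ch)))
  expect_equal(one$maf, sex_allele_freq_test(ch)$maf_all, tolerance = 1e-12)
  males_only <- maf_by_group(ch, ifelse(ch$samples$sex == 1L, "m", "f"))
  sf <- sex_allele_freq_test(ch)
  expect_equal(males_only$maf[males_only$group == "m"], sf$maf_m,
               tolerance = 1e-12)
  expect_error(maf_by_group(ch, rep("all", 3)), "one label per sample")
})

test_that("male het scan finds injected calls and sanitation is idempotent", {
  ch <- make_random_cohort(10, 10, 3, seed = 10, miss = 0)
  ch <- sanitize_male_hets(ch, quiet = TRUE)$cohort
  expect_identical(nrow(male_het_scan(ch)), 0L)
  male <- which(ch$samples$sex == 1L)[3]
  ch$genotypes[male, 2] <- 1L
  scan <- male_het_scan(ch)
  expect_identical(scan$iid, ch$samples$iid[male])
  expect_identical(scan$snp, ch$snps$snp[2])
  san <- sanitize_male_hets(ch, quiet = TRUE)
  expect_identical(nrow(male_het_scan(san$cohort)), 0L)
  expect_true(is.na(san$cohort$genotypes[male, 2]))
  again <- sanitize_male_hets(san$cohort, quiet = TRUE)
  expect_identical(again$cohort$genotypes, san$cohort$genotypes)
})

test_that("apply_qc with all criteria disabled keeps every SNP", {
  ch <- make_random_cohort(30, 30, 4, seed = 13)
  off <- qc_thresholds(NA, NA, NA, NA)
  res <- apply_qc(ch, off)
  expect_identical(n_snps(res$cohort), 4L)
  expect_identical(length(res$report$excluded), 0L)
})

test_that("a monomorphic SNP fails the MAF criterion", {
  ch <- make_random_cohort(30, 30, 2, seed = 14, miss = 0)
  ch$genotypes[, 1] <- 0L
  res <- apply_qc(ch, qc_thresholds(NA, NA, 0.01, NA))
  expect_identical(res$report$excluded, ch$snps$snp[1])
})

test_that("HWE criterion requires control females", {
  ch <- make_random_cohort(10, 10, 2, seed = 15)
  ch$samples$phenotype <- 2
  expect_error(apply_qc(ch, qc_thresholds(NA, NA, NA, 1e-4)),
               "control females")
})
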