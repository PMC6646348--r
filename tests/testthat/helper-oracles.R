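# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# HWE exact test by full enumeration of the conditional distribution of
# the heterozygote count, on the log scale via lfactorial/lchoose.
hwe_oracle <- function(a, h, b) {
  n <- a + h + b
  nA <- 2L * a + h
  nA <- min(nA, 2L * n - nA)
  if (nA == 0L) return(1)
  hets <- seq.int(nA %% 2L, nA, by = 2L)
  lp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (nA + hets) / 2) + hets * log(2) - lchoose(2L * n, nA)
  pr <- exp(lp - max(lp)); pr <- pr / sum(pr)
  pobs <- pr[match(h, hets)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-9)]))
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
# (sum of all tables with fixed margins whose probability does not exceed
# the observed one).
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0L, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  pr <- dhyper(xs, m1, m2, k)
  pobs <- pr[match(a, xs)]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# Closed-form Cochran-Armitage trend statistic from a 2x3 genotype table
# in the (N-1) r^2 (linear-by-linear) convention: counts[1, ] are cases,
# counts[2, ] controls, columns are genotype scores 0/1/2.
ca_trend_oracle <- function(counts, scores = 0:2) {
  N <- sum(counts)
  R <- sum(counts[1, ])
  nj <- colSums(counts)
  sxy <- sum(counts[1, ] * scores) - R * sum(nj * scores) / N
  sxx <- sum(nj * scores^2) - sum(nj * scores)^2 / N
  syy <- R - R^2 / N
  (N - 1) * sxy^2 / (sxx * syy)
}

make_random_cohort <- function(n_f, n_m, m, seed = NULL, maf = c(0.1, 0.5),
                               miss = 0.05, polymorphic = FALSE) {
  draw <- function() {
    pairs <- list(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"))
    snps <- data.frame(
      chr = 23L, snp = sprintf("rs%03d", seq_len(m)), dist = 0,
      bp = sort(sample.int(1e6, m)),
      stringsAsFactors = FALSE)
    al <- do.call(rbind, lapply(sample(pairs, m, replace = TRUE), identity))
    snps$a1 <- al[, 1]; snps$a2 <- al[, 2]
    n <- n_f + n_m
    sex <- sample(c(rep(2L, n_f), rep(1L, n_m)))
    geno <- matrix(NA_integer_, n, m)
    for (j in seq_len(m)) {
      p <- runif(1, maf[1], maf[2])
      geno[sex == 2L, j] <- rbinom(n_f, 2L, p)
      geno[sex == 1L, j] <- 2L * rbinom(n_m, 1L, p)
      gone <- runif(n) < miss
      geno[gone, j] <- NA_integer_
    }
    iid <- sprintf("I%03d", seq_len(n))
    samples <- data.frame(fid = iid, iid = iid, pat = "0", mat = "0",
                          sex = sex,
                          phenotype = sample(c(1, 2), n, replace = TRUE),
                          stringsAsFactors = FALSE)
    x_cohort(samples, snps, geno)
  }
  gen <- function() {
    ch <- draw()
    if (polymorphic) {
      ok <- function(x) {
        g <- x$genotypes
        all(apply(g, 2, function(col) {
          col <- col[!is.na(col)]
          length(col) > 0 && any(col > 0L) && any(col < 2L)
        }))
      }
      while (!ok(ch)) ch <- draw()
      ch <- set_minor_first(ch)
    }
    ch
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
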