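#' Exact test of Hardy-Weinberg equilibrium (Wigginton)
#'
#' Exact conditional test of Hardy-Weinberg genotype proportions given the
#' allele counts, as described and implemented by Wigginton, Cutler and
#' Abecasis (2005) and used by PLINK. On the X chromosome the test applies
#' to female genotype counts only. The p-value is the sum of the
#' probabilities of all heterozygote counts (with the parity fixed by the
#' allele count) whose conditional probability does not exceed that of the
#' observed count. The distribution is built by the numerically stable
#' mode-anchored recurrence.
#'
#' @param n_hom1 count of A1/A1 homozygotes.
#' @param n_het count of heterozygotes.
#' @param n_hom2 count of A2/A2 homozygotes.
#' @return An object of class `hwe_test`: list with `counts`, `o_het`
#'   (observed heterozygosity), `e_het` (expected heterozygosity 2p(1-p))
#'   and `p` (exact p-value).
#' @examples
#' hwe_exact(34, 177, 249)  # p about 0.72
#' @export
hwe_exact <- function(n_hom1, n_het, n_hom2) {
  cnt <- c(n_hom1, n_het, n_hom2)
  if (any(cnt < 0) || any(cnt != round(cnt))) stop("counts must be non-negative integers")
  n <- sum(cnt)
  if (n < 1) stop("at least one genotype is required")
  p1 <- (2 * n_hom1 + n_het) / (2 * n)
  out <- list(counts = c(n_hom1 = n_hom1, n_het = n_het, n_hom2 = n_hom2),
              o_het = n_het / n,
              e_het = 2 * p1 * (1 - p1),
              p = hwe_exact_p(n_hom1, n_het, n_hom2))
  class(out) <- "hwe_test"
  out
}

# mode-anchored recurrence over the conditional distribution of the
# heterozygote count given allele counts
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  rare <- 2L * min(n_hom1, n_hom2) + n_het  # rarer allele count
  if (rare == 0L) return(1)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hets))
  mid <- floor(rare * (2 * n - rare) / (2 * n))
  if (mid %% 2L != rare %% 2L) mid <- mid + 1L
  i_mid <- match(mid, hets)
  probs[i_mid] <- 1
  # downward: P(h-2) = P(h) * h(h-1) / (4 (hr+1)(hc+1))
  h <- mid
  while (h >= 2L) {
    hr <- (rare - h) / 2          # rare-allele homozygotes at h
    hc <- n - h - hr              # common homozygotes
    i <- match(h, hets)
    probs[i - 1L] <- probs[i] * h * (h - 1) / (4 * (hr + 1) * (hc + 1))
    h <- h - 2L
  }
  # upward: P(h+2) = P(h) * 4 hr hc / ((h+2)(h+1))
  h <- mid
  while (h + 2L <= rare) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    i <- match(h, hets)
    probs[i + 1L] <- probs[i] * 4 * hr * hc / ((h + 2) * (h + 1))
    h <- h + 2L
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

#' @export
print.hwe_test <- function(x, ...) {
  cat("Exact Hardy-Weinberg test (Wigginton)\n")
  cat(sprintf("  genotype counts: %d/%d/%d\n", x$counts[1], x$counts[2], x$counts[3]))
  cat(sprintf("  O(HET) = %.4f, E(HET) = %.4f, p = %.4g\n", x$o_het, x$e_het, x$p))
  invisible(x)
}

#' Female Hardy-Weinberg table for a cohort
#'
#' Runs [hwe_exact()] on the female genotype counts of every SNP, within
#' the strata of a standard case-control HWE report: ALL females, AFF
#' (cases) and UNAFF (controls).
#'
#' @param cohort an `x_cohort`.
#' @param strata subset of `c("ALL", "AFF", "UNAFF")`.
#' @return data.frame with one row per SNP x stratum: `snp`, `test`, `a1`,
#'   `geno` ("hom1/het/hom2"), `o_het`, `e_het`, `p`.
#' @export
hwe_female_table <- function(cohort, strata = c("ALL", "AFF", "UNAFF")) {
  strata <- match.arg(strata, several.ok = TRUE)
  fem <- is_female(cohort)
  ph <- cohort$samples$phenotype
  keep <- list(ALL = fem, AFF = fem & ph == 2, UNAFF = fem & ph == 1)
  rows <- list()
  for (j in seq_len(n_snps(cohort))) {
    for (s in strata) {
      g <- cohort$genotypes[keep[[s]], j]
      cnt <- c(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
               sum(g == 0L, na.rm = TRUE))
      if (sum(cnt) == 0L) next
      hw <- hwe_exact(cnt[1], cnt[2], cnt[3])
      rows[[length(rows) + 1L]] <- data.frame(
        snp = cohort$snps$snp[j], test = s, a1 = cohort$snps$a1[j],
        geno = paste(cnt, collapse = "/"),
        o_het = hw$o_het, e_het = hw$e_het, p = hw$p,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
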