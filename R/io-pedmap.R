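#' Read a PLINK text fileset
#'
#' Reads `prefix.ped`/`prefix.map` (whitespace-delimited). The `.map` file
#' carries no allele roles, so the counted allele A1 is taken from `snps`
#' when supplied, otherwise inferred as the minor allele over all genotyped
#' samples (females contributing two alleles, males one; ties broken
#' alphabetically). "0 0" is a missing call.
#'
#' @param prefix filesystem path prefix.
#' @param snps optional data.frame with `snp`, `a1`, `a2` fixing allele roles.
#' @return An `x_cohort`.
#' @export
read_pedmap <- function(prefix, snps = NULL) {
  mapf <- paste0(prefix, ".map"); pedf <- paste0(prefix, ".ped")
  for (p in c(mapf, pedf)) if (!file.exists(p)) stop("missing companion file: ", p)
  map <- utils::read.table(mapf, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric", "integer"))
  names(map) <- c("chr", "snp", "dist", "bp")
  map$chr <- normalize_chr(map$chr)
  m <- nrow(map)
  lines <- readLines(pedf)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  if (length(unique(nt)) > 1L) stop(".ped rows have differing field counts")
  if (length(nt) && nt[1] != 6L + 2L * m) {
    if ((nt[1] - 6L) %% 2L != 0L) stop(".ped has an odd allele-column count")
    stop(".ped allele columns do not match .map SNP count")
  }
  tok <- do.call(rbind, toks)
  samples <- data.frame(fid = tok[, 1], iid = tok[, 2], pat = tok[, 3],
                        mat = tok[, 4], sex = as.integer(tok[, 5]),
                        phenotype = as.numeric(tok[, 6]), stringsAsFactors = FALSE)
  n <- nrow(samples)
  al1 <- tok[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  al2 <- tok[, 6L + 2L * seq_len(m), drop = FALSE]
  ok <- c("A", "C", "G", "T", "0")
  if (!all(al1 %in% ok) || !all(al2 %in% ok))
    stop("allele characters must be A, C, G, T or 0")
  if (any(xor(al1 == "0", al2 == "0")))
    stop("half-missing genotype (single '0' allele) in .ped")
  map$a1 <- NA_character_; map$a2 <- NA_character_
  if (!is.null(snps)) {
    idx <- match(map$snp, snps$snp)
    if (anyNA(idx)) stop("snps table does not cover all .map markers")
    map$a1 <- snps$a1[idx]; map$a2 <- snps$a2[idx]
  }
  geno <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    obs <- c(al1[, j], al2[, j])
    if (is.na(map$a1[j])) {
      # infer minor allele; male pairs are a duplicated single allele, weight 1/2
      cnt <- numeric(0)
      for (al in setdiff(unique(obs), "0")) {
        wts <- (al1[, j] == al) + (al2[, j] == al)
        wts[samples$sex == 1L] <- wts[samples$sex == 1L] / 2
        cnt[al] <- sum(wts)
      }
      if (length(cnt) == 0L) stop("SNP ", map$snp[j], " has no called genotypes")
      if (length(cnt) > 2L) stop("SNP ", map$snp[j], " has more than two alleles")
      ord <- order(cnt, names(cnt))  # minor first; ties alphabetical
      map$a1[j] <- names(cnt)[ord[1]]
      map$a2[j] <- if (length(cnt) == 2L) names(cnt)[ord[2]] else
        setdiff(c("A", "C", "G", "T"), names(cnt))[1]
    }
    extra <- setdiff(unique(obs), c(map$a1[j], map$a2[j], "0"))
    if (length(extra)) stop("SNP ", map$snp[j], " has alleles outside a1/a2: ",
                            paste(extra, collapse = ","))
    called <- al1[, j] != "0"
    geno[called, j] <- (al1[called, j] == map$a1[j]) + (al2[called, j] == map$a1[j])
  }
  x_cohort(samples, map, geno)
}

#' Write a PLINK text fileset
#'
#' Emits `prefix.map` (chr, id, distance, bp) and `prefix.ped` (six sample
#' columns then two allele characters per SNP; hemizygous males are written
#' as homozygous pairs, the PLINK convention; missing calls as "0 0").
#'
#' @param cohort an `x_cohort`.
#' @param prefix filesystem path prefix.
#' @return `prefix`, invisibly.
#' @export
write_pedmap <- function(cohort, prefix) {
  utils::write.table(cohort$snps[, c("chr", "snp", "dist", "bp")],
                     paste0(prefix, ".map"), quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  n <- n_samples(cohort); m <- n_snps(cohort)
  g <- cohort$genotypes
  cols <- vector("list", 2L * m)
  for (j in seq_len(m)) {
    a1 <- cohort$snps$a1[j]; a2 <- cohort$snps$a2[j]
    first <- c(a2, a1, a1)[g[, j] + 1L]
    second <- c(a2, a2, a1)[g[, j] + 1L]
    first[is.na(g[, j])] <- "0"; second[is.na(g[, j])] <- "0"
    cols[[2L * j - 1L]] <- first; cols[[2L * j]] <- second
  }
  ped <- cbind(cohort$samples[, c("fid", "iid", "pat", "mat", "sex", "phenotype")],
               do.call(cbind, c(cols, list(deparse.level = 0))))
  utils::write.table(ped, paste0(prefix, ".ped"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  invisible(prefix)
}
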