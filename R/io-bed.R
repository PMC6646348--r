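#' Read a PLINK binary fileset
#'
#' Decodes a SNP-major PLINK 1 binary fileset (`prefix.bed`, `.bim`, `.fam`)
#' into an [x_cohort()]. The 2-bit genotype fields map to minor-allele
#' counts: `00` = hom A1 -> 2, `10` = het -> 1, `11` = hom A2 -> 0,
#' `01` = missing. Sample order follows the `.fam`, SNP order the `.bim`.
#'
#' @param prefix filesystem path prefix (without extension).
#' @return An `x_cohort`.
#' @export
read_bed <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop("missing companion file: ", p)
  samples <- read_fam(paths[3])
  snps <- read_bim(paths[2])
  n <- nrow(samples); m <- nrow(snps)
  raw <- readBin(paths[1], "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed files (mode byte 0x01) are supported")
  bps <- ceiling(n / 4)  # bytes per SNP block
  if (length(raw) != 3L + bps * m)
    stop("truncated .bed: expected ", 3L + bps * m, " bytes, found ", length(raw))
  geno <- matrix(NA_integer_, n, m)
  if (n > 0L && m > 0L) {
    ints <- matrix(as.integer(raw[-(1:3)]), nrow = bps)
    codes <- c(2L, NA_integer_, 1L, 0L)  # field values 0b00, 0b01, 0b10, 0b11
    full <- matrix(NA_integer_, 4L * bps, m)
    for (s in 0:3)  # sample fields are packed LSB-first within each byte
      full[seq.int(s + 1L, 4L * bps, by = 4L), ] <-
        codes[bitwAnd(bitwShiftR(ints, 2L * s), 3L) + 1L]
    geno <- full[seq_len(n), , drop = FALSE]
  }
  x_cohort(samples, snps, geno)
}

#' Write a PLINK binary fileset
#'
#' Emits `prefix.bed` (SNP-major, v1.00), `.bim` and `.fam` such that
#' `read_bed()` recovers the cohort bit-exactly. Male heterozygote calls are
#' written as-is with a warning; sanitation is a QC decision, not an I/O
#' side effect.
#'
#' @param cohort an `x_cohort`.
#' @param prefix filesystem path prefix.
#' @return `prefix`, invisibly.
#' @export
write_bed <- function(cohort, prefix) {
  n <- n_samples(cohort); m <- n_snps(cohort)
  g <- cohort$genotypes
  mh <- which(is_male(cohort) & apply(g == 1L, 1, function(r) any(r, na.rm = TRUE)))
  if (length(mh))
    warning("writing ", length(mh), " male sample(s) with heterozygote calls")
  write_fam(cohort$samples, paste0(prefix, ".fam"))
  write_bim(cohort$snps, paste0(prefix, ".bim"))
  bps <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (n > 0L && m > 0L) {
    fields <- matrix(0L, 4L * bps, m)  # trailing pad bits are zero
    enc <- c(3L, 2L, 0L)               # code 0 -> 0b11, 1 -> 0b10, 2 -> 0b00
    v <- enc[g + 1L]
    v[is.na(v)] <- 1L                  # missing -> 0b01
    fields[seq_len(n), ] <- v
    bytes <- fields[seq.int(1L, 4L * bps, 4L), , drop = FALSE] +
      4L * fields[seq.int(2L, 4L * bps, 4L), , drop = FALSE] +
      16L * fields[seq.int(3L, 4L * bps, 4L), , drop = FALSE] +
      64L * fields[seq.int(4L, 4L * bps, 4L), , drop = FALSE]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

read_fam <- function(path) {
  fam <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  names(fam) <- c("fid", "iid", "pat", "mat", "sex", "phenotype")
  fam
}

write_fam <- function(samples, path) {
  utils::write.table(samples[, c("fid", "iid", "pat", "mat", "sex", "phenotype")],
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
}

read_bim <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chr = integer(0), snp = character(0), dist = numeric(0),
                      bp = integer(0), a1 = character(0), a2 = character(0),
                      stringsAsFactors = FALSE))
  bim <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  names(bim) <- c("chr", "snp", "dist", "bp", "a1", "a2")
  bim$chr <- normalize_chr(bim$chr)
  bim
}

write_bim <- function(snps, path) {
  utils::write.table(snps[, c("chr", "snp", "dist", "bp", "a1", "a2")],
                     path, quote = FALSE, row.names = FALSE, col.names = FALSE,
                     sep = "\t")
}
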