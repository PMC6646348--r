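#' Read a long-format array-genotyping export
#'
#' Parses the three-column cloud export of an OpenArray/TaqMan genotyping
#' run (NCBI_SNP_Reference, Sample_ID, Genotype_Call), comma- or
#' tab-delimited (auto-detected from the header line), and reshapes it with
#' [long_to_wide()].
#'
#' @param path file path.
#' @param ... passed to [long_to_wide()].
#' @return An `x_cohort`.
#' @export
read_long_calls <- function(path, ...) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  rec <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(rec) < 3L) stop("expected three columns: snp reference, sample id, genotype call")
  long_to_wide(rec[, 1:3], ...)
}

#' Reshape long-format genotype calls to a sample-by-SNP cohort
#'
#' Each record is one (SNP, sample) call. Two-allele calls ("A/G") are
#' female-style genotypes; single-allele calls ("A") are hemizygous male
#' calls, stored on the diploid 0/2 scale. Undetermined tokens and absent
#' (sample, SNP) pairs become missing. Output row/column order is the sorted
#' order of the identifiers, so the result is invariant under permutation of
#' the input records. Duplicate identical records are deduplicated;
#' conflicting duplicates are an error.
#'
#' @param records data.frame (or 3-column coercible) with columns snp
#'   reference, sample id, genotype call, in that order.
#' @param snps optional data.frame (`snp`, `a1`, `a2`, optionally `chr`,
#'   `bp`) fixing allele roles and marker metadata; otherwise A1 is the
#'   minor allele by weighted count (females x2, males x1), ties broken
#'   alphabetically, and `bp` is the marker's rank (placeholder).
#' @param samples optional data.frame (`iid`, `sex`, optionally `fid`,
#'   `phenotype`). Without it, a sample is taken to be male iff it has at
#'   least one single-allele (hemizygous) call; phenotype is set missing.
#' @param missing_tokens call strings treated as undetermined.
#' @return An `x_cohort`.
#' @export
long_to_wide <- function(records, snps = NULL, samples = NULL,
                         missing_tokens = c("", "UND", "UNDETERMINED", "NOAMP",
                                            "NA", "N/A", "./.", "-/-", "0/0", "-")) {
  rec <- as.data.frame(records, stringsAsFactors = FALSE)
  if (ncol(rec) < 3L) stop("records must have three columns")
  names(rec)[1:3] <- c("snp", "iid", "call")
  rec$snp <- as.character(rec$snp); rec$iid <- as.character(rec$iid)
  rec$call <- toupper(gsub("[[:space:]]", "", as.character(rec$call)))
  rec$call[rec$call %in% toupper(missing_tokens)] <- NA_character_
  rec <- unique(rec)
  key <- paste(rec$snp, rec$iid, sep = "\r")
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    clash <- unique(key[dup])
    stop("conflicting duplicate records for ", length(clash),
         " (sample, SNP) pair(s), e.g. ", sub("\r", " / ", clash[1]))
  }
  snp_ids <- sort(unique(rec$snp))
  iids <- sort(unique(rec$iid))
  calls <- matrix(NA_character_, length(iids), length(snp_ids),
                  dimnames = list(iids, snp_ids))
  calls[cbind(match(rec$iid, iids), match(rec$snp, snp_ids))] <- rec$call
  alleles <- function(s) if (is.na(s)) character(0) else strsplit(s, "[/|]")[[1]]
  parsed <- apply(calls, c(1, 2), function(s) list(alleles(s)))
  hemi <- matrix(vapply(parsed, function(p) length(p[[1]]) == 1L, logical(1)),
                 nrow = length(iids))
  if (is.null(samples)) {
    sex <- ifelse(apply(hemi, 1, any), 1L, 2L)
    samples <- data.frame(fid = iids, iid = iids, pat = "0", mat = "0",
                          sex = sex, phenotype = -9, stringsAsFactors = FALSE)
  } else {
    samples <- as.data.frame(samples, stringsAsFactors = FALSE)
    if (!all(iids %in% samples$iid)) stop("samples table does not cover all sample ids")
    samples <- samples[match(iids, samples$iid), , drop = FALSE]
    if (is.null(samples$fid)) samples$fid <- samples$iid
    if (is.null(samples$pat)) samples$pat <- "0"
    if (is.null(samples$mat)) samples$mat <- "0"
    if (is.null(samples$phenotype)) samples$phenotype <- -9
  }
  snp_meta <- data.frame(chr = 23L, snp = snp_ids, dist = 0,
                         bp = seq_along(snp_ids), a1 = NA_character_,
                         a2 = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(snps)) {
    idx <- match(snp_ids, snps$snp)
    if (anyNA(idx)) stop("snps table does not cover all SNP references")
    snp_meta$a1 <- snps$a1[idx]; snp_meta$a2 <- snps$a2[idx]
    if (!is.null(snps$chr)) snp_meta$chr <- normalize_chr(snps$chr[idx])
    if (!is.null(snps$bp)) snp_meta$bp <- snps$bp[idx]
  }
  geno <- matrix(NA_integer_, length(iids), length(snp_ids))
  male <- samples$sex == 1L
  for (j in seq_along(snp_ids)) {
    als <- lapply(seq_along(iids), function(i) parsed[[i, j]][[1]])
    if (is.na(snp_meta$a1[j])) {
      cnt <- numeric(0)
      for (i in seq_along(als)) {
        a <- als[[i]]
        if (!length(a)) next
        w <- if (male[i] && length(a) == 2L) 0.5 else 1  # weight males once
        for (al in a) cnt[al] <- (if (is.na(cnt[al])) 0 else cnt[al]) + w
      }
      if (!length(cnt)) next  # all-missing column: alleles unknowable
      if (length(cnt) > 2L) stop("SNP ", snp_ids[j], " has more than two alleles")
      ord <- order(cnt, names(cnt))
      snp_meta$a1[j] <- names(cnt)[ord[1]]
      snp_meta$a2[j] <- if (length(cnt) == 2L) names(cnt)[ord[2]] else
        setdiff(c("A", "C", "G", "T", "N"), names(cnt))[1]
    }
    for (i in seq_along(iids)) {
      a <- als[[i]]
      if (!length(a)) next
      bad <- setdiff(a, c(snp_meta$a1[j], snp_meta$a2[j]))
      if (length(bad)) stop("SNP ", snp_ids[j], ": allele(s) ",
                            paste(bad, collapse = ","), " outside a1/a2")
      geno[i, j] <- if (length(a) == 1L) 2L * (a == snp_meta$a1[j])
                    else sum(a == snp_meta$a1[j])
    }
  }
  drop <- is.na(snp_meta$a1)
  if (any(drop)) {
    snp_meta$a1[drop] <- "A"; snp_meta$a2[drop] <- "N"  # placeholder for all-missing markers
  }
  x_cohort(samples, snp_meta, geno)
}
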