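#' Pipeline run configuration
#'
#' @param input path prefix of the genotype fileset, or a long-format call
#'   export file when `format = "long"`.
#' @param format `"bed"`, `"ped"` or `"long"`.
#' @param out_dir output directory.
#' @param thresholds QC thresholds, see [qc_thresholds()].
#' @param xci_model X-inactivation model for association dosage coding.
#' @param phenotypes phenotype names to associate (`"affection"` and/or
#'   quantitative column names; quantitative phenotypes can be supplied
#'   via `pheno_file`).
#' @param pheno_file optional TSV/CSV with an `iid` column and one column
#'   per quantitative phenotype.
#' @param seed integer seed recorded in the manifest (the analysis stages
#'   are deterministic; the seed matters for fixture generation).
#' @param prefix output file prefix.
#' @return list of class `run_config`.
#' @export
run_config <- function(input, format = c("bed", "ped", "long"),
                       out_dir = "xchrom_out", thresholds = qc_thresholds(),
                       xci_model = c("inactivation", "escape"),
                       phenotypes = "affection", pheno_file = NULL,
                       seed = 1L, prefix = "xchrom") {
  format <- match.arg(format)
  xci_model <- match.arg(xci_model)
  bad <- vapply(thresholds, function(t) !is.na(t) && (t < 0 || t > 1), logical(1))
  if (any(bad)) stop("thresholds must lie in [0, 1] or be NA")
  structure(list(input = input, format = format, out_dir = out_dir,
                 thresholds = thresholds, xci_model = xci_model,
                 phenotypes = phenotypes, pheno_file = pheno_file,
                 seed = as.integer(seed), prefix = prefix),
            class = "run_config")
}

#' Run the full convert - QC - associate pipeline
#'
#' Reads the input fileset, sanitizes male heterozygote calls, writes the
#' QC report battery, applies the SNP filters, runs the Clayton
#' association tests on the surviving SNPs for each requested phenotype,
#' and writes a run manifest (package version, configuration, seed, file
#' hashes). Deterministic given inputs and seed; all timestamps are
#' confined to the manifest.
#'
#' @param config a [run_config()].
#' @return list with `status` (0 ok, 2 input error, 3 QC removed every
#'   SNP, 4 internal error), `outputs` (paths written), and on success the
#'   `qc` report and `assoc` table. Errors in a stage abort that run with
#'   a stage-labelled message in `$message`.
#' @export
pipeline_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- list(status = 0L, outputs = character(0))
  stage <- "input"
  res <- tryCatch({
    cohort <- switch(config$format,
                     bed = read_bed(config$input),
                     ped = read_pedmap(config$input),
                     long = read_long_calls(config$input))
    if (!is.null(config$pheno_file)) {
      header <- readLines(config$pheno_file, n = 1L)
      sep <- if (grepl("\t", header)) "\t" else ","
      ph <- utils::read.table(config$pheno_file, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE)
      if (!"iid" %in% names(ph)) stop("pheno_file needs an 'iid' column")
      idx <- match(cohort$samples$iid, ph$iid)
      qt <- ph[idx, setdiff(names(ph), "iid"), drop = FALSE]
      rownames(qt) <- cohort$samples$iid
      cohort$qt <- qt
    }
    stage <- "qc"
    san <- sanitize_male_hets(cohort, quiet = TRUE)
    cohort <- san$cohort
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    qc <- apply_qc(cohort, config$thresholds)
    qc$report$male_hets <- san$incidents
    out$outputs <- write_qc_reports(cohort, config$out_dir, config$prefix,
                                    report = qc$report)
    out$qc <- qc$report
    if (n_snps(qc$cohort) == 0L) {
      out$status <- 3L
      out$message <- "qc: every SNP was removed; association stage skipped"
    } else {
      stage <- "assoc"
      tab <- assoc_table(qc$cohort, config$phenotypes, config$xci_model)
      p <- file.path(config$out_dir, paste0(config$prefix, ".assoc.tsv"))
      write_assoc_table(tab, p)
      out$outputs <- c(out$outputs, p)
      out$assoc <- tab
    }
    stage <- "manifest"
    mf <- file.path(config$out_dir, paste0(config$prefix, ".manifest.txt"))
    hashes <- tools::md5sum(out$outputs)
    writeLines(c(
      paste0("package: xchrom ", as.character(utils::packageVersion("xchrom"))),
      paste0("r_version: ", R.version.string),
      paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      paste0("seed: ", config$seed),
      paste0("input: ", config$input, " (", config$format, ")"),
      paste0("xci_model: ", config$xci_model),
      paste0("thresholds: ", paste(names(config$thresholds),
                                   unlist(config$thresholds), sep = "=",
                                   collapse = " ")),
      paste0("status: ", out$status),
      "outputs:",
      paste0("  ", basename(names(hashes)), "  md5=", unname(hashes))), mf)
    out$outputs <- c(out$outputs, mf)
    out
  }, error = function(e) {
    status <- switch(stage, input = 2L, 4L)
    list(status = status, outputs = out$outputs,
         message = paste0(stage, ": ", conditionMessage(e)))
  })
  res
}

#' Write the default synthetic fixture fileset
#'
#' Simulates a cohort from [default_sim_config()] and writes it as a PLINK
#' binary fileset (plus a quantitative phenotype table when present).
#'
#' @param prefix output path prefix.
#' @param config simulation configuration.
#' @param seed integer seed.
#' @return `prefix`, invisibly.
#' @export
make_fixture <- function(prefix, config = default_sim_config(),
                         seed = config$seed) {
  sim <- simulate_cohort(config, seed = seed)
  suppressWarnings(write_bed(sim$cohort, prefix))
  if (!is.null(sim$cohort$qt)) {
    ph <- cbind(iid = sim$cohort$samples$iid, sim$cohort$qt)
    utils::write.table(ph, paste0(prefix, ".pheno.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
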