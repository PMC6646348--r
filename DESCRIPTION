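Package: xchrom
Title: Sex-Aware Quality Control and Association Testing for X Chromosome SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the X-chromosome-specific steps of a candidate-SNP
    case-control analysis: reading and writing PLINK binary (.bed/.bim/.fam)
    and text (.ped/.map) filesets and long-format array genotyping exports;
    sex-stratified quality control including per-sex missingness, differential
    missingness between sexes, sex-specific allele frequency comparison and
    the Wigginton exact test of Hardy-Weinberg equilibrium in females;
    X-inactivation-aware dosage coding of hemizygous males; Clayton's
    1-df and 2-df sex-stratified score tests for binary and quantitative
    phenotypes; a synthetic-cohort generator emulating the sampling design of
    a paediatric obesity study; and a Monte-Carlo harness for type-I error
    and power experiments across sex-ratio and allele-frequency scenarios.
License: MIT
Encoding: UTF-8
Imports: stats, utils, tools, MASS
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
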