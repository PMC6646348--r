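---
title: "Sex-aware QC and association testing on the X chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-aware QC and association testing on the X chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xchrom)
```

## Why the X chromosome needs its own pipeline

At a non-pseudoautosomal X locus, females carry two allele copies and males
one. This single fact touches every stage of a genetic association study:

* **Allele counting.** A female contributes two alleles to a frequency
  estimate, a hemizygous male one. Minor-allele frequencies, Fisher tests of
  frequency differences and group-stratified frequencies must all use this
  weighting.
* **Genotype calling and QC.** Call rates differ systematically between
  sexes (male signal intensities are lower), so missingness must be audited
  per sex, and the *difference* in missingness between sexes is itself a
  quality signal. A heterozygote call in a male is a genotyping error by
  construction and must be surfaced, not silently recoded.
* **Hardy-Weinberg checks** only make sense in females; males carry one
  allele and cannot be in or out of HWE.
* **Association testing.** Pooling sexes naively creates two problems:
  males and females have different dosage ranges, and when allele
  frequencies differ between the sexes, any imbalance in the female/male
  ratio between cases and controls confounds the genotype-phenotype
  relationship and inflates type-I error.
* **X-chromosome inactivation (XCI).** In most female cells one X copy is
  epigenetically silenced, balancing expression dosage with males; but up
  to a third of X-linked genes escape silencing to some degree. Under
  complete XCI, a hemizygous male carrier is biologically comparable to a
  homozygous female, so males are coded 0/2 on the female scale; under
  escape, both female copies are expressed and a male carries a single
  dose, coded 0/1. The correct coding is a property of the locus and
  tissue, and often has to be tested both ways.

`xchrom` implements this analytic path end to end for candidate-SNP panels:
PLINK fileset I/O, the sex-aware QC battery, XCI-aware dosage coding,
Clayton's stratified score tests, and a synthetic-cohort generator that
makes the whole pipeline testable without access to individual-level data.

## The statistical core

### Exact Hardy-Weinberg test in females

`hwe_exact(n_hom1, n_het, n_hom2)` implements the exact conditional test of
Wigginton, Cutler and Abecasis (2005), the same test PLINK uses. Given the
female allele counts, the number of heterozygotes $n_{AB}$ follows

$$P(n_{AB} \mid n, n_A) =
  \frac{n!}{n_{AA}!\,n_{AB}!\,n_{aa}!} \, 2^{n_{AB}}
  \Big/ \binom{2n}{n_A},$$

and the p-value sums the probabilities of all heterozygote counts (of the
parity fixed by $n_A$) no more probable than the observed one. The
implementation uses the numerically stable mode-anchored recurrence; the
test suite checks it against an independent full enumeration on the
exhaustive grid of triples with $n \le 30$ and on random large triples.
Expected heterozygosity is reported as $2p(1-p)$ with no small-sample
correction, which is the convention that reproduces standard `.hwe` report
values from their own printed counts. No mid-p variant is offered; the
plain Wigginton criterion matches the cited reference and the PLINK
default.

### Clayton's stratified score tests

Clayton's S1 and S2 are X-specific versions of the familiar autosomal
tests that include both sexes while respecting XCI. The package constructs
them as sex-stratified score tests. With dosage columns $z_i$ (additive
$x_i$, and for S2 also the female-heterozygote indicator $h_i$), and
phenotype $y$ centred within each sex stratum $s$:

$$U = \sum_s \sum_{i \in s} (y_i - \bar y_s)\, z_i, \qquad
  V = \sum_s \Big[\sum_{i \in s} (y_i - \bar y_s)^2\Big]\,
      \frac{n_s}{n_s - 1}\,\widehat{\mathrm{Cov}}_s(z),$$

$$T = U^\top V^- U, \qquad T \sim \chi^2_{\mathrm{rank}(V)} .$$

Design notes, each of which is pinned by a test:

* **Variance convention.** The $n_s/(n_s-1)$ factor makes $V$ exactly the
  permutation variance of $U$ under within-stratum permutation of $y$.
  Restricted to females with a binary phenotype, S1 then equals
  $(n-1)r^2$ — the linear-by-linear form of the Cochran-Armitage trend
  test used by the snpStats family. The suite verifies this closed-form
  equivalence to $10^{-10}$ relative error, and verifies the
  chi-square calibration directly against a $10^5$-replicate
  within-stratum permutation distribution.
* **Generalised inverse.** $V$ is inverted by Moore-Penrose pseudo-inverse
  with rank-based degrees of freedom, so degenerate strata (males have
  $h \equiv 0$; a stratum may lack heterozygotes entirely) degrade the df
  instead of crashing. On males-only data S2 collapses to S1.
* **Binary and quantitative phenotypes** flow through the same score:
  affection codes 1/2 become 0/1, and the statistic is invariant under
  affine transforms of a quantitative $y$. Quantitative traits are used
  raw, not rank-transformed.
* **Missing data** are excluded pairwise per (SNP, phenotype), so each
  association cell reports its own n.
* **Undefined cases** (constant dosage or phenotype within every stratum)
  return an `NA` statistic with an explicit reason rather than a number.

The female-only trend test and the male-only allelic Fisher test are
provided as the conventional sex-separate fallbacks, and
`pooled_trend_test()` is the deliberately naive comparator used to
demonstrate why stratification matters.

### Dosage coding

`xci_code()` maps genotypes to model dosages: females 0/1/2 under either
model; males 0/2 under inactivation, 0/1 under escape; the dominance
indicator is zero for males. Male heterozygote calls are refused here —
sanitation (`sanitize_male_hets()`) is an explicit, logged QC action, never
an I/O side effect, because a male het is evidence about upstream calling
that the analyst should see.

## The synthetic cohort generator

`default_sim_config()` emulates the sampling design of a paediatric
obesity case-control study of 915 children genotyped at eight X-linked
SNPs (seven in *TNMD*, one in *SLC6A14*): 477 girls and 438 boys, with 258
normal-BMI controls (122 F / 136 M) and 657 overweight/obese cases
(355 F / 302 M) — a deliberately balanced female/male ratio within each
group. Its per-SNP parameters are the published summary statistics of that
study: sex-specific minor-allele frequencies (0.26–0.46), per-sex missing
call rates (females 0.002–0.09, males 0.06–0.14), and a female
heterozygote deficit.

Generator model and the choices behind it:

* **Female genotypes** are drawn from an inbreeding-style trinomial:
  $P(2) = p^2 + f p q$, $P(1) = 2 p q (1 - f)$, $P(0) = q^2 + f p q$. A
  single deficit coefficient $f$ was chosen because the study's female
  heterozygosity tables show a uniform deficit across strata; the default
  per-SNP $f$ is calibrated as $1 - O(\mathrm{HET})/E(\mathrm{HET})$ from
  those published values (0.03–0.32), which makes the expected exact-HWE
  p-value at n = 477 females small, as observed.
* **Male genotypes** are Bernoulli($p_m$) hemizygotes stored on the 0/2
  scale.
* **Phenotypes.** Under the null model, affection labels are assigned at
  the configured margins independently of genotype (the margins are
  recruitment constants, not random variables). Under the logistic model,
  affection is sampled from
  $\mathrm{logit}\,P = \alpha_s + \beta x + \beta_{dom} h + \gamma\,1\{\mathrm{male}\}$
  and the per-sex case counts are then matched to the margins by rejection
  sampling (capped at 10,000 attempts); the stratum intercept $\alpha_s$
  is first calibrated by root-finding so the expected case count equals
  the target, which is what makes rejection sampling feasible. The
  dominance coefficient $\beta_{dom}$ exists so that heterozygote-only
  effects (where S2 should beat S1) are expressible. Quantitative traits
  are Gaussian, $y = \beta x + \beta_{dom} h + \gamma\,1\{\mathrm{male}\} +
  \varepsilon$.
* **Missingness** is independent Bernoulli per (sample, SNP) within sex,
  applied last. No dependence structure is modelled because none is
  described for the emulated study. For QC fixtures that need *exact*
  missingness tables, `deterministic_missingness()` blanks exactly
  $\lfloor \mathrm{rate} \times n_{sex} \rfloor$ calls per sex — floor, not
  round, because a printed rate of 0.02 must remain on the passing side of
  a ≤ 2% filter, matching the reported filter outcomes.
* **Reproducibility.** All randomness flows from one seed
  (default 20190722); the RNG state of the caller is saved and restored.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: linkage disequilibrium between the SNPs (they
are simulated independently, while the seven *TNMD* SNPs are tightly
linked in reality), skewed metabolic trait distributions (HOMA-IR is
log-normal-ish in children; the generator is Gaussian), genotyping batch
and plate effects, and any real XCI biology — the XCI model is an input
switch, not an inferred property.

## Quality-control battery

`apply_qc()` evaluates, per SNP, each individually enableable criterion:

| criterion | default | note |
|---|---|---|
| female missing frequency | ≤ 0.02 | fails when strictly above |
| differential missingness p | ≥ 1e-7 | two-sided Fisher exact, missing × sex |
| minor-allele frequency | ≥ 0.01 in each sex | monomorphic SNPs always fail |
| female exact HWE p | ≥ 1e-4 | evaluated in control females only |

The HWE filter uses control (normal-BMI) females because cases are
selected on the phenotype, which distorts genotype proportions at truly
associated loci; `hwe_female_table()` still reports ALL/AFF/UNAFF strata
for inspection. The differential-missingness p-value is computed by the
exact Fisher test (the flag-based tool the convention comes from computes
an exact test, despite "asymptotic" wording in some report captions).
Sample-level QC (relatedness, heterozygosity-based sex checks, ancestry)
is out of scope — appropriate for GWAS panels, not candidate-SNP panels.

Fisher exact p-values throughout are two-sided by the point-probability
criterion (the sum over all tables no more probable than the observed
one), matching `stats::fisher.test` and the PLINK convention; odds ratios
are reported as sample cross-product ratios, not conditional MLEs, because
that is what standard sex-frequency report tables print.

## Monte-Carlo harness

`run_scenario()` quantifies operating characteristics by simulation:
rejection rates of any subset of {S1, S2, female trend, male allelic,
pooled trend} at nominal alphas, with 99% binomial bands. The bundled
`paper_scenarios()` cover the five situations that drive test selection;
the key contrast is `unbalanced_null` — sex-specific allele frequencies
(0.37/0.30, the *SLC6A14* values) with controls 80% female and cases 30%
female — where the pooled trend test's type-I error roughly quadruples
(about 0.19 at nominal 0.05 in the acceptance run) while S1 stays within
its binomial band. The default of 2000 replicates balances runtime
against band width ([0.037, 0.063] at alpha 0.05); the test suite uses
300–600 replicates with correspondingly wider bands for the directional
properties, and the full 2000 for the calibration checks.

## Numerical and interface choices

* **PLINK binary I/O** is implemented against the v1.00 SNP-major format
  contract (magic bytes `6c 1b`, mode `01`, LSB-first 2-bit fields,
  zero-padded tail bits) and is verified bit-exact on round trips,
  including a hand-packed byte-level example. Chromosome "X" is accepted
  on input and normalised to code 23; phenotype 0 is accepted and
  normalised to -9.
* **The `.ped`/`.map` text dialect carries no allele roles**, so reading
  infers A1 as the minor allele (female alleles weighted twice), with
  ties broken alphabetically, or takes roles from a supplied table. An
  allele never observed in the data cannot be recovered from a `.ped`;
  lossless binary→text→binary round trips therefore presuppose cohorts
  canonicalised with `set_minor_first()` and polymorphic at every SNP,
  which is how the round-trip properties are tested.
* **Long-format exports** (three columns: SNP reference, sample id,
  genotype call) are reshaped with sorted row/column order, making the
  result invariant under record permutation; sex is inferred from
  hemizygous single-allele calls when no sample table is given.
* The **command-line front end** (`inst/cli/xchrom.R`) is a thin
  `optparse` wrapper over `pipeline_run()` with subcommands `convert`,
  `qc`, `assoc`, `simcheck` and `make-fixture`; exit codes 0 (ok),
  2 (input error), 3 (QC removed every SNP), 4 (internal). All analysis
  outputs are deterministic TSVs; timestamps appear only in the run
  manifest.

## A worked example

```{r example}
sim <- simulate_cohort(default_sim_config(), seed = 1)
cohort <- sanitize_male_hets(sim$cohort, quiet = TRUE)$cohort

head(sex_allele_freq_test(cohort), 3)

qc <- apply_qc(cohort)
qc$report$excluded

clayton_test(cohort, "rs2073162", xci_model = "inactivation")
```

## Known limitations

* The Clayton statistics here are a from-first-principles stratified score
  construction pinned by the trend-test equivalence, null calibration and
  permutation agreement; exact numeric agreement with any particular
  legacy implementation is not claimed.
* No LD-aware methods, haplotype analysis, imputation, or Zheng's
  statistic family; no VCF or PLINK2 `.pgen` support; autosomal data pass
  through but get no autosome-specific handling.
* Pseudoautosomal loci must not be analysed with these tools; the sex
  weighting and male coding assume hemizygosity.
* Genome build of base-pair positions is carried verbatim, never lifted
  over.
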