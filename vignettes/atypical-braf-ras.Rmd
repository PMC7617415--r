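---
title: "Methods: co-occurrence and clonality of atypical BRAF and Ras pathway mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence and clonality of atypical BRAF and Ras pathway mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasco)
```

## Background and model

BRAF driver mutations in colorectal cancer fall into three functional
classes defined by their effect on kinase activity: class 1 (codon 600,
essentially V600E) signals as a constitutive monomer; class 2 (codons
464, 469, 597, 601) forms active, Ras-independent homodimers; class 3
(codons 466, 581, 594, 595, 596) is kinase-impaired and signals through
BRAF–CRAF heterodimers only in the presence of active Ras. Class 2/3
("atypical") tumors therefore have an incentive to acquire *additional*
Ras-pathway mutations — frequently at non-hotspot ("atypical") KRAS
codons (14, 19, 22, 33, 34, 59, 60, 68, 117, 146, 147), in NRAS
(12/13/61), or as protein-truncating NF1 changes. `rasco` provides the
annotation rules, exact co-occurrence statistics, clonality model and
spectrum statistics needed to quantify this co-evolution, plus seeded
generators so every stage is testable without access to controlled
patient-level data.

## Annotation rules

Classification is purely protein-level: a codon-rule table
(`ras_rules()`) maps missense substitutions to classes and domains; no
variant-effect prediction or genome-to-protein mapping is attempted.
Choices worth knowing:

* Missense changes at unlisted BRAF codons and all non-missense BRAF
  changes are `unclassified` and treated as presumed passengers: they are
  excluded from class rows but retained in cohort totals.
* A tumor with BRAF mutations of two or more classes is labelled
  `multiple` (the full class list is kept in `braf_classes`), so
  single-label summaries count it once and per-class denominators are not
  double-counted.
* The domain C (ATP-binding-site) set is the explicit list {464, 466,
  469}, not the inclusive range 464–469: the enumerated form is the more
  specific statement of the rule and keeps the domain sets disjoint.
* NF1 "protein-truncating" is operationalized as nonsense or frameshift,
  with splice-site changes included by default; whether splice variants
  belong in the truncating set is genuinely unsettled, so it is a config
  switch (`nf1$truncating_consequences`) rather than a hard-coded guess.
* Gene symbols are case-insensitive; three-letter HGVS protein changes
  are normalized to one-letter form at parse time.

## Exact co-occurrence statistics

`fisher_exact_2x2()` implements the two-sided Fisher exact test by the
minimum-likelihood rule — the sum of hypergeometric point probabilities
not exceeding that of the observed table, with the conventional
`1 + 1e-7` relative fence against floating-point ties. This is the
definition used by mainstream statistical software, and it reproduces the
published p-value of the codon-466 location table (13/18 vs 12/39 →
p = 0.0046, printed as 0.005):

```{r}
fisher_exact_2x2(c(13, 5, 12, 27))$p_two_sided
```

Missing data are handled listwise per table and counted in `n_excluded`,
so each comparison's denominator covers tumors with available data — the
same convention the class-stratified `cohort_summary()` uses for its
percentage columns. A table with a zero margin carries no information
about association and returns p = 1 with a warning. No multiple-testing
correction is applied: the co-occurrence statistics are reported as
nominal exact p-values (`stats::p.adjust` composes naturally downstream
for users who need it).

## The purity–VAF–copy-number relation

For a clonal mutation present on `n_mut` of a cancer cell's alleles with
`n_wt_cancer` wild-type alleles per cancer cell and two wild-type alleles
per contaminating normal cell,

$$\mathrm{VAF} = \frac{\rho\, N_{mut}}{\rho\,(N_{mut}+N_{wt,can}) + 2(1-\rho)},
\qquad
\rho = \frac{2}{N_{mut}/\mathrm{VAF} - N_{mut} - N_{wt,can} + 2},$$

where the second expression is the inversion used to *assign* the mutant
allele copy number: allele-specific copy-number callers report a
segment's two allele copy numbers without saying which carries the
mutation, and substituting each in turn as `n_mut` generally leaves only
one assignment whose implied purity is consistent with the sample's
estimate. In the diploid heterozygous case the relation collapses to the
linear form `purity = 2·VAF`, and `expected_vaf(p, 1, 1) = p/2` exactly.

Numerical conventions: implied purities above `1 + ε` (ε = 0.05 by
default) are flagged invalid rather than clamped; the assignment
tolerance is `|implied − estimated| ≤ 0.1`, chosen to absorb typical
uncertainty of upstream purity estimators and exposed as `tol`; exactly
symmetric copy-number states (a = b) are assigned trivially; when both
assignments fit within tolerance and are numerically indistinguishable
the call is `ambiguous`, and when neither fits it is `no_fit` — a
subclonality signal, not an error. Read counts are treated as exact
binomial draws; no overdispersion model is fitted.

## Pair clonality calls

`test_pair_clonality()` reports two separable components:

1. **Per-variant clonal consistency** — an exact binomial test of the
   mutant read count against the VAF expected under clonality at the
   sample's purity and assigned copy numbers.
2. **Pairwise independence** — a Pearson χ² test on the 2×2 table of the
   two variants' mutant/reference counts, with mutant counts scaled to
   per-allele-copy units (the raw-count version is reported alongside,
   since either convention is defensible).

The call logic is: `co_clonal` when both variants are consistent with
clonality; `nested` when exactly one is and the other sits significantly
*below* its clonal expectation; `distinct` when both fail and their
corrected allele fractions can coexist as disjoint subclones (sum ≤ 1);
`ambiguous` otherwise. Because the co-clonality decision combines two
tests, each is compared at the Šidák-adjusted level
$1 - \sqrt{1-\alpha}$: this keeps the *pair-level* decision at the
nominal α = 0.05, whereas comparing each variant at α would inflate the
pair-level false-subclonality rate to ≈ 9.7% and systematically
under-call co-clonality. The corrected allele fraction
(implied purity / sample purity, capped at 1 + ε) is exact for diploid
loci at any cell fraction and a first-order approximation for subclonal
mutations on aneuploid segments.

## Mutation spectra and causal channels

Spectra are 96-channel trinucleotide single-base-substitution counts
collapsed to the pyrimidine strand (purine-reference mutations are
reverse-complemented before labeling, making the channel
strand-invariant) and normalized to proportional activity within each
sample, so weights sum to one and samples with different mutation burdens
are comparable. Channel order is the conventional lexicographic one
(C>A, C>G, C>T, T>A, T>C, T>G by flanking bases).

The *causal channel* of a driver substitution is the channel whose
mutation generates it: `G[T>A]G` for V600E (coding-strand GTG>GAG). The
class 2/3 causal set is not a published list, so it ships as an editable
audit table (`inst/extdata/braf_causal_channels.tsv`) mapping each
prespecified class 2/3 coding substitution to its coding-strand
trinucleotide context and collapsed channel; the 21 listed substitutions
collapse to 16 distinct channels, and the table is re-verified against
`collapse_to_pyrimidine()` at load time so edits cannot drift out of
sync. `causal_channel_proportion()` is then a plain sum of weights —
additive over disjoint sets and equal to 1 over all 96 channels.

`fit_presence_logistic()` models driver presence on the causal-channel
proportion by maximum-likelihood logistic regression with the covariates
tumor location (distal = 1), MSI status (MSS = 1), age at diagnosis and
sex (male = 1). By default the proportion is the sample's own causal set
(the summed class 2/3 set is available by passing that set); complete
separation is detected from the fitted probabilities and flagged rather
than silently reported.

## What the generators emulate — and what they do not

`simulate_cohort()` reproduces the *marginal, class-stratified* structure
of a combined 6,605-tumor colorectal dataset: class frequencies (10.7% /
0.47% / 1.22% for classes 1/2/3), per-class additional-Ras probabilities
(2.4% / 29% / 45.7%), atypical fractions among those, MSI (class 2/3
tumors are microsatellite stable) and per-class distal-location rates
(16.3% / 62.5% / 56.1%). Variant spellings are drawn from pools of
observed drivers (NF1 truncating spellings are synthetic placeholders).
Ages are normal with mean 68 and SD 10 years, sex is Bernoulli(0.55
male), and stages follow a fixed categorical distribution — unremarkable
choices for a colorectal cancer cohort where no value was specified.
`simulate_read_counts()` draws mutant reads as
`Binomial(depth, cell_fraction × expected VAF)`;
`simulate_catalog()` draws channels from a configurable 96-vector
(`default_channel_probs()` places 0.69% on the class 1 channel and a
summed 12.9% on the class 2/3 set, the mean activities reported for
whole-genome colorectal spectra) and emits each mutation on a random
strand so the collapse path is exercised.

The generators deliberately do **not** emulate: joint dependence between
clinical variables beyond class (everything is conditionally independent
given class), genomic positions or germline variation, signature-shaped
spectra beyond the configured causal masses, sequencing error or
overdispersed read counts, and survival times. Passing tests therefore
demonstrate that the estimators recover the *model they assume*; they do
not certify behavior under real-data pathologies such as FFPE artifacts,
subclonal copy number or purity misestimation.

## Problem sizes and seeds

All randomized checks are seeded and sized for desk-scale runs: 10,000
tumors for generator-fidelity checks (every configured rate recovered
within 3 binomial SEs), 200 simulated pairs per clonality scenario
(purity 0.7, depths 200–1,000; co-clonal vs distinct-subclone
discrimination ≥ 95%), 400 copy-number assignments at depths 500–2,000
(≥ 99% recovery among unambiguous cases), catalogs of 10,000 mutations
for channel-weight recovery (max deviation < 0.015), and exhaustive
Fisher enumeration over all 2×2 tables with total ≤ 60. The logistic
recovery experiments use n = 2,000 with channel proportions drawn from
Beta(0.5, 0.5), which gives the covariate enough spread for the Wald
standard error (≈ 0.14) to support the ±0.3 recovery band checked in the
tests.

## Known limitations

* Annotation is protein-level; a variant reported only by genomic
  coordinates must be annotated upstream.
* The corrected allele fraction is approximate for subclonal mutations on
  non-diploid segments (exact for diploid loci and for clonal mutations).
* The causal-channel table reflects a curated set of recurrent class 2/3
  substitutions; rarer substitutions at the listed codons can be added by
  editing the packaged TSV.
* Copy-number calling, purity estimation and signature deconvolution are
  upstream concerns: their outputs are inputs here.
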