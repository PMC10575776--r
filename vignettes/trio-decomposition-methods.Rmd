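---
title: "Methods: family-based decomposition of common and rare variant effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based decomposition of common and rare variant effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscope)
```

## The problem

In a proband–parent trio design, every allele a proband carries was either
inherited from a parent or arose de novo, and every parental allele that was
*not* transmitted still describes the family's genetic background. This
package decomposes the association between genetics and a binary proband
phenotype (here: school performance in a schizophrenia trio cohort,
binarised from final grades) into:

* **transmitted common alleles** — the proband's polygenic score (PRS),
* **non-transmitted common alleles** — a pseudo-control PRS built from the
  parental alleles the proband did not receive, indexing "genetic nurture",
* **transmission disequilibrium** — per-trio deviation of the proband PRS
  from the midparent expectation (pTDT),
* **rare variants** — damaging coding variants and CNVs classified as
  de novo, transmitted, or non-transmitted within each trio.

All individual-level data of the motivating study design are
access-controlled, so the package ships a synthetic-cohort generator with
the same statistical structure; every analysis stage is exercised end to end
on generated cohorts.

## Rare-variant classification

For a biallelic site, the (proband, father, mother) dosage triple maps to an
inheritance class. A carrier proband with two non-carrier parents is
**de novo**; this takes precedence over the Mendelian-consistency check,
because the de novo configuration is by definition inconsistent with
transmission — `mendelian_error` is reserved for triples that are impossible
*and* not explained by a new mutation (e.g. a hom-alt parent with a
non-carrier child). Calls are only classified if all three members pass the
sequencing filters (depth ≥ 10, genotype quality ≥ 30, allele balance in
[0.2, 0.8] for hets, ≥ 0.9 / ≤ 0.1 for hom-alt / hom-ref); a failure in any
member voids the call for the whole trio, which protects against spurious
de novo calls caused by parental dropout.

Damaging variants are frameshifts, stop-gain/splice variants with CADD ≥ 20,
and missense variants with MPC ≥ 1 and CADD ≥ 20. Transmitted and
non-transmitted analyses are restricted to ultra-rare variants: exactly one
copy among all cohort parents and absent from the external reference
(counted over the full parental cohort, including the carrier's own
parents). De novo variants bypass the rarity filter — new mutations are rare
by construction. Burdens count variants, not genes.

CNVs transmit on *any* overlap (≥ 1 bp) with a same-type parental CNV; a
deletion cannot transmit as a duplication, so types must match (the
convention is ours; the interval logic is deliberately permissive because
array-based endpoints are imprecise). CNV filters: cohort frequency ≤ 1%,
≥ 15 probes, segmental-duplication overlap ≤ 50%, length ≥ 15 kb, and
≥ 100 kb for transmitted/non-transmitted calls, which lack independent
validation. Cohort frequency is computed as the fraction of all individuals
(probands and parents) carrying any same-type overlapping CNV; this is a
documented knob, since "frequency in the sample" admits several readings.
Gene-set membership for a CNV requires overlap with at least one exon of a
set gene; coordinates are BED-style 0-based half-open for intervals and
1-based for variants, converted in one reader layer.

## Polygenic scoring and the pseudo-control

Summary statistics are clumped greedily: best p first, removing SNPs within
250 kb with r² > 0.2, ties broken by (chromosome, position) so the retained
set is independent of row order. LD is estimated from parental genotypes
only, avoiding double-counting of transmitted alleles. Scores sum
`beta × dosage` over retained SNPs below the training p-value threshold
(0.05 primary; 0.001 and 0.5 as sensitivity outputs); alleles are aligned by
direct match, effect/other swap, or strand complement, and A/T–C/G SNPs are
dropped as unresolvable. Missing dosages contribute the SNP's cohort mean
(the convention of standard scoring tools; dropping is available).

The phase-free identity `non-transmitted dosage = father + mother − proband`
defines the pseudo-control, so `proband PRS + nt-PRS = father PRS + mother
PRS` holds exactly on the raw scale; the test suite asserts it to numerical
precision. Mendelian-inconsistent genotypes at common SNPs are masked for
that trio only (panel-wide removal is not needed when error rates are low,
mirroring a QC narrative where nothing was removed).

The pTDT deviation is `(proband PRS − midparent PRS) / SD(midparent PRS)`.
Two structural facts worth knowing: under random transmission the deviation
is orthogonal to the midparent score, but it is *not* orthogonal to the
nt-PRS — for independent SNPs `cor(nt-PRS, proband − midparent) → −1/√2`,
because the pseudo-control is the mirror of the transmission noise. The
tests assert the former and the exact value of the latter.

## Association statistics

Rare-variant categories are tested with **Firth penalized logistic
regression**, written in-package: Newton iteration on the modified score
`X'(y − p + h(1/2 − p))` with step-halving on the penalized log-likelihood
`ℓ + ½ log det I(β)`, convergence when the penalized score drops below 1e−6
or the step below 1e−8, probabilities clipped to [1e−12, 1−1e−12]. The
penalty keeps estimates finite under the (quasi-)separation that a 13-carrier
category invites. For a single binary predictor the estimate equals the
classical add-½-to-each-cell odds ratio, which the tests use as a closed-form
oracle. P-values are penalized-likelihood-ratio by default (each coefficient
refit constrained to zero); Wald is available, and Wald CIs are reported.

PRS predictors use ordinary binomial logistic regression (`glm`), falling
back to the Firth fit — flagged in the output — when separation is detected.
Internally the outcome is always coded 1 = lower performance; PRS rows are
*presented* as the OR for higher performance per SD (the field's convention),
and the multivariable model recodes 1 = higher performance, matching the
usual presentation of joint models. A single internal coding with
presentation-layer inversion avoids sign bugs.

Companion statistics are implemented from the defining formulas:
Clopper–Pearson exact binomial CIs via the beta-quantile characterisation;
Fisher's exact test with the conditional-MLE odds ratio from the noncentral
hypergeometric likelihood (enumerated in log space and inverted for exact
CIs); the rare-variant TDT `(T − NT)²/(T + NT)` against χ²(1); Nagelkerke's
ΔR² from nested binomial fits. Each is cross-checked in the tests against
an independent route (base `binom.test`, `fisher.test`, hand enumeration).
The primary analysis comprises 18 tests (6 PRS + 12 rare categories), so the
family-wise threshold is 0.05/18 ≈ 0.0027.

## Power simulation

The liability-threshold power model draws independent standard normals
(PRS, V2), forms `L = √r² · PRS + √(1 − r²) · V2`, assigns draws with L < 0
to the lower-performance group and L > 0 to the higher group until both
reach their targets (overflow discarded), and compares the groups' PRS with
a pooled-variance t-test; power is the rejection fraction over replicates
(10,000 by default) with a Clopper–Pearson Monte-Carlo CI. The pooled test
matches the construction — both groups are truncated normals with near-equal
variance; Welch is available. A closed-form check: conditional on the sign
of L the PRS means are ±√r²·√(2/π) with within-group variance 1 − r²(2/π),
giving a normal-approximation power that the simulation must match within
Monte-Carlo error. Default group sizes are 347/346 (a cohort of 693 in
near-equal halves).

## The synthetic cohort generator

`synth_config()` fixes the study conditions; `generate_cohort()` is
deterministic given the seed, with per-stage substreams at fixed offsets so
that, e.g., changing the CNV rate does not perturb the SNP panel.

* **Common variants.** Parental dosages are binomial draws at MAFs uniform
  in [0.05, 0.5]; each parent transmits one allele per SNP uniformly at
  random, so Mendelian consistency holds by construction (an error-injection
  knob corrupts proband genotypes into violations at a configured rate). An
  optional block-correlated haplotype mode (latent Gaussian with within-block
  correlation) gives clumping real work; the default is independent SNPs.
  SNPs are uniformly spaced on a single pseudo-chromosome; genes are
  fixed-width blocks with fixed-width exons downstream of the SNP region —
  enough structure to exercise window and overlap logic without real
  annotation.
* **Weights and summary statistics.** A fraction of SNPs (default 20%) carry
  normal liability weights (SD 0.05). The emitted "GWAS" betas are the true
  weights plus estimation noise (SD 0.02) with p-values from a nominal
  standard error of 0.02, so the three training thresholds retain nested SNP
  subsets and the scored PRS is a realistically attenuated estimate of the
  true score. One liability-coupled trait (`cognition`) plus two null traits
  with random weights yield the 6 PRS tests of the primary scan, mirroring a
  design where two cognitive traits associate and a disorder PRS does not.
* **Rare variants.** Damaging de novo counts per proband are Poisson: 0.02
  in DD genes and 0.08 in LoFi-only genes, calibrated so a 656-trio cohort
  carries ≈ 13 damaging DD de novos cohort-wide; a background rate of 0.5
  adds non-qualifying de novos (sub-threshold CADD/MPC, non-set genes) so the
  classifier's filters are load-bearing. Inherited damaging singletons arise
  per parent at rate 1.5 (a quarter in DD genes), each transmitted with
  probability ½; variants failing the ultra-rare rule (two parental copies
  or reference carriers) are generated at rate 0.3 per parent for the filter
  to reject. The DD set is a subset of the LoFi set by construction.
* **Phenotype.** Liability is `−√r²·PRS_std + β_dn·n_DD + √s²·ε` with
  `s² = 1 − r² − β_dn²·rate` (floored), keeping total variance near 1; the
  cognition-like score is protective, de novos deleterious (default β_dn =
  1.5, r² = 0.05 — a realistic PRS contribution for a cognitive trait).
  Grades 3–6 are assigned by liability quantiles with default proportions
  16/29/30/25, and the binary outcome is grades 3–4, giving a ≈ 45% lower
  group — the near-balanced split of the motivating design. This replaces a
  plain median split so that grade-level summaries (carrier grade tables)
  are available; the quantiles are configurable. Comorbid ID is Bernoulli
  with a baseline rate of 4.3% and a log-OR per DD de novo of log 15.
* **CNVs.** Per-parent Poisson (rate 0.15) with log-uniform lengths from
  8 kb to 600 kb — deliberately spanning the 15 kb and 100 kb thresholds —
  transmitted with probability ½ with jittered endpoints; de novo proband
  CNVs at rate 0.03. Probe counts scale with length so some calls fail the
  15-probe rule.

What the generator does **not** emulate: realistic LD maps and allele
frequency spectra, chromosome-level annotation, imputation uncertainty,
population stratification correlated with genotype (PCs are pure noise
columns), assortative mating, or true genetic-nurture channels (the nt-PRS
has no causal path to the phenotype, so nurture analyses are calibrated
under the null only). Passing tests therefore demonstrate correctness of
the decomposition machinery under the stated generative model, not
robustness to the full messiness of real cohort data.

## Problem sizes and numerical choices

The test suite runs cohorts of 25–2,000 trios with 30–200 SNPs, two checks
at 5,000 trios (directional parameter recovery, pTDT structure), 2,000-replicate
power grids, and one 10,000-replicate power point; the analysis drivers use
the full 656-trio, 2,000-SNP configuration. Clumping ties are broken by
(p, chromosome, position); burden categories with no carriers are reported
as untestable (`NA`) rows rather than degenerate fits; rank-deficient
designs are rejected naming the collinear columns; zero-margin 2×2 tables
are rejected rather than patched.

## Limitations

Firth confidence intervals are Wald-based (profile-penalized intervals are a
known refinement); the alternative damaging-variant definition used in some
sensitivity analyses is not encoded (the damage rules are small pure
functions, so a variant rule is a one-line replacement); X-chromosome
inheritance, mosaicism and compound heterozygosity are out of scope; and the
multivariable ΔR² mixes a Firth fallback's likelihood when a factor
separates, which is slightly conservative.
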