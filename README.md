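# trioscope

Family-based decomposition of common and rare genetic contributions to a
binary proband phenotype, for proband–parent trio cohorts.

In a trio design every proband allele is either inherited or de novo, and
the parental alleles that were *not* transmitted describe the family
background without contributing directly to the child's genotype. This
package separates those channels for a binary outcome (the motivating
setting is school performance — a proxy for cognitive ability — in a
schizophrenia trio cohort, binarised from final school grades):

* **Rare variants** — trio genotype QC (depth ≥ 10, GQ ≥ 30, allele-balance
  bands), classification of coding variants and CNVs as de novo /
  transmitted / non-transmitted, damaging-variant prioritisation
  (frameshift; stop-gain/splice with CADD ≥ 20; missense with MPC ≥ 1 and
  CADD ≥ 20), the ultra-rare filter (one parental copy, absent from a
  reference cohort), and a per-proband burden matrix of 6 mutation classes ×
  2 gene sets (loss-of-function-intolerant and developmental-disorder
  genes).
* **Common variants** — LD clumping (250 kb, r² 0.2), thresholded polygenic
  scores, the pseudo-control non-transmitted PRS from the dosage identity
  `nt = father + mother − proband`, and the polygenic transmission
  disequilibrium test, pTDT = (proband PRS − midparent PRS) / SD(midparent
  PRS).
* **Association** — Firth penalized logistic regression (Jeffreys-prior
  penalty `ℓ(β) + ½ log det I(β)`, finite under separation) written
  in-package, binomial logistic regression for PRS, Nagelkerke ΔR² for
  nested models, exact binomial (Clopper–Pearson) CIs, Fisher's exact test
  with the conditional-MLE odds ratio, the rare-variant TDT
  `(T − NT)²/(T + NT)`, and a Bonferroni-corrected 18-test primary scan.
* **Power** — the liability-threshold simulation
  `L = √r²·PRS + √(1 − r²)·V2`, filling lower/higher groups by the sign of L
  and comparing group PRS with a pooled t-test over 10,000 replicates.
* **Synthetic cohorts** — a generator (`synth_config()`,
  `generate_cohort()`) producing Mendelian-consistent trio genotypes,
  Poisson de novo and inherited rare variants, CNVs, GWAS-style summary
  statistics and a liability-threshold phenotype, with writers/readers for
  FAM, VCF 4.2, BED and TSV, so the whole pipeline runs without
  access-controlled data.

## Worked example

```r
library(trioscope)

cohort <- generate_cohort(synth_config(seed = 20230313))
cohort
#> synthetic trio cohort: 656 trios, 2000 SNPs, 2738 coding calls, 313 CNVs
#> phenotype split (lower/higher): 295/361

res <- run_pipeline(cohort)   # QC -> burden -> PRS -> 18-test scan
head(res$univariable[order(res$univariable$p), ], 5)
#>                   category    or ci_lower ci_upper       p
#>               dn_coding_dd 6.126    1.459    25.71 0.00304
#>               nt_coding_dd 0.771    0.588     1.01 0.05466
#>  transmitted_prs_cognition 1.154    0.987     1.35 0.07308
#>                  nt_cnv_dd 0.417    0.147     1.18 0.07591
#>             nt_coding_lofi 0.903    0.794     1.03 0.11149
```

The strongest signal is the damaging de novo burden in
developmental-disorder genes (Firth OR 6.1 for lower performance; rare-variant
rows report the OR for lower performance, PRS rows the OR for higher
performance per SD of score). Of the 13 carriers this cohort generated, 11
have the lower-performance phenotype:

```r
res$carrier_table$lower_ci
#> 11/13 = 84.6% (95% CI 54.6-98.1)  # Clopper-Pearson

simulate_prs_power(r2 = 0.018, n_low = 347, n_high = 346,
                   reps = 10000, seed = 1)$power
#> [1] 0.8154   # ~80% power to detect a PRS explaining 1.8% of liability
```

The numbered drivers under `analysis/` run the same stages as a narrated
workflow (`01_simulate` → `05_power`), writing tables under `results/` and
bulky cohort exports under `scratch/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_classify.R
Rscript analysis/03_prs.R
Rscript analysis/04_associate.R
Rscript analysis/05_power.R
```

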