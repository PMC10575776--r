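#!/usr/bin/env Rscript
# Generate the synthetic trio cohort that stands in for the access-controlled
# study data: 656 proband-parent trios with common-SNP genotypes, rare coding
# variant calls, CNVs and a liability-threshold binary phenotype. Writes the
# standard-format files under scratch/cohort/ and a summary table under
# results/.

source("analysis/00_settings.R")

cfg <- cohort_config()
cohort <- generate_cohort(cfg)
print(cohort)

outdir <- file.path(scratch_dir, "cohort")
write_cohort(cohort, outdir)
message("cohort files written to ", outdir)

summary_tbl <- data.frame(
  quantity = c("trios", "snps", "coding_calls", "cnv_calls",
               "damaging_dd_de_novos", "damaging_lofi_de_novos",
               "inherited_singletons_transmitted",
               "inherited_singletons_non_transmitted",
               "probands_lower", "probands_higher"),
  value = c(nrow(cohort$trios), ncol(cohort$panel$dosage),
            nrow(cohort$coding_calls), nrow(cohort$cnv_calls),
            sum(cohort$truth$n_dn_dd), sum(cohort$truth$n_dn_lofi),
            cohort$truth$singletons_transmitted,
            cohort$truth$singletons_non_transmitted,
            sum(cohort$trios$phenotype == 1),
            sum(cohort$trios$phenotype == 0)))
write_result(summary_tbl, "01_cohort_summary.tsv")
print(summary_tbl, row.names = FALSE)
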