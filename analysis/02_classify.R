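#!/usr/bin/env Rscript
# Trio genotype QC, inheritance classification, damaging-variant
# prioritisation and the 12-category burden matrix, with the filter
# bookkeeping (variants in -> variants retained) at each step.

source("analysis/00_settings.R")

cohort <- generate_cohort(cohort_config())

coding <- suppressWarnings(
  annotate_coding_calls(cohort$coding_calls, cohort$gene_sets))
message(sprintf("coding calls: %d in, %d pass trio genotype filters",
                nrow(coding), sum(coding$filter_pass)))
message(sprintf("  inheritance: %s",
                paste(names(table(coding$class)), table(coding$class),
                      collapse = ", ", sep = "=")))
message(sprintf("  damaging: %d; ultra-rare: %d; damaging & ultra-rare: %d",
                sum(coding$damaging), sum(coding$ultra_rare),
                sum(coding$damaging & coding$ultra_rare)))

cnvs <- annotate_cnv_calls(cohort$cnv_calls, cohort$gene_sets,
                           n_individuals = 3 * nrow(cohort$trios))
message(sprintf("CNV calls: %d in, %d pass quality/size filters",
                nrow(cnvs), sum(cnvs$filter_pass)))

burden <- build_burden_matrix(coding, cnvs, cohort$trios)
write_result(burden, "02_burden_matrix.tsv")

totals <- data.frame(category = setdiff(names(burden), "fid"),
                     total_variants = colSums(burden[-1]),
                     carriers = colSums(burden[-1] > 0))
write_result(totals, "02_burden_totals.tsv")
print(totals, row.names = FALSE)

# de novo share of damaging proband variants (de novo + inherited) per set
for (set in c("lofi", "dd")) {
  frac <- denovo_fraction(sum(burden[[paste0("dn_coding_", set)]]),
                          sum(burden[[paste0("trans_coding_", set)]]))
  message(sprintf("de novo share of damaging proband variants (%s): %.1f%%",
                  set, 100 * frac))
}
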