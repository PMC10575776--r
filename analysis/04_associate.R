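#!/usr/bin/env Rscript
# The association stage: 18 primary univariable tests (Firth for the 12
# rare-variant categories, binomial logistic for the 6 polygenic-score
# predictors), secondary pTDT and rare-variant TDT tests, the multivariable
# joint model on the Bonferroni-significant factors, and the carrier
# phenotype table for damaging de novo variants in DD genes.

source("analysis/00_settings.R")

cohort <- generate_cohort(cohort_config())
res <- suppressWarnings(suppressMessages(run_pipeline(cohort)))

uni <- res$univariable
write_result(uni, "04_univariable.tsv")
message(sprintf("primary scan: %d tests, Bonferroni threshold %.4f, %d significant",
                nrow(uni), bonferroni_threshold(nrow(uni)),
                sum(uni$significant)))
print(as.data.frame(uni), row.names = FALSE, digits = 3)

write_result(res$secondary$ptdt, "04_secondary_ptdt.tsv")
write_result(res$secondary$tdt, "04_secondary_tdt.tsv")

if (!is.null(res$multivariable)) {
  write_result(res$multivariable$delta_r2, "04_multivariable.tsv")
  message(sprintf("multivariable model: total variance explained %.1f%%",
                  100 * res$multivariable$total_r2))
  print(as.data.frame(res$multivariable$delta_r2), row.names = FALSE,
        digits = 3)
} else {
  message("no Bonferroni-significant factors; multivariable model skipped")
}

ct <- res$carrier_table
if (nrow(ct$grade_table) > 0) {
  write_result(ct$grade_table, "04_carrier_grades.tsv")
  message(sprintf(
    "DD de novo carriers with lower performance: %d/%d (%.1f%%, 95%% CI %.1f-%.1f%%)",
    ct$lower_ci$k, ct$lower_ci$n, 100 * ct$lower_ci$estimate,
    100 * ct$lower_ci$lower, 100 * ct$lower_ci$upper))
  if (!is.null(ct$id_test))
    message(sprintf(
      "comorbid-ID contrast among lower-performance probands: OR %.1f, p = %.2g",
      ct$id_test$or, ct$id_test$p.value))
}
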