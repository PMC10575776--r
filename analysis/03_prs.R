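#!/usr/bin/env Rscript
# LD clumping, thresholded polygenic scoring for the three weight sources,
# pseudo-control (non-transmitted) scores and pTDT deviations.

source("analysis/00_settings.R")

cohort <- generate_cohort(cohort_config())

profiles <- lapply(cohort$sumstats, function(st)
  build_prs_profiles(cohort$panel, cohort$trios, st))

rows <- list()
for (trait in names(profiles)) {
  prof <- profiles[[trait]]
  for (th in unique(prof$threshold)) {
    p <- prof[prof$threshold == th, ]
    rows[[paste(trait, th)]] <- data.frame(
      trait = trait, threshold = th,
      mean_proband = mean(p$proband_prs), sd_proband = sd(p$proband_prs),
      mean_nt = mean(p$nt_prs),
      mean_ptdt_dev = mean(p$ptdt_deviation),
      flagged_trios = sum(p$flagged))
  }
}
prs_summary <- do.call(rbind, rows)
write_result(prs_summary, "03_prs_summary.tsv")
print(prs_summary, row.names = FALSE, digits = 3)

# per-trio profiles for the primary threshold, all traits
primary <- do.call(rbind, lapply(names(profiles), function(trait) {
  p <- profiles[[trait]]
  p <- p[p$threshold == 0.05, c("fid", "proband_prs_std", "nt_prs_std",
                                "midparent_prs_std", "ptdt_deviation")]
  p$trait <- trait
  p
}))
write_result(primary, "03_prs_profiles_primary.tsv")

message(sprintf("transmission identity |proband + nt - father - mother| max: %.2e",
                max(abs(with(profiles[[1]],
                             proband_prs + nt_prs - father_prs - mother_prs)))))
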