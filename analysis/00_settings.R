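# Shared settings for the analysis drivers. Every script regenerates the
# cohort deterministically from this configuration, so each can be run on its
# own; bulky per-cohort exports go under scratch/, summary tables under
# results/.

library(trioscope)

ANALYSIS_SEED <- 20230313

cohort_config <- function() {
  synth_config(
    n_trios = 656,      # families with both array and sequencing data
    n_snps = 2000,      # desk-scale common-variant panel
    seed = ANALYSIS_SEED
  )
}

results_dir <- "results"
scratch_dir <- "scratch"
dir.create(results_dir, showWarnings = FALSE)
dir.create(scratch_dir, showWarnings = FALSE)

write_result <- function(d, name) {
  path <- file.path(results_dir, name)
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  message("wrote ", path)
}
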