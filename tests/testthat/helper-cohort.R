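# Shared fixtures: small cohorts are memoised per (n_trios, seed, extras) so
# tests that only read them do not regenerate.

.cohort_cache <- new.env(parent = emptyenv())

test_cohort <- function(n_trios = 150, n_snps = 200, seed = 11, ...) {
  extras <- list(...)
  key <- paste(n_trios, n_snps, seed,
               paste(names(extras), unlist(extras), collapse = "_"),
               sep = "|")
  if (is.null(.cohort_cache[[key]])) {
    cfg <- do.call(synth_config, c(list(n_trios = n_trios, n_snps = n_snps,
                                        seed = seed), extras))
    .cohort_cache[[key]] <- generate_cohort(cfg)
  }
  .cohort_cache[[key]]
}

# Independent enumeration of Mendelian consistency for a dosage triple:
# exists a transmissible allele pair summing to the proband dosage.
mendel_consistent_oracle <- function(pro, fa, mo) {
  allowed <- function(g) switch(as.character(g), `0` = 0, `1` = c(0, 1),
                                `2` = 1)
  any(outer(allowed(fa), allowed(mo), `+`) == pro)
}

# Hand truth table for SNV inheritance over all 27 dosage triples, derived
# from the class definitions independently of the package implementation.
snv_truth_table <- function() {
  grid <- expand.grid(pro = 0:2, fa = 0:2, mo = 0:2)
  grid$class <- apply(grid, 1, function(r) {
    p <- r[["pro"]]; f <- r[["fa"]]; m <- r[["mo"]]
    if (p > 0 && f == 0 && m == 0) return("de_novo")
    if (!mendel_consistent_oracle(p, f, m)) return("mendelian_error")
    if (p > 0) return("transmitted")
    if (f > 0 || m > 0) return("non_transmitted")
    "absent"
  })
  grid
}

# O(n^2) reference clumping: repeatedly take the best remaining SNP and
# re-check every remaining pair against the window and r2 rule.
clump_oracle <- function(stats, ld_dosage, window_kb = 250, r2_max = 0.2) {
  st <- stats[stats$snp %in% colnames(ld_dosage), , drop = FALSE]
  st <- st[order(st$p, st$chr, st$pos), , drop = FALSE]
  kept <- character(0)
  while (nrow(st) > 0) {
    idx <- st[1, ]
    kept <- c(kept, idx$snp)
    st <- st[-1, , drop = FALSE]
    if (nrow(st) == 0) break
    drop <- vapply(seq_len(nrow(st)), function(j) {
      if (st$chr[j] != idx$chr) return(FALSE)
      if (abs(st$pos[j] - idx$pos) > window_kb * 1000) return(FALSE)
      r2 <- suppressWarnings(stats::cor(ld_dosage[, idx$snp],
                                        ld_dosage[, st$snp[j]],
                                        use = "pairwise.complete.obs"))^2
      !is.na(r2) && r2 > r2_max
    }, logical(1))
    st <- st[!drop, , drop = FALSE]
  }
  kept
}
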