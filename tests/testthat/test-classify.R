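test_that("damaging PTV and missense rules implement the CADD/MPC thresholds", {
  expect_true(is_damaging_ptv("frameshift", 5))
  expect_false(is_damaging_ptv("stop_gain", 19.9))
  expect_true(is_damaging_ptv("stop_gain", 20))
  expect_true(is_damaging_ptv("splice_acceptor", 25))
  expect_false(is_damaging_ptv("missense", 35))
  expect_warning(res <- is_damaging_ptv("stop_gain", NA), "CADD")
  expect_false(res)

  expect_true(is_damaging_missense("missense", 1.0, 20))   # boundary inclusive
  expect_false(is_damaging_missense("missense", 0.99, 35))
  expect_false(is_damaging_missense("missense", 2.5, 19))
  expect_false(is_damaging_missense("stop_gain", 2, 30))
  expect_warning(res <- is_damaging_missense("missense", NA, 30), "MPC")
  expect_false(res)
})

test_that("damage classification is a pure function of (consequence, cadd, mpc)", {
  set.seed(501)
  n <- 500
  cons <- sample(c("frameshift", "stop_gain", "splice_donor",
                   "splice_acceptor", "missense", "other"), n, replace = TRUE)
  cadd <- round(runif(n, 0, 45), 2)
  mpc <- ifelse(runif(n) < 0.3, NA, round(runif(n, 0, 3), 2))
  truth <- cons == "frameshift" |
    (cons %in% c("stop_gain", "splice_donor", "splice_acceptor") & cadd >= 20) |
    (cons == "missense" & !is.na(mpc) & mpc >= 1 & cadd >= 20)
  expect_equal(is_damaging(cons, cadd, mpc), truth)
})

test_that("ultra-rare filter requires a parental singleton absent from the reference", {
  expect_true(is_ultra_rare(1, 0))
  expect_false(is_ultra_rare(2, 0))
  expect_false(is_ultra_rare(1, 3))
  expect_error(is_ultra_rare(-1, 0), "non-negative")
})

test_that("CNV filters apply the 15 kb / 100 kb size rules by inheritance class", {
  expect_true(cnv_passes_filters(20000, 0.005, 0.1, 20, "de_novo"))
  expect_false(cnv_passes_filters(60000, 0.005, 0.1, 40, "transmitted"))
  expect_true(cnv_passes_filters(120000, 0.005, 0.1, 40, "transmitted"))
  expect_false(cnv_passes_filters(14000, 0.005, 0.1, 20, "de_novo"))
  expect_true(cnv_passes_filters(15000, 0.005, 0.1, 20, "de_novo"))
  expect_false(cnv_passes_filters(20000, 0.02, 0.1, 20, "de_novo"))
  expect_false(cnv_passes_filters(20000, 0.005, 0.6, 20, "de_novo"))
  expect_false(cnv_passes_filters(20000, 0.005, 0.1, 14, "de_novo"))
  expect_false(cnv_passes_filters(60000, 0.005, 0.1, 40, "non_transmitted"))
})

test_that("gene-set membership needs exonic overlap for CNVs and gene symbols for SNVs", {
  sets <- list(
    genes = tibble::tibble(gene = c("gA", "gB", "gC"),
                           start = c(0L, 20000L, 40000L),
                           end = c(10000L, 30000L, 50000L),
                           lofi = c(TRUE, TRUE, FALSE),
                           dd = c(TRUE, FALSE, FALSE)),
    exons = tibble::tibble(gene = c("gA", "gA", "gB", "gC"),
                           start = c(1000L, 8999L, 21000L, 41000L),
                           end = c(1200L, 9100L, 21200L, 41200L)))
  expect_true(variant_in_set("gA", sets, "lofi"))
  expect_true(variant_in_set("gA", sets, "dd"))   # dd subset of lofi
  expect_false(variant_in_set("gB", sets, "dd"))
  expect_warning(res <- variant_in_set("nope", sets, "lofi"), "gene")
  expect_false(res)
  # 1 bp exon overlap counts
  expect_true(cnv_in_set(5000L, 9000L, sets, "dd"))
  # intronic CNV inside a set gene does not
  expect_false(cnv_in_set(2000L, 8000L, sets, "dd"))
  expect_false(cnv_in_set(5000L, 8999L, sets, "dd"))  # half-open: ends before exon
  expect_false(cnv_in_set(41000L, 41200L, sets, "dd"))  # gC not in dd
  expect_true(cnv_in_set(41000L, 41200L, sets, "lofi") == FALSE)  # gC not lofi either
})

test_that("burden matrix equals a brute-force recount and respects set nesting", {
  coh <- test_cohort(n_trios = 50, seed = 21, lowqual_rate = 0.05)
  coding <- suppressWarnings(annotate_coding_calls(coh$coding_calls,
                                                   coh$gene_sets))
  cnvs <- annotate_cnv_calls(coh$cnv_calls, coh$gene_sets,
                             n_individuals = 150)
  burden <- build_burden_matrix(coding, cnvs, coh$trios)
  expect_equal(names(burden)[-1], trioscope:::BURDEN_CATEGORIES)
  expect_true(all(as.matrix(burden[, -1]) >= 0))

  # brute force: iterate every variant x proband
  recount <- function(fid, what, set) {
    if (what %in% c("de_novo", "transmitted", "non_transmitted") &&
        set %in% c("lofi", "dd")) NULL
    sum_coding <- function(cls, need_ur) {
      sum(coding$fid == fid & as.character(coding$class) == cls &
            coding$damaging & (!need_ur | coding$ultra_rare) &
            coding[[paste0("in_", set)]])
    }
    switch(what,
           dn_coding = sum_coding("de_novo", FALSE),
           trans_coding = sum_coding("transmitted", TRUE),
           nt_coding = sum_coding("non_transmitted", TRUE),
           dn_cnv = sum(cnvs$fid == fid & cnvs$class == "de_novo" &
                          cnvs$filter_pass & cnvs[[paste0("in_", set)]]),
           trans_cnv = sum(cnvs$fid == fid & cnvs$class == "transmitted" &
                             cnvs$filter_pass & cnvs[[paste0("in_", set)]]),
           nt_cnv = sum(cnvs$fid == fid & cnvs$class == "non_transmitted" &
                          cnvs$filter_pass & cnvs[[paste0("in_", set)]]))
  }
  for (cat in c("dn_coding", "trans_coding", "nt_coding", "dn_cnv",
                "trans_cnv", "nt_cnv")) {
    for (set in c("lofi", "dd")) {
      manual <- vapply(coh$trios$fid, function(f) recount(f, cat, set),
                       numeric(1))
      expect_equal(burden[[paste(cat, set, sep = "_")]], unname(manual),
                   info = paste(cat, set))
    }
  }
  # DD is a subset of LoFi in the synthetic sets
  for (cat in c("dn_coding", "trans_coding", "nt_coding")) {
    expect_true(all(burden[[paste0(cat, "_dd")]] <=
                      burden[[paste0(cat, "_lofi")]]))
  }
  # supporting variant lists re-filter to themselves
  support <- attr(burden, "support")
  expect_true(all(support$trans_coding_lofi$damaging))
  expect_true(all(support$trans_coding_lofi$ultra_rare))
  expect_true(all(support$nt_coding_dd$ultra_rare))
  expect_true(all(support$dn_coding_dd$class == "de_novo"))

  # zero-variant cohort gives an all-zero matrix
  empty_coding <- coding[0, ]
  empty_cnv <- cnvs[0, ]
  zero <- build_burden_matrix(empty_coding, empty_cnv, coh$trios)
  expect_true(all(as.matrix(zero[, -1]) == 0))
})

test_that("group-averaged de novo burdens at cohort scale match the printed table layout", {
  # 662 probands split 293 lower / 369 higher; 40 and 26 damaging de novo
  # LoFi variants respectively -> group averages 0.14 and 0.070
  set.seed(502)
  n_lower <- 293; n_higher <- 369
  trios <- tibble::tibble(fid = sprintf("F%03d", 1:(n_lower + n_higher)),
                          phenotype = rep(c(1L, 0L), c(n_lower, n_higher)))
  sets <- list(genes = tibble::tibble(gene = "gL", start = 0L, end = 10000L,
                                      lofi = TRUE, dd = FALSE),
               exons = tibble::tibble(gene = "gL", start = 0L, end = 10000L))
  carrier_fids <- c(sample(trios$fid[trios$phenotype == 1], 40, replace = TRUE),
                    sample(trios$fid[trios$phenotype == 0], 26, replace = TRUE))
  calls <- tibble::tibble(
    fid = carrier_fids, gene = "gL", chr = 1L,
    pos = seq_along(carrier_fids), ref = "A", alt = "G",
    consequence = "frameshift", cadd = 30, mpc = NA_real_,
    parent_ac = 0L, ref_ac = 0L,
    pro_dos = 1L, fa_dos = 0L, mo_dos = 0L,
    pro_dp = 40L, pro_gq = 99L, pro_ab = 0.5,
    fa_dp = 40L, fa_gq = 99L, fa_ab = 0.0,
    mo_dp = 40L, mo_gq = 99L, mo_ab = 0.0)
  coding <- annotate_coding_calls(calls, sets)
  burden <- build_burden_matrix(coding, tibble::tibble(
    fid = character(0), iid = character(0), role = character(0),
    start = integer(0), end = integer(0), type = character(0),
    n_probes = integer(0), segdup_frac = numeric(0),
    class = character(0), cohort_freq = numeric(0), filter_pass = logical(0),
    in_lofi = logical(0), in_dd = logical(0)), trios)
  avg <- tapply(burden$dn_coding_lofi, trios$phenotype, mean)
  expect_equal(round(unname(avg["1"]), 2), 0.14)
  expect_equal(signif(unname(avg["0"]), 2), 0.070)
  # de novo share of all ultra-rare damaging variants, from cohort counts
  expect_equal(round(100 * denovo_fraction(66, c(447, 582))), 6)
  expect_equal(round(100 * denovo_fraction(13, c(114, 152))), 5)
})
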