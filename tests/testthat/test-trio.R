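test_that("SNV inheritance classification matches the 27-triple truth table", {
  truth <- snv_truth_table()
  got <- classify_snv(truth$pro, truth$fa, truth$mo)
  expect_equal(as.character(got), truth$class)
  # missing dosages are filtered
  expect_equal(as.character(classify_snv(c(NA, 1), c(0, NA), c(0, 0))),
               c("filtered", "filtered"))
})

test_that("trio genotype filters enforce depth, quality and allele-balance bands", {
  good <- tibble::tibble(
    pro_dos = 1L, pro_dp = 30L, pro_gq = 60L, pro_ab = 0.5,
    fa_dos = 0L, fa_dp = 30L, fa_gq = 60L, fa_ab = 0.05,
    mo_dos = 0L, mo_dp = 30L, mo_gq = 60L, mo_ab = 0.05)
  expect_true(pass_genotype_filters(good))
  low_depth <- good; low_depth$pro_dp <- 9L
  expect_false(pass_genotype_filters(low_depth))
  boundary_depth <- good; boundary_depth$pro_dp <- 10L
  expect_true(pass_genotype_filters(boundary_depth))
  bad_het_ab <- good; bad_het_ab$pro_ab <- 0.85
  expect_false(pass_genotype_filters(bad_het_ab))
  low_gq <- good; low_gq$mo_gq <- 29L
  expect_false(pass_genotype_filters(low_gq))
  homref_leak <- good; homref_leak$fa_ab <- 0.15
  expect_false(pass_genotype_filters(homref_leak))
  homalt <- good; homalt$pro_dos <- 2L; homalt$pro_ab <- 0.92
  expect_true(pass_genotype_filters(homalt))
  homalt_bad <- homalt; homalt_bad$pro_ab <- 0.85
  expect_false(pass_genotype_filters(homalt_bad))
  expect_error(pass_genotype_filters(good[, -1]), "pro_dos")
})

test_that("pseudo-control dosage is father + mother - proband with Mendelian guards", {
  expect_equal(pseudo_control_dosage(1L, 1L, 2L), 0L)
  expect_equal(pseudo_control_dosage(2L, 0L, 1L), 1L)
  expect_true(is.na(pseudo_control_dosage(0L, 0L, 1L)))  # de novo at common SNP
  expect_true(is.na(pseudo_control_dosage(2L, NA, 1L)))
  # panel-wide transmission identity on a Mendelian-clean cohort
  coh <- test_cohort()
  tr <- coh$trios
  pro <- coh$panel$dosage[tr$proband, ]
  fa <- coh$panel$dosage[tr$father, ]
  mo <- coh$panel$dosage[tr$mother, ]
  nt <- matrix(pseudo_control_dosage(c(fa), c(mo), c(pro)), nrow(pro))
  expect_false(anyNA(nt))
  expect_true(all(pro + nt == fa + mo))
})

test_that("CNV classification uses any same-type overlap and is parent-symmetric", {
  pro <- tibble::tibble(start = 100000L, end = 300000L, type = "del")
  fa <- tibble::tibble(start = 299999L, end = 500000L, type = "del")
  none <- tibble::tibble(start = integer(0), end = integer(0),
                         type = character(0))
  res <- classify_cnv(pro, fa, none)
  expect_equal(res$class[res$role == "proband"], "transmitted")
  expect_equal(res$class[res$role == "father"], "transmitted")
  # 1 bp short of overlap -> de novo + non-transmitted
  fa2 <- tibble::tibble(start = 300000L, end = 500000L, type = "del")
  res2 <- classify_cnv(pro, fa2, none)
  expect_equal(res2$class[res2$role == "proband"], "de_novo")
  expect_equal(res2$class[res2$role == "father"], "non_transmitted")
  # type mismatch does not transmit
  dup <- tibble::tibble(start = 100000L, end = 300000L, type = "dup")
  res3 <- classify_cnv(pro, dup, none)
  expect_equal(res3$class[res3$role == "proband"], "de_novo")
  # parent symmetry
  res4 <- classify_cnv(pro, none, fa)
  expect_equal(res4$class[res4$role == "proband"], "transmitted")
  expect_equal(res4$class[res4$role == "mother"], "transmitted")
  # proband dup with no parental CNVs; mother-only del
  expect_equal(classify_cnv(tibble::tibble(start = 1e5, end = 3e5,
                                           type = "dup"),
                            none, none)$class, "de_novo")
  expect_equal(classify_cnv(none, none,
                            tibble::tibble(start = 1e6, end = 1.2e6,
                                           type = "del"))$class,
               "non_transmitted")
  expect_error(classify_cnv(tibble::tibble(start = 10L, end = 10L,
                                           type = "del"), none, none),
               "malformed")
})

test_that("Mendelian screen rates match brute-force enumeration and flag injected errors", {
  coh <- test_cohort()
  scr <- mendelian_screen(coh$panel, coh$trios)
  expect_true(all(scr$per_snp$rate == 1))
  expect_true(all(scr$per_trio$rate == 1))
  expect_false(any(scr$per_snp$flag))

  # brute-force check on a 10-trio, 5-SNP subset with injected errors
  bad <- test_cohort(seed = 13, mendel_error_rate = 0.05)
  sub_trios <- bad$trios[1:10, ]
  ids <- c(sub_trios$proband, sub_trios$father, sub_trios$mother)
  panel <- list(dosage = bad$panel$dosage[ids, 1:5], map = bad$panel$map[1:5, ])
  scr2 <- mendelian_screen(panel, sub_trios)
  manual <- sapply(1:5, function(s) {
    mean(sapply(1:10, function(t) {
      mendel_consistent_oracle(
        panel$dosage[sub_trios$proband[t], s],
        panel$dosage[sub_trios$father[t], s],
        panel$dosage[sub_trios$mother[t], s])
    }))
  })
  expect_equal(scr2$per_snp$rate, unname(manual))

  # a SNP with 20% injected errors is flagged
  panel3 <- coh$panel
  tr <- coh$trios
  n_bad <- ceiling(0.2 * nrow(tr))
  for (t in seq_len(n_bad)) {
    f <- panel3$dosage[tr$father[t], 1]; m <- panel3$dosage[tr$mother[t], 1]
    bad_vals <- setdiff(0:2, Filter(function(p)
      mendel_consistent_oracle(p, f, m), 0:2))
    if (length(bad_vals) > 0)
      panel3$dosage[tr$proband[t], 1] <- bad_vals[1]
  }
  scr3 <- mendelian_screen(panel3, tr)
  expect_true(scr3$per_snp$flag[1])
  expect_error(mendelian_screen(list(dosage = coh$panel$dosage[, 0],
                                     map = coh$panel$map[0, ]), coh$trios),
               "empty")
})

test_that("masking removes exactly the inconsistent trio-SNP entries", {
  coh <- test_cohort(seed = 13, mendel_error_rate = 0.05)
  scr <- mendelian_screen(coh$panel, coh$trios)
  masked <- mask_mendelian_errors(coh$panel, coh$trios)
  n_bad <- sum(!scr$consistent)
  expect_gt(n_bad, 0)
  expect_equal(sum(is.na(masked$dosage)), 3 * n_bad)
  # after masking, every remaining complete triple is consistent
  scr2 <- mendelian_screen(masked, coh$trios)
  pro <- masked$dosage[coh$trios$proband, ]
  expect_true(all(scr2$consistent | is.na(pro)))
})
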