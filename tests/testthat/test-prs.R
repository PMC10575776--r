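make_ld_pair <- function(n, r, maf = 0.3) {
  # two SNP dosage columns with controllable correlation via shared haplotypes
  h1a <- rbinom(n, 1, maf); h1b <- rbinom(n, 1, maf)
  copy <- function(h) ifelse(runif(n) < sqrt(abs(r)), h, rbinom(n, 1, maf))
  cbind(s1 = h1a + h1b, s2 = copy(h1a) + copy(h1b))
}

test_that("clumping keeps the best SNP of an LD pair inside the window and both outside", {
  set.seed(601)
  d <- make_ld_pair(2000, 0.75)
  while (cor(d[, 1], d[, 2])^2 < 0.4) d <- make_ld_pair(2000, 0.75)
  stats_close <- tibble::tibble(snp = c("s1", "s2"), chr = 1L,
                                pos = c(100000L, 200000L),
                                p = c(1e-8, 1e-4))
  expect_equal(clump(stats_close, d), "s1")
  stats_far <- stats_close
  stats_far$pos <- c(100000L, 400000L)  # 300 kb apart: outside 250 kb window
  expect_setequal(clump(stats_far, d), c("s1", "s2"))
})

test_that("clumping matches the O(n^2) oracle and ignores input row order", {
  coh <- test_cohort(n_trios = 150, n_snps = 30, seed = 31, ld_blocks = TRUE,
                     ld_block_size = 5, ld_rho = 0.9)
  parents <- coh$panel$dosage[c(coh$trios$father, coh$trios$mother), ]
  st <- coh$sumstats$cognition
  ours <- clump(st, parents)
  oracle <- clump_oracle(st, parents)
  expect_equal(sort(ours), sort(oracle))
  expect_lt(length(ours), nrow(st))  # LD blocks force removals
  shuffled <- st[sample(nrow(st)), ]
  expect_equal(sort(clump(shuffled, parents)), sort(ours))
})

test_that("clumping keeps everything when SNPs are independent", {
  coh <- test_cohort(n_trios = 400, n_snps = 40, seed = 32)
  parents <- coh$panel$dosage[c(coh$trios$father, coh$trios$mother), ]
  kept <- clump(coh$sumstats$cognition, parents)
  expect_gte(length(kept), 38)  # sampling noise may push r2 past 0.2 rarely
})

test_that("scoring honours thresholds, weights and allele orientation", {
  map <- tibble::tibble(snp = c("s1", "s2"), chr = 1L, pos = c(1e5, 2e5),
                        a1 = c("G", "C"), a2 = c("A", "T"))
  dosage <- matrix(c(2L, 1L, 0L, 2L), 2, 2,
                   dimnames = list(c("i1", "i2"), c("s1", "s2")))
  st <- tibble::tibble(snp = c("s1", "s2"), chr = 1L, pos = c(1e5, 2e5),
                       effect_allele = c("G", "C"), other_allele = c("A", "T"),
                       beta = c(0.5, 1), p = c(1e-3, 0.1))
  # p = 0.1 SNP contributes at threshold 0.5 but not 0.05
  expect_equal(unname(prs_score(dosage, st, map, 0.05)), c(1.0, 0.5))
  expect_equal(unname(prs_score(dosage, st, map, 0.5)), c(1.0, 2.5))
  zero <- st; zero$beta <- 0
  expect_equal(unname(prs_score(dosage, zero, map, 0.5)), c(0, 0))
  # swapped alleles count the complementary dosage
  swapped <- st; swapped$effect_allele <- c("A", "T")
  swapped$other_allele <- c("G", "C")
  direct <- prs_score(dosage, st, map, 0.5)
  flipped <- prs_score(dosage, swapped, map, 0.5)
  expect_equal(unname(flipped),
               unname(0.5 * (2 - dosage[, "s1"]) + 1 * (2 - dosage[, "s2"])))
  # strand-ambiguous SNPs are dropped
  amb_map <- tibble::tibble(snp = "s3", chr = 1L, pos = 3e5, a1 = "A",
                            a2 = "T")
  amb_st <- tibble::tibble(snp = "s3", chr = 1L, pos = 3e5,
                           effect_allele = "A", other_allele = "T", beta = 5,
                           p = 1e-5)
  d3 <- matrix(2L, 1, 1, dimnames = list("i1", "s3"))
  expect_message(s <- prs_score(d3, amb_st, amb_map, 0.5), "ambiguous")
  expect_equal(unname(s), 0)
})

test_that("profiles satisfy the transmission identity and pTDT basics", {
  coh <- test_cohort(n_trios = 200, n_snps = 150, seed = 33)
  prof <- build_prs_profiles(coh$panel, coh$trios, coh$sumstats$cognition)
  expect_equal(sort(unique(prof$threshold)), c(0.001, 0.05, 0.5))
  # raw-scale identity per trio at every threshold
  expect_equal(prof$proband_prs + prof$nt_prs,
               prof$father_prs + prof$mother_prs, tolerance = 1e-10)
  # standardised scores have mean 0
  for (col in c("proband_prs_std", "nt_prs_std", "midparent_prs_std")) {
    for (th in unique(prof$threshold)) {
      expect_lt(abs(mean(prof[[col]][prof$threshold == th])), 1e-10)
    }
  }
  # scale invariance of the deviation
  p1 <- ptdt(prof$proband_prs, prof$midparent_prs)
  p2 <- ptdt(2 * prof$proband_prs, 2 * prof$midparent_prs)
  expect_equal(p1, p2, tolerance = 1e-12)
  # proband exactly at midparent -> zero deviation
  expect_equal(ptdt(prof$midparent_prs, prof$midparent_prs),
               rep(0, nrow(prof)))
  expect_error(ptdt(c(1, 2), c(3, 3)), "SD")
})

test_that("random transmission gives null pTDT orthogonal to the midparent score", {
  coh <- test_cohort(n_trios = 2000, n_snps = 150, seed = 34, r2_prs = 0)
  prof <- build_prs_profiles(coh$panel, coh$trios, coh$sumstats$cognition,
                             thresholds = 0.5)
  tt <- t.test(prof$ptdt_deviation)
  expect_gt(tt$p.value, 1e-3)
  expect_lt(abs(mean(prof$ptdt_deviation)), 0.1)
  # transmission noise is orthogonal to the parental scores...
  dev <- prof$proband_prs - prof$midparent_prs
  expect_lt(abs(cor(dev, prof$midparent_prs)), 0.06)
  # ...and, by construction of the pseudo-control, anti-correlated with the
  # non-transmitted score (cor -> -1/sqrt(2) for independent SNPs)
  expect_lt(abs(cor(prof$nt_prs, dev) + 1 / sqrt(2)), 0.06)
  # under a phenotype driven only by transmitted alleles, the nt-PRS carries
  # no phenotype association (no synthetic genetic-nurture channel)
  direct <- test_cohort(n_trios = 2000, n_snps = 150, seed = 36,
                        r2_prs = 0.3)
  prof2 <- build_prs_profiles(direct$panel, direct$trios,
                              direct$sumstats$cognition, thresholds = 0.5)
  fit <- binomial_logistic(direct$trios$phenotype,
                           cbind(nt = prof2$nt_prs_std))
  expect_gt(fit$p[["nt"]], 0.01)
})

test_that("phenotype selection on the polygenic score shifts pTDT deviations", {
  # probands selected for high liability (lower performance) under a strong
  # protective PRS under-inherit score relative to midparent
  coh <- test_cohort(n_trios = 1500, n_snps = 150, seed = 35, r2_prs = 0.3)
  prof <- build_prs_profiles(coh$panel, coh$trios, coh$sumstats$cognition,
                             thresholds = 0.5)
  dev_lower <- prof$ptdt_deviation[coh$trios$phenotype == 1]
  dev_higher <- prof$ptdt_deviation[coh$trios$phenotype == 0]
  expect_gt(mean(dev_higher), mean(dev_lower))
  expect_lt(two_sample_t(dev_higher, dev_lower)$p.value, 0.01)
})
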