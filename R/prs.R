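#' Greedy LD clumping of GWAS summary statistics
#'
#' Standard p-value-ordered clumping: take the most significant remaining
#' SNP as an index, remove every remaining SNP within `window_kb` on the same
#' chromosome whose genotype correlation with the index exceeds
#' `sqrt(r2_max)` (r-squared > `r2_max`), and repeat until the list is
#' exhausted. Ties on p are broken by ascending (chromosome, position), so
#' the retained set does not depend on input row order.
#'
#' LD is estimated from the supplied dosage matrix; passing parental
#' genotypes only avoids double-counting transmitted alleles.
#'
#' @param stats summary-statistic table with columns `snp`, `chr`, `pos`,
#'   `p`.
#' @param ld_dosage numeric matrix of allele dosages (individuals x SNPs,
#'   column names = SNP ids) used to estimate r-squared.
#' @param window_kb physical clumping window, kb (default 250).
#' @param r2_max LD threshold (default 0.2).
#' @return character vector of retained SNP ids.
#' @export
clump <- function(stats, ld_dosage, window_kb = 250, r2_max = 0.2) {
  common <- intersect(stats$snp, colnames(ld_dosage))
  if (length(common) == 0) stop("no overlap between summary stats and panel")
  st <- stats[match(common, stats$snp), , drop = FALSE]
  ord <- order(st$p, st$chr, st$pos)
  st <- st[ord, , drop = FALSE]
  window <- window_kb * 1000
  alive <- rep(TRUE, nrow(st))
  kept <- logical(nrow(st))
  for (i in seq_len(nrow(st))) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive & st$chr == st$chr[i] &
                    abs(st$pos - st$pos[i]) <= window)
    if (length(cand) > 0) {
      r2 <- suppressWarnings(
        stats::cor(ld_dosage[, st$snp[i]], ld_dosage[, st$snp[cand]],
                   use = "pairwise.complete.obs"))^2
      r2[is.na(r2)] <- 0
      alive[cand[r2 > r2_max]] <- FALSE
    }
  }
  st$snp[kept]
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Align summary-statistic alleles to the panel's counted allele
#'
#' For each SNP shared between stats and panel, determines the sign with
#' which the reported beta applies to the panel's counted (a1) allele:
#' direct match, effect/other swap (beta applies to 2 - dosage), or the same
#' after strand complementing. Strand-ambiguous SNPs (A/T, C/G) are dropped
#' by default since their orientation cannot be resolved.
#'
#' @param stats summary-stat table with `snp`, `effect_allele`,
#'   `other_allele`, `beta`.
#' @param map panel map with `snp`, `a1` (counted allele), `a2`.
#' @param ambiguous `"drop"` (default) or `"keep"`.
#' @return tibble `snp`, `beta` (oriented to a1), `flipped`; unalignable
#'   SNPs are dropped with a message.
#' @export
align_alleles <- function(stats, map, ambiguous = c("drop", "keep")) {
  ambiguous <- match.arg(ambiguous)
  m <- dplyr::inner_join(stats, map, by = "snp")
  amb <- .complement[m$effect_allele] == m$other_allele
  if (ambiguous == "drop" && any(amb)) {
    message("dropping ", sum(amb), " strand-ambiguous SNP(s)")
    m <- m[!amb, , drop = FALSE]
  }
  direct <- m$effect_allele == m$a1 & m$other_allele == m$a2
  swap <- m$effect_allele == m$a2 & m$other_allele == m$a1
  cdirect <- !direct & !swap &
    .complement[m$effect_allele] == m$a1 & .complement[m$other_allele] == m$a2
  cswap <- !direct & !swap &
    .complement[m$effect_allele] == m$a2 & .complement[m$other_allele] == m$a1
  ok <- direct | swap | cdirect | cswap
  if (any(!ok))
    message("dropping ", sum(!ok), " unalignable SNP(s)")
  m <- m[ok, , drop = FALSE]
  flipped <- (swap | cswap)[ok]
  tibble::tibble(snp = m$snp, beta = ifelse(flipped, -m$beta, m$beta),
                 flipped = flipped)
}

#' Thresholded polygenic score
#'
#' Weighted allele-dosage sum over the retained (clumped) SNPs whose training
#' p-value falls below `threshold`. Missing dosages contribute the SNP's
#' cohort mean dosage times its weight (mean imputation, the behaviour of
#' standard scoring tools); set `impute = FALSE` to contribute nothing.
#'
#' @param dosage dosage matrix (individuals x SNPs; may contain NA).
#' @param stats summary-stat table (`snp`, `p`, `beta`, `effect_allele`,
#'   `other_allele`).
#' @param map panel map for allele alignment.
#' @param threshold training p-value cutoff.
#' @param snps optional SNP subset (e.g. the clumped set).
#' @param impute mean-impute missing dosages (default TRUE).
#' @return named numeric vector of raw scores, one per row of `dosage`.
#' @export
prs_score <- function(dosage, stats, map, threshold, snps = NULL,
                      impute = TRUE) {
  st <- stats[stats$p < threshold, , drop = FALSE]
  if (!is.null(snps)) st <- st[st$snp %in% snps, , drop = FALSE]
  aligned <- align_alleles(st, map)
  use <- intersect(aligned$snp, colnames(dosage))
  if (length(use) == 0)
    return(stats::setNames(rep(0, nrow(dosage)), rownames(dosage)))
  w <- aligned$beta[match(use, aligned$snp)]
  d <- dosage[, use, drop = FALSE]
  flipped <- aligned$flipped[match(use, aligned$snp)]
  if (impute && anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  } else if (!impute) {
    d[is.na(d)] <- 0
  }
  # a flipped beta counts the other allele (2 - dosage): the negated beta is
  # in w already, add back the per-SNP constant 2 * beta_original = -2 * w
  score <- drop(d %*% w) + 2 * sum(-w[flipped])
  stats::setNames(score, rownames(dosage))
}

#' Per-trio polygenic score profiles with pseudo-control scores
#'
#' For each trio and p-value threshold, computes the proband, father, mother
#' and midparent scores plus the non-transmitted (pseudo-control) score on
#' the `father + mother - proband` dosages, all on SNPs retained by LD
#' clumping on parental genotypes. Scores are also standardised cohort-wide
#' (mean 0, SD 1) within each threshold and score type, and the pTDT
#' deviation `(proband - midparent) / SD(midparent)` is attached.
#'
#' Mendelian-inconsistent genotypes are masked per trio before scoring, so a
#' de novo or erroneous call at a common SNP drops that SNP from that trio
#' only.
#'
#' @param panel SNP panel (list with `dosage`, `map`).
#' @param trios trio table (`fid`, `proband`, `father`, `mother`).
#' @param stats summary-stat table for one trait.
#' @param thresholds training p-value cutoffs (default `c(0.001, 0.05, 0.5)`;
#'   0.05 is the primary threshold, the others are sensitivity outputs).
#' @param window_kb,r2_max clumping parameters.
#' @param max_missing flag trios missing more than this fraction of scored
#'   SNPs (default 0.05).
#' @return tibble with one row per trio x threshold: raw scores (`*_prs`),
#'   standardised scores (`*_prs_std`), `ptdt_deviation`, `missing_frac`,
#'   `flagged`.
#' @export
build_prs_profiles <- function(panel, trios, stats,
                               thresholds = c(0.001, 0.05, 0.5),
                               window_kb = 250, r2_max = 0.2,
                               max_missing = 0.05) {
  panel <- mask_mendelian_errors(panel, trios)
  parents <- c(trios$father, trios$mother)
  kept <- clump(stats, panel$dosage[parents, , drop = FALSE],
                window_kb = window_kb, r2_max = r2_max)
  pro <- panel$dosage[trios$proband, , drop = FALSE]
  fa <- panel$dosage[trios$father, , drop = FALSE]
  mo <- panel$dosage[trios$mother, , drop = FALSE]
  nt <- fa + mo - pro
  out <- lapply(thresholds, function(th) {
    sc <- function(d) unname(prs_score(d, stats, panel$map, th, snps = kept))
    prof <- tibble::tibble(
      fid = trios$fid, threshold = th,
      proband_prs = sc(pro), father_prs = sc(fa), mother_prs = sc(mo),
      nt_prs = sc(nt))
    prof$midparent_prs <- (prof$father_prs + prof$mother_prs) / 2
    prof$ptdt_deviation <- ptdt(prof$proband_prs, prof$midparent_prs)
    for (colname in c("proband_prs", "father_prs", "mother_prs", "nt_prs",
                      "midparent_prs"))
      prof[[paste0(colname, "_std")]] <- standardise(prof[[colname]])
    scored <- stats$snp[stats$p < th]
    scored <- intersect(intersect(scored, kept), colnames(pro))
    prof$missing_frac <- if (length(scored) == 0) 0 else
      rowMeans(is.na(pro[, scored, drop = FALSE]))
    prof$flagged <- prof$missing_frac > max_missing
    prof
  })
  dplyr::bind_rows(out)
}

standardise <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Polygenic transmission disequilibrium deviations
#'
#' Per-trio deviation of the proband score from the midparent score,
#' standardised by the across-trio standard deviation of the midparent
#' score: `(proband - midparent) / SD(midparent)`. Under random transmission
#' the deviations have mean zero; over-transmission of trait-increasing
#' alleles shifts them positive. The deviations are invariant to rescaling
#' all scores by a common factor.
#'
#' @param proband,midparent raw score vectors over trios (>= 2 trios).
#' @return numeric vector of deviations.
#' @export
ptdt <- function(proband, midparent) {
  if (length(proband) < 2) stop("pTDT needs at least 2 trios")
  s <- stats::sd(midparent)
  if (is.na(s) || s == 0) stop("midparent score SD is zero")
  (proband - midparent) / s
}
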