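#' Configuration for the synthetic trio-cohort generator
#'
#' Bundles and validates every knob of [generate_cohort()]. Defaults are set
#' to the scale of a sequenced schizophrenia proband-parent trio cohort of
#' 656 families: roughly 0.02 expected damaging de novo variants per proband
#' in developmental-disorder (DD) genes, 0.08 in loss-of-function-intolerant
#' (LoFi) genes outside the DD set, about 1.5 damaging ultra-rare inherited
#' singletons per parent in LoFi genes (a quarter of them in DD genes), and a
#' binary phenotype derived from a liability-threshold model with grade
#' proportions 16/29/30/25 so that grades 3-4 ("lower performance") cover
#' ~45% of probands.
#'
#' @param n_trios number of families.
#' @param n_snps number of common biallelic SNPs.
#' @param maf_range minor-allele-frequency range, pair in (0, 1).
#' @param effect_snp_fraction fraction of SNPs with non-zero liability
#'   weight.
#' @param r2_prs proportion of liability variance explained by the true
#'   polygenic score, in \[0, 1\].
#' @param dn_rate_dd expected damaging de novo variants per proband in DD
#'   genes.
#' @param dn_rate_lofi_only same, for LoFi genes outside the DD set.
#' @param dn_background_rate expected non-qualifying de novo variants per
#'   proband (non-damaging annotations and/or genes outside both sets), so
#'   the damage classifier has real filtering to do.
#' @param dn_effect liability shift per damaging DD de novo variant.
#' @param inherited_singleton_rate expected damaging ultra-rare inherited
#'   variants per parent (LoFi genes).
#' @param dd_singleton_fraction fraction of inherited singletons falling in
#'   DD genes (DD is a subset of LoFi).
#' @param common_inherited_rate expected inherited damaging variants per
#'   parent that fail the ultra-rare filter (seen twice among parents or
#'   present in the reference panel).
#' @param cnv_rate expected CNVs per parent; each is transmitted to the
#'   proband with probability 1/2.
#' @param cnv_dn_rate expected de novo CNVs per proband.
#' @param n_genes_lofi,n_genes_dd,n_genes_other gene counts; the DD set is a
#'   subset of the LoFi set, `n_genes_other` genes belong to neither.
#' @param grade_probs named proportions for school grades 3 (lowest passing)
#'   to 6 (best); the binary phenotype is grade <= 4.
#' @param id_base_rate,id_dn_log_or comorbid intellectual-disability
#'   probability: baseline rate and log-OR per damaging DD de novo variant.
#' @param mendel_error_rate fraction of (trio, SNP) cells whose proband
#'   genotype is corrupted into a Mendelian violation.
#' @param lowqual_rate fraction of coding calls given a failing sequencing
#'   QC field in one trio member.
#' @param ld_blocks use block-correlated haplotypes so LD clumping has work
#'   to do (default independent SNPs).
#' @param ld_block_size,ld_rho block width (SNPs) and within-block haplotype
#'   correlation when `ld_blocks = TRUE`.
#' @param ambiguous_snp_fraction fraction of SNPs given strand-ambiguous
#'   (A/T or C/G) allele pairs.
#' @param weight_sd SD of non-zero liability weights (also the scale of the
#'   summary-statistic betas).
#' @param gwas_noise_sd SD of estimation noise added to the true weights in
#'   the emitted summary statistics.
#' @param gwas_se nominal standard error used to convert betas to training
#'   p-values.
#' @param n_null_traits number of additional summary-statistic sets with
#'   random weights and no liability contribution (so transmitted and
#'   non-transmitted PRS tests have null traits alongside the causal one).
#' @param seed master seed; per-stage substreams use fixed offsets (+1
#'   panel, +2 weights, +3 de novo, +4 inherited, +5 CNV, +6 liability,
#'   +7 QC fields, +8 error injection).
#' @return a validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_trios = 656, n_snps = 2000,
                         maf_range = c(0.05, 0.5),
                         effect_snp_fraction = 0.2, r2_prs = 0.05,
                         dn_rate_dd = 0.02, dn_rate_lofi_only = 0.08,
                         dn_background_rate = 0.5, dn_effect = 1.5,
                         inherited_singleton_rate = 1.5,
                         dd_singleton_fraction = 0.25,
                         common_inherited_rate = 0.3,
                         cnv_rate = 0.15, cnv_dn_rate = 0.03,
                         n_genes_lofi = 300, n_genes_dd = 70,
                         n_genes_other = 300,
                         grade_probs = c(`3` = 0.16, `4` = 0.29,
                                         `5` = 0.30, `6` = 0.25),
                         id_base_rate = 0.043, id_dn_log_or = log(15),
                         mendel_error_rate = 0, lowqual_rate = 0.02,
                         ld_blocks = FALSE, ld_block_size = 10, ld_rho = 0.9,
                         ambiguous_snp_fraction = 0,
                         weight_sd = 0.05, gwas_noise_sd = 0.02,
                         gwas_se = 0.02, n_null_traits = 2, seed = 1) {
  cfg <- as.list(environment())
  check_range <- function(field, lo, hi) {
    v <- cfg[[field]]
    if (!all(is.finite(v)) || any(v < lo) || any(v > hi))
      stop("invalid value for config field '", field, "'")
  }
  check_range("n_trios", 1, Inf); check_range("n_snps", 1, Inf)
  check_range("maf_range", 1e-6, 1 - 1e-6)
  if (diff(cfg$maf_range) < 0) stop("invalid value for config field 'maf_range'")
  check_range("effect_snp_fraction", 0, 1); check_range("r2_prs", 0, 1)
  for (f in c("dn_rate_dd", "dn_rate_lofi_only", "dn_background_rate",
              "inherited_singleton_rate", "common_inherited_rate",
              "cnv_rate", "cnv_dn_rate"))
    check_range(f, 0, Inf)
  check_range("dd_singleton_fraction", 0, 1)
  check_range("dn_effect", -Inf, Inf)
  check_range("n_genes_lofi", 1, Inf); check_range("n_genes_dd", 0, Inf)
  if (cfg$n_genes_dd > cfg$n_genes_lofi)
    stop("invalid value for config field 'n_genes_dd': DD set must be a subset of LoFi")
  check_range("grade_probs", 0, 1)
  if (abs(sum(cfg$grade_probs) - 1) > 1e-8)
    stop("invalid value for config field 'grade_probs': must sum to 1")
  check_range("id_base_rate", 0, 1)
  check_range("mendel_error_rate", 0, 1); check_range("lowqual_rate", 0, 1)
  check_range("ld_rho", 0, 1 - 1e-9); check_range("ld_block_size", 1, Inf)
  check_range("ambiguous_snp_fraction", 0, 1)
  check_range("weight_sd", 0, Inf); check_range("gwas_noise_sd", 0, Inf)
  check_range("gwas_se", 1e-12, Inf)
  check_range("n_null_traits", 0, Inf)
  check_range("seed", -2^31 + 1, 2^31 - 1)
  structure(cfg, class = "synth_config")
}

DAMAGING_CLASS_PROBS <- c(frameshift = 0.30, stop_gain = 0.25,
                          splice_donor = 0.10, splice_acceptor = 0.10,
                          missense = 0.25)

#' Generate a synthetic trio cohort
#'
#' Builds a full cohort with the statistical structure the downstream
#' analysis assumes: parental SNP genotypes drawn at the configured allele
#' frequencies with Mendelian transmission of one allele per SNP per parent;
#' Poisson de novo damaging coding variants in DD and LoFi gene sets plus
#' non-qualifying background de novos; ultra-rare damaging inherited
#' singletons (one parental copy, transmitted with probability 1/2); CNVs in
#' parents (transmitted with probability 1/2, endpoints jittered) and de novo
#' CNVs in probands; and a liability (risk-of-lower-performance scale)
#' \deqn{L = -\sqrt{r^2}\,\mathrm{PRS} + \beta_{dn}\,n_{DD} + \sqrt{s^2}\,\epsilon,}
#' where the noise variance \eqn{s^2} is reduced so the total liability
#' variance stays near 1 when the de novo term is active. School grades are
#' assigned from liability quantiles (higher liability = lower grade) and
#' binarised as grades 3-4 vs 5-6. The result is deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return an object of class `"trio_cohort"`: a list with `trios`, `panel`
#'   (`dosage` matrix + `map`), `true_weights`, `sumstats` (named list of
#'   tables; the first trait, `"cognition"`, is liability-coupled),
#'   `coding_calls`, `cnv_calls`, `gene_sets`, `liability`, `true_prs`,
#'   `truth` (generator-side bookkeeping counts) and `config`.
#' @export
generate_cohort <- function(cfg = synth_config()) {
  if (!inherits(cfg, "synth_config")) cfg <- do.call(synth_config, cfg)
  n <- cfg$n_trios
  fid <- sprintf("F%04d", seq_len(n))
  pro_id <- sprintf("P%04d", seq_len(n))
  fa_id <- sprintf("D%04d", seq_len(n))
  mo_id <- sprintf("M%04d", seq_len(n))

  panel <- synth_panel(cfg, pro_id, fa_id, mo_id)
  ws <- synth_weights(cfg, panel$map)
  genes <- synth_genes(cfg)
  dn <- synth_de_novo(cfg, fid, genes)
  inh <- synth_inherited(cfg, fid, genes)
  coding <- dplyr::bind_rows(dn$calls, inh$calls)
  coding <- synth_qc_fields(cfg, coding)
  cnv <- synth_cnvs(cfg, fid, pro_id, fa_id, mo_id, genes)

  set.seed(cfg$seed + 6L)
  true_prs_raw <- drop(panel$dosage[pro_id, , drop = FALSE] %*% ws$weights)
  true_prs <- standardise(true_prs_raw)
  s2 <- max(0.05, 1 - cfg$r2_prs - cfg$dn_effect^2 * cfg$dn_rate_dd)
  # liability is on the risk-of-lower-performance scale: the cognition-like
  # polygenic score is protective, damaging DD de novos are deleterious
  liability <- as.numeric(-sqrt(cfg$r2_prs) * true_prs +
                            cfg$dn_effect * dn$n_dd +
                            sqrt(s2) * stats::rnorm(n))
  true_prs <- as.numeric(true_prs)
  grade <- grade_from_liability(liability, cfg$grade_probs)
  phenotype <- binarise_grades(grade)
  id_status <- stats::rbinom(n, 1, stats::plogis(
    stats::qlogis(cfg$id_base_rate) + cfg$id_dn_log_or * dn$n_dd))
  trios <- tibble::tibble(
    fid = fid, proband = pro_id, father = fa_id, mother = mo_id,
    sex = sample(1:2, n, replace = TRUE), grade = grade,
    phenotype = phenotype, id_status = id_status)
  pcs <- matrix(stats::rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("PC", 1:10)))
  trios <- dplyr::bind_cols(trios, tibble::as_tibble(pcs))

  panel <- inject_mendel_errors(cfg, panel, trios)

  structure(list(
    trios = trios, panel = panel, true_weights = ws$weights,
    sumstats = ws$sumstats, coding_calls = coding, cnv_calls = cnv$calls,
    gene_sets = genes, liability = liability, true_prs = true_prs,
    truth = list(n_dn_dd = dn$n_dd, n_dn_lofi = dn$n_lofi,
                 singletons_transmitted = inh$n_transmitted,
                 singletons_non_transmitted = inh$n_non_transmitted,
                 cnv_transmitted = cnv$n_transmitted,
                 cnv_non_transmitted = cnv$n_non_transmitted),
    config = cfg), class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic trio cohort: %d trios, %d SNPs, %d coding calls, %d CNVs\n",
    "phenotype split (lower/higher): %d/%d\n"),
    nrow(x$trios), ncol(x$panel$dosage), nrow(x$coding_calls),
    nrow(x$cnv_calls), sum(x$trios$phenotype == 1),
    sum(x$trios$phenotype == 0)))
  invisible(x)
}

#' Binarise school grades
#'
#' Grades run 3 (lowest passing) to 6 (best); the binary outcome combines
#' the bottom two grades (3-4, coded 1 = lower performance) against the top
#' two (5-6, coded 0).
#'
#' @param grade integer vector in 3..6.
#' @return integer 0/1 vector.
#' @export
binarise_grades <- function(grade) {
  if (any(!grade %in% 3:6)) stop("grades must lie in 3..6")
  as.integer(grade <= 4)
}

grade_from_liability <- function(liability, grade_probs) {
  # higher liability -> lower grade; deterministic quantile cut
  qs <- cumsum(grade_probs[c("3", "4", "5")])
  cuts <- stats::quantile(liability, 1 - qs, names = FALSE)
  ifelse(liability > cuts[1], 3L,
  ifelse(liability > cuts[2], 4L,
  ifelse(liability > cuts[3], 5L, 6L)))
}

# ---- generator stages ------------------------------------------------------

.snp_spacing <- 10000L

synth_panel <- function(cfg, pro_id, fa_id, mo_id) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_trios; m <- cfg$n_snps
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  safe_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  amb_pairs <- list(c("A", "T"), c("C", "G"))
  pick <- function(k, pairs) do.call(rbind, pairs[sample(length(pairs), k,
                                                         replace = TRUE)])
  amb <- stats::runif(m) < cfg$ambiguous_snp_fraction
  alleles <- matrix("", m, 2)
  if (any(!amb)) alleles[!amb, ] <- pick(sum(!amb), safe_pairs)
  if (any(amb)) alleles[amb, ] <- pick(sum(amb), amb_pairs)
  map <- tibble::tibble(snp = sprintf("rs%05d", seq_len(m)), chr = 1L,
                        pos = .snp_spacing * seq_len(m),
                        a1 = alleles[, 1], a2 = alleles[, 2], maf = maf)

  draw_parent <- function() {
    if (!cfg$ld_blocks)
      return(matrix(stats::rbinom(n * m, 2, rep(maf, each = n)), n, m))
    # two haplotypes from a block-equicorrelated latent Gaussian
    thr <- stats::qnorm(maf)
    block <- rep(seq_len(ceiling(m / cfg$ld_block_size)),
                 each = cfg$ld_block_size)[seq_len(m)]
    hap <- function() {
      z <- matrix(stats::rnorm(n * max(block)), n)[, block, drop = FALSE]
      e <- matrix(stats::rnorm(n * m), n, m)
      lat <- sqrt(cfg$ld_rho) * z + sqrt(1 - cfg$ld_rho) * e
      (lat < rep(thr, each = n)) + 0L
    }
    hap() + hap()
  }
  fa <- draw_parent(); mo <- draw_parent()
  transmit <- function(g) {
    # hom transmits its allele; het transmits alt with probability 1/2
    t <- matrix(0L, n, m)
    t[g == 2L] <- 1L
    het <- g == 1L
    t[het] <- stats::rbinom(sum(het), 1, 0.5)
    t
  }
  pro <- transmit(fa) + transmit(mo)
  dosage <- rbind(pro, fa, mo)
  mode(dosage) <- "integer"
  dimnames(dosage) <- list(c(pro_id, fa_id, mo_id), map$snp)
  list(dosage = dosage, map = map)
}

synth_weights <- function(cfg, map) {
  set.seed(cfg$seed + 2L)
  m <- nrow(map)
  w <- numeric(m)
  effect <- sample(m, round(cfg$effect_snp_fraction * m))
  w[effect] <- stats::rnorm(length(effect), 0, cfg$weight_sd)
  names(w) <- map$snp
  make_stats <- function(beta) {
    tibble::tibble(snp = map$snp, chr = map$chr, pos = map$pos,
                   effect_allele = map$a1, other_allele = map$a2,
                   beta = unname(beta),
                   p = pmax(2 * stats::pnorm(-abs(beta) / cfg$gwas_se),
                            1e-300))
  }
  sumstats <- list(cognition = make_stats(
    w + stats::rnorm(m, 0, cfg$gwas_noise_sd)))
  if (cfg$n_null_traits > 0) {
    for (i in seq_len(cfg$n_null_traits)) {
      wnull <- numeric(m)
      eff <- sample(m, round(cfg$effect_snp_fraction * m))
      wnull[eff] <- stats::rnorm(length(eff), 0, cfg$weight_sd)
      sumstats[[paste0("null", i)]] <- make_stats(
        wnull + stats::rnorm(m, 0, cfg$gwas_noise_sd))
    }
  }
  list(weights = w, sumstats = sumstats)
}

.gene_len <- 20000L
.gene_spacing <- 50000L
.exon_len <- 400L
.exons_per_gene <- 8L

synth_genes <- function(cfg) {
  n_genes <- cfg$n_genes_lofi + cfg$n_genes_other
  origin <- cfg$n_snps * .snp_spacing + 1000000L
  start <- origin + .gene_spacing * (seq_len(n_genes) - 1L)
  gene <- sprintf("G%04d", seq_len(n_genes))
  membership <- sample(c(rep("dd", cfg$n_genes_dd),
                         rep("lofi", cfg$n_genes_lofi - cfg$n_genes_dd),
                         rep("other", cfg$n_genes_other)))
  genes <- tibble::tibble(gene = gene, start = start,
                          end = start + .gene_len,
                          lofi = membership %in% c("lofi", "dd"),
                          dd = membership == "dd")
  exon_off <- (seq_len(.exons_per_gene) - 1L) *
    ((.gene_len - .exon_len) %/% (.exons_per_gene - 1L))
  exons <- tibble::tibble(
    gene = rep(gene, each = .exons_per_gene),
    start = rep(start, each = .exons_per_gene) + rep(exon_off, n_genes))
  exons$end <- exons$start + .exon_len
  list(genes = genes, exons = exons)
}

.bases <- c("A", "C", "G", "T")

# sample annotation rows; damaging = TRUE draws pass the damage rules,
# damaging = FALSE draws fail them
sample_annotations <- function(k, damaging) {
  cons <- sample(names(DAMAGING_CLASS_PROBS), k, replace = TRUE,
                 prob = DAMAGING_CLASS_PROBS)
  cadd <- numeric(k); mpc <- rep(NA_real_, k)
  mis <- cons == "missense"
  if (damaging) {
    cadd[!mis] <- ifelse(cons[!mis] == "frameshift",
                         stats::runif(sum(!mis), 5, 45),
                         stats::runif(sum(!mis), 20, 45))
    cadd[mis] <- stats::runif(sum(mis), 20, 40)
    mpc[mis] <- stats::runif(sum(mis), 1, 3)
  } else {
    cadd[!mis] <- ifelse(cons[!mis] == "frameshift", NA, # frameshift always damaging
                         stats::runif(sum(!mis), 0, 19.5))
    cons[!mis][is.na(cadd[!mis])] <- "other"
    cadd[is.na(cadd)] <- stats::runif(sum(is.na(cadd)), 0, 19.5)
    cadd[mis] <- stats::runif(sum(mis), 10, 35)
    mpc[mis] <- stats::runif(sum(mis), 0, 0.95)
  }
  tibble::tibble(consequence = cons, cadd = cadd, mpc = mpc)
}

variant_locus <- function(k, genes_tbl) {
  idx <- sample(nrow(genes_tbl), k, replace = TRUE)
  pos <- genes_tbl$start[idx] + sample.int(.gene_len, k, replace = TRUE)
  ref <- sample(.bases, k, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.bases, r), 1), character(1))
  tibble::tibble(gene = genes_tbl$gene[idx], chr = 1L, pos = pos, ref = ref,
                 alt = unname(alt))
}

synth_de_novo <- function(cfg, fid, genes) {
  set.seed(cfg$seed + 3L)
  n <- length(fid)
  n_dd <- stats::rpois(n, cfg$dn_rate_dd)
  n_lofi <- stats::rpois(n, cfg$dn_rate_lofi_only)
  n_bg <- stats::rpois(n, cfg$dn_background_rate)
  g <- genes$genes
  mk <- function(counts, gene_tbl, damaging) {
    k <- sum(counts)
    if (k == 0 || nrow(gene_tbl) == 0) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(fid = rep(fid, counts)),
      variant_locus(k, gene_tbl), sample_annotations(k, damaging),
      tibble::tibble(parent_ac = 0L, ref_ac = 0L,
                     pro_dos = 1L, fa_dos = 0L, mo_dos = 0L))
  }
  calls <- dplyr::bind_rows(
    mk(n_dd, g[g$dd, , drop = FALSE], damaging = TRUE),
    mk(n_lofi, g[g$lofi & !g$dd, , drop = FALSE], damaging = TRUE),
    mk(n_bg, g, damaging = FALSE))
  list(calls = calls, n_dd = n_dd, n_lofi = n_dd + n_lofi)
}

synth_inherited <- function(cfg, fid, genes) {
  set.seed(cfg$seed + 4L)
  n <- length(fid)
  g <- genes$genes
  mk_parent <- function(parent, rate, ultra_rare) {
    counts <- stats::rpois(n, rate)
    k <- sum(counts)
    if (k == 0) return(NULL)
    in_dd <- stats::runif(k) < cfg$dd_singleton_fraction
    gene_tbl_dd <- g[g$dd, , drop = FALSE]
    gene_tbl_lo <- g[g$lofi & !g$dd, , drop = FALSE]
    loci <- variant_locus(k, gene_tbl_lo)
    if (any(in_dd) && nrow(gene_tbl_dd) > 0)
      loci[in_dd, ] <- variant_locus(sum(in_dd), gene_tbl_dd)
    transmitted <- stats::rbinom(k, 1, 0.5) == 1
    dplyr::bind_cols(
      tibble::tibble(fid = rep(fid, counts)), loci,
      sample_annotations(k, damaging = TRUE),
      tibble::tibble(
        parent_ac = if (ultra_rare) 1L else 2L,
        ref_ac = if (ultra_rare) 0L else stats::rpois(k, 2),
        pro_dos = as.integer(transmitted),
        fa_dos = if (parent == "father") 1L else 0L,
        mo_dos = if (parent == "mother") 1L else 0L,
        transmitted_truth = transmitted))
  }
  calls <- dplyr::bind_rows(
    mk_parent("father", cfg$inherited_singleton_rate, TRUE),
    mk_parent("mother", cfg$inherited_singleton_rate, TRUE),
    mk_parent("father", cfg$common_inherited_rate, FALSE),
    mk_parent("mother", cfg$common_inherited_rate, FALSE))
  ur <- !is.null(calls) && nrow(calls) > 0
  singles <- if (ur) calls[calls$parent_ac == 1L, , drop = FALSE] else calls
  list(calls = calls,
       n_transmitted = if (ur) sum(singles$transmitted_truth) else 0L,
       n_non_transmitted = if (ur) sum(!singles$transmitted_truth) else 0L)
}

synth_qc_fields <- function(cfg, calls) {
  set.seed(cfg$seed + 7L)
  if (is.null(calls) || nrow(calls) == 0) {
    return(tibble::tibble(fid = character(0), gene = character(0),
                          chr = integer(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          consequence = character(0), cadd = numeric(0),
                          mpc = numeric(0), parent_ac = integer(0),
                          ref_ac = integer(0),
                          pro_dos = integer(0), fa_dos = integer(0),
                          mo_dos = integer(0),
                          pro_dp = integer(0), pro_gq = integer(0),
                          pro_ab = numeric(0), fa_dp = integer(0),
                          fa_gq = integer(0), fa_ab = numeric(0),
                          mo_dp = integer(0), mo_gq = integer(0),
                          mo_ab = numeric(0),
                          transmitted_truth = logical(0),
                          variant_id = character(0)))
  }
  k <- nrow(calls)
  ab_for <- function(dos) {
    out <- stats::runif(length(dos), 0, 0.05)
    het <- dos == 1L
    out[het] <- pmin(0.79, pmax(0.21, stats::rnorm(sum(het), 0.5, 0.06)))
    out[dos == 2L] <- stats::runif(sum(dos == 2L), 0.95, 1)
    round(out, 3)
  }
  for (member in c("pro", "fa", "mo")) {
    dos <- calls[[paste0(member, "_dos")]]
    calls[[paste0(member, "_dp")]] <- stats::rpois(k, 60) + 10L
    calls[[paste0(member, "_gq")]] <- 99L
    calls[[paste0(member, "_ab")]] <- ab_for(dos)
  }
  # inject failing QC into one random member of a fraction of calls
  bad <- which(stats::runif(k) < cfg$lowqual_rate)
  if (length(bad) > 0) {
    member <- sample(c("pro", "fa", "mo"), length(bad), replace = TRUE)
    what <- sample(c("dp", "gq"), length(bad), replace = TRUE)
    for (i in seq_along(bad)) {
      col <- paste0(member[i], "_", what[i])
      calls[[col]][bad[i]] <- if (what[i] == "dp")
        sample(0:9, 1) else sample(0:29, 1)
    }
  }
  if (!"transmitted_truth" %in% names(calls))
    calls$transmitted_truth <- NA
  calls$variant_id <- sprintf("v%05d", seq_len(nrow(calls)))
  calls
}

synth_cnvs <- function(cfg, fid, pro_id, fa_id, mo_id, genes) {
  set.seed(cfg$seed + 5L)
  n <- length(fid)
  region_lo <- min(genes$genes$start) - 200000L
  region_hi <- max(genes$genes$end) + 200000L
  draw <- function(k) {
    len <- round(exp(stats::runif(k, log(8e3), log(6e5))))
    start <- round(stats::runif(k, region_lo, region_hi - len))
    tibble::tibble(
      start = as.integer(start), end = as.integer(start + len),
      type = sample(c("del", "dup"), k, replace = TRUE),
      n_probes = pmax(1L, as.integer(round(len / 4000 *
                                             stats::runif(k, 0.4, 1.6)))),
      segdup_frac = ifelse(stats::runif(k) < 0.85, 0,
                           round(stats::runif(k), 3)))
  }
  rows <- list(); n_trans <- 0L; n_nt <- 0L
  for (parent in c("father", "mother")) {
    counts <- stats::rpois(n, cfg$cnv_rate)
    k <- sum(counts)
    if (k == 0) next
    d <- draw(k)
    d$fid <- rep(fid, counts)
    d$iid <- rep(if (parent == "father") fa_id else mo_id, counts)
    d$role <- parent
    transmitted <- stats::rbinom(k, 1, 0.5) == 1
    n_trans <- n_trans + sum(transmitted)
    n_nt <- n_nt + sum(!transmitted)
    rows[[parent]] <- d
    if (any(transmitted)) {
      child <- d[transmitted, , drop = FALSE]
      jitter <- function(x) as.integer(x + round(stats::rnorm(length(x), 0, 1000)))
      child$start <- pmin(jitter(child$start), child$end - 1000L)
      child$end <- pmax(jitter(child$end), child$start + 1000L)
      child$iid <- rep(pro_id, counts)[transmitted]
      child$role <- "proband"
      rows[[paste0(parent, "_tx")]] <- child
    }
  }
  counts <- stats::rpois(n, cfg$cnv_dn_rate)
  if (sum(counts) > 0) {
    d <- draw(sum(counts))
    d$fid <- rep(fid, counts); d$iid <- rep(pro_id, counts)
    d$role <- "proband"
    rows[["dn"]] <- d
  }
  calls <- dplyr::bind_rows(rows)
  if (nrow(calls) == 0)
    calls <- tibble::tibble(start = integer(0), end = integer(0),
                            type = character(0), n_probes = integer(0),
                            segdup_frac = numeric(0), fid = character(0),
                            iid = character(0), role = character(0))
  calls <- calls[, c("fid", "iid", "role", "start", "end", "type",
                     "n_probes", "segdup_frac")]
  calls$cnv_id <- sprintf("cnv%05d", seq_len(nrow(calls)))
  list(calls = calls, n_transmitted = n_trans, n_non_transmitted = n_nt)
}

inject_mendel_errors <- function(cfg, panel, trios) {
  if (cfg$mendel_error_rate == 0) return(panel)
  set.seed(cfg$seed + 8L)
  n <- nrow(trios); m <- ncol(panel$dosage)
  n_bad <- round(cfg$mendel_error_rate * n * m)
  if (n_bad == 0) return(panel)
  cells <- cbind(sample(n, n_bad, replace = TRUE),
                 sample(m, n_bad, replace = TRUE))
  cells <- unique(cells)
  dos <- panel$dosage
  pro_rows <- match(trios$proband, rownames(dos))
  fa_rows <- match(trios$father, rownames(dos))
  mo_rows <- match(trios$mother, rownames(dos))
  for (i in seq_len(nrow(cells))) {
    t <- cells[i, 1]; s <- cells[i, 2]
    f <- dos[fa_rows[t], s]; m_ <- dos[mo_rows[t], s]
    bad_vals <- which(!.mendel_ok[, f + 1, m_ + 1]) - 1L
    if (length(bad_vals) > 0)
      dos[pro_rows[t], s] <- if (length(bad_vals) == 1) bad_vals else
        sample(bad_vals, 1)
  }
  panel$dosage <- dos
  panel
}
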