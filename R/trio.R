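#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr %>%
NULL

INHERITANCE_CLASSES <- c("de_novo", "transmitted", "non_transmitted",
                         "absent", "mendelian_error", "filtered")

# Dosages transmissible by a parent with the given genotype at a biallelic
# site: hom-ref transmits 0, het transmits 0 or 1, hom-alt transmits 1.
.parent_alleles <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)

# 27-triple lookup of Mendelian consistency, built by enumeration at load.
.mendel_ok <- local({
  ok <- array(FALSE, dim = c(3, 3, 3))
  for (p in 0:2) for (f in 0:2) for (m in 0:2)
    ok[p + 1, f + 1, m + 1] <-
      any(outer(.parent_alleles[[f + 1]], .parent_alleles[[m + 1]], `+`) == p)
  ok
})

#' Per-genotype sequencing quality filter
#'
#' A single genotype passes when sequencing depth >= `min_depth`, genotype
#' quality >= `min_gq`, and the alternative allele balance lies in the band
#' appropriate to its genotype class: within \[0.2, 0.8\] for heterozygotes,
#' >= 0.9 for hom-alt, <= 0.1 for hom-ref.
#'
#' @param dosage alt-allele count 0/1/2 (NA = missing call).
#' @param depth sequencing depth (reads).
#' @param gq genotype quality score.
#' @param ab alternative allele balance in \[0, 1\]; only defined when
#'   `depth > 0`.
#' @param min_depth,min_gq thresholds (defaults 10 and 30).
#' @return logical vector; `FALSE` for missing genotypes.
#' @export
genotype_passes <- function(dosage, depth, gq, ab, min_depth = 10,
                            min_gq = 30) {
  band_ok <- dplyr::case_when(
    is.na(dosage) ~ FALSE,
    dosage == 1L ~ ab >= 0.2 & ab <= 0.8,
    dosage == 2L ~ ab >= 0.9,
    dosage == 0L ~ ab <= 0.1,
    TRUE ~ FALSE
  )
  !is.na(dosage) & depth >= min_depth & gq >= min_gq & band_ok
}

#' Trio-level genotype filter for rare-variant calls
#'
#' Applies [genotype_passes()] to the proband, father and mother of every call
#' and requires all three to pass: a failure in any member excludes the
#' variant for that whole trio, which protects against spurious de novo calls
#' arising from parental genotype dropout.
#'
#' @param calls a data frame of per-trio variant calls with columns
#'   `pro_dos`, `pro_dp`, `pro_gq`, `pro_ab` and the `fa_*` / `mo_*`
#'   equivalents.
#' @inheritParams genotype_passes
#' @return logical vector, one entry per row of `calls`.
#' @export
pass_genotype_filters <- function(calls, min_depth = 10, min_gq = 30) {
  need <- as.vector(outer(c("pro", "fa", "mo"),
                          c("dos", "dp", "gq", "ab"), paste, sep = "_"))
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols) > 0)
    stop("calls table is missing trio member columns: ",
         paste(missing_cols, collapse = ", "))
  genotype_passes(calls$pro_dos, calls$pro_dp, calls$pro_gq, calls$pro_ab,
                  min_depth, min_gq) &
    genotype_passes(calls$fa_dos, calls$fa_dp, calls$fa_gq, calls$fa_ab,
                    min_depth, min_gq) &
    genotype_passes(calls$mo_dos, calls$mo_dp, calls$mo_gq, calls$mo_ab,
                    min_depth, min_gq)
}

#' Classify SNV inheritance within a trio
#'
#' Maps the (proband, father, mother) dosage triple to one of the inheritance
#' classes: a proband carrier with two non-carrier parents is `de_novo`; a
#' proband carrier with at least one carrier parent is `transmitted`; a
#' non-carrier proband with a carrier parent is `non_transmitted`; an
#' all-zero triple is `absent`. Other triples impossible under Mendelian
#' inheritance at a biallelic site (for example a hom-alt parent with a
#' non-carrier proband) are `mendelian_error` — the de novo configuration
#' takes precedence, since a carrier child of two non-carriers is a new
#' mutation rather than a genotyping error. Triples with any missing dosage
#' are `filtered`.
#'
#' @param pro,fa,mo dosage vectors (0/1/2, NA = missing).
#' @return factor with levels `r paste(INHERITANCE_CLASSES, collapse = ", ")`.
#' @export
classify_snv <- function(pro, fa, mo) {
  n <- length(pro)
  stopifnot(length(fa) == n, length(mo) == n)
  out <- rep("filtered", n)
  done <- is.na(pro) | is.na(fa) | is.na(mo)
  idx <- which(!done)
  if (length(idx) > 0) {
    p <- pro[idx]; f <- fa[idx]; m <- mo[idx]
    consistent <- .mendel_ok[cbind(p + 1, f + 1, m + 1)]
    # a carrier proband with two non-carrier parents is a new mutation, not
    # a genotyping error; all other impossible triples are Mendelian errors
    de_novo <- p > 0 & f == 0 & m == 0
    cls <- ifelse(de_novo, "de_novo",
           ifelse(!consistent, "mendelian_error",
           ifelse(p > 0, "transmitted",
           ifelse(f > 0 | m > 0, "non_transmitted", "absent"))))
    out[idx] <- cls
  }
  factor(out, levels = INHERITANCE_CLASSES)
}

#' Non-transmitted (pseudo-control) dosage at a common SNP
#'
#' The four parental alleles at a biallelic SNP split into two transmitted
#' (the proband genotype) and two non-transmitted; the non-transmitted
#' alt-allele count is therefore `father + mother - proband`, with no phasing
#' required. Triples that are Mendelian-inconsistent (the result would fall
#' outside 0..2, e.g. a de novo allele at a common SNP) and triples with
#' missing members return `NA`.
#'
#' @param fa,mo,pro parental and proband dosage vectors.
#' @return integer vector of pseudo-control dosages in `{0, 1, 2}` (NA where
#'   undefined).
#' @export
pseudo_control_dosage <- function(fa, mo, pro) {
  nt <- fa + mo - pro
  bad <- !is.na(nt) & (nt < 0 | nt > 2 |
                         !.mendel_ok[cbind(pro + 1, fa + 1, mo + 1)])
  nt[bad] <- NA
  as.integer(nt)
}

#' Classify CNV inheritance within one family
#'
#' A proband CNV with any overlap (at least 1 bp, same del/dup type) with a
#' CNV in either parent is `transmitted`; a proband CNV with no such overlap
#' is `de_novo`. A parental CNV with no same-type overlap in the proband is
#' `non_transmitted`. Intervals are 0-based half-open.
#'
#' @param proband_cnvs,father_cnvs,mother_cnvs data frames with columns
#'   `start`, `end`, `type` (`"del"`/`"dup"`); zero-row frames are allowed.
#' @return a data frame binding the input rows with added columns `role`
#'   (`proband`/`father`/`mother`) and `class`; parental CNVs that overlap a
#'   proband CNV (i.e. were transmitted) are labelled `transmitted` on the
#'   parental side too.
#' @export
classify_cnv <- function(proband_cnvs, father_cnvs, mother_cnvs) {
  check_iv <- function(d, who) {
    if (nrow(d) > 0 && any(d$end <= d$start))
      stop("malformed CNV interval (end <= start) in ", who)
    d
  }
  strip_role <- function(d) { d$role <- NULL; d }
  pro <- strip_role(check_iv(proband_cnvs, "proband"))
  fa <- strip_role(check_iv(father_cnvs, "father"))
  mo <- strip_role(check_iv(mother_cnvs, "mother"))
  par <- dplyr::bind_rows(father = fa, mother = mo, .id = "role")

  overlaps_any <- function(a, b) {
    # for each row of a: any same-type >=1bp overlap with rows of b
    if (nrow(a) == 0) return(logical(0))
    if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
    vapply(seq_len(nrow(a)), function(i) {
      same <- b$type == a$type[i]
      any(same & b$start < a$end[i] & b$end > a$start[i])
    }, logical(1))
  }
  pro_hit <- overlaps_any(pro, par)
  par_hit <- overlaps_any(par, pro)
  dplyr::bind_rows(
    if (nrow(pro) > 0)
      dplyr::mutate(pro, role = "proband",
                    class = ifelse(pro_hit, "transmitted", "de_novo")),
    if (nrow(par) > 0)
      dplyr::mutate(par,
                    class = ifelse(par_hit, "transmitted", "non_transmitted"))
  )
}

#' Mendelian consistency screen over a common-SNP panel
#'
#' Computes, for every SNP, the fraction of trios whose genotype triple is
#' consistent with Mendelian inheritance, and for every trio the fraction of
#' SNPs that are consistent; flags entries below `threshold` (default 0.90,
#' the conventional screen).
#'
#' @param panel a SNP panel as produced by [generate_cohort()]: a list with a
#'   `dosage` matrix (individuals x SNPs, rownames = individual IDs) and a
#'   `map` table.
#' @param trios trio table with columns `proband`, `father`, `mother`.
#' @param threshold flagging threshold on the consistency rate.
#' @return list with tibbles `per_snp` (`snp`, `rate`, `flag`) and `per_trio`
#'   (`fid`, `rate`, `flag`), plus a logical matrix `consistent`
#'   (trios x SNPs).
#' @export
mendelian_screen <- function(panel, trios, threshold = 0.90) {
  if (ncol(panel$dosage) == 0 || nrow(trios) == 0) stop("empty panel or trio table")
  pro <- panel$dosage[trios$proband, , drop = FALSE]
  fa <- panel$dosage[trios$father, , drop = FALSE]
  mo <- panel$dosage[trios$mother, , drop = FALSE]
  cons <- array(.mendel_ok[cbind(c(pro) + 1, c(fa) + 1, c(mo) + 1)],
                dim = dim(pro), dimnames = list(trios$fid, colnames(pro)))
  per_snp <- tibble(snp = colnames(cons), rate = unname(colMeans(cons)))
  per_snp$flag <- per_snp$rate < threshold
  per_trio <- tibble(fid = trios$fid, rate = rowMeans(cons))
  per_trio$flag <- per_trio$rate < threshold
  list(per_snp = per_snp, per_trio = per_trio, consistent = cons)
}

#' Mask Mendelian-inconsistent genotypes within trios
#'
#' Sets a SNP missing for all three members of a trio whose triple is
#' inconsistent, leaving other trios untouched: the SNP stays in the panel
#' (nothing is removed cohort-wide) but is excluded from that trio's PRS and
#' pseudo-control.
#'
#' @inheritParams mendelian_screen
#' @return the panel with inconsistent entries set to `NA`.
#' @export
mask_mendelian_errors <- function(panel, trios) {
  scr <- mendelian_screen(panel, trios)
  bad <- which(!scr$consistent, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    dos <- panel$dosage
    for (member in c("proband", "father", "mother")) {
      rows <- match(trios[[member]][bad[, 1]], rownames(dos))
      dos[cbind(rows, bad[, 2])] <- NA_integer_
    }
    panel$dosage <- dos
  }
  panel
}
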