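#' Damaging protein-truncating variant rule
#'
#' A PTV is called damaging when it is a frameshift (unconditionally), or a
#' stop-gain or splice donor/acceptor variant with a scaled CADD score of at
#' least 20. CADD >= 20 corresponds roughly to the top 1% most deleterious
#' variants genome-wide; gating the stop/splice classes on it enriches for
#' alleles of the kind recurrently implicated in developmental disorders.
#'
#' @param consequence character vector: one of `frameshift`, `stop_gain`,
#'   `splice_donor`, `splice_acceptor`, `missense`, `other`.
#' @param cadd scaled CADD scores (NA = unannotated).
#' @return logical vector. A stop/splice variant with missing CADD is `FALSE`
#'   with a warning.
#' @export
is_damaging_ptv <- function(consequence, cadd) {
  gated <- consequence %in% c("stop_gain", "splice_donor", "splice_acceptor")
  if (any(gated & is.na(cadd)))
    warning(sum(gated & is.na(cadd)),
            " stop/splice variant(s) lack a CADD score; treated as non-damaging")
  consequence == "frameshift" | (gated & !is.na(cadd) & cadd >= 20)
}

#' Damaging missense variant rule
#'
#' A missense variant is called damaging when both its MPC score (missense
#' badness, PolyPhen-2, constraint) is at least 1 and its scaled CADD score is
#' at least 20; requiring both a per-variant deleteriousness score and a
#' regional constraint measure selects missense alleles with effect sizes
#' closer to truncating variants.
#'
#' @inheritParams is_damaging_ptv
#' @param mpc MPC scores (NA = unannotated, e.g. non-missense variants).
#' @return logical vector; missense with missing MPC is `FALSE` with a
#'   warning.
#' @export
is_damaging_missense <- function(consequence, mpc, cadd) {
  mis <- consequence == "missense"
  if (any(mis & is.na(mpc)))
    warning(sum(mis & is.na(mpc)),
            " missense variant(s) lack an MPC score; treated as non-damaging")
  mis & !is.na(mpc) & mpc >= 1 & !is.na(cadd) & cadd >= 20
}

#' Combined damaging coding variant rule
#'
#' Union of [is_damaging_ptv()] and [is_damaging_missense()]; the two cannot
#' both fire because the consequence classes partition the variants.
#'
#' @inheritParams is_damaging_missense
#' @export
is_damaging <- function(consequence, cadd, mpc) {
  suppressWarnings(is_damaging_ptv(consequence, cadd) |
                     is_damaging_missense(consequence, mpc, cadd))
}

#' Ultra-rare variant filter
#'
#' A variant is ultra-rare when its allele is observed exactly once among all
#' cohort parents and is absent from the external reference cohort. The
#' filter applies to the transmitted and non-transmitted analyses; de novo
#' variants are new mutations and bypass it.
#'
#' @param parent_ac allele count among all cohort parents (including the
#'   carrier's own parents).
#' @param ref_ac allele count in the external reference panel.
#' @return logical vector.
#' @export
is_ultra_rare <- function(parent_ac, ref_ac) {
  if (any(parent_ac < 0 | ref_ac < 0, na.rm = TRUE))
    stop("allele counts must be non-negative")
  !is.na(parent_ac) & !is.na(ref_ac) & parent_ac == 1 & ref_ac == 0
}

#' CNV quality and size filters
#'
#' All CNVs must have cohort frequency <= `max_freq` (default 1%), at least
#' `min_probes` supporting array probes (default 15), segmental-duplication
#' overlap of at most `max_segdup` of their length (default 50%), and length
#' of at least `min_kb` (default 15 kb). Transmitted and non-transmitted CNVs
#' face a stricter `min_kb_inherited` (default 100 kb) because, unlike de
#' novo calls, they are not independently validated.
#'
#' @param length_bp CNV lengths in bp.
#' @param cohort_freq frequency of an overlapping same-type CNV in the cohort.
#' @param segdup_overlap fraction of the CNV covered by segmental
#'   duplications.
#' @param n_probes supporting probe count.
#' @param inheritance inheritance class per CNV (`de_novo`, `transmitted`,
#'   `non_transmitted`).
#' @param max_freq,min_probes,max_segdup,min_kb,min_kb_inherited thresholds.
#' @return logical vector.
#' @export
cnv_passes_filters <- function(length_bp, cohort_freq, segdup_overlap,
                               n_probes, inheritance, max_freq = 0.01,
                               min_probes = 15, max_segdup = 0.5,
                               min_kb = 15, min_kb_inherited = 100) {
  base <- cohort_freq <= max_freq & n_probes >= min_probes &
    segdup_overlap <= max_segdup & length_bp >= min_kb * 1000
  inherited <- inheritance %in% c("transmitted", "non_transmitted")
  base & (!inherited | length_bp >= min_kb_inherited * 1000)
}

#' Gene-set membership for coding variants
#'
#' @param gene gene symbols of the variants.
#' @param sets a gene-set object: list with `genes` (tibble: `gene`, `lofi`,
#'   `dd`, gene `start`/`end`) and `exons` (tibble: `gene`, `start`, `end`,
#'   0-based half-open).
#' @param which `"lofi"` or `"dd"`.
#' @return logical vector; unknown gene symbols are `FALSE` with a warning.
#' @export
variant_in_set <- function(gene, sets, which = c("lofi", "dd")) {
  which <- match.arg(which)
  idx <- match(gene, sets$genes$gene)
  if (anyNA(idx))
    warning(sum(is.na(idx)), " variant gene symbol(s) not in the gene table")
  out <- sets$genes[[which]][idx]
  out[is.na(out)] <- FALSE
  out
}

#' Gene-set membership for CNVs
#'
#' A CNV belongs to a gene set when it overlaps (>= 1 bp) any exon of at
#' least one gene in the set; a CNV lying entirely within introns of a set
#' gene does not count. Intervals are 0-based half-open.
#'
#' @param start,end CNV interval vectors.
#' @param sets gene-set object (see [variant_in_set()]).
#' @param which `"lofi"` or `"dd"`.
#' @return logical vector.
#' @export
cnv_in_set <- function(start, end, sets, which = c("lofi", "dd")) {
  which <- match.arg(which)
  set_genes <- sets$genes$gene[sets$genes[[which]]]
  ex <- sets$exons[sets$exons$gene %in% set_genes, , drop = FALSE]
  if (nrow(ex) == 0 || length(start) == 0) return(rep(FALSE, length(start)))
  # half-open -> closed coordinates for IRanges
  q <- IRanges::IRanges(start = start + 1L, end = end)
  s <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
  IRanges::overlapsAny(q, s)
}

#' Annotate coding variant calls with filters, inheritance and damage flags
#'
#' Applies the trio genotype filters, classifies inheritance from the dosage
#' triple (calls failing the filters are `filtered`), flags damaging and
#' ultra-rare variants, and records gene-set membership.
#'
#' @param calls coding-call table (one row = one variant in one trio) with
#'   trio member columns (`pro_*`, `fa_*`, `mo_*`), `gene`, `consequence`,
#'   `cadd`, `mpc`, `parent_ac`, `ref_ac`.
#' @param sets gene-set object.
#' @inheritParams genotype_passes
#' @return the table with added columns `filter_pass`, `class`, `damaging`,
#'   `ultra_rare`, `in_lofi`, `in_dd`.
#' @export
annotate_coding_calls <- function(calls, sets, min_depth = 10, min_gq = 30) {
  calls$filter_pass <- pass_genotype_filters(calls, min_depth, min_gq)
  cls <- classify_snv(calls$pro_dos, calls$fa_dos, calls$mo_dos)
  cls[!calls$filter_pass] <- "filtered"
  calls$class <- cls
  calls$damaging <- is_damaging(calls$consequence, calls$cadd, calls$mpc)
  calls$ultra_rare <- is_ultra_rare(calls$parent_ac, calls$ref_ac)
  calls$in_lofi <- variant_in_set(calls$gene, sets, "lofi")
  calls$in_dd <- variant_in_set(calls$gene, sets, "dd")
  calls
}

#' Annotate CNV calls with inheritance, cohort frequency and filters
#'
#' Classifies inheritance family by family via [classify_cnv()], computes the
#' cohort frequency of each CNV (fraction of individuals carrying an
#' overlapping same-type CNV), applies [cnv_passes_filters()], and records
#' exonic gene-set overlap.
#'
#' @param cnv_calls CNV table with columns `fid`, `iid`, `role`
#'   (`proband`/`father`/`mother`), `start`, `end`, `type`, `n_probes`,
#'   `segdup_frac`.
#' @param sets gene-set object.
#' @param n_individuals cohort size for the frequency denominator (defaults
#'   to the number of distinct carriers observed, so pass the true cohort
#'   size when available).
#' @param ... thresholds forwarded to [cnv_passes_filters()].
#' @return the table with added columns `class`, `cohort_freq`,
#'   `filter_pass`, `in_lofi`, `in_dd`.
#' @export
annotate_cnv_calls <- function(cnv_calls, sets, n_individuals = NULL, ...) {
  if (nrow(cnv_calls) == 0) {
    return(dplyr::mutate(cnv_calls, class = character(0),
                         cohort_freq = numeric(0), filter_pass = logical(0),
                         in_lofi = logical(0), in_dd = logical(0)))
  }
  if (is.null(n_individuals)) n_individuals <- dplyr::n_distinct(cnv_calls$iid)
  classified <- dplyr::bind_rows(lapply(split(cnv_calls, cnv_calls$fid),
    function(d) {
      classify_cnv(d[d$role == "proband", , drop = FALSE],
                   d[d$role == "father", , drop = FALSE],
                   d[d$role == "mother", , drop = FALSE])
    }))
  # cohort frequency: individuals carrying any same-type overlapping CNV
  classified$cohort_freq <- vapply(seq_len(nrow(classified)), function(i) {
    hit <- classified$type == classified$type[i] &
      classified$start < classified$end[i] &
      classified$end > classified$start[i]
    dplyr::n_distinct(classified$iid[hit]) / n_individuals
  }, numeric(1))
  classified$filter_pass <- cnv_passes_filters(
    classified$end - classified$start, classified$cohort_freq,
    classified$segdup_frac, classified$n_probes, classified$class, ...)
  classified$in_lofi <- cnv_in_set(classified$start, classified$end, sets, "lofi")
  classified$in_dd <- cnv_in_set(classified$start, classified$end, sets, "dd")
  classified
}

BURDEN_CATEGORIES <- as.vector(outer(
  c("dn_coding", "trans_coding", "nt_coding", "dn_cnv", "trans_cnv", "nt_cnv"),
  c("lofi", "dd"), paste, sep = "_"))

#' Per-proband burden matrix: 6 mutation classes x 2 gene sets
#'
#' Counts, for every proband, damaging de novo coding variants (no rarity
#' filter: new mutations are rare by definition), damaging ultra-rare
#' transmitted and non-transmitted coding variants, and filter-passing de
#' novo / transmitted / non-transmitted CNVs, in the LoFi and DD gene sets.
#' Variants are counted, not genes: two qualifying variants in one gene in
#' one proband contribute two.
#'
#' @param coding annotated coding calls ([annotate_coding_calls()]).
#' @param cnvs annotated CNV calls ([annotate_cnv_calls()]).
#' @param trios trio table with `fid`.
#' @return tibble with one row per proband (`fid` first) and the 12 category
#'   columns; the supporting per-category variant tables are attached as
#'   attribute `"support"`.
#' @export
build_burden_matrix <- function(coding, cnvs, trios) {
  out <- tibble(fid = trios$fid)
  qualifies <- list(
    dn_coding = coding$class == "de_novo" & coding$damaging,
    trans_coding = coding$class == "transmitted" & coding$damaging &
      coding$ultra_rare,
    nt_coding = coding$class == "non_transmitted" & coding$damaging &
      coding$ultra_rare)
  support <- list()
  for (cat in names(qualifies)) {
    for (set in c("lofi", "dd")) {
      rows <- coding[qualifies[[cat]] & coding[[paste0("in_", set)]], ,
                     drop = FALSE]
      col <- paste(cat, set, sep = "_")
      out[[col]] <- as.integer(table(factor(rows$fid, levels = trios$fid)))
      support[[col]] <- rows
    }
  }
  cnv_classes <- c(dn_cnv = "de_novo", trans_cnv = "transmitted",
                   nt_cnv = "non_transmitted")
  for (cat in names(cnv_classes)) {
    for (set in c("lofi", "dd")) {
      rows <- cnvs[cnvs$class == cnv_classes[[cat]] &
                     cnvs$filter_pass & cnvs[[paste0("in_", set)]], ,
                   drop = FALSE]
      col <- paste(cat, set, sep = "_")
      out[[col]] <- as.integer(table(factor(rows$fid, levels = trios$fid)))
      support[[col]] <- rows
    }
  }
  out <- out[, c("fid", BURDEN_CATEGORIES)]
  if (any(is.na(match(trios$fid, out$fid))))
    stop("proband missing from trio table")
  attr(out, "support") <- support
  out
}

#' De novo share of damaging variants carried by probands
#'
#' The fraction of all qualifying proband variants in a gene set (de novo
#' plus inherited, i.e. transmitted) that arose de novo. Non-transmitted
#' variants stay in the parents and do not enter the denominator.
#'
#' @param de_novo cohort-wide de novo count.
#' @param inherited cohort-wide inherited (transmitted) count, or a vector of
#'   per-group counts to be summed.
#' @return proportion in \[0, 1\].
#' @export
denovo_fraction <- function(de_novo, inherited) {
  tot <- de_novo + sum(inherited)
  if (tot == 0) stop("no variants")
  de_novo / tot
}
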