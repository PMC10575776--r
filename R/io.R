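# Readers and writers for the cohort's standard file formats. Writers emit
# plain text (VCF 4.2, FAM-style TSV, BED 0-based half-open, TSV); reading of
# VCF goes through vcfR. Numeric columns are written with 17 significant
# digits so a write/read round trip is exact.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

write_tsv_exact <- function(d, path) {
  d <- as.data.frame(d)
  for (j in seq_along(d)) if (is.double(d[[j]])) d[[j]] <- fmt_num(d[[j]])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

gt_string <- function(dosage) {
  out <- rep("./.", length(dosage))
  out[!is.na(dosage) & dosage == 0L] <- "0/0"
  out[!is.na(dosage) & dosage == 1L] <- "0/1"
  out[!is.na(dosage) & dosage == 2L] <- "1/1"
  out
}

gt_to_dosage <- function(gt) {
  # counts ALT alleles; tolerates phased separators and missing calls
  d <- ifelse(is.na(gt) | gt %in% c("./.", ".|.", "."), NA_integer_,
              lengths(regmatches(gt, gregexpr("1", gt))))
  as.integer(d)
}

vcf_header <- function(samples, format_lines, info_lines) {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    info_lines, format_lines,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

#' Write a synthetic cohort to standard-format files
#'
#' Emits, under `outdir`: `trios.fam` (one row per individual),
#' `phenotypes.tsv` (grades, comorbid-ID status, sex and PC covariates),
#' `genotypes.vcf` (common-SNP GT for every trio member, ALT = counted
#' allele), `coding.vcf` (rare coding calls with INFO GENE/CSQ/CADD/MPC and
#' allele counts, FORMAT GT:DP:GQ:AD:AB), `cnvs.tsv` (BED-like, 0-based
#' half-open), `genes.tsv` + `exons.bed` (gene sets), one
#' `sumstats_<trait>.tsv` per trait, `weights.tsv` (true liability weights)
#' and `liability.tsv`. [read_cohort()] reconstructs the cohort from these
#' files.
#'
#' @param cohort a `"trio_cohort"`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tr <- cohort$trios

  fam <- rbind(
    data.frame(FID = tr$fid, IID = tr$proband, PAT = tr$father,
               MAT = tr$mother, SEX = tr$sex, PHENO = tr$phenotype + 1L),
    data.frame(FID = tr$fid, IID = tr$father, PAT = "0", MAT = "0", SEX = 1L,
               PHENO = -9L),
    data.frame(FID = tr$fid, IID = tr$mother, PAT = "0", MAT = "0", SEX = 2L,
               PHENO = -9L))
  utils::write.table(fam, file.path(outdir, "trios.fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  write_tsv_exact(tr[, c("fid", "grade", "id_status", "sex", "phenotype",
                         paste0("PC", 1:10))],
                  file.path(outdir, "phenotypes.tsv"))

  map <- cohort$panel$map
  samples <- rownames(cohort$panel$dosage)
  gt <- apply(cohort$panel$dosage, 1, gt_string)  # snps x individuals
  body <- paste(map$chr, map$pos, map$snp, map$a2, map$a1, ".", "PASS",
                paste0("MAF=", fmt_num(map$maf)), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(
    samples,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##INFO=<ID=MAF,Number=1,Type=Float,Description="Simulated minor allele frequency">'),
    body), file.path(outdir, "genotypes.vcf"))

  write_coding_vcf(cohort, file.path(outdir, "coding.vcf"))

  cnv <- cohort$cnv_calls
  cnv_out <- data.frame(chrom = 1L, start = cnv$start, end = cnv$end,
                        cnv_id = cnv$cnv_id, type = cnv$type, fid = cnv$fid,
                        iid = cnv$iid, role = cnv$role,
                        n_probes = cnv$n_probes,
                        segdup_frac = cnv$segdup_frac)
  write_tsv_exact(cnv_out, file.path(outdir, "cnvs.tsv"))

  write_tsv_exact(cohort$gene_sets$genes, file.path(outdir, "genes.tsv"))
  ex <- cohort$gene_sets$exons
  utils::write.table(data.frame(1L, ex$start, ex$end, ex$gene),
                     file.path(outdir, "exons.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  for (trait in names(cohort$sumstats)) {
    st <- cohort$sumstats[[trait]]
    write_tsv_exact(
      data.frame(SNP = st$snp, CHR = st$chr, BP = st$pos,
                 A1 = st$effect_allele, A2 = st$other_allele,
                 BETA = st$beta, P = st$p),
      file.path(outdir, paste0("sumstats_", trait, ".tsv")))
  }
  write_tsv_exact(data.frame(snp = names(cohort$true_weights),
                             weight = unname(cohort$true_weights)),
                  file.path(outdir, "weights.tsv"))
  write_tsv_exact(data.frame(fid = tr$fid, liability = cohort$liability,
                             true_prs = cohort$true_prs),
                  file.path(outdir, "liability.tsv"))
  invisible(outdir)
}

write_coding_vcf <- function(cohort, path) {
  calls <- cohort$coding_calls
  tr <- cohort$trios
  samples <- rownames(cohort$panel$dosage)
  ord <- order(calls$pos, calls$variant_id)
  calls <- calls[ord, , drop = FALSE]
  n_var <- nrow(calls)
  gt_mat <- matrix("./.", n_var, length(samples),
                   dimnames = list(NULL, samples))
  trio_idx <- match(calls$fid, tr$fid)
  member_iid <- list(pro = tr$proband, fa = tr$father, mo = tr$mother)
  for (member in c("pro", "fa", "mo")) {
    dos <- calls[[paste0(member, "_dos")]]
    dp <- calls[[paste0(member, "_dp")]]
    gq <- calls[[paste0(member, "_gq")]]
    ab <- calls[[paste0(member, "_ab")]]
    alt_reads <- as.integer(round(dp * ab))
    field <- paste0(gt_string(dos), ":", dp, ":", gq, ":",
                    dp - alt_reads, ",", alt_reads, ":", fmt_num(ab))
    cols <- match(member_iid[[member]][trio_idx], samples)
    gt_mat[cbind(seq_len(n_var), cols)] <- field
  }
  info <- paste0("GENE=", calls$gene, ";CSQ=", calls$consequence,
                 ";CADD=", fmt_num(calls$cadd),
                 ";MPC=", ifelse(is.na(calls$mpc), ".", fmt_num(calls$mpc)),
                 ";PAC=", calls$parent_ac, ";RAC=", calls$ref_ac,
                 ";FID=", calls$fid,
                 ";TRTH=", ifelse(is.na(calls$transmitted_truth), ".",
                                  as.integer(calls$transmitted_truth)))
  body <- paste(calls$chr, calls$pos, calls$variant_id, calls$ref, calls$alt,
                ".", "PASS", info, "GT:DP:GQ:AD:AB",
                apply(gt_mat, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(vcf_header(
    samples,
    c('##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
      '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
      '##FORMAT=<ID=AB,Number=1,Type=Float,Description="Alternative allele balance">'),
    c('##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol">',
      '##INFO=<ID=CSQ,Number=1,Type=String,Description="Consequence">',
      '##INFO=<ID=CADD,Number=1,Type=Float,Description="Scaled CADD score">',
      '##INFO=<ID=MPC,Number=1,Type=Float,Description="MPC score">',
      '##INFO=<ID=PAC,Number=1,Type=Integer,Description="Parental allele count">',
      '##INFO=<ID=RAC,Number=1,Type=Integer,Description="Reference cohort allele count">',
      '##INFO=<ID=FID,Number=1,Type=String,Description="Carrier family">',
      '##INFO=<ID=TRTH,Number=1,Type=Integer,Description="Generator transmission flag">')),
    body), path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory produced by [write_cohort()].
#' @return a `"trio_cohort"` (without the generator `config` and `truth`
#'   entries, which are not serialised).
#' @export
read_cohort <- function(dir) {
  ph <- read_tsv(file.path(dir, "phenotypes.tsv"))
  fam <- utils::read.delim(file.path(dir, "trios.fam"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("FID", "IID", "PAT", "MAT", "SEX",
                                         "PHENO"))
  pro <- fam[fam$PAT != "0", , drop = FALSE]
  trios <- tibble::tibble(fid = pro$FID, proband = pro$IID,
                          father = pro$PAT, mother = pro$MAT)
  trios <- dplyr::left_join(trios, ph, by = "fid")
  trios <- trios[, c("fid", "proband", "father", "mother", "sex", "grade",
                     "phenotype", "id_status", paste0("PC", 1:10))]

  vcf <- vcfR::read.vcfR(file.path(dir, "genotypes.vcf"), verbose = FALSE)
  gt <- vcfR::extract.gt(vcf)
  dosage <- apply(gt, 2, gt_to_dosage)
  rownames(dosage) <- vcf@fix[, "ID"]
  dosage <- t(dosage)
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  map <- tibble::tibble(snp = fix$ID, chr = as.integer(fix$CHROM),
                        pos = as.integer(fix$POS), a1 = fix$ALT, a2 = fix$REF,
                        maf = as.numeric(sub("MAF=", "", fix$INFO)))
  panel <- list(dosage = dosage[, map$snp, drop = FALSE], map = map)

  coding <- read_coding_vcf(file.path(dir, "coding.vcf"), trios)

  cnv_raw <- read_tsv(file.path(dir, "cnvs.tsv"))
  cnv <- tibble::tibble(fid = cnv_raw$fid, iid = cnv_raw$iid,
                        role = cnv_raw$role, start = cnv_raw$start,
                        end = cnv_raw$end, type = cnv_raw$type,
                        n_probes = cnv_raw$n_probes,
                        segdup_frac = cnv_raw$segdup_frac,
                        cnv_id = cnv_raw$cnv_id)

  genes <- read_tsv(file.path(dir, "genes.tsv"))
  ex <- utils::read.delim(file.path(dir, "exons.bed"), header = FALSE,
                          col.names = c("chrom", "start", "end", "gene"))
  gene_sets <- list(genes = genes,
                    exons = tibble::tibble(gene = ex$gene, start = ex$start,
                                           end = ex$end))

  ss_files <- list.files(dir, pattern = "^sumstats_.*\\.tsv$")
  sumstats <- lapply(ss_files, function(f) {
    d <- read_tsv(file.path(dir, f))
    tibble::tibble(snp = d$SNP, chr = d$CHR, pos = d$BP,
                   effect_allele = d$A1, other_allele = d$A2, beta = d$BETA,
                   p = d$P)
  })
  names(sumstats) <- sub("^sumstats_(.*)\\.tsv$", "\\1", ss_files)

  w <- read_tsv(file.path(dir, "weights.tsv"))
  lia <- read_tsv(file.path(dir, "liability.tsv"))

  structure(list(trios = trios, panel = panel,
                 true_weights = stats::setNames(w$weight, w$snp),
                 sumstats = sumstats, coding_calls = coding, cnv_calls = cnv,
                 gene_sets = gene_sets,
                 liability = lia$liability[match(trios$fid, lia$fid)],
                 true_prs = lia$true_prs[match(trios$fid, lia$fid)]),
            class = "trio_cohort")
}

read_coding_vcf <- function(path, trios) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  info_get <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(^|;)", key, "=[^;]*"),
                                      fix$INFO))
    sub(paste0("^;?", key, "="), "", m)
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(x == ".", NA, x)))
  calls <- tibble::tibble(
    fid = info_get("FID"),
    gene = info_get("GENE"), chr = as.integer(fix$CHROM),
    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    consequence = info_get("CSQ"), cadd = num_or_na(info_get("CADD")),
    mpc = num_or_na(info_get("MPC")),
    parent_ac = as.integer(info_get("PAC")),
    ref_ac = as.integer(info_get("RAC")))
  trth <- info_get("TRTH")
  gt <- vcfR::extract.gt(vcf)
  dp <- vcfR::extract.gt(vcf, element = "DP")
  gq <- vcfR::extract.gt(vcf, element = "GQ")
  ab <- vcfR::extract.gt(vcf, element = "AB")
  trio_idx <- match(calls$fid, trios$fid)
  member_iid <- list(pro = trios$proband, fa = trios$father,
                     mo = trios$mother)
  for (member in c("pro", "fa", "mo")) {
    cells <- cbind(seq_len(nrow(calls)),
                   match(member_iid[[member]][trio_idx], colnames(gt)))
    calls[[paste0(member, "_dos")]] <- gt_to_dosage(gt[cells])
    calls[[paste0(member, "_dp")]] <- as.integer(dp[cells])
    calls[[paste0(member, "_gq")]] <- as.integer(gq[cells])
    calls[[paste0(member, "_ab")]] <- as.numeric(ab[cells])
  }
  calls$transmitted_truth <- ifelse(trth == ".", NA, trth == "1")
  calls$variant_id <- fix$ID
  # restore generator row order
  calls[order(calls$variant_id), , drop = FALSE]
}
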