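#' Bonferroni threshold for the primary analysis
#'
#' The primary analysis comprises 18 univariable tests (6 polygenic-score
#' categories: transmitted and non-transmitted scores for three traits, plus
#' 12 rare-variant categories), so the family-wise 5% threshold is
#' `0.05 / 18`.
#'
#' @param n_tests number of primary tests (default 18).
#' @param alpha family-wise level (default 0.05).
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(n_tests = 18, alpha = 0.05) alpha / n_tests

covariate_matrix <- function(trios) {
  as.matrix(cbind(sex = trios$sex, trios[, paste0("PC", 1:10)]))
}

#' Primary univariable association scan
#'
#' Runs the 18 primary tests: Firth penalized logistic regression of the
#' binary phenotype (internally coded 1 = lower performance) on each of the
#' 12 rare-variant burden categories, and binomial logistic regression on
#' the standardised transmitted (proband) and non-transmitted
#' (pseudo-control) polygenic scores of each trait at the primary p-value
#' threshold. All models adjust for sex and 10 principal components.
#' Polygenic-score rows report the OR for *higher* performance per SD (the
#' conventional presentation), rare-variant rows the OR for *lower*
#' performance; the `or_outcome` column records which.
#'
#' @param burden burden matrix from [build_burden_matrix()].
#' @param profiles named list (by trait) of profile tables from
#'   [build_prs_profiles()].
#' @param trios trio table with `phenotype`, `sex`, `PC1`..`PC10`.
#' @param prs_threshold primary training p-value threshold (default 0.05).
#' @param alpha family-wise level for the Bonferroni flag.
#' @return tibble with one row per test: `category`, `class`
#'   (`rare`/`prs`), `n`, `or`, `ci_lower`, `ci_upper`, `p`, `or_outcome`,
#'   `significant`.
#' @export
run_univariable <- function(burden, profiles, trios, prs_threshold = 0.05,
                            alpha = 0.05) {
  stopifnot(identical(burden$fid, trios$fid))
  y <- trios$phenotype  # 1 = lower performance
  covars <- covariate_matrix(trios)
  n_tests <- length(BURDEN_CATEGORIES) + 2 * length(profiles)
  thr <- bonferroni_threshold(n_tests, alpha)

  rare_rows <- lapply(BURDEN_CATEGORIES, function(cat) {
    if (!cat %in% names(burden)) stop("missing burden category: ", cat)
    if (stats::var(burden[[cat]]) == 0) {
      # no carriers (or all identical counts): category untestable
      return(tibble::tibble(category = cat, class = "rare",
                            n = length(y), or = NA_real_,
                            ci_lower = NA_real_, ci_upper = NA_real_,
                            p = NA_real_, or_outcome = "lower"))
    }
    X <- cbind(burden = burden[[cat]], covars)
    fit <- firth_logistic(y, X, plr_terms = "burden")
    tibble::tibble(category = cat, class = "rare", n = fit$n,
                   or = fit$or[["burden"]],
                   ci_lower = fit$ci["burden", "lower"],
                   ci_upper = fit$ci["burden", "upper"],
                   p = fit$p[["burden"]], or_outcome = "lower")
  })

  prs_rows <- lapply(names(profiles), function(trait) {
    prof <- profiles[[trait]]
    prof <- prof[prof$threshold == prs_threshold, , drop = FALSE]
    prof <- prof[match(trios$fid, prof$fid), , drop = FALSE]
    out <- list()
    for (kind in c("transmitted", "non_transmitted")) {
      col <- if (kind == "transmitted") "proband_prs_std" else "nt_prs_std"
      X <- cbind(prs = prof[[col]], covars)
      fit <- binomial_logistic(y, X)
      # present per-SD OR for higher performance: invert the lower-coded beta
      out[[kind]] <- tibble::tibble(
        category = paste(kind, "prs", trait, sep = "_"), class = "prs",
        n = fit$n, or = exp(-fit$coef[["prs"]]),
        ci_lower = 1 / fit$ci["prs", "upper"],
        ci_upper = 1 / fit$ci["prs", "lower"],
        p = fit$p[["prs"]], or_outcome = "higher")
    }
    dplyr::bind_rows(out)
  })

  res <- dplyr::bind_rows(c(rare_rows, prs_rows))
  res$significant <- !is.na(res$p) & res$p < thr
  res
}

#' Secondary transmission tests
#'
#' (1) Polygenic transmission disequilibrium: for each trait, compares the
#' per-trio pTDT deviations between the lower- and higher-performance groups
#' with a two-sample t-test (unadjusted by default; set `adjust = TRUE` to
#' regress deviations on the covariates first). (2) Rare-variant TDT: for
#' ultra-rare damaging coding variants and filter-passing CNVs in each gene
#' set, tests the transmitted vs non-transmitted cohort totals against the
#' chance rate of 1/2 with [tdt_chisq()].
#'
#' @inheritParams run_univariable
#' @param adjust covariate-adjust the pTDT deviations before the group
#'   comparison.
#' @return list with tibbles `ptdt` (per trait) and `tdt` (per rare
#'   category).
#' @export
run_secondary <- function(burden, profiles, trios, prs_threshold = 0.05,
                          adjust = FALSE) {
  ptdt_rows <- lapply(names(profiles), function(trait) {
    prof <- profiles[[trait]]
    prof <- prof[prof$threshold == prs_threshold, , drop = FALSE]
    prof <- prof[match(trios$fid, prof$fid), , drop = FALSE]
    dev <- prof$ptdt_deviation
    if (adjust)
      dev <- stats::resid(stats::lm(dev ~ covariate_matrix(trios)))
    lower <- dev[trios$phenotype == 1]
    higher <- dev[trios$phenotype == 0]
    tt <- two_sample_t(higher, lower)
    tibble::tibble(trait = trait, mean_dev_lower = mean(lower),
                   mean_dev_higher = mean(higher),
                   t = tt$statistic, p = tt$p.value)
  })
  pairs <- list(coding_lofi = c("trans_coding_lofi", "nt_coding_lofi"),
                coding_dd = c("trans_coding_dd", "nt_coding_dd"),
                cnv_lofi = c("trans_cnv_lofi", "nt_cnv_lofi"),
                cnv_dd = c("trans_cnv_dd", "nt_cnv_dd"))
  tdt_rows <- lapply(names(pairs), function(nm) {
    t_count <- sum(burden[[pairs[[nm]][1]]])
    nt_count <- sum(burden[[pairs[[nm]][2]]])
    if (t_count + nt_count == 0)
      return(tibble::tibble(category = nm, transmitted = 0L,
                            non_transmitted = 0L, statistic = NA_real_,
                            p = NA_real_))
    res <- tdt_chisq(t_count, nt_count)
    tibble::tibble(category = nm, transmitted = t_count,
                   non_transmitted = nt_count, statistic = res$statistic,
                   p = res$p.value)
  })
  list(ptdt = dplyr::bind_rows(ptdt_rows), tdt = dplyr::bind_rows(tdt_rows))
}

#' Multivariable joint model with per-factor variance explained
#'
#' Joint Firth penalized fit of the selected genetic factors (typically the
#' Bonferroni-significant univariable hits) with sex and 10 principal
#' components, plus nested binomial logistic fits giving each factor's
#' Nagelkerke delta-R-squared (full model vs the model excluding that
#' factor) and the total variance explained by all factors together. The
#' outcome is coded 0 = lower performance, 1 = higher performance.
#'
#' @param factors data frame or matrix of factor columns (one per selected
#'   genetic component), rows aligned with `trios`.
#' @param trios trio table with `phenotype`, `sex`, PCs.
#' @return list with `fit` (the joint `"trio_fit"`), `delta_r2` (tibble:
#'   `factor`, `beta`, `ci_lower`, `ci_upper`, `p`, `delta_r2`) and
#'   `total_r2`.
#' @export
run_multivariable <- function(factors, trios) {
  factors <- as.matrix(factors)
  if (is.null(colnames(factors)))
    colnames(factors) <- paste0("factor", seq_len(ncol(factors)))
  y <- 1 - trios$phenotype  # 0 = lower, 1 = higher
  covars <- covariate_matrix(trios)
  X_full <- cbind(factors, covars)
  fit <- firth_logistic(y, X_full, plr_terms = colnames(factors))
  ll0 <- null_loglik(y)
  full_ml <- binomial_logistic(y, X_full)
  covars_ml <- binomial_logistic(y, covars)
  dr2 <- vapply(colnames(factors), function(f) {
    reduced <- binomial_logistic(y, X_full[, setdiff(colnames(X_full), f),
                                           drop = FALSE])
    nagelkerke_delta_r2(full_ml, reduced, loglik_null = ll0)
  }, numeric(1))
  total_r2 <- nagelkerke_delta_r2(full_ml, covars_ml, loglik_null = ll0)
  list(fit = fit,
       delta_r2 = tibble::tibble(
         factor = colnames(factors), beta = fit$coef[colnames(factors)],
         ci_lower = log(fit$ci[colnames(factors), "lower"]),
         ci_upper = log(fit$ci[colnames(factors), "upper"]),
         p = fit$p[colnames(factors)], delta_r2 = unname(dr2)),
       total_r2 = total_r2)
}

#' Phenotype summary for carriers of a variant class
#'
#' Tabulates the school-grade distribution of carriers (with the proportion
#' of carriers per grade), the exact binomial CI for the proportion of
#' carriers with lower performance, and — within the lower-performance group
#' — Fisher's exact test of comorbid intellectual disability against carrier
#' status.
#'
#' @param carrier logical vector: proband carries the variant class.
#' @param grade school grades (3..6).
#' @param phenotype binary phenotype (1 = lower).
#' @param id_status comorbid-ID indicator (0/1).
#' @return list with `grade_table` (tibble: `grade`, `n`, `proportion`),
#'   `lower_ci` (Clopper-Pearson interval for carriers with lower
#'   performance), and `id_test` (Fisher result plus the 2x2 counts), or an
#'   empty result when there are no carriers.
#' @export
carrier_phenotype_table <- function(carrier, grade, phenotype, id_status) {
  n_car <- sum(carrier)
  if (n_car == 0)
    return(list(grade_table = tibble::tibble(grade = integer(0),
                                             n = integer(0),
                                             proportion = numeric(0)),
                lower_ci = NULL, id_test = NULL))
  tab <- table(factor(grade[carrier], levels = 3:6))
  grade_table <- tibble::tibble(grade = 3:6, n = as.integer(tab),
                                proportion = as.integer(tab) / n_car)
  grade_table <- grade_table[grade_table$n > 0, , drop = FALSE]
  lower_ci <- clopper_pearson(sum(carrier & phenotype == 1), n_car)
  in_lower <- phenotype == 1
  counts <- matrix(c(sum(in_lower & carrier & id_status == 1),
                     sum(in_lower & !carrier & id_status == 1),
                     sum(in_lower & carrier & id_status == 0),
                     sum(in_lower & !carrier & id_status == 0)),
                   2, 2, byrow = TRUE,
                   dimnames = list(c("id", "no_id"),
                                   c("carrier", "non_carrier")))
  id_test <- if (all(rowSums(counts) > 0) && all(colSums(counts) > 0))
    c(fisher_exact(counts), list(counts = counts)) else NULL
  list(grade_table = grade_table, lower_ci = lower_ci, id_test = id_test)
}

#' End-to-end analysis of a trio cohort
#'
#' Convenience wrapper chaining annotation, burden counting, polygenic
#' scoring, the primary univariable scan, the secondary transmission tests,
#' the multivariable model on the Bonferroni-significant factors, and the
#' carrier phenotype table for damaging de novo variants in DD genes.
#'
#' @param cohort a `"trio_cohort"`.
#' @param prs_threshold primary training p-value threshold.
#' @param thresholds all thresholds to score.
#' @return list with `burden`, `profiles`, `univariable`, `secondary`,
#'   `multivariable` (NULL when nothing is significant), `carrier_table`.
#' @export
run_pipeline <- function(cohort, prs_threshold = 0.05,
                         thresholds = c(0.001, 0.05, 0.5)) {
  coding <- annotate_coding_calls(cohort$coding_calls, cohort$gene_sets)
  cnvs <- annotate_cnv_calls(cohort$cnv_calls, cohort$gene_sets,
                             n_individuals = 3 * nrow(cohort$trios))
  burden <- build_burden_matrix(coding, cnvs, cohort$trios)
  profiles <- lapply(cohort$sumstats, function(st)
    build_prs_profiles(cohort$panel, cohort$trios, st,
                       thresholds = thresholds))
  uni <- run_univariable(burden, profiles, cohort$trios, prs_threshold)
  sec <- run_secondary(burden, profiles, cohort$trios, prs_threshold)
  hits <- uni[uni$significant, , drop = FALSE]
  multi <- NULL
  if (nrow(hits) > 0) {
    cols <- lapply(seq_len(nrow(hits)), function(i) {
      cat <- hits$category[i]
      if (hits$class[i] == "rare") return(burden[[cat]])
      trait <- sub("^(transmitted|non_transmitted)_prs_", "", cat)
      col <- if (grepl("^transmitted", cat)) "proband_prs_std" else
        "nt_prs_std"
      prof <- profiles[[trait]]
      prof <- prof[prof$threshold == prs_threshold, , drop = FALSE]
      prof[[col]][match(cohort$trios$fid, prof$fid)]
    })
    factors <- do.call(cbind, cols)
    colnames(factors) <- hits$category
    multi <- run_multivariable(factors, cohort$trios)
  }
  carrier <- carrier_phenotype_table(
    burden$dn_coding_dd > 0, cohort$trios$grade, cohort$trios$phenotype,
    cohort$trios$id_status)
  list(burden = burden, profiles = profiles, univariable = uni,
       secondary = sec, multivariable = multi, carrier_table = carrier)
}
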