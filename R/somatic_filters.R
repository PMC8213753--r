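#' Hard filters on candidate somatic variant records (rules 1--5)
#'
#' The first five rules of the seven-rule cascade are pure per-record
#' predicates:
#' \enumerate{
#'   \item tumor depth at the site >= 10;
#'   \item tumor alt reads >= 3;
#'   \item normal alt reads <= 2;
#'   \item maximal population allele frequency < 0.01;
#'   \item records present in dbSNP (snp142) are removed unless also
#'     recorded in COSMIC.
#' }
#'
#' @param records Variant records with the columns of
#'   [generate_variants()]'s `variants` table.
#' @return `records` with logical columns `rule1`..`rule5` and
#'   `pass_hard` (`TRUE` iff all five hold).
#' @export
apply_hard_filters <- function(records) {
  need <- c("t_depth", "t_alt", "n_alt", "pop_af_max",
            "in_snp142", "in_cosmic")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("records lack required fields: ", paste(missing, collapse = ", "))
  }
  records$rule1 <- records$t_depth >= 10
  records$rule2 <- records$t_alt >= 3
  records$rule3 <- records$n_alt <= 2
  records$rule4 <- records$pop_af_max < 0.01
  records$rule5 <- !records$in_snp142 | records$in_cosmic
  records$pass_hard <- records$rule1 & records$rule2 & records$rule3 &
    records$rule4 & records$rule5
  records
}

#' Tumor-enrichment test (rule 6)
#'
#' One-sided Fisher's exact test that the variant allele fraction is
#' higher in tumor than in matched normal, on the 2x2 table
#' `[[t_alt, t_depth - t_alt], [n_alt, n_depth - n_alt]]`, with
#' Benjamini--Hochberg correction across all tested records of the
#' cohort. A record is kept iff `P < p_cut` and `q < q_cut`.
#'
#' @param records Records that passed the hard filters.
#' @param p_cut,q_cut Rule-6 thresholds.
#' @return `records` with columns `enrich_p`, `enrich_q`, `rule6`.
#' @export
tumor_enrichment_test <- function(records, p_cut = 0.05, q_cut = 0.1) {
  if (any(records$t_depth <= 0)) stop("zero tumor depth")
  p <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    fisher.test(matrix(c(r$t_alt, r$t_depth - r$t_alt,
                         r$n_alt, r$n_depth - r$n_alt),
                       2, 2, byrow = TRUE),
                alternative = "greater")$p.value
  }, numeric(1))
  records$enrich_p <- p
  records$enrich_q <- p.adjust(p, method = "BH")
  records$rule6 <- records$enrich_p < p_cut & records$enrich_q < q_cut
  records
}

#' Strand-bias test (rule 7)
#'
#' Two-sided Fisher's exact test on the strand distribution of alt
#' versus reference reads,
#' `[[t_alt_fwd, t_alt_rev], [t_ref_fwd, t_ref_rev]]`. A record is kept
#' iff `P > p_keep` (biased records have small P and are removed). An
#' all-zero table is degenerate and kept with P = 1.
#'
#' @param t_alt_fwd,t_alt_rev,t_ref_fwd,t_ref_rev Strand read counts
#'   (vectorized).
#' @return Numeric vector of two-sided P values.
#' @export
strand_bias_test <- function(t_alt_fwd, t_alt_rev, t_ref_fwd, t_ref_rev) {
  vapply(seq_along(t_alt_fwd), function(i) {
    tab <- matrix(c(t_alt_fwd[i], t_alt_rev[i],
                    t_ref_fwd[i], t_ref_rev[i]), 2, 2, byrow = TRUE)
    if (sum(tab) == 0) return(1)
    fisher.test(tab)$p.value
  }, numeric(1))
}

#' Full seven-rule somatic filter cascade
#'
#' Applies the hard filters, then the cohort-wide tumor-enrichment test
#' (BH family = all records surviving rules 1--5 in the cohort), then
#' the strand-bias test, and records the per-rule outcomes and the final
#' verdict.
#'
#' @inheritParams apply_hard_filters
#' @inheritParams tumor_enrichment_test
#' @param strand_p_keep Keep threshold for the strand-bias P value.
#' @return A filter report: `records` plus per-rule columns, `strand_p`,
#'   `rule7` and logical `pass`.
#' @export
filter_somatic <- function(records, p_cut = 0.05, q_cut = 0.1,
                           strand_p_keep = 1e-4) {
  rep0 <- apply_hard_filters(records)
  rep0$enrich_p <- NA_real_
  rep0$enrich_q <- NA_real_
  rep0$rule6 <- FALSE
  surv <- which(rep0$pass_hard)
  if (length(surv)) {
    t6 <- tumor_enrichment_test(rep0[surv, , drop = FALSE], p_cut, q_cut)
    rep0$enrich_p[surv] <- t6$enrich_p
    rep0$enrich_q[surv] <- t6$enrich_q
    rep0$rule6[surv] <- t6$rule6
  }
  rep0$strand_p <- strand_bias_test(rep0$t_alt_fwd, rep0$t_alt_rev,
                                    rep0$t_ref_fwd, rep0$t_ref_rev)
  rep0$rule7 <- rep0$strand_p > strand_p_keep
  rep0$pass <- rep0$pass_hard & rep0$rule6 & rep0$rule7
  rep0
}

#' Cohort-level summary of filtered somatic mutations
#'
#' Summarizes the filtered calls per tissue-preservation class:
#' counts per consequence class, the low allele-fraction share
#' (tumor AF < `low_af`), per-Mb mutation rates for a configurable
#' target size, and fresh-frozen versus FFPE 2x2 comparisons by
#' Yates-continuity-corrected chi-square (the uncorrected P is also
#' reported).
#'
#' @param records Filtered (passing) variant records.
#' @param sample_ffpe Named logical vector: `TRUE` for FFPE samples.
#' @param target_mb Capture target size in Mb for per-Mb rates.
#' @param low_af Low allele-fraction threshold.
#' @return List with `class_counts`, `low_af_fraction`, `rate_per_mb`
#'   (per class), and `comparisons` (a data frame of 2x2 tests).
#' @export
variant_cohort_summary <- function(records, sample_ffpe, target_mb = 35,
                                   low_af = 0.05) {
  if (!all(records$sample %in% names(sample_ffpe))) {
    stop("unknown sample label in records")
  }
  grp <- ifelse(sample_ffpe[records$sample], "FFPE", "FF")
  af <- records$t_alt / records$t_depth
  nonsyn <- records$consequence %in% c("nonsynonymous_snv", "indel")
  cls <- table(group = grp, consequence = records$consequence)
  lowtab <- table(group = grp, low = factor(af < low_af, c(TRUE, FALSE)))
  nstab <- table(group = grp, nonsyn = factor(nonsyn, c(TRUE, FALSE)))
  n_ffpe_samples <- sum(sample_ffpe)
  n_ff_samples <- sum(!sample_ffpe)
  per_group_n <- table(factor(grp, c("FF", "FFPE")))
  rate <- c(FF = unname(per_group_n["FF"]) / max(n_ff_samples, 1) / target_mb,
            FFPE = unname(per_group_n["FFPE"]) / max(n_ffpe_samples, 1) /
              target_mb)
  two_by_two <- function(tab, what) {
    if (nrow(tab) < 2 || any(rowSums(tab) == 0)) {
      return(data.frame(comparison = what, p_yates = NA, p_uncorrected = NA))
    }
    data.frame(comparison = what,
               p_yates = suppressWarnings(chisq.test(tab)$p.value),
               p_uncorrected = suppressWarnings(
                 chisq.test(tab, correct = FALSE)$p.value))
  }
  comparisons <- rbind(
    two_by_two(lowtab, "low_af_fraction_FF_vs_FFPE"),
    two_by_two(nstab, "nonsynonymous_fraction_FF_vs_FFPE"))
  list(class_counts = cls,
       low_af_fraction = prop.table(lowtab, 1)[, "TRUE"],
       rate_per_mb = rate,
       comparisons = comparisons)
}

#' Yates-corrected chi-square P for a 2x2 count table
#'
#' Convenience wrapper used for cross-group proportion comparisons;
#' returns both the continuity-corrected and uncorrected P values.
#'
#' @param tab 2x2 matrix of counts.
#' @return Named numeric vector `c(p_yates, p_uncorrected)`.
#' @export
yates_chisq <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  c(p_yates = suppressWarnings(chisq.test(tab)$p.value),
    p_uncorrected = suppressWarnings(chisq.test(tab, correct = FALSE)$p.value))
}

#' Mutation catalog over the 96 trinucleotide contexts
#'
#' Tabulates SNV records (those with a trinucleotide context) into
#' per-sample and pooled 96-context catalogs in the canonical ordering,
#' and reports substitution-class proportions. Indel records are
#' excluded; their count is returned.
#'
#' @param records Variant records with `tri_context`.
#' @return List with `catalog` (samples x 96 counts), `pooled`
#'   (length-96 counts), `class_proportions` (over the 6 substitution
#'   classes), `ct_proportion` (pooled C>T share) and `n_excluded`.
#' @export
spectrum96 <- function(records) {
  ctx <- contexts96()
  snv <- records[!is.na(records$tri_context), , drop = FALSE]
  n_excluded <- nrow(records) - nrow(snv)
  bad <- setdiff(unique(snv$tri_context), ctx)
  if (length(bad)) stop("unknown trinucleotide context: ", bad[1])
  samples <- unique(records$sample)
  catalog <- matrix(0L, length(samples), 96,
                    dimnames = list(samples, ctx))
  if (nrow(snv)) {
    tab <- table(factor(snv$sample, samples),
                 factor(snv$tri_context, ctx))
    catalog[rownames(tab), ] <- as.integer(tab)
  }
  pooled <- colSums(catalog)
  cls <- context_class(ctx)
  class_counts <- tapply(pooled, cls, sum)[SUBSTITUTIONS]
  total <- sum(pooled)
  props <- if (total > 0) class_counts / total else class_counts * NA
  list(catalog = catalog, pooled = pooled,
       class_proportions = props,
       ct_proportion = unname(props["C>T"]),
       n_excluded = n_excluded)
}
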