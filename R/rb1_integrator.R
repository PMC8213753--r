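#' Integrate mutation, copy-number, splice and IHC evidence for one sample
#'
#' Evidence accumulates into a mechanism set:
#' \itemize{
#'   \item any filtered somatic mutation in the gene: `somatic_mutation`;
#'   \item the exon-resolution deletion class maps to `exon_deletion` or
#'     `whole_gene_deletion`;
#'   \item any splice call: `splice_abnormality`;
#'   \item IHC negative: `protein_loss`;
#'   \item IHC positive with cytoplasmic-only localization:
#'     `mislocalization`;
#'   \item IHC positive together with an in-frame deletion/skipping that
#'     removes at least `epitope_min_codons` codons while leaving the
#'     last `epitope_exons` exons intact:
#'     `epitope_retaining_in_frame_deletion`.
#' }
#' A sample is `disrupted` iff its mechanism set is non-empty. A sample
#' with clean WES, positive nuclear IHC and no RNA assay is reported as
#' `not_disrupted_rna_unassayed`: its splice channel could not be
#' examined.
#'
#' @param mutations Filtered somatic variant records of this sample
#'   overlapping the gene (zero rows for none).
#' @param cnv_call Row of [call_rb1_cohort()] for this sample, or
#'   `NULL`.
#' @param splice_calls [call_splice_cohort()] rows for this sample
#'   (zero rows for none); `NULL` when RNA was not assayed.
#' @param ihc Single IHC record (`status`, `localization`), or `NULL`
#'   when not assayed.
#' @param exon_model Exon model (for the epitope-retention rule).
#' @param epitope_min_codons Minimum codons removed by an in-frame event
#'   for the epitope rule (default 100).
#' @param epitope_exons Number of 3'-terminal exons that must stay
#'   intact (default 2).
#' @return List with `mechanisms` (character vector), `status`, and
#'   `conflicts` (character vector of warnings).
#' @export
integrate_sample <- function(mutations, cnv_call, splice_calls, ihc,
                             exon_model = rb1_exon_model(),
                             epitope_min_codons = 100,
                             epitope_exons = 2) {
  assayed <- c(wes = !is.null(mutations) || !is.null(cnv_call),
               rna = !is.null(splice_calls),
               ihc = !is.null(ihc))
  if (!any(assayed)) stop("at least one evidence channel must be assayed")
  mech <- character()
  conflicts <- character()
  if (!is.null(mutations) && nrow(mutations)) mech <- c(mech, "somatic_mutation")
  del_class <- if (!is.null(cnv_call)) cnv_call$class else "none"
  if (del_class %in% c("exon_deletion", "whole_gene")) {
    mech <- c(mech, if (del_class == "whole_gene") "whole_gene_deletion"
              else "exon_deletion")
  }
  if (!is.null(splice_calls) && nrow(splice_calls)) {
    mech <- c(mech, "splice_abnormality")
  }
  n_exons <- nrow(exon_model)
  ihc_positive <- !is.null(ihc) && ihc$status == "positive"
  if (!is.null(ihc) && ihc$status == "negative") mech <- c(mech, "protein_loss")
  if (ihc_positive && identical(ihc$localization, "cytoplasmic")) {
    mech <- c(mech, "mislocalization")
  }
  if (ihc_positive) {
    # in-frame losses large enough to disable the protein yet retaining
    # the C-terminal antibody epitope explain a positive stain
    events <- list()
    if (!is.null(splice_calls) && nrow(splice_calls)) {
      sk <- splice_calls[splice_calls$class == "exon_skipping" &
                           splice_calls$frame == "in_frame", , drop = FALSE]
      events <- c(events, lapply(seq_len(nrow(sk)), function(i) {
        sk$skip_from[i]:sk$skip_to[i]
      }))
    }
    if (del_class == "exon_deletion" && !is.null(cnv_call) &&
        !is.na(cnv_call$first_exon)) {
      rng <- cnv_call$first_exon:cnv_call$last_exon
      if (frame_effect(rng, exon_model) == "in_frame") {
        events <- c(events, list(rng))
      }
    }
    for (rng in events) {
      codons <- sum(exon_model$coding_len[
        match(rng, exon_model$exon_index)]) / 3
      retains_tail <- max(rng) <= n_exons - epitope_exons
      if (codons >= epitope_min_codons && retains_tail) {
        mech <- c(mech, "epitope_retaining_in_frame_deletion")
        break
      }
    }
    if (del_class == "whole_gene") {
      conflicts <- c(conflicts,
                     "whole-gene deletion with positive IHC stain")
    }
  }
  mech <- unique(mech)
  status <- if (length(mech)) "disrupted"
  else if (ihc_positive && identical(ihc$localization, "nuclear") &&
           !assayed[["rna"]]) "not_disrupted_rna_unassayed"
  else "not_disrupted"
  list(mechanisms = mech, status = status, conflicts = conflicts)
}

# filtered somatic records hitting an exon of the gene
mutations_in_gene <- function(records, exon_model) {
  if (!nrow(records)) return(records)
  hit <- records$chrom == exon_model$chrom[1] &
    vapply(records$pos, function(p) {
      any(p >= exon_model$start & p <= exon_model$end)
    }, logical(1))
  records[hit, , drop = FALSE]
}

#' Integrate disruption evidence across a cohort
#'
#' Runs [integrate_sample()] for every sample, subsetting each evidence
#' table by sample identifier. RNA is considered unassayed for samples
#' listed in `rna_unassayed`.
#'
#' @param filtered_variants Passing variant records (cohort-wide).
#' @param cnv_calls [call_rb1_cohort()] output.
#' @param splice_calls [call_splice_cohort()] output.
#' @param ihc IHC table (`sample`, `status`, `localization`).
#' @param exon_model Exon model of the gene.
#' @param samples Sample identifiers to integrate (default: union of
#'   the evidence tables).
#' @param rna_unassayed Samples without RNA-seq.
#' @inheritParams integrate_sample
#' @return Data frame: `sample`, `status`, `mechanisms`
#'   (comma-collapsed), `n_mechanisms`, `conflict`.
#' @export
integrate_cohort <- function(filtered_variants, cnv_calls, splice_calls,
                             ihc, exon_model = rb1_exon_model(),
                             samples = NULL, rna_unassayed = character(),
                             epitope_min_codons = 100, epitope_exons = 2) {
  if (is.null(samples)) {
    samples <- sort(unique(c(filtered_variants$sample, cnv_calls$sample,
                             splice_calls$sample, ihc$sample)))
  }
  gene_muts <- mutations_in_gene(filtered_variants, exon_model)
  rows <- lapply(samples, function(s) {
    mut <- gene_muts[gene_muts$sample == s, , drop = FALSE]
    cnv <- cnv_calls[cnv_calls$sample == s, , drop = FALSE]
    spl <- if (s %in% rna_unassayed) NULL
    else splice_calls[splice_calls$sample == s, , drop = FALSE]
    ih <- ihc[ihc$sample == s, , drop = FALSE]
    res <- integrate_sample(
      mutations = mut,
      cnv_call = if (nrow(cnv)) cnv[1, ] else NULL,
      splice_calls = spl,
      ihc = if (nrow(ih)) ih[1, ] else NULL,
      exon_model = exon_model,
      epitope_min_codons = epitope_min_codons,
      epitope_exons = epitope_exons)
    data.frame(sample = s, status = res$status,
               mechanisms = paste(res$mechanisms, collapse = ","),
               n_mechanisms = length(res$mechanisms),
               conflict = length(res$conflicts) > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort summary of integrated disruption calls
#'
#' @param calls Output of [integrate_cohort()].
#' @return List with `fraction_disrupted`, `n_disrupted`, `n_samples`,
#'   `mechanism_counts` (samples carrying each mechanism) and
#'   `channel_discordance` (for each ordered channel pair, samples
#'   positive in A but negative in B).
#' @export
disruption_summary <- function(calls) {
  stopifnot(nrow(calls) >= 1)
  mech_list <- strsplit(calls$mechanisms, ",", fixed = TRUE)
  all_mech <- c("somatic_mutation", "exon_deletion", "whole_gene_deletion",
                "splice_abnormality", "protein_loss",
                "epitope_retaining_in_frame_deletion", "mislocalization")
  counts <- vapply(all_mech, function(m) {
    sum(vapply(mech_list, function(v) m %in% v, logical(1)))
  }, numeric(1))
  channel <- function(v, members) any(members %in% v)
  channels <- list(
    wes = c("somatic_mutation", "exon_deletion", "whole_gene_deletion"),
    rna = "splice_abnormality",
    ihc = c("protein_loss", "mislocalization",
            "epitope_retaining_in_frame_deletion"))
  pos <- matrix(unlist(lapply(channels, function(mem) {
    vapply(mech_list, channel, logical(1), members = mem)
  })), ncol = length(channels), dimnames = list(NULL, names(channels)))
  disc <- matrix(0L, 3, 3, dimnames = list(names(channels), names(channels)))
  for (a in 1:3) for (b in 1:3) disc[a, b] <- sum(pos[, a] & !pos[, b])
  n_dis <- sum(calls$status == "disrupted")
  list(fraction_disrupted = n_dis / nrow(calls),
       n_disrupted = n_dis, n_samples = nrow(calls),
       mechanism_counts = counts,
       channel_discordance = disc)
}

#' Cross-cohort disruption-frequency report
#'
#' Two-sided Fisher comparisons of this cohort's disruption frequency
#' against literature frequencies supplied as counts.
#'
#' @param k,n Disrupted count and size of the present cohort.
#' @param comparisons Data frame with `label`, `k`, `n` of the
#'   comparison cohorts (printed literature values supplied by the
#'   caller).
#' @return `comparisons` with `p` (Fisher two-sided) appended.
#' @export
gene_disruption_report <- function(k, n, comparisons) {
  comparisons$p <- vapply(seq_len(nrow(comparisons)), function(i) {
    cross_cohort_fisher(k, n, comparisons$k[i], comparisons$n[i])
  }, numeric(1))
  comparisons
}
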