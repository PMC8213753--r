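#' Copies implied by a log2 coverage ratio
#'
#' For a diploid reference, `copies = 2 * 2^log2`; `copies(0) = 2`,
#' `copies(1) = 4`, and the calling thresholds `0.807` and `-2.0`
#' correspond to 3.5 and 0.5 copies.
#'
#' @param log2ratio Numeric vector of log2 tumor/reference ratios.
#' @return Numeric vector of copy numbers.
#' @export
copies_from_log2 <- function(log2ratio) 2 * 2^log2ratio

#' Discard unusable coverage bins
#'
#' Bins with log2 ratio below -15 are read-count dropouts and are
#' discarded before segmentation (strictly below: a bin at exactly -15
#' is retained). Non-finite bins are also dropped.
#'
#' @param bins Data frame with columns `sample`, `chrom`, `start`,
#'   `end`, `log2`.
#' @param floor Discard threshold.
#' @return Cleaned bins; the number of removals is attached as
#'   `attr(, "n_removed")`.
#' @export
clean_bins <- function(bins, floor = -15) {
  keep <- is.finite(bins$log2) & bins$log2 >= floor
  out <- bins[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Segment bins by rounded copy state
#'
#' Each bin is discretized to `copy_state = round(2 * 2^log2)`, clamped
#' at zero; maximal runs of adjacent bins (same sample and chromosome)
#' with equal copy state are merged into segments whose log2 is the mean
#' of the member bins.
#'
#' @inheritParams clean_bins
#' @return Data frame of segments: `sample`, `chrom`, `start`, `end`,
#'   `log2`, `n_bins`, `copy_state`.
#' @export
segment_bins <- function(bins) {
  if (!nrow(bins)) {
    return(data.frame(sample = character(), chrom = character(),
                      start = integer(), end = integer(), log2 = numeric(),
                      n_bins = integer(), copy_state = integer(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(bins$sample, bins$chrom, bins$start)
  if (!identical(ord, seq_len(nrow(bins)))) {
    warning("bins were not sorted; sorting by sample, chrom, start")
    bins <- bins[ord, , drop = FALSE]
  }
  state <- pmax(0, round(2 * 2^bins$log2))
  key <- paste(bins$sample, bins$chrom, sep = "\r")
  grp <- cumsum(c(TRUE, state[-1] != state[-length(state)] |
                    key[-1] != key[-length(key)]))
  out <- data.frame(
    sample = tapply(bins$sample, grp, `[`, 1),
    chrom = tapply(bins$chrom, grp, `[`, 1),
    start = as.integer(tapply(bins$start, grp, min)),
    end = as.integer(tapply(bins$end, grp, max)),
    log2 = as.numeric(tapply(bins$log2, grp, mean)),
    n_bins = as.integer(tapply(bins$start, grp, length)),
    copy_state = as.integer(tapply(state, grp, `[`, 1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build the common-CNV reference set
#'
#' From a catalog of population CNVs, keep records with population
#' frequency strictly above `min_freq` observed in studies with sample
#' size at least `min_size`, split by type (gain/loss).
#'
#' @param common_cnvs Data frame with `chrom`, `start`, `end`,
#'   `type` (`"gain"`/`"loss"`), `frequency`, `size`.
#' @param min_freq Strict lower frequency bound (default 1%).
#' @param min_size Inclusive minimum study sample size (default 1000).
#' @return The retained records (the "refset").
#' @export
build_refset <- function(common_cnvs, min_freq = 0.01, min_size = 1000) {
  ok <- !is.na(common_cnvs$frequency) & !is.na(common_cnvs$size) &
    common_cnvs$frequency > min_freq & common_cnvs$size >= min_size
  n_bad <- sum(is.na(common_cnvs$frequency) | is.na(common_cnvs$size))
  out <- common_cnvs[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_bad
  out
}

#' Exclude segments matching common population CNVs
#'
#' Segments with log2 > 0.2 are compared to refset gains and segments
#' with log2 < -0.2 to refset losses; a segment is excluded iff some
#' refset record of the matching type overlaps it reciprocally by
#' strictly more than `min_reciprocal` of both lengths. Segments in
#' `[-0.2, 0.2]` are never filtered.
#'
#' @param segments Output of [segment_bins()].
#' @param refset Output of [build_refset()].
#' @param min_reciprocal Strict reciprocal-overlap bound (default 0.5).
#' @return Segments with the common-CNV matches removed; removals are
#'   attached as `attr(, "removed")`.
#' @export
filter_common <- function(segments, refset, min_reciprocal = 0.5) {
  if (!nrow(segments) || !nrow(refset)) {
    attr(segments, "removed") <- segments[0, , drop = FALSE]
    return(segments)
  }
  excluded <- logical(nrow(segments))
  for (ty in c("gain", "loss")) {
    seg_idx <- which(if (ty == "gain") segments$log2 > 0.2
                     else segments$log2 < -0.2)
    ref <- refset[refset$type == ty, , drop = FALSE]
    if (!length(seg_idx) || !nrow(ref)) next
    for (chr in unique(segments$chrom[seg_idx])) {
      si <- seg_idx[segments$chrom[seg_idx] == chr]
      ri <- which(ref$chrom == chr)
      if (!length(si) || !length(ri)) next
      sr <- IRanges::IRanges(segments$start[si], segments$end[si])
      rr <- IRanges::IRanges(ref$start[ri], ref$end[ri])
      hits <- IRanges::findOverlaps(sr, rr)
      if (!length(hits)) next
      ov <- IRanges::width(IRanges::pintersect(
        sr[S4Vectors::queryHits(hits)], rr[S4Vectors::subjectHits(hits)]))
      frac_seg <- ov / IRanges::width(sr[S4Vectors::queryHits(hits)])
      frac_ref <- ov / IRanges::width(rr[S4Vectors::subjectHits(hits)])
      bad <- frac_seg > min_reciprocal & frac_ref > min_reciprocal
      excluded[si[unique(S4Vectors::queryHits(hits)[bad])]] <- TRUE
    }
  }
  out <- segments[!excluded, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- segments[excluded, , drop = FALSE]
  out
}

#' Call amplifications and homozygous deletions from segments
#'
#' Stringent thresholds: amplification iff log2 > 0.807 (more than 3.5
#' copies), deletion iff log2 < -2.0 (fewer than 0.5 copies); both
#' strict. The implied copy number is reported.
#'
#' @param segments Common-CNV-filtered segments.
#' @param amp_log2,del_log2 Call thresholds.
#' @return Segments with `copies` and `call` (`amp`/`del`/`neutral`).
#' @export
call_scnv <- function(segments, amp_log2 = 0.807, del_log2 = -2) {
  segments$copies <- copies_from_log2(segments$log2)
  segments$call <- ifelse(segments$log2 > amp_log2, "amp",
                          ifelse(segments$log2 < del_log2, "del",
                                 "neutral"))
  segments
}

#' Classify a sample's RB1 deletion state at exon resolution
#'
#' Intersects the sample's deletion segments with the exon model:
#' `whole_gene` if every exon is hit, `exon_deletion` if some but not
#' all are, `none` otherwise. The reported length is the genomic span of
#' the union of deletion segments overlapping the gene, in kb.
#'
#' @param calls [call_scnv()] output for one sample.
#' @param exon_model Exon model of the target gene.
#' @return List with `class`, `affected_exons` (integer indices) and
#'   `length_kb`.
#' @export
classify_rb1 <- function(calls, exon_model) {
  exon_model <- validate_exon_model(exon_model)
  dels <- calls[calls$call == "del" &
                  calls$chrom == exon_model$chrom[1], , drop = FALSE]
  if (!nrow(dels)) {
    return(list(class = "none", affected_exons = integer(), length_kb = 0))
  }
  dr <- IRanges::reduce(IRanges::IRanges(dels$start, dels$end))
  er <- IRanges::IRanges(exon_model$start, exon_model$end)
  hit <- IRanges::overlapsAny(er, dr)
  affected <- exon_model$exon_index[hit]
  gene_span <- IRanges::IRanges(min(exon_model$start), max(exon_model$end))
  in_gene <- dr[IRanges::overlapsAny(dr, gene_span)]
  len_kb <- sum(IRanges::width(in_gene)) / 1000
  cls <- if (!length(affected)) "none"
  else if (length(affected) == nrow(exon_model)) "whole_gene"
  else "exon_deletion"
  list(class = cls, affected_exons = affected, length_kb = len_kb)
}

#' RB1 deletion calls for every sample in a bin table
#'
#' Convenience pipeline: clean, segment, (optionally) filter against a
#' refset, call, and classify per sample.
#'
#' @inheritParams clean_bins
#' @param exon_model Exon model of the target gene.
#' @param refset Optional common-CNV refset.
#' @return Data frame: `sample`, `class`, `first_exon`, `last_exon`,
#'   `n_exons`, `length_kb`.
#' @export
call_rb1_cohort <- function(bins, exon_model, refset = NULL) {
  bins <- clean_bins(bins)
  segs <- segment_bins(bins)
  if (!is.null(refset)) segs <- filter_common(segs, refset)
  segs <- call_scnv(segs)
  samples <- unique(bins$sample)
  out <- lapply(samples, function(s) {
    cl <- classify_rb1(segs[segs$sample == s, , drop = FALSE], exon_model)
    data.frame(sample = s, class = cl$class,
               first_exon = if (length(cl$affected_exons))
                 min(cl$affected_exons) else NA_integer_,
               last_exon = if (length(cl$affected_exons))
                 max(cl$affected_exons) else NA_integer_,
               n_exons = length(cl$affected_exons),
               length_kb = cl$length_kb, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hypergeometric mutual-exclusivity test
#'
#' Lower-tail hypergeometric probability of observing at most `overlap`
#' samples carrying both event A and event B, given `n_with_a` and
#' `n_with_b` carriers in a cohort of `n_cohort`.
#'
#' @param n_cohort Cohort size.
#' @param n_with_a,n_with_b Carriers of each event.
#' @param overlap Observed co-carriers.
#' @return Lower-tail P value, `P(X <= overlap)`.
#' @export
#' @examples
#' mutual_exclusivity_test(46, 16, 13, 0)  # ~0.00118
mutual_exclusivity_test <- function(n_cohort, n_with_a, n_with_b, overlap) {
  stopifnot(overlap <= min(n_with_a, n_with_b),
            max(n_with_a, n_with_b) <= n_cohort)
  phyper(overlap, n_with_a, n_cohort - n_with_a, n_with_b)
}

#' Two-sided Fisher comparison of event frequencies across cohorts
#'
#' @param k1,n1 Carriers and size of cohort 1.
#' @param k2,n2 Carriers and size of cohort 2.
#' @return Two-sided Fisher exact P value (sum of table probabilities
#'   not exceeding the observed one).
#' @export
#' @examples
#' cross_cohort_fisher(13, 46, 9, 110)  # ~0.002
cross_cohort_fisher <- function(k1, n1, k2, n2) {
  stopifnot(k1 <= n1, k2 <= n2)
  fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2, 2,
                     byrow = TRUE))$p.value
}
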