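mk_bins <- function(log2, sample = "T01", chrom = "chr1", width = 100L) {
  n <- length(log2)
  start <- seq(1L, by = width, length.out = n)
  data.frame(sample = rep(sample, n), chrom = rep(chrom, n), start = start,
             end = start + width - 1L, log2 = log2,
             stringsAsFactors = FALSE)
}

test_that("bin cleaning uses a strict dropout threshold", {
  b <- mk_bins(c(-15, -16, 0, NaN))
  out <- clean_bins(b)
  expect_equal(out$log2, c(-15, 0))
  expect_equal(attr(out, "n_removed"), 2)
  empty <- clean_bins(mk_bins(numeric(0)))
  expect_equal(nrow(empty), 0)
})

test_that("segmentation merges runs of equal rounded copy state", {
  s <- segment_bins(mk_bins(c(0.01, -0.02, 0.03)))
  expect_equal(nrow(s), 1)
  expect_equal(s$copy_state, 2L)
  expect_equal(s$n_bins, 3L)
  s2 <- segment_bins(mk_bins(c(0, -3.2, -3.4, 0)))
  expect_equal(nrow(s2), 3)
  expect_equal(s2$copy_state, c(2L, 0L, 2L))
  expect_equal(s2$log2[2], mean(c(-3.2, -3.4)))
  s3 <- segment_bins(mk_bins(0.1))
  expect_equal(nrow(s3), 1)
  expect_equal(s3$n_bins, 1L)
})

test_that("segmentation is idempotent on segment means", {
  b <- mk_bins(c(0.05, -0.1, 1.1, 1.2, -3.1, -3.3, 0))
  s <- segment_bins(b)
  again <- segment_bins(data.frame(sample = s$sample, chrom = s$chrom,
                                   start = s$start, end = s$end,
                                   log2 = s$log2, stringsAsFactors = FALSE))
  expect_equal(again$start, s$start)
  expect_equal(again$end, s$end)
  expect_equal(again$copy_state, s$copy_state)
})

test_that("copies are a monotone transform with fixed anchors", {
  expect_equal(copies_from_log2(0), 2)
  expect_equal(copies_from_log2(1), 4)
  x <- seq(-5, 3, by = 0.1)
  expect_true(all(diff(copies_from_log2(x)) > 0))
})

test_that("refset construction enforces strict frequency and size rules", {
  cnvs <- data.frame(chrom = "chr1", start = c(1, 1, 1, 1),
                     end = c(100, 100, 100, 100), type = "loss",
                     frequency = c(0.011, 0.01, 0.02, NA),
                     size = c(1000, 1500, 999, 1200))
  rs <- build_refset(cnvs)
  expect_equal(nrow(rs), 1)
  expect_equal(rs$frequency, 0.011)
  expect_equal(attr(rs, "n_skipped"), 1)
})

test_that("reciprocal-overlap filtering removes exact matches, keeps 50%", {
  seg <- data.frame(sample = "T01", chrom = "chr1", start = 100L,
                    end = 199L, log2 = -1.5, n_bins = 5L, copy_state = 1L,
                    stringsAsFactors = FALSE)
  ref_same <- data.frame(chrom = "chr1", start = 100L, end = 199L,
                         type = "loss", frequency = 0.05, size = 2000)
  expect_equal(nrow(filter_common(seg, ref_same)), 0)
  # exactly half reciprocal overlap is retained (strict >)
  ref_half <- data.frame(chrom = "chr1", start = 150L, end = 249L,
                         type = "loss", frequency = 0.05, size = 2000)
  expect_equal(nrow(filter_common(seg, ref_half)), 1)
  # near-neutral segments are never filtered
  seg_neu <- transform(seg, log2 = -0.1)
  expect_equal(nrow(filter_common(seg_neu, ref_same)), 1)
})

test_that("reciprocal-overlap filtering equals the brute-force oracle", {
  set.seed(99)
  n_seg <- 120
  start <- sample.int(5000, n_seg)
  segs <- data.frame(sample = "T01", chrom = "chr1", start = start,
                     end = start + sample.int(400, n_seg),
                     log2 = runif(n_seg, -3, 3), n_bins = 1L,
                     copy_state = 2L, stringsAsFactors = FALSE)
  rstart <- sample.int(5000, 40)
  refset <- data.frame(chrom = "chr1", start = rstart,
                       end = rstart + sample.int(400, 40),
                       type = sample(c("gain", "loss"), 40, replace = TRUE),
                       frequency = 0.05, size = 2000)
  got <- filter_common(segs, refset)
  # oracle: O(n*m) interval arithmetic from the definitions
  excl <- logical(n_seg)
  for (i in seq_len(n_seg)) {
    ty <- if (segs$log2[i] > 0.2) "gain" else if (segs$log2[i] < -0.2)
      "loss" else NA
    if (is.na(ty)) next
    for (j in which(refset$type == ty)) {
      ov <- min(segs$end[i], refset$end[j]) -
        max(segs$start[i], refset$start[j]) + 1
      if (ov <= 0) next
      ls <- segs$end[i] - segs$start[i] + 1
      lr <- refset$end[j] - refset$start[j] + 1
      if (ov / ls > 0.5 && ov / lr > 0.5) excl[i] <- TRUE
    }
  }
  expect_equal(got$start, segs$start[!excl])
})

test_that("amp/del calls use strict stringent thresholds", {
  segs <- mk_bins(c(0.807, 0.808, -2, -2.01, 0))
  segs$n_bins <- 1L
  segs$copy_state <- 2L
  calls <- call_scnv(segs)
  expect_equal(calls$call, c("neutral", "amp", "neutral", "del", "neutral"))
  expect_equal(calls$copies[1], 3.5, tolerance = 1e-3)
  expect_equal(calls$copies[3], 0.5)
  expect_equal(calls$copies[5], 2)
})

test_that("RB1 classification separates exon-level from whole-gene loss", {
  model <- rb1_exon_model()
  del_3_18 <- data.frame(sample = "T01", chrom = "chrS",
                         start = model$start[3], end = model$end[18],
                         log2 = -5, n_bins = 10L, copy_state = 0L,
                         copies = 0.06, call = "del",
                         stringsAsFactors = FALSE)
  cl <- classify_rb1(del_3_18, model)
  expect_equal(cl$class, "exon_deletion")
  expect_equal(cl$affected_exons, 3:18)
  expect_equal(cl$length_kb, (model$end[18] - model$start[3] + 1) / 1000)
  whole <- transform(del_3_18, start = model$start[1], end = model$end[27])
  expect_equal(classify_rb1(whole, model)$class, "whole_gene")
  none <- transform(del_3_18, call = "neutral")
  expect_equal(classify_rb1(none, model)$class, "none")
})

test_that("planted deletions are recovered at exon resolution", {
  hits <- 0; total <- 0; confusions <- 0
  for (s in 1:10) {
    mix <- c(mutation = 0L, exon_deletion = 6L, whole_gene_deletion = 1L,
             splice_only = 0L, protein_only = 0L, intact = 3L)
    spec <- cohort_spec(n_samples = 10, ffpe_fraction = 0, seed = 500 + s,
                        artifact_rate = 0, true_mut_rate = 0,
                        mechanism_mix = mix)
    cv <- generate_rb1_coverage(spec)
    calls <- call_rb1_cohort(cv$bins, rb1_exon_model())
    m <- merge(calls, cv$truth[, c("sample", "mechanism", "del_from",
                                   "del_to")])
    planted <- m$mechanism == "exon_deletion"
    total <- total + sum(planted)
    hits <- hits + sum(planted & m$class == "exon_deletion" &
                         m$first_exon == m$del_from &
                         m$last_exon == m$del_to)
    confusions <- confusions +
      sum(m$class == "whole_gene" & m$mechanism != "whole_gene_deletion") +
      sum(m$class == "exon_deletion" & m$mechanism == "whole_gene_deletion")
    expect_true(all(m$class[m$mechanism == "intact"] == "none"))
  }
  expect_gte(hits / total, 0.95)
  expect_equal(confusions, 0)
})

test_that("the exclusivity test is the lower hypergeometric tail", {
  expect_equal(mutual_exclusivity_test(46, 16, 13, 0), 0.001176813,
               tolerance = 1e-6)
  expect_equal(mutual_exclusivity_test(10, 4, 3, 3), 1)
  # exhaustive enumeration over all draws of 3 from 10
  draws <- combn(10, 3)
  carriers <- 1:4
  overlaps <- apply(draws, 2, function(d) length(intersect(d, carriers)))
  for (k in 0:3) {
    expect_equal(mutual_exclusivity_test(10, 4, 3, k),
                 mean(overlaps <= k), tolerance = 1e-12)
  }
})

test_that("cross-cohort Fisher comparisons behave as expected", {
  expect_equal(cross_cohort_fisher(13, 46, 9, 110), 0.002, tolerance = 0.01)
  expect_equal(cross_cohort_fisher(5, 10, 5, 10), 1)
  expect_equal(cross_cohort_fisher(3, 10, 6, 20), 1)
})
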