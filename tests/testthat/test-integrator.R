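model <- rb1_exon_model()

mut_record <- function(sample = "T01") {
  data.frame(sample = sample, chrom = "chrS", pos = model$start[8] + 5L,
             stringsAsFactors = FALSE)
}
cnv_row <- function(class = "exon_deletion", from = 3L, to = 18L) {
  data.frame(sample = "T01", class = class, first_exon = from,
             last_exon = to, n_exons = to - from + 1L, length_kb = 50,
             stringsAsFactors = FALSE)
}
splice_row <- function(class = "exon_skipping", from = 3L, to = 17L,
                       frame = "in_frame") {
  data.frame(sample = "T01", class = class, skip_from = from, skip_to = to,
             partner_gene = NA_character_, reads = 30L, frame = frame,
             stringsAsFactors = FALSE)
}
ihc_row <- function(status, localization = "na") {
  data.frame(sample = "T01", marker = "RB1", status = status,
             localization = localization, stringsAsFactors = FALSE)
}
no_mut <- mut_record()[0, ]

test_that("evidence channels accumulate into mechanism sets", {
  # exon deletion plus cytoplasmic-only positive stain
  r <- integrate_sample(no_mut, cnv_row(), splice_row()[0, ],
                        ihc_row("positive", "cytoplasmic"), model)
  expect_setequal(r$mechanisms, c("exon_deletion", "mislocalization"))
  expect_equal(r$status, "disrupted")
  # protein loss alone disrupts
  r2 <- integrate_sample(no_mut, cnv_row("none", NA, NA),
                         splice_row()[0, ], ihc_row("negative"), model)
  expect_equal(r2$mechanisms, "protein_loss")
  expect_equal(r2$status, "disrupted")
  # clean WES, positive nuclear stain, no RNA: flagged unassayed
  r3 <- integrate_sample(no_mut, cnv_row("none", NA, NA), NULL,
                         ihc_row("positive", "nuclear"), model)
  expect_equal(r3$status, "not_disrupted_rna_unassayed")
  expect_length(r3$mechanisms, 0)
  # same sample with RNA assayed and clean: plainly not disrupted
  r4 <- integrate_sample(no_mut, cnv_row("none", NA, NA),
                         splice_row()[0, ], ihc_row("positive", "nuclear"),
                         model)
  expect_equal(r4$status, "not_disrupted")
})

test_that("the epitope-retention rule needs in-frame size and a 3' tail", {
  # exons 3-17 in frame, 477 codons, tail retained: rule fires
  r <- integrate_sample(no_mut, cnv_row("none", NA, NA),
                        splice_row(from = 3L, to = 17L),
                        ihc_row("positive", "nuclear"), model)
  expect_true("epitope_retaining_in_frame_deletion" %in% r$mechanisms)
  # a small in-frame skipping (exons 9-11, 92 codons) does not
  r2 <- integrate_sample(no_mut, cnv_row("none", NA, NA),
                         splice_row(from = 9L, to = 11L),
                         ihc_row("positive", "nuclear"), model)
  expect_false("epitope_retaining_in_frame_deletion" %in% r2$mechanisms)
  # frameshift events never qualify
  r3 <- integrate_sample(no_mut, cnv_row("none", NA, NA),
                         splice_row(from = 3L, to = 18L,
                                    frame = "frameshift"),
                         ihc_row("positive", "nuclear"), model)
  expect_false("epitope_retaining_in_frame_deletion" %in% r3$mechanisms)
})

test_that("conflicting whole-gene deletion with positive stain warns", {
  r <- integrate_sample(no_mut, cnv_row("whole_gene", 1L, 27L),
                        splice_row()[0, ], ihc_row("positive", "nuclear"),
                        model)
  expect_gt(length(r$conflicts), 0)
  expect_equal(r$status, "disrupted")
  expect_error(integrate_sample(NULL, NULL, NULL, NULL), "at least one")
})

test_that("adding evidence never revokes a disruption call", {
  base_args <- list(mutations = no_mut, cnv_call = cnv_row("none", NA, NA),
                    splice_calls = splice_row()[0, ], ihc = NULL,
                    exon_model = model)
  additions <- list(
    mutations = mut_record(),
    cnv_call = cnv_row(),
    splice_calls = splice_row(),
    ihc = ihc_row("negative"))
  # every subset of added evidence keeps status at least as disrupted
  for (k in seq_along(additions)) {
    combos <- combn(names(additions), k, simplify = FALSE)
    for (cmb in combos) {
      args <- base_args
      for (nm in cmb) args[[nm]] <- additions[[nm]]
      r <- do.call(integrate_sample, args)
      expect_equal(r$status, "disrupted")
    }
  }
})

test_that("cohort integration reproduces the planted mechanism mix", {
  spec <- cohort_spec()  # the 46-sample default composition
  co <- generate_cohort(spec)
  rep <- filter_somatic(co$variants)
  cnv <- call_rb1_cohort(co$bins, model)
  tum <- co$junctions[!grepl("^N", co$junctions$sample), ]
  norm <- co$junctions[grepl("^N", co$junctions$sample), ]
  spl <- call_splice_cohort(tum, norm, model, list(partner_gene_model()),
                            exon_coverage = co$exon_coverage)
  truth <- co$truth
  calls <- integrate_cohort(rep[rep$pass, ], cnv, spl, co$ihc,
                            exon_model = model, samples = truth$sample,
                            rna_unassayed =
                              truth$sample[!truth$rna_assayed])
  s <- disruption_summary(calls)
  n_disrupted_truth <- sum(truth$mechanism != "intact")
  expect_equal(s$n_disrupted, n_disrupted_truth)
  expect_equal(s$fraction_disrupted, n_disrupted_truth / nrow(truth))
  # every planted mechanism is recovered in its own channel
  mapping <- c(mutation = "somatic_mutation",
               exon_deletion = "exon_deletion",
               whole_gene_deletion = "whole_gene_deletion",
               splice_only = "splice_abnormality",
               protein_only = "protein_loss")
  for (m in names(mapping)) {
    smp <- truth$sample[truth$mechanism == m]
    got <- vapply(smp, function(x) {
      mapping[[m]] %in% strsplit(calls$mechanisms[calls$sample == x],
                                 ",")[[1]]
    }, logical(1))
    expect_true(all(got), label = paste("mechanism recovered:", m))
  }
  # the intact RNA-unassayed sample is singled out
  expect_equal(calls$status[calls$sample %in%
                              truth$sample[truth$mechanism == "intact"]],
               "not_disrupted_rna_unassayed")
})

test_that("the disruption report wires through the Fisher comparison", {
  cmp <- data.frame(label = c("extreme", "identical", "exon-del"),
                    k = c(5, 45, 9), n = c(50, 46, 110))
  out <- gene_disruption_report(45, 46, cmp)
  expect_lt(out$p[1], 1e-10)
  expect_equal(out$p[2], 1)
  cmp2 <- data.frame(label = "sclc", k = 9, n = 110)
  expect_equal(gene_disruption_report(13, 46, cmp2)$p, 0.002,
               tolerance = 0.01)
})
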