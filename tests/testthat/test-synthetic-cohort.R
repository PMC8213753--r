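test_that("cohort_spec validates its inputs", {
  expect_error(cohort_spec(n_samples = -1), "non-negative")
  expect_error(cohort_spec(ffpe_fraction = 1.2), "ffpe_fraction")
  expect_error(cohort_spec(artifact_rate = -1), "rates")
  expect_error(cohort_spec(n_samples = 5,
                           mechanism_mix = c(mutation = 2L,
                                             exon_deletion = 0L,
                                             whole_gene_deletion = 0L,
                                             splice_only = 0L,
                                             protein_only = 0L,
                                             intact = 1L)),
               "sum to n_samples")
  mix <- c(mutation = 1.5, exon_deletion = 0, whole_gene_deletion = 0,
           splice_only = 0, protein_only = 0, intact = 0.5)
  expect_error(cohort_spec(n_samples = 2, mechanism_mix = mix), "integer")
})

test_that("an empty cohort yields empty tables and truth", {
  mix <- setNames(integer(6), c("mutation", "exon_deletion",
                                "whole_gene_deletion", "splice_only",
                                "protein_only", "intact"))
  spec <- cohort_spec(n_samples = 0, mechanism_mix = mix)
  v <- generate_variants(spec)
  expect_equal(nrow(v$variants), 0)
  expect_equal(nrow(v$truth), 0)
  expect_equal(nrow(cohort_plan(spec)), 0)
})

test_that("with no artifacts every emitted record is truth-true", {
  spec <- cohort_spec(n_samples = 6, ffpe_fraction = 0, artifact_rate = 0,
                      true_mut_rate = 30,
                      mechanism_mix = c(mutation = 2L, exon_deletion = 2L,
                                        whole_gene_deletion = 0L,
                                        splice_only = 1L, protein_only = 0L,
                                        intact = 1L))
  v <- generate_variants(spec)
  expect_true(all(v$truth$is_true))
  expect_gt(nrow(v$variants), 0)
})

test_that("FFPE samples carry a higher low-AF fraction than FF samples", {
  mix <- c(mutation = 2L, exon_deletion = 2L, whole_gene_deletion = 0L,
           splice_only = 2L, protein_only = 0L, intact = 0L)
  worse <- 0
  for (s in 1:10) {
    spec <- cohort_spec(n_samples = 6, ffpe_fraction = 0.5, seed = 100 + s,
                        artifact_rate = 20, true_mut_rate = 40,
                        mechanism_mix = mix)
    v <- generate_variants(spec)
    plan <- cohort_plan(spec)
    ffpe <- setNames(plan$ffpe, plan$sample)
    af <- v$variants$t_alt / v$variants$t_depth
    low <- af < 0.05
    grp <- ffpe[v$variants$sample]
    if (mean(low[grp]) > mean(low[!grp])) worse <- worse + 1
  }
  expect_equal(worse, 10)
})

test_that("generators are deterministic in the seed and vary across seeds", {
  spec <- small_spec()
  v1 <- generate_variants(spec)
  v2 <- generate_variants(spec)
  expect_identical(v1$variants, v2$variants)
  v3 <- generate_variants(small_spec(seed = 1L))
  expect_false(identical(v1$variants, v3$variants))
  c1 <- generate_rb1_coverage(spec)
  c2 <- generate_rb1_coverage(spec)
  expect_identical(c1$bins, c2$bins)
})

test_that("coverage generator plants deletions and respects noise", {
  spec <- small_spec()
  cv <- generate_rb1_coverage(spec, noise_sd = 0.2)
  plan <- cv$truth
  model <- rb1_exon_model()
  # intact sample: no bin beyond a 4-sd noise tail
  s_int <- plan$sample[plan$mechanism == "intact"][1]
  b_int <- cv$bins[cv$bins$sample == s_int, ]
  expect_true(all(abs(b_int$log2) < 4 * 0.2 + 1e-9 | b_int$log2 > -0.9))
  expect_true(all(b_int$log2 > -2))
  # deleted exon range sits at log2 <= -3 on average
  i <- which(plan$mechanism == "exon_deletion" & plan$del_from == 3 &
               plan$del_to == 18)[1]
  b <- cv$bins[cv$bins$sample == plan$sample[i], ]
  del_exons <- model[model$exon_index %in% 3:18, ]
  in_del <- vapply(seq_len(nrow(b)), function(k) {
    any(b$start[k] <= del_exons$end & b$end[k] >= del_exons$start)
  }, logical(1))
  expect_lte(mean(b$log2[in_del]), -3)
  expect_gt(mean(b$log2[!in_del]), -1)
  expect_error(generate_rb1_coverage(spec, del_log2 = -1), "del_log2")
})

test_that("junction generator emits planted events and clean controls", {
  spec <- small_spec()
  jn <- generate_junctions(spec)
  plan <- jn$truth
  model <- rb1_exon_model()
  canon <- annotated_junctions(model)
  # normals carry only canonical junctions
  norm <- jn$junctions[grepl("^N", jn$junctions$sample), ]
  key <- paste(norm$donor, norm$acceptor)
  expect_true(all(key %in% paste(canon$donor, canon$acceptor)))
  # a planted internal deletion yields its skipping junction >= 10 reads
  i <- which(plan$del_from == 3 & plan$del_to == 18)[1]
  tum <- jn$junctions[jn$junctions$sample == plan$sample[i], ]
  hit <- tum$donor == model$end[2] + 1 & tum$acceptor == model$start[19] - 1
  expect_true(any(hit))
  expect_gte(tum$reads[hit][1], 10)
  # the 5' deletion carries a junction ending in the partner gene
  j <- which(plan$splice_class == "gene_fusion")[1]
  pm <- partner_gene_model()
  fus <- jn$junctions[jn$junctions$sample == plan$sample[j], ]
  expect_true(any(fus$donor == pm$end[2] + 1))
  expect_error(generate_junctions(spec, partner_models = list()),
               "partner")
})

test_that("expression generator rejects overlapping programs", {
  expect_error(generate_expression(
    program_genes = list(A = c("X", "Y"), N = c("Y", "Z"))),
    "disjoint")
})

test_that("lineage TF expression separates the planted subtypes", {
  ex <- generate_expression(seed = 42)
  a <- ex$tpm["ASCL1", ex$metadata$subtype == "A"]
  n <- ex$tpm["ASCL1", ex$metadata$subtype == "N"]
  expect_lt(wilcox.test(a, n)$p.value, 1e-3)
  nd_a <- ex$tpm["NEUROD1", ex$metadata$subtype == "A"]
  nd_n <- ex$tpm["NEUROD1", ex$metadata$subtype == "N"]
  expect_lt(wilcox.test(nd_a, nd_n)$p.value, 1e-3)
  expect_gt(median(a) / median(n), 1)   # ASCL1 high in subtype A
  expect_gt(median(nd_n) / median(nd_a), 1)  # NEUROD1 high in subtype N
})

test_that("catalog generator follows its exposure mixture", {
  ref <- synthetic_reference_signatures(5)
  # single signature at exposure 1: empirical cosine ~ 1
  expo <- matrix(c(1, 0, 0, 0, 0), 1)
  cat1 <- generate_catalogs(ref, expo, 10000, seed = 3)
  expect_gte(cosine_sim(cat1[1, ], ref[1, ]), 0.99)
  # zero mutations: all-zero catalog
  cat0 <- generate_catalogs(ref, expo, 0, seed = 3)
  expect_true(all(cat0 == 0))
  expect_error(generate_catalogs(ref, -expo, 10), "non-negative")
  expect_error(generate_catalogs(ref * 2, expo, 10), "sum to 1")
})

test_that("generated tables round-trip through the TSV readers", {
  spec <- small_spec()
  co <- generate_cohort(spec, outdir = tempdir())
  v <- read_tsv(file.path(tempdir(), "variants.tsv"))
  expect_equal(v, co$variants)
  j <- read_tsv(file.path(tempdir(), "junctions.tsv"))
  expect_equal(j, co$junctions)
  i <- read_tsv(file.path(tempdir(), "ihc.tsv"))
  expect_equal(i, co$ihc)
})
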