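# rb1x — integrative multi-omics analysis of RB1 disruption in small cell carcinoma

Small cell carcinomas — of the lung and, more rarely, of the esophagus —
disable the retinoblastoma tumor suppressor *RB1* nearly universally, but
through a mixture of mechanisms that no single assay sees completely:
somatic point mutations and indels (WES), homozygous deletions that remove
*some but not all* exons of the locus (capture coverage), splice
abnormalities such as exon skipping, gene fusion and novel splice sites
(RNA-seq junction evidence), and protein-level loss or mislocalization
(IHC). `rb1x` implements each detection channel and their integration into
per-sample disruption calls, together with the cohort-level machinery used
around such an analysis:

- **Somatic filtering** — the seven-rule cascade for tumor/normal candidate
  calls: tumor depth ≥ 10, tumor alt reads ≥ 3, normal alt reads ≤ 2,
  population AF < 0.01, dbSNP-unless-COSMIC, a one-sided Fisher
  tumor-enrichment test (P < 0.05, BH q < 0.1 across the cohort), and a
  two-sided Fisher strand-bias test (keep if P > 1e-4); plus FF/FFPE
  cohort summaries and 96-context mutation spectra.
- **Exon-resolution CNV calling** — bin cleaning (log2 < −15 dropped),
  segmentation by rounded copy state (copies = 2·2^log2), common-CNV
  filtering by strict >50% reciprocal overlap against a population refset
  (frequency > 1%, study size ≥ 1000), stringent amp/del thresholds
  (log2 > 0.807 ⇔ >3.5 copies; log2 < −2 ⇔ <0.5 copies), and exon-level
  classification of deletions into `none` / `exon_deletion` / `whole_gene`.
- **Splice disruption** — canonical-junction derivation from exon models,
  abnormal-junction detection (≥10 supporting reads, absent from pooled
  normals), classification into exon skipping / gene fusion / new splice
  site, reading-frame effect, and a block-ratio scan for lost 3′-terminal
  exon expression.
- **Integration** — mechanism sets per sample (including the
  epitope-retaining in-frame deletion rule that explains IHC-positive
  tumors with large in-frame losses), cohort summaries, and cross-cohort
  Fisher comparisons; plus the hypergeometric mutual-exclusivity test.
- **Mutational signatures** — NMF by multiplicative updates on samples × 96
  catalogs, with K chosen by an explained-variance plateau rule combined
  with mean cosine similarity to a reference catalog.
- **Molecular subtyping** — quantile normalization, MAD gene selection,
  consensus clustering over subsampled hierarchical clusterings, Tukey-HSD
  signature genes (log2FC ≥ 2, P < 0.05, q < 0.1 against every other
  group), and subtype–SCNV Fisher association.
- **Tumor microenvironment** — ssGSEA and overall-expression (OE) scores,
  a Monte Carlo hypergeometric overlap test for T-cell-exclusion programs,
  two-way ANOVA on scores, and the CD8 inflamed/excluded/desert IHC rules.
- **Synthetic cohorts** — a generator that emits every input the pipeline
  consumes (variant, coverage-bin, junction, exon-coverage, IHC and
  expression tables) with planted ground truth, so the whole pipeline is
  testable without access-controlled patient data.

## Worked example

```r
library(rb1x)

spec <- cohort_spec()          # 46 tumors, 33 FFPE, planted mechanism mix
co   <- generate_cohort(spec)  # variants, bins, junctions, IHC + truth

rep  <- filter_somatic(co$variants)
cnv  <- call_rb1_cohort(co$bins, rb1_exon_model())
tum  <- co$junctions[!grepl("^N", co$junctions$sample), ]
norm <- co$junctions[grepl("^N", co$junctions$sample), ]
spl  <- call_splice_cohort(tum, norm, rb1_exon_model(),
                           list(partner_gene_model()),
                           exon_coverage = co$exon_coverage)
calls <- integrate_cohort(rep[rep$pass, ], cnv, spl, co$ihc,
                          samples = co$truth$sample,
                          rna_unassayed = co$truth$sample[!co$truth$rna_assayed])
summ <- disruption_summary(calls)
summ$n_disrupted; summ$n_samples
#> [1] 45
#> [1] 46
round(summ$mechanism_counts)
#>                    somatic_mutation                       exon_deletion
#>                                  16                                  13
#>                 whole_gene_deletion                  splice_abnormality
#>                                   1                                  24
#>                        protein_loss epitope_retaining_in_frame_deletion
#>                                  36                                   8
#>                     mislocalization
#>                                   1
```

45 of 46 samples are called disrupted: the planted composition (16
mutation, 13 exon-deletion, 1 whole-gene, 11 splice-only, 4 protein-only
samples) is recovered exactly, and the single intact tumor — IHC-positive
with no RNA assay — is reported as `not_disrupted_rna_unassayed`.
`protein_loss` exceeds its planted count because IHC negativity
legitimately co-occurs with most DNA-level mechanisms; per-sample
mechanism sets, not marginal counts, carry the evidence.

Cohort statistics work directly from counts:

```r
cross_cohort_fisher(13, 46, 9, 110)    # exon-deletion rate vs SCLC
#> [1] 0.001995789
mutual_exclusivity_test(46, 16, 13, 0) # deletions vs mutations
#> [1] 0.001176813
```

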