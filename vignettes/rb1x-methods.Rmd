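---
title: "Methods: integrative RB1-disruption analysis with rb1x"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative RB1-disruption analysis with rb1x}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rb1x)
```

# Scope and model

`rb1x` analyzes how a tumor-suppressor locus — modeled on *RB1*, with its
27 exons — is disrupted across a tumor cohort when four evidence channels
are available: candidate somatic variants with tumor/normal read counts,
capture-bin log2 coverage ratios, RNA-seq splice-junction tables, and IHC
protein staining. Each channel has its own calling rules; the integrator
accumulates per-sample mechanism sets and calls a sample disrupted when
the set is non-empty. The surrounding cohort machinery (mutational
signatures, consensus subtyping, immune scoring) operates on the same
tables.

The package ships a synthetic-cohort generator that emits every input
with planted ground truth. All tests and the acceptance script run
against these synthetic cohorts; nothing requires controlled-access
patient data.

# Somatic filtering

Candidate records pass seven rules. Rules 1–5 are pure per-record
predicates (tumor depth ≥ 10, tumor alt ≥ 3, normal alt ≤ 2, population
AF < 0.01, dbSNP-unless-COSMIC); they are order-independent, which the
tests assert by permutation. Rule 6 is a **one-sided** Fisher exact test
that the allele fraction is higher in tumor than in matched normal: the
requirement is directional (a tumor-depleted variant is not somatic
evidence), so a two-sided test would punish the wrong tail. BH correction
for rule 6 is computed across **all records surviving rules 1–5 in the
cohort** — the cascade is a single cohort-wide pass, and a per-sample
family would make a record's fate depend on how mutated its sample
happens to be. Rule 7 is a **two-sided** Fisher strand-bias test (keep
when P > 1e-4): bias in either direction is an artifact signature. An
all-zero strand table is degenerate and kept with P = 1.

2×2 cohort comparisons (FF vs FFPE proportions) use the
Yates-continuity-corrected chi-square, the default convention in standard
statistical environments for 2×2 count tables; the uncorrected value is
reported alongside. Per-Mb mutation rates divide by a configurable
capture size (default 35 Mb) because target sizes differ between kits.

# Exon-resolution copy-number calling

Bins below log2 −15 are read-count dropouts and are discarded (strictly
below; −15 itself is kept). Segmentation merges adjacent bins with equal
**rounded copy state**, `round(2 * 2^log2)` clamped at zero — a
deterministic operationalization of "bins with the same copy number" that
is idempotent and reproducible, where external segmentation algorithms
are not restatable from their descriptions. Segment log2 is the mean of
member bins.

Common population CNVs are removed before calling: segments with
log2 > 0.2 are compared against catalog gains, segments with log2 < −0.2
against losses, and a segment is excluded only on strict >50% reciprocal
overlap (both fractions). Near-neutral segments are never filtered. Calls
then use the stringent thresholds log2 > 0.807 (more than 3.5 copies) and
log2 < −2.0 (fewer than 0.5 copies), both strict, so the threshold values
themselves are not calls.

Deletion segments intersected with the exon model classify each sample as
`none`, `exon_deletion` (some but not all exons) or `whole_gene`.
Reported breakpoints are bin-resolution interval bounds; nucleotide-level
breakpoint refinement is a wet-lab task outside software scope. The
mutual-exclusivity test between deletions and mutations is the lower
hypergeometric tail `P(X ≤ overlap)`; by default the exon-level deletions
are the draw set (whether a whole-gene deletion belongs in the draw is a
judgment call — both margins are easily computed).

# Splice disruption

Junctions use the intron-boundary convention (donor = first intronic
base, acceptor = last intronic base, genomic plus strand), which matches
common aligner outputs and makes comparison with the canonical set exact.
A junction is abnormal iff non-canonical, supported by ≥ 10 reads, and
absent from pooled normal controls (presence in a normal needs ≥ 1 read
by default). The read gate is the one hard numeric rule of this channel;
detection is otherwise a deterministic replacement for manual sashimi
inspection.

Classification is geometric: both ends at annotated boundaries of
non-adjacent exons of one gene → exon skipping (skipped set = exons
strictly between, frame effect = summed coding length mod 3); ends in two
gene bodies → fusion; exactly one annotated end → new splice site;
otherwise unclassified with a warning. The classes partition the abnormal
set.

Loss of 3′-terminal expression has no published quantitative rule, so the
package declares one: scan every split point of the exon sequence and
flag when the trailing block's mean coverage falls below `theta = 0.1`
times the preceding block's. A locus whose maximal exon coverage is below
`min_upstream = 5` is essentially unexpressed (e.g. whole-gene deletion)
and is "not evaluable" rather than flagged. Both constants are arguments.

# Integration

Mechanisms accumulate monotonically — adding evidence can never revoke a
disruption call, which the tests assert over all evidence subsets. Two
rules deserve comment:

* **Epitope-retaining in-frame deletion.** An IHC-positive tumor with an
  in-frame deletion or skipping that removes ≥ 100 codons while leaving
  the last two exons (the C-terminal antibody epitope) intact is called
  disrupted through this mechanism: enough protein is made to stain, but
  the product lacks a functionally essential region. The 100-codon floor
  sits below the smallest such event the generator plants (121 codons)
  and well above small in-frame losses of uncertain effect; both the
  floor and the number of protected terminal exons are arguments.
* **RNA-unassayed intact samples.** A sample with clean WES, positive
  nuclear staining and no RNA assay is `not_disrupted_rna_unassayed`:
  it is counted in the denominator as not disrupted, with the flag
  recording that its splice channel was never examined.

All somatic mutations in the gene count as disrupting evidence (a
configurable restriction to truncating variants is available via the
filtered input the caller supplies).

# Mutational signatures

Catalogs are samples × 96 counts in the canonical context ordering
(substitution class major, then 5′ and 3′ base). NMF minimizes the
Frobenius reconstruction error by multiplicative updates (at most 2000
iterations, relative-change tolerance 1e-6), taking the best of
`n_restarts = 50` uniform random initializations (tests and the
acceptance script use 10 restarts at their problem sizes). The error
trace of the winning restart is returned so monotone descent can be
asserted per iteration. Signatures are row-normalized; explained variance
is `1 − ||X − WH||²/||X||²`.

K selection records, per candidate K, the explained variance and the mean
cosine of each extracted signature to its best reference match. "No
remarkable increase" is operationalized as: K is a plateau candidate iff
every later marginal explained-variance gain in the range is below
`epsilon = 0.005`. The largest K in the range cannot demonstrate a
plateau and is never a candidate. Among candidates the mean cosine
decides; when no plateau exists in the range (typical for sparse
catalogs, where NMF keeps absorbing multinomial noise), the selector
falls back to the global cosine maximum with a warning. The reference
catalog is an input matrix; a synthetic five-signature reference
(`synthetic_reference_signatures()`, sparse near-orthogonal rows with a
deamination-like first signature) serves the tests so no download is
needed, and any curated catalog on the same 96 ordering can be dropped
in.

# Consensus subtyping

Multi-cohort matrices are inner-joined, quantile-normalized (reference =
mean of sorted columns), restricted to the top half by average
expression, and log2(x+1)-transformed. Within-cohort analysis keeps genes
with mean ≥ 5 TPM (inclusive). The top-G genes by MAD (unscaled
`median(|x − median|)`) are median-centered; ties at rank G break by gene
identifier so selection is deterministic.

The base clusterer is average-linkage hierarchical clustering on
1 − Pearson correlation — the common default of consensus-clustering
packages, here stated explicitly since the choice is otherwise
unreported. Each of `reps` replicates subsamples 80% of samples without
replacement; consensus(i, j) is the co-clustering count over the
co-sampling count; final assignments come from hierarchical clustering of
1 − consensus. The CDF of consensus entries and its area are returned,
and the default elbow rule picks the largest N whose area gain is
≥ 0.025 — a deterministic stand-in for manual inspection of tracking
plots, with the full trace emitted for human review. Indistinguishable
samples (all pairwise distances zero) are placed in one cluster rather
than split arbitrarily.

Signature genes require log2FC ≥ 2, Tukey-adjusted P < 0.05 and
per-contrast BH q < 0.1 against **every** other group. Small outlier
clusters can be excluded from contrasts via `min_group`. SCNV–subtype
association tests only events carried by ≥ 3 samples, by two-sided Fisher
with BH across events.

# Tumor microenvironment

ssGSEA follows the rank-weighted running-sum formulation with
`alpha = 0.25` and range normalization across the score matrix; scores
are rank-based and therefore invariant to monotone within-sample
transforms. The OE score centers genes, bins them into 50 equal-size
average-expression bins, and subtracts the mean of 100 bin-matched random
gene sets from the set mean; with many draws this converges to the
closed-form bin-mean subtraction, which the tests verify. Both bin count
and draw count are arguments, as the cited conventions vary.

The exclusion-program overlap test draws L genes uniformly without
replacement from the expressed-gene universe, counts the overlap with the
downregulated-DEG target set, repeats 100,000 times under each of three
seeds, and reports the maximal empirical P together with the exact
hypergeometric upper tail as a cross-check. The two-way ANOVA on immune
scores fits main effects only (organ, histology) with type-II sums of
squares — one df per two-level factor; constant scores return P = 1 by
convention. The CD8 phenotype rules are total: inflamed (≥ 10 positive
cells in ≥ 3 of 10 parenchymal fields; ≥ 6 of 20 for large tumors), else
excluded (same rule at the invasive margin), else desert.

# The synthetic cohort

The generator's defaults are the study conditions the package is built
around: 46 tumors, 33 of them FFPE, and a single planted mechanism per
sample — 16 mutation, 13 exon-deletion, 1 whole-gene deletion, 11
splice-only, 4 protein-only, 1 intact (the intact tumor is RNA-unassayed,
mirroring the one such case a real cohort contained). The mechanism mix
must be disjoint for truth attribution, so the splice-only count absorbs
the samples that in reality carry overlapping evidence.

Channel models, chosen once from the stated contracts:

* True somatic AF ~ Beta(2, 4) (median ≈ 0.31, within the typical
  0.2–0.4 clonal band for impure tumors); tumor depth ~ Poisson(200),
  normal alt reads ~ Binomial(depth, 0.001); about 5% of true somatics
  are dbSNP+COSMIC hotspot alleles. FFPE samples add C>T artifacts with
  AF ~ 0.05·Beta(2, 5) (median ≈ 0.013, all below 0.05), fully
  strand-biased and tumor-only — the fixation-artifact profile.
* Coverage noise is Gaussian on the log2 scale (sd 0.2), matching how
  ratio data are modeled downstream; deleted bins sit at −5, i.e.
  essentially zero copies. Capture bins tile exons at ≤ 120 bp.
* Planted deletion geometries include the recurrent real-world patterns:
  a frame-shifting internal deletion (exons 3–18), a 5′ deletion fused
  in-frame to an upstream partner gene (exons 1–17, protein mislocalized),
  a 3′-terminal deletion (exons 20–27), and a short in-frame,
  epitope-retaining deletion (exons 14–17). The exon model's coding
  lengths are built so these events have their textbook coding
  consequences (477 / 499 / 121 codons; 3–18 frameshifts).
* Junction tables carry canonical junctions over retained exons
  (~Poisson(60) reads), planted abnormal junctions at 10–200 reads, and
  matched normals with canonical junctions only. Per-exon mRNA coverage
  supports terminal-loss detection.
* Expression: log-normal background over 1000 genes plus two disjoint
  40-gene lineage programs (containing ASCL1 and NEUROD1) up-shifted by
  3 log2 units in their own subtype, 29 + 9 samples; an amplification
  flag is drawn at rates 0.17 / 0.56 per subtype.
* Mutation catalogs are multinomial draws from exposure-weighted
  mixtures of reference signatures.

What the generator does **not** emulate — and hence what green tests do
not demonstrate about real data: subclonal structure and purity variation
in AFs, GC/mappability coverage waves and noisy FFPE segmentation
backgrounds, alignment-level junction artifacts, germline CNV
backgrounds, batch effects beyond what quantile normalization removes,
and inter-channel contradictions other than the modeled ones. The
recovery metrics are clean-room upper bounds, not field performance.

# Numerical choices and problem sizes

Default seed 20210618; every stochastic operation takes an explicit seed,
and identical seeds reproduce outputs exactly. NMF initializes uniformly
on (1e-3, 1) and guards denominators with machine epsilon. The test suite
and acceptance script use desk-scale sizes chosen to exercise each
property: 46-sample cohorts for integration, ten replicate cohorts for
deletion sensitivity, 200 samples × 100 mutations × 5 signatures for NMF
recovery (K scanned over 2–8 with 10 restarts), 250–1000 consensus
replicates, 100,000 × 3 Monte Carlo draws for the overlap test, and
exhaustive enumeration (all C(20,5) draws, all C(8,4) rank-sum splits)
wherever a brute-force oracle is feasible.

# Interface

The exported functions are the interface; `scripts/acceptance.R` is a
worked end-to-end driver, and table I/O uses plain TSV via
`read_tsv()`/`write_tsv()` so every artifact is inspectable. A shell CLI
would add nothing over `Rscript` for an analysis package of this shape.

# Known limitations

Single target gene per integration run; no purity/ploidy correction or
allele-specific copy number; no de-novo + refit hybrid signature
extraction; consensus clustering recomputes base clusterings per N rather
than caching across the range; the Tukey-HSD scan fits one ANOVA per gene
and is O(genes × groups²). None of these affect the package's intended
desk scale.
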