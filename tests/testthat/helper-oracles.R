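# Independent brute-force oracles used across test files. These follow
# the definitions directly (hypergeometric enumeration, manual BH) and
# share no code with the package implementation.

# one-sided (greater) Fisher exact P on [[a, b], [c, d]] by explicit
# hypergeometric tail summation over the first cell
enum_fisher_greater <- function(a, b, c, d) {
  m <- a + c            # first-column total
  n <- b + d
  k <- a + b            # first-row total
  lo <- max(0, k - n)
  hi <- min(k, m)
  sum(vapply(a:hi, function(x) dhyper(x, m, n, k), numeric(1)))
}

# two-sided Fisher exact P: sum of all table probabilities not
# exceeding the observed one (with a relative fudge for ties)
enum_fisher_twosided <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  lo <- max(0, k - n)
  hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n, k), numeric(1))
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# manual Benjamini-Hochberg step-up adjustment
bh_manual <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# record-by-record re-evaluation of the full seven-rule cascade,
# written from the rule definitions
brute_filter_oracle <- function(records, p_cut = 0.05, q_cut = 0.1,
                                strand_p_keep = 1e-4) {
  n <- nrow(records)
  hard <- logical(n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    hard[i] <- r$t_depth >= 10 && r$t_alt >= 3 && r$n_alt <= 2 &&
      r$pop_af_max < 0.01 && (!r$in_snp142 || r$in_cosmic)
  }
  enr_p <- rep(NA_real_, n)
  for (i in which(hard)) {
    r <- records[i, ]
    enr_p[i] <- enum_fisher_greater(r$t_alt, r$t_depth - r$t_alt,
                                    r$n_alt, r$n_depth - r$n_alt)
  }
  enr_q <- rep(NA_real_, n)
  enr_q[hard] <- bh_manual(enr_p[hard])
  strand_p <- numeric(n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    if (r$t_alt_fwd + r$t_alt_rev + r$t_ref_fwd + r$t_ref_rev == 0) {
      strand_p[i] <- 1
    } else {
      strand_p[i] <- enum_fisher_twosided(r$t_alt_fwd, r$t_alt_rev,
                                          r$t_ref_fwd, r$t_ref_rev)
    }
  }
  hard & !is.na(enr_p) & enr_p < p_cut & enr_q < q_cut &
    strand_p > strand_p_keep
}

# random variant-record table spanning the interesting regimes
random_records <- function(n, seed) {
  set.seed(seed)
  t_depth <- sample(5:300, n, replace = TRUE)
  t_alt <- rbinom(n, t_depth, runif(n, 0, 0.6))
  n_depth <- sample(5:150, n, replace = TRUE)
  n_alt <- rbinom(n, n_depth, runif(n, 0, 0.08))
  alt_fwd <- rbinom(n, t_alt, runif(n, 0.05, 0.95))
  ref <- t_depth - t_alt
  ref_fwd <- rbinom(n, ref, 0.5)
  data.frame(
    sample = sample(sprintf("T%02d", 1:5), n, replace = TRUE),
    chrom = "chrS", pos = sample.int(1e6, n), ref = "C", alt = "T",
    t_depth = t_depth, t_alt = t_alt, n_depth = n_depth, n_alt = n_alt,
    t_ref_fwd = ref_fwd, t_ref_rev = ref - ref_fwd,
    t_alt_fwd = alt_fwd, t_alt_rev = t_alt - alt_fwd,
    pop_af_max = ifelse(runif(n) < 0.15, runif(n, 0, 0.05), 0),
    in_snp142 = runif(n) < 0.2, in_cosmic = runif(n) < 0.15,
    consequence = sample(c("synonymous", "nonsynonymous_snv", "indel"),
                         n, replace = TRUE),
    tri_context = sample(contexts96(), n, replace = TRUE),
    stringsAsFactors = FALSE)
}

# tiny exon model for toy splice/CNV tests: widths are coding lengths
toy_model <- function(coding, gene = "TOY", tss = 1000L, intron = 500L) {
  start <- integer(length(coding))
  end <- integer(length(coding))
  pos <- tss
  for (i in seq_along(coding)) {
    start[i] <- pos
    end[i] <- pos + coding[i] - 1L
    pos <- end[i] + intron + 1L
  }
  data.frame(gene = gene, transcript = paste0(gene, "-1"),
             exon_index = seq_along(coding), chrom = "chrT",
             start = start, end = end, strand = "+", coding_len = coding,
             stringsAsFactors = FALSE)
}

# small cohort spec used where the full 46-sample default is not needed
small_spec <- function(seed = 20210618L,
                       mix = c(mutation = 3L, exon_deletion = 4L,
                               whole_gene_deletion = 1L, splice_only = 2L,
                               protein_only = 1L, intact = 1L)) {
  cohort_spec(n_samples = sum(mix), ffpe_fraction = 0.5, seed = seed,
              artifact_rate = 10, true_mut_rate = 20, mechanism_mix = mix)
}
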