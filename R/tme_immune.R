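#' Single-sample GSEA scores
#'
#' Per sample, genes are ranked by expression; a running-sum statistic
#' walks down the ranking, stepping up by the rank-normalized expression
#' weight `|r|^alpha` inside the gene set and down uniformly outside.
#' The raw score is the sum of the running-sum deviations over all
#' positions; scores are normalized by the range of raw scores across
#' all samples and sets.
#'
#' @param logmat Log-scale genes x samples expression matrix.
#' @param gene_sets Named list of character vectors.
#' @param alpha Rank weight exponent (default 0.25).
#' @param normalize Divide all scores by the absolute range across the
#'   score matrix (default TRUE).
#' @return Sets x samples score matrix. Sets with fewer than two genes
#'   in the matrix are skipped with a warning.
#' @export
ssgsea_scores <- function(logmat, gene_sets, alpha = 0.25,
                          normalize = TRUE) {
  genes <- rownames(logmat)
  keep <- vapply(gene_sets, function(s) sum(s %in% genes) >= 2, logical(1))
  if (any(!keep)) {
    warning("skipping gene sets with < 2 matched genes: ",
            paste(names(gene_sets)[!keep], collapse = ", "))
  }
  gene_sets <- gene_sets[keep]
  if (!length(gene_sets)) stop("no usable gene sets")
  n_g <- nrow(logmat)
  scores <- matrix(0, length(gene_sets), ncol(logmat),
                   dimnames = list(names(gene_sets), colnames(logmat)))
  for (j in seq_len(ncol(logmat))) {
    r <- rank(logmat[, j], ties.method = "average")
    ord <- order(r, decreasing = TRUE)  # walk from highest expression
    rw <- r[ord]^alpha
    for (si in seq_along(gene_sets)) {
      inset <- genes[ord] %in% gene_sets[[si]]
      step_up <- ifelse(inset, rw, 0)
      step_up <- step_up / sum(step_up)
      step_dn <- ifelse(inset, 0, 1 / (n_g - sum(inset)))
      scores[si, j] <- sum(cumsum(step_up) - cumsum(step_dn))
    }
  }
  if (normalize) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Overall-expression (OE) score of a gene set
#'
#' Genes are centered across samples, then grouped into `n_bins`
#' equal-size bins by average expression. The OE score of a sample is
#' the mean centered expression of the set genes minus the average of
#' the same quantity over `n_draws` random gene sets matched bin-for-bin
#' to the set's expression-bin profile, which removes the expression
#' -level bias of the set.
#'
#' @param logmat Log-scale genes x samples matrix.
#' @param gene_set Character vector of signature genes.
#' @param n_bins Expression bins (default 50).
#' @param n_draws Bin-matched random sets (default 100).
#' @param seed Integer seed.
#' @return Named numeric vector of per-sample OE scores.
#' @export
oe_score <- function(logmat, gene_set, n_bins = 50, n_draws = 100,
                     seed = 1L) {
  stopifnot(n_bins <= nrow(logmat))
  genes <- rownames(logmat)
  set_idx <- which(genes %in% gene_set)
  if (length(set_idx) < 1) stop("no set genes in matrix")
  centered <- logmat - rowMeans(logmat)
  avg <- rowMeans(logmat)
  bin <- ceiling(rank(avg, ties.method = "first") / (nrow(logmat) / n_bins))
  bin <- pmin(bin, n_bins)
  set_bins <- bin[set_idx]
  set.seed(seed)
  raw <- colMeans(centered[set_idx, , drop = FALSE])
  bg <- matrix(0, n_draws, ncol(logmat))
  by_bin <- split(seq_along(bin), bin)
  for (d in seq_len(n_draws)) {
    draw <- vapply(set_bins, function(b) {
      pool <- by_bin[[as.character(b)]]
      pool[sample.int(length(pool), 1)]
    }, integer(1))
    bg[d, ] <- colMeans(centered[draw, , drop = FALSE])
  }
  raw - colMeans(bg)
}

#' Monte Carlo overlap test for gene-set enrichment among DEGs
#'
#' Draws `draw_n` genes uniformly without replacement from a universe
#' of `universe_n` genes, `reps` times, counting how often the overlap
#' with a fixed target set of `target_n` genes reaches the observed
#' overlap `m`. The simulation is repeated with `n_seeds` seeds and the
#' maximal empirical P is reported, alongside the exact hypergeometric
#' upper tail as a cross-check.
#'
#' @param universe_n,target_n,draw_n,observed Test geometry.
#' @param reps Replicates per seed (default 100000).
#' @param n_seeds Seeds (default 3).
#' @param seed Base seed; run `s` uses `seed + s - 1`.
#' @return List with `p_max`, `p_per_seed`, `exact_tail` and the spec.
#' @export
#' @examples
#' overlap_mc_test(20, 8, 5, 4, reps = 2000, n_seeds = 2)
overlap_mc_test <- function(universe_n, target_n, draw_n, observed,
                            reps = 100000, n_seeds = 3, seed = 1L) {
  stopifnot(observed <= min(target_n, draw_n), draw_n <= universe_n,
            target_n <= universe_n)
  p_seed <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    set.seed(seed + s - 1L)
    hits <- 0L
    for (r in seq_len(reps)) {
      m <- sum(sample.int(universe_n, draw_n) <= target_n)
      if (m >= observed) hits <- hits + 1L
    }
    p_seed[s] <- hits / reps
  }
  list(p_max = max(p_seed), p_per_seed = p_seed,
       exact_tail = phyper(observed - 1, target_n,
                           universe_n - target_n, draw_n,
                           lower.tail = FALSE),
       universe_n = universe_n, target_n = target_n,
       draw_n = draw_n, observed = observed, reps = reps)
}

#' Two-way ANOVA of immune scores on organ and histology
#'
#' Main-effects-only two-way ANOVA with type-II sums of squares (each
#' factor tested after adjusting for the other), one degree of freedom
#' per two-level factor. Constant scores return F = 0, P = 1.
#'
#' @param scores Numeric vector of per-sample scores.
#' @param organ,histology Factors (>= 2 levels each).
#' @return Data frame: `factor`, `df`, `f`, `p`.
#' @export
score_anova <- function(scores, organ, histology) {
  organ <- droplevels(as.factor(organ))
  histology <- droplevels(as.factor(histology))
  stopifnot(nlevels(organ) >= 2, nlevels(histology) >= 2)
  if (sd(scores) == 0) {
    return(data.frame(factor = c("organ", "histology"),
                      df = c(nlevels(organ) - 1L, nlevels(histology) - 1L),
                      f = c(0, 0), p = c(1, 1), stringsAsFactors = FALSE))
  }
  fit <- lm(scores ~ organ + histology)
  a2 <- car::Anova(fit, type = 2)
  data.frame(factor = c("organ", "histology"),
             df = a2[c("organ", "histology"), "Df"],
             f = a2[c("organ", "histology"), "F value"],
             p = a2[c("organ", "histology"), "Pr(>F)"],
             stringsAsFactors = FALSE)
}

#' CD8 immune phenotype from high-power-field counts
#'
#' A tumor is `inflamed` when at least `min_fields` parenchymal fields
#' (6 of 20 for large tumors, 3 of 10 otherwise) contain at least
#' `min_cells` CD8-positive lymphocytes in direct tumor contact;
#' otherwise `excluded` when at least 3 of 10 invasive-margin fields do;
#' otherwise `desert`.
#'
#' @param parenchyma Counts per parenchymal field (10, or 20 when
#'   `large_tumor`).
#' @param margin Counts per invasive-margin field (10).
#' @param large_tumor Whether 20 parenchymal fields were scored.
#' @param min_cells Per-field positive-cell threshold (default 10).
#' @return `"inflamed"`, `"excluded"` or `"desert"`.
#' @export
#' @examples
#' cd8_phenotype(c(12, 11, 10, rep(0, 7)), rep(0, 10))  # inflamed
cd8_phenotype <- function(parenchyma, margin, large_tumor = FALSE,
                          min_cells = 10) {
  if (any(parenchyma < 0) || any(margin < 0)) stop("counts must be >= 0")
  expected <- if (large_tumor) 20L else 10L
  if (length(parenchyma) != expected) {
    stop("expected ", expected, " parenchymal fields")
  }
  if (length(margin) != 10L) stop("expected 10 margin fields")
  thresh <- if (large_tumor) 6L else 3L
  if (sum(parenchyma >= min_cells) >= thresh) return("inflamed")
  if (sum(margin >= min_cells) >= 3L) return("excluded")
  "desert"
}
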