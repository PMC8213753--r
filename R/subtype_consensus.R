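#' Quantile-normalize a combined expression matrix
#'
#' Forces every sample onto a common distribution: the reference is the
#' mean of the sorted columns, and each sample's values are replaced by
#' the reference values at their ranks. Rank order within each sample is
#' preserved.
#'
#' @param mat Genes x samples numeric matrix.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  limma::normalizeQuantiles(as.matrix(mat))
}

#' Combine and quantile-normalize multi-cohort expression matrices
#'
#' Inner-joins the cohorts on shared genes, quantile-normalizes across
#' all samples (reference distribution = mean of the sorted columns),
#' keeps genes whose average normalized expression ranks in the top
#' half, and log2(x + 1)-transforms.
#'
#' @param matrices Named list of genes x samples TPM matrices.
#' @return log2 matrix over the shared, highly expressed genes.
#' @export
preprocess_multicancer <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  genes <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(genes)) stop("no shared genes across cohorts")
  combined <- do.call(cbind, lapply(matrices, function(m) {
    m[genes, , drop = FALSE]
  }))
  qn <- quantile_normalize(combined)
  keep <- rowMeans(qn) >= median(rowMeans(qn))
  log2(qn[keep, , drop = FALSE] + 1)
}

#' Filter and log-transform a within-cohort TPM matrix
#'
#' Keeps genes with average expression of at least `min_tpm` TPM
#' (inclusive) and log2(x + 1)-transforms.
#'
#' @param tpm Genes x samples TPM matrix.
#' @param min_tpm Inclusive mean-TPM threshold (default 5).
#' @return Filtered log2 matrix.
#' @export
preprocess_within <- function(tpm, min_tpm = 5) {
  keep <- rowMeans(tpm) >= min_tpm
  log2(tpm[keep, , drop = FALSE] + 1)
}

#' Select the most variable genes by MAD and median-center them
#'
#' MAD is `median(|x - median(x)|)` per gene (unscaled). Ties at rank G
#' are broken by row-name order, so the selection is deterministic.
#'
#' @param logmat Log-scale genes x samples matrix.
#' @param g Number of genes to keep.
#' @return Median-centered top-`g` submatrix.
#' @export
mad_select <- function(logmat, g) {
  stopifnot(g <= nrow(logmat))
  m <- apply(logmat, 1, function(x) median(abs(x - median(x))))
  ord <- order(-m, rownames(logmat))
  top <- logmat[ord[seq_len(g)], , drop = FALSE]
  top - apply(top, 1, median)
}

# Pearson-dissimilarity hierarchical base clusterer; columns = samples
base_cluster <- function(mat, n, method = "average") {
  if (nrow(mat) < 2) {
    d <- dist(t(mat))
  } else {
    cc <- suppressWarnings(cor(mat))
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    d <- as.dist(1 - cc)
  }
  if (all(d < 1e-12)) return(rep(1L, ncol(mat)))  # indistinguishable
  cutree(hclust(d, method = method), k = n)
}

#' Consensus clustering by subsampled hierarchical clustering
#'
#' For each of `reps` replicates, a fraction `subsample_frac` of the
#' samples is drawn without replacement and clustered into `n` groups by
#' average-linkage hierarchical clustering on (1 - Pearson correlation).
#' The consensus between two samples is their co-clustering count over
#' their co-sampling count. Final assignments are obtained by
#' hierarchically clustering (1 - consensus). The empirical CDF of the
#' off-diagonal consensus entries and its area are returned so an
#' elbow over a range of `n` can be examined.
#'
#' @param mat Median-centered genes x samples matrix.
#' @param n_range Candidate numbers of clusters.
#' @param reps Replicates per `n` (default 1000).
#' @param subsample_frac Sample fraction per replicate (default 0.8).
#' @param seed Integer seed.
#' @param delta_min Elbow rule: chosen N is the largest whose gain in
#'   CDF area over N-1 is at least this value (default 0.025).
#' @return Object of class `"consensus_result"`: per-`n` list with
#'   `consensus` matrices and `assignments`, plus `cdf_area`,
#'   `delta_area` and `chosen_n`.
#' @export
consensus_cluster <- function(mat, n_range = 2:6, reps = 1000,
                              subsample_frac = 0.8, seed = 1L,
                              delta_min = 0.025) {
  if (reps < 1) stop("reps must be >= 1")
  n_s <- ncol(mat)
  stopifnot(all(n_range <= ceiling(n_s * subsample_frac)))
  samples <- colnames(mat) %||% paste0("S", seq_len(n_s))
  colnames(mat) <- samples
  per_n <- list()
  cdf_area <- numeric(length(n_range))
  set.seed(seed)
  draw_size <- max(2L, floor(n_s * subsample_frac))
  draws <- lapply(seq_len(reps), function(r) sort(sample.int(n_s, draw_size)))
  for (ni in seq_along(n_range)) {
    n <- n_range[ni]
    co <- matrix(0, n_s, n_s)
    tog <- matrix(0, n_s, n_s)
    for (r in seq_len(reps)) {
      idx <- draws[[r]]
      cl <- base_cluster(mat[, idx, drop = FALSE], n)
      same <- outer(cl, cl, `==`)
      co[idx, idx] <- co[idx, idx] + same
      tog[idx, idx] <- tog[idx, idx] + 1
    }
    cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
    diag(cons) <- 1
    dimnames(cons) <- list(samples, samples)
    assign_final <- cutree(hclust(as.dist(1 - cons), method = "average"),
                           k = n)
    vals <- cons[upper.tri(cons)]
    # area under the empirical CDF of consensus entries
    sv <- sort(vals)
    cdf_area[ni] <- if (length(sv)) mean(sapply(seq(0, 1, by = 0.01),
      function(t) mean(sv <= t))) else 0
    per_n[[as.character(n)]] <- list(consensus = cons,
                                     assignments = assign_final)
  }
  delta_area <- c(NA, diff(cdf_area))
  ok <- which(!is.na(delta_area) & delta_area >= delta_min)
  chosen <- if (length(ok)) n_range[max(ok)] else n_range[1]
  structure(list(per_n = per_n, n_range = n_range, cdf_area = cdf_area,
                 delta_area = delta_area, chosen_n = chosen),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result over N =", paste(x$n_range, collapse = ","),
      "; chosen N =", x$chosen_n, "\n")
  invisible(x)
}

#' Signature genes by one-way ANOVA with Tukey HSD contrasts
#'
#' For each gene, a one-way ANOVA across groups followed by Tukey HSD
#' pairwise contrasts. A gene is a signature gene of a group iff, against
#' EVERY other (eligible) group, its log2 fold change is at least
#' `lfc_min`, the Tukey-adjusted P is below `p_max`, and the
#' BH-corrected q (per contrast, across genes) is below `q_max`.
#' Groups with at most `min_group` samples are reported but excluded
#' from the contrasts (outlier clusters).
#'
#' @param logmat Log2 genes x samples matrix.
#' @param groups Group assignment per sample.
#' @param lfc_min,p_max,q_max Signature thresholds (defaults 2, 0.05,
#'   0.1).
#' @param min_group Groups of at most this size are excluded from the
#'   contrasts (default 0, i.e. keep all groups with at least two
#'   samples; set to 5 to drop small outlier clusters).
#' @return Data frame with one row per gene x group: `gene`, `group`,
#'   `min_lfc`, `max_p`, `max_q`, `signature`.
#' @export
signature_genes <- function(logmat, groups, lfc_min = 2, p_max = 0.05,
                            q_max = 0.1, min_group = 0) {
  groups <- as.character(groups)
  tab <- table(groups)
  eligible <- names(tab)[tab > max(min_group, 1)]
  if (length(eligible) < 2) stop("need >= 2 groups with > 1 sample each")
  keep <- groups %in% eligible
  sub <- logmat[, keep, drop = FALSE]
  g <- factor(groups[keep])
  genes <- rownames(sub) %||% paste0("g", seq_len(nrow(sub)))
  lv <- levels(g)
  pairs_of <- function(a) {
    # TukeyHSD labels contrasts "x-y" with x later in level order
    vapply(setdiff(lv, a), function(b) {
      if (which(lv == a) > which(lv == b)) paste0(a, "-", b)
      else paste0(b, "-", a)
    }, character(1))
  }
  sign_of <- function(a, lab) if (startsWith(lab, paste0(a, "-"))) 1 else -1

  res <- vector("list", nrow(sub))
  for (i in seq_len(nrow(sub))) {
    y <- sub[i, ]
    if (sd(y) == 0) next  # constant gene: leave NULL, never flagged
    fit <- aov(y ~ g)
    res[[i]] <- TukeyHSD(fit)$g
  }
  rows <- list()
  for (a in lv) {
    labs <- pairs_of(a)
    # per-contrast matrices: genes x contrasts
    lfc <- matrix(NA_real_, nrow(sub), length(labs),
                  dimnames = list(genes, labs))
    pmat <- lfc
    for (i in seq_len(nrow(sub))) {
      tk <- res[[i]]
      if (is.null(tk)) next
      for (j in seq_along(labs)) {
        lfc[i, j] <- sign_of(a, labs[j]) * tk[labs[j], "diff"]
        pmat[i, j] <- tk[labs[j], "p adj"]
      }
    }
    qmat <- apply(pmat, 2, p.adjust, method = "BH")
    if (is.null(dim(qmat))) qmat <- matrix(qmat, ncol = length(labs))
    flag <- rowSums(lfc >= lfc_min & pmat < p_max & qmat < q_max,
                    na.rm = TRUE) == length(labs) &
      !apply(is.na(pmat), 1, any)
    rows[[a]] <- data.frame(
      gene = genes, group = a,
      min_lfc = apply(lfc, 1, min),
      max_p = apply(pmat, 1, max),
      max_q = apply(qmat, 1, max),
      signature = flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Association of copy-number events with subtype assignment
#'
#' Only events present in at least `min_n` samples are tested; each is
#' compared between the two subtype groups by two-sided Fisher's exact
#' test, with BH correction across tested events.
#'
#' @param assignments Subtype label per sample (two levels).
#' @param flags Samples x events logical matrix (event present).
#' @param min_n Minimum carriers for an event to be tested (default 3).
#' @return Data frame: `event`, `n_carriers`, counts per group, `p`,
#'   `q`; zero rows if nothing is testable.
#' @export
subtype_scnv_association <- function(assignments, flags, min_n = 3) {
  assignments <- as.factor(assignments)
  stopifnot(nlevels(assignments) == 2)
  flags <- as.matrix(flags)
  testable <- colSums(flags) >= min_n
  events <- colnames(flags)[testable] %||% which(testable)
  rows <- lapply(which(testable), function(j) {
    tab <- table(carrier = factor(flags[, j], c(TRUE, FALSE)), assignments)
    data.frame(event = colnames(flags)[j],
               n_carriers = sum(flags[, j]),
               k1 = tab[1, 1], n1 = sum(tab[, 1]),
               k2 = tab[1, 2], n2 = sum(tab[, 2]),
               p = fisher.test(tab)$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out)) {
    return(data.frame(event = character(), n_carriers = integer(),
                      k1 = integer(), n1 = integer(), k2 = integer(),
                      n2 = integer(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
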