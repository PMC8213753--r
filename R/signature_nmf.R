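#' Extract mutational signatures by NMF
#'
#' Factorizes a samples x 96 mutation catalog `X ~ W H` (`W`: samples x
#' K exposures, `H`: K x 96 signatures) by multiplicative updates
#' minimizing the Frobenius reconstruction error, taking the best of
#' `n_restarts` random initializations. Signatures are row-normalized to
#' sum to 1 and exposures rescaled accordingly. Explained variance is
#' `1 - ||X - WH||^2_F / ||X||^2_F`.
#'
#' @param catalog Samples x 96 non-negative matrix.
#' @param k Number of signatures (>= 1).
#' @param n_restarts Random restarts (default 50).
#' @param seed Integer seed.
#' @param max_iter Maximum multiplicative updates per restart.
#' @param tol Relative-change convergence tolerance on the error.
#' @return Object of class `"signature_solution"`: list with
#'   `signatures` (K x 96, rows sum to 1), `exposures` (samples x K),
#'   `explained_variance`, `error_trace` (per-iteration errors of the
#'   winning restart) and `k`.
#' @export
nmf_decompose <- function(catalog, k, n_restarts = 50, seed = 1L,
                          max_iter = 2000L, tol = 1e-6) {
  x <- as.matrix(catalog)
  if (any(x < 0)) stop("catalog must be non-negative")
  if (all(x == 0)) stop("all-zero catalog cannot be factorized")
  if (k < 1) stop("k must be >= 1")
  if (sum(rowSums(x) > 0) < k) stop("need >= k samples with mutations")
  set.seed(seed)
  eps <- .Machine$double.eps
  best <- NULL
  for (r in seq_len(n_restarts)) {
    w <- matrix(runif(nrow(x) * k, 1e-3, 1), nrow(x), k)
    h <- matrix(runif(k * ncol(x), 1e-3, 1), k, ncol(x))
    trace <- numeric(0)
    err_old <- Inf
    for (it in seq_len(max_iter)) {
      h <- h * (t(w) %*% x) / (t(w) %*% w %*% h + eps)
      w <- w * (x %*% t(h)) / (w %*% (h %*% t(h)) + eps)
      err <- sum((x - w %*% h)^2)
      trace <- c(trace, err)
      if (is.finite(err_old) && (err_old - err) <= tol * max(err_old, eps)) {
        break
      }
      err_old <- err
    }
    if (is.null(best) || err < best$err) {
      best <- list(w = w, h = h, err = err, trace = trace)
    }
  }
  scale <- rowSums(best$h)
  scale[scale == 0] <- 1
  signatures <- best$h / scale
  exposures <- sweep(best$w, 2, scale, `*`)
  rownames(signatures) <- paste0("S", seq_len(k))
  colnames(signatures) <- colnames(x)
  colnames(exposures) <- rownames(signatures)
  rownames(exposures) <- rownames(x)
  structure(list(signatures = signatures, exposures = exposures,
                 explained_variance = 1 - best$err / sum(x^2),
                 error_trace = best$trace, k = k),
            class = "signature_solution")
}

#' @export
print.signature_solution <- function(x, ...) {
  cat("signature_solution: K =", x$k,
      " explained variance =", round(x$explained_variance, 4), "\n")
  invisible(x)
}

#' Match extracted signatures against a reference catalog
#'
#' @param signatures K x 96 matrix (rows on the canonical ordering).
#' @param reference Reference signatures x 96 matrix.
#' @return Data frame: `signature`, `best_match`, `cosine`.
#' @export
cosine_match <- function(signatures, reference) {
  stopifnot(ncol(signatures) == ncol(reference))
  out <- lapply(seq_len(nrow(signatures)), function(i) {
    cs <- apply(reference, 1, cosine_sim, y = signatures[i, ])
    j <- which.max(cs)
    data.frame(signature = rownames(signatures)[i] %||% paste0("S", i),
               best_match = rownames(reference)[j] %||% paste0("R", j),
               cosine = unname(cs[j]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Choose the number of signatures
#'
#' For each candidate K the catalog is factorized and two statistics are
#' recorded: explained variance and the mean cosine to each extracted
#' signature's best reference match. The candidate set comprises the K
#' values beyond which explained variance no longer increases
#' appreciably (every marginal gain at larger K is below `epsilon`);
#' among candidates, the chosen K maximizes the mean best-match cosine.
#' If no K qualifies, the global cosine maximum is returned with a
#' warning.
#'
#' @param catalog Samples x 96 catalog.
#' @param k_range Candidate K values (e.g. `2:20`).
#' @param reference Reference signature matrix for cosine matching.
#' @param epsilon Marginal explained-variance threshold (default 0.005).
#' @param n_restarts,seed,max_iter,tol Passed to [nmf_decompose()].
#' @return List with `chosen_k`, `trace` (per-K data frame:
#'   `explained_variance`, `gain`, `mean_cosine`, `candidate`) and
#'   `solutions` (per-K [nmf_decompose()] fits).
#' @export
select_k <- function(catalog, k_range, reference, epsilon = 0.005,
                     n_restarts = 50, seed = 1L, max_iter = 2000L,
                     tol = 1e-6) {
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(length(k_range) >= 1)
  fits <- lapply(seq_along(k_range), function(i) {
    nmf_decompose(catalog, k_range[i], n_restarts = n_restarts,
                  seed = seed + i, max_iter = max_iter, tol = tol)
  })
  ev <- vapply(fits, function(f) f$explained_variance, numeric(1))
  mean_cos <- vapply(fits, function(f) {
    mean(cosine_match(f$signatures, reference)$cosine)
  }, numeric(1))
  gain <- c(NA, diff(ev))
  # K is a plateau candidate iff every later step adds less than
  # epsilon; the largest K cannot demonstrate a plateau and is excluded
  candidate <- vapply(seq_along(k_range), function(i) {
    if (i == length(k_range)) return(FALSE)
    all(gain[(i + 1):length(gain)] < epsilon, na.rm = TRUE)
  }, logical(1))
  trace <- data.frame(k = k_range, explained_variance = ev, gain = gain,
                      mean_cosine = mean_cos, candidate = candidate)
  if (length(k_range) == 1) {
    chosen <- k_range
  } else if (any(candidate)) {
    cand <- which(candidate)
    chosen <- k_range[cand[which.max(mean_cos[cand])]]
  } else {
    warning("no K reaches an explained-variance plateau; ",
            "falling back to the global cosine maximum")
    chosen <- k_range[which.max(mean_cos)]
  }
  list(chosen_k = chosen, trace = trace, solutions = fits)
}

#' Compare signature exposures between two groups
#'
#' Two-sided Wilcoxon rank-sum tests on per-sample exposure fractions,
#' one per signature.
#'
#' @param exposures Samples x K exposure matrix.
#' @param groups Factor/character vector of two group labels per sample.
#' @return Data frame: `signature`, `median_a`, `median_b`, `p`.
#' @export
exposure_contrast <- function(exposures, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  frac <- exposures / pmax(rowSums(exposures), .Machine$double.eps)
  out <- lapply(seq_len(ncol(frac)), function(j) {
    a <- frac[groups == levels(groups)[1], j]
    b <- frac[groups == levels(groups)[2], j]
    p <- if (all(frac[, j] == frac[1, j])) 1 else
      suppressWarnings(wilcox.test(a, b)$p.value)
    data.frame(signature = colnames(frac)[j] %||% paste0("S", j),
               median_a = median(a), median_b = median(b), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
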