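#' Canonical splice junctions of a transcript model
#'
#' For every pair of adjacent exons, the canonical junction is the
#' (donor, acceptor) pair in intron-boundary convention: donor = first
#' intronic base after the upstream exon, acceptor = last intronic base
#' before the downstream exon, on the genomic plus strand.
#'
#' @param exon_model Exon model data frame (see [rb1_exon_model()]).
#' @return Data frame `gene`, `donor_exon`, `acceptor_exon`, `donor`,
#'   `acceptor`; zero rows for models with fewer than two exons.
#' @export
annotated_junctions <- function(exon_model) {
  if (!nrow(exon_model)) {
    return(data.frame(gene = character(), donor_exon = integer(),
                      acceptor_exon = integer(), donor = integer(),
                      acceptor = integer(), stringsAsFactors = FALSE))
  }
  exon_model <- validate_exon_model(exon_model)
  out <- lapply(split(exon_model, exon_model$gene), function(m) {
    if (nrow(m) < 2) return(NULL)
    i <- seq_len(nrow(m) - 1L)
    data.frame(gene = m$gene[1], donor_exon = m$exon_index[i],
               acceptor_exon = m$exon_index[i + 1L],
               donor = m$end[i] + 1L, acceptor = m$start[i + 1L] - 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, list(NULL)))
  if (is.null(out)) out <- annotated_junctions(exon_model[0, ])
  rownames(out) <- NULL
  out
}

#' Detect abnormal splice junctions
#'
#' A junction is abnormal iff it is not canonical, has at least
#' `min_reads` supporting reads, and is absent from the pooled
#' normal-control junction set (a junction counts as present in normals
#' when any normal sample supports it with at least `normal_min_reads`
#' reads).
#'
#' @param junctions Tumor junction records (`sample`, `chrom`, `donor`,
#'   `acceptor`, `strand`, `reads`), plus-strand normalized.
#' @param canonical Canonical set from [annotated_junctions()] (possibly
#'   for several genes combined).
#' @param normal_junctions Junction records of normal controls.
#' @param min_reads Minimum supporting reads (default 10).
#' @param normal_min_reads Presence threshold in normals (default 1).
#' @return The abnormal junction records.
#' @export
detect_abnormal <- function(junctions, canonical, normal_junctions = NULL,
                            min_reads = 10, normal_min_reads = 1) {
  key <- function(d, a) paste(d, a, sep = ":")
  canon <- key(canonical$donor, canonical$acceptor)
  normal <- character()
  if (!is.null(normal_junctions) && nrow(normal_junctions)) {
    nj <- normal_junctions[normal_junctions$reads >= normal_min_reads, ]
    normal <- unique(key(nj$donor, nj$acceptor))
  }
  k <- key(junctions$donor, junctions$acceptor)
  keep <- junctions$reads >= min_reads & !(k %in% canon) & !(k %in% normal)
  out <- junctions[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify an abnormal junction
#'
#' Decision rules over the annotated exon boundaries:
#' \itemize{
#'   \item both ends at annotated boundaries of non-adjacent exons of
#'     the same gene: exon skipping, skipped set = exons strictly
#'     between;
#'   \item ends within two different gene models: gene fusion;
#'   \item exactly one end at an annotated boundary: novel splice site;
#'   \item otherwise: unclassified (with a warning).
#' }
#' For within-gene coding events the reading-frame effect of the skipped
#' exons is computed; otherwise frame is `"na"`.
#'
#' @param junction Single abnormal junction record (one row).
#' @param exon_model Model of the gene of interest.
#' @param partner_models List of other gene models (fusion partners).
#' @return List with `class`, `skipped` (integer exon indices),
#'   `partner_gene`, `reads`, `frame`.
#' @export
classify_junction <- function(junction, exon_model,
                              partner_models = list()) {
  exon_model <- validate_exon_model(exon_model)
  models <- c(list(exon_model), lapply(partner_models, validate_exon_model))
  # which model/exon has this position as an annotated donor/acceptor?
  find_boundary <- function(pos) {
    for (m in models) {
      d <- which(m$end + 1L == pos)
      if (length(d)) return(list(gene = m$gene[1], exon = m$exon_index[d[1]],
                                 side = "donor"))
      a <- which(m$start - 1L == pos)
      if (length(a)) return(list(gene = m$gene[1], exon = m$exon_index[a[1]],
                                 side = "acceptor"))
    }
    NULL
  }
  in_gene_body <- function(pos) {
    for (m in models) {
      if (pos >= min(m$start) && pos <= max(m$end)) return(m$gene[1])
    }
    NA_character_
  }
  dhit <- find_boundary(junction$donor)
  ahit <- find_boundary(junction$acceptor)
  res <- list(class = "unclassified", skipped = integer(),
              partner_gene = NA_character_, reads = junction$reads,
              frame = "na")
  if (!is.null(dhit) && !is.null(ahit)) {
    if (dhit$gene == ahit$gene) {
      if (ahit$exon > dhit$exon + 1L) {
        res$class <- "exon_skipping"
        res$skipped <- (dhit$exon + 1L):(ahit$exon - 1L)
        if (dhit$gene == exon_model$gene[1]) {
          res$frame <- frame_effect(res$skipped, exon_model)
        }
      }
    } else {
      res$class <- "gene_fusion"
      res$partner_gene <- setdiff(c(dhit$gene, ahit$gene),
                                  exon_model$gene[1])[1]
    }
  } else if (xor(is.null(dhit), is.null(ahit))) {
    res$class <- "new_splice_site"
  } else {
    # neither end annotated: maybe intronic/intergenic on both sides
    g1 <- in_gene_body(junction$donor)
    g2 <- in_gene_body(junction$acceptor)
    if (!is.na(g1) && !is.na(g2) && g1 != g2) {
      res$class <- "gene_fusion"
      res$partner_gene <- setdiff(c(g1, g2), exon_model$gene[1])[1]
    } else {
      warning("junction with no annotated end left unclassified")
    }
  }
  res
}

#' Reading-frame effect of skipping a set of exons
#'
#' @param skipped Integer exon indices removed from the transcript.
#' @param exon_model Exon model with `coding_len`.
#' @return `"in_frame"` iff the summed coding length of the skipped
#'   exons is divisible by 3, else `"frameshift"`.
#' @export
#' @examples
#' frame_effect(3:17, rb1_exon_model())  # in_frame (477 codons)
frame_effect <- function(skipped, exon_model) {
  len <- exon_model$coding_len[match(skipped, exon_model$exon_index)]
  if (anyNA(len)) stop("skipped exon outside the model")
  if (sum(len) %% 3 == 0) "in_frame" else "frameshift"
}

#' Detect loss of 3'-terminal exon expression
#'
#' Scans every split point of the exon sequence: the sample is flagged
#' iff the mean mRNA coverage over some trailing exon block falls below
#' `theta` times the mean over the preceding block. With zero coverage
#' over the candidate upstream block the sample is not evaluable.
#'
#' @param coverage Numeric vector of per-exon mean mRNA coverage,
#'   ordered 5' to 3'.
#' @param theta Ratio threshold (default 0.1); `theta = 0` never flags.
#' @param min_upstream Minimum mean coverage the upstream block must
#'   reach for the sample to be evaluable; a locus that is essentially
#'   unexpressed (e.g. whole-gene deletion) cannot show terminal loss.
#' @return List with `flag` (`TRUE`/`FALSE`/`NA`), `split` (last
#'   retained exon index at the strongest split, or `NA`) and `ratio`.
#' @export
terminal_exon_loss <- function(coverage, theta = 0.1, min_upstream = 5) {
  n <- length(coverage)
  if (n < 2) return(list(flag = FALSE, split = NA_integer_, ratio = NA_real_))
  if (all(coverage == 0) || max(coverage) < min_upstream) {
    return(list(flag = NA, split = NA_integer_, ratio = NA_real_))
  }
  best <- Inf
  best_k <- NA_integer_
  for (k in seq_len(n - 1L)) {
    up <- mean(coverage[seq_len(k)])
    down <- mean(coverage[(k + 1L):n])
    if (up == 0) next
    r <- down / up
    if (r < best) {
      best <- r
      best_k <- k
    }
  }
  if (!is.finite(best)) {
    return(list(flag = NA, split = NA_integer_, ratio = NA_real_))
  }
  list(flag = best < theta, split = best_k, ratio = best)
}

#' Splice-disruption calls for a cohort
#'
#' Runs abnormal-junction detection and classification for every tumor
#' sample and the terminal-loss scan on the per-exon coverage table.
#'
#' @inheritParams detect_abnormal
#' @param exon_model Gene of interest.
#' @param partner_models Fusion partner models.
#' @param exon_coverage Optional per-exon coverage table (`sample`,
#'   `exon_index`, `coverage`).
#' @param theta Terminal-loss threshold.
#' @return Data frame of splice calls: `sample`, `class`, `skip_from`,
#'   `skip_to`, `partner_gene`, `reads`, `frame`.
#' @export
call_splice_cohort <- function(junctions, normal_junctions, exon_model,
                               partner_models = list(),
                               exon_coverage = NULL,
                               min_reads = 10, theta = 0.1) {
  models <- c(list(exon_model), partner_models)
  canon <- do.call(rbind, lapply(models, annotated_junctions))
  abn <- detect_abnormal(junctions, canon, normal_junctions,
                         min_reads = min_reads)
  rows <- lapply(seq_len(nrow(abn)), function(i) {
    cl <- classify_junction(abn[i, ], exon_model, partner_models)
    data.frame(sample = abn$sample[i], class = cl$class,
               skip_from = if (length(cl$skipped)) min(cl$skipped)
                 else NA_integer_,
               skip_to = if (length(cl$skipped)) max(cl$skipped)
                 else NA_integer_,
               partner_gene = cl$partner_gene, reads = cl$reads,
               frame = cl$frame, stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(calls)) {
    calls <- data.frame(sample = character(), class = character(),
                        skip_from = integer(), skip_to = integer(),
                        partner_gene = character(), reads = integer(),
                        frame = character(), stringsAsFactors = FALSE)
  }
  if (!is.null(exon_coverage) && nrow(exon_coverage)) {
    for (s in unique(exon_coverage$sample)) {
      cv <- exon_coverage[exon_coverage$sample == s, , drop = FALSE]
      cv <- cv[order(cv$exon_index), ]
      tl <- terminal_exon_loss(cv$coverage, theta)
      if (isTRUE(tl$flag)) {
        calls <- rbind(calls, data.frame(
          sample = s, class = "terminal_exon_loss",
          skip_from = tl$split + 1L,
          skip_to = max(cv$exon_index),
          partner_gene = NA_character_, reads = NA_integer_,
          frame = "na", stringsAsFactors = FALSE))
      }
    }
  }
  rownames(calls) <- NULL
  calls
}
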