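#' Exon models for the synthetic genome
#'
#' The synthetic cohort lives on a single synthetic chromosome (`"chrS"`)
#' carrying an RB1-like tumor-suppressor gene with 27 exons, the exon
#' count of human RB1. Coding lengths are chosen so that the recurrent
#' deletion/skipping geometries observed in small cell carcinomas are
#' representable with their coding consequences:
#' exons 3--17 encode 477 amino acids (in-frame when skipped),
#' exons 14--17 encode 121 amino acids (in-frame),
#' exons 1--17 encode 499 amino acids, and
#' exons 3--18 are frame-shifting. The full protein is 928 amino acids.
#'
#' Coordinates are 1-based inclusive. Exon widths equal coding lengths;
#' introns have fixed, varied widths so the locus spans roughly 180 kb.
#'
#' @param gene Gene symbol for the model (default `"RB1"`).
#' @param chrom Chromosome name.
#' @param tss Genomic start of the first exon.
#' @return A data frame with columns `gene`, `transcript`, `exon_index`,
#'   `chrom`, `start`, `end`, `strand`, `coding_len`.
#' @export
#' @examples
#' m <- rb1_exon_model()
#' sum(m$coding_len) / 3  # 928 codons
rb1_exon_model <- function(gene = "RB1", chrom = "chrS", tss = 2e6) {
  coding <- c(39, 27,                                   # exons 1-2
              120, 76, 110, 82, 97, 128, 75, 111, 90, 84, 95,  # 3-13
              100, 85, 90, 88,                          # 14-17
              110,                                      # 18 (frame-shifting)
              140, 130, 155, 125, 160, 105, 120, 145, 97)      # 19-27
  stopifnot(length(coding) == 27, sum(coding) == 928 * 3)
  introns <- rep(c(3200, 11800, 5400, 8600, 2400, 14600, 7300,
                   4100, 9800, 6200, 3900, 12400, 5100), length.out = 26)
  start <- integer(27)
  end <- integer(27)
  pos <- as.integer(tss)
  for (i in seq_len(27)) {
    start[i] <- pos
    end[i] <- pos + coding[i] - 1L
    if (i < 27) pos <- end[i] + introns[i] + 1L
  }
  data.frame(gene = gene, transcript = paste0(gene, "-201"),
             exon_index = seq_len(27), chrom = chrom,
             start = start, end = end, strand = "+",
             coding_len = coding, stringsAsFactors = FALSE)
}

#' Synthetic 5' partner gene model for fusion events
#'
#' A small six-exon gene upstream of the RB1-like locus on the same
#' strand, playing the role of the 5' fusion partner seen when a genomic
#' deletion removes the 5' end of the tumor suppressor and splices the
#' upstream gene onto its remaining exons.
#'
#' @inheritParams rb1_exon_model
#' @return Exon-model data frame with the same columns as
#'   [rb1_exon_model()].
#' @export
partner_gene_model <- function(gene = "PTNB1", chrom = "chrS", tss = 17e5) {
  coding <- c(90, 120, 75, 140, 102, 160)
  introns <- c(4200, 2600, 6900, 3100, 5200)
  start <- integer(6)
  end <- integer(6)
  pos <- as.integer(tss)
  for (i in seq_len(6)) {
    start[i] <- pos
    end[i] <- pos + coding[i] - 1L
    if (i < 6) pos <- end[i] + introns[i] + 1L
  }
  data.frame(gene = gene, transcript = paste0(gene, "-201"),
             exon_index = seq_len(6), chrom = chrom,
             start = start, end = end, strand = "+",
             coding_len = coding, stringsAsFactors = FALSE)
}

# sanity checks shared by consumers of exon models
validate_exon_model <- function(model) {
  need <- c("gene", "transcript", "exon_index", "chrom", "start", "end",
            "strand", "coding_len")
  missing <- setdiff(need, names(model))
  if (length(missing)) {
    stop("exon model lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(model$end < model$start)) stop("exon model has end < start")
  model[order(model$gene, model$exon_index), , drop = FALSE]
}
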