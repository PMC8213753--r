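#' Specify a synthetic tumor/normal cohort
#'
#' The generator emulates a small-cell-carcinoma WES + RNA-seq + IHC
#' cohort in which the RB1-like tumor suppressor is disrupted through a
#' mix of mechanisms. Defaults reproduce the study conditions the package
#' is designed around: 46 tumors of which 33 are FFPE, with a
#' single planted disruption mechanism per sample.
#'
#' @param n_samples Number of tumor samples.
#' @param ffpe_fraction Fraction of samples that are FFPE (these receive
#'   additional low allele-frequency C>T fixation artifacts).
#' @param seed Integer seed; all generators derive their randomness from
#'   it so a spec regenerates identical files.
#' @param artifact_rate Expected FFPE artifact variants per FFPE sample.
#' @param true_mut_rate Expected true somatic variants per sample.
#' @param mechanism_mix Named integer vector over
#'   `c("mutation", "exon_deletion", "whole_gene_deletion", "splice_only",
#'   "protein_only", "intact")`, summing to `n_samples`.
#' @return An object of class `"cohort_spec"`.
#' @export
#' @examples
#' spec <- cohort_spec(n_samples = 10, ffpe_fraction = 0.5,
#'                     mechanism_mix = c(mutation = 4, exon_deletion = 3,
#'                                       whole_gene_deletion = 0,
#'                                       splice_only = 2, protein_only = 0,
#'                                       intact = 1))
cohort_spec <- function(n_samples = 46L,
                        ffpe_fraction = 33 / 46,
                        seed = 20210618L,
                        artifact_rate = 25,
                        true_mut_rate = 85,
                        mechanism_mix = c(mutation = 16L,
                                          exon_deletion = 13L,
                                          whole_gene_deletion = 1L,
                                          splice_only = 11L,
                                          protein_only = 4L,
                                          intact = 1L)) {
  if (n_samples != round(n_samples) || n_samples < 0) {
    stop("n_samples must be a non-negative integer")
  }
  if (ffpe_fraction < 0 || ffpe_fraction > 1) {
    stop("ffpe_fraction must be in [0, 1]")
  }
  if (artifact_rate < 0 || true_mut_rate < 0) {
    stop("rates must be non-negative")
  }
  labels <- c("mutation", "exon_deletion", "whole_gene_deletion",
              "splice_only", "protein_only", "intact")
  if (!setequal(names(mechanism_mix), labels)) {
    stop("mechanism_mix must be named over the six mechanism labels")
  }
  mechanism_mix <- mechanism_mix[labels]
  if (any(mechanism_mix != round(mechanism_mix)) || any(mechanism_mix < 0)) {
    stop("mechanism_mix counts must be non-negative integers")
  }
  if (sum(mechanism_mix) != n_samples) {
    stop("mechanism_mix counts must sum to n_samples")
  }
  structure(list(n_samples = as.integer(n_samples),
                 ffpe_fraction = ffpe_fraction,
                 seed = as.integer(seed),
                 artifact_rate = artifact_rate,
                 true_mut_rate = true_mut_rate,
                 mechanism_mix = setNames(as.integer(mechanism_mix), labels)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("cohort_spec:", x$n_samples, "samples,",
      round(x$ffpe_fraction * x$n_samples), "FFPE, seed", x$seed, "\n")
  print(x$mechanism_mix)
  invisible(x)
}

#' Deterministic cohort plan
#'
#' Expands a [cohort_spec()] into the per-sample ground truth shared by
#' all generators: sample identifiers, FFPE status, disruption mechanism,
#' whether RNA was assayed, the planted deleted exon range, the planted
#' splice event and the expected IHC result. The plan is a pure function
#' of the spec (the spec seed drives only read-level noise), so the
#' variant, coverage, junction and IHC channels are mutually consistent.
#'
#' Planted geometry mirrors recurrent real-world events: among exon
#' deletions, one frame-shifting internal deletion (exons 3--18), one 5'
#' deletion spliced onto an upstream partner gene (exons 1--17, in-frame,
#' protein mislocalized), one 3'-terminal deletion (exons 20--27,
#' terminal expression loss), and one short in-frame deletion retaining
#' the C-terminal epitope (exons 14--17, IHC positive); further deletions
#' are internal ranges drawn deterministically. Among splice-only
#' samples, the first two are in-frame skippings that retain the epitope
#' (exons 3--17 and 14--17, IHC positive) and the third is a novel splice
#' site; the rest are frame-agnostic skippings.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame, one row per sample (the cohort truth table).
#' @export
cohort_plan <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  if (n == 0) {
    return(data.frame(sample = character(), ffpe = logical(),
                      mechanism = character(), rna_assayed = logical(),
                      del_from = integer(), del_to = integer(),
                      splice_class = character(),
                      skip_from = integer(), skip_to = integer(),
                      ihc_status = character(), ihc_localization = character(),
                      stringsAsFactors = FALSE))
  }
  mech <- rep(names(spec$mechanism_mix), times = spec$mechanism_mix)
  ids <- sprintf("T%03d", seq_len(n))
  n_ffpe <- round(spec$ffpe_fraction * n)
  ffpe <- seq_len(n) <= n_ffpe
  plan <- data.frame(sample = ids, ffpe = ffpe, mechanism = mech,
                     rna_assayed = mech != "intact",
                     del_from = NA_integer_, del_to = NA_integer_,
                     splice_class = NA_character_,
                     skip_from = NA_integer_, skip_to = NA_integer_,
                     ihc_status = "negative", ihc_localization = "na",
                     stringsAsFactors = FALSE)

  # exon deletions: fixed representative geometries first, then
  # deterministic internal ranges
  idx_del <- which(mech == "exon_deletion")
  fixed <- list(c(3L, 18L), c(1L, 17L), c(20L, 27L), c(14L, 17L))
  extra_from <- c(5L, 9L, 2L, 12L, 7L, 16L, 4L, 10L, 6L, 19L, 3L, 8L, 11L)
  extra_len <- c(6L, 3L, 9L, 4L, 8L, 2L, 12L, 5L, 1L, 4L, 7L, 10L, 3L)
  for (k in seq_along(idx_del)) {
    i <- idx_del[k]
    if (k <= length(fixed)) {
      rng <- fixed[[k]]
    } else {
      j <- ((k - length(fixed) - 1L) %% length(extra_from)) + 1L
      from <- extra_from[j]
      to <- min(from + extra_len[j], 26L)  # internal: never whole gene
      rng <- c(from, to)
    }
    plan$del_from[i] <- rng[1]
    plan$del_to[i] <- rng[2]
    if (rng[1] > 1L && rng[2] < 27L) {
      plan$splice_class[i] <- "exon_skipping"
      plan$skip_from[i] <- rng[1]
      plan$skip_to[i] <- rng[2]
    } else if (rng[1] == 1L) {
      plan$splice_class[i] <- "gene_fusion"
      plan$skip_from[i] <- rng[1]
      plan$skip_to[i] <- rng[2]
    } else {
      plan$splice_class[i] <- "terminal_exon_loss"
    }
  }
  plan$del_from[mech == "whole_gene_deletion"] <- 1L
  plan$del_to[mech == "whole_gene_deletion"] <- 27L

  # splice-only samples: epitope-retaining in-frame skippings first,
  # one novel splice site, then generic skippings
  idx_sp <- which(mech == "splice_only")
  sp_fixed <- list(c("exon_skipping", 3L, 17L),
                   c("exon_skipping", 14L, 17L),
                   c("new_splice_site", 13L, NA))
  generic_from <- c(4L, 7L, 10L, 5L, 16L, 8L, 12L, 6L, 9L, 11L)
  generic_to <- c(8L, 12L, 13L, 9L, 19L, 10L, 15L, 11L, 14L, 16L)
  for (k in seq_along(idx_sp)) {
    i <- idx_sp[k]
    if (k <= length(sp_fixed)) {
      plan$splice_class[i] <- sp_fixed[[k]][[1]]
      plan$skip_from[i] <- as.integer(sp_fixed[[k]][[2]])
      plan$skip_to[i] <- as.integer(sp_fixed[[k]][[3]])
    } else {
      j <- ((k - length(sp_fixed) - 1L) %% length(generic_from)) + 1L
      plan$splice_class[i] <- "exon_skipping"
      plan$skip_from[i] <- generic_from[j]
      plan$skip_to[i] <- generic_to[j]
    }
  }

  # IHC consequences of the planted mechanism
  model <- rb1_exon_model()
  for (i in seq_len(n)) {
    m <- plan$mechanism[i]
    if (m == "intact") {
      plan$ihc_status[i] <- "positive"
      plan$ihc_localization[i] <- "nuclear"
    } else if (m == "exon_deletion" &&
               identical(c(plan$del_from[i], plan$del_to[i]), c(1L, 17L))) {
      # in-frame fusion to the 5' partner: protein made but mislocalized
      plan$ihc_status[i] <- "positive"
      plan$ihc_localization[i] <- "cytoplasmic"
    } else if (!is.na(plan$skip_from[i]) && !is.na(plan$skip_to[i]) &&
               plan$splice_class[i] == "exon_skipping" &&
               plan$skip_to[i] <= 25L &&
               frame_effect(plan$skip_from[i]:plan$skip_to[i],
                            model) == "in_frame") {
      # in-frame loss retaining the two C-terminal (epitope) exons
      plan$ihc_status[i] <- "positive"
      plan$ihc_localization[i] <- "nuclear"
    } else {
      plan$ihc_status[i] <- "negative"
      plan$ihc_localization[i] <- "na"
    }
  }
  plan
}

# class weights over the six substitution classes for true somatic SNVs;
# the C>T share matches fresh-frozen tumor spectra (~43%)
TRUE_CLASS_WEIGHTS <- c("C>A" = 0.10, "C>G" = 0.07, "C>T" = 0.43,
                        "T>A" = 0.05, "T>C" = 0.25, "T>G" = 0.10)

sample_context <- function(n, classes, weights) {
  ctx <- contexts96()
  cls <- context_class(ctx)
  w <- weights[cls] / 16  # uniform over the 16 contexts within a class
  sample(ctx, n, replace = TRUE, prob = w)
}

#' Generate candidate somatic variant records with planted truth
#'
#' True somatic SNVs/indels are drawn with tumor allele fraction
#' `Beta(2, 4)` (median about 0.31) on tumor depth around 200x; matched
#' normals carry `Binomial(depth, 0.001)` alt reads. FFPE samples
#' additionally receive low-AF C>T fixation artifacts (allele fraction
#' below 0.05, fully strand-biased, tumor-only). Samples whose planted
#' mechanism is `mutation` receive one guaranteed clean driver variant
#' inside an RB1 exon.
#'
#' @param spec A [cohort_spec()].
#' @param exon_model Exon model of the target gene, as from
#'   [rb1_exon_model()].
#' @param mean_t_depth,mean_n_depth Mean tumor/normal sequencing depths.
#' @return A list with `variants` (the candidate table; see package
#'   vignette for the column contract) and `truth` (record-level truth
#'   with an `is_true` flag plus the cohort plan).
#' @export
generate_variants <- function(spec, exon_model = rb1_exon_model(),
                              mean_t_depth = 200, mean_n_depth = 100) {
  stopifnot(inherits(spec, "cohort_spec"))
  plan <- cohort_plan(spec)
  set.seed(spec$seed + 1L)
  rows <- vector("list", nrow(plan))
  gene_span <- if (nrow(exon_model)) {
    range(c(exon_model$start, exon_model$end))
  } else c(0, 0)

  one_record <- function(smp, pos, af, is_artifact, consequence, ctx) {
    t_depth <- max(rpois(1, mean_t_depth), 10L)
    n_depth <- max(rpois(1, mean_n_depth), 10L)
    t_alt <- rbinom(1, t_depth, af)
    n_alt <- rbinom(1, n_depth, 0.001)
    if (is_artifact) {
      alt_fwd <- t_alt  # fixation artifacts arise on one strand
    } else {
      alt_fwd <- rbinom(1, t_alt, 0.5)
    }
    ref <- t_depth - t_alt
    ref_fwd <- rbinom(1, ref, 0.5)
    data.frame(sample = smp, chrom = "chrS", pos = pos,
               ref = "C", alt = "T",
               t_depth = t_depth, t_alt = t_alt,
               n_depth = n_depth, n_alt = n_alt,
               t_ref_fwd = ref_fwd, t_ref_rev = ref - ref_fwd,
               t_alt_fwd = alt_fwd, t_alt_rev = t_alt - alt_fwd,
               pop_af_max = 0, in_snp142 = FALSE, in_cosmic = FALSE,
               consequence = consequence, tri_context = ctx,
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(nrow(plan))) {
    smp <- plan$sample[i]
    n_true <- rpois(1, spec$true_mut_rate)
    recs <- list()
    if (n_true > 0) {
      # background positions avoid the target-gene exons so that
      # driver truth stays attributable to the planted mechanism
      pos <- sample.int(5e6, n_true)
      if (nrow(exon_model)) {
        repeat {
          inx <- vapply(pos, function(p) {
            any(p >= exon_model$start & p <= exon_model$end)
          }, logical(1))
          if (!any(inx)) break
          pos[inx] <- sample.int(5e6, sum(inx))
        }
      }
      af <- rbeta(n_true, 2, 4)
      cons <- sample(c("synonymous", "nonsynonymous_snv", "indel"),
                     n_true, replace = TRUE,
                     prob = c(0.244, 0.714, 0.042))
      ctx <- sample_context(n_true, NULL, TRUE_CLASS_WEIGHTS)
      ctx[cons == "indel"] <- NA
      recs <- lapply(seq_len(n_true), function(j) {
        r <- one_record(smp, pos[j], af[j], FALSE, cons[j], ctx[j])
        # a minority of true somatics are known hotspot alleles
        if (runif(1) < 0.05) {
          r$in_snp142 <- TRUE
          r$in_cosmic <- TRUE
        }
        r
      })
    }
    if (plan$mechanism[i] == "mutation") {
      ex <- exon_model[sample.int(nrow(exon_model), 1), ]
      driver <- one_record(smp, sample(ex$start:ex$end, 1), 0.4, FALSE,
                           "nonsynonymous_snv",
                           sample_context(1, NULL, TRUE_CLASS_WEIGHTS))
      recs <- c(recs, list(driver))
      n_true <- n_true + 1L
    }
    n_art <- if (plan$ffpe[i]) rpois(1, spec$artifact_rate) else 0L
    if (n_art > 0) {
      pos <- sample.int(5e6, n_art)
      af <- pmax(0.05 * rbeta(n_art, 2, 5), 0.004)
      ctx <- sample_context(n_art, NULL,
                            c("C>A" = 0, "C>G" = 0, "C>T" = 1,
                              "T>A" = 0, "T>C" = 0, "T>G" = 0))
      recs <- c(recs, lapply(seq_len(n_art), function(j) {
        one_record(smp, pos[j], af[j], TRUE, "nonsynonymous_snv", ctx[j])
      }))
    }
    if (length(recs)) {
      df <- do.call(rbind, recs)
      df$is_true <- rep(c(TRUE, FALSE), c(n_true, n_art))
      rows[[i]] <- df
    }
  }
  variants <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(variants)) {
    variants <- data.frame(
      sample = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), t_depth = integer(),
      t_alt = integer(), n_depth = integer(), n_alt = integer(),
      t_ref_fwd = integer(), t_ref_rev = integer(), t_alt_fwd = integer(),
      t_alt_rev = integer(), pop_af_max = numeric(), in_snp142 = logical(),
      in_cosmic = logical(), consequence = character(),
      tri_context = character(), stringsAsFactors = FALSE)
    truth <- data.frame(sample = character(), chrom = character(),
                        pos = integer(), is_true = logical(),
                        stringsAsFactors = FALSE)
    return(list(variants = variants, truth = truth, plan = plan))
  }
  truth <- variants[, c("sample", "chrom", "pos", "is_true")]
  variants$is_true <- NULL
  rownames(variants) <- NULL
  list(variants = variants, truth = truth, plan = plan)
}

#' Generate capture-bin log2 coverage ratios with planted RB1 deletions
#'
#' Capture bins tile the exons of the target gene (at most `bin_width`
#' bases each). Diploid bins fluctuate around log2 = 0 with Gaussian
#' noise; bins inside a planted homozygous deletion are centered at
#' `del_log2` (default -5, i.e. essentially zero copies). Whole-gene
#' deletion samples have every exon deleted.
#'
#' @inheritParams generate_variants
#' @param noise_sd Gaussian noise SD on the log2 scale.
#' @param del_log2 Mean log2 ratio of deleted bins (must be <= -3).
#' @param bin_width Maximum bin width in bases.
#' @return List with `bins` (sample, chrom, start, end, log2) and
#'   `truth` (the cohort plan, whose `del_from`/`del_to` columns record
#'   the planted exon ranges).
#' @export
generate_rb1_coverage <- function(spec, exon_model = rb1_exon_model(),
                                  noise_sd = 0.2, del_log2 = -5,
                                  bin_width = 120L) {
  stopifnot(inherits(spec, "cohort_spec"))
  exon_model <- validate_exon_model(exon_model)
  if (nrow(exon_model) < 2) stop("exon model must have >= 2 exons")
  if (del_log2 > -3) stop("del_log2 must be <= -3 to plant callable deletions")
  plan <- cohort_plan(spec)
  if (any(!is.na(plan$del_to) & plan$del_to > nrow(exon_model))) {
    stop("planted deletion range outside exon model")
  }
  set.seed(spec$seed + 2L)

  # bin skeleton shared by all samples
  skel <- do.call(rbind, lapply(seq_len(nrow(exon_model)), function(i) {
    e <- exon_model[i, ]
    n_bins <- max(1L, ceiling((e$end - e$start + 1L) / bin_width))
    cuts <- round(seq(e$start, e$end + 1L, length.out = n_bins + 1L))
    data.frame(chrom = e$chrom, start = head(cuts, -1L),
               end = pmax(head(cuts, -1L), tail(cuts, -1L) - 1L),
               exon_index = e$exon_index, stringsAsFactors = FALSE)
  }))
  bins <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
    lg <- rnorm(nrow(skel), 0, noise_sd)
    if (!is.na(plan$del_from[i])) {
      hit <- skel$exon_index >= plan$del_from[i] &
        skel$exon_index <= plan$del_to[i]
      lg[hit] <- lg[hit] + del_log2
    }
    data.frame(sample = plan$sample[i], chrom = skel$chrom,
               start = skel$start, end = skel$end, log2 = lg,
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  list(bins = bins, truth = plan)
}

# canonical intron-boundary junction for adjacent exon pair (i, i+1):
# donor = first intronic base after exon i, acceptor = last intronic
# base before exon i+1 (plus-strand convention)
junction_between <- function(model, i, j) {
  c(donor = model$end[model$exon_index == i] + 1L,
    acceptor = model$start[model$exon_index == j] - 1L)
}

#' Generate splice-junction tables consistent with the planted events
#'
#' Tumor samples carry canonical junctions over their retained exons plus
#' the abnormal junctions implied by their planted mechanism: internal
#' deletions and splice-only skippings produce skipping junctions, 5'
#' deletions produce a fusion junction into a partner gene, one
#' splice-only sample carries a novel (intronic) splice site. Matched
#' normals carry only canonical junctions. A per-exon mRNA coverage table
#' is emitted for terminal-loss detection.
#'
#' @inheritParams generate_variants
#' @param partner_models List of partner gene models (needed when the
#'   plan contains fusion events).
#' @param read_range Range of supporting reads for abnormal junctions.
#' @param canonical_reads Mean reads on canonical junctions.
#' @return List with `junctions` (tumors and matched normals),
#'   `exon_coverage` (sample, gene, exon_index, coverage) and `truth`.
#' @export
generate_junctions <- function(spec, exon_model = rb1_exon_model(),
                               partner_models = list(partner_gene_model()),
                               read_range = c(10L, 200L),
                               canonical_reads = 60) {
  stopifnot(inherits(spec, "cohort_spec"))
  exon_model <- validate_exon_model(exon_model)
  plan <- cohort_plan(spec)
  if (any(plan$splice_class %in% "gene_fusion") && !length(partner_models)) {
    stop("plan contains fusion events but no partner gene model supplied")
  }
  set.seed(spec$seed + 3L)
  n_ex <- nrow(exon_model)
  chrom <- exon_model$chrom[1]

  canonical_rows <- function(smp, model, retained) {
    keep <- retained[-length(retained)] & retained[-1]
    idx <- which(keep)
    if (!length(idx)) return(NULL)
    do.call(rbind, lapply(idx, function(i) {
      jb <- junction_between(model, model$exon_index[i],
                             model$exon_index[i + 1])
      data.frame(sample = smp, chrom = model$chrom[1],
                 donor = jb[["donor"]], acceptor = jb[["acceptor"]],
                 strand = "+", reads = rpois(1, canonical_reads),
                 stringsAsFactors = FALSE)
    }))
  }
  abn_reads <- function() sample(read_range[1]:read_range[2], 1)

  jrows <- list()
  crows <- list()
  for (i in seq_len(nrow(plan))) {
    if (!plan$rna_assayed[i]) next
    smp <- plan$sample[i]
    retained <- rep(TRUE, n_ex)
    if (!is.na(plan$del_from[i])) {
      retained[plan$del_from[i]:plan$del_to[i]] <- FALSE
    }
    cov <- rpois(n_ex, 100)
    cov[!retained] <- rpois(sum(!retained), 1)
    if (plan$mechanism[i] == "whole_gene_deletion") {
      cov[] <- rpois(n_ex, 0.5)
      crows[[length(crows) + 1L]] <-
        data.frame(sample = smp, gene = exon_model$gene[1],
                   exon_index = seq_len(n_ex), coverage = cov,
                   stringsAsFactors = FALSE)
      next  # nothing expressed, no junctions at this locus
    }
    # splice-only skipping also silences the skipped exons in mRNA
    if (!is.na(plan$skip_from[i]) && !is.na(plan$skip_to[i]) &&
        identical(plan$splice_class[i], "exon_skipping")) {
      retained[plan$skip_from[i]:plan$skip_to[i]] <- FALSE
      cov[plan$skip_from[i]:plan$skip_to[i]] <-
        rpois(plan$skip_to[i] - plan$skip_from[i] + 1L, 1)
    }
    jrows[[length(jrows) + 1L]] <- canonical_rows(smp, exon_model, retained)
    cls <- plan$splice_class[i]
    if (!is.na(cls) && cls == "exon_skipping") {
      jrows[[length(jrows) + 1L]] <- data.frame(
        sample = smp, chrom = chrom,
        donor = exon_model$end[plan$skip_from[i] - 1L] + 1L,
        acceptor = exon_model$start[plan$skip_to[i] + 1L] - 1L,
        strand = "+", reads = abn_reads(), stringsAsFactors = FALSE)
    } else if (!is.na(cls) && cls == "gene_fusion") {
      pm <- partner_models[[1]]
      jrows[[length(jrows) + 1L]] <- data.frame(
        sample = smp, chrom = chrom,
        donor = pm$end[2] + 1L,
        acceptor = exon_model$start[plan$del_to[i] + 1L] - 1L,
        strand = "+", reads = abn_reads(), stringsAsFactors = FALSE)
    } else if (!is.na(cls) && cls == "new_splice_site") {
      d <- exon_model$end[plan$skip_from[i]] + 1L
      jrows[[length(jrows) + 1L]] <- data.frame(
        sample = smp, chrom = chrom, donor = d,
        acceptor = d + 512L,  # mid-intron acceptor: not an annotated boundary
        strand = "+", reads = abn_reads(), stringsAsFactors = FALSE)
    } else if (!is.na(cls) && cls == "terminal_exon_loss" &&
               is.na(plan$del_from[i])) {
      cov[20:n_ex] <- rpois(n_ex - 19L, 2)
    }
    crows[[length(crows) + 1L]] <-
      data.frame(sample = smp, gene = exon_model$gene[1],
                 exon_index = seq_len(n_ex), coverage = cov,
                 stringsAsFactors = FALSE)
  }
  # matched normals: canonical junctions only
  n_normals <- max(1L, sum(plan$rna_assayed) %/% 2L)
  for (k in seq_len(if (nrow(plan)) n_normals else 0L)) {
    jrows[[length(jrows) + 1L]] <-
      canonical_rows(sprintf("N%03d", k), exon_model, rep(TRUE, n_ex))
  }
  junctions <- do.call(rbind, c(jrows, list(NULL)))
  exon_coverage <- do.call(rbind, c(crows, list(NULL)))
  if (is.null(junctions)) {
    junctions <- data.frame(sample = character(), chrom = character(),
                            donor = integer(), acceptor = integer(),
                            strand = character(), reads = integer(),
                            stringsAsFactors = FALSE)
  }
  if (is.null(exon_coverage)) {
    exon_coverage <- data.frame(sample = character(), gene = character(),
                                exon_index = integer(), coverage = numeric(),
                                stringsAsFactors = FALSE)
  }
  rownames(junctions) <- rownames(exon_coverage) <- NULL
  list(junctions = junctions, exon_coverage = exon_coverage, truth = plan)
}

#' Generate IHC result records consistent with the planted mechanisms
#'
#' @inheritParams generate_variants
#' @param marker Marker name recorded in the table.
#' @return List with `ihc` (sample, marker, status, localization) and
#'   `truth`.
#' @export
generate_ihc <- function(spec, marker = "RB1") {
  plan <- cohort_plan(spec)
  ihc <- data.frame(sample = plan$sample, marker = marker,
                    status = plan$ihc_status,
                    localization = plan$ihc_localization,
                    stringsAsFactors = FALSE)
  list(ihc = ihc, truth = plan)
}

#' Generate a two-subtype expression matrix driven by lineage-TF programs
#'
#' Background genes are log-normal; each subtype up-shifts its own
#' program (which contains the corresponding lineage transcription
#' factor) by `effect` log2 units. An optional amplification flag is
#' generated with different rates per subtype.
#'
#' @param n_per_subtype Named counts, e.g. `c(A = 29, N = 9)`.
#' @param program_genes Named list of two disjoint character vectors; by
#'   default 40-gene programs containing `ASCL1` and `NEUROD1`.
#' @param effect Subtype up-shift in log2 units.
#' @param n_background Number of background genes.
#' @param seed Integer seed.
#' @param amp_rates Per-subtype probability of the amplification flag.
#' @return List with `tpm` (genes x samples matrix, TPM scale),
#'   `metadata` (sample, subtype, amp) and `truth` (= metadata).
#' @export
generate_expression <- function(n_per_subtype = c(A = 29L, N = 9L),
                                program_genes = NULL,
                                effect = 3,
                                n_background = 1000L,
                                seed = 20210618L,
                                amp_rates = c(A = 0.17, N = 0.56)) {
  if (is.null(program_genes)) {
    program_genes <- list(
      A = c("ASCL1", sprintf("PROGA%02d", 1:39)),
      N = c("NEUROD1", sprintf("PROGN%02d", 1:39)))
  }
  if (length(program_genes) != 2 ||
      length(intersect(program_genes[[1]], program_genes[[2]])) > 0) {
    stop("program_genes must be two disjoint gene sets")
  }
  stopifnot(length(n_per_subtype) == 2, all(n_per_subtype >= 0))
  set.seed(seed)
  subtypes <- rep(names(n_per_subtype), times = n_per_subtype)
  n_s <- length(subtypes)
  samples <- sprintf("E%03d", seq_len(n_s))
  genes <- c(sprintf("BG%04d", seq_len(n_background)),
             program_genes[[1]], program_genes[[2]])
  base <- rnorm(length(genes), mean = 3, sd = 1.5)
  lg <- matrix(rnorm(length(genes) * n_s, 0, 0.7), length(genes), n_s) + base
  for (g in seq_along(program_genes)) {
    rows <- match(program_genes[[g]], genes)
    cols <- subtypes == names(program_genes)[g]
    lg[rows, cols] <- lg[rows, cols] + effect
  }
  tpm <- 2^lg
  dimnames(tpm) <- list(genes, samples)
  amp <- rbinom(n_s, 1, amp_rates[subtypes]) == 1
  meta <- data.frame(sample = samples, subtype = subtypes, amp = amp,
                     stringsAsFactors = FALSE)
  list(tpm = tpm, metadata = meta, truth = meta)
}

#' Synthetic reference mutational signatures
#'
#' A small catalog of sparse, near-orthogonal 96-context signatures used
#' as the planted truth for signature-extraction tests. The first row is
#' deamination-like (C>T concentrated at NpCpG contexts); the rest are
#' sparse random profiles. This is a synthetic stand-in catalog, not a
#' curated reference; any user-supplied reference matrix (rows summing to
#' 1 over the canonical 96 ordering) can be used instead.
#'
#' @param n_signatures Number of signatures (rows).
#' @param seed Integer seed.
#' @return Matrix `n_signatures x 96`, rows summing to 1.
#' @export
synthetic_reference_signatures <- function(n_signatures = 5L, seed = 7L) {
  set.seed(seed)
  ctx <- contexts96()
  out <- matrix(0, n_signatures, 96, dimnames = list(
    paste0("SYN", seq_len(n_signatures)), ctx))
  # deamination-like: C>T at ACG/CCG/GCG/TCG contexts
  w <- rep(1e-4, 96)
  w[ctx %in% c("A[C>T]G", "C[C>T]G", "G[C>T]G", "T[C>T]G")] <- 0.22
  w[context_class(ctx) == "C>T"] <- w[context_class(ctx) == "C>T"] + 0.005
  out[1, ] <- w / sum(w)
  for (i in seq_len(n_signatures)[-1]) {
    w <- rgamma(96, shape = 0.05)
    out[i, ] <- w / sum(w)
  }
  out
}

#' Generate 96-context mutation catalogs from signature exposures
#'
#' Each sample's catalog is a multinomial draw from its exposure-weighted
#' mixture of the reference signatures.
#'
#' @param reference Signatures x 96 matrix; rows must sum to 1.
#' @param exposures Samples x signatures matrix; rows must sum to 1, all
#'   entries non-negative.
#' @param mutations_per_sample Mutations drawn per sample (scalar or per
#'   sample vector).
#' @param seed Integer seed.
#' @return Samples x 96 integer matrix (a mutation catalog).
#' @export
generate_catalogs <- function(reference, exposures, mutations_per_sample,
                              seed = 20210618L) {
  reference <- as.matrix(reference)
  exposures <- as.matrix(exposures)
  if (any(exposures < 0)) stop("exposures must be non-negative")
  if (any(abs(rowSums(reference) - 1) > 1e-6)) {
    stop("reference signature rows must sum to 1")
  }
  if (any(abs(rowSums(exposures) - 1) > 1e-6)) {
    stop("exposure rows must sum to 1")
  }
  stopifnot(ncol(exposures) == nrow(reference))
  n <- nrow(exposures)
  m <- rep_len(mutations_per_sample, n)
  set.seed(seed)
  probs <- exposures %*% reference  # samples x 96
  out <- t(vapply(seq_len(n), function(i) {
    if (m[i] == 0) return(integer(ncol(reference)))
    as.integer(rmultinom(1, m[i], probs[i, ]))
  }, integer(ncol(reference))))
  dimnames(out) <- list(
    if (is.null(rownames(exposures))) sprintf("C%03d", seq_len(n))
    else rownames(exposures),
    colnames(reference))
  out
}

#' Generate every pipeline input for a cohort
#'
#' Convenience orchestrator running all channel generators off one spec
#' and, optionally, writing each table as TSV (round-trippable through
#' [read_tsv()]).
#'
#' @inheritParams generate_variants
#' @param outdir Optional directory for TSV export.
#' @return List with `variants`, `variant_truth`, `bins`, `junctions`,
#'   `exon_coverage`, `ihc` and `truth` (the cohort plan).
#' @export
generate_cohort <- function(spec, exon_model = rb1_exon_model(),
                            outdir = NULL) {
  v <- generate_variants(spec, exon_model)
  cv <- generate_rb1_coverage(spec, exon_model)
  jn <- generate_junctions(spec, exon_model)
  ih <- generate_ihc(spec)
  out <- list(variants = v$variants, variant_truth = v$truth,
              bins = cv$bins, junctions = jn$junctions,
              exon_coverage = jn$exon_coverage, ihc = ih$ihc,
              truth = v$plan)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      write_tsv(out[[nm]], file.path(outdir, paste0(nm, ".tsv")))
    }
  }
  out
}
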