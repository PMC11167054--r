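#' Read a variant table (TSV) or a minimal sites-only VCF
#'
#' The TSV reader expects a header with columns `chrom`, `pos` (1-based),
#' `ref`, `alt`, `id` (extra columns such as a FATHMM score are kept). The
#' VCF reader handles sites-only VCF 4.x files through the
#' `VariantAnnotation` package. Only single-nucleotide variants are
#' accepted: indels and multi-nucleotide variants are rejected, not
#' silently skipped.
#'
#' @param path input file.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`, `id`
#'   (plus any extra TSV columns).
#' @export
readVariantTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c(pos = "integer"), comment.char = "")
  need <- c("chrom", "pos", "ref", "alt", "id")
  if (!all(need %in% names(df)))
    stop("variant table needs columns ", paste(need, collapse = ", "))
  .checkSNV(df)
  df
}

#' @rdname readVariantTable
#' @export
readVariantVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  altChar <- vapply(seq_along(alt), function(i)
    paste(as.character(alt[[i]]), collapse = ","), character(1))
  df <- data.frame(
    chrom = as.character(seqnames(rr)),
    pos = start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = altChar,
    id = names(rr)
  )
  .checkSNV(df)
  df
}

.checkSNV <- function(df) {
  bad <- nchar(df$ref) != 1L | nchar(df$alt) != 1L
  if (any(bad))
    stop("only single-nucleotide variants are supported; offending ids: ",
         paste(head(df$id[bad], 5), collapse = ", "))
  invisible(df)
}

#' Assign each variant to its host enhancer by containment
#'
#' A variant's 1-based position is converted to the 0-based half-open
#' region convention; variants outside every enhancer get `NA`.
#'
#' @param variants variant data.frame (`chrom`, `pos` 1-based).
#' @param regions named [GenomicRanges::GRanges] of enhancers.
#' @return the data.frame with an added/updated `enhancer` column.
#' @export
assignEnhancer <- function(variants, regions) {
  vr <- GRanges(variants$chrom, IRanges(variants$pos, width = 1L))
  hits <- findOverlaps(vr, regions, ignore.strand = TRUE, select = "first")
  variants$enhancer <- names(regions)[hits]
  variants
}

#' Apply an SNV to an enhancer sequence
#'
#' Substitutes the single base; the reference base in the sequence must
#' match the variant's `ref` allele (a mismatch signals stale coordinates or
#' a genome-build mix-up and raises an error with no partial output).
#'
#' @param sequence enhancer sequence (character).
#' @param region the enhancer's [GenomicRanges::GRanges] (single range).
#' @param variant one-row variant data.frame (`pos` 1-based genomic, `ref`,
#'   `alt`).
#' @return the mutant sequence (same length).
#' @export
applyVariant <- function(sequence, region, variant) {
  sequence <- as.character(sequence)
  off <- variant$pos - start(region) + 1L   # 1-based offset in sequence
  if (off < 1L || off > nchar(sequence))
    stop("variant position outside its enhancer region")
  have <- substr(sequence, off, off)
  if (!identical(toupper(have), toupper(variant$ref)))
    stop("reference mismatch at ", variant$chrom, ":", variant$pos,
         " (sequence has ", have, ", variant says ", variant$ref, ")")
  substr(sequence, off, off) <- toupper(variant$alt)
  sequence
}

#' Score variants against an ensemble of thermodynamic models
#'
#' For every variant, the mutant enhancer sequence is re-annotated (sites
#' may appear, disappear or change strength) and each model predicts its
#' activity. The per-model effect is `percentile(mutant) - percentile(WT)`,
#' with percentiles taken against that model's wild-type prediction
#' distribution over all enhancers. A variant whose alternative allele
#' equals its reference scores exactly 0 in every model.
#'
#' @param models list of [ThermoModel-class] objects.
#' @param dataset an [EnhancerDataset-class] (provides WT sequences and the
#'   reference prediction distribution).
#' @param variants variant data.frame with an `enhancer` column (see
#'   [assignEnhancer()]).
#' @param motifs named motif list.
#' @param thresholds named LLR thresholds (default: p = 1e-4 thresholds).
#' @return list with `delta` (matrix, variants x models, percentile
#'   points), `wtPercentile` (matrix of host-enhancer WT percentiles) and
#'   the input `variants`.
#' @export
scoreVariantsEnsemble <- function(models, dataset, variants, motifs,
                                  thresholds = NULL) {
  if (is.null(thresholds))
    thresholds <- vapply(motifs, pvalueThreshold, numeric(1), p = 1e-4)
  if (any(is.na(variants$enhancer)))
    stop("all variants must be assigned to a host enhancer")
  seqs <- as.character(enhancerSequences(dataset))
  regions <- enhancerRegions(dataset)
  wtAnn <- annotateSiteSet(seqs, motifs, thresholds)
  names(wtAnn) <- names(regions)
  mutAnn <- vector("list", nrow(variants))
  for (v in seq_len(nrow(variants))) {
    enh <- variants$enhancer[v]
    mutSeq <- applyVariant(seqs[[enh]], regions[enh], variants[v, ])
    mutAnn[[v]] <- annotateSites(mutSeq, motifs, thresholds)
  }
  delta <- matrix(NA_real_, nrow = nrow(variants), ncol = length(models),
                  dimnames = list(variants$id, NULL))
  wtPct <- matrix(NA_real_, nrow = nrow(variants), ncol = length(models),
                  dimnames = list(variants$id, NULL))
  for (m in seq_along(models)) {
    model <- models[[m]]
    wtCompiled <- .compileSet(wtAnn, model)
    wtPred <- predictExpressionSet(wtCompiled, model)
    hostPct <- percentileNormalize(wtPred[variants$enhancer], wtPred)
    mutPred <- vapply(mutAnn, predictExpression, numeric(1), model = model)
    delta[, m] <- percentileNormalize(mutPred, wtPred) - hostPct
    wtPct[, m] <- hostPct
  }
  list(delta = delta, wtPercentile = wtPct, variants = variants)
}

#' Per-TF binding change caused by a variant
#'
#' For each TF, compares the best window LLR overlapping the variant
#' position between the mutant and wild-type alleles, normalized by a
#' reference maximum LLR for that TF (by default the maximum called-site
#' LLR across the analyzed enhancer collection; the PWM's theoretical
#' maximum is the `"theoretical"` alternative). Windows are only considered
#' when at least one allele reaches the TF's site threshold; otherwise the
#' TF's change is 0. The TF with the largest absolute normalized change is
#' the variant's proposed mechanism.
#'
#' @param motifs named motif list.
#' @param wtSequence,mutSequence the two alleles of the enhancer sequence
#'   (equal length).
#' @param variantOffset 0-based offset of the variant within the sequence.
#' @param thresholds named LLR thresholds.
#' @param siteLLRReference named per-TF reference maximum LLR (e.g. from
#'   [collectionMaxLLR()]); `NULL` uses each motif's theoretical maximum.
#' @return list with `change` (named per-TF normalized delta-LLR) and
#'   `topMechanism` (list `tf`, `value`).
#' @export
bindingChange <- function(motifs, wtSequence, mutSequence, variantOffset,
                          thresholds, siteLLRReference = NULL) {
  if (nchar(wtSequence) != nchar(mutSequence))
    stop("allele sequences must have equal length")
  out <- setNames(numeric(length(motifs)), names(motifs))
  for (nm in names(motifs)) {
    motif <- motifs[[nm]]
    L <- motifLength(motif)
    best <- function(seqch) {
      sc <- scanMotif(seqch, motif)
      sc <- sc[sc$start >= variantOffset - L + 1L &
                 sc$start <= variantOffset, , drop = FALSE]
      if (!nrow(sc)) -Inf else max(sc$llr)
    }
    bw <- best(wtSequence)
    bm <- best(mutSequence)
    if (max(bw, bm) < thresholds[[nm]] || !is.finite(max(bw, bm))) next
    ref <- if (is.null(siteLLRReference)) maxLLR(motif)
           else siteLLRReference[[nm]]
    out[nm] <- (bm - bw) / ref
  }
  top <- which.max(abs(out))
  list(change = out,
       topMechanism = list(tf = names(out)[top], value = unname(out[top])))
}

#' Maximum called-site LLR per TF over a sequence collection
#'
#' The normalization denominator for [bindingChange()]: the strongest site
#' LLR each TF attains anywhere in the analyzed enhancers.
#'
#' @param sequences character vector / DNAStringSet.
#' @param motifs named motif list.
#' @param thresholds named LLR thresholds.
#' @return named numeric per TF (falls back to the theoretical maximum when
#'   a TF has no called site).
#' @export
collectionMaxLLR <- function(sequences, motifs, thresholds) {
  seqs <- as.character(sequences)
  out <- setNames(numeric(length(motifs)), names(motifs))
  for (nm in names(motifs)) {
    mx <- -Inf
    for (s in seqs) {
      sites <- callSites(s, motifs[[nm]], thresholds[[nm]])
      if (nrow(sites)) mx <- max(mx, sites$llr)
    }
    out[nm] <- if (is.finite(mx)) mx else maxLLR(motifs[[nm]])
  }
  out
}

#' Prioritize variants per model
#'
#' Ranks variants by predicted impact within each model (absolute delta by
#' default; signed ranking via `signed = TRUE` takes the most negative
#' first) and returns the top `K` ids, with ties broken by variant id for
#' determinism.
#'
#' @param delta matrix of per-model deltas (variants x models, rownames =
#'   variant ids) as returned in [scoreVariantsEnsemble()]`$delta`.
#' @param K how many variants to shortlist (`0 < K <=` number of variants).
#' @param signed rank by signed delta instead of |delta|.
#' @return list (one per model) of K variant ids.
#' @export
prioritizeVariants <- function(delta, K, signed = FALSE) {
  if (K <= 0) stop("K must be positive")
  if (K > nrow(delta)) stop("K exceeds the number of scored variants")
  ids <- rownames(delta)
  lapply(seq_len(ncol(delta)), function(m) {
    key <- if (signed) delta[, m] else -abs(delta[, m])
    ids[order(key, ids)][seq_len(K)]
  })
}

#' Precision of prioritized variant sets against a true set
#'
#' Model-based strategy: one precision (fraction of the top-K that belong
#' to the true set) per ensemble model. Location-based baseline: K variants
#' sampled uniformly from the in-enhancer variant pool, `nRep` times.
#' Random baseline: K sampled from the full variant collection, `nRep`
#' times. A two-sample t-test compares the model-based and location-based
#' precision distributions.
#'
#' @param prioritized list of per-model top-K id sets (see
#'   [prioritizeVariants()]).
#' @param trueSet character vector of true-positive variant ids (non-empty).
#' @param inEnhancerIds ids of all variants inside enhancers.
#' @param allIds ids of the full variant collection.
#' @param nRep resampling repetitions for the baselines (default 244,
#'   matching the ensemble size convention).
#' @param seed integer seed for the resampling.
#' @return list with `modelPrecision`, `locationPrecision`,
#'   `randomPrecision` (numeric vectors), `K`, and `tTest` (model vs
#'   location, a `htest`).
#' @export
precisionEval <- function(prioritized, trueSet, inEnhancerIds,
                          allIds = inEnhancerIds, nRep = 244, seed = 1) {
  if (!length(trueSet)) stop("empty true set")
  K <- length(prioritized[[1]])
  prec <- function(ids) mean(ids %in% trueSet)
  modelPrecision <- vapply(prioritized, prec, numeric(1))
  set.seed(seed)
  locationPrecision <- replicate(nRep, prec(sample(inEnhancerIds, K)))
  randomPrecision <- replicate(nRep, prec(sample(allIds, K)))
  tt <- if (length(modelPrecision) < 2 ||
            (sd(modelPrecision) == 0 && sd(locationPrecision) == 0)) NULL
        else t.test(modelPrecision, locationPrecision)
  list(modelPrecision = modelPrecision,
       locationPrecision = locationPrecision,
       randomPrecision = randomPrecision, K = K, tTest = tt)
}

#' Summarize per-variant ensemble impact
#'
#' @param scored result of [scoreVariantsEnsemble()].
#' @param mechanisms optional list of [bindingChange()] results parallel to
#'   the variants.
#' @return data.frame: id, enhancer, ensemble mean and sd of delta, and
#'   (when mechanisms are given) the top mechanism TF and its normalized
#'   delta-LLR.
#' @export
variantImpactTable <- function(scored, mechanisms = NULL) {
  out <- data.frame(
    id = scored$variants$id,
    enhancer = scored$variants$enhancer,
    meanDelta = rowMeans(scored$delta),
    sdDelta = apply(scored$delta, 1L, sd)
  )
  if (!is.null(mechanisms)) {
    out$mechanismTF <- vapply(mechanisms, function(m) m$topMechanism$tf,
                              character(1))
    out$mechanismDeltaLLR <- vapply(mechanisms, function(m)
      m$topMechanism$value, numeric(1))
  }
  out
}
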