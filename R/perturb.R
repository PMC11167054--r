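#' Percentile of a value against a reference distribution
#'
#' `100 * #{reference <= value} / |reference|`. In perturbation and variant
#' analyses the reference is always the wild-type prediction distribution of
#' the scoring model, so every delta is bounded in [-100, 100].
#'
#' @param value numeric value(s).
#' @param referenceValues non-empty numeric reference distribution.
#' @return percentile(s) in [0, 100].
#' @export
percentileNormalize <- function(value, referenceValues) {
  if (!length(referenceValues)) stop("empty reference")
  vapply(value, function(v) 100 * mean(referenceValues <= v), numeric(1))
}

.perturbationResult <- function(modelId, perturbation, delta) {
  structure(list(model = modelId, perturbation = perturbation,
                 delta = delta),
            class = "PerturbationResult")
}

.wtContext <- function(model, compiled) {
  wt <- predictExpressionSet(compiled, model)
  list(pred = wt, ref = wt, pct = percentileNormalize(wt, wt))
}

#' In silico TF knock-down
#'
#' Removes a TF from the model by setting its binding parameter `K` to 0 —
#' its sites can never be bound — and reports, per enhancer, the change in
#' percentile-normalized predicted activity, `percentile(perturbed) -
#' percentile(WT)`, where percentiles are taken against the model's
#' wild-type prediction distribution over all enhancers. Knocking down an
#' activator yields negative deltas on its targets.
#'
#' @param model a [ThermoModel-class].
#' @param annotations list of `SiteAnnotation`s (all enhancers, both
#'   classes).
#' @param tfName TF to remove (must be in the model).
#' @param modelId optional identifier stored in the result.
#' @return a `PerturbationResult`: list with `model`, `perturbation` and
#'   named `delta` (percentile points).
#' @export
knockdown <- function(model, annotations, tfName, modelId = NA) {
  if (!tfName %in% model@tfNames) stop("unknown TF: ", tfName)
  compiled <- .compileSet(annotations, model)
  wt <- .wtContext(model, compiled)
  kd <- model
  kd@binding[tfName] <- 0
  pred <- predictExpressionSet(compiled, kd)
  delta <- percentileNormalize(pred, wt$ref) - wt$pct
  names(delta) <- names(annotations)
  .perturbationResult(modelId, paste0("KD:", tfName), delta)
}

#' Nullify one TF-TF interaction
#'
#' Sets the pair's cooperativity `omega` to 1 (no interaction) and reports
#' per-enhancer percentile deltas exactly as [knockdown()] does.
#'
#' @inheritParams knockdown
#' @param pair character vector of the two TF names (order irrelevant).
#' @export
nullInteraction <- function(model, annotations, pair, modelId = NA) {
  cp <- model@coop
  hit <- which((cp$tf1 == pair[1] & cp$tf2 == pair[2]) |
                 (cp$tf1 == pair[2] & cp$tf2 == pair[1]))
  if (!length(hit)) stop("unknown interaction pair: ",
                         paste(pair, collapse = "-"))
  compiled <- .compileSet(annotations, model)
  wt <- .wtContext(model, compiled)
  nullModel <- model
  nullModel@coop$omega[hit] <- 1
  pred <- predictExpressionSet(compiled, nullModel)
  delta <- percentileNormalize(pred, wt$ref) - wt$pct
  names(delta) <- names(annotations)
  .perturbationResult(modelId, paste0("NULL:", pair[1], "-", pair[2]), delta)
}

#' Run all knock-downs and interaction nullifications over an ensemble
#'
#' @param models list of [ThermoModel-class] objects (the final ensemble).
#' @param annotations list of `SiteAnnotation`s.
#' @param tfs TFs to knock down (default: all modeled TFs).
#' @param pairs list of TF pairs to nullify (default: all model
#'   interactions).
#' @return flat list of `PerturbationResult`s (one per model x
#'   perturbation).
#' @export
perturbEnsemble <- function(models, annotations, tfs = NULL, pairs = NULL) {
  if (is.null(tfs)) tfs <- models[[1]]@tfNames
  if (is.null(pairs) && nrow(models[[1]]@coop))
    pairs <- lapply(seq_len(nrow(models[[1]]@coop)), function(i)
      c(models[[1]]@coop$tf1[i], models[[1]]@coop$tf2[i]))
  out <- list()
  for (m in seq_along(models)) {
    compiled <- .compileSet(annotations, models[[m]])
    names(compiled) <- names(annotations)
    for (tf in tfs)
      out[[length(out) + 1L]] <- knockdown(models[[m]], compiled, tf,
                                           modelId = m)
    for (p in pairs)
      out[[length(out) + 1L]] <- nullInteraction(models[[m]], compiled, p,
                                                 modelId = m)
  }
  out
}

#' Summarize perturbation effects across an ensemble
#'
#' For each perturbation: per model, the fraction of enhancers affected
#' (|delta| at or above the threshold) and the mean delta over affected
#' enhancers, then the ensemble mean and standard deviation of both, split
#' by enhancer class. A Wilcoxon rank-sum test compares positive- versus
#' negative-class |delta| (ensemble-mean deltas), with Benjamini-Hochberg
#' adjustment across perturbations.
#'
#' @param results list of `PerturbationResult`s from [perturbEnsemble()].
#' @param labels named class labels of the enhancers
#'   (`positive`/`negative`).
#' @param threshold "affected" threshold in percentile points (default 5).
#' @return data.frame with one row per perturbation: `fracAffected` (mean,
#'   sd), `meanOverAffected` (mean, sd; NA when nothing is affected),
#'   class-split versions, and the adjusted Wilcoxon p-value.
#' @export
summarizePerturbations <- function(results, labels, threshold = 5) {
  stopifnot(length(results) >= 1)
  perts <- unique(vapply(results, `[[`, character(1), "perturbation"))
  lab <- as.character(labels)
  rows <- lapply(perts, function(p) {
    rs <- Filter(function(r) r$perturbation == p, results)
    perModel <- function(f) vapply(rs, function(r) f(r$delta), numeric(1))
    fracAll <- perModel(function(d) mean(abs(d) >= threshold))
    fracPos <- perModel(function(d)
      mean(abs(d[lab == "positive"]) >= threshold))
    fracNeg <- perModel(function(d)
      mean(abs(d[lab == "negative"]) >= threshold))
    meanAff <- perModel(function(d) {
      a <- d[abs(d) >= threshold]
      if (length(a)) mean(a) else NA_real_
    })
    ensembleDelta <- rowMeans(vapply(rs, `[[`, numeric(length(rs[[1]]$delta)),
                                     "delta"))
    dPos <- abs(ensembleDelta[lab == "positive"])
    dNeg <- abs(ensembleDelta[lab == "negative"])
    pval <- if (length(dPos) && length(dNeg))
      suppressWarnings(wilcox.test(dPos, dNeg)$p.value) else NA_real_
    data.frame(
      perturbation = p,
      fracAffected = mean(fracAll), fracAffectedSD = sd(fracAll),
      fracAffectedPos = mean(fracPos), fracAffectedNeg = mean(fracNeg),
      meanOverAffected = mean(meanAff, na.rm = TRUE),
      meanOverAffectedSD = sd(meanAff, na.rm = TRUE),
      anyAffected = any(!is.na(meanAff)),
      wilcoxP = pval
    )
  })
  out <- do.call(rbind, rows)
  out$meanOverAffected[!out$anyAffected] <- NA_real_
  out$wilcoxPAdj <- p.adjust(out$wilcoxP, method = "BH")
  rownames(out) <- NULL
  out
}

#' Ensemble-mean perturbation deltas
#'
#' @param results `PerturbationResult` list.
#' @param perturbation perturbation tag, e.g. `"KD:TF1"`.
#' @return named numeric of per-enhancer ensemble-mean deltas.
#' @export
ensembleMeanDelta <- function(results, perturbation) {
  rs <- Filter(function(r) r$perturbation == perturbation, results)
  if (!length(rs)) stop("no results for perturbation ", perturbation)
  rowMeans(vapply(rs, `[[`, numeric(length(rs[[1]]$delta)), "delta"))
}

#' Define a TF's regulon from ensemble knock-down deltas
#'
#' Enhancers whose ensemble-mean knock-down delta is at or below
#' `-threshold` are the TF's activated targets (their predicted activity
#' drops when the TF is removed); those at or above `+threshold` are
#' repressed targets. The two sets are disjoint by construction.
#'
#' @param results `PerturbationResult` list from [perturbEnsemble()].
#' @param tfName TF whose knock-down defines the regulon.
#' @param threshold percentile-point threshold (default 5).
#' @return list of class `Regulon` with `tf`, `activated`, `repressed`,
#'   `threshold` and the `meanDelta` vector.
#' @export
defineRegulon <- function(results, tfName, threshold = 5) {
  md <- ensembleMeanDelta(results, paste0("KD:", tfName))
  structure(list(
    tf = tfName,
    activated = names(md)[md <= -threshold],
    repressed = names(md)[md >= threshold],
    threshold = threshold,
    meanDelta = md
  ), class = "Regulon")
}

#' Hypergeometric enrichment (upper tail)
#'
#' Probability of observing at least `overlapK` successes when drawing
#' `predictedN` items from a universe of `universeN` containing `observedK`
#' successes: `P(X >= overlapK)` for X hypergeometric, computed by exact
#' summation. Used to test whether a predicted regulon is enriched for
#' experimentally observed TF targets.
#'
#' @param universeN universe size (e.g. all modeled enhancers transcribed
#'   in the control condition).
#' @param observedK experimentally supported targets in the universe.
#' @param predictedN size of the predicted set.
#' @param overlapK overlap between predicted and observed sets.
#' @return upper-tail probability.
#' @examples
#' hypergeomEnrichment(10, 5, 4, 4)   # 5/210
#' hypergeomEnrichment(720, 193, 60, 29)  # the canonical regulon test
#' @export
hypergeomEnrichment <- function(universeN, observedK, predictedN, overlapK) {
  if (observedK > universeN || predictedN > universeN ||
      overlapK > min(observedK, predictedN) || any(c(universeN, observedK,
                                                     predictedN,
                                                     overlapK) < 0))
    stop("inconsistent counts")
  phyper(overlapK - 1, observedK, universeN - observedK, predictedN,
         lower.tail = FALSE)
}

#' Assemble the tripartite TF-enhancer-gene regulatory network
#'
#' TF-to-enhancer edges come from the regulons (sign = activated or
#' repressed target); enhancer-to-gene edges are added when a gene's TSS
#' lies within `proximityKb` of the enhancer, or when a chromatin
#' interaction pair links the enhancer's locus to the gene's TSS locus
#' (which may be megabases away).
#'
#' @param regulons list of `Regulon`s (see [defineRegulon()]).
#' @param enhancers named [GenomicRanges::GRanges] of enhancer regions.
#' @param geneAnnotations data.frame with columns `gene`, `chrom`, `tss`
#'   (1-based TSS coordinate).
#' @param interactionPairs optional data.frame with columns `chrom1`,
#'   `start1`, `end1`, `chrom2`, `start2`, `end2` (BEDPE-like anchors,
#'   0-based half-open).
#' @param proximityKb TSS proximity window in kb (default 10).
#' @return list with `nodes` (id, layer) and `edges` (from, to, type)
#'   data.frames; layers are `TF`, `enhancer`, `gene`.
#' @export
assembleGRN <- function(regulons, enhancers, geneAnnotations,
                        interactionPairs = NULL, proximityKb = 10) {
  edges <- list()
  for (r in regulons) {
    if (length(r$activated))
      edges[[length(edges) + 1L]] <- data.frame(
        from = r$tf, to = r$activated, type = "activates")
    if (length(r$repressed))
      edges[[length(edges) + 1L]] <- data.frame(
        from = r$tf, to = r$repressed, type = "represses")
  }
  usedEnh <- unique(unlist(lapply(regulons, function(r)
    c(r$activated, r$repressed))))
  genes <- GRanges(geneAnnotations$chrom,
                   IRanges(geneAnnotations$tss, width = 1L))
  names(genes) <- geneAnnotations$gene
  if (length(usedEnh)) {
    enh <- enhancers[usedEnh]
    prox <- findOverlaps(enh + proximityKb * 1000, genes,
                         ignore.strand = TRUE)
    if (length(prox))
      edges[[length(edges) + 1L]] <- data.frame(
        from = names(enh)[queryHits(prox)],
        to = names(genes)[subjectHits(prox)], type = "proximity")
    if (!is.null(interactionPairs) && nrow(interactionPairs)) {
      need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
      if (!all(need %in% names(interactionPairs)))
        stop("malformed interaction pairs: need columns ",
             paste(need, collapse = ", "))
      a1 <- GRanges(interactionPairs$chrom1,
                    IRanges(interactionPairs$start1 + 1L,
                            interactionPairs$end1))
      a2 <- GRanges(interactionPairs$chrom2,
                    IRanges(interactionPairs$start2 + 1L,
                            interactionPairs$end2))
      for (swap in c(FALSE, TRUE)) {
        eAnchor <- if (swap) a2 else a1
        gAnchor <- if (swap) a1 else a2
        he <- findOverlaps(enh, eAnchor, ignore.strand = TRUE)
        hg <- findOverlaps(genes, gAnchor, ignore.strand = TRUE)
        if (length(he) && length(hg)) {
          eMap <- split(queryHits(he), subjectHits(he))
          gMap <- split(queryHits(hg), subjectHits(hg))
          common <- intersect(names(eMap), names(gMap))
          for (k in common) {
            grid <- expand.grid(e = eMap[[k]], g = gMap[[k]])
            edges[[length(edges) + 1L]] <- data.frame(
              from = names(enh)[grid$e], to = names(genes)[grid$g],
              type = "interaction")
          }
        }
      }
    }
  }
  edges <- if (length(edges)) unique(do.call(rbind, edges))
           else data.frame(from = character(0), to = character(0),
                           type = character(0))
  rownames(edges) <- NULL
  tfs <- unique(vapply(regulons, `[[`, character(1), "tf"))
  geneNodes <- unique(edges$to[edges$type %in% c("proximity",
                                                 "interaction")])
  nodes <- data.frame(
    id = c(tfs, usedEnh, geneNodes),
    layer = rep(c("TF", "enhancer", "gene"),
                c(length(tfs), length(usedEnh), length(geneNodes)))
  )
  list(nodes = nodes, edges = edges)
}

#' Write a network as node / edge TSV files
#'
#' @param grn list from [assembleGRN()].
#' @param nodePath,edgePath output TSV paths.
#' @return invisibly, a list of the two paths.
#' @export
writeGRN <- function(grn, nodePath, edgePath) {
  write.table(grn$nodes, nodePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(grn$edges, edgePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(nodes = nodePath, edges = edgePath))
}
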