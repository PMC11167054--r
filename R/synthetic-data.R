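#' Configuration for the synthetic enhancer benchmark
#'
#' Bundles every knob of the synthetic-data generator: motif shape, dataset
#' composition, the planted regulatory architecture that separates the two
#' enhancer classes, and the replicate-noise model of the peak tracks.
#'
#' The defaults emulate the statistical structure of the studied system at
#' desk scale: two enhancer classes (transcribed vs silent) whose sequences
#' differ in activator/repressor motif content and in planted
#' activator-pair adjacencies, with the thermodynamic-model training-set
#' composition of 200 positive and 600 negative enhancers.
#'
#' @param nMotifs number of PWMs to generate.
#' @param motifLength motif length in bp (>= 4).
#' @param nPositive,nNegative class sizes.
#' @param enhancerLength enhancer length in bp.
#' @param backgroundFreqs length-4 base frequencies (A, C, G, T) of the
#'   0-order background; must sum to 1 within 1e-9.
#' @param plantingScheme data.frame with columns `tf` (motif name), `role`
#'   (`activator`/`repressor`/`neutral`), `nPos`, `nNeg` (sites planted per
#'   enhancer of each class).
#' @param coopPairs data.frame with columns `tf1`, `tf2`, `nPos`, `nNeg`
#'   (adjacent site pairs planted per enhancer of each class); planted pairs
#'   are placed within `coopDistance` of each other.
#' @param coopDistance maximum start-to-start spacing of planted pairs (bp).
#' @param replicateNoise probability that a true peak is missed in any one
#'   post-treatment replicate track.
#' @param nDecoys near-consensus decoy sites (one base off activator
#'   consensus) planted per enhancer; targets for site-creating variants.
#' @param dominantRange range of the dominant-base probability used when
#'   sampling PWM columns.
#' @param siteMode how planted site sequences are drawn: `"sample"`
#'   (default) samples each base from the PWM column, so site strengths are
#'   dispersed the way genomic sites are; `"consensus"` plants the
#'   consensus sequence, guaranteeing every planted site is called at the
#'   strict site threshold.
#' @param seed integer seed; all generator output is byte-identical under a
#'   fixed seed.
#' @return a validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nMotifs = 5,
                            motifLength = 8,
                            nPositive = 200,
                            nNegative = 600,
                            enhancerLength = 500,
                            backgroundFreqs = rep(0.25, 4),
                            plantingScheme = data.frame(
                              tf = c("TF1", "TF2", "TF3"),
                              role = c("activator", "repressor", "neutral"),
                              nPos = c(3, 0, 1),
                              nNeg = c(1, 2, 1)
                            ),
                            coopPairs = data.frame(
                              tf1 = "TF1", tf2 = "TF3",
                              nPos = 1, nNeg = 0
                            ),
                            coopDistance = 50,
                            replicateNoise = 0,
                            nDecoys = 1,
                            dominantRange = c(0.8, 0.95),
                            siteMode = c("sample", "consensus"),
                            seed = 1) {
  siteMode <- match.arg(siteMode)
  cfg <- list(nMotifs = nMotifs, motifLength = motifLength,
              nPositive = nPositive, nNegative = nNegative,
              enhancerLength = enhancerLength,
              backgroundFreqs = backgroundFreqs,
              plantingScheme = plantingScheme, coopPairs = coopPairs,
              coopDistance = coopDistance, replicateNoise = replicateNoise,
              nDecoys = nDecoys, dominantRange = dominantRange,
              siteMode = siteMode, seed = seed)
  counts <- c(nMotifs, motifLength, nPositive, nNegative, enhancerLength,
              nDecoys)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (motifLength < 4) stop("motifLength must be >= 4")
  if (abs(sum(backgroundFreqs) - 1) > 1e-9)
    stop("backgroundFreqs must sum to 1 (within 1e-9)")
  if (any(backgroundFreqs <= 0)) stop("backgroundFreqs must be positive")
  if (replicateNoise < 0 || replicateNoise > 1)
    stop("replicateNoise must be a probability")
  if (length(dominantRange) != 2L || dominantRange[1] > dominantRange[2] ||
      dominantRange[1] <= 0.25 || dominantRange[2] >= 1)
    stop("dominantRange must be an increasing range within (0.25, 1)")
  motifNames <- paste0("TF", seq_len(nMotifs))
  refd <- unique(c(plantingScheme$tf, coopPairs$tf1, coopPairs$tf2))
  if (!all(refd %in% motifNames))
    stop("plantingScheme/coopPairs reference motifs beyond nMotifs: ",
         paste(setdiff(refd, motifNames), collapse = ", "))
  if (!all(plantingScheme$role %in% c("activator", "repressor", "neutral")))
    stop("roles must be activator/repressor/neutral")
  structure(cfg, class = "SyntheticConfig")
}

#' Generate synthetic PWMs
#'
#' Samples one PWM per motif: each column has a dominant base whose
#' probability is drawn uniformly from `config$dominantRange`, the remaining
#' mass split equally among the other bases. Deterministic under the config
#' seed.
#'
#' @param config a [syntheticConfig()] object.
#' @return named list of [Motif-class] objects (`TF1`, `TF2`, ...).
#' @export
generatePWMs <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  out <- list()
  for (i in seq_len(config$nMotifs)) {
    name <- paste0("TF", i)
    L <- config$motifLength
    dom <- sample.int(4L, L, replace = TRUE)
    p <- runif(L, config$dominantRange[1], config$dominantRange[2])
    m <- matrix(rep((1 - p) / 3, each = 4L), nrow = 4L)
    m[cbind(dom, seq_len(L))] <- p
    rownames(m) <- .BASES
    out[[name]] <- Motif(name, m)
  }
  out
}

.sampleBackground <- function(n, freqs) {
  sample(.BASES, n, replace = TRUE, prob = freqs)
}

.sampleSiteFromPWM <- function(motif) {
  m <- motifMatrix(motif)
  vapply(seq_len(ncol(m)), function(k) sample(.BASES, 1L, prob = m[, k]),
         character(1))
}

.revcompChars <- function(ch) rev(c(A = "T", C = "G", G = "C", T = "A")[ch])

## place an element of length w avoiding occupied intervals; returns 0-based
## start or NA. anchor: optional c(lo, hi) window of admissible starts.
.placeElement <- function(occupied, enhLen, w, anchor = NULL,
                          maxTries = 200L) {
  lo <- if (is.null(anchor)) 0L else max(0L, anchor[1])
  hi <- if (is.null(anchor)) enhLen - w else min(enhLen - w, anchor[2])
  if (hi < lo) return(NA_integer_)
  for (t in seq_len(maxTries)) {
    s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    if (!any(s < occupied$end & (s + w) > occupied$start)) return(s)
  }
  NA_integer_
}

#' Generate a labeled synthetic enhancer set with planted architecture
#'
#' Builds `nPositive + nNegative` enhancer sequences on a synthetic
#' chromosome: background sampled from `backgroundFreqs`, with binding sites
#' (sampled from the PWMs), adjacent cooperative site pairs, and
#' near-consensus decoys planted per the config's `plantingScheme` and
#' `coopPairs`. Planted elements never overlap each other. The ground truth
#' records every planted element and the per-TF roles.
#'
#' @param config a [syntheticConfig()].
#' @param pwms motif list from [generatePWMs()].
#' @return list with elements `dataset` (an [EnhancerDataset-class], labels
#'   positive/negative) and `truth` (class `GroundTruth`: `roles`, `sites`
#'   data.frame with 0-based in-enhancer coordinates, `decoys`, and the
#'   flipped decoy column bookkeeping used by [generateVariants()]).
#' @export
generateEnhancerSet <- function(config, pwms) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed + 1L)
  scheme <- config$plantingScheme
  coop <- config$coopPairs
  if (!all(c(scheme$tf, coop$tf1, coop$tf2) %in% names(pwms)))
    stop("plantingScheme references motifs absent from 'pwms'")
  nTot <- config$nPositive + config$nNegative
  enhLen <- config$enhancerLength
  gap <- 200L
  starts0 <- (seq_len(nTot) - 1L) * (enhLen + gap)   # 0-based
  regions <- GRanges(rep("chrS", nTot), IRanges(starts0 + 1L,
                                                starts0 + enhLen))
  names(regions) <- regionIds(regions)
  label <- rep(c("positive", "negative"),
               c(config$nPositive, config$nNegative))

  activators <- scheme$tf[scheme$role == "activator"]
  seqs <- character(nTot)
  siteRecords <- list()
  for (e in seq_len(nTot)) {
    chars <- .sampleBackground(enhLen, config$backgroundFreqs)
    occupied <- data.frame(start = integer(0), end = integer(0))
    cls <- label[e]
    plant <- function(tf, start, kind, flippedCol = NA_integer_) {
      motif <- pwms[[tf]]
      L <- motifLength(motif)
      strand <- sample(c("+", "-"), 1L)
      if (kind == "site") {
        site <- if (config$siteMode == "consensus")
          strsplit(consensusSequence(motif), "")[[1]]
        else .sampleSiteFromPWM(motif)
      } else {  # near-consensus decoy: worst base at the flipped column
        site <- strsplit(consensusSequence(motif), "")[[1]]
        site[flippedCol] <- .BASES[which.min(motifMatrix(motif)[, flippedCol])]
      }
      if (strand == "-") site <- .revcompChars(site)
      chars[(start + 1L):(start + L)] <<- site
      occupied <<- rbind(occupied,
                         data.frame(start = start, end = start + L))
      siteRecords[[length(siteRecords) + 1L]] <<- data.frame(
        enhancer = names(regions)[e], tf = tf, start = start, width = L,
        strand = strand, kind = kind, flippedCol = flippedCol
      )
    }
    ## cooperative pairs first (they need adjacent room)
    for (r in seq_len(nrow(coop))) {
      nPair <- if (cls == "positive") coop$nPos[r] else coop$nNeg[r]
      for (k in seq_len(nPair)) {
        L1 <- motifLength(pwms[[coop$tf1[r]]])
        L2 <- motifLength(pwms[[coop$tf2[r]]])
        s1 <- .placeElement(occupied, enhLen, L1 + L2 + config$coopDistance)
        if (is.na(s1)) stop("enhancer too short for requested plantings")
        plant(coop$tf1[r], s1, "site")
        s2 <- .placeElement(occupied, enhLen, L2,
                            anchor = c(s1 + L1,
                                       s1 + config$coopDistance))
        if (is.na(s2)) stop("enhancer too short for requested plantings")
        plant(coop$tf2[r], s2, "site")
      }
    }
    ## individual sites
    for (r in seq_len(nrow(scheme))) {
      nSite <- if (cls == "positive") scheme$nPos[r] else scheme$nNeg[r]
      for (k in seq_len(nSite)) {
        L <- motifLength(pwms[[scheme$tf[r]]])
        s <- .placeElement(occupied, enhLen, L)
        if (is.na(s)) stop("enhancer too short for requested plantings")
        plant(scheme$tf[r], s, "site")
      }
    }
    ## decoys for site-creating variants
    if (config$nDecoys > 0 && length(activators)) {
      for (k in seq_len(config$nDecoys)) {
        tf <- sample(activators, 1L)
        motif <- pwms[[tf]]
        L <- motifLength(motif)
        flip <- which.max(apply(llrMatrix(motif), 2L, max) -
                            apply(llrMatrix(motif), 2L, min))
        s <- .placeElement(occupied, enhLen, L)
        if (is.na(s)) stop("enhancer too short for requested plantings")
        plant(tf, s, "decoy", flippedCol = flip)
      }
    }
    seqs[e] <- paste(chars, collapse = "")
  }
  sites <- if (length(siteRecords)) do.call(rbind, siteRecords)
           else data.frame(enhancer = character(0), tf = character(0),
                           start = integer(0), width = integer(0),
                           strand = character(0), kind = character(0),
                           flippedCol = integer(0))
  roles <- setNames(rep("neutral", length(pwms)), names(pwms))
  roles[scheme$tf] <- scheme$role
  truth <- structure(list(roles = roles,
                          sites = sites[sites$kind == "site", , drop = FALSE],
                          decoys = sites[sites$kind == "decoy", ,
                                         drop = FALSE]),
                     class = "GroundTruth")
  dataset <- EnhancerDataset(regions, DNAStringSet(setNames(seqs,
                                                            names(regions))),
                             label)
  list(dataset = dataset, truth = truth)
}

#' Generate replicate peak tracks consistent with the labeling rule
#'
#' Emits four scored peak tracks (two post-treatment replicates, two
#' pre-treatment replicates) such that positive enhancers carry a peak in
#' both post-treatment replicates and in neither pre-treatment replicate,
#' and negative enhancers carry none. With `replicateNoise > 0`, each
#' positive's peak is independently dropped from each post replicate with
#' that probability, so some true positives lose two-replicate support and
#' become `excluded` under [labelRegions()].
#'
#' @param dataset a labeled [EnhancerDataset-class].
#' @param config a [syntheticConfig()] (`replicateNoise` and `seed` used).
#' @param dir optional directory; when given, the four tracks are also
#'   written as scored BED files `post_rep1.bed` ... `pre_rep2.bed`.
#' @return named list of GRanges: `post1`, `post2`, `pre1`, `pre2`.
#' @export
generatePeakTracks <- function(dataset, config, dir = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed + 2L)
  regions <- enhancerRegions(dataset)
  pos <- which(enhancerLabels(dataset) == "positive")
  mkTrack <- function(keep) {
    if (!length(keep)) {
      gr <- GRanges()
      gr$score <- numeric(0)
      return(gr)
    }
    r <- regions[keep]
    w <- width(r)
    peak <- GRanges(seqnames(r),
                    IRanges(start(r) + floor(w * 0.3),
                            start(r) + ceiling(w * 0.7)))
    peak$score <- 10
    unname(peak)
  }
  keep1 <- pos[rbinom(length(pos), 1L, 1 - config$replicateNoise) == 1L]
  keep2 <- pos[rbinom(length(pos), 1L, 1 - config$replicateNoise) == 1L]
  tracks <- list(post1 = mkTrack(keep1), post2 = mkTrack(keep2),
                 pre1 = mkTrack(integer(0)), pre2 = mkTrack(integer(0)))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- c(post1 = "post_rep1.bed", post2 = "post_rep2.bed",
               pre1 = "pre_rep1.bed", pre2 = "pre_rep2.bed")
    for (nm in names(files))
      writeBed(tracks[[nm]], file.path(dir, files[[nm]]))
  }
  tracks
}

#' Generate SNVs hitting or missing planted sites
#'
#' Site-destroying SNVs change a planted site's most informative base to the
#' PWM's worst base at that column; site-creating SNVs restore the flipped
#' consensus base of a planted decoy; neutral SNVs fall outside all planted
#' elements. Positions are reported 1-based on the synthetic chromosome.
#'
#' @param dataset an [EnhancerDataset-class] from [generateEnhancerSet()].
#' @param truth the matching `GroundTruth`.
#' @param pwms the motif list the architecture was planted from.
#' @param nSiteHits number of site-hitting SNVs (split between destroying
#'   and creating, as decoys allow).
#' @param nNeutral number of neutral SNVs.
#' @param seed integer seed.
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `id`, `enhancer`, `effect` (`site_destroying` / `site_creating` /
#'   `neutral`).
#' @export
generateVariants <- function(dataset, truth, pwms, nSiteHits, nNeutral,
                             seed = 1) {
  if (length(dataset) == 0) stop("dataset is empty")
  set.seed(seed)
  regions <- enhancerRegions(dataset)
  seqs <- as.character(enhancerSequences(dataset))
  regionStart0 <- setNames(start(regions) - 1L, names(regions))

  baseAt <- function(enh, off0) substr(seqs[[enh]], off0 + 1L, off0 + 1L)
  rows <- list()
  addVariant <- function(enh, off0, alt, effect) {
    ref <- baseAt(enh, off0)
    rows[[length(rows) + 1L]] <<- data.frame(
      chrom = as.character(seqnames(regions[enh])),
      pos = regionStart0[[enh]] + off0 + 1L,
      ref = ref, alt = alt,
      id = sprintf("var_%04d", length(rows) + 1L),
      enhancer = enh, effect = effect
    )
  }

  nCreate <- min(nrow(truth$decoys), floor(nSiteHits / 2))
  nDestroy <- nSiteHits - nCreate
  if (nDestroy > nrow(truth$sites))
    stop("requested site hits exceed available planted sites")
  if (nDestroy > 0) {
    pick <- sample.int(nrow(truth$sites), nDestroy)
    for (i in pick) {
      s <- truth$sites[i, ]
      motif <- pwms[[s$tf]]
      llr <- llrMatrix(motif)
      col <- which.max(apply(llr, 2L, max) - apply(llr, 2L, min))
      worst <- .BASES[which.min(motifMatrix(motif)[, col])]
      if (s$strand == "+") {
        off0 <- s$start + col - 1L
        alt <- worst
      } else {
        off0 <- s$start + s$width - col
        alt <- c(A = "T", C = "G", G = "C", T = "A")[[worst]]
      }
      if (baseAt(s$enhancer, off0) == alt) {
        ## site base already worst at the informative column: pick any other
        ## base, still site-damaging
        alt <- sample(setdiff(.BASES, alt), 1L)
      }
      addVariant(s$enhancer, off0, alt, "site_destroying")
    }
  }
  if (nCreate > 0) {
    pick <- sample.int(nrow(truth$decoys), nCreate)
    for (i in pick) {
      d <- truth$decoys[i, ]
      motif <- pwms[[d$tf]]
      cons <- .BASES[which.max(motifMatrix(motif)[, d$flippedCol])]
      if (d$strand == "+") {
        off0 <- d$start + d$flippedCol - 1L
        alt <- cons
      } else {
        off0 <- d$start + d$width - d$flippedCol
        alt <- c(A = "T", C = "G", G = "C", T = "A")[[cons]]
      }
      addVariant(d$enhancer, off0, alt, "site_creating")
    }
  }
  if (nNeutral > 0) {
    planted <- rbind(truth$sites[, c("enhancer", "start", "width")],
                     truth$decoys[, c("enhancer", "start", "width")])
    enhPool <- names(regions)
    placed <- 0L
    guard <- 0L
    while (placed < nNeutral) {
      guard <- guard + 1L
      if (guard > 50L * nNeutral)
        stop("requested neutral count exceeds available positions")
      enh <- sample(enhPool, 1L)
      off0 <- sample.int(nchar(seqs[[enh]]), 1L) - 1L
      pl <- planted[planted$enhancer == enh, , drop = FALSE]
      if (any(off0 >= pl$start & off0 < pl$start + pl$width)) next
      ref <- baseAt(enh, off0)
      alt <- sample(setdiff(.BASES, ref), 1L)
      addVariant(enh, off0, alt, "neutral")
      placed <- placed + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         id = character(0), enhancer = character(0),
                         effect = character(0))
  rownames(out) <- NULL
  out
}

#' Write a variant table as TSV
#'
#' @param variants data.frame from [generateVariants()] (or compatible).
#' @param path output TSV with header columns chrom, pos, ref, alt, id.
#' @return `path` invisibly.
#' @export
writeVariantTable <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
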