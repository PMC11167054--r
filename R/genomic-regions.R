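#' Region ids in "chrom:start-end" form
#'
#' @param regions a [GenomicRanges::GRanges]; BED-style 0-based half-open
#'   coordinates are used in the id.
#' @return character vector of ids.
#' @export
regionIds <- function(regions) {
  if (length(regions) == 0) return(character(0))
  paste0(as.character(seqnames(regions)), ":", start(regions) - 1L, "-",
         end(regions))
}

#' Threshold peaks by score and merge nearby peaks
#'
#' Drops peaks whose score is below `minScore`, then merges retained peaks
#' whose gap is at most `mergeDistance` bp ("within `mergeDistance` bp of
#' each other"). The output is sorted and non-overlapping; the operation is
#' idempotent on its own output.
#'
#' @param peaks a [GenomicRanges::GRanges], optionally with a `score`
#'   metadata column (peaks without scores are kept).
#' @param minScore minimum peak score (default 5).
#' @param mergeDistance maximum gap in bp between merged peaks (default 100).
#' @return a sorted, reduced [GenomicRanges::GRanges].
#' @export
thresholdAndMerge <- function(peaks, minScore = 5, mergeDistance = 100) {
  if (!is.null(peaks$score)) {
    keep <- !is.na(peaks$score) & peaks$score >= minScore
    peaks <- peaks[keep]
  }
  out <- reduce(sort(peaks), min.gapwidth = mergeDistance + 1L)
  names(out) <- regionIds(out)
  out
}

#' Build the enhancer universe from two peak tracks
#'
#' Intersects two merged peak tracks (e.g. ER ChIP and H3K27Ac ChIP peaks):
#' only intervals supported by both tracks are candidate enhancers. Each
#' region receives a stable "chrom:start-end" id.
#'
#' @param erRegions,k27Regions merged [GenomicRanges::GRanges] (see
#'   [thresholdAndMerge()]).
#' @return a [GenomicRanges::GRanges] of intersection intervals, named by id.
#' @export
buildUniverse <- function(erRegions, k27Regions) {
  out <- GenomicRanges::intersect(erRegions, k27Regions,
                                  ignore.strand = TRUE)
  names(out) <- regionIds(out)
  out
}

.overlapsAny <- function(query, subject) {
  countOverlaps(query, subject, ignore.strand = TRUE) > 0L
}

#' Label universe regions from replicate nascent-transcription peak tracks
#'
#' Applies the eRNA labeling rule: a region is `positive` (transcribed upon
#' treatment) when it overlaps at least one peak in each of the two
#' post-treatment replicates and overlaps neither pre-treatment replicate;
#' `negative` (silent) when it overlaps no peak in either post-treatment
#' replicate; everything else (single-replicate post support, or
#' both-replicate support with pre-treatment overlap) is `excluded`.
#' Overlap means at least 1 bp of intersection.
#'
#' @param universe [GenomicRanges::GRanges] of candidate enhancers.
#' @param postRep1,postRep2 post-treatment replicate peak tracks (GRanges).
#' @param preRep1,preRep2 pre-treatment replicate peak tracks (GRanges).
#' @return `universe` with metadata column `label` (factor
#'   positive/negative/excluded).
#' @export
labelRegions <- function(universe, postRep1, postRep2, preRep1, preRep2) {
  p1 <- .overlapsAny(universe, postRep1)
  p2 <- .overlapsAny(universe, postRep2)
  q1 <- .overlapsAny(universe, preRep1)
  q2 <- .overlapsAny(universe, preRep2)
  label <- rep("excluded", length(universe))
  label[p1 & p2 & !q1 & !q2] <- "positive"
  label[!p1 & !p2] <- "negative"
  universe$label <- factor(label, levels = .LABEL_LEVELS)
  if (is.null(names(universe))) names(universe) <- regionIds(universe)
  universe
}

.splitFactor <- function(n) factor(rep("none", n), levels = .SPLIT_LEVELS)

#' Construct an EnhancerDataset
#'
#' @param regions [GenomicRanges::GRanges] with unique names (ids).
#' @param sequences [Biostrings::DNAStringSet] parallel to `regions` (names
#'   are matched to region names when present).
#' @param label factor or character of class labels
#'   (positive/negative/excluded).
#' @param split optional factor or character of partition assignments
#'   (train/validation/test/none); defaults to all `none`.
#' @return an [EnhancerDataset-class].
#' @export
EnhancerDataset <- function(regions, sequences, label, split = NULL) {
  if (is.null(names(regions))) names(regions) <- regionIds(regions)
  sequences <- as(sequences, "DNAStringSet")
  if (length(sequences) != length(regions))
    stop("'sequences' and 'regions' must have equal length")
  if (!is.null(names(sequences)) && length(sequences) &&
      all(names(regions) %in% names(sequences)))
    sequences <- sequences[names(regions)]
  names(sequences) <- names(regions)
  label <- factor(as.character(label), levels = .LABEL_LEVELS)
  if (is.null(split)) split <- .splitFactor(length(regions))
  else split <- factor(as.character(split), levels = .SPLIT_LEVELS)
  new("EnhancerDataset", regions = regions, sequences = sequences,
      label = label, split = split)
}

#' @describeIn EnhancerDataset region accessor.
#' @param x,object an [EnhancerDataset-class].
#' @export
enhancerRegions <- function(x) x@regions

#' @describeIn EnhancerDataset sequence accessor.
#' @export
enhancerSequences <- function(x) x@sequences

#' @describeIn EnhancerDataset label accessor.
#' @export
enhancerLabels <- function(x) setNames(x@label, names(x@regions))

#' @describeIn EnhancerDataset split accessor.
#' @export
enhancerSplits <- function(x) setNames(x@split, names(x@regions))

#' @describeIn EnhancerDataset region ids.
#' @export
enhancerIds <- function(x) names(x@regions)

setMethod("length", "EnhancerDataset", function(x) length(x@regions))

setMethod("show", "EnhancerDataset", function(object) {
  cat("EnhancerDataset with", length(object), "enhancers\n")
  cat("  labels:", paste(sprintf("%s=%d", levels(object@label),
                                 tabulate(object@label, 3L)),
                         collapse = ", "), "\n")
  cat("  splits:", paste(sprintf("%s=%d", levels(object@split),
                                 tabulate(object@split, 4L)),
                         collapse = ", "), "\n")
})

#' @describeIn EnhancerDataset subset by index, id or logical.
#' @param i index vector.
#' @param j,drop,... ignored (matrix-style calls are not supported).
#' @export
setMethod("[", "EnhancerDataset", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, names(x@regions))
  new("EnhancerDataset", regions = x@regions[i],
      sequences = x@sequences[i], label = x@label[i], split = x@split[i])
})

#' Partition a labeled dataset into train and test sets
#'
#' Per-class random partition: for each non-excluded class, `floor(n_class *
#' ratioTest)` regions go to the test set and the rest to the training set;
#' excluded regions keep split `none`. With the canonical 449 positive /
#' 1669 negative composition and `ratioTest = 1/5` this yields test sets of
#' 89 and 333 with 360 and 1336 left for training. Deterministic under
#' `seed`.
#'
#' @param dataset an [EnhancerDataset-class] (or a GRanges with a `label`
#'   column, in which case a `split` column is added).
#' @param ratioTest fraction of each class assigned to the test set
#'   (default 1/5); 0 puts everything in training.
#' @param seed integer seed.
#' @return the input with updated split assignments.
#' @export
splitDataset <- function(dataset, ratioTest = 1 / 5, seed = 1) {
  isGr <- is(dataset, "GRanges")
  label <- if (isGr) dataset$label else dataset@label
  split <- rep("none", length(label))
  set.seed(seed)
  for (cls in c("positive", "negative")) {
    idx <- which(label == cls)
    if (!length(idx)) stop("empty class: ", cls)
    nTest <- floor(length(idx) * ratioTest)
    test <- if (nTest > 0) sample(idx, nTest) else integer(0)
    split[idx] <- "train"
    split[test] <- "test"
  }
  split <- factor(split, levels = .SPLIT_LEVELS)
  if (isGr) {
    dataset$split <- split
    dataset
  } else {
    initialize(dataset, split = split)
  }
}

#' Carve a validation set out of the training portion
#'
#' Moves explicit per-class counts of training regions into `train` and
#' `validation` sub-splits (any remaining training regions are set to
#' `none`), mirroring a two-stage design where a later modeling stage uses
#' its own training/validation partition. Deterministic under `seed`.
#'
#' @param dataset an [EnhancerDataset-class] that already has train/test
#'   splits.
#' @param nTrain,nValidation named numeric vectors with elements `positive`
#'   and `negative`: how many training regions of each class to keep as
#'   `train` and to move to `validation`.
#' @param seed integer seed.
#' @return the dataset with updated splits.
#' @export
splitTrainValidation <- function(dataset,
                                 nTrain = c(positive = 200, negative = 600),
                                 nValidation = c(positive = 90,
                                                 negative = 334),
                                 seed = 1) {
  split <- as.character(dataset@split)
  label <- dataset@label
  set.seed(seed)
  for (cls in c("positive", "negative")) {
    idx <- which(label == cls & split == "train")
    need <- nTrain[[cls]] + nValidation[[cls]]
    if (length(idx) < need)
      stop("not enough '", cls, "' training regions (", length(idx),
           ") for requested ", need)
    pick <- sample(idx, need)
    split[idx] <- "none"
    split[pick[seq_len(nTrain[[cls]])]] <- "train"
    split[pick[nTrain[[cls]] + seq_len(nValidation[[cls]])]] <- "validation"
  }
  initialize(dataset, split = factor(split, levels = .SPLIT_LEVELS))
}

#' Read / write scored BED files
#'
#' Thin wrappers reading 4-6 column BED into GRanges (0-based half-open on
#' disk, 1-based closed in GRanges) and writing back.
#'
#' @param path BED file.
#' @return `readBed` returns a [GenomicRanges::GRanges] with `score` when
#'   present.
#' @export
readBed <- function(path) {
  cols <- utils::count.fields(path, sep = "\t")
  if (!length(cols)) {
    return(GRanges())
  }
  nc <- max(cols)
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand")[seq_len(nc)],
                   colClasses = c("character", "integer", "integer",
                                  "character", "numeric",
                                  "character")[seq_len(nc)])
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  if (!is.null(df$name)) names(gr) <- df$name
  if (!is.null(df$score)) gr$score <- df$score
  gr
}

#' @rdname readBed
#' @param regions [GenomicRanges::GRanges] to write; `score` metadata column
#'   and names are used when present.
#' @export
writeBed <- function(regions, path) {
  if (length(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  df <- data.frame(
    chrom = as.character(seqnames(regions)),
    start = start(regions) - 1L,
    end = end(regions),
    name = if (is.null(names(regions))) regionIds(regions)
           else names(regions),
    score = if (is.null(regions$score)) 0 else regions$score,
    strand = "."
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
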