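#' Motif: a position weight matrix with background model
#'
#' A `Motif` stores a per-position base-probability matrix (4 rows, one per
#' base A/C/G/T, and one column per position), a 0-order background model,
#' and the pseudocount that was folded into the matrix. All scoring in the
#' package (log-likelihood ratios, p-value thresholds, affinities) is done
#' against this object.
#'
#' @slot name single motif identifier.
#' @slot matrix 4 x L numeric matrix of base probabilities, rows named
#'   A, C, G, T; every column sums to 1. The stored matrix already includes
#'   the pseudocount.
#' @slot background length-4 numeric vector of background base frequencies
#'   (A, C, G, T), summing to 1.
#' @slot pseudocount the pseudocount that was added to each probability
#'   before renormalization (kept for provenance).
#'
#' @seealso [Motif()] for the user constructor, [llrScore()], [callSites()],
#'   [pvalueThreshold()].
#' @exportClass Motif
setClass("Motif",
  representation(
    name = "character",
    matrix = "matrix",
    background = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("Motif", function(object) {
  msg <- character()
  m <- object@matrix
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!is.numeric(m) || nrow(m) != 4L || ncol(m) < 1L)
    msg <- c(msg, "'matrix' must be a numeric 4 x L matrix with L >= 1")
  else {
    if (!identical(rownames(m), c("A", "C", "G", "T")))
      msg <- c(msg, "'matrix' rows must be named A, C, G, T")
    if (any(m < 0))
      msg <- c(msg, "matrix probabilities must be non-negative")
    if (any(abs(colSums(m) - 1) > 1e-9))
      msg <- c(msg, "each matrix column must sum to 1 (within 1e-9)")
  }
  if (length(object@background) != 4L ||
      abs(sum(object@background) - 1) > 1e-9 ||
      any(object@background <= 0))
    msg <- c(msg, "'background' must be 4 positive frequencies summing to 1")
  if (length(msg)) msg else TRUE
})

#' EnhancerDataset: labeled, partitioned enhancer sequences
#'
#' Container tying together the genomic regions of candidate enhancers, their
#' DNA sequences, the transcription-based class label
#' (positive = eRNA-transcribed, negative = silent, excluded = ambiguous
#' replicate support), and the train/validation/test partition.
#'
#' @slot regions a [GenomicRanges::GRanges] of the enhancer intervals
#'   (0-based half-open when written as BED); names are region ids.
#' @slot sequences a [Biostrings::DNAStringSet] parallel to `regions`.
#' @slot label factor with levels `positive`, `negative`, `excluded`.
#' @slot split factor with levels `train`, `validation`, `test`, `none`.
#'
#' @seealso [EnhancerDataset()], [labelRegions()], [splitDataset()].
#' @exportClass EnhancerDataset
setClass("EnhancerDataset",
  representation(
    regions = "GRanges",
    sequences = "DNAStringSet",
    label = "factor",
    split = "factor"
  )
)

.LABEL_LEVELS <- c("positive", "negative", "excluded")
.SPLIT_LEVELS <- c("train", "validation", "test", "none")

setValidity("EnhancerDataset", function(object) {
  msg <- character()
  n <- length(object@regions)
  if (length(object@sequences) != n)
    msg <- c(msg, "'sequences' and 'regions' must have equal length")
  if (length(object@label) != n)
    msg <- c(msg, "'label' must have one entry per region")
  if (length(object@split) != n)
    msg <- c(msg, "'split' must have one entry per region")
  if (!identical(levels(object@label), .LABEL_LEVELS))
    msg <- c(msg, "label levels must be positive/negative/excluded")
  if (!identical(levels(object@split), .SPLIT_LEVELS))
    msg <- c(msg, "split levels must be train/validation/test/none")
  if (n > 0 && (is.null(names(object@regions)) ||
                anyDuplicated(names(object@regions))))
    msg <- c(msg, "regions must carry unique names (ids)")
  if (n > 0 && !all(width(object@regions) == width(object@sequences)))
    msg <- c(msg, "sequence widths must match region widths")
  if (any(object@label == "excluded" & object@split != "none"))
    msg <- c(msg, "excluded regions must have split 'none'")
  if (length(msg)) msg else TRUE
})

#' ThermoModel: one parameter assignment of the thermodynamic model
#'
#' A `ThermoModel` holds one complete assignment of the free parameters of
#' the thermodynamic sequence-to-expression model: a binding strength `K`
#' and an activation parameter `tau` per TF, a cooperativity `omega` per
#' allowed TF-TF interaction, the basal-machinery weight `q_btm`, and the
#' logistic mapping (`alpha`, `beta`) that turns predicted activity into a
#' class probability. Ensembles are plain lists of `ThermoModel` objects.
#'
#' Interpretation: `tau > 1` marks an activator, `tau < 1` a repressor;
#' `omega > 1` a cooperative interaction, `omega < 1` an antagonistic one.
#' `K` scales the statistical weight of every bound site of the TF.
#'
#' @slot tfNames character vector of modeled TFs (motif names).
#' @slot binding named numeric, `K >= 0` per TF.
#' @slot activation named numeric, `tau > 0` per TF.
#' @slot coop data.frame with columns `tf1`, `tf2`, `omega` (unordered pair
#'   per row; self-pairs allowed).
#' @slot coopDistance maximum start-to-start distance (bp) at which a
#'   cooperativity term applies between consecutively bound sites.
#' @slot qBtm basal transcriptional machinery weight (fixed at 1 by
#'   default during fitting).
#' @slot alpha logistic coefficient (free parameter of the objective).
#' @slot beta logistic bias (free parameter of the objective).
#' @slot bounds named list of length-2 numeric ranges used during fitting
#'   (elements `K`, `tau`, `omega`, `alpha`, `beta`).
#'
#' @seealso [thermoModel()], [fitThermoModel()], [predictExpression()].
#' @exportClass ThermoModel
setClass("ThermoModel",
  representation(
    tfNames = "character",
    binding = "numeric",
    activation = "numeric",
    coop = "data.frame",
    coopDistance = "numeric",
    qBtm = "numeric",
    alpha = "numeric",
    beta = "numeric",
    bounds = "list"
  )
)

setValidity("ThermoModel", function(object) {
  msg <- character()
  tfs <- object@tfNames
  if (anyDuplicated(tfs))
    msg <- c(msg, "duplicate TF names")
  if (!identical(names(object@binding), tfs) ||
      !identical(names(object@activation), tfs))
    msg <- c(msg, "'binding' and 'activation' must be named by tfNames")
  if (any(object@binding < 0))
    msg <- c(msg, "binding parameters K must be >= 0")
  if (any(object@activation <= 0))
    msg <- c(msg, "activation parameters tau must be > 0")
  cp <- object@coop
  if (nrow(cp)) {
    if (!all(c("tf1", "tf2", "omega") %in% names(cp)))
      msg <- c(msg, "'coop' needs columns tf1, tf2, omega")
    else {
      if (!all(cp$tf1 %in% tfs) || !all(cp$tf2 %in% tfs))
        msg <- c(msg, "cooperativity pairs must reference modeled TFs")
      if (any(cp$omega <= 0))
        msg <- c(msg, "cooperativity parameters omega must be > 0")
      key <- apply(cbind(pmin(cp$tf1, cp$tf2), pmax(cp$tf1, cp$tf2)), 1L,
                   paste, collapse = "|")
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate (unordered) cooperativity pairs")
    }
  }
  if (length(object@qBtm) != 1L || object@qBtm <= 0)
    msg <- c(msg, "'qBtm' must be a single positive number")
  if (length(object@alpha) != 1L || object@alpha <= 0)
    msg <- c(msg, "'alpha' must be a single positive number")
  if (length(object@beta) != 1L || object@beta < 0 || object@beta > 1)
    msg <- c(msg, "'beta' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
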