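.BASES <- c("A", "C", "G", "T")

#' Construct a Motif
#'
#' Builds a [Motif-class] from a probability (or count) matrix. Counts are
#' normalized to probabilities per column, the pseudocount is added to every
#' probability, and columns are renormalized, so that no base has
#' probability exactly zero (which would make log-likelihood ratios
#' degenerate).
#'
#' @param name motif identifier.
#' @param matrix numeric matrix of base probabilities or counts; either
#'   4 x L (rows A, C, G, T) or L x 4 (columns A, C, G, T).
#' @param background length-4 base frequencies of the 0-order background
#'   model (A, C, G, T); default uniform.
#' @param pseudocount probability mass added to each entry before column
#'   renormalization (default `1e-3`).
#' @return a [Motif-class] object.
#' @examples
#' m <- Motif("toy", rbind(A = c(8, 1), C = c(1, 7), G = c(1, 1), T = c(0, 1)))
#' motifLength(m)
#' @export
Motif <- function(name, matrix, background = rep(0.25, 4), pseudocount = 1e-3) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4L && ncol(m) == 4L) m <- t(m)
  if (nrow(m) != 4L)
    stop("motif matrix must have 4 rows (or 4 columns) for bases A, C, G, T")
  if (any(m < 0) || any(!is.finite(m)))
    stop("motif matrix entries must be finite and non-negative")
  cs <- colSums(m)
  if (any(cs <= 0)) stop("motif matrix has an empty column")
  m <- sweep(m, 2L, cs, "/")
  m <- m + pseudocount
  m <- sweep(m, 2L, colSums(m), "/")
  dimnames(m) <- list(.BASES, NULL)
  if (length(background) != 4L)
    stop("'background' must have 4 entries (A, C, G, T)")
  background <- as.numeric(background)
  names(background) <- .BASES
  new("Motif", name = name, matrix = m, background = background,
      pseudocount = pseudocount)
}

#' @describeIn Motif motif name accessor.
#' @param x,object a [Motif-class].
#' @export
motifName <- function(x) x@name

#' @describeIn Motif probability matrix accessor (4 x L, pseudocounted).
#' @export
motifMatrix <- function(x) x@matrix

#' @describeIn Motif number of positions L.
#' @export
motifLength <- function(x) ncol(x@matrix)

#' @describeIn Motif background frequencies accessor.
#' @export
motifBackground <- function(x) x@background

#' @describeIn Motif per-base log-likelihood-ratio matrix,
#'   `log(p / background)` in nats (4 x L).
#' @export
llrMatrix <- function(x) log(x@matrix / x@background)

#' @describeIn Motif maximum achievable window LLR (sum of column maxima),
#'   in nats.
#' @export
maxLLR <- function(x) sum(apply(llrMatrix(x), 2L, max))

#' @describeIn Motif consensus sequence (column-wise most probable base).
#' @export
consensusSequence <- function(x) {
  paste(.BASES[apply(x@matrix, 2L, which.max)], collapse = "")
}

setMethod("show", "Motif", function(object) {
  cat("Motif '", object@name, "': ", motifLength(object), " bp, consensus ",
      consensusSequence(object), "\n", sep = "")
})

## LLR matrix for minus-strand scanning: scanning the forward sequence with
## the reverse-complemented matrix yields, at each offset, the LLR of the
## reverse complement of that window.
.llrMatrixRC <- function(motif) {
  llr <- llrMatrix(motif)
  llr[4:1, rev(seq_len(ncol(llr))), drop = FALSE]
}

.encodeSequence <- function(sequence) {
  if (is(sequence, "DNAString") || is(sequence, "DNAStringSet"))
    sequence <- as.character(sequence)
  match(strsplit(toupper(sequence), "")[[1]], .BASES)
}

## Window scores over one strand given a 4 x L score matrix; ambiguity codes
## (encoded as NA) contribute 0 at their position.
.windowScores <- function(enc, scoreMat) {
  L <- ncol(scoreMat)
  n <- length(enc)
  if (n < L) return(numeric(0))
  nw <- n - L + 1L
  out <- numeric(nw)
  for (k in seq_len(L)) {
    v <- scoreMat[enc[k:(k + nw - 1L)] + (k - 1L) * 4L]
    v[is.na(v)] <- 0
    out <- out + v
  }
  out
}

#' Scan a sequence with a motif on both strands
#'
#' Computes the log-likelihood-ratio (LLR) score, in nats, of every window of
#' the sequence against the motif versus the background model, on both
#' strands. Positions carrying ambiguity codes contribute 0 (they score as
#' background).
#'
#' @param sequence a character string, [Biostrings::DNAString] or single-entry
#'   [Biostrings::DNAStringSet].
#' @param motif a [Motif-class].
#' @return a data.frame with columns `start` (0-based window offset),
#'   `strand` (`+`/`-`) and `llr`; one row per window and strand, ordered by
#'   start then strand.
#' @seealso [llrScore()] for a single window, [callSites()] for thresholded
#'   site calls.
#' @export
scanMotif <- function(sequence, motif) {
  enc <- .encodeSequence(sequence)
  fwd <- .windowScores(enc, llrMatrix(motif))
  rev <- .windowScores(enc, .llrMatrixRC(motif))
  nw <- length(fwd)
  if (nw == 0L)
    return(data.frame(start = integer(0), strand = character(0),
                      llr = numeric(0)))
  out <- data.frame(
    start = rep(0:(nw - 1L), each = 2L),
    strand = rep(c("+", "-"), nw),
    llr = as.vector(rbind(fwd, rev))
  )
  rownames(out) <- NULL
  out
}

#' LLR score of a single window
#'
#' Sum over positions of `log(p_col(base) / background(base))`, in nats.
#' The window length must equal the motif length; ambiguity codes contribute
#' 0 at their position.
#'
#' @param window character string of length equal to the motif length.
#' @param motif a [Motif-class].
#' @return the LLR in nats.
#' @examples
#' m <- Motif("toy", cbind(c(0.8, 0.0667, 0.0667, 0.0666),
#'                         c(0.1, 0.7, 0.1, 0.1)), pseudocount = 0)
#' llrScore("AC", m)  # log(0.8/0.25) + log(0.7/0.25)
#' @export
llrScore <- function(window, motif) {
  enc <- .encodeSequence(window)
  if (length(enc) != motifLength(motif))
    stop("window length (", length(enc), ") does not match motif length (",
         motifLength(motif), ")")
  s <- .windowScores(enc, llrMatrix(motif))
  as.numeric(s)
}

#' LLR threshold at a target p-value
#'
#' Finds the smallest score `t` such that a random background window scores
#' at least `t` with probability at most `p`. The null distribution of the
#' window LLR is computed exactly by dynamic programming over the per-column
#' score distribution, with scores discretized on a grid (default `1e-3`
#' nats).
#'
#' @param motif a [Motif-class].
#' @param p tail probability, `0 < p <= 1` (default `1e-4`, the convention
#'   used for calling putative sites).
#' @param grid discretization step in nats.
#' @return the threshold in nats.
#' @examples
#' m <- Motif("toy", rbind(A = c(9, 1, 1), C = c(1, 9, 1),
#'                         G = c(1, 1, 9), T = c(1, 1, 1)))
#' pvalueThreshold(m, 1 / 64)  # consensus-only tail for a 3-mer
#' @export
pvalueThreshold <- function(motif, p = 1e-4, grid = 1e-3) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("'p' must be a single probability in (0, 1]")
  if (any(motif@matrix == 0))
    stop("degenerate motif: zero-probability entries (use a pseudocount)")
  llr <- llrMatrix(motif)
  bg <- motifBackground(motif)
  scoresInt <- round(llr / grid)
  ## distribution over integer grid scores, held as (offset, prob vector)
  probs <- 1
  offset <- 0
  for (k in seq_len(ncol(llr))) {
    s <- scoresInt[, k]
    lo <- min(s); hi <- max(s)
    newLen <- length(probs) + (hi - lo)
    acc <- numeric(newLen)
    for (b in 1:4) {
      sh <- s[b] - lo
      acc[(1L + sh):(length(probs) + sh)] <-
        acc[(1L + sh):(length(probs) + sh)] + probs * bg[b]
    }
    probs <- acc
    offset <- offset + lo
  }
  tail <- rev(cumsum(rev(probs)))
  ## smallest achievable window score whose tail probability is <= p;
  ## lowered by the worst-case accumulated rounding so that discretization
  ## never excludes a window whose true score falls in the threshold cell
  achievable <- which(probs > 0)
  ok <- achievable[tail[achievable] <= p + 1e-12]
  idx <- if (length(ok)) ok[1] else achievable[length(achievable)]
  (offset + idx - 1L) * grid - ncol(llr) * grid / 2
}

#' Summed-affinity score of a sequence for one motif
#'
#' Sums the likelihood ratio `LR = exp(llr)` over all windows on both strands
#' whose LLR exceeds the putative-site floor. The default floor of 0 nats
#' (`LR > 1`) counts every window that looks more like a site than like
#' background; set `floor = -Inf` to sum over all windows unconditionally.
#'
#' @param sequence character / DNAString input sequence.
#' @param motif a [Motif-class].
#' @param floor LLR floor in nats; windows with `llr > floor` contribute.
#' @return a single non-negative number (0 for sequences shorter than the
#'   motif).
#' @export
affinityScore <- function(sequence, motif, floor = 0) {
  sc <- scanMotif(sequence, motif)
  keep <- sc$llr > floor
  if (!any(keep)) return(0)
  sum(exp(sc$llr[keep]))
}

#' Call binding sites above an LLR threshold
#'
#' Reports all windows, on both strands, whose LLR is at or above the
#' threshold (typically obtained from [pvalueThreshold()]). Both strands may
#' report a site at the same start.
#'
#' @param sequence character / DNAString input sequence.
#' @param motif a [Motif-class].
#' @param threshold LLR threshold in nats.
#' @return data.frame with columns `motif`, `start` (0-based), `strand`,
#'   `llr`, `lr`, sorted by start.
#' @export
callSites <- function(sequence, motif, threshold) {
  sc <- scanMotif(sequence, motif)
  sc <- sc[sc$llr >= threshold, , drop = FALSE]
  out <- data.frame(
    motif = rep(motifName(motif), nrow(sc)),
    start = sc$start, strand = sc$strand, llr = sc$llr, lr = exp(sc$llr)
  )
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read PWM files
#'
#' Reads motif files in two plain-text dialects: JASPAR-style records
#' (`>name` followed by four base rows, e.g. `A [ 3 10 2 ]`, counts or
#' probabilities) and a plain whitespace matrix dialect (`>name` followed by
#' L rows of 4 numbers in A C G T column order).
#'
#' @param path file with one or more motif records, or a directory of such
#'   files.
#' @param background,pseudocount passed to [Motif()].
#' @return a named list of [Motif-class] objects.
#' @export
readMotifs <- function(path, background = rep(0.25, 4), pseudocount = 1e-3) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    out <- lapply(files, readMotifs, background = background,
                  pseudocount = pseudocount)
    return(do.call(c, out))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no motif records (lines starting '>') in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (i in seq_along(starts)) {
    name <- trimws(sub("^>", "", lines[starts[i]]))
    name <- strsplit(name, "[ \t]+")[[1]][1]
    block <- lines[(starts[i] + 1L):ends[i]]
    baseRows <- grepl("^[ACGT][^0-9.]", block)
    nums <- lapply(block, function(l) {
      l <- gsub("[][ACGT:|]", " ", l)
      as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
    })
    if (all(baseRows) && length(block) == 4L) {
      m <- do.call(rbind, nums)          # rows A C G T
      rownames(m) <- .BASES
    } else {
      m <- t(do.call(rbind, nums))       # file rows are positions
      if (nrow(m) != 4L)
        stop("motif block '", name, "' is neither 4 x L nor L x 4")
      rownames(m) <- .BASES
    }
    out[[name]] <- Motif(name, m, background = background,
                         pseudocount = pseudocount)
  }
  out
}

#' Write motifs in the plain whitespace dialect
#'
#' Writes `>name` followed by L rows of 4 probabilities (A C G T order),
#' readable by [readMotifs()]. The stored probabilities already include the
#' motif's pseudocount, so read them back with `pseudocount = 0` for an
#' exact round trip.
#'
#' @param motifs named list of [Motif-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeMotifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in motifs) {
    writeLines(paste0(">", motifName(m)), con)
    mat <- t(motifMatrix(m))
    write.table(format(mat, digits = 8), con, quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
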