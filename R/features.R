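#' Count adjacent binding-site pairs
#'
#' Counts unordered pairs of called sites whose start-to-start distance is at
#' most `window` bp. For two different site lists, every pair with one site
#' from each list is considered; for a homotypic count (`sitesB = NULL`),
#' unordered distinct pairs within the one list are counted.
#'
#' @param sitesA,sitesB data.frames of called sites as returned by
#'   [callSites()] (only the `start` column is used); `sitesB = NULL`
#'   requests the homotypic count within `sitesA`.
#' @param window maximum start-to-start distance in bp (default 50).
#' @param mode `"start"` (default) measures start-to-start distance;
#'   `"edge"` measures the gap between site edges (0 for overlapping or
#'   abutting sites), using site widths from the `width` column or motif
#'   length `widthA`/`widthB`.
#' @param widthA,widthB site widths used in `"edge"` mode when the site
#'   data.frames carry no `width` column.
#' @return integer pair count.
#' @examples
#' a <- data.frame(start = 10)
#' b <- data.frame(start = c(40, 80))
#' adjacencyCount(a, b, window = 50)           # 1
#' adjacencyCount(data.frame(start = c(10, 40, 100)), window = 50)  # 1
#' @export
adjacencyCount <- function(sitesA, sitesB = NULL, window = 50,
                           mode = c("start", "edge"),
                           widthA = NULL, widthB = NULL) {
  mode <- match.arg(mode)
  .starts <- function(s) if (is.null(s)) integer(0) else as.numeric(s$start)
  .widths <- function(s, w) {
    if (!is.null(s$width)) as.numeric(s$width)
    else if (!is.null(w)) rep(as.numeric(w), nrow(s))
    else rep(0, NROW(s))
  }
  a <- .starts(sitesA)
  homotypic <- is.null(sitesB)
  b <- if (homotypic) a else .starts(sitesB)
  if (!length(a) || !length(b)) return(0L)
  if (mode == "start") {
    d <- abs(outer(a, b, "-"))
  } else {
    wa <- .widths(sitesA, widthA)
    wb <- .widths(if (homotypic) sitesA else sitesB, widthB)
    lo <- outer(a, b, pmax) - outer(a + wa, b + wb, function(x, y) pmin(x, y))
    d <- pmax(lo, 0)
  }
  if (homotypic) {
    sum(d[upper.tri(d)] <= window)
  } else {
    sum(d <= window)
  }
}

.pairIndex <- function(motifNames) {
  M <- length(motifNames)
  idx <- which(upper.tri(diag(M), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(i = idx[, 1L], j = idx[, 2L],
             name = paste0("adj_", motifNames[idx[, 1L]], "__",
                           motifNames[idx[, 2L]]))
}

#' Build the motif feature matrix
#'
#' For each sequence, computes one summed-affinity feature per motif
#' ([affinityScore()]) followed by one pairwise-adjacency feature per
#' unordered motif pair, homotypic pairs included ([adjacencyCount()] on
#' sites called at the `sitePvalue` threshold). With `M` motifs the matrix
#' has `M + M(M+1)/2` columns; 33 motifs give the canonical 33 + 561 = 594
#' columns.
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet].
#' @param motifs named list of [Motif-class] objects (duplicate names are an
#'   error).
#' @param sitePvalue p-value used to calibrate the site-calling LLR threshold
#'   per motif (default `1e-4`).
#' @param adjacencyWindow pair-distance window in bp (default 50).
#' @param affinityFloor LLR floor for the summed-affinity feature
#'   (default 0, i.e. windows with likelihood ratio above 1).
#' @param thresholds optional pre-computed named vector of LLR thresholds,
#'   bypassing [pvalueThreshold()].
#' @return numeric matrix, rows named by sequence id, affinity columns
#'   (`aff_<motif>`) followed by adjacency columns (`adj_<m1>__<m2>` in
#'   upper-triangle-with-diagonal order).
#' @export
buildFeatureMatrix <- function(sequences, motifs, sitePvalue = 1e-4,
                               adjacencyWindow = 50, affinityFloor = 0,
                               thresholds = NULL) {
  if (length(sequences) < 1L || length(motifs) < 1L)
    stop("need at least one sequence and one motif")
  mNames <- vapply(motifs, motifName, character(1))
  if (anyDuplicated(mNames)) stop("duplicate motif names")
  names(motifs) <- mNames
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq_", seq_along(sequences))
  seqs <- as.character(sequences)
  if (is.null(thresholds))
    thresholds <- vapply(motifs, pvalueThreshold, numeric(1), p = sitePvalue)
  M <- length(motifs)
  pairs <- .pairIndex(mNames)
  out <- matrix(0, nrow = length(seqs), ncol = M + nrow(pairs),
                dimnames = list(names(sequences),
                                c(paste0("aff_", mNames), pairs$name)))
  for (s in seq_along(seqs)) {
    sites <- vector("list", M)
    for (m in seq_len(M)) {
      out[s, m] <- affinityScore(seqs[s], motifs[[m]], floor = affinityFloor)
      sites[[m]] <- callSites(seqs[s], motifs[[m]], thresholds[[mNames[m]]])
    }
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      out[s, M + k] <- if (i == j)
        adjacencyCount(sites[[i]], NULL, window = adjacencyWindow)
      else
        adjacencyCount(sites[[i]], sites[[j]], window = adjacencyWindow)
    }
  }
  out
}

#' z-score normalize feature columns
#'
#' Centers each column to mean 0 and scales to sample standard deviation 1
#' (`n - 1` denominator); constant columns map to all zeros.
#'
#' @param matrix numeric feature matrix with at least 2 rows.
#' @return matrix of the same shape.
#' @export
zscoreColumns <- function(matrix) {
  if (nrow(matrix) < 2L) stop("need at least 2 rows to z-score")
  mu <- colMeans(matrix)
  sdev <- apply(matrix, 2L, sd)
  out <- sweep(matrix, 2L, mu, "-")
  keep <- sdev > 0
  out[, keep] <- sweep(out[, keep, drop = FALSE], 2L, sdev[keep], "/")
  out[, !keep] <- 0
  out
}

#' Write / read a feature matrix as TSV
#'
#' @param matrix numeric matrix with row and column names.
#' @param path output TSV (first column `id`).
#' @return `path` invisibly; `readFeatureMatrix` returns the matrix.
#' @export
writeFeatureMatrix <- function(matrix, path) {
  df <- data.frame(id = rownames(matrix), matrix, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
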