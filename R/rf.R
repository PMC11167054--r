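#' Random Forest configuration
#'
#' @param nTrees number of trees (default 1000).
#' @param mtryGrid candidate values for the number of features tried at each
#'   split; `NULL` derives a grid from the feature count `p` spanning
#'   `sqrt(p)`, `p/9`, `p/6` and `p/3` (for the canonical 594 features this
#'   brackets mtry = 66).
#' @param cvFolds cross-validation folds (default 6).
#' @param cvRepeats repeats of the cross-validation (default 3).
#' @param downsample down-sample the majority class to minority size per
#'   fitting round (default TRUE).
#' @param cvTrees trees per CV fit (default 300; kept smaller than `nTrees`
#'   since CV only ranks mtry values).
#' @param seed integer seed.
#' @return list of class `RFConfig`.
#' @export
rfConfig <- function(nTrees = 1000, mtryGrid = NULL, cvFolds = 6,
                     cvRepeats = 3, downsample = TRUE, cvTrees = 300,
                     seed = 1) {
  if (nTrees < 1) stop("nTrees must be >= 1")
  if (!is.null(mtryGrid) && !length(mtryGrid))
    stop("mtryGrid must be non-empty")
  structure(list(nTrees = nTrees, mtryGrid = mtryGrid, cvFolds = cvFolds,
                 cvRepeats = cvRepeats, downsample = downsample,
                 cvTrees = cvTrees, seed = seed),
            class = "RFConfig")
}

.defaultMtryGrid <- function(p) {
  sort(unique(pmax(1L, floor(c(sqrt(p), p / 9, p / 6, p / 3)))))
}

.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in levels(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.rfFit <- function(x, y, mtry, ntree, downsample, importance = FALSE) {
  sampsize <- if (downsample) rep(min(table(y)), nlevels(y)) else nrow(x)
  randomForest::randomForest(
    x = x, y = y, ntree = ntree, mtry = mtry,
    strata = if (downsample) y else NULL, sampsize = sampsize,
    importance = importance, keep.forest = TRUE
  )
}

#' Train the Random Forest enhancer classifier
#'
#' Binary discrimination of positive (eRNA-transcribed) versus negative
#' (silent) enhancers from the motif feature matrix. The majority class is
#' down-sampled to minority size in every fitting round (per tree), `mtry`
#' is chosen by repeated stratified k-fold cross-validation on mean held-out
#' AUROC, and the final forest keeps the out-of-bag bookkeeping needed for
#' permutation importance.
#'
#' @param features numeric feature matrix (rows = enhancers).
#' @param labels factor/character with values `positive` / `negative`
#'   (at least 2 examples of each).
#' @param config an [rfConfig()].
#' @return list of class `RFClassifier` with elements `model`
#'   (the randomForest fit), `mtry`, `cvResults` (mean CV AUROC per
#'   candidate), and `config`.
#' @export
trainRF <- function(features, labels, config = rfConfig()) {
  stopifnot(inherits(config, "RFConfig"))
  y <- factor(as.character(labels), levels = c("negative", "positive"))
  if (nlevels(droplevels(y)) < 2L || any(table(y) < 2L))
    stop("need at least 2 examples in each class")
  x <- as.data.frame(features)
  p <- ncol(x)
  grid <- if (is.null(config$mtryGrid)) .defaultMtryGrid(p)
          else sort(unique(pmin(p, config$mtryGrid)))
  set.seed(config$seed)
  cvAuc <- matrix(NA_real_, nrow = length(grid),
                  ncol = config$cvRepeats * config$cvFolds)
  if (length(grid) > 1L) {
    col <- 0L
    for (rep in seq_len(config$cvRepeats)) {
      fold <- .stratifiedFolds(y, config$cvFolds)
      for (f in seq_len(config$cvFolds)) {
        col <- col + 1L
        testIdx <- which(fold == f)
        for (g in seq_along(grid)) {
          fit <- .rfFit(x[-testIdx, , drop = FALSE], y[-testIdx], grid[g],
                        config$cvTrees, config$downsample)
          scores <- predict(fit, x[testIdx, , drop = FALSE],
                            type = "prob")[, "positive"]
          cvAuc[g, col] <- evaluateClassifier(scores, y[testIdx])$auroc
        }
      }
    }
    means <- rowMeans(cvAuc)
  } else {
    means <- 1
  }
  mtry <- grid[which.max(means)]
  model <- .rfFit(x, y, mtry, config$nTrees, config$downsample,
                  importance = TRUE)
  sampsize <- if (config$downsample) rep(min(table(y)), nlevels(y))
              else nrow(x)
  structure(list(model = model, mtry = mtry, sampsize = sampsize,
                 cvResults = data.frame(mtry = grid, meanAUROC = means),
                 config = config),
            class = "RFClassifier")
}

#' Predict positive-class scores from a trained classifier
#'
#' @param classifier an `RFClassifier` from [trainRF()].
#' @param features feature matrix to score.
#' @return numeric vector of positive-class probabilities.
#' @export
predictRF <- function(classifier, features) {
  predict(classifier$model, as.data.frame(features),
          type = "prob")[, "positive"]
}

#' Permutation importance from out-of-bag error
#'
#' Importance of a feature is the mean over trees of the increase in
#' out-of-bag error when that feature's values are permuted (raw,
#' unnormalized mean decrease in accuracy). Requires the model to have been
#' fitted with out-of-bag importance bookkeeping (as [trainRF()] does).
#'
#' @param classifier an `RFClassifier` (or a randomForest fit with
#'   `importance = TRUE`).
#' @return data.frame (`feature`, `importance`, `rank`), sorted by
#'   decreasing importance; ranks are a permutation of `1..n_features`.
#' @export
permutationImportance <- function(classifier) {
  model <- if (inherits(classifier, "RFClassifier")) classifier$model
           else classifier
  if (is.null(model$importance) || ncol(model$importance) < 2L)
    stop("model was fitted without out-of-bag importance bookkeeping")
  imp <- randomForest::importance(model, type = 1, scale = FALSE)[, 1L]
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top-k features by permutation importance
#'
#' @param importance data.frame from [permutationImportance()].
#' @param k number of features to keep (canonically 16: 14 motif affinities
#'   plus 2 pairwise-adjacency features in the original analysis).
#' @return character vector of feature names.
#' @export
topFeatures <- function(importance, k = 16) {
  head(importance$feature, k)
}

#' Evaluate a scoring classifier: AUROC, AUPRC, ROC and PR points
#'
#' AUROC is computed by the trapezoid rule over the ROC curve and AUPRC by
#' step-wise precision interpolation over the PR curve; tied scores are
#' grouped into a single threshold. A constant scorer therefore has AUPRC
#' equal to the positive-class prevalence and AUROC 0.5.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels factor/character/logical/0-1 labels; `positive` (or
#'   TRUE/1) marks the positive class.
#' @return list with `auroc`, `auprc`, `roc` (data.frame fpr/tpr/threshold)
#'   and `pr` (data.frame recall/precision/threshold).
#' @export
evaluateClassifier <- function(scores, labels) {
  pos <- if (is.factor(labels) || is.character(labels))
    as.character(labels) == "positive" else as.logical(labels)
  if (length(scores) != length(pos)) stop("scores and labels differ in length")
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  grp <- match(scores, thr)
  tpAt <- cumsum(tabulate(grp[pos], nbins = length(thr)))
  fpAt <- cumsum(tabulate(grp[!pos], nbins = length(thr)))
  tpr <- c(0, tpAt / nP)
  fpr <- c(0, fpAt / nN)
  auroc <- sum((fpr[-1] - fpr[-length(fpr)]) *
                 (tpr[-1] + tpr[-length(tpr)]) / 2)
  recall <- tpAt / nP
  precision <- tpAt / (tpAt + fpAt)
  auprc <- sum(diff(c(0, recall)) * precision)
  list(
    auroc = auroc, auprc = auprc,
    roc = data.frame(fpr = fpr, tpr = tpr,
                     threshold = c(Inf, thr)),
    pr = data.frame(recall = recall, precision = precision, threshold = thr)
  )
}
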