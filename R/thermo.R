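.DEFAULT_BOUNDS <- list(K = c(1e-3, 1e3), tau = c(1e-3, 1e3),
                        omega = c(1e-2, 1e2), alpha = c(0.1, 100),
                        beta = c(0, 1))

#' Construct a ThermoModel
#'
#' @param tfNames modeled TF (motif) names.
#' @param binding named numeric `K >= 0` per TF (default 1).
#' @param activation named numeric `tau > 0` per TF (default 1).
#' @param coop data.frame with columns `tf1`, `tf2`, `omega` (default: no
#'   interactions).
#' @param coopDistance maximum start-to-start distance (bp) at which the
#'   cooperativity term applies between consecutively bound sites
#'   (default 50, matching the pairwise-adjacency feature window).
#' @param qBtm basal machinery weight (default 1, held fixed during
#'   fitting).
#' @param alpha,beta logistic coefficient and bias of the classification
#'   objective.
#' @param bounds named list of parameter ranges used by the optimizer.
#' @return a [ThermoModel-class].
#' @export
thermoModel <- function(tfNames, binding = NULL, activation = NULL,
                        coop = NULL, coopDistance = 50, qBtm = 1,
                        alpha = 1, beta = 0.5, bounds = .DEFAULT_BOUNDS) {
  if (is.null(binding)) binding <- setNames(rep(1, length(tfNames)), tfNames)
  if (is.null(activation))
    activation <- setNames(rep(1, length(tfNames)), tfNames)
  binding <- binding[tfNames]; names(binding) <- tfNames
  activation <- activation[tfNames]; names(activation) <- tfNames
  if (is.null(coop))
    coop <- data.frame(tf1 = character(0), tf2 = character(0),
                       omega = numeric(0))
  new("ThermoModel", tfNames = tfNames, binding = binding,
      activation = activation, coop = coop, coopDistance = coopDistance,
      qBtm = qBtm, alpha = alpha, beta = beta, bounds = bounds)
}

setMethod("show", "ThermoModel", function(object) {
  cat("ThermoModel:", length(object@tfNames), "TFs,",
      nrow(object@coop), "interaction pairs\n")
  roles <- ifelse(object@activation > 1, "activator",
                  ifelse(object@activation < 1, "repressor", "neutral"))
  cat("  roles:", paste(sprintf("%s(%s)", object@tfNames, roles),
                        collapse = ", "), "\n")
  cat(sprintf("  qBtm=%.3g alpha=%.3g beta=%.3g\n", object@qBtm,
              object@alpha, object@beta))
})

#' Annotate binding sites with relative affinities
#'
#' Calls sites for each motif at its threshold (see [callSites()]) and
#' attaches the relative affinity `r = LR_site / LR_optimal` of each site,
#' where `LR_optimal` is the motif's maximum achievable window likelihood
#' ratio; `r = 1` only for optimal-score sites. Sites are sorted by start.
#'
#' @param sequence one sequence (character / DNAString).
#' @param motifs named list of [Motif-class] objects.
#' @param thresholds named LLR thresholds in nats; `NULL` computes the
#'   p = 1e-4 thresholds via [pvalueThreshold()].
#' @return data.frame (`motif`, `start`, `strand`, `llr`, `r`, `width`),
#'   class `SiteAnnotation`.
#' @export
annotateSites <- function(sequence, motifs, thresholds = NULL) {
  if (is.null(thresholds))
    thresholds <- vapply(motifs, pvalueThreshold, numeric(1), p = 1e-4)
  parts <- lapply(motifs, function(m) {
    s <- callSites(sequence, m, thresholds[[motifName(m)]])
    s$r <- exp(s$llr - maxLLR(m))
    s$width <- rep(motifLength(m), nrow(s))
    s
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$start, out$motif, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("SiteAnnotation", "data.frame")
  out
}

#' Annotate a whole set of sequences
#'
#' @param sequences named character vector or DNAStringSet.
#' @inheritParams annotateSites
#' @return named list of `SiteAnnotation` data.frames.
#' @export
annotateSiteSet <- function(sequences, motifs, thresholds = NULL) {
  if (is.null(thresholds))
    thresholds <- vapply(motifs, pvalueThreshold, numeric(1), p = 1e-4)
  seqs <- as.character(sequences)
  out <- lapply(seqs, annotateSites, motifs = motifs,
                thresholds = thresholds)
  names(out) <- names(sequences)
  out
}

## Precompile an annotation against a model's TF set and interaction pairs:
## integer TF index, relative affinities, and per-site lists of compatible
## (non-overlapping) predecessors plus the interaction index that applies
## when they are consecutively bound. Overlapping sites can never be bound
## together (steric exclusion); the interaction applies when the
## start-to-start distance is at most coopDistance.
.compileAnnotation <- function(annotation, tfNames, coop, coopDistance) {
  ann <- annotation[annotation$motif %in% tfNames, , drop = FALSE]
  n <- nrow(ann)
  if (n == 0L)
    return(list(n = 0L, tf = integer(0), r = numeric(0), pred = list()))
  if (is.unsorted(ann$start)) stop("annotation must be sorted by start")
  tf <- match(ann$motif, tfNames)
  pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  coopKeys <- if (nrow(coop)) pairKey(coop$tf1, coop$tf2) else character(0)
  pred <- vector("list", n)
  for (i in seq_len(n)) {
    js <- which(ann$start[seq_len(i - 1L)] + ann$width[seq_len(i - 1L)] <=
                  ann$start[i])
    oidx <- integer(length(js))
    if (length(js) && length(coopKeys)) {
      near <- ann$start[i] - ann$start[js] <= coopDistance
      key <- pairKey(ann$motif[js], rep(ann$motif[i], length(js)))
      hit <- match(key, coopKeys)
      oidx[near & !is.na(hit)] <- hit[near & !is.na(hit)]
    }
    pred[[i]] <- list(js = js, oidx = oidx)
  }
  list(n = n, tf = tf, r = ann$r, pred = pred)
}

## DP over configurations: A[i] = total weight of configurations in which
## site i is the right-most bound site; cooperativity multiplies the weight
## by omega between consecutively bound sites of an allowed pair.
.partitionDP <- function(compiled, w, omega) {
  n <- compiled$n
  if (n == 0L) return(1)
  A <- numeric(n)
  pred <- compiled$pred
  for (i in seq_len(n)) {
    p <- pred[[i]]
    s <- 1
    if (length(p$js)) {
      f <- rep(1, length(p$js))
      hasOm <- p$oidx > 0L
      if (any(hasOm)) f[hasOm] <- omega[p$oidx[hasOm]]
      s <- s + sum(A[p$js] * f)
    }
    A[i] <- w[i] * s
  }
  1 + sum(A)
}

#' Partition functions of the bound-site configuration ensemble
#'
#' Computes the total Boltzmann weight of all configurations of bound and
#' unbound sites, for the OFF ensemble (basal machinery unbound) and the ON
#' ensemble (machinery bound). A configuration is any subset of sites in
#' which no two bound sites overlap; its OFF weight is the product over
#' bound sites of `K_tf * r_site`, times `omega` for every consecutively
#' bound pair of an allowed interaction within the model's `coopDistance`.
#' The ON weight additionally multiplies `tau_tf` per bound site. The empty
#' configuration has weight 1. Computed by dynamic programming linear in the
#' number of sites (quadratic worst case in predecessors).
#'
#' @param annotation a `SiteAnnotation` from [annotateSites()] (sorted by
#'   start), or a pre-compiled annotation.
#' @param model a [ThermoModel-class].
#' @return named numeric `c(Zoff, Zon)`.
#' @export
partitionFunctions <- function(annotation, model) {
  compiled <- if (is.list(annotation) && !is.data.frame(annotation))
    annotation
  else .compileAnnotation(annotation, model@tfNames, model@coop,
                          model@coopDistance)
  K <- model@binding[compiled$tf]
  tau <- model@activation[compiled$tf]
  wOff <- K * compiled$r
  omega <- model@coop$omega
  c(Zoff = .partitionDP(compiled, wOff, omega),
    Zon = .partitionDP(compiled, wOff * tau, omega))
}

#' Predicted expression of one enhancer
#'
#' The fractional occupancy of the basal transcriptional machinery:
#' `yhat = qBtm * Zon / (Zoff + qBtm * Zon)`, strictly inside (0, 1).
#'
#' @inheritParams partitionFunctions
#' @return predicted activity in (0, 1).
#' @export
predictExpression <- function(annotation, model) {
  z <- partitionFunctions(annotation, model)
  unname(model@qBtm * z["Zon"] / (z["Zoff"] + model@qBtm * z["Zon"]))
}

#' Predicted expression for a list of annotations
#'
#' @param annotations list of `SiteAnnotation`s (or compiled annotations).
#' @param model a [ThermoModel-class].
#' @return named numeric vector of predictions.
#' @export
predictExpressionSet <- function(annotations, model) {
  vapply(annotations, predictExpression, numeric(1), model = model)
}

#' Logistic classification loss
#'
#' The training objective: `sum_i ln(1 + exp(-y_i * alpha * (yhat_i -
#' beta)))` with labels `y in {-1, +1}`. At `yhat = beta` each example
#' contributes exactly `ln 2` regardless of label or `alpha`.
#'
#' @param predictions numeric in (0, 1).
#' @param labels numeric -1/+1 (factor/character `positive`/`negative` and
#'   logical inputs are converted).
#' @param alpha logistic coefficient.
#' @param beta logistic bias.
#' @return list with `total` and per-example `terms`.
#' @export
logisticLoss <- function(predictions, labels, alpha, beta) {
  y <- .plusMinusLabels(labels)
  if (any(!is.finite(predictions)) || !is.finite(alpha) || !is.finite(beta))
    stop("non-finite inputs to logisticLoss")
  terms <- log1p(exp(-y * alpha * (predictions - beta)))
  list(total = sum(terms), terms = terms)
}

.plusMinusLabels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 1))) stop("numeric labels must be -1/+1")
    return(labels)
  }
  pos <- if (is.logical(labels)) labels else as.character(labels) == "positive"
  ifelse(pos, 1, -1)
}

## ---- parameter vector <-> model -------------------------------------------
## Free parameters: log K and log tau per TF, log omega per pair, log alpha,
## beta. Each is mapped to its box through a scaled logistic transform so
## the simplex search is unconstrained.

.paramSpec <- function(model) {
  nTF <- length(model@tfNames)
  nCo <- nrow(model@coop)
  b <- model@bounds
  lo <- c(rep(log(b$K[1]), nTF), rep(log(b$tau[1]), nTF),
          rep(log(b$omega[1]), nCo), log(b$alpha[1]), b$beta[1])
  hi <- c(rep(log(b$K[2]), nTF), rep(log(b$tau[2]), nTF),
          rep(log(b$omega[2]), nCo), log(b$alpha[2]), b$beta[2])
  list(nTF = nTF, nCo = nCo, lo = lo, hi = hi,
       logScale = c(rep(TRUE, 2 * nTF + nCo + 1), FALSE))
}

.modelToU <- function(model) {
  spec <- .paramSpec(model)
  v <- c(log(model@binding), log(model@activation),
         if (spec$nCo) log(model@coop$omega), log(model@alpha), model@beta)
  v[!spec$logScale] <- model@beta
  frac <- (v - spec$lo) / (spec$hi - spec$lo)
  frac <- pmin(pmax(frac, 1e-6), 1 - 1e-6)
  qlogis(frac)
}

.uToModel <- function(u, model) {
  spec <- .paramSpec(model)
  v <- spec$lo + (spec$hi - spec$lo) * plogis(u)
  nTF <- spec$nTF; nCo <- spec$nCo
  binding <- setNames(exp(v[seq_len(nTF)]), model@tfNames)
  activation <- setNames(exp(v[nTF + seq_len(nTF)]), model@tfNames)
  coop <- model@coop
  if (nCo) coop$omega <- exp(v[2 * nTF + seq_len(nCo)])
  initialize(model, binding = binding, activation = activation, coop = coop,
             alpha = exp(v[2 * nTF + nCo + 1]), beta = v[2 * nTF + nCo + 2])
}

.compileSet <- function(annotations, model) {
  lapply(annotations, function(a)
    if (is.data.frame(a))
      .compileAnnotation(a, model@tfNames, model@coop, model@coopDistance)
    else a)
}

.ensembleObjective <- function(compiled, y, model) {
  function(u) {
    m <- .uToModel(u, model)
    pred <- vapply(compiled, predictExpression, numeric(1), model = m)
    sum(log1p(exp(-y * m@alpha * (pred - m@beta))))
  }
}

#' Fit a thermodynamic model by simplex search in log-parameter space
#'
#' Minimizes the logistic classification objective over the model's free
#' parameters (log K and log tau per TF, log omega per interaction, log
#' alpha, beta), using a bounded Nelder-Mead simplex from the given
#' initialization; `qBtm` stays fixed. The returned model's training loss is
#' never above the initialization's. `maxit = 0` returns the initialization
#' unchanged.
#'
#' @param annotations list of `SiteAnnotation`s (training enhancers).
#' @param labels training labels (`positive`/`negative`, logical, or -1/+1).
#' @param init a [ThermoModel-class] providing the starting point, TF set,
#'   interaction structure and bounds.
#' @param maxit maximum objective evaluations (default 2000).
#' @param reltol relative convergence tolerance of the simplex.
#' @return the fitted [ThermoModel-class], with attributes `loss` (final
#'   objective), `initialLoss` and `convergence` (0 = converged within
#'   budget).
#' @export
fitThermoModel <- function(annotations, labels, init, maxit = 2000,
                           reltol = 1e-8) {
  y <- .plusMinusLabels(labels)
  if (length(unique(y)) < 2L) stop("training data needs both classes")
  compiled <- .compileSet(annotations, init)
  obj <- .ensembleObjective(compiled, y, init)
  u0 <- .modelToU(init)
  f0 <- obj(u0)
  if (!is.finite(f0)) stop("objective not finite at the initialization")
  if (maxit == 0) {
    out <- init
    attr(out, "loss") <- f0
    attr(out, "initialLoss") <- f0
    attr(out, "convergence") <- 0L
    return(out)
  }
  opt <- optim(u0, obj, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = reltol))
  if (!is.finite(opt$value))
    stop("optimizer diverged: non-finite objective")
  best <- if (opt$value <= f0) opt$par else u0
  out <- .uToModel(best, init)
  attr(out, "loss") <- min(opt$value, f0)
  attr(out, "initialLoss") <- f0
  attr(out, "convergence") <- opt$convergence
  out
}

#' Sample a random model initialization uniformly in log-space
#'
#' @param template a [ThermoModel-class] defining TFs, interactions and
#'   bounds.
#' @return a [ThermoModel-class] with parameters drawn uniformly in
#'   log-space (beta uniform on its linear range).
#' @export
sampleInitialModel <- function(template) {
  spec <- .paramSpec(template)
  v <- runif(length(spec$lo), spec$lo, spec$hi)
  u <- qlogis(pmin(pmax((v - spec$lo) / (spec$hi - spec$lo), 1e-6),
                   1 - 1e-6))
  .uToModel(u, template)
}

#' Train an ensemble of thermodynamic models from random initializations
#'
#' Draws `nInits` initializations uniformly from the parameter space (in
#' log-scale within the bounds) and fits each with [fitThermoModel()].
#' Reproducible under `seed`.
#'
#' @inheritParams fitThermoModel
#' @param template a [ThermoModel-class] defining the TF set, interaction
#'   structure, bounds and `qBtm`.
#' @param nInits ensemble size (desk-scale default 100; the original
#'   analysis used thousands).
#' @param seed integer seed.
#' @return list of fitted [ThermoModel-class] objects, each carrying its
#'   `loss` attribute.
#' @export
buildEnsemble <- function(annotations, labels, template, nInits = 100,
                          maxit = 2000, seed = 1) {
  if (nInits < 1) stop("nInits must be >= 1")
  set.seed(seed)
  inits <- replicate(nInits, sampleInitialModel(template),
                     simplify = FALSE)
  lapply(inits, function(m0)
    fitThermoModel(annotations, labels, m0, maxit = maxit))
}

#' Select the final ensemble on validation performance
#'
#' Scores every model on the validation set and returns the union of the
#' top `k` by validation AUROC and the top `k` by validation AUPRC, so the
#' selection has between `k` and `2k` models. Ties are broken by model
#' index for determinism.
#'
#' @param models list of [ThermoModel-class] objects.
#' @param annotations validation `SiteAnnotation`s.
#' @param labels validation labels (both classes required).
#' @param k per-metric selection size (default 150, as in the original
#'   two-criterion selection that kept 244 of 4624 models).
#' @return list with `models` (the selected sublist), `index` (positions in
#'   the input list) and `metrics` (per-input-model AUROC/AUPRC table).
#' @export
selectEnsemble <- function(models, annotations, labels, k = 150) {
  if (k > length(models)) {
    warning("k larger than ensemble size; clamping")
    k <- length(models)
  }
  metrics <- t(vapply(models, function(m) {
    pred <- predictExpressionSet(.compileSet(annotations, m), m)
    ev <- evaluateClassifier(pred, labels)
    c(auroc = ev$auroc, auprc = ev$auprc)
  }, numeric(2)))
  topRoc <- order(-metrics[, "auroc"], seq_len(nrow(metrics)))[seq_len(k)]
  topPrc <- order(-metrics[, "auprc"], seq_len(nrow(metrics)))[seq_len(k)]
  idx <- sort(union(topRoc, topPrc))
  list(models = models[idx], index = idx,
       metrics = data.frame(model = seq_along(models), metrics,
                            selected = seq_along(models) %in% idx))
}

## ---- serialization --------------------------------------------------------

#' Serialize / restore a ThermoModel as JSON
#'
#' Round-trips all named parameters, the interaction table, bounds and the
#' basal weight; predictions from a restored model agree with the original
#' to numerical precision.
#'
#' @param model a [ThermoModel-class].
#' @param path JSON file path.
#' @return `writeThermoModel` returns `path` invisibly; `readThermoModel`
#'   returns the [ThermoModel-class].
#' @export
writeThermoModel <- function(model, path) {
  obj <- list(
    tfNames = model@tfNames,
    binding = as.list(model@binding),
    activation = as.list(model@activation),
    coop = model@coop,
    coopDistance = model@coopDistance,
    qBtm = model@qBtm, alpha = model@alpha, beta = model@beta,
    bounds = model@bounds
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeThermoModel
#' @export
readThermoModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coop <- as.data.frame(obj$coop)
  if (!nrow(coop))
    coop <- data.frame(tf1 = character(0), tf2 = character(0),
                       omega = numeric(0))
  thermoModel(
    tfNames = obj$tfNames,
    binding = unlist(obj$binding)[obj$tfNames],
    activation = unlist(obj$activation)[obj$tfNames],
    coop = coop, coopDistance = obj$coopDistance, qBtm = obj$qBtm,
    alpha = obj$alpha, beta = obj$beta,
    bounds = lapply(obj$bounds, as.numeric)
  )
}
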