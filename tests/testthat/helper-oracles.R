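## Independent brute-force oracles and shared fixtures for the test suite.

randomSeq <- function(n, freqs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

randomMotif <- function(name, L, concentration = 2) {
  m <- matrix(rgamma(4 * L, shape = concentration), nrow = 4)
  Motif(name, m)
}

## brute-force summed affinity: explicit loop over all windows, both strands
bruteAffinity <- function(sequence, motif, floor = 0) {
  L <- motifLength(motif)
  n <- nchar(sequence)
  if (n < L) return(0)
  total <- 0
  for (i in seq_len(n - L + 1L)) {
    win <- substr(sequence, i, i + L - 1L)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(win)))
    for (w in c(win, rc)) {
      s <- llrScore(w, motif)
      if (s > floor) total <- total + exp(s)
    }
  }
  total
}

## exhaustive enumeration of the window-score null distribution (L <= 6)
enumThreshold <- function(motif, p) {
  L <- motifLength(motif)
  bases <- c("A", "C", "G", "T")
  grids <- rev(expand.grid(rep(list(bases), L), stringsAsFactors = FALSE))
  wins <- apply(grids, 1L, paste, collapse = "")
  bg <- motifBackground(motif)
  wProb <- apply(grids, 1L, function(ch) prod(bg[match(ch, bases)]))
  sc <- vapply(wins, llrScore, numeric(1), motif = motif)
  uniq <- sort(unique(sc))
  tails <- vapply(uniq, function(t) sum(wProb[sc >= t - 1e-9]), numeric(1))
  ok <- which(tails <= p + 1e-9)
  if (length(ok)) uniq[ok[1]] else uniq[length(uniq)]
}

## brute-force 2^n enumeration of the thermodynamic partition function
brutePartition <- function(annotation, model, on = FALSE) {
  ann <- annotation[annotation$motif %in% model@tfNames, , drop = FALSE]
  ann <- ann[order(ann$start), , drop = FALSE]
  n <- nrow(ann)
  K <- model@binding
  tau <- model@activation
  cp <- model@coop
  pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  coopKeys <- if (nrow(cp)) pairKey(cp$tf1, cp$tf2) else character(0)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bound <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    ## steric exclusion: no two bound sites overlap
    ok <- TRUE
    if (length(bound) > 1) {
      for (a in seq_len(length(bound) - 1L)) {
        for (b in (a + 1L):length(bound)) {
          i <- bound[a]; j <- bound[b]
          if (ann$start[i] + ann$width[i] > ann$start[j] &&
              ann$start[j] + ann$width[j] > ann$start[i]) ok <- FALSE
        }
      }
    }
    if (!ok) next
    w <- 1
    for (i in bound) {
      w <- w * K[[ann$motif[i]]] * ann$r[i]
      if (on) w <- w * tau[[ann$motif[i]]]
    }
    if (length(bound) > 1 && length(coopKeys)) {
      for (a in seq_len(length(bound) - 1L)) {
        i <- bound[a]; j <- bound[a + 1L]   # consecutive bound sites
        if (ann$start[j] - ann$start[i] <= model@coopDistance) {
          hit <- match(pairKey(ann$motif[i], ann$motif[j]), coopKeys)
          if (!is.na(hit)) w <- w * cp$omega[hit]
        }
      }
    }
    total <- total + w
  }
  total
}

## random site annotation instance for DP-vs-brute-force property tests
randomAnnotation <- function(nSites, tfNames, seqLen = 200, width = 6) {
  start <- sort(sample.int(seqLen - width, nSites))
  data.frame(
    motif = sample(tfNames, nSites, replace = TRUE),
    start = start,
    strand = sample(c("+", "-"), nSites, replace = TRUE),
    llr = runif(nSites, 2, 8),
    r = runif(nSites, 0.05, 1),
    width = rep(width, nSites)
  )
}

randomThermoModel <- function(tfNames, nCoop = 1) {
  binding <- setNames(exp(runif(length(tfNames), -1, 2)), tfNames)
  activation <- setNames(exp(runif(length(tfNames), -2, 2)), tfNames)
  coop <- if (nCoop > 0) {
    pairs <- t(replicate(nCoop, sample(tfNames, 2, replace = TRUE)))
    cp <- unique(data.frame(tf1 = pmin(pairs[, 1], pairs[, 2]),
                            tf2 = pmax(pairs[, 1], pairs[, 2])))
    cp$omega <- exp(runif(nrow(cp), -1.5, 1.5))
    cp
  } else NULL
  thermoModel(tfNames, binding = binding, activation = activation,
              coop = coop, coopDistance = 50)
}

## single toy enhancer: one consensus site of one TF at a known offset
singleSiteFixture <- function(tau = 4, K = 1, offset = 20) {
  motif <- Motif("TFX", rbind(A = c(0.97, 0.01, 0.01, 0.01),
                              C = c(0.01, 0.97, 0.01, 0.01),
                              G = c(0.01, 0.01, 0.97, 0.01),
                              T = c(0.01, 0.01, 0.01, 0.97)))
  ## consensus ACGT-like 4-mer embedded in an A/T soup that cannot reach the
  ## threshold
  cons <- consensusSequence(motif)
  seqch <- paste0(strrep("ATTA", offset / 4), cons, strrep("TTAA", 10))
  model <- thermoModel("TFX", binding = c(TFX = K),
                       activation = c(TFX = tau))
  thr <- c(TFX = pvalueThreshold(motif, 1e-4))
  list(motif = motif, sequence = seqch, model = model, thresholds = thr,
       offset = offset)
}

## memoized small synthetic bundle shared across test files
.fixtureEnv <- new.env(parent = emptyenv())
fixtureBundle <- function(key = "default", ...) {
  if (!is.null(.fixtureEnv[[key]])) return(.fixtureEnv[[key]])
  args <- list(...)
  cfg <- do.call(syntheticConfig, args)
  pwms <- generatePWMs(cfg)
  gen <- generateEnhancerSet(cfg, pwms)
  thresholds <- vapply(pwms, pvalueThreshold, numeric(1), p = 1e-4)
  out <- list(cfg = cfg, pwms = pwms, dataset = gen$dataset,
              truth = gen$truth, thresholds = thresholds)
  .fixtureEnv[[key]] <- out
  out
}
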