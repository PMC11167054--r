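## two toy enhancers with single sites of an activator (ACT) and a
## repressor (REP), plus an empty one, for closed-form perturbation checks
toyPerturbSetup <- function() {
  empty <- data.frame(motif = character(0), start = integer(0),
                      strand = character(0), llr = numeric(0),
                      r = numeric(0), width = integer(0))
  mkAnn <- function(motif) data.frame(motif = motif, start = 10L,
                                      strand = "+", llr = 3, r = 1,
                                      width = 6L)
  anns <- list(actEnh = mkAnn("ACT"), repEnh = mkAnn("REP"), bare = empty)
  model <- thermoModel(c("ACT", "REP"),
                       binding = c(ACT = 5, REP = 5),
                       activation = c(ACT = 6, REP = 0.1))
  list(anns = anns, model = model)
}

test_that("percentileNormalize follows the counting definition", {
  expect_equal(percentileNormalize(100, 1:100), 100)
  expect_equal(percentileNormalize(0.5, 1:100), 0)
  expect_equal(percentileNormalize(50, 1:100), 50)
  expect_error(percentileNormalize(1, numeric(0)), "empty")
})

test_that("knockdown deltas carry the activator/repressor sign convention", {
  s <- toyPerturbSetup()
  kdAct <- knockdown(s$model, s$anns, "ACT")
  expect_lt(kdAct$delta[["actEnh"]], 0)   # activator removal lowers activity
  expect_equal(kdAct$delta[["bare"]], 0)
  kdRep <- knockdown(s$model, s$anns, "REP")
  expect_gt(kdRep$delta[["repEnh"]], 0)   # repressor removal raises it
  expect_error(knockdown(s$model, s$anns, "GHOST"), "unknown TF")
  ## a TF with no sites anywhere changes nothing
  padded <- thermoModel(c("ACT", "REP", "IDLE"),
                        binding = c(ACT = 5, REP = 5, IDLE = 5),
                        activation = c(ACT = 6, REP = 0.1, IDLE = 9))
  kdIdle <- knockdown(padded, s$anns, "IDLE")
  expect_true(all(kdIdle$delta == 0))
  expect_true(all(abs(kdAct$delta) <= 100))
})

test_that("nullInteraction reverts cooperative pairs and ignores inert ones", {
  tfs <- c("A", "B")
  ann <- data.frame(motif = c("A", "B"), start = c(10L, 30L),
                    strand = "+", llr = 3, r = 1, width = c(6L, 6L))
  far <- data.frame(motif = c("A", "B"), start = c(10L, 400L),
                    strand = "+", llr = 3, r = 1, width = c(6L, 6L))
  coop <- data.frame(tf1 = "A", tf2 = "B", omega = 10)
  model <- thermoModel(tfs, binding = c(A = 1, B = 1),
                       activation = c(A = 4, B = 4), coop = coop,
                       coopDistance = 50)
  anns <- list(near = ann, far = far)
  res <- nullInteraction(model, anns, c("A", "B"))
  expect_lt(res$delta[["near"]], 0)       # lost synergy between activators
  expect_equal(res$delta[["far"]], 0)     # sites beyond the distance cap
  already1 <- model
  already1@coop$omega <- 1
  res1 <- nullInteraction(already1, anns, c("B", "A"))
  expect_true(all(res1$delta == 0))
  expect_error(nullInteraction(model, anns, c("A", "Z")), "unknown")
})

test_that("knocking down a non-interacting TF leaves other single-site predictions intact", {
  s <- toyPerturbSetup()
  kd <- s$model
  kd@binding["REP"] <- 0
  expect_equal(predictExpression(s$anns$actEnh, kd),
               predictExpression(s$anns$actEnh, s$model))
})

test_that("summarizePerturbations reproduces hand-enumerated statistics", {
  mk <- function(modelId, deltas)
    structure(list(model = modelId, perturbation = "KD:X",
                   delta = setNames(deltas, c("e1", "e2", "e3"))),
              class = "PerturbationResult")
  labels <- c(e1 = "positive", e2 = "positive", e3 = "negative")
  one <- summarizePerturbations(list(mk(1, c(-10, -3, 6))), labels,
                                threshold = 5)
  expect_equal(one$fracAffected, 2 / 3)
  expect_equal(one$meanOverAffected, (-10 + 6) / 2)
  ## all-zero deltas: nothing affected, mean reported as NA
  zero <- summarizePerturbations(list(mk(1, c(0, 0, 0))), labels)
  expect_equal(zero$fracAffected, 0)
  expect_true(is.na(zero$meanOverAffected))
  ## three-model ensemble mean +- sd equals the brute-force computation
  deltas <- list(c(-10, -3, 6), c(-8, -6, 2), c(-12, 0, 9))
  res <- lapply(seq_along(deltas), function(i) mk(i, deltas[[i]]))
  s3 <- summarizePerturbations(res, labels, threshold = 5)
  fr <- vapply(deltas, function(d) mean(abs(d) >= 5), numeric(1))
  mo <- vapply(deltas, function(d) mean(d[abs(d) >= 5]), numeric(1))
  expect_equal(s3$fracAffected, mean(fr))
  expect_equal(s3$fracAffectedSD, sd(fr))
  expect_equal(s3$meanOverAffected, mean(mo))
  expect_equal(s3$meanOverAffectedSD, sd(mo))
})

test_that("the affected fraction never increases with the threshold", {
  set.seed(111)
  mk <- function(deltas)
    structure(list(model = 1, perturbation = "KD:X",
                   delta = setNames(deltas,
                                    paste0("e", seq_along(deltas)))),
              class = "PerturbationResult")
  labels <- setNames(rep(c("positive", "negative"), each = 10),
                     paste0("e", 1:20))
  res <- list(mk(runif(20, -40, 40)))
  fr <- vapply(c(1, 5, 10, 20, 50), function(t)
    summarizePerturbations(res, labels, threshold = t)$fracAffected,
    numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("defineRegulon thresholds the ensemble-mean deltas", {
  mk <- function(modelId, deltas)
    structure(list(model = modelId, perturbation = "KD:X",
                   delta = setNames(deltas, c("e1", "e2", "e3"))),
              class = "PerturbationResult")
  res <- list(mk(1, c(-9, 7, 1)), mk(2, c(-7, 9, -1)))
  reg <- defineRegulon(res, "X", threshold = 5)
  expect_equal(reg$activated, "e1")   # mean -8
  expect_equal(reg$repressed, "e2")   # mean +8
  expect_length(intersect(reg$activated, reg$repressed), 0)
  regNone <- defineRegulon(res, "X", threshold = 101)
  expect_length(regNone$activated, 0)
  expect_length(regNone$repressed, 0)
})

test_that("regulon recovery on planted synthetic targets is precise", {
  bundle <- fixtureBundle(
    "tf1only", nPositive = 40, nNegative = 60, siteMode = "consensus",
    plantingScheme = data.frame(tf = c("TF1", "TF2"),
                                role = c("activator", "repressor"),
                                nPos = c(2, 0), nNeg = c(0, 2)),
    coopPairs = data.frame(tf1 = character(0), tf2 = character(0),
                           nPos = numeric(0), nNeg = numeric(0)),
    nDecoys = 0, nMotifs = 2, seed = 13)
  ann <- annotateSiteSet(enhancerSequences(bundle$dataset), bundle$pwms,
                         bundle$thresholds)
  labels <- enhancerLabels(bundle$dataset)
  fit <- fitThermoModel(ann, labels, thermoModel(c("TF1", "TF2")),
                        maxit = 500)
  res <- list(knockdown(fit, ann, "TF1", modelId = 1))
  reg <- defineRegulon(res, "TF1", threshold = 5)
  ## TF1 sites were planted only in positives: the activated targets should
  ## recover that subset with high precision
  carriers <- unique(bundle$truth$sites$enhancer[
    bundle$truth$sites$tf == "TF1"])
  expect_gte(length(reg$activated), 5)
  expect_gte(mean(reg$activated %in% carriers), 0.8)
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  expect_equal(hypergeomEnrichment(10, 5, 4, 0), 1.0)
  expect_equal(hypergeomEnrichment(10, 5, 4, 4), 5 / 210)
  ## exhaustive check against direct summation for small universes
  for (N in c(8, 12)) {
    for (K in c(2, 5)) {
      for (n in c(3, 6)) {
        for (k in 0:min(K, n)) {
          direct <- sum(vapply(k:min(K, n), function(i)
            choose(K, i) * choose(N - K, n - i) / choose(N, n),
            numeric(1)))
          expect_equal(hypergeomEnrichment(N, K, n, k), direct,
                       tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeomEnrichment(10, 12, 3, 1), "inconsistent")
  expect_error(hypergeomEnrichment(10, 5, 4, 5), "inconsistent")
})

test_that("assembleGRN connects layers by regulon, proximity and interaction", {
  emptyNet <- assembleGRN(list(), GenomicRanges::GRanges(),
                          data.frame(gene = character(0),
                                     chrom = character(0),
                                     tss = integer(0)))
  expect_equal(nrow(emptyNet$edges), 0)

  enh <- GenomicRanges::GRanges(c("chr1", "chr1"),
                                IRanges::IRanges(c(100001, 500001),
                                                 c(100500, 500500)))
  names(enh) <- c("enhA", "enhB")
  genes <- data.frame(gene = c("near", "veryfar"),
                      chrom = "chr1",
                      tss = c(104500, 2500000))
  reg <- structure(list(tf = "TF1", activated = c("enhA", "enhB"),
                        repressed = character(0), threshold = 5),
                   class = "Regulon")
  net <- assembleGRN(list(reg), enh, genes, proximityKb = 10)
  ## enhA is 4 kb from the 'near' TSS
  expect_true(any(net$edges$from == "enhA" & net$edges$to == "near" &
                    net$edges$type == "proximity"))
  expect_false(any(net$edges$to == "veryfar"))
  expect_true(all(c("TF", "enhancer", "gene") %in% net$nodes$layer))

  ## a chromatin interaction links enhB to the 2 Mb-distant gene
  pairs <- data.frame(chrom1 = "chr1", start1 = 500000, end1 = 500600,
                      chrom2 = "chr1", start2 = 2499000, end2 = 2501000)
  net2 <- assembleGRN(list(reg), enh, genes, interactionPairs = pairs,
                      proximityKb = 10)
  expect_true(any(net2$edges$from == "enhB" & net2$edges$to == "veryfar" &
                    net2$edges$type == "interaction"))
  expect_error(assembleGRN(list(reg), enh, genes,
                           interactionPairs = data.frame(x = 1)),
               "malformed")
})
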