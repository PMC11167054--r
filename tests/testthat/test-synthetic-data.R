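test_that("generatePWMs is deterministic, shaped and range-checked", {
  cfg <- syntheticConfig(nMotifs = 5, seed = 1)
  p1 <- generatePWMs(cfg)
  p2 <- generatePWMs(cfg)
  expect_identical(lapply(p1, motifMatrix), lapply(p2, motifMatrix))
  cfg33 <- syntheticConfig(nMotifs = 33, plantingScheme = data.frame(
    tf = "TF1", role = "activator", nPos = 1, nNeg = 0), seed = 2)
  p33 <- generatePWMs(cfg33)
  expect_length(p33, 33)
  for (m in p33) expect_true(all(abs(colSums(motifMatrix(m)) - 1) < 1e-9))
  expect_error(syntheticConfig(dominantRange = c(0.2, 0.5)), "dominantRange")
})

test_that("config invariants are enforced", {
  expect_error(syntheticConfig(backgroundFreqs = c(0.5, 0.5, 0.1, 0.1)),
               "sum to 1")
  expect_error(syntheticConfig(motifLength = 3), "motifLength")
  expect_error(syntheticConfig(nMotifs = 2), "reference motifs")
  expect_error(syntheticConfig(replicateNoise = 1.4), "probability")
})

test_that("enhancer set matches the configured composition exactly", {
  cfg <- syntheticConfig(nPositive = 200, nNegative = 600, seed = 4)
  gen <- generateEnhancerSet(cfg, generatePWMs(cfg))
  lab <- table(enhancerLabels(gen$dataset))
  expect_equal(unname(lab[["positive"]]), 200)
  expect_equal(unname(lab[["negative"]]), 600)
  expect_true(all(Biostrings::width(enhancerSequences(gen$dataset)) ==
                    cfg$enhancerLength))
  ## every planted element lies within its enhancer
  sites <- rbind(gen$truth$sites, gen$truth$decoys)
  expect_true(all(sites$start >= 0 &
                    sites$start + sites$width <= cfg$enhancerLength))
  ## byte-identical regeneration under the same seed
  gen2 <- generateEnhancerSet(cfg, generatePWMs(cfg))
  expect_identical(as.character(enhancerSequences(gen$dataset)),
                   as.character(enhancerSequences(gen2$dataset)))
  expect_identical(gen$truth$sites, gen2$truth$sites)
})

test_that("consensus planting yields >= 3 called activator sites per positive", {
  bundle <- fixtureBundle("consensus", nPositive = 25, nNegative = 25,
                          siteMode = "consensus", seed = 9)
  seqs <- as.character(enhancerSequences(bundle$dataset))
  pos <- enhancerLabels(bundle$dataset) == "positive"
  nCalled <- vapply(seqs[pos], function(s)
    nrow(callSites(s, bundle$pwms$TF1, bundle$thresholds["TF1"])),
    numeric(1))
  ## scheme plants 3 TF1 sites plus one TF1 in the cooperative pair
  expect_true(all(nCalled >= 3))
})

test_that("planted activator affinity separates the classes", {
  bundle <- fixtureBundle("default", nPositive = 60, nNegative = 120,
                          enhancerLength = 300, seed = 7)
  seqs <- as.character(enhancerSequences(bundle$dataset))
  aff <- vapply(seqs, affinityScore, numeric(1), motif = bundle$pwms$TF1)
  lab <- enhancerLabels(bundle$dataset)
  p <- t.test(aff[lab == "positive"], aff[lab == "negative"])$p.value
  expect_lt(p, 0.01)
  expect_gt(mean(aff[lab == "positive"]), mean(aff[lab == "negative"]))
})

test_that("a null planting scheme leaves the classes indistinguishable", {
  cfg <- syntheticConfig(
    nPositive = 150, nNegative = 150, enhancerLength = 200,
    plantingScheme = data.frame(tf = "TF1", role = "activator",
                                nPos = 0, nNeg = 0),
    coopPairs = data.frame(tf1 = character(0), tf2 = character(0),
                           nPos = numeric(0), nNeg = numeric(0)),
    nDecoys = 0, nMotifs = 3, seed = 12)
  gen <- generateEnhancerSet(cfg, generatePWMs(cfg))
  ds <- splitDataset(gen$dataset, ratioTest = 0.5, seed = 12)
  fm <- buildFeatureMatrix(enhancerSequences(ds),
                           generatePWMs(cfg), sitePvalue = 1e-3)
  splits <- enhancerSplits(ds)
  fit <- trainRF(fm[splits == "train", ], enhancerLabels(ds)[splits == "train"],
                 rfConfig(nTrees = 150, mtryGrid = 2, seed = 12))
  scores <- predictRF(fit, fm[splits == "test", ])
  auroc <- evaluateClassifier(scores, enhancerLabels(ds)[splits == "test"])$auroc
  expect_gt(auroc, 0.4)
  expect_lt(auroc, 0.6)
})

test_that("peak tracks round-trip labels at zero noise and drop them with noise", {
  bundle <- fixtureBundle("default", nPositive = 60, nNegative = 120,
                          enhancerLength = 300, seed = 7)
  tracks <- generatePeakTracks(bundle$dataset, bundle$cfg)
  lab <- labelRegions(enhancerRegions(bundle$dataset), tracks$post1,
                      tracks$post2, tracks$pre1, tracks$pre2)
  expect_identical(as.character(lab$label),
                   as.character(enhancerLabels(bundle$dataset)))

  ## replicate dropout: P(keep both replicates) = (1 - noise)^2
  noisy <- syntheticConfig(nPositive = 100, nNegative = 0,
                           plantingScheme = data.frame(
                             tf = "TF1", role = "activator",
                             nPos = 1, nNeg = 0),
                           coopPairs = data.frame(tf1 = character(0),
                                                  tf2 = character(0),
                                                  nPos = numeric(0),
                                                  nNeg = numeric(0)),
                           replicateNoise = 0.5, seed = 20)
  lost <- vapply(1:12, function(k) {
    noisy$seed <- 20 + k
    gen <- generateEnhancerSet(noisy, generatePWMs(noisy))
    tr <- generatePeakTracks(gen$dataset, noisy)
    lab <- labelRegions(enhancerRegions(gen$dataset), tr$post1, tr$post2,
                        tr$pre1, tr$pre2)
    sum(lab$label != "positive")
  }, numeric(1))
  ## ~75 of 100 positives lose two-replicate support; binomial tolerance
  expect_gt(mean(lost), 75 - 3 * sqrt(100 * 0.75 * 0.25 / 12))
  expect_lt(mean(lost), 75 + 3 * sqrt(100 * 0.75 * 0.25 / 12))
})

test_that("empty dataset gives four empty peak tracks and BED files", {
  cfg <- syntheticConfig(nPositive = 0, nNegative = 0,
                         plantingScheme = data.frame(
                           tf = "TF1", role = "activator", nPos = 0,
                           nNeg = 0),
                         coopPairs = data.frame(tf1 = character(0),
                                                tf2 = character(0),
                                                nPos = numeric(0),
                                                nNeg = numeric(0)),
                         seed = 1)
  gen <- generateEnhancerSet(cfg, generatePWMs(cfg))
  dir <- tempfile()
  tracks <- generatePeakTracks(gen$dataset, cfg, dir = dir)
  expect_true(all(vapply(tracks, length, numeric(1)) == 0))
  beds <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  expect_length(beds, 4)
  expect_true(all(vapply(beds, function(f) length(readBed(f)) == 0,
                         logical(1))))
})

test_that("an over-stuffed planting scheme fails loudly", {
  cfg <- syntheticConfig(nPositive = 2, nNegative = 2, enhancerLength = 30,
                         plantingScheme = data.frame(
                           tf = "TF1", role = "activator",
                           nPos = 10, nNeg = 0),
                         coopPairs = data.frame(tf1 = character(0),
                                                tf2 = character(0),
                                                nPos = numeric(0),
                                                nNeg = numeric(0)),
                         seed = 1)
  expect_error(generateEnhancerSet(cfg, generatePWMs(cfg)), "too short")
})

test_that("generateVariants labels effects consistently and deterministically", {
  bundle <- fixtureBundle("default", nPositive = 60, nNegative = 120,
                          enhancerLength = 300, seed = 7)
  v1 <- generateVariants(bundle$dataset, bundle$truth, bundle$pwms,
                         nSiteHits = 20, nNeutral = 30, seed = 5)
  v2 <- generateVariants(bundle$dataset, bundle$truth, bundle$pwms,
                         nSiteHits = 20, nNeutral = 30, seed = 5)
  expect_identical(v1, v2)
  expect_equal(nrow(v1), 50)
  expect_equal(sum(v1$effect == "neutral"), 30)
  expect_true(all(v1$ref != v1$alt))
  ## all neutral when no site hits requested
  v0 <- generateVariants(bundle$dataset, bundle$truth, bundle$pwms,
                         nSiteHits = 0, nNeutral = 10, seed = 5)
  expect_true(all(v0$effect == "neutral"))
  ## positions are 1-based within the host enhancer
  regions <- enhancerRegions(bundle$dataset)
  host <- regions[v1$enhancer]
  expect_true(all(v1$pos >= GenomicRanges::start(host) &
                    v1$pos <= GenomicRanges::end(host)))
  ## the reference allele matches the sequence
  seqs <- as.character(enhancerSequences(bundle$dataset))
  off <- v1$pos - GenomicRanges::start(host) + 1L
  expect_identical(unname(substring(seqs[v1$enhancer], off, off)), v1$ref)
  ## neutral variants avoid planted elements
  planted <- rbind(bundle$truth$sites[, c("enhancer", "start", "width")],
                   bundle$truth$decoys[, c("enhancer", "start", "width")])
  for (i in which(v1$effect == "neutral")) {
    pl <- planted[planted$enhancer == v1$enhancer[i], , drop = FALSE]
    off0 <- off[i] - 1L
    expect_false(any(off0 >= pl$start & off0 < pl$start + pl$width))
  }
  expect_error(generateVariants(bundle$dataset, bundle$truth, bundle$pwms,
                                nSiteHits = 1e6, nNeutral = 0),
               "exceed")
})
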