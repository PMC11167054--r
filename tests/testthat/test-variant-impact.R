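## a two-enhancer dataset where enhancer 1 carries one consensus activator
## site and enhancer 2 carries a one-base-off decoy of the same motif
variantFixture <- function() {
  fx <- singleSiteFixture(tau = 6, K = 3, offset = 20)
  motif <- fx$motif
  cons <- consensusSequence(motif)
  decoy <- cons
  worst <- c("T", "A", "T", "A")[1]
  substr(decoy, 1, 1) <- "T"        # consensus starts with A
  seq1 <- fx$sequence
  seq2 <- paste0(strrep("ATTA", 5), decoy, strrep("TTAA", 10))
  n1 <- nchar(seq1); n2 <- nchar(seq2)
  regions <- GenomicRanges::GRanges(c("chrV", "chrV"),
                                    IRanges::IRanges(c(1, 1001),
                                                     c(n1, 1000 + n2)))
  names(regions) <- c("enh1", "enh2")
  ds <- EnhancerDataset(regions,
                        Biostrings::DNAStringSet(c(enh1 = seq1,
                                                   enh2 = seq2)),
                        c("positive", "negative"))
  list(ds = ds, motif = motif, model = fx$model, thr = fx$thresholds,
       offset = fx$offset)
}

test_that("applyVariant substitutes exactly one base and checks the reference", {
  fx <- variantFixture()
  region <- enhancerRegions(fx$ds)["enh1"]
  seq1 <- as.character(enhancerSequences(fx$ds))[["enh1"]]
  v <- data.frame(chrom = "chrV", pos = 8, ref = substr(seq1, 8, 8),
                  alt = "G", id = "v1")
  mut <- applyVariant(seq1, region, v)
  diffs <- which(strsplit(seq1, "")[[1]] != strsplit(mut, "")[[1]])
  expect_equal(diffs, 8)
  expect_equal(nchar(mut), nchar(seq1))
  ## alt equal to ref leaves the sequence unchanged
  same <- v; same$alt <- same$ref
  expect_identical(applyVariant(seq1, region, same), seq1)
  bad <- v; bad$ref <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  expect_error(applyVariant(seq1, region, bad), "mismatch")
  outside <- v; outside$pos <- 10000
  expect_error(applyVariant(seq1, region, outside), "outside")
})

test_that("variant deltas carry the site-destruction/creation sign convention", {
  fx <- variantFixture()
  seq1 <- as.character(enhancerSequences(fx$ds))[["enh1"]]
  ## destroy the consensus site: first site base -> worst base
  sitePos <- fx$offset + 1L
  worst <- c("A", "C", "G", "T")[which.min(
    motifMatrix(fx$motif)[, 1])]
  destroy <- data.frame(chrom = "chrV", pos = sitePos,
                        ref = substr(seq1, sitePos, sitePos), alt = worst,
                        id = "destroy", enhancer = "enh1")
  ## create a site: fix the decoy's broken first base back to consensus
  seq2 <- as.character(enhancerSequences(fx$ds))[["enh2"]]
  create <- data.frame(chrom = "chrV", pos = 1000 + 21,
                       ref = "T", alt = "A", id = "create",
                       enhancer = "enh2")
  neutral <- data.frame(chrom = "chrV", pos = 3,
                        ref = substr(seq1, 3, 3),
                        alt = setdiff(c("A", "C", "G", "T"),
                                      substr(seq1, 3, 3))[1],
                        id = "neutral", enhancer = "enh1")
  identity <- data.frame(chrom = "chrV", pos = 3,
                         ref = substr(seq1, 3, 3),
                         alt = substr(seq1, 3, 3),
                         id = "identity", enhancer = "enh1")
  variants <- rbind(destroy, create, neutral, identity)
  scored <- scoreVariantsEnsemble(list(fx$model), fx$ds, variants,
                                  list(TFX = fx$motif), fx$thr)
  expect_lt(scored$delta["destroy", 1], 0)
  expect_gt(scored$delta["create", 1], 0)
  expect_equal(unname(scored$delta["neutral", 1]), 0)
  expect_equal(unname(scored$delta["identity", 1]), 0)
})

test_that("scoring is antisymmetric under allele swap with a fixed reference", {
  fx <- variantFixture()
  seq1 <- as.character(enhancerSequences(fx$ds))[["enh1"]]
  region <- enhancerRegions(fx$ds)["enh1"]
  sitePos <- fx$offset + 2L
  ref <- substr(seq1, sitePos, sitePos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[2]
  v <- data.frame(chrom = "chrV", pos = sitePos, ref = ref, alt = alt,
                  id = "v")
  mut <- applyVariant(seq1, region, v)
  motifs <- list(TFX = fx$motif)
  refDist <- predictExpressionSet(
    annotateSiteSet(enhancerSequences(fx$ds), motifs, fx$thr), fx$model)
  pct <- function(s) percentileNormalize(
    predictExpression(annotateSites(s, motifs, fx$thr), fx$model), refDist)
  expect_equal(pct(mut) - pct(seq1), -(pct(seq1) - pct(mut)))
})

test_that("bindingChange reports the mechanism with PWM arithmetic", {
  fx <- variantFixture()
  seq1 <- as.character(enhancerSequences(fx$ds))[["enh1"]]
  sitePos <- fx$offset + 1L
  col <- 1L
  worst <- c("A", "C", "G", "T")[which.min(motifMatrix(fx$motif)[, col])]
  mut <- seq1
  substr(mut, sitePos, sitePos) <- worst
  res <- bindingChange(list(TFX = fx$motif), seq1, mut,
                       variantOffset = sitePos - 1L, thresholds = fx$thr)
  llr <- llrMatrix(fx$motif)
  spread <- unname(max(llr[, col]) - llr[worst, col])
  ## normalized by the theoretical maximum LLR by default
  expect_equal(res$change[["TFX"]], -spread / maxLLR(fx$motif),
               tolerance = 1e-9)
  expect_lte(abs(res$change[["TFX"]]), 1)
  expect_equal(res$topMechanism$tf, "TFX")
  ## a variant far from any window that reaches the threshold scores 0
  far <- bindingChange(list(TFX = fx$motif), seq1, mut,
                       variantOffset = 2L, thresholds = fx$thr)
  expect_equal(far$change[["TFX"]], 0)
})

test_that("collectionMaxLLR takes the strongest called site per TF", {
  fx <- variantFixture()
  ref <- collectionMaxLLR(enhancerSequences(fx$ds), list(TFX = fx$motif),
                          fx$thr)
  expect_equal(ref[["TFX"]], maxLLR(fx$motif), tolerance = 1e-9)
})

test_that("prioritizeVariants ranks per model with deterministic ties", {
  delta <- cbind(m1 = c(a = 5, b = -30, c = 10, d = 0, e = -10),
                 m2 = c(a = 40, b = 1, c = 2, d = 3, e = 4))
  expect_equal(prioritizeVariants(delta, 2)[[1]], c("b", "c"))
  expect_equal(prioritizeVariants(delta, 2)[[2]], c("a", "e"))
  expect_setequal(prioritizeVariants(delta, 5)[[1]], rownames(delta))
  ## exact ties fall back to id order
  tied <- cbind(m1 = c(z = 5, y = -5, x = 5))
  expect_equal(prioritizeVariants(tied, 2)[[1]], c("x", "y"))
  expect_error(prioritizeVariants(delta, 0), "positive")
  expect_error(prioritizeVariants(delta, 99), "exceeds")
})

test_that("precisionEval computes count ratios and compares strategies", {
  pri <- list(c("a", "b", "c", "d"), c("a", "b", "x", "y"))
  allIds <- c(letters[1:10], "x", "y")
  ev <- precisionEval(pri, trueSet = c("a", "b"), inEnhancerIds = allIds,
                      nRep = 50, seed = 1)
  expect_equal(ev$modelPrecision, c(0.5, 0.5))
  expect_equal(ev$K, 4)
  full <- precisionEval(pri, trueSet = allIds, inEnhancerIds = allIds,
                        nRep = 10, seed = 1)
  expect_true(all(full$modelPrecision == 1))
  expect_true(all(full$locationPrecision == 1))
  expect_error(precisionEval(pri, character(0), allIds), "empty")
})

test_that("variant tables and minimal VCF files are read back faithfully", {
  tab <- data.frame(chrom = "chr1", pos = c(100L, 200L),
                    ref = c("A", "G"), alt = c("T", "C"),
                    id = c("v1", "v2"))
  path <- tempfile(fileext = ".tsv")
  writeVariantTable(tab, path)
  expect_equal(readVariantTable(path), tab)
  indel <- data.frame(chrom = "chr1", pos = 5L, ref = "AT", alt = "A",
                      id = "bad")
  badPath <- tempfile(fileext = ".tsv")
  writeVariantTable(indel, badPath)
  expect_error(readVariantTable(badPath), "single-nucleotide")

  skip_if_not_installed("VariantAnnotation")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\trs1\tA\tT\t.\t.\t.",
    "chr1\t200\trs2\tG\tC\t.\t.\t."
  ), vcf)
  v <- readVariantVcf(vcf)
  expect_equal(v$pos, c(100, 200))
  expect_equal(v$ref, c("A", "G"))
  expect_equal(v$alt, c("T", "C"))
})

test_that("assignEnhancer resolves hosts by containment", {
  regions <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(c(101, 501),
                                                     c(200, 600)))
  names(regions) <- c("r1", "r2")
  v <- data.frame(chrom = "chr1", pos = c(150L, 550L, 900L),
                  ref = "A", alt = "T", id = paste0("v", 1:3))
  out <- assignEnhancer(v, regions)
  expect_equal(out$enhancer, c("r1", "r2", NA))
})

test_that("model-based prioritization beats location sampling on planted effects", {
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
  variants <- generateVariants(bundle$dataset, bundle$truth, bundle$pwms,
                               nSiteHits = 15, nNeutral = 60, seed = 4)
  scored <- scoreVariantsEnsemble(list(fit), bundle$dataset, variants,
                                  bundle$pwms, bundle$thresholds)
  trueSet <- variants$id[variants$effect != "neutral"]
  pri <- prioritizeVariants(scored$delta, length(trueSet))
  ev <- precisionEval(pri, trueSet, variants$id, nRep = 60, seed = 2)
  expect_gt(median(ev$modelPrecision), median(ev$locationPrecision))
})
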