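.PIPELINE_STAGES <- c("simulate", "dataset", "features", "rf",
                      "thermo-train", "thermo-select", "perturb", "grn",
                      "variants", "evaluate")

.DEFAULT_PARAMS <- list(
  sitePvalue = 1e-4, adjacencyWindow = 50, mergeDistance = 100,
  peakMinScore = 5, ratioTest = 1 / 5, validationRatio = 1 / 4,
  kTopFeatures = 16, nInits = 20, maxit = 600, topK = 5,
  perturbThreshold = 5, proximityKb = 10, kGrid = c(25, 50, 100),
  rfTrees = 300, rfCvRepeats = 1, rfCvFolds = 3
)

#' Build and validate a pipeline run configuration
#'
#' A `RunConfig` couples stage parameters (all defaults are the canonical
#' analysis settings: site p-value 1e-4, adjacency window 50 bp, merge
#' distance 100 bp, peak score threshold 5, test ratio 1/5, perturbation
#' threshold 5 percentile points, gene proximity 10 kb) with either a
#' synthetic-data section or paths to externally provided inputs. Referenced
#' paths are checked up front so a misconfigured run fails before any
#' computation.
#'
#' @param config named list or path to a YAML file with optional sections
#'   `seed`, `params`, `synthetic` (arguments of [syntheticConfig()]) and
#'   `paths` (external inputs: `pwmDir` or `pwmFile`, `fasta`, `postRep1`,
#'   `postRep2`, `preRep1`, `preRep2`, `erPeaks`, `k27Peaks`, `variants`,
#'   `geneTss`, `interactionPairs`).
#' @return validated list of class `RunConfig`.
#' @export
runConfig <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  params <- utils::modifyList(.DEFAULT_PARAMS, config$params %||% list())
  cfg <- list(seed = config$seed %||% 1L,
              params = params,
              synthetic = config$synthetic %||% list(),
              paths = config$paths %||% list())
  for (nm in names(cfg$paths)) {
    p <- cfg$paths[[nm]]
    if (!file.exists(p) && !dir.exists(p))
      stop("config error: path '", nm, "' does not exist: ", p)
  }
  if (params$sitePvalue <= 0 || params$sitePvalue > 1)
    stop("config error: sitePvalue must be in (0, 1]")
  if (params$ratioTest < 0 || params$ratioTest >= 1)
    stop("config error: ratioTest must be in [0, 1)")
  structure(cfg, class = "RunConfig")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stageFile <- function(outDir, ...) file.path(outDir, ...)

.writeManifest <- function(outDir, stage, inputs, outputs, params, seed) {
  manifest <- list(
    stage = stage,
    package = as.character(packageVersion("eRNAthermo")),
    seed = seed,
    params = params,
    inputs = as.list(md5sum(inputs[file.exists(inputs)])),
    outputs = as.list(md5sum(outputs[file.exists(outputs)]))
  )
  jsonlite::write_json(manifest,
                       .stageFile(outDir, paste0("manifest_", stage,
                                                 ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.requireUpstream <- function(outDir, files, stage) {
  paths <- .stageFile(outDir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing))
    stop("stage '", stage, "' is missing upstream outputs: ",
         paste(missing, collapse = ", "))
}

.log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Run one pipeline stage
#'
#' Stages (in order): `simulate` (synthetic fixtures), `dataset` (labeling
#' and splits from peak tracks), `features` (motif feature matrix), `rf`
#' (Random Forest classification report), `thermo-train` (model ensemble),
#' `thermo-select` (validation-based selection), `perturb` (in silico
#' knock-downs), `grn` (network assembly), `variants` (impact scoring) and
#' `evaluate` (prioritization precision). Each stage writes its outputs
#' plus a JSON manifest recording input hashes, parameters and the seed;
#' a rerun with identical inputs and seed is byte-identical.
#'
#' @param stage stage name.
#' @param config a [runConfig()] (or list / YAML path coerced through it).
#' @param outDir working directory for stage outputs.
#' @return invisibly, the paths of the stage's main outputs.
#' @export
runStage <- function(stage, config, outDir) {
  stage <- match.arg(stage, .PIPELINE_STAGES)
  if (!inherits(config, "RunConfig")) config <- runConfig(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  .log("stage '", stage, "' (seed ", config$seed, ")")
  fn <- switch(stage,
    "simulate" = .stageSimulate, "dataset" = .stageDataset,
    "features" = .stageFeatures, "rf" = .stageRF,
    "thermo-train" = .stageThermoTrain,
    "thermo-select" = .stageThermoSelect, "perturb" = .stagePerturb,
    "grn" = .stageGrn, "variants" = .stageVariants,
    "evaluate" = .stageEvaluate)
  fn(config, outDir)
}

#' Run the full pipeline
#'
#' @inheritParams runStage
#' @param stages stages to run, in order (default: all).
#' @return invisibly, `outDir`.
#' @export
runPipeline <- function(config, outDir, stages = .PIPELINE_STAGES) {
  if (!inherits(config, "RunConfig")) config <- runConfig(config)
  for (s in stages) runStage(s, config, outDir)
  invisible(outDir)
}

.syntheticCfg <- function(config) {
  do.call(syntheticConfig,
          utils::modifyList(config$synthetic,
                            list(seed = config$seed), keep.null = TRUE))
}

.stageSimulate <- function(config, outDir) {
  scfg <- .syntheticCfg(config)
  pwms <- generatePWMs(scfg)
  gen <- generateEnhancerSet(scfg, pwms)
  tracks <- generatePeakTracks(gen$dataset, scfg, dir = outDir)
  variants <- generateVariants(gen$dataset, gen$truth, pwms,
                               nSiteHits = max(2L, length(gen$dataset) %/% 5),
                               nNeutral = max(8L,
                                              4 * (length(gen$dataset) %/% 5)),
                               seed = config$seed)
  writeMotifs(pwms, .stageFile(outDir, "pwms.txt"))
  writeXStringSet(enhancerSequences(gen$dataset),
                  .stageFile(outDir, "enhancers.fa"))
  universe <- enhancerRegions(gen$dataset)
  universe$score <- 10
  writeBed(universe, .stageFile(outDir, "universe.bed"))
  writeVariantTable(variants, .stageFile(outDir, "variants.tsv"))
  jsonlite::write_json(
    list(roles = as.list(gen$truth$roles), sites = gen$truth$sites,
         decoys = gen$truth$decoys),
    .stageFile(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
  outs <- c("pwms.txt", "enhancers.fa", "universe.bed", "variants.tsv",
            "truth.json", "post_rep1.bed", "post_rep2.bed", "pre_rep1.bed",
            "pre_rep2.bed")
  .writeManifest(outDir, "simulate", character(0), .stageFile(outDir, outs),
                 config$params, config$seed)
  invisible(.stageFile(outDir, outs))
}

.stageDataset <- function(config, outDir) {
  p <- config$params
  paths <- config$paths
  useExternal <- !is.null(paths$erPeaks)
  if (useExternal) {
    er <- thresholdAndMerge(readBed(paths$erPeaks), p$peakMinScore,
                            p$mergeDistance)
    k27 <- thresholdAndMerge(readBed(paths$k27Peaks), p$peakMinScore,
                             p$mergeDistance)
    universe <- buildUniverse(er, k27)
    trackFiles <- c(paths$postRep1, paths$postRep2, paths$preRep1,
                    paths$preRep2)
  } else {
    .requireUpstream(outDir, c("universe.bed", "post_rep1.bed"), "dataset")
    universe <- readBed(.stageFile(outDir, "universe.bed"))
    trackFiles <- .stageFile(outDir, c("post_rep1.bed", "post_rep2.bed",
                                       "pre_rep1.bed", "pre_rep2.bed"))
  }
  tracks <- lapply(trackFiles, function(f)
    thresholdAndMerge(readBed(f), p$peakMinScore, p$mergeDistance))
  labeled <- labelRegions(universe, tracks[[1]], tracks[[2]], tracks[[3]],
                          tracks[[4]])
  labeled <- splitDataset(labeled, ratioTest = p$ratioTest,
                          seed = config$seed)
  ## thermodynamic-stage sub-split: carve a validation set from training
  split <- as.character(labeled$split)
  set.seed(config$seed + 7L)
  for (cls in c("positive", "negative")) {
    idx <- which(labeled$label == cls & split == "train")
    nVal <- floor(length(idx) * p$validationRatio)
    if (nVal > 0) split[sample(idx, nVal)] <- "validation"
  }
  labeled$split <- factor(split, levels = .SPLIT_LEVELS)
  df <- data.frame(id = names(labeled), label = labeled$label,
                   split = labeled$split)
  write.table(df, .stageFile(outDir, "dataset.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeManifest(outDir, "dataset", trackFiles,
                 .stageFile(outDir, "dataset.tsv"), p, config$seed)
  invisible(.stageFile(outDir, "dataset.tsv"))
}

.readStageDataset <- function(config, outDir) {
  p <- config$params
  fasta <- config$paths$fasta %||% .stageFile(outDir, "enhancers.fa")
  seqs <- readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*", "", names(seqs))
  df <- read.table(.stageFile(outDir, "dataset.tsv"), sep = "\t",
                   header = TRUE)
  seqs <- seqs[df$id]
  pwmPath <- config$paths$pwmDir %||% config$paths$pwmFile
  ## the pipeline's own pwms.txt stores pseudocounted probabilities
  motifs <- if (is.null(pwmPath))
    readMotifs(.stageFile(outDir, "pwms.txt"), pseudocount = 0)
  else readMotifs(pwmPath)
  list(seqs = seqs, table = df, motifs = motifs)
}

.stageFeatures <- function(config, outDir) {
  .requireUpstream(outDir, "dataset.tsv", "features")
  p <- config$params
  d <- .readStageDataset(config, outDir)
  fm <- buildFeatureMatrix(d$seqs, d$motifs, sitePvalue = p$sitePvalue,
                           adjacencyWindow = p$adjacencyWindow)
  writeFeatureMatrix(fm, .stageFile(outDir, "features.tsv"))
  writeFeatureMatrix(zscoreColumns(fm), .stageFile(outDir, "features_z.tsv"))
  .writeManifest(outDir, "features", .stageFile(outDir, "dataset.tsv"),
                 .stageFile(outDir, c("features.tsv", "features_z.tsv")),
                 p, config$seed)
  invisible(.stageFile(outDir, "features.tsv"))
}

.stageRF <- function(config, outDir) {
  .requireUpstream(outDir, c("dataset.tsv", "features.tsv"), "rf")
  p <- config$params
  d <- .readStageDataset(config, outDir)
  fm <- readFeatureMatrix(.stageFile(outDir, "features.tsv"))
  tab <- d$table
  trainIdx <- tab$split %in% c("train", "validation")
  testIdx <- tab$split == "test"
  cfg <- rfConfig(nTrees = p$rfTrees, cvFolds = p$rfCvFolds,
                  cvRepeats = p$rfCvRepeats, seed = config$seed)
  fit <- trainRF(fm[trainIdx, , drop = FALSE], tab$label[trainIdx], cfg)
  scores <- predictRF(fit, fm[testIdx, , drop = FALSE])
  ev <- evaluateClassifier(scores, tab$label[testIdx])
  imp <- permutationImportance(fit)
  write.table(imp, .stageFile(outDir, "rf_importance.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ev$roc, .stageFile(outDir, "rf_roc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ev$pr, .stageFile(outDir, "rf_pr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(auroc = ev$auroc, auprc = ev$auprc,
                            mtry = fit$mtry, nTrees = p$rfTrees),
                       .stageFile(outDir, "rf_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  outs <- c("rf_importance.tsv", "rf_roc.tsv", "rf_pr.tsv",
            "rf_metrics.json")
  .writeManifest(outDir, "rf",
                 .stageFile(outDir, c("dataset.tsv", "features.tsv")),
                 .stageFile(outDir, outs), p, config$seed)
  invisible(.stageFile(outDir, outs))
}

#' Derive the thermodynamic model structure from RF importance
#'
#' Takes the top-k most important features, maps affinity features to
#' modeled TFs and adjacency features to allowed TF-TF interaction pairs
#' (both members of a selected pair are added to the TF set).
#'
#' @param importance data.frame from [permutationImportance()].
#' @param k number of top features to use (default 16).
#' @param extraTFs TFs to include regardless of importance rank.
#' @param extraPairs list of TF pairs to allow regardless of rank.
#' @return list with `tfs` (character) and `pairs` (list of length-2
#'   character vectors).
#' @export
chooseThermoStructure <- function(importance, k = 16, extraTFs = character(0),
                                  extraPairs = list()) {
  feats <- topFeatures(importance, k)
  affTF <- sub("^aff_", "", feats[startsWith(feats, "aff_")])
  pairFeats <- feats[startsWith(feats, "adj_")]
  pairs <- lapply(strsplit(sub("^adj_", "", pairFeats), "__"), identity)
  pairs <- c(pairs, extraPairs)
  tfs <- unique(c(affTF, unlist(pairs), extraTFs))
  keys <- vapply(pairs, function(p)
    paste(sort(p), collapse = "|"), character(1))
  list(tfs = tfs, pairs = pairs[!duplicated(keys)])
}

.thermoTemplate <- function(structure, p) {
  coop <- if (length(structure$pairs))
    data.frame(tf1 = vapply(structure$pairs, `[`, character(1), 1L),
               tf2 = vapply(structure$pairs, `[`, character(1), 2L),
               omega = 1)
  else NULL
  thermoModel(structure$tfs, coop = coop,
              coopDistance = p$adjacencyWindow)
}

.stageAnnotations <- function(config, outDir) {
  p <- config$params
  d <- .readStageDataset(config, outDir)
  thresholds <- vapply(d$motifs, pvalueThreshold, numeric(1),
                       p = p$sitePvalue)
  ann <- annotateSiteSet(d$seqs, d$motifs, thresholds)
  list(d = d, ann = ann, thresholds = thresholds)
}

.stageThermoTrain <- function(config, outDir) {
  .requireUpstream(outDir, c("dataset.tsv", "rf_importance.tsv"),
                   "thermo-train")
  p <- config$params
  ctx <- .stageAnnotations(config, outDir)
  imp <- read.table(.stageFile(outDir, "rf_importance.tsv"), sep = "\t",
                    header = TRUE)
  structure <- chooseThermoStructure(imp, k = p$kTopFeatures)
  template <- .thermoTemplate(structure, p)
  tab <- ctx$d$table
  trainIdx <- tab$split == "train"
  ensemble <- buildEnsemble(ctx$ann[trainIdx], tab$label[trainIdx],
                            template, nInits = p$nInits, maxit = p$maxit,
                            seed = config$seed)
  modelDir <- .stageFile(outDir, "models")
  if (!dir.exists(modelDir)) dir.create(modelDir)
  for (i in seq_along(ensemble))
    writeThermoModel(ensemble[[i]],
                     file.path(modelDir, sprintf("model_%04d.json", i)))
  losses <- data.frame(model = seq_along(ensemble),
                       loss = vapply(ensemble, attr, numeric(1), "loss"))
  write.table(losses, .stageFile(outDir, "thermo_losses.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeManifest(outDir, "thermo-train",
                 .stageFile(outDir, c("dataset.tsv", "rf_importance.tsv")),
                 .stageFile(outDir, "thermo_losses.tsv"), p, config$seed)
  invisible(modelDir)
}

.readEnsemble <- function(outDir) {
  files <- sort(list.files(.stageFile(outDir, "models"),
                           pattern = "^model_.*\\.json$",
                           full.names = TRUE))
  lapply(files, readThermoModel)
}

.stageThermoSelect <- function(config, outDir) {
  .requireUpstream(outDir, c("dataset.tsv", "thermo_losses.tsv"),
                   "thermo-select")
  p <- config$params
  ctx <- .stageAnnotations(config, outDir)
  ensemble <- .readEnsemble(outDir)
  tab <- ctx$d$table
  valIdx <- tab$split == "validation"
  if (!any(valIdx)) valIdx <- tab$split == "train"
  sel <- selectEnsemble(ensemble, ctx$ann[valIdx], tab$label[valIdx],
                        k = min(p$topK, length(ensemble)))
  testIdx <- tab$split == "test"
  testMetrics <- t(vapply(sel$models, function(m) {
    pred <- predictExpressionSet(.compileSet(ctx$ann[testIdx], m), m)
    ev <- evaluateClassifier(pred, tab$label[testIdx])
    c(auroc = ev$auroc, auprc = ev$auprc)
  }, numeric(2)))
  jsonlite::write_json(
    list(selected = sel$index,
         validation = sel$metrics,
         testAUROC = testMetrics[, "auroc"],
         testAUPRC = testMetrics[, "auprc"]),
    .stageFile(outDir, "thermo_selection.json"), digits = NA)
  .writeManifest(outDir, "thermo-select",
                 .stageFile(outDir, "thermo_losses.tsv"),
                 .stageFile(outDir, "thermo_selection.json"), p,
                 config$seed)
  invisible(.stageFile(outDir, "thermo_selection.json"))
}

.selectedEnsemble <- function(outDir) {
  sel <- jsonlite::read_json(.stageFile(outDir, "thermo_selection.json"),
                             simplifyVector = TRUE)
  .readEnsemble(outDir)[sel$selected]
}

.stagePerturb <- function(config, outDir) {
  .requireUpstream(outDir, c("dataset.tsv", "thermo_selection.json"),
                   "perturb")
  p <- config$params
  ctx <- .stageAnnotations(config, outDir)
  models <- .selectedEnsemble(outDir)
  keep <- ctx$d$table$label != "excluded"
  ann <- ctx$ann[keep]
  results <- perturbEnsemble(models, ann)
  summary <- summarizePerturbations(results, ctx$d$table$label[keep],
                                    threshold = p$perturbThreshold)
  write.table(summary, .stageFile(outDir, "perturbation_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  regulons <- lapply(models[[1]]@tfNames, function(tf)
    defineRegulon(results, tf, threshold = p$perturbThreshold))
  regTab <- do.call(rbind, lapply(regulons, function(r)
    if (length(c(r$activated, r$repressed)))
      data.frame(tf = r$tf,
                 enhancer = c(r$activated, r$repressed),
                 direction = rep(c("activated", "repressed"),
                                 c(length(r$activated),
                                   length(r$repressed))))
    else NULL))
  if (is.null(regTab))
    regTab <- data.frame(tf = character(0), enhancer = character(0),
                         direction = character(0))
  write.table(regTab, .stageFile(outDir, "regulons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .writeManifest(outDir, "perturb",
                 .stageFile(outDir, "thermo_selection.json"),
                 .stageFile(outDir, c("perturbation_summary.tsv",
                                      "regulons.tsv")), p, config$seed)
  invisible(.stageFile(outDir, "perturbation_summary.tsv"))
}

.stageGrn <- function(config, outDir) {
  .requireUpstream(outDir, "regulons.tsv", "grn")
  p <- config$params
  ctx <- .stageAnnotations(config, outDir)
  regTab <- read.table(.stageFile(outDir, "regulons.tsv"), sep = "\t",
                       header = TRUE)
  regulons <- lapply(split(regTab, regTab$tf), function(g)
    structure(list(tf = g$tf[1],
                   activated = g$enhancer[g$direction == "activated"],
                   repressed = g$enhancer[g$direction == "repressed"],
                   threshold = p$perturbThreshold),
              class = "Regulon"))
  universe <- readBed(config$paths$universe %||%
                        .stageFile(outDir, "universe.bed"))
  if (!is.null(config$paths$geneTss)) {
    genes <- read.table(config$paths$geneTss, sep = "\t", header = TRUE)
  } else {
    ## synthetic gene annotation: one gene 3 kb downstream of every 5th
    ## enhancer
    idx <- seq(1L, length(universe), by = 5L)
    genes <- data.frame(gene = paste0("gene_", seq_along(idx)),
                        chrom = as.character(seqnames(universe[idx])),
                        tss = end(universe[idx]) + 3000L)
  }
  pairs <- if (!is.null(config$paths$interactionPairs))
    read.table(config$paths$interactionPairs, sep = "\t", header = TRUE)
  else NULL
  grn <- assembleGRN(regulons, universe, genes, pairs,
                     proximityKb = p$proximityKb)
  writeGRN(grn, .stageFile(outDir, "grn_nodes.tsv"),
           .stageFile(outDir, "grn_edges.tsv"))
  .writeManifest(outDir, "grn", .stageFile(outDir, "regulons.tsv"),
                 .stageFile(outDir, c("grn_nodes.tsv", "grn_edges.tsv")),
                 p, config$seed)
  invisible(.stageFile(outDir, c("grn_nodes.tsv", "grn_edges.tsv")))
}

.stageVariants <- function(config, outDir) {
  .requireUpstream(outDir, c("dataset.tsv", "thermo_selection.json"),
                   "variants")
  p <- config$params
  ctx <- .stageAnnotations(config, outDir)
  models <- .selectedEnsemble(outDir)
  varPath <- config$paths$variants %||% .stageFile(outDir, "variants.tsv")
  variants <- readVariantTable(varPath)
  universe <- readBed(config$paths$universe %||%
                        .stageFile(outDir, "universe.bed"))
  variants <- assignEnhancer(variants, universe)
  variants <- variants[!is.na(variants$enhancer), , drop = FALSE]
  ## the percentile reference spans all modeled enhancers
  dataset <- EnhancerDataset(universe, ctx$d$seqs[names(universe)],
                             ctx$d$table$label)
  scored <- scoreVariantsEnsemble(models, dataset, variants, ctx$d$motifs,
                                  ctx$thresholds)
  refMax <- collectionMaxLLR(ctx$d$seqs, ctx$d$motifs, ctx$thresholds)
  seqs <- as.character(enhancerSequences(dataset))
  regions <- enhancerRegions(dataset)
  mechanisms <- lapply(seq_len(nrow(variants)), function(v) {
    enh <- variants$enhancer[v]
    wt <- seqs[[enh]]
    mut <- applyVariant(wt, regions[enh], variants[v, ])
    off0 <- variants$pos[v] - start(regions[enh])
    bindingChange(ctx$d$motifs, wt, mut, off0, ctx$thresholds,
                  siteLLRReference = refMax)
  })
  impact <- variantImpactTable(scored, mechanisms)
  write.table(impact, .stageFile(outDir, "variant_impact.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  deltaPath <- .stageFile(outDir, "variant_delta.tsv")
  write.table(data.frame(id = rownames(scored$delta), scored$delta),
              deltaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(outDir, "variants", varPath,
                 .stageFile(outDir, c("variant_impact.tsv",
                                      "variant_delta.tsv")), p,
                 config$seed)
  invisible(.stageFile(outDir, "variant_impact.tsv"))
}

.stageEvaluate <- function(config, outDir) {
  .requireUpstream(outDir, c("variant_delta.tsv", "variants.tsv"),
                   "evaluate")
  p <- config$params
  deltaTab <- read.table(.stageFile(outDir, "variant_delta.tsv"),
                         sep = "\t", header = TRUE)
  delta <- as.matrix(deltaTab[, -1L, drop = FALSE])
  rownames(delta) <- deltaTab$id
  variants <- readVariantTable(.stageFile(outDir, "variants.tsv"))
  trueSet <- variants$id[variants$effect %in% c("site_destroying",
                                                "site_creating")]
  rows <- list()
  for (K in p$kGrid) {
    if (K > nrow(delta)) next
    pri <- prioritizeVariants(delta, K)
    ev <- precisionEval(pri, trueSet, rownames(delta),
                        nRep = 100, seed = config$seed)
    rows[[length(rows) + 1L]] <- data.frame(
      K = K,
      modelMedian = median(ev$modelPrecision),
      locationMedian = median(ev$locationPrecision),
      randomMedian = median(ev$randomPrecision),
      tTestP = if (is.null(ev$tTest)) NA_real_ else ev$tTest$p.value)
  }
  curves <- do.call(rbind, rows)
  write.table(curves, .stageFile(outDir, "precision_curves.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(outDir, "evaluate",
                 .stageFile(outDir, "variant_delta.tsv"),
                 .stageFile(outDir, "precision_curves.tsv"), p,
                 config$seed)
  invisible(.stageFile(outDir, "precision_curves.tsv"))
}
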