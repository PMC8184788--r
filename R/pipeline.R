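#' Run an analysis stage end to end
#'
#' Orchestrates the package's stages as reproducible runs over files on
#' disk. Every stochastic step receives an explicit seed derived from the
#' global seed and the stage name, and each stage writes a machine-readable
#' `manifest_<stage>.json` (stage, parameters, seeds, package version, input
#' and output checksums) next to its outputs, so re-running a stage with the
#' same config and inputs reproduces its outputs byte-identically.
#'
#' Stages and their outputs under `outDir`:
#' \describe{
#'   \item{simulate}{synthetic inputs for all later stages: per-replicate
#'     section matrices (`tomo_rep*.tsv`), localization truth, SAM-lite
#'     mismatch TSV, cell types, molecule truth, UTR FASTAs, isoform table.}
#'   \item{localize}{QC, normalization, SOM per replicate, localization
#'     calls (`calls.tsv`) and per-replicate prototype TSVs.}
#'   \item{slam-split}{per-UMI classification; labeled/unlabeled MTX
#'     matrices with sidecars, mutation spectrum, T>C histogram, per-cell
#'     labeling efficiency.}
#'   \item{fate}{fold-change table for called vegetal genes, two-component
#'     deconvolution in the focal cell type, Welch comparison against a
#'     sampled background.}
#'   \item{motifs}{weighted length stats, group comparison, k-mer motif
#'     table.}
#'   \item{all}{all of the above in order, sharing `outDir`.}
#' }
#'
#' @param stage One of `"simulate"`, `"localize"`, `"slam-split"`, `"fate"`,
#'   `"motifs"`, `"all"`.
#' @param outDir Output directory (created if missing).
#' @param config Named list overriding stage parameters (see Details), or a
#'   path to a YAML file of the same.
#' @param seed Global integer seed.
#' @param inDir Directory holding the stage's inputs (defaults to `outDir`,
#'   so `simulate` feeds the later stages).
#' @return Invisible list of the manifests written.
#' @export
runPipeline <- function(stage = c("simulate", "localize", "slam-split",
                                  "fate", "motifs", "all"),
                        outDir, config = list(), seed = 1L, inDir = outDir) {
  stage <- match.arg(stage)
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("missing input: config file ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (stage == "all") {
    m <- list()
    for (s in c("simulate", "localize", "slam-split", "fate", "motifs"))
      m[[s]] <- runPipeline(s, outDir, config, seed, inDir = outDir)
    return(invisible(m))
  }
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), "stage ", stage)
  manifest <- switch(stage,
    "simulate" = .stageSimulate(outDir, config, seed),
    "localize" = .stageLocalize(inDir, outDir, config, seed),
    "slam-split" = .stageSlamSplit(inDir, outDir, config, seed),
    "fate" = .stageFate(inDir, outDir, config, seed),
    "motifs" = .stageMotifs(inDir, outDir, config, seed))
  invisible(manifest)
}

.cfg <- function(config, name, default) {
  if (!is.null(config[[name]])) config[[name]] else default
}

.needFile <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  path
}

.writeManifest <- function(outDir, stage, params, seed, inputs, outputs) {
  man <- list(stage = stage, package = "tomoslam",
              version = as.character(utils::packageVersion("tomoslam")),
              seed = seed, params = params,
              inputs = stats::setNames(as.list(unname(tools::md5sum(inputs))),
                                       basename(inputs)),
              outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                                        basename(outputs)))
  path <- file.path(outDir, paste0("manifest_", sub("-", "_", stage), ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  man
}

.stageSimulate <- function(outDir, config, seed) {
  tomoCfg <- do.call(tomoSimConfig,
                     c(.cfg(config, "tomo", list()),
                       list(seed = .deriveSeed(seed, "simulate/tomo"))))
  slamCfg <- do.call(slamSimConfig,
                     c(.cfg(config, "slam", list()),
                       list(seed = .deriveSeed(seed, "simulate/slam"))))
  utrCfg <- do.call(utrSimConfig,
                    c(.cfg(config, "utr", list()),
                      list(seed = .deriveSeed(seed, "simulate/utr"))))
  tomo <- simulateTomoseq(tomoCfg)
  outs <- character(0)
  for (r in names(tomo$replicates)) {
    f <- file.path(outDir, paste0("tomo_", r, ".tsv"))
    writeSectionMatrix(tomo$replicates[[r]], f)
    outs <- c(outs, f)
  }
  f <- file.path(outDir, "tomo_truth.tsv")
  data.table::fwrite(data.frame(gene_id = names(tomo$truth),
                                class = tomo$truth), f, sep = "\t")
  outs <- c(outs, f)

  slam <- simulateSlamReads(slamCfg)
  f <- file.path(outDir, "mismatches.tsv")
  writeMismatchTable(slam$mismatches, f); outs <- c(outs, f)
  f <- file.path(outDir, "cell_types.tsv")
  writeCellTypes(slam$cellTypes, f); outs <- c(outs, f)
  f <- file.path(outDir, "molecule_truth.tsv")
  data.table::fwrite(as.data.frame(slam$truth), f, sep = "\t")
  outs <- c(outs, f)

  utr <- simulateUtrs(utrCfg)
  f <- file.path(outDir, "utr_positive.fa")
  writeUtrFasta(utr$positive, f); outs <- c(outs, f)
  f <- file.path(outDir, "utr_background.fa")
  writeUtrFasta(utr$background, f); outs <- c(outs, f)
  iso <- simulateIsoformTable(seed = .deriveSeed(seed, "simulate/iso"))
  f <- file.path(outDir, "isoforms.tsv")
  writeIsoformTable(iso, f); outs <- c(outs, f)

  .writeManifest(outDir, "simulate",
                 list(tomo = unclass(tomoCfg), slam = unclass(slamCfg),
                      utr = unclass(utrCfg)),
                 seed, character(0), outs)
}

.stageLocalize <- function(inDir, outDir, config, seed) {
  reps <- sort(Sys.glob(file.path(inDir, "tomo_rep*.tsv")))
  if (!length(reps)) stop("missing input: ", file.path(inDir, "tomo_rep*.tsv"))
  params <- list(minSpikein = .cfg(config, "minSpikein", 8000),
                 minCount = .cfg(config, "minCount", 5),
                 nNodes = .cfg(config, "nNodes", 50),
                 epochs = .cfg(config, "epochs", 100),
                 vegetalAll = .cfg(config, "vegetalAll", c(46, 50)),
                 vegetalAny = .cfg(config, "vegetalAny", c(48, 50)),
                 animalWindow = .cfg(config, "animalWindow", c(1, 8)))
  assignments <- list()
  outs <- character(0)
  for (i in seq_along(reps)) {
    sc <- readSectionMatrix(reps[i])
    sc <- qcSections(sc, params$minSpikein)$counts
    sc <- filterGenes(sc, params$minCount)$counts
    ts <- cumulativeTraces(normalizeSections(sc))
    som <- trainSom(ts, nNodes = params$nNodes, epochs = params$epochs,
                    seed = .deriveSeed(seed, paste0("localize/som", i)))
    som <- orderNodes(som, sectionTotals = colSums(counts(sc)))
    assignments[[paste0("rep", i)]] <- assignProfiles(som, ts)
    f <- file.path(outDir, sprintf("som_prototypes_rep%d.tsv", i))
    data.table::fwrite(data.table::data.table(node = seq_len(params$nNodes),
                                              prototypes(som)),
                       f, sep = "\t")
    outs <- c(outs, f)
  }
  calls <- callLocalization(assignments, params$vegetalAll,
                            params$vegetalAny, params$animalWindow)
  f <- file.path(outDir, "calls.tsv")
  writeCalls(calls, f); outs <- c(outs, f)
  .writeManifest(outDir, "localize", params, seed, reps, outs)
}

.stageSlamSplit <- function(inDir, outDir, config, seed) {
  mmFile <- .needFile(file.path(inDir, "mismatches.tsv"))
  ctFile <- .needFile(file.path(inDir, "cell_types.tsv"))
  params <- list(minQual = .cfg(config, "minQual", 20),
                 minTc = .cfg(config, "minTc", 1),
                 readLength = .cfg(config, "readLength", 99))
  mm <- readMismatchTable(mmFile)
  cellTypes <- readCellTypes(ctFile)
  agg <- classifyUmis(aggregateUmis(mm, params$minQual), params$minTc)
  sce <- splitMatrices(agg, cellTypes)
  outs <- character(0)
  for (a in c("labeled", "unlabeled")) {
    f <- file.path(outDir, paste0(a, ".mtx"))
    Matrix::writeMM(assay(sce, a), f)
    writeLines(rownames(sce), file.path(outDir, paste0(a, ".genes.tsv")))
    writeLines(colnames(sce), file.path(outDir, paste0(a, ".barcodes.tsv")))
    outs <- c(outs, f, file.path(outDir, paste0(a, ".genes.tsv")),
              file.path(outDir, paste0(a, ".barcodes.tsv")))
  }
  f <- file.path(outDir, "mutation_spectrum.tsv")
  data.table::fwrite(mutationSpectrum(mm, params$readLength, params$minQual),
                     f, sep = "\t")
  outs <- c(outs, f)
  th <- tcHistogram(agg)
  f <- file.path(outDir, "tc_histogram.tsv")
  data.table::fwrite(th$perUmi, f, sep = "\t"); outs <- c(outs, f)
  f <- file.path(outDir, "labeling_efficiency.tsv")
  data.table::fwrite(labelingEfficiency(sce), f, sep = "\t")
  outs <- c(outs, f)
  .writeManifest(outDir, "slam-split", params, seed,
                 c(mmFile, ctFile), outs)
}

.stageFate <- function(inDir, outDir, config, seed) {
  unlFile <- .needFile(file.path(inDir, "unlabeled.mtx"))
  ctFile <- .needFile(file.path(inDir, "cell_types.tsv"))
  params <- list(minExpr = .cfg(config, "minExpr", 0.1),
                 pseudocount = .cfg(config, "pseudocount", 0.01),
                 focalType = .cfg(config, "focalType", "pgc"),
                 geneSet = .cfg(config, "geneSet", NULL))
  unl <- as(Matrix::readMM(unlFile), "CsparseMatrix")
  rownames(unl) <- readLines(file.path(inDir, "unlabeled.genes.tsv"))
  colnames(unl) <- readLines(file.path(inDir, "unlabeled.barcodes.tsv"))
  cellTypes <- readCellTypes(ctFile)[colnames(unl)]
  geneSet <- params$geneSet
  if (is.null(geneSet)) {
    callsFile <- file.path(inDir, "calls.tsv")
    geneSet <- if (file.exists(callsFile)) {
      calls <- readCalls(callsFile)
      intersect(calls$gene_id[calls$category == "vegetal"], rownames(unl))
    } else rownames(unl)
    if (!length(geneSet)) geneSet <- rownames(unl)
  }
  fc <- foldChange(unl, cellTypes, geneSet, params$minExpr,
                   params$pseudocount)
  outs <- character(0)
  f <- file.path(outDir, "fold_changes.tsv")
  fcDf <- data.frame(gene_id = fc$gene_id, mean_expr = fc$meanExpr,
                     included = fc$included, fc$fc, check.names = FALSE)
  data.table::fwrite(fcDf, f, sep = "\t"); outs <- c(outs, f)
  vals <- fc$fc[fc$included, params$focalType]
  gmmRow <- NULL
  if (sum(is.finite(vals)) >= 4) {
    fit <- deconvolveBimodal(vals, k = 2,
                             seed = .deriveSeed(seed, "fate/gmm"))
    allVals <- foldChange(unl, cellTypes, rownames(unl), params$minExpr,
                          params$pseudocount)
    pop <- allVals$fc[allVals$included, params$focalType]
    bgN <- min(length(vals), length(pop))
    bg <- backgroundSample(pop, bgN, .deriveSeed(seed, "fate/background"))
    hi <- fit@responsibilities[, 2] > 0.5
    welch <- if (sum(hi) >= 2) compareMeansWelch(vals[hi], bg)
             else list(t = NA, df = NA, p = NA)
    gmmRow <- data.frame(component = c("low", "high"),
                         weight = fit@weights, mean = fit@means,
                         sd = fit@sds, logLik = fit@logLik,
                         welch_t = welch$t, welch_p = welch$p)
  }
  f <- file.path(outDir, "gmm_fit.tsv")
  if (!is.null(gmmRow)) data.table::fwrite(gmmRow, f, sep = "\t")
  else writeLines("component\tweight\tmean\tsd\tlogLik\twelch_t\twelch_p", f)
  outs <- c(outs, f)
  .writeManifest(outDir, "fate", params, seed, c(unlFile, ctFile), outs)
}

.stageMotifs <- function(inDir, outDir, config, seed) {
  posFile <- .needFile(file.path(inDir, "utr_positive.fa"))
  bgFile <- .needFile(file.path(inDir, "utr_background.fa"))
  isoFile <- file.path(inDir, "isoforms.tsv")
  params <- list(mink = .cfg(config, "mink", 3),
                 maxk = .cfg(config, "maxk", 10),
                 maxEvalue = .cfg(config, "maxEvalue", 0.5),
                 maxRounds = .cfg(config, "maxRounds", 10),
                 minFpkmGene = .cfg(config, "minFpkmGene", 10))
  pos <- readUtrFasta(posFile)
  bg <- readUtrFasta(bgFile)
  outs <- character(0)
  motifs <- kmerEnrichment(pos, bg, params$mink, params$maxk,
                           params$maxEvalue, params$maxRounds)
  f <- file.path(outDir, "motifs.tsv")
  data.table::fwrite(motifs, f, sep = "\t"); outs <- c(outs, f)
  cmp <- compareGroups(Biostrings::width(pos), Biostrings::width(bg))
  gcp <- gcContent(pos); gcb <- gcContent(bg)
  stats <- data.frame(metric = c("mean_length_positive",
                                 "mean_length_background", "length_fold",
                                 "length_wilcoxon_p", "gc_positive",
                                 "gc_background"),
                      value = c(cmp$meanFocal, cmp$meanBackground, cmp$fold,
                                cmp$p, gcp$group, gcb$group))
  f <- file.path(outDir, "length_stats.tsv")
  data.table::fwrite(stats, f, sep = "\t"); outs <- c(outs, f)
  ins <- c(posFile, bgFile)
  if (file.exists(isoFile)) {
    wl <- weightedLengths(readIsoformTable(isoFile), params$minFpkmGene)
    f <- file.path(outDir, "weighted_lengths.tsv")
    data.table::fwrite(as.data.frame(wl), f, sep = "\t")
    outs <- c(outs, f)
    ins <- c(ins, isoFile)
  }
  .writeManifest(outDir, "motifs", params, seed, ins, outs)
}
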