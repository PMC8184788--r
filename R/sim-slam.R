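#' Configuration for the metabolic-labeling (scSLAM-seq) read simulator
#'
#' Emulates a gastrulation-stage single-cell labeling experiment: several
#' somatic cell types plus a rare PGC-like population, maternal (unlabeled)
#' and zygotic (labeled) gene programs, per-U T-to-C conversion of zygotic
#' molecules, and a uniform sequencing-error background over all 12
#' substitution types. A designated subset of maternal genes (the "vegetal"
#' program) is expressed at elevated levels in the PGC-like cells, and the
#' PGC-like cells have a reduced zygotic program, mirroring their low
#' labeling rates.
#'
#' @param nCells Named integer vector of cells per type; must contain a rare
#'   `pgc` type.
#' @param nMaternalGenes,nZygoticGenes Gene numbers per program.
#' @param nVegetalGenes Number of maternal genes forming the PGC-enriched
#'   vegetal program (taken from the maternal set).
#' @param muMaternal,muZygotic Expected molecules per cell per gene.
#' @param pgcVegetalFactor Fold elevation of vegetal maternal genes in PGCs.
#' @param pgcZygoticFactor Fold reduction (<1) of the zygotic program in PGCs.
#' @param pLabel Per-U conversion probability of a zygotic molecule
#'   (default 0.05). Maternal molecules convert with probability exactly 0.
#' @param errorRate Per-sequenced-base error probability (default 0.001),
#'   spread uniformly over the 12 substitution types.
#' @param readsPerUmi Reads per molecule (default 4).
#' @param readLength Read length in nt (default 99).
#' @param transcriptSpan Distinct transcript positions a molecule's reads can
#'   cover (default 300 nt); effective coverage is
#'   `min(readsPerUmi * readLength, transcriptSpan)`.
#' @param gcContent Mean GC content (default 0.40); the U fraction is
#'   `(1 - gcContent) / 2`.
#' @param qualityValues,qualityProbs Discrete phred-quality distribution of
#'   mismatch base calls.
#' @param seed Integer seed.
#' @return A list of class `SlamSimConfig`.
#' @export
slamSimConfig <- function(nCells = c(ecto = 60, meso = 60, endo = 60,
                                     evl = 40, pgc = 6),
                          nMaternalGenes = 60, nZygoticGenes = 60,
                          nVegetalGenes = 20,
                          muMaternal = 0.5, muZygotic = 1.0,
                          pgcVegetalFactor = 8, pgcZygoticFactor = 0.2,
                          pLabel = 0.05, errorRate = 0.001,
                          readsPerUmi = 4L, readLength = 99L,
                          transcriptSpan = 300L, gcContent = 0.40,
                          qualityValues = c(37L, 33L, 27L),
                          qualityProbs = c(0.8, 0.15, 0.05),
                          seed = 1L) {
  .assertProb(pLabel, "pLabel")
  .assertProb(errorRate, "errorRate")
  .assertProb(gcContent, "gcContent")
  if (is.null(names(nCells)) || !"pgc" %in% names(nCells))
    stop("config error: nCells must be named and include a 'pgc' type")
  if (nVegetalGenes > nMaternalGenes)
    stop("config error: nVegetalGenes must be <= nMaternalGenes")
  if (length(qualityValues) != length(qualityProbs))
    stop("config error: qualityValues/qualityProbs length mismatch")
  structure(list(nCells = nCells, nMaternalGenes = as.integer(nMaternalGenes),
                 nZygoticGenes = as.integer(nZygoticGenes),
                 nVegetalGenes = as.integer(nVegetalGenes),
                 muMaternal = muMaternal, muZygotic = muZygotic,
                 pgcVegetalFactor = pgcVegetalFactor,
                 pgcZygoticFactor = pgcZygoticFactor,
                 pLabel = pLabel, errorRate = errorRate,
                 readsPerUmi = as.integer(readsPerUmi),
                 readLength = as.integer(readLength),
                 transcriptSpan = as.integer(transcriptSpan),
                 gcContent = gcContent, qualityValues = qualityValues,
                 qualityProbs = qualityProbs / sum(qualityProbs),
                 seed = as.integer(seed)),
            class = "SlamSimConfig")
}

#' Simulate per-read mismatch evidence with known maternal/zygotic truth
#'
#' Each (cell, gene) pair draws a Poisson number of molecules; each molecule
#' draws its covered-U count from `Binomial(effectiveCoverage, uFraction)`.
#' Zygotic molecules convert each covered U to a T-to-C mismatch
#' independently with `pLabel`; maternal molecules never convert. On top,
#' every molecule accrues `Binomial(readsPerUmi * readLength, errorRate)`
#' sequencing errors spread uniformly over the 12 substitution types. Base
#' qualities of all mismatch rows are drawn from the configured discrete
#' distribution.
#'
#' @param config A [slamSimConfig()].
#' @return List with `mismatches` (\linkS4class{MismatchRecords}),
#'   `cellTypes` (named factor) and `truth` (DataFrame: cell, umi, gene,
#'   status in maternal/zygotic).
#' @export
simulateSlamReads <- function(config = slamSimConfig()) {
  stopifnot(inherits(config, "SlamSimConfig"))
  .withSeed(config$seed, {
    types <- rep(names(config$nCells), config$nCells)
    cells <- sprintf("%s_%03d", types, unlist(lapply(config$nCells, seq_len)))
    cellTypes <- stats::setNames(factor(types), cells)

    matGenes <- sprintf("matg%03d", seq_len(config$nMaternalGenes))
    zygGenes <- sprintf("zygg%03d", seq_len(config$nZygoticGenes))
    vegGenes <- matGenes[seq_len(config$nVegetalGenes)]
    genes <- c(matGenes, zygGenes)

    # expectation per (gene, cell type)
    mu <- matrix(0, length(genes), length(cells),
                 dimnames = list(genes, cells))
    mu[matGenes, ] <- config$muMaternal
    mu[zygGenes, ] <- config$muZygotic
    ispgc <- types == "pgc"
    if (length(vegGenes))
      mu[vegGenes, ispgc] <- config$muMaternal * config$pgcVegetalFactor
    mu[zygGenes, ispgc] <- config$muZygotic * config$pgcZygoticFactor

    nmol <- stats::rpois(length(mu), as.vector(mu))
    gi <- rep(rep(genes, length(cells)), nmol)
    ci <- rep(rep(cells, each = length(genes)), nmol)
    M <- length(gi)
    umi <- sprintf("UMI%07d", seq_len(M))
    status <- ifelse(gi %in% matGenes, "maternal", "zygotic")

    effCov <- min(config$readsPerUmi * config$readLength,
                  config$transcriptSpan)
    uFrac <- (1 - config$gcContent) / 2
    nU <- stats::rbinom(M, effCov, uFrac)
    conv <- integer(M)
    zy <- status == "zygotic"
    conv[zy] <- stats::rbinom(sum(zy), nU[zy], config$pLabel)
    totalBases <- config$readsPerUmi * config$readLength
    nErr <- stats::rbinom(M, totalBases, config$errorRate)

    idx <- c(rep(seq_len(M), conv), rep(seq_len(M), nErr))
    sub <- c(rep("T>C", sum(conv)),
             sample(.SUBS, sum(nErr), replace = TRUE))
    nRows <- length(idx)
    qual <- sample(config$qualityValues, nRows, replace = TRUE,
                   prob = config$qualityProbs)
    readNo <- sample.int(config$readsPerUmi, nRows, replace = TRUE)
    recs <- DataFrame(cell = ci[idx], umi = umi[idx], gene = gi[idx],
                      sub = sub, qual = as.integer(qual),
                      readId = sprintf("%s_r%d", umi[idx], readNo))
    mols <- DataFrame(cell = ci, umi = umi, gene = gi,
                      reads = rep(config$readsPerUmi, M),
                      coveredT = as.integer(nU))
    list(mismatches = MismatchRecords(recs, mols),
         cellTypes = cellTypes,
         truth = DataFrame(cell = ci, umi = umi, gene = gi, status = status))
  })
}
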