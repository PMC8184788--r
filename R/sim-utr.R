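#' Configuration for the 3'UTR sequence simulator
#'
#' Generates a positive (e.g. vegetally localized) and a background 3'UTR
#' set with a planted motif and a planted length difference. Defaults mirror
#' a 0.6 kb background mean and 1.7-fold longer positives; the planted motif
#' carries a CAC core.
#'
#' @param nPositive,nBackground Sequence numbers per group.
#' @param backgroundMeanLength Mean background length in nt.
#' @param lengthFold Positive mean length = `lengthFold` x background mean.
#' @param lengthCv Coefficient of variation of (gamma-distributed) lengths.
#' @param gcContent GC fraction of random sequence.
#' @param motif Planted motif string over ACGT.
#' @param plantProbPositive,plantProbBackground Per-sequence planting
#'   probabilities.
#' @param minLength Lower bound on sequence length (must be >= motif length).
#' @param seed Integer seed.
#' @return A list of class `UtrSimConfig`.
#' @export
utrSimConfig <- function(nPositive = 200, nBackground = 1000,
                         backgroundMeanLength = 600, lengthFold = 1.7,
                         lengthCv = 0.5, gcContent = 0.40,
                         motif = "CACCAC",
                         plantProbPositive = 0.6, plantProbBackground = 0.05,
                         minLength = 50, seed = 1L) {
  .assertProb(plantProbPositive, "plantProbPositive")
  .assertProb(plantProbBackground, "plantProbBackground")
  .assertProb(gcContent, "gcContent")
  if (nchar(motif) > minLength)
    stop("config error: motif longer than minimum sequence length")
  if (grepl("[^ACGT]", motif)) stop("config error: motif must be over ACGT")
  structure(list(nPositive = as.integer(nPositive),
                 nBackground = as.integer(nBackground),
                 backgroundMeanLength = backgroundMeanLength,
                 lengthFold = lengthFold, lengthCv = lengthCv,
                 gcContent = gcContent, motif = motif,
                 plantProbPositive = plantProbPositive,
                 plantProbBackground = plantProbBackground,
                 minLength = as.integer(minLength), seed = as.integer(seed)),
            class = "UtrSimConfig")
}

.randomSeqs <- function(n, lengths, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(lengths, function(L)
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""), "")
}

#' Simulate positive and background 3'UTR sets with a planted motif
#'
#' Sequence lengths are gamma-distributed around the configured group means
#' (floored at `minLength`); the motif is written verbatim at a uniform
#' random position of each flagged sequence, overwriting the random
#' background.
#'
#' @param config A [utrSimConfig()].
#' @return List with `positive` and `background`
#'   ([Biostrings::DNAStringSet]), and `truth` (list: motif, plantedPositive,
#'   plantedBackground logical flags).
#' @export
simulateUtrs <- function(config = utrSimConfig()) {
  stopifnot(inherits(config, "UtrSimConfig"))
  .withSeed(config$seed, {
    shape <- 1 / config$lengthCv^2
    drawLen <- function(n, mean)
      pmax(config$minLength,
           round(stats::rgamma(n, shape = shape, rate = shape / mean)))
    lp <- drawLen(config$nPositive,
                  config$lengthFold * config$backgroundMeanLength)
    lb <- drawLen(config$nBackground, config$backgroundMeanLength)
    pos <- .randomSeqs(config$nPositive, lp, config$gcContent)
    bg <- .randomSeqs(config$nBackground, lb, config$gcContent)
    plant <- function(seqs, flags, motif) {
      k <- nchar(motif)
      for (i in which(flags)) {
        L <- nchar(seqs[i])
        at <- sample.int(L - k + 1, 1)
        substr(seqs[i], at, at + k - 1) <- motif
      }
      seqs
    }
    fp <- stats::runif(config$nPositive) < config$plantProbPositive
    fb <- stats::runif(config$nBackground) < config$plantProbBackground
    pos <- plant(pos, fp, config$motif)
    bg <- plant(bg, fb, config$motif)
    positive <- Biostrings::DNAStringSet(pos)
    names(positive) <- sprintf("pos%04d", seq_along(pos))
    background <- Biostrings::DNAStringSet(bg)
    names(background) <- sprintf("bg%04d", seq_along(bg))
    list(positive = positive, background = background,
         truth = list(motif = config$motif, plantedPositive = fp,
                      plantedBackground = fb))
  })
}

#' Simulate an isoform expression table
#'
#' Per-gene isoforms with configured FPKM shares and UTR/CDS lengths; used to
#' exercise expression-weighted length statistics.
#'
#' @param nGenes Number of genes.
#' @param maxIsoforms Isoforms per gene drawn uniformly from
#'   `1:maxIsoforms`.
#' @param meanFpkm Mean per-isoform FPKM (exponential).
#' @param meanUtr,meanCds Mean lengths in nt (gamma, CV 0.5).
#' @param seed Integer seed.
#' @return DataFrame in the isoform-table layout of [readIsoformTable()].
#' @export
simulateIsoformTable <- function(nGenes = 100, maxIsoforms = 4,
                                 meanFpkm = 20, meanUtr = 600,
                                 meanCds = 2400, seed = 1L) {
  .withSeed(seed, {
    niso <- sample.int(maxIsoforms, nGenes, replace = TRUE)
    gene <- rep(sprintf("gene%04d", seq_len(nGenes)), niso)
    n <- length(gene)
    DataFrame(isoform_id = sprintf("iso%05d", seq_len(n)),
              gene_id = gene,
              fpkm = stats::rexp(n, 1 / meanFpkm),
              utr3_length = round(stats::rgamma(n, 4, 4 / meanUtr)),
              cds_length = round(stats::rgamma(n, 4, 4 / meanCds)))
  })
}
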