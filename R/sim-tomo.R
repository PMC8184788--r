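#' Configuration for the serial-section (tomo-seq) simulator
#'
#' Defines the study conditions the simulator emulates: a 96-section
#' one-cell-stage embryo with three spatial gene classes (animal, uniform,
#' vegetal), an animal-skewed per-section library size (most mRNA sits in the
#' blastodisc at the animal pole), constant-expectation spike-ins, and
#' overdispersed (negative binomial) count noise.
#'
#' @param nSections Number of sections along the animal-vegetal axis.
#' @param nGenes Named integer vector with classes `animal`, `uniform`,
#'   `vegetal`.
#' @param vegetalWindow Number of terminal (vegetal-most) sections carrying
#'   the vegetal class (default 3).
#' @param animalWindow Number of leading sections carrying the animal class.
#' @param insideMass Fraction of a localized gene's spatial mass inside its
#'   window (default 0.95; the remainder is spread uniformly elsewhere).
#' @param depthMeanLog,depthSdLog Log-normal parameters of per-gene total
#'   expected counts.
#' @param libraryskewAmplitude,libraryskewScale Per-section library-size
#'   factor `floor + amplitude * exp(-(s-1)/scale)`, the animal-skewed
#'   profile; the floor is 0.8.
#' @param spikeinMean Expected spike-in count per section (constant across
#'   sections).
#' @param dispersion Negative-binomial dispersion (variance = mu + dispersion
#'   * mu^2); 0 gives Poisson counts.
#' @param nReplicates Number of replicates sharing gene classes and depths
#'   but with independent noise.
#' @param seed Integer seed; the simulation is fully deterministic given it.
#' @return A list of class `TomoSimConfig`.
#' @export
tomoSimConfig <- function(nSections = 96,
                          nGenes = c(animal = 200, uniform = 1600, vegetal = 200),
                          vegetalWindow = 3, animalWindow = 8,
                          insideMass = 0.95,
                          depthMeanLog = log(800), depthSdLog = 0.7,
                          libraryskewAmplitude = 5, libraryskewScale = 8,
                          spikeinMean = 20000, dispersion = 0.2,
                          nReplicates = 3, seed = 1L) {
  .assertCount(nSections, "nSections")
  if (vegetalWindow >= nSections || animalWindow >= nSections)
    stop("config error: localization window larger than nSections")
  .assertProb(insideMass, "insideMass")
  if (spikeinMean <= 0) stop("config error: spikeinMean must be > 0")
  if (dispersion < 0) stop("config error: dispersion must be >= 0")
  nGenes <- nGenes[c("animal", "uniform", "vegetal")]
  nGenes[is.na(nGenes)] <- 0
  names(nGenes) <- c("animal", "uniform", "vegetal")
  structure(list(nSections = as.integer(nSections), nGenes = nGenes,
                 vegetalWindow = as.integer(vegetalWindow),
                 animalWindow = as.integer(animalWindow),
                 insideMass = insideMass, depthMeanLog = depthMeanLog,
                 depthSdLog = depthSdLog,
                 libraryskewAmplitude = libraryskewAmplitude,
                 libraryskewScale = libraryskewScale,
                 spikeinMean = spikeinMean, dispersion = dispersion,
                 nReplicates = as.integer(nReplicates), seed = as.integer(seed)),
            class = "TomoSimConfig")
}

# Per-section library-size factor (animal-skewed).
.sectionSizeFactor <- function(config) {
  s <- seq_len(config$nSections)
  0.8 + config$libraryskewAmplitude * exp(-(s - 1) / config$libraryskewScale)
}

# Spatial concentration profile (sums to 1 over sections) per class.
.classLambda <- function(config) {
  S <- config$nSections
  lam <- list()
  aw <- seq_len(config$animalWindow)
  lam$animal <- rep((1 - config$insideMass) / (S - length(aw)), S)
  # decaying profile inside the animal window
  w <- exp(-(aw - 1) / max(1, config$animalWindow / 3))
  lam$animal[aw] <- config$insideMass * w / sum(w)
  lam$uniform <- rep(1 / S, S)
  vw <- (S - config$vegetalWindow + 1):S
  lam$vegetal <- rep((1 - config$insideMass) / (S - length(vw)), S)
  lam$vegetal[vw] <- config$insideMass / length(vw)
  lam
}

#' Expected per-section count share of each simulated gene class
#'
#' Returns the expected fraction of a gene's total counts falling in each
#' section, i.e. the spatial profile combined with the per-section library
#' factor and renormalized. This is the mixture weight the simulator draws
#' counts from, exposed so tests and users can derive expectations (e.g. the
#' expected mass of a vegetal gene outside its terminal window) without
#' re-implementing the generator.
#'
#' @param config A [tomoSimConfig()].
#' @return Matrix with rows `animal`, `uniform`, `vegetal` and one column per
#'   section; rows sum to 1.
#' @export
expectedSectionProfile <- function(config) {
  f <- .sectionSizeFactor(config)
  lam <- .classLambda(config)
  w <- rbind(animal = lam$animal * f, uniform = lam$uniform * f,
             vegetal = lam$vegetal * f)
  sweep(w, 1, rowSums(w), "/")
}

#' Simulate serial-section count matrices with known localization truth
#'
#' Draws per-replicate gene x section count matrices from the configured
#' spatial classes. Gene classes and per-gene depths are shared across
#' replicates; counts are independent negative-binomial (or Poisson) noise.
#' Spike-in counts are Poisson with constant expectation per section.
#'
#' @param config A [tomoSimConfig()].
#' @return List with `replicates` (list of \linkS4class{SectionCounts}) and
#'   `truth` (named character vector gene -> class).
#' @export
#' @examples
#' sim <- simulateTomoseq(tomoSimConfig(nSections = 24,
#'   nGenes = c(animal = 10, uniform = 40, vegetal = 10), nReplicates = 2))
#' table(sim$truth)
simulateTomoseq <- function(config = tomoSimConfig()) {
  stopifnot(inherits(config, "TomoSimConfig"))
  .withSeed(config$seed, {
    n <- config$nGenes
    classes <- rep(names(n), n)
    ids <- sprintf("gene%04d", seq_along(classes))
    truth <- stats::setNames(classes, ids)
    depth <- stats::rlnorm(length(ids), config$depthMeanLog, config$depthSdLog)
    W <- expectedSectionProfile(config)
    mu <- depth * W[classes, , drop = FALSE]   # genes x sections expectation
    reps <- vector("list", config$nReplicates)
    for (r in seq_len(config$nReplicates)) {
      if (config$dispersion > 0)
        cts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                     size = 1 / config$dispersion),
                      nrow = nrow(mu))
      else
        cts <- matrix(stats::rpois(length(mu), as.vector(mu)), nrow = nrow(mu))
      dimnames(cts) <- list(ids, NULL)
      sp <- stats::rpois(config$nSections, config$spikeinMean)
      reps[[r]] <- SectionCounts(cts, spikeinCounts = sp,
                                 replicate = paste0("rep", r))
    }
    names(reps) <- paste0("rep", seq_len(config$nReplicates))
    list(replicates = reps, truth = truth)
  })
}
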