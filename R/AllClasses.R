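#' @include AllGenerics.R
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assay<- assayNames rowData rowData<- colData colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

## The 12 ordered nucleotide substitutions (ref > alt, ref != alt).
.SUBS <- c("A>C", "A>G", "A>T",
           "C>A", "C>G", "C>T",
           "G>A", "G>C", "G>T",
           "T>A", "T>C", "T>G")

#' The twelve nucleotide substitution types
#'
#' Ordered reference-to-alternative pairs over A, C, G, T with ref != alt, in
#' the fixed order used by mutation spectra and mismatch tables.
#'
#' @return Character vector of length 12, e.g. `"T>C"`.
#' @export
#' @examples
#' substitutionTypes()
substitutionTypes <- function() .SUBS

# ---------------------------------------------------------------------------
# SectionCounts
# ---------------------------------------------------------------------------

#' SectionCounts: gene x section counts of a serial-section experiment
#'
#' Raw transcript counts of one tomo-seq replicate: genes in rows, ordered
#' sections (1 = animal pole, last = vegetal pole) in columns, plus summed
#' ERCC spike-in counts per section. Extends
#' \linkS4class{SummarizedExperiment}; the `"counts"` assay holds endogenous
#' gene counts, `colData` holds `section` (original index) and `spikein`.
#'
#' @slot .. inherited from SummarizedExperiment.
#' @export
setClass("SectionCounts", contains = "SummarizedExperiment")

.validSectionCounts <- function(object) {
  msg <- NULL
  cts <- assay(object, "counts")
  if (any(cts < 0)) msg <- c(msg, "counts must be >= 0")
  if (any(abs(cts - round(cts)) > 1e-8)) msg <- c(msg, "counts must be integer")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  sec <- colData(object)$section
  if (is.null(sec) || is.null(colData(object)$spikein))
    msg <- c(msg, "colData must contain 'section' and 'spikein'")
  else {
    if (any(diff(sec) <= 0)) msg <- c(msg, "section index must be strictly increasing")
    if (any(colData(object)$spikein < 0)) msg <- c(msg, "spike-in counts must be >= 0")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("SectionCounts", .validSectionCounts)

#' Construct a SectionCounts object
#'
#' @param counts Non-negative integer matrix, genes x sections, with unique
#'   rownames (gene ids).
#' @param spikeinCounts Non-negative numeric vector of summed spike-in counts,
#'   one per section.
#' @param sectionIndex Ordered original section indices (default `1:ncol`).
#' @param replicate,species Optional labels stored in `metadata()`.
#' @param thicknessUm Optional section thickness in micrometres.
#' @return A \linkS4class{SectionCounts}.
#' @export
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4, dimnames = list(paste0("g", 1:3), NULL))
#' sc <- SectionCounts(m, spikeinCounts = rep(100, 4))
#' sectionIndex(sc)
SectionCounts <- function(counts, spikeinCounts,
                          sectionIndex = seq_len(ncol(counts)),
                          replicate = NA_character_, species = NA_character_,
                          thicknessUm = NA_real_) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    stop("counts must have rownames (gene ids)")
  if (length(spikeinCounts) != ncol(counts))
    stop("spikeinCounts must have one entry per section")
  colnames(counts) <- paste0("section_", as.integer(sectionIndex))
  cd <- DataFrame(section = as.integer(sectionIndex),
                  spikein = as.numeric(spikeinCounts))
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  metadata(se) <- list(replicate = replicate, species = species,
                       thicknessUm = thicknessUm)
  new("SectionCounts", se)
}

#' @rdname sectionIndex
#' @export
setMethod("sectionIndex", "SectionCounts",
          function(x) colData(x)$section)

#' @rdname spikeinCounts
#' @export
setMethod("spikeinCounts", "SectionCounts",
          function(x) colData(x)$spikein)

#' @rdname geneIds
#' @export
setMethod("geneIds", "SectionCounts", function(x) rownames(x))

#' @describeIn SectionCounts raw endogenous counts matrix.
#' @param object A SectionCounts.
#' @export
setMethod("counts", "SectionCounts",
          function(object) assay(object, "counts"))

setMethod("show", "SectionCounts", function(object) {
  cat("SectionCounts:", nrow(object), "genes x", ncol(object), "sections\n")
  cat("  sections:", paste(range(sectionIndex(object)), collapse = ".."),
      "| spike-in median:", stats::median(spikeinCounts(object)), "\n")
  md <- metadata(object)
  cat("  replicate:", md$replicate, "| species:", md$species, "\n")
})

# ---------------------------------------------------------------------------
# TraceSet
# ---------------------------------------------------------------------------

#' TraceSet: normalized and cumulative spatial expression traces
#'
#' Per-gene expression traces over retained sections. The `"normalized"`
#' assay holds counts divided by section totals and rescaled to the median
#' section size; the `"cumulative"` assay (added by [cumulativeTraces()])
#' holds the running animal-to-vegetal sum of each row scaled to end at 1.
#' `rowData()$nonzero` flags genes with a nonzero total; all-zero genes carry
#' an all-zero cumulative row and are excluded from SOM training.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

.validTraceSet <- function(object) {
  msg <- NULL
  nm <- assay(object, "normalized")
  if (any(nm < 0)) msg <- c(msg, "normalized values must be >= 0")
  if ("cumulative" %in% assayNames(object)) {
    cm <- assay(object, "cumulative")
    if (ncol(cm) > 1 && any(cm[, -1, drop = FALSE] - cm[, -ncol(cm), drop = FALSE] < -1e-8))
      msg <- c(msg, "cumulative rows must be non-decreasing")
    nz <- rowData(object)$nonzero
    if (!is.null(nz) && any(nz) && any(abs(cm[nz, ncol(cm)] - 1) > 1e-8))
      msg <- c(msg, "nonzero cumulative rows must end at 1")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("TraceSet", .validTraceSet)

#' @rdname sectionIndex
#' @export
setMethod("sectionIndex", "TraceSet", function(x) colData(x)$section)

#' @rdname geneIds
#' @export
setMethod("geneIds", "TraceSet", function(x) rownames(x))

#' @rdname traceMatrix
#' @export
setMethod("traceMatrix", "TraceSet", function(x, type = c("cumulative", "normalized")) {
  type <- match.arg(type)
  if (!type %in% assayNames(x))
    stop("assay '", type, "' not present; run cumulativeTraces() first?")
  assay(x, type)
})

setMethod("show", "TraceSet", function(object) {
  cat("TraceSet:", nrow(object), "genes x", ncol(object), "retained sections\n")
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SomModel
# ---------------------------------------------------------------------------

#' SomModel: 1 x n linear self-organizing map over cumulative traces
#'
#' Prototype vectors of a one-dimensional Kohonen map trained on cumulative
#' spatial traces. Each prototype row is itself a valid cumulative trace
#' (non-decreasing, ending at 1). After [orderNodes()] node indices run
#' animal (1) to vegetal (n), i.e. prototype centroids are non-decreasing.
#'
#' @slot prototypes numeric matrix, nodes x sections.
#' @slot nNodes integer number of map nodes.
#' @slot ordered logical; TRUE after [orderNodes()].
#' @slot meta list of training metadata (epochs, learning-rate and
#'   neighborhood schedules, seed).
#' @export
setClass("SomModel",
         representation(prototypes = "matrix", nNodes = "integer",
                        ordered = "logical", meta = "list"))

.validSomModel <- function(object) {
  msg <- NULL
  P <- object@prototypes
  if (nrow(P) != object@nNodes) msg <- c(msg, "prototype rows != nNodes")
  if (ncol(P) > 1 &&
      any(P[, -1, drop = FALSE] - P[, -ncol(P), drop = FALSE] < -1e-6))
    msg <- c(msg, "prototype rows must be non-decreasing")
  if (any(abs(P[, ncol(P)] - 1) > 1e-6))
    msg <- c(msg, "prototype rows must end at 1")
  if (object@ordered) {
    cen <- .traceCentroids(P)
    if (any(diff(cen) < -1e-8))
      msg <- c(msg, "ordered model must have non-decreasing node centroids")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("SomModel", .validSomModel)

#' @rdname prototypes
#' @export
setMethod("prototypes", "SomModel", function(x) x@prototypes)

setMethod("show", "SomModel", function(object) {
  cat("SomModel: 1 x", object@nNodes, "map over", ncol(object@prototypes),
      "sections;", if (object@ordered) "ordered" else "unordered", "\n")
  cat("  epochs:", object@meta$epochs, "| seed:", object@meta$seed, "\n")
})

# ---------------------------------------------------------------------------
# MismatchRecords
# ---------------------------------------------------------------------------

#' MismatchRecords: per-read alignment mismatch evidence
#'
#' Read-level substitution evidence of a metabolic-labeling experiment,
#' grouped by molecule. `records()` returns one row per mismatch event
#' (`cell`, `umi`, `gene`, `sub`, `qual`, `readId`); `molecules()` returns
#' one row per (cell, umi, gene) molecule with its read count (`reads`) and
#' number of covered T positions (`coveredT`; `NA` when unknown). Molecules
#' without any mismatch appear in `molecules()` only.
#'
#' @slot records DataFrame of mismatch events.
#' @slot molecules DataFrame of molecules.
#' @export
setClass("MismatchRecords",
         representation(records = "DataFrame", molecules = "DataFrame"))

.validMismatchRecords <- function(object) {
  msg <- NULL
  r <- object@records
  m <- object@molecules
  need <- c("cell", "umi", "gene", "sub", "qual", "readId")
  if (!all(need %in% colnames(r))) msg <- c(msg, "records missing columns")
  else {
    bad <- setdiff(unique(r$sub), .SUBS)
    if (length(bad))
      msg <- c(msg, paste0("invalid substitution code(s): ",
                           paste(bad, collapse = ", ")))
    if (any(r$qual < 0, na.rm = TRUE)) msg <- c(msg, "base quality must be >= 0")
  }
  needm <- c("cell", "umi", "gene", "reads")
  if (!all(needm %in% colnames(m))) msg <- c(msg, "molecules missing columns")
  else {
    key <- paste(m$cell, m$umi, m$gene, sep = "\r")
    if (anyDuplicated(key)) msg <- c(msg, "duplicate (cell, umi, gene) molecules")
    if (nrow(r)) {
      rkey <- paste(r$cell, r$umi, r$gene, sep = "\r")
      if (!all(rkey %in% key))
        msg <- c(msg, "records refer to molecules absent from the molecule table")
    }
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("MismatchRecords", .validMismatchRecords)

#' Construct a MismatchRecords object
#'
#' @param records data.frame/DataFrame of mismatch events with columns
#'   `cell`, `umi`, `gene`, `sub` (one of [substitutionTypes()]), `qual`
#'   (phred integer), `readId`.
#' @param molecules data.frame/DataFrame with one row per (cell, umi, gene)
#'   and columns `reads` and optionally `coveredT`. If missing it is derived
#'   from `records` (reads = number of distinct read ids, coveredT = NA).
#' @return A \linkS4class{MismatchRecords}.
#' @export
MismatchRecords <- function(records, molecules = NULL) {
  records <- as(records, "DataFrame")
  if (is.null(molecules)) {
    key <- paste(records$cell, records$umi, records$gene, sep = "\r")
    sp <- !duplicated(key)
    nreads <- vapply(split(records$readId, key), function(z) length(unique(z)), 0L)
    molecules <- DataFrame(cell = records$cell[sp], umi = records$umi[sp],
                           gene = records$gene[sp],
                           reads = as.integer(nreads[paste(records$cell, records$umi,
                                                           records$gene, sep = "\r")[sp]]),
                           coveredT = NA_integer_)
  }
  molecules <- as(molecules, "DataFrame")
  if (!"coveredT" %in% colnames(molecules)) molecules$coveredT <- NA_integer_
  new("MismatchRecords", records = records, molecules = molecules)
}

#' @rdname records
#' @export
setMethod("records", "MismatchRecords", function(x) x@records)

#' @rdname molecules
#' @export
setMethod("molecules", "MismatchRecords", function(x) x@molecules)

setMethod("show", "MismatchRecords", function(object) {
  cat("MismatchRecords:", nrow(object@molecules), "molecules,",
      nrow(object@records), "mismatch events\n")
  cat("  cells:", length(unique(object@molecules$cell)),
      "| genes:", length(unique(object@molecules$gene)), "\n")
})

# ---------------------------------------------------------------------------
# GmmFit
# ---------------------------------------------------------------------------

#' GmmFit: univariate Gaussian mixture fit
#'
#' Result of expectation-maximization on a univariate sample. Components are
#' reported in increasing-mean order; `responsibilities` rows (one per data
#' point) sum to 1.
#'
#' @slot weights,means,sds numeric vectors of length k (weights sum to 1,
#'   sds > 0).
#' @slot responsibilities numeric matrix, n x k.
#' @slot logLik final log-likelihood.
#' @slot logLikTrace per-iteration log-likelihood (non-decreasing).
#' @slot converged logical.
#' @slot iterations integer.
#' @slot seed integer seed used for restarts.
#' @export
setClass("GmmFit",
         representation(weights = "numeric", means = "numeric", sds = "numeric",
                        responsibilities = "matrix", logLik = "numeric",
                        logLikTrace = "numeric", converged = "logical",
                        iterations = "integer", seed = "integer"))

.validGmmFit <- function(object) {
  msg <- NULL
  if (abs(sum(object@weights) - 1) > 1e-6) msg <- c(msg, "weights must sum to 1")
  if (any(object@weights <= 0) || any(object@weights >= 1 + 1e-9))
    msg <- c(msg, "weights must lie in (0, 1)")
  if (any(object@sds <= 0)) msg <- c(msg, "sds must be > 0")
  if (length(object@means) > 1 && any(diff(object@means) < 0))
    msg <- c(msg, "components must be ordered by increasing mean")
  if (nrow(object@responsibilities) &&
      any(abs(rowSums(object@responsibilities) - 1) > 1e-6))
    msg <- c(msg, "responsibility rows must sum to 1")
  if (is.null(msg)) TRUE else msg
}
setValidity("GmmFit", .validGmmFit)

setMethod("show", "GmmFit", function(object) {
  cat("GmmFit:", length(object@means), "components on",
      nrow(object@responsibilities), "values\n")
  cat(sprintf("  means: %s | sds: %s | weights: %s\n",
              paste(round(object@means, 3), collapse = ", "),
              paste(round(object@sds, 3), collapse = ", "),
              paste(round(object@weights, 3), collapse = ", ")))
  cat("  logLik:", object@logLik, "| converged:", object@converged,
      "in", object@iterations, "iterations\n")
})
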