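#' Section quality control by spike-in recovery
#'
#' Drops sections whose spike-in count falls below a threshold, the standard
#' failure mode of serial-section libraries. The threshold is either an
#' absolute transcript count (`minSpikein >= 1`, e.g. 8000) or a fraction of
#' the library's total mapped counts (`minSpikein < 1`, e.g. 0.0004 for
#' ~0.04 percent), where the library total includes endogenous and spike-in
#' counts. Sections with spike-in count >= threshold are kept; original
#' section indices are retained.
#'
#' @param x A \linkS4class{SectionCounts}.
#' @param minSpikein Absolute count or fraction-of-library threshold.
#' @return A list with `counts` (filtered \linkS4class{SectionCounts}) and
#'   `report` (data.frame: section, spikein, threshold, kept).
#' @export
#' @examples
#' m <- matrix(5, 2, 3, dimnames = list(c("g1", "g2"), NULL))
#' sc <- SectionCounts(m, spikeinCounts = c(9000, 7000, 8500))
#' qcSections(sc, minSpikein = 8000)$report
qcSections <- function(x, minSpikein = 8000) {
  sp <- spikeinCounts(x)
  thr <- if (minSpikein < 1) {
    minSpikein * (sum(counts(x)) + sum(sp))
  } else minSpikein
  keep <- sp >= thr
  if (!any(keep))
    stop("all sections dropped by spike-in QC (threshold ", thr, ")")
  report <- data.frame(section = sectionIndex(x), spikein = sp,
                       threshold = thr, kept = keep)
  out <- x[, keep]
  md <- metadata(out)
  md$qcSections <- report
  metadata(out) <- md
  list(counts = out, report = report)
}

#' Filter lowly expressed genes
#'
#' Keeps a gene iff its raw count reaches `minCount` in at least one
#' section, removing genes too shallow to carry a spatial profile.
#'
#' @param x A \linkS4class{SectionCounts} (after section QC).
#' @param minCount Minimum per-section count a gene must reach somewhere
#'   (default 5).
#' @return A list with `counts` (filtered \linkS4class{SectionCounts}) and
#'   `report` (data.frame: gene_id, max_count, kept).
#' @export
filterGenes <- function(x, minCount = 5) {
  mx <- apply(counts(x), 1, max)
  keep <- mx >= minCount
  report <- data.frame(gene_id = geneIds(x), max_count = mx,
                       min_count = minCount, kept = keep)
  out <- x[keep, ]
  md <- metadata(out)
  md$geneFilter <- report
  metadata(out) <- md
  list(counts = out, report = report)
}

#' Normalize counts by section totals
#'
#' Divides each gene's counts by the total endogenous counts of its section
#' and rescales to the median section total, so that every normalized
#' section sums to the same (median) size. Spike-in counts are excluded from
#' the totals by default, normalizing on endogenous genes only.
#'
#' @param x A \linkS4class{SectionCounts} after QC and gene filtering.
#' @param includeSpikeins If TRUE, spike-in counts are added to section
#'   totals before dividing.
#' @return A \linkS4class{TraceSet} with the `"normalized"` assay.
#' @export
normalizeSections <- function(x, includeSpikeins = FALSE) {
  cts <- counts(x)
  tot <- colSums(cts)
  if (includeSpikeins) tot <- tot + spikeinCounts(x)
  if (any(tot == 0))
    stop("retained section with zero total counts; run qcSections first")
  med <- stats::median(tot)
  nm <- sweep(cts, 2, tot, "/") * med
  se <- SummarizedExperiment(assays = list(normalized = nm),
                             colData = DataFrame(section = sectionIndex(x)))
  metadata(se) <- c(metadata(x),
                    list(medianSectionTotal = med,
                         includeSpikeins = includeSpikeins))
  new("TraceSet", se)
}

#' Cumulative animal-to-vegetal traces
#'
#' Adds the `"cumulative"` assay: the running sum of each gene's normalized
#' expression from low to high section numbers, scaled so the maximum (last
#' value) is 1. Genes with zero total are flagged in `rowData()$nonzero =
#' FALSE`, carry an all-zero row and are excluded from SOM training.
#'
#' @param x A \linkS4class{TraceSet} with the normalized assay.
#' @return The \linkS4class{TraceSet} with the cumulative assay added.
#' @export
cumulativeTraces <- function(x) {
  nm <- traceMatrix(x, "normalized")
  cum <- t(apply(nm, 1, cumsum))
  if (ncol(nm) == 1) cum <- matrix(nm, ncol = 1, dimnames = dimnames(nm))
  tot <- cum[, ncol(cum)]
  nonzero <- tot > 0
  cum[nonzero, ] <- cum[nonzero, , drop = FALSE] / tot[nonzero]
  cum[!nonzero, ] <- 0
  assay(x, "cumulative") <- cum
  rowData(x)$nonzero <- nonzero
  validObject(x)
  x
}

#' Per-gene z-scores of normalized expression
#'
#' Standardizes each gene row to mean 0 and population (ddof = 0) standard
#' deviation 1, the scaling used for profile heatmaps. Constant rows map to
#' all-zeros rather than NaN.
#'
#' @param x A \linkS4class{TraceSet} or numeric matrix.
#' @return Numeric matrix of the same shape.
#' @export
zscoreByGene <- function(x) {
  m <- if (is(x, "TraceSet")) traceMatrix(x, "normalized") else as.matrix(x)
  mu <- rowMeans(m)
  ctr <- m - mu
  sdv <- sqrt(rowMeans(ctr^2))
  out <- ctr / ifelse(sdv > 0, sdv, 1)
  out[sdv == 0, ] <- 0
  out
}

#' Correlation of two replicates on per-gene totals
#'
#' Pearson correlation of log1p-transformed per-gene total counts (summed
#' over all sections) over the intersection of gene ids, the standard
#' replicate-concordance diagnostic.
#'
#' @param x,y \linkS4class{SectionCounts} objects.
#' @return Pearson correlation coefficient.
#' @export
correlateReplicates <- function(x, y) {
  shared <- intersect(geneIds(x), geneIds(y))
  if (length(shared) < 3)
    stop("fewer than 3 shared genes between replicates")
  tx <- rowSums(counts(x)[shared, , drop = FALSE])
  ty <- rowSums(counts(y)[shared, , drop = FALSE])
  stats::cor(log1p(tx), log1p(ty))
}
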