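#' Aggregate mismatch evidence per molecule (UMI)
#'
#' Collapses read-level mismatch rows to one record per (cell, umi, gene)
#' molecule. T-to-C mismatches are counted under the base-quality filter
#' (`tcCountQ`: quality strictly greater than `minQual`); all 12
#' substitution types are additionally tallied unfiltered for mutation
#' spectra.
#'
#' @param x A \linkS4class{MismatchRecords}.
#' @param minQual Quality threshold; only T>C calls with quality > `minQual`
#'   count toward `tcCountQ` (default 20).
#' @return DataFrame with one row per molecule: `cell`, `umi`, `gene`,
#'   `reads`, `coveredT`, `tcCountQ`, and a `subCounts` integer matrix
#'   column (unfiltered counts for each of [substitutionTypes()]).
#' @export
aggregateUmis <- function(x, minQual = 20) {
  mol <- molecules(x)
  rec <- records(x)
  key <- paste(mol$cell, mol$umi, mol$gene, sep = "\r")
  subCounts <- matrix(0L, nrow(mol), length(.SUBS),
                      dimnames = list(NULL, .SUBS))
  tcq <- integer(nrow(mol))
  if (nrow(rec)) {
    rkey <- paste(rec$cell, rec$umi, rec$gene, sep = "\r")
    idx <- match(rkey, key)
    for (s in .SUBS) {
      tab <- tabulate(idx[rec$sub == s], nbins = nrow(mol))
      subCounts[, s] <- tab
    }
    pass <- rec$sub == "T>C" & rec$qual > minQual
    tcq <- tabulate(idx[pass], nbins = nrow(mol))
  }
  out <- DataFrame(cell = mol$cell, umi = mol$umi, gene = mol$gene,
                   reads = mol$reads, coveredT = mol$coveredT,
                   tcCountQ = as.integer(tcq))
  out$subCounts <- subCounts
  metadata(out) <- list(minQual = minQual)
  out
}

#' Classify molecules as labeled (zygotic) or unlabeled (maternal)
#'
#' A molecule is labeled iff it carries at least `minTc` quality-passing
#' T-to-C mismatches. The default `minTc = 1` corresponds to the
#' zero-conversion false-negative model: a zygotic molecule is missed
#' exactly when none of its covered Us was converted.
#'
#' @param x DataFrame from [aggregateUmis()].
#' @param minTc Minimum quality-passing T>C count for a labeled call
#'   (default 1).
#' @return The input with a `label` factor column (labeled / unlabeled).
#' @export
classifyUmis <- function(x, minTc = 1) {
  x$label <- factor(ifelse(x$tcCountQ >= minTc, "labeled", "unlabeled"),
                    levels = c("labeled", "unlabeled"))
  metadata(x)$minTc <- minTc
  x
}

#' Split classified molecules into labeled and unlabeled count matrices
#'
#' Tabulates molecules into two sparse gene x cell count matrices. Every
#' molecule contributes exactly one count to exactly one matrix, so
#' labeled + unlabeled equals the total UMI count per (gene, cell).
#'
#' @param x Classified DataFrame from [classifyUmis()].
#' @param cellTypes Optional named factor of cell types, stored in
#'   `colData()`.
#' @return A [SingleCellExperiment::SingleCellExperiment] with sparse assays
#'   `"labeled"` and `"unlabeled"` (genes x cells).
#' @export
splitMatrices <- function(x, cellTypes = NULL) {
  if (is.null(x$label)) stop("run classifyUmis() first")
  key <- paste(x$cell, x$umi, x$gene, sep = "\r")
  if (anyDuplicated(key))
    stop("internal error: duplicate (cell, umi, gene) after aggregation")
  cells <- sort(unique(x$cell))
  genes <- sort(unique(x$gene))
  ci <- match(x$cell, cells)
  gi <- match(x$gene, genes)
  mk <- function(sel) {
    Matrix::sparseMatrix(i = gi[sel], j = ci[sel],
                         x = rep(1, sum(sel)),
                         dims = c(length(genes), length(cells)),
                         dimnames = list(genes, cells))
  }
  lab <- mk(x$label == "labeled")
  unl <- mk(x$label == "unlabeled")
  cd <- DataFrame(row.names = cells)
  if (!is.null(cellTypes)) cd$cellType <- factor(cellTypes[cells])
  SingleCellExperiment::SingleCellExperiment(
    assays = list(labeled = lab, unlabeled = unl), colData = cd)
}

#' Mutation spectrum of a mismatch table
#'
#' Frequency of each of the 12 substitution types, computed on
#' quality-passing mismatches and normalized by the total number of
#' sequenced bases (reads x read length, the denominator convention recorded
#' in the output).
#'
#' @param x A \linkS4class{MismatchRecords}.
#' @param readLength Read length in nt used for the denominator.
#' @param minQual Mismatches with quality > `minQual` are counted
#'   (default 20; use -1 for no filter).
#' @return data.frame with `sub`, `count`, `frequency`; total bases in
#'   `attr(, "totalBases")`.
#' @export
mutationSpectrum <- function(x, readLength = 99, minQual = 20) {
  rec <- records(x)
  rec <- rec[rec$qual > minQual, , drop = FALSE]
  cnt <- table(factor(rec$sub, levels = .SUBS))
  totalBases <- sum(molecules(x)$reads) * readLength
  out <- data.frame(sub = .SUBS, count = as.integer(cnt),
                    frequency = as.numeric(cnt) / totalBases)
  attr(out, "totalBases") <- totalBases
  attr(out, "denominator") <- "reads x readLength (total sequenced bases)"
  out
}

#' Compare T-to-C rates between a labeled and a control sample
#'
#' @param labeled,control \linkS4class{MismatchRecords} of the two samples.
#' @param ... Passed to [mutationSpectrum()].
#' @return data.frame of both spectra with the per-substitution frequency
#'   ratio; the T>C row is the diagnostic of successful labeling.
#' @export
compareSpectra <- function(labeled, control, ...) {
  a <- mutationSpectrum(labeled, ...)
  b <- mutationSpectrum(control, ...)
  data.frame(sub = a$sub, freq_labeled = a$frequency,
             freq_control = b$frequency,
             ratio = a$frequency / ifelse(b$frequency > 0, b$frequency, NA))
}

# Sarle's bimodality coefficient (finite-sample version).
.bimodalityCoefficient <- function(v) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < 4) return(NA_real_)
  m <- mean(v); s <- stats::sd(v)
  if (s == 0) return(NA_real_)
  g1 <- sum((v - m)^3) / n / (sum((v - m)^2) / n)^1.5
  g2 <- sum((v - m)^4) / n / (sum((v - m)^2) / n)^2 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Histogram of T-to-C mutation counts
#'
#' Distribution of quality-passing T-to-C counts per molecule and, per gene,
#' the mean T-to-C frequency (conversions per covered T). A bimodality
#' coefficient (> ~0.555 suggests bimodality) is reported on the per-gene
#' frequencies; mixed maternal + zygotic samples are expected to be bimodal
#' with one mode near zero.
#'
#' @param x DataFrame from [aggregateUmis()].
#' @return List with `perUmi` (data.frame tc count -> molecules), `perGene`
#'   (data.frame gene, mean frequency), and `bimodality`.
#' @export
tcHistogram <- function(x) {
  tab <- table(x$tcCountQ)
  perUmi <- data.frame(tc = as.integer(names(tab)),
                       molecules = as.integer(tab))
  freq <- ifelse(!is.na(x$coveredT) & x$coveredT > 0,
                 x$tcCountQ / x$coveredT, NA_real_)
  pg <- vapply(split(freq, x$gene), function(z) mean(z, na.rm = TRUE), 0)
  perGene <- data.frame(gene = names(pg), meanTcFrequency = as.numeric(pg))
  list(perUmi = perUmi, perGene = perGene,
       bimodality = .bimodalityCoefficient(perGene$meanTcFrequency))
}

#' Per-cell transcript labeling efficiency
#'
#' Fraction of a cell's molecules classified labeled, the per-cell readout
#' of zygotic transcriptional activity. Cells with zero molecules are
#' excluded and reported.
#'
#' @param x SingleCellExperiment from [splitMatrices()].
#' @return data.frame with `cell`, `labeled`, `total`, `efficiency`; excluded
#'   cells in `attr(, "excluded")`.
#' @export
labelingEfficiency <- function(x) {
  lab <- Matrix::colSums(assay(x, "labeled"))
  tot <- lab + Matrix::colSums(assay(x, "unlabeled"))
  keep <- tot > 0
  out <- data.frame(cell = colnames(x)[keep], labeled = lab[keep],
                    total = tot[keep], efficiency = lab[keep] / tot[keep])
  attr(out, "excluded") <- colnames(x)[!keep]
  out
}

#' Analytic false-negative model of molecule classification
#'
#' Parameters of the back-of-the-envelope false-negative calculation: with
#' `readLength` nt reads and `readsPerUmi` reads per molecule, a molecule
#' exposes `effectiveLength` distinct nt (reads may overlap, so this is at
#' most `readsPerUmi * readLength`); at GC content `gcContent` a fraction
#' `(1 - gcContent) / 2` of positions are Us, giving
#' `nU = effectiveLength * (1 - gcContent) / 2` covered Us per molecule (90
#' at the defaults).
#'
#' @param pLabel Per-U conversion probability (default 0.05).
#' @param readLength Read length in nt (default 99).
#' @param readsPerUmi Reads per molecule (default 4).
#' @param effectiveLength Effective distinct coverage in nt (default 300).
#' @param gcContent GC fraction (default 0.40).
#' @return A list of class `FnrModel`.
#' @export
fnrModel <- function(pLabel = 0.05, readLength = 99, readsPerUmi = 4,
                     effectiveLength = 300, gcContent = 0.40) {
  .assertProb(pLabel, "pLabel")
  .assertProb(gcContent, "gcContent")
  if (effectiveLength > readsPerUmi * readLength)
    stop("effectiveLength cannot exceed readsPerUmi * readLength")
  uFraction <- (1 - gcContent) / 2
  structure(list(pLabel = pLabel, readLength = readLength,
                 readsPerUmi = readsPerUmi,
                 effectiveLength = effectiveLength, gcContent = gcContent,
                 uFraction = uFraction, nU = effectiveLength * uFraction),
            class = "FnrModel")
}

#' @rdname fnrModel
#' @param model An `FnrModel`.
#' @return `expectedUCount`: expected covered Us per molecule
#'   (`effectiveLength * uFraction`; 90 at the defaults).
#' @export
expectedUCount <- function(model = fnrModel()) model$nU

#' Analytic false-negative rate of labeled-molecule detection
#'
#' Probability that a truly zygotic (labeled) molecule is classified
#' unlabeled: the binomial lower tail `P(X < minTc)` with
#' `X ~ Binomial(round(nU), pLabel)`. For `minTc = 1` this is
#' `(1 - pLabel)^nU`, e.g. 0.95^90 (about 1%) at the defaults.
#'
#' With `uCountModel = "expected"` every molecule is assumed to carry
#' exactly `nU` Us (the back-of-the-envelope model). With `"binomial"` the
#' per-molecule U count is itself `Binomial(effectiveLength, uFraction)`, in
#' which case the detected-conversion count is
#' `Binomial(effectiveLength, uFraction * pLabel)` exactly; this is the
#' matching analytic model for simulations that draw U counts per molecule,
#' and is slightly larger (0.0107 vs 0.0099 at the defaults).
#'
#' @param model An [fnrModel()].
#' @param minTc Labeled-call threshold as in [classifyUmis()].
#' @param uCountModel `"expected"` (fixed U count, default) or `"binomial"`
#'   (per-molecule binomial U count).
#' @return Probability in `[0, 1]`; non-increasing in `pLabel` and in `nU`.
#' @export
#' @examples
#' analyticFnr(fnrModel())            # 0.95^90, about 0.0099
#' analyticFnr(fnrModel(), minTc = 2)
analyticFnr <- function(model = fnrModel(), minTc = 1,
                        uCountModel = c("expected", "binomial")) {
  uCountModel <- match.arg(uCountModel)
  if (uCountModel == "binomial")
    return(stats::pbinom(minTc - 1, model$effectiveLength,
                         model$uFraction * model$pLabel))
  n <- round(model$nU)
  if (minTc == 1) return((1 - model$pLabel)^model$nU)
  stats::pbinom(minTc - 1, n, model$pLabel)
}

#' Analytic false-positive rate from sequencing errors
#'
#' Probability that a truly maternal (unlabeled) molecule is classified
#' labeled through sequencing errors alone: `P(X >= minTc)` with
#' `X ~ Binomial(readsPerUmi * readLength, errorRate / 12 * qualPassProb)`,
#' the T>C share of a uniform error background after the quality filter.
#'
#' @param errorRate Per-base error probability.
#' @param readLength,readsPerUmi Read geometry (total sequenced bases =
#'   `readsPerUmi * readLength`).
#' @param qualPassProb Probability an error base call passes the quality
#'   filter.
#' @param minTc Labeled-call threshold.
#' @return Probability in `[0, 1]`.
#' @export
analyticFpr <- function(errorRate = 0.001, readLength = 99, readsPerUmi = 4,
                        qualPassProb = 1, minTc = 1) {
  stats::pbinom(minTc - 1, readsPerUmi * readLength,
                errorRate / 12 * qualPassProb, lower.tail = FALSE)
}
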