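#' Per-cell-type fold changes of maternal transcripts
#'
#' For each gene in `geneSet` and each cell type, the log2 ratio of mean
#' expression (molecules per cell) in that type versus all other cells, with
#' a pseudocount on both means. Genes whose overall mean expression falls
#' below `minExpr` molecules per cell are excluded from the fold changes and
#' reported.
#'
#' @param unlabeled Genes x cells count matrix (dense or sparse), e.g. the
#'   `"unlabeled"` assay of [splitMatrices()].
#' @param cellTypes Factor/character of cell types, one per column.
#' @param geneSet Genes to evaluate (default: all rows).
#' @param minExpr Expression cutoff in molecules per cell (default 0.1).
#' @param pseudocount Pseudocount epsilon added to both means (default 0.01).
#' @return DataFrame with `gene_id`, `meanExpr`, `included`, and an `fc`
#'   matrix column (log2 fold change per cell type; NA for excluded genes).
#' @export
foldChange <- function(unlabeled, cellTypes, geneSet = rownames(unlabeled),
                       minExpr = 0.1, pseudocount = 0.01) {
  cellTypes <- factor(cellTypes)
  if (length(cellTypes) != ncol(unlabeled))
    stop("cellTypes must have one entry per cell")
  if (nlevels(cellTypes) < 2) stop("need at least 2 cell types")
  if (any(table(cellTypes) == 0)) stop("cell type with 0 cells")
  miss <- setdiff(geneSet, rownames(unlabeled))
  if (length(miss))
    stop("genes not in matrix: ", paste(utils::head(miss, 5), collapse = ", "))
  m <- unlabeled[geneSet, , drop = FALSE]
  overall <- Matrix::rowMeans(m)
  included <- overall >= minExpr
  fc <- matrix(NA_real_, length(geneSet), nlevels(cellTypes),
               dimnames = list(geneSet, levels(cellTypes)))
  for (ty in levels(cellTypes)) {
    inT <- cellTypes == ty
    mi <- Matrix::rowMeans(m[, inT, drop = FALSE])
    mo <- Matrix::rowMeans(m[, !inT, drop = FALSE])
    fc[included, ty] <- log2((mi[included] + pseudocount) /
                             (mo[included] + pseudocount))
  }
  out <- DataFrame(gene_id = geneSet, meanExpr = overall, included = included)
  out$fc <- fc
  metadata(out) <- list(minExpr = minExpr, pseudocount = pseudocount)
  out
}

# One EM attempt; returns NULL on component degeneracy.
.emOnce <- function(v, k, w, mu, sd, maxIter, tol) {
  n <- length(v)
  ll <- -Inf
  trace <- numeric(0)
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(v, mu[j], sd[j]),
                   numeric(n))
    dens <- matrix(dens, n, k)
    tot <- rowSums(dens)
    if (any(tot == 0) || any(!is.finite(tot))) return(NULL)
    llNew <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(resp * v) / nk
    sd <- sqrt(colSums(resp * (outer(v, mu, "-"))^2) / nk)
    if (any(sd < 1e-6)) return(NULL)
    trace <- c(trace, llNew)
    if (is.finite(ll) && llNew - ll < tol) {
      return(list(w = w, mu = mu, sd = sd, resp = resp, ll = llNew,
                  trace = trace, converged = TRUE, iterations = it))
    }
    ll <- llNew
  }
  list(w = w, mu = mu, sd = sd, resp = resp, ll = ll, trace = trace,
       converged = FALSE, iterations = maxIter)
}

#' Deconvolve a bimodal distribution into Gaussian components
#'
#' Fits a k-component univariate Gaussian mixture by
#' expectation-maximization, initialized from a quantile split of the sorted
#' values. Convergence when the log-likelihood gain drops below `tol`
#' (default 1e-8) or after `maxIter` iterations; a degenerating component
#' (sd below 1e-6) triggers a seeded jitter restart, up to `maxRestarts`
#' times. Components are reported in increasing-mean order.
#'
#' @param values Numeric sample, e.g. per-gene log2 fold changes in one cell
#'   type; needs at least `2 * k` values.
#' @param k Number of components (default 2).
#' @param seed Integer seed for restarts.
#' @param maxIter,tol EM stopping rule.
#' @param maxRestarts Jitter restarts before giving up.
#' @param nStarts Number of EM starts (quantile split plus seeded
#'   perturbations); the fit with the best final log-likelihood is kept.
#' @return A \linkS4class{GmmFit}.
#' @export
#' @examples
#' set.seed(1)
#' v <- c(rnorm(500, 0.4, 0.5), rnorm(500, 1.52, 0.4))
#' deconvolveBimodal(v)
deconvolveBimodal <- function(values, k = 2, seed = 1L, maxIter = 500,
                              tol = 1e-8, maxRestarts = 10, nStarts = 5) {
  v <- values[is.finite(values)]
  if (length(v) < 2 * k)
    stop("need at least ", 2 * k, " finite values")
  if (k == 1) {
    mu <- mean(v); sd <- sqrt(mean((v - mu)^2))
    if (sd < 1e-6) stop("degenerate fit: all values identical")
    return(new("GmmFit", weights = 1, means = mu, sds = sd,
               responsibilities = matrix(1, length(v), 1),
               logLik = sum(stats::dnorm(v, mu, sd, log = TRUE)),
               logLikTrace = numeric(0), converged = TRUE,
               iterations = 0L, seed = as.integer(seed)))
  }
  ord <- sort(v)
  grp <- cut(seq_along(ord), k, labels = FALSE)
  mu <- vapply(split(ord, grp), mean, 0)
  sd <- vapply(split(ord, grp), function(z) max(stats::sd(z), 1e-3), 0)
  sd[!is.finite(sd)] <- max(stats::sd(v), 1e-3)
  w <- rep(1 / k, k)
  # quantile-split start plus seeded perturbed starts; keep the best optimum
  fit <- .emOnce(v, k, w, mu, sd, maxIter, tol)
  att <- 0
  .withSeed(seed, {
    for (s in seq_len(nStarts - 1)) {
      mu2 <- mu + stats::rnorm(k, 0, stats::sd(v) / 4 + 1e-3)
      sd2 <- pmax(sd * stats::runif(k, 0.7, 1.4), 1e-2)
      alt <- .emOnce(v, k, w, mu2, sd2, maxIter, tol)
      if (!is.null(alt) && (is.null(fit) || alt$ll > fit$ll)) fit <- alt
    }
    while (is.null(fit) && att < maxRestarts) {
      att <- att + 1
      mu2 <- mu + stats::rnorm(k, 0, stats::sd(v) / 2 + 1e-3)
      sd2 <- pmax(sd * stats::runif(k, 0.5, 2), 1e-2)
      fit <- .emOnce(v, k, w, mu2, sd2, maxIter, tol)
    }
  })
  if (is.null(fit))
    stop("degenerate fit after ", maxRestarts, " restarts")
  o <- order(fit$mu)
  new("GmmFit", weights = fit$w[o], means = fit$mu[o], sds = fit$sd[o],
      responsibilities = fit$resp[, o, drop = FALSE],
      logLik = fit$ll, logLikTrace = fit$trace,
      converged = fit$converged, iterations = as.integer(fit$iterations),
      seed = as.integer(seed))
}

#' Sample a background gene set
#'
#' Uniform sampling without replacement, e.g. to draw a random gene sample
#' whose fold-change distribution is compared against a mixture component.
#'
#' @param values Numeric population to sample from.
#' @param n Sample size (<= population size).
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
backgroundSample <- function(values, n, seed = 1L) {
  if (n > length(values)) stop("n exceeds population size")
  .withSeed(seed, values[sample.int(length(values), n)])
}

#' One-sided Welch's t test for higher means
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, one-sided by default (is `mean(a) > mean(b)`?).
#'
#' @param a,b Numeric samples (each of size >= 2).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return List with `t`, `df`, `p`.
#' @export
compareMeansWelch <- function(a, b, alternative = "greater") {
  if (length(a) < 2 || length(b) < 2) stop("group size < 2")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both groups")
  ht <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Hypergeometric set-enrichment test
#'
#' Upper-tail hypergeometric probability of observing at least the actual
#' overlap between a gene set and a marker set inside a finite universe,
#' the standard overrepresentation test.
#'
#' @param geneSet,markerSet Character vectors, subsets of `universe`.
#' @param universe Character vector of all eligible genes.
#' @return List with `overlap`, `expected`, `p`.
#' @export
#' @examples
#' setEnrichment(letters[1:5], letters[3:8], letters[1:20])
setEnrichment <- function(geneSet, markerSet, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  geneSet <- unique(intersect(geneSet, universe))
  markerSet <- unique(intersect(markerSet, universe))
  ov <- length(intersect(geneSet, markerSet))
  N <- length(universe); K <- length(geneSet); n <- length(markerSet)
  p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = ov, expected = K * n / N, p = p)
}
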