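#' Train a 1 x n self-organizing map on cumulative traces
#'
#' Online Kohonen training on a one-dimensional grid: for each gene trace
#' the winning node is found by Euclidean distance and all prototypes are
#' pulled toward the trace under a Gaussian neighborhood centred on the
#' winner. Learning rate and neighborhood width decay linearly over epochs;
#' genes are presented in a freshly shuffled order each epoch (seeded, hence
#' deterministic).
#'
#' Two choices make node indices behave like occupancy quantiles along the
#' animal-vegetal axis, which is what windowed profile-calling rules assume:
#' prototypes are initialized as the mean traces of equal-size centroid-rank
#' bins (node j starts as the mean of the j-th n-quantile of genes ranked by
#' trace centroid), and winner selection carries a DeSieno-style conscience
#' bias `- conscience * (1/n - winFreq)` that equalizes node utilization.
#' The bias is small against between-cluster distances but large against
#' within-cluster quantization error, so it balances node allocation without
#' mixing distinct profile shapes. Set `conscience = 0` for plain Kohonen
#' training. After training each prototype row is projected back onto the
#' space of valid cumulative traces (non-decreasing, ending at 1).
#'
#' @param x A \linkS4class{TraceSet} (cumulative assay; all-zero genes are
#'   skipped) or a numeric matrix of cumulative traces.
#' @param nNodes Number of map nodes (default 50).
#' @param epochs Training epochs (default 50).
#' @param lr Learning rate decaying linearly `lr[1] -> lr[2]`.
#' @param sigma Gaussian neighborhood width decaying linearly
#'   `sigma[1] -> sigma[2]`; default `c(10, 2)`.
#' @param conscience Conscience bias coefficient on squared-distance scale
#'   (default 40, sized for traces in `[0,1]`); 0 disables it.
#' @param conscienceRate Running-frequency update rate (default 1e-3).
#' @param seed Integer seed for the per-epoch shuffles.
#' @return An unordered \linkS4class{SomModel}.
#' @export
trainSom <- function(x, nNodes = 50, epochs = 50, lr = c(0.5, 0.01),
                     sigma = c(10, 2), conscience = 40,
                     conscienceRate = 1e-3, seed = 1L) {
  X <- if (is(x, "TraceSet")) {
    nz <- rowData(x)$nonzero
    if (is.null(nz)) nz <- rep(TRUE, nrow(x))
    traceMatrix(x, "cumulative")[nz, , drop = FALSE]
  } else as.matrix(x)
  if (nrow(X) < nNodes)
    stop("fewer genes (", nrow(X), ") than map nodes (", nNodes, ")")
  S <- ncol(X)
  grid <- seq_len(nNodes)

  # density-matched init: node j = mean trace of the j-th centroid-rank bin
  cen <- .traceCentroids(X)
  bins <- cut(rank(cen, ties.method = "first"), nNodes, labels = FALSE)
  P <- do.call(rbind, lapply(split(seq_len(nrow(X)), bins),
                             function(ii) colMeans(X[ii, , drop = FALSE])))
  winFreq <- rep(1 / nNodes, nNodes)

  .withSeed(seed, {
    for (e in seq_len(epochs)) {
      a <- if (epochs > 1) (e - 1) / (epochs - 1) else 1
      lrE <- lr[1] + a * (lr[2] - lr[1])
      sigE <- sigma[1] + a * (sigma[2] - sigma[1])
      for (i in sample.int(nrow(X))) {
        v <- X[i, ]
        d2 <- rowSums((P - rep(v, each = nNodes))^2)
        bmu <- which.min(d2 - conscience * (1 / nNodes - winFreq))
        winFreq <- winFreq + conscienceRate * ((grid == bmu) - winFreq)
        h <- lrE * exp(-(grid - bmu)^2 / (2 * sigE^2))
        P <- P + h * (rep(v, each = nNodes) - P)
      }
    }
  })

  # project prototypes back to valid cumulative traces
  P <- t(apply(P, 1, cummax))
  if (S == 1) P <- matrix(P, ncol = 1)
  P <- pmax(P, 0)
  last <- P[, S]
  P[last > 0, ] <- P[last > 0, , drop = FALSE] / last[last > 0]
  P[last <= 0, S] <- 1
  new("SomModel", prototypes = P, nNodes = as.integer(nNodes),
      ordered = FALSE,
      meta = list(epochs = epochs, lr = lr, sigma = sigma,
                  conscience = conscience, conscienceRate = conscienceRate,
                  seed = seed))
}

#' Centroid position of each map node
#'
#' Expected section index under the per-section increments of each cumulative
#' prototype, i.e. where along the animal-vegetal axis the node's mass sits.
#'
#' @param model A \linkS4class{SomModel}.
#' @return Numeric vector, one centroid per node.
#' @export
nodeCentroids <- function(model) .traceCentroids(prototypes(model))

#' Order map nodes along the animal-vegetal axis
#'
#' Re-indexes nodes so prototype centroids are non-decreasing, making node 1
#' the most animal and the last node the most vegetal profile. Training
#' alone does not fix which end of the physical axis is which; when
#' `sectionTotals` (raw per-section library sizes) is supplied, the map is
#' flipped if the heavy end of the library - the blastodisc at the animal
#' pole - sits at high section numbers, so that calls are invariant to
#' reversing the section order of all inputs. Idempotent.
#'
#' @param model A \linkS4class{SomModel}.
#' @param sectionTotals Optional numeric vector of raw per-section totals
#'   used to orient the axis; NULL assumes sections are already
#'   animal-to-vegetal.
#' @return An ordered \linkS4class{SomModel}.
#' @export
orderNodes <- function(model, sectionTotals = NULL) {
  P <- prototypes(model)
  cen <- .traceCentroids(P)
  ord <- order(cen)
  if (!is.null(sectionTotals)) {
    s <- seq_along(sectionTotals)
    half <- s > length(s) / 2
    if (sum(sectionTotals[half]) > sum(sectionTotals[!half]))
      ord <- rev(ord)   # heavy (animal) end at high sections: flip the map
  }
  out <- model
  out@prototypes <- P[ord, , drop = FALSE]
  out@ordered <- is.null(sectionTotals) ||
    !is.unsorted(.traceCentroids(out@prototypes))
  out@meta$nodeOrder <- ord
  out
}

#' Assign genes to their best-matching map node
#'
#' Maps each gene to the node whose prototype has minimal Euclidean distance
#' to the gene's cumulative trace; ties break toward the lower node index.
#' Deterministic given (model, traces); all-zero genes get NA.
#'
#' @param model An ordered \linkS4class{SomModel}.
#' @param x A \linkS4class{TraceSet} or cumulative-trace matrix.
#' @return Named integer vector gene -> node index (1..nNodes).
#' @export
assignProfiles <- function(model, x) {
  if (is(x, "TraceSet")) {
    nz <- rowData(x)$nonzero
    if (is.null(nz)) nz <- rep(TRUE, nrow(x))
    X <- traceMatrix(x, "cumulative")
  } else {
    X <- as.matrix(x)
    nz <- rep(TRUE, nrow(X))
  }
  P <- prototypes(model)
  if (ncol(X) != ncol(P))
    stop("trace length (", ncol(X), ") != prototype length (", ncol(P), ")")
  d2 <- outer(rowSums(X^2), rowSums(P^2), "+") - 2 * X %*% t(P)
  prof <- max.col(-d2, ties.method = "first")
  prof[!nz] <- NA_integer_
  stats::setNames(as.integer(prof), rownames(X))
}

#' Call localization categories from per-replicate profiles
#'
#' Applies the multi-replicate rule: a gene is vegetal when its profile lies
#' in `vegetalAll` in every replicate and in `vegetalAny` in at least one;
#' animal when its profile lies in `animalWindow` in every replicate;
#' otherwise unlocalized. Only genes detected (non-NA profile) in all
#' replicates are callable; the rest are reported separately.
#'
#' @param assignments List of named integer vectors (one per replicate) as
#'   returned by [assignProfiles()].
#' @param vegetalAll Inclusive node window required in all replicates
#'   (default c(46, 50)).
#' @param vegetalAny Inclusive node window required in at least one
#'   replicate (default c(48, 50)).
#' @param animalWindow Inclusive node window for animal calls
#'   (default c(1, 8)).
#' @return DataFrame with `gene_id`, `category` (animal / unlocalized /
#'   vegetal) and a `profiles` matrix column; genes missing from some
#'   replicate are listed in `metadata()$uncallable`.
#' @export
#' @examples
#' a <- list(r1 = c(g1 = 49L, g2 = 47L), r2 = c(g1 = 47L, g2 = 47L),
#'           r3 = c(g1 = 46L, g2 = 47L))
#' callLocalization(a)$category
callLocalization <- function(assignments, vegetalAll = c(46, 50),
                             vegetalAny = c(48, 50), animalWindow = c(1, 8)) {
  if (!length(assignments)) stop("need at least one replicate")
  if (is.numeric(assignments)) assignments <- list(assignments)
  if (is.null(names(assignments)))
    names(assignments) <- paste0("rep", seq_along(assignments))
  allGenes <- Reduce(union, lapply(assignments, names))
  prof <- vapply(assignments,
                 function(a) unname(a[allGenes]), numeric(length(allGenes)))
  prof <- matrix(prof, nrow = length(allGenes),
                 dimnames = list(allGenes, names(assignments)))
  complete <- rowSums(is.na(prof)) == 0
  inWin <- function(p, w) !is.na(p) & p >= w[1] & p <= w[2]
  veg <- complete &
    rowSums(inWin(prof, vegetalAll)) == ncol(prof) &
    rowSums(inWin(prof, vegetalAny)) >= 1
  ani <- complete & rowSums(inWin(prof, animalWindow)) == ncol(prof)
  category <- factor(ifelse(veg, "vegetal", ifelse(ani, "animal", "unlocalized")),
                     levels = c("animal", "unlocalized", "vegetal"))
  category[!complete] <- NA
  out <- DataFrame(gene_id = allGenes[complete],
                   category = category[complete])
  out$profiles <- prof[complete, , drop = FALSE]
  storage.mode(out$profiles) <- "integer"
  metadata(out) <- list(uncallable = allGenes[!complete],
                        vegetalAll = vegetalAll, vegetalAny = vegetalAny,
                        animalWindow = animalWindow)
  out
}

#' Intersect localization call sets across samples or species
#'
#' Venn-style overlap of 2-3 localized-gene sets, restricted to the universe
#' of genes expressed in all sets. For cross-species comparisons an
#' orthology map (per set, mapping that set's ids to reference ids) resolves
#' many-to-many relations with "any orthologue localized" semantics: a
#' reference gene counts as expressed/localized in a set if any of its
#' orthologues is.
#'
#' @param calls Named list (length 2-3) of character vectors of localized
#'   gene ids per set.
#' @param universes Named list of character vectors of expressed gene ids
#'   per set (same names as `calls`).
#' @param orthology Optional named list of two-column maps (DataFrame /
#'   data.frame: set id, reference id) for sets whose ids are not already
#'   reference ids; omitted sets are taken as identity.
#' @return List with `membership` (DataFrame, reference genes x sets,
#'   logical), `regions` (named counts per Venn region, e.g. `"110"`), and
#'   `genes` (list of gene vectors per region).
#' @export
intersectCalls <- function(calls, universes, orthology = NULL) {
  stopifnot(length(calls) >= 2, length(calls) <= 3,
            identical(names(calls), names(universes)))
  mapIds <- function(ids, set) {
    om <- orthology[[set]]
    if (is.null(om)) return(unique(ids))
    om <- as.data.frame(om)
    unique(om[[2]][om[[1]] %in% ids])
  }
  uniRef <- lapply(names(calls), function(s) mapIds(universes[[s]], s))
  callRef <- lapply(names(calls), function(s) mapIds(calls[[s]], s))
  universe <- Reduce(intersect, uniRef)
  memb <- vapply(callRef, function(z) universe %in% z,
                 logical(length(universe)))
  memb <- matrix(memb, nrow = length(universe),
                 dimnames = list(universe, names(calls)))
  inAny <- rowSums(memb) > 0
  pattern <- apply(memb[inAny, , drop = FALSE], 1,
                   function(z) paste(as.integer(z), collapse = ""))
  genes <- split(universe[inAny], pattern)
  regions <- vapply(genes, length, 0L)
  out <- DataFrame(memb[inAny, , drop = FALSE])
  rownames(out) <- universe[inAny]
  list(membership = out, regions = regions, genes = genes,
       universeSize = length(universe))
}
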