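test_that("UMI aggregation applies the strict quality filter to T>C only", {
  agg <- aggregateUmis(tinyMismatch(), minQual = 20)
  rowU1 <- agg[agg$umi == "U1", ]
  expect_equal(rowU1$tcCountQ, 1L)            # q15 T>C filtered out
  expect_equal(unname(rowU1$subCounts[, "T>C"]), 2L)  # spectrum unfiltered
  rowU2 <- agg[agg$umi == "U2", ]
  expect_equal(rowU2$tcCountQ, 0L)
  expect_equal(unname(rowU2$subCounts[, "A>G"]), 1L)
  rowU4 <- agg[agg$umi == "U4", ]              # no mismatch rows at all
  expect_equal(rowU4$tcCountQ, 0L)
  expect_equal(sum(rowU4$subCounts), 0L)
  # boundary: quality exactly 20 does not pass
  mm <- MismatchRecords(S4Vectors::DataFrame(
    cell = "A", umi = "U", gene = "g", sub = "T>C", qual = 20L, readId = "r"))
  expect_equal(aggregateUmis(mm, 20)$tcCountQ, 0L)
})

test_that("classification threshold behaves and is monotone in minTc", {
  agg <- aggregateUmis(tinyMismatch())
  cl1 <- classifyUmis(agg, minTc = 1)
  expect_equal(as.character(cl1$label[cl1$umi == "U1"]), "labeled")
  expect_equal(as.character(cl1$label[cl1$umi == "U2"]), "unlabeled")
  cl2 <- classifyUmis(agg, minTc = 2)
  f <- function(cl) mean(cl$label == "labeled")
  expect_lte(f(cl2), f(cl1))

  sim <- slamFixture()
  aggS <- aggregateUmis(sim$mismatches)
  fr <- vapply(1:4, function(k) mean(classifyUmis(aggS, k)$label == "labeled"), 0)
  expect_true(all(diff(fr) <= 0))
})

test_that("split matrices conserve molecule counts exactly", {
  sim <- slamFixture()
  cl <- classifyUmis(aggregateUmis(sim$mismatches))
  sce <- splitMatrices(cl, sim$cellTypes)
  tot <- SummarizedExperiment::assay(sce, "labeled") +
    SummarizedExperiment::assay(sce, "unlabeled")
  expect_equal(sum(tot), nrow(cl))
  # per-(gene, cell) totals match a direct tabulation
  tab <- table(cl$gene, cl$cell)
  expect_equal(unname(as.matrix(tot)[rownames(tab), colnames(tab)]),
               unname(unclass(tab)))
  # all labeled -> unlabeled matrix empty
  clAll <- cl; clAll$label[] <- "labeled"
  sceAll <- splitMatrices(clAll)
  expect_equal(sum(SummarizedExperiment::assay(sceAll, "unlabeled")), 0)
})

test_that("mutation spectra flag T>C enrichment and uniform error floors", {
  # error-free labeled sample: only T>C present
  cfg <- slamSimConfig(nCells = c(soma = 10, pgc = 2), nMaternalGenes = 5,
                       nZygoticGenes = 10, nVegetalGenes = 1,
                       errorRate = 0, seed = 12)
  sim <- simulateSlamReads(cfg)
  sp <- mutationSpectrum(sim$mismatches)
  expect_true(sp$frequency[sp$sub == "T>C"] > 0)
  expect_equal(sum(sp$frequency[sp$sub != "T>C"]), 0)

  # label-free control: 12 error frequencies equal within 3 SE
  cfg0 <- slamSimConfig(nCells = c(soma = 60, pgc = 5), nMaternalGenes = 30,
                        nZygoticGenes = 30, nVegetalGenes = 5,
                        pLabel = 0, seed = 12)
  sim0 <- simulateSlamReads(cfg0)
  sp0 <- mutationSpectrum(sim0$mismatches, minQual = -1)
  expTot <- attr(sp0, "totalBases") * 0.001 / 12
  expect_true(all(abs(sp0$count - expTot) < 3 * sqrt(expTot) + 3))

  # labeled vs control T>C ratio is large
  cmp <- compareSpectra(slamFixture()$mismatches, sim0$mismatches)
  expect_gt(cmp$ratio[cmp$sub == "T>C"], 5)
})

test_that("T>C histograms separate mixed and control libraries", {
  sim <- slamFixture()
  agg <- aggregateUmis(sim$mismatches)
  th <- tcHistogram(agg)
  expect_equal(sum(th$perUmi$molecules), nrow(agg))
  # mixed maternal+zygotic: strong mass at zero plus a labeled mode
  p0 <- th$perUmi$molecules[th$perUmi$tc == 0] / sum(th$perUmi$molecules)
  expect_gt(p0, 0.2)
  expect_gt(th$bimodality, 0.555)

  cfg0 <- slamSimConfig(nCells = c(soma = 30, pgc = 3), nMaternalGenes = 20,
                        nZygoticGenes = 20, nVegetalGenes = 4,
                        pLabel = 0, seed = 14)
  th0 <- tcHistogram(aggregateUmis(simulateSlamReads(cfg0)$mismatches))
  expect_true(is.na(th0$bimodality) || th0$bimodality < 0.555)

  one <- tcHistogram(S4Vectors::DataFrame(cell = "c", umi = "u", gene = "g",
                                          reads = 1L, coveredT = 90L,
                                          tcCountQ = 3L))
  expect_equal(one$perUmi, data.frame(tc = 3L, molecules = 1L))
})

test_that("labeling efficiency is a per-cell fraction; PGCs rank lowest", {
  m <- Matrix::Matrix(matrix(c(30, 0, 70, 10), 2), sparse = TRUE)
  dimnames(m) <- list(c("g1", "g2"), c("c1", "c2"))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(labeled = m,
                  unlabeled = Matrix::Matrix(matrix(c(70, 0, 0, 0), 2,
                    dimnames = dimnames(m)), sparse = TRUE)))
  eff <- labelingEfficiency(sce)
  expect_equal(eff$efficiency[eff$cell == "c1"], 0.3)
  expect_equal(eff$efficiency[eff$cell == "c2"], 1.0)

  sim <- slamFixture()
  sce2 <- splitMatrices(classifyUmis(aggregateUmis(sim$mismatches)),
                        sim$cellTypes)
  eff2 <- labelingEfficiency(sce2)
  byType <- tapply(eff2$efficiency, sim$cellTypes[eff2$cell], mean)
  expect_equal(names(which.min(byType)), "pgc")
})

test_that("analytic FNR reproduces the closed form and binomial tails", {
  m <- fnrModel()
  expect_equal(expectedUCount(m), 90)
  expect_equal(analyticFnr(m), 0.95^90)
  expect_equal(round(analyticFnr(m), 2), 0.01)
  expect_equal(analyticFnr(fnrModel(pLabel = 0)), 1)
  # brute-force binomial tail for minTc = 2
  brute <- sum(vapply(0:1, function(x)
    choose(90, x) * 0.05^x * 0.95^(90 - x), 0))
  expect_equal(analyticFnr(m, minTc = 2), brute)
  expect_equal(round(brute, 4), 0.0567, tolerance = 1e-3)

  # monotone in pLabel and in nU
  ps <- seq(0, 0.2, by = 0.02)
  expect_true(all(diff(vapply(ps, function(p)
    analyticFnr(fnrModel(pLabel = p)), 0)) <= 0))
  ls <- seq(60, 396, by = 24)
  expect_true(all(diff(vapply(ls, function(L)
    analyticFnr(fnrModel(effectiveLength = L)), 0)) <= 0))
  expect_error(fnrModel(effectiveLength = 500), "exceed")
})

test_that("simulated misclassification matches the binomial models", {
  grid <- list(list(p = 0.05, e = 0.001, k = 1),
               list(p = 0.05, e = 0.001, k = 2),
               list(p = 0.10, e = 0.002, k = 1))
  for (g in grid) {
    cfg <- slamSimConfig(nCells = c(soma = 150, pgc = 5),
                         nMaternalGenes = 40, nZygoticGenes = 40,
                         nVegetalGenes = 5, pLabel = g$p, errorRate = g$e,
                         seed = 100 + g$k)
    sim <- simulateSlamReads(cfg)
    cl <- classifyUmis(aggregateUmis(sim$mismatches), minTc = g$k)
    zy <- sim$truth$status == "zygotic"
    # FNR against the analytic model (plus the T>C error channel that can
    # rescue a conversion-free molecule, bounded by its probability)
    empFnr <- mean(cl$label[zy] == "unlabeled")
    anaFnr <- analyticFnr(fnrModel(pLabel = g$p), minTc = g$k,
                          uCountModel = "binomial")
    seF <- sqrt(anaFnr * (1 - anaFnr) / sum(zy))
    fprE <- analyticFpr(errorRate = g$e, minTc = g$k)
    expect_lt(abs(empFnr - anaFnr), 3 * seF + fprE + 0.003)
    # FPR against the binomial error model
    empFpr <- mean(cl$label[!zy] == "labeled")
    seP <- sqrt(fprE * (1 - fprE) / sum(!zy))
    expect_lt(abs(empFpr - fprE), 3 * seP + 0.002)
  }
})
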