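test_that("weighted lengths are FPKM-share convex combinations", {
  tab <- S4Vectors::DataFrame(
    isoform_id = c("i1", "i2", "i3", "i4", "i5"),
    gene_id = c("g1", "g1", "g2", "g3", "g3"),
    fpkm = c(3, 1, 8, 0, 0),
    utr3_length = c(1000, 500, 700, 100, 300),
    cds_length = c(2000, 1800, 1500, 900, 900))
  wl <- weightedLengths(tab)
  expect_equal(wl$weightedUtr3[wl$gene_id == "g1"], 875)
  expect_equal(wl$weightedCds[wl$gene_id == "g1"], 1950)
  # single isoform: its own length
  expect_equal(wl$weightedUtr3[wl$gene_id == "g2"], 700)
  # all-zero FPKM gene excluded and reported
  expect_false("g3" %in% wl$gene_id)
  expect_equal(S4Vectors::metadata(wl)$excluded, "g3")
  expect_true(wl$lowExpression[wl$gene_id == "g1"])

  # equal FPKM: arithmetic mean; convexity on simulated isoforms
  tabEq <- S4Vectors::DataFrame(isoform_id = c("a", "b"), gene_id = "g",
                                fpkm = c(2, 2), utr3_length = c(100, 300),
                                cds_length = c(1, 1))
  expect_equal(weightedLengths(tabEq)$weightedUtr3, 200)
  iso <- simulateIsoformTable(nGenes = 40, seed = 3)
  wls <- weightedLengths(iso)
  rng <- vapply(split(as.data.frame(iso), iso$gene_id), function(d)
    c(min(d$utr3_length), max(d$utr3_length)), numeric(2))
  expect_true(all(wls$weightedUtr3 >= rng[1, wls$gene_id] - 1e-9))
  expect_true(all(wls$weightedUtr3 <= rng[2, wls$gene_id] + 1e-9))

  top <- longestUtrPerGene(tab)
  expect_equal(top$utr3_length[top$gene_id == "g1"], 1000)
})

test_that("group comparison matches the enumerated rank-sum null", {
  cmp <- compareGroups(c(10, 11, 12), c(1, 2, 3))
  expect_equal(cmp$p, 0.1)
  expect_equal(cmp$p, enumWilcoxTwoSided(c(10, 11, 12), c(1, 2, 3)))
  expect_equal(cmp$fold, 11 / 2)
  # identical groups: fold 1, exact p = 1 needs distinct values across sets
  same <- compareGroups(c(1.1, 2.2, 3.3), c(1.1, 2.2, 3.3))
  expect_equal(same$fold, 1)
  expect_gt(same$p, 0.99)
  # further enumeration spot-checks
  a <- c(5, 9, 13, 2); b <- c(1, 7, 8)
  expect_equal(compareGroups(a, b)$p, enumWilcoxTwoSided(a, b))
  expect_error(compareGroups(numeric(0), 1:3), "group")

  # planted 1.7-fold length difference is detected
  sim <- simulateUtrs(utrSimConfig(nPositive = 200, nBackground = 2000,
                                   plantProbPositive = 0, seed = 8))
  det <- compareGroups(Biostrings::width(sim$positive),
                       Biostrings::width(sim$background))
  expect_gt(det$fold, 1.5)
  expect_lt(det$fold, 1.9)
  expect_lt(det$p, 1e-6)
})

test_that("GC content counts determined bases only", {
  gc <- gcContent(c(a = "GCGC", b = "ATAT", c = "ACGT", d = "NNNN"))
  expect_equal(unname(gc$perSequence), c(1, 0, 0.5))
  expect_equal(attr(gc, "excluded"), "d")
  expect_equal(gc$group, 6 / 12)
})

test_that("k-mer presence and Fisher scoring match brute-force counting", {
  seqs <- c("ACGTACGT", "TTTACG", "GGGG")
  pres <- kmerPresence(seqs, 3, 4)
  # brute force for sequence 1, k = 3
  s1 <- substring(seqs[1], 1:6, 3:8)
  got <- pres[pres$seq == 1 & pres$k == 3, ]
  expect_setequal(vapply(got$code, tomoslam:::.decodeKmer, "", k = 3),
                  unique(s1))
  # masked letters never produce k-mers
  presN <- kmerPresence("ACNGT", 3, 3)
  expect_equal(nrow(presN), 0L)

  # Fisher one-sided p for (8/10 vs 2/10 containing): enumeration oracle
  pEnum <- enumHyperTail(8, 10, 20, 10)
  expect_equal(stats::phyper(7, 10, 10, 10, lower.tail = FALSE), pEnum,
               tolerance = 1e-12)
  expect_equal(round(pEnum, 5), 0.01151)
  # scoreKmers reproduces it on a constructed table: 10 pos + 10 bg,
  # motif "AAA" in 8 positives and 2 background sequences
  seqs2 <- c(rep("AAAC", 8), rep("CCCC", 2), rep("AAAC", 2), rep("GGGG", 8))
  pres2 <- kmerPresence(seqs2, 3, 3)
  sc <- scoreKmers(pres2, 1:10, 10, 10)
  pAAA <- sc$p[sc$code == 0]
  expect_equal(pAAA, pEnum, tolerance = 1e-12)

  # all tables with total <= 40: phyper tail equals enumeration
  for (nP in c(6, 12)) for (nB in c(8, 20)) for (m in c(3, 7)) {
    for (a in 0:min(m, nP)) {
      if (m - a > nB) next
      expect_equal(stats::phyper(a - 1, m, nP + nB - m, nP, lower.tail = FALSE),
                   enumHyperTail(a, m, nP + nB, nP), tolerance = 1e-10)
    }
  }
})

test_that("planted motifs are recovered and masked motifs never recur", {
  sim <- simulateUtrs(utrSimConfig(nPositive = 60, nBackground = 150,
                                   backgroundMeanLength = 300,
                                   lengthFold = 1, seed = 15))
  res <- kmerEnrichment(sim$positive, sim$background, maxRounds = 5)
  expect_gte(nrow(res), 1)
  expect_true(grepl("CAC", res$motif[1]))
  expect_lt(res$evalue[1], 0.5)
  expect_equal(anyDuplicated(res$motif), 0)

  # robust to position and 10% mutated plantings
  set.seed(33)
  mut <- as.character(sim$positive)
  idx <- sample(length(mut), round(0.1 * length(mut)))
  substr(mut[idx], 1, 1) <- "A"
  res2 <- kmerEnrichment(mut, sim$background, maxRounds = 2)
  expect_true(grepl("CAC", res2$motif[1]))

  expect_error(kmerEnrichment("ACGT", "ACGT", mink = 5, maxk = 3), "maxk")
})

test_that("label-shuffled sets yield no enriched motif", {
  sim <- simulateUtrs(utrSimConfig(nPositive = 60, nBackground = 150,
                                   backgroundMeanLength = 300,
                                   lengthFold = 1, seed = 16))
  seqs <- c(as.character(sim$positive), as.character(sim$background))
  pres <- kmerPresence(seqs, 3, 10)
  set.seed(10)
  hits <- 0
  for (i in 1:20) {
    idx <- sample(length(seqs), 60)
    sc <- scoreKmers(pres, idx, 60, length(seqs) - 60)
    if (min(sc$evalue) <= 0.5) hits <- hits + 1
  }
  expect_lte(hits, 1)
})
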