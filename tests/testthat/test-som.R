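# Small trace sets for map training: step traces at a given section.
stepTrace <- function(at, S) c(rep(0, at - 1), rep(1, S - at + 1))
rampTrace <- function(S) seq_len(S) / S

test_that("training is deterministic and converges on identical traces", {
  S <- 12
  X <- matrix(rep(stepTrace(7, S), 30), 30, S, byrow = TRUE,
              dimnames = list(paste0("g", 1:30), NULL))
  m1 <- trainSom(X, nNodes = 5, epochs = 20, seed = 4)
  m2 <- trainSom(X, nNodes = 5, epochs = 20, seed = 4)
  expect_identical(prototypes(m1), prototypes(m2))
  # fixed point: all prototypes converge to the single input trace
  dev <- max(abs(sweep(prototypes(m1), 2, stepTrace(7, S))))
  expect_lt(dev, 1e-3)
  expect_error(trainSom(X, nNodes = 50), "fewer genes")
})

test_that("well-separated archetypes occupy opposite map ends after ordering", {
  S <- 16
  set.seed(2)
  early <- t(replicate(40, pmin(1, stepTrace(2, S) + runif(S, 0, 0.02))))
  late <- t(replicate(40, c(rep(0, S - 2), 0.5, 1) + c(runif(S - 1, 0, 0.02), 0)))
  late <- t(apply(late, 1, function(z) pmin(cummax(z) / max(z), 1)))
  X <- rbind(early, late)
  rownames(X) <- paste0("g", seq_len(nrow(X)))
  som <- orderNodes(trainSom(X, nNodes = 10, epochs = 20, seed = 5))
  prof <- assignProfiles(som, X)
  expect_true(all(prof[1:40] <= 5))
  expect_true(all(prof[41:80] >= 6))
  cen <- nodeCentroids(som)
  expect_true(!is.unsorted(cen))
})

test_that("node ordering is idempotent and orients by library skew", {
  S <- 16
  set.seed(3)
  X <- t(replicate(60, cummax(runif(S))))
  X <- X / X[, S]
  rownames(X) <- paste0("g", 1:60)
  som <- trainSom(X, nNodes = 8, epochs = 10, seed = 1)
  o1 <- orderNodes(som)
  o2 <- orderNodes(o1)
  expect_identical(prototypes(o1), prototypes(o2))
  # centroid of a terminal-step prototype lands at the last node
  Xs <- rbind(X, step = stepTrace(S, S))
  soms <- orderNodes(trainSom(Xs, nNodes = 8, epochs = 10, seed = 1))
  expect_equal(unname(assignProfiles(soms, matrix(stepTrace(S, S), 1))), 8L)
  # animal-heavy totals at high sections flip the map
  totFwd <- c(rep(100, 8), rep(5, 8))
  totRev <- rev(totFwd)
  a <- orderNodes(som, sectionTotals = totFwd)
  b <- orderNodes(som, sectionTotals = totRev)
  expect_identical(prototypes(a), prototypes(b)[8:1, ])
})

test_that("profile assignment is exact, idempotent and checks lengths", {
  S <- 10
  X <- rbind(a = stepTrace(3, S), b = stepTrace(9, S), c = rampTrace(S))
  som <- orderNodes(trainSom(
    rbind(X, X, X, X)[rep(1:12, 2), ], nNodes = 3, epochs = 30, seed = 2))
  prof <- assignProfiles(som, X)
  # a gene whose trace equals a prototype maps to that node
  P <- prototypes(som)
  i <- unname(which.min(rowSums((P - rep(X["a", ], each = 3))^2)))
  expect_equal(unname(prof["a"]), i)
  expect_identical(assignProfiles(som, X), prof)
  expect_error(assignProfiles(som, X[, 1:5]), "length")
  # identical traces get identical profiles
  expect_equal(unname(assignProfiles(som, X[c("a", "a"), ])[1]),
               unname(prof["a"]))
})

test_that("localization calling implements the two-window replicate rule", {
  asg <- list(r1 = c(v = 49L, w = 47L, a = 3L, u = 20L),
              r2 = c(v = 47L, w = 47L, a = 8L, u = 30L),
              r3 = c(v = 46L, w = 47L, a = 1L, u = 50L))
  calls <- callLocalization(asg)
  cat1 <- setNames(as.character(calls$category), calls$gene_id)
  expect_equal(cat1[["v"]], "vegetal")      # 46-50 all, 49 >= 48 once
  expect_equal(cat1[["w"]], "unlocalized")  # never reaches 48
  expect_equal(cat1[["a"]], "animal")       # 1-8 in all replicates
  expect_equal(cat1[["u"]], "unlocalized")  # 50 only in one replicate

  # single replicate: profile 48 suffices
  one <- callLocalization(list(c(g = 48L)))
  expect_equal(as.character(one$category), "vegetal")

  # genes missing in a replicate are reported, not called
  asg2 <- list(r1 = c(g1 = 49L, g2 = 49L), r2 = c(g1 = 48L))
  c2 <- callLocalization(asg2)
  expect_equal(c2$gene_id, "g1")
  expect_equal(S4Vectors::metadata(c2)$uncallable, "g2")
})

test_that("call-set intersection respects universes and orthology", {
  callsA <- c("g1", "g2", "g3")
  callsB <- c("g2", "g3", "g4")
  uni <- list(A = paste0("g", 1:10), B = paste0("g", 1:10))
  iv <- intersectCalls(list(A = callsA, B = callsB), uni)
  expect_equal(sort(iv$genes[["11"]]), c("g2", "g3"))
  expect_equal(iv$universeSize, 10)

  # identical sets: everything in the full intersection
  iv2 <- intersectCalls(list(A = callsA, B = callsA), uni)
  expect_equal(sort(iv2$genes[["11"]]), sort(callsA))
  # disjoint sets: empty intersection region
  iv3 <- intersectCalls(list(A = c("g1"), B = c("g2")), uni)
  expect_null(iv3$genes[["11"]])

  # 1:1 orthology recovers a planted conserved subset exactly
  oB <- data.frame(b = paste0("x", 1:10), ref = paste0("g", 1:10))
  iv4 <- intersectCalls(
    list(A = c("g1", "g2", "g5"), B = c("x2", "x5", "x7")),
    list(A = paste0("g", 1:10), B = paste0("x", 1:10)),
    orthology = list(B = oB))
  expect_equal(sort(iv4$genes[["11"]]), c("g2", "g5"))
})

test_that("map topology is preserved: neighbors closer than distant nodes", {
  sim <- simulateTomoseq(tomoSimConfig(
    nSections = 48, nGenes = c(animal = 30, uniform = 240, vegetal = 30),
    nReplicates = 1, seed = 37))
  ts <- cumulativeTraces(normalizeSections(sim$replicates[[1]]))
  som <- orderNodes(trainSom(ts, nNodes = 30, epochs = 30, seed = 6))
  D <- as.matrix(dist(prototypes(som)))
  adj <- D[cbind(seq_len(29), 2:30)]
  far <- D[abs(row(D) - col(D)) >= 5]
  expect_lt(median(adj), median(far))
})
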