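# Small fixtures shared across test files; everything built in code.

tinySectionCounts <- function(counts = NULL, spikein = NULL) {
  if (is.null(counts))
    counts <- matrix(c(10, 20, 30,
                       0, 0, 6,
                       4, 4, 4), 3, 3, byrow = TRUE,
                     dimnames = list(c("gA", "gB", "gC"), NULL))
  if (is.null(spikein)) spikein <- rep(1000, ncol(counts))
  SectionCounts(counts, spikeinCounts = spikein)
}

tinyMismatch <- function() {
  rec <- S4Vectors::DataFrame(
    cell = c("AAAC", "AAAC", "AAAC", "AAAG"),
    umi = c("U1", "U1", "U2", "U3"),
    gene = c("dazl", "dazl", "dazl", "wnt8a"),
    sub = c("T>C", "T>C", "A>G", "T>C"),
    qual = c(37L, 15L, 40L, 30L),
    readId = c("r1", "r2", "r1", "r1"))
  mol <- S4Vectors::DataFrame(
    cell = c("AAAC", "AAAC", "AAAG", "AAAG"),
    umi = c("U1", "U2", "U3", "U4"),
    gene = c("dazl", "dazl", "wnt8a", "wnt8a"),
    reads = c(2L, 1L, 1L, 1L),
    coveredT = c(90L, 85L, 88L, 92L))
  MismatchRecords(rec, mol)
}

# Brute-force upper-tail hypergeometric: P(overlap >= x) by enumeration of
# all k-subsets "successes" counts via the hypergeometric pmf computed from
# choose() -- independent of phyper.
enumHyperTail <- function(x, K, N, n) {
  pm <- vapply(0:min(K, n), function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), 0)
  sum(pm[(0:min(K, n)) >= x])
}

# Exact two-sided rank-sum p by enumerating all assignments of ranks.
enumWilcoxTwoSided <- function(a, b) {
  v <- c(a, b)
  n <- length(v); na <- length(a)
  r <- rank(v)
  obs <- sum(r[seq_len(na)])
  combs <- utils::combn(n, na)
  stat <- apply(combs, 2, function(ii) sum(r[ii]))
  mu <- na * (n + 1) / 2
  mean(abs(stat - mu) >= abs(obs - mu) - 1e-9)
}

# Cached medium SLAM simulation shared by slam tests.
slamFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulateSlamReads(slamSimConfig(seed = 77))
    cache
  }
})
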