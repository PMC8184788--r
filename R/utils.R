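# Internal helpers shared across modules.

# data.table is used via :: but with native [.data.table semantics.
.datatable.aware <- TRUE

# Centroid (expected section position) of each cumulative-trace row.
# Increments d_s = c_s - c_{s-1} (c_0 = 0) are the per-section mass; for a
# valid trace they sum to 1 and the centroid is sum(s * d_s).
.traceCentroids <- function(cum) {
  cum <- as.matrix(cum)
  d <- cbind(cum[, 1, drop = FALSE],
             cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE])
  tot <- rowSums(d)
  cen <- as.vector(d %*% seq_len(ncol(cum)))
  ifelse(tot > 0, cen / tot, NA_real_)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stage-specific 31-bit seed from a global seed and a label.
.deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

.assertCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0)
    stop(name, " must be a single non-negative number")
  invisible(x)
}

.assertProb <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(name, " must be a probability in [0, 1]")
  invisible(x)
}
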