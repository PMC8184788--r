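#' Expression-weighted 3'UTR and CDS lengths per gene
#'
#' Each isoform contributes its 3'UTR (and CDS) length in proportion to its
#' share of the gene's total FPKM, so the weighted length is a convex
#' combination of isoform lengths. Genes whose FPKM sum falls below
#' `minFpkmGene` are flagged (`lowExpression`) for downstream comparisons;
#' genes with all-zero FPKM are excluded and reported.
#'
#' @param x Isoform table ([readIsoformTable()] layout).
#' @param minFpkmGene Per-gene FPKM-sum cutoff for the flag (default 10).
#' @return DataFrame with `gene_id`, `weightedUtr3`, `weightedCds`,
#'   `totalFpkm`, `nIsoforms`, `lowExpression`; excluded genes in
#'   `metadata()$excluded`.
#' @export
#' @examples
#' tab <- S4Vectors::DataFrame(isoform_id = c("i1", "i2"),
#'   gene_id = "g1", fpkm = c(3, 1), utr3_length = c(1000, 500),
#'   cds_length = c(2000, 1800))
#' weightedLengths(tab)$weightedUtr3   # 875
weightedLengths <- function(x, minFpkmGene = 10) {
  df <- as.data.frame(x)
  if (!nrow(df)) stop("empty isoform table")
  dt <- data.table::as.data.table(df)
  agg <- dt[, list(
    weightedUtr3 = if (sum(fpkm) > 0) sum(utr3_length * fpkm) / sum(fpkm) else NA_real_,
    weightedCds = if (sum(fpkm) > 0) sum(cds_length * fpkm) / sum(fpkm) else NA_real_,
    totalFpkm = sum(fpkm), nIsoforms = .N), by = "gene_id"]
  excluded <- agg$gene_id[agg$totalFpkm == 0]
  agg <- agg[agg$totalFpkm > 0, ]
  out <- DataFrame(gene_id = agg$gene_id, weightedUtr3 = agg$weightedUtr3,
                   weightedCds = agg$weightedCds, totalFpkm = agg$totalFpkm,
                   nIsoforms = agg$nIsoforms,
                   lowExpression = agg$totalFpkm < minFpkmGene)
  metadata(out) <- list(excluded = excluded, minFpkmGene = minFpkmGene)
  out
}

#' Select the longest annotated 3'UTR per gene
#'
#' Alternative to expression weighting for annotations without reliable
#' quantification: per gene, the single isoform with the longest 3'UTR.
#'
#' @param x Isoform table.
#' @return DataFrame with `gene_id`, `isoform_id`, `utr3_length`.
#' @export
longestUtrPerGene <- function(x) {
  dt <- data.table::as.data.table(as.data.frame(x))
  top <- dt[order(-utr3_length), .SD[1], by = "gene_id"]
  DataFrame(gene_id = top$gene_id, isoform_id = top$isoform_id,
            utr3_length = top$utr3_length)
}

#' Compare a focal value group against a background group
#'
#' Group means, their ratio, and a two-sided two-sample Wilcoxon (rank-sum)
#' p-value: exact for small tie-free samples (both n <= 50), normal
#' approximation with tie correction otherwise.
#'
#' @param focal,background Numeric vectors (each n >= 2).
#' @return List with `meanFocal`, `meanBackground`, `fold`, `p`.
#' @export
compareGroups <- function(focal, background) {
  if (length(focal) < 2 || length(background) < 2) stop("empty or tiny group")
  exact <- max(length(focal), length(background)) <= 50 &&
    !anyDuplicated(c(focal, background))
  ht <- suppressWarnings(
    stats::wilcox.test(focal, background, alternative = "two.sided",
                       exact = exact, correct = !exact))
  list(meanFocal = mean(focal), meanBackground = mean(background),
       fold = mean(focal) / mean(background), p = ht$p.value)
}

#' GC content of sequences
#'
#' Fraction of G + C among determined bases; `N`s are excluded from the
#' denominator, empty (or all-N) sequences are excluded and reported.
#'
#' @param x DNAStringSet or character vector over IUPAC letters.
#' @return List with `perSequence` (named numeric) and `group` (overall GC
#'   over all counted bases); excluded names in `attr(, "excluded")`.
#' @export
gcContent <- function(x) {
  x <- Biostrings::DNAStringSet(x)
  af <- Biostrings::letterFrequency(x, c("G", "C", "A", "T"))
  gc <- af[, "G"] + af[, "C"]
  tot <- rowSums(af)
  keep <- tot > 0
  per <- stats::setNames(gc[keep] / tot[keep],
                         if (is.null(names(x))) NULL else names(x)[keep])
  out <- list(perSequence = per, group = sum(gc[keep]) / sum(tot[keep]))
  attr(out, "excluded") <- if (is.null(names(x))) which(!keep) else names(x)[!keep]
  out
}

# --- k-mer machinery -------------------------------------------------------

# Encode a sequence as integer base codes (A=0 C=1 G=2 T=3, else NA).
.encodeSeq <- function(s) {
  v <- utf8ToInt(s)
  code <- rep(NA_integer_, length(v))
  code[v == 65L] <- 0L; code[v == 67L] <- 1L
  code[v == 71L] <- 2L; code[v == 84L] <- 3L
  code
}

# All k-mer integer codes of an encoded sequence (NA where any base is NA).
.kmerCodes <- function(enc, k) {
  n <- length(enc) - k + 1L
  if (n < 1L) return(integer(0))
  out <- as.numeric(enc[seq_len(n)])
  if (k > 1) for (j in 2:k) out <- out * 4 + enc[j:(j + n - 1L)]
  out[!is.na(out)]
}

.decodeKmer <- function(code, k) {
  b <- character(k)
  for (j in k:1) {
    b[j] <- c("A", "C", "G", "T")[code %% 4 + 1]
    code <- code %/% 4
  }
  paste(b, collapse = "")
}

#' Per-sequence k-mer presence table
#'
#' Enumerates, for every k in `[mink, maxk]`, the distinct k-mers present in
#' each sequence. This is the shared substrate of the discriminative
#' enrichment scan; exposing it lets callers rescore many label assignments
#' (e.g. label shuffles) without re-extracting k-mers.
#'
#' @param seqs Character vector or DNAStringSet (positions already masked
#'   with `N` are skipped).
#' @param mink,maxk Inclusive k-mer length range.
#' @return data.table with columns `seq` (integer index), `k`, `code`
#'   (integer k-mer code), one row per distinct (sequence, k-mer).
#' @export
kmerPresence <- function(seqs, mink = 3, maxk = 10) {
  seqs <- as.character(seqs)
  enc <- lapply(seqs, .encodeSeq)
  res <- vector("list", length(seqs) * (maxk - mink + 1))
  idx <- 0L
  for (i in seq_along(enc)) {
    for (k in mink:maxk) {
      codes <- unique(.kmerCodes(enc[[i]], k))
      idx <- idx + 1L
      if (length(codes))
        res[[idx]] <- data.table::data.table(seq = i, k = k, code = codes)
    }
  }
  data.table::rbindlist(res)
}

#' Score candidate k-mers for discriminative enrichment
#'
#' One-sided Fisher exact (hypergeometric tail) enrichment of every k-mer
#' present in at least one positive sequence, on sequence-level
#' presence/absence. Separated from [kmerEnrichment()] so that many label
#' assignments (e.g. label shuffles for a type-I check) can be rescored on
#' one [kmerPresence()] table.
#'
#' @param presence data.table from [kmerPresence()] over positives and
#'   background jointly.
#' @param posIdx Integer indices (into the presence table's `seq`) of the
#'   positive sequences.
#' @param nPos,nBg Set sizes.
#' @return data.table with `k`, `code`, `a` (positives containing), `m`
#'   (total containing), `p`, `evalue` (p x number of candidates).
#' @export
scoreKmers <- function(presence, posIdx, nPos, nBg) {
  tmp <- data.table::data.table(k = presence$k, code = presence$code,
                                isPos = presence$seq %in% posIdx)
  cnt <- tmp[, list(a = sum(isPos), m = .N), by = c("k", "code")]
  cnt <- cnt[cnt$a > 0, ]
  # P(X >= a), X ~ Hypergeom(containing = m, notContaining = N - m, draws = nPos)
  N <- nPos + nBg
  cnt$p <- stats::phyper(cnt$a - 1, cnt$m, N - cnt$m, nPos, lower.tail = FALSE)
  cnt$evalue <- cnt$p * nrow(cnt)
  cnt
}
.scoreKmers <- scoreKmers

#' Discriminative k-mer enrichment with iterative masking
#'
#' DREME-style discriminative motif discovery on two sequence sets: for each
#' k in `[mink, maxk]` every k-mer present in at least one positive sequence
#' is scored by a one-sided Fisher exact test on sequence-level
#' presence/absence (positives containing vs background containing), and the
#' p-value is Bonferroni-corrected into an E-value by the total number of
#' candidates tested across all k. The best motif is accepted if its E-value
#' is at most `maxEvalue`; its occurrences are then masked (replaced by `N`)
#' in both sets and the scan repeats, so an accepted motif cannot recur in a
#' later round. Only the given strand is considered (no reverse
#' complements), matching `-norc`; candidates are exact k-mers (no IUPAC
#' generalization).
#'
#' @param positive,background Character vectors or DNAStringSets (uppercase
#'   ACGT; other letters act as mask).
#' @param mink,maxk Candidate k-mer length range (defaults 3 and 10).
#' @param maxEvalue Acceptance threshold on the E-value (default 0.5).
#' @param maxRounds Maximum number of mask-and-rescan rounds (default 10).
#' @return data.frame of accepted motifs: `motif`, `posCount`, `bgCount`,
#'   `posFrac`, `bgFrac`, `p`, `evalue`, `rank`, `round`; zero rows when no
#'   motif passes. `attr(, "nCandidates")` records the candidate count of
#'   round 1.
#' @export
kmerEnrichment <- function(positive, background, mink = 3, maxk = 10,
                           maxEvalue = 0.5, maxRounds = 10) {
  if (maxk < mink) stop("config error: maxk < mink")
  pos <- toupper(as.character(positive))
  bg <- toupper(as.character(background))
  if (!length(pos) || !length(bg)) stop("both sequence sets must be non-empty")
  nPos <- length(pos); nBg <- length(bg)
  seqs <- c(pos, bg)
  posIdx <- seq_len(nPos)
  presence <- kmerPresence(seqs, mink, maxk)
  results <- list()
  nCand1 <- NA_integer_
  for (round in seq_len(maxRounds)) {
    cnt <- .scoreKmers(presence, posIdx, nPos, nBg)
    if (!nrow(cnt)) break
    nCand <- nrow(cnt)
    if (round == 1) nCand1 <- nCand
    cnt$evalue <- cnt$p * nCand
    best <- cnt[order(cnt$p, -cnt$a, cnt$k, cnt$code), ][1, ]
    if (best$evalue > maxEvalue) break
    motif <- .decodeKmer(best$code, best$k)
    hit <- grepl(motif, seqs, fixed = TRUE)
    bgHits <- sum(hit[-posIdx])
    results[[round]] <- data.frame(
      motif = motif, posCount = best$a, bgCount = bgHits,
      posFrac = best$a / nPos, bgFrac = bgHits / nBg,
      p = best$p, evalue = best$evalue, rank = round, round = round,
      stringsAsFactors = FALSE)
    # mask and re-extract only the sequences that changed
    seqs[hit] <- gsub(motif, strrep("N", best$k), seqs[hit], fixed = TRUE)
    presence <- presence[!presence$seq %in% which(hit), ]
    if (any(hit)) {
      upd <- kmerPresence(seqs[hit], mink, maxk)
      upd$seq <- which(hit)[upd$seq]
      presence <- data.table::rbindlist(list(presence, upd))
    }
  }
  out <- if (length(results)) do.call(rbind, results) else
    data.frame(motif = character(0), posCount = integer(0),
               bgCount = integer(0), posFrac = numeric(0),
               bgFrac = numeric(0), p = numeric(0), evalue = numeric(0),
               rank = integer(0), round = integer(0))
  attr(out, "nCandidates") <- nCand1
  out
}
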