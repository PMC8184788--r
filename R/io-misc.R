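#' Read a FASTA file of UTR sequences
#'
#' Standard multi-line FASTA via Biostrings; sequences are case-folded to
#' upper case and RNA `U` is normalized to `T`. Duplicate headers and
#' non-IUPAC characters are rejected.
#'
#' @param path Path to the FASTA file.
#' @return A [Biostrings::DNAStringSet].
#' @export
readUtrFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("format error: no FASTA headers in ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  if (anyDuplicated(ids)) stop("validation error: duplicate FASTA headers")
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(z) paste(z, collapse = ""), "")
  seqs <- chartr("u", "U", toupper(seqs))
  seqs <- chartr("U", "T", seqs)
  iupac <- "ACGTRYSWKMBDHVN"
  if (any(grepl(paste0("[^", iupac, "]"), seqs)))
    stop("validation error: non-IUPAC characters in sequences")
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' @rdname readUtrFasta
#' @param x Named character vector or DNAStringSet.
#' @param path Output path.
#' @export
writeUtrFasta <- function(x, path) {
  x <- as.character(x)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  writeLines(paste0(">", names(x), "\n", x), path)
  invisible(path)
}

#' Read / write localization call tables
#'
#' The calls TSV has columns `gene_id`, `category` and one
#' `profile_<replicate>` column per replicate (SOM node index, NA when the
#' gene was not detected in that replicate).
#'
#' @param path Path to the TSV.
#' @return DataFrame with `gene_id`, `category` and a `profiles` integer
#'   matrix column (one column per replicate).
#' @export
readCalls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  if (!all(c("gene_id", "category") %in% colnames(dt)))
    stop("format error: calls table must have gene_id and category columns")
  pcols <- grep("^profile_", colnames(dt), value = TRUE)
  prof <- as.matrix(dt[, pcols, with = FALSE])
  storage.mode(prof) <- "integer"
  colnames(prof) <- sub("^profile_", "", pcols)
  out <- DataFrame(gene_id = dt$gene_id,
                   category = factor(dt$category,
                                     levels = c("animal", "unlocalized", "vegetal")))
  out$profiles <- prof
  out
}

#' @rdname readCalls
#' @param calls DataFrame as produced by [callLocalization()].
#' @export
writeCalls <- function(calls, path) {
  prof <- calls$profiles
  df <- data.frame(gene_id = calls$gene_id,
                   category = as.character(calls$category),
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(prof)))
    df[[paste0("profile_", colnames(prof)[j])]] <- prof[, j]
  data.table::fwrite(df, path, sep = "\t", na = "NA")
  invisible(path)
}
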