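#' Read a SAM-lite mismatch table
#'
#' Reads per-read alignment mismatch evidence from a tab-separated file with
#' header columns `cell`, `umi`, `gene`, `sub`, `qual`, `read_id`, `reads`,
#' `covered_t`. Each mismatch event is one row; molecules whose reads carry
#' no mismatch at all appear as a single sentinel row with `sub = "*"` and
#' empty quality. `reads` (read count of the molecule) and `covered_t`
#' (number of T positions covered; may be NA) are constant within a
#' (cell, umi, gene) group.
#'
#' @param path Path to the TSV file.
#' @return A \linkS4class{MismatchRecords}; all evidence grouped by molecule.
#' @export
readMismatchTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = c("NA", ""))
  need <- c("cell", "umi", "gene", "sub", "qual", "read_id")
  if (!all(need %in% colnames(dt)))
    stop("format error: SAM-lite table must have columns ",
         paste(need, collapse = ", "))
  if (!"reads" %in% colnames(dt)) dt$reads <- 1L
  if (!"covered_t" %in% colnames(dt)) dt$covered_t <- NA_integer_
  bad <- setdiff(unique(dt$sub), c(.SUBS, "*"))
  if (length(bad))
    stop("validation error: unknown substitution code(s): ",
         paste(bad, collapse = ", "))
  is_rec <- dt$sub != "*"
  if (any(dt$qual[is_rec] < 0, na.rm = TRUE))
    stop("validation error: negative base quality")
  mol <- dt[!duplicated(paste(dt$cell, dt$umi, dt$gene, sep = "\r")), ]
  molecules <- DataFrame(cell = mol$cell, umi = mol$umi, gene = mol$gene,
                         reads = as.integer(mol$reads),
                         coveredT = as.integer(mol$covered_t))
  rec <- dt[is_rec, ]
  records <- DataFrame(cell = rec$cell, umi = rec$umi, gene = rec$gene,
                       sub = rec$sub, qual = as.integer(rec$qual),
                       readId = as.character(rec$read_id))
  MismatchRecords(records, molecules)
}

#' Write a MismatchRecords object as SAM-lite TSV
#'
#' Inverse of [readMismatchTable()]. Rows are ordered by (cell, umi, gene,
#' read id, substitution) so that write/read round-trips bit-identically.
#'
#' @param x A \linkS4class{MismatchRecords}.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMismatchTable <- function(x, path) {
  r <- as.data.frame(records(x))
  m <- as.data.frame(molecules(x))
  key <- paste(m$cell, m$umi, m$gene, sep = "\r")
  if (nrow(r)) {
    rkey <- paste(r$cell, r$umi, r$gene, sep = "\r")
    idx <- match(rkey, key)
    out_r <- data.frame(cell = r$cell, umi = r$umi, gene = r$gene,
                        sub = r$sub, qual = r$qual, read_id = r$readId,
                        reads = m$reads[idx], covered_t = m$coveredT[idx],
                        stringsAsFactors = FALSE)
  } else {
    out_r <- NULL
    rkey <- character(0)
  }
  lone <- !(key %in% rkey)
  if (any(lone)) {
    out_s <- data.frame(cell = m$cell[lone], umi = m$umi[lone],
                        gene = m$gene[lone], sub = "*", qual = NA_integer_,
                        read_id = "*", reads = m$reads[lone],
                        covered_t = m$coveredT[lone], stringsAsFactors = FALSE)
    out_r <- rbind(out_r, out_s)
  }
  ord <- order(out_r$cell, out_r$umi, out_r$gene, out_r$read_id, out_r$sub)
  data.table::fwrite(out_r[ord, ], path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read a cell-type label table
#'
#' TSV with header columns `cell`, `cell_type`.
#'
#' @param path Path to the TSV.
#' @return Named factor of cell types, names = cell barcodes.
#' @export
readCellTypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("cell", "cell_type") %in% colnames(dt)))
    stop("format error: cell-type table must have columns cell, cell_type")
  stats::setNames(factor(dt$cell_type), dt$cell)
}

#' @rdname readCellTypes
#' @param cellTypes Named factor/character of cell types.
#' @export
writeCellTypes <- function(cellTypes, path) {
  data.table::fwrite(data.frame(cell = names(cellTypes),
                                cell_type = as.character(cellTypes)),
                     path, sep = "\t")
  invisible(path)
}
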