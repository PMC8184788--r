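#' Read a gene x section count matrix
#'
#' Reads a serial-section count matrix from TSV (first column = gene id,
#' remaining columns = sections in animal-to-vegetal order) or MatrixMarket
#' format (`<path>.mtx` with sidecar files `<stem>.genes.tsv` and
#' `<stem>.sections.tsv`, one id per line). Rows whose id starts with
#' `spikeinPrefix` are separated out and summed into the per-section spike-in
#' vector.
#'
#' @param path Path to the TSV file or the `.mtx` file.
#' @param format `"tsv"` or `"mtx"`; guessed from the file extension by
#'   default.
#' @param spikeinPrefix Gene-id prefix identifying spike-in rows
#'   (default `"ERCC-"`).
#' @param replicate,species Optional metadata labels.
#' @return A \linkS4class{SectionCounts}.
#' @export
readSectionMatrix <- function(path, format = c("auto", "tsv", "mtx"),
                              spikeinPrefix = "ERCC-",
                              replicate = NA_character_,
                              species = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "tsv") {
    if (file.size(path) == 0) stop("format error: empty file: ", path)
    dt <- data.table::fread(path, sep = "\t", header = TRUE,
                            colClasses = list(character = 1))
    if (nrow(dt) == 0 || ncol(dt) < 2)
      stop("format error: no counts in ", path)
    ids <- dt[[1]]
    m <- as.matrix(dt[, -1])
    if (!is.numeric(m)) stop("format error: non-numeric counts in ", path)
    rownames(m) <- ids
  } else {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    gf <- paste0(stem, ".genes.tsv")
    sf <- paste0(stem, ".sections.tsv")
    if (!file.exists(gf)) stop("missing sidecar: ", gf)
    if (!file.exists(sf)) stop("missing sidecar: ", sf)
    rownames(m) <- readLines(gf)
    sections <- as.integer(readLines(sf))
    if (length(sections) != ncol(m))
      stop("format error: section sidecar length != matrix columns")
  }
  if (any(is.na(m))) stop("format error: missing counts")
  if (any(m < 0)) stop("validation error: negative counts")
  if (any(abs(m - round(m)) > 1e-8)) stop("format error: non-integer counts")
  if (anyDuplicated(rownames(m)))
    stop("validation error: duplicate gene ids")
  spike <- startsWith(rownames(m), spikeinPrefix)
  sp <- if (any(spike)) colSums(m[spike, , drop = FALSE]) else rep(0, ncol(m))
  sections <- if (format == "mtx") sections else seq_len(ncol(m))
  SectionCounts(m[!spike, , drop = FALSE], spikeinCounts = sp,
                sectionIndex = sections, replicate = replicate,
                species = species)
}

#' Write a SectionCounts object
#'
#' Inverse of [readSectionMatrix()]; spike-in counts are written back as a
#' single pseudo-row `<spikeinPrefix>total` so that read/write round-trips.
#'
#' @param x A \linkS4class{SectionCounts}.
#' @param path Output path (TSV, or `.mtx` for MatrixMarket).
#' @param format `"tsv"` or `"mtx"`.
#' @param spikeinPrefix Prefix used for the spike-in pseudo-row.
#' @return `path`, invisibly.
#' @export
writeSectionMatrix <- function(x, path, format = c("auto", "tsv", "mtx"),
                               spikeinPrefix = "ERCC-") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  m <- rbind(counts(x),
             matrix(spikeinCounts(x), 1,
                    dimnames = list(paste0(spikeinPrefix, "total"), NULL)))
  if (format == "tsv") {
    dt <- data.table::data.table(gene_id = rownames(m))
    for (j in seq_len(ncol(m)))
      dt[[paste0("section_", sectionIndex(x)[j])]] <- m[, j]
    data.table::fwrite(dt, path, sep = "\t")
  } else {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(m), paste0(stem, ".genes.tsv"))
    writeLines(as.character(sectionIndex(x)), paste0(stem, ".sections.tsv"))
  }
  invisible(path)
}

#' Read an isoform expression table
#'
#' TSV with header columns `isoform_id`, `gene_id`, `fpkm`, `utr3_length`,
#' `cds_length`.
#'
#' @param path Path to the TSV.
#' @return A [S4Vectors::DataFrame] with validated columns.
#' @export
readIsoformTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("isoform_id", "gene_id", "fpkm", "utr3_length", "cds_length")
  if (!all(need %in% colnames(dt)))
    stop("format error: isoform table must have columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(dt$isoform_id))
    stop("validation error: duplicate isoform ids")
  if (any(dt$fpkm < 0)) stop("validation error: negative FPKM")
  if (any(dt$utr3_length < 0) || any(dt$cds_length < 0))
    stop("validation error: negative lengths")
  DataFrame(isoform_id = dt$isoform_id, gene_id = dt$gene_id,
            fpkm = as.numeric(dt$fpkm),
            utr3_length = as.numeric(dt$utr3_length),
            cds_length = as.numeric(dt$cds_length))
}

#' @rdname readIsoformTable
#' @param x Isoform table (DataFrame or data.frame).
#' @param path Output path.
#' @export
writeIsoformTable <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t")
  invisible(path)
}

#' Read an orthology map
#'
#' Two-column TSV (header `gene_a`, `gene_b`) pairing gene ids of two
#' species. May be many-to-many; self-pairs are rejected.
#'
#' @param path Path to the TSV.
#' @return DataFrame with columns `gene_a`, `gene_b`.
#' @export
readOrthologyMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (ncol(dt) < 2) stop("format error: orthology map needs two columns")
  a <- as.character(dt[[1]]); b <- as.character(dt[[2]])
  if (any(a == b)) stop("validation error: self-pairs in orthology map")
  DataFrame(gene_a = a, gene_b = b)
}
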