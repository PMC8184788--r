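#' @import methods
#' @importFrom BiocGenerics counts
NULL

#' Section index of a serial-section experiment
#'
#' Original (1-based, animal-to-vegetal) indices of the sections held by an
#' object. After section QC these are the retained original indices, not a
#' renumbering.
#'
#' @param x A \linkS4class{SectionCounts} or \linkS4class{TraceSet}.
#' @return Integer vector, strictly increasing.
#' @export
setGeneric("sectionIndex", function(x) standardGeneric("sectionIndex"))

#' Spike-in counts per section
#'
#' @param x A \linkS4class{SectionCounts}.
#' @return Numeric vector, one entry per retained section.
#' @export
setGeneric("spikeinCounts", function(x) standardGeneric("spikeinCounts"))

#' Gene identifiers
#'
#' @param x An object holding per-gene data.
#' @return Character vector of gene ids.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Extract a trace matrix from a TraceSet
#'
#' @param x A \linkS4class{TraceSet}.
#' @param type `"normalized"` (per-section normalized expression) or
#'   `"cumulative"` (running animal-to-vegetal sum scaled to end at 1).
#' @return Numeric matrix genes x retained sections.
#' @export
setGeneric("traceMatrix", function(x, type = c("cumulative", "normalized"))
  standardGeneric("traceMatrix"))

#' Prototype matrix of a self-organizing map
#'
#' @param x A \linkS4class{SomModel}.
#' @return Numeric matrix nodes x sections; each row is a cumulative-trace
#'   prototype.
#' @export
setGeneric("prototypes", function(x) standardGeneric("prototypes"))

#' Per-mismatch records of an alignment-evidence table
#'
#' @param x A \linkS4class{MismatchRecords}.
#' @return A [S4Vectors::DataFrame] with one row per mismatch event.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' Per-molecule table of an alignment-evidence table
#'
#' One row per (cell, UMI, gene) molecule with its read count and the number
#' of covered T positions.
#'
#' @param x A \linkS4class{MismatchRecords}.
#' @return A [S4Vectors::DataFrame].
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))
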