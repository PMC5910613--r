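#' @import methods
#' @importFrom IRanges IRanges
NULL

#' Rooted taxonomy
#'
#' An S4 container for a rooted taxonomy such as the NCBI taxonomy: a set of
#' nodes with parent links, rank labels and scientific names. The root is the
#' unique node whose parent is itself. Ranks are carried as free-text labels
#' only; none of the binning algorithms hard-code rank logic.
#'
#' Construct with [readTaxonomy()] or [Taxonomy()].
#'
#' @slot taxid integer vector of node identifiers (unique).
#' @slot parent integer vector, parent identifier of each node; the root's
#'   parent is itself.
#' @slot rank character vector of rank labels ("species", "genus", ...).
#' @slot name character vector of scientific names.
#' @slot root integer scalar, the root's identifier.
#' @slot depth integer vector, number of edges from the root (root = 0).
#'
#' @aliases Taxonomy-class
#' @exportClass Taxonomy
setClass("Taxonomy",
  representation(
    taxid = "integer",
    parent = "integer",
    rank = "character",
    name = "character",
    root = "integer",
    depth = "integer"
  )
)

setValidity("Taxonomy", function(object) {
  n <- length(object@taxid)
  if (n == 0L) return("taxonomy has no nodes")
  if (anyDuplicated(object@taxid)) {
    dup <- object@taxid[duplicated(object@taxid)][1L]
    return(sprintf("malformed taxonomy: duplicate taxon id %d", dup))
  }
  if (length(object@parent) != n || length(object@rank) != n ||
      length(object@name) != n || length(object@depth) != n) {
    return("slot lengths disagree")
  }
  pidx <- match(object@parent, object@taxid)
  if (anyNA(pidx)) {
    bad <- object@taxid[is.na(pidx)][1L]
    return(sprintf("malformed taxonomy: node %d has dangling parent id", bad))
  }
  roots <- object@taxid[object@taxid == object@parent]
  if (length(roots) != 1L) {
    return(sprintf("malformed taxonomy: found %d self-parent roots, need exactly 1",
                   length(roots)))
  }
  if (roots != object@root) return("root slot does not match the self-parent node")
  # cycle check: every node must reach the root
  if (anyNA(object@depth)) {
    bad <- object@taxid[is.na(object@depth)][1L]
    return(sprintf("malformed taxonomy: cycle involving taxon id %d", bad))
  }
  TRUE
})

#' Per-read DNA-to-protein alignments
#'
#' An S4 container holding one row per alignment, localized on forward-strand
#' read coordinates (0-based, half-open), plus per-read metadata (read length,
#' optional contig read count). Alignments are grouped by read in first-seen
#' read order; within a read, input order is preserved.
#'
#' Construct with [collateReads()] (from a parsed alignment table), or via
#' [readAlignmentsTSV()] / [readMAF()] followed by [collateReads()].
#'
#' @slot aln data.frame with columns `read_id`, `start`, `end`, `strand`
#'   ("+"/"-"), `bit_score`, `raw_score`, `ref_acc`, `frame_shifts`,
#'   `taxon_id` (NA until annotated), and list-column `classes` (per-alignment
#'   named list: namespace -> character vector of class ids).
#' @slot reads data.frame with columns `read_id`, `read_length`,
#'   `contig_reads` (NA unless supplied), one row per read in first-seen order.
#'
#' @aliases ReadAlignments-class
#' @exportClass ReadAlignments
setClass("ReadAlignments",
  representation(aln = "data.frame", reads = "data.frame")
)

setValidity("ReadAlignments", function(object) {
  a <- object@aln
  r <- object@reads
  need <- c("read_id", "start", "end", "strand", "bit_score", "raw_score",
            "ref_acc", "frame_shifts", "taxon_id", "classes")
  if (!all(need %in% names(a))) {
    return(sprintf("alignment table lacks column(s): %s",
                   paste(setdiff(need, names(a)), collapse = ", ")))
  }
  if (!all(c("read_id", "read_length", "contig_reads") %in% names(r))) {
    return("read table lacks read_id/read_length/contig_reads")
  }
  if (anyDuplicated(r$read_id)) return("duplicate read_id in read table")
  if (nrow(a)) {
    if (!all(a$read_id %in% r$read_id)) return("alignment read_id missing from read table")
    len <- r$read_length[match(a$read_id, r$read_id)]
    if (any(a$start < 0L)) return("alignment start < 0")
    if (any(a$start >= a$end)) return("alignment with start >= end (empty interval)")
    if (any(a$end > len)) return("alignment end exceeds read length")
    if (!all(a$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
    if (any(!is.finite(a$bit_score))) return("non-finite bit score")
  }
  TRUE
})

#' Binning parameters
#'
#' All user-tunable parameters of the binning pipeline, with their standard
#' defaults. Percent-valued slots are on the 0-100 scale.
#'
#' @slot topPercent significant-score band: an alignment is significant on an
#'   interval if its bit score is within this percent of the best bit score on
#'   that interval. Default 10.
#' @slot percentToCover fraction of the read's covered portion a node's
#'   interval union must reach to qualify for assignment. Default 80.
#' @slot minSupport minimum percent of total assigned weight a taxon needs to
#'   be reported; deficits are pushed up to ancestors. Default 0.05.
#' @slot weightMode one of `"read_count"`, `"total_length"`, `"aligned_bases"`,
#'   `"contig_reads"`. Default `"aligned_bases"`.
#' @slot minPercentCoverToDominate overlap threshold (strict, percent of the
#'   dominated alignment) for functional dominance. Default 50.
#' @slot minPercentCoverToStronglyDominate overlap threshold (percent of the
#'   dominated alignment, inclusive) for strong domination. Default 90.
#' @slot topPercentScoreToStronglyDominate score factor for strong domination:
#'   a dominates b requires (factor/100)*score(a) > score(b). Default 90.
#' @slot strongSameStrand logical; require same strand for strong domination
#'   (off by default: the standard definition is strand-blind).
#'
#' @aliases BinningParams-class
#' @exportClass BinningParams
setClass("BinningParams",
  representation(
    topPercent = "numeric",
    percentToCover = "numeric",
    minSupport = "numeric",
    weightMode = "character",
    minPercentCoverToDominate = "numeric",
    minPercentCoverToStronglyDominate = "numeric",
    topPercentScoreToStronglyDominate = "numeric",
    strongSameStrand = "logical"
  )
)

setValidity("BinningParams", function(object) {
  pc <- function(x) length(x) == 1L && is.finite(x)
  if (!pc(object@topPercent) || object@topPercent < 0 || object@topPercent > 100)
    return("topPercent must be in [0, 100]")
  if (!pc(object@percentToCover) || object@percentToCover < 0 ||
      object@percentToCover > 100)
    return("percentToCover must be in [0, 100]")
  if (!pc(object@minSupport) || object@minSupport < 0 || object@minSupport > 100)
    return("minSupport must be in [0, 100]")
  if (!object@weightMode %in% c("read_count", "total_length", "aligned_bases",
                                "contig_reads"))
    return("unknown weightMode")
  for (s in c("minPercentCoverToDominate", "minPercentCoverToStronglyDominate",
              "topPercentScoreToStronglyDominate")) {
    v <- slot(object, s)
    if (!pc(v) || v <= 0 || v > 100) return(sprintf("%s must be in (0, 100]", s))
  }
  TRUE
})

#' Accumulated per-taxon weights
#'
#' Weights (reads, bases, ...) accumulated per taxon over a dataset, plus the
#' assigned-weight total and the weight of unassigned reads. `total` covers
#' assigned weight only, so minimum-support thresholds depend only on what was
#' actually binned.
#'
#' @slot weights named numeric vector, names are taxon ids.
#' @slot total numeric scalar, sum of `weights`.
#' @slot unassigned numeric scalar, weight of unassigned reads.
#' @slot mode the weight mode the values are measured in.
#'
#' @aliases NodeWeights-class
#' @exportClass NodeWeights
setClass("NodeWeights",
  representation(weights = "numeric", total = "numeric",
                 unassigned = "numeric", mode = "character")
)

setValidity("NodeWeights", function(object) {
  if (length(object@weights) && is.null(names(object@weights)))
    return("weights must be named by taxon id")
  if (any(object@weights < 0)) return("negative weight")
  if (abs(sum(object@weights) - object@total) > 1e-6 * max(1, object@total))
    return("total does not equal the sum of weights")
  TRUE
})

#' Accession-to-taxon and accession-to-class mapping tables
#'
#' @slot taxonMap named integer vector: reference accession -> taxon id.
#' @slot classMaps named list: classification namespace -> (named list:
#'   accession -> character vector of class ids).
#'
#' @aliases MappingTable-class
#' @exportClass MappingTable
setClass("MappingTable",
  representation(taxonMap = "integer", classMaps = "list")
)

setMethod("show", "Taxonomy", function(object) {
  cat(sprintf("Taxonomy with %d nodes (root id %d, max depth %d)\n",
              length(object@taxid), object@root, max(object@depth)))
  rk <- table(object@rank)
  cat("  ranks:", paste(sprintf("%s (%d)", names(rk), rk), collapse = ", "), "\n")
})

setMethod("show", "ReadAlignments", function(object) {
  cat(sprintf("ReadAlignments: %d alignments on %d reads\n",
              nrow(object@aln), nrow(object@reads)))
  if (nrow(object@aln)) {
    cat(sprintf("  taxon-mapped: %d; annotated namespaces: %s\n",
                sum(!is.na(object@aln$taxon_id)),
                paste(unique(unlist(lapply(object@aln$classes, names))),
                      collapse = ", ")))
  }
})

setMethod("show", "BinningParams", function(object) {
  cat("BinningParams:\n")
  cat(sprintf("  topPercent=%g percentToCover=%g minSupport=%g weightMode=%s\n",
              object@topPercent, object@percentToCover, object@minSupport,
              object@weightMode))
  cat(sprintf("  dominate>%g%%; strong: cover>=%g%% score %g%% sameStrand=%s\n",
              object@minPercentCoverToDominate,
              object@minPercentCoverToStronglyDominate,
              object@topPercentScoreToStronglyDominate,
              object@strongSameStrand))
})

setMethod("show", "NodeWeights", function(object) {
  cat(sprintf("NodeWeights (%s): %d taxa, total %g assigned, %g unassigned\n",
              object@mode, length(object@weights), object@total,
              object@unassigned))
})

setMethod("show", "MappingTable", function(object) {
  cat(sprintf("MappingTable: %d accession->taxon entries; namespaces: %s\n",
              length(object@taxonMap),
              if (length(object@classMaps)) paste(names(object@classMaps),
                                                  collapse = ", ") else "(none)"))
})
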