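# Taxonomic binning of long reads from protein alignments.
#
# The interval-union LCA algorithm: cut the read at every alignment boundary
# into atomic pieces; on each piece, alignments within topPercent of the local
# best bit score are significant; each mapped taxon t gets the interval set
# I(t) of pieces carrying a significant alignment to t; interval sets are
# propagated to ancestors by union (post-order). The read is placed on the
# lowest node whose interval set covers percentToCover of the read's covered
# portion while no child's does; when several nodes qualify the read goes to
# their LCA.

# Per-read interval-set computation shared by assignment and coverage.
# Returns NULL when the read has no alignments.
.nodeIntervalSets <- function(aln, tree, params) {
  if (!nrow(aln)) return(NULL)
  pieces <- buildPartition(aln$start, aln$end)
  width <- pieces$end - pieces$start
  # per-piece significant taxa
  pieceTaxa <- lapply(seq_len(nrow(pieces)), function(i) {
    sig <- significantOnPiece(aln, pieces$start[i], pieces$end[i],
                              params@topPercent)
    unique(aln$taxon_id[sig][!is.na(aln$taxon_id[sig])])
  })
  D <- intervalMeasure(aln$start, aln$end)
  taxa <- unique(unlist(pieceTaxa))
  if (!length(taxa)) {
    return(list(pieces = pieces, width = width, D = D,
                nodes = integer(0), measures = numeric(0),
                pieceSets = list()))
  }
  # piece-index sets per leaf taxon, then union onto every ancestor
  pieceSets <- list()
  for (t in taxa) {
    idx <- which(vapply(pieceTaxa, function(s) t %in% s, NA))
    for (node in rootPath(tree, t)) {
      key <- as.character(node)
      pieceSets[[key]] <- union(pieceSets[[key]], idx)
    }
  }
  nodes <- as.integer(names(pieceSets))
  measures <- vapply(pieceSets, function(s) sum(width[s]), 0)
  names(measures) <- names(pieceSets)
  list(pieces = pieces, width = width, D = D, nodes = nodes,
       measures = measures, pieceSets = pieceSets)
}

#' Interval-union LCA assignment of one read
#'
#' Places a read on the lowest taxonomy node whose significantly-aligned
#' interval union covers at least `percentToCover` of the read's covered
#' portion (the union of ALL alignment intervals, including alignments with
#' unmapped accessions) while no child of the node does. If several nodes
#' qualify the read is assigned to their LCA; a read with no taxon-mapped
#' alignment is unassigned.
#'
#' @param aln alignment data.frame for a single read (columns `start`, `end`,
#'   `bit_score`, `taxon_id`), typically one group of
#'   `alignments(x)` after [attachAnnotations()] and
#'   [filterStronglyDominated()].
#' @param tree a [Taxonomy-class].
#' @param params a [BinningParams-class].
#' @return list with `taxon_id` (NA when unassigned), `qualifying` (integer
#'   vector of qualifying node ids, diagnostic) and `covered` (measure of the
#'   read's covered portion in bases).
#' @examples
#' fx <- makeFig1Fixture()
#' intervalUnionAssign(alignments(fx$reads), fx$taxonomy)$taxon_id
#' @export
intervalUnionAssign <- function(aln, tree, params = binningParams()) {
  st <- .nodeIntervalSets(aln, tree, params)
  if (is.null(st) || !length(st$nodes) || st$D == 0) {
    return(list(taxon_id = NA_integer_, qualifying = integer(0),
                covered = if (is.null(st)) 0 else st$D))
  }
  thr <- (params@percentToCover / 100) * st$D
  # nodes reaching the coverage threshold; I(s) contains every child's I(c),
  # so this set is ancestor-closed and the qualifying nodes (threshold reached
  # while no child reaches it) are exactly its minimal elements
  covSet <- st$nodes[st$measures >= thr & st$measures > 0]
  qualifying <- setdiff(covSet,
                        taxonParents(tree, setdiff(covSet, rootId(tree))))
  tax <- if (!length(qualifying)) NA_integer_ else
    if (length(qualifying) == 1L) qualifying else lca(tree, qualifying)
  list(taxon_id = as.integer(tax), qualifying = sort(qualifying),
       covered = st$D)
}

#' Coverage percent of a taxon on one read
#'
#' Percent of the read's covered portion spanned by the node's interval union
#' `I(taxon)`; 0 when the taxon has no significant pieces.
#'
#' @inheritParams intervalUnionAssign
#' @param taxonId a single taxon id (must exist in `tree`).
#' @return Numeric percent in \[0, 100\].
#' @examples
#' fx <- makeFig1Fixture()
#' coverageOfTaxon(alignments(fx$reads), fx$taxonomy, fx$ids[["P"]])  # 100
#' @export
coverageOfTaxon <- function(aln, tree, taxonId, params = binningParams()) {
  .taxIndex(tree, taxonId)
  st <- .nodeIntervalSets(aln, tree, params)
  if (is.null(st) || st$D == 0) return(0)
  m <- st$measures[as.character(as.integer(taxonId))]
  if (is.na(m)) return(0)
  100 * unname(m) / st$D
}

#' Naive LCA assignment of one read
#'
#' The short-read baseline: alignments whose bit score lies within
#' `topPercent` of the read's best bit score are significant, and the read is
#' assigned to the LCA of their mapped taxa (NA when none is mapped).
#'
#' @inheritParams intervalUnionAssign
#' @return list with `taxon_id` and `significant` (row indices).
#' @export
naiveLCAAssign <- function(aln, tree, params = binningParams()) {
  if (!nrow(aln)) return(list(taxon_id = NA_integer_, significant = integer(0)))
  best <- max(aln$bit_score)
  sig <- which(aln$bit_score >= (1 - params@topPercent / 100) * best)
  taxa <- unique(aln$taxon_id[sig][!is.na(aln$taxon_id[sig])])
  tax <- if (length(taxa)) lca(tree, taxa) else NA_integer_
  list(taxon_id = as.integer(tax), significant = sig)
}

#' Weight of one read under a reporting mode
#'
#' `read_count` counts 1 per read; `total_length` the read length;
#' `aligned_bases` the measure of the union of all alignment intervals (the
#' default, which down-weights long unaligned stretches); `contig_reads` the
#' number of reads contained in the assigned contig.
#'
#' @param aln alignment data.frame for a single read.
#' @param readLength the read's length in bp.
#' @param mode one of the four weight modes.
#' @param contigReads number of reads in the contig (required for mode
#'   `contig_reads`).
#' @return Numeric weight.
#' @export
readWeight <- function(aln, readLength,
                       mode = c("aligned_bases", "read_count", "total_length",
                                "contig_reads"),
                       contigReads = NA_integer_) {
  mode <- match.arg(mode)
  switch(mode,
    read_count = 1,
    total_length = as.numeric(readLength),
    aligned_bases = intervalMeasure(aln$start, aln$end),
    contig_reads = {
      if (is.na(contigReads)) {
        stop("weight mode 'contig_reads' requires per-contig read counts")
      }
      as.numeric(contigReads)
    })
}

#' Bin a whole dataset
#'
#' Applies the strong-domination filter, assigns every read with the
#' interval-union LCA algorithm (or the naive baseline), and accumulates
#' per-taxon weights in the requested weight mode. Unassigned weight is
#' tracked separately and excluded from the assigned total, so that
#' minimum-support thresholds depend only on assigned weight.
#'
#' @param x a [ReadAlignments-class] with annotations attached.
#' @param tree a [Taxonomy-class].
#' @param params a [BinningParams-class].
#' @param method `"interval_union"` (default) or `"naive"`.
#' @param strongFilter apply [filterStronglyDominated()] first (default TRUE).
#' @return list with `assignments` (data.frame `read_id`, `taxon_id`,
#'   `weight`, list-column `qualifying`) and `weights` (a
#'   [NodeWeights-class]).
#' @examples
#' fx <- makeFig1Fixture()
#' res <- binDataset(fx$reads, fx$taxonomy)
#' res$assignments$taxon_id
#' @export
binDataset <- function(x, tree, params = binningParams(),
                       method = c("interval_union", "naive"),
                       strongFilter = TRUE) {
  method <- match.arg(method)
  stopifnot(is(x, "ReadAlignments"), is(tree, "Taxonomy"))
  if (strongFilter) x <- filterStronglyDominated(x, params)
  ids <- x@reads$read_id
  a <- x@aln
  groups <- split(seq_len(nrow(a)), factor(a$read_id, levels = ids))
  taxon <- integer(length(ids))
  weight <- numeric(length(ids))
  qual <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    ak <- a[groups[[k]], , drop = FALSE]
    res <- if (method == "interval_union") {
      intervalUnionAssign(ak, tree, params)
    } else {
      c(naiveLCAAssign(ak, tree, params), list(qualifying = integer(0)))
    }
    taxon[k] <- res$taxon_id
    qual[[k]] <- res$qualifying
    weight[k] <- readWeight(ak, x@reads$read_length[k], params@weightMode,
                            x@reads$contig_reads[k])
  }
  assignments <- data.frame(read_id = ids, taxon_id = taxon, weight = weight,
                            stringsAsFactors = FALSE)
  assignments$qualifying <- qual
  assigned <- !is.na(taxon)
  w <- tapply(weight[assigned], as.character(taxon[assigned]), sum)
  weights <- new("NodeWeights",
                 weights = if (length(w)) structure(as.numeric(w),
                                                    names = names(w))
                           else structure(numeric(0), names = character(0)),
                 total = sum(weight[assigned]),
                 unassigned = sum(weight[!assigned]),
                 mode = params@weightMode)
  list(assignments = assignments, weights = weights)
}

#' NodeWeights accessors
#'
#' @param x a [NodeWeights-class].
#' @name nodeweights-accessors
NULL

#' @rdname nodeweights-accessors
#' @export
nodeWeights <- function(x) x@weights

#' @rdname nodeweights-accessors
#' @export
totalWeight <- function(x) x@total

#' @rdname nodeweights-accessors
#' @export
unassignedWeight <- function(x) x@unassigned

#' Minimum-support push-up
#'
#' A taxon is only reported when it obtains at least `minSupport` percent of
#' the total assigned weight. Nodes are processed leaves-first: a node whose
#' accumulated weight (its own plus anything pushed into it) falls below the
#' threshold transfers its entire weight to its parent and reports zero; a
#' parent is re-tested after receiving pushed weight. The root retains any
#' residual weight, so the total is conserved exactly.
#'
#' @param weights a [NodeWeights-class] from [binDataset()].
#' @param tree a [Taxonomy-class].
#' @param params a [BinningParams-class] (uses `minSupport`).
#' @return A [NodeWeights-class] with adjusted weights (zero-weight taxa
#'   dropped).
#' @export
applyMinSupport <- function(weights, tree, params = binningParams()) {
  stopifnot(is(weights, "NodeWeights"), is(tree, "Taxonomy"))
  thr <- (params@minSupport / 100) * weights@total
  w <- structure(numeric(length(tree@taxid)), names = as.character(tree@taxid))
  w[names(weights@weights)] <- weights@weights
  ord <- order(tree@depth, decreasing = TRUE)  # deepest first
  for (i in ord) {
    id <- as.character(tree@taxid[i])
    if (tree@taxid[i] == tree@root) next
    if (w[[id]] > 0 && w[[id]] < thr) {
      pid <- as.character(tree@parent[i])
      w[[pid]] <- w[[pid]] + w[[id]]
      w[[id]] <- 0
    }
  }
  w <- w[w > 0]
  new("NodeWeights", weights = w, total = weights@total,
      unassigned = weights@unassigned, mode = weights@mode)
}

#' Sensitivity and precision of taxonomic assignments
#'
#' Sensitivity is the percentage of all reads assigned either to the correct
#' taxon or to one of its descendants. Precision is the percentage of reads
#' assigned correctly (same clause) out of all reads binned to any node that
#' is not a strict ancestor of the correct taxon. Unassigned reads count in
#' neither numerator nor the precision denominator; precision is `NA` when
#' its denominator is zero.
#'
#' @param assignments data.frame with `read_id` and `taxon_id` (NA =
#'   unassigned), as returned by [binDataset()].
#' @param truth named vector: read_id -> true taxon id; every assigned read
#'   must appear.
#' @param tree a [Taxonomy-class].
#' @return list with `sensitivity` and `precision` (percents), plus counts
#'   `n_reads`, `n_correct`, `n_considered`.
#' @export
evaluateAssignments <- function(assignments, truth, tree) {
  miss <- setdiff(assignments$read_id, names(truth))
  if (length(miss)) {
    stop(sprintf("read '%s' missing from the truth map", miss[1L]))
  }
  tr <- as.integer(truth[assignments$read_id])
  as_ <- assignments$taxon_id
  assigned <- !is.na(as_)
  correct <- assigned
  correct[assigned] <- isAncestorOrSelf(tree, tr[assigned], as_[assigned])
  strictAnc <- assigned
  strictAnc[assigned] <- as_[assigned] != tr[assigned] &
    isAncestorOrSelf(tree, as_[assigned], tr[assigned])
  considered <- assigned & !strictAnc
  sens <- 100 * sum(correct) / nrow(assignments)
  prec <- if (sum(considered) == 0) NA_real_ else
    100 * sum(correct) / sum(considered)
  list(sensitivity = sens, precision = prec,
       n_reads = nrow(assignments), n_correct = sum(correct),
       n_considered = sum(considered))
}
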