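# Functional binning: a long read is binned to the functional classes of its
# non-dominated (representative) alignments. Dominance of a over b requires
# (1) a covers MORE than MinPercentCoverToDominate (default 50%) of b's
# interval, (2) strictly higher bit score, (3) the same read strand, and
# optionally (4) a's reference taxon compatible with the read's taxonomic bin.

#' Taxon compatibility
#'
#' A reference taxon is compatible with a read's taxonomic bin when it equals
#' the bin, is an ancestor of it, or a descendant of it (lineage membership in
#' either direction). With `strict = TRUE` the ancestor direction is excluded
#' (only the bin itself and its descendants are compatible).
#'
#' @param tree a [Taxonomy-class].
#' @param refTaxon,readTaxon taxon ids.
#' @param strict exclude ancestors of the read's bin.
#' @return Logical.
#' @export
taxonCompatible <- function(tree, refTaxon, readTaxon, strict = FALSE) {
  down <- isAncestorOrSelf(tree, readTaxon, refTaxon)
  if (strict) return(down)
  down | isAncestorOrSelf(tree, refTaxon, readTaxon)
}

#' Functional-dominance predicate
#'
#' @param a,b single-row alignment data.frames on the same read.
#' @param params a [BinningParams-class] (uses `minPercentCoverToDominate`).
#' @param tree,readTaxon optional: when both are given, `a` must additionally
#'   be taxon-compatible with the read's bin to dominate.
#' @return `TRUE` iff `a` dominates `b`: overlap strictly greater than the
#'   cover threshold of `b`'s interval, strictly higher bit score, same
#'   strand (and taxon compatibility when requested).
#' @export
dominates <- function(a, b, params = binningParams(), tree = NULL,
                      readTaxon = NULL) {
  ov <- .overlapLen(a$start, a$end, b$start, b$end)
  ok <- ov > (params@minPercentCoverToDominate / 100) * (b$end - b$start) &
    a$bit_score > b$bit_score &
    a$strand == b$strand
  if (ok && !is.null(tree) && !is.null(readTaxon) && !is.na(readTaxon) &&
      !is.na(a$taxon_id)) {
    ok <- ok && taxonCompatible(tree, a$taxon_id, readTaxon)
  }
  ok
}

#' Representative (non-dominated) alignments of one read
#'
#' @param aln alignment data.frame for a single read.
#' @param params a [BinningParams-class].
#' @param tree,readTaxon optional taxon-compatibility clause, as in
#'   [dominates()].
#' @return Logical vector: which alignments are not dominated by any other
#'   alignment of the read (input order preserved among survivors).
#' @export
selectRepresentativeAlignments <- function(aln, params = binningParams(),
                                           tree = NULL, readTaxon = NULL) {
  n <- nrow(aln)
  if (n <= 1L) return(rep(TRUE, n))
  cover <- params@minPercentCoverToDominate / 100
  useTaxon <- !is.null(tree) && !is.null(readTaxon) && !is.na(readTaxon)
  compat <- if (useTaxon) {
    vapply(seq_len(n), function(i) {
      !is.na(aln$taxon_id[i]) &&
        taxonCompatible(tree, aln$taxon_id[i], readTaxon)
    }, NA)
  } else rep(TRUE, n)
  keep <- rep(TRUE, n)
  for (j in seq_len(n)) {
    ov <- .overlapLen(aln$start, aln$end, aln$start[j], aln$end[j])
    dom <- ov > cover * (aln$end[j] - aln$start[j]) &
      aln$bit_score > aln$bit_score[j] &
      aln$strand == aln$strand[j] & compat
    dom[j] <- FALSE
    keep[j] <- !any(dom)
  }
  keep
}

#' Functional classes of one read
#'
#' The union, per classification namespace, of the classes attached to the
#' read's representative alignments. A read can be binned to all functional
#' classes associated with it; the map is empty when no representative
#' alignment carries a class.
#'
#' @inheritParams selectRepresentativeAlignments
#' @return Named list: namespace -> character vector of class ids.
#' @export
assignFunctions <- function(aln, params = binningParams(), tree = NULL,
                            readTaxon = NULL) {
  keep <- selectRepresentativeAlignments(aln, params, tree, readTaxon)
  cls <- aln$classes[keep]
  ns <- unique(unlist(lapply(cls, names)))
  out <- lapply(ns, function(s) {
    sort(unique(unlist(lapply(cls, function(x) x[[s]]))))
  })
  names(out) <- ns
  out[lengths(out) > 0]
}

#' Best-hit functional baseline
#'
#' The short-read rule: the read is assigned the class of its highest-scoring
#' alignment to a reference for which a class in the namespace is known.
#'
#' @param aln alignment data.frame for a single read.
#' @param namespace classification namespace to query.
#' @return Character vector of the top classified alignment's class ids in
#'   the namespace, or `character(0)` when no alignment is classified.
#' @export
bestHitAssign <- function(aln, namespace) {
  has <- vapply(aln$classes, function(x) !is.null(x[[namespace]]), NA)
  if (!any(has)) return(character(0))
  idx <- which(has)[which.max(aln$bit_score[has])]
  sort(unique(aln$classes[[idx]][[namespace]]))
}

#' Functional binning of a whole dataset
#'
#' Runs [assignFunctions()] on every read and accumulates per-class weights
#' (same weight modes as taxonomic binning; a read contributes its full
#' weight to every class it is binned to, since classes are not mutually
#' exclusive).
#'
#' @param x a [ReadAlignments-class] with annotations attached.
#' @param params a [BinningParams-class].
#' @param tree,readTaxa optional: `readTaxa` is a named vector read_id ->
#'   assigned taxon id enabling the taxon-compatibility clause.
#' @return list with `classes` (data.frame `read_id`, `namespace`,
#'   `class_id`) and `weights` (data.frame `namespace`, `class_id`,
#'   `weight`).
#' @export
binFunctions <- function(x, params = binningParams(), tree = NULL,
                         readTaxa = NULL) {
  stopifnot(is(x, "ReadAlignments"))
  ids <- x@reads$read_id
  a <- x@aln
  groups <- split(seq_len(nrow(a)), factor(a$read_id, levels = ids))
  rows <- list()
  wrows <- list()
  for (k in seq_along(ids)) {
    ak <- a[groups[[k]], , drop = FALSE]
    rt <- if (!is.null(readTaxa)) readTaxa[[ids[k]]] else NULL
    fn <- assignFunctions(ak, params, tree, rt)
    if (!length(fn)) next
    wt <- readWeight(ak, x@reads$read_length[k], params@weightMode,
                     x@reads$contig_reads[k])
    for (ns in names(fn)) {
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = ids[k], namespace = ns, class_id = fn[[ns]],
        stringsAsFactors = FALSE)
      wrows[[length(wrows) + 1L]] <- data.frame(
        namespace = ns, class_id = fn[[ns]], weight = wt,
        stringsAsFactors = FALSE)
    }
  }
  classes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), namespace = character(0),
               class_id = character(0), stringsAsFactors = FALSE)
  weights <- if (length(wrows)) {
    wd <- do.call(rbind, wrows)
    agg <- stats::aggregate(weight ~ namespace + class_id, wd, sum)
    agg[order(agg$namespace, -agg$weight, agg$class_id), , drop = FALSE]
  } else {
    data.frame(namespace = character(0), class_id = character(0),
               weight = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(weights) <- NULL
  list(classes = classes, weights = weights)
}
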