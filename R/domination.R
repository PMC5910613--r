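# Strong-domination filtering: the redundancy-removal stage applied when
# converting aligner output, before binning. An alignment a strongly dominates
# b when it covers at least MinPercentCoverToStronglyDominate (default 90%) of
# b's interval and (topPercentScoreToStronglyDominate/100) * bitscore(a) >
# bitscore(b) (strict). The strict inequality with a factor < 1 makes mutual
# domination impossible, so judging every alignment against the ORIGINAL set
# is order-independent and idempotent.

#' Strong-domination predicate
#'
#' @param a,b single-row alignment data.frames (or list-like with `start`,
#'   `end`, `bit_score`, `strand`) on the same read.
#' @param params a [BinningParams-class].
#' @return `TRUE` iff `a` strongly dominates `b`. Strand is not considered
#'   unless `params@strongSameStrand` is set.
#' @examples
#' p <- binningParams()
#' a <- data.frame(start = 0, end = 100, bit_score = 100, strand = "+")
#' b <- data.frame(start = 5, end = 95, bit_score = 80, strand = "+")
#' stronglyDominates(a, b, p)  # TRUE
#' @export
stronglyDominates <- function(a, b, params = binningParams()) {
  ov <- .overlapLen(a$start, a$end, b$start, b$end)
  coverOK <- ov >= (params@minPercentCoverToStronglyDominate / 100) *
    (b$end - b$start)
  scoreOK <- (params@topPercentScoreToStronglyDominate / 100) * a$bit_score >
    b$bit_score
  strandOK <- !params@strongSameStrand | (a$strand == b$strand)
  coverOK & scoreOK & strandOK
}

#' Remove strongly dominated alignments
#'
#' Keeps exactly the alignments not strongly dominated by ANY alignment of the
#' original (unfiltered) set of the same read; input order is preserved among
#' survivors. The per-read maximum-score alignment always survives, and the
#' filter is idempotent.
#'
#' @param x a [ReadAlignments-class] (all reads filtered independently) or an
#'   alignment data.frame for a single read.
#' @param params a [BinningParams-class].
#' @return Object of the same kind as `x` with dominated alignments removed.
#' @export
filterStronglyDominated <- function(x, params = binningParams()) {
  if (is(x, "ReadAlignments")) {
    a <- x@aln
    if (nrow(a)) {
      keep <- unlist(lapply(split(seq_len(nrow(a)), match(a$read_id,
                                                          x@reads$read_id)),
                            function(idx) idx[.survivors(a[idx, , drop = FALSE],
                                                         params)]),
                     use.names = FALSE)
      x@aln <- a[sort(keep), , drop = FALSE]
      rownames(x@aln) <- NULL
    }
    return(x)
  }
  x[.survivors(x, params), , drop = FALSE]
}

# logical survivor mask for one read's alignment table
.survivors <- function(a, params) {
  n <- nrow(a)
  if (n <= 1L) return(rep(TRUE, n))
  cover <- params@minPercentCoverToStronglyDominate / 100
  fac <- params@topPercentScoreToStronglyDominate / 100
  dominated <- rep(FALSE, n)
  for (j in seq_len(n)) {
    ov <- .overlapLen(a$start, a$end, a$start[j], a$end[j])
    dom <- ov >= cover * (a$end[j] - a$start[j]) &
      fac * a$bit_score > a$bit_score[j]
    if (params@strongSameStrand) dom <- dom & a$strand == a$strand[j]
    dom[j] <- FALSE
    dominated[j] <- any(dom)
  }
  !dominated
}
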