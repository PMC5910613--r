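# Interval arithmetic on 0-based half-open read coordinates, delegated to
# IRanges (1-based closed): [lo, hi) maps to IRanges(lo + 1, hi). reduce()
# merges overlapping and abutting ranges, which is exactly the union-with-merge
# the binning algorithms need.

.toIR <- function(start0, end0) {
  IRanges::IRanges(start = as.integer(start0) + 1L, end = as.integer(end0))
}

.fromIR <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Union of half-open intervals
#'
#' Merges overlapping and abutting `[start, end)` intervals into a sorted
#' disjoint set.
#'
#' @param start0,end0 integer vectors, 0-based half-open interval bounds.
#' @return data.frame with columns `start`, `end` (sorted, disjoint).
#' @examples
#' intervalUnion(c(0, 30), c(80, 100))  # [0, 100)
#' @export
intervalUnion <- function(start0, end0) {
  if (!length(start0)) return(data.frame(start = integer(0), end = integer(0)))
  .fromIR(IRanges::reduce(.toIR(start0, end0)))
}

#' Total measure of a union of half-open intervals
#'
#' @inheritParams intervalUnion
#' @return Numeric scalar: the number of bases covered by at least one
#'   interval.
#' @examples
#' intervalMeasure(c(0, 30), c(80, 100))  # 100
#' @export
intervalMeasure <- function(start0, end0) {
  if (!length(start0)) return(0)
  sum(IRanges::width(IRanges::reduce(.toIR(start0, end0))))
}

# length of the overlap of two single intervals [s1,e1) and [s2,e2)
.overlapLen <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

#' Atomic-interval partition of a read's alignments
#'
#' Every alignment start and end becomes a boundary; the covered region of the
#' read is cut into consecutive pieces between boundaries, so that every
#' alignment interval is an exact union of pieces. Pieces not covered by any
#' alignment (gaps) are omitted.
#'
#' @param start0,end0 integer vectors of alignment intervals (0-based,
#'   half-open) on one read.
#' @return data.frame with columns `start`, `end`, one row per atomic piece.
#' @examples
#' buildPartition(c(0, 30), c(80, 100))  # [0,30) [30,80) [80,100)
#' @export
buildPartition <- function(start0, end0) {
  stopifnot(length(start0) == length(end0), length(start0) >= 1L)
  b <- sort(unique(c(as.integer(start0), as.integer(end0))))
  pieces <- data.frame(start = b[-length(b)], end = b[-1L])
  covered <- vapply(seq_len(nrow(pieces)), function(i) {
    any(start0 <= pieces$start[i] & end0 >= pieces$end[i])
  }, NA)
  pieces[covered, , drop = FALSE]
}

#' Alignments significant on a piece
#'
#' Among the alignments whose interval fully contains the piece, those whose
#' bit score lies within `topPercent` of the best bit score on that piece
#' (inclusive threshold: `score >= (1 - topPercent/100) * best`).
#'
#' @param aln data.frame with columns `start`, `end`, `bit_score`.
#' @param pieceStart,pieceEnd bounds of one atomic piece.
#' @param topPercent percent band below the best score.
#' @return Integer indices into `aln` of the significant alignments.
#' @export
significantOnPiece <- function(aln, pieceStart, pieceEnd, topPercent = 10) {
  covers <- which(aln$start <= pieceStart & aln$end >= pieceEnd)
  if (!length(covers)) return(integer(0))
  best <- max(aln$bit_score[covers])
  covers[aln$bit_score[covers] >= (1 - topPercent / 100) * best]
}
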