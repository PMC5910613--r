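#' Construct binning parameters
#'
#' Returns a [BinningParams-class] with the standard defaults: topPercent 10,
#' percentToCover 80, minSupport 0.05, weight mode `aligned_bases`,
#' MinPercentCoverToDominate 50, and strong domination at 90% cover / 90%
#' score. See the class documentation for the meaning of each parameter.
#'
#' @param topPercent percent, significance band below the local best score.
#' @param percentToCover percent of the covered portion a node must reach.
#' @param minSupport percent of total assigned weight below which a taxon's
#'   weight is pushed up to its parent.
#' @param weightMode `"read_count"`, `"total_length"`, `"aligned_bases"` or
#'   `"contig_reads"`.
#' @param minPercentCoverToDominate percent, functional dominance overlap
#'   threshold (strict).
#' @param minPercentCoverToStronglyDominate percent, strong-domination overlap
#'   threshold (inclusive).
#' @param topPercentScoreToStronglyDominate percent, strong-domination score
#'   factor.
#' @param strongSameStrand also require same strand for strong domination.
#' @return A validated [BinningParams-class] object.
#' @examples
#' binningParams()
#' binningParams(percentToCover = 90)
#' @export
binningParams <- function(topPercent = 10,
                          percentToCover = 80,
                          minSupport = 0.05,
                          weightMode = "aligned_bases",
                          minPercentCoverToDominate = 50,
                          minPercentCoverToStronglyDominate = 90,
                          topPercentScoreToStronglyDominate = 90,
                          strongSameStrand = FALSE) {
  new("BinningParams",
      topPercent = as.numeric(topPercent),
      percentToCover = as.numeric(percentToCover),
      minSupport = as.numeric(minSupport),
      weightMode = weightMode,
      minPercentCoverToDominate = as.numeric(minPercentCoverToDominate),
      minPercentCoverToStronglyDominate =
        as.numeric(minPercentCoverToStronglyDominate),
      topPercentScoreToStronglyDominate =
        as.numeric(topPercentScoreToStronglyDominate),
      strongSameStrand = isTRUE(strongSameStrand))
}
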