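# Alignment input/output: LAST MAF (DNA query vs protein reference, frame-shift
# tolerant) and a tabular dialect; per-read collation of batched output; and
# resolution of reference accessions to taxa and functional classes.

.alnColumns <- c("read_id", "read_length", "start", "end", "strand",
                 "bit_score", "raw_score", "ref_acc", "frame_shifts")

.emptyAlnTable <- function() {
  data.frame(read_id = character(0), read_length = integer(0),
             start = integer(0), end = integer(0), strand = character(0),
             bit_score = numeric(0), raw_score = numeric(0),
             ref_acc = character(0), frame_shifts = integer(0),
             stringsAsFactors = FALSE)
}

#' Parse LAST MAF alignments of DNA reads against protein references
#'
#' Reads the text-based multiple alignment format emitted by frame-shift-aware
#' DNA-to-protein aligners: records of one `a score=S` line followed by two
#' `s` lines, the protein reference first and the DNA query second. Query
#' coordinates are converted to forward-strand, 0-based, half-open read
#' coordinates: for strand `+` the interval is `[start, start+alnSize)`, for
#' strand `-` it is `[seqSize-start-alnSize, seqSize-start)`. Frame-shift
#' characters (`/` and `\`) in the query aligned string are counted but not
#' interpreted; the start/alnSize fields are trusted for coordinates.
#'
#' Raw scores are converted to bit scores as
#' `bits = (lambda * S - ln K) / ln 2` when `lambda=` and `K=` were both seen
#' in a `#` header line; otherwise the raw score is passed through unchanged
#' with a warning (score-ratio thresholds such as topPercent remain meaningful
#' under any monotone score).
#'
#' @param file path or connection to MAF text.
#' @return An ungrouped alignment data.frame (one row per alignment) with the
#'   columns expected by [collateReads()].
#' @export
readMAF <- function(file) {
  lines <- readLines(file)
  lambda <- NA_real_
  K <- NA_real_
  for (h in grep("^#", lines, value = TRUE)) {
    lm <- regmatches(h, regexec("lambda=([0-9.eE+-]+)", h))[[1]]
    if (length(lm) == 2L) lambda <- as.numeric(lm[2L])
    km <- regmatches(h, regexec("K=([0-9.eE+-]+)", h))[[1]]
    if (length(km) == 2L) K <- as.numeric(km[2L])
  }
  haveBits <- is.finite(lambda) && is.finite(K)
  aLines <- grep("^a\\b", lines)
  out <- vector("list", length(aLines))
  warned <- FALSE
  for (j in seq_along(aLines)) {
    i <- aLines[j]
    sm <- regmatches(lines[i], regexec("score=([0-9.eE+-]+)", lines[i]))[[1]]
    if (length(sm) != 2L) stop(sprintf("MAF line %d: 'a' line without score=", i))
    score <- as.numeric(sm[2L])
    sIdx <- i + which(grepl("^s\\s", lines[(i + 1):min(i + 6, length(lines))]))
    sIdx <- sIdx[sIdx <= length(lines)][1:2]
    if (length(sIdx) < 2L || anyNA(sIdx)) {
      stop(sprintf("MAF line %d: record lacks two 's' lines", i))
    }
    qf <- strsplit(trimws(lines[sIdx[2L]]), "\\s+")[[1]]
    if (length(qf) < 7L) stop(sprintf("MAF line %d: malformed query 's' line", sIdx[2L]))
    qstart <- suppressWarnings(as.integer(qf[3L]))
    qsize <- suppressWarnings(as.integer(qf[4L]))
    qseqlen <- suppressWarnings(as.integer(qf[6L]))
    if (anyNA(c(qstart, qsize, qseqlen))) {
      stop(sprintf("MAF line %d: non-numeric coordinates", sIdx[2L]))
    }
    if (qsize <= 0L) stop(sprintf("MAF line %d: alnSize <= 0", sIdx[2L]))
    strand <- qf[5L]
    if (strand == "+") {
      start <- qstart
      end <- qstart + qsize
    } else {
      start <- qseqlen - qstart - qsize
      end <- qseqlen - qstart
    }
    rf <- strsplit(trimws(lines[sIdx[1L]]), "\\s+")[[1]]
    fs <- sum(strsplit(qf[7L], "")[[1]] %in% c("/", "\\"))
    if (haveBits) {
      bit <- (lambda * score - log(K)) / log(2)
    } else {
      bit <- score
      if (!warned) {
        warning("MAF header lacks lambda/K; using raw scores as bit scores")
        warned <- TRUE
      }
    }
    out[[j]] <- data.frame(read_id = qf[2L], read_length = qseqlen,
                           start = start, end = end, strand = strand,
                           bit_score = bit, raw_score = score,
                           ref_acc = rf[2L], frame_shifts = fs,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) return(.emptyAlnTable())
  do.call(rbind, out)
}

#' Read / write the tabular alignment dialect
#'
#' Tab-separated columns `read_id, read_length, start, end, strand, bit_score,
#' ref_accession[, frame_shifts]` with 0-based half-open forward-strand
#' coordinates; `#` comment lines are skipped. This plain-text dialect stands
#' in for binary alignment archives as the pipeline's intermediate format.
#'
#' @param file path or connection.
#' @return `readAlignmentsTSV`: an ungrouped alignment data.frame for
#'   [collateReads()].
#' @export
readAlignmentsTSV <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) && grepl("^read_id\t", lines[1L])) lines <- lines[-1L]
  if (!length(lines)) return(.emptyAlnTable())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 7L)
  if (length(bad)) stop(sprintf("alignment TSV line %d has fewer than 7 columns", bad[1L]))
  g <- function(k) vapply(fields, function(f) f[k], "")
  df <- data.frame(
    read_id = g(1L),
    read_length = suppressWarnings(as.integer(g(2L))),
    start = suppressWarnings(as.integer(g(3L))),
    end = suppressWarnings(as.integer(g(4L))),
    strand = g(5L),
    bit_score = suppressWarnings(as.numeric(g(6L))),
    raw_score = NA_real_,
    ref_acc = g(7L),
    frame_shifts = vapply(fields, function(f)
      if (length(f) >= 8L) suppressWarnings(as.integer(f[8L])) else 0L, 0L),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$start) || anyNA(df$end) || anyNA(df$read_length) ||
      anyNA(df$bit_score)) {
    stop("non-numeric field in alignment TSV")
  }
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("alignment TSV line %d: start >= end", bad[1L]))
  }
  bad <- which(df$end > df$read_length | df$start < 0L)
  if (length(bad)) {
    stop(sprintf("alignment TSV line %d: interval outside [0, read_length)", bad[1L]))
  }
  df
}

#' @rdname readAlignmentsTSV
#' @param x a [ReadAlignments-class] object or an ungrouped alignment
#'   data.frame.
#' @export
writeAlignmentsTSV <- function(x, file) {
  df <- if (is(x, "ReadAlignments")) .ungroup(x) else x
  out <- df[, c("read_id", "read_length", "start", "end", "strand",
                "bit_score", "ref_acc", "frame_shifts")]
  names(out)[7L] <- "ref_accession"
  utils::write.table(out, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(out)
}

# flatten a ReadAlignments back into the ungrouped parser table
.ungroup <- function(ra) {
  a <- ra@aln
  a$read_length <- ra@reads$read_length[match(a$read_id, ra@reads$read_id)]
  a[, c("read_id", "read_length", "start", "end", "strand", "bit_score",
        "raw_score", "ref_acc", "frame_shifts")]
}

#' Collate ungrouped alignments into a per-read container
#'
#' Aligners that batch their output do not report all alignments of a query
#' consecutively; this groups an ungrouped alignment table by read, keeping
#' first-seen read order and within-read input order, and enforces a single
#' read length per read id.
#'
#' @param aln ungrouped alignment data.frame as returned by [readMAF()] or
#'   [readAlignmentsTSV()].
#' @param contigReads optional named integer vector: read/contig id -> number
#'   of reads contained in the contig (for the `contig_reads` weight mode).
#' @return A [ReadAlignments-class] object.
#' @export
collateReads <- function(aln, contigReads = NULL) {
  stopifnot(is.data.frame(aln))
  if (nrow(aln)) {
    lenByRead <- tapply(aln$read_length, aln$read_id, function(v) length(unique(v)))
    if (any(lenByRead > 1L)) {
      stop(sprintf("conflicting read_length for read '%s'",
                   names(lenByRead)[lenByRead > 1L][1L]))
    }
  }
  ids <- unique(aln$read_id)
  reads <- data.frame(
    read_id = ids,
    read_length = aln$read_length[match(ids, aln$read_id)],
    contig_reads = if (is.null(contigReads)) rep(NA_integer_, length(ids)) else
      as.integer(contigReads[ids]),
    stringsAsFactors = FALSE
  )
  a <- aln[order(match(aln$read_id, ids)), , drop = FALSE]
  a$read_length <- NULL
  a$taxon_id <- rep(NA_integer_, nrow(a))
  a$classes <- rep(list(list()), nrow(a))
  rownames(a) <- NULL
  new("ReadAlignments", aln = a, reads = reads)
}

#' ReadAlignments accessors
#'
#' `alignments` returns the per-alignment table (with resolved `taxon_id` and
#' `classes` if annotated); `readIds` and `readLengths` the per-read metadata;
#' `nReads` the number of reads.
#'
#' @param x a [ReadAlignments-class].
#' @name readalignments-accessors
NULL

#' @rdname readalignments-accessors
#' @export
alignments <- function(x) x@aln

#' @rdname readalignments-accessors
#' @export
readIds <- function(x) x@reads$read_id

#' @rdname readalignments-accessors
#' @export
readLengths <- function(x) structure(x@reads$read_length, names = x@reads$read_id)

#' @rdname readalignments-accessors
#' @export
nReads <- function(x) nrow(x@reads)

#' Read mapping tables from TSV
#'
#' `readTaxonMapping` reads lines `accession<TAB>taxon_id`;
#' `readClassMapping` reads lines `accession<TAB>namespace<TAB>class_id`
#' (an accession may recur with several classes/namespaces). `MappingTable`
#' assembles a mapping object directly from R objects.
#'
#' @param taxonFile,classFile paths or connections; either may be `NULL`.
#' @return A [MappingTable-class].
#' @export
readMappingTables <- function(taxonFile = NULL, classFile = NULL) {
  taxonMap <- integer(0)
  classMaps <- list()
  if (!is.null(taxonFile)) {
    lines <- readLines(taxonFile)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
    if (length(lines) && grepl("^accession\t", lines[1L])) lines <- lines[-1L]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 2L)) stop("taxon mapping line with fewer than 2 columns")
    taxonMap <- structure(as.integer(vapply(f, `[`, "", 2L)),
                          names = vapply(f, `[`, "", 1L))
  }
  if (!is.null(classFile)) {
    lines <- readLines(classFile)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
    if (length(lines) && grepl("^accession\t", lines[1L])) lines <- lines[-1L]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(f) < 3L)) stop("class mapping line with fewer than 3 columns")
    df <- data.frame(acc = vapply(f, `[`, "", 1L),
                     ns = vapply(f, `[`, "", 2L),
                     cls = vapply(f, `[`, "", 3L), stringsAsFactors = FALSE)
    classMaps <- lapply(split(df, df$ns), function(d)
      lapply(split(d$cls, d$acc), unique))
  }
  MappingTable(taxonMap, classMaps)
}

#' @rdname readMappingTables
#' @param taxonMap named integer vector (accession -> taxon id).
#' @param classMaps named list: namespace -> (named list accession -> class
#'   id character vector).
#' @export
MappingTable <- function(taxonMap = integer(0), classMaps = list()) {
  if (length(taxonMap) && anyDuplicated(names(taxonMap))) {
    stop("duplicate accession in taxon mapping")
  }
  new("MappingTable",
      taxonMap = structure(as.integer(taxonMap), names = names(taxonMap)),
      classMaps = classMaps)
}

#' Resolve accessions to taxa and functional classes
#'
#' Fills `taxon_id` and `classes` on each alignment from a [MappingTable-class].
#' Unmapped accessions are not an error: the alignment is retained with an
#' empty taxon/classes (it still contributes to the covered-portion
#' denominator and to GFF3 export); the number of unmapped accessions is
#' reported via a message.
#'
#' @param x a [ReadAlignments-class].
#' @param mapping a [MappingTable-class].
#' @param quiet suppress the unmapped-accession message.
#' @return `x` with annotations attached.
#' @export
attachAnnotations <- function(x, mapping, quiet = FALSE) {
  stopifnot(is(x, "ReadAlignments"), is(mapping, "MappingTable"))
  a <- x@aln
  if (nrow(a)) {
    a$taxon_id <- unname(mapping@taxonMap[a$ref_acc])
    a$classes <- lapply(a$ref_acc, function(acc) {
      cl <- lapply(mapping@classMaps, function(m) m[[acc]])
      cl[!vapply(cl, is.null, NA)]
    })
    nUnmapped <- sum(is.na(a$taxon_id))
    if (!quiet && nUnmapped) {
      message(sprintf("%d of %d alignments have accessions without a taxon mapping",
                      nUnmapped, nrow(a)))
    }
  }
  x@aln <- a
  validObject(x)
  x
}
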