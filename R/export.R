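# GFF3 export of annotated alignments as CDS features, summary tables, and
# the hierarchical color-class rule used when drawing alignment arrows.

# Percent-encoding for GFF3 attribute values (reserved: ; = & , % and
# control characters). Tabs and newlines cannot occur in our values.
.gff3Encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  gsub(",", "%2C", x, fixed = TRUE)
}

#' Export alignments as GFF3 CDS features
#'
#' Each alignment to a reference sequence is exported as one CDS feature on
#' the read: seqid = read id, 1-based inclusive coordinates, score = bit
#' score, strand from the alignment, phase ".". Attributes are written in a
#' fixed order (ID, Target, taxon, then requested namespaces alphabetically)
#' with percent-encoded values, so output is byte-reproducible. By default
#' only representative (non-dominated) alignments are exported; optionally
#' only those whose reference taxon is compatible with the read's assigned
#' taxon.
#'
#' @param x a [ReadAlignments-class] with annotations attached.
#' @param tree a [Taxonomy-class] (for taxon names and compatibility); may be
#'   `NULL` when neither is needed.
#' @param params a [BinningParams-class].
#' @param namespaces character vector of classification namespaces to write
#'   as attributes; must exist on the annotations.
#' @param assignments optional data.frame `read_id`, `taxon_id` (from
#'   [binDataset()]), required for `requireTaxonCompatible`.
#' @param requireTaxonCompatible drop features whose reference taxon is not
#'   compatible with the read's assigned taxon.
#' @param onlyRepresentatives export only non-dominated alignments (default).
#' @param file optional path or connection to write to.
#' @param source value of the GFF3 source column.
#' @return Character vector of GFF3 lines (invisibly when `file` is given).
#' @export
exportGFF3 <- function(x, tree = NULL, params = binningParams(),
                       namespaces = character(0), assignments = NULL,
                       requireTaxonCompatible = FALSE,
                       onlyRepresentatives = TRUE, file = NULL,
                       source = "LongReadLCA") {
  stopifnot(is(x, "ReadAlignments"))
  a <- x@aln
  known <- unique(unlist(lapply(a$classes, names)))
  bad <- setdiff(namespaces, known)
  if (length(bad)) {
    stop(sprintf("unknown classification namespace(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (requireTaxonCompatible && (is.null(assignments) || is.null(tree))) {
    stop("requireTaxonCompatible needs both assignments and a taxonomy")
  }
  lines <- "##gff-version 3"
  ids <- x@reads$read_id
  groups <- split(seq_len(nrow(a)), factor(a$read_id, levels = ids))
  featNo <- 0L
  for (k in seq_along(ids)) {
    idx <- groups[[k]]
    ak <- a[idx, , drop = FALSE]
    readTaxon <- if (!is.null(assignments)) {
      assignments$taxon_id[match(ids[k], assignments$read_id)]
    } else NA_integer_
    keep <- if (onlyRepresentatives) {
      selectRepresentativeAlignments(ak, params)
    } else rep(TRUE, nrow(ak))
    if (requireTaxonCompatible && !is.na(readTaxon)) {
      keep <- keep & vapply(seq_len(nrow(ak)), function(i) {
        !is.na(ak$taxon_id[i]) &&
          taxonCompatible(tree, ak$taxon_id[i], readTaxon)
      }, NA)
    }
    for (i in which(keep)) {
      featNo <- featNo + 1L
      attrs <- c(sprintf("ID=%s", .gff3Encode(sprintf("cds%06d", featNo))),
                 sprintf("Target=%s", .gff3Encode(ak$ref_acc[i])))
      if (!is.na(ak$taxon_id[i]) && !is.null(tree)) {
        attrs <- c(attrs, sprintf("taxon=%s",
                                  .gff3Encode(taxonNames(tree, ak$taxon_id[i]))))
      }
      for (ns in sort(namespaces)) {
        cl <- ak$classes[[i]][[ns]]
        if (!is.null(cl) && length(cl)) {
          attrs <- c(attrs, sprintf("%s=%s", .gff3Encode(ns),
                                    paste(.gff3Encode(sort(cl)),
                                          collapse = ",")))
        }
      }
      lines <- c(lines, paste(ids[k], source, "CDS",
                              ak$start[i] + 1L, ak$end[i],
                              format(ak$bit_score[i], trim = TRUE),
                              ak$strand[i], ".",
                              paste(attrs, collapse = ";"),
                              sep = "\t"))
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Hierarchical color class of an alignment arrow
#'
#' When drawing the alignments of a read bound to taxon `readTaxon`, an arrow
#' for a reference at taxon `refTaxon` is colored: with the read taxon's own
#' color when the two are equal (`"SELF"`); with the color of the unique child
#' of the read taxon on the path down to the reference when the reference is a
#' strict descendant (`"CHILD"`, with that child returned); and gray otherwise
#' (ancestor, i.e. less specific, or incompatible).
#'
#' @param tree a [Taxonomy-class].
#' @param refTaxon,readTaxon taxon ids.
#' @return list with `class` (`"SELF"`, `"CHILD"` or `"GRAY"`) and `child`
#'   (taxon id, or `NA` unless `class == "CHILD"`).
#' @export
colorClass <- function(tree, refTaxon, readTaxon) {
  refTaxon <- as.integer(refTaxon)
  readTaxon <- as.integer(readTaxon)
  .taxIndex(tree, c(refTaxon, readTaxon))
  if (refTaxon == readTaxon) {
    return(list(class = "SELF", child = NA_integer_))
  }
  if (isAncestorOrSelf(tree, readTaxon, refTaxon)) {
    path <- rootPath(tree, refTaxon)  # refTaxon first, root last
    child <- path[which(path == readTaxon) - 1L]
    return(list(class = "CHILD", child = child))
  }
  list(class = "GRAY", child = NA_integer_)
}

#' Write a per-taxon weight summary as TSV
#'
#' Rows `taxon_id, name, rank, weight`, sorted by weight descending, with a
#' header line.
#'
#' @param weights a [NodeWeights-class].
#' @param tree a [Taxonomy-class].
#' @param file path or connection.
#' @return The summary data.frame, invisibly.
#' @export
writeSummary <- function(weights, tree, file) {
  ids <- as.integer(names(weights@weights))
  df <- data.frame(taxon_id = ids,
                   name = if (length(ids)) taxonNames(tree, ids) else character(0),
                   rank = if (length(ids)) taxonRanks(tree, ids) else character(0),
                   weight = as.numeric(weights@weights),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$weight, df$taxon_id), , drop = FALSE]
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(df)
}

#' Write read-to-taxon assignments as TSV
#'
#' @param assignments data.frame from [binDataset()].
#' @param tree a [Taxonomy-class] (adds name/rank columns when given).
#' @param file path or connection.
#' @export
writeAssignments <- function(assignments, tree = NULL, file) {
  df <- assignments[, c("read_id", "taxon_id", "weight")]
  if (!is.null(tree)) {
    ok <- !is.na(df$taxon_id)
    df$name <- NA_character_
    df$rank <- NA_character_
    df$name[ok] <- taxonNames(tree, df$taxon_id[ok])
    df$rank[ok] <- taxonRanks(tree, df$taxon_id[ok])
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(df)
}
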