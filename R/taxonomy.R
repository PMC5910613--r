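# Taxonomy construction and queries: parsing NCBI-style dump files or a simple
# TSV, LCA computation and ancestry predicates. All binning algorithms are
# rank-agnostic; ranks are labels carried through to reports.

#' Construct a Taxonomy from vectors
#'
#' Low-level constructor; most users will call [readTaxonomy()]. The root is
#' the node whose parent is itself. Validity (unique ids, no dangling parents,
#' exactly one root, no cycles) is enforced.
#'
#' @param taxid integer vector of node ids.
#' @param parent integer vector of parent ids (root: its own id).
#' @param rank character vector of rank labels.
#' @param name character vector of names; defaults to the ids as strings.
#' @return A [Taxonomy-class] object.
#' @examples
#' tx <- Taxonomy(c(1L, 2L, 3L), c(1L, 1L, 1L), c("no rank", "genus", "genus"))
#' lca(tx, c(2L, 3L))
#' @export
Taxonomy <- function(taxid, parent, rank = rep("no rank", length(taxid)),
                     name = as.character(taxid)) {
  taxid <- as.integer(taxid)
  parent <- as.integer(parent)
  if (anyDuplicated(taxid)) {
    stop(sprintf("malformed taxonomy: duplicate taxon id %d",
                 taxid[duplicated(taxid)][1L]))
  }
  pidx <- match(parent, taxid)
  if (anyNA(pidx)) {
    stop(sprintf("malformed taxonomy: node %d has dangling parent id %d",
                 taxid[is.na(pidx)][1L], parent[is.na(pidx)][1L]))
  }
  roots <- which(taxid == parent)
  if (length(roots) != 1L) {
    stop(sprintf("malformed taxonomy: %d self-parent root(s), need exactly 1",
                 length(roots)))
  }
  depth <- .computeDepths(taxid, pidx, roots)
  if (anyNA(depth)) {
    stop(sprintf("malformed taxonomy: cycle involving taxon id %d",
                 taxid[is.na(depth)][1L]))
  }
  new("Taxonomy", taxid = taxid, parent = parent,
      rank = as.character(rank), name = as.character(name),
      root = taxid[roots], depth = depth)
}

# BFS from the root along child links; nodes never reached sit on a cycle.
.computeDepths <- function(taxid, pidx, rootPos) {
  n <- length(taxid)
  depth <- rep(NA_integer_, n)
  depth[rootPos] <- 0L
  childList <- split(seq_len(n), pidx)
  frontier <- rootPos
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unlist(childList[as.character(frontier)], use.names = FALSE)
    nxt <- nxt[is.na(depth[nxt])]
    depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

#' Read a taxonomy from NCBI dump files or a 4-column TSV
#'
#' Two dialects are supported. `"ncbi_dmp"` reads a `nodes.dmp` file (fields
#' separated by `"\t|\t"`, lines terminated `"\t|"`); only tax_id, parent and
#' rank are used. Names come from an optional `names.dmp`, keeping only rows
#' of name class "scientific name". `"tsv"` reads four tab-separated columns
#' `taxon_id, parent_id, rank, name`; a header line is detected by a
#' non-numeric first field. With `dialect = "auto"` (default) a file whose
#' first line contains `"\t|"` is treated as NCBI dump format.
#'
#' @param nodes path (or connection) to nodes.dmp or the TSV.
#' @param names optional path to names.dmp; scientific names override TSV
#'   names when given.
#' @param dialect `"auto"`, `"ncbi_dmp"` or `"tsv"`.
#' @return A [Taxonomy-class] object.
#' @export
readTaxonomy <- function(nodes, names = NULL, dialect = c("auto", "ncbi_dmp", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- readLines(nodes)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty taxonomy source")
  if (dialect == "auto") {
    dialect <- if (grepl("\t\\|", lines[1L])) "ncbi_dmp" else "tsv"
  }
  if (dialect == "ncbi_dmp") {
    fields <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
    taxid <- vapply(fields, function(f) f[1L], "")
    parent <- vapply(fields, function(f) f[2L], "")
    rank <- vapply(fields, function(f) if (length(f) >= 3L) f[3L] else "no rank", "")
    nm <- as.character(taxid)
  } else {
    if (!grepl("^[0-9]+(\\s|$)", lines[1L])) lines <- lines[-1L]  # header
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3L)
    if (length(bad)) stop(sprintf("taxonomy TSV line %d has fewer than 3 columns", bad[1L]))
    taxid <- vapply(fields, function(f) f[1L], "")
    parent <- vapply(fields, function(f) f[2L], "")
    rank <- vapply(fields, function(f) f[3L], "")
    nm <- vapply(fields, function(f) if (length(f) >= 4L) f[4L] else f[1L], "")
  }
  ti <- suppressWarnings(as.integer(taxid))
  pi <- suppressWarnings(as.integer(parent))
  if (anyNA(ti) || anyNA(pi)) stop("non-numeric taxon or parent id in taxonomy source")
  if (!is.null(names)) {
    nl <- readLines(names)
    nl <- nl[nzchar(trimws(nl))]
    nf <- strsplit(sub("\t\\|$", "", nl), "\t\\|\t")
    cls <- vapply(nf, function(f) if (length(f) >= 4L) f[4L] else "", "")
    sci <- nf[cls == "scientific name"]
    sciId <- suppressWarnings(as.integer(vapply(sci, function(f) f[1L], "")))
    sciNm <- vapply(sci, function(f) f[2L], "")
    hit <- match(ti, sciId)
    nm[!is.na(hit)] <- sciNm[hit[!is.na(hit)]]
  }
  Taxonomy(ti, pi, rank, nm)
}

#' Write a taxonomy as 4-column TSV
#'
#' @param tree a [Taxonomy-class].
#' @param file path or connection.
#' @export
writeTaxonomyTSV <- function(tree, file) {
  df <- data.frame(taxon_id = tree@taxid, parent_id = tree@parent,
                   rank = tree@rank, name = tree@name)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(df)
}

.taxIndex <- function(tree, ids, what = "taxon") {
  idx <- match(as.integer(ids), tree@taxid)
  if (anyNA(idx)) {
    stop(sprintf("unknown %s id: %s", what,
                 paste(ids[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Taxonomy accessors
#'
#' `taxonIds`, `taxonNames`, `taxonRanks`, `taxonParents`, `taxonDepths`
#' return the per-node vectors (optionally subset by `ids`); `rootId` returns
#' the root's id; `taxonChildren` the ids of a node's children; `rootPath`
#' the ids from a node up to the root (node first).
#'
#' @param tree a [Taxonomy-class].
#' @param ids optional taxon ids to subset/query.
#' @name taxonomy-accessors
NULL

#' @rdname taxonomy-accessors
#' @export
taxonIds <- function(tree) tree@taxid

#' @rdname taxonomy-accessors
#' @export
rootId <- function(tree) tree@root

#' @rdname taxonomy-accessors
#' @export
taxonNames <- function(tree, ids = NULL) {
  if (is.null(ids)) tree@name else tree@name[.taxIndex(tree, ids)]
}

#' @rdname taxonomy-accessors
#' @export
taxonRanks <- function(tree, ids = NULL) {
  if (is.null(ids)) tree@rank else tree@rank[.taxIndex(tree, ids)]
}

#' @rdname taxonomy-accessors
#' @export
taxonParents <- function(tree, ids = NULL) {
  if (is.null(ids)) tree@parent else tree@parent[.taxIndex(tree, ids)]
}

#' @rdname taxonomy-accessors
#' @export
taxonDepths <- function(tree, ids = NULL) {
  if (is.null(ids)) tree@depth else tree@depth[.taxIndex(tree, ids)]
}

#' @rdname taxonomy-accessors
#' @param id a single taxon id.
#' @export
taxonChildren <- function(tree, id) {
  id <- as.integer(id)
  .taxIndex(tree, id)
  setdiff(tree@taxid[tree@parent == id], id)
}

#' @rdname taxonomy-accessors
#' @export
rootPath <- function(tree, id) {
  i <- .taxIndex(tree, id)
  path <- integer(0)
  repeat {
    path <- c(path, tree@taxid[i])
    p <- tree@parent[i]
    if (p == tree@taxid[i]) break
    i <- match(p, tree@taxid)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' Returns the unique deepest node that is an ancestor-or-self of every input
#' taxon. The operation is commutative, associative under set union, and
#' idempotent.
#'
#' @param tree a [Taxonomy-class].
#' @param ids non-empty vector of taxon ids (all present in `tree`).
#' @return A single taxon id.
#' @examples
#' tx <- Taxonomy(c(1L, 2L, 3L), c(1L, 1L, 1L))
#' lca(tx, c(2L, 3L))  # 1
#' @export
lca <- function(tree, ids) {
  ids <- unique(as.integer(ids))
  if (!length(ids)) stop("lca of an empty taxon set is undefined")
  idx <- .taxIndex(tree, ids)
  d <- tree@depth[idx]
  # walk all nodes up to the shallowest depth, then climb in lockstep
  while (length(unique(idx)) > 1L) {
    dmax <- max(d)
    if (all(d == dmax)) {
      idx <- match(tree@parent[idx], tree@taxid)
      d <- d - 1L
    } else {
      up <- d == dmax
      idx[up] <- match(tree@parent[idx[up]], tree@taxid)
      d[up] <- d[up] - 1L
    }
    keep <- !duplicated(idx)
    idx <- idx[keep]
    d <- d[keep]
  }
  tree@taxid[idx]
}

#' Ancestor-or-self predicate
#'
#' True iff `anc` lies on the parent path of `desc`, inclusive.
#'
#' @param tree a [Taxonomy-class].
#' @param anc,desc taxon ids (vectorized; recycled to common length).
#' @return Logical vector.
#' @export
isAncestorOrSelf <- function(tree, anc, desc) {
  anc <- as.integer(anc)
  desc <- as.integer(desc)
  n <- max(length(anc), length(desc))
  anc <- rep_len(anc, n)
  desc <- rep_len(desc, n)
  .taxIndex(tree, unique(c(anc, desc)))
  vapply(seq_len(n), function(k) {
    i <- match(desc[k], tree@taxid)
    a <- anc[k]
    dTarget <- tree@depth[match(a, tree@taxid)]
    while (tree@depth[i] > dTarget) i <- match(tree@parent[i], tree@taxid)
    tree@taxid[i] == a
  }, NA)
}
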