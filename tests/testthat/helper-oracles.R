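# Independent brute-force oracles and random-instance generators used by the
# property tests. These deliberately avoid the package's own algorithmic path:
# LCA by root-path intersection, coverage by per-base marking, strong
# domination by fixed-point removal.

# LCA by intersecting full root paths (rootPath returns node-first order, so
# the first common element is the deepest common ancestor).
oracleLCA <- function(tree, ids) {
  paths <- lapply(ids, function(i) rootPath(tree, i))
  Reduce(intersect, paths)[1]
}

# random tree over ids 1..n: node i's parent drawn uniformly from 1..(i-1)
randomTree <- function(n) {
  parent <- c(1L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  Taxonomy(seq_len(n), parent)
}

# balanced 3-level taxonomy: root -> genera -> species; returns the tree and
# the leaf ids
rand3Level <- function(nGenera = 3L, speciesPerGenus = 3L) {
  nSp <- nGenera * speciesPerGenus
  gid <- seq_len(nGenera) + 1L
  sid <- seq_len(nSp) + max(gid)
  tree <- Taxonomy(c(1L, gid, sid),
                   c(1L, rep(1L, nGenera), rep(gid, each = speciesPerGenus)),
                   c("no rank", rep("genus", nGenera), rep("species", nSp)))
  list(tree = tree, species = sid)
}

# random single-read alignment table: integer coords <= maxCoord, taxa drawn
# from the supplied leaves (NA with prob pUnmapped)
randomRead <- function(nAln, leaves, maxCoord = 200L, pUnmapped = 0) {
  start <- sample.int(maxCoord - 10L, nAln, replace = TRUE) - 1L
  len <- sample(10:60, nAln, replace = TRUE)
  end <- pmin(start + len, maxCoord)
  tax <- sample(leaves, nAln, replace = TRUE)
  tax[runif(nAln) < pUnmapped] <- NA_integer_
  data.frame(read_id = "r", start = start, end = end,
             strand = sample(c("+", "-"), nAln, replace = TRUE),
             bit_score = round(runif(nAln, 40, 120), 1),
             raw_score = NA_real_, ref_acc = sprintf("acc%d", seq_len(nAln)),
             frame_shifts = 0L, taxon_id = tax,
             stringsAsFactors = FALSE)
}

# per-base coverage oracle: mark every covered base with the set of taxa
# having a significant alignment over it; a node covers a base when any
# marked taxon is its descendant-or-self. Returns counts so callers can
# compare exactly in integer arithmetic.
oracleBaseCoverage <- function(aln, tree, taxonId, topPercent = 10) {
  maxc <- max(aln$end)
  covered <- 0L
  hit <- 0L
  for (b in seq_len(maxc) - 1L) {
    covers <- which(aln$start <= b & aln$end > b)
    if (!length(covers)) next
    covered <- covered + 1L
    best <- max(aln$bit_score[covers])
    sig <- covers[aln$bit_score[covers] >= (1 - topPercent / 100) * best]
    taxa <- unique(aln$taxon_id[sig])
    taxa <- taxa[!is.na(taxa)]
    if (length(taxa) &&
        any(vapply(taxa, function(t) isAncestorOrSelf(tree, taxonId, t), NA))) {
      hit <- hit + 1L
    }
  }
  c(hit = hit, covered = covered)
}

# brute-force qualifying-node search over ALL tree nodes, using the per-base
# oracle; ties resolved by the oracle LCA
oracleAssign <- function(aln, tree, params) {
  pct <- params@percentToCover
  ids <- taxonIds(tree)
  hc <- vapply(ids, function(t)
    oracleBaseCoverage(aln, tree, t, params@topPercent), c(hit = 0L, covered = 0L))
  hit <- hc["hit", ]
  covered <- hc["covered", ]
  covSet <- ids[hit > 0 & 100 * hit >= pct * covered]
  qualifying <- covSet[vapply(covSet, function(q)
    !any(taxonChildren(tree, q) %in% covSet), NA)]
  if (!length(qualifying)) return(NA_integer_)
  if (length(qualifying) == 1L) return(qualifying)
  oracleLCA(tree, qualifying)
}

# fixed-point strong-domination oracle: starting from the full set, each round
# simultaneously removes every alignment dominated by some CURRENT member,
# until the set is stable. (Sequential one-at-a-time removal would be order
# dependent, because domination coverage is not transitive; the simultaneous
# rounds implement "dominated by some other alignment" and stabilize.)
oracleStrongFilter <- function(aln, params) {
  alive <- rep(TRUE, nrow(aln))
  repeat {
    cur <- which(alive)
    drop <- vapply(cur, function(j) {
      any(vapply(setdiff(cur, j), function(i)
        stronglyDominates(aln[i, ], aln[j, ], params), NA))
    }, NA)
    if (!any(drop)) break
    alive[cur[drop]] <- FALSE
  }
  alive
}

# small helper: one-read ReadAlignments from a bare interval/score spec
makeRead <- function(start, end, score, taxon = NA_integer_, strand = "+",
                     readLength = max(end), acc = sprintf("a%d", seq_along(start)),
                     id = "r") {
  n <- length(start)
  data.frame(read_id = id, start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, n), bit_score = as.numeric(score),
             raw_score = NA_real_, ref_acc = acc, frame_shifts = 0L,
             taxon_id = rep_len(as.integer(taxon), n),
             stringsAsFactors = FALSE)
}
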