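# Deterministic synthetic data: the worked-example fixture (eight species in
# two genera under one family) and parameterized simulated datasets with known
# truth, chimeras, and leave-one-out reference removal.

#' The eight-species worked-example fixture
#'
#' Builds a 12-node taxonomy (root -> family R -> genera P, Q -> species A-D
#' under P and E-H under Q) and a single read of length 120 with one
#' equal-bit-score (100) forward-strand alignment per species: A \[0,80),
#' B \[30,100), C \[10,70), D \[40,90), E \[50,90), F \[45,80), G \[55,85),
#' H \[50,70). The covered portion is \[0,100); species coverages run from 80%
#' (A) down to 20% (H); the interval unions of genus P and family R each cover
#' 100% of the aligned read, genus Q covers 45%. With default parameters the
#' read is placed on species A; if A's alignment is shrunk to cover 60%
#' (`shrinkA = TRUE`, interval \[0,60)), the read is assigned to genus P.
#'
#' @param shrinkA replace A's alignment by \[0,60) (the 60%-coverage variant).
#' @return list with `taxonomy` (a [Taxonomy-class]), `reads` (an annotated
#'   [ReadAlignments-class] with one read `"r"`), `mapping` (the
#'   [MappingTable-class]) and `ids` (named vector: label -> taxon id).
#' @examples
#' fx <- makeFig1Fixture()
#' binDataset(fx$reads, fx$taxonomy)$assignments$taxon_id  # species A
#' @export
makeFig1Fixture <- function(shrinkA = FALSE) {
  labels <- c("root", "R", "P", "Q", LETTERS[1:8])
  ids <- structure(1:12, names = labels)
  parent <- c(1L, 1L, 2L, 2L, rep(3L, 4), rep(4L, 4))
  rank <- c("no rank", "family", "genus", "genus", rep("species", 8))
  tree <- Taxonomy(ids, parent, rank, labels)
  iv <- rbind(
    A = c(0, 80), B = c(30, 100), C = c(10, 70), D = c(40, 90),
    E = c(50, 90), F = c(45, 80), G = c(55, 85), H = c(50, 70))
  if (shrinkA) iv["A", ] <- c(0, 60)
  aln <- data.frame(
    read_id = "r", read_length = 120L,
    start = as.integer(iv[, 1]), end = as.integer(iv[, 2]),
    strand = "+", bit_score = 100, raw_score = NA_real_,
    ref_acc = paste0("prot_", rownames(iv)), frame_shifts = 0L,
    stringsAsFactors = FALSE)
  mapping <- MappingTable(
    taxonMap = structure(ids[LETTERS[1:8]],
                         names = paste0("prot_", LETTERS[1:8])))
  reads <- attachAnnotations(collateReads(aln), mapping, quiet = TRUE)
  list(taxonomy = tree, reads = reads, mapping = mapping, ids = ids)
}

#' Simulation parameters
#'
#' Defaults describe a desk-scale community: 24 species in genera of 2-6
#' species (the range over which leave-one-out recovery is informative),
#' 2-3 genera per family, 100 reads of 1-5 kb carrying 3-8 genes each.
#' Alignment scores are in bits, roughly half a bit per aligned base; sister
#' species receive hits at 88% of the top score plus Gaussian noise
#' (`scoreNoiseSD`, default 5 bits), so that at zero noise sister hits sit
#' just below the default 10% significance band. `offtargetRate` is the
#' per-gene probability of a spurious hit to a random distant species;
#' `chimeraRate` the per-read probability of a two-species chimera (split at
#' a uniform 30-70% breakpoint); `leaveOut` suppresses all alignments to the
#' listed taxa while keeping their reads, emulating database incompleteness.
#'
#' @param seed integer seed; the generator is fully reproducible from it.
#' @param nSpecies total number of leaf species.
#' @param speciesPerGenus integer range (min, max).
#' @param generaPerFamily integer range (min, max).
#' @param nReads number of reads.
#' @param readLength bp range (min, max).
#' @param genesPerRead integer range (min, max).
#' @param scoreNoiseSD bits, SD of sister/off-target score noise.
#' @param offtargetRate probability in \[0, 1\].
#' @param chimeraRate probability in \[0, 1\].
#' @param leaveOut optional integer vector of taxon ids to suppress.
#' @return A validated list of class `"SimulationParams"`.
#' @export
simulationParams <- function(seed = 1L, nSpecies = 24L,
                             speciesPerGenus = c(2L, 6L),
                             generaPerFamily = c(2L, 3L),
                             nReads = 100L, readLength = c(1000L, 5000L),
                             genesPerRead = c(3L, 8L), scoreNoiseSD = 5,
                             offtargetRate = 0.02, chimeraRate = 0,
                             leaveOut = NULL) {
  p <- list(seed = as.integer(seed), nSpecies = as.integer(nSpecies),
            speciesPerGenus = as.integer(speciesPerGenus),
            generaPerFamily = as.integer(generaPerFamily),
            nReads = as.integer(nReads), readLength = as.integer(readLength),
            genesPerRead = as.integer(genesPerRead),
            scoreNoiseSD = as.numeric(scoreNoiseSD),
            offtargetRate = as.numeric(offtargetRate),
            chimeraRate = as.numeric(chimeraRate),
            leaveOut = if (is.null(leaveOut)) NULL else as.integer(leaveOut))
  stopifnot(p$nSpecies >= 2L, p$nReads >= 0L,
            length(p$speciesPerGenus) == 2L,
            p$speciesPerGenus[1] >= 1L,
            p$speciesPerGenus[1] <= p$speciesPerGenus[2],
            length(p$readLength) == 2L, p$readLength[1] >= 100L,
            p$readLength[1] <= p$readLength[2],
            length(p$genesPerRead) == 2L, p$genesPerRead[1] >= 1L,
            p$genesPerRead[1] <= p$genesPerRead[2],
            p$scoreNoiseSD >= 0,
            p$offtargetRate >= 0, p$offtargetRate <= 1,
            p$chimeraRate >= 0, p$chimeraRate <= 1)
  class(p) <- "SimulationParams"
  p
}

.sampleRange <- function(rng, n = 1L) {
  if (rng[1] == rng[2]) rep(rng[1], n) else
    sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

#' Simulate an annotated long-read dataset with known truth
#'
#' Builds a random taxonomy (root / families / genera / species), then for
#' each read picks a true leaf species (or two for chimeric reads, split at a
#' random breakpoint), tiles gene intervals along the read, and emits: one
#' top-score alignment to the true species per gene, near-top alignments to
#' sister species of the same genus (score `0.88 x top + N(0, scoreNoiseSD)`),
#' and off-target alignments to random distant species at `offtargetRate`.
#' Taxa in `leaveOut` have all their alignments suppressed while their reads
#' remain. Output is byte-reproducible from `params$seed`.
#'
#' @param params a `"SimulationParams"` list from [simulationParams()].
#' @return list with `taxonomy`, `reads` (annotated [ReadAlignments-class]),
#'   `truth` (named vector read_id -> true taxon id; chimeras are labeled
#'   with the LCA of their two sources — a reporting convention, distinct
#'   from the per-species truth used by the standard metrics), `truthDetail`
#'   (data.frame with both sources) and `mapping`.
#' @examples
#' sim <- simulateDataset(simulationParams(seed = 7, nReads = 10))
#' res <- binDataset(sim$reads, sim$taxonomy)
#' evaluateAssignments(res$assignments, sim$truth, sim$taxonomy)
#' @export
simulateDataset <- function(params = simulationParams()) {
  stopifnot(inherits(params, "SimulationParams"))
  withr::with_seed(params$seed, .simulateDataset(params))
}

.simulateDataset <- function(p) {
  # ---- taxonomy ----
  genusSizes <- integer(0)
  while (sum(genusSizes) < p$nSpecies) {
    genusSizes <- c(genusSizes, .sampleRange(p$speciesPerGenus))
  }
  genusSizes[length(genusSizes)] <-
    genusSizes[length(genusSizes)] - (sum(genusSizes) - p$nSpecies)
  genusSizes <- genusSizes[genusSizes > 0L]
  nGenera <- length(genusSizes)
  famSizes <- integer(0)
  while (sum(famSizes) < nGenera) {
    famSizes <- c(famSizes, .sampleRange(p$generaPerFamily))
  }
  famSizes[length(famSizes)] <- famSizes[length(famSizes)] -
    (sum(famSizes) - nGenera)
  famSizes <- famSizes[famSizes > 0L]
  nFam <- length(famSizes)
  famIds <- seq_len(nFam) + 1L
  genusIds <- seq_len(nGenera) + max(famIds)
  speciesIds <- seq_len(p$nSpecies) + max(genusIds)
  genusParent <- rep(famIds, famSizes)
  speciesParent <- rep(genusIds, genusSizes)
  tree <- Taxonomy(
    taxid = c(1L, famIds, genusIds, speciesIds),
    parent = c(1L, rep(1L, nFam), genusParent, speciesParent),
    rank = c("no rank", rep("family", nFam), rep("genus", nGenera),
             rep("species", p$nSpecies)),
    name = c("root", paste0("family", seq_len(nFam)),
             paste0("genus", seq_len(nGenera)),
             paste0("species", seq_len(p$nSpecies))))
  if (!is.null(p$leaveOut)) .taxIndex(tree, p$leaveOut, "leave-out taxon")
  sisterOf <- split(speciesIds, speciesParent)

  # ---- reads and alignments ----
  rows <- list()
  mapRows <- list()
  truth <- integer(p$nReads)
  src2 <- rep(NA_integer_, p$nReads)
  readIdv <- sprintf("read%04d", seq_len(p$nReads))
  readLen <- .sampleRange(p$readLength, p$nReads)
  geneFamily <- 0L
  emit <- function(species, gs, ge, top, kind) {
    acc <- sprintf("GF%04d_t%d", geneFamily, species)
    score <- switch(kind,
      true = top,
      sister = 0.88 * top + stats::rnorm(1, 0, p$scoreNoiseSD),
      offtarget = 0.75 * top + stats::rnorm(1, 0, p$scoreNoiseSD))
    list(aln = data.frame(start = gs, end = ge,
                          strand = sample(c("+", "-"), 1L, prob = c(0.7, 0.3)),
                          bit_score = max(score, 1), ref_acc = acc,
                          stringsAsFactors = FALSE),
         map = data.frame(acc = acc, taxon = species,
                          class = sprintf("GF%04d", geneFamily),
                          stringsAsFactors = FALSE))
  }
  for (r in seq_len(p$nReads)) {
    L <- readLen[r]
    chimera <- stats::runif(1) < p$chimeraRate
    s1 <- sample(speciesIds, 1L)
    if (chimera) {
      s2 <- sample(setdiff(speciesIds, sisterOf[[as.character(
        speciesParent[match(s1, speciesIds)])]]), 1L)
      bp <- round(stats::runif(1, 0.3, 0.7) * L)
      truth[r] <- lca(tree, c(s1, s2))
      src2[r] <- s2
    } else {
      s2 <- NA_integer_
      bp <- NA_integer_
      truth[r] <- s1
    }
    g <- .sampleRange(p$genesPerRead)
    bounds <- round(seq(0, L, length.out = g + 1L))
    readRows <- list()
    for (k in seq_len(g)) {
      tile <- bounds[k + 1L] - bounds[k]
      gs <- bounds[k] + ceiling(0.05 * tile)
      ge <- bounds[k + 1L] - floor(0.05 * tile)
      if (ge - gs < 30L) next
      geneFamily <<- geneFamily + 1L
      sTrue <- if (chimera && (gs + ge) / 2 >= bp) s2 else s1
      top <- 0.5 * (ge - gs)
      readRows[[length(readRows) + 1L]] <- emit(sTrue, gs, ge, top, "true")
      sis <- setdiff(sisterOf[[as.character(
        speciesParent[match(sTrue, speciesIds)])]], sTrue)
      if (length(sis) > 3L) sis <- sample(sis, 3L)
      for (s in sis) {
        readRows[[length(readRows) + 1L]] <- emit(s, gs, ge, top, "sister")
      }
      if (stats::runif(1) < p$offtargetRate) {
        far <- sample(setdiff(speciesIds, c(sTrue, sis)), 1L)
        readRows[[length(readRows) + 1L]] <- emit(far, gs, ge, top, "offtarget")
      }
    }
    if (!length(readRows)) next
    a <- do.call(rbind, lapply(readRows, `[[`, "aln"))
    a <- cbind(data.frame(read_id = readIdv[r], read_length = L,
                          stringsAsFactors = FALSE), a)
    a$raw_score <- NA_real_
    a$frame_shifts <- 0L
    rows[[length(rows) + 1L]] <- a[, .alnColumns]
    mapRows[[length(mapRows) + 1L]] <- do.call(rbind,
                                               lapply(readRows, `[[`, "map"))
  }
  alnTab <- if (length(rows)) do.call(rbind, rows) else .emptyAlnTable()
  mapTab <- unique(do.call(rbind, mapRows))
  mapping <- MappingTable(
    taxonMap = structure(mapTab$taxon, names = mapTab$acc),
    classMaps = list(GENE = lapply(split(mapTab$class, mapTab$acc), unique)))
  reads <- attachAnnotations(collateReads(alnTab), mapping, quiet = TRUE)
  if (!is.null(p$leaveOut) && nrow(reads@aln)) {
    keep <- !(reads@aln$taxon_id %in% p$leaveOut)
    reads@aln <- reads@aln[keep, , drop = FALSE]
    rownames(reads@aln) <- NULL
  }
  names(truth) <- readIdv
  truthDetail <- data.frame(read_id = readIdv, taxon_id = truth,
                            source2 = src2, stringsAsFactors = FALSE)
  list(taxonomy = tree, reads = reads, truth = truth,
       truthDetail = truthDetail, mapping = mapping, params = p)
}

#' Write a simulated dataset through the public file interfaces
#'
#' Emits `alignments.tsv` (tabular alignment dialect), `taxonomy.tsv`,
#' `taxon_map.tsv`, `class_map.tsv` and `truth.tsv` into a directory, so the
#' whole pipeline can be exercised from files.
#'
#' @param sim result of [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAlignmentsTSV(sim$reads, file.path(dir, "alignments.tsv"))
  writeTaxonomyTSV(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  tm <- sim$mapping@taxonMap
  utils::write.table(data.frame(accession = names(tm), taxon_id = unname(tm)),
                     file.path(dir, "taxon_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  cm <- sim$mapping@classMaps
  if (length(cm)) {
    df <- do.call(rbind, lapply(names(cm), function(ns) {
      do.call(rbind, lapply(names(cm[[ns]]), function(acc) {
        data.frame(accession = acc, namespace = ns, class_id = cm[[ns]][[acc]],
                   stringsAsFactors = FALSE)
      }))
    }))
    utils::write.table(df, file.path(dir, "class_map.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = TRUE)
  }
  utils::write.table(sim$truthDetail, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(dir)
}
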