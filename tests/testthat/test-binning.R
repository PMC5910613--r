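# Interval partition, per-piece significance, interval-union LCA, weights,
# minimum support and the evaluation metrics.

test_that("the atomic partition cuts at every boundary and drops gaps", {
  expect_equal(buildPartition(0, 80), data.frame(start = 0L, end = 80L))
  p <- buildPartition(c(0, 30), c(80, 100))
  expect_equal(p$start, c(0L, 30L, 80L))
  expect_equal(p$end, c(30L, 80L, 100L))
  g <- buildPartition(c(0, 60), c(40, 100))
  expect_equal(g$start, c(0L, 60L))  # uncovered gap [40,60) omitted
  expect_equal(g$end, c(40L, 100L))
})

test_that("per-piece significance uses an inclusive topPercent band", {
  aln <- makeRead(c(0, 0, 0), c(50, 50, 50), c(100, 91, 89))
  expect_setequal(significantOnPiece(aln, 0, 50, 10), c(1L, 2L))  # 91 >= 90
  expect_equal(significantOnPiece(aln, 0, 50, 0), 1L)
  one <- makeRead(0, 50, 42)
  expect_equal(significantOnPiece(one, 0, 50, 10), 1L)
  # only alignments fully containing the piece are considered
  part <- makeRead(c(0, 25), c(50, 75), c(10, 99))
  expect_equal(significantOnPiece(part, 0, 25, 10), 1L)
})

test_that("single-leaf and chimeric reads place as the coverage rule dictates", {
  fx <- makeFig1Fixture()
  id <- fx$ids
  single <- makeRead(10, 90, 50, taxon = id[["C"]])
  expect_equal(intervalUnionAssign(single, fx$taxonomy)$taxon_id, id[["C"]])
  # 50/50 chimera across genera: each side covers 50% < 80; family R spans all
  chim <- makeRead(c(0, 50), c(50, 100), c(60, 60),
                   taxon = c(id[["A"]], id[["E"]]))
  res <- intervalUnionAssign(chim, fx$taxonomy)
  expect_equal(res$taxon_id, id[["R"]])
  expect_equal(intervalUnionAssign(chim[0, ], fx$taxonomy)$taxon_id, NA_integer_)
  # no taxon-mapped alignment -> unassigned, not an error
  unmapped <- makeRead(0, 80, 50)
  expect_true(is.na(intervalUnionAssign(unmapped, fx$taxonomy)$taxon_id))
})

test_that("coverage and assignment match the per-base brute-force oracle", {
  withr::local_seed(101)
  params <- binningParams()
  for (k in 1:200) {
    lv <- rand3Level(sample(2:4, 1L), sample(2:4, 1L))
    n <- sample(1:12, 1L)
    aln <- randomRead(n, lv$species, maxCoord = 200L, pUnmapped = 0.1)
    # coverage equals the per-base union oracle exactly, for a random node
    node <- sample(taxonIds(lv$tree), 1L)
    hc <- oracleBaseCoverage(aln, lv$tree, node, params@topPercent)
    want <- if (hc["covered"] == 0) 0 else 100 * hc[["hit"]] / hc[["covered"]]
    expect_equal(coverageOfTaxon(aln, lv$tree, node, params), want)
    # assignment equals the brute-force qualifying-node search
    expect_equal(intervalUnionAssign(aln, lv$tree, params)$taxon_id,
                 oracleAssign(aln, lv$tree, params))
  }
})

test_that("interval sets grow monotonically toward the root", {
  withr::local_seed(55)
  for (k in 1:30) {
    lv <- rand3Level(3L, 3L)
    aln <- randomRead(sample(2:10, 1L), lv$species)
    covs <- vapply(taxonIds(lv$tree), function(t)
      coverageOfTaxon(aln, lv$tree, t), 0)
    names(covs) <- taxonIds(lv$tree)
    for (t in setdiff(taxonIds(lv$tree), rootId(lv$tree))) {
      expect_gte(covs[[as.character(taxonParents(lv$tree, t))]],
                 covs[[as.character(t)]])
    }
    if (any(!is.na(aln$taxon_id))) {
      expect_equal(covs[[as.character(rootId(lv$tree))]], 100)
    }
  }
})

test_that("naive LCA follows the best-score band", {
  fx <- makeFig1Fixture()
  id <- fx$ids
  allX <- makeRead(c(0, 10), c(50, 60), c(90, 100), taxon = id[["C"]])
  expect_equal(naiveLCAAssign(allX, fx$taxonomy)$taxon_id, id[["C"]])
  sibs <- makeRead(c(0, 0), c(50, 50), c(100, 100),
                   taxon = c(id[["A"]], id[["B"]]))
  expect_equal(naiveLCAAssign(sibs, fx$taxonomy)$taxon_id, id[["P"]])
  gap <- makeRead(c(0, 0), c(50, 50), c(100, 85),
                  taxon = c(id[["A"]], id[["B"]]))
  expect_equal(naiveLCAAssign(gap, fx$taxonomy)$taxon_id, id[["A"]])
})

test_that("interval-union reduces to naive LCA when intervals coincide", {
  withr::local_seed(77)
  for (k in 1:100) {
    lv <- rand3Level(3L, 3L)
    n <- sample(2:8, 1L)
    aln <- makeRead(rep(20, n), rep(120, n), round(runif(n, 50, 100), 1),
                    taxon = sample(lv$species, n, replace = TRUE))
    for (tp in c(0, 5, 10, 20)) {
      p <- binningParams(topPercent = tp)
      expect_equal(intervalUnionAssign(aln, lv$tree, p)$taxon_id,
                   naiveLCAAssign(aln, lv$tree, p)$taxon_id)
    }
  }
})

test_that("read weights follow the four reporting modes", {
  aln <- makeRead(c(0, 30), c(80, 100), c(10, 20))
  expect_equal(readWeight(aln, 120L, "read_count"), 1)
  expect_equal(readWeight(aln, 120L, "total_length"), 120)
  expect_equal(readWeight(aln, 120L, "aligned_bases"), 100)  # union measure
  expect_equal(readWeight(aln, 120L, "contig_reads", contigReads = 7L), 7)
  expect_error(readWeight(aln, 120L, "contig_reads"), "contig")
})

test_that("dataset binning accumulates weights and tracks unassigned reads", {
  fx <- makeFig1Fixture()
  id <- fx$ids
  df <- rbind(makeRead(0, 100, 50, taxon = NA, id = "u1"),
              makeRead(c(0, 30), c(80, 100), c(50, 50),
                       taxon = id[["A"]], id = "r1"),
              makeRead(0, 50, 50, taxon = id[["A"]], id = "r2"))
  df$read_length <- 120L
  df$ref_acc[df$read_id != "u1"] <- "prot_A"
  ra <- attachAnnotations(
    collateReads(df[, c("read_id", "read_length", "start", "end", "strand",
                        "bit_score", "raw_score", "ref_acc", "frame_shifts")]),
    fx$mapping, quiet = TRUE)
  res <- binDataset(ra, fx$taxonomy)
  expect_equal(res$assignments$taxon_id,
               c(NA_integer_, id[["A"]], id[["A"]]))
  expect_equal(unname(nodeWeights(res$weights)[as.character(id[["A"]])]), 150)
  expect_equal(totalWeight(res$weights), 150)
  expect_equal(unassignedWeight(res$weights), 100)

  empty <- collateReads(df[0, c("read_id", "read_length", "start", "end",
                                "strand", "bit_score", "raw_score", "ref_acc",
                                "frame_shifts")])
  res0 <- binDataset(empty, fx$taxonomy)
  expect_equal(nrow(res0$assignments), 0L)
  expect_equal(totalWeight(res0$weights), 0)
})

test_that("minimum support pushes small weights up and conserves the total", {
  fx <- makeFig1Fixture()
  id <- fx$ids
  p <- binningParams()  # minSupport 0.05% -> threshold 5 of 10000
  mk <- function(w) new("NodeWeights", weights = w, total = sum(w),
                        unassigned = 0, mode = "aligned_bases")
  w <- mk(structure(c(4, 9996), names = as.character(c(id[["A"]], id[["B"]]))))
  adj <- applyMinSupport(w, fx$taxonomy, p)
  expect_false(as.character(id[["A"]]) %in% names(nodeWeights(adj)))
  # the parent gains the 4 but, being itself under threshold, cascades it on
  # up to the root, which always retains residual weight
  expect_equal(unname(nodeWeights(adj)["1"]), 4)
  expect_equal(sum(nodeWeights(adj)), 10000)
  expect_equal(totalWeight(adj), 10000)

  w5 <- mk(structure(c(5, 9995), names = as.character(c(id[["A"]], id[["B"]]))))
  adj5 <- applyMinSupport(w5, fx$taxonomy, p)
  expect_equal(unname(nodeWeights(adj5)[as.character(id[["A"]])]), 5)  # retained

  # two sub-threshold siblings pool in the parent, which then qualifies
  ws <- mk(structure(c(3, 3, 9994),
                     names = as.character(c(id[["A"]], id[["B"]], id[["E"]]))))
  adjs <- applyMinSupport(ws, fx$taxonomy, p)
  expect_equal(unname(nodeWeights(adjs)[as.character(id[["P"]])]), 6)
  expect_equal(sum(nodeWeights(adjs)), 10000)

  # no-op when everything is above threshold
  big <- mk(structure(c(5000, 5000),
                      names = as.character(c(id[["A"]], id[["E"]]))))
  expect_equal(nodeWeights(applyMinSupport(big, fx$taxonomy, p)),
               nodeWeights(big))
})

test_that("evaluation applies the descendant clause on both metrics", {
  fx <- makeFig1Fixture()
  id <- fx$ids
  tr <- structure(rep(id[["A"]], 4), names = paste0("r", 1:4))
  perfect <- data.frame(read_id = paste0("r", 1:4), taxon_id = id[["A"]])
  ev <- evaluateAssignments(perfect, tr, fx$taxonomy)
  expect_equal(ev$sensitivity, 100)
  expect_equal(ev$precision, 100)

  # 2 correct, 1 ancestor (P), 1 sibling (B): sens 50, prec 100*2/3
  mixed <- data.frame(read_id = paste0("r", 1:4),
                      taxon_id = c(id[["A"]], id[["A"]], id[["P"]], id[["B"]]))
  ev2 <- evaluateAssignments(mixed, tr, fx$taxonomy)
  expect_equal(ev2$sensitivity, 50)
  expect_equal(ev2$precision, 100 * 2 / 3)

  # assignment below the true taxon counts as correct
  deepTr <- structure(id[["P"]], names = "r1")
  deep <- data.frame(read_id = "r1", taxon_id = id[["A"]])
  expect_equal(evaluateAssignments(deep, deepTr, fx$taxonomy)$sensitivity, 100)

  # unassigned reads dilute sensitivity but not precision
  un <- data.frame(read_id = paste0("r", 1:4),
                   taxon_id = c(id[["A"]], NA, NA, NA))
  ev3 <- evaluateAssignments(un, tr, fx$taxonomy)
  expect_equal(ev3$sensitivity, 25)
  expect_equal(ev3$precision, 100)

  allUn <- data.frame(read_id = paste0("r", 1:4), taxon_id = NA_integer_)
  expect_true(is.na(evaluateAssignments(allUn, tr, fx$taxonomy)$precision))
  expect_error(evaluateAssignments(perfect, tr[-1], fx$taxonomy), "missing")
})

test_that("raising percentToCover never deepens an assignment", {
  withr::local_seed(202)
  for (k in 1:25) {
    lv <- rand3Level(3L, 3L)
    aln <- randomRead(sample(3:10, 1L), lv$species)
    prev <- NA_integer_
    for (pc in c(50, 60, 70, 80, 90, 100)) {
      res <- intervalUnionAssign(aln, lv$tree, binningParams(percentToCover = pc))
      # the tie rule (several qualifying nodes -> their LCA) can step off the
      # monotone path; the invariant holds along single-qualifying steps
      if (length(res$qualifying) > 1L) {
        prev <- NA_integer_
        next
      }
      cur <- res$taxon_id
      if (!is.na(prev) && !is.na(cur)) {
        expect_true(isAncestorOrSelf(lv$tree, cur, prev))
      }
      prev <- cur
    }
  }
})
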