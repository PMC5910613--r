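# MAF and tabular parsing, per-read collation, annotation attachment.

mafText <- function(...) textConnection(paste(..., sep = "\n"))

test_that("MAF records parse with bit-score conversion and strand mapping", {
  maf <- mafText(
    "# LAST run",
    "# lambda=0.324 K=0.14",
    "a score=100",
    "s protX 5 30 + 500 MKVLAT",
    "s read1 0 90 + 120 ATGAAA",
    "a score=60",
    "s protY 0 10 + 200 MKV",
    "s read1 10 30 - 120 ATG/AA\\T")
  aln <- readMAF(maf)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$start[1], 0L)
  expect_equal(aln$end[1], 90L)
  expect_equal(aln$bit_score[1], (0.324 * 100 - log(0.14)) / log(2))
  # reverse strand: [seqSize-start-alnSize, seqSize-start) = [80, 110)
  expect_equal(aln$start[2], 80L)
  expect_equal(aln$end[2], 110L)
  expect_equal(aln$strand[2], "-")
  expect_equal(aln$frame_shifts[2], 2L)
  expect_equal(aln$ref_acc, c("protX", "protY"))
})

test_that("MAF reverse-strand conversion is an involution", {
  # applying the minus-strand map twice recovers the raw MAF coordinates
  conv <- function(start, alnSize, seqSize) {
    c(start = seqSize - start - alnSize, alnSize = alnSize)
  }
  for (raw in list(c(10L, 30L), c(0L, 120L), c(89L, 31L))) {
    once <- conv(raw[1], raw[2], 120L)
    twice <- conv(once["start"], once["alnSize"], 120L)
    expect_equal(unname(twice), raw)
  }
})

test_that("MAF without lambda/K falls back to raw scores with a warning", {
  maf <- mafText("a score=77",
                 "s protX 0 9 + 100 MKV",
                 "s read1 0 27 + 120 ATGATGATG")
  expect_warning(aln <- readMAF(maf), "lambda/K")
  expect_equal(aln$bit_score, 77)
})

test_that("malformed MAF records are rejected with line context", {
  expect_error(readMAF(mafText("a score=5", "s protX 0 9 + 100 MKV")),
               "two 's' lines")
  expect_error(readMAF(mafText("a score=5",
                               "s protX 0 9 + 100 MKV",
                               "s read1 x 27 + 120 ATG")),
               "non-numeric")
  expect_equal(nrow(readMAF(mafText("# empty"))), 0L)
})

test_that("tabular dialect parses, validates and round-trips", {
  tsv <- textConnection("r1\t120\t0\t80\t+\t100.0\tP_A")
  aln <- readAlignmentsTSV(tsv)
  expect_equal(aln$read_id, "r1")
  expect_equal(aln$start, 0L)
  expect_equal(aln$end, 80L)
  expect_equal(aln$bit_score, 100)
  expect_equal(aln$ref_acc, "P_A")
  expect_equal(aln$frame_shifts, 0L)

  expect_equal(nrow(readAlignmentsTSV(textConnection("# only a comment"))), 0L)
  expect_error(readAlignmentsTSV(textConnection("r1\t120\t80\t10\t+\t5\tX")),
               "start >= end")
  expect_error(readAlignmentsTSV(textConnection("r1\t120\t0\t130\t+\t5\tX")),
               "read_length")
  expect_error(readAlignmentsTSV(textConnection("r1\t120\t0\t80\t+\t5")),
               "fewer than 7")

  withr::local_seed(5)
  big <- do.call(rbind, lapply(1:40, function(i) {
    d <- makeRead(sample(0:100, 3), 110:112, runif(3, 10, 99), id = sprintf("r%d", i))
    d$read_length <- 120L
    d[, c("read_id", "read_length", "start", "end", "strand", "bit_score",
          "raw_score", "ref_acc", "frame_shifts")]
  }))
  f <- withr::local_tempfile()
  writeAlignmentsTSV(big, f)
  back <- readAlignmentsTSV(f)
  expect_equal(back[, c("read_id", "read_length", "start", "end", "strand",
                        "ref_acc", "frame_shifts")],
               big[, c("read_id", "read_length", "start", "end", "strand",
                       "ref_acc", "frame_shifts")],
               ignore_attr = TRUE)
  expect_equal(back$bit_score, big$bit_score, tolerance = 1e-12)
})

test_that("collation preserves first-seen read order and alignment multisets", {
  df <- data.frame(read_id = c("r1", "r2", "r1"), read_length = c(100L, 50L, 100L),
                   start = c(0L, 0L, 10L), end = c(20L, 30L, 40L),
                   strand = "+", bit_score = c(9, 8, 7), raw_score = NA_real_,
                   ref_acc = c("x", "y", "z"), frame_shifts = 0L,
                   stringsAsFactors = FALSE)
  ra <- collateReads(df)
  expect_equal(readIds(ra), c("r1", "r2"))
  expect_equal(alignments(ra)$ref_acc, c("x", "z", "y"))
  expect_equal(unname(readLengths(ra)), c(100L, 50L))

  # conflicting lengths are a consistency error naming the read
  bad <- df; bad$read_length[3] <- 99L
  expect_error(collateReads(bad), "conflicting read_length for read 'r1'")

  # property: shuffled input over 10 reads loses and duplicates nothing
  withr::local_seed(7)
  many <- do.call(rbind, lapply(1:1000, function(i) {
    rid <- sprintf("r%02d", sample.int(10L, 1L))
    data.frame(read_id = rid, read_length = 500L, start = i %% 400L,
               end = i %% 400L + 50L, strand = "+", bit_score = i,
               raw_score = NA_real_, ref_acc = sprintf("a%d", i),
               frame_shifts = 0L, stringsAsFactors = FALSE)
  }))
  ra2 <- collateReads(many)
  expect_equal(nReads(ra2), 10L)
  expect_equal(nrow(alignments(ra2)), 1000L)
  expect_setequal(alignments(ra2)$ref_acc, many$ref_acc)
  # within-read order preserved (scores were emitted increasing)
  byRead <- split(alignments(ra2)$bit_score, alignments(ra2)$read_id)
  expect_true(all(vapply(byRead, function(v) all(diff(v) > 0), NA)))
})

test_that("annotation attachment resolves taxa and classes, keeps unmapped", {
  df <- makeRead(c(0, 10), c(50, 60), c(10, 20), acc = c("P_A", "nope"))
  df$read_length <- 100L
  ra <- collateReads(df[, c("read_id", "read_length", "start", "end", "strand",
                            "bit_score", "raw_score", "ref_acc", "frame_shifts")])
  mp <- MappingTable(taxonMap = c(P_A = 5L),
                     classMaps = list(InterPro = list(P_A = "IPR001"),
                                      KEGG = list(P_A = c("K1", "K2"))))
  expect_message(ra <- attachAnnotations(ra, mp), "1 of 2")
  a <- alignments(ra)
  expect_equal(a$taxon_id, c(5L, NA_integer_))
  expect_equal(a$classes[[1]]$InterPro, "IPR001")
  expect_setequal(a$classes[[1]]$KEGG, c("K1", "K2"))  # both namespaces held
  expect_length(a$classes[[2]], 0)  # unmapped retained, no classes
})

test_that("mapping tables read from TSV", {
  mp <- readMappingTables(
    textConnection("accession\ttaxon_id\nP_A\t5\nP_B\t6"),
    textConnection("P_A\tInterPro\tIPR001\nP_A\tKEGG\tK1\nP_B\tKEGG\tK2"))
  expect_equal(unname(mp@taxonMap["P_A"]), 5L)
  expect_equal(mp@classMaps$KEGG$P_B, "K2")
  expect_setequal(names(mp@classMaps), c("InterPro", "KEGG"))
})
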