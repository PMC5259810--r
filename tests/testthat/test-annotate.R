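## Direct index construction for controlled majority-vote scenarios
mkIndex <- function(tags, lineages, longSeqs = NULL) {
  ranks <- as.data.frame(parseLineage(lineages))
  entries <- cbind(data.frame(tag = tags, region = "V4",
                              seqId = sprintf("db%04d", seq_along(tags)),
                              stringsAsFactors = FALSE), ranks)
  longEntries <- if (is.null(longSeqs)) {
    cbind(data.frame(longSeq = character(0), region = character(0),
                     seqId = character(0)),
          as.data.frame(parseLineage(character(0))))
  } else {
    cbind(data.frame(longSeq = longSeqs, region = "V4",
                     seqId = sprintf("db%04d", seq_along(tags)),
                     stringsAsFactors = FALSE), ranks)
  }
  new("ReferenceIndex", entries = entries, longEntries = longEntries,
      sourceDb = "synthetic")
}
tagX <- strrep("TGA", 11)

test_that("index construction keys tags to containing references", {
  idx <- buildIndex(fixRef$seqs, fixRef$lineage, fixProf)
  ## all 16 taxa detectable, distinct V4 tags
  expect_equal(length(idx), 16L)
  e <- indexEntries(idx)
  expect_setequal(e$seqId, names(fixRef$seqs))

  ## two references sharing an identical V-region -> one key, two entries
  dup <- fixRef$seqs[c(1, 1)]
  names(dup) <- c("a", "b")
  idx2 <- buildIndex(dup, rep("k__Bacteria; p__P1", 2), fixProf)
  expect_equal(length(idx2), 1L)
  expect_equal(nrow(indexEntries(idx2)), 2L)

  ## a destroyed RS contributes no key
  broken <- as.character(fixRef$seqs[[1]])
  ws <- fixProf@metadata$windowStart
  substr(broken, ws + 1, ws + 23) <- strrep("T", 23)
  both <- Biostrings::DNAStringSet(c(ok = as.character(fixRef$seqs[[2]]),
                                     broken = broken))
  idx3 <- buildIndex(both, rep("k__Bacteria", 2), fixProf)
  expect_false("broken" %in% indexEntries(idx3)$seqId)
  expect_true("ok" %in% indexEntries(idx3)$seqId)
})

test_that("unanimous annotation reaches the deepest rank at confidence 1", {
  idx <- mkIndex(rep(tagX, 4),
                 rep("k__B; p__P1; c__C1; o__O1; f__F1; g__G1; s__S1", 4))
  a <- annotateTag(tagX, index = idx)
  expect_identical(a$use, "tag")
  expect_equal(a$support, 4L)
  expect_equal(a$confidence, 1.0)
  expect_identical(a$taxon_level, "s")
  expect_identical(a$g, "G1")
})

test_that("discordant references produce majority calls with confidence", {
  lin <- c(rep("k__B; p__P1", 19), "k__B; p__P2")
  idx <- mkIndex(rep(tagX, 20), lin)
  a <- annotateTag(tagX, index = idx)
  expect_identical(a$taxon_level, "p")
  expect_identical(a$p, "P1")
  expect_equal(a$confidence, 0.95)
  expect_equal(a$support, 20L)
})

test_that("unmatched tags return an empty annotation with support 0", {
  idx <- mkIndex(rep(tagX, 2), rep("k__B; p__P1", 2))
  a <- annotateTag(strrep("CCA", 11), index = idx)
  expect_equal(a$support, 0L)
  expect_identical(a$k, "")
  expect_identical(a$taxon_level, "")
})

test_that("long-sequence lookup takes precedence over the tag", {
  longA <- paste0(tagX, strrep("A", 27))
  idx <- mkIndex(rep(tagX, 3),
                 c("k__B; p__P1", "k__B; p__P1", "k__B; p__P2"),
                 longSeqs = c(longA, longA, paste0(tagX, strrep("G", 27))))
  a <- annotateTag(tagX, longSeq = longA, index = idx)
  expect_identical(a$use, "long")
  expect_equal(a$support, 2L)          # only the two longA references
  expect_identical(a$p, "P1")
  expect_equal(a$confidence, 1.0)
})

test_that("concordance is the modal fraction excluding empty labels", {
  idx1 <- mkIndex(rep(tagX, 3), rep("k__B; p__P1; c__C; o__O; f__F; g__G; s__S1", 3))
  expect_equal(unname(concordance(idx1, "s")), 1.0)

  lin <- c(rep("k__B; p__P1", 95), rep("k__B; p__P2", 5))
  idx2 <- mkIndex(rep(tagX, 100), lin)
  expect_equal(unname(concordance(idx2, "p")), 0.95)

  idx3 <- mkIndex(rep(tagX, 2), c("k__B; p__P1", "k__B; p__P2"))
  expect_equal(unname(concordance(idx3, "p")), 0.5)

  ## empty labels leave the denominator
  idx4 <- mkIndex(rep(tagX, 3), c("k__B; p__P1", "k__B; p__P1", "k__B"))
  expect_equal(unname(concordance(idx4, "p")), 1.0)
  ## no labelled sequence at the rank -> tag omitted
  idx5 <- mkIndex(rep(tagX, 2), rep("k__B", 2))
  expect_length(concordance(idx5, "p"), 0L)
})

test_that("annotation confidence equals concordance at the emitted rank", {
  idx <- buildIndex(fixRef$seqs, fixRef$lineage, fixProf)
  for (tag in head(unique(indexEntries(idx)$tag), 5)) {
    a <- annotateTag(tag, index = idx)
    cc <- concordance(idx, a$taxon_level)
    expect_equal(a$confidence, unname(cc[tag]))
  }
})

test_that("raising the vote threshold can only shorten the lineage", {
  lin <- c(rep("k__B; p__P1; c__C1; o__O1; f__F1; g__G1; s__S1", 6),
           rep("k__B; p__P1; c__C1; o__O1; f__F1; g__G2; s__S2", 4))
  idx <- mkIndex(rep(tagX, 10), lin)
  depth <- function(minConf) {
    a <- annotateTag(tagX, index = idx, minConfidence = minConf)
    match(a$taxon_level, c("", "k", "p", "c", "o", "f", "g", "s")) - 1L
  }
  depths <- vapply(c(0.3, 0.5, 0.7, 0.9, 1.0), depth, integer(1))
  expect_true(all(diff(depths) <= 0L))
  ## 0.6 majority at genus emitted at threshold 0.5, not at 0.7
  expect_identical(annotateTag(tagX, index = idx, minConfidence = 0.5)$g, "G1")
  expect_identical(annotateTag(tagX, index = idx, minConfidence = 0.7)$g, "")
})

test_that("training references round-trip through index and annotation", {
  idx <- buildIndex(fixRef$seqs, fixRef$lineage, fixProf)
  e <- indexEntries(idx)
  perTag <- table(e$tag)
  for (i in seq_len(nrow(e))) {
    if (perTag[e$tag[i]] > 1L) next       # shared V-regions can't be unique
    a <- annotateTag(e$tag[i], index = idx)
    expect_equal(a$confidence, 1.0)
    truth <- fixRef$lineage[e$seqId[i], ]
    expect_identical(unlist(a[riboscan:::RANKS], use.names = FALSE),
                     unname(truth))
  }
})

test_that("concordance histogram bins are exact-1 first, then 0.05 steps", {
  h1 <- concordanceHistogram(rep(1, 10))
  expect_equal(unname(h1[1]), 100)
  expect_equal(sum(h1), 100)

  h2 <- concordanceHistogram(c(1.0, 0.97, 0.5))
  expect_equal(unname(h2["1"]), 100 / 3, tolerance = 1e-9)
  expect_equal(unname(h2["[0.95,1.00)"]), 100 / 3, tolerance = 1e-9)
  expect_equal(unname(h2["[0.50,0.55)"]), 100 / 3, tolerance = 1e-9)
  expect_equal(sum(h2), 100, tolerance = 1e-9)

  expect_equal(sum(concordanceHistogram(numeric(0))), 0)
})

test_that("species-label reuse shows up as sub-unit concordance mass", {
  ## two species labels shared across 10 references each with the same tag
  lin <- c(rep("k__B; p__P; c__C; o__O; f__F; g__G; s__SA", 8),
           rep("k__B; p__P; c__C; o__O; f__F; g__G; s__SB", 2))
  idx <- mkIndex(rep(tagX, 10), lin)
  cc <- concordance(idx, "s")
  expect_equal(unname(cc[tagX]), 0.8)
  h <- concordanceHistogram(cc)
  expect_equal(unname(h["[0.80,0.85)"]), 100)
})

test_that("reference index serializes to TSV and back", {
  idx <- buildIndex(fixRef$seqs, fixRef$lineage, fixProf,
                    sourceDb = "fixture-db")
  f <- tempfile(fileext = ".tsv")
  writeIndex(idx, f)
  back <- readIndex(f)
  expect_identical(sourceDb(back), "fixture-db")
  o1 <- indexEntries(idx)[order(indexEntries(idx)$tag), ]
  o2 <- indexEntries(back)[order(indexEntries(back)$tag), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(nrow(indexLongEntries(back)), nrow(indexLongEntries(idx)))
})
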