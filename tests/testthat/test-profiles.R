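test_that("column entropy matches the Shannon formula, gaps excluded", {
  ref <- tinyAlignment()
  expect_equal(columnEntropy(ref, 0), 0)          # 100% A
  expect_equal(columnEntropy(ref, 1), 2)          # 25% each base
  ## A:2, C:2 -> 1 bit (direct evaluation of -sum p log2 p)
  ref2 <- alignedReference(
    c(a = "AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",
      b = "AAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",
      c = "CAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA",
      d = "CAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAAA"),
    rep("k__Bacteria", 4),
    data.frame(region = "V1", start = 30L, end = 36L))
  expect_equal(columnEntropy(ref2, 0), 1)
  ## all-gap column carries no information -> maximum 2 bits
  expect_equal(columnEntropy(ref, 3), 2)
  expect_error(columnEntropy(ref, 36), "out of range")
  expect_error(columnEntropy(ref, -1), "out of range")
})

test_that("PSSM entries follow the smoothed log-odds formula", {
  ## 100 sequences, all A at every window position
  n <- 100L
  seqs <- setNames(rep(strrep("A", 30), n), paste0("s", 1:n))
  ref <- alignedReference(seqs, rep("k__Bacteria", n),
                          data.frame(region = "V1", start = 25L, end = 30L))
  m <- buildPssm(ref, 0, pseudocount = 0.5)
  expect_equal(dim(m), c(23L, 4L))
  expect_equal(unname(m[1, "A"]), log2((100.5 / 102) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(m[1, "A"]), 1.979, tolerance = 1e-3)

  ## counts proportional to the background (with pseudocount folded in):
  ## log-odds of the background against itself is zero
  base <- paste(rep(c("A", "C", "G", "T"), each = 1), collapse = "")
  seqs2 <- setNames(rep(c(strrep("A", 30), strrep("C", 30),
                          strrep("G", 30), strrep("T", 30)), 25), paste0("s", 1:100))
  ref2 <- alignedReference(seqs2, rep("k__Bacteria", 100),
                           data.frame(region = "V1", start = 25L, end = 30L))
  m2 <- buildPssm(ref2, 0, pseudocount = 0.5)
  expect_equal(unname(m2[1, ]), rep(0, 4), tolerance = 1e-12)

  ## all-gap window rows are zero vectors
  seqs3 <- setNames(rep(paste0(strrep("-", 23), strrep("A", 7)), 4),
                    paste0("s", 1:4))
  ref3 <- alignedReference(seqs3, rep("k__Bacteria", 4),
                           data.frame(region = "V1", start = 25L, end = 30L))
  m3 <- buildPssm(ref3, 0)
  expect_true(all(m3 == 0))

  expect_error(buildPssm(ref, 20), "does not fit")
})

test_that("PSSM round-trips to the smoothed training frequencies", {
  m <- buildPssm(fixRef$aligned, 10, pseudocount = 0.5)
  ## exponentiate against background and renormalize
  p <- 0.25 * 2^m
  p <- p / rowSums(p)
  counts <- t(Biostrings::consensusMatrix(
    Biostrings::subseq(alignment(fixRef$aligned), 11, 33),
    baseOnly = TRUE))[, c("A", "C", "G", "T")]
  smoothed <- (counts + 0.5) / (rowSums(counts) + 2)
  expect_equal(unname(p), unname(smoothed), tolerance = 1e-10)
})

test_that("a perfectly conserved flank is recovered noiselessly", {
  spec0 <- communitySpec(nTaxa = 10, conservedMutRate = 0, seed = 77)
  ref0 <- makeReference(spec0)
  p <- buildProfile(ref0$aligned, "V4", "bacteria")
  ## consensus of the PSSM equals the (unique) 23-mer flank
  cons <- paste(c("A", "C", "G", "T")[apply(pssm(p), 1, which.max)],
                collapse = "")
  ws <- p@metadata$windowStart
  truth <- substr(as.character(ref0$seqs[[1]]), ws + 1, ws + 23)
  expect_identical(cons, truth)
  expect_equal(p@metadata$trainingSensitivity, 1)
  ## every training sequence is detected at the emitted threshold
  expect_equal(profileSensitivity(p, ref0$seqs)$sensitivity, 1)
})

test_that("training sensitivity meets the target under flank noise", {
  ## default generator noise: 2% per-base substitution in conserved blocks
  p <- fixProf
  expect_gte(p@metadata$trainingSensitivity, 0.95)
  ## re-scan of training data confirms the sweep
  sens <- profileSensitivity(p, fixRef$seqs)
  expect_gte(sens$sensitivity, 0.95)
})

test_that("profile geometry is fixed: 23-nt RS window, 33-nt tag", {
  expect_equal(nrow(pssm(fixProf)), 23L)
  expect_equal(tagLength(fixProf), 33L)
  expect_lte(scoreThreshold(fixProf), maxScore(fixProf))
  expect_gte(nchar(probePattern(fixProf)), 6L)
})

test_that("the selected RS window minimizes mean entropy over shifts", {
  p <- fixProf
  aln <- alignment(fixRef$aligned)
  ent <- function(s) {
    cm <- Biostrings::consensusMatrix(Biostrings::subseq(aln, s + 1, s + 23),
                                      baseOnly = TRUE)[1:4, ]
    mean(apply(cm, 2, function(cc) {
      n <- sum(cc); if (n == 0) return(2)
      pr <- cc[cc > 0] / n; -sum(pr * log2(pr))
    }))
  }
  nominal <- regionMap(fixRef$aligned)
  v4start <- nominal$start[nominal$region == "V4"]
  shifts <- (v4start - 23) + (-5:5)
  best <- p@metadata$windowStart
  expect_true(best %in% shifts)
  expect_equal(ent(best), min(vapply(shifts, ent, numeric(1))),
               tolerance = 1e-12)
})

test_that("a region absent from the region map is rejected", {
  expect_error(buildProfile(fixRef$aligned, "V12", "bacteria"),
               "not present")
})

test_that("supplementary profiles appear only for divergent phyla", {
  ## Construct an alignment where n divergent phyla carry a private,
  ## unrelated RS flank that the universal profile must miss.
  ## divergent phyla are kept under 5% of the training set so the 95%
  ## threshold sweep settles on the shared flank and genuinely misses them
  makeSplitRef <- function(nDivergent) {
    set.seed(55)
    nShared <- 4L; perShared <- 30L; perDivergent <- 2L
    flankShared <- riboscan:::.randomDnaString(33)
    seqs <- character(0); lin <- character(0)
    addPhylum <- function(label, flank, nMembers) {
      for (j in seq_len(nMembers)) {
        v <- riboscan:::.randomDnaString(40)
        tail <- riboscan:::.randomDnaString(20)
        seqs <<- c(seqs, paste0(flank, v, tail))
        lin <<- c(lin, sprintf("k__Bacteria; p__%s", label))
      }
    }
    for (ph in seq_len(nShared))
      addPhylum(sprintf("S%02d", ph), flankShared, perShared)
    for (ph in seq_len(nDivergent))
      addPhylum(sprintf("P%02d", ph), riboscan:::.randomDnaString(33),
                perDivergent)
    names(seqs) <- sprintf("s%03d", seq_along(seqs))
    alignedReference(seqs, lin,
                     data.frame(region = "V1", start = 33L, end = 73L))
  }
  cfg <- profileConfig(shiftRange = 0L)
  ## all phyla share the flank -> universal captures everything
  ref0 <- makeSplitRef(0)
  sup0 <- buildTaxonProfiles(ref0, "V1", "bacteria", config = cfg)
  expect_length(sup0, 0L)
  ## one divergent phylum -> exactly one supplement scoped to it
  ref1 <- makeSplitRef(1)
  sup1 <- buildTaxonProfiles(ref1, "V1", "bacteria", config = cfg)
  expect_length(sup1, 1L)
  expect_identical(profileScope(sup1[[1]]), "P01")
  ## three divergent phyla -> three supplements
  ref3 <- makeSplitRef(3)
  sup3 <- buildTaxonProfiles(ref3, "V1", "bacteria", config = cfg)
  expect_length(sup3, 3L)
  expect_setequal(vapply(sup3, profileScope, ""), c("P01", "P02", "P03"))
})

test_that("profiles serialize and reload bit-identically", {
  profs <- buildProfileSet(fixRef$aligned, "V4", supplements = TRUE)
  f <- tempfile(fileext = ".json")
  writeProfiles(profs, f)
  back <- readProfiles(f)
  expect_length(back, length(profs))
  for (i in seq_along(profs)) {
    expect_identical(pssm(back[[i]]), pssm(profs[[i]]))
    expect_identical(scoreThreshold(back[[i]]), scoreThreshold(profs[[i]]))
    expect_identical(probePattern(back[[i]]), probePattern(profs[[i]]))
    expect_identical(back[[i]]@probeOffset, profs[[i]]@probeOffset)
  }
})

test_that("aligned reference round-trips through FASTA + lineage TSV", {
  d <- tempfile(); dir.create(d)
  fa <- file.path(d, "aln.fasta"); tsv <- file.path(d, "lin.tsv")
  Biostrings::writeXStringSet(alignment(fixRef$aligned), fa)
  write.table(data.frame(names(fixRef$seqs), fixRef$lineageStrings),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  back <- readAlignedReference(fa, tsv, fixRef$regionMap)
  expect_identical(as.character(alignment(back)),
                   as.character(alignment(fixRef$aligned)))
  expect_identical(unname(lineage(back)), unname(fixRef$lineage))
})
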