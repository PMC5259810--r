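test_that("Phred conversion is the closed form 10^(-q/10)", {
  expect_equal(phredErrorProb(30), 0.001)
  expect_equal(phredErrorProb(0), 1.0)
  expect_equal(phredErrorProb(10), 0.1)
  expect_error(phredErrorProb(-1), "non-negative")
})

test_that("PSSM scoring equals position-by-position summation", {
  zero <- matrix(0, 23, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  expect_equal(pssmScore(zero, strrep("A", 23)), 0)

  set.seed(10)
  mat <- matrix(rnorm(92), 23, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  ## consensus window attains the matrix maximum
  cons <- paste(c("A", "C", "G", "T")[apply(mat, 1, which.max)], collapse = "")
  expect_equal(pssmScore(mat, cons), sum(apply(mat, 1, max)))

  ## brute-force oracle: naive loop, independent of the vectorized path
  naiveScore <- function(m, w) {
    s <- 0
    for (i in 1:23) {
      b <- substr(w, i, i)
      s <- s + unname(if (b == "N") min(m[i, ]) else m[i, b])
    }
    s
  }
  for (k in 1:200) {
    w <- paste(sample(c("A", "C", "G", "T", "N"), 23, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    expect_equal(pssmScore(mat, w), naiveScore(mat, w), tolerance = 1e-12)
  }
  expect_error(pssmScore(mat, "ACGT"), "exactly 23")
})

test_that("a read of exactly RS + TS yields one observation", {
  read <- tagBearingRead(taxon = 1L, len = 56L)
  expect_equal(nchar(read), 56L)
  obs <- scanRead("r1", read, q40(56), fixProf)
  expect_equal(nrow(obs), 1L)
  expect_identical(obs$strand, "+")
  expect_equal(obs$rsOffset, 0L)
  ## the tag is the 33 nt immediately after the 23-nt RS
  expect_identical(obs$tag, substr(read, 24, 56))
  expect_equal(obs$minTagQuality, 40L)
})

test_that("insufficient tag length drops the hit", {
  read <- tagBearingRead(taxon = 1L, len = 43L)   # RS + 20 nt only
  obs <- scanRead("r1", read, q40(43), fixProf)
  expect_equal(nrow(obs), 0L)
})

test_that("reverse-complement reads report gene-sense tags on strand -", {
  read <- tagBearingRead(taxon = 2L, len = 70L)
  fwd <- scanRead("r1", read, profiles = fixProf)
  rcRead <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  rev <- scanRead("r1", rcRead, profiles = fixProf)
  expect_equal(nrow(fwd), 1L)
  expect_equal(nrow(rev), 1L)
  expect_identical(rev$strand, "-")
  expect_identical(rev$tag, fwd$tag)          # gene-sense orientation
  expect_identical(rev$longSeq, fwd$longSeq)
  expect_equal(rev$rsOffset, fwd$rsOffset)    # mirrored coordinate
})

test_that("one low-quality tag base disqualifies the observation", {
  read <- tagBearingRead(taxon = 1L, len = 56L)
  qual <- q40(56)
  substr(qual, 30, 30) <- "5"                 # Q20 inside the tag
  obs <- scanRead("r1", read, qual, fixProf)
  expect_equal(nrow(obs), 0L)
  ## Q20 outside the tag is harmless
  qual2 <- q40(56)
  substr(qual2, 3, 3) <- "5"                  # inside the RS, not the tag
  expect_equal(nrow(scanRead("r1", read, qual2, fixProf)), 1L)
})

test_that("ambiguity bases in the tag disqualify the observation", {
  read <- tagBearingRead(taxon = 1L, len = 56L)
  substr(read, 40, 40) <- "N"
  expect_equal(nrow(scanRead("r1", read, q40(56), fixProf)), 0L)
})

test_that("long sequences begin with the tag and need full quality", {
  read <- tagBearingRead(taxon = 3L, len = 23L + 60L)
  obs <- scanRead("r1", read, q40(83), fixProf)
  expect_equal(nrow(obs), 1L)
  expect_false(is.na(obs$longSeq))
  expect_equal(nchar(obs$longSeq), 60L)
  expect_identical(substr(obs$longSeq, 1, 33), obs$tag)
  ## low quality in the long tail keeps the tag but drops the long variant
  qual <- q40(83)
  substr(qual, 80, 80) <- "5"
  obs2 <- scanRead("r1", read, qual, fixProf)
  expect_equal(nrow(obs2), 1L)
  expect_true(is.na(obs2$longSeq))
})

test_that("scanning is strand-symmetric over a read set", {
  reads <- simulateReads(fixRef, fixSpec, n = 2000, seed = 7)
  obs <- scanReads(reads, fixProf)
  rc <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(
      as.character(reads))),
    Biostrings::PhredQuality(Biostrings::reverse(
      Biostrings::BStringSet(Biostrings::quality(reads)))))
  names(rc) <- names(reads)
  obsRC <- scanReads(rc, fixProf)
  expect_equal(nrow(obs), nrow(obsRC))
  o1 <- obs[order(obs$readId), ]
  o2 <- obsRC[order(obsRC$readId), ]
  expect_identical(o1$tag, o2$tag)
  expect_identical(o1$readId, o2$readId)
  ## strands flip; offsets agree because both are reported gene-sense
  expect_true(all(o1$strand != o2$strand))
  expect_equal(o1$rsOffset, o2$rsOffset)
})

test_that("the probe prefilter only removes, never adds, confirmed hits", {
  reads <- simulateReads(fixRef, fixSpec, n = 3000, seed = 8)
  pre <- scanReads(reads, fixProf, scanConfig(probeMismatches = 1))
  full <- scanReads(reads, fixProf, scanConfig(probeMismatches = Inf))
  keyPre <- paste(pre$readId, pre$tag)
  keyFull <- paste(full$readId, full$tag)
  expect_true(all(keyPre %in% keyFull))
  ## measured loss at the default budget is below 1%
  expect_gte(length(keyPre), 0.99 * length(keyFull))
})

test_that("quality/sequence length mismatches reject the read, not the run", {
  good <- tagBearingRead(taxon = 1L, len = 56L)
  reads <- Biostrings::DNAStringSet(c(r1 = good, r2 = good))
  quals <- Biostrings::BStringSet(c(q40(56), q40(50)))
  expect_warning(obs <- scanReads(reads, fixProf, qualities = quals),
                 "length mismatch")
  expect_equal(nrow(obs), 1L)
  expect_identical(obs$readId, "r1")
})

test_that("the best-scoring profile wins when several target one region", {
  profs <- buildProfileSet(fixRef$aligned, "V4", supplements = TRUE)
  reads <- simulateReads(fixRef, fixSpec, n = 1000, seed = 9)
  obs <- scanReads(reads, profs)
  ## one observation per read at most (single region)
  expect_equal(anyDuplicated(obs$readId), 0L)
})
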