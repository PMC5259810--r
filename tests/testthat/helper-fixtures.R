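## Shared fixtures, built once per test run. Small community: fast to
## generate, big enough to exercise hierarchy and profile training.

fixSpec <- communitySpec(nTaxa = 16L, nReads = 8000, seed = 101L)
fixRef <- makeReference(fixSpec)
fixProf <- buildProfile(fixRef$aligned, "V4", "bacteria")

## Hand-built gap-aware alignment for entropy / PSSM unit tests.
## Columns: 1 all-A, 2 uniform ACGT, 3 A/C half-half, 4 all-gap, then a
## filler region so a region map can exist.
tinyAlignment <- function() {
  seqs <- c(a = "AAA-ACGTACGTACGTACGTACGTACGTACGTACGT",
            b = "ACA-ACGTACGTACGTACGTACGTACGTACGTACGT",
            c = "AGC-ACGTACGTACGTACGTACGTACGTACGTACGT",
            d = "ATC-ACGTACGTACGTACGTACGTACGTACGTACGT")
  alignedReference(seqs, rep("k__Bacteria; p__P1", 4),
                   data.frame(region = "V1", start = 30L, end = 36L))
}

## A read guaranteed to contain profile RS + tag for a given taxon:
## cut from the reference at the observed RS offset.
tagBearingRead <- function(taxon = 1L, pad = 0L, len = 56L,
                           profile = fixProf, ref = fixRef) {
  obs <- scanReads(ref$seqs[taxon], profile)
  stopifnot(nrow(obs) == 1L)
  start <- obs$rsOffset + 1L - pad
  substr(as.character(ref$seqs[[taxon]]), start, start + len - 1L)
}

q40 <- function(n) strrep("I", n)   # Phred 40 at offset 33

`%||%` <- function(a, b) if (is.null(a)) b else a
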