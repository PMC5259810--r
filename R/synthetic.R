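#' Specification of a synthetic SSU community
#'
#' Describes the generative model used for validation fixtures: reference
#' sequences built from alternating conserved and hypervariable blocks
#' (default 10 conserved and 9 variable blocks, mirroring the canonical
#' SSU architecture), a nested taxonomy whose sequence similarity tracks
#' lineage depth, and error-bearing shotgun reads with Phred qualities
#' consistent with the simulated error rate.
#'
#' @param nTaxa number of leaf taxa (species).
#' @param branching children per node at each rank k,p,c,o,f,g (species
#'   indices are derived from \code{nTaxa}); used to lay out the nested
#'   lineage labels.
#' @param nConserved,conservedLen number and length (nt) of conserved
#'   blocks.
#' @param nVariable,variableLen number and length (nt) of variable blocks
#'   (the V-regions V1..V9).
#' @param conservedMutRate per-base substitution rate of each taxon's
#'   conserved blocks away from the master template (default 0.02).
#' @param variableDiversity per-base substitution rate applied at each
#'   rank step when evolving variable blocks down the lineage tree; 0
#'   collapses every taxon to identical V-regions.
#' @param abundances per-taxon weights (normalized to sum to 1); uniform
#'   when NULL.
#' @param readLength simulated read length (nt).
#' @param nReads number of reads to simulate.
#' @param perBaseError per-base substitution error rate of simulated
#'   reads; the Phred string reflects it (\code{Q = -10 log10 e}).
#' @param seed RNG seed; a fixed seed makes all generated artifacts
#'   byte-identical across runs.
#' @return object of class \code{CommunitySpec} (a named list).
#' @examples
#' spec <- communitySpec(nTaxa = 20, seed = 1)
#' @export
communitySpec <- function(nTaxa = 20L,
                          branching = c(1L, 3L, 2L, 2L, 2L, 2L),
                          nConserved = 10L, conservedLen = 40L,
                          nVariable = 9L, variableLen = 70L,
                          conservedMutRate = 0.02,
                          variableDiversity = 0.15,
                          abundances = NULL,
                          readLength = 150L,
                          nReads = 1e5,
                          perBaseError = 0.001,
                          seed = 1L) {
  stopifnot(nTaxa >= 1L, nConserved == nVariable + 1L,
            conservedMutRate >= 0, conservedMutRate <= 1,
            variableDiversity >= 0, variableDiversity <= 1,
            perBaseError >= 0, perBaseError <= 1)
  if (is.null(abundances)) abundances <- rep(1 / nTaxa, nTaxa)
  stopifnot(length(abundances) == nTaxa, all(abundances >= 0))
  abundances <- abundances / sum(abundances)
  structure(list(
    nTaxa = as.integer(nTaxa), branching = as.integer(branching),
    nConserved = as.integer(nConserved),
    conservedLen = as.integer(conservedLen),
    nVariable = as.integer(nVariable),
    variableLen = as.integer(variableLen),
    conservedMutRate = conservedMutRate,
    variableDiversity = variableDiversity,
    abundances = abundances,
    readLength = as.integer(readLength),
    nReads = nReads, perBaseError = perBaseError,
    seed = as.integer(seed)), class = "CommunitySpec")
}

## Nested mixed-radix group index per taxon at ranks k..g; species = leaf.
## Returns integer matrix nTaxa x 7 of global group indices.
.lineageGroups <- function(nTaxa, branching) {
  idx <- matrix(0L, nrow = nTaxa, ncol = 7L)
  idx[, 7L] <- seq_len(nTaxa) - 1L
  cur <- idx[, 7L]
  for (j in 6:1) {
    cur <- cur %/% branching[j]          # children per node at rank j
    idx[, j] <- cur
  }
  idx
}

#' Generate a synthetic aligned SSU reference with lineages
#'
#' Conserved blocks are drawn once from a master template and mutated
#' independently in each taxon at \code{conservedMutRate}; variable blocks
#' are evolved down the lineage tree (one substitution round of rate
#' \code{variableDiversity} per rank step) so that sequence similarity
#' tracks taxonomic relatedness. Block lengths are equal across taxa, so
#' the alignment is trivial (gap-free) and V-region coordinates are known
#' exactly.
#'
#' @param spec a [communitySpec()].
#' @return list with elements \code{aligned} (an
#'   [AlignedReference-class]), \code{seqs} (unaligned
#'   \code{DNAStringSet}), \code{lineage} (7-column rank matrix),
#'   \code{lineageStrings} (semicolon strings) and \code{regionMap}.
#' @export
makeReference <- function(spec) {
  set.seed(spec$seed)
  nT <- spec$nTaxa
  groups <- .lineageGroups(nT, spec$branching)

  ## master conserved blocks
  consMaster <- lapply(seq_len(spec$nConserved), function(i)
    strsplit(.randomDnaString(spec$conservedLen), "")[[1L]])

  ## variable blocks evolved down the tree: per rank level keep the group
  ## sequences; leaves read off the species-level sequences
  varLeaf <- vector("list", spec$nVariable)
  for (v in seq_len(spec$nVariable)) {
    parent <- list(strsplit(.randomDnaString(spec$variableLen), "")[[1L]])
    parentIdx <- rep(1L, nT)
    for (j in 2:7) {
      gids <- groups[, j]
      ug <- unique(gids)
      child <- vector("list", length(ug))
      childIdx <- integer(nT)
      for (g in seq_along(ug)) {
        sel <- gids == ug[g]
        p <- parent[[parentIdx[which(sel)[1L]]]]
        child[[g]] <- .mutateBases(p, spec$variableDiversity)
        childIdx[sel] <- g
      }
      parent <- child
      parentIdx <- childIdx
    }
    varLeaf[[v]] <- lapply(parentIdx, function(g) parent[[g]])
  }

  ## assemble per-taxon sequences: C1 V1 C2 V2 ... V9 C10
  seqs <- character(nT)
  for (t in seq_len(nT)) {
    parts <- character(spec$nConserved + spec$nVariable)
    k <- 1L
    for (b in seq_len(spec$nConserved)) {
      parts[k] <- paste(.mutateBases(consMaster[[b]],
                                     spec$conservedMutRate), collapse = "")
      k <- k + 1L
      if (b <= spec$nVariable) {
        parts[k] <- paste(varLeaf[[b]][[t]], collapse = "")
        k <- k + 1L
      }
    }
    seqs[t] <- paste(parts, collapse = "")
  }
  ids <- sprintf("tax%05d", seq_len(nT))
  names(seqs) <- ids

  ## lineage labels from group indices
  lin <- matrix("", nrow = nT, ncol = 7L, dimnames = list(ids, RANKS))
  lin[, 1L] <- "Bacteria"
  for (j in 2:7)
    lin[, j] <- sprintf("%s%03d", RANKS[j], groups[, j] + 1L)

  blockLen <- spec$conservedLen + spec$variableLen
  vstart <- spec$conservedLen + (seq_len(spec$nVariable) - 1L) * blockLen
  regionMap <- data.frame(
    region = paste0("V", seq_len(spec$nVariable)),
    start = vstart, end = vstart + spec$variableLen)

  dss <- Biostrings::DNAStringSet(seqs)
  list(aligned = alignedReference(dss, lin, regionMap),
       seqs = dss, lineage = lin,
       lineageStrings = formatLineage(lin),
       regionMap = regionMap)
}

## quality char for an error rate (Q = -10 log10 e, capped at Q40 for e=0)
.qualityChar <- function(e, offset = 33L) {
  q <- if (e <= 0) 40L else as.integer(round(-10 * log10(e)))
  intToUtf8(min(q, 93L) + offset)
}

#' Simulate shotgun reads from a synthetic community
#'
#' Reads are drawn from taxa weighted by the community abundances, with
#' uniform start positions ("shotgun" mode) or constrained to cover one
#' V-region's recognition site and tag ("anchored" mode, useful for
#' error-model studies). Substitution errors are applied at
#' \code{perBaseError} per base (no indels — the tag scheme is
#' fixed-length and the error analysis considers substitutions only), and
#' the constant Phred string matches the simulated error rate. About half
#' the reads are emitted as reverse complements.
#'
#' @param ref output of [makeReference()].
#' @param spec the [communitySpec()].
#' @param n number of reads (default \code{spec$nReads}).
#' @param mode \code{"shotgun"} or \code{"anchored"}.
#' @param region V-region to anchor on (anchored mode).
#' @param side flank carrying the RS (anchored mode).
#' @param tagLength,longLength tag geometry used to size the anchored
#'   window.
#' @param revCompFrac fraction of reads emitted on the reverse strand.
#' @param seed RNG seed (default \code{spec$seed + 1} so reference
#'   generation and read simulation are decoupled).
#' @return \link[Biostrings]{QualityScaledDNAStringSet} with per-read
#'   origin metadata (taxon index, 1-based start, strand) in
#'   \code{mcols()}.
#' @export
simulateReads <- function(ref, spec, n = spec$nReads,
                          mode = c("shotgun", "anchored"),
                          region = "V4",
                          side = c("upstream", "downstream"),
                          tagLength = 33L, longLength = 60L,
                          revCompFrac = 0.5,
                          seed = spec$seed + 1L) {
  mode <- match.arg(mode)
  side <- match.arg(side)
  set.seed(seed)
  n <- as.integer(n)
  L <- spec$readLength
  refChars <- as.character(ref$seqs)
  refLen <- nchar(refChars[1L])
  taxon <- sample.int(spec$nTaxa, n, replace = TRUE,
                      prob = spec$abundances)

  if (mode == "shotgun") {
    start <- sample.int(refLen - L + 1L, n, replace = TRUE)
  } else {
    rm <- ref$regionMap
    row <- rm[rm$region == region, ]
    ## 1-based RS start on the (gap-free) reference
    rsStart <- if (side == "upstream") row$start - RS_LENGTH + 1L
               else row$end + 1L
    span <- RS_LENGTH + tagLength                 # bases that must be covered
    if (side == "upstream") {
      lo <- max(1L, rsStart + span - L)
      hi <- min(rsStart, refLen - L + 1L)
    } else {
      lo <- max(1L, rsStart + RS_LENGTH - L)
      hi <- min(rsStart - tagLength, refLen - L + 1L)
    }
    if (hi < lo) stop("read length too short to cover RS + tag")
    start <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  }

  reads <- substr(refChars[taxon], start, start + L - 1L)

  ## substitution errors: exact per-read Binomial(L, e) error counts
  e <- spec$perBaseError
  if (e > 0) {
    nErr <- stats::rbinom(n, L, e)
    one <- which(nErr == 1L)
    if (length(one)) {
      pos <- sample.int(L, length(one), replace = TRUE)
      cur <- substr(reads[one], pos, pos)
      newb <- .substituteBase(cur)
      substr(reads[one], pos, pos) <- newb
    }
    multi <- which(nErr >= 2L)
    for (i in multi) {
      pos <- sample.int(L, nErr[i])
      for (p in pos) {
        cur <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- .substituteBase(cur)
      }
    }
  }

  strand <- ifelse(runif(n) < revCompFrac, "-", "+")
  rc <- strand == "-"
  if (any(rc)) {
    reads[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[rc])))
  }
  qchar <- .qualityChar(e)
  qual <- strrep(qchar, L)
  ids <- sprintf("read%07d", seq_len(n))
  out <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads, ids)),
    Biostrings::PhredQuality(rep(qual, n)))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    taxon = taxon, start = start, strand = strand)
  out
}

## uniform substitution to one of the other three bases, vectorized
.substituteBase <- function(base) {
  offs <- sample.int(3L, length(base), replace = TRUE)
  idx <- match(base, DNA_ALPHABET4)
  alt <- matrix(c(2L, 3L, 4L,   # A ->
                  1L, 3L, 4L,   # C ->
                  1L, 2L, 4L,   # G ->
                  1L, 2L, 3L),  # T ->
                nrow = 4L, byrow = TRUE)
  DNA_ALPHABET4[alt[cbind(idx, offs)]]
}

#' Generate non-SSU faux fragments for false-positive-rate estimation
#'
#' Emits fixed-length fragments of random uniform-composition sequence,
#' non-overlapping by construction, as used to measure the detector's
#' empirical false-positive rate.
#'
#' @param nFragments number of fragments.
#' @param fragLen fragment length (default 80 nt).
#' @param seed RNG seed.
#' @return \link[Biostrings]{DNAStringSet}.
#' @export
fauxFragments <- function(nFragments, fragLen = 80L, seed = 1L) {
  set.seed(seed)
  nFragments <- as.integer(nFragments)
  s <- .randomDnaString(nFragments * fragLen)
  Biostrings::DNAStringSet(Biostrings::DNAString(s),
                           start = seq(1L, nFragments * fragLen,
                                       by = fragLen),
                           width = fragLen)
}

#' Write a ready-made synthetic test set to disk
#'
#' Emits the reference (unaligned FASTA + aligned FASTA + lineage TSV +
#' region map TSV) and one or more samples of simulated reads as gzipped
#' FASTQ — a complete fixture for exercising the full pipeline.
#'
#' @param dir output directory (created if needed).
#' @param spec a [communitySpec()].
#' @param nSamples number of read samples to simulate.
#' @return named list of the written paths, invisibly.
#' @export
writeFixtures <- function(dir, spec = communitySpec(), nSamples = 2L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- makeReference(spec)
  paths <- list(
    fasta = file.path(dir, "reference.fasta"),
    alignedFasta = file.path(dir, "reference.aligned.fasta"),
    lineage = file.path(dir, "reference.lineage.tsv"),
    regions = file.path(dir, "reference.regions.tsv"))
  Biostrings::writeXStringSet(ref$seqs, paths$fasta)
  Biostrings::writeXStringSet(alignment(ref$aligned), paths$alignedFasta)
  write.table(data.frame(names(ref$seqs), ref$lineageStrings),
              paths$lineage, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(ref$regionMap, paths$regions, sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (s in seq_len(nSamples)) {
    reads <- simulateReads(ref, spec, seed = spec$seed + s)
    fq <- file.path(dir, sprintf("sample%d.fastq.gz", s))
    Biostrings::writeQualityScaledXStringSet(reads, fq, compress = TRUE)
    paths[[sprintf("sample%d", s)]] <- fq
  }
  invisible(paths)
}
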