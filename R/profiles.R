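#' Profile-construction settings
#'
#' Collects the tunable parameters of recognition-profile training.
#'
#' @param pseudocount additive smoothing count per base in the PSSM.
#' @param background length-4 base composition prior (sums to 1).
#' @param shiftRange the RS window is shift-searched within +/- this many
#'   alignment columns of the nominal V-region boundary, keeping the shift
#'   with minimal mean column entropy.
#' @param probeLength length of the degenerate probe run selected inside
#'   the RS window (lowest mean-entropy run of this length).
#' @param probeFreqMin bases with at least this frequency at a probe column
#'   enter the degenerate IUPAC code.
#' @param sensitivityTarget training sensitivity the score threshold must
#'   achieve; the threshold is the largest value at which at least this
#'   fraction of training sequences score at or above it at the true site.
#' @param tagLength tag (TS) length in nt.
#' @param longLength long-variant length in nt.
#' @param maxMeanEntropy construction fails when the best window's mean
#'   column entropy exceeds this many bits (not conserved enough to be a
#'   recognition sequence).
#' @param missRate in [buildTaxonProfiles()]: a supplementary profile is
#'   trained for every phylum whose members miss the universal threshold at
#'   a rate above this.
#' @return named list of settings.
#' @export
profileConfig <- function(pseudocount = 0.5,
                          background = rep(0.25, 4),
                          shiftRange = 5L,
                          probeLength = 8L,
                          probeFreqMin = 0.05,
                          sensitivityTarget = 0.95,
                          tagLength = 33L,
                          longLength = 60L,
                          maxMeanEntropy = 1.0,
                          missRate = 0.05) {
  stopifnot(pseudocount > 0, length(background) == 4L,
            all(background > 0), abs(sum(background) - 1) < 1e-8,
            probeLength >= 6L, tagLength >= 1L, tagLength <= longLength)
  list(pseudocount = pseudocount, background = background,
       shiftRange = as.integer(shiftRange), probeLength = as.integer(probeLength),
       probeFreqMin = probeFreqMin, sensitivityTarget = sensitivityTarget,
       tagLength = as.integer(tagLength), longLength = as.integer(longLength),
       maxMeanEntropy = maxMeanEntropy, missRate = missRate)
}

## Base counts per column of an aligned (gapped) DNAStringSet, columns sel
.columnCounts <- function(aln, cols) {
  cm <- Biostrings::consensusMatrix(aln, baseOnly = TRUE)
  ## rows A,C,G,T,other; gaps and ambiguity land in "other"
  t(cm[DNA_ALPHABET4, cols + 1L, drop = FALSE])
}

#' Shannon entropy of an alignment column
#'
#' Entropy (bits) of the A/C/G/T frequency distribution at one alignment
#' column; gap characters are excluded from the denominator. An all-gap
#' column carries no information and returns the maximum of 2 bits.
#'
#' @param ref an [AlignedReference-class].
#' @param col 0-based alignment column.
#' @return entropy in bits, in \code{[0, 2]}.
#' @examples
#' ref <- alignedReference(c(a = "AAT", b = "AAT"), c("k__B", "k__B"),
#'                         data.frame(region = "V1", start = 2, end = 3))
#' columnEntropy(ref, 0)  # 0: perfectly conserved
#' @export
columnEntropy <- function(ref, col) {
  col <- as.integer(col)
  w <- Biostrings::width(ref@alignment)[1L]
  if (col < 0L || col >= w)
    stop("column index out of range [0, ", w, ")")
  counts <- .columnCounts(ref@alignment, col)[1L, ]
  .entropyFromCounts(counts)
}

.entropyFromCounts <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(2.0)
  p <- counts[counts > 0] / n
  -sum(p * log2(p))
}

## Entropy per column for a block of columns (vectorized)
.columnEntropies <- function(aln, cols) {
  cc <- .columnCounts(aln, cols)
  apply(cc, 1L, .entropyFromCounts)
}

#' Build a PSSM over a 23-column alignment window
#'
#' Per-position base-2 log-odds weights against a background composition,
#' with additive smoothing:
#' \deqn{w_{ib} = \log_2 \frac{(c_{ib} + \alpha)/(N_i + 4\alpha)}{\pi_b}}
#' where \eqn{c_{ib}} is the count of base \eqn{b} at window position
#' \eqn{i}, \eqn{N_i} the non-gap count, \eqn{\alpha} the pseudocount and
#' \eqn{\pi_b} the background. All-gap positions are uninformative and get
#' a zero row.
#'
#' @param ref an [AlignedReference-class].
#' @param windowStart 0-based alignment column where the 23-nt window
#'   starts.
#' @param pseudocount,background see [profileConfig()].
#' @param which optional integer/logical subset of sequences to train on.
#' @return 23 x 4 numeric matrix, columns \code{A,C,G,T}.
#' @export
buildPssm <- function(ref, windowStart, pseudocount = 0.5,
                      background = rep(0.25, 4), which = NULL) {
  windowStart <- as.integer(windowStart)
  w <- Biostrings::width(ref@alignment)[1L]
  if (windowStart < 0L || windowStart + RS_LENGTH > w)
    stop("23-column window [", windowStart, ", ", windowStart + RS_LENGTH,
         ") does not fit in alignment of length ", w)
  aln <- ref@alignment
  if (!is.null(which)) aln <- aln[which]
  counts <- .columnCounts(aln, windowStart + seq_len(RS_LENGTH) - 1L)
  n <- rowSums(counts)
  m <- log2(((counts + pseudocount) / (n + 4 * pseudocount)) /
              rep(background, each = RS_LENGTH))
  m[n == 0L, ] <- 0
  dimnames(m) <- list(NULL, DNA_ALPHABET4)
  m
}

## IUPAC degenerate consensus of window columns; bases with freq >= freqMin
.iupacConsensus <- function(counts, freqMin) {
  apply(counts, 1L, function(cc) {
    n <- sum(cc)
    if (n == 0L) return("N")
    keep <- DNA_ALPHABET4[cc / n >= freqMin]
    if (length(keep) == 0L) keep <- DNA_ALPHABET4[which.max(cc)]
    if (length(keep) == 4L) return("N")
    Biostrings::mergeIUPACLetters(paste(sort(keep), collapse = ""))
  })
}

## RS window columns (0-based start) for a region flank, before shifting
.nominalWindowStart <- function(ref, region, side) {
  rm <- ref@regionMap
  row <- rm[rm$region == region, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("region '", region, "' not present in the reference regionMap")
  if (side == "upstream") row$start - RS_LENGTH else row$end
}

## Degapped true-site window sequences for training sequences; NA when the
## window contains gaps or ambiguity for that sequence
.trueSiteWindows <- function(aln, windowStart) {
  win <- Biostrings::subseq(aln, start = windowStart + 1L, width = RS_LENGTH)
  s <- as.character(win)
  s[grepl("[^ACGT]", s)] <- NA_character_
  s
}

#' Train a universal recognition profile for one V-region flank
#'
#' Selects the 23-column window flanking the region (shift-searched within
#' \code{+/- shiftRange} columns to minimise mean column entropy), builds
#' the PSSM, derives the degenerate probe pattern from the most conserved
#' probe-length run inside the window, and sets the score threshold to the
#' largest value at which at least \code{sensitivityTarget} of the training
#' sequences score at or above it at their true site.
#'
#' @param ref an [AlignedReference-class].
#' @param region region name present in \code{regionMap(ref)}.
#' @param domain \code{bacteria}, \code{archaea} or \code{eukaryota};
#'   training is restricted to sequences whose kingdom matches
#'   (case-insensitively). \code{"all"} uses every sequence.
#' @param side which flank carries the RS: \code{upstream} (default) or
#'   \code{downstream}.
#' @param config see [profileConfig()].
#' @param scope profile scope label; \code{"universal"} for the main
#'   profile, a taxon name for supplementary profiles.
#' @param which optional explicit subset of training sequences (indices),
#'   applied after the domain filter.
#' @return a [RecognitionProfile-class].
#' @examples
#' spec <- communitySpec(nTaxa = 12, seed = 7)
#' ref <- makeReference(spec)
#' p <- buildProfile(ref$aligned, "V4", "bacteria")
#' p
#' @export
buildProfile <- function(ref, region, domain = "bacteria",
                         side = c("upstream", "downstream"),
                         config = profileConfig(),
                         scope = "universal", which = NULL) {
  side <- match.arg(side)
  sel <- .domainSubset(ref, domain)
  if (!is.null(which)) sel <- intersect(sel, which)
  if (length(sel) < 2L)
    stop("need at least 2 training sequences for domain '", domain, "'")
  aln <- ref@alignment[sel]

  nominal <- .nominalWindowStart(ref, region, side)
  shifts <- -config$shiftRange:config$shiftRange
  alnLen <- Biostrings::width(aln)[1L]
  starts <- nominal + shifts
  starts <- starts[starts >= 0L & starts + RS_LENGTH <= alnLen]
  if (length(starts) == 0L)
    stop("RS window for region '", region, "' (", side,
         ") falls outside the alignment")
  meanEnt <- vapply(starts, function(s)
    mean(.columnEntropies(aln, s + seq_len(RS_LENGTH) - 1L)), numeric(1))
  windowStart <- starts[which.min(meanEnt)]
  bestEnt <- min(meanEnt)
  if (bestEnt > config$maxMeanEntropy)
    stop("no sufficiently conserved RS window for region '", region,
         "' (", side, "): best mean entropy ", round(bestEnt, 3),
         " bits exceeds ", config$maxMeanEntropy)

  mat <- buildPssm(ref, windowStart, config$pseudocount, config$background,
                   which = sel)

  ## probe: most conserved probeLength-run inside the window
  winCols <- windowStart + seq_len(RS_LENGTH) - 1L
  ent <- .columnEntropies(aln, winCols)
  nRuns <- RS_LENGTH - config$probeLength + 1L
  runMeans <- vapply(seq_len(nRuns), function(i)
    mean(ent[i:(i + config$probeLength - 1L)]), numeric(1))
  probeStart <- which.min(runMeans)          # 1-based within window
  probeCounts <- .columnCounts(aln,
    winCols[probeStart:(probeStart + config$probeLength - 1L)])
  probe <- paste(.iupacConsensus(probeCounts, config$probeFreqMin),
                 collapse = "")

  ## threshold sweep at the true sites
  sites <- .trueSiteWindows(aln, windowStart)
  ok <- !is.na(sites)
  if (sum(ok) < 2L)
    stop("too few gap-free training sites in the RS window")
  scores <- .scoreWindowStrings(mat, sites[ok])
  sorted <- sort(scores, decreasing = TRUE)
  k <- ceiling(config$sensitivityTarget * length(sorted))
  threshold <- sorted[k]
  trainSens <- mean(scores >= threshold)

  new("RecognitionProfile",
      profileId = paste(region, tolower(domain), scope, side, sep = "."),
      targetRegion = region, targetDomain = tolower(domain), side = side,
      pssm = mat, probePattern = probe,
      probeOffset = probeStart - 1L,
      scoreThreshold = threshold,
      tagLength = config$tagLength, longLength = config$longLength,
      scope = scope,
      metadata = list(trainingSensitivity = trainSens,
                      windowMeanEntropy = bestEnt,
                      windowStart = windowStart,
                      nTraining = sum(ok)))
}

.domainSubset <- function(ref, domain) {
  if (identical(domain, "all")) return(seq_along(ref@alignment))
  k <- tolower(ref@lineage[, "k"])
  which(k == tolower(domain))
}

#' Train supplementary taxon-specific profiles
#'
#' For every phylum whose members miss the universal profile's threshold at
#' a rate above \code{config$missRate}, trains an additional profile on that
#' phylum alone (scope set to the phylum label). Returns an empty list when
#' the universal profile already captures every phylum adequately.
#'
#' @inheritParams buildProfile
#' @param universal the universal [RecognitionProfile-class] for the same
#'   region/side (built first).
#' @return list of [RecognitionProfile-class] objects (possibly empty).
#' @export
buildTaxonProfiles <- function(ref, region, domain = "bacteria",
                               side = c("upstream", "downstream"),
                               config = profileConfig(),
                               universal = NULL) {
  side <- match.arg(side)
  if (is.null(universal))
    universal <- buildProfile(ref, region, domain, side, config)
  sel <- .domainSubset(ref, domain)
  windowStart <- universal@metadata$windowStart
  sites <- .trueSiteWindows(ref@alignment[sel], windowStart)
  ok <- !is.na(sites)
  scores <- rep(-Inf, length(sel))
  scores[ok] <- .scoreWindowStrings(universal@pssm, sites[ok])
  miss <- scores < universal@scoreThreshold
  phyla <- ref@lineage[sel, "p"]
  out <- list()
  for (ph in sort(unique(phyla[nzchar(phyla)]))) {
    inPh <- phyla == ph
    if (sum(inPh) >= 2L && mean(miss[inPh]) > config$missRate) {
      prof <- buildProfile(ref, region, domain, side, config,
                           scope = ph, which = sel[inPh])
      out[[ph]] <- prof
    }
  }
  unname(out)
}

#' Serialize recognition profiles to JSON
#'
#' Writes a versioned JSON document holding the full profile set (matrices
#' as nested arrays, all configuration echoed). [readProfiles()] restores
#' the profiles bit-identically.
#'
#' @param profiles a [RecognitionProfile-class] or list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProfiles <- function(profiles, path) {
  if (is(profiles, "RecognitionProfile")) profiles <- list(profiles)
  doc <- list(
    format = "riboscan-profiles",
    version = 1L,
    profiles = lapply(profiles, function(p) list(
      profileId = p@profileId, targetRegion = p@targetRegion,
      targetDomain = p@targetDomain, side = p@side,
      pssm = unname(p@pssm),          # 23 x 4 matrix -> nested row arrays
      probePattern = p@probePattern, probeOffset = p@probeOffset,
      scoreThreshold = p@scoreThreshold,
      tagLength = p@tagLength, longLength = p@longLength,
      scope = p@scope, metadata = p@metadata))
  )
  ## 17 significant digits: IEEE doubles reload bit-identically
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read recognition profiles from JSON
#'
#' @param path file written by [writeProfiles()].
#' @return list of [RecognitionProfile-class] objects.
#' @export
readProfiles <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(doc$format, "riboscan-profiles"))
    stop("not a riboscan profile document: ", path)
  lapply(doc$profiles, function(p) {
    m <- p$pssm
    if (is.list(m)) m <- do.call(rbind, m)
    dimnames(m) <- list(NULL, DNA_ALPHABET4)
    new("RecognitionProfile",
        profileId = p$profileId, targetRegion = p$targetRegion,
        targetDomain = p$targetDomain, side = p$side, pssm = m,
        probePattern = p$probePattern,
        probeOffset = as.integer(p$probeOffset),
        scoreThreshold = p$scoreThreshold,
        tagLength = as.integer(p$tagLength),
        longLength = as.integer(p$longLength),
        scope = p$scope, metadata = p$metadata)
  })
}

#' Read an aligned reference from FASTA plus a lineage TSV
#'
#' @param fastaPath aligned FASTA (gaps as \code{-} or \code{.}, the latter
#'   converted to \code{-}).
#' @param lineagePath 2-column TSV (no header): sequence id, semicolon
#'   lineage string (Greengenes or SILVA dialect).
#' @param regionMap data.frame of V-region alignment coordinates
#'   (\code{region,start,end}, 0-based half-open).
#' @return an [AlignedReference-class].
#' @export
readAlignedReference <- function(fastaPath, lineagePath, regionMap) {
  aln <- Biostrings::readDNAStringSet(fastaPath)
  names(aln) <- sub("\\s.*$", "", names(aln))
  aln <- Biostrings::DNAStringSet(chartr(".", "-", as.character(aln)))
  lin <- read.delim(lineagePath, header = FALSE, sep = "\t",
                    colClasses = "character")
  m <- parseLineage(lin[[2L]][match(names(aln), lin[[1L]])])
  alignedReference(aln, m, regionMap)
}
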