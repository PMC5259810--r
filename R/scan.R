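#' Phred score to error probability
#'
#' @param q integer Phred quality score(s), \code{q >= 0}.
#' @return \code{10^(-q/10)}; Q30 corresponds to an error probability of
#'   0.001 (0.1\%).
#' @examples
#' phredErrorProb(30)  # 0.001
#' @export
phredErrorProb <- function(q) {
  if (any(q < 0)) stop("Phred scores must be non-negative")
  10^(-q / 10)
}

#' Scanner settings
#'
#' @param qvThreshold minimum Phred quality required of every tag base
#'   (and of every long-sequence base for the long variant to be kept).
#' @param probeMismatches mismatch budget of the probe-pattern prefilter;
#'   \code{Inf} disables the prefilter and evaluates the PSSM at every
#'   position.
#' @param phredOffset ASCII offset of the quality encoding (33 =
#'   Sanger/Illumina 1.8+).
#' @param keepLong extract long variants when enough high-quality sequence
#'   is available.
#' @return named list of settings.
#' @export
scanConfig <- function(qvThreshold = 30L, probeMismatches = 1L,
                       phredOffset = 33L, keepLong = TRUE) {
  list(qvThreshold = as.integer(qvThreshold),
       probeMismatches = probeMismatches,
       phredOffset = as.integer(phredOffset),
       keepLong = isTRUE(keepLong))
}

## Score equal-width (23 nt) window strings against a PSSM; N scores the
## column minimum (conservative worst case). Vectorized via char-matrix
## indexing.
.scoreWindowStrings <- function(mat, windows) {
  if (length(windows) == 0L) return(numeric(0))
  ext <- cbind(mat, N = apply(mat, 1L, min))
  cm <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
               ncol = RS_LENGTH, byrow = TRUE)
  idx <- match(cm, c(DNA_ALPHABET4, "N"))
  if (anyNA(idx)) stop("window contains characters outside {A,C,G,T,N}")
  sc <- matrix(ext[cbind(rep(seq_len(RS_LENGTH), each = nrow(cm)),
                         as.vector(idx))], nrow = nrow(cm))
  rowSums(sc)
}

.scoreWindowSet <- function(mat, windows) {
  ## windows: DNAStringSet of width 23
  if (length(windows) == 0L) return(numeric(0))
  ext <- cbind(mat, N = apply(mat, 1L, min))
  cm <- as.matrix(windows)
  idx <- match(cm, c(DNA_ALPHABET4, "N"))
  idx[is.na(idx)] <- 5L   # other ambiguity codes score like N
  sc <- matrix(ext[cbind(rep(seq_len(RS_LENGTH), each = nrow(cm)),
                         as.vector(idx))], nrow = nrow(cm))
  rowSums(sc)
}

#' Score a 23-nt window against a PSSM
#'
#' Additive log-odds score: the sum of the matrix entries selected by the
#' window's bases. \code{N} contributes the column minimum (worst case).
#'
#' @param mat 23 x 4 PSSM (columns A,C,G,T) or a
#'   [RecognitionProfile-class].
#' @param window character string of length 23 over \code{A,C,G,T,N}.
#' @return score in bits.
#' @export
pssmScore <- function(mat, window) {
  if (is(mat, "RecognitionProfile")) mat <- mat@pssm
  if (nchar(window) != RS_LENGTH)
    stop("window must be exactly ", RS_LENGTH, " nt")
  .scoreWindowStrings(mat, window)
}

## Candidate RS start positions (1-based) per sequence for one profile.
## Returns data.table(seqIdx, rsStart). An optional environment caches the
## probe-match positions so profiles sharing a probe pattern are matched
## once per strand.
.candidateStarts <- function(seqs, profile, config, cache = NULL) {
  widths <- Biostrings::width(seqs)
  if (is.finite(config$probeMismatches)) {
    key <- profile@probePattern
    si <- if (!is.null(cache)) cache[[key]] else NULL
    if (is.null(si)) {
      m <- Biostrings::vmatchPattern(
        profile@probePattern, seqs,
        max.mismatch = config$probeMismatches,
        fixed = c(pattern = FALSE, subject = TRUE))
      si <- Biostrings::startIndex(m)   # plain list: fast MIndex accessor
      si[lengths(si) == 0L] <- list(integer(0))
      if (!is.null(cache)) cache[[key]] <- si
    }
    cnt <- lengths(si)
    if (sum(cnt) == 0L)
      return(data.table::data.table(seqIdx = integer(0),
                                    rsStart = integer(0)))
    seqIdx <- rep(seq_along(seqs), cnt)
    rsStart <- unlist(si, use.names = FALSE) - profile@probeOffset
    data.table::data.table(seqIdx = seqIdx, rsStart = rsStart)
  } else {
    ## exhaustive: every position where the RS window fits
    nPos <- pmax(widths - RS_LENGTH + 1L, 0L)
    data.table::data.table(
      seqIdx = rep(seq_along(seqs), nPos),
      rsStart = unlist(lapply(nPos, seq_len), use.names = FALSE))
  }
}

## Scan one oriented strand of a sequence set with one profile.
## quals: BStringSet parallel to seqs, or NULL.
## Returns data.table(seqIdx, rsOffset, score, tag, longSeq, minTagQuality,
## tagQual).
.scanOneStrand <- function(seqs, quals, profile, config, cache = NULL) {
  empty <- data.table::data.table(
    seqIdx = integer(0), rsOffset = integer(0), score = numeric(0),
    tag = character(0), longSeq = character(0),
    minTagQuality = integer(0), tagQual = character(0))
  cand <- .candidateStarts(seqs, profile, config, cache)
  if (nrow(cand) == 0L) return(empty)

  widths <- Biostrings::width(seqs)
  tagLen <- profile@tagLength
  longLen <- profile@longLength
  up <- profile@side == "upstream"

  ## geometry: RS window and tag window must lie inside the read
  w <- widths[cand$seqIdx]
  okRS <- cand$rsStart >= 1L & cand$rsStart + RS_LENGTH - 1L <= w
  if (up) {
    tagStart <- cand$rsStart + RS_LENGTH
    okTag <- tagStart + tagLen - 1L <= w
  } else {
    tagStart <- cand$rsStart - tagLen
    okTag <- tagStart >= 1L
  }
  keep <- okRS & okTag
  cand <- cand[keep]
  tagStart <- tagStart[keep]
  if (nrow(cand) == 0L) return(empty)

  ## PSSM confirmation
  rsWin <- Biostrings::subseq(seqs[cand$seqIdx], start = cand$rsStart,
                              width = RS_LENGTH)
  score <- .scoreWindowSet(profile@pssm, rsWin)
  conf <- score >= profile@scoreThreshold
  cand <- cand[conf]
  tagStart <- tagStart[conf]
  score <- score[conf]
  if (nrow(cand) == 0L) return(empty)

  tag <- as.character(Biostrings::subseq(seqs[cand$seqIdx],
                                         start = tagStart, width = tagLen))
  okACGT <- !grepl("[^ACGT]", tag)

  ## long window: from the tag's RS-adjacent end further into the V-region
  w <- widths[cand$seqIdx]
  if (up) {
    longStart <- cand$rsStart + RS_LENGTH
    longFits <- longStart + longLen - 1L <= w
  } else {
    longStart <- cand$rsStart - longLen
    longFits <- longStart >= 1L
  }

  minQ <- rep(NA_integer_, nrow(cand))
  tagQual <- rep(NA_character_, nrow(cand))
  qOK <- rep(TRUE, nrow(cand))
  longQOK <- rep(TRUE, nrow(cand))
  if (!is.null(quals)) {
    tq <- Biostrings::subseq(quals[cand$seqIdx], start = tagStart,
                             width = tagLen)
    qm <- .qualIntMatrix(tq, config$phredOffset)
    minQ <- .rowMins(qm)
    tagQual <- as.character(tq)
    qOK <- minQ >= config$qvThreshold
    if (config$keepLong && any(longFits)) {
      lf <- which(longFits)
      lq <- Biostrings::subseq(quals[cand$seqIdx[lf]],
                               start = longStart[lf], width = longLen)
      longQOK[lf] <- .rowMins(.qualIntMatrix(lq, config$phredOffset)) >=
        config$qvThreshold
    }
  }

  keep <- okACGT & qOK
  if (!any(keep)) return(empty)

  longSeq <- rep(NA_character_, nrow(cand))
  takeLong <- config$keepLong & longFits & longQOK
  if (any(takeLong & keep)) {
    tl <- which(takeLong & keep)
    ls <- as.character(Biostrings::subseq(seqs[cand$seqIdx[tl]],
                                          start = longStart[tl],
                                          width = longLen))
    ls[grepl("[^ACGT]", ls)] <- NA_character_
    longSeq[tl] <- ls
  }

  data.table::data.table(
    seqIdx = cand$seqIdx[keep],
    rsOffset = cand$rsStart[keep] - 1L,      # 0-based, reported orientation
    score = score[keep],
    tag = tag[keep],
    longSeq = longSeq[keep],
    minTagQuality = minQ[keep],
    tagQual = tagQual[keep])
}

#' Scan reads for recognition sequences and extract tags
#'
#' Both the forward sequence and the reverse complement of every read are
#' screened with each profile's probe-pattern prefilter (allowing
#' \code{probeMismatches} mismatches); candidate sites are confirmed
#' against the profile PSSM at its score threshold, and the adjacent tag
#' (and, when enough sequence is present, the long variant) is extracted.
#' With quality data, an observation is dropped unless every tag base
#' reaches \code{qvThreshold}; tags containing ambiguity codes are dropped.
#' When several profiles target the same region, only the highest-scoring
#' hit per read is kept (ties broken by profile id, then strand, then
#' offset). Tags are always reported in SSU gene-sense orientation so that
#' forward and reverse reads aggregate together.
#'
#' @param reads a \link[Biostrings]{DNAStringSet},
#'   \link[Biostrings]{QualityScaledDNAStringSet}, or character vector.
#' @param profiles a [RecognitionProfile-class] or list of them.
#' @param config see [scanConfig()].
#' @param qualities optional \code{BStringSet}/character of Phred strings
#'   parallel to \code{reads} (ignored when \code{reads} carries its own).
#' @param sampleId sample label attached to every observation.
#' @return a \link[S4Vectors]{DataFrame} of tag observations with columns
#'   \code{readId, sampleId, profileId, region, strand, rsOffset, tag,
#'   longSeq, minTagQuality, tagQual, score}. \code{rsOffset} is the
#'   0-based RS start on the read in reported (gene-sense) orientation.
#' @examples
#' spec <- communitySpec(nTaxa = 8, seed = 3)
#' ref <- makeReference(spec)
#' prof <- buildProfile(ref$aligned, "V4", "bacteria")
#' obs <- scanReads(ref$seqs, prof)
#' head(obs)
#' @export
scanReads <- function(reads, profiles, config = scanConfig(),
                      qualities = NULL, sampleId = "sample1") {
  if (is(profiles, "RecognitionProfile")) profiles <- list(profiles)
  quals <- NULL
  if (is(reads, "QualityScaledDNAStringSet")) {
    quals <- Biostrings::BStringSet(Biostrings::quality(reads))
    reads <- Biostrings::DNAStringSet(as.character(reads))
  } else if (is.character(reads)) {
    reads <- Biostrings::DNAStringSet(reads)
  }
  if (!is.null(qualities) && is.null(quals)) {
    quals <- Biostrings::BStringSet(qualities)
  }
  readIds <- names(reads) %||% as.character(seq_along(reads))
  if (is.null(names(reads))) names(reads) <- readIds

  ## reject reads whose quality string length mismatches (counted, logged)
  if (!is.null(quals)) {
    bad <- Biostrings::width(quals) != Biostrings::width(reads)
    if (any(bad)) {
      warning(sum(bad), " read(s) rejected: quality/sequence length mismatch")
      reads <- reads[!bad]
      quals <- quals[!bad]
      readIds <- readIds[!bad]
    }
  }

  hits <- list()
  if (length(reads)) {
    seqsRC <- NULL
    qualsRC <- NULL
    cacheF <- new.env(parent = emptyenv())
    cacheR <- new.env(parent = emptyenv())
    for (p in profiles) {
      fwd <- .scanOneStrand(reads, quals, p, config, cacheF)
      if (nrow(fwd)) {
        fwd[, `:=`(strand = "+", profileId = p@profileId,
                   region = p@targetRegion)]
        hits[[length(hits) + 1L]] <- fwd
      }
      if (is.null(seqsRC)) {
        seqsRC <- Biostrings::reverseComplement(reads)
        if (!is.null(quals)) qualsRC <- Biostrings::reverse(quals)
      }
      rev <- .scanOneStrand(seqsRC, qualsRC, p, config, cacheR)
      if (nrow(rev)) {
        rev[, `:=`(strand = "-", profileId = p@profileId,
                   region = p@targetRegion)]
        hits[[length(hits) + 1L]] <- rev
      }
    }
  }

  if (length(hits) == 0L) {
    return(S4Vectors::DataFrame(
      readId = character(0), sampleId = character(0),
      profileId = character(0), region = character(0),
      strand = character(0), rsOffset = integer(0), tag = character(0),
      longSeq = character(0), minTagQuality = integer(0),
      tagQual = character(0), score = numeric(0)))
  }
  dt <- data.table::rbindlist(hits)
  ## best hit per read x region: max score, ties by profileId, strand, offset
  data.table::setorder(dt, seqIdx, region, -score, profileId, strand,
                       rsOffset)
  dt <- dt[, utils::head(.SD, 1L), by = c("seqIdx", "region")]
  S4Vectors::DataFrame(
    readId = readIds[dt$seqIdx],
    sampleId = sampleId,
    profileId = dt$profileId,
    region = dt$region,
    strand = dt$strand,
    rsOffset = dt$rsOffset,
    tag = dt$tag,
    longSeq = dt$longSeq,
    minTagQuality = dt$minTagQuality,
    tagQual = dt$tagQual,
    score = dt$score)
}

#' Scan a single read
#'
#' Convenience wrapper around [scanReads()] for one read.
#'
#' @param id read identifier.
#' @param seq read sequence (character).
#' @param qual optional Phred quality string of the same length.
#' @inheritParams scanReads
#' @return a \link[S4Vectors]{DataFrame}; see [scanReads()].
#' @export
scanRead <- function(id, seq, qual = NULL, profiles,
                     config = scanConfig(), sampleId = "sample1") {
  if (!nzchar(seq)) stop("read sequence must be non-empty")
  reads <- Biostrings::DNAStringSet(setNames(seq, id))
  scanReads(reads, profiles, config,
            qualities = if (!is.null(qual)) Biostrings::BStringSet(qual),
            sampleId = sampleId)
}
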