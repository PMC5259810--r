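#' Per-position mean sequencing-error probability along the tag
#'
#' For each tag position, the mean over all observations of the Phred
#' error probability of the base at that position. When no quality data
#' are available (FASTA input) a constant fallback vector is returned.
#'
#' @param observations tag observations from [scanReads()] (needs the
#'   \code{tagQual} column).
#' @param tagLength tag length; inferred from the observations when
#'   omitted.
#' @param fallbackError constant per-base error probability used when
#'   qualities are absent (default 0.001, i.e. Q30-equivalent).
#' @param phredOffset quality encoding offset.
#' @return numeric vector of length \code{tagLength}.
#' @examples
#' # all bases at Q30 give a flat 0.001 profile
#' @export
positionErrorProfile <- function(observations, tagLength = NULL,
                                 fallbackError = 0.001,
                                 phredOffset = 33L) {
  tq <- observations$tagQual
  if (is.null(tagLength)) {
    tagLength <- if (length(observations$tag))
      nchar(observations$tag[1L]) else 33L
  }
  tq <- tq[!is.na(tq)]
  if (length(tq) == 0L)
    return(rep(fallbackError, tagLength))
  qm <- .qualIntMatrix(Biostrings::BStringSet(tq), phredOffset)
  colMeans(phredErrorProb(qm))
}

## All 1-nt substitution neighbors of each tag, vectorized.
## Returns data.table(tag, neighbor, position).
.neighborTable <- function(tags) {
  L <- nchar(tags[1L])
  n <- length(tags)
  pos <- rep(seq_len(L), each = n * 3L)
  tagRep <- rep(tags, times = 3L * L)
  orig <- substr(tagRep, pos, pos)
  altSets <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
  altIdx <- rep(rep(1:3, each = n), times = L)
  alt <- vapply(seq_along(tagRep), function(i)
    altSets[[orig[i]]][altIdx[i]], character(1))
  neighbor <- tagRep
  substr(neighbor, pos, pos) <- alt
  data.table::data.table(tag = tagRep, neighbor = neighbor, position = pos)
}

## Faster neighbor enumeration: avoid per-element vapply
.neighborTableFast <- function(tags) {
  L <- nchar(tags[1L])
  n <- length(tags)
  cm <- matrix(unlist(strsplit(tags, "", fixed = TRUE), use.names = FALSE),
               nrow = n, byrow = TRUE)
  out <- vector("list", L)
  bases <- DNA_ALPHABET4
  for (p in seq_len(L)) {
    cur <- cm[, p]
    ## 3 alternatives per tag at this position
    altm <- matrix("", nrow = n, ncol = 3L)
    for (b in seq_along(bases)) {
      sel <- cur == bases[b]
      if (any(sel))
        altm[sel, ] <- matrix(rep(bases[-b], each = sum(sel)), ncol = 3L)
    }
    pre <- if (p > 1L) substr(tags, 1L, p - 1L) else ""
    post <- if (p < L) substr(tags, p + 1L, L) else ""
    out[[p]] <- data.table::data.table(
      tag = rep(tags, 3L),
      neighbor = paste0(pre, as.vector(altm), post),
      position = p)
  }
  data.table::rbindlist(out)
}

#' Expected count of a tag arising from sequencing error alone
#'
#' Assuming the focal tag is not truly present, each observed tag at
#' Hamming distance 1 (a "1-nt neighbor") contributes
#' \deqn{E = n \times e / 3} expected false-positive reads, where \eqn{n}
#' is the number of reads covering the neighbor and \eqn{e} the observed
#' error probability at the differing position of the focal tag. The
#' expected false-positive count is the sum of \eqn{E} over all neighbors;
#' neighbors not observed in the data contribute 0, and multiple-error
#' paths are neglected (their probability is negligible after per-base
#' quality filtering).
#'
#' @param tag focal tag sequence.
#' @param counts named integer vector: observed read count per tag.
#' @param err per-position error-probability vector from
#'   [positionErrorProfile()]; length must equal \code{nchar(tag)}.
#' @return expected false-positive count (non-negative real).
#' @examples
#' err <- rep(0.01, 33)
#' tagA <- paste(rep("A", 33), collapse = "")
#' tagC <- paste0("C", paste(rep("A", 32), collapse = ""))
#' expectedFp(tagA, c(setNames(300, tagC)), err)  # 300 * 0.01 / 3 = 1
#' @export
expectedFp <- function(tag, counts, err) {
  L <- nchar(tag)
  if (length(err) != L)
    stop("error profile length ", length(err),
         " does not match tag length ", L)
  nb <- .neighborTableFast(tag)
  n <- counts[nb$neighbor]
  n[is.na(n)] <- 0
  sum(n * err[nb$position] / 3)
}

#' Expected false-positive counts for a whole tag table
#'
#' Vectorized [expectedFp()] over every observed tag, looking neighbors up
#' among the observed tags only.
#'
#' @param counts named integer vector of read counts per tag.
#' @param err per-position error-probability vector.
#' @return numeric vector parallel to \code{counts}.
#' @export
expectedFpTable <- function(counts, err) {
  if (length(counts) == 0L) return(numeric(0))
  tags <- names(counts)
  L <- nchar(tags[1L])
  if (length(err) != L)
    stop("error profile length does not match tag length")
  nb <- .neighborTableFast(tags)
  n <- counts[nb$neighbor]
  n[is.na(n)] <- 0
  contrib <- as.numeric(n) * err[nb$position] / 3
  dt <- data.table::data.table(tag = nb$tag, contrib = contrib)
  agg <- dt[, list(fp = sum(contrib)), by = "tag"]
  out <- setNames(agg$fp[match(tags, agg$tag)], tags)
  out[is.na(out)] <- 0
  out
}
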