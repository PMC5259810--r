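#' Aggregate tag observations into per-sample ribotag records
#'
#' Collapses the per-read observations of one sample into one record per
#' distinct tag:
#' \describe{
#'   \item{n}{number of reads containing the tag}
#'   \item{npos}{number of distinct tag locations (RS offsets) on the
#'     source reads; a large \code{n} with a small \code{npos} is the
#'     signature of PCR-duplicated reads (or of amplicon input)}
#'   \item{fp}{expected number of reads showing this tag from sequencing
#'     errors alone (see [expectedFp()])}
#'   \item{long.total.count}{reads carrying a long variant of the tag}
#'   \item{long1.count, long2.count, long3.count}{read counts of the three
#'     most abundant long variants (ties broken lexicographically); a low
#'     \code{long1.count / long.total.count} ratio suggests the tag pools
#'     several distinct organisms}
#'   \item{long1, long2}{the two most abundant long variant sequences}
#' }
#'
#' @param observations tag observations from [scanReads()]; must all come
#'   from one sample.
#' @param sampleId sample label; defaults to the observations' label.
#' @param errProfile per-position error vector for the fp computation;
#'   computed from the observations' qualities when \code{NULL}.
#' @param collapseByReadName collapse same-tag observations sharing a read
#'   name (e.g. paired-end mates hitting the same tag) to one count.
#' @param fallbackError constant error probability when qualities are
#'   absent.
#' @return data.frame with the columns above plus a \code{sampleId}
#'   attribute; one row per distinct tag, ordered by decreasing \code{n}
#'   then tag.
#' @examples
#' spec <- communitySpec(nTaxa = 6, seed = 11)
#' ref <- makeReference(spec)
#' prof <- buildProfile(ref$aligned, "V4", "bacteria")
#' obs <- scanReads(ref$seqs, prof)
#' aggregateTags(obs)
#' @export
aggregateTags <- function(observations, sampleId = NULL,
                          errProfile = NULL, collapseByReadName = FALSE,
                          fallbackError = 0.001) {
  if (is.null(sampleId))
    sampleId <- if (length(observations$sampleId))
      observations$sampleId[1L] else "sample1"
  dt <- data.table::data.table(
    readId = observations$readId,
    rsOffset = observations$rsOffset,
    tag = observations$tag,
    longSeq = observations$longSeq)
  if (nrow(dt) && length(unique(observations$sampleId)) > 1L)
    stop("observations must all come from one sample")
  if (collapseByReadName && nrow(dt))
    dt <- unique(dt, by = c("readId", "tag"))

  if (nrow(dt) == 0L) {
    out <- data.frame(tag = character(0), n = integer(0),
                      npos = integer(0), fp = numeric(0),
                      long.total.count = integer(0),
                      long1.count = integer(0), long2.count = integer(0),
                      long3.count = integer(0),
                      long1 = character(0), long2 = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "sampleId") <- sampleId
    return(out)
  }

  base <- dt[, list(n = .N,
                    npos = data.table::uniqueN(rsOffset)), by = "tag"]

  ## long-variant ranking: by count desc, ties lexicographic
  lv <- dt[!is.na(longSeq),
           list(cnt = .N), by = c("tag", "longSeq")]
  data.table::setorder(lv, tag, -cnt, longSeq)
  lsum <- lv[, list(
    long.total.count = sum(cnt),
    long1.count = cnt[1L],
    long2.count = if (.N >= 2L) cnt[2L] else 0L,
    long3.count = if (.N >= 3L) cnt[3L] else 0L,
    long1 = longSeq[1L],
    long2 = if (.N >= 2L) longSeq[2L] else ""), by = "tag"]

  out <- merge(base, lsum, by = "tag", all.x = TRUE)
  out[is.na(long.total.count),
      `:=`(long.total.count = 0L, long1.count = 0L, long2.count = 0L,
           long3.count = 0L, long1 = "", long2 = "")]

  if (is.null(errProfile))
    errProfile <- positionErrorProfile(observations,
                                       tagLength = nchar(out$tag[1L]),
                                       fallbackError = fallbackError)
  counts <- setNames(out$n, out$tag)
  out[, fp := expectedFpTable(counts, errProfile)[tag]]

  data.table::setorder(out, -n, tag)
  out <- as.data.frame(out[, c("tag", "n", "npos", "fp",
                               "long.total.count", "long1.count",
                               "long2.count", "long3.count",
                               "long1", "long2"), with = FALSE])
  attr(out, "sampleId") <- sampleId
  out
}
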