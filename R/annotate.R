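#' Build a tag-to-taxonomy reference index
#'
#' Scans every (unaligned) reference sequence exactly like a read — probe
#' prefilter plus PSSM confirmation on both strands, no quality gate — and
#' keys each detected tag and long sequence to the reference sequences and
#' lineages containing it.
#'
#' @param refSeqs \link[Biostrings]{DNAStringSet} (or character vector) of
#'   reference sequences, named by sequence id.
#' @param lineages character vector of semicolon lineage strings parallel
#'   to \code{refSeqs}, or a 7-column rank matrix from [parseLineage()].
#' @param profiles profile(s) to apply, see [buildProfile()].
#' @param config scanner settings, see [scanConfig()].
#' @param sourceDb label recorded in the index.
#' @return a [ReferenceIndex-class]. Zero detectable sequences give an
#'   empty index with a warning.
#' @examples
#' spec <- communitySpec(nTaxa = 8, seed = 5)
#' ref <- makeReference(spec)
#' prof <- buildProfile(ref$aligned, "V4", "bacteria")
#' idx <- buildIndex(ref$seqs, ref$lineage, prof)
#' idx
#' @export
buildIndex <- function(refSeqs, lineages, profiles,
                       config = scanConfig(), sourceDb = "custom") {
  if (!is(refSeqs, "DNAStringSet"))
    refSeqs <- Biostrings::DNAStringSet(refSeqs)
  if (!is.matrix(lineages)) lineages <- parseLineage(lineages)
  obs <- scanReads(refSeqs, profiles, config, sampleId = sourceDb)
  emptyRanks <- matrix(character(0), 0L, 7L, dimnames = list(NULL, RANKS))
  if (nrow(obs) == 0L) {
    warning("no reference sequence was detectable; returning empty index")
    entries <- cbind(data.frame(tag = character(0), region = character(0),
                                seqId = character(0)),
                     as.data.frame(emptyRanks))
    longEntries <- cbind(data.frame(longSeq = character(0),
                                    region = character(0),
                                    seqId = character(0)),
                        as.data.frame(emptyRanks))
    return(new("ReferenceIndex", entries = entries,
               longEntries = longEntries, sourceDb = sourceDb))
  }
  ids <- names(refSeqs) %||% as.character(seq_along(refSeqs))
  ri <- match(obs$readId, ids)
  ranks <- as.data.frame(lineages[ri, , drop = FALSE])
  entries <- cbind(data.frame(tag = obs$tag, region = obs$region,
                              seqId = obs$readId,
                              stringsAsFactors = FALSE), ranks)
  hasLong <- !is.na(obs$longSeq)
  longEntries <- cbind(data.frame(longSeq = obs$longSeq[hasLong],
                                  region = obs$region[hasLong],
                                  seqId = obs$readId[hasLong],
                                  stringsAsFactors = FALSE),
                       ranks[hasLong, , drop = FALSE])
  rownames(entries) <- NULL
  rownames(longEntries) <- NULL
  new("ReferenceIndex", entries = entries, longEntries = longEntries,
      sourceDb = sourceDb)
}

#' Serialize a reference index to a tabular file
#'
#' Versioned TSV with one row per (tag, reference sequence) pair — columns
#' \code{kind} (tag/long), \code{key}, \code{region}, \code{seqId} and the
#' 7 rank labels. [readIndex()] restores the index.
#'
#' @param index a [ReferenceIndex-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIndex <- function(index, path) {
  e <- cbind(kind = "tag", key = index@entries$tag,
             index@entries[, c("region", "seqId", RANKS)])
  l <- cbind(kind = "long", key = index@longEntries$longSeq,
             index@longEntries[, c("region", "seqId", RANKS)])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# riboscan-index v1 source=", index@sourceDb), con)
  write.table(rbind(e, l), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a reference index written by [writeIndex()]
#'
#' @param path index TSV.
#' @return a [ReferenceIndex-class].
#' @export
readIndex <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "# riboscan-index"))
    stop("not a riboscan index file: ", path)
  src <- sub("^.*source=", "", header)
  x <- read.delim(path, skip = 1L, colClasses = "character")
  x[is.na(x)] <- ""
  e <- x[x$kind == "tag", , drop = FALSE]
  l <- x[x$kind == "long", , drop = FALSE]
  entries <- data.frame(tag = e$key, region = e$region, seqId = e$seqId,
                        e[, RANKS], stringsAsFactors = FALSE)
  longEntries <- data.frame(longSeq = l$key, region = l$region,
                            seqId = l$seqId, l[, RANKS],
                            stringsAsFactors = FALSE)
  rownames(entries) <- NULL
  rownames(longEntries) <- NULL
  new("ReferenceIndex", entries = entries, longEntries = longEntries,
      sourceDb = src)
}

## majority-vote walk over ranks for a set of index rows
.majorityWalk <- function(rows, minConfidence) {
  labels <- setNames(rep("", 7L), RANKS)
  level <- ""
  conf <- NA_real_
  dataLevel <- ""
  for (r in RANKS) {
    v <- rows[[r]]
    v <- v[nzchar(v)]
    if (length(v)) dataLevel <- r
  }
  for (r in RANKS) {
    v <- rows[[r]]
    v <- v[nzchar(v)]
    if (length(v) == 0L) break
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L]) break   # modal tie
    frac <- as.numeric(tab[1L]) / length(v)
    if (frac < minConfidence) break
    labels[r] <- names(tab)[1L]
    level <- r
    conf <- frac
  }
  list(labels = labels, level = level, confidence = conf,
       dataLevel = dataLevel)
}

#' Annotate one tag by majority vote over the reference index
#'
#' Looks the long sequence up first (more specific context) and falls back
#' to the tag. Walking ranks kingdom to species, the modal label is
#' emitted at each rank while its fraction among non-empty labels stays at
#' or above \code{minConfidence}; modal ties stop the walk. Empty labels
#' are treated as missing and excluded from denominators.
#'
#' @param tag tag sequence.
#' @param longSeq optional long variant sequence.
#' @param index a [ReferenceIndex-class].
#' @param minConfidence minimum modal fraction to emit a rank label
#'   (default 0.5; exact ties are left unannotated).
#' @return one-row data.frame: \code{tag, use, taxon_level, taxon_data,
#'   support, confidence, k, p, c, o, f, g, s}. Unmatched tags get empty
#'   labels and support 0.
#' @examples
#' spec <- communitySpec(nTaxa = 8, seed = 5)
#' ref <- makeReference(spec)
#' prof <- buildProfile(ref$aligned, "V4", "bacteria")
#' idx <- buildIndex(ref$seqs, ref$lineage, prof)
#' annotateTag(indexEntries(idx)$tag[1], index = idx)
#' @export
annotateTag <- function(tag, longSeq = NULL, index, minConfidence = 0.5) {
  use <- ""
  rows <- NULL
  if (!is.null(longSeq) && !is.na(longSeq) && nzchar(longSeq)) {
    le <- index@longEntries
    hit <- le$longSeq == longSeq
    if (any(hit)) {
      rows <- le[hit, , drop = FALSE]
      use <- "long"
    }
  }
  if (is.null(rows)) {
    e <- index@entries
    hit <- e$tag == tag
    if (any(hit)) {
      rows <- e[hit, , drop = FALSE]
      use <- "tag"
    }
  }
  if (is.null(rows)) {
    out <- data.frame(tag = tag, use = "", taxon_level = "",
                      taxon_data = "", support = 0L, confidence = NA_real_,
                      stringsAsFactors = FALSE)
    out[RANKS] <- ""
    return(out)
  }
  mw <- .majorityWalk(rows, minConfidence)
  out <- data.frame(tag = tag, use = use, taxon_level = mw$level,
                    taxon_data = mw$dataLevel, support = nrow(rows),
                    confidence = mw$confidence, stringsAsFactors = FALSE)
  out[RANKS] <- as.list(mw$labels)
  out
}

#' Annotate a set of tags
#'
#' Vectorized [annotateTag()].
#'
#' @param tags character vector of tag sequences.
#' @param longSeqs optional character vector of long variants parallel to
#'   \code{tags} (NA where absent).
#' @inheritParams annotateTag
#' @return data.frame with one row per tag; see [annotateTag()].
#' @export
annotateTags <- function(tags, longSeqs = NULL, index,
                         minConfidence = 0.5) {
  rows <- lapply(seq_along(tags), function(i)
    annotateTag(tags[i],
                if (!is.null(longSeqs)) longSeqs[i],
                index, minConfidence))
  do.call(rbind, rows)
}

#' Per-tag concordance at a taxonomic rank
#'
#' A tag is fully concordant (concordance 1) at a rank when all reference
#' sequences containing it share the same label at that rank; in general
#' the concordance is the modal-label fraction. Sequences with an empty
#' label at the rank are excluded from the denominator, and tags with no
#' labelled sequence at the rank are omitted.
#'
#' @param index a [ReferenceIndex-class].
#' @param rank one of \code{k,p,c,o,f,g,s}.
#' @return named numeric vector in \code{[0, 1]}, one element per tag.
#' @export
concordance <- function(index, rank) {
  rank <- match.arg(rank, RANKS)
  e <- data.table::as.data.table(index@entries[, c("tag", rank)])
  data.table::setnames(e, c("tag", "lab"))
  e <- e[nzchar(lab)]
  if (nrow(e) == 0L) return(setNames(numeric(0), character(0)))
  cc <- e[, list(conc = max(table(lab)) / .N), by = "tag"]
  setNames(cc$conc, cc$tag)
}

#' Histogram of concordance values
#'
#' Bins concordance values as the exact bin \{1\} first, then
#' \code{[1-w, 1)}, \code{[1-2w, 1-w)}, ... and returns the percentage of
#' tags per bin (summing to 100 up to rounding).
#'
#' @param values numeric vector from [concordance()].
#' @param binWidth width of the sub-unit bins (default 0.05).
#' @return named numeric vector of percentages; names describe the bins,
#'   first bin is \code{"1"}.
#' @export
concordanceHistogram <- function(values, binWidth = 0.05) {
  lows <- rev(seq(0, 1 - binWidth, by = binWidth))
  labs <- c("1", sprintf("[%.2f,%.2f)", lows, lows + binWidth))
  out <- setNames(numeric(length(labs)), labs)
  n <- length(values)
  if (n == 0L) return(out)
  exact1 <- values >= 1
  out[1L] <- 100 * sum(exact1) / n
  rest <- values[!exact1]
  if (length(rest)) {
    breaks <- seq(0, 1, by = binWidth)
    bi <- findInterval(rest, breaks)          # low-edge index, ascending
    li <- match(round(breaks[bi], 10), round(lows, 10)) + 1L
    tb <- table(factor(li, levels = seq_along(labs)[-1L]))
    out[-1L] <- 100 * as.numeric(tb) / n
  }
  out
}
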