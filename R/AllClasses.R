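#' AlignedReference: an aligned SSU reference collection
#'
#' Holds a gapped multiple alignment of SSU rRNA sequences together with
#' 7-rank taxonomic lineages and a map of hypervariable-region (V-region)
#' coordinates on the alignment. Alignment columns are 0-based and region
#' intervals are half-open, i.e. \code{[start, end)}.
#'
#' @slot alignment a \link[Biostrings]{DNAStringSet} of identical widths;
#'   gaps are \code{-}.
#' @slot lineage character matrix, one row per sequence, columns
#'   \code{k,p,c,o,f,g,s}; empty string marks a missing rank.
#' @slot regionMap data.frame with columns \code{region}, \code{start},
#'   \code{end} (0-based half-open alignment columns).
#'
#' @seealso [alignedReference()], [buildProfile()]
#' @export
setClass("AlignedReference",
  representation(
    alignment = "DNAStringSet",
    lineage   = "matrix",
    regionMap = "data.frame"
  )
)

setValidity("AlignedReference", function(object) {
  w <- Biostrings::width(object@alignment)
  if (length(w) == 0L) return("alignment must contain at least one sequence")
  if (length(unique(w)) != 1L)
    return("all aligned sequences must have identical length")
  if (nrow(object@lineage) != length(object@alignment))
    return("lineage must have one row per aligned sequence")
  if (!identical(colnames(object@lineage), RANKS))
    return("lineage columns must be k,p,c,o,f,g,s in order")
  rm <- object@regionMap
  if (!all(c("region", "start", "end") %in% names(rm)))
    return("regionMap needs columns region, start, end")
  if (nrow(rm)) {
    if (any(rm$start < 0L) || any(rm$end > w[1L]) || any(rm$start >= rm$end))
      return("regionMap intervals must be within [0, alignment_length)")
    o <- order(rm$start)
    if (any(rm$end[o][-nrow(rm)] > rm$start[o][-1L]))
      return("regionMap intervals must not overlap")
  }
  TRUE
})

#' Construct an AlignedReference
#'
#' @param alignment \link[Biostrings]{DNAStringSet} (gapped, equal widths) or
#'   a named character vector of gapped sequences.
#' @param lineage either a character vector of semicolon-delimited lineage
#'   strings (parsed with [parseLineage()]) or a 7-column rank matrix.
#' @param regionMap data.frame with columns \code{region}, \code{start},
#'   \code{end}; 0-based half-open alignment columns.
#' @return an [AlignedReference-class] object.
#' @export
alignedReference <- function(alignment, lineage, regionMap) {
  if (!is(alignment, "DNAStringSet"))
    alignment <- Biostrings::DNAStringSet(alignment)
  if (!is.matrix(lineage)) lineage <- parseLineage(lineage)
  regionMap <- as.data.frame(regionMap)
  regionMap$start <- as.integer(regionMap$start)
  regionMap$end <- as.integer(regionMap$end)
  new("AlignedReference", alignment = alignment, lineage = lineage,
      regionMap = regionMap)
}

setMethod("show", "AlignedReference", function(object) {
  cat("AlignedReference with", length(object@alignment), "sequences,",
      "alignment length", Biostrings::width(object@alignment)[1L], "\n")
  cat("  regions:", paste(object@regionMap$region, collapse = ", "), "\n")
})

#' @describeIn AlignedReference-class number of sequences
#' @param x an AlignedReference
#' @export
setMethod("length", "AlignedReference", function(x) length(x@alignment))

#' Accessors for AlignedReference
#'
#' @param x an [AlignedReference-class].
#' @return \code{alignment()} the gapped \code{DNAStringSet};
#'   \code{lineage()} the 7-column rank matrix; \code{regionMap()} the
#'   V-region coordinate table.
#' @name AlignedReference-accessors
NULL

#' @rdname AlignedReference-accessors
#' @export
alignment <- function(x) x@alignment
#' @rdname AlignedReference-accessors
#' @export
lineage <- function(x) x@lineage
#' @rdname AlignedReference-accessors
#' @export
regionMap <- function(x) x@regionMap


#' RecognitionProfile: a conserved V-region boundary detector
#'
#' A recognition profile detects the conserved 23-nt recognition sequence
#' (RS) flanking a hypervariable region of the SSU gene. Detection is a
#' two-stage test: a fast degenerate probe-pattern prefilter followed by
#' confirmation against a 23-position position-specific scoring matrix
#' (PSSM) of base-2 log-odds scores. The tag sequence (TS, default 33 nt)
#' is extracted from the V-region side adjacent to the RS.
#'
#' @slot profileId unique identifier string.
#' @slot targetRegion one of \code{V4,V5,V6,V7} (any region name in the
#'   reference's region map is accepted).
#' @slot targetDomain \code{bacteria}, \code{archaea} or \code{eukaryota}.
#' @slot side which flank of the V-region the RS occupies:
#'   \code{upstream} (RS 5' of the region, tag follows the RS) or
#'   \code{downstream} (RS 3' of the region, tag precedes the RS).
#' @slot pssm 23 x 4 numeric matrix of log-odds (bits), columns A,C,G,T.
#' @slot probePattern IUPAC degenerate string over the most conserved
#'   probe window inside the RS.
#' @slot probeOffset 0-based column offset of the probe within the RS.
#' @slot scoreThreshold minimum PSSM score (bits) to accept a site.
#' @slot tagLength tag length in nt (default 33).
#' @slot longLength long-variant length in nt (default 60).
#' @slot scope \code{"universal"} or the taxon label of a supplementary
#'   taxon-specific profile.
#' @slot metadata list of training diagnostics (training sensitivity,
#'   window entropy, window alignment columns, training size).
#'
#' @seealso [buildProfile()], [scanReads()]
#' @export
setClass("RecognitionProfile",
  representation(
    profileId      = "character",
    targetRegion   = "character",
    targetDomain   = "character",
    side           = "character",
    pssm           = "matrix",
    probePattern   = "character",
    probeOffset    = "integer",
    scoreThreshold = "numeric",
    tagLength      = "integer",
    longLength     = "integer",
    scope          = "character",
    metadata       = "list"
  )
)

RS_LENGTH <- 23L

setValidity("RecognitionProfile", function(object) {
  p <- object@pssm
  if (!identical(dim(p), c(RS_LENGTH, 4L)))
    return("pssm must be a 23 x 4 matrix (RS length is fixed at 23 nt)")
  if (!identical(colnames(p), DNA_ALPHABET4))
    return("pssm columns must be A,C,G,T")
  if (any(!is.finite(p)))
    return("pssm entries must be finite")
  np <- nchar(object@probePattern)
  if (np < 6L)
    return("probePattern must be at least 6 nt")
  if (object@probeOffset < 0L || object@probeOffset + np > RS_LENGTH)
    return("probePattern must fit inside the 23-nt RS window")
  if (!object@side %in% c("upstream", "downstream"))
    return("side must be 'upstream' or 'downstream'")
  if (object@tagLength < 1L || object@tagLength > object@longLength)
    return("need 1 <= tagLength <= longLength")
  if (object@scoreThreshold > sum(apply(p, 1L, max)) + 1e-9)
    return("scoreThreshold exceeds the maximum attainable PSSM score")
  TRUE
})

setMethod("show", "RecognitionProfile", function(object) {
  cat("RecognitionProfile", object@profileId, "\n")
  cat("  region ", object@targetRegion, " (", object@side, " flank), domain ",
      object@targetDomain, ", scope ", object@scope, "\n", sep = "")
  cat("  probe ", object@probePattern, " @", object@probeOffset,
      ", threshold ", round(object@scoreThreshold, 2), " bits",
      " (max ", round(sum(apply(object@pssm, 1L, max)), 2), ")\n", sep = "")
  cat("  tag ", object@tagLength, " nt, long ", object@longLength,
      " nt\n", sep = "")
})

#' Accessors for RecognitionProfile
#'
#' @param x a [RecognitionProfile-class].
#' @name RecognitionProfile-accessors
NULL

#' @rdname RecognitionProfile-accessors
#' @export
profileId <- function(x) x@profileId
#' @rdname RecognitionProfile-accessors
#' @export
pssm <- function(x) x@pssm
#' @rdname RecognitionProfile-accessors
#' @export
probePattern <- function(x) x@probePattern
#' @rdname RecognitionProfile-accessors
#' @export
scoreThreshold <- function(x) x@scoreThreshold
#' @rdname RecognitionProfile-accessors
#' @export
tagLength <- function(x) x@tagLength
#' @rdname RecognitionProfile-accessors
#' @export
targetRegion <- function(x) x@targetRegion
#' @rdname RecognitionProfile-accessors
#' @export
profileScope <- function(x) x@scope

#' Maximum attainable PSSM score of a profile
#' @param x a [RecognitionProfile-class].
#' @return numeric, the sum of per-position column maxima (bits).
#' @export
maxScore <- function(x) sum(apply(x@pssm, 1L, max))


#' ReferenceIndex: map from ribotags to reference sequences and lineages
#'
#' Built by applying recognition profiles to an (unaligned) reference
#' collection; each detected tag / long sequence is keyed to the reference
#' sequences containing it, together with their 7-rank lineages. Used for
#' majority-vote annotation and concordance statistics.
#'
#' @slot entries data.frame: \code{tag, region, seqId, k..s}.
#' @slot longEntries data.frame: \code{longSeq, region, seqId, k..s}.
#' @slot sourceDb free-text label of the reference collection.
#'
#' @seealso [buildIndex()], [annotateTag()], [concordance()]
#' @export
setClass("ReferenceIndex",
  representation(
    entries     = "data.frame",
    longEntries = "data.frame",
    sourceDb    = "character"
  )
)

setValidity("ReferenceIndex", function(object) {
  need <- c("tag", "region", "seqId", RANKS)
  if (!all(need %in% names(object@entries)))
    return("entries needs columns tag, region, seqId, k..s")
  needL <- c("longSeq", "region", "seqId", RANKS)
  if (!all(needL %in% names(object@longEntries)))
    return("longEntries needs columns longSeq, region, seqId, k..s")
  TRUE
})

setMethod("show", "ReferenceIndex", function(object) {
  cat("ReferenceIndex on", object@sourceDb, "\n")
  cat(" ", length(unique(object@entries$tag)), "tags from",
      length(unique(object@entries$seqId)), "reference sequences;",
      length(unique(object@longEntries$longSeq)), "long sequences\n")
})

#' @describeIn ReferenceIndex-class number of distinct tags in the index
#' @param x a ReferenceIndex
#' @export
setMethod("length", "ReferenceIndex", function(x)
  length(unique(x@entries$tag)))

#' Accessors for ReferenceIndex
#' @param x a [ReferenceIndex-class].
#' @name ReferenceIndex-accessors
NULL

#' @rdname ReferenceIndex-accessors
#' @export
indexEntries <- function(x) x@entries
#' @rdname ReferenceIndex-accessors
#' @export
indexLongEntries <- function(x) x@longEntries
#' @rdname ReferenceIndex-accessors
#' @export
sourceDb <- function(x) x@sourceDb
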