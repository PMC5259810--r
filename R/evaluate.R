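#' Detection sensitivity of a profile set on full-length sequences
#'
#' Fraction of the supplied sequences in which at least one profile
#' confirms a recognition site (scanned exactly like reads, both strands,
#' no quality gate).
#'
#' @param profiles profile(s), see [buildProfile()].
#' @param seqs \code{DNAStringSet} or character vector of sequences.
#' @param config scanner settings.
#' @return list: \code{sensitivity} (fraction detected), \code{detected}
#'   (count), \code{total}.
#' @export
profileSensitivity <- function(profiles, seqs, config = scanConfig()) {
  if (!is(seqs, "DNAStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- as.character(seq_along(seqs))
  obs <- scanReads(seqs, profiles, config)
  det <- length(unique(obs$readId))
  list(sensitivity = det / length(seqs), detected = det,
       total = length(seqs))
}

#' Empirical false-positive rate on faux fragments
#'
#' Scans fixed-length fragments of non-SSU (random-composition) sequence
#' and reports the fraction of fragments producing at least one confirmed
#' recognition-site hit. Fragments are generated and scanned in chunks so
#' memory stays bounded.
#'
#' @param profiles profile(s) to evaluate.
#' @param nFragments number of faux fragments (default 1e7).
#' @param fragLen fragment length (default 80 nt).
#' @param config scanner settings.
#' @param chunkSize fragments per chunk.
#' @param seed RNG seed.
#' @return list: \code{fpr}, \code{falsePositives} (fragments with a
#'   hit), \code{nFragments}.
#' @export
estimateFpr <- function(profiles, nFragments = 1e7, fragLen = 80L,
                        config = scanConfig(), chunkSize = 2e5,
                        seed = 1L) {
  if (is(profiles, "RecognitionProfile")) profiles <- list(profiles)
  nFragments <- as.integer(nFragments)
  chunkSize <- as.integer(chunkSize)
  set.seed(seed)
  done <- 0L
  hits <- 0L
  while (done < nFragments) {
    m <- min(chunkSize, nFragments - done)
    s <- .randomDnaString(m * fragLen)
    frags <- Biostrings::DNAStringSet(
      Biostrings::DNAString(s),
      start = seq(1L, m * fragLen, by = fragLen), width = fragLen)
    names(frags) <- as.character(seq_len(m))
    obs <- scanReads(frags, profiles, config)
    hits <- hits + length(unique(obs$readId))
    done <- done + m
  }
  list(fpr = hits / nFragments, falsePositives = hits,
       nFragments = nFragments)
}

#' Expected per-V-region read yield of a shotgun survey
#'
#' Back-of-the-envelope estimate of how many reads should originate from
#' any single V-region: assuming a typical free-living bacterium carries
#' \code{genesPerGenome} genes of which one is the SSU gene, made up of
#' \code{nRegions} roughly equal-sized segments (9 variable plus 10
#' conserved = 19), a survey of \code{totalReads} reads contributes
#' \code{floor(totalReads / (nRegions * genesPerGenome))} reads per
#' V-region.
#'
#' @param totalReads total reads in the survey.
#' @param genesPerGenome genes per genome (default 5000).
#' @param nRegions equal-sized SSU segments (default 19).
#' @return integer expected read count.
#' @examples
#' expectedTagYield(308505950, 5000, 19)  # 3247
#' @export
expectedTagYield <- function(totalReads, genesPerGenome = 5000L,
                             nRegions = 19L) {
  if (genesPerGenome <= 0L || nRegions <= 0L)
    stop("genesPerGenome and nRegions must be positive")
  if (totalReads < 0) stop("totalReads must be non-negative")
  as.integer(floor(totalReads / (as.numeric(nRegions) * genesPerGenome)))
}
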