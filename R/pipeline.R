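#' Run the tag pipeline on a single input file
#'
#' Reads a FASTQ/FASTA file (optionally gzip/bzip2 compressed), scans it
#' with the supplied profiles, aggregates tag records and writes the
#' per-sample tag table. FASTA input has no quality information, so the
#' per-base quality gate is skipped and the false-positive expectation
#' falls back to a constant per-base error rate.
#'
#' @param input path to the reads file.
#' @param profiles profile(s), or path to a JSON file from
#'   [writeProfiles()].
#' @param output output path for the tag table; NULL skips writing.
#' @param config scanner settings, see [scanConfig()].
#' @param sampleId sample label; defaults to the file base name.
#' @param fallbackError constant per-base error rate for FASTA input.
#' @return the tag table (data.frame), invisibly when \code{output} is
#'   written.
#' @export
runSingle <- function(input, profiles, output = NULL,
                      config = scanConfig(), sampleId = NULL,
                      fallbackError = 0.001) {
  if (is.character(profiles)) profiles <- readProfiles(profiles)
  if (is.null(sampleId))
    sampleId <- sub("\\.(fastq|fq|fasta|fa|fna)(\\.(gz|bz2))?$", "",
                    basename(input), ignore.case = TRUE)
  reads <- readSeqs(input)
  obs <- scanReads(reads, profiles, config, sampleId = sampleId)
  tab <- aggregateTags(obs, sampleId = sampleId,
                       fallbackError = fallbackError)
  message(sprintf("%s: %d reads in, %d observations, %d distinct tags",
                  sampleId, length(reads), nrow(obs), nrow(tab)))
  if (!is.null(output)) {
    writeTagTable(tab, output)
    return(invisible(tab))
  }
  tab
}

#' Run the tag pipeline over multiple samples (batch mode)
#'
#' Processes every sample (each given as one file or a pair of mate
#' files, combined into a single output column), merges the per-sample
#' tables into a count matrix and writes the full output set: per-sample
#' tag tables, the \code{.tab} count matrix, the \code{.anno} annotation
#' table (when an index is supplied), a valid BIOM v1 file and a combined
#' TSV. Batch mode fails fast: all inputs are checked before any output
#' is produced.
#'
#' @param inputs named list; each element is a character vector of 1 or 2
#'   (paired-end) file paths. Names are sample ids.
#' @param profiles profile(s), or path to a profile JSON.
#' @param outPrefix path prefix for all outputs.
#' @param index optional [ReferenceIndex-class] for annotation.
#' @param config scanner settings.
#' @param minConfidence majority-vote cutoff for annotation.
#' @param fallbackError constant per-base error rate for FASTA input.
#' @return list with \code{tables} (per-sample tag tables), \code{se}
#'   (count-matrix \code{SummarizedExperiment}), \code{annotations}, and
#'   \code{files} (paths written), invisibly.
#' @export
runBatch <- function(inputs, profiles, outPrefix, index = NULL,
                     config = scanConfig(), minConfidence = 0.5,
                     fallbackError = 0.001) {
  if (is.character(profiles)) profiles <- readProfiles(profiles)
  if (is.null(names(inputs)) || any(!nzchar(names(inputs))))
    stop("inputs must be a named list (names are sample ids)")
  all_files <- unlist(inputs)
  missing <- all_files[!file.exists(all_files)]
  if (length(missing))
    stop("unreadable input file(s): ", paste(missing, collapse = ", "))

  tables <- list()
  for (sid in names(inputs)) {
    obsList <- lapply(inputs[[sid]], function(f) {
      reads <- readSeqs(f)
      scanReads(reads, profiles, config, sampleId = sid)
    })
    obs <- if (length(obsList) == 1L) obsList[[1L]] else
      do.call(rbind, obsList)                 # mates pooled before counting
    tables[[sid]] <- aggregateTags(obs, sampleId = sid,
                                   fallbackError = fallbackError)
  }
  se <- mergeSamples(tables)

  files <- list()
  for (sid in names(tables)) {
    f <- paste0(outPrefix, ".", sid, ".tab")
    writeTagTable(tables[[sid]], f)
    files[[paste0("sample_", sid)]] <- f
  }
  files$tab <- paste0(outPrefix, ".tab")
  writeCountMatrix(se, files$tab)

  anno <- NULL
  longMeta <- computeLongMeta(tables)
  if (!is.null(index)) {
    tags <- rownames(se)
    longs <- longMeta$long[match(tags, longMeta$tag)]
    longs[!nzchar(longs) | is.na(longs)] <- NA_character_
    anno <- annotateTags(tags, longs, index, minConfidence)
    files$anno <- paste0(outPrefix, ".anno")
    writeAnno(anno, longMeta, files$anno)
  }
  files$biom <- paste0(outPrefix, ".biom")
  writeBiom(se, anno, files$biom)

  ## combined TSV: counts joined with annotations
  files$combined <- paste0(outPrefix, ".combined.tsv")
  comb <- data.frame(tag = rownames(se),
                     SummarizedExperiment::assay(se, "counts"),
                     check.names = FALSE)
  if (!is.null(anno))
    comb <- cbind(comb, anno[match(comb$tag, anno$tag),
                             setdiff(names(anno), "tag")])
  write.table(comb, files$combined, sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(tables = tables, se = se, annotations = anno,
                 files = files))
}

#' Build the default universal + supplementary profile set
#'
#' Convenience wrapper: universal profile for each requested region plus
#' any supplementary taxon-specific profiles the training data call for.
#'
#' @param ref an [AlignedReference-class].
#' @param regions V-regions to target.
#' @param domain taxon domain.
#' @param side RS flank.
#' @param config see [profileConfig()].
#' @param supplements also train taxon-specific supplements.
#' @return list of [RecognitionProfile-class] objects.
#' @export
buildProfileSet <- function(ref, regions = "V4", domain = "bacteria",
                            side = "upstream", config = profileConfig(),
                            supplements = TRUE) {
  out <- list()
  for (rg in regions) {
    uni <- buildProfile(ref, rg, domain, side, config)
    out[[length(out) + 1L]] <- uni
    if (supplements) {
      sup <- buildTaxonProfiles(ref, rg, domain, side, config,
                                universal = uni)
      out <- c(out, sup)
    }
  }
  out
}
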