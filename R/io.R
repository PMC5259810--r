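TAB_COLUMNS <- c("tag", "n", "npos", "fp", "long.total.count",
                 "long1.count", "long2.count", "long3.count",
                 "long1", "long2")

ANNO_COLUMNS <- c("tag", "use", "taxon_level", "taxon_data", "long",
                  "long_total", "long_this", "support", "confidence",
                  RANKS)

## bzip2 needs a connection-based detour; gzip is handled natively by the
## Biostrings readers
.maybeDecompress <- function(path) {
  if (grepl("\\.bz2$", path)) {
    tmp <- tempfile(fileext = sub("\\.bz2$", "", basename(path)))
    con <- bzfile(path, "rb")
    out <- file(tmp, "wb")
    while (length(chunk <- readBin(con, "raw", 1e6)))
      writeBin(chunk, out)
    close(con); close(out)
    return(tmp)
  }
  path
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' Format is detected from the file name (\code{.fastq/.fq} vs
#' \code{.fasta/.fa/.fna}); gzip and bzip2 compression are transparent.
#' FASTQ input returns a \link[Biostrings]{QualityScaledDNAStringSet}
#' carrying per-base Phred qualities; FASTA returns a plain
#' \code{DNAStringSet}.
#'
#' @param path input file.
#' @param format \code{"auto"}, \code{"fastq"} or \code{"fasta"}.
#' @return a \code{DNAStringSet} or \code{QualityScaledDNAStringSet}.
#' @export
readSeqs <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (format == "auto") {
    base <- sub("\\.(gz|bz2)$", "", path)
    format <- if (grepl("\\.(fastq|fq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  p <- .maybeDecompress(path)
  if (format == "fastq") {
    ## the reader warns about (empty) metadata columns it drops internally
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(p),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  } else {
    x <- Biostrings::readDNAStringSet(p)
  }
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a per-sample tag table
#'
#' Tab-delimited with the fixed header \code{tag n npos fp
#' long.total.count long1.count long2.count long3.count long1 long2};
#' \code{fp} is printed with 4 decimal places.
#'
#' @param table data.frame from [aggregateTags()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTagTable <- function(table, path) {
  if (!all(TAB_COLUMNS %in% names(table)))
    stop("tag table is missing required columns")
  if (anyDuplicated(table$tag))
    stop("tag table has duplicate tags")
  out <- table[, TAB_COLUMNS]
  out$fp <- sprintf("%.4f", out$fp)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tag table written by [writeTagTable()]
#'
#' @param path file path.
#' @param sampleId sample label to attach.
#' @return data.frame in tag-table schema.
#' @export
readTagTable <- function(path, sampleId = NULL) {
  x <- read.delim(path, sep = "\t", header = TRUE,
                  colClasses = c(tag = "character", long1 = "character",
                                 long2 = "character"),
                  check.names = FALSE)
  x$long1[is.na(x$long1)] <- ""
  x$long2[is.na(x$long2)] <- ""
  attr(x, "sampleId") <- sampleId %||%
    sub("\\.[^.]*$", "", basename(path))
  x
}

#' Merge per-sample tag tables into a count matrix
#'
#' Takes the union of tags across samples and fills a tags x samples
#' matrix of read counts (\code{n}; 0 where a tag is absent).
#'
#' @param tables named list of tag tables ([aggregateTags()] output); the
#'   names (or \code{sampleId} attributes) are the sample ids, which must
#'   be unique.
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{"counts"} and the tag sequence in \code{rowData} — the
#'   annotation skeleton to be filled by [annotateTags()].
#' @export
mergeSamples <- function(tables) {
  stopifnot(length(tables) >= 1L)
  ids <- names(tables)
  if (is.null(ids))
    ids <- vapply(tables, function(t)
      attr(t, "sampleId") %||% NA_character_, character(1))
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("every table needs a sample id (list names or sampleId attribute)")
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  tags <- sort(unique(unlist(lapply(tables, `[[`, "tag"))))
  counts <- matrix(0L, nrow = length(tags), ncol = length(tables),
                   dimnames = list(tags, ids))
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    counts[match(t$tag, tags), j] <- as.integer(t$n)
  }
  keep <- rowSums(counts) > 0L
  counts <- counts[keep, , drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(tag = rownames(counts)))
}

#' Write the multi-sample count matrix (.tab)
#'
#' Ribotags in rows, samples in columns, unnormalized read counts.
#'
#' @param se \code{SummarizedExperiment} from [mergeSamples()] or a plain
#'   counts matrix with tag rownames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCountMatrix <- function(se, path) {
  m <- if (is(se, "SummarizedExperiment"))
    SummarizedExperiment::assay(se, "counts") else se
  out <- data.frame(tag = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-tag long-variant metadata across samples
#'
#' For each tag: \code{long} = the modal major long representative across
#' samples (ties lexicographic); \code{long_total} = number of samples
#' having any long representative; \code{long_this} = number of samples
#' whose major representative is \code{long}.
#'
#' @param tables named list of tag tables.
#' @return data.frame \code{tag, long, long_total, long_this}.
#' @export
computeLongMeta <- function(tables) {
  rows <- data.table::rbindlist(lapply(tables, function(t)
    data.table::data.table(tag = t$tag, long1 = t$long1,
                           hasLong = t$long.total.count > 0L)))
  meta <- rows[, {
    tot <- sum(hasLong)
    maj <- long1[nzchar(long1)]
    if (length(maj)) {
      tb <- sort(table(maj), decreasing = TRUE)
      top <- sort(names(tb)[tb == max(tb)])[1L]
      list(long = top, long_total = tot,
           long_this = as.integer(sum(maj == top)))
    } else {
      list(long = "", long_total = tot, long_this = 0L)
    }
  }, by = "tag"]
  as.data.frame(meta)
}

#' Write the annotation table (.anno)
#'
#' Tab-delimited with columns \code{tag use taxon_level taxon_data long
#' long_total long_this support confidence k p c o f g s}.
#'
#' @param annotations data.frame from [annotateTags()].
#' @param longMeta data.frame from [computeLongMeta()] (may be NULL for
#'   empty long metadata).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnno <- function(annotations, longMeta = NULL, path) {
  a <- annotations
  if (is.null(longMeta))
    longMeta <- data.frame(tag = character(0), long = character(0),
                           long_total = integer(0), long_this = integer(0))
  m <- longMeta[match(a$tag, longMeta$tag), , drop = FALSE]
  a$long <- ifelse(is.na(m$long), "", m$long)
  a$long_total <- ifelse(is.na(m$long_total), 0L, m$long_total)
  a$long_this <- ifelse(is.na(m$long_this), 0L, m$long_this)
  out <- a[, ANNO_COLUMNS]
  out$confidence <- ifelse(is.na(out$confidence), "",
                           sprintf("%.4f", out$confidence))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a BIOM v1.0 (JSON, sparse) community table
#'
#' Emits the Biological Observation Matrix format, version 1.0, with
#' matrix_type "sparse" (zero cells omitted) and, when annotations are
#' supplied, a 7-element \code{taxonomy} list per observation under
#' observation metadata — the layout downstream tools such as QIIME
#' expect.
#'
#' @param se \code{SummarizedExperiment} from [mergeSamples()] or counts
#'   matrix with tag rownames and sample colnames.
#' @param annotations optional data.frame from [annotateTags()] supplying
#'   k..s labels per tag.
#' @param path output path.
#' @param id table id string.
#' @return \code{path}, invisibly.
#' @export
writeBiom <- function(se, annotations = NULL, path, id = "riboscan") {
  m <- if (is(se, "SummarizedExperiment"))
    SummarizedExperiment::assay(se, "counts") else se
  tags <- rownames(m)
  samples <- colnames(m)
  taxonomy <- NULL
  if (!is.null(annotations)) {
    ai <- match(tags, annotations$tag)
    taxonomy <- lapply(ai, function(i) {
      if (is.na(i)) rep("", 7L) else
        unname(unlist(annotations[i, RANKS]))
    })
  }
  obsRows <- lapply(seq_along(tags), function(i) {
    md <- if (is.null(taxonomy)) NULL else list(taxonomy = taxonomy[[i]])
    list(id = tags[i], metadata = md)
  })
  colRows <- lapply(samples, function(s) list(id = s, metadata = NULL))
  nz <- which(m != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
  data <- lapply(seq_len(nrow(nz)), function(k)
    list(nz[k, 1L] - 1L, nz[k, 2L] - 1L, unname(m[nz[k, 1L], nz[k, 2L]])))
  doc <- list(
    id = id,
    format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org",
    type = "OTU table",
    generated_by = paste0("riboscan ",
                          as.character(utils::packageVersion("riboscan"))),
    date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    rows = obsRows,
    columns = colRows,
    matrix_type = "sparse",
    matrix_element_type = "int",
    shape = c(nrow(m), ncol(m)),
    data = data)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                           digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read a BIOM v1.0 JSON file into a dense count matrix
#'
#' @param path BIOM v1 JSON file.
#' @return list with \code{counts} (dense matrix, tags x samples) and
#'   \code{taxonomy} (list of 7-element vectors or NULL).
#' @export
readBiom <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  shape <- unlist(doc$shape)
  m <- matrix(0, nrow = shape[1L], ncol = shape[2L],
              dimnames = list(vapply(doc$rows, `[[`, "", "id"),
                              vapply(doc$columns, `[[`, "", "id")))
  if (identical(doc$matrix_type, "sparse")) {
    for (cell in doc$data)
      m[cell[[1L]] + 1L, cell[[2L]] + 1L] <- cell[[3L]]
  } else {
    for (i in seq_len(shape[1L]))
      m[i, ] <- unlist(doc$data[[i]])
  }
  taxonomy <- lapply(doc$rows, function(r)
    if (!is.null(r$metadata$taxonomy)) unlist(r$metadata$taxonomy))
  if (all(vapply(taxonomy, is.null, logical(1)))) taxonomy <- NULL
  list(counts = m, taxonomy = taxonomy)
}
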