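#' @import methods
#' @import data.table
#' @importFrom stats setNames cor runif
#' @importFrom utils head read.delim write.table
NULL

.datatable.aware <- TRUE

## Canonical rank letters, kingdom -> species
RANKS <- c("k", "p", "c", "o", "f", "g", "s")

DNA_ALPHABET4 <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse 7-rank lineage strings
#'
#' Accepts both Greengenes-style (\code{"k__Bacteria; p__Firmicutes; ..."})
#' and SILVA-style (\code{"Bacteria;Firmicutes;..."}) semicolon-delimited
#' lineages and returns a character matrix with one column per rank
#' (k, p, c, o, f, g, s). Missing or placeholder ranks become empty strings.
#'
#' @param x character vector of lineage strings.
#' @return character matrix with \code{length(x)} rows and 7 columns
#'   named \code{k,p,c,o,f,g,s}.
#' @examples
#' parseLineage("k__Bacteria; p__Proteobacteria")
#' parseLineage("Bacteria;Proteobacteria;Gammaproteobacteria")
#' @export
parseLineage <- function(x) {
  parts <- strsplit(as.character(x), ";", fixed = TRUE)
  out <- matrix("", nrow = length(x), ncol = 7L,
                dimnames = list(NULL, RANKS))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    ## strip Greengenes-style rank prefixes ("k__", "p__", ...)
    p <- sub("^[kpcofgs]__", "", p)
    p[p %in% c("unclassified", "uncultured", "NA")] <- ""
    n <- min(length(p), 7L)
    out[i, seq_len(n)] <- p[seq_len(n)]
  }
  out
}

## Collapse a rank matrix row back to a semicolon string (Greengenes dialect)
formatLineage <- function(m) {
  apply(m, 1L, function(r) paste0(RANKS, "__", r, collapse = "; "))
}

## Character matrix (reads x positions) from an XStringSet of equal width
.charMatrix <- function(x) {
  as.matrix(x)
}

## Phred integer matrix from a BStringSet of equal-width quality substrings
.qualIntMatrix <- function(q, offset = 33L) {
  w <- unique(Biostrings::width(q))
  stopifnot(length(w) == 1L)
  ints <- utf8ToInt(paste(as.character(q), collapse = "")) - offset
  matrix(ints, ncol = w, byrow = TRUE)
}

## Row-wise minimum of an integer matrix without extra deps
.rowMins <- function(m) {
  Reduce(pmin, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

## Random DNA of n bases as a single string (uniform composition)
.randomDnaString <- function(n) {
  chartr("1234", "ACGT", intToUtf8(sample.int(4L, n, replace = TRUE) + 48L))
}

## Mutate a character vector of bases at per-base rate; substitutions only
.mutateBases <- function(bases, rate) {
  if (rate <= 0) return(bases)
  hit <- which(stats::runif(length(bases)) < rate)
  if (length(hit)) {
    for (i in hit) {
      alt <- setdiff(DNA_ALPHABET4, bases[i])
      bases[i] <- alt[sample.int(3L, 1L)]
    }
  }
  bases
}
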