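# Tab-separated tables: homology hit tables and the taxonomy serialisation.

HIT_COLUMNS <- c("query_id", "subject_id", "subject_taxid",
                 "bitscore", "evalue")

#' Read a homology hit table
#'
#' Dialect: BLAST-tabular-like TSV with exactly five columns — `qseqid`,
#' `sseqid`, `staxid`, `bitscore`, `evalue` — no header.  Negative scores or
#' e-values and wrong column counts are errors naming the offending line.
#'
#' @param path path to the TSV file
#' @return data.frame with columns `query_id`, `subject_id`,
#'   `subject_taxid` (integer), `bitscore`, `evalue`, in file order
#' @export
readHitTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(emptyHitTable())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 5L))
    stop(sprintf("line %d: expected 5 tab-separated columns, got %d",
                 which(nc != 5L)[1], nc[nc != 5L][1]), call. = FALSE)
  m <- do.call(rbind, parts)
  out <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                    subject_taxid = suppressWarnings(as.integer(m[, 3])),
                    bitscore = suppressWarnings(as.numeric(m[, 4])),
                    evalue = suppressWarnings(as.numeric(m[, 5])),
                    stringsAsFactors = FALSE)
  bad <- which(is.na(out$subject_taxid) | is.na(out$bitscore) |
                 is.na(out$evalue))
  if (length(bad) > 0L)
    stop(sprintf("line %d: malformed numeric field", bad[1]), call. = FALSE)
  neg <- which(out$bitscore < 0 | out$evalue < 0)
  if (length(neg) > 0L)
    stop(sprintf("line %d: negative bitscore or evalue", neg[1]),
         call. = FALSE)
  out
}

#' @noRd
emptyHitTable <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             subject_taxid = integer(0), bitscore = numeric(0),
             evalue = numeric(0), stringsAsFactors = FALSE)
}

#' Write a homology hit table
#' @param hits data.frame as returned by [readHitTable()]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeHitTable <- function(hits, path) {
  stopifnot(all(HIT_COLUMNS %in% names(hits)))
  write.table(hits[, HIT_COLUMNS], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Dialect: 4-column TSV with header `taxid  parent_taxid  rank  name`.
#' Validation (single root, no orphans, no duplicates, no cycles) happens in
#' the [Taxonomy()] constructor; each violation is a distinct error message.
#'
#' @param path path to the TSV file
#' @return a [Taxonomy-class]
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE)
  Taxonomy(df)
}

#' Write a taxonomy table
#' @param tax a [Taxonomy-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeTaxonomy <- function(tax, path) {
  df <- data.frame(taxid = tax@taxid, parent_taxid = tax@parent,
                   rank = tax@rank, name = tax@name,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
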