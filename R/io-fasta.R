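# FASTA reading/writing with strict alphabet validation.
# Parsing and serialisation are delegated to Biostrings; validation of ids
# and alphabets (and the nucleotide/protein mode switch) is enforced here.

NT_ALPHABET <- c("A", "C", "G", "T", "N")
AA_ALPHABET <- c(AA_STANDARD, "X")

#' Read a FASTA file
#'
#' Sequences are validated against the declared alphabet: `{A,C,G,T,N}` in
#' nucleotide mode, the 20 standard amino acids plus `X` in protein mode.
#' Lower-case input is accepted and stored upper-case.  Duplicate ids and
#' illegal characters are errors; an empty file yields an empty set.
#'
#' @param path path to a FASTA file
#' @param mode `"nucleotide"` or `"protein"`
#' @return a [Biostrings::DNAStringSet] (nucleotide) or
#'   [Biostrings::AAStringSet] (protein), named by record id (first
#'   whitespace-separated token of the header); the full header is kept in
#'   the `description` metadata column
#' @seealso [writeFasta()]
#' @export
readFasta <- function(path, mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  txt <- readLines(path, warn = FALSE)
  if (length(txt) == 0L || all(!nzchar(trimws(txt)))) {
    empty <- if (mode == "nucleotide") Biostrings::DNAStringSet()
             else Biostrings::AAStringSet()
    return(empty)
  }
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, "", 1L)
  if (any(!nzchar(ids))) stop("FASTA record with empty id", call. = FALSE)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  seqs <- toupper(as.character(raw))
  if (any(!nzchar(seqs)))
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  alphabet <- if (mode == "nucleotide") NT_ALPHABET else AA_ALPHABET
  for (k in seq_along(seqs)) {
    chars <- strsplit(seqs[k], "")[[1]]
    bad <- which(!chars %in% alphabet)
    if (length(bad) > 0L)
      stop(sprintf(
        "illegal character '%s' at position %d of record '%s' (%s mode)",
        chars[bad[1]], bad[1], ids[k], mode), call. = FALSE)
  }
  out <- if (mode == "nucleotide") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  attr(out, "description") <- setNames(headers, ids)
  out
}

#' Write sequences to a FASTA file
#'
#' Lines are wrapped at 60 columns, so `writeFasta(readFasta(x))` reproduces
#' ids and sequences exactly (byte-identical after wrapping normalisation).
#'
#' @param seqs a named `XStringSet` or a named character vector
#' @param path output path
#' @return `path`, invisibly
#' @export
writeFasta <- function(seqs, path) {
  s <- as.character(seqs)
  names(s) <- names(seqs)
  if (is.null(names(s)) || any(!nzchar(names(s))))
    stop("all sequences must be named", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(s)) {
    writeLines(paste0(">", names(s)[k]), con)
    sq <- s[k]
    starts <- seq(1L, nchar(sq), by = 60L)
    writeLines(substring(sq, starts, pmin(starts + 59L, nchar(sq))), con)
  }
  invisible(path)
}
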