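# Six-frame translation with exact residue-to-nucleotide coordinate maps,
# ORF finding, and reverse translation (used by the gene planter).
# Coordinates are 0-based half-open on the forward strand throughout.

#' Six-frame translation of a contig
#'
#' Translates all six reading frames with the standard genetic code.  Stops
#' are rendered as `*`; codons containing `N` translate to `X` unless the
#' code resolves them unambiguously.  Each track carries an exact coordinate
#' map from residue index to the codon's half-open nucleotide interval on
#' the forward strand.
#'
#' @param contig a nucleotide string (or `DNAString`)
#' @return list of six tracks, each a list with `strand` (`"+"`/`"-"`),
#'   `frame` (0, 1, 2), `protein` (translated string, possibly empty) and
#'   `map` — a function `(i) -> c(start, end)` giving residue `i`'s codon
#'   interval on the forward strand
#' @examples
#' sixFrameTranslate("ATGGCC")[[1]]$protein  # "MA"
#' @export
sixFrameTranslate <- function(contig) {
  s <- toupper(as.character(contig))
  n <- nchar(s)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  strands <- rep(c("+", "-"), each = 3L)
  frames <- rep(0:2, 2L)
  nt <- character(6)
  for (k in 1:6) {
    src <- if (strands[k] == "+") s else rc
    ncod <- max(0L, (n - frames[k]) %/% 3L)
    nt[k] <- if (ncod == 0L) "" else
      substr(src, frames[k] + 1L, frames[k] + 3L * ncod)
  }
  prots <- character(6)
  nonempty <- nzchar(nt)
  if (any(nonempty))   # one batched call keeps dispatch overhead constant
    prots[nonempty] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(nt[nonempty]), if.fuzzy.codon = "X"))
  lapply(1:6, function(k)
    list(strand = strands[k], frame = frames[k], protein = prots[k],
         map = makeCodonMap(strands[k], frames[k], n)))
}

#' @noRd
translateCodons <- function(nt) {
  if (nchar(nt) == 0L) return("")
  aa <- Biostrings::translate(Biostrings::DNAString(nt),
                              if.fuzzy.codon = "X")
  as.character(aa)
}

# residue i (1-based) of a track -> forward-strand nt interval [start, end)
#' @noRd
makeCodonMap <- function(strand, frame, contig_length) {
  force(strand); force(frame); force(contig_length)
  function(i) {
    if (strand == "+") {
      st <- frame + 3L * (i - 1L)
      c(st, st + 3L)
    } else {
      st <- contig_length - frame - 3L * i
      c(st, st + 3L)
    }
  }
}

#' Open reading frames of a region track
#'
#' Finds ORFs `ATG..stop` in a translated track, together with
#' edge-truncated ORFs: a reading frame running into the region start is
#' reported from the first residue, and one running off the region end is
#' reported without a stop.
#'
#' @param protein translated track (with `*` for stops)
#' @return data.frame with 1-based residue columns `aa_start`, `aa_end`
#'   (inclusive, excluding the stop) and `truncated` (logical); zero rows if
#'   none
#' @export
findOrfs <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  res <- list()
  if (n == 0L)
    return(data.frame(aa_start = integer(0), aa_end = integer(0),
                      truncated = logical(0)))
  stops <- c(0L, which(chars == "*"), n + 1L)
  for (seg in seq_len(length(stops) - 1L)) {
    from <- stops[seg] + 1L
    to <- stops[seg + 1L] - 1L
    if (to < from) next
    truncated_end <- stops[seg + 1L] == n + 1L
    # canonical ORF: first ATG in the segment to the stop
    m <- which(chars[from:to] == "M")
    if (length(m) > 0L)
      res[[length(res) + 1L]] <- data.frame(
        aa_start = from + m[1] - 1L, aa_end = to,
        truncated = truncated_end)
    # edge-truncated at the region start: segment beginning at residue 1
    if (from == 1L && (length(m) == 0L || m[1] > 1L))
      res[[length(res) + 1L]] <- data.frame(
        aa_start = 1L, aa_end = to, truncated = TRUE)
  }
  if (length(res) == 0L)
    return(data.frame(aa_start = integer(0), aa_end = integer(0),
                      truncated = logical(0)))
  do.call(rbind, res)
}

#' Reverse-translate a protein with uniformly chosen synonymous codons
#'
#' @param protein protein string (standard residues only)
#' @param seed RNG seed
#' @return nucleotide string of length `3 * nchar(protein)` whose
#'   translation reproduces `protein` exactly
#' @export
reverseTranslate <- function(protein, seed = NULL) {
  code <- Biostrings::GENETIC_CODE
  byAA <- split(names(code), code)
  chars <- strsplit(toupper(protein), "")[[1]]
  if (!all(chars %in% AA_STANDARD))
    stop("protein contains non-standard residues", call. = FALSE)
  withSeed(seed, paste(vapply(chars, function(a) {
    cands <- byAA[[a]]
    cands[sample.int(length(cands), 1L)]
  }, character(1)), collapse = ""))
}

#' @noRd
randomDna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, TRUE, p), collapse = "")
}

#' @noRd
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
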