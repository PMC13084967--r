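# Position-specific scoring profiles: construction from a small core set of
# orthologues, window scoring, and empirical-null threshold calibration used
# both by the assembly search and by the domain filter.

MAX_TRAINING <- 6L

#' Build a scoring profile from core orthologues
#'
#' At most six training sequences are accepted, mirroring the deliberately
#' small core groups used for targeted orthologue searches.  If the training
#' sequences differ in length they are globally aligned to the first one and
#' projected onto its coordinates (insertions relative to the first sequence
#' are dropped), so the model length always equals the length of the first
#' sequence.  Column scores are
#' `log2((count + 1) / (n + 20)) - log2(1/20)` — add-one pseudocounts over a
#' uniform background.  The consensus is the per-column majority residue,
#' ties broken alphabetically.
#'
#' @param core_sequences named character vector or `AAStringSet` (1 to 6
#'   sequences)
#' @param ... passed to [globalAlign()] when projection is needed
#' @return a [ScoringProfile-class] with an uncalibrated score threshold
#' @export
buildProfile <- function(core_sequences, ...) {
  s <- toupper(as.character(core_sequences))
  names(s) <- names(core_sequences)
  if (length(s) == 0L) stop("no training sequences", call. = FALSE)
  if (length(s) > MAX_TRAINING)
    stop(sprintf("at most %d training sequences allowed, got %d",
                 MAX_TRAINING, length(s)), call. = FALSE)
  ids <- names(s)
  if (is.null(ids)) ids <- paste0("core", seq_along(s))
  L <- nchar(s[1])
  rows <- matrix("-", nrow = length(s), ncol = L)
  rows[1, ] <- strsplit(s[1], "")[[1]]
  if (length(s) > 1L) for (k in 2:length(s)) {
    if (nchar(s[k]) == L && length(unique(nchar(s))) == 1L) {
      rows[k, ] <- strsplit(s[k], "")[[1]]
    } else {
      al <- globalAlign(s[1], s[k], ...)
      ca <- strsplit(al$a, "")[[1]]
      cb <- strsplit(al$b, "")[[1]]
      rows[k, ] <- cb[ca != "-"]   # project onto first-sequence columns
    }
  }
  counts <- apply(rows, 2, function(col) {
    table(factor(col[col %in% AA_STANDARD], levels = AA_STANDARD))
  })
  counts <- matrix(as.numeric(counts), nrow = 20L,
                   dimnames = list(AA_STANDARD, NULL))
  n <- length(s)
  pssm <- log2((counts + 1) / (n + 20)) - log2(1 / 20)
  pssm <- matrix(as.numeric(pssm), nrow = 20L,
                 dimnames = list(AA_STANDARD, NULL))
  consensus <- paste(AA_STANDARD[apply(counts, 2, which.max)], collapse = "")
  new("ScoringProfile", consensus = consensus, pssm = pssm,
      trainingIds = ids, scoreThreshold = NA_real_)
}

#' Score every length-L window of a protein against a profile
#'
#' Residues outside the 20 standard amino acids (e.g. `X`, `*`) contribute
#' the column minimum, so unknown residues and stop codons can only hurt a
#' window.
#'
#' @param profile a [ScoringProfile-class]
#' @param protein a single protein string
#' @return numeric vector of window scores (one per start position);
#'   length 0 when the protein is shorter than the profile
#' @export
profileWindowScores <- function(profile, protein) {
  L <- nchar(profile@consensus)
  chars <- strsplit(toupper(protein), "")[[1]]
  n <- length(chars)
  if (n < L) return(numeric(0))
  # residues outside the 20-letter alphabet get the column minimum (row 21)
  idx <- match(chars, AA_STANDARD)
  idx[is.na(idx)] <- 21L
  P <- as.vector(rbind(profile@pssm, apply(profile@pssm, 2, min)))
  nw <- n - L + 1L
  scores <- numeric(nw)
  for (j in seq_len(L))
    scores <- scores + P[(j - 1L) * 21L + idx[j:(j + nw - 1L)]]
  scores
}

#' Best window score of a protein under a profile
#' @inheritParams profileWindowScores
#' @return the maximum window score, or `-Inf` for proteins shorter than the
#'   profile
#' @export
profileBestScore <- function(profile, protein) {
  ws <- profileWindowScores(profile, protein)
  if (length(ws) == 0L) -Inf else max(ws)
}

#' Calibrate the domain-filter threshold against an empirical null
#'
#' Random proteins of the supplied length and residue composition are scored
#' and the threshold is set to the upper `1 - fpr` quantile of their best
#' window scores, so that unrelated proteins of the same composition pass
#' the domain filter with frequency at most ~`fpr` (the stand-in for an
#' e-value cut-off of 0.01).
#'
#' @param profile a [ScoringProfile-class]
#' @param fpr target false-positive rate (default 0.01)
#' @param n_null number of null proteins to draw
#' @param null_length length of null proteins (default: profile length)
#' @param composition residue frequencies for the null (default: the
#'   profile's training composition is unknown here, so uniform)
#' @param seed RNG seed
#' @return a copy of `profile` with `scoreThreshold` set
#' @export
calibrateDomainThreshold <- function(profile, fpr = 0.01, n_null = 1000L,
                                     null_length = NULL, composition = NULL,
                                     seed = 1L) {
  assertScalarNumber(fpr, "fpr", 0, 1)
  if (is.null(null_length)) null_length <- nchar(profile@consensus)
  best <- withSeed(seed, vapply(seq_len(n_null), function(i) {
    profileBestScore(profile, randomProtein(null_length, composition))
  }, numeric(1)))
  thr <- as.numeric(quantile(best, 1 - fpr, type = 1)) + 1e-9
  initialize(profile, scoreThreshold = thr)
}

#' Calibrate the assembly-search threshold against background contigs
#'
#' Scores six-frame translations of random nucleotide contigs and sets the
#' threshold to the upper `1 - fpr` quantile of the per-contig maximum
#' window score (a family-wise null: with `fpr = 0.01`, at most ~1% of
#' gene-free contigs of the calibrated size yield any hit region).
#'
#' @param profile a [ScoringProfile-class]
#' @param contig_length length of null contigs
#' @param n_null number of null contigs
#' @param fpr target per-contig false-positive rate
#' @param gc GC content of the null background
#' @param seed RNG seed
#' @return a copy of `profile` with `scoreThreshold` set
#' @export
calibrateSearchThreshold <- function(profile, contig_length, n_null = 100L,
                                     fpr = 0.01, gc = 0.5, seed = 1L) {
  assertScalarNumber(fpr, "fpr", 0, 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  best <- withSeed(seed, vapply(seq_len(n_null), function(i) {
    contig <- paste(sample(names(p), contig_length, TRUE, p), collapse = "")
    tracks <- sixFrameTranslate(contig)
    m <- vapply(tracks, function(tr) profileBestScore(profile, tr$protein),
                numeric(1))
    max(m)
  }, numeric(1)))
  thr <- as.numeric(quantile(best, 1 - fpr, type = 1)) + 1e-9
  initialize(profile, scoreThreshold = thr)
}

#' Domain annotation of a candidate protein
#'
#' @param protein a single protein string
#' @param domain_profile a calibrated [ScoringProfile-class]
#' @return list with `score` (best window score) and `pass` (logical);
#'   proteins shorter than the profile never pass
#' @export
annotateDomain <- function(protein, domain_profile) {
  if (is.na(domain_profile@scoreThreshold))
    stop("domain profile has no calibrated score threshold", call. = FALSE)
  sc <- profileBestScore(domain_profile, protein)
  list(score = sc, pass = is.finite(sc) &&
         sc >= domain_profile@scoreThreshold)
}
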