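# Targeted search of unannotated assemblies: PSSM scan of six-frame
# translations, hit-region extension, longest-ORF gene prediction, domain
# and orthology validation, representative selection.

#' Scan an assembly for profile hit regions
#'
#' Ungapped sliding-window scan of the profile over all six reading frames
#' of every contig.  Windows scoring at least the threshold are merged when
#' they overlap on the same strand and frame, and reported as nucleotide
#' regions (0-based half-open, forward-strand coordinates).
#'
#' @param assembly named character vector or `DNAStringSet` of contigs
#' @param profile a calibrated [ScoringProfile-class]
#' @param threshold score threshold; defaults to the profile's calibrated
#'   threshold
#' @return data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `frame`, `score` (best window score in the region); zero rows if no
#'   window passes
#' @export
searchRegions <- function(assembly, profile,
                          threshold = profile@scoreThreshold) {
  if (is.na(threshold))
    stop("no score threshold: calibrate the profile first", call. = FALSE)
  seqs <- as.character(assembly)
  res <- list()
  if (length(seqs) > 0L) {
    ids <- names(assembly)
    if (is.null(ids)) ids <- paste0("contig", seq_along(seqs))
    names(seqs) <- ids
  }
  L <- nchar(profile@consensus)
  for (k in seq_along(seqs)) {
    n <- nchar(seqs[k])
    tracks <- sixFrameTranslate(seqs[k])
    for (tr in tracks) {
      ws <- profileWindowScores(profile, tr$protein)
      hit <- which(ws >= threshold)
      if (length(hit) == 0L) next
      # merge window starts whose residue spans [i, i+L-1] overlap
      grp <- cumsum(c(1L, diff(hit) >= L))
      for (g in unique(grp)) {
        h <- hit[grp == g]
        aa_from <- min(h); aa_to <- max(h) + L - 1L
        iv1 <- tr$map(aa_from); iv2 <- tr$map(aa_to)
        res[[length(res) + 1L]] <- data.frame(
          contig = ids[k],
          start = min(iv1[1], iv2[1]),
          end = max(iv1[2], iv2[2]),
          strand = tr$strand, frame = tr$frame,
          score = max(ws[h]), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      frame = integer(0), score = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Extend a hit region by a flank on either side, clipped to the contig
#'
#' @param region data.frame row(s) with `start`, `end`
#' @param contig_length contig length in nucleotides
#' @param flank flank size in nucleotides (default 500)
#' @return the region(s) with extended, clipped coordinates; idempotent at
#'   contig boundaries
#' @export
extendRegion <- function(region, contig_length, flank = 500) {
  assertScalarNumber(flank, "flank", 0)
  region$start <- pmax(0L, as.integer(region$start - flank))
  region$end <- pmin(as.integer(contig_length), as.integer(region$end + flank))
  region
}

#' Predict the gene in an extended candidate region
#'
#' Collects all open reading frames (`ATG..stop`, plus edge-truncated ORFs
#' at the region borders) on the region's strand, keeps those overlapping
#' the original (pre-extension) hit interval, and returns the longest.
#' Candidates with no qualifying ORF of at least `min_codons` codons are
#' dropped (`NULL`; [searchAssembly()] logs the reason).
#'
#' @param extended data.frame row with `start`, `end`, `strand` (the
#'   extended region)
#' @param hit data.frame row with `start`, `end` (the original hit)
#' @param contig the contig sequence (single string)
#' @param min_codons minimum ORF length in codons (default 30)
#' @return list with `protein`, `start`, `end`, `strand` (gene coordinates,
#'   0-based half-open, forward strand, stop codon excluded) or `NULL`
#' @export
predictGene <- function(extended, hit, contig, min_codons = 30L) {
  s <- toupper(as.character(contig))
  reg <- substr(s, extended$start + 1L, extended$end)
  if (extended$strand == "-") reg <- revcomp(reg)
  Lr <- nchar(reg)
  best <- NULL
  for (frame in 0:2) {
    ncod <- (Lr - frame) %/% 3L
    if (ncod <= 0L) next
    prot <- translateCodons(substr(reg, frame + 1L, frame + 3L * ncod))
    orfs <- findOrfs(prot)
    if (nrow(orfs) == 0L) next
    for (r in seq_len(nrow(orfs))) {
      aa_len <- orfs$aa_end[r] - orfs$aa_start[r] + 1L
      if (aa_len < min_codons) next
      loc_start <- frame + 3L * (orfs$aa_start[r] - 1L)
      loc_end <- frame + 3L * orfs$aa_end[r]
      if (extended$strand == "+") {
        g_start <- extended$start + loc_start
        g_end <- extended$start + loc_end
      } else {
        g_start <- extended$end - loc_end
        g_end <- extended$end - loc_start
      }
      if (g_end <= hit$start || g_start >= hit$end) next  # must overlap hit
      if (is.null(best) || aa_len > best$aa_len ||
          (aa_len == best$aa_len && g_start < best$start)) {
        best <- list(protein = substr(prot, orfs$aa_start[r], orfs$aa_end[r]),
                     start = g_start, end = g_end,
                     strand = extended$strand, aa_len = aa_len)
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$aa_len <- NULL
  best
}

#' Orthology check against the seed-species proteome
#'
#' A candidate is accepted as an orthologue if its best-scoring global
#' alignment partner in the seed-species proteome is the seed gene itself or
#' one of its listed co-orthologues (a targeted best-hit criterion standing
#' in for a full orthology-inference run).
#'
#' @param candidate candidate protein (single string)
#' @param proteome named character vector: the seed species' protein set
#' @param orthologue_ids ids within `proteome` that count as the seed gene
#'   or its co-orthologues
#' @param ... passed to [globalAlign()]
#' @return `TRUE`/`FALSE`; the best-hit id is attached as attribute
#'   `best_hit`
#' @export
checkOrthology <- function(candidate, proteome, orthologue_ids, ...) {
  if (length(proteome) == 0L) stop("empty proteome", call. = FALSE)
  if (is.null(names(proteome)))
    stop("proteome must be named", call. = FALSE)
  scores <- vapply(proteome, function(p)
    globalAlign(candidate, p, score_only = TRUE, ...), numeric(1))
  ord <- order(-scores, names(proteome))    # ties: lexicographic id
  best <- names(proteome)[ord[1]]
  out <- best %in% orthologue_ids
  attr(out, "best_hit") <- best
  out
}

#' Select the representative co-orthologue
#'
#' Among several accepted co-orthologues of one species, the representative
#' for tree reconstruction is the one most similar to the seed protein
#' (highest global alignment score; ties broken by lexicographic gene id).
#'
#' @param co_orthologues named character vector of candidate proteins
#' @param seed_protein the seed protein (single string)
#' @param ... passed to [globalAlign()]
#' @return the name of the representative
#' @export
selectRepresentative <- function(co_orthologues, seed_protein, ...) {
  if (length(co_orthologues) == 0L)
    stop("no co-orthologues to select from", call. = FALSE)
  ids <- names(co_orthologues)
  if (is.null(ids)) stop("co-orthologues must be named", call. = FALSE)
  scores <- vapply(co_orthologues, function(p)
    globalAlign(p, seed_protein, score_only = TRUE, ...), numeric(1))
  ids[order(-scores, ids)][1]
}

#' Full targeted search of one assembly
#'
#' Runs the complete per-species workflow: profile scan, region extension,
#' gene prediction, domain annotation, orthology check, and representative
#' selection.
#'
#' @param assembly named character vector or `DNAStringSet` of contigs
#' @param search_profile calibrated profile for the assembly scan
#' @param domain_profile calibrated profile for the domain filter
#' @param seed_protein the seed protein string
#' @param proteome named character vector, the seed species' proteome
#' @param orthologue_ids ids in `proteome` accepted by the orthology check
#' @param flank region extension in nucleotides (default 500)
#' @param min_codons minimum ORF length in codons (default 30)
#' @param species species id recorded in the output (default `"species"`)
#' @return list with `candidates` (data.frame: `gene_id`, `species`,
#'   `contig`, `start`, `end`, `strand`, `score`, `domain_pass`,
#'   `orthology_pass`, `representative`), `proteins` (named character
#'   vector of predicted proteins) and `dropped` (character log of dropped
#'   regions)
#' @export
searchAssembly <- function(assembly, search_profile, domain_profile,
                           seed_protein, proteome, orthologue_ids,
                           flank = 500, min_codons = 30L,
                           species = "species") {
  seqs <- as.character(assembly)
  names(seqs) <- names(assembly)
  regions <- searchRegions(seqs, search_profile)
  cand <- list(); prots <- character(0); dropped <- character(0)
  if (nrow(regions) > 0) for (r in seq_len(nrow(regions))) {
    contig <- seqs[[regions$contig[r]]]
    ext <- extendRegion(regions[r, ], nchar(contig), flank)
    gene <- predictGene(ext, regions[r, ], contig, min_codons)
    if (is.null(gene)) {
      dropped <- c(dropped, sprintf(
        "%s:%d-%d(%s): no ORF of >= %d codons overlapping the hit",
        regions$contig[r], regions$start[r], regions$end[r],
        regions$strand[r], min_codons))
      next
    }
    gid <- sprintf("%s_g%d", species, length(cand) + 1L)
    dom <- annotateDomain(gene$protein, domain_profile)
    orth <- checkOrthology(gene$protein, proteome, orthologue_ids)
    cand[[length(cand) + 1L]] <- data.frame(
      gene_id = gid, species = species, contig = regions$contig[r],
      start = gene$start, end = gene$end, strand = gene$strand,
      score = dom$score, domain_pass = dom$pass,
      orthology_pass = as.logical(orth), representative = FALSE,
      stringsAsFactors = FALSE)
    prots[gid] <- gene$protein
  }
  candidates <- if (length(cand) == 0L)
    data.frame(gene_id = character(0), species = character(0),
               contig = character(0), start = integer(0), end = integer(0),
               strand = character(0), score = numeric(0),
               domain_pass = logical(0), orthology_pass = logical(0),
               representative = logical(0), stringsAsFactors = FALSE)
  else do.call(rbind, cand)
  accepted <- candidates$gene_id[candidates$domain_pass &
                                   candidates$orthology_pass]
  if (length(accepted) > 0L) {
    rep_id <- selectRepresentative(prots[accepted], seed_protein)
    candidates$representative <- candidates$gene_id == rep_id
  }
  rownames(candidates) <- NULL
  list(candidates = candidates, proteins = prots, dropped = dropped)
}
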