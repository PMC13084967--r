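# Planting genes in synthetic contigs and injecting contaminant contigs.
#
# Each planted gene is a cassette: an in-frame stop codon (insulator),
# the reverse-translated coding sequence (uniform synonymous codons), and a
# stop codon.  The insulator guarantees that the longest-ORF gene predictor
# cannot extend a planted gene through upstream background sequence, so
# prediction is exact by construction (single-exon genes, no UTR model).
# Coordinates are 0-based half-open on the forward strand; for minus-strand
# loci the reverse complement of contig[start, end) is the coding sequence.

#' @noRd
geneCassette <- function(protein, seed = NULL) {
  withSeed(seed, {
    coding <- reverseTranslate(protein)
    paste0("TAA", coding, sample(c("TAA", "TAG", "TGA"), 1L))
  })
}

#' Plant gene copies in synthetic contigs
#'
#' Builds one small assembly per species: random intergenic background with
#' the species' gene copies inserted as single-exon genes on random strands,
#' separated by at least `2 * flank` background nucleotides and kept at
#' least `2 * flank` from contig ends.  Copies that do not fit on one
#' contig spill over to additional contigs; a gene that cannot fit at all
#' is an error.  Species with zero copies receive one pure-background
#' contig.  Translating each planted locus (strand-aware) reproduces its
#' protein exactly.
#'
#' @param proteins named character vector of tip proteins (names
#'   `<species>|<copy>`, as produced by [evolveSequences()])
#' @param truth the [GeneFamilyTruth-class] the proteins belong to
#' @param contig_length contig length in nucleotides
#' @param flank flank used downstream by the search (spacing unit)
#' @param gc background GC content
#' @param seed RNG seed
#' @return list with `assemblies` (named list: species -> named character
#'   vector of contigs) and `truth` (the input truth with `plantedLoci`
#'   filled in)
#' @export
plantGenes <- function(proteins, truth, contig_length = 8000L, flank = 500L,
                       gc = 0.5, seed = 1L) {
  species <- names(copyNumber(truth))
  loci <- list()
  assemblies <- list()
  withSeed(seed, {
    for (sp in species) {
      own <- proteins[grepl(paste0("^", sp, "\\|"), names(proteins))]
      contigs <- character(0)
      cassettes <- lapply(own, geneCassette)
      remaining <- seq_along(cassettes)
      ci <- 0L
      while (length(remaining) > 0L || ci == 0L) {
        ci <- ci + 1L
        contig <- randomDna(contig_length, gc)
        p <- 2L * flank
        placed <- integer(0)
        for (j in remaining) {
          C <- nchar(cassettes[[j]])
          jitter <- sample.int(flank %/% 2L + 1L, 1L) - 1L
          start <- p + jitter
          if (start + C + 2L * flank > contig_length) break
          strand <- sample(c("+", "-"), 1L)
          ins <- if (strand == "+") cassettes[[j]] else revcomp(cassettes[[j]])
          if (start + C > contig_length - 2L * flank) break
          substr(contig, start + 1L, start + C) <- ins
          Laa <- nchar(own[j])
          loci[[length(loci) + 1L]] <- data.frame(
            species = sp, contig = sprintf("%s_c%d", sp, ci),
            start = start + 3L, end = start + 3L + 3L * Laa,
            strand = strand, protein_id = names(own)[j],
            stringsAsFactors = FALSE)
          placed <- c(placed, j)
          p <- start + C + 2L * flank
        }
        if (length(remaining) > 0L && length(placed) == 0L)
          stop(sprintf(
            "contig capacity overflow: gene of %d nt does not fit in %d nt",
            nchar(cassettes[[remaining[1]]]), contig_length), call. = FALSE)
        contigs[sprintf("%s_c%d", sp, ci)] <- contig
        remaining <- setdiff(remaining, placed)
      }
      assemblies[[sp]] <- contigs
    }
  })
  lociDf <- if (length(loci) > 0) do.call(rbind, loci) else
    truth@plantedLoci
  truth@plantedLoci <- lociDf
  validObject(truth)
  list(assemblies = assemblies, truth = truth)
}

#' Extract and translate a planted locus (strand-aware)
#'
#' Convenience used in validation: returns the protein encoded at a locus.
#'
#' @param contig contig sequence (single string)
#' @param start,end 0-based half-open coordinates of the coding sequence
#' @param strand `"+"` or `"-"`
#' @return the translated protein string
#' @export
extractLocusProtein <- function(contig, start, end, strand) {
  s <- substr(as.character(contig), start + 1L, end)
  if (strand == "-") s <- revcomp(s)
  translateCodons(s)
}

#' Inject contaminant contigs into assemblies
#'
#' Appends, per species, `round(fraction * n_contigs)` foreign contigs,
#' each carrying one gene from a foreign lineage (planted with the same
#' cassette machinery as native genes).  With `fraction = 0` the assemblies
#' are returned unchanged.  The truth record is extended with the exact
#' contaminant contig labels and their source taxa.
#'
#' @param assemblies named list: species -> named character vector of
#'   contigs (as from [plantGenes()])
#' @param foreign_proteins named character vector of foreign proteins
#' @param foreign_taxids named integer vector: foreign protein name ->
#'   source taxid
#' @param fraction contaminant fraction in `[0, 1]`
#' @param truth the [GeneFamilyTruth-class] to extend
#' @param flank spacing unit (as in [plantGenes()])
#' @param gc background GC content
#' @param seed RNG seed
#' @return list with `assemblies` and `truth`
#' @export
injectContamination <- function(assemblies, foreign_proteins, foreign_taxids,
                                fraction, truth, flank = 500L, gc = 0.5,
                                seed = 1L) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  if (fraction == 0) return(list(assemblies = assemblies, truth = truth))
  stopifnot(length(foreign_proteins) >= 1L,
            all(names(foreign_proteins) %in% names(foreign_taxids)))
  labels <- list()
  withSeed(seed, {
    for (sp in names(assemblies)) {
      n_add <- ceiling(length(assemblies[[sp]]) * fraction - 1e-9)
      if (n_add == 0L) next
      contig_length <- max(nchar(assemblies[[sp]]))
      for (k in seq_len(n_add)) {
        fp <- sample(names(foreign_proteins), 1L)
        cassette <- geneCassette(foreign_proteins[[fp]])
        C <- nchar(cassette)
        if (4L * flank + C > contig_length)
          stop("contig capacity overflow for contaminant gene",
               call. = FALSE)
        contig <- randomDna(contig_length, gc)
        start <- 2L * flank +
          sample.int(max(1L, contig_length - 4L * flank - C), 1L) - 1L
        strand <- sample(c("+", "-"), 1L)
        ins <- if (strand == "+") cassette else revcomp(cassette)
        substr(contig, start + 1L, start + C) <- ins
        cid <- sprintf("%s_cont%d", sp, k)
        assemblies[[sp]][cid] <- contig
        Laa <- nchar(foreign_proteins[[fp]])
        labels[[length(labels) + 1L]] <- data.frame(
          species = sp, contig = cid,
          source_taxid = as.integer(foreign_taxids[[fp]]),
          start = start + 3L, end = start + 3L + 3L * Laa,
          strand = strand, protein_id = sprintf("%s@%s", fp, cid),
          protein = foreign_proteins[[fp]],
          stringsAsFactors = FALSE)
      }
    }
  })
  if (length(labels) > 0)
    truth@contaminantContigs <- do.call(rbind, labels)
  list(assemblies = assemblies, truth = truth)
}
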