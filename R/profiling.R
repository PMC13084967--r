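# Presence/absence profiling: genome inclusion by assembly completeness,
# aggregation of accepted candidates into a copy-count matrix, clade
# summaries, and the 3-column phylogenetic-profile exchange format.

#' Filter genomes by assembly completeness
#'
#' A genome is kept when its completeness is at least the threshold
#' (inclusive: exactly 50% passes a 0.50 threshold).
#'
#' @param meta data.frame with columns `species_id` and
#'   `busco_completeness`
#' @param min_completeness inclusion threshold (default 0.50)
#' @return character vector of kept species ids
#' @export
filterGenomes <- function(meta, min_completeness = 0.50) {
  assertScalarNumber(min_completeness, "min_completeness", 0, 1)
  meta$species_id[meta$busco_completeness >= min_completeness]
}

#' Build the species-by-family presence matrix
#'
#' Each cell counts the candidates of a species that passed both the domain
#' and the orthology filter.  Species in the kept set with no candidates get
#' a zero; candidates of species outside the kept set are dropped with a
#' warning.
#'
#' @param candidates data.frame with columns `species`, `domain_pass`,
#'   `orthology_pass` (and optionally `family`; default family `"GH45"`)
#' @param meta species metadata data.frame (see [PresenceProfile-class])
#' @param kept_species character vector of species to include (rows);
#'   default: all species in `meta`
#' @param family family label for the single-family case
#' @return a [PresenceProfile-class]
#' @export
buildPresenceMatrix <- function(candidates, meta,
                                kept_species = meta$species_id,
                                family = "GH45") {
  if (!"family" %in% names(candidates)) {
    candidates$family <- if (nrow(candidates) > 0) family else character(0)
  }
  outside <- setdiff(unique(candidates$species), kept_species)
  if (length(outside) > 0) {
    warning("dropping candidates of species outside the kept set: ",
            paste(outside, collapse = ", "), call. = FALSE)
    candidates <- candidates[candidates$species %in% kept_species, ,
                             drop = FALSE]
  }
  meta <- meta[match(kept_species, meta$species_id), , drop = FALSE]
  fams <- unique(c(family, candidates$family))
  counts <- matrix(0L, nrow = length(kept_species), ncol = length(fams),
                   dimnames = list(kept_species, fams))
  acc <- candidates[candidates$domain_pass & candidates$orthology_pass, ,
                    drop = FALSE]
  if (nrow(acc) > 0) {
    tab <- table(acc$species, acc$family)
    counts[rownames(tab), colnames(tab)] <- counts[rownames(tab),
                                                   colnames(tab)] +
      matrix(as.integer(tab), nrow = nrow(tab))
  }
  rownames(meta) <- NULL
  new("PresenceProfile", counts = counts, meta = meta)
}

#' Per-clade presence summary
#'
#' @param profile a [PresenceProfile-class]
#' @param family column to summarise (default: first)
#' @return data.frame with `clade`, `n_present`, `n_total`, `fraction`;
#'   species with missing clade labels are grouped under `"unknown"`
#' @export
summarizeByClade <- function(profile, family = 1L) {
  counts <- presenceCounts(profile)[, family]
  clade <- speciesMeta(profile)$clade
  clade[is.na(clade) | !nzchar(clade)] <- "unknown"
  out <- do.call(rbind, lapply(split(seq_along(clade), clade), function(i) {
    data.frame(n_present = sum(counts[i] >= 1), n_total = length(i))
  }))
  data.frame(clade = rownames(out), n_present = out$n_present,
             n_total = out$n_total,
             fraction = out$n_present / out$n_total,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a phylogenetic-profile table
#'
#' Minimal 3-column exchange dialect: header `geneID ncbiID orthoID`, one
#' row per (family, species, orthologue), `ncbiID` rendered as
#' `ncbi<taxid>`.  Species with zero copies produce no row.
#'
#' @param profile a [PresenceProfile-class]
#' @param path output path
#' @param orthologue_ids optional data.frame (`species`, `family`,
#'   `gene_id`) naming the individual orthologues; when absent, synthetic
#'   `<family>@<species>#<k>` ids are emitted per copy
#' @return `path`, invisibly
#' @export
writeProfileTsv <- function(profile, path, orthologue_ids = NULL) {
  counts <- presenceCounts(profile)
  meta <- speciesMeta(profile)
  rows <- list()
  for (fam in colnames(counts)) for (i in seq_len(nrow(counts))) {
    k <- counts[i, fam]
    if (k == 0) next
    sp <- rownames(counts)[i]
    ids <- if (!is.null(orthologue_ids)) {
      sel <- orthologue_ids$species == sp & orthologue_ids$family == fam
      orthologue_ids$gene_id[sel]
    } else sprintf("%s@%s#%d", fam, sp, seq_len(k))
    for (id in ids)
      rows[[length(rows) + 1L]] <- data.frame(
        geneID = fam, ncbiID = paste0("ncbi", meta$taxid[i]), orthoID = id,
        stringsAsFactors = FALSE)
  }
  df <- if (length(rows) > 0) do.call(rbind, rows)
        else data.frame(geneID = character(0), ncbiID = character(0),
                        orthoID = character(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phylogenetic-profile table back
#'
#' @param path path to a file written by [writeProfileTsv()]
#' @return data.frame with columns `geneID`, `ncbiID`, `orthoID`
#' @export
readProfileTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
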