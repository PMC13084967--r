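# Species-tree and taxonomy simulation.

#' Simulate a species tree under a Yule process
#'
#' Pure-birth (Yule) tree with exponential waiting times, rescaled to unit
#' root-to-tip height so that branch lengths are interpretable as fractions
#' of the clade's total depth (and substitution rates as expected
#' substitutions per site over the whole history).  Tips are labelled
#' `sp01, sp02, ...` and internal nodes `n1, n2, ...` (the root is `n1`);
#' output is identical for identical seeds.
#'
#' @param n_species number of tips (>= 2)
#' @param seed RNG seed
#' @param scale_height if `TRUE` (default) rescale to unit height
#' @return a rooted binary ape `phylo` with positive branch lengths and
#'   labelled internal nodes
#' @export
simulateSpeciesTree <- function(n_species, seed = 1L, scale_height = TRUE) {
  if (!is.numeric(n_species) || n_species < 2)
    stop("n_species must be at least 2", call. = FALSE)
  n_species <- as.integer(n_species)
  tree <- withSeed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  if (scale_height) {
    h <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / h
  }
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree$node.label <- paste0("n", seq_len(tree$Nnode))
  tree
}

#' Build a study taxonomy around a set of species
#'
#' Constructs a small NCBI-like taxonomy: a root of cellular life, a
#' eukaryote domain holding the native phylum (one genus per study species,
#' each with the species itself plus one annotated relative) and a foreign
#' fungal lineage, and a bacterial domain.  This is the reference frame for
#' margin-LCA assignment and contaminant flagging.
#'
#' @param species_ids character vector of study species ids
#' @param n_foreign number of foreign (fungal) species (>= 1)
#' @param n_bacteria number of bacterial species
#' @return list with `taxonomy` ([Taxonomy-class]), `species_taxids` (named
#'   integer: study species -> leaf taxid), `relative_taxids` (named
#'   integer: congeneric relatives), `foreign_taxids`, `bacteria_taxids`,
#'   `phylum_taxid` (the native phylum), `foreign_phylum_taxid`
#' @export
makeStudyTaxonomy <- function(species_ids, n_foreign = 6L, n_bacteria = 3L) {
  stopifnot(length(species_ids) >= 1L, n_foreign >= 1L)
  rows <- list()
  addRow <- function(taxid, parent, rank, name)
    rows[[length(rows) + 1L]] <<- data.frame(
      taxid = taxid, parent_taxid = parent, rank = rank, name = name)
  addRow(1L, 1L, "root", "cellular organisms")
  addRow(2L, 1L, "domain", "Eukaryota")
  addRow(3L, 1L, "domain", "Bacteria")
  addRow(10L, 2L, "phylum", "NativePhylum")
  addRow(11L, 2L, "kingdom", "ForeignFungi")
  addRow(12L, 11L, "phylum", "ForeignPhylum")
  nextId <- 100L
  species_taxids <- integer(0); relative_taxids <- integer(0)
  for (sp in species_ids) {
    genus <- nextId; nextId <- nextId + 1L
    addRow(genus, 10L, "genus", paste0("Genus_", sp))
    species_taxids[sp] <- nextId
    addRow(nextId, genus, "species", sp); nextId <- nextId + 1L
    relative_taxids[sp] <- nextId
    addRow(nextId, genus, "species", paste0(sp, "_relative"))
    nextId <- nextId + 1L
  }
  foreign_taxids <- integer(0)
  for (k in seq_len(n_foreign)) {
    genus <- nextId; nextId <- nextId + 1L
    addRow(genus, 12L, "genus", paste0("FungalGenus_", k))
    foreign_taxids[paste0("fungus", k)] <- nextId
    addRow(nextId, genus, "species", paste0("fungus", k))
    nextId <- nextId + 1L
  }
  bacteria_taxids <- integer(0)
  for (k in seq_len(n_bacteria)) {
    bacteria_taxids[paste0("bact", k)] <- nextId
    addRow(nextId, 3L, "species", paste0("bact", k))
    nextId <- nextId + 1L
  }
  tab <- do.call(rbind, rows)
  list(taxonomy = Taxonomy(tab),
       species_taxids = species_taxids,
       relative_taxids = relative_taxids,
       foreign_taxids = foreign_taxids,
       bacteria_taxids = bacteria_taxids,
       phylum_taxid = 10L,
       foreign_phylum_taxid = 12L)
}
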