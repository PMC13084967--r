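# One call that generates a complete synthetic study: species tree,
# taxonomy, gene-family truth, assemblies with planted genes and
# contamination, hit tables, species metadata, and the reference material
# (seed protein, core orthologue set, seed-species proteome) the search
# stages need.

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic-data generator.  The
#' defaults describe the study conditions the pipeline is exercised under:
#' 20 species, family gained at the root, mild duplication/loss dynamics,
#' root-to-tip divergence 0.25 substitutions per site, 220-residue
#' proteins, 8 kb contigs, 20% contaminant contigs, noiseless hit tables.
#'
#' @param n_species number of study species (>= 2)
#' @param seed master RNG seed; all stages draw from streams derived from it
#' @param duplication_rate,loss_rate per-copy, per-branch-length rates
#' @param origin_branch `"root"` or a branch id of the species tree
#' @param forced_events optional forced event table
#'   (see [simulateGeneFamily()])
#' @param substitution_rate expected substitutions per site per unit branch
#'   length (the species tree has unit height)
#' @param protein_length seed protein length in residues
#' @param contig_length contig length in nucleotides (must be at least
#'   `3 * protein_length + 2 * flank`)
#' @param flank search flank in nucleotides
#' @param gc background GC content
#' @param contamination_fraction fraction of contigs added as contaminants
#' @param hit_noise_sd bit-score noise standard deviation
#' @param base_score distance-zero bit score
#' @param decay_lambda bit-score decay per taxonomy edge
#' @param n_foreign number of foreign (fungal) reference species
#' @param n_decoys number of unrelated proteins in the seed-species proteome
#' @param core_divergence divergence of the profile training orthologues
#'   from the seed
#' @param foreign_divergence divergence of foreign family members from the
#'   seed
#' @param completeness_range range assembly completeness is drawn from
#' @param p_parthenogenetic probability a species is parthenogenetic
#' @param p_unknown probability the reproduction mode is unknown
#' @return a validated list of class `ghp_sim_config`
#' @export
simulationConfig <- function(n_species = 20L, seed = 1L,
                             duplication_rate = 0.1, loss_rate = 0.05,
                             origin_branch = "root", forced_events = NULL,
                             substitution_rate = 0.25,
                             protein_length = 220L, contig_length = 8000L,
                             flank = 500L, gc = 0.5,
                             contamination_fraction = 0.2,
                             hit_noise_sd = 0, base_score = 200,
                             decay_lambda = 0.3, n_foreign = 6L,
                             n_decoys = 30L, core_divergence = 0.08,
                             foreign_divergence = 0.15,
                             completeness_range = c(0.55, 0.98),
                             p_parthenogenetic = 0.4, p_unknown = 0.05) {
  cfg <- list(n_species = as.integer(n_species), seed = as.integer(seed),
              duplication_rate = duplication_rate, loss_rate = loss_rate,
              origin_branch = origin_branch, forced_events = forced_events,
              substitution_rate = substitution_rate,
              protein_length = as.integer(protein_length),
              contig_length = as.integer(contig_length),
              flank = as.integer(flank), gc = gc,
              contamination_fraction = contamination_fraction,
              hit_noise_sd = hit_noise_sd, base_score = base_score,
              decay_lambda = decay_lambda, n_foreign = as.integer(n_foreign),
              n_decoys = as.integer(n_decoys),
              core_divergence = core_divergence,
              foreign_divergence = foreign_divergence,
              completeness_range = completeness_range,
              p_parthenogenetic = p_parthenogenetic,
              p_unknown = p_unknown)
  if (cfg$n_species < 2) stop("n_species must be >= 2", call. = FALSE)
  assertScalarNumber(cfg$duplication_rate, "duplication_rate", 0)
  assertScalarNumber(cfg$loss_rate, "loss_rate", 0)
  assertScalarNumber(cfg$substitution_rate, "substitution_rate", 0)
  assertScalarNumber(cfg$contamination_fraction, "contamination_fraction",
                     0, 1)
  assertScalarNumber(cfg$hit_noise_sd, "hit_noise_sd", 0)
  assertScalarNumber(cfg$gc, "gc", 0, 1)
  if (cfg$protein_length < 30)
    stop("protein_length must be at least 30", call. = FALSE)
  if (cfg$contig_length < 3 * cfg$protein_length + 2 * cfg$flank)
    stop("contig_length must be at least 3*protein_length + 2*flank",
         call. = FALSE)
  class(cfg) <- "ghp_sim_config"
  cfg
}

#' Generate a complete synthetic study
#'
#' Runs every generator stage under independent RNG streams derived from
#' the master seed and returns the full data set plus the ground truth.
#'
#' @param config a [simulationConfig()]
#' @return list with elements `species_tree`, `taxonomy`, `species_taxids`,
#'   `phylum_taxid`, `foreign_taxids`, `assemblies` (species -> contigs),
#'   `tip_proteins`, `seed_protein`, `core_proteins`, `proteome`,
#'   `orthologue_ids`, `foreign_proteins`, `hit_tables` (protein id -> hit
#'   data.frame), `meta` (species metadata data.frame), `truth`
#'   ([GeneFamilyTruth-class]) and `config`
#' @export
simulateStudy <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "ghp_sim_config"))
  seed <- config$seed
  tree <- simulateSpeciesTree(config$n_species, deriveSeed(seed, 1))
  taxinfo <- makeStudyTaxonomy(tree$tip.label, config$n_foreign)
  truth <- simulateGeneFamily(tree, config$duplication_rate,
                              config$loss_rate, config$origin_branch,
                              config$forced_events, deriveSeed(seed, 2))
  seed_protein <- withSeed(deriveSeed(seed, 3), paste0(
    "M", randomProtein(config$protein_length - 1L)))
  core <- withSeed(deriveSeed(seed, 4), {
    out <- c(seed_ref = seed_protein)
    for (k in 2:MAX_TRAINING)
      out[paste0("core", k)] <-
        paste(mutateChars(strsplit(seed_protein, "")[[1]],
                          config$core_divergence, 1), collapse = "")
    out
  })
  tip_proteins <- evolveSequences(seed_protein, tree, truth,
                                  config$substitution_rate,
                                  deriveSeed(seed, 5))
  planted <- plantGenes(tip_proteins, truth, config$contig_length,
                        config$flank, config$gc, deriveSeed(seed, 6))
  truth <- planted$truth
  foreign_proteins <- withSeed(deriveSeed(seed, 7), {
    setNames(vapply(seq_len(config$n_foreign), function(k)
      paste(mutateChars(strsplit(seed_protein, "")[[1]],
                        config$foreign_divergence, 1), collapse = ""),
      character(1)), names(taxinfo$foreign_taxids))
  })
  contaminated <- injectContamination(planted$assemblies, foreign_proteins,
                                      taxinfo$foreign_taxids,
                                      config$contamination_fraction, truth,
                                      config$flank, config$gc,
                                      deriveSeed(seed, 8))
  truth <- contaminated$truth
  assemblies <- contaminated$assemblies

  hit_tables <- list()
  loci <- plantedLoci(truth)
  if (nrow(loci) > 0) for (r in seq_len(nrow(loci))) {
    pid <- loci$protein_id[r]
    hit_tables[[pid]] <- simulateHitTable(
      pid, taxinfo$species_taxids[[loci$species[r]]], taxinfo$taxonomy,
      config$hit_noise_sd, deriveSeed(seed, 100 + r),
      config$base_score, config$decay_lambda)
  }
  cont <- contaminantContigs(truth)
  if (nrow(cont) > 0) for (r in seq_len(nrow(cont))) {
    pid <- cont$protein_id[r]
    hit_tables[[pid]] <- simulateHitTable(
      pid, cont$source_taxid[r], taxinfo$taxonomy,
      config$hit_noise_sd, deriveSeed(seed, 5000 + r),
      config$base_score, config$decay_lambda)
  }

  meta <- withSeed(deriveSeed(seed, 9), {
    n <- config$n_species
    mode <- ifelse(runif(n) < config$p_unknown, "unknown",
                   ifelse(runif(n) < config$p_parthenogenetic,
                          "parthenogenetic", "sexual"))
    rk <- rootNode(tree)
    firstChild <- childList(tree)[[rk]][1]
    inA <- cladeTips(tree)[[firstChild]]
    data.frame(
      species_id = tree$tip.label,
      taxid = as.integer(taxinfo$species_taxids[tree$tip.label]),
      busco_completeness = runif(n, config$completeness_range[1],
                                 config$completeness_range[2]),
      reproduction_mode = mode,
      clade = ifelse(seq_len(n) %in% inA, "cladeA", "cladeB"),
      stringsAsFactors = FALSE)
  })

  proteome <- withSeed(deriveSeed(seed, 10), {
    decoys <- vapply(seq_len(config$n_decoys), function(k)
      randomProtein(config$protein_length), character(1))
    c(setNames(decoys, paste0("decoy", seq_len(config$n_decoys))),
      seed_ref = seed_protein)
  })

  list(species_tree = tree, taxonomy = taxinfo$taxonomy,
       species_taxids = taxinfo$species_taxids,
       phylum_taxid = taxinfo$phylum_taxid,
       foreign_taxids = taxinfo$foreign_taxids,
       assemblies = assemblies, tip_proteins = tip_proteins,
       seed_protein = seed_protein, core_proteins = core,
       proteome = proteome, orthologue_ids = "seed_ref",
       foreign_proteins = foreign_proteins, hit_tables = hit_tables,
       meta = meta, truth = truth, config = config)
}
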