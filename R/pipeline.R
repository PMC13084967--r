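# End-to-end pipeline: simulate -> contig screen -> targeted search ->
# gene screen -> presence profile -> comparative trees -> association test,
# with a machine-readable run report.

#' Pipeline configuration
#'
#' Single home for every analysis threshold, with validation.  Defaults:
#' 10% bit-score margin, 500 nt flank, at most 6 training sequences, 1%
#' domain false-positive rate, 50% minimum assembly completeness, 50%
#' maximum gap fraction, 75% minimum supermatrix occupancy, 30-codon
#' minimum ORF.
#'
#' @param margin bit-score margin in (0, 1)
#' @param flank region extension in nucleotides
#' @param max_training maximum profile training sequences
#' @param domain_fpr domain-filter false-positive rate, between 0 and 1
#' @param min_completeness genome inclusion threshold (0 to 1)
#' @param max_gap_fraction alignment trimming threshold (0 to 1)
#' @param min_occupancy supermatrix occupancy threshold (0 to 1)
#' @param min_orf_codons minimum predicted ORF length (codons)
#' @param seed master seed for the run
#' @param simulation a [simulationConfig()] for the simulate stage
#' @return validated list of class `ghp_pipeline_config`
#' @export
pipelineConfig <- function(margin = 0.10, flank = 500L, max_training = 6L,
                           domain_fpr = 0.01, min_completeness = 0.50,
                           max_gap_fraction = 0.50, min_occupancy = 0.75,
                           min_orf_codons = 30L, seed = 1L,
                           simulation = simulationConfig(seed = seed)) {
  cfg <- list(margin = margin, flank = as.integer(flank),
              max_training = as.integer(max_training),
              domain_fpr = domain_fpr,
              min_completeness = min_completeness,
              max_gap_fraction = max_gap_fraction,
              min_occupancy = min_occupancy,
              min_orf_codons = as.integer(min_orf_codons),
              seed = as.integer(seed), simulation = simulation)
  if (!is.numeric(margin) || margin <= 0 || margin >= 1)
    stop("margin must lie in (0, 1)", call. = FALSE)
  assertScalarNumber(domain_fpr, "domain_fpr", 1e-6, 1)
  assertScalarNumber(min_completeness, "min_completeness", 0, 1)
  assertScalarNumber(max_gap_fraction, "max_gap_fraction", 0, 1)
  assertScalarNumber(min_occupancy, "min_occupancy", 0, 1)
  if (cfg$flank < 0) stop("flank must be >= 0", call. = FALSE)
  if (cfg$max_training < 1 || cfg$max_training > 6)
    stop("max_training must be between 1 and 6", call. = FALSE)
  if (cfg$min_orf_codons < 1)
    stop("min_orf_codons must be >= 1", call. = FALSE)
  stopifnot(inherits(simulation, "ghp_sim_config"))
  class(cfg) <- "ghp_pipeline_config"
  cfg
}

#' Run the full pipeline on a synthetic study
#'
#' Executes, in order: data simulation, contig-level taxonomic filtering,
#' targeted search of every kept assembly, per-gene contaminant screening,
#' presence-matrix construction and clade summaries, gene-tree
#' reconstruction with origin counting, Dollo history, duplication/loss
#' reconciliation and tanglegram, and the presence-vs-reproduction-mode
#' chi-squared test.  Identical config and seed produce an identical
#' report.
#'
#' @param config a [pipelineConfig()]
#' @param study optionally a pre-built [simulateStudy()] result (otherwise
#'   the simulate stage runs `config$simulation`)
#' @param report_path optional path; when given the report is written as
#'   JSON
#' @return the run report (a nested list); the heavyweight intermediate
#'   objects travel in `report$objects`
#' @export
runPipeline <- function(config = pipelineConfig(), study = NULL,
                        report_path = NULL) {
  stopifnot(inherits(config, "ghp_pipeline_config"))
  t0 <- proc.time()[["elapsed"]]

  ## stage 1: simulate -------------------------------------------------
  if (is.null(study)) study <- simulateStudy(config$simulation)
  truth <- study$truth
  tax <- study$taxonomy
  simc <- study$config

  ## stage 2: genome inclusion ----------------------------------------
  kept_species <- filterGenomes(study$meta, config$min_completeness)

  ## stage 3: profiles -------------------------------------------------
  core <- study$core_proteins[seq_len(min(length(study$core_proteins),
                                          config$max_training))]
  profile <- buildProfile(core)
  domain_profile <- calibrateDomainThreshold(
    profile, fpr = config$domain_fpr,
    n_null = 1000L, null_length = simc$protein_length,
    seed = deriveSeed(config$seed, 21))
  search_profile <- calibrateSearchThreshold(
    profile, contig_length = simc$contig_length, n_null = 60L,
    fpr = config$domain_fpr, gc = simc$gc,
    seed = deriveSeed(config$seed, 22))

  ## stage 4: contig-level taxonomic filter ----------------------------
  lociByContig <- function(sp) {
    pl <- plantedLoci(truth); cc <- contaminantContigs(truth)
    ids <- c(if (nrow(pl) > 0) setNames(pl$protein_id, pl$contig)[
               pl$species == sp] else NULL,
             if (nrow(cc) > 0) setNames(cc$protein_id, cc$contig)[
               cc$species == sp] else NULL)
    split(unname(ids), names(ids))
  }
  contigs_kept <- list(); n_contigs_total <- 0L; n_contigs_dropped <- 0L
  for (sp in kept_species) {
    contigs <- names(study$assemblies[[sp]])
    n_contigs_total <- n_contigs_total + length(contigs)
    byContig <- lociByContig(sp)
    assign_vec <- setNames(rep(NA_integer_, length(contigs)), contigs)
    for (cid in names(byContig)) {
      pooled <- do.call(rbind, study$hit_tables[byContig[[cid]]])
      # drop the self-hits of every gene on the contig, then margin-LCA
      pooled <- pooled[!pooled$subject_id %in% byContig[[cid]], ,
                       drop = FALSE]
      a <- assignByMargin(pooled, "__contig__", tax, config$margin)
      assign_vec[cid] <- a@taxid
    }
    kept <- filterContigs(assign_vec, study$phylum_taxid, tax)
    n_contigs_dropped <- n_contigs_dropped + length(contigs) - length(kept)
    contigs_kept[[sp]] <- kept
  }

  ## stage 5: targeted search ------------------------------------------
  all_candidates <- list(); all_proteins <- character(0)
  for (sp in kept_species) {
    asm <- study$assemblies[[sp]][contigs_kept[[sp]]]
    res <- searchAssembly(asm, search_profile, domain_profile,
                          study$seed_protein, study$proteome,
                          study$orthologue_ids, config$flank,
                          config$min_orf_codons, species = sp)
    all_candidates[[sp]] <- res$candidates
    all_proteins <- c(all_proteins, res$proteins)
  }
  candidates <- do.call(rbind, all_candidates)
  rownames(candidates) <- NULL

  ## stage 6: per-gene taxonomic screen --------------------------------
  matchHitTable <- function(row) {
    pl <- plantedLoci(truth); cc <- contaminantContigs(truth)
    hit <- NULL
    if (nrow(pl) > 0) {
      sel <- pl$species == row$species & pl$contig == row$contig &
        pl$start < row$end & row$start < pl$end
      if (any(sel)) hit <- pl$protein_id[which(sel)[1]]
    }
    if (is.null(hit) && nrow(cc) > 0) {
      sel <- cc$species == row$species & cc$contig == row$contig &
        cc$start < row$end & row$start < cc$end
      if (any(sel)) hit <- cc$protein_id[which(sel)[1]]
    }
    hit
  }
  screened <- 0L; flagged_genes <- character(0)
  candidates$flagged <- FALSE
  if (nrow(candidates) > 0) for (r in seq_len(nrow(candidates))) {
    pid <- matchHitTable(candidates[r, ])
    if (is.null(pid)) next
    ht <- study$hit_tables[[pid]]
    a <- assignByMargin(ht, pid, tax, config$margin)
    a <- flagContaminant(a, study$species_taxids[[candidates$species[r]]],
                         tax)
    screened <- screened + 1L
    candidates$flagged[r] <- a@flagged
    if (a@flagged)
      flagged_genes <- c(flagged_genes, candidates$gene_id[r])
  }

  ## stage 7: presence profile -----------------------------------------
  accepted <- candidates[!candidates$flagged, , drop = FALSE]
  profile_matrix <- buildPresenceMatrix(
    accepted, study$meta[study$meta$species_id %in% kept_species, ,
                         drop = FALSE], kept_species)
  clade_summary <- summarizeByClade(profile_matrix)

  ## stage 8: comparative trees ----------------------------------------
  acc_ok <- accepted[accepted$domain_pass & accepted$orthology_pass, ,
                     drop = FALSE]
  gene_analysis <- NULL
  if (nrow(acc_ok) >= 2) {
    reps <- vapply(split(acc_ok, acc_ok$species), function(d) {
      if (nrow(d) == 1L) d$gene_id else
        selectRepresentative(all_proteins[d$gene_id], study$seed_protein)
    }, character(1))
    rep_prots <- all_proteins[reps]
    seqs <- c(rep_prots, outgroup_seed = study$seed_protein)
    dmat <- alignmentDistances(seqs)
    gtree <- njTree(dmat)
    rooted <- rootByOutgroup(gtree, "outgroup_seed")
    groups <- setNames(rep("animal", length(reps)), reps)
    groups["outgroup_seed"] <- "fungal"
    origins <- countGroupOrigins(rooted, groups, "animal")
    ingroup <- ape::drop.tip(rooted, "outgroup_seed")
    recon <- NULL; tangle <- NULL
    if (!is.null(ingroup) && ape::Ntip(ingroup) >= 2) {
      sp_of <- setNames(names(reps), reps)   # gene id -> species
      sp_present <- unique(sp_of[ingroup$tip.label])
      if (length(sp_present) >= 2) {
        st_sub <- ape::keep.tip(study$species_tree, sp_present)
        recon <- reconcileTrees(ingroup, st_sub, sp_of[ingroup$tip.label])
        links <- data.frame(left = ingroup$tip.label,
                            right = unname(sp_of[ingroup$tip.label]),
                            stringsAsFactors = FALSE)
        tangle <- tanglegram(ingroup, st_sub, links)
      }
    }
    gene_analysis <- list(tree = rooted, origins = origins,
                          reconciliation = recon, tanglegram = tangle,
                          representatives = reps)
  }

  ## stage 9: Dollo history on the species tree ------------------------
  presence <- setNames(presenceCounts(profile_matrix)[, 1] >= 1,
                       rownames(presenceCounts(profile_matrix)))
  full_presence <- setNames(rep(FALSE, length(study$species_tree$tip.label)),
                            study$species_tree$tip.label)
  full_presence[names(presence)] <- presence
  dollo <- dolloHistory(study$species_tree, full_presence)

  ## stage 10: association test ----------------------------------------
  assoc <- tryCatch({
    pbt <- presenceByTrait(profile_matrix)
    test <- chiSquaredTest(pbt$table, yates = TRUE)
    list(table = pbt$table, excluded = pbt$excluded,
         statistic = test$statistic, df = test$df, p_value = test$p_value)
  }, error = function(e) list(error = conditionMessage(e)))

  ## evaluation against truth ------------------------------------------
  truth_presence <- copyNumber(truth)[names(full_presence)] >= 1
  presence_accuracy <- mean(full_presence[kept_species] ==
                              truth_presence[kept_species])
  cont <- contaminantContigs(truth)
  cont_ids <- if (nrow(cont) > 0)
    paste(cont$species, cont$contig, sep = "/") else character(0)
  dropped_ids <- unlist(lapply(kept_species, function(sp)
    paste(sp, setdiff(names(study$assemblies[[sp]]), contigs_kept[[sp]]),
          sep = "/")))
  cont_in_kept <- intersect(cont_ids, unlist(lapply(kept_species,
    function(sp) paste(sp, names(study$assemblies[[sp]]), sep = "/"))))
  tp <- length(intersect(dropped_ids, cont_in_kept))
  contamination_recall <- if (length(cont_in_kept) == 0) 1 else
    tp / length(cont_in_kept)
  contamination_precision <- if (length(dropped_ids) == 0) 1 else
    tp / length(dropped_ids)

  report <- list(
    version = as.character(packageVersion("ghprospect")),
    seed = config$seed,
    config = config[setdiff(names(config), "simulation")],
    simulation_config = unclass(config$simulation)[
      !vapply(config$simulation, is.data.frame, logical(1))],
    stages = list(
      genomes = list(total = nrow(study$meta),
                     kept = length(kept_species)),
      contigs = list(total = n_contigs_total,
                     dropped = n_contigs_dropped),
      candidates = list(found = nrow(candidates),
                        screened = screened,
                        flagged = length(flagged_genes),
                        accepted = sum(accepted$domain_pass &
                                         accepted$orthology_pass)),
      clades = clade_summary,
      origins = if (!is.null(gene_analysis)) gene_analysis$origins else NA,
      dollo = list(gain_branch = dollo$gain_branch,
                   n_losses = dollo$n_losses),
      reconciliation = if (!is.null(gene_analysis) &&
                           !is.null(gene_analysis$reconciliation))
        list(duplications = gene_analysis$reconciliation$duplications,
             losses = gene_analysis$reconciliation$losses) else NULL,
      tanglegram_crossings = if (!is.null(gene_analysis) &&
                                 !is.null(gene_analysis$tanglegram))
        gene_analysis$tanglegram$crossings else NA,
      association = assoc),
    evaluation = list(presence_accuracy = presence_accuracy,
                      contamination_precision = contamination_precision,
                      contamination_recall = contamination_recall),
    elapsed_seconds = proc.time()[["elapsed"]] - t0,
    objects = list(presence = profile_matrix, candidates = candidates,
                   gene_analysis = gene_analysis, dollo = dollo,
                   truth = truth, kept_species = kept_species))
  if (!is.null(report_path)) {
    out <- report[setdiff(names(report), c("objects", "elapsed_seconds"))]
    jsonlite::write_json(out, report_path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
  }
  report
}
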