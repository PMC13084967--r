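# Taxonomic screening: margin-based LCA assignment of each query, the
# off-lineage contaminant flag, the contig-level phylum filter and the
# per-assembly screening report.

#' Assign a query to the LCA of its best hits within a bit-score margin
#'
#' The trivial self-hit (every hit whose `subject_id` equals the query id)
#' is removed first.  Among the remaining hits, each subject is represented
#' by its maximum bit score, the best score defines the inclusion threshold
#' `(1 - margin) * best` (inclusive, so boundary ties contribute), and the
#' query is assigned to the last common ancestor of the contributing taxa.
#' With no remaining hit the query is unassigned.
#'
#' @param hits hit table data.frame (columns as in [readHitTable()])
#' @param self_id the query's own id (self-hits are excluded)
#' @param taxonomy a [Taxonomy-class]
#' @param margin bit-score margin in (0, 1); default 0.10
#' @return a [TaxAssignment-class] (not yet flagged)
#' @export
assignByMargin <- function(hits, self_id, taxonomy, margin = 0.10) {
  if (!is.numeric(margin) || margin <= 0 || margin >= 1)
    stop("margin must lie in (0, 1)", call. = FALSE)
  h <- hits[hits$subject_id != self_id, , drop = FALSE]
  if (nrow(h) == 0L)
    return(new("TaxAssignment", queryId = self_id, taxid = NA_integer_,
               marginUsed = margin,
               hits = h[integer(0), , drop = FALSE], flagged = FALSE))
  # one score per subject: its best HSP
  best_per_subject <- vapply(split(h$bitscore, h$subject_id), max,
                             numeric(1))
  keep_first <- !duplicated(h$subject_id)
  h <- h[keep_first, , drop = FALSE]
  h$bitscore <- as.numeric(best_per_subject[h$subject_id])
  best <- max(h$bitscore)
  contributing <- h[h$bitscore >= (1 - margin) * best, , drop = FALSE]
  assigned <- taxLCA(taxonomy, unique(contributing$subject_taxid))
  new("TaxAssignment", queryId = self_id, taxid = as.integer(assigned),
      marginUsed = margin, hits = contributing, flagged = FALSE)
}

#' Flag an assignment as a putative contaminant
#'
#' A query is flagged when it has an assignment and that assignment is not
#' placed on the lineage from the query species to the root: ancestors of
#' the species, the species itself and its descendants all count as
#' on-lineage.  Unassigned queries are never flagged.
#'
#' @param assignment a [TaxAssignment-class]
#' @param query_species_taxid taxid of the species whose genome is screened
#' @param taxonomy a [Taxonomy-class]
#' @return the assignment with its `flagged` slot set
#' @export
flagContaminant <- function(assignment, query_species_taxid, taxonomy) {
  taxIndex(taxonomy, query_species_taxid, "query species taxid")
  flag <- !is.na(assignment@taxid) &&
    !taxOnLineage(taxonomy, assignment@taxid, query_species_taxid)
  initialize(assignment, flagged = flag)
}

#' Contig-level phylum filter
#'
#' Keeps contigs assigned to the target phylum (its subtree or the lineage
#' through it) and unassigned contigs; everything else is dropped.
#'
#' @param per_contig_assignments named integer vector: contig id ->
#'   assigned taxid (`NA` for unassigned), or a named list of
#'   [TaxAssignment-class] objects
#' @param target_phylum_taxid taxid of the target species' phylum
#' @param taxonomy a [Taxonomy-class]
#' @return character vector of kept contig ids
#' @export
filterContigs <- function(per_contig_assignments, target_phylum_taxid,
                          taxonomy) {
  taxIndex(taxonomy, target_phylum_taxid, "target phylum taxid")
  if (!identical(taxRank(taxonomy, target_phylum_taxid), "phylum"))
    warning("target taxon is not at rank 'phylum' (rank: ",
            taxRank(taxonomy, target_phylum_taxid), ")", call. = FALSE)
  if (is.list(per_contig_assignments))
    per_contig_assignments <- vapply(per_contig_assignments,
                                     function(a) a@taxid, integer(1))
  ok_taxa <- union(taxDescendants(taxonomy, target_phylum_taxid),
                   taxLineage(taxonomy, target_phylum_taxid))
  keep <- is.na(per_contig_assignments) |
    per_contig_assignments %in% ok_taxa
  names(per_contig_assignments)[keep]
}

#' Screen all genes of one assembly
#'
#' Runs [assignByMargin()] and [flagContaminant()] for every gene and
#' aggregates the result into a report.
#'
#' @param hit_tables named list: gene id -> hit table data.frame
#' @param query_species_taxid taxid of the screened species
#' @param taxonomy a [Taxonomy-class]
#' @param margin bit-score margin (default 0.10)
#' @return list with `assignments` (named list of [TaxAssignment-class]),
#'   `table` (data.frame: `gene`, `assigned_taxid`, `assigned_name`,
#'   `flagged`) and `counts` (named integer: assigned, unassigned, flagged)
#' @export
screenAssembly <- function(hit_tables, query_species_taxid, taxonomy,
                           margin = 0.10) {
  if (length(hit_tables) == 0L)
    return(list(assignments = list(),
                table = data.frame(gene = character(0),
                                   assigned_taxid = integer(0),
                                   assigned_name = character(0),
                                   flagged = logical(0)),
                counts = c(assigned = 0L, unassigned = 0L, flagged = 0L)))
  assignments <- list()
  for (g in names(hit_tables)) {
    a <- tryCatch({
      a0 <- assignByMargin(hit_tables[[g]], g, taxonomy, margin)
      flagContaminant(a0, query_species_taxid, taxonomy)
    }, error = function(e)
      stop(sprintf("gene '%s': %s", g, conditionMessage(e)), call. = FALSE))
    assignments[[g]] <- a
  }
  taxids <- vapply(assignments, function(a) a@taxid, integer(1))
  flagged <- vapply(assignments, function(a) a@flagged, logical(1))
  tab <- data.frame(
    gene = names(hit_tables),
    assigned_taxid = unname(taxids),
    assigned_name = ifelse(is.na(taxids), NA_character_,
                           vapply(taxids, function(t)
                             if (is.na(t)) NA_character_
                             else taxName(taxonomy, t), character(1))),
    flagged = unname(flagged), stringsAsFactors = FALSE)
  list(assignments = assignments, table = tab,
       counts = c(assigned = sum(!is.na(taxids)),
                  unassigned = sum(is.na(taxids)),
                  flagged = sum(flagged)))
}
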