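# Central S4 containers.

#' Taxonomy: a rooted tree of taxon identifiers
#'
#' Holds a taxonomy as parallel vectors of taxon id, parent id, rank and name.
#' Exactly one node is its own parent (the root).  Supports parent, lineage
#' and last-common-ancestor queries; see [taxLineage()] and [taxLCA()].
#'
#' @slot taxid integer vector of taxon ids (unique)
#' @slot parent integer vector, parent taxon id of each node
#' @slot rank character vector of rank names
#' @slot name character vector of scientific names
#' @exportClass Taxonomy
setClass("Taxonomy",
         representation(taxid = "integer", parent = "integer",
                        rank = "character", name = "character"))

setValidity("Taxonomy", function(object) {
  n <- length(object@taxid)
  if (length(object@parent) != n || length(object@rank) != n ||
      length(object@name) != n)
    return("taxid, parent, rank and name must have equal length")
  if (n == 0L) return("taxonomy must contain at least the root")
  if (anyDuplicated(object@taxid))
    return(sprintf("duplicate taxid: %s",
                   paste(unique(object@taxid[duplicated(object@taxid)]),
                         collapse = ", ")))
  roots <- object@taxid[object@taxid == object@parent]
  if (length(roots) == 0L) return("no root (no node with taxid == parent)")
  if (length(roots) > 1L)
    return(sprintf("multiple roots: %s", paste(roots, collapse = ", ")))
  orphan <- setdiff(object@parent, object@taxid)
  if (length(orphan) > 0L)
    return(sprintf("orphan parent taxid(s): %s",
                   paste(orphan, collapse = ", ")))
  # cycle check: walking rootward from any node must terminate at the root
  idx <- match(object@parent, object@taxid)
  for (start in seq_len(n)) {
    i <- start; steps <- 0L
    while (object@taxid[i] != object@parent[i]) {
      i <- idx[i]; steps <- steps + 1L
      if (steps > n) return("cycle detected in parent pointers")
    }
  }
  TRUE
})

#' @describeIn Taxonomy number of taxa
#' @param x,object a `Taxonomy`
#' @export
setMethod("length", "Taxonomy", function(x) length(x@taxid))

setMethod("show", "Taxonomy", function(object) {
  cat(sprintf("Taxonomy with %d taxa (root: %d '%s')\n",
              length(object@taxid), taxRoot(object),
              object@name[match(taxRoot(object), object@taxid)]))
  tab <- table(object@rank)
  cat("  ranks:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
})

#' ScoringProfile: a position-specific scoring model for a protein family
#'
#' A fixed-length log-odds model built from at most six core orthologues.
#' Column scores are `log2((count + 1) / (n + 20)) - log2(1/20)` (add-one
#' pseudocounts against a uniform background).  The consensus is the
#' per-column majority residue, ties broken alphabetically, and is by
#' construction the argmax residue of every column.
#'
#' @slot consensus single protein string, one residue per column
#' @slot pssm numeric matrix, 20 rows (standard amino acids, alphabetical)
#'   by `nchar(consensus)` columns
#' @slot trainingIds ids of the sequences the model was trained on
#' @slot scoreThreshold acceptance threshold for window scores; `NA` until
#'   calibrated (see [calibrateDomainThreshold()], [calibrateSearchThreshold()])
#' @exportClass ScoringProfile
setClass("ScoringProfile",
         representation(consensus = "character", pssm = "matrix",
                        trainingIds = "character",
                        scoreThreshold = "numeric"))

setValidity("ScoringProfile", function(object) {
  if (length(object@consensus) != 1L || nchar(object@consensus) == 0L)
    return("consensus must be a single non-empty string")
  L <- nchar(object@consensus)
  if (ncol(object@pssm) != L)
    return("pssm must have one column per consensus position")
  if (nrow(object@pssm) != 20L ||
      !identical(rownames(object@pssm), AA_STANDARD))
    return("pssm rows must be the 20 standard amino acids, alphabetical")
  cons <- strsplit(object@consensus, "")[[1]]
  am <- AA_STANDARD[apply(object@pssm, 2, which.max)]
  if (!identical(am, cons))
    return("each column's argmax residue must equal the consensus residue")
  if (length(object@scoreThreshold) != 1L)
    return("scoreThreshold must be a single number (possibly NA)")
  TRUE
})

#' @describeIn ScoringProfile model length (number of columns)
#' @param x,object a `ScoringProfile`
#' @export
setMethod("length", "ScoringProfile", function(x) nchar(x@consensus))

setMethod("show", "ScoringProfile", function(object) {
  cat(sprintf("ScoringProfile of length %d (trained on %d sequence%s)\n",
              nchar(object@consensus), length(object@trainingIds),
              if (length(object@trainingIds) == 1L) "" else "s"))
  cat("  consensus:",
      if (nchar(object@consensus) > 60)
        paste0(substr(object@consensus, 1, 57), "...") else object@consensus,
      "\n")
  cat("  score threshold:",
      if (is.na(object@scoreThreshold)) "uncalibrated"
      else format(object@scoreThreshold, digits = 4), "\n")
})

#' TaxAssignment: the taxonomic call for one query sequence
#'
#' Result of the margin-based last-common-ancestor rule: self-hits removed,
#' hits within the bit-score margin of the best hit collected, their taxa
#' intersected on the taxonomy.  `taxid` is `NA` when no non-self hit remains
#' (unassigned).  `flagged` is set by [flagContaminant()] when the assignment
#' is off the query species' root lineage; an unassigned query is never
#' flagged.
#'
#' @slot queryId query sequence id
#' @slot taxid assigned taxon id, or `NA_integer_` when unassigned
#' @slot marginUsed the bit-score margin applied, in (0,1)
#' @slot hits data.frame of the contributing hits (margin set)
#' @slot flagged logical contaminant flag
#' @exportClass TaxAssignment
setClass("TaxAssignment",
         representation(queryId = "character", taxid = "integer",
                        marginUsed = "numeric", hits = "data.frame",
                        flagged = "logical"))

setValidity("TaxAssignment", function(object) {
  if (length(object@taxid) != 1L) return("taxid must be length 1")
  if (object@marginUsed <= 0 || object@marginUsed >= 1)
    return("marginUsed must lie in (0, 1)")
  if (object@flagged && is.na(object@taxid))
    return("an unassigned query cannot be flagged")
  TRUE
})

setMethod("show", "TaxAssignment", function(object) {
  cat(sprintf("TaxAssignment '%s': %s (margin %.2f, %d contributing hit%s)%s\n",
              object@queryId,
              if (is.na(object@taxid)) "unassigned" else object@taxid,
              object@marginUsed, nrow(object@hits),
              if (nrow(object@hits) == 1L) "" else "s",
              if (isTRUE(object@flagged)) " [FLAGGED]" else ""))
})

#' PresenceProfile: species-by-family copy counts with species metadata
#'
#' Rows are species, columns gene families, cells non-negative integer copy
#' counts.  Per-species metadata (taxid, assembly completeness, reproduction
#' mode, clade) travels with the matrix.
#'
#' @slot counts integer matrix, species x families, rownames = species ids
#' @slot meta data.frame with one row per species (same order as `counts`),
#'   columns `species_id`, `taxid`, `busco_completeness`, `reproduction_mode`,
#'   `clade`
#' @exportClass PresenceProfile
setClass("PresenceProfile",
         representation(counts = "matrix", meta = "data.frame"))

setValidity("PresenceProfile", function(object) {
  if (any(object@counts < 0)) return("copy counts must be non-negative")
  if (any(object@counts != round(object@counts)))
    return("copy counts must be integers")
  if (nrow(object@meta) != nrow(object@counts))
    return("meta must have one row per species")
  need <- c("species_id", "taxid", "busco_completeness",
            "reproduction_mode", "clade")
  if (!all(need %in% names(object@meta)))
    return(paste("meta must contain columns:", paste(need, collapse = ", ")))
  if (!identical(rownames(object@counts), object@meta$species_id))
    return("rownames(counts) must equal meta$species_id")
  ok <- is.na(object@meta$busco_completeness) |
    (object@meta$busco_completeness >= 0 & object@meta$busco_completeness <= 1)
  if (!all(ok)) return("busco_completeness must lie in [0, 1]")
  TRUE
})

setMethod("show", "PresenceProfile", function(object) {
  cat(sprintf("PresenceProfile: %d species x %d famil%s\n",
              nrow(object@counts), ncol(object@counts),
              if (ncol(object@counts) == 1L) "y" else "ies"))
  pres <- colSums(object@counts >= 1)
  for (j in seq_len(ncol(object@counts)))
    cat(sprintf("  %s: present in %d/%d species\n",
                colnames(object@counts)[j], pres[j], nrow(object@counts)))
})

#' @describeIn PresenceProfile copy-count matrix
#' @param x,object a `PresenceProfile`
#' @export
presenceCounts <- function(x) {
  stopifnot(is(x, "PresenceProfile"))
  x@counts
}

#' @describeIn PresenceProfile species metadata
#' @export
speciesMeta <- function(x) {
  stopifnot(is(x, "PresenceProfile"))
  x@meta
}

#' GeneFamilyTruth: the complete record of a simulated gene-family history
#'
#' Produced by [simulateGeneFamily()] and enriched by [plantGenes()] and
#' [injectContamination()].  Branches are identified by the label of the node
#' each branch leads to.
#'
#' @slot originBranch branch on which the family is gained
#' @slot duplications character vector of branches carrying a duplication
#' @slot losses character vector of branches carrying a loss
#' @slot transfers data.frame with columns `donor`, `recipient` (branch ids)
#' @slot copyNumber named integer vector: copies per species tip
#' @slot genealogy the copy genealogy as an ape `phylo` (tips named
#'   `<species>|<copy>`), or `NULL` when no copy survives
#' @slot plantedLoci data.frame: `species`, `contig`, `start`, `end`,
#'   `strand`, `protein_id` (0-based half-open coordinates)
#' @slot contaminantContigs data.frame: `species`, `contig`, `source_taxid`
#' @exportClass GeneFamilyTruth
setClass("GeneFamilyTruth",
         representation(originBranch = "character",
                        duplications = "character",
                        losses = "character",
                        transfers = "data.frame",
                        copyNumber = "integer",
                        genealogy = "ANY",
                        plantedLoci = "data.frame",
                        contaminantContigs = "data.frame"))

setValidity("GeneFamilyTruth", function(object) {
  if (any(object@copyNumber < 0)) return("copy numbers must be non-negative")
  if (is.null(names(object@copyNumber)))
    return("copyNumber must be named by species")
  if (nrow(object@plantedLoci) > 0) {
    tab <- table(factor(object@plantedLoci$species,
                        levels = names(object@copyNumber)))
    if (!all(as.integer(tab) == as.integer(object@copyNumber)))
      return("planted locus count per species must equal the copy number")
  }
  TRUE
})

setMethod("show", "GeneFamilyTruth", function(object) {
  cat(sprintf(paste0("GeneFamilyTruth: origin on '%s'; %d duplication(s), ",
                     "%d loss(es), %d transfer(s)\n"),
              object@originBranch, length(object@duplications),
              length(object@losses), nrow(object@transfers)))
  cat(sprintf("  %d/%d species carry the family (total %d copies)\n",
              sum(object@copyNumber >= 1), length(object@copyNumber),
              sum(object@copyNumber)))
  if (nrow(object@plantedLoci) > 0)
    cat(sprintf("  %d planted loci\n", nrow(object@plantedLoci)))
  if (nrow(object@contaminantContigs) > 0)
    cat(sprintf("  %d contaminant contigs\n",
                nrow(object@contaminantContigs)))
})

#' @describeIn GeneFamilyTruth per-species copy numbers
#' @param x,object a `GeneFamilyTruth`
#' @export
copyNumber <- function(x) {
  stopifnot(is(x, "GeneFamilyTruth"))
  x@copyNumber
}

#' @describeIn GeneFamilyTruth planted locus table
#' @export
plantedLoci <- function(x) {
  stopifnot(is(x, "GeneFamilyTruth"))
  x@plantedLoci
}

#' @describeIn GeneFamilyTruth contaminant contig table
#' @export
contaminantContigs <- function(x) {
  stopifnot(is(x, "GeneFamilyTruth"))
  x@contaminantContigs
}
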