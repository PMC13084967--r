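# Taxonomy construction and queries: parent, lineage, last common ancestor.

#' Build a Taxonomy from a taxon table
#'
#' @param table data.frame with columns `taxid`, `parent_taxid`, `rank`,
#'   `name` (integer, integer, character, character).  Exactly one row must
#'   have `taxid == parent_taxid`; that row is the root.
#' @return a [Taxonomy-class] object
#' @examples
#' tax <- Taxonomy(data.frame(taxid = c(1L, 2L, 3L),
#'                            parent_taxid = c(1L, 1L, 1L),
#'                            rank = c("root", "phylum", "phylum"),
#'                            name = c("root", "P1", "P2")))
#' taxLineage(tax, 2L)
#' @export
Taxonomy <- function(table) {
  need <- c("taxid", "parent_taxid", "rank", "name")
  if (!all(need %in% names(table)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  new("Taxonomy",
      taxid = as.integer(table$taxid),
      parent = as.integer(table$parent_taxid),
      rank = as.character(table$rank),
      name = as.character(table$name))
}

#' @noRd
taxIndex <- function(tax, taxid, context = "taxid") {
  idx <- match(as.integer(taxid), tax@taxid)
  if (any(is.na(idx)))
    stop(sprintf("unknown %s: %s", context,
                 paste(taxid[is.na(idx)], collapse = ", ")), call. = FALSE)
  idx
}

#' Root taxon of a taxonomy
#' @param tax a [Taxonomy-class]
#' @return the root taxid
#' @export
taxRoot <- function(tax) tax@taxid[tax@taxid == tax@parent]

#' Parent of a taxon
#' @param tax a [Taxonomy-class]
#' @param taxid taxon id(s)
#' @return parent taxid(s); the root is its own parent
#' @export
taxParent <- function(tax, taxid) tax@parent[taxIndex(tax, taxid)]

#' Rank and name lookups
#' @rdname taxParent
#' @export
taxRank <- function(tax, taxid) tax@rank[taxIndex(tax, taxid)]

#' @rdname taxParent
#' @export
taxName <- function(tax, taxid) tax@name[taxIndex(tax, taxid)]

#' Root-ward lineage of a taxon
#'
#' @param tax a [Taxonomy-class]
#' @param taxid a single taxon id
#' @return integer vector of taxids from `taxid` up to and including the
#'   root.  `taxLineage(tax, root)` is the root alone.
#' @export
taxLineage <- function(tax, taxid) {
  i <- taxIndex(tax, taxid)
  pidx <- match(tax@parent, tax@taxid)
  out <- integer(0)
  repeat {
    out <- c(out, tax@taxid[i])
    if (tax@taxid[i] == tax@parent[i]) break
    i <- pidx[i]
  }
  out
}

#' Depth of a taxon (edges from the root; root has depth 0)
#' @inheritParams taxLineage
#' @export
taxDepth <- function(tax, taxid) length(taxLineage(tax, taxid)) - 1L

#' Last common ancestor of a set of taxa
#'
#' The deepest taxonomy node whose subtree contains every input taxon.
#' Commutative and idempotent: `taxLCA(tax, c(x, x)) == x`.
#'
#' @param tax a [Taxonomy-class]
#' @param taxids non-empty vector of taxon ids, all present in `tax`
#' @return a single taxid
#' @export
taxLCA <- function(tax, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) stop("empty taxon set", call. = FALSE)
  taxIndex(tax, taxids)
  cur <- taxids[1]
  for (other in taxids[-1]) {
    a <- cur; b <- other
    da <- taxDepth(tax, a); db <- taxDepth(tax, b)
    while (da > db) { a <- taxParent(tax, a); da <- da - 1L }
    while (db > da) { b <- taxParent(tax, b); db <- db - 1L }
    while (a != b) { a <- taxParent(tax, a); b <- taxParent(tax, b) }
    cur <- a
  }
  cur
}

#' All descendants of a taxon (including itself)
#' @inheritParams taxLineage
#' @return integer vector of taxids in the subtree rooted at `taxid`
#' @export
taxDescendants <- function(tax, taxid) {
  taxIndex(tax, taxid)
  taxid <- as.integer(taxid)
  out <- taxid
  frontier <- taxid
  repeat {
    kids <- tax@taxid[tax@parent %in% frontier & tax@taxid != tax@parent]
    kids <- setdiff(kids, out)
    if (length(kids) == 0L) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Is taxon `a` on the root lineage of taxon `b` (or equal, or below it)?
#'
#' "On the lineage" in the contaminant-screen sense: ancestors of `b`, `b`
#' itself, and descendants of `b` all count as on-lineage.
#' @param tax a [Taxonomy-class]
#' @param a,b taxon ids
#' @export
taxOnLineage <- function(tax, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  a %in% taxLineage(tax, b) || b %in% taxLineage(tax, a)
}
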