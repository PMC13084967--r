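# Newick reading/writing on ape phylo objects, with validation the parser
# itself does not enforce (duplicate leaves, balance, defaulted lengths).

#' Read a Newick tree
#'
#' Wraps `ape::read.tree` with stricter validation: unbalanced parentheses
#' and duplicate leaf labels are errors.  Trees without branch lengths get
#' every length defaulted to 1.0 and carry the attribute
#' `lengths_defaulted = TRUE`.  Internal node labels are kept as plain
#' strings (support values or names), never interpreted numerically.
#'
#' @param text a Newick string, or `NULL` to read from `path`
#' @param path optional path to a Newick file
#' @return an ape `phylo`
#' @seealso [writeNewick()]
#' @export
readNewick <- function(text = NULL, path = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("supply 'text' or 'path'", call. = FALSE)
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (open != close)
    stop(sprintf("unbalanced parentheses: %d '(' vs %d ')'", open, close),
         call. = FALSE)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error near offset 1: ", substr(text, 1, 40),
         call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L)
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1.0, nrow(tree$edge))
    attr(tree, "lengths_defaulted") <- TRUE
  }
  tree
}

#' Write a tree as Newick text
#' @param tree an ape `phylo`
#' @param path optional path; when given the text is also written to file
#' @return the Newick string, invisibly when `path` is given
#' @export
writeNewick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
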