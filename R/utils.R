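# Internal helpers: seed handling, validation, small shared utilities.

#' Evaluate an expression under a fixed RNG seed, restoring RNG state afterwards
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Documented stream-splitting: every pipeline stage draws from its own stream
# derived from the master seed, so adding draws to one stage never perturbs
# another.  Kept below 2^31 - 1 (R integers are 32-bit).
#' @noRd
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  as.integer((as.numeric(seed) * 48271 + 7919 * stream) %% 2147483647)
}

#' @noRd
assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  invisible(x)
}

#' @noRd
randomProtein <- function(n, composition = NULL) {
  if (is.null(composition))
    composition <- rep(1 / 20, 20)
  paste(sample(AA_STANDARD, n, replace = TRUE, prob = composition),
        collapse = "")
}

#' @noRd
aaComposition <- function(seqs) {
  tab <- table(factor(unlist(strsplit(seqs, "")), levels = AA_STANDARD))
  n <- sum(tab)
  if (n == 0) rep(1 / 20, 20) else as.numeric(tab) / n
}

# Branch identifiers: every branch of a rooted tree is named after its child
# node (tip label for terminal branches, internal node label otherwise).
# Trees produced by simulateSpeciesTree() always carry internal node labels.
#' @noRd
branchIds <- function(tree) {
  labs <- c(tree$tip.label, tree$node.label)
  labs[tree$edge[, 2]]
}

#' @noRd
nodeLabels <- function(tree) c(tree$tip.label, tree$node.label)

#' @noRd
labelToNode <- function(tree, label) {
  idx <- match(label, nodeLabels(tree))
  if (any(is.na(idx)))
    stop("unknown node label(s): ", paste(label[is.na(idx)], collapse = ", "),
         call. = FALSE)
  idx
}

# children of each node as an adjacency list (rooted tree)
#' @noRd
childList <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

# leaves under each node, as a list of tip-index vectors
#' @noRd
cladeTips <- function(tree) {
  ntip <- ape::Ntip(tree)
  n <- ntip + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(ntip)) out[[i]] <- i
  ord <- rev(ape::postorder(tree))  # not used; keep postorder below
  edges <- tree$edge[ape::postorder(tree), , drop = FALSE]
  for (i in seq_len(nrow(edges)))
    out[[edges[i, 1]]] <- c(out[[edges[i, 1]]], out[[edges[i, 2]]])
  out
}

#' @noRd
rootNode <- function(tree) ape::Ntip(tree) + 1L
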