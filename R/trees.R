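# Comparative tree machinery: alignment trimming, supermatrix assembly,
# neighbor-joining, outgroup rooting, majority consensus, monophyly and
# origin counting, Dollo gain/loss histories, duplication/loss
# reconciliation and tanglegram untangling.

#' Remove gap-rich alignment columns
#'
#' A column is removed when strictly more than `max_gap_fraction` of its
#' characters are gaps; a column with exactly the threshold fraction is
#' retained.  Idempotent.
#'
#' @param alignment named character vector of equal-length gapped rows
#' @param max_gap_fraction threshold (default 0.50)
#' @return the trimmed alignment (possibly zero-width, with a warning)
#' @export
trimAlignment <- function(alignment, max_gap_fraction = 0.50) {
  assertScalarNumber(max_gap_fraction, "max_gap_fraction", 0, 1)
  if (length(unique(nchar(alignment))) != 1L)
    stop("alignment rows must have equal length", call. = FALSE)
  m <- do.call(rbind, strsplit(alignment, ""))
  gapfrac <- colMeans(m == "-")
  keep <- gapfrac <= max_gap_fraction
  if (!any(keep))
    warning("all columns removed by gap trimming", call. = FALSE)
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  setNames(out, names(alignment))
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes present in fewer than `min_occupancy` of the species are
#' discarded (a gene present in exactly 75% of species survives a 0.75
#' threshold).  Species missing a retained gene are padded with gaps.
#'
#' @param alignments named list of alignments (each a named character
#'   vector of equal-length rows; row names are species ids)
#' @param species character vector: the full species set
#' @param min_occupancy retention threshold (default 0.75)
#' @return list with `alignment` (named character vector over `species`)
#'   and `partitions` (data.frame `gene`, `start`, `end`, 1-based
#'   inclusive column ranges)
#' @export
buildSupermatrix <- function(alignments, species, min_occupancy = 0.75) {
  assertScalarNumber(min_occupancy, "min_occupancy", 0, 1)
  occ <- vapply(alignments, function(a)
    mean(species %in% names(a)), numeric(1))
  keep <- names(alignments)[occ >= min_occupancy]
  if (length(keep) == 0L)
    stop("no gene meets the occupancy threshold", call. = FALSE)
  rows <- setNames(rep("", length(species)), species)
  parts <- list()
  pos <- 0L
  for (g in keep) {
    a <- alignments[[g]]
    w <- unique(nchar(a))
    if (length(w) != 1L)
      stop("gene '", g, "': rows of unequal length", call. = FALSE)
    for (sp in species) {
      rows[sp] <- paste0(rows[sp],
                         if (sp %in% names(a)) a[[sp]] else strrep("-", w))
    }
    parts[[length(parts) + 1L]] <- data.frame(
      gene = g, start = pos + 1L, end = pos + w, stringsAsFactors = FALSE)
    pos <- pos + w
  }
  list(alignment = rows, partitions = do.call(rbind, parts))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via ape); on additive distance matrices the
#' generating topology is recovered exactly.  With fewer than three taxa a
#' trivial tree is returned.
#'
#' @param d symmetric numeric matrix with zero diagonal (dimnames = taxa)
#' @return an unrooted ape `phylo`
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d)) || any(diag(d) != 0) || any(d < 0))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal",
         call. = FALSE)
  n <- nrow(d)
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (n == 1L) {
    tr <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = labs,
               edge.length = 0, Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               tip.label = labs, edge.length = rep(d[1, 2] / 2, 2),
               Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  ape::nj(d)
}

#' Root a tree on an outgroup
#'
#' The root is placed at the midpoint of the branch separating the outgroup
#' from the ingroup.  The outgroup must form one side of a split of the
#' unrooted tree; otherwise the error names the leaves that violate it.
#'
#' @param tree an ape `phylo` (rooted trees are unrooted first)
#' @param outgroup_labels tip labels of the outgroup
#' @return a rooted ape `phylo`
#' @export
rootByOutgroup <- function(tree, outgroup_labels) {
  missing <- setdiff(outgroup_labels, tree$tip.label)
  if (length(missing) > 0)
    stop("outgroup labels missing from tree: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(outgroup_labels) >= ape::Ntip(tree))
    stop("outgroup cannot contain all leaves", call. = FALSE)
  ingroup <- setdiff(tree$tip.label, outgroup_labels)
  work <- if (ape::is.rooted(tree) && ape::Ntip(tree) > 2)
    ape::unroot(tree) else tree
  # root provisionally at an ingroup tip, then ask for the outgroup clade
  prov <- ape::root(work, outgroup = ingroup[1], resolve.root = TRUE)
  og_tips <- match(outgroup_labels, prov$tip.label)
  mrca <- if (length(og_tips) == 1L) og_tips else
    ape::getMRCA(prov, og_tips)
  below <- cladeTips(prov)[[mrca]]
  if (!setequal(below, og_tips)) {
    extra <- setdiff(prov$tip.label[below], outgroup_labels)
    stop("outgroup is not a split of the tree; intruding leaves: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  edge_row <- which(prov$edge[, 2] == mrca)
  len <- prov$edge.length[edge_row]
  phytools::reroot(prov, mrca, position = len / 2)
}

#' Majority-rule consensus of trees
#'
#' Retains exactly the splits present in strictly more than half of the
#' input trees (mutually compatible by construction); conflicting 50/50
#' splits collapse to polytomies.
#'
#' @param trees list (or `multiPhylo`) of at least two trees with identical
#'   leaf sets
#' @return an ape `phylo` (no branch lengths)
#' @export
majorityConsensus <- function(trees) {
  if (length(trees) < 2L)
    stop("need at least two trees", call. = FALSE)
  sets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(sets, identical, logical(1), sets[[1]])))
    stop("trees have differing leaf sets", call. = FALSE)
  ape::consensus(trees, p = 0.5, rooted = FALSE)
}

#' Is a label set monophyletic in a rooted tree?
#'
#' `TRUE` iff some clade's leaf set equals `labels` exactly.  Singletons
#' are always monophyletic.
#'
#' @param tree a rooted ape `phylo`
#' @param labels tip labels (all must be present in the tree)
#' @return logical
#' @export
isMonophyleticGroup <- function(tree, labels) {
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing) > 0)
    stop("labels missing from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tips <- match(labels, tree$tip.label)
  if (length(tips) == 1L) return(TRUE)
  mrca <- ape::getMRCA(tree, tips)
  setequal(cladeTips(tree)[[mrca]], tips)
}

#' Count independent origins of a group on a gene tree
#'
#' The number of maximal clades whose leaves all belong to `group`; equals
#' 1 iff the group is monophyletic, and 0 when the group is absent.
#'
#' @param tree a rooted ape `phylo`
#' @param groups named character vector: leaf label -> group label
#' @param group the group to count
#' @return integer count
#' @export
countGroupOrigins <- function(tree, groups, group) {
  inGroup <- function(tip) {
    g <- groups[tree$tip.label[tip]]
    !is.na(g) && g == group
  }
  ntip <- ape::Ntip(tree)
  if (!any(vapply(seq_len(ntip), inGroup, logical(1)))) return(0L)
  clades <- cladeTips(tree)
  n <- ntip + tree$Nnode
  pure <- vapply(seq_len(n), function(nd)
    all(vapply(clades[[nd]], inGroup, logical(1))), logical(1))
  parent <- integer(n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- rootNode(tree)
  sum(vapply(seq_len(n), function(nd)
    pure[nd] && (nd == root || !pure[parent[nd]]), logical(1)))
}

#' Dollo gain/loss history of a presence pattern
#'
#' Under Dollo parsimony with a single gain, the gain is placed on the
#' branch above the last common ancestor of all present species and the
#' losses are the maximal subtrees below the gain containing no present
#' species; this loss set is minimal given one gain.
#'
#' @param tree a rooted ape `phylo` with labelled internal nodes
#' @param presence named logical (or 0/1) vector over the tip labels
#' @return list with `gain_branch` (node label of the gain clade, `NA` if
#'   the family is absent everywhere), `loss_branches` (node labels) and
#'   `n_losses`
#' @export
dolloHistory <- function(tree, presence) {
  labs <- nodeLabels(tree)
  if (is.null(tree$node.label))
    labs <- c(tree$tip.label, paste0("node", seq_len(tree$Nnode)))
  pres <- as.logical(presence[tree$tip.label])
  pres[is.na(pres)] <- FALSE
  if (!any(pres))
    return(list(gain_branch = NA_character_,
                loss_branches = character(0), n_losses = 0L))
  tips <- which(pres)
  gain <- if (length(tips) == 1L) tips else ape::getMRCA(tree, tips)
  clades <- cladeTips(tree)
  inGain <- downNodes(tree, gain)
  parent <- integer(length(labs))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  hasPres <- vapply(seq_along(labs), function(nd)
    any(pres[clades[[nd]]]), logical(1))
  lossNodes <- Filter(function(nd)
    nd != gain && !hasPres[nd] && hasPres[parent[nd]],
    setdiff(inGain, gain))
  list(gain_branch = labs[gain],
       loss_branches = labs[unlist(lossNodes)],
       n_losses = length(lossNodes))
}

#' Duplication/loss reconciliation of a gene tree with a species tree
#'
#' Standard last-common-ancestor reconciliation: each gene-tree node is
#' mapped to the species-tree LCA of its descendant species; a node is a
#' duplication iff its image equals the image of at least one child;
#' losses are counted along the mapping gaps.  The returned counts are the
#' parsimony minimum for LCA reconciliation.
#'
#' @param gene_tree rooted ape `phylo`
#' @param species_tree rooted ape `phylo`
#' @param map named character vector: gene leaf label -> species leaf label
#' @return list with `duplications`, `losses` (integer counts) and
#'   `mapping` (named character: gene node label -> species node label)
#' @export
reconcileTrees <- function(gene_tree, species_tree, map) {
  gt <- gene_tree; st <- species_tree
  unmapped <- setdiff(gt$tip.label, names(map))
  if (length(unmapped) > 0)
    stop("unmapped gene leaves: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(map[gt$tip.label], st$tip.label)
  if (length(bad) > 0)
    stop("mapped species not in species tree: ",
         paste(bad, collapse = ", "), call. = FALSE)
  ntipS <- ape::Ntip(st)
  nS <- ntipS + st$Nnode
  parentS <- integer(nS); parentS[st$edge[, 2]] <- st$edge[, 1]
  rootS <- rootNode(st)
  depthS <- integer(nS)
  # breadth-first depths
  queue <- rootS
  while (length(queue) > 0) {
    nd <- queue[1]; queue <- queue[-1]
    kids <- st$edge[st$edge[, 1] == nd, 2]
    depthS[kids] <- depthS[nd] + 1L
    queue <- c(queue, kids)
  }
  lcaS <- function(a, b) {
    while (depthS[a] > depthS[b]) a <- parentS[a]
    while (depthS[b] > depthS[a]) b <- parentS[b]
    while (a != b) { a <- parentS[a]; b <- parentS[b] }
    a
  }
  ntipG <- ape::Ntip(gt)
  nG <- ntipG + gt$Nnode
  M <- integer(nG)
  for (i in seq_len(ntipG))
    M[i] <- match(map[[gt$tip.label[i]]], st$tip.label)
  kidsG <- childList(gt)
  ordG <- rev(unique(gt$edge[ape::postorder(gt), 1]))
  for (nd in unique(gt$edge[ape::postorder(gt), 1])) {
    imgs <- M[kidsG[[nd]]]
    m <- imgs[1]
    for (x in imgs[-1]) m <- lcaS(m, x)
    M[nd] <- m
  }
  isDup <- vapply(seq_len(nG), function(nd) {
    if (nd <= ntipG) return(FALSE)
    any(M[kidsG[[nd]]] == M[nd])
  }, logical(1))
  losses <- 0L
  for (r in seq_len(nrow(gt$edge))) {
    u <- gt$edge[r, 1]; v <- gt$edge[r, 2]
    pathlen <- depthS[M[v]] - depthS[M[u]]
    losses <- losses + if (isDup[u]) pathlen else max(0L, pathlen - 1L)
  }
  labsG <- nodeLabels(gt)
  if (is.null(gt$node.label))
    labsG <- c(gt$tip.label, paste0("g", seq_len(gt$Nnode)))
  labsS <- nodeLabels(st)
  if (is.null(st$node.label))
    labsS <- c(st$tip.label, paste0("s", seq_len(st$Nnode)))
  list(duplications = sum(isDup), losses = losses,
       mapping = setNames(labsS[M], labsG))
}

#' Tanglegram between two trees
#'
#' Pairs leaves of the two trees by the given links, then unscrambles both
#' trees by greedy subtree rotation (repeated sweeps over all internal
#' nodes; single and pairwise flips) until no rotation reduces the number
#' of link crossings.
#'
#' @param tree1,tree2 rooted ape `phylo` objects
#' @param links data.frame with columns `left` (tip of `tree1`) and
#'   `right` (tip of `tree2`)
#' @return list with `links`, `initial_crossings` (crossings of the input
#'   leaf orders), `crossings` (after untangling), `order1`, `order2`
#'   (tip label orders after untangling)
#' @export
tanglegram <- function(tree1, tree2, links) {
  bad1 <- setdiff(links$left, tree1$tip.label)
  bad2 <- setdiff(links$right, tree2$tip.label)
  if (length(bad1) + length(bad2) > 0)
    stop("links reference missing leaves: ",
         paste(c(bad1, bad2), collapse = ", "), call. = FALSE)
  internals <- function(tree)
    (ape::Ntip(tree) + 1L):(ape::Ntip(tree) + tree$Nnode)
  tipOrder <- function(tree, flip) {
    kids <- childList(tree)
    out <- integer(0)
    rec <- function(nd) {
      if (nd <= ape::Ntip(tree)) { out <<- c(out, nd); return(invisible()) }
      ch <- kids[[nd]]
      if (flip[nd - ape::Ntip(tree)]) ch <- rev(ch)
      for (k in ch) rec(k)
    }
    rec(rootNode(tree))
    tree$tip.label[out]
  }
  crossings <- function(o1, o2) {
    a <- match(links$left, o1)
    b <- match(links$right, o2)
    n <- length(a); cr <- 0L
    if (n < 2) return(0L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if ((a[i] - a[j]) * (b[i] - b[j]) < 0) cr <- cr + 1L
    cr
  }
  f1 <- rep(FALSE, tree1$Nnode); f2 <- rep(FALSE, tree2$Nnode)
  cur <- crossings(tipOrder(tree1, f1), tipOrder(tree2, f2))
  initial <- cur
  repeat {
    improved <- FALSE
    for (side in 1:2) {
      nn <- if (side == 1) tree1$Nnode else tree2$Nnode
      for (i in seq_len(nn)) {
        g1 <- f1; g2 <- f2
        if (side == 1) g1[i] <- !g1[i] else g2[i] <- !g2[i]
        cand <- crossings(tipOrder(tree1, g1), tipOrder(tree2, g2))
        if (cand < cur) {
          f1 <- g1; f2 <- g2; cur <- cand; improved <- TRUE
        }
      }
    }
    if (!improved && cur > 0) {
      # pairwise flips across the two trees escape simple local minima
      for (i in seq_len(tree1$Nnode)) {
        for (j in seq_len(tree2$Nnode)) {
          g1 <- f1; g2 <- f2
          g1[i] <- !g1[i]; g2[j] <- !g2[j]
          cand <- crossings(tipOrder(tree1, g1), tipOrder(tree2, g2))
          if (cand < cur) {
            f1 <- g1; f2 <- g2; cur <- cand; improved <- TRUE
          }
        }
        if (improved) break
      }
    }
    if (!improved) break
  }
  list(links = links, initial_crossings = initial, crossings = cur,
       order1 = tipOrder(tree1, f1), order2 = tipOrder(tree2, f2))
}
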