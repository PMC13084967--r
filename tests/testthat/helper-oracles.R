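# Independent oracles and fixture builders used across the suite.
# Every oracle here is written from the definition, by a different route
# than the package implementation it checks.

# --- taxonomy fixtures -----------------------------------------------

tinyTax <- function() {
  Taxonomy(data.frame(
    taxid        = c(1L, 2L, 3L, 10L, 11L, 20L, 21L, 22L, 30L),
    parent_taxid = c(1L, 1L, 1L, 2L, 2L, 10L, 10L, 11L, 3L),
    rank = c("root", "domain", "domain", "phylum", "phylum",
             "species", "species", "species", "species"),
    name = c("root", "Euk", "Bac", "P1", "P2", "a", "b", "c", "d")))
}

# random taxonomy: node k's parent drawn among nodes < k
randomTaxonomy <- function(n, seed) {
  withr::with_seed(seed, {
    parent <- c(1L, vapply(2:n, function(k)
      sample.int(k - 1L, 1L), integer(1)))
    Taxonomy(data.frame(taxid = seq_len(n), parent_taxid = parent,
                        rank = "clade",
                        name = paste0("t", seq_len(n))))
  })
}

# lineage by naive repeated parent lookup (root-ward, inclusive)
oracleLineage <- function(tax, id) {
  out <- id
  repeat {
    p <- tax@parent[match(out[length(out)], tax@taxid)]
    if (p == out[length(out)]) break
    out <- c(out, p)
  }
  out
}

# LCA as the first element of the root-ward lineage of the first taxon
# that appears in every other taxon's lineage
oracleLCA <- function(tax, ids) {
  lins <- lapply(ids, function(i) oracleLineage(tax, i))
  for (cand in lins[[1]])
    if (all(vapply(lins, function(l) cand %in% l, logical(1))))
      return(cand)
  stop("no common ancestor (broken taxonomy)")
}

# brute-force margin rule: sort, threshold, intersect lineages
oracleAssign <- function(hits, self_id, tax, margin) {
  h <- hits[hits$subject_id != self_id, , drop = FALSE]
  if (nrow(h) == 0L) return(NA_integer_)
  scores <- tapply(h$bitscore, h$subject_id, max)
  best <- max(scores)
  taxa <- unique(h$subject_taxid[
    vapply(h$subject_id, function(s) scores[[s]] >= (1 - margin) * best,
           logical(1))])
  oracleLCA(tax, taxa)
}

oracleFlag <- function(assigned, species, tax) {
  if (is.na(assigned)) return(FALSE)
  !(assigned %in% oracleLineage(tax, species)) &&
    !(species %in% oracleLineage(tax, assigned))
}

randomHitTable <- function(tax, n_hits, self_id = "q") {
  leaves <- setdiff(tax@taxid, tax@parent[tax@taxid != tax@parent])
  taxa <- sample(tax@taxid, n_hits, replace = TRUE)
  data.frame(query_id = self_id,
             subject_id = c(self_id,
                            paste0("s", seq_len(n_hits))),
             subject_taxid = c(sample(leaves, 1), taxa),
             bitscore = c(500, round(runif(n_hits, 10, 400), 1)),
             evalue = rep(1e-10, n_hits + 1L),
             stringsAsFactors = FALSE)
}

# --- exhaustive global alignment -------------------------------------

# enumerate every global alignment of a and b; affine gaps with the
# package convention: a gap of length L costs open + (L-1)*extend
enumAlignScore <- function(a, b, sm, open, extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, acc, last) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, acc); return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1L, j + 1L, acc + sm[ca[i], cb[j]], "m")
    if (i <= length(ca))
      rec(i + 1L, j, acc - if (last == "a") extend else open, "a")
    if (j <= length(cb))
      rec(i, j + 1L, acc - if (last == "b") extend else open, "b")
  }
  rec(1L, 1L, 0, "m")
  best
}

# --- trees ------------------------------------------------------------

randomRootedTree <- function(n, seed) {
  withr::with_seed(seed, {
    t <- ape::rtree(n, rooted = TRUE)
    t$node.label <- paste0("n", seq_len(t$Nnode))
    t
  })
}

# tips below each node, computed by following edges recursively
# (independent of the package's cladeTips)
oracleCladeTips <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  if (length(kids) == 0L) return(node)
  unlist(lapply(kids, function(k) oracleCladeTips(tree, k)))
}

# brute-force origin count: scan every node, test purity and maximality
oracleOrigins <- function(tree, groups, group) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  isIn <- function(tipset)
    all(groups[tree$tip.label[tipset]] == group, na.rm = FALSE)
  pure <- vapply(seq_len(nn), function(nd) {
    g <- groups[tree$tip.label[oracleCladeTips(tree, nd)]]
    all(!is.na(g) & g == group)
  }, logical(1))
  count <- 0L
  for (nd in seq_len(nn)) {
    if (!pure[nd]) next
    par <- tree$edge[tree$edge[, 2] == nd, 1]
    if (length(par) == 0L || !pure[par]) count <- count + 1L
  }
  count
}

# brute-force Dollo: gain fixed at the LCA of present tips, losses found
# by trying all subsets of descendant nodes in increasing size
oracleDollo <- function(tree, presence) {
  pres <- which(as.logical(presence[tree$tip.label]))
  if (length(pres) == 0L) return(list(gain = NA, n_losses = 0L))
  gain <- if (length(pres) == 1L) pres else ape::getMRCA(tree, pres)
  below <- setdiff(unlist(lapply(
    tree$edge[tree$edge[, 1] == gain, 2],
    function(k) oracleSubtreeNodes(tree, k))), integer(0))
  gainTips <- oracleCladeTips(tree, gain)
  target <- sort(pres)
  for (k in 0:length(below)) {
    for (S in combnList(below, k)) {
      lost <- unique(unlist(lapply(S, function(s)
        oracleCladeTips(tree, s))))
      if (setequal(setdiff(gainTips, lost), target) &&
          !anyNested(tree, S))
        return(list(gain = gain, n_losses = k))
    }
  }
  stop("no Dollo explanation found")
}

oracleSubtreeNodes <- function(tree, node) {
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  c(node, unlist(lapply(kids, function(k) oracleSubtreeNodes(tree, k))))
}

combnList <- function(x, k) {
  if (k == 0L) return(list(integer(0)))
  if (k > length(x)) return(list())
  asplit(utils::combn(x, k), 2)
}

anyNested <- function(tree, S) {
  if (length(S) < 2L) return(FALSE)
  for (i in seq_along(S)) for (j in seq_along(S)) {
    if (i != j && S[j] %in% oracleSubtreeNodes(tree, S[i])) return(TRUE)
  }
  FALSE
}

# --- reconciliation oracle -------------------------------------------

# exhaustive reconciliation: enumerate all ancestrally consistent
# mappings of gene internal nodes to species nodes (each at or above the
# LCA image), count duplications and losses per the general definition,
# and return the minima.
oracleReconcile <- function(gt, st, map) {
  ntipS <- ape::Ntip(st)
  parentS <- integer(ntipS + st$Nnode)
  parentS[st$edge[, 2]] <- st$edge[, 1]
  rootS <- ntipS + 1L
  depthS <- function(nd) {
    d <- 0L
    while (nd != rootS) { nd <- parentS[nd]; d <- d + 1L }
    d
  }
  ancestors <- function(nd) {
    out <- nd
    while (nd != rootS) { nd <- parentS[nd]; out <- c(out, nd) }
    out
  }
  lcaS <- function(a, b) intersect(ancestors(a), ancestors(b))[1]
  childOfContaining <- function(anc, nd) {
    # which child subtree of anc contains nd (nd strictly below anc)
    while (parentS[nd] != anc) nd <- parentS[nd]
    nd
  }
  ntipG <- ape::Ntip(gt)
  kidsG <- lapply(seq_len(ntipG + gt$Nnode), function(nd)
    gt$edge[gt$edge[, 1] == nd, 2])
  # postorder internal nodes
  po <- integer(0)
  rec <- function(nd) {
    for (k in kidsG[[nd]]) if (k > ntipG) rec(k)
    po <<- c(po, nd)
  }
  rec(ntipG + 1L)
  Mtip <- integer(ntipG)
  for (i in seq_len(ntipG)) Mtip[i] <- match(map[[gt$tip.label[i]]],
                                             st$tip.label)
  # LCA images (to restrict the search space to valid candidates)
  Mlca <- integer(ntipG + gt$Nnode)
  Mlca[seq_len(ntipG)] <- Mtip
  for (nd in po) {
    imgs <- Mlca[kidsG[[nd]]]
    m <- imgs[1]
    for (x in imgs[-1]) m <- lcaS(m, x)
    Mlca[nd] <- m
  }
  cand <- lapply(po, function(nd) ancestors(Mlca[nd]))
  best_d <- Inf; best_l <- Inf
  evalMap <- function(M) {
    # ancestral consistency: child's image at or below parent's image
    for (nd in po) for (k in kidsG[[nd]])
      if (!(M[nd] %in% ancestors(M[k]))) return(NULL)
    dups <- 0L; losses <- 0L
    for (nd in po) {
      ch <- kidsG[[nd]]
      sep <- FALSE
      if (M[ch[1]] != M[nd] && M[ch[2]] != M[nd]) {
        c1 <- childOfContaining(M[nd], M[ch[1]])
        c2 <- childOfContaining(M[nd], M[ch[2]])
        sep <- c1 != c2
      }
      isdup <- !sep
      dups <- dups + isdup
      for (k in ch) {
        gap <- depthS(M[k]) - depthS(M[nd])
        losses <- losses + if (isdup) gap else max(0L, gap - 1L)
      }
    }
    c(dups, losses)
  }
  M <- c(Mtip, integer(gt$Nnode))
  assignRec <- function(pos) {
    if (pos > length(po)) {
      r <- evalMap(M)
      if (!is.null(r)) {
        best_d <<- min(best_d, r[1]); best_l <<- min(best_l, r[2])
      }
      return(invisible())
    }
    for (v in cand[[pos]]) {
      M[po[pos]] <<- v
      assignRec(pos + 1L)
    }
  }
  assignRec(1L)
  list(duplications = best_d, losses = best_l)
}

# --- tanglegram oracle ------------------------------------------------

# exact minimum crossings over all rotation combinations of both trees
oracleMinCrossings <- function(t1, t2, links) {
  orders <- function(tree) {
    ntip <- ape::Ntip(tree)
    kids <- lapply(seq_len(ntip + tree$Nnode), function(nd)
      tree$edge[tree$edge[, 1] == nd, 2])
    flips <- expand.grid(rep(list(c(FALSE, TRUE)), tree$Nnode))
    lapply(seq_len(nrow(flips)), function(r) {
      fl <- unlist(flips[r, ])
      out <- integer(0)
      rec <- function(nd) {
        if (nd <= ntip) { out <<- c(out, nd); return(invisible()) }
        ch <- kids[[nd]]
        if (fl[nd - ntip]) ch <- rev(ch)
        for (k in ch) rec(k)
      }
      rec(ntip + 1L)
      tree$tip.label[out]
    })
  }
  cross <- function(o1, o2) {
    a <- match(links$left, o1); b <- match(links$right, o2)
    s <- 0L
    n <- length(a)
    if (n < 2) return(0L)
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if ((a[i] - a[j]) * (b[i] - b[j]) < 0) s <- s + 1L
    s
  }
  o1s <- orders(t1); o2s <- orders(t2)
  best <- Inf
  for (o1 in o1s) for (o2 in o2s) best <- min(best, cross(o1, o2))
  best
}

# --- misc -------------------------------------------------------------

# a fixed, valid protein for search fixtures (starts with M)
fixtureProtein <- function(len = 220L, seed = 99L) {
  withr::with_seed(seed, paste0(
    "M", paste(sample(ghprospect:::AA_STANDARD, len - 1L, replace = TRUE),
               collapse = "")))
}

# --- recoverable Dollo scenarios -------------------------------------

# sample k loss branches below `origin` such that the planted history is
# the unique minimal single-gain explanation: losses pairwise disjoint,
# every loss's parent keeps a surviving tip, and both children of the
# origin keep surviving tips (so the gain node equals the LCA of the
# present species).
sampleRecoverableLosses <- function(tree, origin, k) {
  labs <- c(tree$tip.label, tree$node.label)
  below <- setdiff(oracleSubtreeNodes(tree, origin), origin)
  tipsUnder <- function(nd) oracleCladeTips(tree, nd)
  originTips <- tipsUnder(origin)
  parentOf <- function(nd) tree$edge[tree$edge[, 2] == nd, 1]
  kidsOf <- function(nd) tree$edge[tree$edge[, 1] == nd, 2]
  for (attempt in 1:200) {
    S <- sample(below, min(k, length(below)))
    if (anyNested(tree, S)) next
    lost <- unique(unlist(lapply(S, tipsUnder)))
    present <- setdiff(originTips, lost)
    if (length(present) == 0) next
    ok <- TRUE
    for (v in S)
      if (length(intersect(tipsUnder(parentOf(v)), present)) == 0)
        ok <- FALSE
    for (ch in kidsOf(origin))
      if (length(intersect(tipsUnder(ch), present)) == 0) ok <- FALSE
    if (ok) return(list(losses = S, present = present))
  }
  NULL
}
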