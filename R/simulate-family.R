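# Gene-family history simulation: gain, duplication, loss and horizontal
# transfer replayed down a species tree, producing per-tip copy numbers and
# the exact copy genealogy used for sequence evolution.
#
# Branches are identified by the label of the node they lead to; the origin
# "root" means the family is present in the ancestral species at the root.

#' Simulate a gene-family history on a species tree
#'
#' Copies evolve down the species tree by a per-copy birth-death process
#' (duplication rate and loss rate per unit branch length; Gillespie
#' simulation with exponential waiting times).  Deterministic `forced_events`
#' are applied at the midpoint of their branch: a forced loss removes all
#' copies on the branch, a forced duplication duplicates one copy, a forced
#' transfer moves a copy from a donor branch into a recipient branch
#' (donor and recipient must lie in disjoint subtrees).  With all rates zero
#' and origin at the root, every tip ends up with exactly one copy.
#'
#' @param species_tree rooted binary ape `phylo` with labelled internal
#'   nodes (see [simulateSpeciesTree()])
#' @param duplication_rate,loss_rate per-copy, per-branch-length event rates
#'   (>= 0)
#' @param origin_branch `"root"` (family present at the root) or the branch
#'   id (node label) on which the family is gained
#' @param forced_events `NULL` or a data.frame with columns `type`
#'   (`"duplication"`, `"loss"`, `"transfer"`), `branch` (branch id), and
#'   for transfers `to` (recipient branch id)
#' @param seed RNG seed
#' @return a [GeneFamilyTruth-class]; its `genealogy` slot holds the copy
#'   genealogy as a list with `edges` (data.frame `parent`, `child`,
#'   `length`), `root` (origin node id) and `tips` (data.frame `node`,
#'   `species`, `label` with labels `<species>|<copy>`), or `NULL` when no
#'   copy survives
#' @export
simulateGeneFamily <- function(species_tree, duplication_rate = 0,
                               loss_rate = 0, origin_branch = "root",
                               forced_events = NULL, seed = 1L) {
  assertScalarNumber(duplication_rate, "duplication_rate", 0)
  assertScalarNumber(loss_rate, "loss_rate", 0)
  labs <- nodeLabels(species_tree)
  rootLab <- labs[rootNode(species_tree)]
  if (!identical(origin_branch, "root") &&
      !identical(origin_branch, rootLab) && !(origin_branch %in% labs))
    stop("origin_branch references unknown branch: ", origin_branch,
         call. = FALSE)
  fe <- validateForcedEvents(forced_events, labs, rootLab)

  kids <- childList(species_tree)
  edgeLen <- numeric(length(labs))
  edgeLen[species_tree$edge[, 2]] <- species_tree$edge.length
  ntip <- ape::Ntip(species_tree)

  env <- new.env()
  env$nextNode <- 1L
  env$edges <- list()
  env$tips <- list()
  env$dups <- character(0)
  env$losses <- character(0)
  env$transfers <- list()
  env$pendingTransfers <- list()   # recipient branch id -> genealogy nodes
  newNode <- function() {
    id <- env$nextNode; env$nextNode <- id + 1L; id
  }
  addEdge <- function(parent, child, len)
    env$edges[[length(env$edges) + 1L]] <-
      data.frame(parent = parent, child = child, length = len)

  d <- duplication_rate; l <- loss_rate
  # simulate birth-death dynamics on one branch segment of given duration;
  # copies are rows of a list with fields pnode, plen
  simSegment <- function(copies, dur, branchId) {
    t <- 0
    repeat {
      n <- length(copies)
      rate <- (d + l) * n
      if (rate == 0) {
        copies <- lapply(copies, function(cp) {
          cp$plen <- cp$plen + (dur - t); cp
        })
        break
      }
      dt <- rexp(1, rate)
      if (t + dt > dur) {
        copies <- lapply(copies, function(cp) {
          cp$plen <- cp$plen + (dur - t); cp
        })
        break
      }
      t <- t + dt
      copies <- lapply(copies, function(cp) {
        cp$plen <- cp$plen + dt; cp
      })
      i <- sample.int(n, 1L)
      if (runif(1) < d / (d + l)) {
        g <- newNode()
        addEdge(copies[[i]]$pnode, g, copies[[i]]$plen)
        copies[[i]] <- list(pnode = g, plen = 0)
        copies[[length(copies) + 1L]] <- list(pnode = g, plen = 0)
        env$dups <- c(env$dups, branchId)
      } else {
        copies[[i]] <- NULL
        env$losses <- c(env$losses, branchId)
      }
    }
    copies
  }

  applyForced <- function(copies, branchId) {
    # transfers in (earlier-processed donors may have stashed copies here)
    if (!is.null(env$pendingTransfers[[branchId]])) {
      for (g in env$pendingTransfers[[branchId]])
        copies[[length(copies) + 1L]] <- list(pnode = g, plen = 0)
      env$pendingTransfers[[branchId]] <- NULL
    }
    these <- fe[fe$branch == branchId, , drop = FALSE]
    if (nrow(these) > 0) for (r in seq_len(nrow(these))) {
      type <- these$type[r]
      if (type == "loss") {
        env$losses <- c(env$losses, rep(branchId, 1L))
        copies <- list()
      } else if (type == "duplication") {
        if (length(copies) == 0L)
          stop("forced duplication on branch without copies: ", branchId,
               call. = FALSE)
        g <- newNode()
        addEdge(copies[[1]]$pnode, g, copies[[1]]$plen)
        copies[[1]] <- list(pnode = g, plen = 0)
        copies[[length(copies) + 1L]] <- list(pnode = g, plen = 0)
        env$dups <- c(env$dups, branchId)
      } else if (type == "transfer") {
        if (length(copies) == 0L)
          stop("forced transfer from branch without copies: ", branchId,
               call. = FALSE)
        g <- newNode()
        addEdge(copies[[1]]$pnode, g, copies[[1]]$plen)
        copies[[1]] <- list(pnode = g, plen = 0)
        env$pendingTransfers[[these$to[r]]] <-
          c(env$pendingTransfers[[these$to[r]]], g)
        env$transfers[[length(env$transfers) + 1L]] <-
          data.frame(donor = branchId, recipient = these$to[r])
      }
    }
    copies
  }

  # subtree branch-id sets, for ordering children so transfer donors are
  # always visited before their recipients
  subtreeIds <- function(node) {
    out <- labs[node]
    for (k in kids[[node]]) out <- c(out, subtreeIds(k))
    out
  }
  orderChildren <- function(children) {
    if (is.null(fe) || !any(fe$type == "transfer") || length(children) < 2L)
      return(children)
    tr <- fe[fe$type == "transfer", , drop = FALSE]
    s1 <- subtreeIds(children[1]); s2 <- subtreeIds(children[2])
    oneFirst <- any(tr$branch %in% s1 & tr$to %in% s2)
    twoFirst <- any(tr$branch %in% s2 & tr$to %in% s1)
    if (oneFirst && twoFirst)
      stop("circular transfer dependencies between sibling subtrees",
           call. = FALSE)
    if (twoFirst) rev(children) else children
  }

  processBranch <- function(node, copies) {
    branchId <- labs[node]
    T2 <- edgeLen[node] / 2
    copies <- simSegment(copies, T2, branchId)
    copies <- applyForced(copies, branchId)
    copies <- simSegment(copies, T2, branchId)
    atNodeEnd(node, copies)
  }

  atNodeEnd <- function(node, copies) {
    if (node <= ntip) {
      for (cp in copies) {
        tn <- newNode()
        addEdge(cp$pnode, tn, cp$plen)
        env$tips[[length(env$tips) + 1L]] <-
          data.frame(node = tn, species = labs[node])
      }
      return(invisible(NULL))
    }
    children <- orderChildren(kids[[node]])
    if (length(copies) == 0L) {
      for (k in children) processBranch(k, list())
      return(invisible(NULL))
    }
    perChild <- lapply(children, function(k) list())
    for (cp in copies) {
      g <- newNode()
      addEdge(cp$pnode, g, cp$plen)
      for (j in seq_along(children))
        perChild[[j]][[length(perChild[[j]]) + 1L]] <-
          list(pnode = g, plen = 0)
    }
    for (j in seq_along(children)) processBranch(children[j], perChild[[j]])
  }

  withSeed(seed, {
    originNode <- newNode()
    if (identical(origin_branch, "root") ||
        identical(origin_branch, rootLab)) {
      atNodeEnd(rootNode(species_tree),
                list(list(pnode = originNode, plen = 0)))
    } else {
      target <- labelToNode(species_tree, origin_branch)
      # process siblings of the origin path without copies, origin with one
      processEmptyOrOrigin <- function(node) {
        if (node == target) {
          processBranch(node, list(list(pnode = originNode, plen = 0)))
        } else if (node <= ntip) {
          processBranch(node, list())
        } else {
          # internal branch not the origin: no copies on the branch itself,
          # but descend (origin may be below)
          if (target %in% downNodes(species_tree, node)) {
            for (k in orderChildren(kids[[node]])) processEmptyOrOrigin(k)
          } else {
            processBranch(node, list())
          }
        }
      }
      for (k in orderChildren(kids[[rootNode(species_tree)]]))
        processEmptyOrOrigin(k)
    }
  })
  if (length(env$pendingTransfers) > 0 &&
      any(lengths(env$pendingTransfers) > 0))
    stop("transfer recipient branch was never reached: ",
         paste(names(env$pendingTransfers)[lengths(env$pendingTransfers) > 0],
               collapse = ", "), call. = FALSE)

  tips <- if (length(env$tips) > 0) do.call(rbind, env$tips)
          else data.frame(node = integer(0), species = character(0))
  cn <- integer(ntip)
  names(cn) <- species_tree$tip.label
  if (nrow(tips) > 0) {
    tt <- table(tips$species)
    cn[names(tt)] <- as.integer(tt)
    tips$label <- ""
    for (sp in unique(tips$species)) {
      sel <- which(tips$species == sp)
      tips$label[sel] <- paste0(sp, "|", seq_along(sel))
    }
  }
  genealogy <- if (nrow(tips) == 0) NULL else
    list(edges = do.call(rbind, env$edges), root = 1L, tips = tips)
  transfers <- if (length(env$transfers) > 0) do.call(rbind, env$transfers)
               else data.frame(donor = character(0), recipient = character(0))
  new("GeneFamilyTruth",
      originBranch = as.character(origin_branch),
      duplications = env$dups, losses = env$losses,
      transfers = transfers, copyNumber = cn, genealogy = genealogy,
      plantedLoci = data.frame(species = character(0), contig = character(0),
                               start = integer(0), end = integer(0),
                               strand = character(0),
                               protein_id = character(0)),
      contaminantContigs = data.frame(species = character(0),
                                      contig = character(0),
                                      source_taxid = integer(0)))
}

#' @noRd
validateForcedEvents <- function(forced_events, labs, rootLab) {
  if (is.null(forced_events))
    return(data.frame(type = character(0), branch = character(0),
                      to = character(0)))
  fe <- as.data.frame(forced_events, stringsAsFactors = FALSE)
  if (!all(c("type", "branch") %in% names(fe)))
    stop("forced_events needs columns 'type' and 'branch'", call. = FALSE)
  if (!"to" %in% names(fe)) fe$to <- NA_character_
  bad <- setdiff(fe$branch, setdiff(labs, rootLab))
  if (length(bad) > 0)
    stop("forced event on unknown branch: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(fe$type %in% c("duplication", "loss", "transfer")))
    stop("forced event types must be duplication/loss/transfer",
         call. = FALSE)
  tr <- fe$type == "transfer"
  if (any(tr & (is.na(fe$to) | !(fe$to %in% setdiff(labs, rootLab)))))
    stop("transfer events need a valid 'to' branch", call. = FALSE)
  fe
}

# all node indices in the subtree rooted at `node` (including node)
#' @noRd
downNodes <- function(tree, node) {
  kids <- childList(tree)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    x <- stack[1]; stack <- stack[-1]
    out <- c(out, x)
    stack <- c(stack, kids[[x]])
  }
  out
}
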