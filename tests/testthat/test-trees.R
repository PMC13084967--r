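# Alignment, trimming, supermatrix, NJ, rooting, consensus, monophyly,
# origins, Dollo, reconciliation, tanglegram.

test_that("global alignment matches its cost convention", {
  sm <- defaultSubstitutionMatrix()
  al <- globalAlign("MKV", "MKV")
  expect_equal(al$score, sm["M","M"] + sm["K","K"] + sm["V","V"])
  expect_equal(al$a, "MKV")
  # a single residue against the empty string costs one gap opening
  expect_equal(globalAlign("A", "", gap_open = 10, gap_extend = 1)$score,
               -10)
  expect_equal(globalAlign("", "AAA", gap_open = 10, gap_extend = 1)$score,
               -12)
  expect_equal(globalAlign("", "")$score, 0)
})

test_that("alignment scores equal exhaustive enumeration on short pairs", {
  sm <- defaultSubstitutionMatrix()
  withr::with_seed(1234, {
    for (k in 1:60) {
      a <- paste(sample(ghprospect:::AA_STANDARD, sample(0:6, 1), TRUE),
                 collapse = "")
      b <- paste(sample(ghprospect:::AA_STANDARD, sample(0:6, 1), TRUE),
                 collapse = "")
      got <- globalAlign(a, b, sm, gap_open = 10, gap_extend = 1,
                         score_only = TRUE)
      expect_equal(got, enumAlignScore(a, b, sm, 10, 1),
                   info = paste(a, b))
    }
  })
})

test_that("gap-column trimming removes strictly-more-than-half gap columns", {
  aln <- c(r1 = "A-CA", r2 = "A--A", r3 = "AAC-")
  # col2: 2/3 gaps (> 0.5) removed; col3: 1/3 kept; col4: 1/3 kept
  tr <- trimAlignment(aln)
  expect_equal(unname(tr), c("ACA", "A-A", "AC-"))
  # exactly half gaps in 4 rows is retained
  aln4 <- c(a = "A-", b = "A-", c = "AC", d = "AC")
  expect_equal(unname(trimAlignment(aln4)), c("A-", "A-", "AC", "AC"))
  # gap-free alignment unchanged; idempotence
  clean <- c(a = "MKV", b = "MLV")
  expect_equal(trimAlignment(clean), clean)
  expect_equal(trimAlignment(trimAlignment(aln)), trimAlignment(aln))
  expect_warning(trimAlignment(c(a = "-", b = "-", c = "A")), "all columns")
})

test_that("supermatrix drops low-occupancy genes and pads with gaps", {
  sp <- c("s1", "s2", "s3", "s4")
  alns <- list(
    g1 = c(s1 = "AAAA", s2 = "CCCC", s3 = "GGGG", s4 = "TTTT"),
    g2 = c(s1 = "MK", s2 = "ML"),                   # 2/4 = 0.5 < 0.75
    g3 = c(s1 = "DE", s2 = "DE", s3 = "DD"))        # 3/4 = 0.75 kept
  sm <- buildSupermatrix(alns, sp, 0.75)
  expect_equal(sm$partitions$gene, c("g1", "g3"))
  expect_equal(nchar(sm$alignment[["s1"]]), 6L)
  expect_equal(sm$alignment[["s4"]], "TTTT--")      # gap block for g3
  expect_equal(sm$partitions$start, c(1L, 5L))
  expect_equal(sm$partitions$end, c(4L, 6L))
  expect_error(buildSupermatrix(alns["g2"], sp, 0.75), "occupancy")
})

test_that("neighbor joining recovers additive topologies exactly", {
  skip_if_not_installed("phangorn")
  for (seed in 1:25) {
    n <- withr::with_seed(seed, sample(4:16, 1))
    t0 <- randomRootedTree(n, seed)
    d <- ape::cophenetic.phylo(t0)
    t1 <- njTree(d)
    expect_equal(phangorn::RF.dist(ape::unroot(t0), t1), 0)
  }
  # 3 taxa: the unique unrooted topology
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
               dimnames = list(c("A","B","C"), c("A","B","C")))
  expect_equal(ape::Ntip(njTree(d3)), 3L)
  # hand-checkable ultrametric 4-taxon case: ((A,B),(C,D))
  d4 <- matrix(c(0,1,4,4, 1,0,4,4, 4,4,0,1, 4,4,1,0), 4,
               dimnames = list(c("A","B","C","D"), c("A","B","C","D")))
  t4 <- njTree(d4)
  expect_true(isMonophyleticGroup(rootByOutgroup(t4, c("C", "D")),
                                  c("A", "B")))
})

test_that("outgroup rooting splits the outgroup branch at its midpoint", {
  tr <- readNewick("((A:1,B:1):1,(C:1,D:2):3);")
  r1 <- rootByOutgroup(tr, "D")
  expect_true(ape::is.rooted(r1))
  expect_true(isMonophyleticGroup(r1, c("A", "B", "C")))
  # the two root edges each carry half of D's original branch
  rootKids <- r1$edge[r1$edge[, 1] == ape::Ntip(r1) + 1L, 2]
  dEdge <- r1$edge.length[r1$edge[, 2] == match("D", r1$tip.label)]
  expect_equal(dEdge, 1)  # 2 split as 1 + 1
  # non-split outgroups error with the intruding leaves
  expect_error(rootByOutgroup(tr, c("A", "C")), "not a split")
  expect_error(rootByOutgroup(tr, c("A", "B", "C", "D")), "all leaves")
  # rooting then unrooting preserves the split set
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(ape::unroot(r1), ape::unroot(tr)), 0)
})

test_that("majority consensus keeps splits in strictly more than half", {
  t1 <- readNewick("((A,B),(C,D));")
  t2 <- readNewick("((A,C),(B,D));")
  # 4 identical trees -> same topology
  c1 <- majorityConsensus(list(t1, t1, t1, t1))
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(c1, ape::unroot(t1)), 0)
  # 3 of 4 trees share the split -> retained
  c2 <- majorityConsensus(list(t1, t1, t1, t2))
  expect_equal(phangorn::RF.dist(c2, ape::unroot(t1)), 0)
  # 50/50 conflict -> polytomy (neither split retained)
  c3 <- majorityConsensus(list(t1, t2))
  expect_equal(c3$Nnode, 1L)
  expect_error(majorityConsensus(list(t1)), "at least two")
  t3 <- readNewick("((A,B),(C,E));")
  expect_error(majorityConsensus(list(t1, t3)), "differing leaf sets")
})

test_that("monophyly and origin counting agree and match brute force", {
  tr <- readNewick("(((a1,f1),(a2,f2)),f3);")
  tr$node.label <- paste0("n", seq_len(tr$Nnode))
  groups <- c(a1 = "animal", a2 = "animal", f1 = "fungal", f2 = "fungal",
              f3 = "fungal")
  expect_equal(countGroupOrigins(tr, groups, "animal"), 2L)
  expect_equal(countGroupOrigins(tr, groups, "plant"), 0L)
  tr2 <- readNewick("((A,B),C);")
  expect_true(isMonophyleticGroup(tr2, c("A", "B")))
  expect_false(isMonophyleticGroup(readNewick("((A,C),B);"), c("A", "B")))
  expect_true(isMonophyleticGroup(tr2, "C"))
  expect_error(isMonophyleticGroup(tr2, "Z"), "missing")

  # random trees: equals the exhaustive clade scan, and the
  # origins==1 <=> monophyletic equivalence holds
  for (seed in 1:15) {
    n <- withr::with_seed(seed, sample(4:10, 1))
    tr <- randomRootedTree(n, seed + 40)
    groups <- withr::with_seed(seed + 80, setNames(
      sample(c("g", "h"), n, TRUE), tr$tip.label))
    got <- countGroupOrigins(tr, groups, "g")
    expect_equal(got, oracleOrigins(tr, groups, "g"))
    if (sum(groups == "g") >= 1)
      expect_equal(got == 1L,
                   isMonophyleticGroup(tr, names(groups)[groups == "g"]))
  }
})

test_that("Dollo history places the gain at the LCA with minimal losses", {
  tr <- readNewick("((A:1,B:1):1,(C:1,D:1):1);")
  tr$node.label <- c("root", "nAB", "nCD")
  # all present: gain at root, no losses
  h <- dolloHistory(tr, c(A = TRUE, B = TRUE, C = TRUE, D = TRUE))
  expect_equal(h$gain_branch, "root")
  expect_equal(h$n_losses, 0L)
  # presence {A,B,C}: gain at root, single loss on the branch to D
  h2 <- dolloHistory(tr, c(A = TRUE, B = TRUE, C = TRUE, D = FALSE))
  expect_equal(h2$gain_branch, "root")
  expect_equal(h2$loss_branches, "D")
  # all absent
  h3 <- dolloHistory(tr, c(A = FALSE, B = FALSE, C = FALSE, D = FALSE))
  expect_true(is.na(h3$gain_branch))
  expect_equal(h3$n_losses, 0L)
})

test_that("Dollo loss counts equal exhaustive minimisation on small trees", {
  for (seed in 1:4) {
    n <- 4 + seed
    tr <- randomRootedTree(n, seed + 300)
    prev <- NULL
    for (mask in 1:(2^n - 1)) {
      presence <- setNames(as.logical(bitwAnd(mask, 2^(0:(n - 1)))),
                           tr$tip.label)
      got <- dolloHistory(tr, presence)
      oracle <- oracleDollo(tr, presence)
      expect_equal(got$n_losses, oracle$n_losses,
                   info = paste("seed", seed, "mask", mask))
    }
  }
})

test_that("Dollo losses are bounded and vanish iff the gain clade is full", {
  tr <- randomRootedTree(8, 17)
  withr::with_seed(18, {
    for (k in 1:40) {
      pres <- setNames(sample(c(TRUE, FALSE), 8, TRUE), tr$tip.label)
      if (!any(pres)) next
      h <- dolloHistory(tr, pres)
      gainNode <- match(h$gain_branch, c(tr$tip.label, tr$node.label))
      underGain <- tr$tip.label[intersect(oracleCladeTips(tr, gainNode),
                                          seq_len(8))]
      absentUnder <- sum(!pres[underGain])
      # every maximal empty subtree holds >= 1 absent tip
      expect_lte(h$n_losses, absentUnder)
      expect_equal(h$n_losses == 0L, absentUnder == 0L)
      # loss branches are disjoint subtrees covering all absent tips
      lossNodes <- match(h$loss_branches, c(tr$tip.label, tr$node.label))
      covered <- unlist(lapply(lossNodes, function(nd)
        oracleCladeTips(tr, nd)))
      expect_setequal(tr$tip.label[covered], underGain[!pres[underGain]])
    }
  })
})

test_that("reconciliation reproduces hand-checkable cases", {
  st <- readNewick("(A,B);")
  # congruent one-copy gene tree: no duplications, no losses
  gt0 <- readNewick("(a,b);")
  r0 <- reconcileTrees(gt0, st, c(a = "A", b = "B"))
  expect_equal(r0$duplications, 0L)
  expect_equal(r0$losses, 0L)
  # two copies in A, one in B: the duplication maps inside A; exhaustive
  # search confirms (1 duplication, 0 losses) is the parsimony optimum
  gt1 <- readNewick("((a1,a2),b);")
  map1 <- c(a1 = "A", a2 = "A", b = "B")
  r1 <- reconcileTrees(gt1, st, map1)
  o1 <- oracleReconcile(gt1, st, map1)
  expect_equal(r1$duplications, o1$duplications)
  expect_equal(r1$losses, o1$losses)
  expect_equal(r1$duplications, 1L)
  expect_equal(r1$losses, 0L)
  # classic incongruence: ((a,c),b) on ((A,B),C) costs 1 dup + 3 losses
  st2 <- readNewick("((A,B),C);")
  gt2 <- readNewick("((a,c),b);")
  r2 <- reconcileTrees(gt2, st2, c(a = "A", b = "B", c = "C"))
  expect_equal(r2$duplications, 1L)
  expect_equal(r2$losses, 3L)
  expect_error(reconcileTrees(gt2, st2, c(a = "A")), "unmapped")
})

test_that("reconciliation counts match the exhaustive oracle", {
  for (seed in 1:20) {
    st <- randomRootedTree(4, seed + 600)
    ngene <- withr::with_seed(seed + 700, sample(3:6, 1))
    gt <- randomRootedTree(ngene, seed + 800)
    gt$tip.label <- paste0("g", seq_len(ngene))
    map <- withr::with_seed(seed + 900, setNames(
      sample(st$tip.label, ngene, TRUE), gt$tip.label))
    got <- reconcileTrees(gt, st, map)
    oracle <- oracleReconcile(gt, st, map)
    expect_equal(got$duplications, oracle$duplications,
                 info = paste("seed", seed))
    expect_equal(got$losses, oracle$losses, info = paste("seed", seed))
  }
})

test_that("reconciliation mapping respects descent", {
  st <- randomRootedTree(5, 41)
  gt <- randomRootedTree(6, 42)
  gt$tip.label <- paste0("g", 1:6)
  map <- withr::with_seed(43, setNames(sample(st$tip.label, 6, TRUE),
                                       gt$tip.label))
  r <- reconcileTrees(gt, st, map)
  labsS <- c(st$tip.label, st$node.label)
  for (e in seq_len(nrow(gt$edge))) {
    pu <- r$mapping[[gt$edge[e, 1] |>
      (\(nd) c(gt$tip.label, gt$node.label)[nd])()]]
    pv <- r$mapping[[gt$edge[e, 2] |>
      (\(nd) c(gt$tip.label, gt$node.label)[nd])()]]
    ui <- match(pu, labsS); vi <- match(pv, labsS)
    # u's image is an ancestor-or-equal of v's image
    anc <- vi
    repeat {
      if (anc == ui) break
      up <- st$edge[st$edge[, 2] == anc, 1]
      if (length(up) == 0) { anc <- NA; break }
      anc <- up
    }
    expect_false(is.na(anc))
  }
})

test_that("tanglegram crossings reach the exhaustive optimum on small trees", {
  # identical trees with identity links: zero crossings
  t1 <- randomRootedTree(6, 50)
  links <- data.frame(left = t1$tip.label, right = t1$tip.label)
  tg <- tanglegram(t1, t1, links)
  expect_equal(tg$crossings, 0L)
  # two-leaf trees with swapped links start with one crossing, which a
  # single root rotation removes
  a <- readNewick("(x:1,y:1);"); b <- readNewick("(u:1,v:1);")
  swap <- data.frame(left = c("x", "y"), right = c("v", "u"))
  tgs <- tanglegram(a, b, swap)
  expect_equal(tgs$initial_crossings, 1L)
  expect_equal(tgs$crossings, 0L)
  expect_error(tanglegram(a, b, data.frame(left = "z", right = "u")),
               "missing leaves")
  # random pairs up to 7 leaves: greedy equals the exhaustive minimum
  for (seed in 1:10) {
    n <- withr::with_seed(seed + 70, sample(4:7, 1))
    ta <- randomRootedTree(n, seed + 71)
    tb <- randomRootedTree(n, seed + 72)
    tb$tip.label <- withr::with_seed(seed + 73, sample(ta$tip.label))
    links <- data.frame(left = ta$tip.label, right = ta$tip.label)
    got <- tanglegram(ta, tb, links)$crossings
    expect_equal(got, oracleMinCrossings(ta, tb, links),
                 info = paste("seed", seed))
  }
})
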