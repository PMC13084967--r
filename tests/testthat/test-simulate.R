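# Synthetic-data generator: species trees, gene-family histories,
# sequence evolution, gene planting, contamination, hit tables.

test_that("species tree simulation is deterministic and well-formed", {
  t2 <- simulateSpeciesTree(2, 1)
  expect_equal(ape::Ntip(t2), 2L)
  expect_true(ape::is.rooted(t2))
  expect_identical(writeNewick(simulateSpeciesTree(7, 99)),
                   writeNewick(simulateSpeciesTree(7, 99)))
  expect_false(identical(writeNewick(simulateSpeciesTree(7, 99)),
                         writeNewick(simulateSpeciesTree(7, 100))))
  t50 <- simulateSpeciesTree(50, 3)
  # a rooted binary tree on 50 tips has 49 internal splits
  expect_equal(t50$Nnode, 49L)
  expect_true(all(t50$edge.length > 0))
  expect_equal(max(ape::node.depth.edgelength(t50)), 1, tolerance = 1e-9)
  expect_error(simulateSpeciesTree(1), "at least 2")
})

test_that("gene-family replay yields the expected deterministic histories", {
  tr <- simulateSpeciesTree(6, 5)
  # rates 0, origin at root: one copy everywhere
  th <- simulateGeneFamily(tr, 0, 0, "root")
  expect_true(all(copyNumber(th) == 1L))
  # forced loss on the branch to one clade zeroes exactly that clade
  node <- tr$node.label[2]   # some internal branch
  inClade <- ghprospect:::cladeTips(tr)[[ghprospect:::labelToNode(tr, node)]]
  fl <- simulateGeneFamily(tr, 0, 0, "root",
                           data.frame(type = "loss", branch = node))
  cn <- copyNumber(fl)
  expect_true(all(cn[tr$tip.label[inClade]] == 0L))
  expect_true(all(cn[setdiff(tr$tip.label, tr$tip.label[inClade])] == 1L))
  # forced duplication doubles the clade below it
  fd <- simulateGeneFamily(tr, 0, 0, "root",
                           data.frame(type = "duplication", branch = node))
  expect_true(all(copyNumber(fd)[tr$tip.label[inClade]] == 2L))
  # origin on a branch: only that subtree carries the family
  og <- simulateGeneFamily(tr, 0, 0, node)
  expect_true(all(copyNumber(og)[tr$tip.label[inClade]] == 1L))
  expect_true(all(copyNumber(og)[tr$tip.label[-inClade]] == 0L))
  expect_error(simulateGeneFamily(tr, 0, 0, "nosuch"), "unknown branch")
  expect_error(simulateGeneFamily(tr, 0, 0, "root",
                                  data.frame(type = "loss", branch = "zz")),
               "unknown branch")
})

test_that("forced transfers move a copy between disjoint subtrees", {
  tr <- readNewick("((A:1,B:1)x:1,(C:1,D:1)y:1)r;")
  # donor branch A (left subtree), recipient branch C (right subtree)
  tt <- simulateGeneFamily(tr, 0, 0, "x",
                           data.frame(type = "transfer", branch = "A",
                                      to = "C"))
  cn <- copyNumber(tt)
  expect_equal(unname(cn[c("A", "B", "C", "D")]), c(1L, 1L, 1L, 0L))
  expect_equal(nrow(tt@transfers), 1L)
  expect_equal(tt@transfers$donor, "A")
  expect_equal(tt@transfers$recipient, "C")
})

test_that("mean copy number follows the branching-process expectation", {
  # single branch of length 1 (cherry tips at depth 1), duplication only:
  # E[copies per tip] = exp((d - l) * t)
  tr <- simulateSpeciesTree(2, 7)
  d <- 0.4; l <- 0.1
  tot <- withr::with_seed(1000, {
    vapply(1:400, function(k)
      mean(copyNumber(simulateGeneFamily(tr, d, l, "root",
                                         seed = sample.int(1e8, 1)))),
      numeric(1))
  })
  expected <- exp((d - l) * 1)
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 3 * se + 1e-9)
})

test_that("sequence evolution matches its closed-form divergence", {
  tr <- simulateSpeciesTree(2, 11)
  th <- simulateGeneFamily(tr, 0, 0, "root")
  seedp <- fixtureProtein(201)
  # rate 0: all tip sequences equal the seed
  s0 <- evolveSequences(seedp, tr, th, 0, 1)
  expect_length(s0, 2L)
  expect_true(all(s0 == seedp))
  expect_error(evolveSequences("MKV", tr, th, 0.1), "at least 30")
  # rate r over unit depth: expected differing fraction among variable
  # sites is (19/20) * (1 - exp(-(20/19) * r))  [uniform-other-19 model]
  r <- 0.3
  fracs <- withr::with_seed(2000, {
    unlist(lapply(1:60, function(k) {
      s <- evolveSequences(seedp, tr, th, r, sample.int(1e8, 1))
      vapply(s, function(x) {
        a <- strsplit(x, "")[[1]][-1]
        b <- strsplit(seedp, "")[[1]][-1]
        mean(a != b)
      }, numeric(1))
    }))
  })
  expected <- (19 / 20) * (1 - exp(-(20 / 19) * r))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * se + 1e-9)
})

test_that("sister copies share ancestral-branch substitutions", {
  # cherry; forced duplication at the midpoint of tip branch A:
  # shared history t1 = 0.5, independent tails t2 = 0.5 each
  tr <- readNewick("(A:1,B:1)r;")
  tr$node.label <- "r"
  th <- simulateGeneFamily(tr, 0, 0, "root",
                           data.frame(type = "duplication", branch = "A"))
  expect_equal(unname(copyNumber(th)["A"]), 2L)
  seedp <- fixtureProtein(301)
  r <- 0.5
  q <- function(t) (19 / 20) * (1 - exp(-(20 / 19) * r * t))
  t1 <- 0.5; t2 <- 0.5
  # P(copy differs from seed) and P(both differ): the shared segment makes
  # the joint probability exceed the independence product
  pboth_expected <- (1 - q(t1)) * q(t2)^2 +
    q(t1) * (1 - q(t2) / 19)^2
  both <- withr::with_seed(3000, {
    unlist(lapply(1:80, function(k) {
      s <- evolveSequences(seedp, tr, th, r, sample.int(1e8, 1))
      a <- strsplit(s[["A|1"]], "")[[1]][-1]
      b <- strsplit(s[["A|2"]], "")[[1]][-1]
      sd0 <- strsplit(seedp, "")[[1]][-1]
      (a != sd0) & (b != sd0)
    }))
  })
  se <- sqrt(mean(both) * (1 - mean(both)) / length(both))
  expect_lt(abs(mean(both) - pboth_expected), 3 * se + 1e-9)
  pind <- q(t1 + t2)^2
  expect_gt(mean(both), pind)   # positive covariance from shared branch
})

test_that("planted genes translate back exactly and respect spacing", {
  tr <- simulateSpeciesTree(5, 13)
  th <- simulateGeneFamily(tr, 0.6, 0, "root", seed = 5)
  seedp <- fixtureProtein(150)
  seqs <- evolveSequences(seedp, tr, th, 0.1, 3)
  pg <- plantGenes(seqs, th, contig_length = 8000L, flank = 500L, seed = 9)
  loci <- plantedLoci(pg$truth)
  expect_equal(nrow(loci), sum(copyNumber(th)))
  for (r in seq_len(nrow(loci))) {
    ct <- pg$assemblies[[loci$species[r]]][[loci$contig[r]]]
    expect_equal(extractLocusProtein(ct, loci$start[r], loci$end[r],
                                     loci$strand[r]),
                 unname(seqs[loci$protein_id[r]]))
  }
  # loci on a shared contig are separated by at least 2 * flank
  for (ct in unique(loci$contig)) {
    l <- loci[loci$contig == ct, ]
    if (nrow(l) < 2) next
    l <- l[order(l$start), ]
    gaps <- l$start[-1] - l$end[-nrow(l)]
    expect_true(all(gaps >= 2 * 500 - 6))  # cassette stops sit in the gap
  }
  # zero copies -> pure background contig (forced loss on both root children)
  kids <- ghprospect:::childList(tr)[[ghprospect:::rootNode(tr)]]
  labs <- ghprospect:::nodeLabels(tr)
  zero <- simulateGeneFamily(tr, 0, 0, "root",
                             data.frame(type = "loss",
                                        branch = labs[kids]))
  expect_true(all(copyNumber(zero) == 0L))
  pz <- plantGenes(character(0), zero, 6000L, 500L, seed = 2)
  expect_true(all(lengths(pz$assemblies) == 1L))
  expect_equal(nrow(plantedLoci(pz$truth)), 0L)
  # capacity overflow errors
  expect_error(plantGenes(seqs, th, contig_length = 2000L, flank = 500L),
               "capacity")
})

test_that("contamination injection is exact and labelled", {
  asm <- list(sp1 = setNames(rep(strrep("ACGT", 2000), 10),
                             paste0("sp1_c", 1:10)))
  tr <- simulateSpeciesTree(2, 3)
  th <- simulateGeneFamily(tr, 0, 0, "root")
  fp <- c(f1 = fixtureProtein(120, 7))
  ftx <- c(f1 = 500L)
  # fraction 0: identity
  id <- injectContamination(asm, fp, ftx, 0, th)
  expect_identical(id$assemblies, asm)
  # fraction 0.2 on 10 contigs: exactly 2 foreign contigs appended
  out <- injectContamination(asm, fp, ftx, 0.2, th, seed = 4)
  expect_equal(length(out$assemblies$sp1), 12L)
  cc <- contaminantContigs(out$truth)
  expect_equal(nrow(cc), 2L)
  expect_true(all(cc$source_taxid == 500L))
  expect_setequal(cc$contig, setdiff(names(out$assemblies$sp1),
                                     names(asm$sp1)))
  expect_error(injectContamination(asm, fp, ftx, 1.5, th), "\\[0, 1\\]")
})

test_that("simulated hit tables decay with taxonomic distance", {
  tax <- tinyTax()
  ht <- simulateHitTable("q1", 20L, tax, hit_noise_sd = 0, seed = 1)
  # always a self-hit with the top score
  self <- ht[ht$subject_id == "q1", ]
  expect_equal(nrow(self), 1L)
  expect_equal(max(ht$bitscore), self$bitscore)
  # noiseless: best non-self hit is the true source
  nonself <- ht[ht$subject_id != "q1", ]
  expect_equal(nonself$subject_taxid[which.max(nonself$bitscore)], 20L)
  # scores strictly decrease with path distance
  d <- vapply(nonself$subject_taxid, function(tx) {
    la <- oracleLineage(tax, tx); lb <- oracleLineage(tax, 20L)
    anc <- intersect(la, lb)[1]
    (match(anc, la) - 1L) + (match(anc, lb) - 1L)
  }, integer(1))
  expect_true(all(diff(nonself$bitscore[order(d)]) < 0))
  # margin replay: with decay 0.3, only distance-0 subjects fall inside a
  # 10% margin, so the assignment equals the true source
  a <- assignByMargin(ht, "q1", tax, 0.10)
  expect_equal(a@taxid, 20L)
  expect_error(simulateHitTable("q", 999L, tax), "unknown")
  # self-hit present in every replicate
  selfs <- vapply(1:50, function(k)
    sum(simulateHitTable("q", 21L, tax, 5, seed = k)$subject_id == "q"),
    integer(1))
  expect_true(all(selfs == 1L))
})

test_that("the study generator is deterministic and self-consistent", {
  s1 <- simulateStudy(simulationConfig(n_species = 4, seed = 77))
  s2 <- simulateStudy(simulationConfig(n_species = 4, seed = 77))
  expect_identical(writeNewick(s1$species_tree), writeNewick(s2$species_tree))
  expect_identical(s1$assemblies, s2$assemblies)
  expect_identical(s1$hit_tables, s2$hit_tables)
  expect_identical(copyNumber(s1$truth), copyNumber(s2$truth))
  # truth invariant: planted loci per species equal the copy number
  expect_true(validObject(s1$truth))
  # every planted locus translates back to its protein
  loci <- plantedLoci(s1$truth)
  for (r in seq_len(nrow(loci))) {
    ct <- s1$assemblies[[loci$species[r]]][[loci$contig[r]]]
    expect_equal(extractLocusProtein(ct, loci$start[r], loci$end[r],
                                     loci$strand[r]),
                 unname(s1$tip_proteins[loci$protein_id[r]]))
  }
})
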