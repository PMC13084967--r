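# Profile construction, six-frame translation, region search, gene
# prediction, domain filter, orthology and representative selection.

test_that("profile scores follow the pseudocount log-odds formula", {
  # single training sequence "MK": column 1 score for M = log2(2/21*20)
  p <- buildProfile(c(x = "MK"))
  expect_equal(unname(p@pssm["M", 1]), log2(2 / 21 * 20),
               tolerance = 1e-12)
  expect_equal(p@consensus, "MK")

  # identical training sequences: consensus equals them, on-consensus
  # columns score positive
  p3 <- buildProfile(c(a = "MKVA", b = "MKVA", c = "MKVA"))
  expect_equal(p3@consensus, "MKVA")
  cons <- strsplit(p3@consensus, "")[[1]]
  for (j in seq_along(cons)) expect_gt(p3@pssm[cons[j], j], 0)

  # the training cap is enforced
  expect_error(buildProfile(setNames(rep("MKVA", 7), paste0("s", 1:7))),
               "at most 6")
  expect_error(buildProfile(character(0)), "no training")
})

test_that("unequal-length training sequences are projected onto the first", {
  p <- buildProfile(c(a = "MKVAW", b = "MKAW"))  # b aligns with one gap
  expect_equal(nchar(p@consensus), 5L)
})

test_that("six-frame translation and coordinate maps are exact", {
  tr <- sixFrameTranslate("ATGGCC")
  expect_equal(tr[[1]]$protein, "MA")
  expect_equal(tr[[1]]$map(1), c(0, 3))
  expect_equal(tr[[1]]$map(2), c(3, 6))
  # reverse strand frame 0 translates the reverse complement GGCCAT -> GH
  rev0 <- Filter(function(t) t$strand == "-" && t$frame == 0, tr)[[1]]
  expect_equal(rev0$protein, "GH")
  expect_equal(rev0$map(1), c(3, 6))  # first revcomp codon = last 3 nt
  # stops and fuzzy codons
  expect_equal(sixFrameTranslate("ATGTAANNN")[[1]]$protein, "M*X")
  # too short for a codon: six empty tracks
  expect_true(all(vapply(sixFrameTranslate("AT"), function(t)
    t$protein == "", logical(1))))
})

test_that("region extension clips at contig bounds and is idempotent", {
  r <- data.frame(start = 1000L, end = 1300L)
  e <- extendRegion(r, 10000L, 500)
  expect_equal(c(e$start, e$end), c(500L, 1800L))
  r2 <- data.frame(start = 200L, end = 400L)
  e2 <- extendRegion(r2, 10000L, 500)
  expect_equal(c(e2$start, e2$end), c(0L, 900L))
  expect_equal(extendRegion(e2, 900L, 500)$start, 0L)  # clip twice = once
  expect_equal(unlist(extendRegion(r, 10000L, 0)), unlist(r))
})

test_that("gene prediction picks the longest hit-overlapping ORF", {
  withr::with_seed(42, {
    p60 <- paste0("M", paste(sample(setdiff(ghprospect:::AA_STANDARD, "M"),
                                    59, TRUE), collapse = ""))
    p90 <- paste0("M", paste(sample(setdiff(ghprospect:::AA_STANDARD, "M"),
                                    89, TRUE), collapse = ""))
    bg <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")
  })
  orf <- function(p) paste0(ghprospect::reverseTranslate(p, 1), "TAA")
  # two ORFs, both overlapping the hit: the 90-codon one wins
  contig <- paste0("TAATAA", orf(p60), "TAATAA", orf(p90), "TAATAA")
  ext <- data.frame(start = 0L, end = nchar(contig), strand = "+")
  hit <- data.frame(start = 0L, end = nchar(contig))
  g <- predictGene(ext, hit, contig, min_codons = 30L)
  expect_equal(g$protein, p90)
  # a 10-codon ORF only: dropped
  p10 <- "MAAAAAAAAA"
  contig2 <- paste0("TAATAA", orf(p10), "TAATAA")
  g2 <- predictGene(data.frame(start = 0L, end = nchar(contig2),
                               strand = "+"),
                    data.frame(start = 0L, end = nchar(contig2)),
                    contig2, min_codons = 30L)
  expect_null(g2)
  # minus strand: reverse-complement then translate equals the protein
  contig3 <- paste0("TTTTTT", ghprospect:::revcomp(paste0("TAA", orf(p90))),
                    "TTTTTT")
  g3 <- predictGene(data.frame(start = 0L, end = nchar(contig3),
                               strand = "-"),
                    data.frame(start = 6L, end = nchar(contig3) - 6L),
                    contig3, min_codons = 30L)
  expect_equal(g3$protein, p90)
  expect_equal(g3$strand, "-")
  expect_equal(extractLocusProtein(contig3, g3$start, g3$end, "-"), p90)
})

test_that("search finds planted genes and nothing in background", {
  seedp <- fixtureProtein(120)
  prof <- buildProfile(c(seed = seedp))
  prof <- calibrateSearchThreshold(prof, 4000L, n_null = 40L, seed = 3)
  # one planted, undiverged gene -> exactly one region overlapping it
  withr::with_seed(8, {
    contig <- paste(sample(c("A","C","G","T"), 4000, TRUE), collapse = "")
  })
  cassette <- paste0("TAA", reverseTranslate(seedp, 2), "TAA")
  substr(contig, 1201, 1200 + nchar(cassette)) <- cassette
  regions <- searchRegions(c(ctg = contig), prof)
  expect_equal(nrow(regions), 1L)
  expect_lt(regions$start, 1200 + 3 * 120)
  expect_gt(regions$end, 1203)
  expect_equal(regions$strand, "+")
  # two planted copies far apart -> two regions
  withr::with_seed(9, {
    big <- paste(sample(c("A","C","G","T"), 8000, TRUE), collapse = "")
  })
  substr(big, 1001, 1000 + nchar(cassette)) <- cassette
  substr(big, 5001, 5000 + nchar(cassette)) <- cassette
  expect_equal(nrow(searchRegions(c(ctg = big), prof)), 2L)
  # empty assembly
  expect_equal(nrow(searchRegions(character(0), prof)), 0L)
})

test_that("domain filter passes family members and rejects random proteins", {
  seedp <- fixtureProtein(150)
  prof <- buildProfile(c(seed = seedp))
  dom <- calibrateDomainThreshold(prof, fpr = 0.01, n_null = 600L,
                                  null_length = 150L, seed = 4)
  # protein identical to the consensus: passes with the maximal score
  res <- annotateDomain(prof@consensus, dom)
  expect_true(res$pass)
  expect_equal(res$score, sum(apply(dom@pssm, 2, max)))
  # diverged family member (0.3 subs/site) still passes
  div <- ghprospect:::mutateProtein(seedp, 0.3, 1, seed = 11)
  expect_true(annotateDomain(div, dom)$pass)
  # null pass rate stays near the calibrated false-positive rate
  withr::with_seed(12, {
    nulls <- vapply(1:400, function(i)
      annotateDomain(ghprospect:::randomProtein(150), dom)$pass, logical(1))
  })
  expect_lte(mean(nulls), 0.01 + 3 * sqrt(0.01 * 0.99 / 400))
  # shorter than the profile: never passes
  expect_false(annotateDomain("MKV", dom)$pass)
})

test_that("orthology check and representative selection use alignment scores", {
  seedp <- fixtureProtein(100)
  withr::with_seed(31, {
    decoys <- setNames(vapply(1:20, function(i)
      ghprospect:::randomProtein(100), character(1)), paste0("d", 1:20))
  })
  proteome <- c(decoys, seed_ref = seedp)
  # candidate == seed
  expect_true(checkOrthology(seedp, proteome, "seed_ref"))
  # candidate evolved from the seed
  cand <- ghprospect:::mutateProtein(seedp, 0.25, 1, seed = 5)
  expect_true(checkOrthology(cand, proteome, "seed_ref"))
  # unrelated background protein
  withr::with_seed(32, bgp <- ghprospect:::randomProtein(100))
  expect_false(checkOrthology(bgp, proteome, "seed_ref"))
  expect_error(checkOrthology(seedp, character(0), "x"), "empty proteome")

  # representative = argmax alignment score to the seed, brute-forced
  cands <- c(g2 = ghprospect:::mutateProtein(seedp, 0.3, 1, seed = 7),
             g1 = seedp,
             g3 = ghprospect:::mutateProtein(seedp, 0.15, 1, seed = 8))
  expect_equal(selectRepresentative(cands, seedp), "g1")
  scores <- vapply(cands, function(p)
    globalAlign(p, seedp, score_only = TRUE), numeric(1))
  expect_equal(selectRepresentative(cands, seedp),
               names(cands)[order(-scores, names(cands))][1])
  expect_equal(selectRepresentative(cands["g2"], seedp), "g2")
})
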