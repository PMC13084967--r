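---
title: "Methods: models, parameters and design choices in ghprospect"
author: "ghprospect authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ghprospect` detects members of a protein family in unannotated genome
assemblies, screens the candidates for microbial contamination, profiles
presence/absence across species, and characterises the family's
evolutionary history.  This vignette explains the models behind each
stage, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the design choices made where the design was
genuinely open.

## The search model

The search stage is a desk-scale stand-in for a profile-HMM/alignment
tool chain, built so that every decision it makes is fully specified and
testable.

**Scoring model.**  A profile is trained on at most six core orthologues
(a deliberately small core group, as used in targeted-orthologue
pipelines).  If the training sequences differ in length they are globally
aligned to the first and projected onto its columns.  Column scores are
log-odds with add-one pseudocounts against a uniform background,

$$ s_j(a) \;=\; \log_2\frac{c_{ja}+1}{n+20} \;-\; \log_2\frac{1}{20}, $$

where $c_{ja}$ counts residue $a$ in column $j$ and $n$ is the number of
training sequences.  The consensus is the per-column majority residue
(ties broken alphabetically) and is by construction the argmax of every
column, which the class validity check enforces.  Residues outside the
20-letter alphabet (`X`, stop `*`) score the column minimum, so unknown
sequence can only hurt a window.

**Scan.**  The profile slides ungapped over all six reading frames of
every contig; windows at or above the score threshold are merged when
they overlap on the same strand and frame, and reported in forward-strand
nucleotide coordinates (0-based, half-open throughout the package).

**Threshold calibration.**  Instead of an analytic e-value, both
acceptance thresholds are calibrated on empirical nulls at a target
false-positive rate of 0.01:

* the *domain* threshold is the upper 99% quantile of best-window scores
  of random proteins of the same length (1000 draws by default), so
  unrelated proteins pass the domain filter at a rate of about 1%;
* the *search* threshold is the upper 99% quantile of the per-contig
  maximum window score over random contigs of the study's contig length
  (a family-wise null: about 1% of gene-free contigs yield any region).

Matched family members score hundreds of bits above both thresholds at
the divergences the pipeline is designed for (≤ 0.3 substitutions per
site), so the exact null sample size is uncritical.

**Gene prediction.**  Hit regions are extended by `flank` nucleotides
(default 500) on either side, clipped at contig ends (clipping is
idempotent).  Among all open reading frames on the region's strand —
`ATG..stop`, plus edge-truncated frames at the region borders — that
overlap the original hit, the longest is returned; ORFs shorter than 30
codons are ignored, since the target domains exceed 100 residues and
micro-ORFs are noise.  This single-exon model deliberately omits splicing
(see *Limitations*).

**Orthology.**  A candidate is accepted if its best-scoring global
alignment partner in the seed-species proteome is the seed gene or a
listed co-orthologue.  This targeted best-hit criterion preserves the
decision an orthology-inference run makes for this one family without
re-implementing a full orthology pipeline.  When a species yields several
accepted co-orthologues, the one most similar to the seed protein is the
representative for tree building (ties broken by lexicographic id).

Global alignments use Needleman–Wunsch with affine gaps (BLOSUM62 by
default), with the convention that a gap of length $L$ costs
`gap_open + (L-1) * gap_extend` (defaults 10 and 1); the optimisation is
delegated to `Biostrings::pairwiseAlignment`, mapped onto this
convention.

## The contamination screen

Each query is assigned to the last common ancestor of the taxa within a
10% bit-score margin of its best database hit.  Decisions fixed here:

* every hit whose subject id equals the query id is removed (not only the
  top one);
* each subject is represented by its best HSP's bit score;
* the threshold `(1 - margin) * best` is inclusive — boundary ties
  contribute, so ties never silently drop taxa;
* a query with no remaining hit is *unassigned*, and unassigned is never
  flagged (absence of evidence is not evidence of contamination);
* "on the lineage" includes ancestors of the query species, the species
  itself, and its descendants.

Enlarging the margin can only move an assignment root-ward; the suite
checks this monotonicity and the exact agreement of the whole rule with a
brute-force lineage-intersection oracle on randomly generated taxonomies.

At the contig level, the hits of all genes on a contig are pooled (their
self-hits removed) and the margin-LCA of the pool decides the contig;
contigs assigned to the target phylum's subtree or lineage, and
unassigned contigs, are kept.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated.  Its defaults describe one fixed scenario and are not tuned
per experiment:

| parameter | default | meaning |
|---|---|---|
| `n_species` | 20 | study species (tips of the species tree) |
| `duplication_rate`, `loss_rate` | 0.1, 0.05 | per-copy, per-unit-length birth/death rates |
| `substitution_rate` | 0.25 | expected substitutions/site over the tree height |
| `protein_length` | 220 aa | seed protein length |
| `contig_length` | 8000 nt | per-contig size |
| `flank` | 500 nt | spacing unit and search flank |
| `contamination_fraction` | 0.2 | foreign contigs appended per assembly |
| `hit_noise_sd` | 0 | bit-score noise (5% of base = 10 in noise runs) |
| `base_score`, `decay_lambda` | 200, 0.3 | hit-score decay with taxonomic distance |

**Species trees** are pure-birth (Yule) trees with exponential waiting
times, rescaled to unit root-to-tip height so `substitution_rate` is the
root-to-tip divergence.  **Gene families** evolve down the tree as a
per-copy birth-death process (Gillespie simulation); deterministic forced
events (duplication, loss, transfer between disjoint subtrees) are
applied at branch midpoints, which is how planted Dollo scenarios and
horizontal transfers are constructed.  The replay simultaneously builds
the copy genealogy, so duplicated copies share the substitutions of their
common ancestral branches.

**Sequences** evolve by per-site Poisson replacement events, each drawing
uniformly from the other 19 residues.  Under this model the expected
fraction of variable sites differing from the ancestor after time $t$ at
rate $r$ is

$$ \tfrac{19}{20}\left(1 - e^{-\tfrac{20}{19} r t}\right), $$

the 20-state analogue of the Jukes–Cantor correction; the tests hold the
simulation to this closed form (and to the joint distribution of sister
copies after a duplication).  The uniform-replacement model was chosen
over an empirical exchangeability matrix precisely because it has this
closed form.  Site 1 (the initiator methionine) is held invariant so
every planted gene keeps a translatable `ATG` start.

**Gene planting** reverse-translates each tip protein with uniformly
chosen synonymous codons and inserts it — on a random strand — into
random intergenic background, separated by at least `2 * flank` from
other genes and contig ends.  Each cassette carries an in-frame stop
codon immediately 5' of the `ATG`: the generator has no UTR model, and
this insulation guarantees the longest-ORF predictor cannot extend a gene
into upstream background, keeping prediction exact by construction.  The
220-residue default is realistic for the motivating enzyme family and
long enough that random background ORFs of comparable length are
vanishingly rare.

**Contamination** appends `ceiling(fraction * n_contigs)` foreign contigs
per assembly, each carrying one gene from the foreign (fungal) lineage —
so contaminants are genuine family members that the search *will* find
and only the taxonomic screen can remove.

**Hit tables** emulate a database search: each reference taxon receives a
hit with bit score `base * exp(-lambda * d)` where `d` is the taxonomy
path distance to the true source, plus optional Gaussian noise; a
self-hit with maximal score is always present.  Monotone decay is the
only property the margin-LCA rule needs, so this is the entire model.

**What the generator does not emulate:** introns and spliced genes,
indels, codon-usage and composition biases, assembly errors and
fragmented genes, paralogous families that are similar but distinct, and
database incompleteness.  Passing the end-to-end tests therefore shows
the *inference chain* is correct under its stated assumptions, not that
the stand-ins match the behaviour of the full external tool chain on real
data.

## Comparative machinery

* **Trimming** removes alignment columns with strictly more than 50%
  gaps (a column at exactly one half is kept), and is idempotent.
* **Supermatrices** drop genes present in fewer than 75% of species
  (exactly 75% survives) and pad missing species with gaps; a partition
  table records each gene's column interval.
* **Trees** are neighbor joining on alignment p-distances
  (mismatches / aligned non-gap columns, no multiple-hit correction —
  adequate at the mild divergences simulated; a correction would slot in
  at the distance step).  NJ recovers additive matrices exactly, which
  the suite verifies on random trees; maximum-likelihood inference is
  deliberately out of scope because the downstream conclusions
  (monophyly, origin counts, reconciliation) are topological.
* **Rooting** places the root at the midpoint of the branch separating a
  user-given outgroup; a non-split outgroup is an error naming the
  intruding leaves.
* **Consensus** is strict-majority: splits in strictly more than half of
  the input trees (50/50 conflicts collapse to polytomies).  The
  summarisation mode of multi-run consensus trees is not standardised
  across tools; strict majority is this package's declared choice.
* **Origin counting** counts maximal clades whose leaves all belong to
  the group; it equals 1 exactly when the group is monophyletic.
* **Dollo histories** place a single gain on the branch above the LCA of
  present species, with losses at the maximal present-free subtrees
  below it — the minimal loss set given one gain.  Note the loss count
  is *not* monotone in the presence set (adding a species can move the
  gain or split an empty subtree); the tests assert the correct bounds
  instead.
* **Reconciliation** is standard LCA mapping: a node is a duplication
  iff it maps to the same species node as one of its children; losses
  are counted along mapping gaps.  The counts are the parsimony minimum,
  which the suite verifies against an exhaustive search over all
  ancestrally consistent mappings.
* **Tanglegrams** count link crossings as order inversions and untangle
  by greedy subtree rotation (sweeps of single flips, then paired flips
  across the two trees).  On trees of up to 7 leaves the greedy result
  matches the exhaustive optimum in the test suite; global optimality on
  larger trees is not promised.  Both the input-order crossing count and
  the untangled count are reported.

## Association test

The 2×2 chi-squared test of family presence against reproduction mode
uses the Yates continuity correction by default, matching the common
default in R; the uncorrected statistic is available with
`yates = FALSE`.  The correction is deliberately conservative, so the
null calibration (type-I error ≈ 5% at α = 0.05 over 1000 simulated
cohorts of 80 species) is run with the uncorrected statistic.  Species
with unknown reproduction mode are excluded and counted.  Tables with a
zero expected count raise an error recommending an exact test, which is
out of scope.  A phylogenetically corrected association test would be the
statistically preferable extension: species are not independent samples.

## Determinism and problem sizes

Every stochastic operation is a pure function of its inputs and a seed;
pipeline stages draw from independent streams derived from the master
seed by a documented linear scheme, so adding draws to one stage never
perturbs another.  Identical configuration and seed reproduce a
byte-identical report.

The test suite and the acceptance script run at the sizes the package
documents: 1000 random hit tables for the margin-rule oracle, 200
exhaustively enumerated alignment pairs, 100 additive NJ recoveries, all
presence labelings on trees of 4–8 tips for the Dollo/origin oracles, 60
exhaustively reconciled gene/species pairs, 1000 null cohorts for the
association calibration, 100 gain/loss recovery scenarios, and a
20-species end-to-end study with contamination.

## Limitations

Single-exon gene models only; no frameshift or assembly-error repair; a
best-hit orthology criterion rather than full orthology inference; NJ
topologies rather than ML; no bootstrap support; greedy (not exact)
tanglegram untangling beyond 7 leaves; the association test ignores
phylogenetic non-independence.  These are the points to revisit before
applying the package to real assemblies rather than simulated ones.
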