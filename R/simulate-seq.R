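# Protein sequence evolution along the simulated copy genealogy.
# Substitution model: per-site Poisson replacement events, each replacing
# the current residue with one drawn uniformly from the other 19.  The
# initiator methionine (site 1) is held invariant so every planted gene
# keeps a translatable ATG start.  Under this model the expected fraction
# of variable sites differing from the ancestor after time t at rate r is
# (19/20) * (1 - exp(-(20/19) * r * t)).

#' @noRd
mutateChars <- function(chars, rate, len) {
  L <- length(chars)
  if (L <= 1L || rate <= 0 || len <= 0) return(chars)
  nsub <- rpois(L - 1L, rate * len)   # sites 2..L; site 1 anchored
  hit <- which(nsub > 0L) + 1L
  for (i in hit) {
    for (k in seq_len(nsub[i - 1L])) {
      chars[i] <- sample(setdiff(AA_STANDARD, chars[i]), 1L)
    }
  }
  chars
}

#' @noRd
mutateProtein <- function(protein, rate, len = 1, seed = NULL) {
  chars <- strsplit(protein, "")[[1]]
  withSeed(seed, paste(mutateChars(chars, rate, len), collapse = ""))
}

#' Evolve protein sequences along a simulated gene-family genealogy
#'
#' Walks the copy genealogy recorded in a [GeneFamilyTruth-class] from the
#' origin to every surviving copy, applying the substitution model along
#' each genealogy edge.  Copies that duplicated late share the ancestral
#' substitutions accumulated before the duplication.  With rate 0 all tip
#' sequences equal the seed protein.
#'
#' @param seed_protein the ancestral protein (single string, length >= 30,
#'   starting with `M`)
#' @param species_tree the species tree the truth was simulated on (kept in
#'   the signature for interface clarity; the genealogy carries all timing)
#' @param truth a [GeneFamilyTruth-class] with a genealogy
#' @param substitution_rate expected substitutions per site per unit branch
#'   length (>= 0)
#' @param seed RNG seed
#' @return named character vector of tip proteins, names `<species>|<copy>`;
#'   empty when no copy survives
#' @export
evolveSequences <- function(seed_protein, species_tree, truth,
                            substitution_rate, seed = 1L) {
  if (nchar(seed_protein) < 30L)
    stop("seed protein must be at least 30 residues", call. = FALSE)
  assertScalarNumber(substitution_rate, "substitution_rate", 0)
  gen <- truth@genealogy
  if (is.null(gen)) return(setNames(character(0), character(0)))
  edges <- gen$edges
  chars0 <- strsplit(toupper(seed_protein), "")[[1]]
  if (!all(chars0 %in% AA_STANDARD))
    stop("seed protein contains non-standard residues", call. = FALSE)
  seqs <- list()
  seqs[[as.character(gen$root)]] <- chars0
  withSeed(seed, {
    # edges were recorded parent-before-child during simulation
    for (r in seq_len(nrow(edges))) {
      p <- as.character(edges$parent[r])
      if (is.null(seqs[[p]]))
        stop("genealogy edges out of order (internal error)")
      seqs[[as.character(edges$child[r])]] <-
        mutateChars(seqs[[p]], substitution_rate, edges$length[r])
    }
  })
  out <- vapply(gen$tips$node, function(nd)
    paste(seqs[[as.character(nd)]], collapse = ""), character(1))
  setNames(out, gen$tips$label)
}
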