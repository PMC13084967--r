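# Simulated homology hit tables: bit scores decay exponentially with
# taxonomic path distance from the true source taxon, plus optional
# Gaussian noise.  A self-hit with maximal score is always present.

#' Simulate a homology hit table for one query
#'
#' Emulates a protein database search: every subject taxon receives one hit
#' whose bit score is `base_score * exp(-lambda * d)` where `d` is the path
#' distance (edge count) in the taxonomy between the subject and the true
#' source taxon, plus `N(0, hit_noise_sd)` noise.  In noiseless mode the
#' score therefore strictly decreases with taxonomic distance from the true
#' source.  A trivial self-hit (`subject_id == query_id`) with maximal
#' score is always included.
#'
#' @param query_id query sequence id
#' @param true_source_taxid taxid of the genome the query really came from
#'   (must be present in the taxonomy)
#' @param taxonomy a [Taxonomy-class]
#' @param hit_noise_sd standard deviation of additive score noise (>= 0)
#' @param seed RNG seed
#' @param base_score bit score of a distance-zero hit
#' @param lambda decay rate per taxonomy edge (default 0.3)
#' @param subject_taxids taxa to generate hits for; defaults to all leaf
#'   taxa of the taxonomy
#' @return hit table data.frame (columns as in [readHitTable()]), sorted by
#'   decreasing bit score
#' @export
simulateHitTable <- function(query_id, true_source_taxid, taxonomy,
                             hit_noise_sd = 0, seed = 1L, base_score = 200,
                             lambda = 0.3, subject_taxids = NULL) {
  assertScalarNumber(hit_noise_sd, "hit_noise_sd", 0)
  taxIndex(taxonomy, true_source_taxid, "true_source_taxid")
  if (is.null(subject_taxids))
    subject_taxids <- setdiff(taxonomy@taxid,
                              taxonomy@parent[taxonomy@taxid !=
                                                taxonomy@parent])
  subject_taxids <- as.integer(subject_taxids)
  taxIndex(taxonomy, subject_taxids, "subject taxid")
  srcLineage <- taxLineage(taxonomy, true_source_taxid)
  dist <- vapply(subject_taxids, function(tx) {
    lin <- taxLineage(taxonomy, tx)
    anc <- intersect(lin, srcLineage)[1]
    (match(anc, lin) - 1L) + (match(anc, srcLineage) - 1L)
  }, integer(1))
  withSeed(seed, {
    score <- base_score * exp(-lambda * dist)
    if (hit_noise_sd > 0)
      score <- score + rnorm(length(score), 0, hit_noise_sd)
    score <- pmax(score, 0.1)
    selfScore <- max(base_score * 1.05, max(score) + 1)
    hits <- data.frame(
      query_id = query_id,
      subject_id = c(query_id, paste0("prot_", subject_taxids)),
      subject_taxid = c(as.integer(true_source_taxid), subject_taxids),
      bitscore = c(selfScore, score),
      evalue = exp(-c(selfScore, score) / 10),
      stringsAsFactors = FALSE)
    hits[order(-hits$bitscore, hits$subject_id), , drop = FALSE]
  })
}
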