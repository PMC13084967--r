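# Chi-squared association between family presence and a binary trait.

#' Chi-squared test on a 2x2 contingency table
#'
#' Computes `X^2 = sum((|O - E| - c)^2 / E)` with `c = min(0.5, |O - E|)`
#' under the Yates continuity correction (matching the standard R
#' behaviour) or `c = 0` without it, and the upper-tail p-value from the
#' chi-square distribution with 1 degree of freedom.
#'
#' @param table 2x2 matrix of non-negative integer counts
#' @param yates apply the continuity correction (default `TRUE`)
#' @return list with `statistic`, `df` (1), `p_value`, `expected`, `yates`
#' @examples
#' chiSquaredTest(matrix(c(10, 10, 10, 10), 2))$p_value  # 1
#' @export
chiSquaredTest <- function(table, yates = TRUE) {
  O <- as.matrix(table)
  if (!all(dim(O) == c(2L, 2L)))
    stop("table must be 2x2", call. = FALSE)
  if (any(O < 0) || any(O != round(O)))
    stop("counts must be non-negative integers", call. = FALSE)
  N <- sum(O)
  if (N == 0) stop("empty table", call. = FALSE)
  E <- outer(rowSums(O), colSums(O)) / N
  if (any(E == 0))
    stop("zero expected count; use an exact test instead", call. = FALSE)
  cc <- if (yates) pmin(0.5, abs(O - E)) else 0
  stat <- sum((abs(O - E) - cc)^2 / E)
  list(statistic = stat, df = 1L,
       p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       expected = E, yates = yates)
}

#' Cross-tabulate family presence against reproduction mode
#'
#' Builds the 2x2 table (rows present/absent, columns sexual/
#' parthenogenetic) from a presence profile, optionally restricted to one
#' clade.  Species with unknown reproduction mode are excluded and counted.
#'
#' @param profile a [PresenceProfile-class]
#' @param clade optional clade label to filter on
#' @param family family column (default: first)
#' @return list with `table` (2x2 matrix), `excluded` (number of
#'   unknown-mode species), `n` (species used)
#' @export
presenceByTrait <- function(profile, clade = NULL, family = 1L) {
  counts <- presenceCounts(profile)[, family]
  meta <- speciesMeta(profile)
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(clade)) keep <- keep & meta$clade == clade
  known <- meta$reproduction_mode %in% c("sexual", "parthenogenetic")
  excluded <- sum(keep & !known)
  keep <- keep & known
  if (sum(keep) == 0L)
    stop("no species left after filtering", call. = FALSE)
  present <- factor(ifelse(counts[keep] >= 1, "present", "absent"),
                    levels = c("present", "absent"))
  mode <- factor(meta$reproduction_mode[keep],
                 levels = c("sexual", "parthenogenetic"))
  tab <- table(present, mode)
  list(table = matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab)),
       excluded = excluded, n = sum(keep))
}
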