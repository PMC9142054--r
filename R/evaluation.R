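#' Contingency table of two partitions
#'
#' Co-occurrence counts \eqn{n_{kl} = |S_k \cap T_l|} between the parts of two
#' partitions of the same node set, with row and column marginals.
#'
#' @param s,t label vectors of equal length (any label coding).
#' @return List with `counts` (K x L integer matrix), `row_marginals`,
#'   `col_marginals` and `n`.
#' @export
contingency_table <- function(s, t) {
  if (length(s) != length(t)) stop("partitions differ in length")
  counts <- table(s, t)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  list(counts = counts,
       row_marginals = rowSums(counts),
       col_marginals = colSums(counts),
       n = length(s))
}

#' Adjusted Rand Index
#'
#' Hubert-Arabie chance-corrected pair-counting agreement between two
#' partitions, computed from the contingency table:
#' \deqn{ARI = \frac{\sum_{kl} \binom{n_{kl}}{2} - \sum_k \binom{a_k}{2} \sum_l \binom{b_l}{2} / \binom{N}{2}}
#'            {\frac12 [\sum_k \binom{a_k}{2} + \sum_l \binom{b_l}{2}] - \sum_k \binom{a_k}{2} \sum_l \binom{b_l}{2} / \binom{N}{2}}}
#' ARI is 1 iff the partitions coincide, 0 in expectation under independent
#' random labelings; when one partition is a single all-node cluster the index
#' is 0 by convention (the denominator vanishes).
#'
#' @param s,t label vectors of equal length, at least 2 nodes.
#' @return Scalar in \eqn{[-1, 1]}.
#' @export
adjusted_rand_index <- function(s, t) {
  ct <- contingency_table(s, t)
  if (ct$n < 2L) stop("ARI needs at least 2 nodes")
  choose2 <- function(x) x * (x - 1) / 2
  sum_nkl <- sum(choose2(as.numeric(ct$counts)))
  sum_a <- sum(choose2(as.numeric(ct$row_marginals)))
  sum_b <- sum(choose2(as.numeric(ct$col_marginals)))
  expected <- sum_a * sum_b / choose2(ct$n)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(if (sum_nkl == expected) 0 else 1)
  (sum_nkl - expected) / denom
}

#' Normalized Mutual Information
#'
#' Mutual information of the joint label distribution normalized by the
#' arithmetic mean of the two label entropies; 1 iff the partitions are
#' identical up to relabeling, near 0 for independent labelings at large N.
#'
#' @param s,t label vectors of equal length.
#' @return Scalar in [0, 1].
#' @export
normalized_mutual_information <- function(s, t) {
  ct <- contingency_table(s, t)
  n <- ct$n
  pj <- ct$counts / n
  pa <- ct$row_marginals / n
  pb <- ct$col_marginals / n
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha == 0 && hb == 0) return(1)  # both single-cluster: identical partitions
  if (ha == 0 || hb == 0) return(0)
  outerp <- outer(pa, pb)
  mi <- sum(ifelse(pj > 0, pj * log(pj / outerp), 0))
  max(0, min(1, mi / ((ha + hb) / 2)))
}
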