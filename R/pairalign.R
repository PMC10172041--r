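## Gamma-centroid pairwise SAF decoding.

#' Gamma hyper-parameter pair
#'
#' `gamma_match` controls the precision/recall trade-off of nucleotide
#' matches, `gamma_pair` that of matched base pairs; both must exceed 1.
#'
#' @param match,pair Numeric values > 1.
#' @return Named numeric vector of class `gamma_pair`.
#' @export
gamma_pair <- function(match = 2, pair = 2) {
  stopifnot(match > 1, pair > 1)
  structure(c(match = match, pair = pair), class = "gamma_pair")
}

#' Gamma-centroid expected-accuracy objective
#'
#' `sum_{(i,k) in M} (gamma_M p^M_ik - 1) +
#'  sum_{(i,j,k,l)} (gamma_P (p^P_ij + p^P_kl) - 2)`;
#' quadruple endpoint matches contribute their match terms as members of M.
#'
#' @param saf A [pairwise_saf].
#' @param post An `saf_posteriors` object.
#' @param gamma A [gamma_pair].
#' @return The objective value.
#' @export
objective <- function(saf, post, gamma) {
  gamma <- as_gamma(gamma)
  v <- 0
  if (nrow(saf$match) > 0)
    v <- v + sum(gamma[["match"]] * post$pm[saf$match] - 1)
  if (nrow(saf$quad) > 0)
    v <- v + sum(gamma[["pair"]] *
                   (post$px[saf$quad[, c(1, 2), drop = FALSE]] +
                    post$py[saf$quad[, c(3, 4), drop = FALSE]]) - 2)
  v
}

as_gamma <- function(g) {
  if (inherits(g, "gamma_pair")) return(g)
  gamma_pair(g[[1]], g[[2]])
}

#' Gamma-centroid pairwise SAF
#'
#' Maximizes [objective()] over all pseudoknot-free,
#' base-pairing-indel-free candidates by the sparse two-level recursion;
#' only matches with `p^M >= 1/gamma_M` and base pairs with
#' `p^P >= 1/gamma_P` are materialized (set `prune = FALSE` to run the
#' unthresholded recursion over the same candidate space).  Ties are broken
#' deterministically toward fewer matches.
#'
#' @param post An `saf_posteriors` object (or any list with dense `pm`,
#'   `px`, `py` tables).
#' @param gamma A [gamma_pair].
#' @param prune Apply the 1/gamma eligibility thresholds (the default).
#' @param min_hairpin Minimum hairpin loop length.
#' @return A list with the optimal `saf` ([pairwise_saf]) and its `score`.
#' @export
align_pair <- function(post, gamma, prune = TRUE, min_hairpin = 3L) {
  gamma <- as_gamma(gamma)
  res <- cpp_centroid(post$pm, post$px, post$py,
                      gamma[["match"]], gamma[["pair"]],
                      prune = prune, min_hairpin = as.integer(min_hairpin))
  saf <- pairwise_saf(res$match, res$quad, nrow(post$pm), ncol(post$pm),
                      min_hairpin = min_hairpin)
  list(saf = saf, score = res$score)
}
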