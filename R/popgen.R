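#' Hudson two-population F_ST for a single SNP
#'
#' The standard pairwise single-SNP estimator from population allele
#' frequencies, without finite-sample correction:
#' `(p1 - p2)^2 / (p1 (1 - p2) + p2 (1 - p1))`.  Symmetric in its arguments,
#' 0 at equal frequencies, and 1 when alternate alleles are fixed in the two
#' populations.
#'
#' @param p1,p2 allele frequencies in `[0, 1]`.
#' @return F_ST value in `[0, 1]`.
#' @examples
#' hudson_fst(0.52, 0.02)
#' @export
hudson_fst <- function(p1, p2) {
  p1 <- check_number(p1, "p1", 0, 1)
  p2 <- check_number(p2, "p2", 0, 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  if (den == 0) {
    cm_stop("F_ST undefined: both populations fixed for the same allele",
            "undefined_fst")
  }
  (p1 - p2)^2 / den
}

#' Wright-style variance-partition F_ST for a single SNP
#'
#' `(H_T - H_S) / H_T` where `H_T = 2 pbar (1 - pbar)` is the expected
#' heterozygosity at the (weighted) pooled frequency and `H_S` the weighted
#' mean within-population heterozygosity.
#'
#' @param p1,p2 allele frequencies in `[0, 1]`.
#' @param weights nonnegative weights summing to 1 (default equal).
#' @return F_ST value in `[0, 1]`.
#' @export
wright_fst <- function(p1, p2, weights = c(0.5, 0.5)) {
  p1 <- check_number(p1, "p1", 0, 1)
  p2 <- check_number(p2, "p2", 0, 1)
  if (length(weights) != 2L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-12) {
    cm_stop("weights must be nonnegative and sum to 1", "invalid_parameter")
  }
  pbar <- weights[1L] * p1 + weights[2L] * p2
  ht <- 2 * pbar * (1 - pbar)
  if (ht == 0) cm_stop("F_ST undefined: pooled heterozygosity is zero",
                       "undefined_fst")
  hs <- weights[1L] * 2 * p1 * (1 - p1) + weights[2L] * 2 * p2 * (1 - p2)
  (ht - hs) / ht
}

#' Pairwise F_ST matrix over a population allele-frequency table
#'
#' @param freqs data.frame with columns `population` and `p` (frequency of
#'   the designated allele); an optional `n_chromosomes` column is carried
#'   but unused by these estimators.
#' @param estimator `"hudson"` (default) or `"wright"`.
#' @return symmetric matrix with zero diagonal, dimnames = population labels.
#' @export
pairwise_fst_matrix <- function(freqs, estimator = c("hudson", "wright")) {
  estimator <- match.arg(estimator)
  if (!all(c("population", "p") %in% names(freqs))) {
    cm_stop("freqs must have columns population, p", "parse_error")
  }
  if (nrow(freqs) < 2L) cm_stop("need at least 2 populations", "invalid_parameter")
  if (anyDuplicated(freqs$population)) {
    cm_stop("duplicate population labels", "invalid_parameter")
  }
  n <- nrow(freqs)
  fn <- if (estimator == "hudson") hudson_fst else function(a, b) wright_fst(a, b)
  m <- matrix(0, n, n, dimnames = list(freqs$population, freqs$population))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- fn(freqs$p[i], freqs$p[j])
    }
  }
  m
}
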