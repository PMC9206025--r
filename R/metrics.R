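# Clustering agreement metrics (pair-counting and information-theoretic) and
# the log-modulus score for cluster-number estimation.

.check_labels <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors have different lengths")
  if (length(a) < 2L) stop("need at least 2 observations")
}

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement between two partitions
#' (Hubert-Arabie). 1 for identical partitions (up to label permutation),
#' about 0 for independent ones.
#'
#' @param a,b Label vectors of equal length (any atomic type).
#' @return A number in `[-1, 1]`.
#' @export
ari <- function(a, b) {
  .check_labels(a, b)
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# expected mutual information under the permutation (hypergeometric) model
.emi <- function(a_marg, b_marg, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (ai in a_marg) {
    for (bj in b_marg) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      logp <- lgamma(ai + 1) + lgamma(bj + 1) +
        lgamma(n - ai + 1) + lgamma(n - bj + 1) -
        lgn - lgamma(nij + 1) - lgamma(ai - nij + 1) -
        lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum(nij / n * log(n * nij / (ai * bj)) * exp(logp))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information between two partitions, corrected by its expectation
#' under random permutations of the labels and normalized by the arithmetic
#' mean of the two entropies: `(MI - E[MI]) / (mean(H_a, H_b) - E[MI])`.
#'
#' @inheritParams ari
#' @return A number `<= 1`; 1 for identical partitions, about 0 for
#'   independent ones.
#' @export
ami <- function(a, b) {
  .check_labels(a, b)
  tab <- table(a, b)
  n <- sum(tab)
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  ha <- .entropy(pa); hb <- .entropy(pb)
  if (ha == 0 && hb == 0) return(1)
  p <- tab / n
  nzi <- which(tab > 0, arr.ind = TRUE)
  mi <- sum(p[nzi] * log(p[nzi] / (pa[nzi[, 1L]] * pb[nzi[, 2L]])))
  emi <- .emi(rowSums(tab), colSums(tab), n)
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < .Machine$double.eps) denom <- .Machine$double.eps
  (mi - emi) / denom
}

#' V-measure
#'
#' Harmonic mean (beta = 1) of homogeneity (`1 - H(a|b)/H(a)`) and
#' completeness (`1 - H(b|a)/H(b)`).
#'
#' @inheritParams ari
#' @return A number in `[0, 1]`.
#' @export
v_measure <- function(a, b) {
  .check_labels(a, b)
  tab <- table(a, b)
  n <- sum(tab)
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  ha <- .entropy(pa); hb <- .entropy(pb)
  p <- tab / n
  nzi <- which(tab > 0, arr.ind = TRUE)
  mi <- sum(p[nzi] * log(p[nzi] / (pa[nzi[, 1L]] * pb[nzi[, 2L]])))
  hom <- if (ha == 0) 1 else mi / ha        # 1 - H(a|b)/H(a) = MI/H(a)
  com <- if (hb == 0) 1 else mi / hb
  if (hom + com == 0) return(0)
  2 * hom * com / (hom + com)
}

#' Absolute log-modulus of a cluster-count error
#'
#' `L(x) = |sign(x) * log10(|x| + 1)|` with `x = n_found - n_true`: 0 means the
#' estimated number of clusters is exactly right, 1 means off by 9, 2 off by
#' 99, symmetric in over- and under-estimation.
#'
#' @param n_found Estimated number of clusters.
#' @param n_true True number of classes (>= 1).
#' @return A non-negative number.
#' @export
log_modulus <- function(n_found, n_true) {
  if (n_true < 1) stop("n_true must be >= 1")
  x <- n_found - n_true
  abs(sign(x) * log10(abs(x) + 1))
}
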