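# Shared fixture builders for the test suite. Everything is generated in code
# under fixed seeds; nothing is read from disk.

# Gaussian blobs directly in a latent-like space (skips the autoencoders).
make_blobs <- function(n = 60, d = 5, k = 3, sep = 8, sd = 1, seed = 1) {
  set.seed(seed)
  labels <- sort(rep_len(seq_len(k), n))
  centers <- matrix(rnorm(k * d), k, d)
  centers <- centers / sqrt(rowSums(centers^2)) * sep
  x <- centers[labels, ] + matrix(rnorm(n * d, sd = sd), n, d)
  rownames(x) <- paste0("cell_", seq_len(n))
  list(x = x, labels = labels)
}

# A block-diagonal affinity matrix with c blocks of random positive weights.
make_block_affinity <- function(sizes, seed = 1, within = c(0.5, 1)) {
  set.seed(seed)
  m <- sum(sizes)
  A <- matrix(0, m, m)
  at <- 0L
  for (s in sizes) {
    idx <- at + seq_len(s)
    blk <- matrix(runif(s * s, within[1], within[2]), s, s)
    blk <- (blk + t(blk)) / 2
    A[idx, idx] <- blk
    at <- at + s
  }
  diag(A) <- 0
  A
}

# Independent brute-force eigengap: dense full spectrum + the package's
# published selection rule re-derived from scratch.
brute_eigengap_k <- function(A, i_min = 2, i_max = 15) {
  diag(A) <- 0
  L <- diag(rowSums(A)) - A
  ev <- sort(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  gi <- i_min:i_max
  gaps <- ev[gi + 1] - ev[gi]
  floor_tol <- 1e-9 * max(1, abs(ev[i_max + 1]))
  pos <- which(gaps > floor_tol)
  if (length(pos) == 0) return(i_min)
  ord <- pos[order(-gaps[pos])]
  k <- gi[ord[1]]
  if (length(ord) >= 2 && gaps[ord[2]] >= 0.5 * gaps[ord[1]])
    k <- min(k, gi[ord[2]])
  k
}


# Pair-counting ARI by explicit enumeration over all pairs (O(n^2) oracle).
brute_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- s11 + s00 + s10 + s01
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  if (max_idx == exp_idx) return(1)
  (s11 - exp_idx) / (max_idx - exp_idx)
}

# Information-theoretic oracles built directly from definitions with exact
# hypergeometric expectations (choose(), small n only).
brute_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

brute_mi <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (u in unique(a)) for (v in unique(b)) {
    nij <- sum(a == u & b == v)
    if (nij == 0) next
    mi <- mi + nij / n * log(n * nij / (sum(a == u) * sum(b == v)))
  }
  mi
}

brute_emi <- function(a, b) {
  n <- length(a)
  av <- as.integer(table(a)); bv <- as.integer(table(b))
  emi <- 0
  for (ai in av) for (bj in bv) {
    for (nij in max(1, ai + bj - n):min(ai, bj)) {
      p <- choose(bj, nij) * choose(n - bj, ai - nij) / choose(n, ai)
      emi <- emi + p * nij / n * log(n * nij / (ai * bj))
    }
  }
  emi
}

brute_ami <- function(a, b) {
  ha <- brute_entropy(a); hb <- brute_entropy(b)
  if (ha == 0 && hb == 0) return(1)
  emi <- brute_emi(a, b)
  (brute_mi(a, b) - emi) / ((ha + hb) / 2 - emi)
}

brute_v <- function(a, b) {
  ha <- brute_entropy(a); hb <- brute_entropy(b)
  mi <- brute_mi(a, b)
  hom <- if (ha == 0) 1 else mi / ha
  com <- if (hb == 0) 1 else mi / hb
  if (hom + com == 0) return(0)
  2 * hom * com / (hom + com)
}
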