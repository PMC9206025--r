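# Eigengap-based cluster-number estimation and spectral partitioning.
#
# Small graphs use a dense LAPACK eigensolve; larger graphs use ARPACK
# (via igraph) on the shifted operator c*I - L so the smallest Laplacian
# eigenvalues become the largest algebraic ones.

.as_affinity <- function(P) {
  if (inherits(P, "fused_network")) P <- P$P
  if (methods::is(P, "Matrix")) return(P)
  as.matrix(P)
}

# smallest `nev` eigenvalues (ascending) of L = D - A, plus vectors if asked
.laplacian_smallest <- function(A, nev, vectors = FALSE, dense_cutoff = 1000L) {
  m <- nrow(A)
  dg <- Matrix::rowSums(A)
  if (m <= dense_cutoff) {
    L <- diag(dg) - as.matrix(A)
    e <- eigen(L, symmetric = TRUE)
    idx <- m:(m - nev + 1L)
    return(list(values = e$values[idx],
                vectors = if (vectors) e$vectors[, idx, drop = FALSE]))
  }
  cshift <- 2 * max(dg) + 1
  fn <- function(x, extra) as.numeric(cshift * x - dg * x + A %*% x)
  ar <- igraph::arpack(fn, sym = TRUE,
                       options = list(n = m, nev = nev,
                                      ncv = min(m, max(2L * nev + 10L, 40L)),
                                      which = "LA", maxiter = 5000L))
  ord <- order(ar$values, decreasing = TRUE)   # largest shifted = smallest L
  list(values = cshift - ar$values[ord],
       vectors = if (vectors) ar$vectors[, ord, drop = FALSE])
}

#' Estimate the number of clusters with the eigengap heuristic
#'
#' Forms the unnormalized graph Laplacian `L = D - A` of the fused network
#' (diagonal zeroed), computes its smallest `i_max + 1` eigenvalues, and
#' inspects the gaps `eigengap_i = lambda_{i+1} - lambda_i` for
#' `i in [i_min, i_max]`. Gaps at or below a relative noise floor (1e-9) are
#' discarded as carrying no evidence. Among the remaining gaps the two largest
#' are located; when they are comparable (the smaller one at least half the
#' larger) the smaller index of the two is chosen, guarding against
#' overestimating the number of clusters, and otherwise the index of the
#' dominant gap wins — a second-ranked gap many times smaller than the
#' dominant one is not treated as competing evidence. For a graph with c
#' connected components the zero eigenvalue has multiplicity c, so the
#' dominant gap sits at i = c and the rule recovers c exactly.
#'
#' @param P A `"fused_network"`, or any symmetric non-negative affinity matrix.
#' @param i_min,i_max Range of candidate cluster counts (defaults 2 and 15).
#' @param dense_cutoff Matrix sizes up to this use a dense full eigensolve.
#' @return List of class `"eigengap"`: `values` (the `i_max + 1` smallest
#'   Laplacian eigenvalues, ascending), `gaps` (named by i), and the chosen `k`.
#' @export
eigengap_k <- function(P, i_min = 2L, i_max = 15L, dense_cutoff = 1000L) {
  A <- .as_affinity(P)
  m <- nrow(A)
  if (m <= i_max) stop("need more than i_max = ", i_max, " cells (have ", m, ")")
  if (i_min < 1L || i_min > i_max) stop("invalid [i_min, i_max] range")
  A <- A - Matrix::Diagonal(m, Matrix::diag(A))
  ev <- .laplacian_smallest(A, nev = i_max + 1L, dense_cutoff = dense_cutoff)$values
  ev <- sort(ev)                      # guard solver round-off ordering
  gi <- i_min:i_max
  gaps <- ev[gi + 1L] - ev[gi]
  names(gaps) <- gi
  k <- .choose_gap(gaps, floor_tol = 1e-9 * max(1, abs(ev[i_max + 1L])))
  structure(list(values = ev, gaps = gaps, k = as.integer(k),
                 i_min = as.integer(i_min), i_max = as.integer(i_max)),
            class = "eigengap")
}

# Gap-selection rule: drop gaps at/below the noise floor; locate the two
# largest remaining gaps (stable ordering, smaller index first on exact
# ties); prefer the smaller index when the runner-up gap is comparable
# (>= half the largest), otherwise the dominant gap's index wins. Falls
# back to the smallest candidate when every gap is noise.
.choose_gap <- function(gaps, floor_tol = 0) {
  gi <- as.integer(names(gaps))
  pos <- which(gaps > floor_tol)
  if (length(pos) == 0L) return(gi[1L])
  top <- pos[order(-gaps[pos])]
  k <- gi[top[1L]]
  if (length(top) >= 2L && gaps[top[2L]] >= 0.5 * gaps[top[1L]])
    k <- min(k, gi[top[2L]])
  k
}

#' Partition cells by spectral clustering of an affinity matrix
#'
#' Standard normalized spectral clustering: embeds the cells with the k
#' leading eigenvectors of `D^{-1/2} A D^{-1/2}` (equivalently the smallest
#' eigenvectors of the symmetric normalized Laplacian), normalizes the
#' embedding rows to unit length, and runs k-means with multiple restarts.
#'
#' @param P A `"fused_network"` or symmetric non-negative affinity matrix
#'   (dense or sparse).
#' @param k Number of clusters (>= 2).
#' @param seed Seed controlling the k-means initialization.
#' @param nstart k-means restarts (default 20; best inertia kept).
#' @param dense_cutoff Matrix sizes up to this use a dense eigensolve.
#' @return Integer vector of cluster labels in `1..k`, named by cell ids when
#'   the affinity has dimnames.
#' @export
spectral_partition <- function(P, k, seed = 1L, nstart = 20L,
                               dense_cutoff = 1000L) {
  A <- .as_affinity(P)
  m <- nrow(A)
  if (k < 2L) stop("k must be >= 2")
  if (k > m) stop("k cannot exceed the number of cells")
  A <- A - Matrix::Diagonal(m, Matrix::diag(A))
  dg <- pmax(Matrix::rowSums(A), 1e-12)
  dh <- 1 / sqrt(dg)
  if (m <= dense_cutoff) {
    Mn <- as.matrix(A) * outer(dh, dh)
    U <- eigen(Mn, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  } else {
    fn <- function(x, extra) as.numeric(dh * (A %*% (dh * x)))
    ar <- igraph::arpack(fn, sym = TRUE,
                         options = list(n = m, nev = k,
                                        ncv = min(m, max(2L * k + 10L, 40L)),
                                        which = "LA", maxiter = 5000L))
    U <- ar$vectors[, order(ar$values, decreasing = TRUE), drop = FALSE]
  }
  rn <- sqrt(rowSums(U * U))
  rn[rn <= 0] <- 1
  U <- U / rn
  set.seed(seed)
  km <- tryCatch(
    stats::kmeans(U, centers = k, nstart = nstart, iter.max = 100L),
    error = function(e) {
      # degenerate embeddings (fewer distinct rows than k): deterministic jitter
      set.seed(seed)
      Uj <- U + matrix(stats::rnorm(length(U), sd = 1e-8), nrow(U))
      stats::kmeans(Uj, centers = k, nstart = nstart, iter.max = 100L)
    })
  labels <- as.integer(km$cluster)
  names(labels) <- rownames(A)
  labels
}
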