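#' Build a cell-similarity network from a latent matrix
#'
#' Computes the locally-scaled Gaussian affinity used by similarity network
#' fusion. With `rho_ij` the Euclidean distance between cells i and j, and
#' `rho_i` the mean distance from cell i to its `k` nearest neighbors
#' (self excluded), the bandwidth is `eps_ij = (rho_ij + rho_i + rho_j) / 3`
#' and the edge weight is
#' `W_ij = exp(-rho_ij^2 / (mu * eps_ij))`.
#' The local bandwidth makes the kernel adaptive to differing cluster
#' densities; the denominator is floored at `1e-12` so fully coincident
#' point sets stay defined (exact otherwise).
#'
#' @param latent Cells x d numeric matrix (one latent realization).
#' @param k Number of nearest neighbors defining the local scale (default 30).
#' @param mu Bandwidth multiplier of the kernel (default 0.5).
#' @return A list of class `"affinity"` with `W` (m x m symmetric matrix in
#'   `(0, 1]`) and `k`.
#' @export
affinity_matrix <- function(latent, k = 30L, mu = 0.5) {
  latent <- as.matrix(latent)
  m <- nrow(latent)
  if (m <= k) stop("number of cells (", m, ") must exceed k (", k, ")")
  D <- as.matrix(stats::dist(latent))
  # mean distance to the k nearest neighbors (self excluded)
  rho <- as.numeric(.knn_mean_dist(D, as.integer(k)))
  eps <- (D + outer(rho, rep(1, m)) + outer(rep(1, m), rho)) / 3
  # clamp the exponent so extreme outliers underflow to a tiny positive
  # weight instead of exactly zero (which would isolate the vertex)
  W <- exp(pmax(-(D * D) / pmax(mu * eps, 1e-12), -700))
  dimnames(W) <- dimnames(D)
  structure(list(W = W, k = as.integer(k)), class = "affinity")
}

#' Full and sparse transition kernels of a similarity network
#'
#' Normalizes an affinity matrix into the two row-stochastic kernels used by
#' the fusion iteration: the full kernel
#' `P[i, j] = W_ij / (2 * sum_{l != i} W_il)` off-diagonal with `P[i, i] = 1/2`,
#' and the sparse kernel `S[i, j] = W_ij / sum_{l in N_i} W_il` restricted to
#' the neighbor set `N_i` = the cell itself plus its `k` most similar
#' neighbors, zero elsewhere. Keeping the self-affinity in the sparse kernel
#' anchors each cell's identity across fusion rounds — without it repeated
#' diffusion leaks similarity mass across cluster boundaries and blurs the
#' spectrum the eigengap relies on. The sparse kernel carries the trusted
#' local structure during fusion; the full kernel carries the global state
#' being diffused.
#'
#' @param net An `"affinity"` object from [affinity_matrix()].
#' @return List of class `"kernel_pair"` with dense `P` and sparse `S`
#'   (`Matrix::dgCMatrix`), both rows summing to 1.
#' @export
transition_kernels <- function(net) {
  W <- net$W; k <- net$k
  m <- nrow(W)
  Wod <- W
  diag(Wod) <- 0                 # sum tiny off-diagonals without cancellation
  offsum <- rowSums(Wod)
  if (any(offsum <= 0)) {
    bad <- which(offsum <= 0)[1L]
    stop("isolated cell with no similarity mass: ",
         rownames(W)[bad] %||% bad)
  }
  P <- Wod / (2 * offsum)
  diag(P) <- 0.5
  # self plus the k most similar neighbors per row (ties by column order)
  nbm <- cbind(seq_len(m), .row_topk(W, as.integer(k)))
  ii <- rep(seq_len(m), each = k + 1L)
  jj <- as.integer(t(nbm))
  xx <- W[cbind(ii, jj)]
  norm <- rep(rowsum(xx, ii)[, 1L], each = k + 1L)
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx / norm, dims = c(m, m),
                            dimnames = dimnames(W))
  structure(list(P = P, S = S), class = "kernel_pair")
}

#' Fuse per-latent similarity networks
#'
#' Iterative cross-diffusion of the full kernels through the sparse kernels:
#' at every round each view `v` is replaced by
#' `P(v) <- S(v) %*% mean_{k != v}(P(k)) %*% t(S(v))`
#' using the previous round's states for all views, after which each updated
#' matrix is symmetrized and its rows renormalized to sum to 1 (numerical
#' stabilization). Iteration stops after `t_iter` rounds or when the largest
#' entry-wise change across views drops below `tol`. The final network is the
#' arithmetic mean over views, symmetrized.
#'
#' @param kernels List (one per latent realization) of `"kernel_pair"` objects.
#' @param t_iter Maximum number of fusion rounds (default 20).
#' @param tol Early-stopping tolerance on the maximum change (default 1e-6).
#' @return List of class `"fused_network"` with the consolidated matrix `P`,
#'   `n_views`, and the number of `iterations` performed.
#' @export
fuse_networks <- function(kernels, t_iter = 20L, tol = 1e-6) {
  V <- length(kernels)
  if (V < 2L) stop("need at least 2 views to fuse")
  dims <- vapply(kernels, function(kp) nrow(kp$P), 0L)
  if (length(unique(dims)) != 1L) stop("views have mismatched dimensions")
  dn <- dimnames(kernels[[1L]]$P)
  P <- lapply(kernels, `[[`, "P")
  S <- lapply(kernels, `[[`, "S")
  St <- lapply(S, Matrix::t)
  kernels <- NULL              # round-0 state lives on only through P/S
  iters <- 0L
  for (it in seq_len(t_iter)) {
    total <- Reduce(`+`, P)
    newP <- vector("list", V)
    delta <- 0
    for (v in seq_len(V)) {
      Pbar <- (total - P[[v]]) / (V - 1)
      res <- .fuse_step(S[[v]]@p, S[[v]]@i, S[[v]]@x,
                        St[[v]]@p, St[[v]]@i, St[[v]]@x, Pbar, P[[v]])
      rm(Pbar)
      delta <- max(delta, res$delta)
      newP[[v]] <- res$P
    }
    rm(total)
    P <- newP
    rm(newP)
    gc(FALSE)
    iters <- it
    if (delta < tol) break
  }
  fused <- Reduce(`+`, P) / V
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- dn
  structure(list(P = fused, n_views = V, iterations = iters),
            class = "fused_network")
}
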