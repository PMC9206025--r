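# Large-dataset path: cluster a random training sample, pick the most
# representative latent space by weighted meta-clustering agreement, then
# propagate labels to the remaining cells with kNN classification.

#' Split cells into a training sample and a held-out remainder
#'
#' @param n Total number of cells (must exceed `threshold`).
#' @param threshold Training sample size (default 5000).
#' @param seed Seed for the uniform sample without replacement.
#' @return List of class `"cell_split"` with sorted `train` and `test` index
#'   vectors (disjoint, covering `1:n`).
#' @export
split_cells <- function(n, threshold = 5000L, seed = 1L) {
  if (n <= threshold)
    stop("n (", n, ") does not exceed the training threshold (", threshold,
         "); use the standard (non-sampling) clustering path")
  set.seed(seed)
  train <- sort(sample.int(n, threshold))
  structure(list(train = train, test = setdiff(seq_len(n), train),
                 seed = seed), class = "cell_split")
}

# union-symmetrized kNN adjacency (0/1), made connected if needed by adding
# the shortest available edge between components
.knn_graph <- function(x, k) {
  m <- nrow(x)
  k <- min(k, m - 1L)
  D <- as.matrix(stats::dist(x))
  nb <- .row_topk(-D, as.integer(k))        # k smallest distances per row
  ii <- rep(seq_len(m), each = k)
  jj <- as.integer(t(nb))
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                            dims = c(m, m), use.last.ij = TRUE)
  A@x[] <- 1
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = NULL, diag = FALSE)
  comp <- igraph::components(g)
  while (comp$no > 1L) {
    message("kNN graph disconnected (", comp$no,
            " components); bridging nearest components")
    c1 <- which(comp$membership == 1L)
    rest <- which(comp$membership != 1L)
    sub <- D[c1, rest, drop = FALSE]
    w <- arrayInd(which.min(sub), dim(sub))
    i <- c1[w[1L]]; j <- rest[w[2L]]
    A[i, j] <- 1; A[j, i] <- 1
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = NULL, diag = FALSE)
    comp <- igraph::components(g)
  }
  A
}

#' Cluster each latent realization independently via kNN spectral clustering
#'
#' For every latent matrix, builds a symmetrized k-nearest-neighbor graph and
#' partitions it into `k_clusters` groups by spectral clustering. Disconnected
#' graphs are bridged by their nearest inter-component edge (with a message).
#'
#' @param latents A `"latent_set"` (or plain list of cells x d matrices).
#' @param k_clusters Number of clusters for every latent.
#' @param k_neighbors Graph neighborhood size (default 30).
#' @param seed Seed; latent r uses `seed + r` for its k-means stage.
#' @return List of integer label vectors, one per latent.
#' @export
knn_spectral_labels <- function(latents, k_clusters, k_neighbors = 30L,
                                seed = 1L) {
  lapply(seq_along(latents), function(r) {
    A <- .knn_graph(as.matrix(latents[[r]]), k_neighbors)
    spectral_partition(A, k_clusters, seed = seed + r)
  })
}

#' Weighted meta-clustering of replicate label vectors
#'
#' Consensus over clusterings of the same cells. For each cell pair,
#' `s_ij` is the fraction of replicates in which the cells co-cluster and
#' `w_ij = s_ij (1 - s_ij)` scores the pair's co-clustering uncertainty
#' (0 for pairs the replicates agree on, maximal 0.25 at `s = 0.5`). Taking C
#' as the union of all clusters from all replicates, a `|C| x |C|`
#' cluster-cluster similarity matrix is formed as the weighted mean of `s_ij`
#' over cell pairs spanning the two clusters, with pair weights `w_ij + 0.1`
#' so uncertain pairs count more while fully-agreed replicates (all weights
#' zero) still yield the plain mean co-clustering chance. This matrix is cut
#' into `k_clusters` meta-clusters by average-linkage
#' hierarchical clustering, and each cell votes with its replicate memberships;
#' its final label is the meta-cluster winning the majority (ties toward the
#' lowest meta-cluster id). Meta-clusters left empty by the vote are dropped
#' and the labels renumbered (with a message).
#'
#' @param per_latent_labels List (length >= 2) of equal-length label vectors.
#' @param k_clusters Number of meta-clusters to cut.
#' @return Integer vector of final labels.
#' @export
wmetac <- function(per_latent_labels, k_clusters) {
  R <- length(per_latent_labels)
  if (R < 2L) stop("need at least 2 label vectors")
  n <- length(per_latent_labels[[1L]])
  if (any(vapply(per_latent_labels, length, 0L) != n))
    stop("label vectors cover different cells")
  s <- matrix(0, n, n)
  for (lab in per_latent_labels) {
    lab <- as.integer(factor(lab))
    s <- s + outer(lab, lab, "==")
  }
  s <- s / R
  w <- s * (1 - s)
  cell_weight <- rowSums(w)
  # membership matrix over the union of all replicate clusters
  Ms <- lapply(per_latent_labels, function(lab) {
    f <- factor(lab)
    m <- matrix(0, n, nlevels(f))
    m[cbind(seq_len(n), as.integer(f))] <- 1
    m
  })
  M <- do.call(cbind, Ms)
  wgt <- w + 0.1
  Sim <- crossprod(M, (wgt * s) %*% M) / crossprod(M, wgt %*% M)
  dd <- stats::as.dist(max(Sim) - Sim)
  hc <- stats::hclust(dd, method = "average")
  meta <- stats::cutree(hc, k = min(k_clusters, ncol(M)))
  votes <- matrix(0, n, max(meta))
  for (cl in seq_along(meta)) votes[, meta[cl]] <- votes[, meta[cl]] + M[, cl]
  final <- max.col(votes, ties.method = "first")
  used <- sort(unique(final))
  if (length(used) < ncol(votes))
    message("dropping ", ncol(votes) - length(used),
            " meta-cluster(s) that received no cells")
  final <- match(final, used)
  attr(final, "cell_weight") <- cell_weight
  final
}

#' Pick the latent realization most consistent with the consensus
#'
#' Computes the adjusted Rand index between the consensus labels and each
#' replicate labeling; returns the index of the maximum (ties toward the
#' lowest index).
#'
#' @param per_latent_labels List of replicate label vectors.
#' @param final_labels Consensus labels from [wmetac()].
#' @return Integer index of the best latent; the per-replicate ARIs are
#'   attached as attribute `"ari"`.
#' @export
select_best_latent <- function(per_latent_labels, final_labels) {
  aris <- vapply(per_latent_labels, function(lab) ari(final_labels, lab), 0)
  best <- which.max(aris)     # which.max returns the first (lowest) maximum
  attr(best, "ari") <- aris
  best
}

#' Propagate training labels to held-out cells by kNN classification
#'
#' Each held-out cell receives the majority label among its `k_classify`
#' nearest training cells (Euclidean distance in the chosen latent space);
#' majority ties fall back to the label of the single nearest neighbor.
#'
#' @param latent Cells x d matrix covering all n cells (the best latent).
#' @param split A `"cell_split"` from [split_cells()].
#' @param train_labels Integer labels for `split$train` (same order).
#' @param k_classify Neighborhood size (default 10; must not exceed the
#'   training size).
#' @return Integer labels for all n cells in original order.
#' @export
propagate_labels <- function(latent, split, train_labels, k_classify = 10L) {
  latent <- as.matrix(latent)
  tr <- split$train; te <- split$test
  if (length(train_labels) != length(tr))
    stop("train_labels must match the training indices")
  if (k_classify > length(tr))
    stop("k_classify (", k_classify, ") exceeds the training size (",
         length(tr), ")")
  train_labels <- as.integer(train_labels)
  xt <- latent[tr, , drop = FALSE]
  tnorm <- rowSums(xt * xt)
  out <- integer(nrow(latent))
  out[tr] <- train_labels
  chunk <- 1024L
  for (start in seq(1L, length(te), by = chunk)) {
    idx <- te[start:min(start + chunk - 1L, length(te))]
    xq <- latent[idx, , drop = FALSE]
    d2 <- outer(rowSums(xq * xq), tnorm, "+") - 2 * xq %*% t(xt)
    for (q in seq_along(idx)) {
      ord <- order(d2[q, ])[seq_len(k_classify)]
      tab <- tabulate(train_labels[ord])
      winners <- which(tab == max(tab))
      out[idx[q]] <- if (length(winners) == 1L) winners else train_labels[ord[1L]]
    }
  }
  names(out) <- rownames(latent)
  out
}
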