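#' Cluster single cells by autoencoder compression and network fusion
#'
#' Fits the full clustering pipeline to a normalized cells x genes expression
#' matrix:
#' \enumerate{
#'   \item conditional `log2(x + 1)` transform (applied when the data range
#'     exceeds 100) and per-cell min-max scaling to `[0, 1]`;
#'   \item gene filtering with a non-negative-kernel autoencoder
#'     ([score_genes_autoencoder()], [select_genes()]);
#'   \item compression into `n_latents` stochastic d-dimensional latent
#'     realizations with a variational autoencoder ([train_vae()],
#'     [sample_latents()]);
#'   \item for `n <= big_threshold` cells: per-latent similarity networks,
#'     full/sparse kernel fusion ([fuse_networks()]), eigengap estimation of
#'     the number of clusters ([eigengap_k()]) and spectral partitioning
#'     ([spectral_partition()]);
#'   \item for larger datasets: the same procedure on a random training
#'     sample of `big_threshold` cells, consensus over per-latent kNN spectral
#'     clusterings by weighted meta-clustering ([wmetac()]), selection of the
#'     most representative latent, and kNN label propagation to the remaining
#'     cells ([propagate_labels()]).
#' }
#'
#' One master `seed` drives every stochastic stage (stage r uses `seed + r`,
#' in the order: gene-filter AE, VAE, latent draws, k-means, sample split,
#' per-latent clustering), so a single integer reproduces the entire run.
#' Cells are never reordered: element i of the returned labels describes row i
#' of `x`.
#'
#' @param x Cells x genes matrix of non-negative normalized expression (dense
#'   or `Matrix` sparse). Row and column names are used as cell/gene ids and
#'   generated when missing.
#' @param k Number of clusters; `NULL` (default) estimates it with the
#'   eigengap heuristic over `[k_min, k_max]`.
#' @param seed Master seed (default 1).
#' @param n_genes Maximum number of genes kept by the filter (default 5000).
#' @param bottleneck Gene-filter autoencoder bottleneck width (default 50).
#' @param ae_epochs,ae_batch Gene-filter training schedule (defaults 30, 64).
#' @param latent_dim Latent dimensionality d (default 15).
#' @param n_latents Number of stochastic latent realizations (default 5).
#' @param vae_epochs,vae_batch,hidden VAE schedule and width (30, 128, 64).
#' @param k_neighbors Neighborhood size for kernels and kNN graphs (default 30;
#'   reduced to n - 1 on tiny inputs).
#' @param kernel_mu Similarity kernel bandwidth multiplier (default 0.5).
#' @param fusion_iters,fusion_tol Fusion rounds and early-stop tolerance
#'   (defaults 8, 1e-6).
#' @param k_min,k_max Eigengap search range (defaults 2, 15).
#' @param big_threshold Sample size above which the sampling + propagation
#'   path is used (default 5000).
#' @param k_classify kNN classifier neighborhood for label propagation
#'   (default 10).
#' @param kmeans_restarts k-means restarts in spectral partitioning (20).
#' @param verbose Print one line per stage.
#' @return An object of class `"scnf"`: a list with `cluster` (named integer
#'   labels, original cell order), `k`, `eigen` (the `"eigengap"` result),
#'   `gene_scores`, `selected_genes`, `path` (`"small"` or `"big"`),
#'   `big` (split, per-latent agreement and best-latent index; big path only),
#'   `vae`, `mu` (encoder means, used by [predict.scnf()]), `log2_applied`,
#'   `timings`, `params`, `call` and `seed`.
#' @seealso [predict.scnf()], [write_clusters()], [simulate_cells()]
#' @examples
#' sim <- simulate_cells(n_cells = 150, n_genes = 120, n_clusters = 3,
#'                       n_informative = 30, separation = 5, sparsity = 0.3,
#'                       seed = 42)
#' fit <- scnf(sim$matrix, bottleneck = 20, ae_epochs = 10, vae_epochs = 10,
#'             k_max = 8, seed = 42)
#' fit
#' ari(fit$cluster, sim$labels)
#' @export
scnf <- function(x, k = NULL, seed = 1L,
                 n_genes = 5000L, bottleneck = 50L,
                 ae_epochs = 30L, ae_batch = 64L,
                 latent_dim = 15L, n_latents = 5L,
                 vae_epochs = 30L, vae_batch = 128L, hidden = 64L,
                 k_neighbors = 30L, kernel_mu = 0.5,
                 fusion_iters = 8L, fusion_tol = 1e-6,
                 k_min = 2L, k_max = 15L,
                 big_threshold = 5000L, k_classify = 10L,
                 kmeans_restarts = 20L, verbose = FALSE) {
  cl <- match.call()
  if (is.null(rownames(x))) rownames(x) <- paste0("cell_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("gene_", seq_len(ncol(x)))
  validate_expression(x)
  n <- nrow(x)
  say <- function(...) if (verbose) message(...)
  tick <- function() proc.time()[["elapsed"]]
  timings <- c(); t0 <- tick()

  xd <- as.matrix(x)
  log2_applied <- (max(xd) - min(xd)) > 100
  xd <- conditional_log2(xd)
  xs <- minmax_scale(xd)
  timings["preprocess"] <- tick() - t0; t0 <- tick()
  say("preprocess: ", n, " cells x ", ncol(xs), " genes (log2: ", log2_applied, ")")

  bneck <- min(bottleneck, ncol(xs))
  scores <- score_genes_autoencoder(xs, bottleneck = bneck,
                                    epochs = ae_epochs, batch_size = ae_batch,
                                    seed = seed + 1L)
  xf <- select_genes(scores, xs, n_genes_target = n_genes)
  rm(xd, xs); gc(FALSE)
  timings["feature_selection"] <- tick() - t0; t0 <- tick()
  say("feature selection: kept ", ncol(xf), " genes")

  vae <- train_vae(xf, latent_dim = latent_dim, hidden = hidden,
                   epochs = vae_epochs, batch_size = vae_batch,
                   seed = seed + 2L)
  lat <- sample_latents(vae, xf, n_latents = n_latents, seed = seed + 3L)
  timings["latents"] <- tick() - t0; t0 <- tick()
  say("latents: ", n_latents, " realizations in ", latent_dim, " dims")

  big <- NULL
  if (n <= big_threshold) {
    path <- "small"
    knn <- min(k_neighbors, n - 1L)
    fused <- fuse_networks(
      lapply(lat, function(z)
        transition_kernels(affinity_matrix(z, k = knn, mu = kernel_mu))),
      t_iter = fusion_iters, tol = fusion_tol)
    gc(FALSE)
    timings["fusion"] <- tick() - t0; t0 <- tick()
    eig <- eigengap_k(fused, i_min = k_min, i_max = min(k_max, n - 1L))
    kk <- if (is.null(k)) eig$k else as.integer(k)
    labels <- spectral_partition(fused, kk, seed = seed + 4L,
                                 nstart = kmeans_restarts)
    timings["clustering"] <- tick() - t0
    say("small path: k = ", kk, " (eigengap ", eig$k, ")")
  } else {
    path <- "big"
    split <- split_cells(n, threshold = big_threshold, seed = seed + 5L)
    lat_tr <- lapply(lat, function(z) z[split$train, , drop = FALSE])
    knn <- min(k_neighbors, length(split$train) - 1L)
    fused <- fuse_networks(
      lapply(lat_tr, function(z)
        transition_kernels(affinity_matrix(z, k = knn, mu = kernel_mu))),
      t_iter = fusion_iters, tol = fusion_tol)
    gc(FALSE)
    timings["fusion"] <- tick() - t0; t0 <- tick()
    eig <- eigengap_k(fused, i_min = k_min,
                      i_max = min(k_max, length(split$train) - 1L))
    kk <- if (is.null(k)) eig$k else as.integer(k)
    rm(fused); gc(FALSE)
    per_lat <- knn_spectral_labels(lat_tr, kk, k_neighbors = knn,
                                   seed = seed + 6L)
    final_tr <- wmetac(per_lat, kk)
    best <- select_best_latent(per_lat, final_tr)
    labels <- propagate_labels(lat[[best]], split, final_tr,
                               k_classify = k_classify)
    big <- list(split = split, per_latent_ari = attr(best, "ari"),
                best_latent = as.integer(best),
                train_labels = as.integer(final_tr))
    timings["clustering"] <- tick() - t0
    say("big path: trained on ", length(split$train), " cells, k = ", kk,
        ", best latent ", best)
  }
  labels <- as.integer(labels)
  names(labels) <- rownames(x)
  structure(list(
    cluster = labels,
    k = length(unique(labels)),
    eigen = eig,
    gene_scores = scores,
    selected_genes = attr(xf, "selected"),
    path = path,
    big = big,
    vae = vae,
    mu = structure(.vae_encode(vae, xf)$mu, dimnames = list(rownames(x), NULL)),
    log2_applied = log2_applied,
    timings = timings,
    params = list(k = k, seed = seed, n_genes = n_genes, bottleneck = bneck,
                  ae_epochs = ae_epochs, ae_batch = ae_batch,
                  latent_dim = latent_dim, n_latents = n_latents,
                  vae_epochs = vae_epochs, vae_batch = vae_batch,
                  hidden = hidden, k_neighbors = k_neighbors,
                  kernel_mu = kernel_mu, fusion_iters = fusion_iters,
                  fusion_tol = fusion_tol, k_min = k_min, k_max = k_max,
                  big_threshold = big_threshold, k_classify = k_classify,
                  kmeans_restarts = kmeans_restarts),
    call = cl,
    seed = seed
  ), class = "scnf")
}

#' @export
print.scnf <- function(x, ...) {
  cat("Single-cell network-fusion clustering\n")
  cat("  cells:", length(x$cluster),
      " genes kept:", length(x$selected_genes), "\n")
  cat("  path:", x$path, " clusters:", x$k,
      if (is.null(x$params$k)) "(eigengap)" else "(user-set)", "\n")
  cat("  cluster sizes:", paste(table(x$cluster), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.scnf <- function(object, ...) {
  structure(list(fit = object), class = "summary.scnf")
}

#' @export
print.summary.scnf <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nEigengap (smallest Laplacian eigenvalues):\n")
  print(signif(f$eigen$values, 4))
  cat("gaps:\n")
  print(signif(f$eigen$gaps, 4))
  if (!is.null(f$big)) {
    cat("\nBig-data path: best latent", f$big$best_latent,
        "; per-latent consensus ARI:",
        paste(round(f$big$per_latent_ari, 3), collapse = " "), "\n")
  }
  cat("\nTimings (s):\n")
  print(round(f$timings, 2))
  invisible(x)
}

#' @export
fitted.scnf <- function(object, ...) object$cluster

#' Plot eigengap diagnostics for a fitted clustering
#'
#' Shows the smallest Laplacian eigenvalues of the fused network and the
#' gap profile from which the number of clusters was chosen.
#'
#' @param x A `"scnf"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.scnf <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ev <- x$eigen$values
  graphics::plot(seq_along(ev), ev, type = "b", xlab = "index",
                 ylab = "eigenvalue", main = "Laplacian spectrum", ...)
  graphics::abline(v = x$eigen$k + 0.5, lty = 2)
  graphics::barplot(x$eigen$gaps, xlab = "candidate k", ylab = "eigengap",
                    main = paste0("chosen k = ", x$eigen$k))
  invisible(x)
}

#' Classify new cells with a fitted clustering
#'
#' Embeds new cells with the fitted encoder (posterior means) after applying
#' the same preprocessing as in training (conditional log transform decision
#' frozen from the fit, per-cell min-max scaling, the fitted gene subset) and
#' assigns each to the majority cluster among its `k_classify` nearest
#' training cells in latent space.
#'
#' @param object A `"scnf"` fit.
#' @param newdata Cells x genes matrix; must contain the fitted genes.
#' @param k_classify Neighborhood size (defaults to the fitted value).
#' @param ... Unused.
#' @return Named integer vector of cluster labels for the new cells.
#' @export
predict.scnf <- function(object, newdata, k_classify = NULL, ...) {
  if (missing(newdata)) return(object$cluster)
  k_classify <- k_classify %||% object$params$k_classify
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$selected_genes, colnames(newdata))
  if (length(miss))
    stop("newdata is missing ", length(miss), " fitted genes")
  xd <- if (object$log2_applied) log2(newdata + 1) else newdata
  xs <- minmax_scale(xd)[, object$selected_genes, drop = FALSE]
  mu_new <- .vae_encode(object$vae, xs)$mu
  ref <- object$mu
  labs <- object$cluster
  k_classify <- min(k_classify, nrow(ref))
  d2 <- outer(rowSums(mu_new^2), rowSums(ref^2), "+") - 2 * mu_new %*% t(ref)
  out <- integer(nrow(mu_new))
  for (q in seq_len(nrow(mu_new))) {
    ord <- order(d2[q, ])[seq_len(k_classify)]
    tab <- tabulate(labs[ord])
    winners <- which(tab == max(tab))
    out[q] <- if (length(winners) == 1L) winners else labs[ord[1L]]
  }
  names(out) <- rownames(newdata)
  out
}

#' Write cluster labels to CSV
#'
#' Writes a two-column `cell_id,cluster` CSV in the original cell order;
#' byte-identical across runs with the same labels.
#'
#' @param fit A `"scnf"` object, or a named integer label vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(fit, path) {
  labels <- if (inherits(fit, "scnf")) fit$cluster else fit
  df <- data.frame(cell_id = names(labels) %||% seq_along(labels),
                   cluster = as.integer(labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
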