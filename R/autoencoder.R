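#' Score genes with a non-negative-kernel autoencoder
#'
#' Trains a 1-layer linear autoencoder whose encoder weights are constrained to
#' be non-negative (projected to `max(w, 0)` after every optimizer step), so
#' each bottleneck unit is a part-based, additive combination of genes. Genes
#' that contribute little to reconstruction have their encoder coefficients
#' shrunk to exactly zero by the projection; informative genes retain large,
#' variable coefficients. The per-gene variance of the encoder weight vector
#' across bottleneck units is the gene's score.
#'
#' @param x Cells x genes matrix scaled to `[0, 1]` (see [minmax_scale()]).
#' @param bottleneck Width of the compressed layer (default 50).
#' @param epochs Number of passes over the data (default 30).
#' @param batch_size Minibatch size (default 64).
#' @param lr Adam learning rate.
#' @param seed Integer seed; training is fully reproducible given the seed.
#' @return A `data.frame` of class `"gene_scores"` with columns `gene_id`,
#'   `coef_variance` (non-negative) and `nonzero` (any encoder weight above
#'   `1e-8` in magnitude). Attributes: `loss` (per-epoch mean reconstruction
#'   MSE), `min_weight_by_epoch` (most negative encoder weight observed after
#'   each epoch's projections; identically 0 up to float noise), `bottleneck`.
#' @examples
#' sim <- simulate_cells(n_cells = 60, n_genes = 30, n_clusters = 2,
#'                       n_informative = 6, seed = 1)
#' x <- minmax_scale(sim$matrix)
#' sc <- score_genes_autoencoder(x, bottleneck = 5, epochs = 5, seed = 1)
#' head(sc)
#' @export
score_genes_autoencoder <- function(x, bottleneck = 50L, epochs = 30L,
                                    batch_size = 64L, lr = 0.01, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x); g <- ncol(x)
  if (n < 2L) stop("need at least 2 cells")
  if (g < bottleneck) stop("number of genes (", g, ") must be >= bottleneck (", bottleneck, ")")
  set.seed(seed)
  h <- as.integer(bottleneck)
  sc <- sqrt(6 / (g + h))
  params <- list(
    We = matrix(stats::runif(g * h, 0, sc), g, h),   # non-negative init
    be = numeric(h),
    Wd = matrix(stats::runif(h * g, -sc, sc), h, g),
    bd = numeric(g)
  )
  opt <- .adam_init(params)
  loss_by_epoch <- numeric(epochs)
  minw_by_epoch <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    tot <- 0; nb <- 0L
    for (b in .batches(n, batch_size)) {
      xb <- x[b, , drop = FALSE]
      m <- length(b)
      hid <- xb %*% params$We
      hid <- sweep_add(hid, params$be)
      rec <- hid %*% params$Wd
      rec <- sweep_add(rec, params$bd)
      err <- rec - xb
      loss <- sum(err * err) / (m * g)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", ep, "; lower the learning rate")
      tot <- tot + loss; nb <- nb + 1L
      de <- 2 * err / (m * g)
      grads <- list(
        We = crossprod(xb, de %*% t(params$Wd)),
        be = colSums(de %*% t(params$Wd)),
        Wd = crossprod(hid, de),
        bd = colSums(de)
      )
      st <- .adam_step(params, grads, opt, lr = lr)
      params <- st$params; opt <- st$state
      params$We[params$We < 0] <- 0           # non-negativity projection
    }
    loss_by_epoch[ep] <- tot / nb
    minw_by_epoch[ep] <- min(params$We)
  }
  cv <- apply(params$We, 1L, stats::var)
  nz <- apply(abs(params$We) > 1e-8, 1L, any)
  out <- data.frame(
    gene_id = colnames(x) %||% paste0("gene_", seq_len(g)),
    coef_variance = cv,
    nonzero = nz,
    stringsAsFactors = FALSE
  )
  attr(out, "loss") <- loss_by_epoch
  attr(out, "min_weight_by_epoch") <- minw_by_epoch
  attr(out, "bottleneck") <- h
  class(out) <- c("gene_scores", class(out))
  out
}

#' Select informative genes from autoencoder scores
#'
#' Keeps genes with any non-zero encoder coefficient, ranked by coefficient
#' variance (descending), truncated to `n_genes_target`. Ties at the cutoff are
#' resolved by original column order (stable sort). The returned matrix keeps
#' the surviving columns in their original order.
#'
#' @param scores A `"gene_scores"` table from [score_genes_autoencoder()].
#' @param x The matrix the scores were computed on (cells x genes).
#' @param n_genes_target Maximum number of genes to keep (default 5000).
#' @return Cells x selected-genes matrix; attribute `selected` holds the kept
#'   gene ids (in original column order).
#' @export
select_genes <- function(scores, x, n_genes_target = 5000L) {
  x <- as.matrix(x)
  if (!identical(as.character(scores$gene_id),
                 as.character(colnames(x) %||% paste0("gene_", seq_len(ncol(x))))))
    stop("gene scores are not aligned with the matrix columns")
  cand <- which(scores$nonzero)
  if (length(cand) == 0L) stop("no genes with non-zero encoder coefficients; cannot proceed")
  ord <- cand[order(-scores$coef_variance[cand])]   # stable: ties keep column order
  keep <- sort(ord[seq_len(min(n_genes_target, length(ord)))])
  out <- x[, keep, drop = FALSE]
  attr(out, "selected") <- scores$gene_id[keep]
  out
}

# add a vector to every row of a matrix (bias broadcast)
sweep_add <- function(m, v) m + rep(v, each = nrow(m))
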