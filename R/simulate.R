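#' Simulate a cluster-structured single-cell expression matrix
#'
#' Generates non-negative continuous expression with planted cluster
#' structure: a set of informative (marker) genes is divided evenly among the
#' clusters, and a marker gene's mean is elevated by `separation` noise-SD
#' units in its own cluster. Non-informative genes are i.i.d. across clusters
#' with a common baseline. Values are drawn as `max(0, N(mean, 1))` and a
#' fraction `sparsity` of all entries is then zeroed uniformly at random,
#' emulating the high sparsity of droplet scRNA-seq. Informative genes are
#' placed at random column positions.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param n_clusters Number of planted cell groups (>= 2).
#' @param n_informative Number of marker genes (<= `n_genes`).
#' @param separation Cluster mean shift in noise-SD units (default 5).
#' @param sparsity Fraction of entries zeroed (in `[0, 1)`, default 0.6).
#' @param seed Integer seed; output is fully reproducible.
#' @return List of class `"sim_cells"`: `matrix` (cells x genes, named),
#'   `labels` (integer `1..n_clusters` per cell), `informative` (marker gene
#'   ids), and `params`.
#' @examples
#' sim <- simulate_cells(n_cells = 100, n_genes = 50, n_clusters = 3,
#'                       n_informative = 12, seed = 7)
#' table(sim$labels)
#' @export
simulate_cells <- function(n_cells = 2000L, n_genes = 2000L, n_clusters = 5L,
                           n_informative = 100L, separation = 5,
                           sparsity = 0.6, seed = 1L) {
  if (n_clusters < 2L) stop("n_clusters must be >= 2")
  if (n_cells < n_clusters) stop("n_cells must be >= n_clusters")
  if (n_informative > n_genes) stop("n_informative cannot exceed n_genes")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must be in [0, 1)")
  set.seed(seed)
  labels <- sample(rep_len(seq_len(n_clusters), n_cells))
  info_pos <- sort(sample.int(n_genes, n_informative))
  marker_of <- rep_len(seq_len(n_clusters), n_informative)
  mu <- matrix(1, n_cells, n_genes)              # baseline expression level
  for (j in seq_len(n_informative))
    mu[labels == marker_of[j], info_pos[j]] <- 1 + separation
  m <- matrix(pmax(stats::rnorm(n_cells * n_genes, mean = mu, sd = 1), 0),
              n_cells, n_genes)
  if (sparsity > 0) {
    nz <- round(sparsity * length(m))
    m[sample.int(length(m), nz)] <- 0
  }
  rownames(m) <- paste0("cell_", seq_len(n_cells))
  colnames(m) <- paste0("gene_", seq_len(n_genes))
  structure(list(matrix = m, labels = labels,
                 informative = colnames(m)[info_pos],
                 params = list(n_cells = n_cells, n_genes = n_genes,
                               n_clusters = n_clusters,
                               n_informative = n_informative,
                               separation = separation, sparsity = sparsity,
                               seed = seed)),
            class = "sim_cells")
}

#' Inject dropout events into an expression matrix
#'
#' Replaces exactly `round(rate * nnz)` of the non-zero entries (chosen
#' uniformly at random without replacement) with zeros; zero entries are never
#' touched. Exact-count sampling makes the realized dropout rate
#' deterministic.
#'
#' @param m Expression matrix with at least one non-zero entry.
#' @param rate Dropout rate, strictly between 0 and 1.
#' @param seed Integer seed.
#' @return Matrix of the same shape with reduced support.
#' @export
inject_dropout <- function(m, rate, seed = 1L) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate >= 1)
    stop("rate must be a single number strictly between 0 and 1")
  m <- as.matrix(m)
  nz <- which(m != 0)
  if (length(nz) == 0L) stop("matrix has no non-zero entries")
  set.seed(seed)
  n_drop <- round(rate * length(nz))
  if (n_drop > 0L) m[sample(nz, n_drop)] <- 0
  m
}
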