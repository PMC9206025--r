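# Latent sets for the sampling path built directly as noisy blob embeddings;
# the autoencoder stages have their own tests.
blob_latents <- function(n = 120, k = 3, n_lat = 3, sd = 0.5, seed = 1) {
  b <- make_blobs(n = n, d = 6, k = k, sep = 8, seed = seed)
  lat <- lapply(seq_len(n_lat), function(r) {
    set.seed(seed + 100 * r)
    b$x + matrix(rnorm(length(b$x), sd = sd), nrow(b$x))
  })
  list(latents = lat, labels = b$labels)
}

test_that("cell splitting is exact, disjoint and reproducible", {
  sp <- split_cells(6000, threshold = 5000, seed = 3)
  expect_length(sp$train, 5000L)
  expect_length(sp$test, 1000L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), 1:6000)
  expect_identical(split_cells(6000, 5000, seed = 3)$train, sp$train)
  expect_error(split_cells(5000, 5000), "standard")
})

test_that("per-latent kNN spectral clustering recovers blob structure", {
  fx <- blob_latents(seed = 2)
  labs <- knn_spectral_labels(fx$latents, 3, k_neighbors = 10, seed = 1)
  expect_length(labs, 3L)
  for (l in labs) expect_equal(ari(l, fx$labels), 1)
  # a pure-noise latent carries no signal
  set.seed(9)
  noise <- list(matrix(rnorm(120 * 6), 120, 6))
  ln <- knn_spectral_labels(noise, 3, k_neighbors = 10, seed = 1)
  expect_lt(abs(ari(ln[[1]], fx$labels)), 0.1)
})

test_that("wmetac reproduces unanimous labelings and majority splits", {
  base <- rep(1:2, each = 6)
  expect_equal(ari(wmetac(list(base, base, base), 2), base), 1)
  # 2 agreeing + 1 random labeling: consensus follows the majority
  set.seed(4)
  rnd <- sample(1:2, 12, replace = TRUE)
  fin <- wmetac(list(base, base, rnd), 2)
  expect_equal(ari(fin, base), 1)
  # s = 0.5 gives the maximal pair weight s(1-s) = 0.25
  s <- 0.5
  expect_equal(s * (1 - s), 0.25)
  expect_error(wmetac(list(base), 2), "at least 2")
  expect_error(wmetac(list(base, base[1:6]), 2), "different cells")
})

test_that("best-latent selection maximizes agreement with ties to the lowest index", {
  fx <- blob_latents(seed = 5)
  labs <- knn_spectral_labels(fx$latents, 3, k_neighbors = 10, seed = 2)
  fin <- wmetac(labs, 3)
  best <- select_best_latent(labs, fin)
  aris <- attr(best, "ari")
  expect_equal(as.integer(best), which.max(aris))
  # all-tie case
  tie <- select_best_latent(list(fin, fin, fin), fin)
  expect_equal(as.integer(tie), 1L)
  expect_equal(attr(tie, "ari"), rep(1, 3))
})

test_that("label propagation follows nearest training cells", {
  fx <- blob_latents(n = 150, seed = 7)
  sp <- split_cells(150, threshold = 90, seed = 2)
  truth <- fx$labels
  out <- propagate_labels(fx$latents[[1]], sp, truth[sp$train], k_classify = 10)
  expect_length(out, 150L)
  expect_identical(unname(out[sp$train]), as.integer(truth[sp$train]))
  expect_gte(ari(out, truth), 0.9)
  # coincident test cell with k = 1 copies its twin's label
  lat <- matrix(c(0, 0, 1, 1, 5, 5, 0, 0), 4, 2, byrow = TRUE)
  sp2 <- structure(list(train = 1:3, test = 4L), class = "cell_split")
  out2 <- propagate_labels(lat, sp2, c(1L, 2L, 3L), k_classify = 1)
  expect_equal(out2[4], 1L)
  # degenerate single training label
  out3 <- propagate_labels(lat, sp2, c(2L, 2L, 2L), k_classify = 3)
  expect_equal(out3[4], 2L)
  expect_error(propagate_labels(lat, sp2, c(1L, 2L, 3L), k_classify = 5),
               "exceeds")
})

test_that("threshold at or above n keeps the standard path and label order", {
  sim <- simulate_cells(n_cells = 150, n_genes = 100, n_clusters = 3,
                        n_informative = 30, separation = 5, sparsity = 0.3,
                        seed = 8)
  fit <- scnf(sim$matrix, seed = 2, bottleneck = 20, ae_epochs = 10,
              vae_epochs = 15, k_max = 8, big_threshold = 150)
  expect_equal(fit$path, "small")
  expect_identical(names(fit$cluster), rownames(sim$matrix))
})

test_that("big path covers every cell once, in input order, deterministically", {
  sim <- simulate_cells(n_cells = 400, n_genes = 120, n_clusters = 3,
                        n_informative = 30, separation = 5, sparsity = 0.3,
                        seed = 9)
  fit1 <- scnf(sim$matrix, seed = 5, bottleneck = 20, ae_epochs = 10,
               vae_epochs = 15, k_max = 8, big_threshold = 200)
  expect_equal(fit1$path, "big")
  expect_length(fit1$cluster, 400L)
  expect_identical(names(fit1$cluster), rownames(sim$matrix))
  expect_gte(ari(fit1$cluster, sim$labels), 0.9)
  fit2 <- scnf(sim$matrix, seed = 5, bottleneck = 20, ae_epochs = 10,
               vae_epochs = 15, k_max = 8, big_threshold = 200)
  expect_identical(fit1$cluster, fit2$cluster)
})
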