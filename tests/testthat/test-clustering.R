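test_that("disconnected cliques yield a zero eigenvalue per component and k = c", {
  A <- make_block_affinity(c(4, 4, 4), seed = 1, within = c(1, 1))  # 3 cliques
  eg <- eigengap_k(A, i_min = 2, i_max = 8)
  expect_lt(max(abs(eg$values[1:3])), 1e-10)
  expect_equal(eg$k, 3L)
})

test_that("equal maximal gaps resolve to the smaller candidate k", {
  gaps <- setNames(c(0.01, 0.02, 4, 0.05, 0.1, 0.03, 0.2, 4, 0.01, 0),
                   2:11)                      # maximal at i = 4 and i = 9
  expect_equal(scnf:::.choose_gap(gaps), 4L)
  # a dominant gap is not dragged down by a much smaller earlier gap
  gaps2 <- setNames(c(0.15, 0.01, 0.01, 0.84, 0.02, 0.01), 2:7)
  expect_equal(scnf:::.choose_gap(gaps2), 5L)
  # ... but a genuinely comparable earlier gap wins the guard
  gaps3 <- setNames(c(0.6, 0.01, 0.01, 0.84, 0.02, 0.01), 2:7)
  expect_equal(scnf:::.choose_gap(gaps3), 2L)
  # all-noise gaps fall back to the smallest candidate
  expect_equal(scnf:::.choose_gap(setNames(rep(0, 5), 2:6), floor_tol = 1e-9), 2L)
  # end-to-end contract on a clean clique graph
  A <- make_block_affinity(rep(3, 4), seed = 2, within = c(1, 1))   # 4 cliques
  eg <- eigengap_k(A, i_min = 2, i_max = 10)
  expect_equal(eg$k, 4L)
  expect_true(all(eg$gaps >= 0))
  expect_equal(as.integer(names(eg$gaps)), 2:10)
  expect_identical(eg$values, sort(eg$values))
})

test_that("eigengap matches a dense brute-force implementation on random graphs", {
  set.seed(99)
  for (case in 1:15) {
    A <- matrix(runif(900), 30, 30)
    A <- (A + t(A)) / 2
    eg <- eigengap_k(A, i_min = 2, i_max = 10)
    expect_equal(eg$k, brute_eigengap_k(A, 2, 10))
  }
})

test_that("partial (ARPACK) and dense eigensolves agree", {
  A <- make_block_affinity(c(40, 35, 45), seed = 5)
  eg_dense <- eigengap_k(A, i_max = 10, dense_cutoff = 1e6)
  eg_arpack <- eigengap_k(A, i_max = 10, dense_cutoff = 10)
  expect_equal(eg_dense$k, eg_arpack$k)
  expect_equal(eg_dense$values, eg_arpack$values, tolerance = 1e-7)
})

test_that("spectral partition recovers disconnected blocks exactly", {
  A <- make_block_affinity(c(10, 15), seed = 3)
  labels <- spectral_partition(A, 2, seed = 1)
  truth <- rep(1:2, c(10, 15))
  expect_equal(ari(labels, truth), 1)
  expect_error(spectral_partition(A, 1), ">= 2")
  expect_error(spectral_partition(A, 26), "exceed")
})

test_that("spectral partition is seed-deterministic and stable across seeds", {
  b <- make_blobs(n = 60, d = 4, k = 3, sep = 10, seed = 8)
  kerns <- lapply(1:3, function(v)
    transition_kernels(affinity_matrix(b$x + matrix(rnorm(240, sd = 0.1), 60, 4), k = 6)))
  fu <- fuse_networks(kerns)
  l1 <- spectral_partition(fu, 3, seed = 4)
  l2 <- spectral_partition(fu, 3, seed = 4)
  expect_identical(l1, l2)
  l3 <- spectral_partition(fu, 3, seed = 99)
  expect_gte(ari(l1, l3), 0.99)
  # invariance to cell order (up to label names)
  perm <- sample(60)
  kp <- lapply(1:3, function(v)
    transition_kernels(affinity_matrix((b$x + matrix(rnorm(240, sd = 0.1), 60, 4))[perm, ], k = 6)))
  # same fused matrix permuted is enough for the partition contract
  lp <- spectral_partition(fu$P[perm, perm], 3, seed = 4)
  expect_equal(ari(lp, l1[perm]), 1)
})

test_that("requesting more clusters than blocks still returns a full partition", {
  A <- make_block_affinity(c(12, 12), seed = 6, within = c(1, 1))
  labels <- spectral_partition(A, 4, seed = 2)
  expect_length(labels, 24L)
  expect_equal(sort(unique(labels)), 1:4)
})
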