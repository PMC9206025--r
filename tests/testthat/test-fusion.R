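test_that("3-point toy affinity matches the closed-form kernel", {
  # coordinates 0, 1, 10 with k = 1, mu = 0.5:
  # rho = (1, 1, 9); eps01 = 1, eps02 = 20/3, eps12 = 19/3
  net <- affinity_matrix(matrix(c(0, 1, 10), 3, 1), k = 1, mu = 0.5)
  W <- net$W
  expect_equal(W[1, 2], exp(-2), tolerance = 1e-12)
  expect_equal(W[1, 3], exp(-100 / (0.5 * 20 / 3)), tolerance = 1e-12)
  expect_equal(W[2, 3], exp(-81 / (0.5 * 19 / 3)), tolerance = 1e-12)
  expect_equal(W, t(W))
  expect_true(all(W > 0 & W <= 1))
  expect_equal(unname(diag(W)), rep(1, 3))  # coincident points: exp(0) = 1
})

test_that("kernel pair matches a hand-computed 4-cell table", {
  W <- rbind(c(1.0, 0.8, 0.4, 0.2),
             c(0.8, 1.0, 0.5, 0.3),
             c(0.4, 0.5, 1.0, 0.9),
             c(0.2, 0.3, 0.9, 1.0))
  kp <- transition_kernels(structure(list(W = W, k = 2L), class = "affinity"))
  P <- kp$P
  # off-diagonal W_ij / (2 * off-diagonal row sum), diagonal 1/2
  expect_equal(P[1, 2:4], c(0.8, 0.4, 0.2) / 2.8, tolerance = 1e-12)
  expect_equal(P[2, c(1, 3, 4)], c(0.8, 0.5, 0.3) / 3.2, tolerance = 1e-12)
  expect_equal(unname(diag(P)), rep(0.5, 4))
  expect_equal(unname(rowSums(P)), rep(1, 4), tolerance = 1e-12)
  S <- as.matrix(kp$S)
  # neighbor sets (k = 2 plus self): row 1 -> {1,2,3}, row 4 -> {4,3,2}
  expect_equal(S[1, ], c(1, 0.8, 0.4, 0) / 2.2, tolerance = 1e-12)
  expect_equal(S[4, ], c(0, 0.3, 0.9, 1) / 2.2, tolerance = 1e-12)
  expect_equal(unname(Matrix::rowSums(kp$S)), rep(1, 4), tolerance = 1e-12)
})

test_that("with k = m - 1 the sparse kernel equals the row-normalized affinity", {
  b <- make_blobs(n = 12, d = 3, k = 2, seed = 4)
  net <- affinity_matrix(b$x, k = nrow(b$x) - 1L, mu = 0.5)
  kp <- transition_kernels(net)
  expect_equal(as.matrix(kp$S), net$W / rowSums(net$W), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("kernel and fusion invariants hold on random latent sets", {
  set.seed(42)
  for (case in 1:20) {
    lat <- lapply(1:3, function(v) matrix(rnorm(40 * 4), 40, 4))
    kerns <- lapply(lat, function(z) transition_kernels(affinity_matrix(z, k = 5)))
    for (kp in kerns) {
      W <- NULL
      expect_equal(unname(rowSums(kp$P)), rep(1, 40), tolerance = 1e-8)
      expect_equal(unname(Matrix::rowSums(kp$S)), rep(1, 40), tolerance = 1e-8)
      expect_true(all(kp$P >= 0) && all(kp$S@x >= 0))
    }
    fused <- fuse_networks(kerns, t_iter = 5)
    expect_true(all(fused$P >= 0))
    expect_lt(max(abs(fused$P - t(fused$P))), 1e-8)
  }
})

test_that("affinity matrices are symmetric with entries in (0, 1]", {
  set.seed(11)
  for (case in 1:5) {
    z <- matrix(rnorm(30 * 3), 30, 3)
    W <- affinity_matrix(z, k = 4)$W
    expect_lt(max(abs(W - t(W))), 1e-10)
    expect_true(all(W > 0 & W <= 1))
  }
})

test_that("fusion is invariant to view order and equivariant to cell relabeling", {
  b <- make_blobs(n = 30, d = 4, k = 2, seed = 9)
  lat <- lapply(1:3, function(v) b$x + matrix(rnorm(120, sd = 0.1), 30, 4))
  kerns <- lapply(lat, function(z) transition_kernels(affinity_matrix(z, k = 5)))
  f1 <- fuse_networks(kerns, t_iter = 8)
  f2 <- fuse_networks(rev(kerns), t_iter = 8)
  expect_lt(max(abs(f1$P - f2$P)), 1e-10)

  perm <- sample(30)
  kp <- lapply(lat, function(z)
    transition_kernels(affinity_matrix(z[perm, , drop = FALSE], k = 5)))
  fp <- fuse_networks(kp, t_iter = 8)
  expect_lt(max(abs(fp$P - f1$P[perm, perm])), 1e-8)
})

test_that("identical views evolve exactly like a single-view diffusion oracle", {
  b <- make_blobs(n = 6, d = 2, k = 2, sep = 4, seed = 2)
  kp <- transition_kernels(affinity_matrix(b$x, k = 2))
  t_iter <- 4
  fused <- fuse_networks(list(kp, kp, kp), t_iter = t_iter, tol = 0)
  # oracle: plain dense matrix arithmetic, same per-round normalization
  P <- kp$P; S <- as.matrix(kp$S)
  for (it in seq_len(t_iter)) {
    Q <- S %*% P %*% t(S)
    Q <- (Q + t(Q)) / 2
    P <- Q / rowSums(Q)
  }
  P <- (P + t(P)) / 2
  expect_lt(max(abs(fused$P - P)), 1e-10)
})

test_that("two views cross-diffuse through each other", {
  b <- make_blobs(n = 8, d = 2, k = 2, seed = 3)
  kp1 <- transition_kernels(affinity_matrix(b$x, k = 2))
  kp2 <- transition_kernels(affinity_matrix(b$x + 0.1, k = 2))
  fused <- fuse_networks(list(kp1, kp2), t_iter = 1, tol = 0)
  # with n = 2 views the (n-1) denominator is 1: P1 <- S1 P2 S1^T etc.
  step <- function(S, Pother) {
    Q <- as.matrix(S) %*% Pother %*% t(as.matrix(S))
    Q <- (Q + t(Q)) / 2
    Q / rowSums(Q)
  }
  manual <- (step(kp1$S, kp2$P) + step(kp2$S, kp1$P)) / 2
  manual <- (manual + t(manual)) / 2
  expect_lt(max(abs(fused$P - manual)), 1e-10)
})

test_that("fused network of separated blobs is near block-diagonal", {
  b <- make_blobs(n = 40, d = 5, k = 2, sep = 10, seed = 6)
  lat <- lapply(1:3, function(v) b$x + matrix(rnorm(200, sd = 0.2), 40, 5))
  kerns <- lapply(lat, function(z) transition_kernels(affinity_matrix(z, k = 6)))
  fused <- fuse_networks(kerns)
  P <- fused$P; diag(P) <- 0
  same <- outer(b$labels, b$labels, "==") & upper.tri(P)
  diff <- (!outer(b$labels, b$labels, "==")) & upper.tri(P)
  expect_gt(mean(P[same]), 10 * mean(P[diff]))
})

test_that("fusion rejects degenerate inputs", {
  b <- make_blobs(n = 10, d = 2, k = 2, seed = 1)
  kp <- transition_kernels(affinity_matrix(b$x, k = 3))
  expect_error(fuse_networks(list(kp)), "at least 2")
  b2 <- make_blobs(n = 12, d = 2, k = 2, seed = 1)
  kp2 <- transition_kernels(affinity_matrix(b2$x, k = 3))
  expect_error(fuse_networks(list(kp, kp2)), "mismatched")
  expect_error(affinity_matrix(b$x, k = 10), "must exceed")
})
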