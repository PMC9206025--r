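#' Train a variational autoencoder on filtered expression data
#'
#' Fits a small VAE: encoder `g' -> hidden (ReLU) -> (mu, sigma)` with a
#' softplus link on `sigma`, decoder `d -> hidden (ReLU) -> g'` with a sigmoid
#' output. Because the inputs live in `[0, 1]`, the reconstruction term is the
#' binomial cross-entropy summed over genes (the standard likelihood for
#' unit-interval data, and strong enough that the KL regularizer does not
#' collapse the posterior on sparse expression data); the loss adds the
#' analytic KL divergence of `N(mu, sigma^2)` from `N(0, I)`.
#' The trained encoder is later sampled several times through
#' the reparameterization trick (`z = mu + sigma * eps`) to produce multiple
#' stochastic latent representations of the same cells ([sample_latents()]),
#' which downstream network fusion consolidates.
#'
#' @param x Cells x genes matrix in `[0, 1]` (typically [select_genes()] output).
#' @param latent_dim Latent dimensionality `d` (default 15).
#' @param hidden Hidden layer width (default 64).
#' @param epochs Training epochs (default 30).
#' @param batch_size Minibatch size (default 128).
#' @param lr Adam learning rate.
#' @param kl_weight Weight on the KL term (default 0.01; larger values favor
#'   the prior and can wash out cluster structure on sparse data).
#' @param seed Integer seed; training is reproducible given the seed.
#' @return An opaque encoder/decoder state of class `"scnf_vae"` with the
#'   per-epoch loss in `$loss`.
#' @export
train_vae <- function(x, latent_dim = 15L, hidden = 64L, epochs = 30L,
                      batch_size = 128L, lr = 1e-2, kl_weight = 0.01, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x); g <- ncol(x)
  if (n < 2L) stop("need at least 2 cells")
  if (latent_dim < 2L) stop("latent_dim must be >= 2")
  d <- as.integer(latent_dim); hdim <- as.integer(hidden)
  set.seed(seed)
  gl <- function(a, b) matrix(stats::rnorm(a * b, 0, sqrt(2 / (a + b))), a, b)
  params <- list(
    W1 = gl(g, hdim), b1 = numeric(hdim),
    Wm = gl(hdim, d), bm = numeric(d),
    Ws = gl(hdim, d), bs = numeric(d),
    W2 = gl(d, hdim), b2 = numeric(hdim),
    W3 = gl(hdim, g), b3 = numeric(g)
  )
  opt <- .adam_init(params)
  loss_by_epoch <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    tot <- 0; nb <- 0L
    for (b in .batches(n, batch_size)) {
      xb <- x[b, , drop = FALSE]
      m <- length(b)
      h1p <- sweep_add(xb %*% params$W1, params$b1)
      h1 <- pmax(h1p, 0)
      mu <- sweep_add(h1 %*% params$Wm, params$bm)
      sp <- sweep_add(h1 %*% params$Ws, params$bs)
      sg <- softplus(sp)
      eps <- matrix(stats::rnorm(m * d), m, d)
      z <- mu + sg * eps
      h2p <- sweep_add(z %*% params$W2, params$b2)
      h2 <- pmax(h2p, 0)
      yp <- sweep_add(h2 %*% params$W3, params$b3)
      y <- 1 / (1 + exp(-yp))
      yc <- pmin(pmax(y, 1e-7), 1 - 1e-7)
      bce <- -sum(xb * log(yc) + (1 - xb) * log(1 - yc))
      kl <- 0.5 * sum(mu * mu + sg * sg - 2 * log(sg) - 1)
      loss <- (bce + kl_weight * kl) / m
      if (!is.finite(loss))
        stop("non-finite VAE loss at epoch ", ep, "; lower the learning rate")
      tot <- tot + loss; nb <- nb + 1L
      # backprop; d(bce)/d(pre-activation) has the standard sigmoid form
      dyp <- (y - xb) / m
      dh2 <- dyp %*% t(params$W3)
      dh2p <- dh2 * (h2p > 0)
      dz <- dh2p %*% t(params$W2)
      dmu <- dz + kl_weight * mu / m
      dsg <- dz * eps + kl_weight * (sg - 1 / sg) / m
      dsp <- dsg / (1 + exp(-sp))     # d softplus = logistic
      dh1 <- dmu %*% t(params$Wm) + dsp %*% t(params$Ws)
      dh1p <- dh1 * (h1p > 0)
      grads <- list(
        W1 = crossprod(xb, dh1p), b1 = colSums(dh1p),
        Wm = crossprod(h1, dmu),  bm = colSums(dmu),
        Ws = crossprod(h1, dsp),  bs = colSums(dsp),
        W2 = crossprod(z, dh2p),  b2 = colSums(dh2p),
        W3 = crossprod(h2, dyp),  b3 = colSums(dyp)
      )
      st <- .adam_step(params, grads, opt, lr = lr)
      params <- st$params; opt <- st$state
    }
    loss_by_epoch[ep] <- tot / nb
  }
  structure(list(params = params, latent_dim = d, hidden = hdim,
                 n_genes = g, loss = loss_by_epoch, seed = seed),
            class = "scnf_vae")
}

#' @keywords internal
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# encoder forward pass: returns the posterior moments for every cell
.vae_encode <- function(state, x) {
  p <- state$params
  h1 <- pmax(sweep_add(as.matrix(x) %*% p$W1, p$b1), 0)
  list(mu = sweep_add(h1 %*% p$Wm, p$bm),
       sigma = softplus(sweep_add(h1 %*% p$Ws, p$bs)))
}

#' Draw multiple latent representations from a trained encoder
#'
#' Pushes the data through the encoder once to obtain `(mu, sigma)` per cell,
#' then draws `n_latents` independent realizations `z_r = mu + sigma * eps_r`
#' with fresh standard-normal `eps_r` seeded as `seed + r`. Each realization is
#' a cells x d matrix; the set of realizations is what network fusion operates
#' on.
#'
#' @param state A `"scnf_vae"` object from [train_vae()].
#' @param x The cells x genes matrix to embed (same gene set as training).
#' @param n_latents Number of stochastic realizations (default 5).
#' @param seed Base seed for the realization draws.
#' @return A list of class `"latent_set"` of `n_latents` matrices (cells x d),
#'   all with the same rownames as `x`.
#' @export
sample_latents <- function(state, x, n_latents = 5L, seed = 1L) {
  if (!inherits(state, "scnf_vae")) stop("state must come from train_vae()")
  if (n_latents < 1L) stop("n_latents must be >= 1")
  enc <- .vae_encode(state, x)
  out <- lapply(seq_len(n_latents), function(r) {
    set.seed(seed + r)
    eps <- matrix(stats::rnorm(length(enc$mu)), nrow(enc$mu), ncol(enc$mu))
    z <- enc$mu + enc$sigma * eps
    rownames(z) <- rownames(x)
    z
  })
  class(out) <- "latent_set"
  out
}
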