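# Parameter construction and small layer helpers for the equivariant backbone.
# Parameters live in a flat named list of plain matrices; during training each
# matrix is wrapped in a tape leaf, so the same forward code serves both modes.

lin_init <- function(d_in, d_out, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(1 / d_in)
  matrix(stats::rnorm(d_in * d_out, 0, scale), d_in, d_out)
}

zeros_init <- function(d_in, d_out) matrix(0, d_in, d_out)

bias_init <- function(d_out) matrix(0, 1L, d_out)

# y = silu(x W1 + b1) W2 + b2
mlp2 <- function(x, p, pr) {
  h <- ad_silu(ad_addvec(ad_matmul(x, p[[paste0(pr, ".W1")]]), p[[paste0(pr, ".b1")]]))
  ad_addvec(ad_matmul(h, p[[paste0(pr, ".W2")]]), p[[paste0(pr, ".b2")]])
}

mlp2_params <- function(d_in, d_hidden, d_out, pr, out_zero = FALSE) {
  out <- list(lin_init(d_in, d_hidden), bias_init(d_hidden),
              if (out_zero) zeros_init(d_hidden, d_out) else lin_init(d_hidden, d_out),
              bias_init(d_out))
  stats::setNames(out, paste0(pr, c(".W1", ".b1", ".W2", ".b2")))
}

# Gaussian radial basis expansion of a (pairs x 1) distance column.
# Centers uniform on [0, 10] A, width = center spacing.
rbf_expand <- function(dist, n_rbf) {
  centers <- seq(0, 10, length.out = n_rbf)
  width <- centers[2L] - centers[1L]
  dmat <- ad_matmul(dist, matrix(1, 1L, n_rbf))
  ad_exp(ad_scale(ad_sq(ad_addvec(dmat, -centers)), -1 / width^2))
}

# sinusoidal embedding of flow time t in [0, 1], as a 1 x 8 constant row
time_features <- function(t) {
  f <- 2^(0:3)
  matrix(c(sin(2 * pi * f * t), cos(2 * pi * f * t)), 1L)
}

# invariant per-channel norms of an equivariant feature list (3 matrices N x d)
equi_norms <- function(v, W = NULL) {
  comps <- if (is.null(W)) v else lapply(v, function(m) ad_matmul(m, W))
  ad_sqrt(ad_add(ad_add(ad_sq(comps[[1L]]), ad_sq(comps[[2L]])), ad_sq(comps[[3L]])),
          eps = 1e-8)
}

## ---- Adam optimizer ---------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  state$t <- state$t + 1L
  # global gradient-norm clipping
  gn <- sqrt(sum(vapply(grads, function(g) if (is.null(g)) 0 else sum(g^2), numeric(1))))
  sc <- if (gn > clip) clip / gn else 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- g * sc
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
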