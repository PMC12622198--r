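# Small numerical utilities shared across modules.

#' Derive a named substream seed from a master seed
#'
#' One global seed is fanned out to named substreams (data, init, sampling,
#' steering, per-record counters) so components are independently reproducible
#' and insertion order never changes a record.
#'
#' @param master Integer master seed.
#' @param name Stream name.
#' @param counter Optional record counter within the stream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(master, name, counter = 0L) {
  h <- sum(utf8ToInt(as.character(name)) * seq_along(utf8ToInt(as.character(name))))
  val <- (as.double(master) %% 2147483647) * 48271 + h * 69621 + as.double(counter) * 16807
  as.integer(val %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

# uniform random proper rotation (Haar measure via QR of a Gaussian matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  R <- qr.Q(qr_)
  d <- diag(sign(diag(qr.R(qr_))))
  R <- R %*% d
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

# rigid motion applied to an N x 3 coordinate matrix
apply_rigid <- function(coords, R, u = c(0, 0, 0)) {
  sweep(coords %*% t(R), 2L, -u)
}

#' Canonical pocket frame
#'
#' A rotation and origin determined by the pocket geometry alone: origin at the
#' atom centroid, axes the principal axes of the coordinate covariance, signs
#' fixed by the third moment of the projections (falling back to the first
#' nonzero component), handedness forced to det = +1. Sampling the noise prior
#' in this frame makes whole-pipeline generation equivariant: rigidly moving
#' the pocket moves generated ligands identically (same seed).
#'
#' @param coords M x 3 pocket coordinates.
#' @return List with `center` (length 3) and `rotation` (3 x 3, rows = axes).
#' @export
canonical_frame <- function(coords) {
  ctr <- colMeans(coords)
  xc <- sweep(coords, 2L, ctr)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  E <- ev$vectors
  for (a in 1:3) {
    pr <- xc %*% E[, a]
    m3 <- mean(pr^3)
    if (abs(m3) > 1e-8) {
      if (m3 < 0) E[, a] <- -E[, a]
    } else {
      nz <- which(abs(E[, a]) > 1e-8)[1L]
      if (length(nz) && E[nz, a] < 0) E[, a] <- -E[, a]
    }
  }
  if (det(E) < 0) E[, 3L] <- -E[, 3L]
  list(center = ctr, rotation = t(E))
}

#' Empirical Wasserstein-1 distance between two samples
#'
#' The area between the empirical quantile functions, computed exactly from
#' the pooled order statistics.
#'
#' @param x,y Numeric samples.
#' @return Nonnegative scalar (units of the inputs).
#' @export
wasserstein1 <- function(x, y) {
  x <- sort(x); y <- sort(y)
  grid <- sort(unique(c(x, y)))
  if (length(grid) < 2L) return(0)
  Fx <- stats::ecdf(x)(grid)
  Fy <- stats::ecdf(y)(grid)
  sum(abs(Fx - Fy)[-length(grid)] * diff(grid))
}

softmax_vec <- function(z) {
  z <- z - max(z)
  ez <- exp(z)
  ez / sum(ez)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pairwise Euclidean distance matrix between two coordinate sets
cross_distances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}
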