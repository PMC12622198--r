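# Reverse-mode automatic differentiation on dense matrices.
#
# Every operator works in two modes: called on plain matrices it just computes
# the value; called (under an active tape) on tape nodes it additionally records
# a backward closure. Network code is therefore written once and reused for
# training (taped) and sampling/prediction (plain, no recording overhead).
# Shapes are restricted to what the backbone needs: matrices, row-vector biases
# and scalars.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

#' @keywords internal
ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

#' Evaluate an expression while recording onto a tape
#' @keywords internal
with_tape <- function(tape, expr) {
  old <- .ad$tape
  .ad$tape <- tape
  on.exit(.ad$tape <- old)
  force(expr)
}

is_nd <- function(x) inherits(x, "adnode")

# value of a node or the object itself
vof <- function(x) if (is_nd(x)) x$val else x

nd_new <- function(val, parents = NULL, backfn = NULL) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  class(node) <- "adnode"
  tp <- .ad$tape
  if (!is.null(tp)) {
    tp$n <- tp$n + 1L
    if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    tp$nodes[[tp$n]] <- node
  }
  node
}

#' Create a differentiable leaf (parameter) on the active tape
#' @keywords internal
ad_leaf <- function(val) nd_new(val)

# record a result if any input is a node
ad_result <- function(val, inputs, backfn) {
  if (any(vapply(inputs, is_nd, logical(1)))) nd_new(val, inputs, backfn) else val
}

#' Backpropagate from a scalar loss node through a tape
#' @keywords internal
ad_backward <- function(tape, loss) {
  stopifnot(is_nd(loss))
  loss$grad <- 1
  for (k in seq(tape$n, 1L)) {
    node <- tape$nodes[[k]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    gs <- node$backfn(node$grad)
    ps <- node$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      if (!is_nd(p)) next
      g <- gs[[i]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

## ---- elementwise arithmetic -------------------------------------------------

ad_add <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ad_result(av + bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L && length(g) > 1L) sum(g) else g
    gb <- if (length(bv) == 1L && length(g) > 1L) sum(g) else g
    list(ga, gb)
  })
}

ad_sub <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ad_result(av - bv, list(a, b), function(g) {
    ga <- if (length(av) == 1L && length(g) > 1L) sum(g) else g
    gb <- if (length(bv) == 1L && length(g) > 1L) -sum(g) else -g
    list(ga, gb)
  })
}

ad_mul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ad_result(av * bv, list(a, b), function(g) {
    ga <- g * bv
    gb <- g * av
    if (length(av) == 1L && length(g) > 1L) ga <- sum(ga)
    if (length(bv) == 1L && length(g) > 1L) gb <- sum(gb)
    list(ga, gb)
  })
}

# multiply by a non-differentiated constant (matrix or scalar)
ad_scale <- function(a, s) {
  av <- vof(a)
  ad_result(av * s, list(a), function(g) list(g * s))
}

ad_neg <- function(a) ad_scale(a, -1)

## ---- linear algebra ---------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  ad_result(av %*% bv, list(a, b), function(g)
    list(g %*% t(bv), t(av) %*% g))
}

ad_t <- function(a) {
  av <- vof(a)
  ad_result(t(av), list(a), function(g) list(t(g)))
}

# add a row vector bias to every row of a matrix
ad_addvec <- function(a, b) {
  av <- vof(a); bv <- vof(b)
  val <- av + matrix(as.numeric(bv), nrow(av), length(bv), byrow = TRUE)
  ad_result(val, list(a, b), function(g)
    list(g, matrix(colSums(g), 1L)))
}

## ---- nonlinearities ---------------------------------------------------------

ad_sigmoid <- function(a) {
  av <- vof(a)
  s <- 1 / (1 + exp(-av))
  ad_result(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_silu <- function(a) {
  av <- vof(a)
  s <- 1 / (1 + exp(-av))
  ad_result(av * s, list(a), function(g) list(g * s * (1 + av * (1 - s))))
}

ad_relu <- function(a) {
  av <- vof(a)
  ad_result(pmax(av, 0), list(a), function(g) list(g * (av > 0)))
}

ad_tanh <- function(a) {
  av <- vof(a)
  th <- tanh(av)
  ad_result(th, list(a), function(g) list(g * (1 - th^2)))
}

ad_exp <- function(a) {
  av <- vof(a)
  ex <- exp(av)
  ad_result(ex, list(a), function(g) list(g * ex))
}

ad_sq <- function(a) {
  av <- vof(a)
  ad_result(av * av, list(a), function(g) list(2 * g * av))
}

ad_sqrt <- function(a, eps = 1e-12) {
  av <- vof(a)
  r <- sqrt(av + eps)
  ad_result(r, list(a), function(g) list(g / (2 * r)))
}

## ---- reductions -------------------------------------------------------------

ad_sum <- function(a) {
  av <- vof(a)
  ad_result(sum(av), list(a), function(g) list(array(g, dim(as.matrix(av)))))
}

ad_mean <- function(a) {
  av <- vof(a)
  n <- length(av)
  ad_result(sum(av) / n, list(a), function(g) list(array(g / n, dim(as.matrix(av)))))
}

# rowSums as an n x 1 column
ad_rsum <- function(a) {
  av <- vof(a)
  ad_result(matrix(rowSums(av), ncol = 1L), list(a), function(g)
    list(matrix(g, nrow(av), ncol(av))))
}

# colSums as a 1 x k row
ad_csum <- function(a) {
  av <- vof(a)
  ad_result(matrix(colSums(av), nrow = 1L), list(a), function(g)
    list(matrix(g, nrow(av), ncol(av), byrow = TRUE)))
}

## ---- structure ops ----------------------------------------------------------

ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, vof)
  ncols <- vapply(vals, ncol, integer(1))
  ends <- cumsum(ncols)
  starts <- c(1L, head(ends, -1L) + 1L)
  ad_result(do.call(cbind, vals), args, function(g)
    lapply(seq_along(args), function(i) g[, starts[i]:ends[i], drop = FALSE]))
}

ad_cols <- function(a, idx) {
  av <- vof(a)
  ad_result(av[, idx, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    ga[, idx] <- ga[, idx] + g
    list(ga)
  })
}

# gather rows (embedding lookup); idx may repeat
ad_gather <- function(a, idx) {
  av <- vof(a)
  idx <- as.integer(idx)
  ad_result(av[idx, , drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(av), ncol(av))
    acc <- rowsum(g, idx)
    ga[as.integer(rownames(acc)), ] <- acc
    list(ga)
  })
}

## ---- softmax family ---------------------------------------------------------

# row-wise softmax; `shift` (constant matrix, e.g. -Inf masking) is added first
ad_softmax_rows <- function(a, shift = NULL) {
  av <- vof(a)
  if (!is.null(shift)) av <- av + shift
  m <- apply(av, 1L, max)
  ex <- exp(av - m)
  p <- ex / rowSums(ex)
  ad_result(p, list(a), function(g)
    list(p * (g - rowSums(g * p))))
}

ad_logsoftmax_rows <- function(a) {
  av <- vof(a)
  m <- apply(av, 1L, max)
  ls <- av - m - log(rowSums(exp(av - m)))
  p <- exp(ls)
  ad_result(ls, list(a), function(g)
    list(g - p * rowSums(g)))
}

## ---- pairwise ops (flattened pair index p = (i-1)*Nk + j, j fastest) --------

pair_i <- function(nq, nk) rep(seq_len(nq), each = nk)
pair_j <- function(nq, nk) rep(seq_len(nk), times = nq)

reorder_rowsum <- function(m) {
  m <- m[order(as.integer(rownames(m))), , drop = FALSE]
  dimnames(m) <- NULL
  m
}

# D[p, f] = Q[i(p), f] - K[j(p), f]
ad_pairdiff <- function(q, k) {
  qv <- vof(q); kv <- vof(k)
  nq <- nrow(qv); nk <- nrow(kv)
  iq <- pair_i(nq, nk); jk <- pair_j(nq, nk)
  ad_result(qv[iq, , drop = FALSE] - kv[jk, , drop = FALSE], list(q, k), function(g)
    list(reorder_rowsum(rowsum(g, iq)), -reorder_rowsum(rowsum(g, jk))))
}

# P[p, f] = Q[i(p), f] * K[j(p), f]
ad_pairprod <- function(q, k) {
  qv <- vof(q); kv <- vof(k)
  nq <- nrow(qv); nk <- nrow(kv)
  iq <- pair_i(nq, nk); jk <- pair_j(nq, nk)
  ad_result(qv[iq, , drop = FALSE] * kv[jk, , drop = FALSE], list(q, k), function(g)
    list(reorder_rowsum(rowsum(g * kv[jk, , drop = FALSE], iq)),
         reorder_rowsum(rowsum(g * qv[iq, , drop = FALSE], jk))))
}

# out[i, ] = sum_j A[i, j] * M[p(i,j), ];  A is Nq x Nk, M is (Nq*Nk) x d
ad_attn_agg <- function(a, m) {
  av <- vof(a); mv <- vof(m)
  nq <- nrow(av); nk <- ncol(av)
  iq <- pair_i(nq, nk)
  w <- as.vector(t(av))
  ad_result(reorder_rowsum(rowsum(mv * w, iq)), list(a, m), function(g) {
    grows <- g[iq, , drop = FALSE]
    ga <- matrix(rowSums(grows * mv), nq, nk, byrow = TRUE)
    gm <- grows * w
    list(ga, gm)
  })
}

# elementwise reciprocal 1 / (a + eps)
ad_recip <- function(a, eps = 0) {
  av <- vof(a)
  r <- 1 / (av + eps)
  ad_result(r, list(a), function(g) list(-g * r * r))
}

# softmax over the key dimension of flattened pair logits: column h of
# `a` ((Nq*Nk) x H) becomes an Nq x Nk attention matrix normalized over j.
# Returns a list of H matrices.
ad_pair_softmax <- function(a, nq, nk) {
  av <- vof(a)
  lapply(seq_len(ncol(av)), function(h) {
    lg <- matrix(av[, h], nq, nk, byrow = TRUE)
    m <- apply(lg, 1L, max)
    ex <- exp(lg - m)
    p <- ex / rowSums(ex)
    ad_result(p, list(a), function(g) {
      gl <- p * (g - rowSums(g * p))          # grad wrt the Nq x Nk logits
      ga <- matrix(0, nrow(av), ncol(av))
      ga[, h] <- as.vector(t(gl))
      list(ga)
    })
  })
}

# broadcast per-row-of-A scalars across pair rows: out[p, f] = M[p, f] * s[i(p), 1]
ad_rowscale_pairs <- function(m, s, nq, nk) {
  mv <- vof(m); sv <- vof(s)
  iq <- pair_i(nq, nk)
  sc <- sv[iq, 1L]
  ad_result(mv * sc, list(m, s), function(g)
    list(g * sc, reorder_rowsum(rowsum(matrix(rowSums(g * mv), ncol = 1L), iq))))
}
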