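# The SE(3)-equivariant backbone: pairwise geometric features, attention
# update blocks with residual coordinate and RBF edge updates, the pocket
# encoder and the ligand decoder.
#
# Representation conventions: invariant node features are N x d matrices;
# equivariant features are lists of three N x d_equi matrices (x/y/z
# components), which keeps every channel operation a plain matrix product;
# pairwise tensors are flattened to (Nq*Nk) x d with pair index
# p = (i-1)*Nk + j. Invariant quantities entering messages are squared
# distances (S), cross-product magnitudes and Gaussian RBF distance
# expansions; equivariant updates are built exclusively from pairwise
# difference vectors, cross products and coordinate differences, which is what
# guarantees the SE(3) contract by construction.

#' Backbone architecture configuration
#'
#' Defaults are the desk-scale configuration used throughout this package.
#' The full-scale configuration from which it is shrunk (4 encoder / 12
#' decoder layers, invariant widths 256/384, 128 equivariant channels, latent
#' 64 with 32 heads, confidence depth 8) validates but is far too large to
#' train on one CPU.
#'
#' @param enc_layers,dec_layers Pocket-encoder and ligand-decoder depths.
#' @param d_inv_enc,d_inv_dec Invariant feature widths.
#' @param d_equi Equivariant channel count.
#' @param latent_size,attention_heads Attention latent width per head and
#'   number of heads.
#' @param rbf_count Gaussian radial basis functions (centers uniform on
#'   \[0, 10\] Angstrom, width = spacing).
#' @param d_edge Pairwise edge feature width.
#' @param d_msg Pairwise message width (default `latent_size * attention_heads`).
#' @param d_head Affinity-head pooled width.
#' @param confidence_depth Decoder depth at which the confidence head reads
#'   features (must be <= `dec_layers`).
#' @param n_lddt_bins lDDT bin count for the confidence head.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(enc_layers = 2L, dec_layers = 4L,
                            d_inv_enc = 64L, d_inv_dec = 96L,
                            d_equi = 16L, latent_size = 16L, attention_heads = 4L,
                            rbf_count = 16L, d_edge = 16L, d_msg = NULL,
                            d_head = 32L, confidence_depth = 3L, n_lddt_bins = 50L) {
  if (is.null(d_msg)) d_msg <- latent_size * attention_heads
  cfg <- list(enc_layers = as.integer(enc_layers), dec_layers = as.integer(dec_layers),
              d_inv_enc = as.integer(d_inv_enc), d_inv_dec = as.integer(d_inv_dec),
              d_equi = as.integer(d_equi), latent_size = as.integer(latent_size),
              attention_heads = as.integer(attention_heads),
              rbf_count = as.integer(rbf_count), d_edge = as.integer(d_edge),
              d_msg = as.integer(d_msg), d_head = as.integer(d_head),
              confidence_depth = as.integer(confidence_depth),
              n_lddt_bins = as.integer(n_lddt_bins))
  if (any(unlist(cfg) <= 0L)) stop("all backbone dimensions must be positive")
  if (cfg$confidence_depth > cfg$dec_layers)
    stop("confidence_depth must not exceed dec_layers")
  structure(cfg, class = "backbone_config")
}

# interaction-channel categories attached to pocket atoms (generative mode 2)
interaction_vocab <- c("none", "hbond_donor", "hbond_acceptor", "hydrophobic")

## ---- parameter construction -------------------------------------------------

block_param_set <- function(pr, d_q, d_kv, cfg) {
  de <- cfg$d_equi
  d_u <- 2L * de + 4L  # pairwise equivariant channels: D, C, 4 copies of dx
  msg_in <- d_q + d_kv + cfg$d_edge + cfg$rbf_count + 2L * de
  hl <- cfg$attention_heads * cfg$latent_size
  c(stats::setNames(list(lin_init(de, de), lin_init(de, de)),
                    paste0(pr, c(".Wqe", ".Wke"))),
    mlp2_params(msg_in, cfg$d_msg, cfg$d_msg, paste0(pr, ".msg")),
    stats::setNames(list(lin_init(cfg$d_msg, cfg$attention_heads), bias_init(cfg$attention_heads),
                         lin_init(cfg$d_msg, hl),
                         lin_init(hl, d_q, scale = 0.5 / sqrt(hl)), bias_init(d_q),
                         lin_init(cfg$d_msg, d_u), bias_init(d_u),
                         lin_init(d_u, de),
                         zeros_init(cfg$d_msg, cfg$attention_heads)),
                    paste0(pr, c(".Wa", ".ba", ".Wv", ".Wo", ".bo",
                                 ".Wg", ".bg", ".Wvm", ".Wx"))),
    mlp2_params(d_q, 2L * d_q, d_q, paste0(pr, ".ff"), out_zero = FALSE),
    mlp2_params(cfg$d_edge + cfg$d_msg + cfg$rbf_count, 2L * cfg$d_edge, cfg$d_edge,
                paste0(pr, ".edge")))
}

init_backbone_params <- function(cfg, vocab, seed = 1L) {
  with_seed(seed, {
    kt <- length(vocab$atom_types); kq <- length(vocab$charge_values)
    kh <- length(vocab$hybridizations); kb <- length(vocab$bond_orders)
    de <- cfg$d_equi; dd <- cfg$d_inv_dec; dp <- cfg$d_inv_enc
    p <- list()
    # pocket encoder input
    p[["emb.ptype"]] <- lin_init(kt, dp, 0.5)
    p[["emb.iflag"]] <- zeros_init(length(interaction_vocab), dp)
    p[["emb.pglob.W"]] <- lin_init(2L, dp)
    p[["emb.pedge.W"]] <- lin_init(cfg$rbf_count, cfg$d_edge)
    p[["emb.pedge.b"]] <- bias_init(cfg$d_edge)
    for (l in seq_len(cfg$enc_layers))
      p <- c(p, block_param_set(sprintf("enc%d", l), dp, dp, cfg))
    # ligand decoder input
    p[["emb.type"]] <- lin_init(kt, dd, 0.5)
    p[["emb.charge"]] <- lin_init(kq, dd, 0.5)
    p[["emb.hyb"]] <- lin_init(kh, dd, 0.5)
    p[["emb.bond"]] <- lin_init(kb, cfg$d_edge, 0.5)
    p[["emb.time.W"]] <- lin_init(8L, dd)
    p[["emb.time.b"]] <- bias_init(dd)
    p[["emb.sedge.W"]] <- lin_init(cfg$rbf_count, cfg$d_edge)
    p[["emb.sedge.b"]] <- bias_init(cfg$d_edge)
    p[["emb.cedge.W"]] <- lin_init(cfg$rbf_count, cfg$d_edge)
    p[["emb.cedge.b"]] <- bias_init(cfg$d_edge)
    p[["proj.pocket.W"]] <- lin_init(dp, dd)
    p[["proj.pocket.b"]] <- bias_init(dd)
    p[["proj.pequi.W"]] <- lin_init(de, de)
    for (l in seq_len(cfg$dec_layers)) {
      p <- c(p, block_param_set(sprintf("dec%d.self", l), dd, dd, cfg))
      p <- c(p, block_param_set(sprintf("dec%d.cross", l), dd, dd, cfg))
    }
    # structure output heads
    p[["out.type.W"]] <- lin_init(dd, kt); p[["out.type.b"]] <- bias_init(kt)
    p[["out.charge.W"]] <- lin_init(dd, kq); p[["out.charge.b"]] <- bias_init(kq)
    p[["out.hyb.W"]] <- lin_init(dd, kh); p[["out.hyb.b"]] <- bias_init(kh)
    p <- c(p, mlp2_params(cfg$d_edge + cfg$rbf_count, 2L * cfg$d_edge, kb, "out.bond"))
    # confidence head (reads decoder features at reduced depth)
    p <- c(p, mlp2_params(dd, dd, cfg$n_lddt_bins, "out.conf"))
    # affinity head
    p[["aff.Wgv.lig"]] <- lin_init(de, de)
    p[["aff.Wgv.pocket"]] <- lin_init(de, de)
    p <- c(p, mlp2_params(dd + de, cfg$d_head, cfg$d_head, "aff.gate_lig"))
    p <- c(p, mlp2_params(dp + de, cfg$d_head, cfg$d_head, "aff.gate_pocket"))
    p <- c(p, mlp2_params(2L * cfg$d_head, cfg$d_head, cfg$d_head, "aff.zlig"))
    p <- c(p, mlp2_params(cfg$d_head, cfg$d_head, cfg$d_head, "aff.zpocket"))
    p <- c(p, mlp2_params(cfg$d_edge, cfg$d_head, cfg$d_head, "aff.zint"))
    p <- c(p, mlp2_params(3L * cfg$d_head, cfg$d_head, 4L, "aff.out"))
    p
  })
}

## ---- pairwise geometric features -------------------------------------------

#' Pairwise difference, squared-distance and cross-product features
#'
#' Given equivariant queries and keys (lists of three N x d component
#' matrices), computes the flattened pairwise squared-norm features
#' `S[p, f] = |q_i - k_j|^2` (rotation-invariant) and cross products
#' `C[p, , f] = q_i x k_j` (rotation-equivariant under proper rotations).
#'
#' @param q_equi,k_equi Equivariant features: lists of 3 matrices (Nq x d and
#'   Nk x d).
#' @return List with `S` ((Nq*Nk) x d) and `C` (list of 3 (Nq*Nk) x d
#'   component matrices); pair index `(i-1)*Nk + j`.
#' @export
pairwise_geometric_features <- function(q_equi, k_equi) {
  stopifnot(length(q_equi) == 3L, length(k_equi) == 3L,
            ncol(vof(q_equi[[1]])) == ncol(vof(k_equi[[1]])))
  D <- lapply(1:3, function(c) ad_pairdiff(q_equi[[c]], k_equi[[c]]))
  S <- ad_add(ad_add(ad_sq(D[[1]]), ad_sq(D[[2]])), ad_sq(D[[3]]))
  C <- list(
    ad_sub(ad_pairprod(q_equi[[2]], k_equi[[3]]), ad_pairprod(q_equi[[3]], k_equi[[2]])),
    ad_sub(ad_pairprod(q_equi[[3]], k_equi[[1]]), ad_pairprod(q_equi[[1]], k_equi[[3]])),
    ad_sub(ad_pairprod(q_equi[[1]], k_equi[[2]]), ad_pairprod(q_equi[[2]], k_equi[[1]])))
  list(S = S, C = C)
}

#' Gated fusion of invariant and equivariant features
#'
#' Combines invariant node features with rotation-invariant reductions
#' (per-channel norms of a learned linear map) of the equivariant features;
#' the output is rotation-invariant by construction and zero for masked rows.
#'
#' @param inv N x d invariant features.
#' @param equi List of 3 N x d_equi component matrices.
#' @param p Parameter list.
#' @param pr Parameter prefix of the fusion MLP.
#' @param Wgv Name of the equivariant mixing matrix in `p`.
#' @param mask Optional logical per node.
#' @return N x d_out invariant features.
#' @export
gated_fuse <- function(inv, equi, p, pr, Wgv, mask = NULL) {
  f <- mlp2(ad_cbind(inv, equi_norms(equi, p[[Wgv]])), p, pr)
  f <- ad_silu(f)
  if (!is.null(mask) && any(!mask)) f <- ad_scale(f, as.numeric(mask))
  f
}

## ---- the attention update block --------------------------------------------

#' One equivariant attention + feed-forward update
#'
#' Multi-head attention over (query, key) node pairs in which invariant
#' messages carry the squared-distance features S, cross-product magnitudes,
#' edge features and an RBF distance expansion; updates invariant features,
#' equivariant features (from difference vectors, cross products and gated
#' coordinate differences), optionally the query coordinates (residual update
#' along normalized coordinate differences), and the edge features (driven by
#' an RBF expansion of the updated distances).
#'
#' @param p Parameter list (plain or tape leaves).
#' @param pr Block parameter prefix.
#' @param hq,hk Invariant features of queries / keys.
#' @param vq,vk Equivariant features (lists of 3 component matrices).
#' @param xq,xk Coordinates.
#' @param e Flattened pairwise edge features ((Nq*Nk) x d_edge).
#' @param cfg [backbone_config()].
#' @param update_coords Apply the residual coordinate update to `xq`.
#' @return List with updated `h`, `v`, `x`, `e`.
#' @export
equivariant_update_block <- function(p, pr, hq, hk, vq, vk, xq, xk, e, cfg,
                                     update_coords = TRUE) {
  nq <- nrow(vof(hq)); nk <- nrow(vof(hk))
  iq <- pair_i(nq, nk); jk <- pair_j(nq, nk)
  g <- function(s) p[[paste0(pr, s)]]

  dxp <- ad_pairdiff(xq, xk)
  dist <- ad_sqrt(ad_rsum(ad_sq(dxp)), eps = 1e-12)
  rbf <- rbf_expand(dist, cfg$rbf_count)

  q_e <- lapply(vq, function(m) ad_matmul(m, g(".Wqe")))
  k_e <- lapply(vk, function(m) ad_matmul(m, g(".Wke")))
  geo <- pairwise_geometric_features(q_e, k_e)
  Cn <- ad_sqrt(ad_add(ad_add(ad_sq(geo$C[[1]]), ad_sq(geo$C[[2]])), ad_sq(geo$C[[3]])),
                eps = 1e-8)

  m <- ad_silu(mlp2(ad_cbind(ad_gather(hq, iq), ad_gather(hk, jk), e, rbf, geo$S, Cn),
                    p, paste0(pr, ".msg")))

  A <- ad_pair_softmax(ad_addvec(ad_matmul(m, g(".Wa")), g(".ba")), nq, nk)
  V <- ad_matmul(m, g(".Wv"))
  ls <- cfg$latent_size
  agg <- do.call(ad_cbind, lapply(seq_len(cfg$attention_heads), function(h)
    ad_attn_agg(A[[h]], ad_cols(V, (h - 1L) * ls + seq_len(ls)))))
  h1 <- ad_add(hq, ad_addvec(ad_matmul(agg, g(".Wo")), g(".bo")))
  h2 <- ad_add(h1, mlp2(h1, p, paste0(pr, ".ff")))

  # equivariant update: difference vectors, cross products, coordinate rays
  invd <- ad_recip(ad_add(dist, 1))
  dxn <- lapply(1:3, function(c) ad_mul(ad_cols(dxp, c), invd))
  G <- ad_silu(ad_addvec(ad_matmul(m, g(".Wg")), g(".bg")))
  ones4 <- matrix(1, 1L, 4L)
  v1 <- lapply(1:3, function(c) {
    U <- ad_cbind(ad_pairdiff(q_e[[c]] , k_e[[c]]), geo$C[[c]],
                  ad_matmul(dxn[[c]], ones4))
    ad_add(vq[[c]], ad_matmul(ad_attn_agg(A[[1L]], ad_mul(U, G)), g(".Wvm")))
  })

  x1 <- xq
  if (update_coords) {
    phi <- ad_matmul(m, g(".Wx"))   # one transport gate per attention head
    x1 <- ad_add(xq, do.call(ad_cbind, lapply(1:3, function(c) {
      contribs <- lapply(seq_len(cfg$attention_heads), function(h)
        ad_attn_agg(A[[h]], ad_mul(dxn[[c]], ad_cols(phi, h))))
      Reduce(ad_add, contribs)
    })))
    dxp2 <- ad_pairdiff(x1, xk)
    rbf <- rbf_expand(ad_sqrt(ad_rsum(ad_sq(dxp2)), eps = 1e-12), cfg$rbf_count)
  }
  e1 <- ad_add(e, mlp2(ad_cbind(e, m, rbf), p, paste0(pr, ".edge")))
  list(h = h2, v = v1, x = x1, e = e1)
}

## ---- pocket encoder ---------------------------------------------------------

#' Encode a pocket into invariant and equivariant context features
#'
#' Stacked equivariant self-attention blocks without coordinate updates (the
#' pocket is fixed context). Input features are the pocket element embedding,
#' optional interaction-channel flags (attribute `interaction_flags` on the
#' pocket, an integer vector into the categories none / hbond_donor /
#' hbond_acceptor / hydrophobic) and two invariant global scalars (atom count,
#' mean local density).
#'
#' @param p Parameter list.
#' @param pocket A [pocket_state()].
#' @param cfg [backbone_config()].
#' @return List with `h` (M x d_inv_enc), `v` (equivariant list), `coords`.
#' @export
pocket_encode <- function(p, pocket, cfg) {
  M <- nrow(pocket$coords)
  if (M == 0L) stop("empty pocket")
  xp <- pocket$coords
  dens <- rowSums(cross_distances(xp, xp) < 5) - 1
  glob <- matrix(c(M / 100, mean(dens) / 10), 1L)
  h <- ad_addvec(ad_gather(p[["emb.ptype"]], pocket$atom_type),
                 ad_matmul(glob, p[["emb.pglob.W"]]))
  fl <- attr(pocket, "interaction_flags")
  if (!is.null(fl)) h <- ad_add(h, ad_gather(p[["emb.iflag"]], as.integer(fl)))
  v <- replicate(3, matrix(0, M, cfg$d_equi), simplify = FALSE)
  dist <- ad_sqrt(ad_rsum(ad_sq(ad_pairdiff(xp, xp))), eps = 1e-12)
  e <- ad_addvec(ad_matmul(rbf_expand(dist, cfg$rbf_count), p[["emb.pedge.W"]]),
                 p[["emb.pedge.b"]])
  for (l in seq_len(cfg$enc_layers)) {
    blk <- equivariant_update_block(p, sprintf("enc%d", l), h, h, v, v, xp, xp, e,
                                    cfg, update_coords = FALSE)
    h <- blk$h; v <- blk$v; e <- blk$e
  }
  list(h = h, v = v, coords = xp)
}

## ---- ligand decoder ---------------------------------------------------------

#' Decode a noisy ligand conditioned on pocket features
#'
#' Runs the decoder stack (per layer: ligand self-attention, then
#' cross-attention into the pocket context, with residual coordinate and edge
#' updates) and returns the clean-endpoint parameterization: predicted clean
#' coordinates and categorical logits for atom type, charge, hybridization and
#' bonds (bond logits symmetric by construction), confidence logits read at
#' reduced depth, and the final latent features consumed by the affinity head.
#'
#' @param p Parameter list.
#' @param noisy A [ligand_state()] at flow time `t`.
#' @param t Flow time in \[0, 1\] (0 = noise, 1 = data).
#' @param pocket_feats Output of [pocket_encode()].
#' @param cfg [backbone_config()].
#' @return List with `coords`, `type_logits`, `charge_logits`, `hyb_logits`,
#'   `bond_logits` ((N^2) x K, pair-flattened), `conf_logits` (N x bins) and
#'   `feat` (final `h`, `v`, `cross_edges`).
#' @export
ligand_decode <- function(p, noisy, t, pocket_feats, cfg) {
  if (t < 0 || t > 1) stop("flow time t must be in [0, 1]")
  N <- nrow(noisy$coords)
  x <- noisy$coords
  xp <- pocket_feats$coords
  h <- ad_add(ad_add(ad_gather(p[["emb.type"]], noisy$atom_type),
                     ad_gather(p[["emb.charge"]], noisy$charge)),
              ad_gather(p[["emb.hyb"]], noisy$hybridization))
  h <- ad_addvec(h, ad_addvec(ad_matmul(time_features(t), p[["emb.time.W"]]),
                              p[["emb.time.b"]]))
  v <- replicate(3, matrix(0, N, cfg$d_equi), simplify = FALSE)
  hp <- ad_addvec(ad_matmul(pocket_feats$h, p[["proj.pocket.W"]]), p[["proj.pocket.b"]])
  vp <- lapply(pocket_feats$v, function(mm) ad_matmul(mm, p[["proj.pequi.W"]]))

  dist_ll <- ad_sqrt(ad_rsum(ad_sq(ad_pairdiff(x, x))), eps = 1e-12)
  es <- ad_add(ad_gather(p[["emb.bond"]], as.vector(t(noisy$bonds))),
               ad_addvec(ad_matmul(rbf_expand(dist_ll, cfg$rbf_count), p[["emb.sedge.W"]]),
                         p[["emb.sedge.b"]]))
  dist_lp <- ad_sqrt(ad_rsum(ad_sq(ad_pairdiff(x, xp))), eps = 1e-12)
  ec <- ad_addvec(ad_matmul(rbf_expand(dist_lp, cfg$rbf_count), p[["emb.cedge.W"]]),
                  p[["emb.cedge.b"]])

  h_conf <- NULL
  for (l in seq_len(cfg$dec_layers)) {
    blk <- equivariant_update_block(p, sprintf("dec%d.self", l), h, h, v, v, x, x, es,
                                    cfg, update_coords = TRUE)
    h <- blk$h; v <- blk$v; x <- blk$x; es <- blk$e
    blk <- equivariant_update_block(p, sprintf("dec%d.cross", l), h, hp, v, vp, x, xp, ec,
                                    cfg, update_coords = TRUE)
    h <- blk$h; v <- blk$v; x <- blk$x; ec <- blk$e
    if (l == cfg$confidence_depth) h_conf <- h
  }

  lin_out <- function(z, nm) ad_addvec(ad_matmul(z, p[[paste0("out.", nm, ".W")]]),
                                       p[[paste0("out.", nm, ".b")]])
  # symmetric bond logits: symmetrized edge features + RBF of predicted distances
  perm <- as.vector(matrix(seq_len(N * N), N, N, byrow = TRUE))
  dist_hat <- ad_sqrt(ad_rsum(ad_sq(ad_pairdiff(x, x))), eps = 1e-12)
  bond_in <- ad_cbind(ad_scale(ad_add(es, ad_gather(es, perm)), 0.5),
                      rbf_expand(dist_hat, cfg$rbf_count))
  list(coords = x,
       type_logits = lin_out(h, "type"),
       charge_logits = lin_out(h, "charge"),
       hyb_logits = lin_out(h, "hyb"),
       bond_logits = mlp2(bond_in, p, "out.bond"),
       conf_logits = mlp2(h_conf, p, "out.conf"),
       feat = list(h = h, v = v, cross_edges = ec))
}

## ---- model container --------------------------------------------------------

new_pf_model <- function(params, config, vocab, trace = NULL) {
  structure(list(params = params, config = config, vocab = vocab,
                 trace = trace, version = 1L), class = "pf_model")
}

#' Initialize an untrained model
#' @param config A [backbone_config()].
#' @param vocab An [atom_vocabulary()].
#' @param seed Weight-initialization seed.
#' @return A `pf_model`.
#' @export
init_model <- function(config = backbone_config(), vocab = atom_vocabulary(), seed = 1L) {
  new_pf_model(init_backbone_params(config, vocab, seed), config, vocab)
}

#' @export
print.pf_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("pf_model: %d parameters, %d+%d layers (enc+dec), d_inv %d/%d\n",
              np, x$config$enc_layers, x$config$dec_layers,
              x$config$d_inv_enc, x$config$d_inv_dec))
  invisible(x)
}

#' Save a model checkpoint
#'
#' Stores weights, backbone configuration and vocabulary with a format
#' version; [load_checkpoint()] refuses incompatible files.
#'
#' @param model A `pf_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pf_model"))
  saveRDS(unclass(model), path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return A `pf_model`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("missing checkpoint: ", path)
  obj <- readRDS(path)
  if (!identical(obj$version, 1L) || is.null(obj$params) || is.null(obj$config))
    stop("incompatible checkpoint format at ", path)
  expected <- names(init_backbone_params(obj$config, obj$vocab, seed = 1L))
  if (!setequal(names(obj$params), expected))
    stop("checkpoint parameters do not match its configuration")
  new_pf_model(obj$params, obj$config, obj$vocab, obj$trace)
}
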