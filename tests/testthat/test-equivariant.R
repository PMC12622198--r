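# SE(3) and permutation symmetry contracts of the backbone.

test_that("pairwise geometric features match the hand-computed case", {
  q <- list(matrix(1, 1, 1), matrix(0, 1, 1), matrix(0, 1, 1))  # (1,0,0)
  k <- list(matrix(0, 1, 1), matrix(1, 1, 1), matrix(0, 1, 1))  # (0,1,0)
  geo <- pairwise_geometric_features(q, k)
  expect_equal(as.numeric(geo$S), 2)
  expect_equal(sapply(geo$C, as.numeric), c(0, 0, 1))
  # identical inputs give zero difference and zero cross product
  geo0 <- pairwise_geometric_features(q, q)
  expect_equal(as.numeric(geo0$S), 0)
  expect_true(all(abs(sapply(geo0$C, as.numeric)) < 1e-15))
})

rotate_equi <- function(v, R) {
  lapply(1:3, function(c) R[c, 1] * v[[1]] + R[c, 2] * v[[2]] + R[c, 3] * v[[3]])
}

test_that("S is invariant and C equivariant under joint rotation", {
  set.seed(5)
  q <- lapply(1:3, function(i) matrix(rnorm(12), 4, 3))
  k <- lapply(1:3, function(i) matrix(rnorm(6), 2, 3))
  geo <- pairwise_geometric_features(q, k)
  mv <- rigid_motion(2)
  geo2 <- pairwise_geometric_features(rotate_equi(q, mv$R), rotate_equi(k, mv$R))
  expect_lt(max(abs(geo2$S - geo$S)), 1e-5)
  Crot <- rotate_equi(geo$C, mv$R)
  for (c in 1:3) expect_lt(max(abs(geo2$C[[c]] - Crot[[c]])), 1e-5)
})

test_that("gated fusion is rotation-invariant and masks to zero rows", {
  set.seed(8)
  v <- atom_vocabulary()
  cfg <- tiny_config()
  model <- init_model(cfg, v, seed = 2)
  h <- matrix(rnorm(5 * cfg$d_inv_dec), 5)
  ve <- lapply(1:3, function(i) matrix(rnorm(5 * cfg$d_equi), 5))
  f1 <- gated_fuse(h, ve, model$params, "aff.gate_lig", "aff.Wgv.lig")
  mv <- rigid_motion(3)
  f2 <- gated_fuse(h, rotate_equi(ve, mv$R), model$params, "aff.gate_lig", "aff.Wgv.lig")
  expect_lt(max(abs(f1 - f2)), 1e-5)
  # zero equivariant part: output depends on h alone, any rotation is a no-op
  z <- lapply(1:3, function(i) matrix(0, 5, cfg$d_equi))
  expect_equal(gated_fuse(h, z, model$params, "aff.gate_lig", "aff.Wgv.lig"),
               gated_fuse(h, rotate_equi(z, mv$R), model$params, "aff.gate_lig", "aff.Wgv.lig"))
  fm <- gated_fuse(h, ve, model$params, "aff.gate_lig", "aff.Wgv.lig",
                   mask = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_true(all(fm[3, ] == 0))
})

test_that("the update block keeps identity coordinates with zero-initialized updates", {
  v <- atom_vocabulary()
  cfg <- tiny_config()
  model <- init_model(cfg, v, seed = 4)   # .Wx blocks are zero at init
  cm <- test_complex(6, 15, seed = 6)
  x <- cm$ligand$coords
  h <- matrix(rnorm(6 * cfg$d_inv_dec), 6)
  ve <- lapply(1:3, function(i) matrix(0, 6, cfg$d_equi))
  e <- matrix(rnorm(36 * cfg$d_edge), 36)
  blk <- equivariant_update_block(model$params, "dec1.self", h, h, ve, ve, x, x, e, cfg)
  expect_equal(blk$x, x)
})

test_that("the update block transforms exactly under rigid motion", {
  v <- atom_vocabulary()
  cfg <- tiny_config()
  model <- activate_coord_updates(init_model(cfg, v, seed = 4))
  set.seed(9)
  x <- matrix(rnorm(18, 0, 3), 6)
  h <- matrix(rnorm(6 * cfg$d_inv_dec), 6)
  ve <- lapply(1:3, function(i) matrix(rnorm(6 * cfg$d_equi), 6))
  e <- matrix(rnorm(36 * cfg$d_edge), 36)
  blk <- equivariant_update_block(model$params, "dec1.self", h, h, ve, ve, x, x, e, cfg)
  mv <- rigid_motion(11)
  blk2 <- equivariant_update_block(model$params, "dec1.self", h, h,
                                   rotate_equi(ve, mv$R), rotate_equi(ve, mv$R),
                                   mv$apply(x), mv$apply(x), e, cfg)
  expect_lt(max(abs(blk2$h - blk$h)), 1e-4)
  expect_lt(max(abs(blk2$e - blk$e)), 1e-4)
  expect_lt(max(abs(blk2$x - mv$apply(blk$x))), 1e-4)
  vrot <- rotate_equi(blk$v, mv$R)
  for (c in 1:3) expect_lt(max(abs(blk2$v[[c]] - vrot[[c]])), 1e-4)
})

test_that("pocket encoding is deterministic and rotation splits inv/equi correctly", {
  v <- atom_vocabulary()
  cfg <- tiny_config()
  model <- init_model(cfg, v, seed = 12)
  cm <- test_complex(7, 18, seed = 13)
  enc1 <- pocket_encode(model$params, cm$pocket, cfg)
  enc1b <- pocket_encode(model$params, cm$pocket, cfg)
  expect_identical(enc1$h, enc1b$h)
  mv <- rigid_motion(14)
  pock2 <- cm$pocket; pock2$coords <- mv$apply(cm$pocket$coords)
  enc2 <- pocket_encode(model$params, pock2, cfg)
  expect_lt(max(abs(enc2$h - enc1$h)), 1e-4)
  vrot <- rotate_equi(enc1$v, mv$R)
  for (c in 1:3) expect_lt(max(abs(enc2$v[[c]] - vrot[[c]])), 1e-4)
  empty <- cm$pocket; empty$coords <- empty$coords[0, , drop = FALSE]
  expect_error(pocket_encode(model$params, empty, cfg), "empty")
})

test_that("full decode satisfies the SE(3) contract including heads", {
  v <- atom_vocabulary()
  cfg <- tiny_config()
  model <- activate_coord_updates(init_model(cfg, v, seed = 21))
  cm <- test_complex(8, 20, seed = 22)
  penc <- pocket_encode(model$params, cm$pocket, cfg)
  dec <- ligand_decode(model$params, cm$ligand, 0.3, penc, cfg)
  y <- affinity_forward(model$params, dec$feat, penc, dec$feat$cross_edges, cfg)
  mv <- rigid_motion(23)
  lig2 <- cm$ligand; lig2$coords <- mv$apply(lig2$coords)
  pock2 <- cm$pocket; pock2$coords <- mv$apply(pock2$coords)
  penc2 <- pocket_encode(model$params, pock2, cfg)
  dec2 <- ligand_decode(model$params, lig2, 0.3, penc2, cfg)
  y2 <- affinity_forward(model$params, dec2$feat, penc2, dec2$feat$cross_edges, cfg)
  expect_lt(max(abs(dec2$coords - mv$apply(dec$coords))), 1e-4)
  for (nm in c("type_logits", "charge_logits", "hyb_logits", "bond_logits", "conf_logits"))
    expect_lt(max(abs(dec2[[nm]] - dec[[nm]])), 1e-4)
  expect_lt(max(abs(y2 - y)), 1e-5)
})

test_that("decode is equivariant under ligand atom permutation", {
  v <- atom_vocabulary()
  cfg <- tiny_config()
  model <- activate_coord_updates(init_model(cfg, v, seed = 31))
  cm <- test_complex(7, 16, seed = 32)
  penc <- pocket_encode(model$params, cm$pocket, cfg)
  dec <- ligand_decode(model$params, cm$ligand, 0.6, penc, cfg)
  perm <- pocketflow:::with_seed(33, sample(7))
  lig2 <- ligand_state(cm$ligand$coords[perm, ], cm$ligand$atom_type[perm],
                       cm$ligand$charge[perm], cm$ligand$hybridization[perm],
                       cm$ligand$bonds[perm, perm])
  dec2 <- ligand_decode(model$params, lig2, 0.6, penc, cfg)
  expect_lt(max(abs(dec2$coords - dec$coords[perm, ])), 1e-6)
  expect_lt(max(abs(dec2$type_logits - dec$type_logits[perm, ])), 1e-6)
  n <- 7L
  pair_of <- function(i, j) (i - 1L) * n + j
  for (pr in list(c(1, 2), c(3, 5), c(6, 7))) {
    i2 <- match(pr[1], perm); j2 <- match(pr[2], perm)
    expect_lt(max(abs(dec2$bond_logits[pair_of(i2, j2), ] -
                        dec$bond_logits[pair_of(pr[1], pr[2]), ])), 1e-6)
  }
})

test_that("bond logits are symmetric and the affinity head is permutation-invariant", {
  v <- atom_vocabulary()
  cfg <- tiny_config()
  model <- activate_coord_updates(init_model(cfg, v, seed = 41))
  cm <- test_complex(6, 14, seed = 42)
  penc <- pocket_encode(model$params, cm$pocket, cfg)
  dec <- ligand_decode(model$params, cm$ligand, 0.9, penc, cfg)
  n <- 6L
  bl <- dec$bond_logits
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    expect_lt(max(abs(bl[(i - 1) * n + j, ] - bl[(j - 1) * n + i, ])), 1e-10)
  # permuting pocket atoms leaves the affinity prediction unchanged
  y <- affinity_forward(model$params, dec$feat, penc, dec$feat$cross_edges, cfg)
  perm <- pocketflow:::with_seed(43, sample(nrow(cm$pocket$coords)))
  pock2 <- cm$pocket
  pock2$coords <- pock2$coords[perm, ]; pock2$atom_type <- pock2$atom_type[perm]
  pock2$residue_id <- pock2$residue_id[perm]
  pock2$residue_name <- pock2$residue_name[perm]; pock2$chain_id <- pock2$chain_id[perm]
  pock2$atom_mask <- pock2$atom_mask[perm]
  penc2 <- pocket_encode(model$params, pock2, cfg)
  dec2 <- ligand_decode(model$params, cm$ligand, 0.9, penc2, cfg)
  y2 <- affinity_forward(model$params, dec2$feat, penc2, dec2$feat$cross_edges, cfg)
  expect_lt(max(abs(y - y2)), 1e-5)
})

test_that("checkpoints round-trip and refuse incompatible files", {
  v <- atom_vocabulary()
  model <- init_model(tiny_config(), v, seed = 51)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_equal(back$params, model$params)
  expect_equal(unclass(back$config), unclass(model$config))
  saveRDS(list(version = 99L), f)
  expect_error(load_checkpoint(f), "incompatible")
})

test_that("the full-scale configuration validates and invariants are enforced", {
  cfg <- backbone_config(enc_layers = 4L, dec_layers = 12L, d_inv_enc = 256L,
                         d_inv_dec = 384L, d_equi = 128L, latent_size = 64L,
                         attention_heads = 32L, confidence_depth = 8L)
  expect_s3_class(cfg, "backbone_config")
  expect_error(backbone_config(confidence_depth = 9L, dec_layers = 4L), "confidence_depth")
  expect_error(backbone_config(d_equi = 0L), "positive")
})
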