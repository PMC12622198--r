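# Flow engine: priors, interpolation/corruption marginals, losses, the
# Euler/jump sampler, conditioning and training sanity.

test_that("coordinate interpolation follows the linear conditional path", {
  x0 <- matrix(0, 1, 3)
  x1 <- matrix(c(2, 4, 6), 1, 3)
  expect_equal(interpolate_coords(x0, x1, 0), x0)
  expect_equal(interpolate_coords(x0, x1, 1), x1)
  expect_equal(interpolate_coords(x0, x1, 0.5), matrix(c(1, 2, 3), 1, 3))
})

test_that("prior draws are centered, deterministic and degenerate at sd 0", {
  v <- atom_vocabulary()
  cm <- test_complex(6, 20, seed = 61)
  cfg0 <- sampler_config(noise_sd = 0)
  pr <- sample_prior(4, cm$pocket, cfg0, v, seed = 1)
  ctr <- colMeans(cm$pocket$coords)
  expect_lt(max(abs(sweep(pr$coords, 2, ctr))), 1e-12)
  expect_identical(sample_prior(5, cm$pocket, sampler_config(), v, seed = 9),
                   sample_prior(5, cm$pocket, sampler_config(), v, seed = 9))
  # CLT check on the coordinate mean over many draws
  sd0 <- 2
  draws <- sapply(1:300, function(i)
    colMeans(sample_prior(12, cm$pocket, sampler_config(noise_sd = sd0), v, seed = i)$coords))
  se <- sd0 / sqrt(12 * 300)
  expect_lt(max(abs(rowMeans(draws) - ctr)), 4 * se)
})

test_that("categorical corruption reproduces the discrete-path marginal", {
  K <- 5L
  n <- 2e4L
  for (t in c(0, 0.4, 1)) {
    z <- pocketflow:::with_seed(100 + round(t * 10), corrupt_categorical(rep(2L, n), t, K))
    p_keep <- t + (1 - t) / K
    se <- sqrt(p_keep * (1 - p_keep) / n)
    expect_lt(abs(mean(z == 2L) - p_keep), 4 * se + 1e-12)
  }
  # corrupted bond matrices stay symmetric with a no-bond diagonal
  lig <- generate_toy_ligand(7, seed = 71)
  cm <- test_complex(7, 16, seed = 71)
  pr <- sample_prior(7, cm$pocket, sampler_config(), atom_vocabulary(), seed = 2)
  noisy <- pocketflow:::with_seed(5, pocketflow:::corrupt_ligand(lig, 0.3, pr, atom_vocabulary()))
  expect_identical(noisy$bonds, t(noisy$bonds))
  expect_true(all(diag(noisy$bonds) == 1L))
})

test_that("total_loss matches a hand-computed two-atom case", {
  v <- atom_vocabulary()
  n <- 2L
  target <- ligand_state(matrix(c(0, 0, 0, 1.5, 0, 0), 2, byrow = TRUE),
                         c(1L, 2L), c(3L, 3L), c(3L, 3L),
                         matrix(c(1L, 2L, 2L, 1L), 2))
  kt <- length(v$atom_types); kq <- length(v$charge_values)
  kh <- length(v$hybridizations); kb <- length(v$bond_orders)
  pred <- list(
    coords = matrix(c(0.1, 0, 0, 1.4, 0, 0), 2, byrow = TRUE),
    type_logits = matrix(c(2, rep(0, kt - 1), rep(0, kt)), 2, kt, byrow = TRUE),
    charge_logits = matrix(0, 2, kq),
    hyb_logits = matrix(1, 2, kh),
    bond_logits = matrix(0.5, 4, kb))
  got <- total_loss(pred, target, loss_weights(), v)
  mse <- mean(c(0.1, 0, 0, -0.1, 0, 0)^2)
  ce_t <- mean(c(-(2 - log(exp(2) + kt - 1)), log(kt)))
  ce_q <- log(kq); ce_h <- log(kh); ce_b <- log(kb)
  expect_equal(unname(got$terms["mse"]), mse, tolerance = 1e-6)
  expect_equal(unname(got$terms["ce_type"]), ce_t, tolerance = 1e-6)
  expect_equal(unname(got$terms["ce_bond"]), ce_b, tolerance = 1e-6)
  expect_equal(got$total,
               1 * mse + 0.5 * (ce_t + ce_q + ce_h + ce_b), tolerance = 1e-6)
  # identical predictions with saturated logits drive every term to zero
  oh <- function(idx, k) { m <- matrix(-50, length(idx), k); m[cbind(seq_along(idx), idx)] <- 50; m }
  perfect <- list(coords = target$coords,
                  type_logits = oh(target$atom_type, kt),
                  charge_logits = oh(target$charge, kq),
                  hyb_logits = oh(target$hybridization, kh),
                  bond_logits = oh(as.vector(t(target$bonds)), kb))
  expect_lt(total_loss(perfect, target, loss_weights(), v)$total, 1e-10)
  expect_equal(total_loss(pred, target,
                          loss_weights(0, 0, 0, 0, 0), v)$total, 0)
})

test_that("integrate_step has the Euler fixed point and closed forms", {
  v <- atom_vocabulary()
  lig <- generate_toy_ligand(5, seed = 81)
  kt <- length(v$atom_types)
  mk_pred <- function(coords, state) {
    oh <- function(idx, k) { m <- matrix(-50, length(idx), k); m[cbind(seq_along(idx), idx)] <- 50; m }
    list(coords = coords,
         type_logits = oh(state$atom_type, kt),
         charge_logits = oh(state$charge, length(v$charge_values)),
         hyb_logits = oh(state$hybridization, length(v$hybridizations)),
         bond_logits = oh(as.vector(t(state$bonds)), length(v$bond_orders)))
  }
  # prediction equal to the current state: coordinates do not move
  pred <- mk_pred(lig$coords, lig)
  stepped <- pocketflow:::with_seed(1, integrate_step(lig, pred, 0.5, 0.1, v))
  expect_equal(stepped$coords, lig$coords)
  # one step from t=0 with dt=1 lands exactly on the predicted endpoint
  other <- generate_toy_ligand(5, seed = 82)
  pred2 <- mk_pred(other$coords, other)
  jumped <- pocketflow:::with_seed(2, integrate_step(lig, pred2, 0, 1, v))
  expect_equal(jumped$coords, other$coords)
  expect_identical(jumped$atom_type, other$atom_type)
  expect_identical(jumped$bonds, other$bonds)
  expect_error(integrate_step(lig, pred, 1, 0.1, v), "t < 1")
})

test_that("a frozen clean-endpoint oracle absorbs the jump process", {
  # decoder stub that always predicts one fixed target: after full integration
  # every categorical equals that target regardless of the prior draw
  v <- atom_vocabulary()
  target <- generate_toy_ligand(6, seed = 91)
  cm <- test_complex(6, 15, seed = 91)
  kt <- length(v$atom_types)
  oh <- function(idx, k) { m <- matrix(-30, length(idx), k); m[cbind(seq_along(idx), idx)] <- 30; m }
  frozen <- list(coords = target$coords,
                 type_logits = oh(target$atom_type, kt),
                 charge_logits = oh(target$charge, length(v$charge_values)),
                 hyb_logits = oh(target$hybridization, length(v$hybridizations)),
                 bond_logits = oh(as.vector(t(target$bonds)), length(v$bond_orders)))
  for (rep in 1:5) {
    state <- sample_prior(6, cm$pocket, sampler_config(), v, seed = 900 + rep)
    ts <- seq(0, 1, length.out = 11)
    pocketflow:::with_seed(rep, {
      for (k in 1:10) state <- integrate_step(state, frozen, ts[k], 0.1, v)
    })
    expect_identical(state$atom_type, target$atom_type)
    expect_identical(state$charge, target$charge)
    expect_identical(state$bonds, target$bonds)
    expect_lt(max(abs(state$coords - target$coords)), 1e-9)
  }
})

test_that("conditioning clamps exactly the fixed entries", {
  lig <- generate_toy_ligand(8, seed = 95)
  ref <- generate_toy_ligand(8, seed = 96)
  all_mask <- conditioning_mask(rep(TRUE, 8))
  expect_equal(apply_conditioning(lig, all_mask, ref)$coords, ref$coords)
  none_mask <- conditioning_mask(rep(FALSE, 8))
  expect_identical(apply_conditioning(lig, none_mask, ref), lig)
  part <- conditioning_mask(c(rep(TRUE, 3), rep(FALSE, 5)))
  got <- apply_conditioning(lig, part, ref)
  expect_equal(got$coords[1:3, ], ref$coords[1:3, ])
  expect_equal(got$coords[4:8, ], lig$coords[4:8, ])
  expect_identical(got$bonds[1:3, 1:3], ref$bonds[1:3, 1:3])
  expect_identical(got$bonds[4:8, 4:8], lig$bonds[4:8, 4:8])
  expect_error(conditioning_mask(c(TRUE, FALSE), matrix(TRUE, 2, 2)), "fixed atoms")
})

test_that("generation returns valid states of the requested sizes, deterministically", {
  v <- atom_vocabulary()
  cm <- test_complex(8, 20, seed = 101)
  model <- activate_coord_updates(init_model(tiny_config(), v, seed = 7))
  sam <- sampler_config(steps = 6, seed = 11)
  ligs <- generate_ligands(model, cm$pocket, 5, 7L, sam)
  expect_length(ligs, 5L)
  for (lg in ligs) {
    expect_equal(nrow(lg$coords), 7L)
    expect_silent(validate_ligand_state(lg, v))
  }
  ligs2 <- generate_ligands(model, cm$pocket, 5, 7L, sam)
  expect_identical(ligs, ligs2)
})

test_that("generation moves rigidly with the pocket (same seed)", {
  v <- atom_vocabulary()
  cm <- test_complex(8, 24, seed = 105)
  model <- activate_coord_updates(init_model(tiny_config(), v, seed = 8))
  sam <- sampler_config(steps = 5, seed = 13)
  ligs <- generate_ligands(model, cm$pocket, 2, 6L, sam)
  mv <- rigid_motion(106)
  pock2 <- cm$pocket; pock2$coords <- mv$apply(cm$pocket$coords)
  ligs2 <- generate_ligands(model, pock2, 2, 6L, sam)
  for (b in 1:2) {
    expect_lt(max(abs(ligs2[[b]]$coords - mv$apply(ligs[[b]]$coords))), 1e-3)
    expect_identical(ligs2[[b]]$atom_type, ligs[[b]]$atom_type)
    expect_identical(ligs2[[b]]$bonds, ligs[[b]]$bonds)
  }
})

test_that("fragment conditioning survives a full generation run", {
  v <- atom_vocabulary()
  cm <- test_complex(9, 22, seed = 111)
  model <- activate_coord_updates(init_model(tiny_config(), v, seed = 9))
  ref <- cm$ligand
  mask <- conditioning_mask(seq_len(9) <= 6)
  ligs <- generate_ligands(model, cm$pocket, 3, 9L,
                           sampler_config(steps = 8, seed = 17, mode = "fragment"),
                           conditioning = list(mask = mask, reference = ref))
  for (lg in ligs) {
    expect_lt(max(abs(lg$coords[1:6, ] - ref$coords[1:6, ])), 1e-6)
    expect_identical(lg$atom_type[1:6], ref$atom_type[1:6])
    expect_identical(lg$bonds[1:6, 1:6], ref$bonds[1:6, 1:6])
  }
  expect_error(generate_ligands(model, cm$pocket, 1, 9L,
                                sampler_config(steps = 2, mode = "fragment")),
               "conditioning")
})

test_that("short training decreases the loss and is seed-reproducible", {
  v <- atom_vocabulary()
  recs <- lapply(1:10, function(i) test_complex(6, 14, seed = 1200 + i))
  cfg <- tiny_config()
  m1 <- train_model(recs, cfg, epochs = 2, lr = 2e-3, seed = 5)
  tr <- m1$trace
  expect_lt(mean(tr$loss[11:20]), mean(tr$loss[1:10]))
  m2 <- train_model(recs, cfg, epochs = 2, lr = 2e-3, seed = 5)
  expect_equal(m1$trace$loss, m2$trace$loss)
  expect_equal(m1$params, m2$params)
})
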