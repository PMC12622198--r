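# Mixed continuous/discrete flow matching: priors, corruption, the multi-task
# loss, Euler/jump sampling, conditioning and the training loop.
#
# Convention: flow time runs t = 0 (noise) -> 1 (data). Coordinates follow the
# linear conditional path x_t = (1-t) x0 + t x1 with the clean-endpoint
# velocity v = (Xhat - x_t)/(1 - t); categoricals follow a uniform-prior
# discrete flow (keep the data value with probability t, else uniform) whose
# sampler is a jump process resampling from the predicted clean posterior with
# probability dt/(1 - t).

#' Loss weights for the multi-task objective
#'
#' @param lambda_c Coordinate MSE weight.
#' @param lambda_t,lambda_ch,lambda_h,lambda_b Cross-entropy weights for atom
#'   type, charge, hybridization and bonds.
#' @param lambda_affinity,lambda_confidence Auxiliary head weights.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_c = 1, lambda_t = 0.5, lambda_ch = 0.5,
                         lambda_h = 0.5, lambda_b = 0.5,
                         lambda_affinity = 0.1, lambda_confidence = 0.1) {
  w <- list(lambda_c = lambda_c, lambda_t = lambda_t, lambda_ch = lambda_ch,
            lambda_h = lambda_h, lambda_b = lambda_b,
            lambda_affinity = lambda_affinity, lambda_confidence = lambda_confidence)
  if (any(unlist(w) < 0)) stop("loss weights must be nonnegative")
  structure(w, class = "loss_weights")
}

#' Sampler configuration
#'
#' @param steps Euler integration steps (>= 1).
#' @param noise_sd Prior coordinate standard deviation around the pocket
#'   centroid (Angstrom).
#' @param time_distribution Training time distribution (only `"uniform"`).
#' @param seed Sampling seed.
#' @param mode Generative mode: `"denovo"`, `"fragment"` (inpainting around a
#'   fixed anchor) or `"interaction"` (pocket interaction channels).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(steps = 100L, noise_sd = 2.0,
                           time_distribution = "uniform", seed = 1L,
                           mode = c("denovo", "fragment", "interaction")) {
  mode <- match.arg(mode)
  if (steps < 1L) stop("steps must be >= 1")
  if (!identical(time_distribution, "uniform"))
    stop("only the uniform time distribution is supported")
  structure(list(steps = as.integer(steps), noise_sd = noise_sd,
                 time_distribution = time_distribution,
                 seed = as.integer(seed), mode = mode),
            class = "sampler_config")
}

#' Sample the ligand prior
#'
#' Coordinates are isotropic Gaussian around the pocket centroid (drawn in the
#' canonical pocket frame, so same-seed draws move rigidly with the pocket);
#' categorical attributes are uniform over the vocabulary with a symmetric
#' bond matrix and a no-bond diagonal.
#'
#' @param n_atoms Atom count.
#' @param pocket A [pocket_state()].
#' @param config A [sampler_config()] (uses `noise_sd`).
#' @param vocab Vocabulary.
#' @param seed Integer seed.
#' @return A [ligand_state()] draw from the prior.
#' @export
sample_prior <- function(n_atoms, pocket, config = sampler_config(),
                         vocab = atom_vocabulary(), seed = 1L) {
  stopifnot(n_atoms >= 1L)
  frame <- canonical_frame(pocket$coords)
  with_seed(seed, {
    z <- matrix(stats::rnorm(3L * n_atoms, 0, config$noise_sd), n_atoms, 3L)
    coords <- sweep(z %*% frame$rotation, 2L, frame$center, "+")
    bonds <- matrix(1L, n_atoms, n_atoms)
    ut <- upper.tri(bonds)
    bonds[ut] <- sample(length(vocab$bond_orders), sum(ut), replace = TRUE)
    bonds <- symmetrize_bonds(bonds)
    ligand_state(coords,
                 atom_type = sample(length(vocab$atom_types), n_atoms, replace = TRUE),
                 charge = sample(length(vocab$charge_values), n_atoms, replace = TRUE),
                 hybridization = sample(length(vocab$hybridizations), n_atoms, replace = TRUE),
                 bonds = bonds)
  })
}

#' Linear coordinate interpolation between prior and data
#'
#' @param x0 Prior coordinates.
#' @param x1 Data coordinates (same shape).
#' @param t Time in \[0, 1\].
#' @return `(1 - t) * x0 + t * x1`.
#' @export
interpolate_coords <- function(x0, x1, t) {
  stopifnot(identical(dim(x0), dim(x1)), t >= 0, t <= 1)
  (1 - t) * x0 + t * x1
}

#' Corrupt categorical indices along the uniform-prior discrete flow
#'
#' Each entry keeps its data value with probability `t` and is otherwise
#' replaced by a uniform draw over the `K` categories, giving the marginal
#' `P(z_t = z1) = t + (1 - t)/K`.
#'
#' @param z1 Integer data indices.
#' @param t Time in \[0, 1\].
#' @param K Vocabulary size.
#' @return Corrupted indices, same length as `z1`.
#' @export
corrupt_categorical <- function(z1, t, K) {
  stopifnot(t >= 0, t <= 1, all(z1 >= 1L & z1 <= K))
  keep <- stats::runif(length(z1)) < t
  out <- sample.int(K, length(z1), replace = TRUE)
  out[keep] <- z1[keep]
  out
}

# corrupt a full ligand state at time t (symmetric bond corruption); uses the
# current RNG stream
corrupt_ligand <- function(ligand, t, prior, vocab) {
  n <- nrow(ligand$coords)
  bonds <- ligand$bonds
  ut <- which(upper.tri(bonds))
  bu <- corrupt_categorical(bonds[ut], t, length(vocab$bond_orders))
  bonds[ut] <- bu
  bonds <- symmetrize_bonds(bonds)
  ligand_state(interpolate_coords(prior$coords, ligand$coords, t),
               atom_type = corrupt_categorical(ligand$atom_type, t, length(vocab$atom_types)),
               charge = corrupt_categorical(ligand$charge, t, length(vocab$charge_values)),
               hybridization = corrupt_categorical(ligand$hybridization, t,
                                                   length(vocab$hybridizations)),
               bonds = bonds)
}

#' Multi-task structure loss
#'
#' Weighted sum of the coordinate MSE (mean over unmasked atoms and 3
#' coordinates) and cross-entropies for atom type, charge, hybridization
#' (mean over unmasked atoms) and bonds (mean over unordered pairs i < j).
#'
#' @param predictions Decoder output (see [ligand_decode()]); logits may be
#'   plain matrices or tape nodes.
#' @param target The clean [ligand_state()].
#' @param weights A [loss_weights()].
#' @param vocab Vocabulary.
#' @return List with `total` (scalar or tape node) and `terms` (named numeric
#'   vector of the unweighted terms).
#' @export
total_loss <- function(predictions, target, weights = loss_weights(),
                       vocab = atom_vocabulary()) {
  n <- nrow(target$coords)
  ce_term <- function(logits, idx, w = NULL) {
    k <- ncol(vof(logits))
    oh <- matrix(0, length(idx), k)
    oh[cbind(seq_along(idx), idx)] <- 1
    if (!is.null(w)) oh <- oh * w
    denom <- if (is.null(w)) length(idx) else sum(w)
    ad_scale(ad_sum(ad_mul(ad_logsoftmax_rows(logits), oh)), -1 / denom)
  }
  mse <- ad_mean(ad_sq(ad_sub(predictions$coords, target$coords)))
  ce_t <- ce_term(predictions$type_logits, target$atom_type)
  ce_q <- ce_term(predictions$charge_logits, target$charge)
  ce_h <- ce_term(predictions$hyb_logits, target$hybridization)
  wpair <- as.numeric(pair_i(n, n) < pair_j(n, n))
  ce_b <- ce_term(predictions$bond_logits, as.vector(t(target$bonds)), wpair)
  total <- ad_add(ad_add(ad_add(ad_scale(mse, weights$lambda_c),
                                ad_scale(ce_t, weights$lambda_t)),
                         ad_add(ad_scale(ce_q, weights$lambda_ch),
                                ad_scale(ce_h, weights$lambda_h))),
                  ad_scale(ce_b, weights$lambda_b))
  terms <- c(mse = vof(mse), ce_type = vof(ce_t), ce_charge = vof(ce_q),
             ce_hyb = vof(ce_h), ce_bond = vof(ce_b))
  if (!all(is.finite(terms))) stop("non-finite loss term: ",
                                   paste(names(terms)[!is.finite(terms)], collapse = ", "))
  list(total = total, terms = terms)
}

#' One Euler/jump integration step of the generative flow
#'
#' Coordinates take an Euler step along the clean-endpoint velocity
#' `(Xhat - x_t)/(1 - t)`; each categorical variable jumps to a draw from the
#' predicted clean posterior with probability `dt/(1 - t)` (clamped at 1),
#' bonds jumping symmetrically. At the final step (t + dt = 1) categoricals
#' take the predicted argmax. Uses the current RNG stream.
#'
#' @param state The [ligand_state()] at time `t`.
#' @param prediction Decoder output at `(state, t)`.
#' @param t Current time (< 1).
#' @param dt Step size with `t + dt <= 1`.
#' @param vocab Vocabulary.
#' @return The state at `t + dt`.
#' @export
integrate_step <- function(state, prediction, t, dt, vocab = atom_vocabulary()) {
  if (t >= 1) stop("integrate_step requires t < 1")
  stopifnot(dt > 0, t + dt <= 1 + 1e-9)
  n <- nrow(state$coords)
  xhat <- vof(prediction$coords)
  x <- state$coords + dt * (xhat - state$coords) / (1 - t)
  final <- (t + dt) >= 1 - 1e-9
  p_jump <- min(dt / (1 - t), 1)
  jump_attr <- function(cur, logits) {
    lg <- vof(logits)
    if (final) return(max.col(lg, ties.method = "first"))
    resample <- stats::runif(length(cur)) < p_jump
    if (any(resample)) {
      pm <- exp(lg - apply(lg, 1L, max))
      pm <- pm / rowSums(pm)
      for (i in which(resample))
        cur[i] <- sample.int(ncol(lg), 1L, prob = pm[i, ])
    }
    cur
  }
  bonds <- state$bonds
  ut_lin <- which(upper.tri(bonds))
  # map matrix positions (column-major upper triangle) to flattened pair rows
  rc <- arrayInd(ut_lin, dim(bonds))
  pair_rows <- (rc[, 1L] - 1L) * n + rc[, 2L]
  bl <- vof(prediction$bond_logits)[pair_rows, , drop = FALSE]
  bonds[ut_lin] <- jump_attr(bonds[ut_lin], bl)
  bonds <- symmetrize_bonds(bonds)
  ligand_state(x,
               atom_type = jump_attr(state$atom_type, prediction$type_logits),
               charge = jump_attr(state$charge, prediction$charge_logits),
               hybridization = jump_attr(state$hybridization, prediction$hyb_logits),
               bonds = bonds)
}

#' Conditioning mask for fragment inpainting
#'
#' @param fixed_atoms Logical per atom.
#' @param fixed_bonds Logical N x N; defaults to all pairs between fixed
#'   atoms. Fixed bonds are only allowed between fixed atoms.
#' @return An object of class `conditioning_mask`.
#' @export
conditioning_mask <- function(fixed_atoms, fixed_bonds = NULL) {
  fixed_atoms <- as.logical(fixed_atoms)
  if (is.null(fixed_bonds)) fixed_bonds <- outer(fixed_atoms, fixed_atoms, "&")
  if (any(fixed_bonds & !outer(fixed_atoms, fixed_atoms, "&")))
    stop("fixed bonds are only allowed between fixed atoms")
  diag(fixed_bonds) <- FALSE
  structure(list(fixed_atoms = fixed_atoms, fixed_bonds = fixed_bonds),
            class = "conditioning_mask")
}

#' Clamp fixed fragment atoms onto a state
#'
#' Fixed atoms take the reference coordinates and categories; fixed bonds take
#' the reference bond orders; everything else is untouched.
#'
#' @param state Current [ligand_state()].
#' @param mask A [conditioning_mask()].
#' @param reference The anchor [ligand_state()] (same size).
#' @return The clamped state.
#' @export
apply_conditioning <- function(state, mask, reference) {
  if (length(mask$fixed_atoms) != nrow(state$coords) ||
      nrow(reference$coords) != nrow(state$coords))
    stop("conditioning mask/reference do not match the state size")
  fa <- mask$fixed_atoms
  state$coords[fa, ] <- reference$coords[fa, , drop = FALSE]
  state$atom_type[fa] <- reference$atom_type[fa]
  state$charge[fa] <- reference$charge[fa]
  state$hybridization[fa] <- reference$hybridization[fa]
  fb <- mask$fixed_bonds
  state$bonds[fb] <- reference$bonds[fb]
  state$bonds <- symmetrize_bonds(state$bonds)
  validate_ligand_state(state)
  state
}

#' Generate ligands in a pocket
#'
#' Runs the Euler/jump sampler from the prior to t = 1. Sizes are either an
#' explicit integer vector (recycled over ligands) or a single reference size,
#' optionally sampled uniformly within a relative margin (`size_jitter = 0.1`
#' gives the -10%/+10% protocol; the default 0 keeps sizes fixed). In `"fragment"` mode the
#' `conditioning` anchor is clamped after every step, so fixed atoms are never
#' perturbed; `"interaction"` mode reads the `interaction_flags` attribute of
#' the pocket.
#'
#' @param model A trained `pf_model`.
#' @param pocket The target [pocket_state()].
#' @param n_ligands Number of ligands.
#' @param sizes Integer vector of atom counts, or a single reference count.
#' @param sampler A [sampler_config()].
#' @param conditioning For fragment mode: list with `mask`
#'   (a [conditioning_mask()]) and `reference` (a [ligand_state()]).
#' @param size_jitter Relative margin for single-reference sizes (default 0).
#' @return List of [ligand_state()] objects (attribute `trajectory_seeds`
#'   records the per-ligand substreams).
#' @export
generate_ligands <- function(model, pocket, n_ligands, sizes,
                             sampler = sampler_config(), conditioning = NULL,
                             size_jitter = 0) {
  stopifnot(inherits(model, "pf_model"), n_ligands >= 0)
  if (sampler$mode == "fragment" && is.null(conditioning))
    stop("fragment mode requires a conditioning anchor")
  cfg <- model$config; vocab <- model$vocab; p <- model$params
  penc <- pocket_encode(p, pocket, cfg)
  nsizes <- if (length(sizes) > 1L) rep_len(as.integer(sizes), n_ligands)
  else if (size_jitter > 0) {
    with_seed(substream_seed(sampler$seed, "sizes"), {
      lo <- max(1L, floor(sizes * (1 - size_jitter)))
      hi <- ceiling(sizes * (1 + size_jitter))
      sample(seq(lo, hi), n_ligands, replace = TRUE)
    })
  } else rep(as.integer(sizes), n_ligands)
  ts <- seq(0, 1, length.out = sampler$steps + 1L)
  out <- vector("list", n_ligands)
  for (b in seq_len(n_ligands)) {
    seed_b <- substream_seed(sampler$seed, "trajectory", b)
    state <- sample_prior(nsizes[b], pocket, sampler, vocab, seed = seed_b)
    if (!is.null(conditioning))
      state <- apply_conditioning(state, conditioning$mask, conditioning$reference)
    with_seed(substream_seed(sampler$seed, "jumps", b), {
      for (k in seq_len(sampler$steps)) {
        dec <- ligand_decode(p, state, ts[k], penc, cfg)
        state <- integrate_step(state, dec, ts[k], ts[k + 1L] - ts[k], vocab)
        if (!is.null(conditioning))
          state <- apply_conditioning(state, conditioning$mask, conditioning$reference)
      }
    })
    out[[b]] <- state
  }
  attr(out, "sizes") <- nsizes
  out
}

#' Train the joint flow/affinity/confidence model
#'
#' Streams single complexes: at each step a flow time is drawn uniformly, the
#' ligand is corrupted, and one backward pass minimizes the structure loss
#' plus the confidence cross-entropy (lDDT of the noisy-input coordinate
#' prediction against the true pose) plus the masked Huber affinity loss
#' computed on a clean-input forward pass (flow time 1), the representation
#' the affinity head is consumed on at inference. Optimized with Adam under
#' global gradient-norm clipping.
#'
#' @param records List of [complex_record()] training complexes.
#' @param config A [backbone_config()].
#' @param weights A [loss_weights()].
#' @param vocab Vocabulary.
#' @param epochs Passes over the data.
#' @param lr Adam learning rate; decays by `lr_decay` over the final third of
#'   training (precision phase).
#' @param lr_decay Multiplier applied to `lr` in the final third.
#' @param noise_sd Prior coordinate spread used for corruption (must match
#'   sampling).
#' @param seed Seed for initialization, shuffling, times and corruption.
#' @param coord_aug_sd Extra Gaussian jitter (Angstrom) added to interpolated
#'   training coordinates. Sampled trajectories condition on their own
#'   imperfect predictions, which drift slightly off the exact interpolant
#'   path; training on jittered inputs (target unchanged) teaches the decoder
#'   to pull such inputs back onto the data manifold.
#' @param affinity_every Compute the clean-pass affinity loss every k-th step.
#' @param verbose Print a progress line every 100 steps.
#' @return A `pf_model` with the loss trace (data frame) in `$trace`.
#' @export
train_model <- function(records, config = backbone_config(), weights = loss_weights(),
                        vocab = atom_vocabulary(), epochs = 4L, lr = 1e-3,
                        lr_decay = 0.3,
                        noise_sd = 2.0, seed = 1L, coord_aug_sd = 0.15,
                        affinity_every = 1L,
                        verbose = FALSE) {
  stopifnot(length(records) >= 1L)
  params <- init_backbone_params(config, vocab, seed = substream_seed(seed, "init"))
  opt <- adam_state(params)
  scfg <- sampler_config(steps = 1L, noise_sd = noise_sd, seed = seed)
  n_steps <- epochs * length(records)
  order_all <- with_seed(substream_seed(seed, "shuffle"), {
    as.vector(vapply(seq_len(epochs), function(e) sample(length(records)),
                     integer(length(records))))
  })
  trace <- vector("list", n_steps)
  for (step in seq_len(n_steps)) {
    rec <- records[[order_all[step]]]
    lig <- ligand_drop_padding(rec$ligand)
    step_seed <- substream_seed(seed, "corrupt", step)
    t_step <- with_seed(step_seed, stats::runif(1, 0, 0.999))
    prior <- sample_prior(nrow(lig$coords), rec$pocket, scfg, vocab,
                          seed = substream_seed(seed, "prior", step))
    noisy <- with_seed(step_seed + 1L, {
      st <- corrupt_ligand(lig, t_step, prior, vocab)
      if (coord_aug_sd > 0)
        st$coords <- st$coords + matrix(stats::rnorm(length(st$coords), 0, coord_aug_sd),
                                        nrow(st$coords))
      st
    })
    tape <- ad_tape()
    res <- with_tape(tape, {
      leaves <- lapply(params, ad_leaf)
      penc <- pocket_encode(leaves, rec$pocket, config)
      dec <- ligand_decode(leaves, noisy, t_step, penc, config)
      # coordinate precision matters most near the data end of the flow:
      # ramp the MSE weight with t^2 (mean over t ~ lambda_c)
      w_t <- weights
      w_t$lambda_c <- weights$lambda_c * (0.5 + 1.5 * t_step^2)
      fm <- total_loss(dec, lig, w_t, vocab)
      d_true <- cross_distances(lig$coords, rec$pocket$coords)
      d_pred <- cross_distances(vof(dec$coords), rec$pocket$coords)
      conf <- confidence_loss(dec$conf_logits,
                              lddt_per_atom(d_true, d_pred))
      loss <- ad_add(fm$total, ad_scale(conf, weights$lambda_confidence))
      aff_term <- NA_real_
      if (length(rec$affinity) && step %% affinity_every == 0L) {
        dec1 <- ligand_decode(leaves, lig, 1, penc, config)
        y <- affinity_forward(leaves, dec1$feat, penc, dec1$feat$cross_edges, config)
        haff <- ad_huber_masked(y, rec$affinity)
        loss <- ad_add(loss, ad_scale(haff, weights$lambda_affinity))
        aff_term <- vof(haff)
      }
      if (!is.finite(vof(loss)))
        stop(sprintf("training diverged at step %d (loss %g); lower lr", step, vof(loss)))
      ad_backward(tape, loss)
      list(loss = vof(loss), terms = fm$terms, conf = vof(conf), aff = aff_term,
           grads = lapply(leaves, function(nd) nd$grad))
    })
    lr_step <- if (step > 2 * n_steps / 3) lr * lr_decay else lr
    upd <- adam_step(params, res$grads, opt, lr = lr_step)
    params <- upd$params; opt <- upd$state
    trace[[step]] <- c(step = step, t = t_step, loss = res$loss, res$terms,
                       ce_conf = res$conf, huber_aff = res$aff)
    if (verbose && step %% 100L == 0L)
      message(sprintf("step %d/%d loss %.4f", step, n_steps, res$loss))
  }
  new_pf_model(params, config, vocab,
               trace = as.data.frame(do.call(rbind, trace)))
}
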