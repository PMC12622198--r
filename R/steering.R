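# Inference-time steering by sequential Monte Carlo importance resampling:
# an ensemble of generation trajectories is periodically scored with the
# model's own affinity head (on the current denoised estimate), reweighted by
# a softmax of the reward and resampled multinomially, biasing final samples
# toward high-reward ligands without retraining.

#' Reward specification for steered generation
#'
#' @param objectives List of objectives; each a list with `pocket` (a
#'   [pocket_state()]), `endpoint` (one of pIC50/pKi/pKd/pEC50 or
#'   `"aggregate"`), `direction` (`"maximize"` or `"minimize"`) and `weight`
#'   (positive real). A dual-objective selectivity reward is one maximize
#'   objective on the on-target pocket plus one minimize objective on the
#'   off-target pocket.
#' @param temperature Softmax temperature lambda applied to rewards.
#' @return An object of class `reward_spec`.
#' @export
reward_spec <- function(objectives, temperature = 1) {
  if (!length(objectives)) stop("at least one objective is required")
  for (ob in objectives) {
    stopifnot(inherits(ob$pocket, "pocket_state"),
              ob$endpoint %in% c(affinity_endpoints, "aggregate"),
              ob$direction %in% c("maximize", "minimize"),
              is.finite(ob$weight))
  }
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(objectives = objectives, temperature = temperature),
            class = "reward_spec")
}

#' Evaluate the reward of a particle ensemble
#'
#' Scores each particle's current denoised estimate with the affinity head:
#' `score_i = sum_k w_k * sign_k * affinity(l1_i, pocket_k, endpoint_k)` with
#' sign +1 for maximize and -1 for minimize.
#'
#' @param particles List of [ligand_state()] denoised estimates.
#' @param spec A [reward_spec()].
#' @param model A trained `pf_model`.
#' @return Numeric scores, one per particle.
#' @export
evaluate_reward <- function(particles, spec, model) {
  scores <- numeric(length(particles))
  for (ob in spec$objectives) {
    sgn <- if (ob$direction == "maximize") 1 else -1
    penc <- pocket_encode(model$params, ob$pocket, model$config)
    for (i in seq_along(particles)) {
      dec <- ligand_decode(model$params, particles[[i]], 1, penc, model$config)
      y <- affinity_forward(model$params, dec$feat, penc, dec$feat$cross_edges,
                            model$config)
      val <- if (ob$endpoint == "aggregate")
        aggregate_endpoints(stats::setNames(as.numeric(y), affinity_endpoints))
      else as.numeric(y)[match(ob$endpoint, affinity_endpoints)]
      scores[i] <- scores[i] + ob$weight * sgn * val
    }
  }
  scores
}

#' Softmax resampling weights
#'
#' `w_i = exp(lambda * score_i) / sum_j exp(lambda * score_j)`, stabilized by
#' max subtraction (hence shift-invariant).
#'
#' @param scores Finite numeric scores.
#' @param lambda Temperature (default 1).
#' @return Probabilities summing to 1.
#' @export
resampling_weights <- function(scores, lambda = 1) {
  stopifnot(all(is.finite(scores)))
  softmax_vec(lambda * scores)
}

#' Multinomial particle resampling
#'
#' Draws `B` particle indices with replacement proportionally to the weights;
#' after resampling, weights are implicitly uniform.
#'
#' @param weights Probabilities (will be normalized).
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return Integer vector of `length(weights)` selected indices.
#' @export
resample_indices <- function(weights, seed = NULL) {
  if (any(weights < 0) || sum(weights) <= 0) stop("degenerate resampling weights")
  w <- weights / sum(weights)
  draw <- function() sample.int(length(w), length(w), replace = TRUE, prob = w)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# denoised estimate from a decoder output: predicted coordinates + argmax
# categories (the representation rewards are computed on)
denoised_estimate <- function(prediction, n) {
  bl <- vof(prediction$bond_logits)
  bm <- matrix(max.col(bl, ties.method = "first"), n, n, byrow = TRUE)
  ligand_state(vof(prediction$coords),
               atom_type = max.col(vof(prediction$type_logits), ties.method = "first"),
               charge = max.col(vof(prediction$charge_logits), ties.method = "first"),
               hybridization = max.col(vof(prediction$hyb_logits), ties.method = "first"),
               bonds = symmetrize_bonds(bm))
}

#' Steered ligand generation via sequential Monte Carlo
#'
#' Runs `B` parallel generation trajectories in the target pocket; at every
#' `every`-th integration step whose time lies in `[start, stop]` the current
#' denoised estimates are scored with [evaluate_reward()], converted to
#' softmax importance weights and multinomially resampled. Outside the window
#' the trajectories evolve unguided. With `start == stop` the window is empty
#' and the output equals unguided generation under the same seeds.
#'
#' @param model A trained `pf_model`.
#' @param pocket Generation pocket (usually the first objective's pocket).
#' @param spec A [reward_spec()].
#' @param B Number of particles (>= 2).
#' @param steering List with `start`, `stop` (times in \[0, 1\]) and `every`
#'   (resampling cadence in steps, default 10).
#' @param sampler A [sampler_config()].
#' @param sizes Atom counts as in [generate_ligands()].
#' @return List of `B` final [ligand_state()]s with attributes `scores`
#'   (final reward per ligand) and `n_resamples`.
#' @export
steered_generate <- function(model, pocket, spec, B = 16L,
                             steering = list(start = 0.5, stop = 1, every = 10L),
                             sampler = sampler_config(), sizes = 9L) {
  stopifnot(B >= 2L, steering$start >= 0, steering$stop <= 1,
            steering$start <= steering$stop)
  every <- steering$every %||% 10L
  cfg <- model$config; vocab <- model$vocab; p <- model$params
  penc <- pocket_encode(p, pocket, cfg)
  # one common particle size keeps resampled trajectories exchangeable
  nsizes <- rep(as.integer(sizes[1L]), B)
  states <- lapply(seq_len(B), function(b)
    sample_prior(nsizes[b], pocket, sampler, vocab,
                 seed = substream_seed(sampler$seed, "trajectory", b)))
  ts <- seq(0, 1, length.out = sampler$steps + 1L)
  n_resamples <- 0L
  scores <- rep(NA_real_, B)
  with_seed(substream_seed(sampler$seed, "steering"), {
    for (k in seq_len(sampler$steps)) {
      preds <- lapply(states, function(s) ligand_decode(p, s, ts[k], penc, cfg))
      in_window <- ts[k] >= steering$start && ts[k] < steering$stop &&
        steering$start < steering$stop
      if (in_window && (k %% every == 0L)) {
        l1 <- lapply(seq_len(B), function(b) denoised_estimate(preds[[b]], nsizes[b]))
        sc <- evaluate_reward(l1, spec, model)
        w <- resampling_weights(sc, spec$temperature)
        idx <- resample_indices(w)
        states <- states[idx]
        preds <- preds[idx]
        n_resamples <- n_resamples + 1L
      }
      states <- lapply(seq_len(B), function(b)
        integrate_step(states[[b]], preds[[b]], ts[k], ts[k + 1L] - ts[k], vocab))
    }
    scores <- evaluate_reward(states, spec, model)
  })
  attr(states, "scores") <- scores
  attr(states, "n_resamples") <- n_resamples
  states
}
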