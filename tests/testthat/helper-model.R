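# One shared trained model for the training-dependent acceptance properties
# (distribution recovery, affinity recovery, steering). Trained lazily on
# first use and cached for the remainder of the test run.
#
# Study conditions (documented in the methods vignette): 600 synthetic
# complexes at the generator defaults (500 train / 100 held out), the reduced
# study configuration of the backbone, 5 epochs with the affinity pass every
# second step, lambda_c = 3, lr 2e-3 (0.3x decay in the final third), prior
# noise 1.5 A, coordinate augmentation 0.25 A.

.study_cache <- new.env(parent = emptyenv())

study_backbone <- function() {
  backbone_config(enc_layers = 2L, dec_layers = 3L, d_inv_enc = 48L, d_inv_dec = 64L,
                  d_equi = 8L, latent_size = 8L, attention_heads = 4L, rbf_count = 48L,
                  d_edge = 12L, confidence_depth = 2L)
}

study_fixtures <- function() {
  if (is.null(.study_cache$records)) {
    .study_cache$records <-
      build_fixture_dataset(fixture_config(n_complexes = 600L, seed = 42L),
                            dir = NULL)$records
  }
  .study_cache$records
}

study_model <- function() {
  if (is.null(.study_cache$model)) {
    recs <- study_fixtures()
    .study_cache$model <- train_model(
      recs[1:500], study_backbone(), weights = loss_weights(lambda_c = 3),
      epochs = 5L, lr = 2e-3, noise_sd = 1.5, coord_aug_sd = 0.25,
      affinity_every = 2L, seed = 9L)
  }
  .study_cache$model
}

study_sampler <- function(seed, steps = 16L) {
  sampler_config(steps = steps, noise_sd = 1.5, seed = seed)
}
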