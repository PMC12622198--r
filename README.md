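# pocketflow

Desk-scale, pure-R implementation of SE(3)-equivariant joint
continuous/discrete flow matching for pocket-conditioned 3D ligand design.
One equivariant backbone serves three coupled tasks:

- **Generation** — ligand coordinates follow conditional flow matching on the
  linear path `x_t = (1-t)x0 + t x1` with a clean-endpoint decoder
  (`v = (X̂ - x_t)/(1-t)`); atom types, formal charges, hybridizations and
  bond orders follow a uniform-prior discrete flow with marginal
  `P(z_t = z1) = t + (1-t)/K`, sampled as a jump process. De novo,
  fragment-inpainting and interaction-channel modes share one backbone.
- **Affinity** — a pooled head (`C = 100` and `|L|` ligand pools,
  mean-pooled pocket, masked-mean ligand-pocket edges) predicts four
  nonnegative log-unit endpoints (pIC50, pKi, pKd, pEC50) trained with a
  masked mean Huber loss (δ = 1); `ΔG = -RT ln10 · pK` with
  `R = 1.987e-3 kcal/(K·mol)`, `T = 298 K`.
- **Confidence** — per-atom lDDT (12 Å strict inclusion, thresholds
  0.5/1/2/4 Å, neighbor count clamped to ≥ 1) binned into 50 classes for
  cross-entropy; the scalar pLDDT is 100 × mean expected bin center.
- **Steering** — sequential Monte Carlo over B parallel trajectories:
  rewards on denoised estimates, softmax weights
  `w_i = exp(λ ŷ_i)/Σ exp(λ ŷ_j)`, multinomial resampling; dual-objective
  rewards (maximize on-target, minimize off-target) give selectivity.

Everything trainable runs on a package-internal reverse-mode autodiff tape
over base-R matrices — no deep-learning runtime is required. A procedural
fixture generator emulates ligand-pocket complexes with an analytically
known contact-count affinity ground truth, so the full
train/sample/steer/predict loop runs on one CPU in minutes.

Who this is for: anyone who wants a fully inspectable, tested reference of
the method's contracts — equivariance, flow marginals, pooling semantics,
lDDT edge cases, SMC statistics — at a scale where every property can be
verified against brute-force oracles.

## Worked example

```r
library(pocketflow)

# 1. synthetic complexes with known affinity ground truth
fx   <- build_fixture_dataset(fixture_config(n_complexes = 60, seed = 7))
recs <- fx$records

# 2. train the joint model (a couple of minutes at this size)
cfg <- backbone_config(enc_layers = 1, dec_layers = 2, d_inv_enc = 32,
                       d_inv_dec = 48, d_equi = 8, latent_size = 8,
                       attention_heads = 2, rbf_count = 8, d_edge = 8,
                       confidence_depth = 1)
model <- train_model(recs[1:50], cfg, weights = loss_weights(lambda_c = 3),
                     epochs = 6, lr = 2e-3, noise_sd = 1.5, seed = 1)

# 3. generate ligands in a held-out pocket
ligs <- generate_ligands(model, recs[[55]]$pocket, n_ligands = 4, sizes = 9,
                         sampler_config(steps = 16, noise_sd = 1.5, seed = 2))
ligs[[1]]
#> ligand_state: 9 atoms (9 unmasked), 8 bonds

# 4. predict affinity + confidence for a held-out complex
res <- predict_affinity(model, recs[[56]]$ligand, recs[[56]]$pocket)
round(res$affinity, 2)
#> pIC50   pKi   pKd pEC50
#>  3.89  4.43  4.37  3.53
round(res$plddt, 1)
#> [1] 88.2
recs[[56]]$affinity["pIC50"]   # ground truth of the contact-count model
#>    pIC50
#> 2.929935
```

The four endpoints are correlated but distinct (they are affine transforms
of one latent in the synthetic ground truth), the pLDDT is high because the
input pose is the reference pose, and the prediction tracks the low true
potency of this loosely wrapped pocket. At this miniature training size the
ranking is already informative; the packaged study (500 complexes) reaches a
held-out Pearson near 0.9.

Steering toward potency, and away from an off-target pocket:

```r
spec <- reward_spec(list(
  list(pocket = recs[[55]]$pocket, endpoint = "pIC50",
       direction = "maximize", weight = 1),
  list(pocket = recs[[56]]$pocket, endpoint = "pIC50",
       direction = "minimize", weight = 1)))
out <- steered_generate(model, recs[[55]]$pocket, spec, B = 16,
                        steering = list(start = 0.5, stop = 1, every = 2),
                        sampler = sampler_config(steps = 16, noise_sd = 1.5,
                                                 seed = 3), sizes = 9)
mean(attr(out, "scores"))   # mean selectivity reward (on-target - off-target)
#> [1] 0.01788249
```

A selectivity reward near zero at this tiny training size reflects two toy
pockets the miniature model cannot yet tell far apart; the packaged study
separates on- and off-target predictions by several tenths of a log unit.

## Command line

A thin wrapper over the same functions lives at `inst/cli/pocketflow`:

```sh
Rscript inst/cli/pocketflow run.yaml steer.window=0.3,1 seed=11
```

with commands `make-fixtures`, `train`, `sample`, `steer`, `predict`,
`evaluate` configured in YAML (see `parse_run_config()`).

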