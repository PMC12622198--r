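# Shared helpers: tiny configurations, toy complexes, independent oracles.

tiny_config <- function(...) {
  backbone_config(enc_layers = 1L, dec_layers = 2L, d_inv_enc = 24L, d_inv_dec = 32L,
                  d_equi = 6L, latent_size = 6L, attention_heads = 2L, rbf_count = 6L,
                  d_edge = 6L, d_head = 12L, confidence_depth = 1L, ...)
}

test_complex <- function(lig_size = 8L, pock_size = 24L, seed = 1L,
                         vocab = atom_vocabulary()) {
  lig <- generate_toy_ligand(lig_size, seed = seed, vocab = vocab)
  pock <- generate_toy_pocket(lig, pock_size, seed = seed + 1000L, vocab = vocab)
  cm <- assemble_complex(lig, pock, source_id = sprintf("test_%d", seed))
  cm$affinity <- synthetic_affinity(cm, seed = seed + 2000L)
  cm
}

rigid_motion <- function(seed = 1L) {
  pocketflow:::with_seed(seed, {
    R <- pocketflow:::random_rotation()
    u <- stats::rnorm(3, 0, 5)
    list(R = R, u = u, apply = function(x) sweep(x %*% t(R), 2L, -u))
  })
}

# activate the (zero-initialized) residual coordinate updates of a model so
# equivariance tests exercise a moving coordinate path
activate_coord_updates <- function(model, seed = 99L) {
  pocketflow:::with_seed(seed, {
    for (nm in grep("\\.Wx$", names(model$params), value = TRUE))
      model$params[[nm]][] <- stats::rnorm(length(model$params[[nm]]), 0, 0.3)
  })
  model
}

## ---- independent oracles ----------------------------------------------------

# quadruple-loop lDDT (atoms x neighbors x thresholds), no vectorization
oracle_lddt <- function(d_true, d_pred, thresholds, inclusion = 12) {
  n <- nrow(d_true)
  out <- numeric(n)
  for (i in seq_len(n)) {
    b <- 0L
    acc <- 0
    for (j in seq_len(ncol(d_true))) {
      if (d_true[i, j] < inclusion) {
        b <- b + 1L
        for (cthr in thresholds) {
          if (abs(d_true[i, j] - d_pred[i, j]) < cthr)
            acc <- acc + 1 / length(thresholds)
        }
      }
    }
    out[i] <- acc / max(b, 1L)
  }
  out
}

# double-loop residue-level pocket membership
oracle_pocket_atoms <- function(protein_atoms, lig_coords, radius) {
  n <- nrow(protein_atoms)
  within <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(lig_coords))) {
      d <- sqrt(sum((c(protein_atoms$x[i], protein_atoms$y[i], protein_atoms$z[i]) -
                       lig_coords[j, ])^2))
      if (d < radius) within[i] <- TRUE
    }
  }
  keys <- paste(protein_atoms$chain, protein_atoms$resid)
  keys %in% unique(keys[within])
}

# nested-loop contact counter
oracle_contacts <- function(lig_coords, pock_coords, cutoff = 4) {
  cnt <- 0L
  for (i in seq_len(nrow(lig_coords)))
    for (j in seq_len(nrow(pock_coords)))
      if (sqrt(sum((lig_coords[i, ] - pock_coords[j, ])^2)) < cutoff) cnt <- cnt + 1L
  cnt
}

# pocket_state as a protein-atom table (for extract_pocket round trips)
pocket_as_protein <- function(pocket, vocab = atom_vocabulary()) {
  data.frame(x = pocket$coords[, 1], y = pocket$coords[, 2], z = pocket$coords[, 3],
             element = decode_label(vocab, "atom_types", pocket$atom_type),
             resid = pocket$residue_id, resname = pocket$residue_name,
             chain = pocket$chain_id, atom_name = "X", stringsAsFactors = FALSE)
}

bond_lengths_of <- function(state) {
  d <- as.matrix(stats::dist(state$coords))
  d[upper.tri(state$bonds) & state$bonds > 1L]
}
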