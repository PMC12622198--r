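#' One-hot encode a ligand state
#'
#' Expands the categorical fields of a [ligand_state()] into one-hot blocks:
#' per-atom matrices for element, formal charge and hybridization, and a
#' flattened per-pair block for bond orders (pair index `(i-1)*N + j`, `j`
#' fastest, matching the pairwise ops of the backbone).
#'
#' @param ligand A [ligand_state()].
#' @param vocab The [atom_vocabulary()] it is encoded in.
#' @return List with `type`, `charge`, `hybridization` (N x K one-hot
#'   matrices), `bonds` (N^2 x K_bond) and `n_atoms`.
#' @export
encode_ligand_features <- function(ligand, vocab) {
  validate_ligand_state(ligand, vocab)
  onehot <- function(idx, k) {
    m <- matrix(0, length(idx), k)
    m[cbind(seq_along(idx), idx)] <- 1
    m
  }
  n <- nrow(ligand$coords)
  list(type = onehot(ligand$atom_type, length(vocab$atom_types)),
       charge = onehot(ligand$charge, length(vocab$charge_values)),
       hybridization = onehot(ligand$hybridization, length(vocab$hybridizations)),
       bonds = onehot(as.vector(t(ligand$bonds)), length(vocab$bond_orders)),
       n_atoms = n)
}

#' Decode one-hot ligand features back to category indices
#'
#' Inverse of [encode_ligand_features()] (argmax per row), combined with
#' coordinates into a [ligand_state()].
#'
#' @param feats Feature bundle from [encode_ligand_features()] (or soft
#'   probabilities of the same shapes).
#' @param coords N x 3 coordinate matrix.
#' @param vocab The vocabulary.
#' @return A [ligand_state()].
#' @export
decode_ligand_features <- function(feats, coords, vocab) {
  n <- feats$n_atoms
  bm <- matrix(max.col(feats$bonds, ties.method = "first"), n, n, byrow = TRUE)
  bm <- symmetrize_bonds(bm)
  ligand_state(coords,
               atom_type = max.col(feats$type, ties.method = "first"),
               charge = max.col(feats$charge, ties.method = "first"),
               hybridization = max.col(feats$hybridization, ties.method = "first"),
               bonds = bm)
}

# force symmetry + no-bond diagonal on an integer bond matrix
symmetrize_bonds <- function(bm) {
  bm[lower.tri(bm)] <- t(bm)[lower.tri(bm)]
  diag(bm) <- 1L
  bm
}
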