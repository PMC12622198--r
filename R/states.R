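#' Ligand state: coordinates plus categorical structure
#'
#' The object that the flow both corrupts and generates: 3D coordinates in
#' Angstrom together with per-atom category indices for element, formal charge
#' and hybridization, and a symmetric per-pair bond-order matrix.
#'
#' @param coords Numeric N x 3 matrix of coordinates (Angstrom).
#' @param atom_type,charge,hybridization Integer category indices per atom
#'   (1-based, into an [atom_vocabulary()]).
#' @param bonds Integer N x N symmetric matrix of bond-order indices with the
#'   no-bond category (index 1) on the diagonal.
#' @param atom_mask Logical per atom; `FALSE` marks padding. Masked atoms carry
#'   index 1 and zero coordinates.
#'
#' @return An object of class `ligand_state`.
#' @export
ligand_state <- function(coords, atom_type, charge, hybridization, bonds,
                         atom_mask = rep(TRUE, nrow(coords))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  x <- structure(list(coords = coords,
                      atom_type = as.integer(atom_type),
                      charge = as.integer(charge),
                      hybridization = as.integer(hybridization),
                      bonds = matrix(as.integer(bonds), nrow(coords)),
                      atom_mask = as.logical(atom_mask)),
                 class = "ligand_state")
  validate_ligand_state(x)
  x
}

#' Validate a ligand state against its structural invariants
#'
#' Checks coordinate finiteness, bond-matrix symmetry, a no-bond diagonal,
#' index ranges (when a vocabulary is supplied) and the padding contract.
#'
#' @param x A [ligand_state()].
#' @param vocab Optional [atom_vocabulary()] for index-range checks.
#' @return `x`, invisibly; errors describe the violated invariant.
#' @export
validate_ligand_state <- function(x, vocab = NULL) {
  n <- nrow(x$coords)
  if (ncol(x$coords) != 3L) stop("coords must be N x 3")
  if (!all(is.finite(x$coords[x$atom_mask, , drop = FALSE])))
    stop("non-finite coordinates on unmasked atoms")
  lens <- c(length(x$atom_type), length(x$charge), length(x$hybridization),
            length(x$atom_mask))
  if (any(lens != n)) stop("per-atom fields must have length N")
  if (!identical(dim(x$bonds), c(n, n))) stop("bonds must be N x N")
  if (!isTRUE(all.equal(x$bonds, t(x$bonds)))) stop("bond matrix is not symmetric")
  if (n > 0L && any(diag(x$bonds) != 1L)) stop("bond diagonal must be the no-bond category")
  if (any(x$atom_type < 1L) || any(x$charge < 1L) || any(x$hybridization < 1L) ||
      any(x$bonds < 1L))
    stop("category indices must be >= 1")
  if (!is.null(vocab)) {
    if (any(x$atom_type > length(vocab$atom_types))) stop("atom_type index out of vocabulary")
    if (any(x$charge > length(vocab$charge_values))) stop("charge index out of vocabulary")
    if (any(x$hybridization > length(vocab$hybridizations))) stop("hybridization index out of vocabulary")
    if (any(x$bonds > length(vocab$bond_orders))) stop("bond index out of vocabulary")
  }
  if (any(!x$atom_mask)) {
    pad <- !x$atom_mask
    if (any(x$coords[pad, ] != 0) || any(x$atom_type[pad] != 1L))
      stop("masked padding atoms must carry index 1 and zero coordinates")
  }
  invisible(x)
}

#' @export
print.ligand_state <- function(x, ...) {
  cat(sprintf("ligand_state: %d atoms (%d unmasked), %d bonds\n",
              nrow(x$coords), sum(x$atom_mask),
              sum(x$bonds[upper.tri(x$bonds)] > 1L)))
  invisible(x)
}

# drop padding atoms, returning a dense state
ligand_drop_padding <- function(x) {
  if (all(x$atom_mask)) return(x)
  keep <- which(x$atom_mask)
  ligand_state(x$coords[keep, , drop = FALSE], x$atom_type[keep], x$charge[keep],
               x$hybridization[keep], x$bonds[keep, keep, drop = FALSE])
}

#' Pocket state: the conditioning context
#'
#' Pocket atom coordinates and element indices with residue bookkeeping.
#'
#' @param coords Numeric M x 3 matrix (Angstrom).
#' @param atom_type Integer element indices (into the vocabulary atom types,
#'   with out-of-vocabulary protein elements mapped on extraction).
#' @param residue_id Integer residue serial per atom.
#' @param residue_name,chain_id Character per atom.
#' @param atom_mask Logical per atom.
#' @return An object of class `pocket_state`.
#' @export
pocket_state <- function(coords, atom_type, residue_id,
                         residue_name = rep("UNK", nrow(coords)),
                         chain_id = rep("A", nrow(coords)),
                         atom_mask = rep(TRUE, nrow(coords))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (!all(is.finite(coords))) stop("pocket coordinates must be finite")
  structure(list(coords = coords,
                 atom_type = as.integer(atom_type),
                 residue_id = as.integer(residue_id),
                 residue_name = as.character(residue_name),
                 chain_id = as.character(chain_id),
                 atom_mask = as.logical(atom_mask)),
            class = "pocket_state")
}

#' @export
print.pocket_state <- function(x, ...) {
  cat(sprintf("pocket_state: %d atoms, %d residues\n",
              nrow(x$coords), length(unique(paste(x$chain_id, x$residue_id)))))
  invisible(x)
}

#' A ligand-pocket complex with optional affinity annotations
#'
#' @param ligand A [ligand_state()].
#' @param pocket A [pocket_state()] sharing the ligand's coordinate frame.
#' @param affinity Named numeric vector with any of `pIC50`, `pKi`, `pKd`,
#'   `pEC50` (log units, nonnegative); missing endpoints are simply absent.
#' @param source_id Identifier string.
#' @return An object of class `complex_record`.
#' @export
complex_record <- function(ligand, pocket, affinity = numeric(0), source_id = "complex") {
  stopifnot(inherits(ligand, "ligand_state"), inherits(pocket, "pocket_state"))
  if (length(affinity)) {
    ok <- names(affinity) %in% c("pIC50", "pKi", "pKd", "pEC50")
    if (!all(ok)) stop("unknown affinity endpoint: ", paste(names(affinity)[!ok], collapse = ", "))
    if (any(affinity < 0)) stop("affinity values are log units and must be >= 0")
  }
  structure(list(ligand = ligand, pocket = pocket,
                 affinity = affinity, source_id = as.character(source_id)),
            class = "complex_record")
}

#' @export
print.complex_record <- function(x, ...) {
  cat(sprintf("complex_record '%s': %d ligand atoms / %d pocket atoms; endpoints: %s\n",
              x$source_id, nrow(x$ligand$coords), nrow(x$pocket$coords),
              if (length(x$affinity)) paste(names(x$affinity), collapse = ",") else "none"))
  invisible(x)
}

# hybridization from the bond environment; shared by the SDF reader and the
# toy generator so that write -> read round-trips are category-stable
derive_hybridization <- function(bonds, vocab) {
  labs <- vocab$bond_orders
  n <- nrow(bonds)
  out <- integer(n)
  for (i in seq_len(n)) {
    bl <- labs[bonds[i, ]]
    if (any(bl == "triple") || sum(bl == "double") >= 2L) h <- "sp"
    else if (any(bl %in% c("double", "aromatic"))) h <- "sp2"
    else h <- "sp3"
    out[i] <- match(h, vocab$hybridizations)
  }
  out
}
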