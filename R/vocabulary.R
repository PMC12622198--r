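#' Categorical vocabulary for ligand atoms and bonds
#'
#' Defines the ordered label sets used to encode atom elements, formal charges,
#' hybridization states and bond orders as category indices. The first bond
#' label must be `"none"` (the no-bond category); encoding followed by decoding
#' any in-vocabulary label is the identity.
#'
#' @param atom_types Character vector of element symbols, in encoding order.
#' @param charge_values Integer vector of formal charges.
#' @param hybridizations Character vector of hybridization labels.
#' @param bond_orders Character vector of bond-order labels; must start with
#'   `"none"`.
#'
#' @details The defaults cover drug-like heavy-atom chemistry at toy scale:
#' C/N/O/F/P/S/Cl/Br/I, charges -2..+2, sp/sp2/sp3/other and
#' none/single/double/triple/aromatic bonds. Hydrogens are not represented by
#' default (heavy-atom-only convention).
#'
#' @return An object of class `atom_vocabulary`.
#' @export
#' @examples
#' v <- atom_vocabulary()
#' encode_label(v, "atom_types", "N")
atom_vocabulary <- function(atom_types = c("C", "N", "O", "F", "P", "S", "Cl", "Br", "I"),
                            charge_values = -2:2,
                            hybridizations = c("sp", "sp2", "sp3", "other"),
                            bond_orders = c("none", "single", "double", "triple", "aromatic")) {
  chk <- function(x, nm) {
    if (length(x) == 0L || anyDuplicated(x))
      stop(sprintf("vocabulary field '%s' must be nonempty and duplicate-free", nm))
  }
  chk(atom_types, "atom_types"); chk(charge_values, "charge_values")
  chk(hybridizations, "hybridizations"); chk(bond_orders, "bond_orders")
  if (bond_orders[1L] != "none")
    stop("bond_orders must have 'none' as its first (no-bond) category")
  structure(list(atom_types = as.character(atom_types),
                 charge_values = as.integer(charge_values),
                 hybridizations = as.character(hybridizations),
                 bond_orders = as.character(bond_orders)),
            class = "atom_vocabulary")
}

#' Encode labels as 1-based category indices
#'
#' @param vocab An [atom_vocabulary()].
#' @param field One of `"atom_types"`, `"charge_values"`, `"hybridizations"`,
#'   `"bond_orders"`.
#' @param labels Labels (or integer charges) to encode.
#' @return Integer indices into the vocabulary field.
#' @export
encode_label <- function(vocab, field, labels) {
  lv <- vocab[[field]]
  idx <- match(labels, lv)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop(sprintf("out-of-vocabulary %s: %s", field, paste(bad, collapse = ", ")))
  }
  idx
}

#' Decode 1-based category indices back to labels
#' @inheritParams encode_label
#' @param idx Integer indices.
#' @return The labels at `idx`.
#' @export
decode_label <- function(vocab, field, idx) {
  lv <- vocab[[field]]
  if (any(idx < 1L | idx > length(lv))) stop(sprintf("index out of range for %s", field))
  lv[idx]
}

#' @export
print.atom_vocabulary <- function(x, ...) {
  cat("atom_vocabulary:",
      length(x$atom_types), "elements,",
      length(x$charge_values), "charges,",
      length(x$hybridizations), "hybridizations,",
      length(x$bond_orders), "bond orders\n")
  invisible(x)
}

# maximum heavy-atom valence per element (aromatic counted as 1.5)
element_max_valence <- function(el) {
  v <- c(C = 4, N = 4, O = 2, F = 1, P = 5, S = 6, Cl = 1, Br = 1, I = 1)
  unname(v[el])
}

bond_order_numeric <- function(label) {
  v <- c(none = 0, single = 1, double = 2, triple = 3, aromatic = 1.5)
  unname(v[label])
}
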