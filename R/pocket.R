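#' Extract a binding pocket around a reference ligand
#'
#' Selects the protein atoms forming the conditioning pocket: by default every
#' residue with at least one atom within `radius_A` of any ligand atom is
#' included whole (residue-level cutting keeps side chains chemically
#' complete); `level = "atom"` instead keeps exactly the atoms inside the
#' cutoff. Complexes whose pocket falls outside `[min_atoms, max_atoms]` are
#' rejected with an error, mirroring dataset-level filtering.
#'
#' @param protein_atoms Protein-atom table (see [read_pocket_pdb()]).
#' @param ligand A [ligand_state()] in the same coordinate frame.
#' @param radius_A Cutoff radius in Angstrom (default 7).
#' @param min_atoms,max_atoms Accepted pocket size bounds (defaults 10 and
#'   800); overridable for toy fixtures.
#' @param level `"residue"` (default) or `"atom"` inclusion.
#' @param vocab Vocabulary for element encoding; protein elements outside it
#'   are mapped to carbon (the backbone only consumes coarse element identity).
#' @return A [pocket_state()].
#' @export
extract_pocket <- function(protein_atoms, ligand, radius_A = 7,
                           min_atoms = 10L, max_atoms = 800L,
                           level = c("residue", "atom"),
                           vocab = atom_vocabulary()) {
  level <- match.arg(level)
  stopifnot(radius_A > 0, nrow(ligand$coords) >= 1L)
  P <- as.matrix(protein_atoms[, c("x", "y", "z")])
  L <- ligand$coords[ligand$atom_mask, , drop = FALSE]
  # min distance from each protein atom to the ligand
  d2 <- outer(rowSums(P^2), rowSums(L^2), "+") - 2 * P %*% t(L)
  mind <- sqrt(pmax(apply(d2, 1L, min), 0))
  inside <- mind < radius_A
  keep <- if (level == "residue") {
    rkey <- paste(protein_atoms$chain, protein_atoms$resid)
    rkey %in% unique(rkey[inside])
  } else inside
  m <- sum(keep)
  if (m < min_atoms)
    stop(sprintf("too few pocket atoms: %d < %d within %.1f A", m, min_atoms, radius_A))
  if (m > max_atoms)
    stop(sprintf("too many pocket atoms: %d > %d", m, max_atoms))
  sel <- protein_atoms[keep, , drop = FALSE]
  el <- sel$element
  el[!(el %in% vocab$atom_types)] <- "C"
  pocket_state(coords = as.matrix(sel[, c("x", "y", "z")]),
               atom_type = encode_label(vocab, "atom_types", el),
               residue_id = sel$resid,
               residue_name = sel$resname,
               chain_id = sel$chain)
}

#' Assemble a complex record, re-centering on the pocket centroid
#'
#' Pairs a ligand with its extracted pocket and moves both into the pocket
#' centroid frame (the origin convention under which the model is trained;
#' only relative geometry matters downstream).
#'
#' @param ligand A [ligand_state()].
#' @param pocket A [pocket_state()].
#' @param affinity Named numeric endpoint vector (log units), optional.
#' @param source_id Identifier.
#' @param recenter Re-center on the pocket centroid (default `TRUE`).
#' @return A [complex_record()].
#' @export
assemble_complex <- function(ligand, pocket, affinity = numeric(0),
                             source_id = "complex", recenter = TRUE) {
  if (recenter) {
    ctr <- colMeans(pocket$coords)
    pocket$coords <- sweep(pocket$coords, 2L, ctr)
    lc <- ligand$coords
    lc[ligand$atom_mask, ] <- sweep(lc[ligand$atom_mask, , drop = FALSE], 2L, ctr)
    ligand$coords <- lc
  }
  complex_record(ligand, pocket, affinity, source_id)
}

#' Read an affinity sidecar table
#'
#' CSV with columns `source_id,endpoint,value`; endpoints are one of pIC50,
#' pKi, pKd, pEC50 with values in log units.
#'
#' @param path CSV path.
#' @return A named list mapping `source_id` to a named endpoint vector.
#' @export
read_affinity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source_id", "endpoint", "value")
  if (!all(need %in% names(df))) stop("affinity CSV must have columns ", paste(need, collapse = ","))
  bad <- setdiff(unique(df$endpoint), c("pIC50", "pKi", "pKd", "pEC50"))
  if (length(bad)) stop("unknown endpoint(s): ", paste(bad, collapse = ", "))
  out <- list()
  for (sid in unique(df$source_id)) {
    sub <- df[df$source_id == sid, ]
    out[[sid]] <- stats::setNames(sub$value, sub$endpoint)
  }
  out
}

#' Write an affinity sidecar table
#' @param affinities Named list of named endpoint vectors.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_affinity_csv <- function(affinities, path) {
  rows <- do.call(rbind, lapply(names(affinities), function(sid) {
    a <- affinities[[sid]]
    if (!length(a)) return(NULL)
    data.frame(source_id = sid, endpoint = names(a), value = as.numeric(a),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) rows <- data.frame(source_id = character(0), endpoint = character(0),
                                        value = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
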