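# PDB reading/writing via bio3d, with the altloc and error-reporting policies
# applied on top (bio3d reports neither line numbers nor an altloc filter).

#' Read protein atoms from a PDB file
#'
#' Returns ATOM records as a protein-atom table and HETATM records separately.
#' When alternate locations are present only the highest-occupancy altloc of
#' each atom is retained (ties broken by altloc letter order).
#'
#' @param path Path to a PDB file.
#' @return A list with data frames `protein` and `hetero`, each with columns
#'   `x`, `y`, `z`, `element`, `resid` (residue serial), `resname`, `chain`,
#'   `atom_name`.
#' @export
read_pocket_pdb <- function(path) {
  if (!file.exists(path)) stop("no such PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("empty structure: no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(!is.finite(xyz)))
      stop(sprintf("malformed coordinate field at line %d of %s", i, path))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE))
  at <- pdb$atom
  # altloc filter: among records that share (type, chain, residue, atom name)
  # and carry altloc letters, keep the highest occupancy (ties by letter)
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$type, at$chain, at$resno, at$elety)
  has_alt <- key %in% unique(key[at$alt != ""])
  ord <- order(key, -at$o, at$alt)
  dup <- duplicated(key[ord]) & has_alt[ord]
  keep_rows <- rownames(at)[ord][!dup]
  at <- at[rownames(at) %in% keep_rows, ]
  elem <- trimws(at$elesy)
  blank <- !nzchar(elem) | is.na(elem)
  elem[blank] <- substr(gsub("[^A-Za-z].*$", "", trimws(at$elety[blank])), 1L, 1L)
  tab <- data.frame(x = at$x, y = at$y, z = at$z,
                    element = elem,
                    resid = at$resno,
                    resname = at$resid,
                    chain = at$chain,
                    atom_name = trimws(at$elety),
                    stringsAsFactors = FALSE)
  list(protein = tab[at$type == "ATOM", , drop = FALSE],
       hetero = tab[at$type == "HETATM", , drop = FALSE])
}

#' Write a pocket (or any protein-atom table) as a PDB file
#'
#' @param atoms Either a `pocket_state` or a protein-atom table as returned by
#'   [read_pocket_pdb()].
#' @param path Output path.
#' @param vocab Vocabulary used to decode `pocket_state` atom types.
#' @return `path`, invisibly.
#' @export
write_pocket_pdb <- function(atoms, path, vocab = atom_vocabulary()) {
  if (inherits(atoms, "pocket_state")) {
    el <- decode_label(vocab, "atom_types", atoms$atom_type)
    # PDB atom names must be unique within a residue
    nm <- paste0(el, stats::ave(seq_along(el), atoms$residue_id, atoms$chain_id,
                                FUN = seq_along))
    atoms <- data.frame(x = atoms$coords[, 1], y = atoms$coords[, 2], z = atoms$coords[, 3],
                        element = el,
                        resid = atoms$residue_id,
                        resname = atoms$residue_name,
                        chain = atoms$chain_id,
                        atom_name = nm,
                        stringsAsFactors = FALSE)
  }
  n <- nrow(atoms)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
                   type = rep("ATOM", n),
                   resno = atoms$resid,
                   resid = atoms$resname,
                   chain = atoms$chain,
                   elety = atoms$atom_name,
                   elesy = atoms$element,
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}
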