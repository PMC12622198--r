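# SDF (MDL V2000) reading and writing.
#
# Written in-package because the formal-charge block (M  CHG) and 4-decimal
# coordinate precision are part of the ligand contract. Aromatic bonds use MDL
# order code 4. Only heavy atoms are expected; records are separated by $$$$.

sdf_bond_code <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)

#' Read ligands from an SDF file
#'
#' Parses every V2000 record into a [ligand_state()]. Bond matrices are
#' symmetrized, formal charges taken from `M  CHG` blocks and hybridization
#' derived from the bond environment (SDF does not store it). SD data tags are
#' attached as the `props` attribute of each state.
#'
#' @param path Path to an SDF file.
#' @param vocab An [atom_vocabulary()]; elements outside it raise an error
#'   naming the element rather than being dropped.
#' @return A list of [ligand_state()] objects (empty list for an empty file).
#' @export
read_ligand_sdf <- function(path, vocab = atom_vocabulary()) {
  if (!file.exists(path)) stop("no such SDF file: ", path)
  lines <- readLines(path, warn = FALSE)
  # strip trailing blank lines
  while (length(lines) && !nzchar(trimws(lines[length(lines)]))) lines <- head(lines, -1L)
  if (!length(lines)) return(list())
  recs <- split(lines, cumsum(c(0L, head(lines == "$$$$", -1L))))
  out <- list()
  for (r in seq_along(recs)) {
    block <- recs[[r]]
    block <- block[block != "$$$$"]
    if (!length(block) || all(!nzchar(trimws(block)))) next
    st <- tryCatch(parse_sdf_record(block, vocab),
                   vocab_error = function(e) stop(e),
                   error = function(e)
                     stop(sprintf("SDF parse failure in record %d: %s", r, conditionMessage(e)),
                          call. = FALSE))
    attr(st, "source_id") <- trimws(block[1L])
    out[[length(out) + 1L]] <- st
  }
  out
}

parse_sdf_record <- function(block, vocab) {
  if (length(block) < 4L) stop("record too short")
  counts <- block[4L]
  natoms <- as.integer(substr(counts, 1L, 3L))
  nbonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(natoms) || is.na(nbonds)) stop("bad counts line")
  atom_lines <- block[4L + seq_len(natoms)]
  coords <- matrix(NA_real_, natoms, 3L)
  elements <- character(natoms)
  for (i in seq_len(natoms)) {
    ln <- atom_lines[i]
    coords[i, ] <- c(as.numeric(substr(ln, 1L, 10L)),
                     as.numeric(substr(ln, 11L, 20L)),
                     as.numeric(substr(ln, 21L, 30L)))
    elements[i] <- trimws(substr(ln, 31L, 34L))
  }
  if (any(!is.finite(coords))) stop("unreadable atom coordinates")
  bad <- setdiff(unique(elements), vocab$atom_types)
  if (length(bad)) {
    cond <- structure(class = c("vocab_error", "error", "condition"),
                      list(message = paste0("out-of-vocabulary element: ",
                                            paste(bad, collapse = ", ")),
                           call = NULL))
    stop(cond)
  }
  bonds <- matrix(1L, natoms, natoms)
  bond_lines <- block[4L + natoms + seq_len(nbonds)]
  for (ln in bond_lines) {
    i <- as.integer(substr(ln, 1L, 3L))
    j <- as.integer(substr(ln, 4L, 6L))
    code <- as.integer(substr(ln, 7L, 9L))
    lab <- names(sdf_bond_code)[match(code, sdf_bond_code)]
    if (is.na(i) || is.na(j) || is.na(lab)) stop("bad bond line: ", ln)
    idx <- match(lab, vocab$bond_orders)
    bonds[i, j] <- idx
    bonds[j, i] <- idx
  }
  charges <- integer(natoms)  # formal charge values, default 0
  rest <- block[-seq_len(4L + natoms + nbonds)]
  for (ln in grep("^M  CHG", rest, value = TRUE)) {
    flds <- as.integer(strsplit(trimws(substr(ln, 7L, nchar(ln))), "\\s+")[[1]])
    npairs <- flds[1L]
    for (k in seq_len(npairs)) {
      charges[flds[2L * k]] <- flds[2L * k + 1L]
    }
  }
  props <- list()
  tag_at <- grep("^> *<", rest)
  for (ti in tag_at) {
    nm <- sub("^> *<([^>]+)>.*$", "\\1", rest[ti])
    if (ti + 1L <= length(rest)) props[[nm]] <- trimws(rest[ti + 1L])
  }
  st <- ligand_state(
    coords = coords,
    atom_type = encode_label(vocab, "atom_types", elements),
    charge = encode_label(vocab, "charge_values", charges),
    hybridization = derive_hybridization(bonds, vocab),
    bonds = bonds)
  attr(st, "props") <- props
  st
}

#' Write ligands to an SDF file
#'
#' Emits one V2000 record per state with coordinates at 4 decimals, `M  CHG`
#' blocks for nonzero formal charges and optional SD data tags. Padding atoms
#' (mask `FALSE`) are omitted.
#'
#' @param ligands A list of [ligand_state()] objects (may be empty).
#' @param path Output path.
#' @param vocab The [atom_vocabulary()] the states are encoded in.
#' @param ids Optional record titles; defaults to `source_id` attributes or
#'   `lig_<i>`.
#' @param props Optional list (one element per ligand) of named SD tag values,
#'   e.g. steering scores.
#' @return `path`, invisibly.
#' @export
write_ligand_sdf <- function(ligands, path, vocab = atom_vocabulary(),
                             ids = NULL, props = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ligands)) {
    lg <- ligands[[k]]
    validate_ligand_state(lg, vocab)
    lg <- ligand_drop_padding(lg)
    n <- nrow(lg$coords)
    id <- if (!is.null(ids)) ids[[k]] else {
      sid <- attr(ligands[[k]], "source_id")
      if (is.null(sid)) sprintf("lig_%d", k) else sid
    }
    ut <- which(upper.tri(lg$bonds) & lg$bonds > 1L, arr.ind = TRUE)
    writeLines(c(id, "  pocketflow", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(ut)), con)
    els <- decode_label(vocab, "atom_types", lg$atom_type)
    for (i in seq_len(n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         lg$coords[i, 1], lg$coords[i, 2], lg$coords[i, 3], els[i]), con)
    }
    if (nrow(ut)) {
      labs <- decode_label(vocab, "bond_orders", lg$bonds[ut])
      for (b in seq_len(nrow(ut))) {
        writeLines(sprintf("%3d%3d%3d  0", ut[b, 1L], ut[b, 2L],
                           sdf_bond_code[[labs[b]]]), con)
      }
    }
    chg <- decode_label(vocab, "charge_values", lg$charge)
    nz <- which(chg != 0L)
    if (length(nz)) {
      # M CHG lines carry at most 8 atom/charge pairs each
      for (grp in split(nz, ceiling(seq_along(nz) / 8L))) {
        writeLines(paste0("M  CHG", sprintf("%3d", length(grp)),
                          paste0(sprintf("%4d%4d", grp, chg[grp]), collapse = "")), con)
      }
    }
    writeLines("M  END", con)
    pr <- if (!is.null(props)) props[[k]] else attr(ligands[[k]], "props")
    for (nm in names(pr)) {
      writeLines(c(sprintf(">  <%s>", nm), as.character(pr[[nm]]), ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}
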