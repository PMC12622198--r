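# Procedural toy ligand-pocket complexes with an analytically known affinity
# ground truth. Geometry is template-based (rings, chains, branched chains)
# with canonical bond lengths, so the training distribution is known in closed
# form; the affinity ground truth is a pocket-contact linear model, which makes
# it recomputable by a brute-force oracle and forces any successful predictor
# to use pocket context.

#' Configuration for a synthetic fixture dataset
#'
#' @param n_complexes Number of complexes.
#' @param ligand_size_range Heavy-atom count range, drawn uniformly.
#' @param pocket_size_range Pocket atom count range, drawn uniformly.
#' @param seed Master seed; every record derives counter-based substreams from
#'   it, so records are independent of insertion order.
#' @param noise_sd Geometric jitter around canonical bond geometry (Angstrom).
#' @param affinity_coefficients `c(intercept, per-contact, per-heavy-atom)` of
#'   the ground-truth pIC50 model.
#' @param affinity_noise_sd Observation noise on each endpoint (log units).
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(n_complexes = 500L,
                           ligand_size_range = c(6L, 12L),
                           pocket_size_range = c(24L, 48L),
                           seed = 1L,
                           noise_sd = 0.04,
                           affinity_coefficients = c(2.0, 0.1, 0.02),
                           affinity_noise_sd = 0.3) {
  stopifnot(n_complexes >= 0, noise_sd >= 0, affinity_noise_sd >= 0,
            length(ligand_size_range) == 2L, diff(ligand_size_range) >= 0,
            ligand_size_range[1] > 0,
            length(pocket_size_range) == 2L, diff(pocket_size_range) >= 0,
            pocket_size_range[1] > 0,
            length(affinity_coefficients) == 3L)
  structure(list(n_complexes = as.integer(n_complexes),
                 ligand_size_range = as.integer(ligand_size_range),
                 pocket_size_range = as.integer(pocket_size_range),
                 seed = as.integer(seed),
                 noise_sd = noise_sd,
                 affinity_coefficients = as.numeric(affinity_coefficients),
                 affinity_noise_sd = affinity_noise_sd),
            class = "fixture_config")
}

#' Generate a toy ligand
#'
#' Builds a connected heavy-atom molecule from a geometric template with bond
#' lengths near canonical values (single 1.54, double 1.34, aromatic 1.39
#' Angstrom), elements assigned to respect maximum valences, and hybridization
#' derived from the bond environment. Deterministic given `seed`.
#'
#' @param size Atom count, between 3 and 32.
#' @param seed Integer seed.
#' @param template `"random"`, `"ring"` (aromatic 6-ring, planar),
#'   `"chain"` or `"branched"`.
#' @param noise_sd Coordinate jitter (Angstrom); ring jitter stays in-plane.
#' @param vocab Vocabulary.
#' @return A [ligand_state()].
#' @export
generate_toy_ligand <- function(size, seed = 1L, template = "random",
                                noise_sd = 0.04, vocab = atom_vocabulary()) {
  if (size < 3L || size > 32L) stop("ligand size must be in [3, 32]")
  with_seed(seed, {
    if (template == "random")
      template <- sample(c(if (size >= 6L) "ring", "chain", "branched"), 1L)
    n <- as.integer(size)
    bonds <- matrix(1L, n, n)
    bidx <- function(lab) match(lab, vocab$bond_orders)
    set_bond <- function(i, j, lab) {
      bonds[i, j] <<- bidx(lab); bonds[j, i] <<- bidx(lab)
    }
    coords <- matrix(0, n, 3L)
    chain_geom <- function(m, origin = c(0, 0, 0), dir = 1) {
      # tetrahedral zigzag in the xz plane
      a <- 1.54 * sin(109.47 * pi / 360); b <- 1.54 * cos(109.47 * pi / 360)
      p <- matrix(0, m, 3L)
      p[1L, ] <- origin
      for (i in seq_len(m - 1L))
        p[i + 1L, ] <- p[i, ] + c(a, 0, dir * b * (-1)^i)
      p
    }
    if (template == "ring") {
      nr <- 6L
      ang <- 2 * pi * (seq_len(nr) - 1L) / nr
      r <- 1.39 / (2 * sin(pi / nr))
      coords[1:nr, ] <- cbind(r * cos(ang), r * sin(ang), 0)
      for (i in seq_len(nr)) set_bond(i, if (i == nr) 1L else i + 1L, "aromatic")
      if (n > nr) {  # grow a substituent chain radially off ring atom 1
        m <- n - nr
        u <- coords[1L, ] / sqrt(sum(coords[1L, ]^2))
        for (k in seq_len(m)) coords[nr + k, ] <- coords[1L, ] + u * 1.54 * k
        set_bond(1L, nr + 1L, "single")
        if (m > 1L) for (k in seq_len(m - 1L)) set_bond(nr + k, nr + k + 1L, "single")
      }
      planar <- seq_len(nr)
    } else if (template == "chain") {
      coords <- chain_geom(n)
      for (i in seq_len(n - 1L)) set_bond(i, i + 1L, "single")
      # occasional double bond, never adjacent to another double
      for (i in seq_len(n - 1L)) {
        if (stats::runif(1) < 0.2) {
          nb <- bonds[c(i, i + 1L), , drop = FALSE]
          if (!any(nb == bidx("double"))) {
            set_bond(i, i + 1L, "double")
            d <- coords[i + 1L, ] - coords[i, ]
            coords[(i + 1L):n, ] <- sweep(coords[(i + 1L):n, , drop = FALSE], 2L,
                                          d * (1 - 1.34 / 1.54), "-")
          }
        }
      }
      planar <- integer(0)
    } else {  # branched
      nb <- max(3L, n - sample(1:max(1L, n %/% 3L), 1L))
      coords[seq_len(nb), ] <- chain_geom(nb)
      for (i in seq_len(nb - 1L)) set_bond(i, i + 1L, "single")
      host <- sample(2:(nb - 1L), n - nb, replace = (n - nb) > (nb - 2L))
      for (k in seq_len(n - nb)) {
        i <- nb + k
        side <- c(0, 1.54 * ifelse(sum(host == host[k] & seq_along(host) < k) %% 2 == 0, 1, -1), 0)
        coords[i, ] <- coords[host[k], ] + side
        set_bond(host[k], i, "single")
      }
      planar <- integer(0)
    }
    if (noise_sd > 0) {
      jit <- matrix(stats::rnorm(3L * n, 0, noise_sd), n, 3L)
      if (length(planar)) jit[planar, 3L] <- 0  # keep template ring exactly planar
      coords <- coords + jit
    }
    # element assignment respecting valence caps
    ordsum <- vapply(seq_len(n), function(i)
      sum(bond_order_numeric(vocab$bond_orders[bonds[i, ]])), numeric(1))
    deg <- vapply(seq_len(n), function(i) sum(bonds[i, ] > 1L), numeric(1))
    pool <- c(C = 0.62, N = 0.14, O = 0.14, F = 0.04, S = 0.03, Cl = 0.03)
    elements <- character(n)
    for (i in seq_len(n)) {
      ok <- names(pool)[element_max_valence(names(pool)) >= ceiling(ordsum[i]) &
                          !(names(pool) %in% c("F", "Cl") & deg[i] > 1L) &
                          !(names(pool) == "O" & deg[i] > 2L) &
                          !(names(pool) == "N" & ordsum[i] > 3)]
      elements[i] <- sample(ok, 1L, prob = pool[ok])
    }
    charges <- integer(n)
    for (i in seq_len(n)) {
      if (elements[i] == "N" && stats::runif(1) < 0.05) charges[i] <- 1L
      if (elements[i] == "O" && deg[i] == 1L && stats::runif(1) < 0.05) charges[i] <- -1L
    }
    # a random overall orientation (planarity is rotation-stable)
    R <- random_rotation()
    coords <- coords %*% t(R)
    ligand_state(coords,
                 atom_type = encode_label(vocab, "atom_types", elements),
                 charge = encode_label(vocab, "charge_values", charges),
                 hybridization = derive_hybridization(bonds, vocab),
                 bonds = bonds)
  })
}

#' Generate a toy pocket shell around a ligand
#'
#' Places pocket atoms on a partial shell between `inner_radius` and
#' `inner_radius + 1.5` Angstrom from randomly chosen ligand atoms, never
#' closer than 2.5 A to any ligand atom nor 1.5 A to another pocket atom.
#' Restricting directions to a random hemisphere leaves the site open on one
#' face, as real binding sites are. The per-complex `inner_radius` (drawn
#' uniformly on [3, 5.5] when not given) varies how tightly the pocket wraps
#' the ligand, which is the dominant source of contact-count - and hence
#' affinity - variation across fixtures. Residue identifiers are assigned in
#' triples of atoms.
#'
#' @param ligand A [ligand_state()].
#' @param size Number of pocket atoms (>= 10).
#' @param seed Integer seed.
#' @param inner_radius Inner shell radius (Angstrom) or `NULL` to draw it.
#' @param vocab Vocabulary.
#' @return A [pocket_state()].
#' @export
generate_toy_pocket <- function(ligand, size, seed = 1L, inner_radius = NULL,
                                vocab = atom_vocabulary()) {
  if (size < 10L) stop("pocket size must be >= 10")
  with_seed(seed, {
    L <- ligand$coords[ligand$atom_mask, , drop = FALSE]
    if (is.null(inner_radius)) inner_radius <- stats::runif(1, 3, 5.5)
    width <- 1.5
    axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
    placed <- matrix(NA_real_, size, 3L)
    got <- 0L
    tries <- 0L
    max_tries <- 500L * size
    while (got < size && tries < max_tries) {
      tries <- tries + 1L
      anchor <- L[sample(nrow(L), 1L), ]
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      if (sum(dir * axis) < -0.2) next  # keep one face open
      cand <- anchor + dir * (inner_radius + stats::runif(1, 0, width))
      dl <- sqrt(colSums((t(L) - cand)^2))
      if (min(dl) < 2.5) next
      if (got > 0L) {
        dp <- sqrt(colSums((t(placed[seq_len(got), , drop = FALSE]) - cand)^2))
        if (min(dp) < 1.5) next
      }
      got <- got + 1L
      placed[got, ] <- cand
    }
    if (got < size)
      stop(sprintf("pocket placement failed after %d attempts (%d/%d atoms)",
                   tries, got, size))
    elements <- sample(c("C", "N", "O", "S"), size, replace = TRUE,
                       prob = c(0.6, 0.18, 0.18, 0.04))
    resnames <- c("ALA", "GLY", "SER", "LEU", "VAL", "THR")
    rid <- ceiling(seq_len(size) / 3L)
    pocket_state(placed,
                 atom_type = encode_label(vocab, "atom_types", elements),
                 residue_id = rid,
                 residue_name = sample(resnames, max(rid), replace = TRUE)[rid],
                 chain_id = rep("A", size))
  })
}

#' Count ligand-pocket contact pairs
#'
#' Number of (ligand atom, pocket atom) pairs strictly closer than `cutoff`.
#'
#' @param ligand A [ligand_state()].
#' @param pocket A [pocket_state()] in the same frame.
#' @param cutoff Contact cutoff (Angstrom), default 4.
#' @return Integer count.
#' @export
count_contacts <- function(ligand, pocket, cutoff = 4) {
  L <- ligand$coords[ligand$atom_mask, , drop = FALSE]
  P <- pocket$coords[pocket$atom_mask, , drop = FALSE]
  sum(cross_distances(L, P) < cutoff)
}

#' Ground-truth synthetic affinity of a toy complex
#'
#' pIC50 = c0 + c1 * (contact pairs within 4 A) + c2 * (ligand heavy atoms) +
#' Gaussian noise, clipped to \[0, 12\]. pKi, pKd and pEC50 are affine
#' transforms of the same noiseless latent with independent noise, emulating
#' correlated but distinct assay endpoints.
#'
#' @param cmpl A [complex_record()] (or list with `ligand` and `pocket`).
#' @param coefficients `c(c0, c1, c2)`.
#' @param noise_sd Endpoint observation noise (log units).
#' @param seed Integer seed.
#' @return Named numeric vector with pIC50, pKi, pKd, pEC50.
#' @export
synthetic_affinity <- function(cmpl, coefficients = c(2.0, 0.1, 0.02),
                               noise_sd = 0.3, seed = 1L) {
  contacts <- count_contacts(cmpl$ligand, cmpl$pocket)
  nheavy <- sum(cmpl$ligand$atom_mask)
  latent <- coefficients[1] + coefficients[2] * contacts + coefficients[3] * nheavy
  with_seed(seed, {
    clip <- function(x) pmin(pmax(x, 0), 12)
    c(pIC50 = clip(latent + stats::rnorm(1, 0, noise_sd)),
      pKi   = clip(0.9 * latent + 0.5 + stats::rnorm(1, 0, noise_sd)),
      pKd   = clip(0.8 * latent + 1.0 + stats::rnorm(1, 0, noise_sd)),
      pEC50 = clip(1.1 * latent - 0.5 + stats::rnorm(1, 0, noise_sd)))
  })
}

#' Build a synthetic fixture dataset on disk
#'
#' Generates `config$n_complexes` ligand-pocket complexes, writes them through
#' the standard-format writers (one multi-record SDF, one PDB per pocket, an
#' affinity sidecar CSV) plus a YAML manifest of the configuration, and returns
#' the in-memory records. Deterministic given `config$seed`; each record uses
#' counter-based substreams. Each of pKi/pKd/pEC50 is dropped with probability
#' 0.3 to exercise endpoint masking (pIC50 is always kept).
#'
#' @param config A [fixture_config()].
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @param vocab Vocabulary.
#' @return Invisibly, a list with `records` (list of [complex_record()]) and
#'   `dir`.
#' @export
build_fixture_dataset <- function(config, dir = NULL, vocab = atom_vocabulary()) {
  stopifnot(inherits(config, "fixture_config"))
  records <- vector("list", config$n_complexes)
  for (i in seq_len(config$n_complexes)) {
    lig_seed <- substream_seed(config$seed, "ligand", i)
    size <- with_seed(substream_seed(config$seed, "sizes", i), {
      c(sample(seq(config$ligand_size_range[1], config$ligand_size_range[2]), 1L),
        sample(seq(config$pocket_size_range[1], config$pocket_size_range[2]), 1L))
    })
    lig <- generate_toy_ligand(size[1], seed = lig_seed, noise_sd = config$noise_sd,
                               vocab = vocab)
    pock <- generate_toy_pocket(lig, size[2], seed = substream_seed(config$seed, "pocket", i),
                                vocab = vocab)
    cmpl <- assemble_complex(lig, pock, source_id = sprintf("complex_%04d", i))
    aff <- synthetic_affinity(cmpl, config$affinity_coefficients,
                              config$affinity_noise_sd,
                              seed = substream_seed(config$seed, "affinity", i))
    keep <- with_seed(substream_seed(config$seed, "endpoints", i),
                      c(TRUE, stats::runif(3) > 0.3))
    cmpl$affinity <- aff[keep]
    records[[i]] <- cmpl
  }
  if (!is.null(dir) && config$n_complexes >= 0) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (config$n_complexes > 0) {
      write_ligand_sdf(lapply(records, `[[`, "ligand"),
                       file.path(dir, "ligands.sdf"), vocab = vocab,
                       ids = vapply(records, `[[`, "", "source_id"))
      for (i in seq_along(records))
        write_pocket_pdb(records[[i]]$pocket,
                         file.path(dir, sprintf("pocket_%04d.pdb", i)), vocab)
      write_affinity_csv(stats::setNames(lapply(records, `[[`, "affinity"),
                                         vapply(records, `[[`, "", "source_id")),
                         file.path(dir, "affinities.csv"))
    }
    yaml::write_yaml(unclass(config), file.path(dir, "manifest.yaml"))
  }
  invisible(list(records = records, dir = dir))
}

#' Load a fixture dataset written by [build_fixture_dataset()]
#'
#' @param dir Dataset directory.
#' @param vocab Vocabulary.
#' @return List of [complex_record()] objects.
#' @export
load_fixture_dataset <- function(dir, vocab = atom_vocabulary()) {
  ligands <- read_ligand_sdf(file.path(dir, "ligands.sdf"), vocab)
  affs <- read_affinity_csv(file.path(dir, "affinities.csv"))
  pdbs <- sort(list.files(dir, pattern = "^pocket_\\d+\\.pdb$", full.names = TRUE))
  stopifnot(length(pdbs) == length(ligands))
  lapply(seq_along(ligands), function(i) {
    prot <- read_pocket_pdb(pdbs[i])$protein
    el <- prot$element
    el[!(el %in% vocab$atom_types)] <- "C"
    pock <- pocket_state(as.matrix(prot[, c("x", "y", "z")]),
                         atom_type = encode_label(vocab, "atom_types", el),
                         residue_id = prot$resid, residue_name = prot$resname,
                         chain_id = prot$chain)
    sid <- attr(ligands[[i]], "source_id")
    assemble_complex(ligands[[i]], pock, affs[[sid]] %||% numeric(0), sid,
                     recenter = TRUE)
  })
}
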