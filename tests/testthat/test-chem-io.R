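# Domain types, SDF/PDB I/O and pocket extraction.

test_that("vocabulary encodes and decodes as identity and rejects bad input", {
  v <- atom_vocabulary()
  for (f in c("atom_types", "hybridizations", "bond_orders")) {
    labs <- v[[f]]
    expect_identical(decode_label(v, f, encode_label(v, f, labs)), labs)
  }
  expect_identical(decode_label(v, "charge_values",
                                encode_label(v, "charge_values", -2:2)), -2:2)
  expect_error(encode_label(v, "atom_types", "Se"), "out-of-vocabulary")
  expect_error(atom_vocabulary(bond_orders = c("single", "none")), "none")
  expect_error(atom_vocabulary(atom_types = c("C", "C")), "duplicate")
})

test_that("ligand_state enforces its invariants", {
  v <- atom_vocabulary()
  lig <- generate_toy_ligand(6, seed = 3)
  expect_silent(validate_ligand_state(lig, v))
  bad <- lig
  bad$bonds[1, 2] <- 3L  # breaks symmetry
  expect_error(validate_ligand_state(bad), "symmetric")
  bad <- lig
  bad$bonds[2, 2] <- 2L
  expect_error(validate_ligand_state(bad), "diagonal")
})

test_that("a hand-written methane-like SDF parses to the expected state", {
  v <- atom_vocabulary()
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("toy5", "  comment", "",
               "  5  4  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "    1.5400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
               "   -1.5400    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
               "    0.0000    1.5400    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
               "    0.0000   -1.5400    0.0000 F   0  0  0  0  0  0  0  0  0  0  0  0",
               "  1  2  1  0", "  1  3  1  0", "  1  4  1  0", "  1  5  1  0",
               "M  CHG  1   3   1",
               "M  END", "$$$$"), f)
  ligs <- read_ligand_sdf(f, v)
  expect_length(ligs, 1L)
  lg <- ligs[[1]]
  expect_equal(nrow(lg$coords), 5L)
  expect_identical(decode_label(v, "atom_types", lg$atom_type),
                   c("C", "C", "N", "O", "F"))
  # all bonds to the central atom, single
  expect_true(all(lg$bonds[1, 2:5] == match("single", v$bond_orders)))
  expect_identical(decode_label(v, "charge_values", lg$charge), c(0L, 0L, 1L, 0L, 0L))
})

test_that("SDF write/read round-trips coordinates, categories and charges", {
  v <- atom_vocabulary()
  ligs <- lapply(1:6, function(i) generate_toy_ligand(5L + i, seed = 100L + i))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(ligs, f, v)
  back <- read_ligand_sdf(f, v)
  expect_length(back, length(ligs))
  for (i in seq_along(ligs)) {
    expect_lt(max(abs(back[[i]]$coords - ligs[[i]]$coords)), 1e-3)
    expect_identical(back[[i]]$atom_type, ligs[[i]]$atom_type)
    expect_identical(back[[i]]$charge, ligs[[i]]$charge)
    expect_identical(back[[i]]$bonds, ligs[[i]]$bonds)
    expect_identical(back[[i]]$hybridization, ligs[[i]]$hybridization)
  }
})

test_that("written SDF is readable by an independent parser", {
  skip_if_not_installed("ChemmineR")
  v <- atom_vocabulary()
  ligs <- lapply(1:3, function(i) generate_toy_ligand(7L, seed = 200L + i))
  f <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(ligs, f, v)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(f))
  expect_length(sdfset, 3L)
  for (i in 1:3) {
    ab <- ChemmineR::atomblock(sdfset[[i]])
    expect_equal(nrow(ab), 7L)
    expect_lt(max(abs(ab[, 1:3] - ligs[[i]]$coords)), 1e-3)
    bb <- ChemmineR::bondblock(sdfset[[i]])
    expect_equal(nrow(bb), sum(ligs[[i]]$bonds[upper.tri(ligs[[i]]$bonds)] > 1L))
  }
})

test_that("SDF edge cases: empty list, masked padding, out-of-vocabulary atom", {
  v <- atom_vocabulary()
  f <- withr::local_tempfile(fileext = ".sdf")
  write_ligand_sdf(list(), f, v)
  expect_true(file.exists(f))
  expect_length(read_ligand_sdf(f, v), 0L)

  lig <- generate_toy_ligand(6, seed = 5)
  padded <- ligand_state(rbind(lig$coords, 0), c(lig$atom_type, 1L),
                         c(lig$charge, 1L), c(lig$hybridization, 1L),
                         rbind(cbind(lig$bonds, 1L), 1L),
                         atom_mask = c(rep(TRUE, 6), FALSE))
  write_ligand_sdf(list(padded), f, v)
  expect_equal(nrow(read_ligand_sdf(f, v)[[1]]$coords), 6L)

  writeLines(c("se", "", "", "  1  0  0  0  0  0  0  0  0  0999 V2000",
               "    0.0000    0.0000    0.0000 Se  0  0  0  0  0  0  0  0  0  0  0  0",
               "M  END", "$$$$"), f)
  expect_error(read_ligand_sdf(f, v), "Se")
})

test_that("PDB reading returns protein and hetero tables, filters altlocs, flags bad lines", {
  f <- withr::local_tempfile(fileext = ".pdb")
  lines <- c(
    sprintf("ATOM  %5d  N   ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00           N", 1, 0, 0, 0),
    sprintf("ATOM  %5d  CA  ALA A   1    %8.3f%8.3f%8.3f  1.00  0.00           C", 2, 1.5, 0, 0),
    sprintf("ATOM  %5d  N   GLY A   2    %8.3f%8.3f%8.3f  1.00  0.00           N", 3, 3, 0, 0),
    "ATOM      4  CA AGLY A   2       4.000   0.000   0.000  0.40  0.00           C",
    "ATOM      5  CA BGLY A   2       4.500   0.000   0.000  0.60  0.00           C",
    sprintf("ATOM  %5d  N   SER A   3    %8.3f%8.3f%8.3f  1.00  0.00           N", 6, 6, 0, 0),
    sprintf("HETATM%5d  C1  LIG A 101    %8.3f%8.3f%8.3f  1.00  0.00           C", 7, 2, 2, 2),
    "END")
  writeLines(lines, f)
  res <- read_pocket_pdb(f)
  expect_equal(nrow(res$protein), 5L)   # altloc A dropped, B (occ 0.6) kept
  expect_equal(nrow(res$hetero), 1L)
  kept_ca2 <- res$protein[res$protein$resid == 2 & res$protein$atom_name == "CA", ]
  expect_equal(kept_ca2$x, 4.5)

  writeLines(sub("   4.500", "   4.5x0", lines), f)
  expect_error(read_pocket_pdb(f), "line 5")

  writeLines(c("REMARK nothing", "END"), f)
  expect_error(read_pocket_pdb(f), "empty structure")
})

test_that("pocket PDB write/read round-trips coordinates and residues", {
  v <- atom_vocabulary()
  lig <- generate_toy_ligand(8, seed = 9)
  pock <- generate_toy_pocket(lig, 21, seed = 10)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pocket_pdb(pock, f, v)
  back <- read_pocket_pdb(f)$protein
  expect_equal(nrow(back), 21L)
  expect_lt(max(abs(as.matrix(back[, c("x", "y", "z")]) - pock$coords)), 1e-3)
  expect_identical(back$resid, pock$residue_id)
  expect_identical(back$element, decode_label(v, "atom_types", pock$atom_type))
})

test_that("extract_pocket keeps whole residues inside the cutoff", {
  lig <- ligand_state(matrix(0, 1, 3), 1L, 3L, 3L, matrix(1L, 1, 1))
  prot <- data.frame(x = c(6.9, 7.1), y = 0, z = 0, element = "C",
                     resid = 1:2, resname = "ALA", chain = "A", atom_name = "CA")
  pk <- extract_pocket(prot, lig, radius_A = 7, min_atoms = 1L)
  expect_equal(nrow(pk$coords), 1L)
  expect_equal(pk$coords[1, 1], 6.9)
})

test_that("extract_pocket enforces the size bounds as rejection", {
  lig <- ligand_state(matrix(0, 1, 3), 1L, 3L, 3L, matrix(1L, 1, 1))
  shell <- function(n, r) {
    ang <- 2 * pi * seq_len(n) / n
    data.frame(x = r * cos(ang), y = r * sin(ang), z = 0, element = "C",
               resid = seq_len(n), resname = "GLY", chain = "A", atom_name = "CA")
  }
  pk <- extract_pocket(shell(12, 5), lig, min_atoms = 10L)
  expect_equal(nrow(pk$coords), 12L)
  expect_error(extract_pocket(shell(5, 5), lig), "too few")
  expect_error(extract_pocket(shell(12, 5), lig, max_atoms = 11L), "too many")
})

test_that("extract_pocket matches the brute-force oracle on random complexes", {
  v <- atom_vocabulary()
  for (i in 1:100) {
    cm <- pocketflow:::with_seed(i, {
      lig <- generate_toy_ligand(sample(4:10, 1), seed = i)
      pock <- generate_toy_pocket(lig, sample(12:30, 1), seed = i + 500L)
      list(lig = lig, prot = pocket_as_protein(pock))
    })
    keep <- oracle_pocket_atoms(cm$prot, cm$lig$coords, 7)
    got <- extract_pocket(cm$prot, cm$lig, min_atoms = 1L)
    expect_identical(nrow(got$coords), sum(keep))
    expect_equal(got$coords, unname(as.matrix(cm$prot[keep, c("x", "y", "z")])))
  }
})

test_that("pocket extraction is invariant to rigid motion of the whole complex", {
  for (i in 1:5) {
    lig <- generate_toy_ligand(8, seed = 40L + i)
    pock <- generate_toy_pocket(lig, 24, seed = 140L + i)
    prot <- pocket_as_protein(pock)
    mv <- rigid_motion(i)
    sel1 <- extract_pocket(prot, lig, min_atoms = 1L)
    prot2 <- prot
    prot2[, c("x", "y", "z")] <- mv$apply(as.matrix(prot[, c("x", "y", "z")]))
    lig2 <- lig; lig2$coords <- mv$apply(lig$coords)
    sel2 <- extract_pocket(prot2, lig2, min_atoms = 1L)
    expect_identical(sel1$residue_id, sel2$residue_id)
  }
})

test_that("one-hot featurization is a bijection on valid states", {
  v <- atom_vocabulary()
  lig <- generate_toy_ligand(7, seed = 77)
  enc <- encode_ligand_features(lig, v)
  expect_equal(rowSums(enc$type), rep(1, 7))
  expect_equal(sum(enc$type[, lig$atom_type[1]] == 1), sum(lig$atom_type == lig$atom_type[1]))
  dec <- decode_ligand_features(enc, lig$coords, v)
  expect_identical(dec$atom_type, lig$atom_type)
  expect_identical(dec$charge, lig$charge)
  expect_identical(dec$hybridization, lig$hybridization)
  expect_identical(dec$bonds, lig$bonds)
  # all-"none" bond matrix encodes to the index-1 block
  lone <- ligand_state(matrix(rnorm(9), 3), rep(1L, 3), rep(3L, 3), rep(3L, 3),
                       matrix(1L, 3, 3))
  expect_true(all(encode_ligand_features(lone, v)$bonds[, 1] == 1))
})

test_that("affinity sidecar CSV round-trips endpoint maps", {
  f <- withr::local_tempfile(fileext = ".csv")
  affs <- list(c1 = c(pIC50 = 5.2, pKd = 4.1), c2 = c(pKi = 6.0))
  write_affinity_csv(affs, f)
  back <- read_affinity_csv(f)
  expect_equal(back$c1[c("pIC50", "pKd")], affs$c1)
  expect_equal(back$c2["pKi"], affs$c2)
})
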