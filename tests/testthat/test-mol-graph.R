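# SMILES parsing, canonicalization, sanitization and featurization.

roundtrip <- function(s) mol_to_smiles(mol_from_smiles(s))

test_that("canonical SMILES round-trips are stable", {
  cases <- c("CCO", "CC(=O)O", "c1ccccc1", "c1ccc2ccccc2c1", "C1CCCCC1",
             "CC(C)(C)OC(=O)N", "O=C(O)c1ccccc1O", "c1ccncc1", "c1cc[nH]c1",
             "CC(=O)Nc1ccc(O)cc1", "N[C@@H](C)C(=O)O", "C/C=C/C=O",
             "F[C@H](Cl)Br", "CN1C(=O)c2ccccc2C1=O", "[O-]C(=O)C",
             "C[N+](C)(C)C", "OCC1OC(O)C(O)C(O)C1O", "c1ccc(-c2ccccc2)cc1")
  for (s in cases) {
    c1 <- roundtrip(s)
    expect_identical(roundtrip(c1), c1, label = sprintf("restabilize '%s'", s))
  }
})

test_that("canonicalization collapses alternative spellings", {
  groups <- list(
    c("CCO", "OCC", "C(O)C"),
    c("c1ccccc1C", "Cc1ccccc1"),
    c("C1=CC=CC=C1", "c1ccccc1"),
    c("N[C@@H](C)C(=O)O", "[C@H](N)(C)C(=O)O"),
    c("C/C=C/C", "C(\\C)=C/C"))
  for (g in groups) {
    canon <- unique(vapply(g, roundtrip, character(1)))
    expect_length(canon, 1L)
  }
})

test_that("canonical form is independent of atom order", {
  set.seed(41)
  mols <- c("CC(=O)Nc1ccc(O)cc1", "O=C(O)c1ccccc1O", "c1ccc2ccccc2c1",
            "CC(C)CC1CCC(C)CC1", "N[C@@H](CC(=O)O)C(=O)O")
  for (s in mols) {
    m <- mol_from_smiles(s)
    ref <- mol_to_smiles(m)
    for (rep in 1:5) {
      perm <- sample(m$n)
      expect_identical(mol_to_smiles(mol_permute(m, perm)), ref)
    }
  }
})

test_that("aromaticity perception and kekulization agree", {
  m <- mol_from_smiles("c1ccccc1")
  expect_true(all(m$atom$aromatic))
  expect_identical(sort(m$bond$order), c(1L, 1L, 1L, 2L, 2L, 2L))
  m2 <- mol_from_smiles("C1=CC=CC=C1")
  expect_true(all(m2$atom$aromatic))
  expect_false(any(mol_from_smiles("C1CCCCC1")$atom$aromatic))
  # pyridine vs pyrrole nitrogen hydrogen counts
  expect_identical(mol_from_smiles("c1ccncc1")$atom$nH[
    mol_from_smiles("c1ccncc1")$atom$element == "N"], 0L)
  pyr <- mol_from_smiles("c1cc[nH]c1")
  expect_identical(pyr$atom$nH[pyr$atom$element == "N"], 1L)
})

test_that("implicit hydrogens follow minimum valence", {
  m <- mol_from_smiles("CC(=O)O")
  expect_identical(m$atom$nH, c(3L, 0L, 0L, 1L))
  expect_identical(mol_from_smiles("S")$atom$nH, 2L)
  expect_identical(mol_from_smiles("[SH4]")$atom$nH, 4L)
  expect_identical(mol_from_smiles("[NH4+]")$atom$nH, 4L)
})

test_that("invalid inputs are rejected", {
  expect_error(mol_from_smiles("C(C"), "parse")
  expect_error(mol_from_smiles("C1CC"), "ring")
  expect_error(mol_from_smiles("C=1CC=1C"), NA)
  expect_error(mol_from_smiles("[CH5]"), "valence")
  expect_error(mol_from_smiles("Xx"), "parse|element")
})

test_that("atom maps survive round trips and can be stripped", {
  m <- mol_from_smiles("[CH3:7][OH:2]")
  expect_setequal(m$atom$map, c(7L, 2L))
  out <- mol_to_smiles(m)
  expect_match(out, ":7")
  expect_false(grepl(":", mol_to_smiles(m, strip_maps = TRUE)))
})

test_that("tetrahedral stereo is preserved and distinct", {
  l <- roundtrip("N[C@@H](C)C(=O)O")
  d <- roundtrip("N[C@H](C)C(=O)O")
  expect_false(identical(l, d))
  expect_identical(roundtrip(l), l)
  flat <- mol_to_smiles(mol_from_smiles("N[C@@H](C)C(=O)O"), keep_stereo = FALSE)
  expect_false(grepl("@", flat))
})

test_that("cis/trans stereo is preserved and distinct", {
  tr <- roundtrip("C/C=C/C")
  cs <- roundtrip("C/C=C\\C")
  expect_false(identical(tr, cs))
  expect_identical(roundtrip(tr), tr)
})

test_that("multi-fragment output is sorted deterministically", {
  a <- roundtrip("CCO.CC")
  b <- roundtrip("CC.CCO")
  expect_identical(a, b)
})

test_that("sanitization catches over-valent atoms and duplicate maps", {
  m <- mol_from_smiles("CC")
  m$atom$nH[1] <- 5L
  expect_error(mol_sanitize(m), "valence")
  m2 <- mol_from_smiles("[CH3:1][CH3:1]", sanitize = FALSE)
  expect_error(mol_sanitize(m2), "map")
})

test_that("featurization has config-driven shapes and is deterministic", {
  cfg <- default_feature_config()
  m <- mol_from_smiles("CC(=O)Nc1ccc(O)cc1")
  f1 <- featurize_mol(m, cfg)
  f2 <- featurize_mol(m, cfg)
  expect_identical(f1, f2)
  expect_identical(dim(f1$atom), c(m$n, cfg$d_atom))
  expect_identical(dim(f1$bond), c(mol_nbonds(m), cfg$d_bond))
  expect_true(all(rowSums(f1$atom[, seq_along(cfg$elements) + 1L - 1L]) <= 1))
  # one-hot blocks: every atom row sums to the number of one-hot groups
  n_groups <- 4L  # element, degree, charge, chiral, hydrogens are one-hot; aromatic is a flag
  expect_true(all(rowSums(f1$atom) >= 5))
})

test_that("mol_split and mol_combine are inverse-like", {
  m <- mol_from_smiles("CCO.c1ccccc1.CBr")
  parts <- mol_split(m)
  expect_length(parts, 3L)
  back <- mol_combine(parts)
  expect_identical(mol_to_smiles(back), mol_to_smiles(m))
})
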