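# Edit constructors and the deterministic application engine.

smi <- function(mol) mol_to_smiles(mol, strip_maps = TRUE)

test_that("delete bond frees valence into hydrogens and can split", {
  m <- mol_from_smiles("[CH3:1][CH2:2][O:3][CH3:4]")
  r <- apply_edit(m, edit_delete_bond(2, 3))
  expect_length(mol_split(r), 2L)
  expect_identical(smi(r), "CC.CO")
  # double-bond deletion frees two hydrogens per end
  m2 <- mol_from_smiles("[CH2:1]=[CH2:2]")
  r2 <- apply_edit(m2, edit_delete_bond(1, 2))
  expect_identical(r2$atom$nH, c(4L, 4L))
})

test_that("change bond consumes and releases hydrogens", {
  m <- mol_from_smiles("[CH3:1][CH2:2][OH:3]")
  up <- apply_edit(m, edit_change_bond(2, 3, 2L))
  expect_identical(smi(up), "C(C)=O")
  down <- apply_edit(up, edit_change_bond(2, 3, 1L))
  expect_identical(smi(down), smi(m))
  # insufficient hydrogens is a chemistry error
  m3 <- mol_from_smiles("[CH3:1][C:2]([CH3:4])([CH3:5])[OH:3]")
  expect_error(apply_edit(m3, edit_change_bond(2, 3, 2L)), "hydrogen|chemistry|valence")
})

test_that("attach consumes hydrogens by bond order, respecting pins", {
  m <- mol_from_smiles("[CH4:1]")
  expect_identical(smi(apply_edit(m, edit_attach_lg(1, "*O"))), "CO")
  # double-bond dummy removes two hydrogens
  e <- mol_from_smiles("[CH3:1][CH3:2]")
  expect_identical(smi(apply_edit(e, edit_attach_lg(2, "*=O"))), "C(C)=O")
  # pinned atom keeps its hydrogen count through attachment
  am <- mol_from_smiles("[CH3:1][NH2:2]")
  s <- apply_edit(am, edit_change_atom(2, 0L, 0L))
  s <- apply_edit(s, edit_attach_lg(2, "*C(=O)c1ccccc1C(*)=O"))
  ref <- mol_to_smiles(mol_from_smiles("CN1C(=O)c2ccccc2C1=O"))
  expect_identical(mol_to_smiles(s, strip_maps = TRUE), ref)
})

test_that("attached leaving-group atoms receive fresh map numbers", {
  m <- mol_from_smiles("[CH4:1]")
  r <- apply_edit(m, edit_attach_lg(1, "*OC"))
  expect_setequal(r$atom$map, 1:3)
})

test_that("site and payload errors are reported", {
  m <- mol_from_smiles("[CH3:1][CH3:2]")
  expect_error(apply_edit(m, edit_delete_bond(1, 9)), "site|map|bond")
  expect_error(apply_edit(m, edit_attach_lg(9, "*O")), "site|map")
  expect_error(apply_edit(m, edit_attach_lg(1, "CO")), "dummy|\\*")
  # over-valence through attachment is a chemistry error
  expect_error(apply_edit(mol_from_smiles("[CH4:1]"),
                          edit_attach_lg(1, "*=C(*)(*)*")), "valence|dummy|chemistry")
})

test_that("terminate freezes the graph", {
  m <- mol_from_smiles("[CH4:1]")
  t1 <- apply_edit(m, edit_terminate())
  expect_true(attr(t1, "terminated"))
  expect_identical(smi(t1), smi(m))
  expect_error(apply_edit(t1, edit_attach_lg(1, "*O")), "terminat")
})

test_that("apply_edit_sequence validates the terminate position", {
  m <- mol_from_smiles("[CH4:1]")
  expect_error(apply_edit_sequence(m, list(edit_terminate(), edit_attach_lg(1, "*O"))),
               "Terminate")
  res <- apply_edit_sequence(m, list(edit_attach_lg(1, "*O"), edit_terminate()))
  expect_true(res$complete)
  expect_length(res$graphs, 2L)
  # step errors carry the failing index
  expect_error(apply_edit_sequence(m, list(edit_delete_bond(1, 2), edit_terminate())),
               "step 1")
})

test_that("chirality is cleared when a center loses a distinct substituent", {
  m <- mol_from_smiles("[NH2:1][C@@H:2]([CH3:3])[C:4](=[O:5])[OH:6]")
  r <- apply_edit(m, edit_delete_bond(1, 2))
  a <- which(r$atom$map == 2L)
  expect_identical(r$atom$chiral[a], 0L)
})

test_that("chirality payload on a complete shell yields distinct enantiomers", {
  base <- "[NH2:1][CH:2]([CH3:3])[C:4](=[O:5])[OH:6]"
  out <- character(2)
  for (tag in c(1L, 2L)) {
    m <- mol_from_smiles(base)
    s <- apply_edit(m, edit_change_atom(2, 1L, tag))
    expect_identical(s$atom$chiral[s$atom$map == 2L][1], tag)
    out[tag] <- smi(s)
  }
  expect_false(out[1] == out[2])
  expect_true(all(grepl("@", out)))
})

test_that("edits serialize to JSON lines and back", {
  edits <- list(edit_delete_bond(2, 5), edit_change_bond(1, 2, 2L, 1L),
                edit_change_atom(3, 0L, 2L), edit_attach_lg(3, "*C(=O)O"),
                edit_terminate())
  lines <- edits_to_jsonl(edits)
  expect_length(lines, 5L)
  back <- edits_from_jsonl(lines)
  expect_identical(vapply(back, format, character(1)),
                   vapply(edits, format, character(1)))
})

test_that("application is purely functional", {
  m <- mol_from_smiles("[CH3:1][CH3:2]")
  before <- mol_to_smiles(m)
  invisible(apply_edit(m, edit_attach_lg(1, "*O")))
  expect_identical(mol_to_smiles(m), before)
})
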