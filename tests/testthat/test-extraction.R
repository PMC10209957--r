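# Reaction diffing into edit sequences, vocabulary, applicability.

extract_fmt <- function(rxn) {
  rec <- canonicalize_reaction(parse_reaction(rxn))
  vapply(extract_edits(rec), format, character(1))
}

test_that("simple disconnections extract the expected sequences", {
  ed <- extract_fmt("[CH3:1][Br:9].[OH2:2]>>[CH3:1][OH:2]")
  expect_identical(ed, c("DeleteBond [1, 2]", "AttachLG 1 '*Br'", "Terminate"))
  ed2 <- extract_fmt("[CH3:1][C:2](=[O:3])[OH:4].[NH2:5][CH3:6]>>[CH3:1][C:2](=[O:3])[NH:5][CH3:6]")
  expect_length(ed2, 3L)
  expect_match(ed2[1], "DeleteBond")
  expect_match(ed2[2], "AttachLG .* '\\*O'")
})

test_that("bond order changes extract as change-bond edits", {
  ed <- extract_fmt("[CH3:1][C:2](=[O:3])[CH3:4]>>[CH3:1][CH:2]([OH:3])[CH3:4]")
  expect_identical(ed, c("ChangeBond [1, 4] -> (2, 0)", "Terminate"))
})

test_that("geometry and chirality changes extract as stereo payloads", {
  ed <- extract_fmt("[CH3:1]/[CH:2]=[CH:3]\\[CH3:4]>>[CH3:1]/[CH:2]=[CH:3]/[CH3:4]")
  expect_identical(ed, c("ChangeBond [1, 2] -> (2, 1)", "Terminate"))
  ed2 <- extract_fmt("[NH2:1][C@@H:2]([CH3:3])[CH2:4][OH:5]>>[NH2:1][C@H:2]([CH3:3])[CH2:4][OH:5]")
  expect_length(ed2, 2L)
  expect_match(ed2[1], "ChangeAtom")
})

test_that("two leaving groups attach in deterministic order", {
  ed <- extract_fmt(paste0(
    "[Br:13][c:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1.",
    "[OH:14][B:15]([OH:16])[c:7]1[cH:8][cH:9][cH:10][cH:11][cH:12]1",
    ">>[c:1]1([c:7]2[cH:8][cH:9][cH:10][cH:11][cH:12]2)[cH:2][cH:3][cH:4][cH:5][cH:6]1"))
  expect_identical(ed[1], "DeleteBond [1, 2]")
  expect_match(ed[2], "AttachLG 1")
  expect_match(ed[3], "AttachLG 2")
})

test_that("aromatic spectator rings yield no spurious bond edits", {
  ed <- extract_fmt(paste0("[Br:7][c:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1.[OH2:8]",
                           ">>[OH:8][c:1]1[cH:2][cH:3][cH:4][cH:5][cH:6]1"))
  expect_length(ed, 3L)
  expect_false(any(grepl("ChangeBond", ed)))
})

test_that("unextractable reactions are rejected with reasons", {
  r <- canonicalize_reaction(parse_reaction(
    "[CH3:1][CH2:2][CH2:3][CH3:4]>>[CH3:1][CH3:2].[CH3:3][CH3:4]"))
  expect_error(extract_edits(r), "bond formation")
  r2 <- canonicalize_reaction(parse_reaction("CC.[CH3:1][OH:2]>>[CH3:1][OH:2]"))
  expect_error(extract_edits(r2), "shares no atoms")
})

test_that("extraction replay reproduces reactants for generated sets", {
  recs <- generate_reactions(40, seed = 202)
  expect_identical(as.numeric(edit_applicability(recs)), 1)
})

test_that("extraction ordering follows edit priority", {
  recs <- generate_reactions(30, seed = 7,
                             template_mix = c(coupling = 0.5, ringopen = 0.5))
  prio <- c(DeleteBond = 1L, ChangeBond = 2L, ChangeAtom = 3L,
            AttachLG = 4L, Terminate = 5L)
  for (r in recs) {
    ranks <- prio[vapply(r$edits, function(e) e$type, character(1))]
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("vocabulary is sorted, thresholded and stable", {
  recs <- generate_reactions(40, seed = 55)
  v <- build_edit_vocab(recs)
  expect_s3_class(v, "edit_vocab")
  expect_true(all(diff(v$bond$count) <= 0))
  expect_true(all(diff(v$atom$count) <= 0))
  # order of input records must not matter
  v2 <- build_edit_vocab(rev(recs))
  expect_identical(v, v2)
  # min count applies to leaving groups only
  v3 <- build_edit_vocab(recs, min_lg_count = 1000L)
  expect_identical(sum(grepl("^AttachLG", v3$atom$key)), 0L)
  expect_identical(v3$bond, v$bond)
})

test_that("vocabulary saves and loads through JSON", {
  recs <- generate_reactions(15, seed = 9)
  v <- build_edit_vocab(recs)
  path <- tempfile(fileext = ".json")
  save_vocab(v, path)
  v2 <- load_vocab(path)
  expect_identical(v$bond$key, v2$bond$key)
  expect_identical(v$atom$count, v2$atom$count)
  expect_identical(retroedits:::vocab_hash(v), retroedits:::vocab_hash(v2))
})

test_that("edit coverage detects out-of-vocabulary payloads", {
  recs <- generate_reactions(20, seed = 31)
  v <- build_edit_vocab(recs)
  expect_identical(edit_coverage(recs, v), 1)
  v_small <- build_edit_vocab(recs[1:2])
  expect_lte(edit_coverage(recs, v_small), 1)
})

test_that("reaction CSV round-trips through preprocessing", {
  recs <- generate_reactions(10, seed = 77)
  path <- tempfile(fileext = ".csv")
  write_reactions_csv(recs, path)
  back <- read_reactions_csv(path)
  pp <- preprocess_reactions(back)
  expect_identical(nrow(pp$failures), 0L)
  expect_identical(vapply(pp$records, reactants_key, character(1)),
                   vapply(recs, reactants_key, character(1)))
})

test_that("canonicalize_reaction is idempotent and renumbers maps 1..n", {
  rec <- parse_reaction("[OH2:9].[CH3:4][Br:7]>>[CH3:4][OH:9]")
  c1 <- canonicalize_reaction(rec)
  expect_identical(sort(c1$product$atom$map), seq_len(c1$product$n))
  c2 <- canonicalize_reaction(c1)
  expect_identical(c1$raw, c2$raw)
})
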