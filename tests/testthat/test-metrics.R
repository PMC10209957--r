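# Evaluation metrics and fingerprints.

fake_pred <- function(reactants) {
  data.frame(rank = seq_along(reactants), reactants = reactants,
             score = -seq_along(reactants), n_edits = rep(1L, length(reactants)),
             stringsAsFactors = FALSE)
}

test_that("top-k exact match counts ranked hits", {
  recs <- generate_reactions(4, seed = 88)
  truth <- vapply(recs, reactants_key, character(1))
  preds <- list(fake_pred(c(truth[1], "CC")),            # hit at 1
                fake_pred(c("CC", truth[2])),            # hit at 2
                fake_pred(c("CC", "CCO")),               # miss
                fake_pred(character(0)))                 # empty
  acc <- topk_exact_match(preds, recs, ks = c(1, 2, 10))
  expect_equal(unname(acc), c(0.25, 0.5, 0.5))
})

test_that("maxfrag dominates exact match and top-k is monotone", {
  recs <- generate_reactions(12, seed = 88)
  truth <- vapply(recs, reactants_key, character(1))
  set.seed(3)
  preds <- lapply(seq_along(recs), function(i) {
    # perturb some predictions by dropping all but the largest fragment
    if (i %% 3 == 0) fake_pred(retroedits:::.max_fragment(truth[i]))
    else if (i %% 3 == 1) fake_pred(c("CC", truth[i]))
    else fake_pred("CCOC")
  })
  ks <- c(1, 3, 5, 10)
  ex <- topk_exact_match(preds, recs, ks)
  mf <- maxfrag_accuracy(preds, recs, ks)
  expect_true(all(mf >= ex))
  expect_true(all(diff(ex) >= 0))
  expect_true(all(diff(mf) >= 0))
})

test_that("largest fragment selection breaks ties deterministically", {
  expect_identical(retroedits:::.max_fragment("CC.CCO"), "CCO")
  expect_identical(retroedits:::.max_fragment("CCN.CCO"),
                   sort(c("CCN", "CCO"))[1])
})

test_that("fingerprints are deterministic and order-invariant", {
  m <- mol_from_smiles("CC(=O)Nc1ccc(O)cc1")
  f1 <- mol_fingerprint(m)
  expect_length(f1, 2048L)
  expect_identical(f1, mol_fingerprint(m))
  set.seed(6)
  m2 <- mol_permute(m, sample(m$n))
  expect_identical(mol_fingerprint(m2), f1)
  # different molecules give different prints
  expect_false(identical(mol_fingerprint(mol_from_smiles("CCO")), f1))
})

test_that("tanimoto has the expected range and identities", {
  a <- mol_fingerprint(mol_from_smiles("CCO"))
  b <- mol_fingerprint(mol_from_smiles("c1ccccc1"))
  expect_equal(tanimoto(a, a), 1)
  expect_gte(tanimoto(a, b), 0)
  expect_lt(tanimoto(a, b), 1)
  expect_equal(tanimoto(logical(8), logical(8)), 1)   # empty-vs-empty
  # similar molecules score higher than dissimilar ones
  c2 <- mol_fingerprint(mol_from_smiles("CCCO"))
  expect_gt(tanimoto(a, c2), tanimoto(a, b))
})

test_that("prediction diversity averages pairwise similarity", {
  p1 <- fake_pred(c("CCO", "CCO"))       # identical pair -> similarity 1
  p2 <- fake_pred(c("CCO", "c1ccccc1"))  # dissimilar pair
  div <- prediction_diversity(list(p1, p2))
  expect_equal(div$per_product[1], 1)
  expect_lt(div$per_product[2], 1)
  expect_true(div$mean_similarity < 1)
  expect_true(is.na(prediction_diversity(list(fake_pred("CC")))$per_product[1]))
})

test_that("similarity split keeps near-duplicates in training", {
  # four near-duplicates + four dissimilar molecules
  smi <- c("CCCCCCCCO", "CCCCCCCCOC", "CCCCCCCCN", "CCCCCCCC",
           "c1ccc2ccccc2c1", "FC(F)(F)c1ccncc1", "OC1CCCCC1N", "BrCC=CBr")
  recs <- lapply(smi, function(s) {
    m <- mol_from_smiles(s); m$atom$map <- seq_len(m$n)
    structure(list(product = m, reactants = list(m), class = NA_integer_),
              class = "reaction_record")
  })
  sp <- tanimoto_split(recs, fractions = c(0.5, 0.25, 0.25), sigma = 0.4, seed = 2L)
  expect_setequal(c(sp$train, sp$val, sp$test), seq_along(recs))
  fps <- lapply(recs, function(r) mol_fingerprint(r$product))
  for (h in c(sp$val, sp$test)) {
    sims <- vapply(sp$train, function(t) tanimoto(fps[[h]], fps[[t]]), numeric(1))
    expect_lte(max(sims), 0.4)
  }
  # sigma = 1 never moves anything
  sp1 <- tanimoto_split(recs, fractions = c(0.5, 0.25, 0.25), sigma = 1, seed = 2L)
  expect_identical(length(sp1$train), 4L)
})

test_that("edit length distribution reflects the template mix", {
  recs <- generate_reactions(20, seed = 5, template_mix = c(ringopen = 1))
  d <- edit_length_distribution(recs)
  expect_identical(names(d), "7")
  expect_identical(as.integer(d[["7"]]), 20L)
})
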