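# Beam-search decoding properties.

beam_fixture_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      recs <- generate_reactions(12, seed = 61)
      cfg <- retroedits_config(hidden = 12L, depth = 2L, head_hidden = 12L,
                               dropout = 0, head_dropout = 0, epochs = 8L,
                               batch_size = 6L, val_fraction = 0, seed = 13L)
      cache <<- list(recs = recs,
                     model = retroedits_fit(recs, config = cfg, verbose = FALSE))
    }
    cache
  }
})

# exhaustive enumeration of all terminating edit sequences up to max_steps
brute_force <- function(model, product, max_steps) {
  out <- list()
  recurse <- function(mol, prev, prev_maps, logp, idxseq, edits, depth) {
    sc <- policy_score(model, mol, prev = prev, prev_maps = prev_maps)
    for (ix in seq_along(sc$probs)) {
      ed <- sc$candidates[[ix]]
      lp <- logp + log(sc$probs[ix])
      if (ed$type == "Terminate") {
        out[[length(out) + 1L]] <<- list(mol = mol, logp = lp,
                                         idxseq = c(idxseq, ix),
                                         edits = c(edits, list(ed)))
      } else if (depth < max_steps) {
        g2 <- tryCatch(apply_edit(mol, ed), error = function(e) NULL)
        if (!is.null(g2))
          recurse(g2, sc$fused, sc$maps, lp, c(idxseq, ix),
                  c(edits, list(ed)), depth + 1L)
      }
    }
  }
  recurse(product, NULL, NULL, 0, integer(0), list(), 1L)
  out <- out[retroedits:::.rank_hypotheses(out)]
  keys <- vapply(out, function(h) retroedits:::.reactant_key_mol(h$mol), character(1))
  keep <- !duplicated(keys)
  data.frame(reactants = keys[keep],
             score = vapply(out[keep], `[[`, numeric(1), "logp"),
             stringsAsFactors = FALSE)
}

test_that("beam equals brute-force enumeration on a small problem", {
  fx <- beam_fixture_model()
  # tiny product so the candidate space stays enumerable
  product <- mol_from_smiles("[CH3:1][OH:2]")
  oracle <- brute_force(fx$model, product, max_steps = 2L)
  bs <- beam_search(fx$model, product, k = 64L, max_steps = 2L)
  n <- min(nrow(oracle), nrow(bs))
  expect_gt(n, 1L)
  expect_identical(bs$reactants[seq_len(n)], oracle$reactants[seq_len(n)])
  expect_equal(bs$score[seq_len(n)], oracle$score[seq_len(n)], tolerance = 1e-9)
})

test_that("width-1 beam is greedy decoding", {
  fx <- beam_fixture_model()
  product <- fx$recs[[1]]$product
  bs <- beam_search(fx$model, product, k = 1L, max_steps = 6L)
  # greedy reference
  mol <- product; prev <- NULL; pm <- NULL; lp <- 0; steps <- 0L; ok <- FALSE
  while (steps < 6L) {
    sc <- policy_score(fx$model, mol, prev = prev, prev_maps = pm)
    ord <- order(-sc$probs)
    advanced <- FALSE
    for (ix in ord) {
      ed <- sc$candidates[[ix]]
      if (ed$type == "Terminate") { lp <- lp + log(sc$probs[ix]); ok <- TRUE; break }
      g2 <- tryCatch(apply_edit(mol, ed), error = function(e) NULL)
      if (is.null(g2)) next                # greedy drops invalid, takes next best
      lp <- lp + log(sc$probs[ix]); mol <- g2; prev <- sc$fused; pm <- sc$maps
      advanced <- TRUE; break
    }
    steps <- steps + 1L
    if (ok || !advanced) break
  }
  if (ok && nrow(bs) > 0) {
    expect_identical(bs$reactants[1], retroedits:::.reactant_key_mol(mol))
    expect_equal(bs$score[1], lp, tolerance = 1e-9)
  } else succeed("greedy path did not terminate; nothing to compare")
})

test_that("beam scores are non-increasing in rank and non-positive", {
  fx <- beam_fixture_model()
  bs <- beam_search(fx$model, fx$recs[[2]]$product, k = 8L, max_steps = 6L)
  expect_true(all(diff(bs$score) <= 1e-12))
  expect_true(all(bs$score <= 0))
})

test_that("beam output is deterministic and deduplicated", {
  fx <- beam_fixture_model()
  b1 <- beam_search(fx$model, fx$recs[[3]]$product, k = 6L, max_steps = 6L)
  b2 <- beam_search(fx$model, fx$recs[[3]]$product, k = 6L, max_steps = 6L)
  expect_identical(b1$reactants, b2$reactants)
  expect_identical(anyDuplicated(b1$reactants), 0L)
})

test_that("larger beams only extend the result set prefix-consistently", {
  fx <- beam_fixture_model()
  product <- mol_from_smiles("[CH3:1][CH2:2][OH:3]")
  b_small <- beam_search(fx$model, product, k = 4L, max_steps = 2L)
  b_big <- beam_search(fx$model, product, k = 32L, max_steps = 2L)
  oracle <- brute_force(fx$model, product, max_steps = 2L)
  n <- min(nrow(b_big), nrow(oracle))
  expect_identical(b_big$reactants[seq_len(n)], oracle$reactants[seq_len(n)])
  expect_true(all(b_small$score[1] <= b_big$score[1] + 1e-12))
})

test_that("predict dispatches over SMILES, molecules and records", {
  fx <- beam_fixture_model()
  p1 <- predict(fx$model, fx$recs[1:2], k = 3L, max_steps = 4L)
  expect_length(p1, 2L)
  smiles <- mol_to_smiles(fx$recs[[1]]$product, strip_maps = TRUE)
  p2 <- predict(fx$model, smiles, k = 3L, max_steps = 4L)
  expect_s3_class(p2[[1]], "data.frame")
})
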