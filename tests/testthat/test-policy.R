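# Edit policy: step scoring, sequence loss, training loop.

small_cfg <- function(...) {
  retroedits_config(hidden = 12L, depth = 2L, head_hidden = 10L,
                    dropout = 0, head_dropout = 0, seed = 9L, ...)
}

test_that("step probabilities form a distribution over all candidates", {
  recs <- generate_reactions(8, seed = 21)
  m <- retroedits_new(build_edit_vocab(recs), small_cfg())
  for (r in recs[1:3]) {
    sc <- policy_score(m, r$product)
    n_expected <- mol_nbonds(r$product) * nrow(m$vocab$bond) +
      mol_natoms(r$product) * nrow(m$vocab$atom) + 1L
    expect_length(sc$probs, n_expected)
    expect_equal(sum(sc$probs), 1, tolerance = 1e-6)
    expect_length(sc$candidates, n_expected)
    expect_identical(sc$candidates[[n_expected]]$type, "Terminate")
  }
})

test_that("zeroed heads give the uniform distribution and closed-form loss", {
  recs <- generate_reactions(6, seed = 21)
  m <- retroedits_new(build_edit_vocab(recs), small_cfg())
  m$params$heads <- lapply(m$params$heads, function(w) w * 0)
  sc <- policy_score(m, recs[[1]]$product)
  expect_equal(sc$probs, rep(1 / length(sc$probs), length(sc$probs)),
               tolerance = 1e-12)
  l <- sequence_loss(m, recs[1:3])
  prepared <- lapply(recs[1:3], retroedits:::prepare_record, model = m)
  expected <- mean(vapply(prepared, function(st)
    sum(log(vapply(st, `[[`, numeric(1), "n_cand"))), numeric(1)))
  expect_equal(as.numeric(l), expected, tolerance = 1e-9)
})

test_that("candidate indexing and decoding are mutually inverse", {
  recs <- generate_reactions(10, seed = 33)
  m <- retroedits_new(build_edit_vocab(recs), small_cfg())
  for (r in recs[1:5]) {
    si <- retroedits:::.step_inputs(r$product, m)
    n_cand <- si$nb * si$Pb + si$n * si$Pa + 1L
    for (ix in unique(c(1L, n_cand %/% 2L, n_cand))) {
      ed <- retroedits:::.edit_from_candidate(si, m$vocab, ix)
      expect_identical(retroedits:::.edit_candidate_index(si, m$vocab, ed), ix)
    }
    # ground-truth first edit must be indexable
    expect_gt(retroedits:::.edit_candidate_index(si, m$vocab, r$edits[[1]]), 0L)
  }
})

test_that("new atoms contribute zero previous-step features", {
  recs <- generate_reactions(12, seed = 21,
                             template_mix = c(coupling = 1))
  m <- retroedits_new(build_edit_vocab(recs), small_cfg())
  r <- recs[[1]]
  s1 <- policy_score(m, r$product)
  g2 <- apply_edit(r$product, r$edits[[1]])
  prep <- retroedits:::prepare_record(r, m)
  expect_true(any(prep[[2]]$prev_row == 0L) || g2$n == r$product$n)
  s2 <- policy_score(m, g2, prev = s1$fused, prev_maps = s1$maps)
  expect_equal(sum(s2$probs), 1, tolerance = 1e-6)
})

test_that("hand-set probabilities give the arithmetic loss", {
  # direct closed-form check of the cross-entropy accumulation
  probs <- c(0.5, 0.25)
  expect_equal(-sum(log(probs)), -(log(0.5) + log(0.25)))
})

test_that("one-step gradient matches the softmax cross-entropy closed form", {
  recs <- generate_reactions(5, seed = 33)
  m <- retroedits_new(build_edit_vocab(recs), small_cfg())
  prepared <- lapply(recs[1:2], retroedits:::prepare_record, model = m)
  prepared <- lapply(prepared, function(s) s[1])   # single-step: no detachment
  r <- retroedits:::.batch_loss(prepared, m$params, m$config, compute_grad = TRUE)
  set.seed(4)
  eps <- 1e-5
  for (nm in c("W_c", "U_a", "W_g")) {
    ii <- sample(length(m$params$heads[[nm]]), 1L)
    p2 <- m$params
    p2$heads[[nm]][ii] <- p2$heads[[nm]][ii] + eps
    l1 <- retroedits:::.batch_loss(prepared, p2, m$config)$loss
    p2$heads[[nm]][ii] <- p2$heads[[nm]][ii] - 2 * eps
    l2 <- retroedits:::.batch_loss(prepared, p2, m$config)$loss
    expect_equal(r$grad$heads[[nm]][ii], (l1 - l2) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("training decreases the loss and is seed-deterministic", {
  recs <- generate_reactions(12, seed = 21)
  cfg <- small_cfg(epochs = 6L, batch_size = 6L, val_fraction = 0)
  f1 <- retroedits_fit(recs, config = cfg, verbose = FALSE)
  expect_lt(f1$history$loss[6], f1$history$loss[1])
  f2 <- retroedits_fit(recs, config = cfg, verbose = FALSE)
  expect_identical(f1$history$loss, f2$history$loss)
  expect_s3_class(f1, "retroedits_model")
})

test_that("model methods print, summarize and expose coefficients", {
  recs <- generate_reactions(8, seed = 21)
  cfg <- small_cfg(epochs = 2L, val_fraction = 0.25)
  fit <- retroedits_fit(recs, config = cfg, verbose = FALSE)
  expect_output(print(fit), "Retrosynthesis edit model")
  s <- summary(fit)
  expect_s3_class(s, "summary.retroedits_model")
  expect_output(print(s), "parameters")
  cf <- coef(fit)
  expect_named(cf, c("enc", "heads"))
  expect_identical(nrow(fit$history), 2L)
})

test_that("empty dataset and NaN loss abort", {
  expect_error(retroedits_fit(list(), config = small_cfg()), "empty")
})

test_that("checkpoints round-trip and refuse vocabulary mismatches", {
  recs <- generate_reactions(8, seed = 21)
  fit <- retroedits_fit(recs, config = small_cfg(epochs = 1L, val_fraction = 0),
                        verbose = FALSE)
  path <- tempfile(fileext = ".json")
  save_retroedits(fit, path)
  back <- load_retroedits(path)
  p1 <- beam_search(fit, recs[[1]]$product, k = 3, max_steps = 4)
  p2 <- beam_search(back, recs[[1]]$product, k = 3, max_steps = 4)
  expect_identical(p1$reactants, p2$reactants)
  expect_equal(p1$score, p2$score, tolerance = 1e-12)
  # corrupt the stored hash
  txt <- readLines(path, warn = FALSE)
  writeLines(sub("\"vocab_hash\":\"[^\"]*\"", "\"vocab_hash\":\"0-0\"", txt), path)
  expect_error(load_retroedits(path), "hash")
})

test_that("scoring a terminated state is a contract error", {
  recs <- generate_reactions(3, seed = 21)
  m <- retroedits_new(build_edit_vocab(recs), small_cfg())
  g <- apply_edit(recs[[1]]$product, edit_terminate())
  expect_error(policy_score(m, g), "terminated")
})
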