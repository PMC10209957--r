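# Graph encoder: forward structure, gradients, invariances.

enc_setup <- function(smiles, hidden = 8L, depth = 3L, variant = "dmpnn", seed = 3L) {
  cfg <- default_feature_config()
  m <- mol_from_smiles(smiles)
  list(mol = m,
       params = encoder_init(cfg$d_atom, cfg$d_bond, hidden, depth, variant, seed),
       struct = retroedits:::encoder_structure(m, featurize_mol(m, cfg), variant))
}

test_that("single atom graph encodes through an empty neighbor sum", {
  s <- enc_setup("C")
  out <- encode_graph(s$struct, s$params)
  expect_identical(dim(out$atom), c(1L, 8L))
  expect_true(all(is.finite(out$atom)))
  expect_true(all(out$atom >= 0))           # final ReLU
})

test_that("directed message structure excludes the reverse edge", {
  for (smiles in c("CCO", "c1ccccc1", "CC(C)C", "C1CC1O")) {
    s <- enc_setup(smiles)
    M <- s$struct$M
    m <- nrow(M)
    rev_of <- ifelse(seq_len(m) %% 2L == 1L, seq_len(m) + 1L, seq_len(m) - 1L)
    expect_true(all(M[cbind(seq_len(m), rev_of)] == 0))
  }
})

test_that("zeroing a reverse edge state never changes the forward message", {
  s <- enc_setup("CC(=O)O", depth = 1L)
  h <- matrix(stats::rnorm(nrow(s$struct$X) * 4), ncol = 4)
  for (e in seq_len(nrow(h))) {
    rev_e <- if (e %% 2L == 1L) e + 1L else e - 1L
    h2 <- h; h2[rev_e, ] <- 0
    msg1 <- as.matrix(s$struct$M %*% h)[e, ]
    msg2 <- as.matrix(s$struct$M %*% h2)[e, ]
    expect_equal(msg1, msg2)
  }
})

test_that("encoding is permutation equivariant", {
  set.seed(17)
  cfg <- default_feature_config()
  p <- encoder_init(cfg$d_atom, cfg$d_bond, 8L, 3L, "dmpnn", seed = 3L)
  for (smiles in c("CC(=O)Nc1ccc(O)cc1", "C1CCOC1", "CC(C)CBr")) {
    m <- mol_from_smiles(smiles)
    a1 <- encode_graph(retroedits:::encoder_structure(m, featurize_mol(m, cfg)), p)$atom
    perm <- sample(m$n)
    m2 <- mol_permute(m, perm)
    a2 <- encode_graph(retroedits:::encoder_structure(m2, featurize_mol(m2, cfg)), p)$atom
    expect_equal(a1, a2[perm, , drop = FALSE], tolerance = 1e-12)
  }
})

test_that("both variants produce finite deterministic outputs", {
  for (variant in c("dmpnn", "mpnn")) {
    s <- enc_setup("O=C(O)c1ccccc1", variant = variant)
    o1 <- encode_graph(s$struct, s$params)
    o2 <- encode_graph(s$struct, s$params)
    expect_identical(o1$atom, o2$atom)
    expect_true(all(is.finite(o1$atom)))
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(5)
  for (variant in c("dmpnn", "mpnn")) {
    s <- enc_setup("CC(=O)OC", hidden = 6L, depth = 2L, variant = variant)
    fw <- encode_graph(s$struct, s$params, keep_cache = TRUE)
    g <- retroedits:::encode_backward(2 * fw$atom, fw, s$params)
    eps <- 1e-5
    for (nm in names(s$params)) {
      ii <- sample(length(s$params[[nm]]), 1L)
      p2 <- s$params
      p2[[nm]][ii] <- p2[[nm]][ii] + eps
      l1 <- sum(encode_graph(s$struct, p2)$atom^2)
      p2[[nm]][ii] <- p2[[nm]][ii] - 2 * eps
      l2 <- sum(encode_graph(s$struct, p2)$atom^2)
      fd <- (l1 - l2) / (2 * eps)
      expect_equal(g[[nm]][ii], fd, tolerance = 1e-4,
                   label = sprintf("%s grad %s[%d]", variant, nm, ii))
    }
  }
})

test_that("dropout is inactive at rate zero and stochastic otherwise", {
  s <- enc_setup("CCO")
  o1 <- encode_graph(s$struct, s$params, dropout = 0)
  o2 <- encode_graph(s$struct, s$params, dropout = 0)
  expect_identical(o1$atom, o2$atom)
  set.seed(1); d1 <- encode_graph(s$struct, s$params, dropout = 0.5)$atom
  set.seed(2); d2 <- encode_graph(s$struct, s$params, dropout = 0.5)$atom
  expect_false(identical(d1, d2))
})

test_that("initialization is seeded and shape-consistent", {
  cfg <- default_feature_config()
  p1 <- encoder_init(cfg$d_atom, cfg$d_bond, 16L, 4L, seed = 11L)
  p2 <- encoder_init(cfg$d_atom, cfg$d_bond, 16L, 4L, seed = 11L)
  expect_identical(p1, p2)
  expect_identical(dim(p1$W_in), c(cfg$d_atom + cfg$d_bond, 16L))
  expect_identical(dim(p1$W_out), c(cfg$d_atom + 16L, 16L))
  expect_error(encoder_init(cfg$d_atom, cfg$d_bond, 16L, 0L), "depth")
})
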