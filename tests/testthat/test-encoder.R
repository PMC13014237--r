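# Directed message-passing encoder: base cases, invariances, gradients.

enc_names <- c("W_in", "b_in", "W_msg", "b_msg", "W_atom", "b_atom")

test_that("single-atom molecule embeds as the bare atom projection", {
  cfg <- encoder_config(hidden_dim = 7, depth = 3)
  par <- init_encoder_params(cfg, seed = 5)
  g <- parse_smiles("C", "methane")
  emb <- encode_molecule(g, par, cfg)
  x <- funscreen:::.atom_features(g$atoms)[1, ]
  expected <- pmax(par$W_atom %*% c(x, numeric(7)) + par$b_atom, 0)
  expect_equal(emb$vector, as.numeric(expected), tolerance = 1e-12)
})

test_that("embeddings are invariant to atom ordering", {
  cfg <- encoder_config(hidden_dim = 12, depth = 3)
  par <- init_encoder_params(cfg, seed = 2)
  set.seed(77)
  for (smi in fixture_smiles()[c(1, 7, 22, 35)]) {
    g <- parse_smiles(smi)
    e0 <- encode_molecule(g, par, cfg)$vector
    for (k in 1:20) {
      g2 <- parse_smiles(random_smiles(g))
      expect_lt(max(abs(encode_molecule(g2, par, cfg)$vector - e0)), 1e-5)
    }
  }
})

test_that("depth 0 matches a direct bag-of-atoms computation", {
  cfg <- encoder_config(hidden_dim = 6, depth = 0)
  par <- init_encoder_params(cfg, seed = 9)
  g <- parse_smiles("CC(=O)N", "amide")
  emb <- encode_molecule(g, par, cfg)$vector
  # plain per-atom loop: initial bond states (no message steps), atom
  # aggregation, relu projections, sum readout
  Xa <- funscreen:::.atom_features(g$atoms)
  db <- directed_bonds(g)
  h0 <- matrix(0, nrow(db), 6)
  for (b in seq_len(nrow(db))) {
    e <- c(as.numeric(db$order[b] == 1:4), as.numeric(db$conj[b]),
           as.numeric(db$ring[b]))
    h0[b, ] <- pmax(par$W_in %*% c(Xa[db$src[b], ], e) + par$b_in, 0)
  }
  out <- numeric(6)
  for (v in seq_len(g$n_atoms)) {
    mv <- colSums(h0[db$dst == v, , drop = FALSE])
    out <- out + pmax(par$W_atom %*% c(Xa[v, ], mv) + par$b_atom, 0)
  }
  expect_equal(emb, as.numeric(out), tolerance = 1e-10)
})

test_that("one message-passing step matches a hand-unrolled forward pass", {
  cfg <- encoder_config(hidden_dim = 4, depth = 1)
  par <- init_encoder_params(cfg, seed = 4)
  g <- parse_smiles("CCO", "chain")
  db <- directed_bonds(g)
  Xa <- funscreen:::.atom_features(g$atoms)
  bf <- function(b) c(as.numeric(db$order[b] == 1:4),
                      as.numeric(db$conj[b]), as.numeric(db$ring[b]))
  h0 <- t(vapply(seq_len(nrow(db)), function(b)
    as.numeric(pmax(par$W_in %*% c(Xa[db$src[b], ], bf(b)) + par$b_in, 0)),
    numeric(4)))
  h1 <- h0
  for (b in seq_len(nrow(db))) {
    inc <- which(db$dst == db$src[b] & db$src != db$dst[b])
    m <- colSums(h0[inc, , drop = FALSE])
    h1[b, ] <- pmax(h0[b, ] + par$W_msg %*% m + par$b_msg, 0)
  }
  out <- numeric(4)
  for (v in seq_len(g$n_atoms)) {
    mv <- colSums(h1[db$dst == v, , drop = FALSE])
    out <- out + pmax(par$W_atom %*% c(Xa[v, ], mv) + par$b_atom, 0)
  }
  expect_equal(encode_molecule(g, par, cfg)$vector, as.numeric(out),
               tolerance = 1e-10)
})

test_that("analytic gradients agree with finite differences", {
  cfg <- encoder_config(hidden_dim = 6, depth = 2)
  set.seed(31)
  par <- init_encoder_params(cfg, seed = 31)
  # move off relu kinks (zero-initialized biases put pre-activations at 0)
  par <- lapply(par, function(p) p + rnorm(length(p), 0, 0.05))
  gs <- list(parse_smiles("CC(=O)Oc1ccccc1", "a"), parse_smiles("NCCO", "b"))
  batch <- funscreen:::build_batch(lapply(gs, funscreen:::featurize_graph))
  w <- matrix(rnorm(2 * 6), 2, 6)  # random linear readout as the test loss
  loss <- function(p) sum(w * encode_batch(p, cfg, batch)$H_mol)
  fwd <- encode_batch(par, cfg, batch, keep_cache = TRUE)
  gr <- encode_backward(par, cfg, batch, fwd$cache, w)
  for (nm in enc_names) {
    for (k in sample(length(par[[nm]]), min(5, length(par[[nm]])))) {
      pp <- par; pp[[nm]][k] <- pp[[nm]][k] + 1e-6
      pm <- par; pm[[nm]][k] <- pm[[nm]][k] - 1e-6
      fd <- (loss(pp) - loss(pm)) / 2e-6
      an <- gr[[nm]][k]
      expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
    }
  }
})

test_that("prompt hook shifts initial bond states and validates inputs", {
  cfg <- encoder_config(hidden_dim = 5, depth = 1, prompt_enabled = TRUE)
  par <- init_encoder_params(cfg, seed = 6)
  g <- parse_smiles("CCO")
  e0 <- encode_molecule(g, par, cfg)$vector
  e1 <- encode_molecule(g, par, cfg, prompt = rep(0.5, 5))$vector
  expect_false(isTRUE(all.equal(e0, e1)))
  expect_error(encode_molecule(g, par, cfg, prompt = rep(0.5, 4)), "length")
  cfg_off <- encoder_config(hidden_dim = 5, depth = 1)
  expect_error(encode_molecule(g, init_encoder_params(cfg_off, 6), cfg_off,
                               prompt = rep(0.5, 5)), "prompt")
})

test_that("weight/config dimension mismatches error", {
  cfg <- encoder_config(hidden_dim = 5, depth = 1)
  par <- init_encoder_params(encoder_config(hidden_dim = 6), seed = 1)
  g <- parse_smiles("CC")
  expect_error(encode_molecule(g, par, cfg), "dimensions")
})
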