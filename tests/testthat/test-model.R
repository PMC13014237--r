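# Fusion, classification head, training loop, ensembles, checkpoints.

test_that("fusion add/concat semantics", {
  cfg_add <- fusion_config("add")
  expect_equal(fuse(c(1, 2, 3), c(0, 0, 0), cfg_add), c(1, 2, 3))
  expect_equal(fuse(c(0.5, -1, 2), c(0.25, 1, -3), cfg_add), c(0.75, 0, -1))
  expect_error(fuse(c(1, 2, 3), c(1, 2), cfg_add), "equal")
  cfg_cat <- fusion_config("concat")
  v <- fuse(c(1, 2, 3), c(9, 8, 7, 6), cfg_cat)
  expect_length(v, 7)
  expect_equal(v[1:3], c(1, 2, 3))
  expect_equal(v[4:7], c(9, 8, 7, 6))
})

test_that("all-zero weights predict exactly 0.5; inference is deterministic", {
  model <- init_model(encoder_config(hidden_dim = 4, depth = 1),
                      fusion_config(ffn_hidden = 4), n_func = 6, seed = 1)
  model$params <- lapply(model$params, function(p) p * 0)
  g <- parse_smiles("CCO", "m")
  f <- runif(6)
  expect_identical(predict_pair(f, g, model), 0.5)
  p1 <- predict_pair(f, g, model)
  p2 <- predict_pair(f, g, model)
  expect_identical(p1, p2)
})

test_that("pinned one-layer head reproduces a hand-computed sigmoid", {
  enc <- encoder_config(hidden_dim = 3, depth = 1)
  fus <- fusion_config("add", ffn_layers = 1, dropout = 0)
  model <- init_model(enc, fus, n_func = 2, seed = 1)
  model$params <- lapply(model$params, function(p) p * 0)
  model$params$W_p <- matrix(c(1, 0, 0, 1, 1, 0), 3, 2)  # pins h_prot = W_p f
  model$params$b_p <- c(0.1, -0.2, 0.3)
  model$params$ffn_W1 <- matrix(c(2, -1, 0.5), 1, 3)
  model$params$ffn_b1 <- -0.25
  f <- c(0.6, 0.8)
  # encoder weights are zero so h_mol = 0 and fused = W_p f + b_p
  fused <- as.numeric(model$params$W_p %*% f) + model$params$b_p
  expected <- 1 / (1 + exp(-(sum(c(2, -1, 0.5) * fused) - 0.25)))
  expect_equal(predict_pair(f, parse_smiles("CC"), model), expected,
               tolerance = 1e-12)
})

test_that("training separates two separable pairs and is seed-deterministic", {
  g1 <- parse_smiles("CCO", "m1")
  graphs <- list(m1 = g1)
  func <- func_vectors(matrix(c(1, 0, 0, 0, 0, 0, 0, 1), 2, 4, byrow = TRUE,
                              dimnames = list(c("pA", "pB"), NULL)))
  ds <- list(pairs = data.frame(protein_id = c("pA", "pB"),
                                mol_id = "m1", label = c("active", "inactive")),
             graphs = graphs, func = func)
  tc <- train_config(epochs = 200, batch_size = 4, learning_rate = 0.05,
                     seed = 3, split_seed = 3, val_fraction = 0)
  m <- train_model(ds, fusion_config(ffn_hidden = 8, dropout = 0),
                   encoder_config(hidden_dim = 8, depth = 1), tc)
  expect_lt(m$log$final_train_loss, 0.1)
  expect_gt(predict_pair("pA", g1, m, func), 0.8)
  expect_lt(predict_pair("pB", g1, m, func), 0.2)
  m2 <- train_model(ds, fusion_config(ffn_hidden = 8, dropout = 0),
                    encoder_config(hidden_dim = 8, depth = 1), tc)
  expect_identical(m$params, m2$params)
})

test_that("training refuses single-class data", {
  ds <- list(pairs = data.frame(protein_id = "pA", mol_id = "m1",
                                label = "active"),
             graphs = list(m1 = parse_smiles("CC", "m1")),
             func = func_vectors(matrix(0.5, 1, 4,
                                        dimnames = list("pA", NULL))))
  expect_error(train_model(ds), "positive and")
})

test_that("decoys act as label-0 examples identically to inactives", {
  w <- tiny_world(5)
  cur <- curate_activity(w$records)
  dec <- sample_decoys(cur$pairs, w$molecules$mol_id, 1, seed = 5)
  as_inactive <- dec; as_inactive$label <- "inactive"
  tc <- train_config(epochs = 3, batch_size = 128, learning_rate = 5e-3,
                     seed = 5, split_seed = 5)
  fus <- fusion_config(ffn_hidden = 8)
  enc <- encoder_config(hidden_dim = 8, depth = 1)
  m1 <- train_model(list(pairs = merge_labeled_pairs(cur$pairs, dec),
                         graphs = w$graphs, func = w$func), fus, enc, tc)
  m2 <- train_model(list(pairs = merge_labeled_pairs(cur$pairs, as_inactive),
                         graphs = w$graphs, func = w$func), fus, enc, tc)
  expect_identical(m1$params, m2$params)
})

test_that("label-flipped training approximately inverts predictions", {
  w <- tiny_world(7)
  cur <- curate_activity(w$records)
  pairs <- cur$pairs
  flipped <- pairs
  flipped$label <- ifelse(pairs$label == "active", "inactive", "active")
  fus <- fusion_config(ffn_hidden = 12, dropout = 0)
  enc <- encoder_config(hidden_dim = 12, depth = 1)
  tc <- train_config(epochs = 40, batch_size = 256, learning_rate = 5e-3,
                     seed = 7, split_seed = 7, val_fraction = 0)
  m1 <- train_model(list(pairs = pairs, graphs = w$graphs, func = w$func),
                    fus, enc, tc)
  m2 <- train_model(list(pairs = flipped, graphs = w$graphs, func = w$func),
                    fus, enc, tc)
  probe <- pairs[seq(1, nrow(pairs), by = 3), ]
  p1 <- predict_pairs(m1, probe, w$graphs, w$func)
  p2 <- predict_pairs(m2, probe, w$graphs, w$func)
  expect_lt(mean(abs(p1 + p2 - 1)), 0.2)
})

test_that("ensemble prediction is the arithmetic mean of member predictions", {
  enc <- encoder_config(hidden_dim = 6, depth = 1)
  fus <- fusion_config(ffn_hidden = 6)
  members <- lapply(1:3, function(s) init_model(enc, fus, n_func = 5, seed = s))
  ens <- structure(list(members = members, member_seeds = 1:3),
                   class = "ensemble_model")
  set.seed(55)
  graphs <- lapply(fixture_smiles()[1:10], parse_smiles)
  names(graphs) <- paste0("m", 1:10)
  for (i in 1:10) graphs[[i]]$mol_id <- names(graphs)[i]
  func <- func_vectors(matrix(runif(2 * 5), 2, 5,
                              dimnames = list(c("p1", "p2"), NULL)))
  pairs <- expand.grid(protein_id = c("p1", "p2"), mol_id = names(graphs),
                       stringsAsFactors = FALSE)
  pe <- ensemble_predict_pairs(ens, pairs, graphs, func)
  pm <- sapply(members, function(m) predict_pairs(m, pairs, graphs, func))
  expect_equal(pe, rowMeans(pm), tolerance = 1e-12)
  # identical members reduce to a single member
  ens1 <- structure(list(members = members[c(1, 1, 1)], member_seeds = c(1, 1, 1)),
                    class = "ensemble_model")
  f <- runif(5)
  expect_identical(ensemble_predict(ens1, f, graphs[[1]]),
                   predict_pair(f, graphs[[1]], members[[1]]))
})

test_that("checkpoints round-trip through the JSON archive", {
  w <- tiny_world(3)
  cur <- curate_activity(w$records)
  ds <- list(pairs = cur$pairs, graphs = w$graphs, func = w$func)
  tc <- train_config(epochs = 2, batch_size = 256, seed = 3, split_seed = 3)
  m <- train_model(ds, fusion_config(ffn_hidden = 8),
                   encoder_config(hidden_dim = 8, depth = 1), tc)
  tmp <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, tmp)
  m2 <- load_checkpoint(tmp)
  probe <- cur$pairs[1:10, ]
  expect_equal(predict_pairs(m2, probe, w$graphs, w$func),
               predict_pairs(m, probe, w$graphs, w$func), tolerance = 1e-12)
  ens <- train_ensemble(ds, 2, fusion_config(ffn_hidden = 8),
                        encoder_config(hidden_dim = 8, depth = 1), tc)
  save_checkpoint(ens, tmp)
  e2 <- load_checkpoint(tmp)
  expect_equal(ensemble_predict_pairs(e2, probe, w$graphs, w$func),
               ensemble_predict_pairs(ens, probe, w$graphs, w$func),
               tolerance = 1e-12)
})

test_that("screen_library orders by probability with mol_id tiebreak", {
  model <- init_model(encoder_config(hidden_dim = 4, depth = 0),
                      fusion_config(ffn_hidden = 4), n_func = 3, seed = 2)
  model$params <- lapply(model$params, function(p) p * 0)  # constant scores
  graphs <- list(b = parse_smiles("CC", "b"), a = parse_smiles("CCO", "a"),
                 c = parse_smiles("CCN", "c"))
  func <- func_vectors(matrix(0.5, 1, 3, dimnames = list("p1", NULL)))
  sc <- screen_library(model, "p1", func, graphs)
  expect_equal(sc$mol_id, c("a", "b", "c"))
  expect_equal(sc$rank, 1:3)
})
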