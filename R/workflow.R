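# Desk-scale experiment drivers: curation -> training -> ground-truth
# screening evaluation on a synthetic world. Shared by the test-suite, the
# acceptance script and the vignette so every reported number comes from the
# same code path.

.desk_enc <- function(hidden = 32L, depth = 2L) {
  encoder_config(hidden_dim = hidden, depth = depth)
}
.desk_tc <- function(seed, epochs = 12L, batch_size = 512L, lr = 5e-3) {
  train_config(epochs = epochs, batch_size = batch_size, learning_rate = lr,
               seed = seed, split_seed = seed)
}

#' Curate a synthetic world into labeled training pairs
#'
#' Runs the activity records through the 50 uM labeling rule and optionally
#' augments with per-protein decoys sampled from the world's molecules.
#'
#' @param world A `synthetic_world`.
#' @param decoy_ratio Decoys per active (0 disables augmentation).
#' @param seed Decoy-sampling seed.
#' @param pairs Optional pre-curated measured pairs (defaults to curating
#'   `world$records`).
#' @return data.frame of labeled pairs.
#' @export
curate_world <- function(world, decoy_ratio = 1.0, seed = 1L, pairs = NULL) {
  cur <- curate_activity(world$records)
  if (is.null(pairs)) pairs <- cur$pairs
  if (decoy_ratio > 0) {
    blockers <- rbind(cur$pairs, cur$ambiguous)[, c("protein_id", "mol_id",
                                                    "label", "provenance")]
    dec <- sample_decoys(blockers, world$molecules$mol_id,
                         ratio = decoy_ratio, seed = seed)
    # decoys may collide with measured pairs dropped by thinning; exclude
    dec <- dec[!(paste(dec$protein_id, dec$mol_id) %in%
                   paste(pairs$protein_id, pairs$mol_id)), ]
    return(merge_labeled_pairs(pairs, dec))
  }
  pairs
}

#' Thin measured inactives to emulate per-protein negative scarcity
#'
#' Keeps all actives and, per protein, a seeded subsample of measured
#' inactives sized `round(per_active x active count)`; `per_active = 0.1`
#' yields the 10:1 active:inactive regime in which assumed-negative decoys
#' are expected to help.
#'
#' @param pairs Labeled measured pairs.
#' @param per_active Inactives retained per active (default 0.1).
#' @param seed Subsampling seed.
#' @return Thinned pairs data.frame.
#' @export
thin_inactives <- function(pairs, per_active = 0.1, seed = 1L) {
  set.seed(seed)
  keep <- logical(nrow(pairs))
  keep[pairs$label == "active"] <- TRUE
  for (p in sort(unique(pairs$protein_id), method = "radix")) {
    ina <- which(pairs$protein_id == p & pairs$label == "inactive")
    n_act <- sum(pairs$protein_id == p & pairs$label == "active")
    want <- min(length(ina), max(1L, round(per_active * n_act)))
    if (want > 0L && length(ina))
      keep[sample(ina, want)] <- TRUE
  }
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Train on a synthetic world and measure held-out enrichment
#'
#' Molecules are split by scaffold (seeded); the model trains on pairs whose
#' molecule falls in the train portion and is evaluated by pooled ranking of
#' every (protein, held-out molecule) pair against the world's ground-truth
#' compatibility labels. A random ranking has EF = 1 in expectation.
#'
#' @param world A `synthetic_world`.
#' @param seed Seed controlling the split, decoys, initialization and
#'   shuffling.
#' @param n_members Ensemble size (1 = single model).
#' @param decoy_ratio Decoys per active (default 1).
#' @param pairs Optional pre-thinned measured pairs (see
#'   [thin_inactives()]); defaults to full curation.
#' @param test_fraction Fraction of scaffolds held out (default 0.1).
#' @param epochs,hidden,depth,batch_size,lr Desk-scale training settings.
#' @param alpha EF fraction (default 0.01).
#' @return List: `ef` (EF at alpha), `model`, `result` (`screen_result`),
#'   `n_test_pairs`, `n_train_pairs`.
#' @export
heldout_experiment <- function(world, seed = 1L, n_members = 1L,
                               decoy_ratio = 1.0, pairs = NULL,
                               test_fraction = 0.1, epochs = 12L,
                               hidden = 32L, depth = 2L, batch_size = 512L,
                               lr = 5e-3, alpha = 0.01) {
  lab <- curate_world(world, decoy_ratio = decoy_ratio, seed = seed,
                      pairs = pairs)
  scaff <- vapply(world$graphs, function(g) murcko_scaffold(g)$scaffold_smiles,
                  "")
  sp <- scaffold_balanced_split(names(world$graphs), scaff,
                                c(1 - test_fraction, 0, test_fraction),
                                seed = seed)
  test_mols <- sp$assignment$mol_id[sp$assignment$partition == "test"]
  lab_tr <- lab[!(lab$mol_id %in% test_mols), , drop = FALSE]
  ds <- list(pairs = lab_tr, graphs = world$graphs, func = world$func)
  fus <- fusion_config(ffn_hidden = hidden)
  enc <- .desk_enc(hidden, depth)
  tc <- .desk_tc(seed, epochs, batch_size, lr)
  model <- if (n_members > 1L) train_ensemble(ds, n_members, fus, enc, tc)
           else train_model(ds, fus, enc, tc)
  pairs_te <- expand.grid(protein_id = world$proteins$protein_id,
                          mol_id = test_mols, stringsAsFactors = FALSE)
  p <- ensemble_predict_pairs(model, pairs_te, world$graphs, world$func)
  y <- world$truth[cbind(pairs_te$protein_id, pairs_te$mol_id)]
  res <- screen_result("heldout_pool",
                       paste(pairs_te$protein_id, pairs_te$mol_id, sep = ":"),
                       p, y)
  list(ef = enrichment_factor(res, alpha), model = model, result = res,
       n_test_pairs = nrow(pairs_te), n_train_pairs = nrow(lab_tr))
}

#' Zero-shot transfer experiment on held-out proteins
#'
#' Holds out whole proteins (every record, actives included) during
#' training, then screens all world molecules against the held proteins and
#' scores the pooled ranking against ground truth. Transfer must come from
#' retained proteins of the same function archetype.
#'
#' @param world A `synthetic_world`.
#' @param seed Training/decoy seed.
#' @param held_protein_count Proteins held out (default 2, same archetype).
#' @param decoy_ratio,epochs,hidden,depth,batch_size,lr,alpha As in
#'   [heldout_experiment()].
#' @return List: `ef`, `model`, `result`, `held_proteins`.
#' @export
zero_shot_experiment <- function(world, seed = 1L, held_protein_count = 2L,
                                 decoy_ratio = 1.0, epochs = 25L,
                                 hidden = 32L, depth = 2L, batch_size = 256L,
                                 lr = 5e-3, alpha = 0.01) {
  hold <- zero_shot_holdout(world, held_protein_count)
  cur <- curate_activity(hold$train_records)
  blockers <- rbind(cur$pairs, cur$ambiguous)
  lab <- cur$pairs
  if (decoy_ratio > 0) {
    dec <- sample_decoys(blockers, world$molecules$mol_id,
                         ratio = decoy_ratio, seed = seed)
    lab <- merge_labeled_pairs(cur$pairs, dec)
  }
  ds <- list(pairs = lab, graphs = world$graphs, func = world$func)
  model <- train_model(ds, fusion_config(ffn_hidden = hidden),
                       .desk_enc(hidden, depth),
                       .desk_tc(seed, epochs, batch_size, lr))
  pairs_te <- expand.grid(protein_id = hold$held_proteins,
                          mol_id = world$molecules$mol_id,
                          stringsAsFactors = FALSE)
  p <- predict_pairs(model, pairs_te, world$graphs, world$func)
  y <- world$truth[cbind(pairs_te$protein_id, pairs_te$mol_id)]
  res <- screen_result("zero_shot_pool",
                       paste(pairs_te$protein_id, pairs_te$mol_id, sep = ":"),
                       p, y)
  list(ef = enrichment_factor(res, alpha), model = model, result = res,
       held_proteins = hold$held_proteins)
}
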