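# Fusion of protein and molecule representations, the feed-forward
# classification head, seeded minibatch training with Adam, and ensemble
# prediction. Decoys contribute as label-0 examples identically to measured
# inactives.

#' Fusion and classification-head configuration
#'
#' @param mode `"add"` (default; protein projection added elementwise to the
#'   molecule embedding) or `"concat"`.
#' @param ffn_layers Number of linear layers in the head (>= 1). Default 2.
#' @param ffn_hidden Hidden width of the head. Default 64.
#' @param dropout Dropout rate in the head's hidden layers during training
#'   (inference is always dropout-off). Default 0.1.
#' @param d_prot Dimension of the projected protein vector. In `"add"` mode
#'   this must equal the molecule embedding dimension and defaults to it;
#'   in `"concat"` mode it is free.
#' @return List of class `fusion_config`.
#' @export
fusion_config <- function(mode = "add", ffn_layers = 2L, ffn_hidden = 64L,
                          dropout = 0.1, d_prot = NULL) {
  mode <- match.arg(mode, c("add", "concat"))
  stopifnot(ffn_layers >= 1L, dropout >= 0, dropout < 1)
  structure(list(mode = mode, ffn_layers = as.integer(ffn_layers),
                 ffn_hidden = as.integer(ffn_hidden), dropout = dropout,
                 d_prot = if (is.null(d_prot)) NULL else as.integer(d_prot)),
            class = "fusion_config")
}

#' Training configuration
#'
#' @param epochs Number of passes over the training pairs. Default 20.
#' @param batch_size Minibatch size in pairs. Default 256.
#' @param learning_rate Adam learning rate. Default 1e-3.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param class_handling `"none"` (default; the data are balanced via decoys)
#'   or `"pos_weight"` (positive class weighted by n_neg/n_pos in the loss).
#' @param split_seed Seed of the internal scaffold-balanced validation split.
#' @param val_fraction Fraction of training scaffolds held out for
#'   validation loss. Default 0.1.
#' @return List of class `train_config`.
#' @export
train_config <- function(epochs = 20L, batch_size = 256L, learning_rate = 1e-3,
                         seed = 1L, class_handling = "none", split_seed = 1L,
                         val_fraction = 0.1) {
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            val_fraction >= 0, val_fraction < 1)
  class_handling <- match.arg(class_handling, c("none", "pos_weight"))
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 class_handling = class_handling,
                 split_seed = as.integer(split_seed),
                 val_fraction = val_fraction),
            class = "train_config")
}

#' Fuse a molecule embedding with a projected protein vector
#'
#' @param h_mol Molecule embedding (vector, or matrix with one row per pair).
#' @param h_prot Projected protein function vector, same shape convention.
#' @param config A `fusion_config`.
#' @return Fused vector/matrix: elementwise sum (`add`) or concatenation
#'   (`concat`, molecule block first).
#' @export
fuse <- function(h_mol, h_prot, config = fusion_config()) {
  if (is.null(dim(h_mol))) h_mol <- matrix(h_mol, 1L)
  if (is.null(dim(h_prot))) h_prot <- matrix(h_prot, 1L)
  out <- if (config$mode == "add") {
    if (!all(dim(h_mol) == dim(h_prot)))
      stop("add fusion requires equal molecule and protein dimensions")
    h_mol + h_prot
  } else {
    cbind(h_mol, h_prot)
  }
  if (nrow(out) == 1L) as.numeric(out) else out
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.ffn_dims <- function(fin, fusion) {
  L <- fusion$ffn_layers
  if (L == 1L) return(list(ins = fin, outs = 1L))
  ins <- c(fin, rep(fusion$ffn_hidden, L - 1L))
  outs <- c(rep(fusion$ffn_hidden, L - 1L), 1L)
  list(ins = ins, outs = outs)
}

#' Initialize a full model (encoder + projection + head)
#'
#' @param enc An `encoder_config`.
#' @param fusion A `fusion_config`.
#' @param n_func Length of the protein function vectors.
#' @param seed RNG seed (recorded in the checkpoint).
#' @return List of class `funscreen_model` holding configs and a flat named
#'   list of weight arrays.
#' @export
init_model <- function(enc = encoder_config(), fusion = fusion_config(),
                       n_func = 489L, seed = 1L) {
  h <- enc$hidden_dim
  d_prot <- if (is.null(fusion$d_prot)) h else fusion$d_prot
  if (fusion$mode == "add" && d_prot != h)
    stop("add fusion requires d_prot == hidden_dim")
  set.seed(seed)
  params <- list(W_in = .glorot(h, .D_ATOM + .D_BOND), b_in = numeric(h),
                 W_msg = .glorot(h, h), b_msg = numeric(h),
                 W_atom = .glorot(h, .D_ATOM + h), b_atom = numeric(h),
                 W_p = .glorot(d_prot, n_func), b_p = numeric(d_prot))
  fin <- if (fusion$mode == "add") h else h + d_prot
  dims <- .ffn_dims(fin, fusion)
  for (l in seq_len(fusion$ffn_layers)) {
    params[[sprintf("ffn_W%d", l)]] <- .glorot(dims$outs[l], dims$ins[l])
    params[[sprintf("ffn_b%d", l)]] <- numeric(dims$outs[l])
  }
  structure(list(version = "funscreen-checkpoint-1",
                 encoder = enc, fusion = fusion,
                 n_func = as.integer(n_func), d_prot = d_prot,
                 seed = as.integer(seed), params = params, log = NULL),
            class = "funscreen_model")
}

#' @method print funscreen_model
#' @export
print.funscreen_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(paste0("<funscreen_model: hidden=%d depth=%d fusion=%s ",
                     "n_func=%d, %d trainable parameters>\n"),
              x$encoder$hidden_dim, x$encoder$depth, x$fusion$mode,
              x$n_func, np))
  invisible(x)
}

# head forward; masks non-NULL => training-mode dropout (inverted scaling)
.head_forward <- function(params, fusion, fused, masks = NULL) {
  L <- fusion$ffn_layers
  A <- fused
  acts <- vector("list", L)
  for (l in seq_len(L)) {
    W <- params[[sprintf("ffn_W%d", l)]]; b <- params[[sprintf("ffn_b%d", l)]]
    acts[[l]] <- A
    Zl <- sweep(A %*% t(W), 2L, b, "+")
    if (l < L) {
      A <- pmax(Zl, 0)
      if (!is.null(masks)) A <- A * masks[[l]] / (1 - fusion$dropout)
    } else {
      A <- Zl
    }
  }
  list(logit = as.numeric(A), acts = acts)
}

.head_backward <- function(params, fusion, fwd, dlogit, masks = NULL) {
  L <- fusion$ffn_layers
  grads <- list()
  dA <- matrix(dlogit, ncol = 1L)
  for (l in rev(seq_len(L))) {
    W <- params[[sprintf("ffn_W%d", l)]]
    A_in <- fwd$acts[[l]]
    grads[[sprintf("ffn_W%d", l)]] <- t(crossprod(A_in, dA))
    grads[[sprintf("ffn_b%d", l)]] <- colSums(dA)
    dA_in <- dA %*% W
    if (l > 1L) {
      # through the previous layer's relu (+ inverted dropout); mask zeros
      # already imply a zero post-activation, scaling is the extra factor
      dA <- dA_in * (fwd$acts[[l]] > 0)
      if (!is.null(masks)) dA <- dA * masks[[l - 1L]] / (1 - fusion$dropout)
    } else {
      dA <- dA_in
    }
  }
  list(grads = grads, d_fused = dA)
}

# full forward over aligned pair rows
.pairs_forward <- function(model, Hmol_pairs, Fv_pairs, masks = NULL) {
  P <- sweep(Fv_pairs %*% t(model$params$W_p), 2L, model$params$b_p, "+")
  fused <- if (model$fusion$mode == "add") Hmol_pairs + P
           else cbind(Hmol_pairs, P)
  fwd <- .head_forward(model$params, model$fusion, fused, masks)
  list(logit = fwd$logit, prob = .sigmoid(fwd$logit), fwd = fwd,
       fused = fused, P = P)
}

#' Predict binding probabilities for aligned (protein, molecule) pairs
#'
#' Deterministic inference (dropout off).
#'
#' @param model A trained `funscreen_model`.
#' @param pairs data.frame with `protein_id`, `mol_id`.
#' @param graphs Named list of `molgraph` objects covering `pairs$mol_id`.
#' @param func A `func_vectors` object covering `pairs$protein_id`.
#' @param prompt Optional encoder prompt vector.
#' @return Numeric vector of probabilities in (0, 1), one per row of `pairs`.
#' @export
predict_pairs <- function(model, pairs, graphs, func, prompt = NULL) {
  if (func$n_func != model$n_func)
    stop(sprintf("model expects n_func=%d, got %d", model$n_func, func$n_func))
  miss <- setdiff(unique(pairs$mol_id), names(graphs))
  if (length(miss)) stop("missing molgraph for: ", paste(miss, collapse = ", "))
  umol <- unique(pairs$mol_id)
  feats <- lapply(graphs[umol], featurize_graph)
  batch <- build_batch(feats, model$encoder$readout)
  Hmol <- encode_batch(model$params[c("W_in", "b_in", "W_msg", "b_msg",
                                      "W_atom", "b_atom")],
                       model$encoder, batch, prompt = prompt)$H_mol
  pi <- match(pairs$protein_id, rownames(func$scores))
  if (anyNA(pi)) stop("missing function vector for: ",
                      paste(unique(pairs$protein_id[is.na(pi)]), collapse = ", "))
  Hp <- Hmol[match(pairs$mol_id, umol), , drop = FALSE]
  Fv <- func$scores[pi, , drop = FALSE]
  .pairs_forward(model, Hp, Fv)$prob
}

#' Predict the binding probability of one (protein, molecule) pair
#'
#' @param protein Either a numeric function-score vector or a protein_id
#'   resolved against `func`.
#' @param graph A `molgraph`.
#' @param model A trained `funscreen_model`.
#' @param func Required when `protein` is an id: a `func_vectors` object.
#' @return Probability in (0, 1).
#' @export
predict_pair <- function(protein, graph, model, func = NULL) {
  if (is.character(protein)) {
    if (is.null(func)) stop("func_vectors required to resolve a protein id")
    f <- func$scores[protein, ]
  } else f <- as.numeric(protein)
  if (length(f) != model$n_func)
    stop(sprintf("model expects n_func=%d, got %d", model$n_func, length(f)))
  fv <- func_vectors(matrix(f, 1L, dimnames = list("q", NULL)))
  predict_pairs(model,
                data.frame(protein_id = "q", mol_id = graph$mol_id),
                stats::setNames(list(graph), graph$mol_id), fv)
}

# --- training --------------------------------------------------------------

.adam_step <- function(params, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0; state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.pair_labels <- function(pairs) {
  if (is.numeric(pairs$label)) return(as.numeric(pairs$label))
  as.numeric(pairs$label == "active")
}

.bce_loss <- function(prob, y, w) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

#' Train a binder-classification model
#'
#' Minimizes binary cross-entropy over labeled (protein, molecule) pairs with
#' seeded minibatch Adam. Decoys are label-0 examples exactly like measured
#' inactives. A scaffold-balanced validation split (controlled by
#' `tc$split_seed`) is carved out of the training molecules for the reported
#' validation loss.
#'
#' @param dataset List with `pairs` (data.frame: protein_id, mol_id, label
#'   where label is `"active"`/`"inactive"`/`"decoy"` or numeric 0/1),
#'   `graphs` (named list of `molgraph`), `func` (a `func_vectors`).
#' @param fusion A `fusion_config`.
#' @param enc An `encoder_config`.
#' @param tc A `train_config`.
#' @param verbose Print per-epoch losses.
#' @return A trained `funscreen_model` whose `log` holds per-epoch train and
#'   validation losses and all seeds.
#' @export
train_model <- function(dataset, fusion = fusion_config(),
                        enc = encoder_config(), tc = train_config(),
                        verbose = FALSE) {
  pairs <- dataset$pairs
  y_all <- .pair_labels(pairs)
  if (length(unique(y_all)) < 2L)
    stop("training requires at least one positive and one negative pair")
  func <- dataset$func
  model <- init_model(enc, fusion, n_func = func$n_func, seed = tc$seed)
  enc_names <- c("W_in", "b_in", "W_msg", "b_msg", "W_atom", "b_atom")

  umol <- unique(pairs$mol_id)
  graphs <- dataset$graphs[umol]
  if (any(vapply(graphs, is.null, TRUE)))
    stop("missing molgraph for: ",
         paste(umol[vapply(graphs, is.null, TRUE)], collapse = ", "))
  feats <- lapply(graphs, featurize_graph)

  # validation split on scaffolds of the unique molecules
  scaff <- vapply(graphs, function(g) murcko_scaffold(g)$scaffold_smiles, "")
  split <- scaffold_balanced_split(umol, scaff,
                                   fractions = c(1 - tc$val_fraction,
                                                 tc$val_fraction, 0),
                                   seed = tc$split_seed)
  part <- split$assignment$partition[match(pairs$mol_id, split$assignment$mol_id)]
  tr_idx <- which(part == "train"); va_idx <- which(part == "val")
  if (!length(tr_idx)) stop("validation split left no training pairs")
  if (length(unique(y_all[tr_idx])) < 2L)
    stop("training partition is single-class after the validation split")

  pi_all <- match(pairs$protein_id, rownames(func$scores))
  if (anyNA(pi_all)) stop("missing function vector for some proteins")
  mi_all <- match(pairs$mol_id, umol)

  w_pos <- if (tc$class_handling == "pos_weight")
    sum(y_all[tr_idx] == 0) / max(1, sum(y_all[tr_idx] == 1)) else 1
  lw_all <- ifelse(y_all == 1, w_pos, 1)

  set.seed(tc$seed)
  state <- list(m = list(), v = list()); step <- 0L
  epoch_log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
  L <- fusion$ffn_layers
  for (ep in seq_len(tc$epochs)) {
    ord <- sample(tr_idx)
    nb <- ceiling(length(ord) / tc$batch_size)
    tot_loss <- 0; tot_w <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * tc$batch_size + 1L):min(bi * tc$batch_size,
                                                      length(ord))]
      bm <- unique(mi_all[idx])
      batch <- build_batch(feats[bm], enc$readout)
      encf <- encode_batch(model$params[enc_names], enc, batch,
                           keep_cache = TRUE)
      row_of <- match(mi_all[idx], bm)
      Hp <- encf$H_mol[row_of, , drop = FALSE]
      Fv <- func$scores[pi_all[idx], , drop = FALSE]
      masks <- NULL
      if (fusion$dropout > 0 && L > 1L) {
        masks <- lapply(seq_len(L - 1L), function(l)
          matrix(stats::runif(length(idx) * fusion$ffn_hidden) >= fusion$dropout,
                 length(idx), fusion$ffn_hidden) * 1)
      }
      out <- .pairs_forward(model, Hp, Fv, masks)
      y <- y_all[idx]; w <- lw_all[idx]
      loss <- .bce_loss(out$prob, y, w)
      if (!is.finite(loss))
        stop(sprintf("NaN/Inf loss at epoch %d batch %d; reduce learning_rate",
                     ep, bi))
      tot_loss <- tot_loss + loss * sum(w); tot_w <- tot_w + sum(w)
      dlogit <- w * (out$prob - y) / sum(w)
      hb <- .head_backward(model$params, fusion, out$fwd, dlogit, masks)
      grads <- hb$grads
      d_fused <- hb$d_fused
      h <- enc$hidden_dim
      if (fusion$mode == "add") {
        d_Hp <- d_fused; d_P <- d_fused
      } else {
        d_Hp <- d_fused[, seq_len(h), drop = FALSE]
        d_P <- d_fused[, (h + 1L):ncol(d_fused), drop = FALSE]
      }
      grads$W_p <- t(crossprod(Fv, d_P))
      grads$b_p <- colSums(d_P)
      d_Hmol <- rowsum(d_Hp, group = row_of)
      d_Hmol_full <- matrix(0, length(bm), h)
      d_Hmol_full[as.integer(rownames(d_Hmol)), ] <- d_Hmol
      eg <- encode_backward(model$params[enc_names], enc, batch, encf$cache,
                            d_Hmol_full)
      grads[enc_names] <- eg[enc_names]
      step <- step + 1L
      up <- .adam_step(model$params, grads, state, tc$learning_rate, step)
      model$params <- up$params; state <- up$state
    }
    val_loss <- NA_real_
    if (length(va_idx)) {
      vp <- predict_pairs(model, pairs[va_idx, ], graphs, func)
      val_loss <- .bce_loss(vp, y_all[va_idx], lw_all[va_idx])
    }
    epoch_log <- rbind(epoch_log, data.frame(epoch = ep,
                                             train_loss = tot_loss / tot_w,
                                             val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %s", ep, tot_loss / tot_w,
                      ifelse(is.na(val_loss), "NA", sprintf("%.4f", val_loss))))
  }
  model$log <- list(epochs = epoch_log,
                    final_train_loss = epoch_log$train_loss[nrow(epoch_log)],
                    final_val_loss = epoch_log$val_loss[nrow(epoch_log)],
                    seed = tc$seed, split_seed = tc$split_seed,
                    class_handling = tc$class_handling, pos_weight = w_pos)
  model$train <- tc
  model
}

#' Train an ensemble with distinct scaffold-split seeds
#'
#' Members differ by their scaffold-balanced validation split seed (and
#' initialization seed): member k uses `split_seed + k - 1` and
#' `seed + k - 1`.
#'
#' @param dataset As in [train_model()].
#' @param n_members Number of members (default 3).
#' @param fusion,enc,tc As in [train_model()].
#' @param verbose Print progress.
#' @return List of class `ensemble_model` with `members` and `member_seeds`.
#' @export
train_ensemble <- function(dataset, n_members = 3L, fusion = fusion_config(),
                           enc = encoder_config(), tc = train_config(),
                           verbose = FALSE) {
  stopifnot(n_members >= 1L)
  members <- vector("list", n_members)
  seeds <- integer(n_members)
  for (k in seq_len(n_members)) {
    tck <- tc
    tck$seed <- tc$seed + k - 1L
    tck$split_seed <- tc$split_seed + k - 1L
    seeds[k] <- tck$split_seed
    if (verbose) message(sprintf("training member %d/%d (split seed %d)",
                                 k, n_members, tck$split_seed))
    members[[k]] <- train_model(dataset, fusion, enc, tck, verbose = FALSE)
  }
  structure(list(members = members, member_seeds = seeds),
            class = "ensemble_model")
}

#' Ensemble prediction: arithmetic mean of member probabilities
#'
#' @param ensemble An `ensemble_model` (or a single `funscreen_model`).
#' @param protein,graph,func As in [predict_pair()].
#' @return Probability in (0, 1).
#' @export
ensemble_predict <- function(ensemble, protein, graph, func = NULL) {
  if (inherits(ensemble, "funscreen_model"))
    return(predict_pair(protein, graph, ensemble, func))
  mean(vapply(ensemble$members, function(m)
    predict_pair(protein, graph, m, func), 0))
}

#' Batched ensemble prediction over aligned pairs
#'
#' @param ensemble An `ensemble_model` or single model.
#' @param pairs,graphs,func As in [predict_pairs()].
#' @return Numeric probability vector (mean over members).
#' @export
ensemble_predict_pairs <- function(ensemble, pairs, graphs, func) {
  if (inherits(ensemble, "funscreen_model"))
    return(predict_pairs(ensemble, pairs, graphs, func))
  ps <- vapply(ensemble$members, function(m)
    predict_pairs(m, pairs, graphs, func), numeric(nrow(pairs)))
  if (is.null(dim(ps))) mean(ps) else rowMeans(ps)
}

#' Screen a compound library against one protein
#'
#' @param model A `funscreen_model` or `ensemble_model`.
#' @param protein_id Protein to screen against.
#' @param func A `func_vectors` covering `protein_id`.
#' @param graphs Named list of `molgraph` (the library).
#' @return data.frame `protein_id, mol_id, probability, rank`, ordered by
#'   probability descending with mol_id-ascending tiebreak.
#' @export
screen_library <- function(model, protein_id, func, graphs) {
  pairs <- data.frame(protein_id = protein_id, mol_id = names(graphs))
  p <- ensemble_predict_pairs(model, pairs, graphs, func)
  ord <- order(-p, pairs$mol_id, method = "radix")
  data.frame(protein_id = protein_id, mol_id = pairs$mol_id[ord],
             probability = p[ord], rank = seq_along(p))
}

# --- checkpoint I/O --------------------------------------------------------

.pack_params <- function(params) {
  lapply(params, function(p) {
    if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
    else list(dim = length(p), data = as.numeric(p))
  })
}
.unpack_params <- function(packed) {
  lapply(packed, function(p) {
    d <- unlist(p$dim)
    if (length(d) == 2L) matrix(unlist(p$data), d[1], d[2])
    else as.numeric(unlist(p$data))
  })
}

#' Save a model or ensemble checkpoint (versioned JSON archive)
#'
#' A single text file carrying configs, weight arrays and RNG seeds.
#'
#' @param model `funscreen_model` or `ensemble_model`.
#' @param path Output path.
#' @export
save_checkpoint <- function(model, path) {
  strip <- function(m) list(version = m$version,
                            encoder = unclass(m$encoder),
                            fusion = unclass(m$fusion),
                            n_func = m$n_func, d_prot = m$d_prot,
                            seed = m$seed, params = .pack_params(m$params))
  obj <- if (inherits(model, "ensemble_model")) {
    list(kind = "ensemble", member_seeds = model$member_seeds,
         members = lapply(model$members, strip))
  } else list(kind = "single", model = strip(model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param path Checkpoint path.
#' @return `funscreen_model` or `ensemble_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path)
  rebuild <- function(s) {
    enc <- do.call(encoder_config, s$encoder[c("hidden_dim", "depth", "readout",
                                               "activation", "prompt_enabled")])
    fus <- do.call(fusion_config, s$fusion[c("mode", "ffn_layers", "ffn_hidden",
                                             "dropout")])
    structure(list(version = s$version, encoder = enc, fusion = fus,
                   n_func = s$n_func, d_prot = s$d_prot, seed = s$seed,
                   params = .unpack_params(s$params), log = NULL),
              class = "funscreen_model")
  }
  if (obj$kind == "ensemble") {
    structure(list(members = lapply(obj$members, rebuild),
                   member_seeds = unlist(obj$member_seeds)),
              class = "ensemble_model")
  } else rebuild(obj$model)
}
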