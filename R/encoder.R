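# Directed bond-level message-passing molecular encoder (Chemprop-style).
# One hidden state per directed bond; messages flow along bonds, excluding
# the reverse bond; atom features enter at initialization and at the final
# atom aggregation only. Implemented as dense/sparse matrix ops over a
# block-concatenated batch so whole-dataset passes are cheap on one CPU.


#' Encoder hyperparameter configuration
#'
#' @param hidden_dim Hidden width of bond/atom states and of the molecule
#'   embedding. Default 64 (desk scale).
#' @param depth Number of message-passing steps (>= 0). Default 3.
#' @param readout Atom-state aggregation into the molecule embedding:
#'   `"sum"` (default) or `"mean"`.
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param prompt_enabled If TRUE, an externally supplied prompt vector of
#'   length `hidden_dim` is added to every initial bond-state projection
#'   before message passing (functional-prompt hook; the prompt itself is an
#'   input, not learned here).
#' @return List of class `encoder_config`.
#' @export
encoder_config <- function(hidden_dim = 64L, depth = 3L, readout = "sum",
                           activation = "relu", prompt_enabled = FALSE) {
  stopifnot(hidden_dim >= 1L, depth >= 0L)
  readout <- match.arg(readout, c("sum", "mean"))
  activation <- match.arg(activation, c("relu", "tanh"))
  structure(list(hidden_dim = as.integer(hidden_dim), depth = as.integer(depth),
                 readout = readout, activation = activation,
                 prompt_enabled = isTRUE(prompt_enabled)),
            class = "encoder_config")
}

.act <- function(x, kind) if (kind == "relu") pmax(x, 0) else tanh(x)
# derivative expressed through the post-activation value
.dact <- function(post, kind) if (kind == "relu") (post > 0) * 1 else 1 - post^2

.glorot <- function(nout, nin) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
}

#' Initialize encoder weights (Glorot-uniform, seeded)
#'
#' @param config An `encoder_config`.
#' @param seed Integer RNG seed recorded in checkpoints.
#' @return Named list of weight matrices/vectors.
#' @export
init_encoder_params <- function(config, seed = 1L) {
  set.seed(seed)
  h <- config$hidden_dim
  din <- .D_ATOM + .D_BOND
  list(W_in = .glorot(h, din), b_in = numeric(h),
       W_msg = .glorot(h, h), b_msg = numeric(h),
       W_atom = .glorot(h, .D_ATOM + h), b_atom = numeric(h))
}

# --- featurization ---------------------------------------------------------

.atom_features <- function(atoms) {
  n <- nrow(atoms)
  X <- matrix(0, n, .D_ATOM)
  ei <- match(atoms$element, .ELEMENT_VOCAB, nomatch = .N_ELEM_FEAT)
  X[cbind(seq_len(n), ei)] <- 1
  di <- pmin(atoms$degree, .N_DEG_FEAT - 1L) + 1L
  X[cbind(seq_len(n), .N_ELEM_FEAT + di)] <- 1
  hi <- pmin(atoms$hcount, .N_H_FEAT - 1L) + 1L
  X[cbind(seq_len(n), .N_ELEM_FEAT + .N_DEG_FEAT + hi)] <- 1
  X[, .D_ATOM - 1L] <- atoms$charge
  X[, .D_ATOM] <- as.numeric(atoms$aromatic)
  X
}

#' Featurize a molecular graph for the encoder
#'
#' @param graph A `molgraph`.
#' @return List with atom feature matrix, directed-bond input matrix, and the
#'   index sets used to build sparse aggregation operators.
#' @keywords internal
featurize_graph <- function(graph) {
  Xa <- .atom_features(graph$atoms)
  db <- directed_bonds(graph)
  B <- nrow(db)
  E <- matrix(0, B, .D_BOND)
  if (B) {
    E[cbind(seq_len(B), pmin(db$order, 4L))] <- 1
    E[, 5L] <- as.numeric(db$conj)
    E[, 6L] <- as.numeric(db$ring)
  }
  Z <- cbind(Xa[db$src, , drop = FALSE], E)
  # message pairs: bond i (u->v) receives from bonds j (w->u), w != v
  msg_i <- integer(0); msg_j <- integer(0)
  if (B) {
    by_dst <- split(seq_len(B), db$dst)
    for (i in seq_len(B)) {
      inc <- by_dst[[as.character(db$src[i])]]
      inc <- inc[db$src[inc] != db$dst[i]]
      if (length(inc)) {
        msg_i <- c(msg_i, rep.int(i, length(inc)))
        msg_j <- c(msg_j, inc)
      }
    }
  }
  list(Xa = Xa, Z = Z, src = db$src, dst = db$dst,
       msg_i = msg_i, msg_j = msg_j,
       n_atoms = graph$n_atoms, n_dirbonds = B, mol_id = graph$mol_id)
}

#' Assemble featurized molecules into one block-diagonal batch
#'
#' @param feats List of outputs of [featurize_graph()].
#' @param readout `"sum"` or `"mean"`.
#' @return List with concatenated feature matrices and sparse operators
#'   `A_msg` (bond <- bond aggregation), `A_atom` (atom <- incoming bonds),
#'   `A_mol` (molecule <- atoms).
#' @keywords internal
build_batch <- function(feats, readout = "sum") {
  M <- length(feats)
  na <- vapply(feats, `[[`, 0L, "n_atoms")
  nb <- vapply(feats, `[[`, 0L, "n_dirbonds")
  off_a <- c(0L, cumsum(na))[seq_len(M)]
  off_b <- c(0L, cumsum(nb))[seq_len(M)]
  A_tot <- sum(na); B_tot <- sum(nb)
  Xa <- do.call(rbind, lapply(feats, `[[`, "Xa"))
  Z <- do.call(rbind, lapply(feats, `[[`, "Z"))
  mi <- unlist(lapply(seq_len(M), function(k) feats[[k]]$msg_i + off_b[k]))
  mj <- unlist(lapply(seq_len(M), function(k) feats[[k]]$msg_j + off_b[k]))
  A_msg <- Matrix::sparseMatrix(i = mi, j = mj, x = 1,
                                dims = c(B_tot, B_tot))
  ai <- unlist(lapply(seq_len(M), function(k) feats[[k]]$dst + off_a[k]))
  aj <- unlist(lapply(seq_len(M), function(k) seq_len(nb[k]) + off_b[k]))
  A_atom <- Matrix::sparseMatrix(i = ai, j = aj, x = 1,
                                 dims = c(A_tot, B_tot))
  w <- if (readout == "mean") rep(1 / na, na) else rep(1, A_tot)
  A_mol <- Matrix::sparseMatrix(i = rep(seq_len(M), na), j = seq_len(A_tot),
                                x = w, dims = c(M, A_tot))
  list(Xa = Xa, Z = Z, A_msg = A_msg, A_atom = A_atom, A_mol = A_mol,
       mol_ids = vapply(feats, `[[`, "", "mol_id"),
       n_mols = M, n_atoms = A_tot, n_dirbonds = B_tot)
}

# --- forward / backward ----------------------------------------------------

#' Batched encoder forward pass
#'
#' @param params Encoder weights from [init_encoder_params()].
#' @param config An `encoder_config`.
#' @param batch Output of [build_batch()].
#' @param prompt Optional prompt vector (length `hidden_dim`); requires
#'   `config$prompt_enabled`.
#' @param keep_cache Keep intermediates for [encode_backward()].
#' @return List with `H_mol` (n_mols x hidden_dim embedding matrix) and, if
#'   requested, `cache`.
#' @export
encode_batch <- function(params, config, batch, prompt = NULL,
                         keep_cache = FALSE) {
  h <- config$hidden_dim; kind <- config$activation
  if (ncol(params$W_in) != ncol(batch$Z) || nrow(params$W_in) != h)
    stop("encoder weight dimensions do not match config/featurization")
  if (!is.null(prompt)) {
    if (!config$prompt_enabled) stop("prompt given but prompt_enabled is FALSE")
    if (length(prompt) != h) stop("prompt length must equal hidden_dim")
  }
  B <- batch$n_dirbonds
  pre0 <- batch$Z %*% t(params$W_in)
  pre0 <- sweep(pre0, 2L, params$b_in, "+")
  if (!is.null(prompt) && B) pre0 <- sweep(pre0, 2L, prompt, "+")
  H0 <- .act(pre0, kind)
  H_list <- vector("list", config$depth + 1L)
  M_list <- vector("list", config$depth)
  H <- H0; H_list[[1L]] <- H0
  t <- 1L
  while (t <= config$depth) {
    Mt <- as.matrix(batch$A_msg %*% H)
    pre <- H0 + Mt %*% t(params$W_msg)
    pre <- sweep(pre, 2L, params$b_msg, "+")
    H <- .act(pre, kind)
    M_list[[t]] <- Mt; H_list[[t + 1L]] <- H
    t <- t + 1L
  }
  Mv <- as.matrix(batch$A_atom %*% H)
  U <- cbind(batch$Xa, Mv)
  preV <- sweep(U %*% t(params$W_atom), 2L, params$b_atom, "+")
  Hv <- .act(preV, kind)
  H_mol <- as.matrix(batch$A_mol %*% Hv)
  rownames(H_mol) <- batch$mol_ids
  out <- list(H_mol = H_mol)
  if (keep_cache) out$cache <- list(H_list = H_list, M_list = M_list,
                                    U = U, Hv = Hv)
  out
}

#' Batched encoder backward pass
#'
#' Analytic gradients of a scalar loss w.r.t. all encoder weights, given the
#' gradient w.r.t. the molecule embeddings.
#'
#' @param params,config,batch As in [encode_batch()].
#' @param cache The cache returned by `encode_batch(..., keep_cache = TRUE)`.
#' @param d_Hmol Gradient matrix (n_mols x hidden_dim).
#' @return Named list of gradients matching `params`, plus `d_prompt`.
#' @export
encode_backward <- function(params, config, batch, cache, d_Hmol) {
  kind <- config$activation
  h <- config$hidden_dim
  dHv <- as.matrix(Matrix::crossprod(batch$A_mol, d_Hmol))
  dpreV <- dHv * .dact(cache$Hv, kind)
  gW_atom <- t(crossprod(cache$U, dpreV))   # h x (d_a + h)
  gb_atom <- colSums(dpreV)
  dU <- dpreV %*% params$W_atom
  dMv <- dU[, (.D_ATOM + 1L):(.D_ATOM + h), drop = FALSE]
  dH <- as.matrix(Matrix::crossprod(batch$A_atom, dMv))
  dH0 <- matrix(0, batch$n_dirbonds, h)
  gW_msg <- matrix(0, h, h); gb_msg <- numeric(h)
  t <- config$depth
  while (t >= 1L) {
    dpre <- dH * .dact(cache$H_list[[t + 1L]], kind)
    dH0 <- dH0 + dpre
    gW_msg <- gW_msg + t(crossprod(cache$M_list[[t]], dpre))
    gb_msg <- gb_msg + colSums(dpre)
    dH <- as.matrix(Matrix::crossprod(batch$A_msg, dpre %*% params$W_msg))
    t <- t - 1L
  }
  dH0 <- dH0 + dH
  dpre0 <- dH0 * .dact(cache$H_list[[1L]], kind)
  gW_in <- t(crossprod(batch$Z, dpre0))
  gb_in <- colSums(dpre0)
  list(W_in = gW_in, b_in = gb_in, W_msg = gW_msg, b_msg = gb_msg,
       W_atom = gW_atom, b_atom = gb_atom, d_prompt = colSums(dpre0))
}

#' Encode a single molecule
#'
#' Convenience wrapper over the batched pass.
#'
#' @param graph A `molgraph`.
#' @param params Encoder weights.
#' @param config An `encoder_config`.
#' @param prompt Optional prompt vector.
#' @return List of class `mol_embedding`: `vector` (length `hidden_dim`) and
#'   `mol_id`.
#' @export
encode_molecule <- function(graph, params, config, prompt = NULL) {
  batch <- build_batch(list(featurize_graph(graph)), config$readout)
  hm <- encode_batch(params, config, batch, prompt = prompt)$H_mol
  structure(list(vector = hm[1L, ], mol_id = graph$mol_id),
            class = "mol_embedding")
}
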