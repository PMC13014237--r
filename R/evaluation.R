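# Virtual-screening evaluation: enrichment factors, threshold confusion
# analysis, Needleman-Wunsch global sequence identity, and the train/test
# similarity leakage filter (sequence identity x Tanimoto).

#' Construct a screening result (ranked library)
#'
#' Rows are sorted by probability descending with mol_id-ascending tiebreak,
#' so enrichment factors are reproducible even for degenerate constant-score
#' models.
#'
#' @param protein_id Protein screened against.
#' @param mol_id Compound ids.
#' @param probability Predicted binding probabilities.
#' @param true_label Optional logical/0-1 vector (TRUE = active).
#' @return Object of class `screen_result`.
#' @export
screen_result <- function(protein_id, mol_id, probability, true_label = NULL) {
  stopifnot(length(mol_id) == length(probability))
  if (!is.null(true_label)) {
    stopifnot(length(true_label) == length(mol_id))
    true_label <- as.logical(true_label)
  }
  ord <- order(-probability, mol_id, method = "radix")
  structure(list(protein_id = protein_id,
                 table = data.frame(mol_id = mol_id[ord],
                                    probability = probability[ord],
                                    rank = seq_along(ord),
                                    true_label = if (is.null(true_label)) NA
                                                 else true_label[ord]),
                 N = length(mol_id)),
            class = "screen_result")
}

#' @method print screen_result
#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result %s: %d compounds%s>\n", x$protein_id, x$N,
              if (all(is.na(x$table$true_label))) "" else
                sprintf(", %d actives", sum(x$table$true_label))))
  invisible(x)
}

#' Enrichment factor at fraction alpha
#'
#' EF_alpha = (actives among the top `ceiling(alpha N)` ranked compounds) /
#' (alpha x total actives). Equals 1 in expectation for random ranking,
#' at most 1/alpha, and exactly 1 at alpha = 1.
#'
#' @param result A `screen_result` with known labels and >= 1 active.
#' @param alpha Fraction in (0, 1].
#' @return Numeric EF value.
#' @export
enrichment_factor <- function(result, alpha) {
  stopifnot(inherits(result, "screen_result"), alpha > 0, alpha <= 1)
  lab <- result$table$true_label
  if (all(is.na(lab))) stop("enrichment factor requires known labels")
  n_act <- sum(lab)
  if (n_act == 0L) stop("enrichment factor undefined: no true actives")
  k <- ceiling(alpha * result$N)
  sum(lab[seq_len(k)]) / (alpha * n_act)
}

#' Confusion counts and precision/recall/F1 at a probability threshold
#'
#' Predicted positive iff probability >= tau (closed threshold). Precision is
#' `NA` when there are no predicted positives; F1 is `NA` whenever precision
#' or recall is undefined or both are zero.
#'
#' @param result A `screen_result` with known labels.
#' @param tau Threshold in \[0, 1\].
#' @return List `TP, FP, TN, FN, precision, recall, f1`.
#' @export
confusion_at_threshold <- function(result, tau) {
  lab <- result$table$true_label
  if (all(is.na(lab))) stop("confusion analysis requires known labels")
  pred <- result$table$probability >= tau
  TP <- sum(pred & lab); FP <- sum(pred & !lab)
  FN <- sum(!pred & lab); TN <- sum(!pred & !lab)
  precision <- if (TP + FP == 0L) NA_real_ else TP / (TP + FP)
  recall <- if (TP + FN == 0L) NA_real_ else TP / (TP + FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       precision = precision, recall = recall, f1 = f1)
}

#' Full evaluation report: EF at several fractions + confusion at thresholds
#'
#' @param result A `screen_result` with known labels.
#' @param alphas EF fractions (default 0.01, 0.05, 0.1).
#' @param taus Probability thresholds (default 0.45 and 0.5).
#' @return List of class `eval_report` with `ef` (named by alpha) and
#'   `confusion` (named by tau).
#' @export
eval_report <- function(result, alphas = c(0.01, 0.05, 0.1),
                        taus = c(0.45, 0.5)) {
  ef <- vapply(alphas, function(a) enrichment_factor(result, a), 0)
  names(ef) <- as.character(alphas)
  conf <- lapply(taus, function(t) confusion_at_threshold(result, t))
  names(conf) <- as.character(taus)
  structure(list(protein_id = result$protein_id, N = result$N,
                 n_actives = sum(result$table$true_label),
                 ef = as.list(ef), confusion = conf),
            class = "eval_report")
}

#' Write an evaluation report to JSON
#' @param report An `eval_report`.
#' @param path Output path.
#' @param meta Optional metadata list (seeds, thresholds) stored alongside.
#' @export
write_eval_report <- function(report, path, meta = NULL) {
  obj <- unclass(report)
  if (!is.null(meta)) obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

# --- global sequence identity ----------------------------------------------

#' Global pairwise sequence identity (Needleman-Wunsch)
#'
#' BLOSUM62 scoring, gap opening 10, gap extension 0.5. Identity = identical
#' aligned positions / full alignment length (gap columns included). `X`
#' never counts as identical.
#'
#' @param seq_a,seq_b Non-empty amino-acid strings (20-letter alphabet plus
#'   X).
#' @return Identity in \[0, 1\].
#' @export
global_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = .blosum62(),
                                       gapOpening = 10, gapExtension = 0.5)
  a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(a == b & a != "-" & a != "X") / length(a)
}

.blosum62_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum62_cache$m <- e$BLOSUM62
  }
  .blosum62_cache$m
}

#' Pairwise identity matrix between two sets of sequences
#'
#' @param seqs_a,seqs_b Named character vectors.
#' @return Matrix of identities, rows = `seqs_a`, columns = `seqs_b`.
#' @export
identity_matrix <- function(seqs_a, seqs_b = seqs_a) {
  out <- matrix(NA_real_, length(seqs_a), length(seqs_b),
                dimnames = list(names(seqs_a), names(seqs_b)))
  for (i in seq_along(seqs_a)) {
    for (j in seq_along(seqs_b)) {
      if (identical(seqs_a[[i]], seqs_b[[j]])) { out[i, j] <- {
        a <- strsplit(seqs_a[[i]], "")[[1]]
        sum(a != "X") / length(a)
      }; next }
      out[i, j] <- global_identity(seqs_a[[i]], seqs_b[[j]])
    }
  }
  out
}

# --- similarity leakage filter ---------------------------------------------

#' Filter test pairs too similar to training pairs
#'
#' A test pair (p, m) is removed when some train pair (p', m') has
#' `identity(p, p') x tanimoto(m, m') > threshold` (the product is taken per
#' train pair, then maximized). `mode = "identical"` instead removes test
#' pairs whose compound's canonical SMILES occurs among the training
#' compounds.
#'
#' @param test_pairs,train_pairs data.frames with `protein_id`, `mol_id`.
#' @param sequences Named character vector covering all proteins.
#' @param fingerprints Named list of `fingerprint` objects covering all
#'   compounds (mode "product").
#' @param threshold Similarity threshold in (0, 1\] (mode "product";
#'   typically 0.9, 0.7 or 0.5).
#' @param mode `"product"` (default) or `"identical"`.
#' @param smiles Named character vector of canonical SMILES (mode
#'   "identical").
#' @return List: `retained` (test pairs kept), `removed` (with best-match
#'   score S and its I, T components), `n_removed`.
#' @export
filter_similar_pairs <- function(test_pairs, train_pairs, sequences = NULL,
                                 fingerprints = NULL, threshold = 0.9,
                                 mode = "product", smiles = NULL) {
  mode <- match.arg(mode, c("product", "identical"))
  if (mode == "identical") {
    if (is.null(smiles)) stop("mode 'identical' requires canonical smiles")
    miss <- setdiff(unique(c(test_pairs$mol_id, train_pairs$mol_id)),
                    names(smiles))
    if (length(miss)) stop("missing SMILES for: ", paste(miss, collapse = ", "))
    train_smi <- unique(smiles[train_pairs$mol_id])
    hit <- smiles[test_pairs$mol_id] %in% train_smi
    removed <- test_pairs[hit, , drop = FALSE]
    if (nrow(removed)) removed$S <- 1
    return(list(retained = test_pairs[!hit, , drop = FALSE],
                removed = removed, n_removed = sum(hit)))
  }
  stopifnot(threshold > 0, threshold <= 1)
  prots <- unique(c(test_pairs$protein_id, train_pairs$protein_id))
  mols <- unique(c(test_pairs$mol_id, train_pairs$mol_id))
  missp <- setdiff(prots, names(sequences))
  if (length(missp)) stop("missing sequence for: ", paste(missp, collapse = ", "))
  missm <- setdiff(mols, names(fingerprints))
  if (length(missm)) stop("missing fingerprint for: ",
                          paste(missm, collapse = ", "))
  tp_u <- unique(test_pairs$protein_id); trp_u <- unique(train_pairs$protein_id)
  I <- identity_matrix(sequences[tp_u], sequences[trp_u])
  tm_u <- unique(test_pairs$mol_id); trm_u <- unique(train_pairs$mol_id)
  Tm <- matrix(NA_real_, length(tm_u), length(trm_u),
               dimnames = list(tm_u, trm_u))
  for (i in seq_along(tm_u))
    for (j in seq_along(trm_u))
      Tm[i, j] <- tanimoto(fingerprints[[tm_u[i]]], fingerprints[[trm_u[j]]])
  pi_tr <- match(train_pairs$protein_id, trp_u)
  mi_tr <- match(train_pairs$mol_id, trm_u)
  n_test <- nrow(test_pairs)
  S_best <- numeric(n_test); I_best <- numeric(n_test); T_best <- numeric(n_test)
  for (i in seq_len(n_test)) {
    iv <- I[match(test_pairs$protein_id[i], tp_u), pi_tr]
    tv <- Tm[match(test_pairs$mol_id[i], tm_u), mi_tr]
    s <- iv * tv
    k <- which.max(s)
    S_best[i] <- s[k]; I_best[i] <- iv[k]; T_best[i] <- tv[k]
  }
  hit <- S_best > threshold
  removed <- test_pairs[hit, , drop = FALSE]
  if (nrow(removed)) {
    removed$S <- S_best[hit]; removed$I <- I_best[hit]; removed$T <- T_best[hit]
  }
  list(retained = test_pairs[!hit, , drop = FALSE],
       removed = removed, n_removed = sum(hit))
}
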