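# Protein-side representation: molecular-function score vectors (the
# protein's only representation; DeepFRI-style, 489 classes at full scale)
# and their learned linear projection into the fusion space.

#' Construct a set of protein function vectors
#'
#' @param scores Numeric matrix, one row per protein, entries in \[0, 1\];
#'   rownames are protein ids.
#' @param sequences Optional named character vector of amino-acid sequences
#'   (used only by the evaluation module's identity computation).
#' @return Object of class `func_vectors`.
#' @export
func_vectors <- function(scores, sequences = NULL) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)))
  if (anyDuplicated(rownames(scores)))
    stop("duplicate protein_id in function vectors")
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("function scores must be finite and in [0, 1]")
  structure(list(scores = scores, sequences = sequences,
                 n_func = ncol(scores)), class = "func_vectors")
}

#' @method print func_vectors
#' @export
print.func_vectors <- function(x, ...) {
  cat(sprintf("<func_vectors: %d proteins x %d function classes%s>\n",
              nrow(x$scores), x$n_func,
              if (is.null(x$sequences)) "" else ", with sequences"))
  invisible(x)
}

#' Load protein function-score vectors from CSV
#'
#' Expected header: `protein_id,f_1..f_n`. Values in `[-eps, 1+eps]` are
#' clipped into \[0, 1\] (float round-off); larger violations are data errors
#' reported with the offending row.
#'
#' @param path CSV path.
#' @param n_func Expected vector length; default inferred from the header.
#' @param eps Clipping tolerance (default 1e-6).
#' @return A `func_vectors` object, proteins in file order.
#' @export
load_function_vectors <- function(path, n_func = NULL, eps = 1e-6) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (names(df)[1] != "protein_id")
    stop("function-score CSV must start with a protein_id column: ", path)
  nf <- ncol(df) - 1L
  if (!is.null(n_func) && nf != n_func)
    stop(sprintf("expected %d function scores per row, found %d", n_func, nf))
  if (anyDuplicated(df$protein_id))
    stop("duplicate protein_id in ", path, ": ",
         paste(unique(df$protein_id[duplicated(df$protein_id)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m) || any(is.na(m)))
    stop("non-numeric or missing function scores in ", path)
  bad <- which(m < -eps | m > 1 + eps, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("function score out of [0,1] beyond tolerance at row %d (%s), column %s: %g",
                 bad[1, 1], df$protein_id[bad[1, 1]],
                 colnames(m)[bad[1, 2]], m[bad[1, , drop = FALSE]]))
  }
  m <- pmin(pmax(m, 0), 1)
  rownames(m) <- df$protein_id
  func_vectors(m)
}

#' Write function vectors to CSV (inverse of [load_function_vectors()])
#'
#' @param fv A `func_vectors` object.
#' @param path Output CSV path.
#' @export
write_function_vectors <- function(fv, path) {
  df <- data.frame(protein_id = rownames(fv$scores), fv$scores,
                   check.names = FALSE)
  names(df) <- c("protein_id", sprintf("f_%d", seq_len(fv$n_func)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read protein sequences from a FASTA file
#'
#' First whitespace-delimited token of each description line is the
#' protein_id.
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, "", 1L)
  out <- as.character(ss)
  names(out) <- ids
  out
}

#' Write protein sequences to FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_protein_fasta <- function(sequences, path) {
  ss <- Biostrings::AAStringSet(sequences)
  names(ss) <- names(sequences)
  Biostrings::writeXStringSet(ss, path)
}

#' Initialize the learnable function projection
#'
#' The linear map W f + b taking an n_func score vector into the fusion
#' space.
#'
#' @param n_func Input length.
#' @param d_embed Output (fusion-space) dimension.
#' @param seed RNG seed.
#' @return List of class `function_projection` with `weight` (d_embed x
#'   n_func) and `bias` (d_embed).
#' @export
init_projection <- function(n_func, d_embed, seed = 1L) {
  set.seed(seed)
  structure(list(weight = .glorot(d_embed, n_func), bias = numeric(d_embed)),
            class = "function_projection")
}

#' Project a function vector into the fusion space
#'
#' @param f Numeric vector of length n_func, or a `func_vectors` object (all
#'   proteins projected at once, one row each).
#' @param proj A `function_projection`.
#' @return Numeric vector of length d_embed (or a matrix, one row per
#'   protein).
#' @export
project_function <- function(f, proj) {
  W <- proj$weight; b <- proj$bias
  if (inherits(f, "func_vectors")) f <- f$scores
  if (is.matrix(f)) {
    if (ncol(f) != ncol(W)) stop("function vector length does not match projection")
    return(sweep(f %*% t(W), 2L, b, "+"))
  }
  if (length(f) != ncol(W)) stop("function vector length does not match projection")
  as.numeric(W %*% f + b)
}
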