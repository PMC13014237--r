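# Shared fixtures and independent oracles (brute-force implementations kept
# deliberately separate from the package's code paths).

# 50 drug-like SMILES within the package's 2D dialect
fixture_smiles <- function() c(
  "CC(=O)Oc1ccccc1C(=O)O", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  "CN1CCC[C@H]1c1cccnc1", "Clc1ccccc1", "c1ccc2ccccc2c1",
  "c1ccc2[nH]ccc2c1", "CC(=O)Nc1ccc(O)cc1",
  "CN(C)CCCN1c2ccccc2CCc2ccccc21", "OC(=O)c1ccccc1O", "NC(=O)c1ccccc1",
  "CCN(CC)CCNC(=O)c1ccc(N)cc1", "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
  "CC(C)NCC(O)COc1ccccc1", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  "OCC1OC(O)C(O)C(O)C1O", "C1CCC(CC1)N", "c1ccsc1", "c1ccoc1",
  "c1cnc2[nH]ccc2c1", "CC1=CC(=O)CC(C)(C)C1", "N#Cc1ccccc1", "O=C1CCCCC1",
  "O=S(=O)(N)c1ccc(N)cc1", "FC(F)(F)c1ccccc1", "CCOC(=O)C1CCN(CC1)C",
  "Oc1ccc(cc1)C2(c3ccc(O)cc3)CCCC2", "C#CC(O)(C)C", "CC(N)Cc1ccccc1",
  "CNC(C)Cc1ccccc1", "COC(=O)c1ccccc1N", "CSc1ccccc1", "O=C(O)CCc1ccccc1",
  "NCCc1c[nH]c2ccccc12", "OC(=O)C(N)Cc1c[nH]c2ccccc12", "C1CN(CCN1)c1ccccc1",
  "CC(=O)c1ccc(Br)cc1", "Ic1ccccc1", "CC(Cl)C(=O)O", "[O-][N+](=O)c1ccccc1",
  "CC[N+](C)(C)CC", "CC(=O)[O-]", "c1cc[n+](C)cc1", "C1CCOC1", "C1COCCN1",
  "O=C(NC1CC1)Nc1ccccc1", "CC12CCC(CC1)CC2", "c1ccc(cc1)-c1ccccc1",
  "CC(=CCCC(C)=C)C", "OCCOCCO", "CC(O)C(O)CO"
)

# Needleman-Wunsch with affine gaps (Gotoh), BLOSUM62-style scoring matrix
# passed in; returns optimal score and identity over the traceback alignment
nw_oracle <- function(a, b, submat, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Iy[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- s + max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  score <- max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
  # traceback
  st <- which.max(c(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  ident <- 0L; len <- 0L
  while (i > 1 || j > 1) {
    len <- len + 1L
    if (st == 1L) {
      s <- submat[A[i - 1], B[j - 1]]
      if (A[i - 1] == B[j - 1] && A[i - 1] != "X") ident <- ident + 1L
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      st <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (st == 2L) {
      if (i == 1) { st <- 3L; len <- len - 1L; next }
      from_m <- M[i - 1, j] - open - ext
      from_x <- Ix[i - 1, j] - ext
      st <- if (from_m >= from_x) 1L else 2L
      i <- i - 1
    } else {
      if (j == 1) { st <- 2L; len <- len - 1L; next }
      from_m <- M[i, j - 1] - open - ext
      from_y <- Iy[i, j - 1] - ext
      st <- if (from_m >= from_y) 1L else 3L
      j <- j - 1
    }
  }
  list(score = score, identity = ident / len)
}

blosum62_matrix <- function() {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# brute-force enrichment factor from raw scores/labels
ef_oracle <- function(prob, ids, label, alpha) {
  ord <- order(-prob, ids)
  lab <- label[ord]
  k <- ceiling(alpha * length(prob))
  sum(lab[seq_len(k)]) / (alpha * sum(lab))
}

# exhaustive O(n*m) similarity-filter oracle over precomputed matrices
filter_oracle <- function(test_pairs, train_pairs, I, Tm, threshold) {
  removed <- logical(nrow(test_pairs))
  for (i in seq_len(nrow(test_pairs))) {
    for (j in seq_len(nrow(train_pairs))) {
      s <- I[test_pairs$protein_id[i], train_pairs$protein_id[j]] *
        Tm[test_pairs$mol_id[i], train_pairs$mol_id[j]]
      if (s > threshold) { removed[i] <- TRUE; break }
    }
  }
  removed
}

random_aa_seq <- function(len) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"), len,
               replace = TRUE), collapse = "")
}

# hand-checked 12-row activity fixture; expected partition:
#   active:    P1/M1, P1/M6, P2/M1, P2/M3
#   inactive:  P1/M2, P2/M2, P2/M6
#   ambiguous: P1/M3 (mixed sides), P1/M4 (exactly 50 uM),
#              P1/M5 (0.05 mM = exactly 50 uM)
activity_fixture <- function() data.frame(
  protein_id = c("P1","P1","P1","P1","P1","P1","P1",
                 "P2","P2","P2","P2","P2"),
  mol_id = c("M1","M2","M3","M3","M4","M5","M6",
             "M1","M2","M3","M3","M6"),
  metric = c("IC50","KD","IC50","KD","KI","EC50","KD",
             "KD","IC50","KI","EC50","IC50"),
  value = c(10, 100, 10, 200, 50, 0.05, 0.001,
            50, 2e-4, 1, 5, 75),
  unit = c("uM","uM","uM","uM","uM","mM","mM",
           "nM","M","uM","uM","uM"),
  source = "fixture",
  stringsAsFactors = FALSE
)

# small world for fast training tests
tiny_world <- function(seed = 1) {
  generate_world(world_spec(n_proteins = 10L, n_molecules = 60L,
                            n_measured_per_protein = 12L, seed = seed))
}
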