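# Enrichment factors, confusion analysis, global identity, leakage filter.

test_that("enrichment factor matches hand-derived cases", {
  # perfect ranking: 10 actives all in the top 10 of 1000
  p <- seq(1, 0.001, length.out = 1000)
  lab <- c(rep(TRUE, 10), rep(FALSE, 990))
  res <- screen_result("t", sprintf("m%04d", 1:1000), p, lab)
  expect_equal(enrichment_factor(res, 0.01), 100.0)
  # actives at ranks 1, 3, 150 of 200; alpha 0.05 -> top 10 holds 2
  p <- seq(1, 0.005, length.out = 200)
  lab <- rep(FALSE, 200); lab[c(1, 3, 150)] <- TRUE
  res <- screen_result("t", sprintf("m%03d", 1:200), p, lab)
  expect_equal(enrichment_factor(res, 0.05), 2 / (0.05 * 3), tolerance = 1e-12)
  # alpha = 1 retrieves the whole library
  expect_equal(enrichment_factor(res, 1), 1.0)
  # no actives -> undefined
  res0 <- screen_result("t", c("a", "b"), c(0.9, 0.1), c(FALSE, FALSE))
  expect_error(enrichment_factor(res0, 0.1), "no true actives")
})

test_that("EF is rank-based: invariant to monotone probability rescaling", {
  set.seed(19)
  p <- runif(300)
  lab <- runif(300) < 0.1; lab[1] <- TRUE
  ids <- sprintf("m%03d", 1:300)
  r1 <- screen_result("t", ids, p, lab)
  r2 <- screen_result("t", ids, plogis(5 * p - 2), lab)
  for (a in c(0.01, 0.05, 0.2))
    expect_identical(enrichment_factor(r1, a), enrichment_factor(r2, a))
})

test_that("confusion analysis at thresholds", {
  # 6-item fixture, counts enumerated by hand
  res <- screen_result("t", paste0("m", 1:6),
                       c(0.9, 0.8, 0.6, 0.5, 0.3, 0.1),
                       c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  cf <- confusion_at_threshold(res, 0.5)
  expect_equal(cf[c("TP", "FP", "TN", "FN")], list(TP = 2L, FP = 2L,
                                                   TN = 1L, FN = 1L))
  expect_equal(cf$precision, 0.5)
  expect_equal(cf$recall, 2 / 3)
  expect_equal(cf$f1, 2 * 0.5 * (2 / 3) / (0.5 + 2 / 3))
  # tau = 0: everything predicted positive
  cf0 <- confusion_at_threshold(res, 0)
  expect_equal(cf0$TP, 3L); expect_equal(cf0$FP, 3L)
  expect_equal(cf0$TN + cf0$FN, 0L)
  # tau above the maximum: empty positive set, precision undefined
  cf1 <- confusion_at_threshold(res, 0.95)
  expect_equal(cf1$TP + cf1$FP, 0L)
  expect_true(is.na(cf1$precision))
  # counts always sum to N
  for (tau in seq(0, 1, by = 0.1)) {
    cc <- confusion_at_threshold(res, tau)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 6L)
  }
})

test_that("global identity agrees with an independent affine-gap DP oracle", {
  bl <- blosum62_matrix()
  expect_equal(global_identity("MKVLA", "MKVLA"), 1.0)
  expect_equal(global_identity("AAAA", "CCCC"), 0.0)
  ora <- nw_oracle("HEAGAWGHEE", "PAWHEAE", bl)
  expect_equal(global_identity("HEAGAWGHEE", "PAWHEAE"), ora$identity)
  # distinct co-optimal alignments can differ in identity, so on random
  # pairs the oracle pins the optimal alignment *score* (which is unique);
  # the identity convention is pinned by the example above and the
  # degenerate cases
  set.seed(23)
  for (i in 1:8) {
    a <- random_aa_seq(sample(20:40, 1))
    b <- random_aa_seq(sample(20:40, 1))
    ora <- nw_oracle(a, b, bl)
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = bl,
                                         gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), ora$score, tolerance = 1e-9)
  }
  expect_error(global_identity("", "AAA"), "empty")
})

test_that("X never counts as an identical position", {
  expect_equal(global_identity("AXA", "AXA"), 2 / 3)
})

test_that("similarity filter matches the exhaustive double-loop oracle", {
  set.seed(29)
  prots <- paste0("p", 1:5)
  seqs <- setNames(c(random_aa_seq(30), random_aa_seq(30), random_aa_seq(30),
                     random_aa_seq(30), random_aa_seq(30)), prots)
  seqs["p2"] <- seqs["p1"]  # one identical protein pair
  mols <- paste0("m", 1:8)
  graphs <- lapply(fixture_smiles()[1:8], parse_smiles)
  names(graphs) <- mols
  fps <- setNames(lapply(mols, function(m) morgan_fingerprint(graphs[[m]])), mols)
  test_pairs <- data.frame(protein_id = sample(prots, 5, TRUE),
                           mol_id = sample(mols, 5, TRUE))
  train_pairs <- data.frame(protein_id = sample(prots, 8, TRUE),
                            mol_id = sample(mols, 8, TRUE))
  I <- identity_matrix(seqs, seqs)
  Tm <- outer(mols, mols, Vectorize(function(a, b) tanimoto(fps[[a]], fps[[b]])))
  dimnames(Tm) <- list(mols, mols)
  for (thr in c(0.9, 0.7, 0.5, 0.2)) {
    fl <- filter_similar_pairs(test_pairs, train_pairs, seqs, fps,
                               threshold = thr)
    ora <- filter_oracle(test_pairs, train_pairs, I, Tm, thr)
    expect_equal(fl$n_removed, sum(ora))
    expect_equal(nrow(fl$retained), sum(!ora))
  }
  # a test pair identical to a train pair is removed at every threshold < 1
  tp <- train_pairs[1, ]
  for (thr in c(0.9, 0.7, 0.5))
    expect_equal(filter_similar_pairs(tp, train_pairs, seqs, fps,
                                      threshold = thr)$n_removed, 1L)
  # threshold 1 removes nothing (S <= 1 with equality only for identity)
  expect_equal(filter_similar_pairs(tp, train_pairs, seqs, fps,
                                    threshold = 1)$n_removed, 0L)
  expect_error(filter_similar_pairs(test_pairs, train_pairs, seqs[-1], fps,
                                    threshold = 0.5), "missing sequence")
  expect_error(filter_similar_pairs(test_pairs, train_pairs, seqs, fps[-1],
                                    threshold = 0.5), "missing fingerprint")
})

test_that("exact-identity mode removes canonical-SMILES duplicates", {
  graphs <- list(a = parse_smiles("OCC", "a"), b = parse_smiles("CCO", "b"),
                 c = parse_smiles("CCN", "c"))
  smi <- vapply(graphs, `[[`, "", "smiles")
  test_pairs <- data.frame(protein_id = "p1", mol_id = c("a", "c"))
  train_pairs <- data.frame(protein_id = "p2", mol_id = "b")
  fl <- filter_similar_pairs(test_pairs, train_pairs, mode = "identical",
                             smiles = smi)
  expect_equal(fl$removed$mol_id, "a")  # OCC and CCO are the same compound
  expect_equal(fl$retained$mol_id, "c")
})

test_that("eval_report JSON export carries EF and confusion blocks", {
  res <- screen_result("t", paste0("m", 1:50), runif(50),
                       c(rep(TRUE, 5), rep(FALSE, 45)))
  rep <- eval_report(res, alphas = c(0.1, 1), taus = 0.5)
  expect_equal(rep$ef[["1"]], 1.0)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, tmp, meta = list(seed = 1))
  parsed <- jsonlite::read_json(tmp)
  expect_equal(parsed$N, 50L)
  expect_true(!is.null(parsed$confusion[["0.5"]]$TP))
})
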