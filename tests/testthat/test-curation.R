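# Labeling rule, unit normalization, decoy sampling, scaffold splits.

test_that("affinity units convert exactly to micromolar", {
  expect_equal(normalize_affinity(50, "nM"), 0.05)
  expect_equal(normalize_affinity(0.05, "mM"), 50)
  expect_equal(normalize_affinity(1e-7, "M"), 0.1)
  expect_equal(normalize_affinity(2, "uM"), 2)
  expect_equal(normalize_affinity(1e3, "pM"), 1e-3)
  expect_error(normalize_affinity(1, "fM"), "unknown")
})

test_that("50 uM labeling rule: sides, boundary, conflicts, order-independence", {
  expect_equal(label_records(10), "active")
  expect_equal(label_records(100), "inactive")
  expect_equal(label_records(50), "ambiguous")
  expect_equal(label_records(c(10, 200)), "ambiguous")
  expect_equal(label_records(c(200, 10)), "ambiguous")
  expect_equal(label_records(c(1, 5, 49.9)), "active")
  expect_error(label_records(numeric(0)), "empty")
  set.seed(3)
  vals <- c(2, 70, 49, 51)
  for (i in 1:5) expect_equal(label_records(sample(vals)),
                              label_records(vals))
})

test_that("12-row fixture partitions into the hand-counted label sets", {
  cur <- curate_activity(activity_fixture())
  key <- function(df) paste(df$protein_id, df$mol_id, sep = "/")
  act <- key(cur$pairs[cur$pairs$label == "active", ])
  ina <- key(cur$pairs[cur$pairs$label == "inactive", ])
  amb <- key(cur$ambiguous)
  expect_setequal(act, c("P1/M1", "P1/M6", "P2/M1", "P2/M3"))
  expect_setequal(ina, c("P1/M2", "P2/M2", "P2/M6"))
  expect_setequal(amb, c("P1/M3", "P1/M4", "P1/M5"))
  expect_equal(cur$stats$n_records, 12L)
  # ambiguous pairs never reach the usable set; keys unique
  expect_false(any(amb %in% key(cur$pairs)))
  expect_false(anyDuplicated(key(cur$pairs)) > 0)
})

test_that("per-protein inactive cap applies at ingestion", {
  rec <- data.frame(protein_id = "P1", mol_id = sprintf("M%02d", 1:6),
                    metric = "IC50", value = c(500, 500, 500, 500, 500, 1),
                    unit = "uM", source = "x")
  cur <- curate_activity(rec, inactive_cap = 3L)
  expect_equal(cur$stats$n_inactive, 3L)
  expect_equal(cur$stats$n_inactive_capped, 2L)
  expect_equal(cur$stats$n_active, 1L)
})

test_that("decoy sampling excludes measured pairs and respects the ratio", {
  labeled <- data.frame(
    protein_id = c(rep("P1", 7), "P2"),
    mol_id = c(sprintf("A%02d", 1:5), "B1", "B2", "B1"),
    label = c(rep("active", 5), "inactive", "ambiguous", "inactive"),
    provenance = "measured")
  pool <- c(sprintf("A%02d", 1:5), "B1", "B2", sprintf("C%03d", 1:100))
  dec <- sample_decoys(labeled, pool, ratio = 1.0, seed = 42)
  d1 <- dec[dec$protein_id == "P1", ]
  expect_equal(nrow(d1), 5L)  # round(1.0 x 5 actives)
  # exhaustive exclusion: no decoy collides with any measured P1 pair
  expect_length(intersect(d1$mol_id, labeled$mol_id[labeled$protein_id == "P1"]), 0)
  expect_true(all(dec$provenance == "assumed_negative"))
  # zero actives -> zero decoys
  expect_equal(nrow(dec[dec$protein_id == "P2", ]), 0L)
  # seeded determinism
  expect_identical(dec, sample_decoys(labeled, pool, ratio = 1.0, seed = 42))
  expect_false(identical(dec, sample_decoys(labeled, pool, ratio = 1.0,
                                            seed = 43)))
})

test_that("decoy pool exhaustion logs a shortfall and samples the remainder", {
  labeled <- data.frame(protein_id = "P1", mol_id = sprintf("A%d", 1:4),
                        label = "active", provenance = "measured")
  pool <- c(sprintf("A%d", 1:4), "X1", "X2")
  expect_warning(dec <- sample_decoys(labeled, pool, ratio = 1.0, seed = 1),
                 "exhausted")
  expect_setequal(dec$mol_id, c("X1", "X2"))
})

test_that("scaffold-balanced split honors group structure", {
  # ten singleton scaffolds at (0.8, 0.1, 0.1) fill 8/1/1
  sp <- scaffold_balanced_split(paste0("m", 1:10), paste0("s", 1:10),
                                c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(sum(sp$assignment$partition == "train"), 8L)
  expect_equal(sum(sp$assignment$partition == "val"), 1L)
  expect_equal(sum(sp$assignment$partition == "test"), 1L)
  # one shared scaffold cannot be divided
  expect_warning(sp1 <- scaffold_balanced_split(paste0("m", 1:5), rep("s", 5),
                                                c(0.8, 0.1, 0.1), seed = 1),
                 "fewer scaffold groups")
  expect_true(all(sp1$assignment$partition == "train"))
  # determinism
  ids <- paste0("m", 1:40)
  sc <- rep(paste0("s", 1:10), each = 4)
  a <- scaffold_balanced_split(ids, sc, c(0.7, 0.15, 0.15), seed = 9)
  b <- scaffold_balanced_split(ids, sc, c(0.7, 0.15, 0.15), seed = 9)
  expect_identical(a$assignment, b$assignment)
  # scaffold-disjointness
  tab <- table(sc, a$assignment$partition)
  expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("merging labeled pairs rejects duplicate keys", {
  a <- data.frame(protein_id = "P1", mol_id = "M1", label = "active",
                  provenance = "measured")
  d <- data.frame(protein_id = "P1", mol_id = "M1", label = "decoy",
                  provenance = "assumed_negative")
  expect_error(merge_labeled_pairs(a, d), "duplicate")
  ok <- merge_labeled_pairs(a, data.frame(protein_id = "P1", mol_id = "M2",
                                          label = "decoy",
                                          provenance = "assumed_negative"))
  expect_equal(nrow(ok), 2L)
})
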