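# Activity-record curation: unit normalization to micromolar, the 50 uM
# active/inactive labeling rule, decoy sampling (assumed negatives),
# deduplication, and Bemis-Murcko scaffold-balanced dataset splitting.


#' Normalize an affinity value to micromolar
#'
#' Exact power-of-ten conversion.
#'
#' @param value Positive numeric value(s).
#' @param unit Unit string(s) from `M, mM, uM, nM, pM`.
#' @return Value(s) in uM.
#' @export
normalize_affinity <- function(value, unit) {
  f <- .UNIT_TO_UM[unit]
  if (anyNA(f))
    stop("unknown affinity unit: ",
         paste(unique(unit[is.na(f)]), collapse = ", "))
  unname(value * f)
}

#' Label one (protein, compound) pair from its affinity records
#'
#' All metrics strictly below the cutoff: active. All strictly above:
#' inactive. Mixed sides, or any metric exactly at the cutoff: ambiguous
#' (excluded from training). Order-independent in the records.
#'
#' @param values_um Numeric vector of affinity values in uM (>= 1 record).
#' @param cutoff Cutoff in uM (default 50).
#' @return One of `"active"`, `"inactive"`, `"ambiguous"`.
#' @export
label_records <- function(values_um, cutoff = 50) {
  if (!length(values_um)) stop("empty record set for labeling")
  if (all(values_um < cutoff)) return("active")
  if (all(values_um > cutoff)) return("inactive")
  "ambiguous"
}

#' Curate an activity-record table into labeled pairs
#'
#' Validates metrics/units, normalizes values to uM, groups records by
#' (protein_id, mol_id), applies the labeling rule, and drops ambiguous
#' pairs from the usable set (they are returned separately and still block
#' decoy sampling). An optional per-protein cap limits measured inactives
#' (screening-deck ingestion convention).
#'
#' @param records data.frame with columns `protein_id, mol_id, metric,
#'   value, unit` (optional `source`).
#' @param cutoff Labeling cutoff in uM (default 50).
#' @param inactive_cap Per-protein cap on measured inactives (default 2000);
#'   kept inactives are the first by mol_id order for determinism.
#' @return List of class `curation_result`: `pairs` (data.frame protein_id,
#'   mol_id, label, provenance for active/inactive pairs), `ambiguous`
#'   (excluded pairs), `stats` (record counts).
#' @export
curate_activity <- function(records, cutoff = 50, inactive_cap = 2000L) {
  need <- c("protein_id", "mol_id", "metric", "value", "unit")
  if (!all(need %in% names(records)))
    stop("activity table must have columns: ", paste(need, collapse = ", "))
  badm <- !(records$metric %in% .METRICS)
  if (any(badm))
    stop("unknown affinity metric in rows ",
         paste(utils::head(which(badm)), collapse = ", "))
  if (any(!is.finite(records$value) | records$value <= 0))
    stop("affinity values must be positive, see row ",
         which(!is.finite(records$value) | records$value <= 0)[1])
  um <- normalize_affinity(records$value, records$unit)
  key <- paste(records$protein_id, records$mol_id, sep = "\r")
  key <- factor(key, levels = sort(unique(key), method = "radix"))
  lab <- vapply(split(um, key), label_records, "", cutoff = cutoff)
  ks <- strsplit(names(lab), "\r", fixed = TRUE)
  pairs <- data.frame(protein_id = vapply(ks, `[[`, "", 1L),
                      mol_id = vapply(ks, `[[`, "", 2L),
                      label = unname(lab),
                      provenance = "measured",
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$protein_id, pairs$mol_id, method = "radix"), ]
  rownames(pairs) <- NULL
  amb <- pairs[pairs$label == "ambiguous", ]
  keep <- pairs[pairs$label != "ambiguous", ]
  # per-protein inactive cap
  dropped_cap <- 0L
  if (is.finite(inactive_cap)) {
    ina <- keep$label == "inactive"
    idx_by_prot <- split(which(ina), keep$protein_id[ina])
    drop <- unlist(lapply(idx_by_prot, function(ix)
      if (length(ix) > inactive_cap) ix[-seq_len(inactive_cap)] else integer(0)))
    dropped_cap <- length(drop)
    if (dropped_cap) keep <- keep[-drop, ]
  }
  rownames(keep) <- NULL
  structure(list(pairs = keep, ambiguous = amb,
                 stats = list(n_records = nrow(records),
                              n_pairs = nrow(pairs),
                              n_active = sum(keep$label == "active"),
                              n_inactive = sum(keep$label == "inactive"),
                              n_ambiguous = nrow(amb),
                              n_inactive_capped = dropped_cap)),
            class = "curation_result")
}

#' Sample decoys (assumed negatives) per protein
#'
#' For each protein, compounds are drawn uniformly without replacement from
#' the pool, excluding every compound with a measured record (active,
#' inactive or ambiguous) against that protein. The per-protein count is
#' `round(ratio x active count)`; an exhausted pool yields all available
#' eligible compounds with a warning.
#'
#' @param labeled data.frame of labeled pairs (`protein_id, mol_id, label`);
#'   pass ambiguous pairs too so they are excluded from eligibility.
#' @param compound_pool Character vector of candidate mol_ids (typically all
#'   compounds with any measured activity).
#' @param ratio Decoys per active (default 1).
#' @param seed Integer seed; identical seeds give identical decoy sets.
#' @return data.frame of decoy pairs: `protein_id, mol_id, label = "decoy",
#'   provenance = "assumed_negative"`.
#' @export
sample_decoys <- function(labeled, compound_pool, ratio = 1.0, seed = 1L) {
  set.seed(seed)
  pool <- sort(unique(compound_pool), method = "radix")
  prots <- sort(unique(labeled$protein_id), method = "radix")
  out <- vector("list", length(prots))
  for (i in seq_along(prots)) {
    p <- prots[i]
    mine <- labeled[labeled$protein_id == p, ]
    n_act <- sum(mine$label == "active")
    want <- round(ratio * n_act)
    if (want == 0L) next
    eligible <- setdiff(pool, mine$mol_id)
    if (length(eligible) < want) {
      warning(sprintf("decoy pool exhausted for %s: %d requested, %d available",
                      p, want, length(eligible)))
      want <- length(eligible)
    }
    if (want == 0L) next
    picked <- if (length(eligible) == 1L) eligible
              else sample(eligible, want)
    out[[i]] <- data.frame(protein_id = p, mol_id = picked,
                           label = "decoy", provenance = "assumed_negative",
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(protein_id = character(0), mol_id = character(0),
                      label = character(0), provenance = character(0))
  rownames(res) <- NULL
  res
}

#' Scaffold-balanced train/val/test split
#'
#' Molecules are grouped by Bemis-Murcko scaffold string (the empty acyclic
#' scaffold is one group). Groups larger than half the smallest non-train
#' target are assigned to train first; the remaining groups are shuffled with
#' the seed and placed greedily into the partition currently furthest below
#' its target count (ties: train, then val, then test). No scaffold ever
#' spans partitions.
#'
#' @param mol_ids Character vector of molecule ids.
#' @param scaffolds Scaffold strings aligned with `mol_ids` (e.g. from
#'   [murcko_scaffold()]).
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1.
#' @param seed Integer seed; identical seeds give identical assignments.
#' @return List of class `split_assignment`: `assignment` (data.frame
#'   mol_id, partition), `seed`, `fractions`.
#' @export
scaffold_balanced_split <- function(mol_ids, scaffolds,
                                    fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(mol_ids) == length(scaffolds), length(fractions) == 3L)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  parts <- c("train", "val", "test")
  groups <- split(mol_ids, factor(scaffolds, levels = sort(unique(scaffolds),
                                                 method = "radix")))
  n <- length(mol_ids)
  assign_part <- rep(NA_character_, length(groups))
  names(assign_part) <- names(groups)
  if (length(groups) < sum(fractions > 0)) {
    warning("fewer scaffold groups than partitions; everything assigned to train")
    assign_part[] <- "train"
  } else {
    target <- fractions * n
    sizes <- lengths(groups)
    nontrain <- target[-1][fractions[-1] > 0]
    # a group is forced into train when it would swamp the smallest
    # non-train partition; singletons are never "big"
    big_thr <- if (length(nontrain)) max(1, min(nontrain) / 2) else Inf
    big <- sizes > big_thr
    count <- c(train = 0, val = 0, test = 0)
    assign_part[big] <- "train"
    count["train"] <- sum(sizes[big])
    set.seed(seed)
    rest <- which(!big)
    if (length(rest) > 1L) rest <- sample(rest)
    for (g in rest) {
      deficit <- target - count
      deficit[fractions == 0] <- -Inf
      k <- parts[which.max(deficit)]
      assign_part[g] <- k
      count[k] <- count[k] + sizes[g]
    }
  }
  df <- data.frame(mol_id = mol_ids,
                   partition = unname(assign_part[match(scaffolds,
                                                        names(groups))]),
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(list(assignment = df, seed = as.integer(seed),
                 fractions = fractions),
            class = "split_assignment")
}

#' Merge measured pairs and decoys into one training table
#'
#' Enforces uniqueness of (protein_id, mol_id); ambiguous pairs never enter.
#'
#' @param measured `pairs` from [curate_activity()].
#' @param decoys Output of [sample_decoys()] (optional).
#' @return data.frame of labeled pairs.
#' @export
merge_labeled_pairs <- function(measured, decoys = NULL) {
  all <- if (is.null(decoys) || !nrow(decoys)) measured
         else rbind(measured, decoys)
  key <- paste(all$protein_id, all$mol_id)
  if (anyDuplicated(key))
    stop("duplicate (protein_id, mol_id) after merging: ",
         key[duplicated(key)][1])
  rownames(all) <- NULL
  all
}

#' Read an activity-record CSV (`protein_id,mol_id,metric,value,unit,source`)
#' @param path CSV path.
#' @return data.frame.
#' @export
read_activity_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}
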