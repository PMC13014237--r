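# Planted-rule synthetic world: latent function archetypes, fragment-grammar
# molecules, and a compatibility rule mapping (archetype, fragment set) to
# micromolar affinities, so curation, training, decoy ablation, zero-shot
# transfer and evaluation are exercisable end to end with no external data.

# fixed fragment library: valid SMILES pieces, one attachment point at each
# end when concatenated head-to-tail; ring labels close internally
.FRAGMENT_LIBRARY <- c(
  "CC", "CCC", "CCO", "CCN", "COC",
  "CNC", "CSC", "CC(C)C", "C(=O)N", "C(=O)O",
  "c1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1", "Cc1ccccc1",
  "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "C1CCCC1", "CC=C"
)
.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

#' Specification of a synthetic screening world
#'
#' Defaults define the study conditions used throughout the package's tests:
#' 4 latent function archetypes, 50 proteins, 400 molecules, 16 function
#' classes.
#'
#' @param n_archetypes Latent function archetypes (default 4).
#' @param n_proteins Number of proteins (default 50).
#' @param n_molecules Number of molecules (default 400).
#' @param n_func Function-vector length (default 16; must allow the disjoint
#'   archetype support, i.e. `n_func >= n_archetypes`).
#' @param noise_sd SD of clipped Gaussian noise added to the archetype
#'   function prototype (default 0.1).
#' @param label_flip_rate Fraction of pairs whose affinity is drawn from the
#'   wrong side of the cutoff, emulating assay noise (default 0.05).
#' @param affinity_active,affinity_inactive Log-uniform uM affinity ranges
#'   for compatible / incompatible pairs; defaults (0.1, 10) and (100, 1000)
#'   straddle the 50 uM labeling cutoff with a margin.
#' @param n_measured_per_protein Compounds with measured records per protein
#'   (default 30).
#' @param seq_length Synthetic protein sequence length (default 120).
#' @param mutation_rate Per-position substitution rate away from the
#'   archetype core sequence (default 0.1), so within-archetype identity
#'   exceeds between-archetype identity.
#' @param fragments_per_molecule Range of fragments per molecule (default
#'   2:4).
#' @param seed Integer seed; the world is a deterministic function of the
#'   spec.
#' @return List of class `world_spec`.
#' @export
world_spec <- function(n_archetypes = 4L, n_proteins = 50L, n_molecules = 400L,
                       n_func = 16L, noise_sd = 0.1, label_flip_rate = 0.05,
                       affinity_active = c(0.1, 10),
                       affinity_inactive = c(100, 1000),
                       n_measured_per_protein = 30L, seq_length = 120L,
                       mutation_rate = 0.1, fragments_per_molecule = 2:4,
                       seed = 1L) {
  stopifnot(n_archetypes >= 1L, n_proteins >= 1L, n_molecules >= 1L,
            n_func >= 1L, noise_sd >= 0, label_flip_rate >= 0,
            label_flip_rate < 1)
  if (n_func < n_archetypes)
    stop("n_func must be >= n_archetypes (disjoint prototype support)")
  structure(as.list(environment()), class = "world_spec")
}

.preferred_sets <- function(n_archetypes) {
  nf <- length(.FRAGMENT_LIBRARY)
  per <- floor(nf / n_archetypes)
  lapply(seq_len(n_archetypes), function(a)
    ((a - 1L) * per + 1L):(a * per))
}

#' Expected active-pair fraction implied by the compatibility rule
#'
#' Exact enumeration over the number of fragments per molecule and the
#' binomial count of archetype-preferred fragments; a pair is compatible
#' when at least half of the molecule's fragments are preferred.
#'
#' @param spec A `world_spec`.
#' @return Expected fraction of compatible (protein, molecule) pairs.
#' @export
expected_active_fraction <- function(spec = world_spec()) {
  pref <- .preferred_sets(spec$n_archetypes)
  p_pref <- length(pref[[1]]) / length(.FRAGMENT_LIBRARY)
  ks <- spec$fragments_per_molecule
  mean(vapply(ks, function(k) {
    sum(stats::dbinom(ceiling(k / 2):k, k, p_pref))
  }, 0))
}

#' Generate a synthetic screening world
#'
#' Each archetype owns a sparse function prototype (disjoint support, so the
#' planted signal is linearly recoverable) and a preferred fragment set.
#' Proteins draw an archetype, add clipped Gaussian noise to the prototype,
#' and mutate an archetype core sequence. Molecules concatenate 2-4 library
#' fragments. True binding = at least half the fragments preferred by the
#' protein's archetype; compatible pairs get log-uniform affinities in the
#' active range, incompatible in the inactive range, and `label_flip_rate`
#' of measured pairs draw from the wrong side.
#'
#' @param spec A `world_spec`.
#' @return List of class `synthetic_world`: `spec`, `proteins` (data.frame
#'   with archetype and sequence), `func` (a `func_vectors` with sequences),
#'   `molecules` (data.frame with smiles), `graphs` (named `molgraph` list),
#'   `records` (activity table), `truth` (logical protein x molecule
#'   compatibility matrix), `fragment_sets` (list of fragment indices per
#'   molecule), `preferred` (per-archetype fragment indices).
#' @export
generate_world <- function(spec = world_spec()) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(spec$seed)
  A <- spec$n_archetypes
  pref <- .preferred_sets(A)
  # function prototypes: disjoint support blocks
  sup <- floor(spec$n_func / A)
  proto <- matrix(0.05, A, spec$n_func)
  for (a in seq_len(A)) proto[a, ((a - 1L) * sup + 1L):(a * sup)] <- 0.9
  # archetype core sequences
  cores <- vapply(seq_len(A), function(a)
    paste(sample(.AA20, spec$seq_length, replace = TRUE), collapse = ""), "")
  # proteins
  pid <- sprintf("P%03d", seq_len(spec$n_proteins))
  arch <- sample(seq_len(A), spec$n_proteins, replace = TRUE)
  scores <- matrix(NA_real_, spec$n_proteins, spec$n_func,
                   dimnames = list(pid, NULL))
  seqs <- character(spec$n_proteins)
  for (i in seq_len(spec$n_proteins)) {
    scores[i, ] <- pmin(pmax(proto[arch[i], ] +
                               stats::rnorm(spec$n_func, 0, spec$noise_sd),
                             0), 1)
    s <- strsplit(cores[arch[i]], "")[[1]]
    mut <- stats::runif(spec$seq_length) < spec$mutation_rate
    s[mut] <- sample(.AA20, sum(mut), replace = TRUE)
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- pid
  # molecules from the fragment grammar
  mid <- sprintf("M%04d", seq_len(spec$n_molecules))
  frag_sets <- vector("list", spec$n_molecules)
  smiles <- character(spec$n_molecules)
  for (j in seq_len(spec$n_molecules)) {
    k <- sample(spec$fragments_per_molecule, 1L)
    fs <- sample(length(.FRAGMENT_LIBRARY), k, replace = TRUE)
    frag_sets[[j]] <- fs
    smiles[j] <- paste(.FRAGMENT_LIBRARY[fs], collapse = "")
  }
  names(frag_sets) <- mid
  graphs <- lapply(seq_len(spec$n_molecules), function(j)
    parse_smiles(smiles[j], mid[j]))
  names(graphs) <- mid
  # ground-truth compatibility
  truth <- matrix(FALSE, spec$n_proteins, spec$n_molecules,
                  dimnames = list(pid, mid))
  for (i in seq_len(spec$n_proteins)) {
    pf <- pref[[arch[i]]]
    truth[i, ] <- vapply(frag_sets, function(fs)
      sum(fs %in% pf) >= length(fs) / 2, TRUE)
  }
  # measured activity records
  rec <- list()
  runif_log <- function(n, rng) exp(stats::runif(n, log(rng[1]), log(rng[2])))
  units <- c("uM", "nM", "mM")
  for (i in seq_len(spec$n_proteins)) {
    ms <- sort(sample(spec$n_molecules, min(spec$n_measured_per_protein,
                                            spec$n_molecules)))
    for (j in ms) {
      side <- truth[i, j]
      if (stats::runif(1) < spec$label_flip_rate) side <- !side
      n_rec <- if (stats::runif(1) < 0.1) 2L else 1L
      um <- runif_log(n_rec, if (side) spec$affinity_active
                             else spec$affinity_inactive)
      u <- sample(units, n_rec, replace = TRUE)
      rec[[length(rec) + 1L]] <- data.frame(
        protein_id = pid[i], mol_id = mid[j],
        metric = sample(.METRICS, n_rec, replace = TRUE),
        value = um / .UNIT_TO_UM[u], unit = u,
        source = "synthetic", stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec)
  rownames(records) <- NULL
  structure(list(spec = spec,
                 proteins = data.frame(protein_id = pid, archetype = arch,
                                       sequence = seqs,
                                       stringsAsFactors = FALSE,
                                       row.names = NULL),
                 func = func_vectors(scores, sequences = seqs),
                 molecules = data.frame(mol_id = mid, smiles = smiles,
                                        stringsAsFactors = FALSE),
                 graphs = graphs, records = records, truth = truth,
                 fragment_sets = frag_sets, preferred = pref),
            class = "synthetic_world")
}

#' @method print synthetic_world
#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world: %d proteins (%d archetypes), %d molecules, %d records>\n",
              nrow(x$proteins), x$spec$n_archetypes, nrow(x$molecules),
              nrow(x$records)))
  invisible(x)
}

#' Zero-shot holdout: remove every record of selected proteins from training
#'
#' All pairs (actives and inactives alike) of the held proteins move to the
#' test side, so training retains zero actives for them; transfer must come
#' from retained same-archetype proteins.
#'
#' @param world A `synthetic_world`.
#' @param held_protein_count Number of proteins to hold out (default 2);
#'   chosen from the archetype with the most proteins so at least one
#'   same-archetype protein remains in training.
#' @param held_proteins Optional explicit protein ids (overrides the count).
#' @return List: `train_records`, `test_records`, `held_proteins`. Holding
#'   out an entire archetype emits a warning (the transfer signal is removed
#'   by construction).
#' @export
zero_shot_holdout <- function(world, held_protein_count = 2L,
                              held_proteins = NULL) {
  if (is.null(held_proteins)) {
    if (held_protein_count == 0L)
      return(list(train_records = world$records,
                  test_records = world$records[0, ],
                  held_proteins = character(0)))
    tab <- table(world$proteins$archetype)
    a <- as.integer(names(tab)[which.max(tab)])
    cand <- world$proteins$protein_id[world$proteins$archetype == a]
    if (length(cand) < held_protein_count)
      stop("not enough same-archetype proteins to hold out")
    held_proteins <- cand[seq_len(held_protein_count)]
  }
  held_arch <- world$proteins$archetype[match(held_proteins,
                                              world$proteins$protein_id)]
  for (a in unique(held_arch)) {
    all_a <- world$proteins$protein_id[world$proteins$archetype == a]
    if (all(all_a %in% held_proteins))
      warning(sprintf("archetype %d held out entirely; no transfer signal remains", a))
  }
  held <- world$records$protein_id %in% held_proteins
  list(train_records = world$records[!held, , drop = FALSE],
       test_records = world$records[held, , drop = FALSE],
       held_proteins = held_proteins)
}

#' Write a synthetic world as the file set the pipeline consumes
#'
#' Emits `compounds.csv`, `proteins.fasta`, `function_scores.csv`,
#' `activity.csv` into a directory.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("compounds.csv", "proteins.fasta",
                            "function_scores.csv", "activity.csv"))
  utils::write.csv(world$molecules, paths[1], row.names = FALSE, quote = FALSE)
  write_protein_fasta(world$func$sequences, paths[2])
  write_function_vectors(world$func, paths[3])
  utils::write.csv(world$records, paths[4], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
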