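# Chemistry core: SMILES -> attributed molecular graph, canonical SMILES,
# Morgan-style circular fingerprints, Tanimoto similarity, Murcko scaffolds.
#
# Scope: the SMILES dialect used in 2D ligand screening -- organic subset
# atoms, bracket atoms with charge/explicit H, branches, ring closures
# (including %nn), aromatic lowercase notation, '.'-separated fragments.
# Stereochemistry markers are parsed and discarded (2D graph model).


smiles_parse_error <- function(msg, mol_id) {
  structure(
    class = c("funscreen_parse_error", "error", "condition"),
    list(message = sprintf("SMILES parse failure for '%s': %s", mol_id, msg),
         call = NULL, mol_id = mol_id)
  )
}

#' Parse a SMILES string into an attributed molecular graph
#'
#' Builds the 2D graph the molecular encoder consumes: one record per heavy
#' atom (element, aromaticity, formal charge, implicit hydrogen count) and one
#' record per undirected bond (order, aromatic/ring/conjugation flags). Every
#' undirected bond is exposed as two directed records for bond-level message
#' passing (see [directed_bonds()]). Hydrogens are implicit; for multi-fragment
#' inputs (salts) only the largest covalent fragment is kept. Stereochemistry
#' markers are ignored.
#'
#' @param smiles A single non-empty SMILES string.
#' @param mol_id Identifier carried through fingerprints and embeddings.
#' @return An object of class `molgraph`: a list with `mol_id`, `smiles`
#'   (canonical form), `atoms` (data.frame: element, aromatic, charge, hcount,
#'   bracket, degree), `bonds` (data.frame: a1, a2, order with 4 = aromatic,
#'   ring, conj), `n_atoms`, `n_directed_bonds`.
#' @details Unparseable input signals a condition of class
#'   `funscreen_parse_error` carrying `mol_id`, so bulk callers can skip and
#'   log while single-compound callers abort.
#' @export
parse_smiles <- function(smiles, mol_id = "mol") {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop(smiles_parse_error("empty or non-string input", mol_id))
  }
  g <- .parse_smiles_raw(smiles, mol_id)
  g <- .keep_largest_fragment(g)
  g <- .finalize_graph(g, mol_id)
  g$smiles <- .write_smiles(g, canonical_atom_ranks(g))
  g
}

# --- tokenizer / raw parse -------------------------------------------------

.parse_smiles_raw <- function(smiles, mol_id) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list()   # each: list(element, aromatic, charge, hcount, bracket)
  bonds <- list()   # each: list(a1, a2, sym)  sym in {"", "-","=","#",":"}
  prev <- NA_integer_
  stack <- integer(0)
  pending <- ""     # pending bond symbol
  rings <- list()   # digit -> list(atom, sym)
  i <- 1L
  add_atom <- function(a) {
    atoms[[length(atoms) + 1L]] <<- a
    idx <- length(atoms)
    if (!is.na(prev)) {
      bonds[[length(bonds) + 1L]] <<- list(a1 = prev, a2 = idx, sym = pending)
    }
    pending <<- ""
    prev <<- idx
    idx
  }
  close_ring <- function(key, sym) {
    if (is.null(rings[[key]])) {
      if (is.na(prev)) stop(smiles_parse_error("ring digit before any atom", mol_id))
      rings[[key]] <<- list(atom = prev, sym = sym)
    } else {
      op <- rings[[key]]
      use <- if (nzchar(sym)) sym else op$sym
      if (op$atom == prev)
        stop(smiles_parse_error("ring closure to self", mol_id))
      bonds[[length(bonds) + 1L]] <<- list(a1 = op$atom, a2 = prev, sym = use)
      rings[[key]] <<- NULL
    }
    pending <<- ""
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop(smiles_parse_error("unclosed bracket atom", mol_id))
      a <- .parse_bracket_atom(paste(chars[(i + 1L):(j - 1L)], collapse = ""),
                               mol_id)
      add_atom(a)
      i <- j + 1L
    } else if (ch %in% c("-", "=", "#", ":")) {
      pending <- ch; i <- i + 1L
    } else if (ch %in% c("/", "\\")) {       # stereo bond -> plain single
      pending <- ""; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) stop(smiles_parse_error("branch before any atom", mol_id))
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop(smiles_parse_error("unmatched ')'", mol_id))
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- ""; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch, pending); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop(smiles_parse_error("truncated %nn ring label", mol_id))
      close_ring(paste0(chars[i + 1L], chars[i + 2L]), pending)
      i <- i + 3L
    } else {
      # organic-subset atom, possibly two characters (Cl, Br)
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        add_atom(list(element = two, aromatic = FALSE, charge = 0L,
                      hcount = NA_integer_, bracket = FALSE))
        i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        add_atom(list(element = ch, aromatic = FALSE, charge = 0L,
                      hcount = NA_integer_, bracket = FALSE))
        i <- i + 1L
      } else if (ch %in% .AROMATIC_OK) {
        add_atom(list(element = toupper(ch), aromatic = TRUE, charge = 0L,
                      hcount = NA_integer_, bracket = FALSE))
        i <- i + 1L
      } else {
        stop(smiles_parse_error(sprintf("unexpected character '%s'", ch), mol_id))
      }
    }
  }
  if (length(stack)) stop(smiles_parse_error("unmatched '('", mol_id))
  if (length(rings)) stop(smiles_parse_error("unclosed ring bond", mol_id))
  if (!length(atoms)) stop(smiles_parse_error("no atoms", mol_id))
  list(atoms = atoms, bonds = bonds, mol_id = mol_id)
}

.parse_bracket_atom <- function(body, mol_id) {
  # [isotope? element chirality? Hcount? charge?]  -- chirality discarded
  m <- regmatches(body, regexec(
    "^([0-9]*)([A-Z][a-z]?|[a-z]{1,2})(@{0,2})(H[0-9]*)?([+-][0-9]*|[+]+|[-]+)?$",
    body))[[1]]
  if (!length(m)) stop(smiles_parse_error(sprintf("bad bracket atom [%s]", body), mol_id))
  elem <- m[3]
  aromatic <- elem %in% .AROMATIC_OK
  if (aromatic) elem <- paste0(toupper(substr(elem, 1, 1)), substring(elem, 2))
  h <- 0L
  if (nzchar(m[5])) {
    h <- if (m[5] == "H") 1L else as.integer(substring(m[5], 2))
  }
  chg <- 0L
  if (nzchar(m[6])) {
    cs <- m[6]
    if (grepl("^[+-][0-9]+$", cs)) {
      chg <- as.integer(substring(cs, 2)) * if (substr(cs, 1, 1) == "+") 1L else -1L
    } else {
      chg <- nchar(cs) * if (substr(cs, 1, 1) == "+") 1L else -1L
    }
  }
  list(element = elem, aromatic = aromatic, charge = chg,
       hcount = h, bracket = TRUE)
}

# --- graph finalization ----------------------------------------------------

.keep_largest_fragment <- function(g) {
  n <- length(g$atoms)
  if (n == 1L || !length(g$bonds)) {
    # possibly disconnected single atoms; component of each atom is itself
    if (!length(g$bonds) && n > 1L) {
      g$atoms <- g$atoms[1L]   # all singletons: keep the first
    }
    return(g)
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (b in g$bonds) {
      r <- min(comp[b$a1], comp[b$a2])
      if (comp[b$a1] != r || comp[b$a2] != r) {
        comp[comp == comp[b$a1] | comp == comp[b$a2]] <- r
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  keep_c <- as.integer(names(sizes)[which.max(sizes)])
  keep <- which(comp == keep_c)
  if (length(keep) == n) return(g)
  remap <- match(seq_len(n), keep)
  g$atoms <- g$atoms[keep]
  g$bonds <- Filter(function(b) !is.na(remap[b$a1]) && !is.na(remap[b$a2]), g$bonds)
  g$bonds <- lapply(g$bonds, function(b) {
    b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]; b
  })
  g
}

# bridges via DFS; non-bridge edges lie on a cycle
.ring_bond_flags <- function(n_atoms, a1, a2) {
  m <- length(a1)
  if (!m) return(logical(0))
  adj <- vector("list", n_atoms)
  for (k in seq_len(m)) {
    adj[[a1[k]]] <- c(adj[[a1[k]]], k)
    adj[[a2[k]]] <- c(adj[[a2[k]]], k)
  }
  disc <- integer(n_atoms); low <- integer(n_atoms)
  bridge <- logical(m); timer <- 0L
  for (root in seq_len(n_atoms)) {
    if (disc[root] != 0L) next
    # iterative DFS: stack of (node, incoming edge, next adj pointer)
    st_node <- root; st_edge <- 0L; st_ptr <- 1L
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(st_node)) {
      top <- length(st_node)
      v <- st_node[top]; pe <- st_edge[top]; p <- st_ptr[top]
      if (p <= length(adj[[v]])) {
        st_ptr[top] <- p + 1L
        e <- adj[[v]][p]
        if (e == pe) next
        w <- if (a1[e] == v) a2[e] else a1[e]
        if (disc[w] == 0L) {
          timer <- timer + 1L; disc[w] <- low[w] <- timer
          st_node <- c(st_node, w); st_edge <- c(st_edge, e); st_ptr <- c(st_ptr, 1L)
        } else {
          low[v] <- min(low[v], disc[w])
        }
      } else {
        st_node <- st_node[-top]; st_edge <- st_edge[-top]; st_ptr <- st_ptr[-top]
        if (length(st_node)) {
          u <- st_node[length(st_node)]
          low[u] <- min(low[u], low[v])
          if (low[v] > disc[u]) bridge[pe] <- TRUE
        }
      }
    }
  }
  !bridge
}

.implicit_h <- function(element, aromatic, charge, order_sum, n_arom_bonds) {
  val <- unname(.DEFAULT_VALENCE[element])
  if (is.na(val)) return(0L)
  val <- if (element %in% c("N", "P", "O", "S")) val + charge
         else val - abs(charge)
  # aromatic atoms: each aromatic bond counts 1 sigma; one extra unit for
  # participation in the aromatic pi system
  used <- order_sum + if (aromatic && n_arom_bonds > 0L) 1L else 0L
  max(0L, as.integer(val - used))
}

.finalize_graph <- function(g, mol_id) {
  n <- length(g$atoms)
  atoms <- data.frame(
    element  = vapply(g$atoms, `[[`, "", "element"),
    aromatic = vapply(g$atoms, `[[`, TRUE, "aromatic"),
    charge   = vapply(g$atoms, `[[`, 0L, "charge"),
    hcount   = vapply(g$atoms, `[[`, NA_integer_, "hcount"),
    bracket  = vapply(g$atoms, `[[`, TRUE, "bracket"),
    stringsAsFactors = FALSE
  )
  if (length(g$bonds)) {
    a1 <- vapply(g$bonds, `[[`, 0L, "a1")
    a2 <- vapply(g$bonds, `[[`, 0L, "a2")
    sym <- vapply(g$bonds, `[[`, "", "sym")
    if (anyDuplicated(paste(pmin(a1, a2), pmax(a1, a2))))
      stop(smiles_parse_error("duplicate bond", mol_id))
    ring <- .ring_bond_flags(n, a1, a2)
    both_arom <- atoms$aromatic[a1] & atoms$aromatic[a2]
    order <- ifelse(sym == "=", 2L, ifelse(sym == "#", 3L, 1L))
    aromatic_bond <- ring & both_arom & (sym %in% c("", ":"))
    order[aromatic_bond] <- 4L
    bonds <- data.frame(a1 = a1, a2 = a2, order = order, ring = ring)
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0),
                        order = integer(0), ring = logical(0))
  }
  out <- list(mol_id = mol_id, smiles = NA_character_,
              atoms = atoms, bonds = bonds)
  out <- .recompute_hydrogens(out)
  # conjugation: aromatic bonds, or bonds whose both endpoints carry a
  # multiple/aromatic bond
  multi <- rep(FALSE, n)
  if (nrow(bonds)) {
    hi <- bonds$order >= 2L
    multi[unique(c(bonds$a1[hi], bonds$a2[hi]))] <- TRUE
    out$bonds$conj <- bonds$order == 4L | (multi[bonds$a1] & multi[bonds$a2])
  } else {
    out$bonds$conj <- logical(0)
  }
  out$n_atoms <- n
  out$n_directed_bonds <- 2L * nrow(bonds)
  class(out) <- "molgraph"
  out
}

# recompute degree + implicit H for non-bracket atoms from current bonds
.recompute_hydrogens <- function(g) {
  n <- nrow(g$atoms)
  deg <- integer(n); osum <- integer(n); narom <- integer(n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]; o <- g$bonds$order[k]
      deg[a1] <- deg[a1] + 1L; deg[a2] <- deg[a2] + 1L
      eff <- if (o == 4L) 1L else o
      osum[a1] <- osum[a1] + eff; osum[a2] <- osum[a2] + eff
      if (o == 4L) { narom[a1] <- narom[a1] + 1L; narom[a2] <- narom[a2] + 1L }
    }
  }
  g$atoms$degree <- deg
  for (i in seq_len(n)) {
    if (!g$atoms$bracket[i] || is.na(g$atoms$hcount[i])) {
      g$atoms$hcount[i] <- .implicit_h(g$atoms$element[i], g$atoms$aromatic[i],
                                       g$atoms$charge[i], osum[i], narom[i])
    }
  }
  g
}

#' @method print molgraph
#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph %s: %d atoms, %d directed bonds, smiles=%s>\n",
              x$mol_id, x$n_atoms, x$n_directed_bonds, x$smiles))
  invisible(x)
}

#' Directed bond records of a molecular graph
#'
#' Each undirected bond appears twice, once per direction; the encoder keeps
#' one hidden state per directed record.
#'
#' @param graph A `molgraph`.
#' @return data.frame with columns `src`, `dst`, `order`, `ring`, `conj`.
#' @export
directed_bonds <- function(graph) {
  b <- graph$bonds
  data.frame(src = c(b$a1, b$a2), dst = c(b$a2, b$a1),
             order = c(b$order, b$order), ring = c(b$ring, b$ring),
             conj = c(b$conj, b$conj))
}

# --- canonical ranking and SMILES writing ----------------------------------

.bond_code <- function(order) order  # 1,2,3,4 already distinct

#' Canonical atom ranks by iterative neighborhood refinement
#'
#' Morgan-style invariant refinement (element, aromaticity, charge, H count,
#' degree; then sorted neighbor rank multisets) with deterministic tie
#' breaking; the basis of the canonical SMILES writer.
#'
#' @param graph A `molgraph`.
#' @return Integer vector of 0-based ranks, one per atom, all distinct.
#' @keywords internal
canonical_atom_ranks <- function(graph) {
  n <- graph$n_atoms
  a <- graph$atoms
  key <- sprintf("%s|%d|%d|%d|%d", a$element, as.integer(a$aromatic),
                 a$charge, a$hcount, a$degree)
  rank <- match(key, sort(unique(key), method = "radix")) - 1L
  nb <- vector("list", n)
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      a1 <- graph$bonds$a1[k]; a2 <- graph$bonds$a2[k]
      o <- .bond_code(graph$bonds$order[k])
      nb[[a1]] <- rbind(nb[[a1]], c(a2, o))
      nb[[a2]] <- rbind(nb[[a2]], c(a1, o))
    }
  }
  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(n), function(i) {
        if (is.null(nb[[i]])) return(sprintf("%08d|", rank[i] + 1L))
        nk <- sprintf("%d:%08d", nb[[i]][, 2], rank[nb[[i]][, 1]])
        sprintf("%08d|%s", rank[i] + 1L, paste(sort(nk), collapse = ","))
      }, "")
      new_rank <- match(key, sort(unique(key), method = "radix")) - 1L
      if (length(unique(new_rank)) == length(unique(rank))) return(new_rank)
      rank <- new_rank
    }
  }
  rank <- refine(rank)
  # break residual ties (symmetric atoms) deterministically
  while (anyDuplicated(rank)) {
    dup_ranks <- sort(unique(rank[duplicated(rank)]))
    r <- dup_ranks[1]
    i <- which(rank == r)[1]
    rank[rank > r | (rank == r & seq_len(n) != i)] <-
      rank[rank > r | (rank == r & seq_len(n) != i)] + 1L
    rank <- refine(rank)
  }
  rank
}

#' Canonical SMILES of a molecular graph
#'
#' Deterministic: isomorphic graphs (any atom input order) yield the same
#' string, so parse -> canonicalize -> parse is idempotent.
#'
#' @param graph A `molgraph`.
#' @return A SMILES string.
#' @export
canonical_smiles <- function(graph) {
  .write_smiles(graph, canonical_atom_ranks(graph))
}

#' Random SMILES respelling of a molecular graph
#'
#' Rewrites the molecule starting from a random atom with shuffled branch
#' order; used to test representation invariance of fingerprints, scaffolds
#' and embeddings.
#'
#' @param graph A `molgraph`.
#' @param seed Optional integer seed.
#' @return A SMILES string parsing to an isomorphic graph.
#' @export
random_smiles <- function(graph, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  .write_smiles(graph, sample.int(graph$n_atoms) - 1L)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# write SMILES traversing atoms in increasing `rank` order
.write_smiles <- function(g, rank) {
  n <- g$n_atoms
  a <- g$atoms
  nb <- vector("list", n)   # rows: neighbor, order, bond index
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      a1 <- g$bonds$a1[k]; a2 <- g$bonds$a2[k]
      nb[[a1]] <- rbind(nb[[a1]], c(a2, g$bonds$order[k], k))
      nb[[a2]] <- rbind(nb[[a2]], c(a1, g$bonds$order[k], k))
    }
  }
  # spanning DFS from min-rank atom; ring closures = non-tree edges
  visited <- rep(FALSE, n)
  parent_edge <- rep(NA_integer_, n)
  children <- vector("list", n)
  ring_open <- vector("list", n)   # at first endpoint: list of c(bond, other)
  is_tree <- rep(FALSE, max(1L, nrow(g$bonds)))
  root <- which.min(rank)
  stack <- root; visited[root] <- TRUE
  order_visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_visit <- c(order_visit, v)
    if (is.null(nb[[v]])) next
    nbr <- nb[[v]][order(rank[nb[[v]][, 1]]), , drop = FALSE]
    togo <- integer(0)
    for (r in seq_len(nrow(nbr))) {
      w <- nbr[r, 1]; e <- nbr[r, 3]
      if (!visited[w]) {
        visited[w] <- TRUE
        parent_edge[w] <- e
        is_tree[e] <- TRUE
        children[[v]] <- c(children[[v]], w)
        togo <- c(togo, w)
      }
    }
    if (length(togo)) stack <- c(stack, rev(togo))
  }
  # ring-closure digits: assign in visit order at the first-visited endpoint
  pos <- match(seq_len(n), order_visit)
  digit_of_bond <- rep(NA_integer_, max(1L, nrow(g$bonds)))
  free <- 1:99; used_at <- list()
  ring_at <- vector("list", n)  # per atom: rows c(digit, order, is_open)
  if (nrow(g$bonds)) {
    nontree <- which(!is_tree[seq_len(nrow(g$bonds))])
    if (length(nontree)) {
      ev1 <- g$bonds$a1[nontree]; ev2 <- g$bonds$a2[nontree]
      first <- ifelse(pos[ev1] <= pos[ev2], ev1, ev2)
      second <- ifelse(pos[ev1] <= pos[ev2], ev2, ev1)
      ord <- order(pos[first], pos[second])
      # digits: smallest free digit, reusable after closing
      events <- data.frame(bond = nontree[ord])
      open_atom <- first[ord]; close_atom <- second[ord]
      # process all open/close events in atom-visit order
      evs <- rbind(
        data.frame(atom = open_atom, bond = events$bond, open = TRUE),
        data.frame(atom = close_atom, bond = events$bond, open = FALSE)
      )
      evs <- evs[order(pos[evs$atom], !evs$open, evs$bond), ]
      for (r in seq_len(nrow(evs))) {
        b <- evs$bond[r]
        if (evs$open[r]) {
          d <- free[1]; free <- free[-1]
          digit_of_bond[b] <- d
        } else {
          d <- digit_of_bond[b]
          free <- sort(c(free, d))
        }
        ring_at[[evs$atom[r]]] <- rbind(
          ring_at[[evs$atom[r]]],
          c(d, g$bonds$order[b], as.integer(evs$open[r]))
        )
      }
    }
  }
  bond_str <- function(o, i1, i2) {
    if (o == 2L) return("=")
    if (o == 3L) return("#")
    if (o == 1L && a$aromatic[i1] && a$aromatic[i2]) return("-")
    ""
  }
  atom_str <- function(i) {
    el <- a$element[i]
    sym <- if (a$aromatic[i]) tolower(el) else el
    # implicit-H the parser would infer for an unbracketed atom
    inferred <- {
      nbr <- nb[[i]]
      osum <- 0L; narom <- 0L
      if (!is.null(nbr)) {
        for (r in seq_len(nrow(nbr))) {
          o <- nbr[r, 2]
          osum <- osum + if (o == 4L) 1L else o
          if (o == 4L) narom <- narom + 1L
        }
      }
      .implicit_h(el, a$aromatic[i], a$charge[i], osum, narom)
    }
    need_bracket <- a$charge[i] != 0L || !(el %in% .ORGANIC_SUBSET) ||
      a$hcount[i] != inferred
    if (!need_bracket) return(sym)
    h <- a$hcount[i]
    hs <- if (h == 0L) "" else if (h == 1L) "H" else sprintf("H%d", h)
    ch <- a$charge[i]
    cs <- if (ch == 0L) "" else if (ch == 1L) "+" else if (ch == -1L) "-"
          else sprintf("%+d", ch)
    sprintf("[%s%s%s]", sym, hs, cs)
  }
  emit <- function(v) {
    s <- atom_str(v)
    if (!is.null(ring_at[[v]])) {
      ra <- ring_at[[v]][order(ring_at[[v]][, 1]), , drop = FALSE]
      for (r in seq_len(nrow(ra))) {
        d <- ra[r, 1]; o <- ra[r, 2]
        bs <- if (ra[r, 3] == 1L) {
          # opening: emit order marker if non-default
          if (o == 2L) "=" else if (o == 3L) "#" else ""
        } else ""
        ds <- if (d < 10) as.character(d) else sprintf("%%%02d", d)
        s <- paste0(s, bs, ds)
      }
    }
    kids <- children[[v]]
    if (length(kids)) {
      parts <- vapply(kids, function(w) {
        e <- parent_edge[w]
        paste0(bond_str(g$bonds$order[e], v, w), emit(w))
      }, "")
      if (length(parts) > 1L) {
        s <- paste0(s, paste0("(", parts[-length(parts)], ")", collapse = ""),
                    parts[length(parts)])
      } else {
        s <- paste0(s, parts)
      }
    }
    s
  }
  emit(root)
}

# --- fingerprints ----------------------------------------------------------

.HASH_MOD <- 1048573  # prime < 2^20; products stay exact in doubles

.hash_ints <- function(x) {
  h <- 7
  for (v in x) h <- (h * 31 + (v %% .HASH_MOD)) %% .HASH_MOD
  h
}

#' Morgan-style circular fingerprint
#'
#' Iteratively hashed atom environments up to `radius` bonds, folded into a
#' fixed-length bit vector (ECFP-like; radius 2 corresponds to ECFP4).
#' Deterministic and invariant to atom input ordering.
#'
#' @param graph A `molgraph`.
#' @param radius Environment radius in bonds (>= 0). Default 2.
#' @param n_bits Folded length (>= 64). Default 2048.
#' @return Object of class `fingerprint`: list with logical `bits`, `radius`,
#'   `n_bits`, `mol_id`.
#' @export
morgan_fingerprint <- function(graph, radius = 2L, n_bits = 2048L) {
  stopifnot(radius >= 0L, n_bits >= 64L)
  n <- graph$n_atoms
  a <- graph$atoms
  elem <- match(a$element, .ELEMENT_VOCAB, nomatch = length(.ELEMENT_VOCAB) + 1L)
  inv <- vapply(seq_len(n), function(i) {
    .hash_ints(c(elem[i], a$degree[i], a$hcount[i], a$charge[i] + 16L,
                 as.integer(a$aromatic[i])))
  }, 0)
  nb <- vector("list", n)
  if (nrow(graph$bonds)) {
    for (k in seq_len(nrow(graph$bonds))) {
      a1 <- graph$bonds$a1[k]; a2 <- graph$bonds$a2[k]; o <- graph$bonds$order[k]
      nb[[a1]] <- rbind(nb[[a1]], c(a2, o))
      nb[[a2]] <- rbind(nb[[a2]], c(a1, o))
    }
  }
  envs <- unique(inv)
  r <- 0L
  while (r < radius) {
    inv_new <- vapply(seq_len(n), function(i) {
      if (is.null(nb[[i]])) return(.hash_ints(c(inv[i], 0)))
      pairs <- cbind(nb[[i]][, 2], inv[nb[[i]][, 1]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      .hash_ints(c(inv[i], as.vector(t(pairs))))
    }, 0)
    inv <- inv_new
    envs <- unique(c(envs, inv))
    r <- r + 1L
  }
  bits <- rep(FALSE, n_bits)
  bits[(envs %% n_bits) + 1L] <- TRUE
  structure(list(bits = bits, radius = as.integer(radius),
                 n_bits = as.integer(n_bits), mol_id = graph$mol_id),
            class = "fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection over union of set bits. By convention two all-zero
#' fingerprints have similarity 1 and an all-zero vs a non-zero fingerprint 0,
#' so degenerate tiny molecules compare sanely.
#'
#' @param a,b `fingerprint` objects of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  ba <- if (inherits(a, "fingerprint")) a$bits else as.logical(a)
  bb <- if (inherits(b, "fingerprint")) b$bits else as.logical(b)
  if (length(ba) != length(bb)) stop("fingerprint length mismatch")
  na <- sum(ba); nbb <- sum(bb)
  if (na == 0L && nbb == 0L) return(1.0)
  u <- sum(ba | bb)
  if (u == 0L) return(0.0)
  sum(ba & bb) / u
}

# --- Murcko scaffold -------------------------------------------------------

#' Bemis-Murcko scaffold of a molecule
#'
#' Ring systems plus connecting linkers: terminal (degree-1) atoms are pruned
#' iteratively until none remain. Acyclic molecules have the empty scaffold.
#'
#' @param graph A `molgraph`.
#' @return List of class `scaffold` with `scaffold_smiles` (canonical; `""`
#'   for acyclic input).
#' @export
murcko_scaffold <- function(graph) {
  keep <- rep(TRUE, graph$n_atoms)
  bonds <- graph$bonds
  repeat {
    deg <- integer(graph$n_atoms)
    if (nrow(bonds)) {
      act <- keep[bonds$a1] & keep[bonds$a2]
      bb <- bonds[act, , drop = FALSE]
      for (k in seq_len(nrow(bb))) {
        deg[bb$a1[k]] <- deg[bb$a1[k]] + 1L
        deg[bb$a2[k]] <- deg[bb$a2[k]] + 1L
      }
    }
    leaf <- keep & deg <= 1L
    if (!any(leaf)) break
    keep[leaf] <- FALSE
    if (!any(keep)) break
  }
  if (!any(keep)) {
    return(structure(list(scaffold_smiles = ""), class = "scaffold"))
  }
  idx <- which(keep)
  remap <- match(seq_len(graph$n_atoms), idx)
  sub <- list(mol_id = paste0(graph$mol_id, "_scaffold"), smiles = NA_character_,
              atoms = graph$atoms[idx, , drop = FALSE],
              bonds = {
                b <- bonds[keep[bonds$a1] & keep[bonds$a2], , drop = FALSE]
                b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]; b
              })
  rownames(sub$atoms) <- NULL
  # side chains gone: recompute degree and implicit H from the pruned graph
  sub$atoms$bracket <- sub$atoms$bracket & sub$atoms$charge != 0L
  sub$atoms$hcount <- NA_integer_
  sub <- .recompute_hydrogens(sub)
  sub$n_atoms <- nrow(sub$atoms)
  sub$n_directed_bonds <- 2L * nrow(sub$bonds)
  class(sub) <- "molgraph"
  structure(list(scaffold_smiles = canonical_smiles(sub)), class = "scaffold")
}

# --- compound tables -------------------------------------------------------

#' Read a compound table (CSV/TSV with mol_id and smiles columns)
#'
#' Lines starting with `#` are comments. Unparseable SMILES are skipped with
#' a warning naming the molecule (bulk-curation behavior).
#'
#' @param path File path; delimiter inferred from the extension (`.tsv` vs
#'   comma).
#' @param parse If TRUE (default) parse each SMILES into a `molgraph`.
#' @return If `parse`, a named list of `molgraph` objects; otherwise the raw
#'   data.frame.
#' @export
read_compound_table <- function(path, parse = TRUE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "\"")
  if (!all(c("mol_id", "smiles") %in% names(df)))
    stop("compound table must have columns mol_id, smiles: ", path)
  if (!parse) return(df)
  out <- list()
  for (i in seq_len(nrow(df))) {
    g <- tryCatch(parse_smiles(df$smiles[i], df$mol_id[i]),
                  funscreen_parse_error = function(e) {
                    warning(conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(g)) out[[df$mol_id[i]]] <- g
  }
  out
}
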