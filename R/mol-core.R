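# Molecular graph data model.
#
# A molgraph is a plain list with copy-on-modify semantics:
#   n        number of atoms
#   atom     list of parallel vectors: element, charge, nH (total hydrogen
#            count), aromatic, chiral (0 none / 1 '@' / 2 '@@' relative to
#            the reference neighbor order), map (atom-map number, 0 = none),
#            pinned (hydrogen count fixed by an explicit atom edit)
#   bond     list of parallel vectors: i, j (atom indices, i < j), order
#            (kekulized 1/2/3), aromatic, stereo (0 none / 1 cis / 2 trans
#            relative to the lowest-index substituent on each end)
#
# Chirality convention: the reference neighbor order of an atom is its
# neighbor indices in ascending order, preceded by a phantom hydrogen
# (label 0) when the atom has three heavy neighbors and at least one H.
# Tag 1 means the last three reference neighbors appear anticlockwise when
# viewed from the first; tag 2 means clockwise.

new_molgraph <- function(atom = NULL, bond = NULL) {
  if (is.null(atom)) {
    atom <- list(element = character(), charge = integer(), nH = integer(),
                 aromatic = logical(), chiral = integer(), map = integer(),
                 pinned = logical(), chiral_pending = integer())
  }
  if (is.null(bond)) {
    bond <- list(i = integer(), j = integer(), order = integer(),
                 aromatic = logical(), stereo = integer())
  }
  structure(list(n = length(atom$element), atom = atom, bond = bond),
            class = "molgraph")
}

#' Number of atoms and bonds in a molecular graph
#' @param mol A `molgraph` object.
#' @return Integer count.
#' @export
mol_natoms <- function(mol) mol$n

#' @rdname mol_natoms
#' @export
mol_nbonds <- function(mol) length(mol$bond$i)

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph: %d atoms, %d bonds> %s\n",
              mol_natoms(x), mol_nbonds(x),
              tryCatch(mol_to_smiles(x), error = function(e) "<unwritable>")))
  invisible(x)
}

# Adjacency list: integer vector of neighbor atom indices per atom.
mol_adjacency <- function(mol) {
  adj <- vector("list", mol$n)
  for (b in seq_along(mol$bond$i)) {
    i <- mol$bond$i[b]; j <- mol$bond$j[b]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) if (is.null(v)) integer() else v)
}

# Index of the bond joining atoms a and b, or 0 if absent.
bond_index <- function(mol, a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  hit <- which(mol$bond$i == lo & mol$bond$j == hi)
  if (length(hit) == 0L) 0L else hit[1L]
}

atom_by_map <- function(mol, map) {
  hit <- which(mol$atom$map == map)
  if (length(hit) == 0L) 0L else hit[1L]
}

# Sum of kekulized bond orders incident to each atom.
atom_bond_order_sums <- function(mol) {
  s <- numeric(mol$n)
  for (b in seq_along(mol$bond$i)) {
    s[mol$bond$i[b]] <- s[mol$bond$i[b]] + mol$bond$order[b]
    s[mol$bond$j[b]] <- s[mol$bond$j[b]] + mol$bond$order[b]
  }
  s
}

## ---- permutation parity helpers -------------------------------------------

# Parity (0 even / 1 odd) of the permutation taking ordering `from` to
# ordering `to`; both must contain the same labels.
ordering_parity <- function(from, to) {
  p <- match(from, to)
  inv <- 0L
  k <- length(p)
  if (k > 1L) {
    for (a in 1:(k - 1L)) for (b in (a + 1L):k) if (p[a] > p[b]) inv <- inv + 1L
  }
  inv %% 2L
}

flip_tag <- function(tag) ifelse(tag == 0L, 0L, 3L - tag)

# Reference neighbor ordering used to anchor chiral tags.
chiral_reference <- function(mol, a, adj = NULL) {
  nb <- if (is.null(adj)) {
    c(mol$bond$j[mol$bond$i == a], mol$bond$i[mol$bond$j == a])
  } else adj[[a]]
  nb <- sort(nb)
  if (length(nb) == 3L && mol$atom$nH[a] >= 1L) c(0L, nb) else nb
}

## ---- structural editing primitives ----------------------------------------

mol_add_atom <- function(mol, element, charge = 0L, nH = 0L, aromatic = FALSE,
                         chiral = 0L, map = 0L, pinned = FALSE) {
  mol$atom$element <- c(mol$atom$element, element)
  mol$atom$charge <- c(mol$atom$charge, as.integer(charge))
  mol$atom$nH <- c(mol$atom$nH, as.integer(nH))
  mol$atom$aromatic <- c(mol$atom$aromatic, aromatic)
  mol$atom$chiral <- c(mol$atom$chiral, as.integer(chiral))
  mol$atom$map <- c(mol$atom$map, as.integer(map))
  mol$atom$pinned <- c(mol$atom$pinned, pinned)
  mol$atom$chiral_pending <- c(mol$atom$chiral_pending, 0L)
  mol$n <- mol$n + 1L
  mol
}

mol_add_bond <- function(mol, a, b, order = 1L, aromatic = FALSE, stereo = 0L) {
  if (a == b) stop("self-bond is not allowed")
  if (bond_index(mol, a, b) != 0L) stop("bond already exists")
  mol$bond$i <- c(mol$bond$i, min(a, b))
  mol$bond$j <- c(mol$bond$j, max(a, b))
  mol$bond$order <- c(mol$bond$order, as.integer(order))
  mol$bond$aromatic <- c(mol$bond$aromatic, aromatic)
  mol$bond$stereo <- c(mol$bond$stereo, as.integer(stereo))
  mol
}

mol_drop_bond <- function(mol, b) {
  keep <- setdiff(seq_along(mol$bond$i), b)
  mol$bond <- lapply(mol$bond, function(v) v[keep])
  mol
}

#' Relabel the atoms of a molecular graph
#'
#' @param mol A `molgraph`.
#' @param perm Integer permutation; `perm[old_index] = new_index`. Chiral
#'   tags and double-bond stereo flags are re-anchored to the new
#'   reference neighbors so the described 3D configuration is unchanged.
#' @return The relabelled `molgraph`.
#' @export
mol_permute <- function(mol, perm) {
  stopifnot(length(perm) == mol$n, all(sort(perm) == seq_len(mol$n)))
  adj <- mol_adjacency(mol)
  new_chiral <- mol$atom$chiral
  for (a in seq_len(mol$n)) {
    if (mol$atom$chiral[a] == 0L) next
    old_ref <- chiral_reference(mol, a, adj)
    if (length(old_ref) != 4L) next
    mapped <- ifelse(old_ref == 0L, 0L, perm[pmax(old_ref, 1L)])
    new_ref <- if (0L %in% mapped) c(0L, sort(mapped[mapped != 0L])) else sort(mapped)
    if (ordering_parity(mapped, new_ref) == 1L)
      new_chiral[a] <- flip_tag(mol$atom$chiral[a])
  }
  new_stereo <- mol$bond$stereo
  for (b in seq_along(mol$bond$i)) {
    if (mol$bond$stereo[b] == 0L) next
    i <- mol$bond$i[b]; j <- mol$bond$j[b]
    flips <- 0L
    for (end in c(i, j)) {
      other <- if (end == i) j else i
      subs <- setdiff(adj[[end]], other)
      if (length(subs) == 0L) next
      old_ref <- min(subs)
      new_ref_old_label <- subs[which.min(perm[subs])]
      if (new_ref_old_label != old_ref) flips <- flips + 1L
    }
    if (flips %% 2L == 1L) new_stereo[b] <- flip_tag(new_stereo[b])
  }
  inv <- order(perm)   # inv[new_index] = old_index
  atom <- lapply(mol$atom, function(v) v[inv])
  atom$chiral <- new_chiral[inv]
  bi <- perm[mol$bond$i]; bj <- perm[mol$bond$j]
  bond <- list(i = pmin(bi, bj), j = pmax(bi, bj), order = mol$bond$order,
               aromatic = mol$bond$aromatic, stereo = new_stereo)
  out <- new_molgraph(atom, bond)
  out
}

# Delete the given atoms (and their bonds), compacting indices.
mol_delete_atoms <- function(mol, drop) {
  keep <- setdiff(seq_len(mol$n), drop)
  remap <- integer(mol$n)
  remap[keep] <- seq_along(keep)
  bkeep <- which(!(mol$bond$i %in% drop) & !(mol$bond$j %in% drop))
  atom <- lapply(mol$atom, function(v) v[keep])
  bond <- lapply(mol$bond, function(v) v[bkeep])
  bond$i <- remap[bond$i]; bond$j <- remap[bond$j]
  sw <- bond$i > bond$j
  if (any(sw)) { tmp <- bond$i[sw]; bond$i[sw] <- bond$j[sw]; bond$j[sw] <- tmp }
  new_molgraph(atom, bond)
}

# Connected components; returns integer component id per atom.
mol_components <- function(mol) {
  comp <- integer(mol$n)
  adj <- mol_adjacency(mol)
  cur <- 0L
  for (s in seq_len(mol$n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      a <- queue[1L]; queue <- queue[-1L]
      for (nb in adj[[a]]) if (comp[nb] == 0L) { comp[nb] <- cur; queue <- c(queue, nb) }
    }
  }
  comp
}

## ---- rings -----------------------------------------------------------------

# Logical vector: is each bond part of some cycle?
ring_bond_flags <- function(mol) {
  m <- length(mol$bond$i)
  flags <- logical(m)
  if (m == 0L) return(flags)
  adj <- mol_adjacency(mol)
  for (b in seq_len(m)) {
    i <- mol$bond$i[b]; j <- mol$bond$j[b]
    # BFS from i to j avoiding bond b
    seen <- logical(mol$n); seen[i] <- TRUE
    queue <- i
    found <- FALSE
    while (length(queue) > 0L && !found) {
      a <- queue[1L]; queue <- queue[-1L]
      for (nb in adj[[a]]) {
        if (min(a, nb) == mol$bond$i[b] && max(a, nb) == mol$bond$j[b]) next
        if (!seen[nb]) {
          if (nb == j) { found <- TRUE; break }
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    flags[b] <- found
  }
  flags
}

# All simple cycles of length 5 or 6, as lists of atom index vectors.
small_rings <- function(mol, sizes = c(5L, 6L)) {
  adj <- mol_adjacency(mol)
  found <- list()
  seen_keys <- character()
  maxlen <- max(sizes)
  for (s in seq_len(mol$n)) {
    if (length(adj[[s]]) < 2L) next
    stack <- list(list(path = s))
    while (length(stack) > 0L) {
      fr <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      path <- fr$path
      last <- path[length(path)]
      for (nb in adj[[last]]) {
        if (nb == s && length(path) %in% sizes) {
          key <- paste(sort(path), collapse = ",")
          if (!(key %in% seen_keys)) {
            seen_keys <- c(seen_keys, key)
            found[[length(found) + 1L]] <- path
          }
        } else if (!(nb %in% path) && nb > s && length(path) < maxlen) {
          stack[[length(stack) + 1L]] <- list(path = c(path, nb))
        }
      }
    }
  }
  found
}

## ---- aromaticity ------------------------------------------------------------

# Number of pi electrons an atom contributes to a candidate aromatic ring,
# or NA if the atom disqualifies the ring.  A double bond leaving the ring
# toward another ring atom (fused aromatics such as naphthalene) still
# counts as sp2 participation; an exocyclic double to a chain atom
# (quinones, pyridones) disqualifies the ring.
.ring_pi_contribution <- function(mol, a, ring, adj, in_any_ring) {
  el <- mol$atom$element[a]
  if (!(el %in% .AROMATIC_ELEMENTS)) return(NA_integer_)
  ch <- mol$atom$charge[a]
  nb <- adj[[a]]
  doubles_in <- 0L; doubles_exo <- 0L
  for (x in nb) {
    b <- bond_index(mol, a, x)
    if (mol$bond$order[b] >= 3L) return(NA_integer_)
    if (mol$bond$order[b] == 2L) {
      if (x %in% ring) doubles_in <- doubles_in + 1L
      else if (in_any_ring[x]) doubles_in <- doubles_in + 1L
      else doubles_exo <- doubles_exo + 1L
    }
  }
  if (doubles_in == 1L && doubles_exo == 0L) return(1L)
  if (doubles_in > 1L || doubles_exo > 0L) return(NA_integer_)
  # no double bond on this atom: lone-pair donors
  if (el == "C") {
    if (ch == -1L) return(2L)
    if (ch == 1L) return(0L)
    return(NA_integer_)
  }
  if (el %in% c("N", "P", "As")) {
    if (ch == 0L) return(2L)
    return(NA_integer_)
  }
  if (el %in% c("O", "S", "Se") && ch == 0L) return(2L)
  NA_integer_
}

# Re-derive aromatic flags from the kekulized structure.  Only isolated
# 5- and 6-membered Hueckel rings are recognized; this matches the common
# "default" aromaticity model closely enough for reaction data.
perceive_aromaticity <- function(mol) {
  mol$atom$aromatic <- rep(FALSE, mol$n)
  mol$bond$aromatic <- rep(FALSE, length(mol$bond$i))
  if (mol$n < 5L) return(mol)
  adj <- mol_adjacency(mol)
  ringb <- ring_bond_flags(mol)
  in_any_ring <- logical(mol$n)
  for (b in seq_along(mol$bond$i)) if (ringb[b]) {
    in_any_ring[mol$bond$i[b]] <- TRUE; in_any_ring[mol$bond$j[b]] <- TRUE
  }
  for (ring in small_rings(mol)) {
    pis <- vapply(ring, function(a) .ring_pi_contribution(mol, a, ring, adj, in_any_ring), integer(1))
    if (anyNA(pis)) next
    if (sum(pis) %% 4L != 2L) next
    mol$atom$aromatic[ring] <- TRUE
    k <- length(ring)
    for (t in seq_len(k)) {
      b <- bond_index(mol, ring[t], ring[t %% k + 1L])
      mol$bond$aromatic[b] <- TRUE
    }
  }
  mol
}

# Given aromatic flags from parsing (orders of aromatic bonds provisionally
# 1), assign alternating double bonds.  Errors if no Kekule structure exists.
kekulize <- function(mol) {
  arom_atoms <- which(mol$atom$aromatic)
  if (length(arom_atoms) == 0L) return(mol)
  adj <- mol_adjacency(mol)
  needs <- logical(mol$n)
  for (a in arom_atoms) {
    el <- mol$atom$element[a]
    ch <- mol$atom$charge[a]
    nh <- mol$atom$nH[a]
    if (is.na(nh)) nh <- 0L
    deg <- length(adj[[a]])
    has_exo_double <- any(vapply(adj[[a]], function(x) {
      b <- bond_index(mol, a, x)
      !mol$bond$aromatic[b] && mol$bond$order[b] >= 2L
    }, logical(1)))
    needs[a] <- switch(el,
      C = ch == 0L && !has_exo_double,
      N = , P = , As = if (ch == 1L) (deg + nh) <= 3L else (ch == 0L && nh == 0L && deg == 2L),
      O = , S = , Se = FALSE,
      B = FALSE,
      FALSE)
  }
  # perfect matching on needy atoms over aromatic bonds
  needy <- which(needs)
  if (length(needy) %% 2L != 0L) stop("kekulization failed: odd pi count")
  matched <- integer(0)   # bond indices set to double
  used <- logical(mol$n)
  try_match <- function(used, matched) {
    rem <- needy[!used[needy]]
    if (length(rem) == 0L) return(matched)
    a <- rem[1L]
    for (x in adj[[a]]) {
      if (!needs[x] || used[x]) next
      b <- bond_index(mol, a, x)
      if (!mol$bond$aromatic[b]) next
      used2 <- used; used2[a] <- TRUE; used2[x] <- TRUE
      res <- try_match(used2, c(matched, b))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  res <- try_match(used, matched)
  if (is.null(res)) stop("kekulization failed: no alternating bond assignment")
  mol$bond$order[mol$bond$aromatic] <- 1L
  mol$bond$order[res] <- 2L
  mol
}

## ---- sanitization -----------------------------------------------------------

#' Validate a molecular graph under standard valence rules
#'
#' Checks that no atom exceeds its maximum allowed valence (kekulized bond
#' orders plus hydrogens), that nonzero atom-map numbers are unique, and
#' re-perceives aromaticity from the kekulized structure.
#'
#' @param mol A `molgraph`.
#' @param strict If `TRUE`, undervalent atoms (open valences) are also
#'   rejected; edit intermediates are validated with `strict = FALSE`.
#' @return The sanitized `molgraph` (aromaticity re-perceived).
#' @export
mol_sanitize <- function(mol, strict = FALSE) {
  maps <- mol$atom$map[mol$atom$map > 0L]
  if (anyDuplicated(maps)) stop("chemistry error: duplicate atom-map numbers")
  sums <- atom_bond_order_sums(mol)
  for (a in seq_len(mol$n)) {
    el <- mol$atom$element[a]
    if (el == "*") next
    av <- allowed_valences(el, mol$atom$charge[a])
    if (length(av) == 1L && is.na(av)) next
    tot <- sums[a] + mol$atom$nH[a]
    if (tot > max(av)) {
      stop(sprintf("chemistry error: valence %d on atom %d (%s) exceeds maximum %d",
                   as.integer(tot), a, el, max(av)))
    }
    if (strict && !(tot %in% av)) {
      stop(sprintf("chemistry error: valence %d on atom %d (%s) is not an allowed state",
                   as.integer(tot), a, el))
    }
  }
  perceive_aromaticity(mol)
}
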