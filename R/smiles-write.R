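# Canonical SMILES writer.
#
# Atoms are ranked by iterative neighborhood refinement of structural
# invariants (element, aromaticity, charge, hydrogen count, degree, ring
# membership), with deterministic tie-breaking; the string is emitted by a
# depth-first traversal that visits neighbors in rank order.  Aromatic
# systems are written in lowercase aromatic form, so the output does not
# depend on which Kekule assignment the graph happens to carry.

# Dense canonical ranks (1..n), permutation-stable for symmetric inputs.
canon_ranks <- function(mol) {
  n <- mol$n
  if (n == 0L) return(integer())
  adj <- mol_adjacency(mol)
  ringb <- ring_bond_flags(mol)
  in_ring <- logical(n)
  for (b in seq_along(mol$bond$i)) if (ringb[b]) {
    in_ring[mol$bond$i[b]] <- TRUE; in_ring[mol$bond$j[b]] <- TRUE
  }
  bcls <- function(a, x) {
    b <- bond_index(mol, a, x)
    if (mol$bond$aromatic[b]) 4L else mol$bond$order[b]
  }
  inv <- vapply(seq_len(n), function(a) {
    paste(mol$atom$element[a], mol$atom$aromatic[a], mol$atom$charge[a],
          mol$atom$nH[a], length(adj[[a]]), in_ring[a], sep = "|")
  }, character(1))
  ranks <- match(inv, sort(unique(inv)))
  refine <- function(ranks) {
    repeat {
      keys <- vapply(seq_len(n), function(a) {
        nb <- adj[[a]]
        nbkey <- if (length(nb) == 0L) "" else
          paste(sort(sprintf("%06d:%d", ranks[nb], vapply(nb, function(x) bcls(a, x), integer(1)))),
                collapse = ",")
        sprintf("%06d|%s", ranks[a], nbkey)
      }, character(1))
      new <- match(keys, sort(unique(keys)))
      if (length(unique(new)) == length(unique(ranks))) return(new)
      ranks <- new
    }
  }
  ranks <- refine(ranks)
  while (length(unique(ranks)) < n) {
    # split the lowest tied class at its first member
    tab <- table(ranks)
    tied <- as.integer(names(tab)[tab > 1L])
    cls <- min(tied)
    a <- which(ranks == cls)[1L]
    ranks <- ranks * 2L
    ranks[a] <- ranks[a] - 1L
    ranks <- match(ranks, sort(unique(ranks)))
    ranks <- refine(ranks)
  }
  ranks
}

.charge_token <- function(ch) {
  if (ch == 0L) ""
  else if (ch == 1L) "+"
  else if (ch == -1L) "-"
  else if (ch > 1L) paste0("+", ch)
  else paste0("-", abs(ch))
}

#' Write a molecular graph as SMILES
#'
#' @param mol A `molgraph`.
#' @param canonical Use canonical atom ranking (default TRUE).  With
#'   `FALSE` the input atom order is kept.
#' @param keep_stereo Retain tetrahedral chirality and double-bond
#'   cis/trans marks (default TRUE).
#' @param strip_maps Drop atom-map numbers from the output (default FALSE).
#' @return A SMILES string; multi-fragment graphs are joined with `"."`
#'   (fragments sorted lexicographically when `canonical`).
#' @examples
#' mol_to_smiles(mol_from_smiles("OC"))   # "CO"
#' @export
mol_to_smiles <- function(mol, canonical = TRUE, keep_stereo = TRUE,
                          strip_maps = FALSE) {
  .smiles_emit(mol, canonical, keep_stereo, strip_maps)$smiles
}

#' Canonical atom order of a molecular graph
#'
#' Indices of the atoms in the order they appear in the canonical SMILES
#' output; used to renumber atom maps canonically.
#'
#' @param mol A `molgraph`.
#' @return Integer vector of atom indices.
#' @export
canonical_atom_order <- function(mol) {
  .smiles_emit(mol, canonical = TRUE, keep_stereo = TRUE, strip_maps = FALSE)$order
}

.smiles_emit <- function(mol, canonical, keep_stereo, strip_maps) {
  if (!keep_stereo) {
    mol$atom$chiral <- rep(0L, mol$n)
    mol$bond$stereo <- rep(0L, length(mol$bond$i))
  }
  n <- mol$n
  if (n == 0L) return(list(smiles = "", order = integer()))
  adj <- mol_adjacency(mol)
  ranks <- if (canonical) canon_ranks(mol) else seq_len(n)
  sums <- atom_bond_order_sums(mol)

  # directional-mark plan for double-bond stereo; marks are anchored to
  # canonical ranks so the emitted string is independent of atom indexing
  # (the stored stereo flag is anchored to lowest-index substituents)
  plan <- list()  # key: bond index as character -> list(sub, dbl, v)
  for (b in seq_along(mol$bond$i)) {
    if (mol$bond$stereo[b] == 0L) next
    i <- mol$bond$i[b]; j <- mol$bond$j[b]
    subs_i <- setdiff(adj[[i]], j); subs_j <- setdiff(adj[[j]], i)
    if (length(subs_i) == 0L || length(subs_j) == 0L) next
    ri0 <- min(subs_i); rj0 <- min(subs_j)
    ri <- subs_i[which.min(ranks[subs_i])]
    rj <- subs_j[which.min(ranks[subs_j])]
    same <- mol$bond$stereo[b] == 1L
    if (ri != ri0) same <- !same
    if (rj != rj0) same <- !same
    bi <- bond_index(mol, ri, i); bj <- bond_index(mol, rj, j)
    if (mol$bond$order[bi] != 1L || mol$bond$order[bj] != 1L) next
    if (ranks[i] <= ranks[j]) {
      plan[[as.character(bi)]] <- list(sub = ri, dbl = i, v = 1L)
      plan[[as.character(bj)]] <- list(sub = rj, dbl = j, v = if (same) 1L else -1L)
    } else {
      plan[[as.character(bj)]] <- list(sub = rj, dbl = j, v = 1L)
      plan[[as.character(bi)]] <- list(sub = ri, dbl = i, v = if (same) 1L else -1L)
    }
  }

  bond_sym <- function(b, first, second) {
    if (mol$bond$aromatic[b]) {
      return("")
    }
    if (mol$bond$order[b] == 2L) return("=")
    if (mol$bond$order[b] == 3L) return("#")
    p <- plan[[as.character(b)]]
    if (!is.null(p)) {
      v <- p$v
      mark <- if (first == p$sub) { if (v > 0L) "/" else "\\" }
              else { if (v > 0L) "\\" else "/" }
      return(mark)
    }
    if (mol$atom$aromatic[first] && mol$atom$aromatic[second]) return("-")
    ""
  }

  atom_token <- function(a, wo_h_first) {
    el <- mol$atom$element[a]
    arom <- mol$atom$aromatic[a]
    ch <- mol$atom$charge[a]
    map <- if (strip_maps) 0L else mol$atom$map[a]
    chiral <- mol$atom$chiral[a]
    sym <- if (arom) tolower(el) else el
    plain_ok <- el %in% .ORGANIC_SUBSET && ch == 0L && map == 0L && chiral == 0L &&
      !(arom && el %in% c("N", "P", "As") && mol$atom$nH[a] > 0L)
    if (el == "*") plain_ok <- map == 0L && ch == 0L && chiral == 0L
    if (plain_ok && el != "*") {
      av <- allowed_valences(el, 0L)
      fit <- av[av >= sums[a]]
      imp <- if (length(fit) == 0L) 0L else as.integer(min(fit) - sums[a])
      if (arom && el %in% c("N", "P", "As")) imp <- 0L
      plain_ok <- imp == mol$atom$nH[a]
    }
    if (plain_ok) return(sym)
    nh <- mol$atom$nH[a]
    htok <- if (nh == 0L) "" else if (nh == 1L) "H" else paste0("H", nh)
    ctok <- if (chiral == 1L) "@" else if (chiral == 2L) "@@" else ""
    mtok <- if (map > 0L) paste0(":", map) else ""
    paste0("[", sym, ctok, htok, .charge_token(ch), mtok, "]")
  }

  comp <- mol_components(mol)
  pieces <- list()
  for (cid in sort(unique(comp))) {
    members <- which(comp == cid)
    root <- members[which.min(ranks[members])]

    # pass 1: classify tree/back edges with rank-ordered DFS
    parent <- integer(n)
    visited <- logical(n)
    back_at_open <- vector("list", n)   # bond idx opened at this atom
    back_at_close <- vector("list", n)
    order_visited <- integer()
    used_bond <- logical(length(mol$bond$i))
    dfs1 <- function(a) {
      visited[a] <<- TRUE
      order_visited <<- c(order_visited, a)
      nbs <- adj[[a]][order(ranks[adj[[a]]])]
      for (x in nbs) {
        b <- bond_index(mol, a, x)
        if (used_bond[b]) next
        if (visited[x]) {
          used_bond[b] <<- TRUE
          back_at_open[[x]] <<- c(back_at_open[[x]], b)
          back_at_close[[a]] <<- c(back_at_close[[a]], b)
        } else {
          used_bond[b] <<- TRUE
          parent[x] <<- a
          dfs1(x)
        }
      }
    }
    dfs1(root)

    # pass 2: emit, allocating ring digits in encounter order
    digit_of <- list()
    free_digits <- as.character(1:99)
    out <- character(0)
    emit_order <- integer(0)
    emit <- function(a) {
      emit_order <<- c(emit_order, a)
      closes <- back_at_close[[a]]
      opens <- back_at_open[[a]]
      # written neighbor order for chirality
      wo <- integer()
      if (parent[a] != 0L) wo <- c(wo, parent[a])
      has_h_slot <- mol$atom$chiral[a] != 0L && mol$atom$nH[a] >= 1L
      if (has_h_slot) wo <- c(wo, 0L)
      other_end <- function(b) if (mol$bond$i[b] == a) mol$bond$j[b] else mol$bond$i[b]
      for (b in closes) wo <- c(wo, other_end(b))
      for (b in opens) wo <- c(wo, other_end(b))
      kids <- adj[[a]][order(ranks[adj[[a]]])]
      kids <- kids[parent[kids] == a]
      wo <- c(wo, kids)
      tok <- atom_token(a, has_h_slot)
      if (mol$atom$chiral[a] != 0L && length(wo) == 4L) {
        ref <- chiral_reference(mol, a, adj)
        if (length(ref) == 4L && setequal(ref, wo)) {
          tag <- mol$atom$chiral[a]
          if (ordering_parity(wo, ref) == 1L) tag <- flip_tag(tag)
          tok <- sub("@@?", if (tag == 1L) "@" else "@@", tok, fixed = FALSE)
        }
      }
      out <<- c(out, tok)
      for (b in closes) {
        d <- digit_of[[as.character(b)]]
        out <<- c(out, if (nchar(d) > 1L) paste0("%", d) else d)
        free_digits <<- c(d, free_digits)
      }
      for (b in opens) {
        d <- free_digits[1L]; free_digits <<- free_digits[-1L]
        digit_of[[as.character(b)]] <<- d
        sym <- bond_sym(b, a, other_end(b))
        out <<- c(out, sym, if (nchar(d) > 1L) paste0("%", d) else d)
      }
      nk <- length(kids)
      for (t in seq_along(kids)) {
        x <- kids[t]
        b <- bond_index(mol, a, x)
        sym <- bond_sym(b, a, x)
        if (t < nk) {
          out <<- c(out, "(", sym)
          emit(x)
          out <<- c(out, ")")
        } else {
          out <<- c(out, sym)
          emit(x)
        }
      }
    }
    emit(root)
    pieces[[length(pieces) + 1L]] <- list(s = paste(out, collapse = ""),
                                          order = emit_order)
  }
  if (canonical && length(pieces) > 1L) {
    pieces <- pieces[order(vapply(pieces, `[[`, character(1), "s"))]
  }
  list(smiles = paste(vapply(pieces, `[[`, character(1), "s"), collapse = "."),
       order = unlist(lapply(pieces, `[[`, "order")))
}
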