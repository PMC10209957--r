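# Graph edits: the five edit variants and the engine that applies them.
#
# Edits address atoms by atom-map number (map numbers survive
# canonicalization; indices do not).  Application is purely functional:
# the input graph is never mutated.  Hydrogen bookkeeping: deleting a bond
# converts each freed valence into an implicit hydrogen; raising a bond
# order consumes hydrogens; attaching a leaving group consumes hydrogens
# on the target atom unless a preceding change-atom edit pinned the
# hydrogen count (a pinned atom carries open valences until its leaving
# group arrives, the usual synthon picture).

#' Construct graph edits
#'
#' The five edit variants.  Sites are atom-map numbers.  `edit_delete_bond`
#' removes the bond between two mapped atoms (each end gains one implicit
#' hydrogen per unit of bond order); `edit_change_bond` sets a bond's
#' order and cis/trans descriptor; `edit_change_atom` sets an atom's
#' hydrogen count and chirality tag and pins the hydrogen count against
#' later attachments; `edit_attach_lg` grafts a leaving group, given as
#' SMILES with `*` dummy attachment atoms, onto an atom;
#' `edit_terminate` ends a sequence.
#'
#' @param i,j Atom-map numbers of the edit site.
#' @param order New bond order (1-3).
#' @param stereo New cis/trans descriptor (0 none, 1 cis, 2 trans between
#'   the lowest-map substituents), anchored to atom-map order.
#' @param nH New implicit hydrogen count.
#' @param chiral New chirality tag (0 none, 1/2 tetrahedral), anchored to
#'   atom-map order with an implicit hydrogen first.
#' @param lg_smiles Leaving-group SMILES; every `*` becomes one bond to
#'   the site atom, carrying the order it has to the `*`.
#' @return A `mol_edit` object.
#' @export
#' @rdname edit_delete_bond
edit_delete_bond <- function(i, j) {
  structure(list(type = "DeleteBond", site = c(min(i, j), max(i, j)), payload = NULL),
            class = "mol_edit")
}

#' @rdname edit_delete_bond
#' @export
edit_change_bond <- function(i, j, order, stereo = 0L) {
  structure(list(type = "ChangeBond", site = c(min(i, j), max(i, j)),
                 payload = c(as.integer(order), as.integer(stereo))),
            class = "mol_edit")
}

#' @rdname edit_delete_bond
#' @export
edit_change_atom <- function(i, nH, chiral = 0L) {
  structure(list(type = "ChangeAtom", site = as.integer(i),
                 payload = c(as.integer(nH), as.integer(chiral))),
            class = "mol_edit")
}

#' @rdname edit_delete_bond
#' @export
edit_attach_lg <- function(i, lg_smiles) {
  structure(list(type = "AttachLG", site = as.integer(i), payload = lg_smiles),
            class = "mol_edit")
}

#' @rdname edit_delete_bond
#' @export
edit_terminate <- function() {
  structure(list(type = "Terminate", site = NULL, payload = NULL), class = "mol_edit")
}

#' @export
print.mol_edit <- function(x, ...) {
  cat(format.mol_edit(x), "\n")
  invisible(x)
}

#' @export
format.mol_edit <- function(x, ...) {
  switch(x$type,
    DeleteBond = sprintf("DeleteBond [%d, %d]", x$site[1], x$site[2]),
    ChangeBond = sprintf("ChangeBond [%d, %d] -> (%d, %d)", x$site[1], x$site[2],
                         x$payload[1], x$payload[2]),
    ChangeAtom = sprintf("ChangeAtom %d -> (%d, %d)", x$site, x$payload[1], x$payload[2]),
    AttachLG = sprintf("AttachLG %d '%s'", x$site, x$payload),
    Terminate = "Terminate")
}

# Site-independent payload key, the unit the edit vocabulary indexes.
edit_payload_key <- function(edit) {
  switch(edit$type,
    DeleteBond = "DeleteBond",
    ChangeBond = sprintf("ChangeBond:(%d,%d)", edit$payload[1], edit$payload[2]),
    ChangeAtom = sprintf("ChangeAtom:(%d,%d)", edit$payload[1], edit$payload[2]),
    AttachLG = sprintf("AttachLG:%s", edit$payload),
    Terminate = "Terminate")
}

# Is an edit of this payload a bond edit (sited on a bond) or an atom edit?
edit_kind <- function(payload_key) {
  if (payload_key == "Terminate") return("graph")
  if (grepl("^(DeleteBond|ChangeBond)", payload_key)) "bond" else "atom"
}

## ---- stereo bookkeeping helpers --------------------------------------------

# Returns TRUE if atom a of mol can carry a tetrahedral tag.
.stereo_capable <- function(mol, a, adj = NULL) {
  deg <- if (is.null(adj)) {
    sum(mol$bond$i == a) + sum(mol$bond$j == a)
  } else length(adj[[a]])
  (deg == 4L && mol$atom$nH[a] == 0L) || (deg == 3L && mol$atom$nH[a] == 1L)
}

# Fix the chiral tag of atom a after neighbor old_label was replaced by
# new_label (label 0 = the implicit-hydrogen slot).  ref_old must be the
# reference ordering captured before the mutation.
.fix_chirality_swap <- function(mol, a, ref_old, old_label, new_label) {
  if (mol$atom$chiral[a] == 0L) return(mol)
  if (length(ref_old) != 4L || !.stereo_capable(mol, a)) {
    mol$atom$chiral[a] <- 0L
    return(mol)
  }
  mapped <- ref_old
  mapped[mapped == old_label] <- new_label
  ref_new <- chiral_reference(mol, a)
  if (length(ref_new) != 4L || !setequal(ref_new, mapped)) {
    mol$atom$chiral[a] <- 0L
    return(mol)
  }
  if (ordering_parity(mapped, ref_new) == 1L)
    mol$atom$chiral[a] <- flip_tag(mol$atom$chiral[a])
  mol
}

# Capture the cis/trans reference substituent of every stereo double bond.
.stereo_refs <- function(mol, adj = NULL) {
  if (is.null(adj)) adj <- mol_adjacency(mol)
  refs <- list()
  for (b in seq_along(mol$bond$i)) {
    if (mol$bond$stereo[b] == 0L) next
    i <- mol$bond$i[b]; j <- mol$bond$j[b]
    si <- setdiff(adj[[i]], j); sj <- setdiff(adj[[j]], i)
    refs[[sprintf("%d-%d", i, j)]] <- list(b = b, ri = if (length(si)) min(si) else NA_integer_,
                                           rj = if (length(sj)) min(sj) else NA_integer_)
  }
  refs
}

# After a structural change (atom indices unchanged), re-anchor stereo
# flags whose reference substituent changed, clearing unanchorable ones.
.fix_bond_stereo <- function(mol, refs_before) {
  adj <- mol_adjacency(mol)
  for (key in names(refs_before)) {
    old <- refs_before[[key]]
    ij <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
    b <- bond_index(mol, ij[1], ij[2])
    if (b == 0L || mol$bond$stereo[b] == 0L || mol$bond$order[b] != 2L) next
    flips <- 0L
    ok <- TRUE
    for (endpos in 1:2) {
      end <- ij[endpos]; other <- ij[3 - endpos]
      subs <- setdiff(adj[[end]], other)
      if (length(subs) == 0L) { ok <- FALSE; break }
      newref <- min(subs)
      oldref <- if (endpos == 1L) old$ri else old$rj
      if (is.na(oldref)) { ok <- FALSE; break }
      if (!(oldref %in% subs)) {
        # the anchoring substituent is gone; geometry is no longer tracked
        ok <- FALSE; break
      }
      if (newref != oldref) flips <- flips + 1L
    }
    if (!ok) mol$bond$stereo[b] <- 0L
    else if (flips %% 2L == 1L) mol$bond$stereo[b] <- flip_tag(mol$bond$stereo[b])
  }
  mol
}

## ---- map-anchored stereo descriptors ----------------------------------------
#
# Chiral tags and cis/trans flags are stored anchored to internal atom
# indices, which differ between the graphs an edit is extracted from and
# applied to.  Edit payloads therefore carry stereo descriptors anchored
# to atom-map numbers, converted to/from the index anchoring at the graph
# boundary.

# Parity between the index-anchored and map-anchored reference orderings
# of atom a (NA when not anchorable).
.map_ref_parity <- function(mol, a, adj = NULL) {
  ref_idx <- chiral_reference(mol, a, adj)
  if (length(ref_idx) != 4L) return(NA_integer_)
  heavy <- ref_idx[ref_idx != 0L]
  maps <- mol$atom$map[heavy]
  if (any(maps == 0L) || anyDuplicated(maps) > 0L) return(NA_integer_)
  ref_map <- c(if (0L %in% ref_idx) 0L, heavy[order(maps)])
  ordering_parity(ref_idx, ref_map)
}

map_anchored_tag <- function(mol, a, adj = NULL) {
  t <- mol$atom$chiral[a]
  if (t == 0L) return(0L)
  p <- .map_ref_parity(mol, a, adj)
  if (is.na(p) || p == 0L) t else flip_tag(t)
}

# number of double-bond ends whose min-index and min-map substituents
# differ (NA when unanchorable)
.stereo_map_flips <- function(mol, b, adj = NULL) {
  if (is.null(adj)) adj <- mol_adjacency(mol)
  i <- mol$bond$i[b]; j <- mol$bond$j[b]
  flips <- 0L
  for (endpos in 1:2) {
    end <- if (endpos == 1L) i else j
    other <- if (endpos == 1L) j else i
    subs <- setdiff(adj[[end]], other)
    if (length(subs) == 0L) return(NA_integer_)
    maps <- mol$atom$map[subs]
    if (any(maps == 0L)) return(NA_integer_)
    if (subs[which.min(maps)] != min(subs)) flips <- flips + 1L
  }
  flips
}

map_anchored_bond_stereo <- function(mol, b, adj = NULL) {
  s <- mol$bond$stereo[b]
  if (s == 0L) return(0L)
  fl <- .stereo_map_flips(mol, b, adj)
  if (is.na(fl) || fl %% 2L == 0L) s else flip_tag(s)
}

# Resolve pending (map-anchored) chiral tags on atoms whose neighbor
# shell has become a complete stereocenter.
.finalize_pending_chirality <- function(mol) {
  pend <- which(mol$atom$chiral_pending != 0L)
  if (length(pend) == 0L) return(mol)
  for (a in pend) {
    if (!.stereo_capable(mol, a)) next
    p <- .map_ref_parity(mol, a)
    t <- mol$atom$chiral_pending[a]
    mol$atom$chiral[a] <- if (is.na(p) || p == 0L) t else flip_tag(t)
    mol$atom$chiral_pending[a] <- 0L
  }
  mol
}

## ---- the engine -------------------------------------------------------------

.site_atom <- function(mol, map) {
  a <- atom_by_map(mol, map)
  if (a == 0L) stop(sprintf("site error: no atom with map number %d", map))
  a
}

#' Apply a single graph edit
#'
#' @param mol A sanitized `molgraph`.
#' @param edit A `mol_edit`.
#' @return The edited `molgraph` (a new object; the input is untouched).
#'   A `Terminate` edit returns the graph unchanged with attribute
#'   `terminated` set.
#' @export
apply_edit <- function(mol, edit) {
  if (isTRUE(attr(mol, "terminated")))
    stop("state error: cannot edit a terminated graph")
  switch(edit$type,
    Terminate = {
      attr(mol, "terminated") <- TRUE
      mol
    },
    DeleteBond = {
      a <- .site_atom(mol, edit$site[1]); b2 <- .site_atom(mol, edit$site[2])
      b <- bond_index(mol, a, b2)
      if (b == 0L) stop(sprintf("site error: no bond between maps %d and %d",
                                edit$site[1], edit$site[2]))
      o <- mol$bond$order[b]
      refs <- .stereo_refs(mol)
      ref_a <- chiral_reference(mol, a); ref_b <- chiral_reference(mol, b2)
      mol <- mol_drop_bond(mol, b)
      mol$atom$nH[a] <- mol$atom$nH[a] + o
      mol$atom$nH[b2] <- mol$atom$nH[b2] + o
      mol <- .fix_chirality_swap(mol, a, ref_a, b2, 0L)
      mol <- .fix_chirality_swap(mol, b2, ref_b, a, 0L)
      mol <- .fix_bond_stereo(mol, refs)
      .finalize_pending_chirality(mol_sanitize(mol))
    },
    ChangeBond = {
      a <- .site_atom(mol, edit$site[1]); b2 <- .site_atom(mol, edit$site[2])
      b <- bond_index(mol, a, b2)
      if (b == 0L) stop(sprintf("site error: no bond between maps %d and %d",
                                edit$site[1], edit$site[2]))
      delta <- edit$payload[1] - mol$bond$order[b]
      for (x in c(a, b2)) {
        nh <- mol$atom$nH[x] - delta
        if (nh < 0L) stop(sprintf("chemistry error: not enough hydrogens on map %d",
                                  mol$atom$map[x]))
        mol$atom$nH[x] <- nh
      }
      mol$bond$order[b] <- edit$payload[1]
      s <- edit$payload[2]
      if (s != 0L) {
        fl <- .stereo_map_flips(mol, b)
        if (!is.na(fl) && fl %% 2L == 1L) s <- flip_tag(s)
      }
      mol$bond$stereo[b] <- s
      mol$bond$aromatic[b] <- FALSE
      .finalize_pending_chirality(mol_sanitize(mol))
    },
    ChangeAtom = {
      a <- .site_atom(mol, edit$site)
      mol$atom$nH[a] <- edit$payload[1]
      # the (map-anchored) tag becomes meaningful once the leaving group
      # completes the neighbor shell; until then it stays pending
      mol$atom$chiral[a] <- 0L
      mol$atom$chiral_pending[a] <- edit$payload[2]
      mol$atom$pinned[a] <- TRUE
      .finalize_pending_chirality(mol_sanitize(mol))
    },
    AttachLG = attach_leaving_group(mol, edit$site, edit$payload),
    stop(sprintf("unknown edit type '%s'", edit$type))
  )
}

#' Attach a leaving group to an atom
#'
#' The leaving-group SMILES contains one or more dummy atoms `*`; for each
#' dummy, a bond with the dummy's bond order is created between the
#' dummy's neighbor and the target atom, then the dummies are removed.
#' Multi-dummy groups form several bonds to the same target atom.  New
#' atoms receive fresh map numbers continuing from the current maximum.
#'
#' @param mol A sanitized `molgraph`.
#' @param atom_map Map number of the target atom.
#' @param lg_smiles Leaving-group SMILES, e.g. `"*Br"`, `"*=O"`,
#'   `"*C(=O)c1ccccc1C(*)=O"`.
#' @return The edited `molgraph`.
#' @export
attach_leaving_group <- function(mol, atom_map, lg_smiles) {
  target <- .site_atom(mol, atom_map)
  lg <- mol_from_smiles(lg_smiles, sanitize = FALSE)
  dummies <- which(lg$atom$element == "*")
  if (length(dummies) == 0L)
    stop(sprintf("leaving group '%s' contains no dummy atom", lg_smiles))
  lg_adj <- mol_adjacency(lg)
  for (d in dummies) if (length(lg_adj[[d]]) != 1L)
    stop(sprintf("dummy atom in '%s' must have exactly one neighbor", lg_smiles))

  n0 <- mol$n
  keep <- setdiff(seq_len(lg$n), dummies)
  # final index of lg atom k (for kept atoms): n0 + rank among kept
  lg_final <- integer(lg$n)
  lg_final[keep] <- n0 + seq_along(keep)

  refs <- .stereo_refs(mol)
  ref_target <- chiral_reference(mol, target)

  out <- mol
  maxmap <- max(c(0L, out$atom$map))
  for (k in keep) {
    maxmap <- maxmap + 1L
    out <- mol_add_atom(out, lg$atom$element[k], charge = lg$atom$charge[k],
                        nH = lg$atom$nH[k], aromatic = lg$atom$aromatic[k],
                        chiral = lg$atom$chiral[k], map = maxmap)
  }
  # leaving-group internal bonds
  for (b in seq_along(lg$bond$i)) {
    i <- lg$bond$i[b]; j <- lg$bond$j[b]
    if (i %in% dummies || j %in% dummies) next
    out <- mol_add_bond(out, lg_final[i], lg_final[j], order = lg$bond$order[b],
                        aromatic = lg$bond$aromatic[b], stereo = lg$bond$stereo[b])
  }
  # chirality inside the leaving group: kept atoms keep ascending order, so
  # parity is unchanged except where a dummy neighbor becomes the target
  attach_orders <- integer(0)
  for (d in dummies) {
    u <- lg_adj[[d]][1L]
    db <- bond_index(lg, d, u)
    o <- lg$bond$order[db]
    attach_orders <- c(attach_orders, o)
    if (bond_index(out, target, lg_final[u]) != 0L)
      stop("chemistry error: leaving group attaches twice through the same neighbor")
    out <- mol_add_bond(out, target, lg_final[u], order = o)
    if (lg$atom$chiral[u] != 0L) {
      ref_u_old <- chiral_reference(lg, u, lg_adj)      # in lg indexing
      mapped <- ifelse(ref_u_old == 0L, 0L,
                       ifelse(ref_u_old == d, target, lg_final[pmax(ref_u_old, 1L)]))
      mapped[ref_u_old == 0L] <- 0L
      ref_u_new <- chiral_reference(out, lg_final[u])
      if (length(ref_u_new) == 4L && length(mapped) == 4L && setequal(ref_u_new, mapped)) {
        if (ordering_parity(mapped, ref_u_new) == 1L)
          out$atom$chiral[lg_final[u]] <- flip_tag(out$atom$chiral[lg_final[u]])
      } else out$atom$chiral[lg_final[u]] <- 0L
    }
  }
  # hydrogen bookkeeping on the target
  if (!mol$atom$pinned[target]) {
    consume <- sum(attach_orders)
    out$atom$nH[target] <- max(out$atom$nH[target] - consume, 0L)
  }
  # target chirality: the new neighbor takes the implicit-hydrogen slot
  if (out$atom$chiral[target] != 0L) {
    if (length(attach_orders) == 1L && length(ref_target) == 4L) {
      u_final <- lg_final[lg_adj[[dummies[1L]]][1L]]
      out <- .fix_chirality_swap(out, target, ref_target, 0L, u_final)
    } else if (!.stereo_capable(out, target)) {
      out$atom$chiral[target] <- 0L
    }
  }
  out <- .fix_bond_stereo(out, refs)
  .finalize_pending_chirality(mol_sanitize(out))
}

#' Apply a sequence of edits to a product graph
#'
#' @param product A sanitized `molgraph`.
#' @param edits List of `mol_edit` objects, ending in a `Terminate` (a
#'   missing terminate still returns the final graph, flagged incomplete).
#' @return List with `graphs` (all intermediates plus the final reactant
#'   graph), `reactants` (the final graph), and `complete` (logical).
#'   Errors during a step are re-signalled with the failing step index.
#' @export
apply_edit_sequence <- function(product, edits) {
  if (length(edits) == 0L) stop("edit sequence must be non-empty")
  term_pos <- which(vapply(edits, function(e) e$type == "Terminate", logical(1)))
  if (length(term_pos) > 1L || (length(term_pos) == 1L && term_pos != length(edits)))
    stop("at most one Terminate is allowed, and only at the end")
  g <- product
  graphs <- list()
  complete <- FALSE
  for (s in seq_along(edits)) {
    g <- tryCatch(apply_edit(g, edits[[s]]),
                  error = function(e) stop(sprintf("step %d (%s): %s", s,
                                                   format.mol_edit(edits[[s]]),
                                                   conditionMessage(e)), call. = FALSE))
    if (isTRUE(attr(g, "terminated"))) complete <- TRUE
    graphs[[length(graphs) + 1L]] <- g
  }
  list(graphs = graphs, reactants = g, complete = complete)
}

## ---- serialization -----------------------------------------------------------

#' Serialize edits to JSON lines / parse them back
#'
#' @param edits List of `mol_edit`.
#' @return Character vector, one JSON object per edit.
#' @export
edits_to_jsonl <- function(edits) {
  vapply(edits, function(e) {
    obj <- list(type = e$type)
    if (!is.null(e$site)) obj$site <- e$site
    if (!is.null(e$payload)) obj$payload <- e$payload
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, character(1))
}

#' @param lines Character vector of JSON objects as written by
#'   [edits_to_jsonl()].
#' @rdname edits_to_jsonl
#' @export
edits_from_jsonl <- function(lines) {
  lapply(lines, function(ln) {
    obj <- jsonlite::fromJSON(ln)
    switch(obj$type,
      DeleteBond = edit_delete_bond(obj$site[1], obj$site[2]),
      ChangeBond = edit_change_bond(obj$site[1], obj$site[2], obj$payload[1], obj$payload[2]),
      ChangeAtom = edit_change_atom(obj$site, obj$payload[1], obj$payload[2]),
      AttachLG = edit_attach_lg(obj$site, obj$payload),
      Terminate = edit_terminate(),
      stop(sprintf("unknown edit type '%s'", obj$type)))
  })
}
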