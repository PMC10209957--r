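# Ground-truth edit extraction by atom-mapped reaction diffing, and the
# edit vocabulary.
#
# Priority order of extracted edits: DeleteBond > ChangeBond > ChangeAtom
# > AttachLG, with Terminate last.  Within a priority class the ordering
# is deterministic: bond edits by (min map, max map), atom edits by map
# number (attachments additionally by leaving-group string).  Change-atom
# edits are emitted exactly where the automatic hydrogen/stereo
# bookkeeping of the engine would not already land on the reactant state,
# which keeps training labels minimal and replay exact.

#' Extract the ground-truth edit sequence of a reaction
#'
#' Diffs the atom-mapped product against the reactants of a canonicalized
#' record.  The returned sequence, replayed on the product with
#' [apply_edit_sequence()], reproduces the reactants exactly (canonical
#' SMILES, stereochemistry retained); extraction fails otherwise.
#'
#' @param record A canonicalized `reaction_record` (see
#'   [canonicalize_reaction()]).
#' @return List of `mol_edit` objects ending in Terminate.
#' @export
extract_edits <- function(record) {
  p <- record$product
  n <- p$n
  rall <- mol_combine(record$reactants)
  r_idx_of_map <- integer(max(c(rall$atom$map, n)))
  r_idx_of_map[rall$atom$map[rall$atom$map > 0L]] <- which(rall$atom$map > 0L)
  radj <- mol_adjacency(rall)

  # --- bond diffs over product bonds
  deletes <- list(); changes <- list()
  for (b in seq_along(p$bond$i)) {
    mi <- p$atom$map[p$bond$i[b]]; mj <- p$atom$map[p$bond$j[b]]
    ra <- r_idx_of_map[mi]; rb2 <- r_idx_of_map[mj]
    rb <- if (ra > 0L && rb2 > 0L) bond_index(rall, ra, rb2) else 0L
    if (rb == 0L) {
      deletes[[length(deletes) + 1L]] <- edit_delete_bond(mi, mj)
    } else {
      if (p$bond$aromatic[b] && rall$bond$aromatic[rb]) next
      po <- p$bond$order[b]; ro <- rall$bond$order[rb]
      ps <- map_anchored_bond_stereo(p, b)
      rs <- map_anchored_bond_stereo(rall, rb, radj)
      if (po != ro || ps != rs || (p$bond$aromatic[b] != rall$bond$aromatic[rb] && po != ro))
        if (po != ro || ps != rs)
          changes[[length(changes) + 1L]] <- edit_change_bond(mi, mj, ro, rs)
    }
  }
  # new bond between two product atoms is outside the edit scheme
  for (rb in seq_along(rall$bond$i)) {
    mi <- rall$atom$map[rall$bond$i[rb]]; mj <- rall$atom$map[rall$bond$j[rb]]
    if (mi > 0L && mi <= n && mj > 0L && mj <= n) {
      pa <- atom_by_map(p, mi); pb <- atom_by_map(p, mj)
      if (bond_index(p, pa, pb) == 0L)
        stop(sprintf("unextractable: bond formation between mapped atoms %d and %d", mi, mj))
    }
  }

  # --- leaving groups: connected components of atoms absent from the product
  lg_atoms <- which(rall$atom$map > n | rall$atom$map == 0L)
  attaches <- list()
  if (length(lg_atoms) > 0L) {
    sub <- mol_delete_atoms(rall, setdiff(seq_len(rall$n), lg_atoms))
    comp <- mol_components(sub)
    for (cid in sort(unique(comp))) {
      members <- lg_atoms[comp == cid]
      # attachment bonds from this component to mapped atoms
      targets <- integer(0); dummy_bonds <- list()
      for (a in members) for (x in radj[[a]]) {
        if (!(x %in% members)) {
          m <- rall$atom$map[x]
          if (m == 0L || m > n)
            stop("unextractable: leaving-group atoms form an unexpected bridge")
          targets <- c(targets, m)
          dummy_bonds[[length(dummy_bonds) + 1L]] <-
            list(inner = a, order = rall$bond$order[bond_index(rall, a, x)])
        }
      }
      if (length(unique(targets)) == 0L)
        stop("unextractable: reactant molecule shares no atoms with the product")
      if (length(unique(targets)) > 1L)
        stop("unextractable: leaving group attaches to more than one atom")
      lg_smiles <- .leaving_group_smiles(rall, members, dummy_bonds)
      attaches[[length(attaches) + 1L]] <- edit_attach_lg(targets[1L], lg_smiles)
    }
  }

  ord_bond <- function(es) es[order(vapply(es, function(e) e$site[1], numeric(1)),
                                    vapply(es, function(e) e$site[2], numeric(1)))]
  deletes <- ord_bond(deletes); changes <- ord_bond(changes)
  attaches <- attaches[order(vapply(attaches, function(e) e$site, numeric(1)),
                             vapply(attaches, function(e) e$payload, character(1)))]

  # --- change-atom edits by simulation against the reactant state
  base <- c(deletes, changes)
  target_state <- function(m) {
    a <- r_idx_of_map[m]
    list(nH = rall$atom$nH[a], tag = map_anchored_tag(rall, a, radj))
  }
  sim <- function(edits) {
    tryCatch(apply_edit_sequence(p, c(edits, list(edit_terminate()))),
             error = function(e) NULL)
  }
  res0 <- sim(c(base, attaches))
  fixes <- list()
  if (!is.null(res0)) {
    g <- res0$reactants
    for (m in seq_len(n)) {
      a <- atom_by_map(g, m)
      ts <- target_state(m)
      if (g$atom$nH[a] != ts$nH || map_anchored_tag(g, a) != ts$tag)
        fixes[[length(fixes) + 1L]] <- edit_change_atom(m, ts$nH, ts$tag)
    }
  } else {
    # conservative fallback: pin every atom whose static state differs
    for (m in seq_len(n)) {
      a <- atom_by_map(p, m)
      ts <- target_state(m)
      if (p$atom$nH[a] != ts$nH || map_anchored_tag(p, a) != ts$tag)
        fixes[[length(fixes) + 1L]] <- edit_change_atom(m, ts$nH, ts$tag)
    }
  }
  if (length(fixes) > 0L)
    fixes <- fixes[order(vapply(fixes, function(e) e$site, numeric(1)))]
  edits <- c(base, fixes, attaches, list(edit_terminate()))

  # --- verification: replay must reproduce the reactants exactly
  res <- sim(c(base, fixes, attaches))
  if (is.null(res))
    stop("extraction-consistency error: extracted sequence is not applicable")
  got <- .reactant_key_mol(res$reactants)
  want <- reactants_key(record)
  if (!identical(got, want))
    stop(sprintf("extraction-consistency error: replay gives '%s', expected '%s'", got, want))
  edits
}

.reactant_key_mol <- function(mol) {
  frags <- vapply(mol_split(mol), mol_to_smiles, character(1),
                  keep_stereo = TRUE, strip_maps = TRUE)
  paste(sort(frags), collapse = ".")
}

# Dummy-rooted SMILES of a leaving-group component: the component's atoms
# plus one dummy per attachment bond, carrying the original bond order.
.leaving_group_smiles <- function(rall, members, dummy_bonds) {
  keep <- sort(members)
  sub <- mol_delete_atoms(rall, setdiff(seq_len(rall$n), keep))
  local_of <- integer(rall$n); local_of[keep] <- seq_along(keep)
  for (db in dummy_bonds) {
    sub <- mol_add_atom(sub, "*")
    sub <- mol_add_bond(sub, local_of[db$inner], sub$n, order = db$order)
  }
  mol_to_smiles(sub, canonical = TRUE, keep_stereo = TRUE, strip_maps = TRUE)
}

## ---- vocabulary --------------------------------------------------------------

#' Build the edit vocabulary from training records
#'
#' Collects the distinct bond-edit payloads (including DeleteBond), atom-edit
#' payloads (ChangeAtom pairs and AttachLG leaving-group strings) and the
#' Terminate symbol seen in the records' edit sequences.  AttachLG payloads
#' occurring fewer than `min_lg_count` times are dropped.  Entries are
#' sorted by descending count, ties by payload string, so the result is
#' independent of record order.
#'
#' @param records List of `reaction_record` objects with `$edits` attached
#'   (see [preprocess_reactions()]).
#' @param min_lg_count Minimum training-set frequency for an AttachLG
#'   payload (default 1; large noisy sets typically use 50).
#' @return An `edit_vocab`: list with data frames `bond` and `atom`
#'   (columns `key`, `count`) plus index helpers.
#' @export
build_edit_vocab <- function(records, min_lg_count = 1L) {
  stopifnot(min_lg_count >= 1L)
  counts <- new.env(parent = emptyenv())
  for (rec in records) {
    if (is.null(rec$edits)) next
    for (e in rec$edits) {
      if (e$type == "Terminate") next
      key <- edit_payload_key(e)
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  cnt <- vapply(keys, function(k) counts[[k]], integer(1))
  keep <- !(grepl("^AttachLG:", keys) & cnt < min_lg_count)
  keys <- keys[keep]; cnt <- cnt[keep]
  o <- order(-cnt, keys)
  keys <- keys[o]; cnt <- cnt[o]
  kinds <- vapply(keys, edit_kind, character(1))
  vocab <- list(
    bond = data.frame(key = keys[kinds == "bond"], count = cnt[kinds == "bond"],
                      stringsAsFactors = FALSE, row.names = NULL),
    atom = data.frame(key = keys[kinds == "atom"], count = cnt[kinds == "atom"],
                      stringsAsFactors = FALSE, row.names = NULL)
  )
  class(vocab) <- "edit_vocab"
  vocab
}

#' @export
print.edit_vocab <- function(x, ...) {
  n_ca <- sum(grepl("^ChangeAtom", x$atom$key))
  n_lg <- sum(grepl("^AttachLG", x$atom$key))
  cat(sprintf("<edit_vocab: %d bond edits, %d atom edits (%d ChangeAtom, %d AttachLG), + Terminate>\n",
              nrow(x$bond), nrow(x$atom), n_ca, n_lg))
  invisible(x)
}

#' Total number of payload entries (bond + atom + terminate)
#' @param vocab An `edit_vocab`.
#' @return Integer.
#' @export
vocab_size <- function(vocab) nrow(vocab$bond) + nrow(vocab$atom) + 1L

# Reconstruct a sited edit from a vocabulary payload key.
edit_from_key <- function(key, site = NULL) {
  if (key == "Terminate") return(edit_terminate())
  if (key == "DeleteBond") return(edit_delete_bond(site[1], site[2]))
  m <- regmatches(key, regexec("^ChangeBond:\\((-?\\d+),(-?\\d+)\\)$", key))[[1]]
  if (length(m) == 3L)
    return(edit_change_bond(site[1], site[2], as.integer(m[2]), as.integer(m[3])))
  m <- regmatches(key, regexec("^ChangeAtom:\\((-?\\d+),(-?\\d+)\\)$", key))[[1]]
  if (length(m) == 3L)
    return(edit_change_atom(site, as.integer(m[2]), as.integer(m[3])))
  if (startsWith(key, "AttachLG:"))
    return(edit_attach_lg(site, substring(key, nchar("AttachLG:") + 1L)))
  stop(sprintf("malformed vocabulary key '%s'", key))
}

#' Save / load an edit vocabulary as JSON
#' @param vocab An `edit_vocab`.
#' @param path File path.
#' @export
save_vocab <- function(vocab, path) {
  jsonlite::write_json(list(bond = vocab$bond, atom = vocab$atom), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_vocab
#' @export
load_vocab <- function(path) {
  obj <- jsonlite::fromJSON(path)
  empty <- data.frame(key = character(), count = integer(), stringsAsFactors = FALSE)
  vocab <- list(bond = if (length(obj$bond)) obj$bond else empty,
                atom = if (length(obj$atom)) obj$atom else empty)
  class(vocab) <- "edit_vocab"
  vocab
}

# Stable fingerprint of a vocabulary, stored in checkpoints so a model is
# never decoded against the wrong edit index.
vocab_hash <- function(vocab) {
  s <- paste(c(vocab$bond$key, "|", vocab$atom$key), collapse = "\n")
  # small rolling hash; no digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%d-%d", nchar(s), h)
}

## ---- preprocessing & applicability ------------------------------------------

#' Canonicalize records and extract their edit sequences
#'
#' @param records List of `reaction_record`.
#' @param progress Print a dot every 100 records (default FALSE).
#' @return List with `records` (canonicalized, `$edits` attached where
#'   extraction succeeded) and `failures` (data frame of index + reason).
#' @export
preprocess_reactions <- function(records, progress = FALSE) {
  fails <- list()
  out <- vector("list", length(records))
  for (k in seq_along(records)) {
    rec <- records[[k]]
    res <- tryCatch({
      rec <- canonicalize_reaction(rec)
      rec$edits <- extract_edits(rec)
      rec
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fails[[length(fails) + 1L]] <- data.frame(index = k, reason = res,
                                                stringsAsFactors = FALSE)
      out[[k]] <- records[[k]]
    } else out[[k]] <- res
    if (progress && k %% 100L == 0L) cat(".")
  }
  if (progress) cat("\n")
  list(records = out,
       failures = if (length(fails)) do.call(rbind, fails)
                  else data.frame(index = integer(), reason = character()))
}

#' Fraction of records whose edit sequence replays exactly
#'
#' Replays each record's extracted sequence on its product and compares
#' the result to the reactants by canonical SMILES with stereochemistry
#' retained.  Records without an extracted sequence count as failures.
#'
#' @param records Preprocessed records.
#' @return Numeric fraction in `[0, 1]`, with attribute `failures` (data
#'   frame of index + reason).
#' @export
edit_applicability <- function(records) {
  ok <- 0L
  fails <- list()
  for (k in seq_along(records)) {
    rec <- records[[k]]
    reason <- NULL
    if (is.null(rec$edits)) {
      reason <- "no extracted edit sequence"
    } else {
      res <- tryCatch(apply_edit_sequence(rec$product, rec$edits),
                      error = function(e) conditionMessage(e))
      if (is.character(res)) reason <- res
      else if (!identical(.reactant_key_mol(res$reactants), reactants_key(rec)))
        reason <- "replayed reactants differ from ground truth"
    }
    if (is.null(reason)) ok <- ok + 1L
    else fails[[length(fails) + 1L]] <- data.frame(index = k, reason = reason,
                                                   stringsAsFactors = FALSE)
  }
  out <- ok / max(length(records), 1L)
  attr(out, "failures") <- if (length(fails)) do.call(rbind, fails)
                           else data.frame(index = integer(), reason = character())
  out
}

#' Edit coverage of a held-out split
#'
#' Fraction of records whose every edit payload is present in the given
#' vocabulary.
#'
#' @param records Preprocessed records (with `$edits`).
#' @param vocab An `edit_vocab` built on the training split.
#' @return Numeric fraction.
#' @export
edit_coverage <- function(records, vocab) {
  keys <- c(vocab$bond$key, vocab$atom$key, "Terminate")
  covered <- vapply(records, function(rec) {
    if (is.null(rec$edits)) return(FALSE)
    all(vapply(rec$edits, edit_payload_key, character(1)) %in% keys)
  }, logical(1))
  mean(covered)
}
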