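# Atom-mapped reaction records: parsing, canonicalization and remapping.

#' Combine several molecular graphs into one multi-fragment graph
#' @param mols List of `molgraph` objects.
#' @return A single `molgraph`.
#' @export
mol_combine <- function(mols) {
  out <- new_molgraph()
  for (m in mols) {
    off <- out$n
    out$atom <- Map(c, out$atom, m$atom)
    out$bond <- Map(c, out$bond, list(m$bond$i + off, m$bond$j + off,
                                      m$bond$order, m$bond$aromatic, m$bond$stereo)[c(1, 2, 3, 4, 5)])
    names(out$bond) <- c("i", "j", "order", "aromatic", "stereo")
    out$n <- out$n + m$n
  }
  out
}

#' Split a multi-fragment graph into its connected components
#' @param mol A `molgraph`.
#' @return List of `molgraph` objects, in order of each component's first atom.
#' @export
mol_split <- function(mol) {
  comp <- mol_components(mol)
  lapply(sort(unique(comp)), function(cid) {
    mol_delete_atoms(mol, which(comp != cid))
  })
}

#' Parse an atom-mapped reaction SMILES
#'
#' Accepts `"reactants>>product"`; every product atom must carry an
#' atom-map number.  The reactant side may contain several dot-separated
#' molecules.
#'
#' @param reaction_smiles Reaction SMILES text.
#' @param class Optional reaction-class integer (1-10) or NA.
#' @return A `reaction_record`: list with `raw`, `product` (a `molgraph`),
#'   `reactants` (list of `molgraph`), `class`, and (after extraction)
#'   `edits`.
#' @examples
#' r <- parse_reaction("[CH3:1][Br:3].[OH2:2]>>[CH3:1][OH:2]")
#' length(r$reactants)
#' @export
parse_reaction <- function(reaction_smiles, class = NA_integer_) {
  parts <- strsplit(reaction_smiles, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2L || grepl(">", gsub(">>", "", reaction_smiles, fixed = TRUE), fixed = TRUE))
    stop("parse error: reaction SMILES must contain exactly one '>>'")
  product <- tryCatch(mol_from_smiles(parts[2]),
                      error = function(e) stop(sprintf("parse error on product side: %s",
                                                       conditionMessage(e))))
  reactant_all <- tryCatch(mol_from_smiles(parts[1]),
                           error = function(e) stop(sprintf("parse error on reactant side: %s",
                                                            conditionMessage(e))))
  if (any(product$atom$map == 0L))
    stop("mapping error: every product atom must have an atom-map number")
  structure(list(raw = reaction_smiles, product = product,
                 reactants = mol_split(reactant_all),
                 class = as.integer(class), edits = NULL),
            class = "reaction_record")
}

#' @export
print.reaction_record <- function(x, ...) {
  cat(sprintf("<reaction_record: %d product atoms, %d reactant molecule(s)%s>\n",
              mol_natoms(x$product), length(x$reactants),
              if (!is.null(x$edits)) sprintf(", %d edits", length(x$edits)) else ""))
  cat(" ", x$raw, "\n")
  invisible(x)
}

#' Canonicalize a reaction record and renumber its atom maps
#'
#' The product is rewritten in canonical atom order and its atoms
#' renumbered 1..n in that order; reactant map numbers are rewritten to
#' follow, and reactant atoms without a counterpart in the product
#' (future leaving-group atoms) receive fresh numbers n+1, n+2, ... in
#' reactant canonical order.  The operation is idempotent.
#'
#' @param record A `reaction_record`.
#' @return The canonicalized `reaction_record` (its `raw` field is updated
#'   to the canonical reaction SMILES).
#' @export
canonicalize_reaction <- function(record) {
  p <- record$product
  ord <- canonical_atom_order(p)          # emission order of atom indices
  perm <- integer(p$n); perm[ord] <- seq_len(p$n)
  old_maps <- p$atom$map
  p2 <- mol_permute(p, perm)
  map_translate <- integer(0)
  map_translate[old_maps] <- perm         # old map number -> new map number
  p2$atom$map <- seq_len(p2$n)
  n <- p2$n

  fresh <- n
  seen <- integer(0)
  new_reactants <- lapply(record$reactants, function(r) {
    known <- r$atom$map > 0L & r$atom$map <= length(map_translate) &
      r$atom$map %in% old_maps
    newmap <- integer(r$n)
    newmap[known] <- map_translate[r$atom$map[known]]
    r$atom$map <- newmap
    # fresh numbers for leaving-group atoms, in canonical order
    ordr <- canonical_atom_order(r)
    for (a in ordr) {
      if (r$atom$map[a] == 0L) {
        fresh <<- fresh + 1L
        r$atom$map[a] <- fresh
      }
    }
    seen <<- c(seen, r$atom$map[r$atom$map <= n & r$atom$map > 0L])
    r
  })
  if (anyDuplicated(seen) > 0L)
    stop("internal error: product map number appears in more than one reactant atom")
  missing <- setdiff(seq_len(n), seen)
  if (length(missing) > 0L)
    stop(sprintf("mapping error: product atom map(s) %s missing from reactants",
                 paste(missing, collapse = ", ")))
  record$product <- p2
  record$reactants <- new_reactants
  record$raw <- paste0(
    paste(vapply(new_reactants, mol_to_smiles, character(1)), collapse = "."),
    ">>", mol_to_smiles(p2, canonical = FALSE))
  record
}

#' Canonical reactant-side SMILES of a record
#'
#' Fragments are individually canonicalized, maps stripped, and joined
#' sorted with `"."`; used as the ground-truth string for exact-match
#' evaluation.
#'
#' @param record A `reaction_record`.
#' @param keep_stereo Retain stereochemistry (default TRUE).
#' @return Character scalar.
#' @export
reactants_key <- function(record, keep_stereo = TRUE) {
  frags <- vapply(record$reactants, mol_to_smiles, character(1),
                  keep_stereo = keep_stereo, strip_maps = TRUE)
  paste(sort(frags), collapse = ".")
}

#' Read a reaction CSV file
#'
#' Auto-detects the common layouts: a column named
#' `reactants>reagents>production` holding `A>B>C` strings (reagents are
#' merged into the reactant side when present) or a column `rxn_smiles`
#' holding `A>>C`; an optional `class` column (integer or `"UNK"`) and
#' `id` column are carried through.
#'
#' @param path CSV path (UTF-8, header required).
#' @return List of `reaction_record` objects.
#' @export
read_reactions_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  col <- intersect(c("reactants>reagents>production", "rxn_smiles"), names(df))
  if (length(col) == 0L)
    stop("reaction CSV must contain a 'reactants>reagents>production' or 'rxn_smiles' column")
  col <- col[1]
  cls <- if ("class" %in% names(df)) {
    suppressWarnings(as.integer(ifelse(df$class == "UNK", NA, df$class)))
  } else rep(NA_integer_, nrow(df))
  out <- vector("list", nrow(df))
  for (k in seq_len(nrow(df))) {
    s <- df[[col]][k]
    if (col == "reactants>reagents>production") {
      parts <- strsplit(s, ">", fixed = TRUE)[[1]]
      if (length(parts) == 3L) {
        lhs <- if (nchar(parts[2]) > 0L) paste(parts[1], parts[2], sep = ".") else parts[1]
        s <- paste0(lhs, ">>", parts[3])
      }
    }
    out[[k]] <- parse_reaction(s, class = cls[k])
    if ("id" %in% names(df)) out[[k]]$id <- df$id[k]
  }
  out
}
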