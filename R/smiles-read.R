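# SMILES reader.
#
# Supports the Daylight dialect used in reaction datasets: organic-subset
# atoms, bracket atoms with charge / explicit H / tetrahedral chirality /
# atom maps, aromatic lowercase forms (kekulized on input), ring-closure
# digits including %nn, branches, dot-separated fragments, and directional
# bonds for double-bond cis/trans assignments.  Isotope labels are parsed
# and discarded.

.BRACKET_RE <- "^\\[([0-9]+)?([A-Za-z][a-z]?|\\*)(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\+{2,3}|-{2,3})?(?::([0-9]+))?\\]"
.AROMATIC_TOKENS <- c("b", "c", "n", "o", "p", "s", "se", "as")

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles SMILES text for one molecule (possibly multi-fragment).
#' @param sanitize Validate valences and perceive aromaticity (default TRUE).
#' @return A `molgraph`.
#' @examples
#' m <- mol_from_smiles("[CH3:1][OH:2]")
#' mol_natoms(m)
#' @export
mol_from_smiles <- function(smiles, sanitize = TRUE) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || nchar(smiles) == 0L)
    stop("parse error: SMILES must be a single non-empty string")
  s <- smiles
  mol <- new_molgraph()
  prev <- 0L                      # index of previous atom in chain
  pend_bond <- ""                 # pending explicit bond symbol
  branch <- integer()             # stack of atom indices
  rings <- list()                 # open ring closures: digit -> list(atom, sym, placeholder)
  written <- list()               # per-atom written neighbor order (0 = implicit H slot)
  hbracket <- logical()           # chirality parsed with in-bracket H
  parsed_tag <- integer()         # raw @ (1) / @@ (2) tags in written order
  dirs <- list()                  # directional single bonds: list(a_first, a_second, mark)
  placeholder_count <- 0L

  add_parsed_atom <- function(element, aromatic, charge, nH, tag, map, h_in_bracket) {
    mol <<- mol_add_atom(mol, element, charge = charge,
                         nH = if (is.na(nH)) NA_integer_ else as.integer(nH),
                         aromatic = aromatic, chiral = 0L, map = map)
    a <- mol$n
    written[[a]] <<- integer()
    parsed_tag[a] <<- tag
    hbracket[a] <<- h_in_bracket
    if (prev != 0L) {
      connect(prev, a, pend_bond)
    }
    if (h_in_bracket && tag > 0L) written[[a]] <<- c(written[[a]], 0L)
    prev <<- a
    pend_bond <<- ""
  }

  connect <- function(a, b, sym) {
    order <- switch(sym, "=" = 2L, "#" = 3L, 1L)
    arom_candidate <- sym == "" && mol$atom$aromatic[a] && mol$atom$aromatic[b]
    if (sym == ":") arom_candidate <- TRUE
    mol <<- mol_add_bond(mol, a, b, order = order, aromatic = arom_candidate)
    if (sym %in% c("/", "\\"))
      dirs[[length(dirs) + 1L]] <<- list(first = a, second = b, mark = sym)
    written[[a]] <<- c(written[[a]], b)
    written[[b]] <<- c(written[[b]], a)
  }

  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    rest <- substr(s, i, n)
    if (ch == "[") {
      m <- regmatches(rest, regexec(.BRACKET_RE, rest, perl = TRUE))[[1]]
      if (length(m) == 0L) stop(sprintf("parse error: bad bracket atom at position %d in '%s'", i, s))
      sym <- m[3]
      aromatic <- sym %in% .AROMATIC_TOKENS
      element <- if (sym == "*") "*" else {
        el <- if (aromatic) paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10)) else sym
        el
      }
      tag <- if (m[4] == "") 0L else nchar(m[4])
      nH <- if (m[5] == "") 0L else if (m[5] == "H") 1L else as.integer(substr(m[5], 2, 10))
      charge <- if (m[6] == "") 0L else {
        cs <- m[6]
        if (cs %in% c("+", "-")) as.integer(paste0(cs, "1"))
        else if (grepl("^\\++$", cs)) nchar(cs)
        else if (grepl("^-+$", cs)) -nchar(cs)
        else as.integer(cs)
      }
      map <- if (is.na(m[7]) || m[7] == "") 0L else as.integer(m[7])
      add_parsed_atom(element, aromatic, charge, nH, tag, map, h_in_bracket = nH >= 1L)
      i <- i + attr(regexpr(.BRACKET_RE, rest, perl = TRUE), "match.length")
    } else if (grepl("^[A-Z]", ch)) {
      two <- substr(s, i, i + 1L)
      sym <- if (two %in% .TWO_LETTER_ORGANIC) two else ch
      if (!(sym %in% .ORGANIC_SUBSET))
        stop(sprintf("parse error: unknown atom '%s' at position %d in '%s'", sym, i, s))
      add_parsed_atom(sym, FALSE, 0L, NA_integer_, 0L, 0L, FALSE)
      i <- i + nchar(sym)
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      two <- substr(s, i, i + 1L)
      sym <- if (two %in% c("se", "as")) two else ch
      element <- paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 10))
      add_parsed_atom(element, TRUE, 0L, NA_integer_, 0L, 0L, FALSE)
      i <- i + nchar(sym)
    } else if (ch == "*") {
      add_parsed_atom("*", FALSE, 0L, 0L, 0L, 0L, FALSE)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pend_bond <- ch
      i <- i + 1L
    } else if (ch == "(") {
      branch <- c(branch, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(branch) == 0L) stop(sprintf("parse error: unbalanced ')' in '%s'", s))
      prev <- branch[length(branch)]
      branch <- branch[-length(branch)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- 0L
      pend_bond <- ""
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        digit <- substr(s, i + 1L, i + 2L)
        if (!grepl("^[0-9]{2}$", digit)) stop(sprintf("parse error: bad %%ring closure in '%s'", s))
        i <- i + 3L
      } else {
        digit <- ch
        i <- i + 1L
      }
      if (prev == 0L) stop(sprintf("parse error: ring digit before any atom in '%s'", s))
      key <- paste0("r", digit)
      if (is.null(rings[[key]])) {
        placeholder_count <- placeholder_count + 1L
        pl <- -placeholder_count
        rings[[key]] <- list(atom = prev, sym = pend_bond, placeholder = pl)
        written[[prev]] <- c(written[[prev]], pl)
      } else {
        op <- rings[[key]]
        rings[[key]] <- NULL
        sym <- if (pend_bond != "") pend_bond else op$sym
        a <- op$atom; b <- prev
        if (a == b) stop("parse error: ring closure to same atom")
        order <- switch(sym, "=" = 2L, "#" = 3L, 1L)
        arom_candidate <- (sym == "" && mol$atom$aromatic[a] && mol$atom$aromatic[b]) || sym == ":"
        mol <- mol_add_bond(mol, a, b, order = order, aromatic = arom_candidate)
        if (sym %in% c("/", "\\"))
          dirs[[length(dirs) + 1L]] <- list(first = a, second = b, mark = sym)
        written[[a]][written[[a]] == op$placeholder] <- b
        written[[b]] <- c(written[[b]], a)
      }
      pend_bond <- ""
    } else {
      stop(sprintf("parse error: unexpected character '%s' at position %d in '%s'", ch, i, s))
    }
  }
  if (length(branch) > 0L) stop(sprintf("parse error: unbalanced '(' in '%s'", s))
  if (length(rings) > 0L) stop(sprintf("parse error: unclosed ring bond in '%s'", s))

  # aromatic bonds must lie in rings (a bare bond joining two aromatic rings
  # is a plain single bond)
  if (any(mol$bond$aromatic)) {
    in_ring <- ring_bond_flags(mol)
    mol$bond$aromatic <- mol$bond$aromatic & in_ring
    mol <- kekulize(mol)
  }

  # implicit hydrogens for organic-subset atoms written without brackets
  sums <- atom_bond_order_sums(mol)
  for (a in seq_len(mol$n)) {
    if (!is.na(mol$atom$nH[a])) next
    av <- allowed_valences(mol$atom$element[a], mol$atom$charge[a])
    fit <- av[av >= sums[a]]
    mol$atom$nH[a] <- if (length(fit) == 0L) 0L else as.integer(min(fit) - sums[a])
  }

  # tetrahedral chirality: convert written-order tags to reference-order tags
  for (a in seq_len(mol$n)) {
    if (parsed_tag[a] == 0L) next
    wo <- written[[a]]
    if (!hbracket[a] && length(wo) == 3L && mol$atom$nH[a] == 1L) {
      # implicit-H slot defaults to just after the preceding atom
      wo <- if (length(wo) >= 1L) c(wo[1L], 0L, wo[-1L]) else c(0L, wo)
    }
    if (length(wo) != 4L) next   # non-tetrahedral annotation: ignored
    ref <- chiral_reference(mol, a)
    if (length(ref) != 4L || !setequal(ref, wo)) next
    tag <- parsed_tag[a]
    if (ordering_parity(wo, ref) == 1L) tag <- flip_tag(tag)
    mol$atom$chiral[a] <- tag
  }

  # double-bond stereo from directional single bonds
  mol <- .assign_bond_stereo(mol, dirs)

  if (sanitize) mol <- mol_sanitize(mol) else mol <- perceive_aromaticity(mol)
  mol
}

# v-value of a directional mark relative to (substituent, double-bond atom)
# orientation: '/' written substituent-first is +1.
.dir_value <- function(entry, sub, dbl) {
  v <- if (entry$mark == "/") 1L else -1L
  if (entry$first == dbl) v <- -v
  v
}

.assign_bond_stereo <- function(mol, dirs) {
  if (length(dirs) == 0L) return(mol)
  adj <- mol_adjacency(mol)
  for (b in seq_along(mol$bond$i)) {
    if (mol$bond$order[b] != 2L || mol$bond$aromatic[b]) next
    i <- mol$bond$i[b]; j <- mol$bond$j[b]
    side <- function(dbl, other) {
      subs <- setdiff(adj[[dbl]], other)
      if (length(subs) == 0L) return(NULL)
      ref <- min(subs)
      for (entry in dirs) {
        k <- if (entry$first == dbl) entry$second else if (entry$second == dbl) entry$first else 0L
        if (k != 0L && k %in% subs) {
          v <- .dir_value(entry, sub = k, dbl = dbl)
          return(v * (if (k == ref) 1L else -1L))
        }
      }
      NULL
    }
    vi <- side(i, j); vj <- side(j, i)
    if (!is.null(vi) && !is.null(vj))
      mol$bond$stereo[b] <- if (vi * vj > 0L) 1L else 2L
  }
  mol
}
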