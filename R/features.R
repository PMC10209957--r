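# Atom and bond featurization for the graph encoder.
#
# Standard D-MPNN-style input features: concatenated one-hot blocks plus
# binary flags.  The blocks are configuration-driven so dimensions can be
# changed without touching code; out-of-vocabulary elements map to a
# dedicated "other" slot and out-of-range ordinal values are clamped to
# the nearest block edge, so featurization never throws.

#' Default featurization configuration
#'
#' @return A list with the element vocabulary and ordinal ranges used to
#'   build atom and bond feature vectors, plus the derived dimensions
#'   `d_atom` and `d_bond`.
#' @export
default_feature_config <- function() {
  cfg <- list(
    elements = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B",
                 "Si", "Se", "Sn", "Mg", "Zn", "Cu", "Fe", "Mn", "Al",
                 "K", "Na", "Ca", "Li", "H", "*"),
    degrees = 0:5,
    charges = -2:2,
    chirals = 0:2,
    hydrogens = 0:4,
    bond_types = 1:4,     # single, double, triple, aromatic
    stereos = 0:2
  )
  cfg$d_atom <- length(cfg$elements) + 1L + length(cfg$degrees) +
    length(cfg$charges) + length(cfg$chirals) + length(cfg$hydrogens) + 1L
  cfg$d_bond <- length(cfg$bond_types) + 1L + 1L + length(cfg$stereos)
  cfg
}

.onehot <- function(value, levels) {
  v <- numeric(length(levels))
  idx <- match(value, levels)
  if (is.na(idx)) idx <- if (value < levels[1]) 1L else length(levels)
  v[idx] <- 1
  v
}

# conjugation: part of an alternating/aromatic pi system
.bond_conjugated <- function(mol, b, adj) {
  if (mol$bond$aromatic[b]) return(TRUE)
  i <- mol$bond$i[b]; j <- mol$bond$j[b]
  has_pi <- function(a, excl) {
    any(vapply(setdiff(adj[[a]], excl), function(x) {
      bb <- bond_index(mol, a, x)
      mol$bond$order[bb] >= 2L || mol$bond$aromatic[bb]
    }, logical(1)))
  }
  if (mol$bond$order[b] >= 2L) return(has_pi(i, j) || has_pi(j, i))
  has_pi(i, j) && has_pi(j, i)
}

#' Featurize a molecular graph
#'
#' @param mol A sanitized `molgraph`.
#' @param config Featurization configuration (see
#'   [default_feature_config()]).
#' @return List with `atom` (n_atoms x d_atom matrix) and `bond`
#'   (n_bonds x d_bond matrix); deterministic given the graph.
#' @export
featurize_mol <- function(mol, config = default_feature_config()) {
  # stereo descriptors are map-anchored so the features do not depend on
  # the storage order of atoms
  n <- mol$n
  adj <- mol_adjacency(mol)
  ringb <- ring_bond_flags(mol)
  A <- matrix(0, nrow = n, ncol = config$d_atom)
  for (a in seq_len(n)) {
    el <- mol$atom$element[a]
    elv <- numeric(length(config$elements) + 1L)
    idx <- match(el, config$elements)
    elv[if (is.na(idx)) length(elv) else idx] <- 1
    A[a, ] <- c(elv,
                .onehot(length(adj[[a]]), config$degrees),
                .onehot(mol$atom$charge[a], config$charges),
                .onehot(map_anchored_tag(mol, a, adj), config$chirals),
                .onehot(mol$atom$nH[a], config$hydrogens),
                as.numeric(mol$atom$aromatic[a]))
  }
  m <- length(mol$bond$i)
  B <- matrix(0, nrow = m, ncol = config$d_bond)
  for (b in seq_len(m)) {
    btype <- if (mol$bond$aromatic[b]) 4L else mol$bond$order[b]
    B[b, ] <- c(.onehot(btype, config$bond_types),
                as.numeric(.bond_conjugated(mol, b, adj)),
                as.numeric(ringb[b]),
                .onehot(map_anchored_bond_stereo(mol, b, adj), config$stereos))
  }
  list(atom = A, bond = B)
}
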