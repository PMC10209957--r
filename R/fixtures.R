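# Synthetic atom-mapped reaction generator.
#
# Each template builds a randomized product molecule and derives the
# reactant side by applying a known retro edit sequence with the same
# engine used at inference time (or, for the pure stereo templates, by
# a direct descriptor flip).  Products are assembled from SMILES
# skeletons whose reactive sites are marked with atom-map numbers; after
# parsing, all atoms are renumbered 1..n so the marked sites become
# ordinary mapped atoms.  Every candidate is validated end-to-end
# (canonicalize, extract, replay) and resampled on failure, so the
# returned set is fully applicable by construction.
#
# The defaults (template mix, substituent and leaving-group pools) are
# the study conditions used by the examples, tests and acceptance runs.

.FIXTURE_SUBS <- c("", "C", "CC", "OC", "F", "C(C)C", "CO", "C(F)(F)F")
.FIXTURE_LGS1 <- c("*Br", "*Cl", "*I", "*O", "*OC", "*OCC", "*B(O)O",
                   "*N(C)C", "*OC(C)=O", "*C(=O)O")
.FIXTURE_LG_PHTH <- "*C(=O)c1ccccc1C(*)=O"

.brch <- function(s) if (nzchar(s)) paste0("(", s, ")") else ""

# parse a marker skeleton and renumber atoms 1..n; returns mol + the new
# map numbers of the marked sites (marker k -> element k of `site`)
.parse_skeleton <- function(smi, n_markers) {
  mol <- mol_from_smiles(smi)
  idx <- vapply(seq_len(n_markers), function(k) atom_by_map(mol, k), integer(1))
  mol$atom$map <- seq_len(mol$n)
  list(mol = mol, site = idx)
}

.pick <- function(pool) pool[[sample.int(length(pool), 1L)]]

# each template returns list(product = molgraph, reactant = molgraph
# [multi-fragment, mapped], class = integer)
.fixture_templates <- list(
  # 1: single-site functionalization (AttachLG on a CH2/CH3/aromatic CH)
  attach = function() {
    sk <- .pick(list(
      sprintf("c1ccc%scc1[CH2:1]C%s", .brch(.pick(.FIXTURE_SUBS)), .brch(.pick(.FIXTURE_SUBS))),
      sprintf("C%s[CH2:1]CC%s", .brch(.pick(.FIXTURE_SUBS)), .brch(.pick(.FIXTURE_SUBS))),
      sprintf("c1ccnc%sc1[CH2:1]%s", .brch(.pick(.FIXTURE_SUBS)), .pick(c("C", "CC", "CO")))))
    ps <- .parse_skeleton(sk, 1L)
    lg <- .pick(.FIXTURE_LGS1)
    res <- apply_edit_sequence(ps$mol, list(
      edit_attach_lg(ps$site[1], lg), edit_terminate()))
    list(product = ps$mol, reactant = res$reactants, class = 1L)
  },
  # 2: amine deprotection with a two-point leaving group (pin + double attach)
  deprotect = function() {
    sk <- .pick(list(
      sprintf("c1ccc%scc1C[CH2:2][NH2:1]", .brch(.pick(.FIXTURE_SUBS))),
      sprintf("C%sCC[CH2:2][NH2:1]", .brch(.pick(.FIXTURE_SUBS)))))
    ps <- .parse_skeleton(sk, 2L)
    res <- apply_edit_sequence(ps$mol, list(
      edit_change_atom(ps$site[1], 0L, 0L),
      edit_attach_lg(ps$site[1], .FIXTURE_LG_PHTH),
      edit_terminate()))
    list(product = ps$mol, reactant = res$reactants, class = 2L)
  },
  # 3: bond disconnection into two coupling partners
  coupling = function() {
    sk <- .pick(list(
      sprintf("C%s[CH2:1][c:2]1ccc%scc1", .brch(.pick(.FIXTURE_SUBS)), .brch(.pick(.FIXTURE_SUBS))),
      sprintf("[c:1]1ccc%scc1[c:2]2ccc%scc2", .brch(.pick(c("C", "OC", "F"))),
              .brch(.pick(c("", "C")))),
      sprintf("C%sC[CH2:1][NH:2]C%s", .brch(.pick(.FIXTURE_SUBS)), .brch(.pick(.FIXTURE_SUBS)))))
    ps <- .parse_skeleton(sk, 2L)
    lg_a <- .pick(c("*Br", "*I", "*B(O)O"))
    lg_b <- .pick(c("*Br", "*B(O)O", "*O"))
    res <- apply_edit_sequence(ps$mol, list(
      edit_delete_bond(ps$site[1], ps$site[2]),
      edit_attach_lg(ps$site[1], lg_a),
      edit_attach_lg(ps$site[2], lg_b),
      edit_terminate()))
    list(product = ps$mol, reactant = res$reactants, class = 3L)
  },
  # 4: hydrogen-count change only (synthetic deprotonation-like ChangeAtom)
  hcount = function() {
    sk <- .pick(list(
      sprintf("C%sC[CH2:2][NH2:1]", .brch(.pick(.FIXTURE_SUBS))),
      sprintf("c1ccc%scc1[CH2:2][OH:1]", .brch(.pick(.FIXTURE_SUBS)))))
    ps <- .parse_skeleton(sk, 2L)
    rx <- ps$mol
    rx$atom$nH[ps$site[1]] <- rx$atom$nH[ps$site[1]] - 1L
    list(product = ps$mol, reactant = rx, class = 4L)
  },
  # 5: carbonyl reduction plus a second-site functionalization
  reduction = function() {
    sk <- .pick(list(
      sprintf("C%sC[CH:1]([OH:2])C[CH2:3]C", .brch(.pick(.FIXTURE_SUBS))),
      sprintf("c1ccc%scc1[CH:1]([OH:2])[CH2:3]C", .brch(.pick(.FIXTURE_SUBS))),
      sprintf("C%sC([CH2:3]C)C[CH2:1][OH:2]", .brch(.pick(.FIXTURE_SUBS)))))
    ps <- .parse_skeleton(sk, 3L)
    res <- apply_edit_sequence(ps$mol, list(
      edit_change_bond(ps$site[1], ps$site[2], 2L, 0L),
      edit_attach_lg(ps$site[3], .pick(c("*Br", "*Cl", "*OC"))),
      edit_terminate()))
    list(product = ps$mol, reactant = res$reactants, class = 5L)
  },
  # 6: multi-center ring opening, always 7 edits
  # (2 deletes + 3 bond changes + 2 attachments)
  ringopen = function() {
    sk <- sprintf("%s[N:1]1[CH2:2][C:3](=[C:4]([CH2:6][OH:7])[CH2:5]1)[CH2:8][OH:9]",
                  .pick(c("C", "CC", "CCC", "CC(C)")))
    ps <- .parse_skeleton(sk, 9L)
    res <- apply_edit_sequence(ps$mol, list(
      edit_delete_bond(ps$site[1], ps$site[2]),
      edit_delete_bond(ps$site[1], ps$site[5]),
      edit_change_bond(ps$site[3], ps$site[4], 1L, 0L),
      edit_change_bond(ps$site[6], ps$site[7], 2L, 0L),
      edit_change_bond(ps$site[8], ps$site[9], 2L, 0L),
      edit_attach_lg(ps$site[2], "*=O"),
      edit_attach_lg(ps$site[5], "*=O"),
      edit_terminate()))
    list(product = ps$mol, reactant = res$reactants, class = 6L)
  },
  # 7: stereochemistry change only (chirality inversion or cis/trans flip)
  stereo = function() {
    if (sample.int(2L, 1L) == 1L) {
      sk <- sprintf("N[C@@H:1](C%s)C(=O)O%s", .brch(.pick(c("", "C", "O"))),
                    .pick(c("", "C")))
      ps <- .parse_skeleton(sk, 1L)
      rx <- ps$mol
      a <- ps$site[1]
      rx$atom$chiral[a] <- flip_tag(rx$atom$chiral[a])
      list(product = ps$mol, reactant = rx, class = 7L)
    } else {
      sk <- sprintf("C%s/[CH:1]=[CH:2]/C%s", .brch(.pick(c("", "C"))),
                    .brch(.pick(c("", "C", "O"))))
      ps <- .parse_skeleton(sk, 2L)
      rx <- ps$mol
      b <- bond_index(rx, atom_by_map(rx, ps$site[1]), atom_by_map(rx, ps$site[2]))
      rx$bond$stereo[b] <- if (rx$bond$stereo[b] == 1L) 2L else 1L
      list(product = ps$mol, reactant = rx, class = 7L)
    }
  }
)

#' Default template mix of the reaction generator
#' @return Named numeric vector of sampling weights.
#' @export
default_template_mix <- function() {
  c(attach = 0.25, deprotect = 0.10, coupling = 0.20, hcount = 0.05,
    reduction = 0.15, ringopen = 0.15, stereo = 0.10)
}

#' Generate synthetic atom-mapped reactions
#'
#' Draws reactions from seven template families: single-site
#' functionalization, two-point deprotection, coupling disconnection,
#' hydrogen-count change, carbonyl reduction with a second
#' functionalization, multi-center ring opening (always 7 edits), and
#' stereochemistry change.
#' Every returned record is validated: it canonicalizes, its edit
#' sequence extracts, and replay reproduces the reactants exactly;
#' invalid draws are resampled.
#'
#' @param n Number of reactions.
#' @param seed Integer seed (`< 2^31`); the full set is a deterministic
#'   function of `n`, `seed` and `template_mix`.
#' @param template_mix Named sampling weights over template families
#'   (default [default_template_mix()]).
#' @return List of `reaction_record` objects, each with `$class` set to
#'   its template family index and `$template` to its name.
#' @examples
#' recs <- generate_reactions(5, seed = 1)
#' recs[[1]]
#' @export
generate_reactions <- function(n, seed, template_mix = default_template_mix()) {
  stopifnot(n >= 1L, seed == as.integer(seed))
  bad <- setdiff(names(template_mix), names(.fixture_templates))
  if (length(bad) > 0L)
    stop(sprintf("unknown template name(s): %s", paste(bad, collapse = ", ")))
  set.seed(as.integer(seed))
  out <- vector("list", n)
  for (k in seq_len(n)) {
    for (attempt in seq_len(60L)) {
      rec <- tryCatch({
        tname <- sample(names(template_mix), 1L, prob = template_mix)
        draw <- .fixture_templates[[tname]]()
        rs <- paste(vapply(mol_split(draw$reactant), mol_to_smiles, character(1)),
                    collapse = ".")
        rec <- parse_reaction(paste0(rs, ">>", mol_to_smiles(draw$product, canonical = FALSE)),
                              class = draw$class)
        rec <- canonicalize_reaction(rec)
        rec$edits <- extract_edits(rec)
        rec$template <- tname
        rec
      }, error = function(e) NULL)
      if (!is.null(rec)) break
    }
    if (is.null(rec))
      stop(sprintf("fixture generation failed repeatedly at record %d", k))
    out[[k]] <- rec
  }
  out
}

#' Write reactions to CSV / read them back
#'
#' The CSV has columns `id`, `class` and `rxn_smiles` and is readable by
#' [read_reactions_csv()].
#'
#' @param records List of `reaction_record`.
#' @param path Output path.
#' @export
write_reactions_csv <- function(records, path) {
  df <- data.frame(
    id = vapply(seq_along(records), function(k) {
      if (!is.null(records[[k]]$id)) as.character(records[[k]]$id) else sprintf("rx%05d", k)
    }, character(1)),
    class = vapply(records, function(r) {
      if (is.null(r$class) || is.na(r$class)) "UNK" else as.character(r$class)
    }, character(1)),
    rxn_smiles = vapply(records, function(r) r$raw, character(1)),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Similarity-aware train/validation/test split
#'
#' Randomly splits records, then moves every validation/test record whose
#' product has fingerprint Tanimoto similarity above `sigma` to any
#' training product into the training split, so held-out products are
#' structurally dissimilar from training at level `sigma`.
#'
#' @param records List of `reaction_record`.
#' @param fractions Numeric length-3 `(train, val, test)` summing to 1.
#' @param sigma Similarity threshold in `(0, 1]`; lower values move more
#'   records into training.
#' @param seed Integer seed for the initial random split.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
tanimoto_split <- function(records, fractions = c(0.8, 0.1, 0.1),
                           sigma = 0.6, seed = 1L) {
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8)
  n <- length(records)
  set.seed(as.integer(seed))
  idx <- sample.int(n)
  n_tr <- round(fractions[1] * n); n_va <- round(fractions[2] * n)
  train <- idx[seq_len(n_tr)]
  val <- idx[n_tr + seq_len(n_va)]
  test <- idx[setdiff(seq_len(n), seq_len(n_tr + n_va))]
  fps <- lapply(records, function(r) mol_fingerprint(r$product))
  move <- function(held) {
    keep <- logical(length(held))
    for (k in seq_along(held)) {
      sims <- vapply(train, function(t) tanimoto(fps[[held[k]]], fps[[t]]), numeric(1))
      keep[k] <- length(sims) == 0L || max(sims) <= sigma
    }
    train <<- c(train, held[!keep])
    held[keep]
  }
  val <- move(val)
  test <- move(test)
  list(train = sort(train), val = sort(val), test = sort(test))
}
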