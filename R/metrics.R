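# Evaluation metrics: top-k exact match, largest-fragment accuracy,
# circular fingerprints, Tanimoto similarity and prediction diversity.

#' Circular (ECFP4-style) fingerprint of a molecule
#'
#' Hand-rolled 2048-bit circular fingerprint of radius 2: atom
#' environments start from (element, degree, charge, H count,
#' aromaticity, ring membership) invariants and are iteratively combined
#' with sorted (bond type, neighbor environment) lists; every
#' environment of radius 0..2 sets one folded bit.  Fragments of a
#' multi-fragment graph contribute to the same bit vector (environments
#' never cross fragments).
#'
#' @param mol A `molgraph`.
#' @param nbits Number of bits (default 2048).
#' @param radius Environment radius (default 2).
#' @return Logical vector of length `nbits`.
#' @export
mol_fingerprint <- function(mol, nbits = 2048L, radius = 2L) {
  n <- mol$n
  bits <- logical(nbits)
  if (n == 0L) return(bits)
  adj <- mol_adjacency(mol)
  ringb <- ring_bond_flags(mol)
  in_ring <- logical(n)
  if (length(ringb) > 0L) {
    in_ring[mol$bond$i[ringb]] <- TRUE; in_ring[mol$bond$j[ringb]] <- TRUE
  }
  hash_str <- function(s) {
    h <- 17
    for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
    h
  }
  env <- vapply(seq_len(n), function(a) hash_str(paste(
    mol$atom$element[a], length(adj[[a]]), mol$atom$charge[a],
    mol$atom$nH[a], mol$atom$aromatic[a], in_ring[a], sep = "|")), numeric(1))
  set_bit <- function(h) bits[(h %% nbits) + 1L] <<- TRUE
  for (h in env) set_bit(h)
  for (r in seq_len(radius)) {
    env2 <- numeric(n)
    for (a in seq_len(n)) {
      nb <- adj[[a]]
      parts <- sort(vapply(nb, function(x) {
        b <- bond_index(mol, a, x)
        bt <- if (mol$bond$aromatic[b]) 4L else mol$bond$order[b]
        sprintf("%d:%.0f", bt, env[x])
      }, character(1)))
      env2[a] <- hash_str(paste(r, env[a], paste(parts, collapse = ","), sep = ";"))
    }
    env <- env2
    for (h in env) set_bit(h)
  }
  bits
}

#' Tanimoto similarity of two bit vectors
#' @param a,b Logical vectors of equal length.
#' @return Numeric in `[0, 1]` (1 when both are empty).
#' @export
tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

.truth_key <- function(record) reactants_key(record, keep_stereo = TRUE)

#' Top-k exact-match accuracy
#'
#' A prediction hits at k when the ground-truth reactant set (canonical,
#' stereochemistry retained, fragments sorted) appears among the k
#' best-ranked predicted reactant sets.
#'
#' @param predictions List of beam-result data frames (from
#'   [predict.retroedits_model()]), aligned with `records`.
#' @param records The corresponding `reaction_record`s.
#' @param ks Integer vector of cutoffs.
#' @return Named numeric vector of accuracies.
#' @export
topk_exact_match <- function(predictions, records, ks = c(1L, 3L, 5L, 10L)) {
  stopifnot(length(predictions) == length(records))
  truth <- vapply(records, .truth_key, character(1))
  hit_rank <- vapply(seq_along(records), function(i) {
    r <- match(truth[i], predictions[[i]]$reactants)
    if (is.na(r)) Inf else r
  }, numeric(1))
  vapply(stats::setNames(ks, paste0("top", ks)),
         function(k) mean(hit_rank <= k), numeric(1))
}

# largest fragment of a multi-fragment SMILES by heavy-atom count,
# ties by lexicographic canonical SMILES
.max_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  heavy <- vapply(frags, function(s) {
    m <- mol_from_smiles(s)
    sum(m$atom$element != "H")
  }, numeric(1))
  frags <- sort(frags[heavy == max(heavy)])
  frags[1]
}

#' Top-k largest-fragment (MaxFrag) accuracy
#'
#' Exact match restricted to the largest reactant fragment, crediting
#' predictions that recover the main precursor while differing in small
#' leaving groups.  Never below [topk_exact_match()] at the same k.
#'
#' @inheritParams topk_exact_match
#' @return Named numeric vector of accuracies.
#' @export
maxfrag_accuracy <- function(predictions, records, ks = c(1L, 3L, 5L, 10L)) {
  stopifnot(length(predictions) == length(records))
  truth <- vapply(records, function(r) .max_fragment(.truth_key(r)), character(1))
  hit_rank <- vapply(seq_along(records), function(i) {
    preds <- predictions[[i]]$reactants
    if (length(preds) == 0L) return(Inf)
    mf <- vapply(preds, .max_fragment, character(1))
    r <- match(truth[i], mf)
    if (is.na(r)) Inf else r
  }, numeric(1))
  vapply(stats::setNames(ks, paste0("top", ks)),
         function(k) mean(hit_rank <= k), numeric(1))
}

#' Diversity of predicted reactant sets
#'
#' For each product with at least two predictions, the mean pairwise
#' Tanimoto similarity between the fingerprints of its predicted
#' reactant sets; lower values mean more diverse suggestions.
#'
#' @param predictions List of beam-result data frames.
#' @param nbits,radius Fingerprint settings (see [mol_fingerprint()]).
#' @return List with `mean_similarity` (average over products) and
#'   `per_product` (numeric vector, NA where fewer than 2 predictions).
#' @export
prediction_diversity <- function(predictions, nbits = 2048L, radius = 2L) {
  per <- vapply(predictions, function(df) {
    if (nrow(df) < 2L) return(NA_real_)
    fps <- lapply(df$reactants, function(s)
      mol_fingerprint(mol_from_smiles(s), nbits, radius))
    sims <- numeric(0)
    for (i in seq_len(length(fps) - 1L))
      for (j in seq(i + 1L, length(fps)))
        sims <- c(sims, tanimoto(fps[[i]], fps[[j]]))
    mean(sims)
  }, numeric(1))
  list(mean_similarity = mean(per, na.rm = TRUE), per_product = per)
}

#' Distribution of edit-sequence lengths
#'
#' @param records Preprocessed records with `$edits`.
#' @param include_terminate Count the trailing Terminate (default FALSE).
#' @return A table of sequence lengths.
#' @export
edit_length_distribution <- function(records, include_terminate = FALSE) {
  lens <- vapply(records, function(r) {
    if (is.null(r$edits)) return(NA_integer_)
    length(r$edits) - if (include_terminate) 0L else 1L
  }, integer(1))
  table(lens, useNA = "no")
}
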