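# Beam-search decoding of edit sequences for a product molecule.
#
# Each step, every live hypothesis proposes its k most probable edits;
# of the at most k^2 resulting candidates the global top k by cumulative
# log-probability survive.  Edits whose application fails chemistry
# sanitization are dropped without renormalizing the remaining mass, so
# scores stay comparable across branches.  Hypotheses that emit
# Terminate are carried frozen in the beam and compete by score; at
# max_steps everything still unterminated is discarded.  Final ranking
# is by cumulative log-probability, ties broken by shorter sequence and
# then lexicographically on the chosen candidate indices; duplicate
# reactant sets keep their best-scoring hypothesis.

#' Beam-search retrosynthesis prediction for one product
#'
#' @param model A fitted `retroedits_model`.
#' @param product A `molgraph` or product SMILES; atoms without map
#'   numbers are mapped 1..n automatically.
#' @param k Beam width (default 10).
#' @param max_steps Maximum number of edit steps (default 9).
#' @return A data frame with columns `rank`, `reactants` (canonical
#'   dot-joined SMILES), `score` (cumulative log-probability), `n_edits`,
#'   and a list column `edits`; zero rows (with a warning) when no
#'   hypothesis terminates.
#' @export
beam_search <- function(model, product, k = 10L, max_steps = 9L) {
  stopifnot(k >= 1L, max_steps >= 1L)
  if (is.character(product)) product <- mol_from_smiles(product)
  if (any(product$atom$map == 0L)) product$atom$map <- seq_len(product$n)

  hyps <- list(list(mol = product, edits = list(), idxseq = integer(0),
                    logp = 0, terminated = FALSE, prev = NULL, prev_maps = NULL))
  done <- list()
  for (step in seq_len(max_steps)) {
    cand <- list()
    for (hy in hyps) {
      if (hy$terminated) { cand[[length(cand) + 1L]] <- hy; next }
      si <- .step_inputs(hy$mol, model)
      prev_row <- if (is.null(hy$prev)) integer(si$n)
                  else match(si$maps, hy$prev_maps, nomatch = 0L)
      fwd <- .score_forward(si, hy$prev, prev_row, model$params, model$config)
      top <- order(-fwd$probs)[seq_len(min(k, length(fwd$probs)))]
      for (ix in top) {
        ed <- .edit_from_candidate(si, model$vocab, ix)
        lp <- hy$logp + log(fwd$probs[ix])
        if (ed$type == "Terminate") {
          cand[[length(cand) + 1L]] <- list(
            mol = hy$mol, edits = c(hy$edits, list(ed)),
            idxseq = c(hy$idxseq, ix), logp = lp, terminated = TRUE,
            prev = NULL, prev_maps = NULL)
          next
        }
        g2 <- tryCatch(apply_edit(hy$mol, ed), error = function(e) NULL)
        if (is.null(g2)) next                 # dropped, no renormalization
        cand[[length(cand) + 1L]] <- list(
          mol = g2, edits = c(hy$edits, list(ed)),
          idxseq = c(hy$idxseq, ix), logp = lp, terminated = FALSE,
          prev = fwd$fused, prev_maps = si$maps)
      }
    }
    if (length(cand) == 0L) break
    cand <- cand[.rank_hypotheses(cand)]
    hyps <- cand[seq_len(min(k, length(cand)))]
    if (all(vapply(hyps, `[[`, logical(1), "terminated"))) break
  }
  done <- hyps[vapply(hyps, `[[`, logical(1), "terminated")]
  if (length(done) == 0L) {
    warning("beam search: no hypothesis terminated")
    return(data.frame(rank = integer(), reactants = character(),
                      score = numeric(), n_edits = integer()))
  }
  done <- done[.rank_hypotheses(done)]
  keys <- vapply(done, function(h) .reactant_key_mol(h$mol), character(1))
  keep <- !duplicated(keys)
  done <- done[keep]; keys <- keys[keep]
  out <- data.frame(rank = seq_along(done), reactants = keys,
                    score = vapply(done, `[[`, numeric(1), "logp"),
                    n_edits = vapply(done, function(h) length(h$edits), integer(1)),
                    stringsAsFactors = FALSE)
  out$edits <- lapply(done, `[[`, "edits")
  out
}

# deterministic ranking: score desc, then fewer edits, then candidate
# index sequence lexicographically
.rank_hypotheses <- function(hyps) {
  lens <- vapply(hyps, function(h) length(h$idxseq), integer(1))
  lex <- vapply(hyps, function(h) paste(formatC(h$idxseq, width = 9L, flag = "0"),
                                        collapse = ","), character(1))
  order(-vapply(hyps, `[[`, numeric(1), "logp"), lens, lex)
}

#' Predict reactant sets for new products
#'
#' Runs [beam_search()] on each product.
#'
#' @param object A fitted `retroedits_model`.
#' @param newdata A list of `molgraph`/`reaction_record` objects or a
#'   character vector of product SMILES.
#' @param k Beam width.
#' @param max_steps Maximum edit steps.
#' @param ... Unused.
#' @return A list (one element per product) of beam-result data frames.
#' @export
predict.retroedits_model <- function(object, newdata, k = 10L, max_steps = 9L, ...) {
  if (is.character(newdata)) newdata <- as.list(newdata)
  if (inherits(newdata, c("molgraph", "reaction_record"))) newdata <- list(newdata)
  lapply(newdata, function(x) {
    if (inherits(x, "reaction_record")) x <- x$product
    beam_search(object, x, k = k, max_steps = max_steps)
  })
}
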