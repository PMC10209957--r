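---
title: "Single-step retrosynthesis by autoregressive graph editing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-step retrosynthesis by autoregressive graph editing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroedits)
```

## The problem

Single-step retrosynthesis asks: given a product molecule, which reactant
molecules could have produced it in one reaction?  `retroedits` takes the
semi-template view: instead of translating SMILES strings or retrieving a
reaction template, the model predicts a short **sequence of graph edits**
that transforms the product graph into the reactant graphs.  Because each
edit is a chemically meaningful local operation, the predicted route is
interpretable and the output is a valid molecular graph by construction
at every intermediate step.

Five edit types are enough to express single-step transformations on
atom-mapped reactions:

* `DeleteBond(u, v)` — remove the bond between mapped atoms u and v,
  returning the freed valence to implicit hydrogens;
* `ChangeBond(u, v, order, stereo)` — change a bond's order and/or
  cis/trans annotation;
* `ChangeAtom(u, Δstereo, ΔH)` — change an atom's chiral tag and/or
  implicit hydrogen count;
* `AttachLG(u, lg)` — graft a leaving group (a dummy-rooted fragment
  from a learned vocabulary) onto atom u;
* `Terminate` — declare the current graph to be the reactants.

## Ground-truth extraction

`extract_edits()` diffs an atom-mapped reaction.  Bonds present in the
product but absent in the reactants become `DeleteBond`; bonds whose
kekulized order or anchored cis/trans annotation differs become
`ChangeBond` (a bond aromatic on both sides is treated as unchanged);
reactant atoms that are unmapped or mapped beyond the product are grouped
into connected leaving-group components, each contributing one
`AttachLG` at its unique product-side anchor.  `ChangeAtom` edits are
derived *by simulation*: the bond/attach edits are replayed on the
product and a `ChangeAtom` is emitted only where the simulated hydrogen
count or chiral tag still disagrees with the reactant.  This yields
minimal sequences and guarantees, by a final replay check, that applying
the extracted sequence reproduces the reactant graphs exactly.  Reactions
that form bonds, or whose leaving group touches several product atoms,
are rejected as unextractable rather than silently approximated.

Edits are ordered deterministically: deletions, then bond changes, then
atom changes, then attachments, then `Terminate`, with site-sorted order
within each class.  The model therefore learns a canonical serialization
of each reaction's edit set.

## Model

### Encoder

The encoder is a directed-edge message passing network.  Each directed
bond (i→j) carries a hidden state initialized from the atom and bond
features, `h_ij = W_in [x_i ∥ x_ij]`.  At each of `depth` iterations the
incoming messages *excluding the reverse edge* are summed,
`m_ij = Σ_{k∈N(i)\j} h_ki`, and the state is updated by a single GRU cell
shared across depths, with `h⁰ + m` as input.  Excluding the reverse edge
is what makes the network *directed*: information cannot bounce straight
back along the bond it arrived on.  Atom representations are read out as
`ReLU(W_out [x_i ∥ Σ_j h_ji])`.  A plain MPNN variant (`variant =
"mpnn"`) reuses the same code path with atoms as the message-passing
units and the adjacency matrix as both message and aggregation operator;
it serves as an ablation baseline.

Both the structural directionality (the message operator has exact zeros
at reverse-edge positions) and permutation equivariance (relabelling
atoms permutes the rows of the output and changes nothing else) are
enforced by tests on random graphs, not assumed.

### Autoregressive decoder

At step *t* the current intermediate graph is encoded, and each atom's
representation is fused with its representation from the previous step's
intermediate (zero for step 1 and for atoms introduced by an attachment):
`h = ReLU(prev W_v + enc W_c)`.  Bond features are concatenations of the
two endpoint atom vectors (smaller map number first); a graph-level
feature is the column sum of the atom matrix.  Three two-layer scoring
heads produce a logit for every (bond, bond-edit-type), every (atom,
atom-edit-type), and for `Terminate`, and a **single joint softmax** over
the concatenation gives one distribution over all applicable edits.
Training minimizes the teacher-forced negative log-likelihood of the
extracted sequences with Adam, global gradient-norm clipping, and a
plateau learning-rate schedule.

One deliberate simplification: the previous-step atom representations
enter the fusion as constants — gradients are not propagated backwards
across decoding steps.  This bounds memory, keeps each step's gradient
exactly verifiable against finite differences, and in practice does not
prevent memorization-level fits (see the overfit acceptance test).

### Beam-search decoding

`predict()` / `beam_search()` decode with a width-`k` beam: each live
hypothesis proposes its `k` best edits, the pooled candidates are cut
back to `k`, and hypotheses that emit `Terminate` are frozen.  Edits
whose application fails chemistry checks (valence, missing sites) are
dropped *without renormalizing* the step distribution, so scores remain
true joint log-probabilities.  Final hypotheses are ranked by score with
deterministic tie-breaking and deduplicated by their canonical reactant
SMILES.  A brute-force enumeration oracle in the test suite certifies
that the beam recovers the exact top-k on small problems.

## Synthetic reaction generator

Real reaction corpora cannot ship inside the package, so the test and
demonstration data come from `generate_reactions()`: a seeded generator
of atom-mapped reactions built from seven template families (leaving-group
attachment, deprotection, two-fragment coupling, H-count change,
reduction, ring opening with a seven-edit script, and stereochemistry
flips), each instantiated over randomized skeletons and substituent
pools.  The defaults — family mix, substituent pools, size ranges — are
study conditions, fixed before any evaluation.  Every generated record is
validated by canonicalize → extract → replay; the generator resamples on
failure, and the test suite checks that extraction applicability on
generated sets is exactly 1.

Limitations worth knowing: the generator's chemistry is plausible but
synthetic (the H-count family in particular exists to exercise
`ChangeAtom`-only sequences, not to model a real transformation), and
difficulty is far below real corpora — it measures correctness of the
machinery, not chemical generalization.

## Numerical choices

Everything is base R plus `Matrix` sparse operators; no deep-learning
runtime is involved.  Gradients are hand-derived and verified against
central finite differences parameter-by-parameter.  Determinism comes
from a single seeded RNG stream per fit and seed-threaded generators;
checkpoints serialize to JSON (text only) and refuse to load against a
mismatched edit-vocabulary hash.

Other limitations: stereocenter perception is local (a carbon with four
distinct neighbor *elements* by map anchor, not full CIP), so
pseudo-stereocenters can carry tags a chemist would drop; canonical
SMILES output prefers the aromatic form; and only single-product,
atom-mapped reactions are supported.
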