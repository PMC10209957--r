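# Autoregressive edit policy: per-step scoring heads over the encoder,
# teacher-forced sequence loss, and the model-fitting front end.
#
# At each step the current intermediate graph is encoded, fused with the
# previous step's atom representations (zero rows for atoms that did not
# exist then, and all zeros at the first step), and scored by three
# two-layer heads: one logit per (bond x bond payload), one per
# (atom x atom payload), and a single terminate logit from the summed
# graph representation.  A single softmax over the concatenation gives
# the step distribution; training minimizes its cross-entropy against
# the ground-truth edit, feeding the ground-truth intermediate to the
# next step (teacher forcing).  Gradients do not flow through the
# previous step's representations.

#' Model configuration
#'
#' @param hidden Encoder hidden width.
#' @param depth Message-passing depth.
#' @param dropout Dropout on atom embeddings during training.
#' @param head_hidden Hidden width of the scoring heads.
#' @param head_dropout Dropout inside the heads during training.
#' @param variant Encoder variant, `"dmpnn"` or `"mpnn"`.
#' @param lr Initial Adam learning rate.
#' @param epochs Maximum training epochs.
#' @param batch_size Reactions per gradient step.
#' @param lr_factor,lr_patience,lr_threshold Plateau schedule: multiply
#'   the rate by `lr_factor` when validation accuracy has not improved
#'   by more than `lr_threshold` for `lr_patience` epochs.
#' @param clip Global gradient-norm clip.
#' @param val_fraction Fraction of records held out for validation when
#'   no explicit validation set is supplied.
#' @param seed Integer seed governing initialization, the train/val
#'   split, batch order and dropout.
#' @return Named list of settings.
#' @export
retroedits_config <- function(hidden = 256L, depth = 10L, dropout = 0.15,
                              head_hidden = 512L, head_dropout = 0.2,
                              variant = c("dmpnn", "mpnn"), lr = 0.001,
                              epochs = 150L, batch_size = 32L,
                              lr_factor = 0.8, lr_patience = 5L,
                              lr_threshold = 0.01, clip = 10,
                              val_fraction = 0.1, seed = 1L) {
  list(hidden = as.integer(hidden), depth = as.integer(depth),
       dropout = dropout, head_hidden = as.integer(head_hidden),
       head_dropout = head_dropout, variant = match.arg(variant),
       lr = lr, epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
       lr_threshold = lr_threshold, clip = clip,
       val_fraction = val_fraction, seed = as.integer(seed))
}

#' Construct an untrained model
#'
#' @param vocab An `edit_vocab`.
#' @param config See [retroedits_config()].
#' @param feature_config See [default_feature_config()].
#' @return A `retroedits_model` with freshly initialized parameters.
#' @export
retroedits_new <- function(vocab, config = retroedits_config(),
                           feature_config = default_feature_config()) {
  set.seed(config$seed)
  h <- config$hidden; H <- config$head_hidden
  enc <- encoder_init(feature_config$d_atom, feature_config$d_bond,
                      hidden = h, depth = config$depth,
                      variant = config$variant, seed = NULL)
  Pb <- nrow(vocab$bond); Pa <- nrow(vocab$atom)
  heads <- list(
    W_v = .glorot(h, h), W_c = .glorot(h, h),
    W_b = .glorot(2L * h, H), c_b = numeric(H), U_b = .glorot(H, max(Pb, 1L)),
    W_a = .glorot(h, H), c_a = numeric(H), U_a = .glorot(H, max(Pa, 1L)),
    W_g = .glorot(h, H), c_g = numeric(H), u_g = .glorot(H, 1L)
  )
  structure(list(params = list(enc = enc, heads = heads), vocab = vocab,
                 vocab_hash = vocab_hash(vocab), config = config,
                 feature_config = feature_config, history = NULL),
            class = "retroedits_model")
}

## ---- step state preparation --------------------------------------------------

# Static per-graph scoring inputs: encoder structure, bond endpoint order
# (smaller map number first) and the atom maps, plus candidate counts.
.step_inputs <- function(mol, model) {
  feat <- featurize_mol(mol, model$feature_config)
  struct <- encoder_structure(mol, feat, model$config$variant)
  nb <- length(mol$bond$i)
  maps <- mol$atom$map
  swap <- nb > 0L & maps[mol$bond$i] > maps[mol$bond$j]
  u <- ifelse(swap, mol$bond$j, mol$bond$i)
  v <- ifelse(swap, mol$bond$i, mol$bond$j)
  list(struct = struct, n = mol$n, nb = nb, u = u, v = v, maps = maps,
       Pb = nrow(model$vocab$bond), Pa = nrow(model$vocab$atom))
}

# Candidate index of an edit in the joint logit vector, or 0 if absent.
.edit_candidate_index <- function(si, vocab, edit) {
  key <- edit_payload_key(edit)
  n_bond_cand <- si$nb * si$Pb
  if (edit$type == "Terminate") return(n_bond_cand + si$n * si$Pa + 1L)
  if (edit_kind(key) == "bond") {
    p <- match(key, vocab$bond$key)
    mu <- min(edit$site); mv <- max(edit$site)
    k <- which((si$maps[si$u] == mu & si$maps[si$v] == mv) |
               (si$maps[si$u] == mv & si$maps[si$v] == mu))
    if (is.na(p) || length(k) != 1L) return(0L)
    return((k - 1L) * si$Pb + p)
  }
  p <- match(key, vocab$atom$key)
  a <- which(si$maps == edit$site)
  if (is.na(p) || length(a) != 1L) return(0L)
  n_bond_cand + (a - 1L) * si$Pa + p
}

# Decode a candidate index back to a sited edit.
.edit_from_candidate <- function(si, vocab, idx) {
  n_bond_cand <- si$nb * si$Pb
  if (idx <= n_bond_cand) {
    k <- (idx - 1L) %/% si$Pb + 1L
    p <- (idx - 1L) %% si$Pb + 1L
    return(edit_from_key(vocab$bond$key[p],
                         site = c(si$maps[si$u[k]], si$maps[si$v[k]])))
  }
  idx <- idx - n_bond_cand
  n_atom_cand <- si$n * si$Pa
  if (idx <= n_atom_cand) {
    a <- (idx - 1L) %/% si$Pa + 1L
    p <- (idx - 1L) %% si$Pa + 1L
    return(edit_from_key(vocab$atom$key[p], site = si$maps[a]))
  }
  edit_terminate()
}

# Teacher-forcing plan of one record: per-step inputs, label index, and
# the row alignment of each step's atoms into the previous step's state.
prepare_record <- function(record, model) {
  if (is.null(record$edits))
    stop(sprintf("data error: record %s has no extracted edit sequence",
                 if (!is.null(record$id)) record$id else "<unnamed>"))
  res <- apply_edit_sequence(record$product, record$edits)
  steps <- vector("list", length(record$edits))
  prev_maps <- NULL
  for (t in seq_along(record$edits)) {
    g <- if (t == 1L) record$product else res$graphs[[t - 1L]]
    si <- .step_inputs(g, model)
    lab <- .edit_candidate_index(si, model$vocab, record$edits[[t]])
    if (lab == 0L)
      stop(sprintf("data error: edit '%s' of record %s not representable (site or payload missing)",
                   format(record$edits[[t]]),
                   if (!is.null(record$id)) record$id else "<unnamed>"))
    prev_row <- if (t == 1L) integer(si$n) else match(si$maps, prev_maps, nomatch = 0L)
    steps[[t]] <- list(si = si, label = lab, prev_row = prev_row,
                       n_cand = si$nb * si$Pb + si$n * si$Pa + 1L)
    prev_maps <- si$maps
  }
  steps
}

## ---- scoring forward / backward ----------------------------------------------

.softmax <- function(x) { e <- exp(x - max(x)); e / sum(e) }

# forward score of one step; prev = fused atom states of the previous
# step (rows aligned via prev_row; 0 = new atom -> zero row)
.score_forward <- function(si, prev, prev_row, params, config,
                           training = FALSE, keep_cache = FALSE) {
  hd <- params$heads
  drop_e <- if (training) config$dropout else 0
  drop_h <- if (training) config$head_dropout else 0
  fw <- encode_graph(si$struct, params$enc, dropout = drop_e,
                     keep_cache = keep_cache)
  h <- config$hidden
  prev_al <- matrix(0, si$n, h)
  has_prev <- which(prev_row > 0L)
  if (length(has_prev) > 0L && !is.null(prev))
    prev_al[has_prev, ] <- prev[prev_row[has_prev], , drop = FALSE]
  fuse_pre <- prev_al %*% hd$W_v + fw$atom %*% hd$W_c
  fused <- pmax(fuse_pre, 0)
  dmask <- function(mat) {
    if (drop_h > 0) matrix(stats::runif(length(mat)) >= drop_h, nrow(mat)) / (1 - drop_h)
    else NULL
  }
  if (si$nb > 0L) {
    B <- cbind(fused[si$u, , drop = FALSE], fused[si$v, , drop = FALSE])
    Hb_pre <- sweep(B %*% hd$W_b, 2L, hd$c_b, "+")
    Hb <- pmax(Hb_pre, 0); mb <- dmask(Hb); if (!is.null(mb)) Hb <- Hb * mb
    Lb <- Hb %*% hd$U_b
  } else { B <- NULL; Hb_pre <- NULL; Hb <- NULL; mb <- NULL
           Lb <- matrix(0, 0L, max(si$Pb, 1L)) }
  Ha_pre <- sweep(fused %*% hd$W_a, 2L, hd$c_a, "+")
  Ha <- pmax(Ha_pre, 0); ma <- dmask(Ha); if (!is.null(ma)) Ha <- Ha * ma
  La <- Ha %*% hd$U_a
  hg <- matrix(colSums(fused), 1L)
  Hg_pre <- sweep(hg %*% hd$W_g, 2L, hd$c_g, "+")
  Hg <- pmax(Hg_pre, 0); mg <- dmask(Hg); if (!is.null(mg)) Hg <- Hg * mg
  lg <- as.numeric(Hg %*% hd$u_g)
  logits <- c(if (si$nb > 0L && si$Pb > 0L) as.vector(t(Lb)) else numeric(0),
              if (si$Pa > 0L) as.vector(t(La)) else numeric(0),
              lg)
  out <- list(logits = logits, probs = .softmax(logits), fused = fused)
  if (keep_cache)
    out$cache <- list(fw = fw, prev_al = prev_al, fuse_pre = fuse_pre,
                      fused = fused, B = B, Hb_pre = Hb_pre, Hb = Hb, mb = mb,
                      Ha_pre = Ha_pre, Ha = Ha, ma = ma, hg = hg,
                      Hg_pre = Hg_pre, Hg = Hg, mg = mg, si = si)
  out
}

# backward: d(loss)/d(logits) -> parameter gradients (accumulated into `grad`)
.score_backward <- function(dlogits, cache, params, grad) {
  hd <- params$heads; si <- cache$si
  h <- ncol(cache$fused)
  nbc <- si$nb * si$Pb
  d_fused <- matrix(0, si$n, h)
  if (si$nb > 0L && si$Pb > 0L) {
    dLb <- matrix(dlogits[seq_len(nbc)], nrow = si$nb, byrow = TRUE)
    dHb <- dLb %*% t(hd$U_b)
    grad$heads$U_b <- grad$heads$U_b + t(cache$Hb) %*% dLb
    if (!is.null(cache$mb)) dHb <- dHb * cache$mb
    dHb_pre <- dHb * (cache$Hb_pre > 0)
    grad$heads$W_b <- grad$heads$W_b + t(cache$B) %*% dHb_pre
    grad$heads$c_b <- grad$heads$c_b + colSums(dHb_pre)
    dB <- dHb_pre %*% t(hd$W_b)
    for (k in seq_len(si$nb)) {
      d_fused[si$u[k], ] <- d_fused[si$u[k], ] + dB[k, seq_len(h)]
      d_fused[si$v[k], ] <- d_fused[si$v[k], ] + dB[k, h + seq_len(h)]
    }
  }
  if (si$Pa > 0L) {
    dLa <- matrix(dlogits[nbc + seq_len(si$n * si$Pa)], nrow = si$n, byrow = TRUE)
    dHa <- dLa %*% t(hd$U_a)
    grad$heads$U_a <- grad$heads$U_a + t(cache$Ha) %*% dLa
    if (!is.null(cache$ma)) dHa <- dHa * cache$ma
    dHa_pre <- dHa * (cache$Ha_pre > 0)
    grad$heads$W_a <- grad$heads$W_a + t(cache$fused) %*% dHa_pre
    grad$heads$c_a <- grad$heads$c_a + colSums(dHa_pre)
    d_fused <- d_fused + dHa_pre %*% t(hd$W_a)
  }
  dlg <- dlogits[length(dlogits)]
  dHg <- dlg * t(hd$u_g)
  grad$heads$u_g <- grad$heads$u_g + t(cache$Hg) * dlg
  if (!is.null(cache$mg)) dHg <- dHg * cache$mg
  dHg_pre <- dHg * (cache$Hg_pre > 0)
  grad$heads$W_g <- grad$heads$W_g + t(cache$hg) %*% dHg_pre
  grad$heads$c_g <- grad$heads$c_g + colSums(dHg_pre)
  d_hg <- dHg_pre %*% t(hd$W_g)
  d_fused <- d_fused + matrix(d_hg, si$n, h, byrow = TRUE)
  d_fuse_pre <- d_fused * (cache$fuse_pre > 0)
  grad$heads$W_v <- grad$heads$W_v + t(cache$prev_al) %*% d_fuse_pre
  grad$heads$W_c <- grad$heads$W_c + t(cache$fw$atom) %*% d_fuse_pre
  d_enc <- d_fuse_pre %*% t(hd$W_c)
  grad$enc <- encode_backward(d_enc, cache$fw, params$enc, grad$enc)
  grad
}

#' Score the next edit for an intermediate graph
#'
#' Evaluates the policy on one step: joint probabilities over every
#' (bond, bond payload) pair, every (atom, atom payload) pair, and
#' Terminate.
#'
#' @param model A `retroedits_model`.
#' @param mol Current intermediate `molgraph` (atoms must carry maps).
#' @param prev Optional previous-step atom state matrix (from a prior
#'   call's `$fused`), with `prev_maps` giving the map number of each of
#'   its rows; omit at the first step.
#' @param prev_maps Integer vector of map numbers aligned to `prev` rows.
#' @return List with `logits`, `probs` (sums to 1), `fused` (atom states
#'   to feed the next step), and `candidates` (list of sited `mol_edit`
#'   objects aligned to `probs`).
#' @export
policy_score <- function(model, mol, prev = NULL, prev_maps = NULL) {
  if (isTRUE(attr(mol, "terminated")))
    stop("contract error: cannot score a terminated state")
  si <- .step_inputs(mol, model)
  prev_row <- if (is.null(prev)) integer(si$n) else match(si$maps, prev_maps, nomatch = 0L)
  out <- .score_forward(si, prev, prev_row, model$params, model$config)
  out$candidates <- lapply(seq_along(out$probs), function(ix)
    .edit_from_candidate(si, model$vocab, ix))
  out$maps <- si$maps
  out
}

## ---- loss and training -------------------------------------------------------

.zero_like <- function(p) lapply(p, function(x) if (is.list(x)) .zero_like(x) else x * 0)

# teacher-forced loss over prepared records; optionally gradients and
# per-step argmax accuracy
.batch_loss <- function(prepared, params, config, training = FALSE,
                        compute_grad = FALSE) {
  grad <- if (compute_grad) .zero_like(params) else NULL
  total <- 0; nstep <- 0L; ncorrect <- 0L
  for (steps in prepared) {
    prev <- NULL
    for (st in steps) {
      fwd <- .score_forward(st$si, prev, st$prev_row, params, config,
                            training = training, keep_cache = compute_grad)
      pr <- fwd$probs[st$label]
      total <- total - log(max(pr, 1e-300))
      nstep <- nstep + 1L
      if (which.max(fwd$probs) == st$label) ncorrect <- ncorrect + 1L
      if (compute_grad) {
        dlog <- fwd$probs; dlog[st$label] <- dlog[st$label] - 1
        grad <- .score_backward(dlog, fwd$cache, params, grad)
      }
      prev <- fwd$fused                      # detached: constants next step
    }
  }
  nrec <- max(length(prepared), 1L)
  if (compute_grad && nrec > 1L) grad <- .scale_params(grad, 1 / nrec)
  list(loss = total / nrec, grad = grad,
       steps = nstep, accuracy = ncorrect / max(nstep, 1L))
}

#' Teacher-forced sequence loss
#'
#' Mean over records of the summed per-step cross-entropy of the
#' ground-truth edit under the joint softmax, with ground-truth
#' intermediates fed forward.
#'
#' @param model A `retroedits_model`.
#' @param records Preprocessed `reaction_record`s with `$edits`.
#' @return Scalar loss with attribute `accuracy` (per-step argmax
#'   accuracy).
#' @export
sequence_loss <- function(model, records) {
  prepared <- lapply(records, prepare_record, model = model)
  r <- .batch_loss(prepared, model$params, model$config)
  structure(r$loss, accuracy = r$accuracy)
}

.flatten_params <- function(p) unlist(p, use.names = FALSE)

.gradient_norm <- function(g) sqrt(sum(.flatten_params(g)^2))

.scale_params <- function(g, s) lapply(g, function(x) if (is.list(x)) .scale_params(x, s) else x * s)

.adam_step <- function(params, grad, state, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    for (nm in names(p)) {
      if (is.list(p[[nm]])) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      } else {
        m[[nm]] <- 0.9 * m[[nm]] + 0.1 * g[[nm]]
        v[[nm]] <- 0.999 * v[[nm]] + 0.001 * g[[nm]]^2
        mhat <- m[[nm]] / (1 - b1^state$t)
        vhat <- v[[nm]] / (1 - b2^state$t)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    list(p = p, m = m, v = v)
  }
  r <- walk(params, grad, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(params = r$p, state = state)
}

#' Fit the retrosynthesis edit model
#'
#' Trains the graph encoder and edit-scoring heads by teacher forcing on
#' reactions with extracted edit sequences, using Adam with gradient
#' clipping and a reduce-on-plateau learning-rate schedule monitored on
#' teacher-forced validation step accuracy.  The best-validation
#' parameters are retained.
#'
#' @param records Preprocessed training records (see
#'   [preprocess_reactions()]); records whose sequence is missing or not
#'   representable under the vocabulary are dropped with a warning.
#' @param vocab Optional `edit_vocab`; built from `records` when NULL.
#' @param config See [retroedits_config()].
#' @param val_records Optional explicit validation records; otherwise a
#'   seeded `val_fraction` of `records` is held out (none when
#'   `val_fraction = 0`, in which case training accuracy is monitored).
#' @param feature_config See [default_feature_config()].
#' @param verbose Print one line per epoch.
#' @return A fitted `retroedits_model`; see [predict.retroedits_model()]
#'   for decoding.
#' @export
retroedits_fit <- function(records, vocab = NULL, config = retroedits_config(),
                           val_records = NULL,
                           feature_config = default_feature_config(),
                           verbose = TRUE) {
  if (length(records) == 0L) stop("empty dataset")
  if (is.null(vocab)) vocab <- build_edit_vocab(records)
  model <- retroedits_new(vocab, config, feature_config)

  if (is.null(val_records) && config$val_fraction > 0) {
    n_val <- max(1L, round(config$val_fraction * length(records)))
    vi <- sample.int(length(records), n_val)
    val_records <- records[vi]
    records <- records[-vi]
  }
  prep <- function(recs, label) {
    out <- list()
    for (k in seq_along(recs)) {
      p <- tryCatch(prepare_record(recs[[k]], model), error = function(e) e)
      if (inherits(p, "error")) warning(sprintf("dropping %s record %d: %s",
                                                label, k, conditionMessage(p)))
      else out[[length(out) + 1L]] <- p
    }
    out
  }
  train_prep <- prep(records, "training")
  val_prep <- if (!is.null(val_records)) prep(val_records, "validation") else NULL
  if (length(train_prep) == 0L) stop("empty dataset after preparation")

  params <- model$params
  adam <- list(m = .zero_like(params), v = .zero_like(params), t = 0L)
  lr <- config$lr
  best_acc <- -Inf; best_params <- params; stall <- 0L
  hist <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(train_prep))
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, length(ord), by = config$batch_size)) {
      batch <- train_prep[ord[start:min(start + config$batch_size - 1L, length(ord))]]
      r <- .batch_loss(batch, params, config, training = TRUE, compute_grad = TRUE)
      if (!is.finite(r$loss))
        stop(sprintf("NaN/Inf loss at epoch %d (batch starting %d); aborting", epoch, start))
      gn <- .gradient_norm(r$grad)
      g <- if (gn > config$clip) .scale_params(r$grad, config$clip / gn) else r$grad
      upd <- .adam_step(params, g, adam, lr)
      params <- upd$params; adam <- upd$state
      ep_loss <- ep_loss + r$loss * length(batch); nb <- nb + length(batch)
    }
    ep_loss <- ep_loss / nb
    vr <- .batch_loss(if (is.null(val_prep)) train_prep else val_prep, params, config)
    hist[[epoch]] <- data.frame(epoch = epoch, loss = ep_loss,
                                val_accuracy = vr$accuracy,
                                val_loss = vr$loss, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val_acc %.4f  val_loss %.4f  lr %.5f",
                      epoch, ep_loss, vr$accuracy, vr$loss, lr))
    if (vr$accuracy > best_acc) { best_params <- params; }
    if (vr$accuracy > best_acc + config$lr_threshold) {
      best_acc <- max(best_acc, vr$accuracy); stall <- 0L
    } else {
      best_acc <- max(best_acc, vr$accuracy)
      stall <- stall + 1L
      if (stall >= config$lr_patience) { lr <- lr * config$lr_factor; stall <- 0L }
    }
  }
  model$params <- best_params
  model$history <- do.call(rbind, hist)
  model$n_train <- length(train_prep)
  model$n_val <- if (is.null(val_prep)) 0L else length(val_prep)
  model$best_val_accuracy <- best_acc
  model
}

## ---- S3 methods --------------------------------------------------------------

#' @export
print.retroedits_model <- function(x, ...) {
  cat("Retrosynthesis edit model\n")
  cat(sprintf("  encoder: %s, hidden %d, depth %d\n", x$config$variant,
              x$config$hidden, x$config$depth))
  cat(sprintf("  vocabulary: %d bond + %d atom payloads + Terminate\n",
              nrow(x$vocab$bond), nrow(x$vocab$atom)))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs on %d records (best val step-accuracy %.3f)\n",
                nrow(x$history), x$n_train, x$best_val_accuracy))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
summary.retroedits_model <- function(object, ...) {
  np <- length(.flatten_params(object$params))
  out <- list(config = object$config, n_parameters = np,
              vocab_bond = nrow(object$vocab$bond),
              vocab_atom = nrow(object$vocab$atom),
              history = object$history,
              best_val_accuracy = object$best_val_accuracy)
  class(out) <- "summary.retroedits_model"
  out
}

#' @export
print.summary.retroedits_model <- function(x, ...) {
  cat(sprintf("Retrosynthesis edit model: %d parameters (%s, hidden %d, depth %d)\n",
              x$n_parameters, x$config$variant, x$config$hidden, x$config$depth))
  cat(sprintf("Vocabulary: %d bond + %d atom payloads + Terminate\n",
              x$vocab_bond, x$vocab_atom))
  if (!is.null(x$history)) {
    cat(sprintf("Training: %d epochs, final loss %.4f, best val step-accuracy %.3f\n",
                nrow(x$history), x$history$loss[nrow(x$history)],
                x$best_val_accuracy))
    tail_n <- min(5L, nrow(x$history))
    print(utils::tail(x$history, tail_n), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.retroedits_model <- function(object, ...) object$params

#' Save / load a fitted model
#'
#' Text (JSON) checkpoint with parameters, configuration, vocabulary and
#' the vocabulary hash; loading refuses a checkpoint whose vocabulary
#' hash does not match its stored vocabulary.
#'
#' @param model A `retroedits_model`.
#' @param path File path.
#' @export
save_retroedits <- function(model, path) {
  ser <- function(p) lapply(p, function(x) {
    if (is.list(x)) ser(x)
    else if (is.matrix(x)) list(dim = dim(x), data = as.numeric(x))
    else list(dim = NULL, data = as.numeric(x))
  })
  obj <- list(params = ser(model$params), config = model$config,
              feature_config = model$feature_config,
              vocab = list(bond = model$vocab$bond, atom = model$vocab$atom),
              vocab_hash = model$vocab_hash)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_retroedits
#' @export
load_retroedits <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  deser <- function(p) lapply(p, function(x) {
    if (!is.null(x$data) || (is.list(x) && all(c("dim", "data") %in% names(x)))) {
      if (length(x$dim) == 2L) matrix(x$data, x$dim[1], x$dim[2]) else as.numeric(x$data)
    } else deser(x)
  })
  vocab <- structure(list(bond = obj$vocab$bond, atom = obj$vocab$atom),
                     class = "edit_vocab")
  if (!identical(vocab_hash(vocab), obj$vocab_hash))
    stop("checkpoint refused: vocabulary hash mismatch")
  cfg <- obj$config
  params <- deser(obj$params)
  enc <- params$enc
  attr(enc, "hidden") <- cfg$hidden; attr(enc, "depth") <- cfg$depth
  attr(enc, "variant") <- cfg$variant
  attr(enc, "d_atom") <- obj$feature_config$d_atom
  attr(enc, "d_bond") <- obj$feature_config$d_bond
  params$enc <- enc
  structure(list(params = params, vocab = vocab, vocab_hash = obj$vocab_hash,
                 config = cfg, feature_config = obj$feature_config,
                 history = NULL),
            class = "retroedits_model")
}
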