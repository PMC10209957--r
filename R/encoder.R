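# Directed-edge message-passing graph encoder with a hand-written
# backward pass.
#
# The default variant passes hidden states along directed bond edges:
# the incoming message for edge i->j sums the states of edges k->i with
# k != j, so information never flows straight back along the reverse
# edge.  Updates use a single GRU cell shared across depth, fed the
# initial edge state plus the message, with the previous layer as the
# cell state; per-atom outputs aggregate the incoming edge states
# through one dense ReLU layer.
#
# The plain node-message variant ("mpnn") reuses the same code path: its
# "edges" are the atoms themselves and its message structure is the
# neighbor adjacency, messages summing over all neighbors.
#
# All linear maps act on the right (rows = edges/atoms), so a forward is
# a short chain of dense products plus one sparse aggregation; caches
# hold every intermediate needed for the exact gradient.

.runif_mat <- function(nr, nc, limit) {
  matrix(stats::runif(nr * nc, -limit, limit), nr, nc)
}

.glorot <- function(nr, nc) .runif_mat(nr, nc, sqrt(6 / (nr + nc)))

#' Initialize encoder parameters
#'
#' @param d_atom,d_bond Input feature dimensions.
#' @param hidden Hidden width (default 256).
#' @param depth Number of message-passing iterations (default 10).
#' @param variant `"dmpnn"` (directed edge messages, default) or
#'   `"mpnn"` (node messages over all neighbors).
#' @param seed Integer seed for the uniform Glorot initialization, or
#'   NULL to draw from the current RNG state.
#' @return Named list of weight matrices/vectors with attributes
#'   `hidden`, `depth`, `variant`, `d_atom`, `d_bond`.
#' @export
encoder_init <- function(d_atom, d_bond, hidden = 256L, depth = 10L,
                         variant = c("dmpnn", "mpnn"), seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(depth >= 1L, hidden >= 1L)
  if (!is.null(seed)) set.seed(as.integer(seed))
  h <- hidden
  p <- list(
    W_in = .glorot(d_atom + d_bond, h),
    Wr = .glorot(h, h), Ur = .glorot(h, h), br = numeric(h),
    Wz = .glorot(h, h), Uz = .glorot(h, h), bz = numeric(h),
    Wn = .glorot(h, h), Un = .glorot(h, h), bn = numeric(h),
    W_out = .glorot(d_atom + h, h), c_out = numeric(h)
  )
  attr(p, "hidden") <- h; attr(p, "depth") <- as.integer(depth)
  attr(p, "variant") <- variant
  attr(p, "d_atom") <- d_atom; attr(p, "d_bond") <- d_bond
  p
}

# Precompute the message-passing structure of one graph: the input
# feature matrix of the "edge" units, the sparse message matrix M
# (unit e receives sum over units f with M[e, f] = 1) and the sparse
# atom-aggregation matrix A (atom i sums units f with A[i, f] = 1).
encoder_structure <- function(mol, feat, variant = "dmpnn") {
  n <- mol$n
  nb <- length(mol$bond$i)
  if (variant == "dmpnn") {
    m <- 2L * nb
    # directed edge 2b-1 = i->j, 2b = j->i
    src <- integer(m); dst <- integer(m)
    if (nb > 0L) {
      src[seq(1L, m, 2L)] <- mol$bond$i; dst[seq(1L, m, 2L)] <- mol$bond$j
      src[seq(2L, m, 2L)] <- mol$bond$j; dst[seq(2L, m, 2L)] <- mol$bond$i
    }
    X <- if (m > 0L) cbind(feat$atom[src, , drop = FALSE],
                           feat$bond[rep(seq_len(nb), each = 2L), , drop = FALSE])
         else matrix(0, 0L, ncol(feat$atom) + ncol(feat$bond))
    # message: edge e=(i->j) sums edges f=(k->i), k != j, i.e. incoming
    # to src[e] except the reverse of e
    mi <- integer(0); mj <- integer(0)
    if (m > 0L) {
      by_dst <- split(seq_len(m), dst)
      rev_of <- ifelse(seq_len(m) %% 2L == 1L, seq_len(m) + 1L, seq_len(m) - 1L)
      for (e in seq_len(m)) {
        inc <- by_dst[[as.character(src[e])]]
        inc <- inc[inc != rev_of[e]]
        mi <- c(mi, rep(e, length(inc))); mj <- c(mj, inc)
      }
    }
    M <- Matrix::sparseMatrix(i = mi, j = mj, x = 1, dims = c(m, m))
    # atom readout sums incoming edges j->i
    A <- Matrix::sparseMatrix(i = dst, j = seq_len(m), x = rep(1, m), dims = c(n, m))
  } else {
    # node variant: units are the atoms, messages over all neighbors
    X <- cbind(feat$atom, matrix(0, n, ncol(feat$bond)))
    ii <- c(mol$bond$i, mol$bond$j); jj <- c(mol$bond$j, mol$bond$i)
    M <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)), dims = c(n, n))
    A <- M
  }
  list(X = X, M = M, A = A, atom_x = feat$atom, n = n)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# rows-as-units GRU cell shared across layers
.gru_forward <- function(x, h_prev, p) {
  r <- .sigmoid(sweep(x %*% p$Wr + h_prev %*% p$Ur, 2L, p$br, "+"))
  z <- .sigmoid(sweep(x %*% p$Wz + h_prev %*% p$Uz, 2L, p$bz, "+"))
  hn_lin <- sweep(h_prev %*% p$Un, 2L, p$bn, "+")
  nst <- tanh(x %*% p$Wn + r * hn_lin)
  h <- (1 - z) * nst + z * h_prev
  list(h = h, r = r, z = z, nst = nst, hn_lin = hn_lin, x = x, h_prev = h_prev)
}

.gru_backward <- function(dh, cache, p, grad) {
  r <- cache$r; z <- cache$z; nst <- cache$nst
  dz <- dh * (cache$h_prev - nst)
  dn <- dh * (1 - z)
  dh_prev <- dh * z
  dn_pre <- dn * (1 - nst^2)                       # through tanh
  dx <- dn_pre %*% t(p$Wn)
  grad$Wn <- grad$Wn + t(cache$x) %*% dn_pre
  dr <- dn_pre * cache$hn_lin
  d_hn_lin <- dn_pre * r
  grad$Un <- grad$Un + t(cache$h_prev) %*% d_hn_lin
  grad$bn <- grad$bn + colSums(d_hn_lin)
  dh_prev <- dh_prev + d_hn_lin %*% t(p$Un)
  dz_pre <- dz * z * (1 - z)
  dx <- dx + dz_pre %*% t(p$Wz)
  dh_prev <- dh_prev + dz_pre %*% t(p$Uz)
  grad$Wz <- grad$Wz + t(cache$x) %*% dz_pre
  grad$Uz <- grad$Uz + t(cache$h_prev) %*% dz_pre
  grad$bz <- grad$bz + colSums(dz_pre)
  dr_pre <- dr * r * (1 - r)
  dx <- dx + dr_pre %*% t(p$Wr)
  dh_prev <- dh_prev + dr_pre %*% t(p$Ur)
  grad$Wr <- grad$Wr + t(cache$x) %*% dr_pre
  grad$Ur <- grad$Ur + t(cache$h_prev) %*% dr_pre
  grad$br <- grad$br + colSums(dr_pre)
  list(dx = dx, dh_prev = dh_prev, grad = grad)
}

#' Encode a featurized graph into per-atom hidden states
#'
#' @param struct Precomputed structure from `encoder_structure()`.
#' @param params Encoder parameters from [encoder_init()].
#' @param dropout Dropout probability applied to the final atom
#'   embeddings; use 0 for deterministic evaluation.
#' @return List with `atom` (n x hidden matrix) and, when
#'   `keep_cache = TRUE`, the forward cache for `encode_backward()`.
#' @param keep_cache Retain intermediates for the backward pass.
#' @export
encode_graph <- function(struct, params, dropout = 0, keep_cache = FALSE) {
  depth <- attr(params, "depth")
  h0 <- struct$X %*% params$W_in
  h <- h0
  caches <- if (keep_cache) vector("list", depth) else NULL
  for (l in seq_len(depth)) {
    msg <- as.matrix(struct$M %*% h)
    st <- .gru_forward(h0 + msg, h, params)
    if (keep_cache) caches[[l]] <- st
    h <- st$h
  }
  agg <- as.matrix(struct$A %*% h)
  pre <- sweep(cbind(struct$atom_x, agg) %*% params$W_out, 2L, params$c_out, "+")
  atom <- pmax(pre, 0)
  mask <- NULL
  if (dropout > 0) {
    mask <- matrix(stats::runif(length(atom)) >= dropout, nrow(atom)) / (1 - dropout)
    atom <- atom * mask
  }
  out <- list(atom = atom)
  if (keep_cache)
    out$cache <- list(h0 = h0, hL = h, caches = caches, agg = agg, pre = pre,
                      mask = mask, struct = struct)
  out
}

# Gradient of a scalar loss w.r.t. encoder parameters given d(loss)/d(atom
# states); returns a named gradient list congruent with `params`.
encode_backward <- function(d_atom, fw, params, grad = NULL) {
  cache <- fw$cache
  if (is.null(grad)) grad <- lapply(params, function(w) w * 0)
  if (!is.null(cache$mask)) d_atom <- d_atom * cache$mask
  d_pre <- d_atom * (cache$pre > 0)
  inp <- cbind(cache$struct$atom_x, cache$agg)
  grad$W_out <- grad$W_out + t(inp) %*% d_pre
  grad$c_out <- grad$c_out + colSums(d_pre)
  d_inp <- d_pre %*% t(params$W_out)
  da <- ncol(cache$struct$atom_x)
  d_agg <- d_inp[, (da + 1L):ncol(d_inp), drop = FALSE]
  dh <- as.matrix(Matrix::t(cache$struct$A) %*% d_agg)
  dh0 <- matrix(0, nrow(cache$h0), ncol(cache$h0))
  for (l in rev(seq_along(cache$caches))) {
    bk <- .gru_backward(dh, cache$caches[[l]], params, grad)
    grad <- bk$grad
    dh0 <- dh0 + bk$dx                       # x = h0 + msg: h0 part
    dmsg <- bk$dx
    dh <- bk$dh_prev + as.matrix(Matrix::t(cache$struct$M) %*% dmsg)
  }
  dh0 <- dh0 + dh                            # layer-0 state is h0 itself
  grad$W_in <- grad$W_in + t(cache$struct$X) %*% dh0
  grad
}
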