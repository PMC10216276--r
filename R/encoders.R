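# The two classical trunk branches and their gradients.
#
# Cell branch : 735-dim binary mutation vector -> three (conv1d -> ReLU ->
#               max-pool) blocks -> flatten -> dense -> 128-dim embedding.
# Drug branch : molecular graph -> three symmetric-normalized graph
#               convolutions (78 -> 78 -> 156 -> 312, ReLU each) -> global
#               max pool over nodes -> dense 312->1024 (ReLU) -> dense
#               1024->128 -> 128-dim embedding.
#
# Backpropagation is written out explicitly (conv via im2col, pooling via
# stored argmax) so the whole model trains without an autograd framework.

CELL_INPUT_LEN <- 735L
EMBED_DIM <- 128L

glorot <- function(rng, n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(rng$runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# ---- 1-D convolution building blocks ------------------------------------

# x: L x C_in signal. W: (kernel * C_in) x C_out with column layout
# (k, c) -> k + kernel*(c-1). Valid convolution, stride 1.
im2col <- function(x, kernel) {
  L_out <- nrow(x) - kernel + 1L
  C_in <- ncol(x)
  xc <- matrix(0, L_out, kernel * C_in)
  for (k in seq_len(kernel)) {
    xc[, seq(k, kernel * C_in, by = kernel)] <-
      x[k:(k + L_out - 1L), , drop = FALSE]
  }
  xc
}

conv1d_forward <- function(x, W, b, kernel) {
  xc <- im2col(x, kernel)
  out <- sweep(xc %*% W, 2L, b, "+")
  list(out = out, xc = xc, L_in = nrow(x), C_in = ncol(x))
}

conv1d_backward <- function(cache, W, kernel, dout) {
  dW <- crossprod(cache$xc, dout)
  db <- colSums(dout)
  dxc <- dout %*% t(W)
  dx <- matrix(0, cache$L_in, cache$C_in)
  L_out <- nrow(dout)
  for (k in seq_len(kernel)) {
    rows <- k:(k + L_out - 1L)
    dx[rows, ] <- dx[rows, ] +
      dxc[, seq(k, kernel * cache$C_in, by = kernel), drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

# Non-overlapping max pooling along the length axis; remainder rows dropped.
maxpool_forward <- function(x, width) {
  L_out <- nrow(x) %/% width
  vals <- x[seq(1L, by = width, length.out = L_out), , drop = FALSE]
  amax <- matrix(1L, L_out, ncol(x))
  if (width > 1L) {
    for (k in 2:width) {
      cand <- x[seq(k, by = width, length.out = L_out), , drop = FALSE]
      upd <- cand > vals
      vals[upd] <- cand[upd]
      amax[upd] <- k
    }
  }
  list(out = vals, argmax = amax, L_in = nrow(x), width = width)
}

maxpool_backward <- function(cache, dout) {
  L_out <- nrow(dout)
  C <- ncol(dout)
  dx <- matrix(0, cache$L_in, C)
  rowidx <- (seq_len(L_out) - 1L) * cache$width + cache$argmax
  lin <- rowidx + rep((seq_len(C) - 1L) * cache$L_in, each = L_out)
  dx[lin] <- dout
  dx
}

# ---- cell-line encoder ---------------------------------------------------

#' Initialize the cell-line encoder
#'
#' Three (1-D convolution, ReLU, max-pool) blocks followed by one dense layer
#' down to the 128-dimensional embedding. Defaults: channels 32/64/96,
#' kernel width 8, pool width 3 (all overridable).
#'
#' @param seed integer seed for the weight initialization (Glorot uniform).
#' @param channels output channels of the three convolutions.
#' @param kernel convolution kernel width.
#' @param pool max-pool width (non-overlapping).
#' @param input_len length of the binary mutation vector (735).
#' @param embed_dim embedding size (128).
#' @return a weight list of class `cell_encoder`.
#' @export
cell_encoder_init <- function(seed = 1L, channels = c(32L, 64L, 96L),
                              kernel = 8L, pool = 3L,
                              input_len = CELL_INPUT_LEN,
                              embed_dim = EMBED_DIM) {
  stopifnot(length(channels) == 3L, kernel >= 1L, pool >= 1L)
  rng <- local_rng(seed)
  chans <- c(1L, as.integer(channels))
  L <- as.integer(input_len)
  conv <- vector("list", 3L)
  for (i in 1:3) {
    n_in <- kernel * chans[i]
    conv[[i]] <- list(W = glorot(rng, n_in, chans[i + 1L]),
                      b = numeric(chans[i + 1L]))
    L <- (L - kernel + 1L) %/% pool
    if (L < 1L) stop("input too short for this geometry", call. = FALSE)
  }
  flat <- L * chans[4L]
  structure(
    list(conv = conv,
         fc = list(W = glorot(rng, flat, embed_dim), b = numeric(embed_dim)),
         kernel = as.integer(kernel), pool = as.integer(pool),
         input_len = as.integer(input_len), flat_dim = flat,
         embed_dim = as.integer(embed_dim)),
    class = "cell_encoder"
  )
}

cell_forward_cache <- function(profile, weights) {
  if (length(profile) != weights$input_len) {
    stop("cell profile must have length ", weights$input_len, ", got ",
         length(profile), call. = FALSE)
  }
  x <- matrix(as.numeric(profile), ncol = 1L)
  caches <- vector("list", 3L)
  for (i in 1:3) {
    cv <- conv1d_forward(x, weights$conv[[i]]$W, weights$conv[[i]]$b,
                         weights$kernel)
    a <- relu(cv$out)
    mp <- maxpool_forward(a, weights$pool)
    caches[[i]] <- list(conv = cv, pre_relu = cv$out, pool = mp)
    x <- mp$out
  }
  flat <- as.numeric(x)
  emb <- as.numeric(crossprod(weights$fc$W, flat)) + weights$fc$b
  list(embedding = emb, flat = flat, pool_dim = dim(x), caches = caches)
}

cell_backward <- function(cache, weights, d_emb) {
  g <- list(conv = vector("list", 3L), fc = NULL)
  g$fc <- list(W = outer(cache$flat, d_emb), b = d_emb)
  dflat <- as.numeric(weights$fc$W %*% d_emb)
  dx <- matrix(dflat, cache$pool_dim[1L], cache$pool_dim[2L])
  for (i in 3:1) {
    ci <- cache$caches[[i]]
    da <- maxpool_backward(ci$pool, dx)
    da[ci$pre_relu <= 0] <- 0
    bk <- conv1d_backward(ci$conv, weights$conv[[i]]$W, weights$kernel, da)
    g$conv[[i]] <- list(W = bk$dW, b = bk$db)
    dx <- bk$dx
  }
  g
}

#' Encode a cell-line mutation profile
#'
#' Deterministic forward pass of the cell branch: three blocks of
#' (1-D convolution, ReLU, max-pool) over the 735-long binary vector, then a
#' dense layer to the 128-dimensional embedding.
#'
#' @param profile numeric binary vector of length 735 (or a list with a
#'   `mutations` field).
#' @param weights a [cell_encoder_init()] object.
#' @return numeric embedding of length `weights$embed_dim`.
#' @export
cell_encoder_forward <- function(profile, weights) {
  if (is.list(profile)) profile <- profile$mutations
  cell_forward_cache(profile, weights)$embedding
}

# ---- graph convolution ---------------------------------------------------

# Symmetric-normalized adjacency with self-loops:
# Ahat = Dhat^{-1/2} (A + I) Dhat^{-1/2}.
normalized_adjacency <- function(adjacency) {
  n <- nrow(adjacency)
  ai <- adjacency + diag(n)
  dinv <- 1 / sqrt(rowSums(ai))
  ai * outer(dinv, dinv)
}

#' One graph-convolution layer
#'
#' Computes `ReLU( Dhat^(-1/2) (A + I) Dhat^(-1/2) X W )` — the
#' symmetric-normalized graph convolution with self-loops.
#'
#' @param node_features N x C_in numeric matrix.
#' @param adjacency N x N symmetric binary matrix with zero diagonal.
#' @param layer_weights C_in x C_out weight matrix.
#' @return N x C_out matrix of activated node features.
#' @export
gcn_layer_forward <- function(node_features, adjacency, layer_weights) {
  node_features <- as.matrix(node_features)
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency) ||
      !isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency must be square and symmetric", call. = FALSE)
  }
  if (nrow(node_features) != nrow(adjacency)) {
    stop("node_features rows must match adjacency size", call. = FALSE)
  }
  if (ncol(node_features) != nrow(layer_weights)) {
    stop("layer_weights rows must match feature columns", call. = FALSE)
  }
  relu(normalized_adjacency(adjacency) %*% node_features %*% layer_weights)
}

#' Initialize the drug encoder
#'
#' Three graph convolutions widening 78 -> 78 -> 156 -> 312, global max
#' pooling over nodes, then dense layers 312 -> 1024 (ReLU) -> 128.
#'
#' @param seed integer seed (Glorot uniform initialization).
#' @param gcn_dims channel plan of the graph convolutions (length 4).
#' @param hidden_dim width of the penultimate dense layer.
#' @param embed_dim embedding size (128).
#' @return a weight list of class `drug_encoder`.
#' @export
drug_encoder_init <- function(seed = 1L,
                              gcn_dims = c(N_ATOM_FEATURES, 78L, 156L, 312L),
                              hidden_dim = 1024L, embed_dim = EMBED_DIM) {
  stopifnot(length(gcn_dims) == 4L)
  rng <- local_rng(seed)
  structure(
    list(gcn = lapply(1:3, function(i) glorot(rng, gcn_dims[i], gcn_dims[i + 1L])),
         fc1 = list(W = glorot(rng, gcn_dims[4L], hidden_dim),
                    b = numeric(hidden_dim)),
         fc2 = list(W = glorot(rng, hidden_dim, embed_dim),
                    b = numeric(embed_dim)),
         gcn_dims = as.integer(gcn_dims), hidden_dim = as.integer(hidden_dim),
         embed_dim = as.integer(embed_dim)),
    class = "drug_encoder"
  )
}

drug_forward_cache <- function(graph, weights) {
  if (is.null(graph$n_atoms) || graph$n_atoms < 1L) {
    stop("molecular graph must contain at least one atom", call. = FALSE)
  }
  ahat <- normalized_adjacency(graph$adjacency)
  x <- graph$node_features
  layers <- vector("list", 3L)
  for (i in 1:3) {
    pre <- ahat %*% x %*% weights$gcn[[i]]
    layers[[i]] <- list(x_in = x, pre = pre)
    x <- relu(pre)
  }
  # global max pool over nodes, first-max tie break
  amax <- max.col(t(x), ties.method = "first")
  pooled <- x[cbind(amax, seq_len(ncol(x)))]
  h_pre <- as.numeric(crossprod(weights$fc1$W, pooled)) + weights$fc1$b
  h <- relu(h_pre)
  emb <- as.numeric(crossprod(weights$fc2$W, h)) + weights$fc2$b
  list(embedding = emb, ahat = ahat, layers = layers, node_out = x,
       pool_argmax = amax, pooled = pooled, h_pre = h_pre, h = h)
}

drug_backward <- function(cache, weights, d_emb) {
  g <- list(gcn = vector("list", 3L))
  g$fc2 <- list(W = outer(cache$h, d_emb), b = d_emb)
  dh <- as.numeric(weights$fc2$W %*% d_emb)
  dh[cache$h_pre <= 0] <- 0
  g$fc1 <- list(W = outer(cache$pooled, dh), b = dh)
  dpool <- as.numeric(weights$fc1$W %*% dh)
  dx <- matrix(0, nrow(cache$node_out), ncol(cache$node_out))
  dx[cbind(cache$pool_argmax, seq_along(dpool))] <- dpool
  for (i in 3:1) {
    li <- cache$layers[[i]]
    dpre <- dx
    dpre[li$pre <= 0] <- 0
    ax <- cache$ahat %*% li$x_in
    g$gcn[[i]] <- crossprod(ax, dpre)
    if (i > 1L) dx <- cache$ahat %*% (dpre %*% t(weights$gcn[[i]]))
  }
  g
}

#' Encode a drug molecular graph
#'
#' Deterministic forward pass of the drug branch; invariant under node
#' permutations of the input graph.
#'
#' @param graph a `molecular_graph` from [smiles_to_graph()].
#' @param weights a [drug_encoder_init()] object.
#' @return numeric embedding of length `weights$embed_dim`.
#' @export
drug_encoder_forward <- function(graph, weights) {
  drug_forward_cache(graph, weights)$embedding
}

#' Fuse the two branch embeddings
#'
#' Concatenates the drug embedding (first 128 slots) and the cell embedding
#' (last 128 slots) into the 256-dimensional vector consumed by the model
#' head. The order (drug block first) is fixed.
#'
#' @param cell,drug numeric embeddings of equal length.
#' @return numeric vector of length `2 * length(drug)`.
#' @export
fuse <- function(cell, drug) {
  stopifnot(length(cell) == length(drug))
  c(drug, cell)
}
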