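# Shared neural-network plumbing: graph batching, scatter operations, and
# parameter initialization. Networks are implemented directly on BLAS-backed
# matrix operations with hand-derived backpropagation; gradient correctness
# is contracted by finite-difference checks in the test suite.

# Stack a list of sc_graph objects into one block-diagonal batch.
#
# Returns: N, G, X (N x d), gid (node -> graph), n_per_graph,
#   edges (M x 2 global, undirected), E (M x de or NULL),
#   src/dst (2M directed endpoints), deidx (directed edge -> undirected row),
#   pool_idx (N x Dmax closed-neighbourhood indices, padded with self),
#   gather_idx (G x nmax node indices, padded with N+1 for a -Inf sentinel).
batch_graphs <- function(graphs) {
  G <- length(graphs)
  if (G == 0L) stop("empty batch")
  ns <- vapply(graphs, function(g) g$n, 1L)
  offs <- cumsum(c(0L, ns[-G]))
  N <- sum(ns)
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  gid <- rep(seq_len(G), times = ns)

  el <- lapply(seq_len(G), function(i) {
    e <- graphs[[i]]$edges
    if (nrow(e) == 0L) return(matrix(0L, 0L, 2L))
    e + offs[i]
  })
  edges <- do.call(rbind, el)
  M <- nrow(edges)
  E <- if (!is.null(graphs[[1L]]$edge_features)) {
    do.call(rbind, lapply(graphs, function(g) g$edge_features))
  } else NULL

  src <- c(edges[, 1L], edges[, 2L])
  dst <- c(edges[, 2L], edges[, 1L])
  deidx <- c(seq_len(M), seq_len(M))

  adj <- vector("list", N)
  for (k in seq_len(M)) {
    adj[[edges[k, 1L]]] <- c(adj[[edges[k, 1L]]], edges[k, 2L])
    adj[[edges[k, 2L]]] <- c(adj[[edges[k, 2L]]], edges[k, 1L])
  }
  Dmax <- max(1L, vapply(adj, length, 1L) + 1L)
  pool_idx <- matrix(0L, N, Dmax)
  for (i in seq_len(N)) {
    nb <- c(i, adj[[i]])
    pool_idx[i, ] <- c(nb, rep(i, Dmax - length(nb)))
  }

  nmax <- max(ns)
  gather_idx <- matrix(N + 1L, G, nmax)
  for (g in seq_len(G)) {
    gather_idx[g, seq_len(ns[g])] <- offs[g] + seq_len(ns[g])
  }

  list(N = N, G = G, X = X, gid = gid, n_per_graph = ns, edges = edges,
       E = E, src = src, dst = dst, deidx = deidx, pool_idx = pool_idx,
       gather_idx = gather_idx)
}

# scatter-add rows of `x` (len(group) x k) into an N x k matrix by group index
.scatter_add <- function(x, group, N) {
  out <- matrix(0, N, ncol(x))
  rs <- rowsum(x, group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# per-group sum of rows (groups must cover 1..G)
.group_sum <- function(x, gid, G) {
  out <- matrix(0, G, ncol(x))
  rs <- rowsum(x, gid)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

# elementwise max over an index matrix (rows x slots of row indices into H,
# with sentinel rows allowed); returns value and winning slot for backprop
.index_max <- function(H, idx, sentinel_value = -Inf) {
  n <- nrow(idx); k <- ncol(H)
  Hs <- rbind(H, matrix(sentinel_value, 1L, k))
  val <- Hs[idx[, 1L], , drop = FALSE]
  win <- matrix(1L, n, k)
  for (s in seq_len(ncol(idx))[-1L]) {
    cand <- Hs[idx[, s], , drop = FALSE]
    better <- cand > val
    val[better] <- cand[better]
    win[better] <- s
  }
  list(value = val, win = win)
}

# backprop for .index_max: route dval to the winning source rows
.index_max_backward <- function(dval, idx, win, N) {
  g <- matrix(0, N + 1L, ncol(dval))
  for (s in seq_len(ncol(idx))) {
    mask <- win == s
    if (!any(mask)) next
    contrib <- dval * mask
    rs <- rowsum(contrib, idx[, s])
    rows <- as.integer(rownames(rs))
    g[rows, ] <- g[rows, ] + rs
  }
  g[seq_len(N), , drop = FALSE]
}

# uniform fan-in initialization
.init_mat <- function(nin, nout) {
  lim <- 1 / sqrt(max(nin, 1L))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}
.init_vec <- function(nin, nout) {
  lim <- 1 / sqrt(max(nin, 1L))
  stats::runif(nout, -lim, lim)
}

.relu <- function(x) x * (x > 0)
.sigmoid <- function(x) 1 / (1 + exp(-x))

# inverted dropout; returns the mask scaled by 1/keep so inference needs none
.dropout_mask <- function(nr, nc, rate) {
  keep <- 1 - rate
  matrix((stats::runif(nr * nc) < keep) / keep, nr, nc)
}

# flatten/unflatten a named list of arrays (Adam state, serialization)
.flatten_params <- function(p) unlist(p, use.names = FALSE)
.map_params <- function(a, b, f) {
  stopifnot(identical(names(a), names(b)))
  out <- a
  for (nm in names(a)) out[[nm]] <- f(a[[nm]], b[[nm]])
  out
}

# Adam optimizer state and update
.adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim = if (is.null(dim(p))) length(p) else dim(p)))
  list(m = zeros, v = zeros, t = 0L)
}
.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    delta <- lr * mhat / (sqrt(vhat) + eps)
    if (is.null(dim(params[[nm]]))) delta <- as.numeric(delta)
    params[[nm]] <- params[[nm]] - delta
  }
  list(params = params, state = state)
}

# sum two gradient lists
.add_grads <- function(a, b) .map_params(a, b, `+`)
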