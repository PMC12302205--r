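# Edge-conditioned message passing network (Gilmer-style):
#   linear embed (ReLU) to d = 64
#   3 x [ NNConv message passing -> ReLU -> shared GRU update ]
#   readout: Set2Set (6 steps) or sum of node states
#   head: two linear layers (ReLU between) to a scalar
# The NNConv edge network maps each edge feature vector through a two-layer
# MLP (hidden width 128) to a d x d mixing operator; messages from source
# nodes are transformed by their edge operator and sum-aggregated at the
# destination. Edge operators are computed once per forward pass: identical
# edge feature rows share one operator, which makes one-hot bond-type
# featurizations essentially free.

#' MPNN architecture configuration
#'
#' @param node_embed Node embedding width (default 64).
#' @param edge_hidden Hidden width of the edge network (default 128).
#' @param mp_steps Number of message-passing steps (default 3; GRU and edge
#'   network parameters are shared across steps).
#' @param readout `"set2set"` (default) or `"sum"`.
#' @param set2set_steps Internal Set2Set iterations (default 6).
#' @returns An `mpnn_config` list.
#' @export
mpnn_config <- function(node_embed = 64L, edge_hidden = 128L, mp_steps = 3L,
                        readout = c("set2set", "sum"), set2set_steps = 6L) {
  readout <- match.arg(readout)
  if (mp_steps < 1L) stop("mp_steps must be >= 1")
  structure(list(node_embed = as.integer(node_embed),
                 edge_hidden = as.integer(edge_hidden),
                 mp_steps = as.integer(mp_steps), readout = readout,
                 set2set_steps = as.integer(set2set_steps)),
            class = "mpnn_config")
}

.mpnn_init <- function(config, node_dim, edge_dim) {
  d <- config$node_embed
  eh <- config$edge_hidden
  if (edge_dim < 1L) stop("the message-passing architecture requires edge features")
  w <- list(
    Wemb = .init_mat(node_dim, d), bemb = .init_vec(node_dim, d),
    We1 = .init_mat(edge_dim, eh), be1 = .init_vec(edge_dim, eh),
    We2 = .init_mat(eh, d * d), be2 = .init_vec(eh, d * d),
    Wroot = .init_mat(d, d), bconv = .init_vec(d, d),
    Wz = .init_mat(d, d), Uz = .init_mat(d, d), bz = .init_vec(d, d),
    Wr = .init_mat(d, d), Ur = .init_mat(d, d), br = .init_vec(d, d),
    Wn = .init_mat(d, d), Un = .init_mat(d, d),
    bwn = .init_vec(d, d), bun = .init_vec(d, d)
  )
  head_in <- if (config$readout == "set2set") 2L * d else d
  if (config$readout == "set2set") {
    for (gate in c("i", "f", "g", "o")) {
      w[[paste0("Wl", gate)]] <- .init_mat(2L * d, d)
      w[[paste0("Ul", gate)]] <- .init_mat(d, d)
      w[[paste0("bl", gate)]] <- .init_vec(2L * d, d)
    }
  }
  w$Wh1 <- .init_mat(head_in, d)
  w$bh1 <- .init_vec(head_in, d)
  w$Wh2 <- .init_mat(d, 1L)
  w$bh2 <- .init_vec(d, 1L)
  w
}

# edge operators: unique edge feature rows -> list(Ms), per-edge unique index
.edge_operators <- function(weights, batch, d) {
  Eu <- batch$E
  key <- apply(Eu, 1L, paste, collapse = "\r")
  dkey <- key[batch$deidx]
  ukeys <- unique(dkey)
  uidx <- match(dkey, ukeys)
  urows <- match(ukeys, key)
  Ez <- Eu[urows, , drop = FALSE] %*% weights$We1 +
    matrix(weights$be1, length(ukeys), length(weights$be1), byrow = TRUE)
  Eh <- .relu(Ez)
  Aun <- Eh %*% weights$We2 +
    matrix(weights$be2, length(ukeys), length(weights$be2), byrow = TRUE)
  # per unique row: M[l, k] = A[k, l]; msg = h_src %*% M
  Ms <- lapply(seq_len(nrow(Aun)), function(u) matrix(Aun[u, ], d, d))
  list(Ms = Ms, uidx = uidx, urows = urows, Ez = Ez, Eh = Eh,
       Eun = Eu[urows, , drop = FALSE])
}

.mpnn_forward <- function(weights, batch, config, training = FALSE) {
  d <- config$node_embed
  N <- batch$N; G <- batch$G
  if (any(batch$n_per_graph < 2L)) {
    stop("the MPNN cannot process single-node graphs")
  }
  if (is.null(batch$E)) stop("batch has no edge features")

  H0 <- .relu(batch$X %*% weights$Wemb +
                matrix(weights$bemb, N, d, byrow = TRUE))
  ops <- .edge_operators(weights, batch, d)
  src <- batch$src; dst <- batch$dst
  edge_rows <- split(seq_along(src),
                     factor(ops$uidx, levels = seq_along(ops$Ms)))

  h <- H0
  steps <- vector("list", config$mp_steps)
  for (t in seq_len(config$mp_steps)) {
    Hs <- h[src, , drop = FALSE]
    msg <- matrix(0, length(src), d)
    for (u in seq_along(edge_rows)) {
      rows <- edge_rows[[u]]
      msg[rows, ] <- Hs[rows, , drop = FALSE] %*% ops$Ms[[u]]
    }
    agg <- .scatter_add(msg, dst, N)
    C <- h %*% weights$Wroot + agg +
      matrix(weights$bconv, N, d, byrow = TRUE)
    m <- .relu(C)
    # GRU(h_prev, input = m)
    az <- m %*% weights$Wz + h %*% weights$Uz +
      matrix(weights$bz, N, d, byrow = TRUE)
    z <- .sigmoid(az)
    ar <- m %*% weights$Wr + h %*% weights$Ur +
      matrix(weights$br, N, d, byrow = TRUE)
    r <- .sigmoid(ar)
    hu <- h %*% weights$Un + matrix(weights$bun, N, d, byrow = TRUE)
    an <- m %*% weights$Wn + matrix(weights$bwn, N, d, byrow = TRUE) + r * hu
    nt <- tanh(an)
    hnew <- (1 - z) * nt + z * h
    steps[[t]] <- list(h_prev = h, Hs = Hs, msg = msg, C = C, m = m,
                       z = z, r = r, hu = hu, nt = nt)
    h <- hnew
  }

  if (config$readout == "set2set") {
    ro <- .set2set_forward(weights, h, batch, config)
    gvec <- ro$qstar
  } else {
    ro <- NULL
    gvec <- .group_sum(h, batch$gid, G)
  }
  Zh <- gvec %*% weights$Wh1 + matrix(weights$bh1, G, d, byrow = TRUE)
  Hh <- .relu(Zh)
  pred <- as.numeric(Hh %*% weights$Wh2 + weights$bh2)

  list(pred = pred,
       cache = list(H0 = H0, ops = ops, edge_rows = edge_rows, steps = steps,
                    h_final = h, ro = ro, gvec = gvec, Zh = Zh, Hh = Hh))
}

.set2set_forward <- function(weights, H, batch, config) {
  d <- config$node_embed
  G <- batch$G; gid <- batch$gid
  q <- matrix(0, G, d); c_ <- matrix(0, G, d)
  qstar <- matrix(0, G, 2L * d)
  Tn <- config$set2set_steps
  states <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    x <- qstar
    gi <- .sigmoid(x %*% weights$Wli + q %*% weights$Uli +
                     matrix(weights$bli, G, d, byrow = TRUE))
    gf <- .sigmoid(x %*% weights$Wlf + q %*% weights$Ulf +
                     matrix(weights$blf, G, d, byrow = TRUE))
    gg <- tanh(x %*% weights$Wlg + q %*% weights$Ulg +
                 matrix(weights$blg, G, d, byrow = TRUE))
    go <- .sigmoid(x %*% weights$Wlo + q %*% weights$Ulo +
                     matrix(weights$blo, G, d, byrow = TRUE))
    cn <- gf * c_ + gi * gg
    qn <- go * tanh(cn)
    e <- rowSums(H * qn[gid, , drop = FALSE])
    emax <- .index_max(matrix(e, ncol = 1L), batch$gather_idx)$value
    w <- exp(e - emax[gid, 1L])
    s <- .group_sum(matrix(w, ncol = 1L), gid, G)
    alpha <- w / s[gid, 1L]
    r <- .group_sum(H * alpha, gid, G)
    states[[t]] <- list(x = x, q_prev = q, c_prev = c_, gi = gi, gf = gf,
                        gg = gg, go = go, cn = cn, qn = qn, alpha = alpha,
                        r = r)
    q <- qn; c_ <- cn
    qstar <- cbind(qn, r)
  }
  list(qstar = qstar, states = states)
}

.set2set_backward <- function(weights, H, batch, states, dqstar, config,
                              grads) {
  d <- config$node_embed
  G <- batch$G; gid <- batch$gid
  N <- nrow(H)
  dH <- matrix(0, N, d)
  dq_carry <- matrix(0, G, d)
  dc_carry <- matrix(0, G, d)
  dx_carry <- dqstar                     # gradient w.r.t. qstar_t at t = T
  for (t in rev(seq_len(config$set2set_steps))) {
    st <- states[[t]]
    dqn <- dx_carry[, seq_len(d), drop = FALSE] + dq_carry
    dr <- dx_carry[, d + seq_len(d), drop = FALSE]
    # attention backward
    dalpha <- rowSums(H * dr[gid, , drop = FALSE])
    dH <- dH + st$alpha * dr[gid, , drop = FALSE]
    S <- .group_sum(matrix(st$alpha * dalpha, ncol = 1L), gid, G)
    de <- st$alpha * (dalpha - S[gid, 1L])
    dH <- dH + de * st$qn[gid, , drop = FALSE]
    dqn <- dqn + .group_sum(H * de, gid, G)
    # LSTM backward
    tcn <- tanh(st$cn)
    dgo <- dqn * tcn
    dcn <- dqn * st$go * (1 - tcn^2) + dc_carry
    dgf <- dcn * st$c_prev
    dc_carry <- dcn * st$gf
    dgi <- dcn * st$gg
    dgg <- dcn * st$gi
    dai <- dgi * st$gi * (1 - st$gi)
    daf <- dgf * st$gf * (1 - st$gf)
    dag <- dgg * (1 - st$gg^2)
    dao <- dgo * st$go * (1 - st$go)
    x <- st$x; qp <- st$q_prev
    grads$Wli <- grads$Wli + t(x) %*% dai
    grads$Wlf <- grads$Wlf + t(x) %*% daf
    grads$Wlg <- grads$Wlg + t(x) %*% dag
    grads$Wlo <- grads$Wlo + t(x) %*% dao
    grads$Uli <- grads$Uli + t(qp) %*% dai
    grads$Ulf <- grads$Ulf + t(qp) %*% daf
    grads$Ulg <- grads$Ulg + t(qp) %*% dag
    grads$Ulo <- grads$Ulo + t(qp) %*% dao
    grads$bli <- grads$bli + colSums(dai)
    grads$blf <- grads$blf + colSums(daf)
    grads$blg <- grads$blg + colSums(dag)
    grads$blo <- grads$blo + colSums(dao)
    dx_carry <- dai %*% t(weights$Wli) + daf %*% t(weights$Wlf) +
      dag %*% t(weights$Wlg) + dao %*% t(weights$Wlo)
    dq_carry <- dai %*% t(weights$Uli) + daf %*% t(weights$Ulf) +
      dag %*% t(weights$Ulg) + dao %*% t(weights$Ulo)
  }
  list(dH = dH, grads = grads)
}

.mpnn_backward <- function(weights, batch, cache, dpred, config) {
  d <- config$node_embed
  N <- batch$N; G <- batch$G
  src <- batch$src; dst <- batch$dst
  dpred <- matrix(dpred, ncol = 1L)

  grads <- lapply(weights, function(p) {
    array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
  })

  grads$Wh2 <- t(cache$Hh) %*% dpred
  grads$bh2 <- sum(dpred)
  dHh <- dpred %*% t(weights$Wh2)
  dZh <- dHh * (cache$Zh > 0)
  grads$Wh1 <- t(cache$gvec) %*% dZh
  grads$bh1 <- colSums(dZh)
  dgvec <- dZh %*% t(weights$Wh1)

  if (config$readout == "set2set") {
    s2s <- .set2set_backward(weights, cache$h_final, batch, cache$ro$states,
                             dgvec, config, grads)
    dh <- s2s$dH
    grads <- s2s$grads
  } else {
    dh <- dgvec[batch$gid, , drop = FALSE]
  }

  ops <- cache$ops
  edge_rows <- cache$edge_rows
  dAun <- vector("list", length(ops$Ms))
  for (u in seq_along(dAun)) dAun[[u]] <- matrix(0, d, d)

  for (t in rev(seq_along(cache$steps))) {
    st <- cache$steps[[t]]
    h <- st$h_prev
    # GRU backward: h_new = (1 - z) * nt + z * h
    dz <- dh * (h - st$nt)
    dnt <- dh * (1 - st$z)
    dh_prev <- dh * st$z
    dan <- dnt * (1 - st$nt^2)
    dm <- dan %*% t(weights$Wn)
    grads$Wn <- grads$Wn + t(st$m) %*% dan
    grads$bwn <- grads$bwn + colSums(dan)
    dr <- dan * st$hu
    dhu <- dan * st$r
    dh_prev <- dh_prev + dhu %*% t(weights$Un)
    grads$Un <- grads$Un + t(h) %*% dhu
    grads$bun <- grads$bun + colSums(dhu)
    dar <- dr * st$r * (1 - st$r)
    dm <- dm + dar %*% t(weights$Wr)
    dh_prev <- dh_prev + dar %*% t(weights$Ur)
    grads$Wr <- grads$Wr + t(st$m) %*% dar
    grads$Ur <- grads$Ur + t(h) %*% dar
    grads$br <- grads$br + colSums(dar)
    daz <- dz * st$z * (1 - st$z)
    dm <- dm + daz %*% t(weights$Wz)
    dh_prev <- dh_prev + daz %*% t(weights$Uz)
    grads$Wz <- grads$Wz + t(st$m) %*% daz
    grads$Uz <- grads$Uz + t(h) %*% daz
    grads$bz <- grads$bz + colSums(daz)
    # NNConv backward: C = h Wroot + agg + b; m = relu(C)
    dC <- dm * (st$C > 0)
    grads$Wroot <- grads$Wroot + t(h) %*% dC
    grads$bconv <- grads$bconv + colSums(dC)
    dh_prev <- dh_prev + dC %*% t(weights$Wroot)
    dmsg <- dC[dst, , drop = FALSE]
    dHs <- matrix(0, length(src), d)
    for (u in seq_along(edge_rows)) {
      rows <- edge_rows[[u]]
      Hsr <- st$Hs[rows, , drop = FALSE]
      dmr <- dmsg[rows, , drop = FALSE]
      dHs[rows, ] <- dmr %*% t(ops$Ms[[u]])
      dAun[[u]] <- dAun[[u]] + t(Hsr) %*% dmr
    }
    dh_prev <- dh_prev + .scatter_add(dHs, src, N)
    dh <- dh_prev
  }

  # embed backward
  dH0 <- dh
  dZemb <- dH0 * (cache$H0 > 0)
  grads$Wemb <- grads$Wemb + t(batch$X) %*% dZemb
  grads$bemb <- grads$bemb + colSums(dZemb)

  # edge network backward (operators shared across steps)
  U <- length(ops$Ms)
  dAmat <- matrix(0, U, d * d)
  for (u in seq_len(U)) dAmat[u, ] <- as.numeric(dAun[[u]])
  grads$We2 <- grads$We2 + t(ops$Eh) %*% dAmat
  grads$be2 <- grads$be2 + colSums(dAmat)
  dEh <- dAmat %*% t(weights$We2)
  dEz <- dEh * (ops$Ez > 0)
  grads$We1 <- grads$We1 + t(ops$Eun) %*% dEz
  grads$be1 <- grads$be1 + colSums(dEz)

  grads
}
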