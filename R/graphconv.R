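# Duvenaud-style graph convolution regressor:
#   conv(53) -> neighbourhood max pool -> conv(38) -> pool ->
#   per-atom dense(27, ReLU) -> graph gather (sum || max) -> linear -> scalar
# Edge features are not used. Dropout 0.4 after every learned layer during
# training. Each convolution mixes a node's own features with the sum of its
# neighbours' features through separate weight matrices.

#' GraphConv architecture configuration
#'
#' @param conv_sizes Widths of the two convolutional layers (default 53, 38).
#' @param dense_size Width of the atom-level dense layer (default 27).
#' @param dropout Dropout rate applied after all layers during training
#'   (default 0.4).
#' @returns A `graphconv_config` list.
#' @export
graphconv_config <- function(conv_sizes = c(53L, 38L), dense_size = 27L,
                             dropout = 0.4) {
  if (length(conv_sizes) != 2L) stop("exactly two convolution layers")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(conv_sizes = as.integer(conv_sizes),
                 dense_size = as.integer(dense_size), dropout = dropout),
            class = "graphconv_config")
}

.graphconv_init <- function(config, node_dim) {
  c1 <- config$conv_sizes[1L]; c2 <- config$conv_sizes[2L]
  dn <- config$dense_size
  list(
    Wself1 = .init_mat(node_dim, c1), Wnb1 = .init_mat(node_dim, c1),
    b1 = .init_vec(node_dim, c1),
    Wself2 = .init_mat(c1, c2), Wnb2 = .init_mat(c1, c2),
    b2 = .init_vec(c1, c2),
    W3 = .init_mat(c2, dn), b3 = .init_vec(c2, dn),
    W4 = .init_mat(2L * dn, 1L), b4 = .init_vec(2L * dn, 1L)
  )
}

# sparse adjacency of a batch (no self loops)
.batch_adjacency <- function(batch) {
  if (nrow(batch$edges) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0L), j = integer(0L), x = numeric(0L),
                                dims = c(batch$N, batch$N)))
  }
  Matrix::sparseMatrix(
    i = c(batch$edges[, 1L], batch$edges[, 2L]),
    j = c(batch$edges[, 2L], batch$edges[, 1L]),
    x = 1, dims = c(batch$N, batch$N)
  )
}

.graphconv_forward <- function(weights, batch, config, training = FALSE) {
  A <- .batch_adjacency(batch)
  drop <- function(H) {
    if (!training || config$dropout == 0) return(list(H = H, mask = NULL))
    mask <- .dropout_mask(nrow(H), ncol(H), config$dropout)
    list(H = H * mask, mask = mask)
  }

  X <- batch$X
  Z1 <- X %*% weights$Wself1 + as.matrix(A %*% X) %*% weights$Wnb1 +
    matrix(weights$b1, batch$N, length(weights$b1), byrow = TRUE)
  H1 <- .relu(Z1)
  d1 <- drop(H1)
  P1m <- .index_max(d1$H, batch$pool_idx)

  Z2 <- P1m$value %*% weights$Wself2 + as.matrix(A %*% P1m$value) %*% weights$Wnb2 +
    matrix(weights$b2, batch$N, length(weights$b2), byrow = TRUE)
  H2 <- .relu(Z2)
  d2 <- drop(H2)
  P2m <- .index_max(d2$H, batch$pool_idx)

  Z3 <- P2m$value %*% weights$W3 +
    matrix(weights$b3, batch$N, length(weights$b3), byrow = TRUE)
  D <- .relu(Z3)
  d3 <- drop(D)

  gsum <- .group_sum(d3$H, batch$gid, batch$G)
  gmaxm <- .index_max(d3$H, batch$gather_idx)
  g <- cbind(gsum, gmaxm$value)
  pred <- as.numeric(g %*% weights$W4 + weights$b4)

  list(pred = pred,
       cache = list(A = A, Z1 = Z1, d1 = d1, P1m = P1m, Z2 = Z2, d2 = d2,
                    P2m = P2m, Z3 = Z3, d3 = d3, gmaxm = gmaxm, g = g))
}

.graphconv_backward <- function(weights, batch, cache, dpred, config) {
  A <- cache$A
  N <- batch$N
  dpred <- matrix(dpred, ncol = 1L)

  gW4 <- t(cache$g) %*% dpred
  gb4 <- sum(dpred)
  dg <- dpred %*% t(weights$W4)
  dn <- config$dense_size
  dgsum <- dg[, seq_len(dn), drop = FALSE]
  dgmax <- dg[, dn + seq_len(dn), drop = FALSE]

  dD <- dgsum[batch$gid, , drop = FALSE] +
    .index_max_backward(dgmax, batch$gather_idx, cache$gmaxm$win, N)
  if (!is.null(cache$d3$mask)) dD <- dD * cache$d3$mask
  dZ3 <- dD * (cache$Z3 > 0)
  gW3 <- t(cache$P2m$value) %*% dZ3
  gb3 <- colSums(dZ3)
  dP2 <- dZ3 %*% t(weights$W3)

  dH2d <- .index_max_backward(dP2, batch$pool_idx, cache$P2m$win, N)
  if (!is.null(cache$d2$mask)) dH2d <- dH2d * cache$d2$mask
  dZ2 <- dH2d * (cache$Z2 > 0)
  P1 <- cache$P1m$value
  gWself2 <- t(P1) %*% dZ2
  gWnb2 <- t(as.matrix(A %*% P1)) %*% dZ2
  gb2 <- colSums(dZ2)
  dP1 <- dZ2 %*% t(weights$Wself2) +
    as.matrix(Matrix::t(A) %*% (dZ2 %*% t(weights$Wnb2)))

  dH1d <- .index_max_backward(dP1, batch$pool_idx, cache$P1m$win, N)
  if (!is.null(cache$d1$mask)) dH1d <- dH1d * cache$d1$mask
  dZ1 <- dH1d * (cache$Z1 > 0)
  X <- batch$X
  gWself1 <- t(X) %*% dZ1
  gWnb1 <- t(as.matrix(A %*% X)) %*% dZ1
  gb1 <- colSums(dZ1)

  list(Wself1 = gWself1, Wnb1 = gWnb1, b1 = gb1,
       Wself2 = gWself2, Wnb2 = gWnb2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}
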