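# Deterministic 3D embedding of molecules. Physics features (inverse bonded
# distances, Born radii, EEM charges) need plausible Cartesian geometry; when
# no structure file is supplied, a conformer is generated by minimizing a
# distance-geometry style stress function (bond-length targets, 1-3 distances
# from ideal hybridization angles, and a nonbonded lower bound), started from
# a random configuration seeded per molecule id. Same id, same conformer.

.COVALENT_RADII <- c(H = 0.31, C = 0.77, N = 0.75, O = 0.73, F = 0.71,
                     P = 1.10, S = 1.03, Cl = 0.99, Br = 1.14, I = 1.33)

# target length of a bond given the two elements and the bond order
.bond_length <- function(el1, el2, order) {
  base <- .COVALENT_RADII[[el1]] + .COVALENT_RADII[[el2]]
  scale <- if (order == 2) 0.87 else if (order == 3) 0.78
           else if (order == 1.5) 0.92 else 1.0
  base * scale
}

.ideal_angle <- function(hyb) {
  switch(hyb, sp = pi, sp2 = 2 * pi / 3, sp3 = 109.47 * pi / 180,
         other = 109.47 * pi / 180)
}

# deterministic 31-bit seed derived from a string id
.id_seed <- function(id, salt = 0L) {
  v <- utf8ToInt(id)
  h <- salt %% 2147483647
  for (x in v) h <- (h * 131 + x) %% 2147483647
  as.integer(h)
}

#' Generate a deterministic 3D conformer for a molecule
#'
#' Hydrogens are placed explicitly (they matter for charge assignment) and
#' can be stripped afterwards. The embedding minimizes a stress function over
#' bonded distances, angle-derived 1-3 distances, and a soft nonbonded lower
#' bound, from a seeded random start; it aims for plausible, reproducible
#' geometry, not a force-field minimum.
#'
#' @param mol An `sc_mol` object.
#' @param seed Integer seed (derive one per molecule id for reproducibility).
#' @returns A list: `coords` (n_total x 3 matrix, heavy atoms first, then
#'   hydrogens), `element` (per row), `heavy` (indices of heavy-atom rows,
#'   in the molecule's atom order), `h_parent` (for each hydrogen row, the
#'   heavy-atom index it is bonded to).
#' @export
embed_conformer <- function(mol, seed = 1L) {
  n_heavy <- mol$n
  h_parent <- rep(seq_len(n_heavy), times = mol$hcount)
  n_h <- length(h_parent)
  n <- n_heavy + n_h
  element <- c(mol$element, rep("H", n_h))

  # bond list: heavy-heavy then heavy-H
  b1 <- c(mol$bonds$a1, h_parent)
  b2 <- c(mol$bonds$a2, n_heavy + seq_len(n_h))
  border <- c(mol$bonds$order, rep(1, n_h))
  d0 <- vapply(seq_along(b1), function(k) {
    .bond_length(element[b1[k]], element[b2[k]], border[k])
  }, 1)

  # 1-3 targets through each centre atom
  adj <- vector("list", n)
  for (k in seq_along(b1)) {
    adj[[b1[k]]] <- c(adj[[b1[k]]], b2[k])
    adj[[b2[k]]] <- c(adj[[b2[k]]], b1[k])
  }
  blen <- function(i, j) {
    k <- which((b1 == i & b2 == j) | (b1 == j & b2 == i))[1L]
    d0[k]
  }
  hyb_all <- c(mol$hybridization, rep("sp3", n_h))
  t1 <- integer(0L); t2 <- integer(0L); t0 <- numeric(0L)
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2L) next
    th <- .ideal_angle(hyb_all[j])
    for (a in seq_len(length(nb) - 1L)) {
      for (b in (a + 1L):length(nb)) {
        i <- nb[a]; k <- nb[b]
        dij <- blen(i, j); djk <- blen(j, k)
        t1 <- c(t1, i); t2 <- c(t2, k)
        t0 <- c(t0, sqrt(dij^2 + djk^2 - 2 * dij * djk * cos(th)))
      }
    }
  }

  # nonbonded pairs (not 1-2, not 1-3) with a soft lower bound
  pair_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  excluded <- unique(c(pair_key(b1, b2), pair_key(t1, t2)))
  all_pairs <- utils::combn(n, 2L)
  nb_keep <- !(pair_key(all_pairs[1L, ], all_pairs[2L, ]) %in% excluded)
  nb1 <- all_pairs[1L, nb_keep]; nb2 <- all_pairs[2L, nb_keep]
  nb_min <- ifelse(element[nb1] == "H" | element[nb2] == "H", 1.9, 2.6)

  stress <- function(x) {
    p <- matrix(x, ncol = 3L)
    db <- sqrt(rowSums((p[b1, , drop = FALSE] - p[b2, , drop = FALSE])^2))
    s <- 10 * sum((db - d0)^2)
    if (length(t1) > 0L) {
      dt <- sqrt(rowSums((p[t1, , drop = FALSE] - p[t2, , drop = FALSE])^2))
      s <- s + 2 * sum((dt - t0)^2)
    }
    if (length(nb1) > 0L) {
      dn <- sqrt(rowSums((p[nb1, , drop = FALSE] - p[nb2, , drop = FALSE])^2))
      s <- s + sum(pmax(0, nb_min - dn)^2)
    }
    s
  }
  grad <- function(x) {
    p <- matrix(x, ncol = 3L)
    g <- matrix(0, n, 3L)
    acc <- function(i, j, w) {
      # accumulate w * (p_i - p_j) into gradient rows i and j
      for (col in 1:3) {
        dv <- w * (p[i, col] - p[j, col])
        gi <- rowsum(dv, i); g[as.integer(rownames(gi)), col] <<-
          g[as.integer(rownames(gi)), col] + gi
        gj <- rowsum(-dv, j); g[as.integer(rownames(gj)), col] <<-
          g[as.integer(rownames(gj)), col] + gj
      }
    }
    db <- sqrt(rowSums((p[b1, , drop = FALSE] - p[b2, , drop = FALSE])^2))
    acc(b1, b2, 10 * 2 * (db - d0) / pmax(db, 1e-8))
    if (length(t1) > 0L) {
      dt <- sqrt(rowSums((p[t1, , drop = FALSE] - p[t2, , drop = FALSE])^2))
      acc(t1, t2, 2 * 2 * (dt - t0) / pmax(dt, 1e-8))
    }
    if (length(nb1) > 0L) {
      dn <- sqrt(rowSums((p[nb1, , drop = FALSE] - p[nb2, , drop = FALSE])^2))
      viol <- pmax(0, nb_min - dn)
      acc(nb1, nb2, -2 * viol / pmax(dn, 1e-8))
    }
    as.numeric(g)
  }

  x0 <- .with_seed(seed, stats::rnorm(3L * n, sd = 0.5 + 0.15 * n^(1 / 3) * 3))
  opt <- stats::optim(x0, stress, grad, method = "L-BFGS-B",
                      control = list(maxit = 400L))
  coords <- matrix(opt$par, ncol = 3L)
  coords <- sweep(coords, 2L, colMeans(coords))
  list(coords = coords, element = element, heavy = seq_len(n_heavy),
       h_parent = h_parent)
}

# pairwise distances between heavy atoms of a conformer, in molecule order
.heavy_distances <- function(conf) {
  as.matrix(stats::dist(conf$coords[conf$heavy, , drop = FALSE]))
}
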