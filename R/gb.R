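# Generalized Born polar solvation energy with effective Born radii and
# electrostatic size:
#
#   dG_pol = -1/2 (1/eps_in - 1/eps_out) 1/(1 + beta*alpha)
#            sum_ij q_i q_j (1/f_ij + alpha*beta/A),   beta = eps_in/eps_out
#
# with the canonical pair function f_ij = sqrt(r^2 + Ri Rj exp(-r^2/(4 Ri Rj))).
# The i = j diagonal terms are the per-atom self energies offered as candidate
# node features; the module also provides the partial-charge and inverse-Born-
# radius features themselves.

#' Generalized Born parameters
#'
#' @param eps_in Interior (solute) dielectric constant; default 1.
#' @param eps_out Solvent dielectric constant; default 78.5 (water).
#' @param alpha Dimensionless constant of the alpha/beta/A-augmented GB
#'   flavour; default 0.571412.
#' @param coulomb_k Electrostatic conversion constant,
#'   kcal A / (mol e^2); default 332.06.
#' @returns A `gb_parameters` list.
#' @export
gb_parameters <- function(eps_in = 1, eps_out = 78.5, alpha = 0.571412,
                          coulomb_k = 332.06) {
  if (!(eps_out > eps_in && eps_in >= 1)) stop("require eps_out > eps_in >= 1")
  if (alpha < 0) stop("alpha must be >= 0")
  structure(list(eps_in = eps_in, eps_out = eps_out, alpha = alpha,
                 coulomb_k = coulomb_k),
            class = "gb_parameters")
}

# beta of the augmented GB expression is derived, never stored
.gb_beta <- function(params) params$eps_in / params$eps_out

# Bondi-style intrinsic radii (A) per element
.INTRINSIC_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                      P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98)

#' Bundled intrinsic (Bondi-style) radii
#'
#' @param elements Character vector of element symbols.
#' @returns Numeric vector of radii in Angstrom.
#' @export
intrinsic_radii <- function(elements) {
  r <- .INTRINSIC_RADII[elements]
  if (anyNA(r)) stop("no intrinsic radius for element(s): ",
                     paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Construct a GB system
#'
#' @param coords n x 3 matrix of Cartesian coordinates (Angstrom).
#' @param charges Per-atom partial charges (e).
#' @param radii Per-atom intrinsic radii (Angstrom).
#' @param born_radii Optional per-atom effective Born radii; computed by
#'   [effective_born_radii()] when omitted.
#' @param electrostatic_size Optional molecular electrostatic size A;
#'   computed by [electrostatic_size()] when omitted.
#' @returns A `gb_system` list.
#' @export
gb_system <- function(coords, charges, radii, born_radii = NULL,
                      electrostatic_size = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n == 0L) stop("empty system")
  stopifnot(ncol(coords) == 3L, length(charges) == n, length(radii) == n)
  if (any(radii <= 0)) stop("intrinsic radii must be positive")
  sys <- structure(list(coords = coords, charges = as.numeric(charges),
                        radii = as.numeric(radii), born_radii = born_radii,
                        electrostatic_size = electrostatic_size),
                   class = "gb_system")
  if (!is.null(born_radii)) {
    stopifnot(length(born_radii) == n)
    if (any(born_radii < radii - 1e-9)) {
      stop("born_radii must be >= intrinsic radii")
    }
  }
  sys
}

# HCT pairwise descreening integral of the Coulomb-field kernel 1/r^4 over
# the volume of sphere j (radius rho_j at distance r), seen from atom i with
# inner cutoff rho_i. Closed form; validated against a numerical grid
# integration oracle in the test suite.
.descreen_integral <- function(r, rho_i, rho_j) {
  if (r + rho_j <= rho_i) return(0)          # j buried inside i's own sphere
  L <- max(abs(r - rho_j), rho_i)
  U <- r + rho_j
  val <- 0.5 * (1 / L - 1 / U + (r / 4) * (1 / U^2 - 1 / L^2) +
                (1 / (2 * r)) * log(L / U) +
                (rho_j^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
  if (r + rho_i <= rho_j) val <- val + (1 / rho_i - 1 / L)  # i engulfed by j
  val
}

#' Effective Born radii by pairwise descreening
#'
#' Coulomb-field approximation: the inverse intrinsic radius of each atom is
#' reduced by the analytic descreening integral of every other atom's sphere,
#' and the result is clamped from below by the intrinsic radius. An isolated
#' atom keeps exactly its intrinsic radius; burial by neighbours can only
#' grow the effective radius.
#'
#' @param system A `gb_system` (born radii not required).
#' @returns Numeric vector of effective Born radii (Angstrom).
#' @export
effective_born_radii <- function(system) {
  coords <- system$coords
  rho <- system$radii
  n <- nrow(coords)
  if (n == 1L) return(rho)
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] < 1e-9)) {
    stop("coincident atoms (zero interatomic distance)")
  }
  inv <- 1 / rho
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-i]) {
      inv[i] <- inv[i] - .descreen_integral(d[i, j], rho[i], rho[j])
    }
  }
  pmax(1 / pmax(inv, 1e-8), rho)
}

#' Molecular electrostatic size A
#'
#' Computed as the capacitance of the assembly of atom spheres by a
#' method-of-moments solve (potential coefficient matrix built from the
#' smooth GB pair kernel, which reduces to 1/r at long range and to the
#' sphere self term on the diagonal). For a single atom A equals its
#' intrinsic radius exactly, so the polar energy reduces to the Born formula;
#' A is invariant to rigid motion and grows under uniform coordinate scaling.
#'
#' @param system A `gb_system`.
#' @returns The electrostatic size A in Angstrom.
#' @export
electrostatic_size <- function(system) {
  coords <- system$coords
  a <- system$radii
  n <- nrow(coords)
  if (n == 0L) stop("empty system")
  if (n == 1L) return(a[1L])
  d <- as.matrix(stats::dist(coords))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      M[i, j] <- if (i == j) 1 / a[i]
                 else 1 / gb_pair_function(d[i, j], a[i], a[j])
    }
  }
  q <- solve(M, rep(1, n))
  sum(q)
}

#' Canonical GB pair function
#'
#' `f(r, Ri, Rj) = sqrt(r^2 + Ri * Rj * exp(-r^2 / (4 * Ri * Rj)))`:
#' equals `R` at zero separation when `Ri = Rj = R` (self term) and tends to
#' `r` at large separation (Coulomb limit); continuous, non-decreasing in
#' `r`, symmetric in the two radii.
#'
#' @param r Interatomic distance (Angstrom), `>= 0`.
#' @param R_i,R_j Effective Born radii (Angstrom), `> 0`.
#' @returns The pair function value in Angstrom (vectorized over `r`).
#' @export
gb_pair_function <- function(r, R_i, R_j) {
  if (any(r < 0) || any(R_i <= 0) || any(R_j <= 0)) {
    stop("require r >= 0 and positive Born radii")
  }
  sqrt(r^2 + R_i * R_j * exp(-r^2 / (4 * R_i * R_j)))
}

#' GB polar solvation energy with pair decomposition
#'
#' Evaluates the screened pairwise sum over all ordered atom pairs, including
#' the i = j self terms. The returned `pair_terms` matrix is symmetric; its
#' grand sum equals `total`, and its diagonal holds the per-atom self
#' energies used as candidate node features.
#'
#' @param system A `gb_system`; if `born_radii` or `electrostatic_size` are
#'   missing they are computed first.
#' @param params A `gb_parameters` object.
#' @returns A `gb_energy` list: `total` (kcal/mol), `pair_terms` (n x n
#'   matrix), `self_energies` (its diagonal), plus the Born radii and A used.
#' @export
gb_polar_energy <- function(system, params = gb_parameters()) {
  stopifnot(inherits(system, "gb_system"), inherits(params, "gb_parameters"))
  R <- system$born_radii
  if (is.null(R)) R <- effective_born_radii(system)
  A <- system$electrostatic_size
  if (is.null(A)) A <- electrostatic_size(system)
  if (A <= 0) stop("electrostatic size must be positive")
  q <- system$charges
  n <- length(q)
  beta <- .gb_beta(params)
  pref <- -0.5 * params$coulomb_k * (1 / params$eps_in - 1 / params$eps_out) /
    (1 + beta * params$alpha)
  d <- if (n > 1L) as.matrix(stats::dist(system$coords)) else
    matrix(0, 1L, 1L)
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      f[i, j] <- gb_pair_function(d[i, j], R[i], R[j])
    }
  }
  pair <- pref * outer(q, q) * (1 / f + params$alpha * beta / A)
  structure(list(total = sum(pair), pair_terms = pair,
                 self_energies = diag(pair), born_radii = R,
                 electrostatic_size = A),
            class = "gb_energy")
}

#' @export
print.gb_energy <- function(x, ...) {
  cat("<gb energy> total =", format(x$total, digits = 8), "kcal/mol over",
      nrow(x$pair_terms), "atoms\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# partial charges: electronegativity equalization + hydrogen condensation

# Mulliken-style electronegativity (chi, eV) and hardness (eta, eV/e) tables
.EEM_CHI <- c(H = 7.18, C = 6.27, N = 7.30, O = 7.54, F = 10.41,
              P = 5.62, S = 6.22, Cl = 8.30, Br = 7.59, I = 6.76)
.EEM_ETA <- c(H = 6.45, C = 5.00, N = 7.23, O = 6.08, F = 7.01,
              P = 4.88, S = 4.14, Cl = 4.68, Br = 4.22, I = 3.69)
.EEM_COULOMB <- 14.4   # eV A / e^2

#' Assign per-heavy-atom partial charges
#'
#' Default method is electronegativity equalization (EEM) over the full
#' molecule including explicit hydrogens, followed by condensation of each
#' hydrogen's charge onto its bonded heavy atom; the condensed charges sum
#' exactly to the molecular formal charge. When a structure file with charges
#' is attached to the record, `method = "from_structure"` passes those
#' through (H-condensed) instead.
#'
#' @param record One row of an `sc_records` data frame (or a list with
#'   `id` and `smiles`), or directly an `sc_mol` plus `id`.
#' @param method `"eem"` (default) or `"from_structure"`.
#' @param structure Optional atom table (element, x, y, z, charge) as stored
#'   by [attach_structures()]; required for `"from_structure"`.
#' @returns Numeric vector of heavy-atom charges (e), in molecule atom order.
#' @export
assign_partial_charges <- function(record, method = c("eem", "from_structure"),
                                   structure = NULL) {
  method <- match.arg(method)
  mol <- parse_smiles(record$smiles)
  if (method == "from_structure") {
    if (is.null(structure) || all(is.na(structure$charge))) {
      stop("from_structure requested but no charges present for record '",
           record$id, "'")
    }
    heavy <- which(structure$element != "H")
    q <- structure$charge[heavy]
    # condense hydrogens onto nearest heavy atom
    hs <- which(structure$element == "H")
    if (length(hs) > 0L) {
      hx <- as.matrix(structure[hs, c("x", "y", "z")])
      px <- as.matrix(structure[heavy, c("x", "y", "z")])
      for (k in seq_along(hs)) {
        d2 <- colSums((t(px) - hx[k, ])^2)
        q[which.min(d2)] <- q[which.min(d2)] + structure$charge[hs[k]]
      }
    }
    return(q)
  }
  conf <- embed_conformer(mol, seed = .id_seed(record$id))
  el <- conf$element
  n <- length(el)
  chi <- .EEM_CHI[el]
  eta <- .EEM_ETA[el]
  M <- matrix(0, n + 1L, n + 1L)
  d <- as.matrix(stats::dist(conf$coords))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      M[i, j] <- if (i == j) 2 * eta[i] else .EEM_COULOMB / max(d[i, j], 0.5)
    }
  }
  M[n + 1L, seq_len(n)] <- 1
  M[seq_len(n), n + 1L] <- 1
  rhs <- c(-chi, .formal_charge(mol))
  sol <- solve(M, rhs)
  q_full <- sol[seq_len(n)]
  q <- q_full[conf$heavy]
  for (k in seq_along(conf$h_parent)) {
    p <- conf$h_parent[k]
    q[p] <- q[p] + q_full[mol$n + k]
  }
  q
}

#' Per-atom GB feature table for a record
#'
#' Computes, over the heavy atoms of one molecule, the physics node features
#' (partial charge, effective Born radius and its inverse) and the GB
#' self-energy diagnostic. Geometry comes from an attached structure when
#' available, otherwise from the deterministic conformer.
#'
#' @param record One row of an `sc_records` data frame.
#' @param params A `gb_parameters` object.
#' @param structure Optional structure table (element, x, y, z, charge).
#' @returns A data frame: id, atom (1-based heavy-atom index), element,
#'   charge (e), born_radius (A), inv_born_radius (1/A), self_energy
#'   (kcal/mol); plus attribute `distances`, the heavy-atom distance matrix.
#' @export
gb_atom_features <- function(record, params = gb_parameters(),
                             structure = NULL) {
  mol <- parse_smiles(record$smiles)
  if (!is.null(structure)) {
    heavy <- which(structure$element != "H")
    if (!identical(structure$element[heavy], mol$element)) {
      if (!identical(sort(structure$element[heavy]), sort(mol$element))) {
        stop("structure for '", record$id, "' has different elements than ",
             "its SMILES")
      }
      stop("structure atom order for '", record$id, "' does not match the ",
           "SMILES atom order; reorder the structure file (ambiguous match)")
    }
    coords <- as.matrix(structure[heavy, c("x", "y", "z")])
    q <- if (!all(is.na(structure$charge))) {
      assign_partial_charges(record, "from_structure", structure)
    } else {
      assign_partial_charges(record)
    }
  } else {
    conf <- embed_conformer(mol, seed = .id_seed(record$id))
    coords <- conf$coords[conf$heavy, , drop = FALSE]
    q <- assign_partial_charges(record)
  }
  sys <- gb_system(coords, q, intrinsic_radii(mol$element))
  en <- gb_polar_energy(sys, params)
  out <- data.frame(
    id = record$id, atom = seq_len(mol$n), element = mol$element,
    charge = q, born_radius = en$born_radii,
    inv_born_radius = 1 / en$born_radii, self_energy = en$self_energies,
    stringsAsFactors = FALSE
  )
  attr(out, "distances") <- as.matrix(stats::dist(coords))
  out
}

#' Write per-atom GB feature tables as CSV
#'
#' @param records An `sc_records` data frame.
#' @param file Output path.
#' @param params A `gb_parameters` object.
#' @returns `file`, invisibly.
#' @export
write_gb_features_csv <- function(records, file, params = gb_parameters()) {
  structures <- attr(records, "structures")
  tabs <- lapply(seq_len(nrow(records)), function(i) {
    st <- if (!is.null(structures)) structures[[records$id[i]]] else NULL
    gb_atom_features(records[i, ], params, structure = st)
  })
  utils::write.csv(do.call(rbind, tabs), file, row.names = FALSE)
  invisible(file)
}
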