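# Generalized Born module: limits, invariances, and numerical oracles.

born_formula <- function(q, R, params = gb_parameters()) {
  -params$coulomb_k / 2 * (1 / params$eps_in - 1 / params$eps_out) * q^2 / R
}

test_that("single-atom energy equals the Born formula (alpha terms cancel)", {
  p <- gb_parameters()
  for (case in list(c(1, 2), c(-0.5, 1.3), c(2, 3.7))) {
    sys <- make_toy_gb_system("single_ion", q = case[1], radius = case[2])
    en <- gb_polar_energy(sys, p)
    expect_equal(en$total, born_formula(case[1], case[2], p),
                 tolerance = 1e-9)
  }
  # the spec's reference point: q = 1 e, R = 2 A, water dielectric
  en <- gb_polar_energy(make_toy_gb_system("single_ion", q = 1, radius = 2))
  expect_equal(en$total, -81.957, tolerance = 1e-4)
})

test_that("gb_pair_function satisfies its limits and symmetry", {
  expect_equal(gb_pair_function(0, 2, 2), 2)
  expect_lt(abs(gb_pair_function(100, 1, 1) - 100), 1e-3)
  # independent arithmetic evaluation of the exponential form
  r <- 3; Ri <- 1.5; Rj <- 2
  expect_equal(gb_pair_function(r, Ri, Rj),
               sqrt(r^2 + Ri * Rj * exp(-r^2 / (4 * Ri * Rj))),
               tolerance = 1e-12)
  expect_equal(gb_pair_function(3, 1.5, 2), 3.2275532, tolerance = 1e-6)
  expect_identical(gb_pair_function(2.2, 1.1, 1.9),
                   gb_pair_function(2.2, 1.9, 1.1))
  # continuity / monotonicity in r
  rs <- seq(0, 12, by = 0.05)
  vals <- gb_pair_function(rs, 1.4, 2.1)
  expect_true(all(diff(vals) >= 0))
  expect_error(gb_pair_function(-1, 1, 1), "r >= 0")
})

test_that("effective Born radii: isolated atom, symmetry, monotone burial", {
  expect_equal(effective_born_radii(make_toy_gb_system("single_ion",
                                                       radius = 1.5)), 1.5)
  di <- make_toy_gb_system("diatomic", d = 3.4, radius = 1.5)
  R <- effective_born_radii(di)
  expect_equal(R[1], R[2])
  expect_gt(R[1], 1.5)
  # adding a third atom can only grow the radii of the first two
  ch <- make_toy_gb_system("linear_chain", n = 3, d = 3.4, radius = 1.5)
  R3 <- effective_born_radii(ch)
  expect_gte(R3[2], R[1] - 1e-12)    # centre atom at least as buried
  # rigid-motion invariance
  rot <- function(th) matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0,
                               0, 0, 1), 3, 3)
  m <- ch$coords %*% rot(0.7)
  m <- sweep(m, 2L, c(3, -2, 5), "+")
  R3b <- effective_born_radii(gb_system(m, ch$charges, ch$radii))
  expect_equal(R3b, R3, tolerance = 1e-9)
  expect_error(effective_born_radii(gb_system(rbind(c(0, 0, 0), c(0, 0, 0)),
                                              c(1, 1), c(1.5, 1.5))),
               "coincident")
})

test_that("effective Born radii match a grid-integration oracle within 5%", {
  # numerical volume integration of the 1/r^4 kernel over the other spheres
  grid_inverse_radius <- function(sys, i, h = 0.05) {
    rho <- sys$radii
    acc <- 0
    for (j in seq_len(nrow(sys$coords))[-i]) {
      c_j <- sys$coords[j, ]
      xs <- seq(c_j[1] - rho[j], c_j[1] + rho[j], by = h)
      ys <- seq(c_j[2] - rho[j], c_j[2] + rho[j], by = h)
      zs <- seq(c_j[3] - rho[j], c_j[3] + rho[j], by = h)
      gr <- expand.grid(x = xs, y = ys, z = zs)
      keep <- (gr$x - c_j[1])^2 + (gr$y - c_j[2])^2 + (gr$z - c_j[3])^2 <=
        rho[j]^2
      g <- gr[keep, ]
      d2 <- (g$x - sys$coords[i, 1])^2 + (g$y - sys$coords[i, 2])^2 +
        (g$z - sys$coords[i, 3])^2
      d2 <- d2[d2 > rho[i]^2]
      acc <- acc + sum(1 / d2^2) * h^3 / (4 * pi)
    }
    1 / rho[i] - acc
  }
  sys <- make_toy_gb_system("linear_chain", n = 3, d = 3.2, radius = 1.5)
  R <- effective_born_radii(sys)
  for (i in 1:3) {
    oracle <- 1 / grid_inverse_radius(sys, i)
    expect_lt(abs(R[i] - oracle) / oracle, 0.05)
  }
})

test_that("electrostatic size: Born limit, scaling, and capacitance oracle", {
  expect_equal(electrostatic_size(make_toy_gb_system("single_ion",
                                                     radius = 2)), 2)
  sys <- make_toy_gb_system("linear_chain", n = 4, d = 2.8, radius = 1.5)
  A1 <- electrostatic_size(sys)
  sys2 <- gb_system(sys$coords * 2, sys$charges, sys$radii)
  expect_gt(electrostatic_size(sys2), A1)
  # two unit spheres 10 A apart vs a boundary-element capacitance oracle
  bem_capacitance <- function(centers, radius, n_panel = 400L) {
    fib_sphere <- function(n) {
      i <- seq_len(n) - 0.5
      phi <- acos(1 - 2 * i / n)
      th <- pi * (1 + sqrt(5)) * i
      cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
    }
    pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
      sweep(fib_sphere(n_panel) * radius, 2L, centers[k, ], "+")
    }))
    n <- nrow(pts)
    area <- 4 * pi * radius^2 / n_panel
    r0 <- sqrt(area / pi)
    P <- 1 / as.matrix(stats::dist(pts))
    diag(P) <- 8 / (3 * pi * r0)   # mean self-potential of a uniform disc
    q <- solve(P, rep(1, n))
    sum(q)
  }
  two <- make_toy_gb_system("diatomic", d = 10, radius = 1)
  A <- electrostatic_size(two)
  C <- bem_capacitance(two$coords, 1)
  expect_lt(abs(A - C) / C, 0.10)
  expect_error(electrostatic_size(gb_system(matrix(0, 1, 3)[0, , drop = FALSE],
                                            numeric(0), numeric(0))), "empty")
})

test_that("pair decomposition sums to the total and self terms sit on the diagonal", {
  sys <- make_toy_gb_system("linear_chain", n = 3, d = 3.0, radius = 1.4,
                            q = c(0.4, -0.8, 0.4))
  en <- gb_polar_energy(sys)
  expect_equal(sum(en$pair_terms), en$total, tolerance = 1e-9 * abs(en$total))
  expect_equal(en$self_energies, diag(en$pair_terms))
  expect_true(isSymmetric(en$pair_terms, tol = 1e-12))
  expect_lt(en$total, 0)
  # brute-force double-sum oracle for a two-atom system
  two <- make_toy_gb_system("diatomic", d = 3.1, radius = 1.5,
                            q = c(0.3, -0.9))
  en2 <- gb_polar_energy(two)
  p <- gb_parameters()
  beta <- p$eps_in / p$eps_out
  R <- en2$born_radii; A <- en2$electrostatic_size
  q <- two$charges
  d <- 3.1
  acc <- 0
  for (i in 1:2) for (j in 1:2) {
    f <- gb_pair_function(if (i == j) 0 else d, R[i], R[j])
    acc <- acc + q[i] * q[j] * (1 / f + p$alpha * beta / A)
  }
  acc <- -0.5 * p$coulomb_k * (1 / p$eps_in - 1 / p$eps_out) /
    (1 + beta * p$alpha) * acc
  expect_equal(en2$total, acc, tolerance = 1e-12)
})

test_that("energy is invariant to charge inversion and rigid motion, and vanishes in the dielectric limit", {
  sys <- make_toy_gb_system("linear_chain", n = 3, d = 3.0, radius = 1.4,
                            q = c(0.4, -0.8, 0.4))
  en <- gb_polar_energy(sys)
  flip <- gb_system(sys$coords, -sys$charges, sys$radii)
  expect_equal(gb_polar_energy(flip)$total, en$total, tolerance = 1e-12)
  th <- 1.1
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- gb_system(sweep(sys$coords %*% rot, 2L, c(-4, 2, 9), "+"),
                     sys$charges, sys$radii)
  expect_equal(gb_polar_energy(moved)$total, en$total,
               tolerance = 1e-9 * abs(en$total))
  near <- gb_parameters(eps_in = 1, eps_out = 1 + 1e-9)
  expect_lt(abs(gb_polar_energy(sys, near)$total), 1e-6)
})

test_that("EEM charges: neutrality, symmetry, and structure pass-through", {
  rec <- make_records("methanol", "CO", expt = -5.1)
  q <- assign_partial_charges(rec[1L, ])
  expect_equal(sum(q), 0, tolerance = 1e-6)
  expect_lt(q[2], q[1])              # oxygen more negative than carbon
  rec2 <- make_records("ethane", "CC", expt = 1.8)
  q2 <- assign_partial_charges(rec2[1L, ])
  expect_equal(q2[1], q2[2], tolerance = 1e-6)
  # explicit structure charges pass through, H-condensed
  st <- data.frame(element = c("C", "C", "H", "H", "H", "H", "H", "H"),
                   x = c(0, 1.54, -0.5, -0.5, -0.5, 2.0, 2.0, 2.0),
                   y = c(0, 0, 0.9, -0.9, 0, 0.9, -0.9, 0),
                   z = c(0, 0, 0, 0, 0.9, 0, 0, -0.9),
                   charge = c(-0.3, -0.3, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1))
  q3 <- assign_partial_charges(rec2[1L, ], "from_structure", st)
  expect_equal(q3, c(0, 0), tolerance = 1e-12)
  expect_error(assign_partial_charges(rec2[1L, ], "from_structure",
                                      within(st, charge <- NA_real_)),
               "no charges")
})

test_that("gb_atom_features produces the physics node feature table", {
  rec <- make_records("eth", "CCO", expt = -5)
  tab <- gb_atom_features(rec[1L, ])
  expect_identical(nrow(tab), 3L)
  expect_equal(tab$inv_born_radius, 1 / tab$born_radius)
  expect_true(all(tab$born_radius >= intrinsic_radii(tab$element) - 1e-9))
  expect_true(all(tab$self_energy < 0 | tab$charge == 0))
  d <- attr(tab, "distances")
  expect_identical(dim(d), c(3L, 3L))
  expect_gt(d[1, 2], 1.0)
})
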