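# Pair-force engine: analytic two-body terms, multi-body decomposition,
# scalarization sign convention, group sums and interaction energies.
# The master oracle is the central finite difference of the total energy.

two_atoms <- function(q1 = 0, q2 = 0, d = 1, sigma = 0, eps = 0,
                      bond = NULL) {
  atoms <- atom_table(c("A", "B"), c(1, 2), charge = c(q1, q2),
                      lj_sigma = sigma, lj_epsilon = eps)
  sys <- molecular_system(atoms, bonds = bond)
  list(system = sys,
       frame = make_frame(rbind(c(0, 0, 0), c(d, 0, 0))))
}

test_that("harmonic bond follows Hooke's law with restoring direction", {
  tw <- two_atoms(bond = data.frame(i = 1, j = 2, k_b = 1000, r0 = 0.1),
                  d = 0.12)
  pfm <- pair_forces_frame(tw$system, tw$frame, cutoff = 1)
  expect_equal(nrow(pfm), 1)
  # stretched bond: magnitude k*(r-r0) = 20 kJ/mol/nm, attractive (negative)
  expect_equal(convert_force(pfm$f_pn, "pN", "kJ/mol/nm"), -20,
               tolerance = 1e-10)
})

test_that("Coulomb pair force matches the MD-unit prefactor", {
  tw <- two_atoms(q1 = 1, q2 = 1, d = 1)
  pfm <- pair_forces_frame(tw$system, tw$frame, cutoff = 2)
  expect_equal(convert_force(pfm$f_pn, "pN", "kJ/mol/nm"), 138.935458,
               tolerance = 1e-6)
  expect_gt(pfm$f_pn, 0)  # like charges repel
  # and the attractive counterpart is its negation
  tw2 <- two_atoms(q1 = 1, q2 = -1, d = 1)
  pfm2 <- pair_forces_frame(tw2$system, tw2$frame, cutoff = 2)
  expect_equal(pfm2$f_pn, -pfm$f_pn, tolerance = 1e-12)
})

test_that("scalarization sign equals the analytic sign of dU/dr", {
  # repulsive LJ core
  tw <- two_atoms(sigma = 0.3, eps = 1, d = 0.25)
  expect_gt(pair_forces_frame(tw$system, tw$frame, cutoff = 1)$f_pn, 0)
  # attractive LJ tail
  tw <- two_atoms(sigma = 0.3, eps = 1, d = 0.45)
  expect_lt(pair_forces_frame(tw$system, tw$frame, cutoff = 1)$f_pn, 0)
  # zero vector scalarizes to 0
  expect_equal(scalarize_pair_force(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), 0)
  expect_error(scalarize_pair_force(c(1, 0, 0), c(0, 0, 0), c(0, 0, 0)),
               "positive")
})

test_that("overlapping atoms in a nonbonded pair raise a singular-geometry error", {
  tw <- two_atoms(q1 = 1, q2 = 1, d = 1e-9)
  expect_error(pair_forces_frame(tw$system, tw$frame, cutoff = 1),
               "overlapping")
})

test_that("per-atom forces reconstructed from pairs match finite differences", {
  for (seed in 1:4) {
    rs <- random_system(20, seed = seed)
    x <- as.matrix(rs$frame)
    pfm <- pair_forces_frame(rs$system, x, cutoff = 50, vectors = TRUE)
    f_pairs <- atom_forces_from_pairs(pfm, 20)
    f_fd <- fd_gradient(rs$system, x, cutoff = 50)
    scale <- max(abs(f_fd))
    expect_lt(max(abs(f_pairs - f_fd)) / scale, 1e-5)
    # analytic engine agrees too
    expect_lt(max(abs(system_forces(rs$system, x, cutoff = 50) - f_pairs)) /
                scale, 1e-9)
    # Newton's third law is structural; total internal force vanishes
    expect_lt(max(abs(colSums(f_pairs))) / scale, 1e-9)
    expect_equal(attr(pfm, "n_degenerate"), 0L)
  }
})

test_that("angle decomposition reproduces analytic forces on a bent triplet", {
  # water-like bent geometry
  atoms <- atom_table(c("O", "H1", "H2"), c(1, 1, 1))
  sys <- molecular_system(atoms,
                          angles = data.frame(i = 2, j = 1, k = 3,
                                              k_theta = 400, theta0 = 104.5))
  x <- rbind(c(0, 0, 0),
             c(0.096, 0, 0),
             c(-0.024, 0.093, 0))
  pfm <- pair_forces_frame(sys, x, cutoff = 1, vectors = TRUE)
  f_pairs <- atom_forces_from_pairs(pfm, 3)
  f_ana <- system_forces(sys, x, cutoff = 1)
  expect_lt(max(abs(f_pairs - f_ana)), 1e-10)
  # at theta == theta0 all pair forces vanish
  sys0 <- sys
  sys0$angles$theta0 <- bending_angle(x, c(2, 1, 3))
  pfm0 <- pair_forces_frame(sys0, x, cutoff = 1)
  expect_lt(max(abs(pfm0$f_pn)), 1e-9)
})

test_that("collinear angle geometry falls back to minimum norm and is flagged", {
  atoms <- atom_table(c("A", "B", "C"), c(1, 1, 1))
  sys <- molecular_system(atoms,
                          angles = data.frame(i = 1, j = 2, k = 3,
                                              k_theta = 100, theta0 = 150))
  x <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0))
  pfm <- pair_forces_frame(sys, x, cutoff = 1)
  expect_equal(attr(pfm, "n_degenerate"), 1L)
})

test_that("dihedral at its potential minimum produces zero pair forces", {
  atoms <- atom_table(c("A", "B", "C", "D"), rep(1, 4))
  # phi for this staggered geometry, then set the phase so U is minimal there
  x <- rbind(c(0, 0.1, 0), c(0, 0, 0), c(0.15, 0, 0), c(0.15, 0.1, 0.1))
  g <- fdanet:::dihedral_kernel(x[1, ], x[2, ], x[3, ], x[4, ])
  phase_min <- 180 + 2 * (g$phi * 180 / pi)  # cos(2 phi - phase) = -1
  sys <- molecular_system(atoms,
                          dihedrals = data.frame(i = 1, j = 2, k = 3, l = 4,
                                                 k_phi = 10, mult = 2,
                                                 phase = phase_min))
  pfm <- pair_forces_frame(sys, x, cutoff = 1)
  expect_lt(max(abs(pfm$f_pn)), 1e-7)
  # 4-body least-squares decomposition is exact away from the minimum
  sys$dihedrals$phase <- phase_min + 90
  pfm2 <- pair_forces_frame(sys, x, cutoff = 1, vectors = TRUE)
  f_pairs <- atom_forces_from_pairs(pfm2, 4)
  f_ana <- system_forces(sys, x, cutoff = 1)
  expect_lt(max(abs(f_pairs - f_ana)) / max(abs(f_ana)), 1e-8)
})

test_that("group pair forces equal a brute-force double loop", {
  rs <- random_system(30, seed = 9, bonded = FALSE)
  pfm <- pair_forces_frame(rs$system, rs$frame, cutoff = 0.8)
  gu <- 1:10; gv <- 21:30
  # independent oracle: direct Coulomb + LJ scalar per spanning pair
  x <- as.matrix(rs$frame)
  a <- rs$system$atoms
  acc <- 0
  for (i in gu) for (j in gv) {
    d <- x[i, ] - x[j, ]
    r <- sqrt(sum(d * d))
    if (r <= 0.8) {
      s <- 138.935458 * a$charge[i] * a$charge[j] / r^2
      sig <- (a$lj_sigma[i] + a$lj_sigma[j]) / 2
      eps <- sqrt(a$lj_epsilon[i] * a$lj_epsilon[j])
      sr6 <- (sig / r)^6
      s <- s - 4 * eps * (-12 * sr6^2 + 6 * sr6) / r
      acc <- acc + s * KJNM_TO_PN
    }
  }
  expect_equal(group_pair_forces(pfm, gu, gv), acc, tolerance = 1e-9)
  expect_error(group_pair_forces(pfm, 1:10, 10:12), "disjoint")
  # groups with no pairs within cutoff
  far <- random_system(4, seed = 2, bonded = FALSE)
  pfar <- pair_forces_frame(far$system, far$frame, cutoff = 1e-3)
  expect_equal(group_pair_forces(pfar, 1:2, 3:4), 0)
})

test_that("interaction energy matches Coulomb arithmetic and is additive", {
  tw <- two_atoms(q1 = 1, q2 = -1, d = 1, sigma = 0.3, eps = 0.5)
  ie <- interaction_energy(tw$system, tw$frame, 1, 2, cutoff = 2)
  lj <- 4 * 0.5 * ((0.3)^12 - (0.3)^6)
  expect_equal(ie$mean, -138.935458 + lj, tolerance = 1e-9)
  expect_equal(sum(ie$breakdown), ie$mean, tolerance = 1e-12)
  expect_equal(unname(ie$breakdown["coulomb"]), -138.935458,
               tolerance = 1e-9)
  # beyond the cutoff the interaction is zero
  ie0 <- interaction_energy(tw$system, tw$frame, 1, 2, cutoff = 0.5)
  expect_equal(ie0$mean, 0)
  expect_error(interaction_energy(tw$system, tw$frame, integer(), 2),
               "empty group")
  expect_error(interaction_energy(tw$system, tw$frame, 1:2, 2), "disjoint")
})
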