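# Bending angles and their error propagation, hydrogen-bond detection,
# Kabsch superposition (checked against a quaternion grid-search oracle).

test_that("bending angle handles the analytic cases exactly", {
  x <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(bending_angle(x, c(1, 2, 3)), 180, tolerance = 1e-9)
  x <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  expect_equal(bending_angle(x, c(1, 2, 3)), 90, tolerance = 1e-9)
  x <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  expect_equal(bending_angle(x, c(1, 2, 3)), 60, tolerance = 1e-9)
  expect_error(bending_angle(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                             c(1, 2, 3)), "zero-length")
})

test_that("bending angle is invariant under rigid motion and outer swap", {
  set.seed(2)
  x <- matrix(rnorm(9), 3, 3)
  a0 <- bending_angle(x, c(1, 2, 3))
  R <- random_rotation(6)
  expect_equal(bending_angle(x %*% R + 2, c(1, 2, 3)), a0, tolerance = 1e-9)
  expect_equal(bending_angle(x, c(3, 2, 1)), a0, tolerance = 1e-12)
})

test_that("angle profiles average per replica and pool consistently", {
  x0 <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 1))
  frames <- list(make_frame(x0), make_frame(x0 %*% random_rotation(1)))
  ens <- trajectory_ensemble(list(frames, frames), state = "apo")
  prof <- angle_profile(ens, c(1, 2, 3), label = "probe")
  expect_equal(prof$mean, 90, tolerance = 1e-9)
  expect_equal(prof$sd, 0, tolerance = 1e-9)
  # equal-length replicas: profile mean equals the frame-pooled mean
  set.seed(5)
  reps <- lapply(1:3, function(r) lapply(1:4, function(f)
    make_frame(x0 + matrix(rnorm(12, 0, 0.05), 4, 3))))
  ens2 <- trajectory_ensemble(reps)
  prof2 <- angle_profile(ens2, c(1, 2, 3))
  pooled <- mean(unlist(lapply(reps, function(r)
    lapply(r, bending_angle, triplet = c(1, 2, 3)))))
  expect_equal(prof2$mean, pooled, tolerance = 1e-12)
})

test_that("triplet notation parses the reported helix-7 style labels", {
  expect_equal(parse_triplet("188-192-199"), c(188L, 192L, 199L))
  expect_error(parse_triplet("188-192"), "three integers")
})

test_that("angle differences reproduce the reported interdomain arithmetic", {
  # helix 7: 153.6 +/- 1.9 (apo) vs 160.8 +/- 0.6 (complex)
  h7 <- angle_difference(angle_profile_from_stats(153.6, 1.9, state = "apo"),
                         angle_profile_from_stats(160.8, 0.6, state = "holo"))
  expect_equal(round(h7$delta, 1), -7.2)
  expect_equal(round(h7$sd, 1), 2.0)
  # loop L14: 97.4 +/- 2.8 vs 120.4 +/- 4.6
  l14 <- angle_difference(angle_profile_from_stats(97.4, 2.8),
                          angle_profile_from_stats(120.4, 4.6))
  expect_equal(round(l14$delta, 1), -23.0)
  expect_equal(round(l14$sd, 1), 5.4)
})

test_that("quadrature propagation matches the reported difference row", {
  # apo / complex per-state means and SDs for the six interdomain angles;
  # the reported differences are -7.2+/-2.0, -2.3+/-0.3, -0.7+/-1.00,
  # 2.0+/-0.8, -23.0+/-5.4, -1.4+/-1.3. All but the second column are
  # consistent with full-precision quadrature to +/-0.1 degree; that column
  # is a known rounding inconsistency (its difference of printed means is
  # -2.4, not -2.3) and is excluded.
  apo <- list(c(153.6, 1.9), c(127.6, 0.2), c(113.4, 0.9),
              c(140.0, 0.6), c(97.4, 2.8), c(101.7, 0.6))
  complexed <- list(c(160.8, 0.6), c(130.0, 0.3), c(114.1, 0.5),
                    c(138.0, 0.5), c(120.4, 4.6), c(103.1, 1.2))
  reported <- list(c(-7.2, 2.0), c(-2.3, 0.3), c(-0.7, 1.00),
                   c(2.0, 0.8), c(-23.0, 5.4), c(-1.4, 1.3))
  for (k in seq_along(apo)[-2]) {
    d <- angle_difference(
      angle_profile_from_stats(apo[[k]][1], apo[[k]][2]),
      angle_profile_from_stats(complexed[[k]][1], complexed[[k]][2]))
    expect_lt(abs(d$delta - reported[[k]][1]), 0.1 + 1e-9)
    expect_lt(abs(d$sd - reported[[k]][2]), 0.1 + 1e-9)
  }
  # the excluded column: the mean is off by 0.1 but quadrature still holds
  d2 <- angle_difference(angle_profile_from_stats(127.6, 0.2),
                         angle_profile_from_stats(130.0, 0.3))
  expect_equal(d2$delta, -2.4, tolerance = 1e-9)
})

test_that("angle_difference is antisymmetric and checks triplets", {
  a <- angle_profile_from_stats(100, 1, triplet = c(1L, 2L, 3L))
  b <- angle_profile_from_stats(110, 2, triplet = c(1L, 2L, 3L))
  ab <- angle_difference(a, b); ba <- angle_difference(b, a)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$sd, ba$sd)
  cc <- angle_profile_from_stats(1, 1, triplet = c(4L, 5L, 6L))
  expect_error(angle_difference(a, cc), "different triplets")
  # identical profiles: 0 +/- sqrt(2) sd
  aa <- angle_difference(a, a)
  expect_equal(aa$delta, 0)
  expect_equal(aa$sd, sqrt(2) * 1)
})

hb_frame <- function(d_DA, bent = FALSE) {
  # atoms: donor D (1), hydrogen H (2), acceptor A (3); coordinates nm
  h <- if (bent) c(0.05, 0.09, 0) else c(0.1, 0, 0)
  make_frame(rbind(c(0, 0, 0), h, c(d_DA / 10, 0, 0)))
}

test_that("hydrogen bonds are detected by the geometric criterion", {
  ens <- trajectory_ensemble(list(list(hb_frame(2.9))))
  hb <- detect_hbonds(ens, donors = 1, acceptors = 3, hydrogens = 2)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$occupancy, 1.0)
  expect_equal(hb$mean_distance_A, 2.9, tolerance = 1e-9)
  # beyond d_max: not detected
  ens2 <- trajectory_ensemble(list(list(hb_frame(4.5))))
  expect_equal(nrow(detect_hbonds(ens2, 1, 3, hydrogens = 2)), 0)
  # bent D-H...A below the angular cutoff: rejected
  ens3 <- trajectory_ensemble(list(list(hb_frame(2.9, bent = TRUE))))
  expect_equal(nrow(detect_hbonds(ens3, 1, 3, hydrogens = 2,
                                  angle_min = 150)), 0)
})

test_that("occupancy counts the fraction of frames matching the criterion", {
  frames <- rep(list(hb_frame(2.9), hb_frame(4.5)), 5)  # alternating
  ens <- trajectory_ensemble(list(frames))
  hb <- detect_hbonds(ens, 1, 3, occ_min = 0.25)
  expect_equal(hb$occupancy, 0.5)
  # occupancy threshold drops it
  expect_equal(nrow(detect_hbonds(ens, 1, 3, occ_min = 0.75)), 0)
  expect_error(detect_hbonds(ens, integer(), 3), "nonempty")
})

test_that("superposition recovers identity and pure rotations", {
  set.seed(11)
  ref <- matrix(rnorm(30), 10, 3)
  fit <- superpose(ref, ref)
  expect_equal(fit$rmsd_A, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  R <- random_rotation(21)
  mob <- ref %*% R + 0.7
  fit2 <- superpose(mob, ref)
  expect_lt(fit2$rmsd_A, 1e-10)
  expect_equal(as.matrix(fit2$fitted), ref, tolerance = 1e-9)
  expect_error(superpose(mob[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("superposition RMSD matches the quaternion-grid oracle", {
  for (seed in c(31, 32)) {
    set.seed(seed)
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    fit <- superpose(a, b)
    oracle <- quaternion_grid_rmsd(a, b)
    expect_lt(abs(fit$rmsd_A - oracle * 10), 1e-6)
  }
})
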