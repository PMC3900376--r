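# Averaging, differencing, punctual stress, binding profiles, convergence.

pfm_from <- function(i, j, f_pn, n_atoms = 10L) {
  structure(data.frame(i = i, j = j, f_pn = f_pn),
            class = c("pair_force_matrix", "data.frame"),
            n_atoms = as.integer(n_atoms))
}

test_that("replica-first averaging and the absent-pair rule", {
  # constant pair force: mean equals it, SD 0 across replicas
  reps <- list(list(pfm_from(1, 2, 5), pfm_from(1, 2, 5)),
               list(pfm_from(1, 2, 5)))
  avg <- average_pair_forces(reps)
  expect_equal(avg$mean_pn, 5)
  expect_equal(avg$sd_pn, 0)

  # equal-length replicas: grand mean equals the pooled frame mean
  set.seed(1)
  vals <- matrix(rnorm(6), 2, 3)
  reps <- lapply(1:2, function(r) lapply(1:3, function(f)
    pfm_from(1, 2, vals[r, f])))
  avg <- average_pair_forces(reps)
  expect_equal(avg$mean_pn, mean(vals), tolerance = 1e-12)

  # a pair absent from a frame counts as zero for that frame
  reps <- list(list(pfm_from(1, 2, 6), pfm_from(3, 4, 9)))
  avg <- average_pair_forces(reps)
  expect_equal(avg$mean_pn[avg$i == 1], 3)   # 6 observed once over 2 frames
  expect_equal(avg$mean_pn[avg$i == 3], 4.5)
  expect_error(average_pair_forces(list(list())), "at least one frame")
})

test_that("force_difference: identity, antisymmetry, absent-pair rule, errors", {
  a <- avg_from_table(c(1, 2), c(2, 3), c(10, -5), 5)
  b <- avg_from_table(c(1, 3), c(2, 4), c(4, 7), 5)
  d <- force_difference(a, b)
  expect_equal(d$delta_pn[d$i == 1 & d$j == 2], 6)
  expect_equal(d$delta_pn[d$i == 2 & d$j == 3], -5)  # only in state a
  expect_equal(d$delta_pn[d$i == 3 & d$j == 4], -7)  # only in state b
  # identical inputs -> all zero
  expect_true(all(force_difference(a, a)$delta_pn == 0))
  # swap -> negation
  d2 <- force_difference(b, a)
  expect_equal(d2$delta_pn, -d$delta_pn)
  # atom count mismatch -> error
  expect_error(force_difference(a, avg_from_table(1, 2, 1, 7)),
               "atom count mismatch")
})

test_that("punctual stress equals the brute-force double loop", {
  # single-pair worked example
  d1 <- structure(data.frame(i = 3L, j = 7L, delta_pn = -5),
                  class = c("force_difference", "data.frame"), n_atoms = 10L)
  ps <- punctual_stress(d1)
  expect_equal(ps$atom, c(0, 0, 5, 0, 0, 0, 5, 0, 0, 0))
  # zero difference -> zero profile
  d0 <- structure(data.frame(i = integer(), j = integer(),
                             delta_pn = numeric()),
                  class = c("force_difference", "data.frame"), n_atoms = 4L)
  expect_equal(punctual_stress(d0)$atom, rep(0, 4))
  # random sparse cases against the oracle
  for (seed in 1:5) {
    d <- random_diff(n = 25, m = 80, seed = seed)
    expect_equal(punctual_stress(d)$atom, brute_stress(d, 25),
                 tolerance = 1e-12)
  }
  # symmetric under state swap by construction
  dn <- random_diff(seed = 42)
  dswap <- dn; dswap$delta_pn <- -dswap$delta_pn
  expect_equal(punctual_stress(dn)$atom, punctual_stress(dswap)$atom)
})

test_that("per-residue stress aggregation modes", {
  d <- structure(data.frame(i = c(1L, 2L), j = c(3L, 3L),
                            delta_pn = c(10, -20)),
                 class = c("force_difference", "data.frame"), n_atoms = 4L)
  res <- c(1L, 1L, 2L, 2L)
  ps_sum <- punctual_stress(d, res)
  expect_equal(unname(ps_sum$residue), c(30, 30))
  ps_max <- punctual_stress(d, res, residue_mode = "max")
  expect_equal(unname(ps_max$residue), c(20, 30))
  expect_error(punctual_stress(d, 1:3), "length")
})

test_that("punctual stress is invariant under rigid motion of all frames", {
  spec <- two_domain_spec(n_replicas = 1, n_frames = 25, burn_in = 200)
  built <- build_two_domain_system(spec)
  ens <- sample_ensemble(built$system, built$frame, spec, seed = 3)
  avg1 <- ensemble_average_forces(built$system, ens, spec$cutoff,
                                  lj_cutoff = spec$lj_cutoff)
  R <- random_rotation(5)
  rot <- lapply(ens$replicas, function(arr) {
    out <- arr
    for (f in seq_len(dim(arr)[1])) out[f, , ] <- arr[f, , ] %*% R + 1.5
    out
  })
  avg2 <- ensemble_average_forces(built$system,
                                  trajectory_ensemble(rot, "apo"),
                                  spec$cutoff, lj_cutoff = spec$lj_cutoff)
  d12 <- force_difference(avg1, avg2)
  expect_lt(max(punctual_stress(d12)$atom), 1e-6)
})

test_that("streaming ensemble averaging equals the per-frame route", {
  spec <- two_domain_spec(n_replicas = 2, n_frames = 10, burn_in = 100)
  built <- build_two_domain_system(spec)
  ens <- sample_ensemble(built$system, built$frame, spec, seed = 8)
  stream <- ensemble_average_forces(built$system, ens, spec$cutoff,
                                    lj_cutoff = spec$lj_cutoff)
  perframe <- average_pair_forces(lapply(ens$replicas, function(arr) {
    lapply(seq_len(dim(arr)[1]), function(f) {
      pair_forces_frame(built$system, arr[f, , ], spec$cutoff,
                        lj_cutoff = spec$lj_cutoff)
    })
  }))
  key_s <- paste(stream$i, stream$j)
  key_p <- paste(perframe$i, perframe$j)
  common <- intersect(key_s, key_p)
  expect_gt(length(common), 100)
  expect_equal(stream$mean_pn[match(common, key_s)],
               perframe$mean_pn[match(common, key_p)], tolerance = 1e-9)
  # pairs only in one route carry (numerically) zero mean force
  only_s <- setdiff(key_s, key_p)
  if (length(only_s)) {
    expect_lt(max(abs(stream$mean_pn[match(only_s, key_s)])), 1e-9)
  }
})

test_that("ligand binding profile ranks the contacted residue first", {
  # 4 protein atoms in 2 residues + 1 ligand atom near residue 2 only
  atoms <- atom_table(c("A", "B", "C", "D", "L"), c(1, 1, 2, 2, 3),
                      charge = c(0, 0, 0.5, 0.2, -1))
  sys <- molecular_system(atoms, groups = list(ligand = 5L))
  x <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(3, 0, 0), c(3.3, 0, 0),
             c(3.15, 0.4, 0))
  pfm <- pair_forces_frame(sys, x, cutoff = 1.0)
  avg <- average_pair_forces(list(list(pfm)))
  prof <- ligand_binding_profile(avg, sys, 5L)
  expect_equal(prof$residue[1], 2)
  expect_equal(prof$abs_pn[prof$residue == 1], 0)
  expect_error(ligand_binding_profile(avg, sys, integer()), "empty")
})

test_that("designed anchors dominate the synthetic binding profile", {
  spec <- two_domain_spec(n_replicas = 1, n_frames = 150, burn_in = 500)
  built <- build_two_domain_system(spec)
  holo <- make_holo(built, spec)
  ens <- sample_ensemble(holo$system, holo$frame, spec, seed = 17,
                         state = "holo")
  avg <- ensemble_average_forces(holo$system, ens, spec$cutoff,
                                 lj_cutoff = spec$lj_cutoff)
  lig <- holo$system$groups$ligand
  # per ligand, the top-ranked protein residue is one of its designed
  # anchors (charged pathway residues rank high too, by design, so the
  # strict all-anchors-top-k form is not asserted)
  for (m in seq_along(lig)) {
    prof_m <- ligand_binding_profile(avg, holo$system, lig[m])
    expect_true(prof_m$residue[1] %in% spec$anchor_residues[[m]])
  }
  prof <- ligand_binding_profile(avg, holo$system, lig)
  med <- stats::median(prof$abs_pn)
  expect_true(all(prof$abs_pn[prof$residue %in% built$truth$binding] > med))
})

test_that("convergence profile flags drift and accepts stationary series", {
  const <- convergence_profile(rep(3.3, 100))
  expect_true(const$converged)
  expect_equal(const$running_mean, rep(3.3, 100))
  expect_equal(const$half_difference, 0)
  drift <- convergence_profile(seq(0, 10, length.out = 200), tol = 0.5)
  expect_false(drift$converged)
  expect_error(convergence_profile(1), "at least 2")
  set.seed(4)
  x <- rnorm(5000)
  noise <- convergence_profile(x)
  expect_equal(noise$running_mean[5000], mean(x), tolerance = 1e-12)
  expect_equal(noise$half_difference,
               mean(x[2501:5000]) - mean(x[1:2500]), tolerance = 1e-12)
})
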