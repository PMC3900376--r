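# Analytic potential energy and atomic forces for the supported interaction
# terms: harmonic bonds, harmonic angles, periodic dihedrals, plain-cutoff
# Coulomb and 12-6 Lennard-Jones. The same kernels back the pair-force
# engine, the energy minimizer and the Langevin sampler. All forces are in
# kJ/mol/nm on coordinates in nm.

MIN_DIST <- 1e-6  # nm; below this a nonbonded pair is singular

vnorm <- function(m) sqrt(rowSums(m * m))

#' Enumerate nonbonded candidate pairs
#'
#' All atom pairs within `cutoff` (optionally plus a `skin` margin for reuse
#' across frames of a fluctuating trajectory) that are not excluded and for
#' which at least one interaction parameter is nonzero.
#'
#' @param system a `molecular_system`.
#' @param frame coordinates (nm) used for the distance test.
#' @param cutoff Coulomb cutoff, nm.
#' @param skin extra margin added to the cutoffs, nm.
#' @param lj_cutoff Lennard-Jones cutoff, nm (defaults to `cutoff`).
#' @return two-column integer matrix (i < j).
#' @export
nonbonded_pairs <- function(system, frame, cutoff, skin = 0,
                            lj_cutoff = cutoff) {
  n <- n_atoms(system)
  if (n < 2) return(matrix(integer(), ncol = 2))
  cmb <- t(utils::combn(n, 2L))
  x <- as.matrix(frame)
  d <- vnorm(x[cmb[, 1], , drop = FALSE] - x[cmb[, 2], , drop = FALSE])
  a <- system$atoms
  qq <- a$charge[cmb[, 1]] * a$charge[cmb[, 2]]
  ee <- a$lj_epsilon[cmb[, 1]] * a$lj_epsilon[cmb[, 2]]
  keep <- (qq != 0 & d <= cutoff + skin) | (ee > 0 & d <= lj_cutoff + skin)
  if (nrow(system$exclusions)) {
    exk <- paste(system$exclusions[, 1], system$exclusions[, 2])
    keep <- keep & !(paste(cmb[, 1], cmb[, 2]) %in% exk)
  }
  cmb[keep, , drop = FALSE]
}

# Precomputed per-pair nonbonded parameters for a fixed candidate list;
# avoids atom-table lookups in inner loops (minimizer, sampler, streaming
# averages).
nb_cache <- function(system, pairs) {
  a <- system$atoms
  list(pairs = pairs,
       qq = .fda_const$ke_coulomb * a$charge[pairs[, 1]] * a$charge[pairs[, 2]],
       sig = (a$lj_sigma[pairs[, 1]] + a$lj_sigma[pairs[, 2]]) / 2,
       eps = sqrt(a$lj_epsilon[pairs[, 1]] * a$lj_epsilon[pairs[, 2]]),
       idx = c(pairs[, 1], pairs[, 2]))
}

# dU/dr (kJ/mol/nm^2... per nm) for cached pairs at separations r, with the
# two cutoffs applied; returns a vector aligned with cache$pairs.
nb_dudr_cached <- function(cache, r, cutoff, lj_cutoff) {
  dudr <- numeric(length(r))
  inc <- cache$qq != 0 & r <= cutoff
  if (any(inc)) dudr[inc] <- -cache$qq[inc] / r[inc]^2
  inl <- cache$eps > 0 & r <= lj_cutoff
  if (any(inl)) {
    sr6 <- (cache$sig[inl] / r[inl])^6
    dudr[inl] <- dudr[inl] +
      4 * cache$eps[inl] * (-12 * sr6^2 + 6 * sr6) / r[inl]
  }
  dudr
}

# dU/dr and energy for the nonbonded interaction of given pairs at
# separations r (no cutoff masking; callers apply it).
# Returns list(e_coul, e_lj, dudr_coul, dudr_lj).
nonbonded_kernel <- function(system, pairs, r) {
  a <- system$atoms
  qq <- a$charge[pairs[, 1]] * a$charge[pairs[, 2]]
  sig <- (a$lj_sigma[pairs[, 1]] + a$lj_sigma[pairs[, 2]]) / 2
  eps <- sqrt(a$lj_epsilon[pairs[, 1]] * a$lj_epsilon[pairs[, 2]])
  ke <- .fda_const$ke_coulomb
  e_coul <- ke * qq / r
  dudr_coul <- -ke * qq / r^2
  sr6 <- ifelse(eps > 0, (sig / r)^6, 0)
  e_lj <- 4 * eps * (sr6^2 - sr6)
  dudr_lj <- ifelse(eps > 0, 4 * eps * (-12 * sr6^2 + 6 * sr6) / r, 0)
  list(e_coul = e_coul, e_lj = e_lj, dudr_coul = dudr_coul, dudr_lj = dudr_lj)
}

# Angle geometry: value (radians) and gradient wrt the three atoms.
angle_kernel <- function(xi, xj, xk) {
  u <- xi - xj; v <- xk - xj
  lu <- sqrt(sum(u * u)); lv <- sqrt(sum(v * v))
  if (lu < MIN_DIST || lv < MIN_DIST) stop("zero-length arm in angle term")
  uh <- u / lu; vh <- v / lv
  ct <- max(-1, min(1, sum(uh * vh)))
  st <- sqrt(max(1 - ct^2, 1e-24))
  theta <- acos(ct)
  dth_i <- (ct * uh - vh) / (lu * st)
  dth_k <- (ct * vh - uh) / (lv * st)
  list(theta = theta, d_i = dth_i, d_j = -(dth_i + dth_k), d_k = dth_k,
       degenerate = st < 1e-8)
}

skew <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

# Dihedral geometry: value (radians; sign convention
# phi = atan2((n1 x n2) . b2hat, n1 . n2)) and exact gradient, assembled by
# the chain rule through n1 = b1 x b2, n2 = b2 x b3 with skew-matrix
# Jacobians (d(a x b) = -skew(b) da + skew(a) db).
dihedral_kernel <- function(xi, xj, xk, xl) {
  b1 <- xj - xi; b2 <- xk - xj; b3 <- xl - xk
  sb1 <- skew(b1); sb2 <- skew(b2); sb3 <- skew(b3)
  n1 <- sb1 %*% b2; n2 <- sb2 %*% b3
  m <- skew(n1) %*% n2
  lb2 <- sqrt(sum(b2 * b2))
  y <- sum(m * b2) / lb2
  cc <- sum(n1 * n2)
  phi <- atan2(y, cc)
  s1 <- sum(n1 * n1); s2 <- sum(n2 * n2)
  degenerate <- s1 < 1e-18 || s2 < 1e-18
  denom <- max(y^2 + cc^2, 1e-24)
  sn1 <- skew(as.vector(n1)); sn2 <- skew(as.vector(n2))
  my <- m / lb2 - (sum(m * b2) / lb2^3) * b2  # d y / d b2 (direct part)
  grad_at <- function(Jb1, Jb2, Jb3) {
    # Jb* are scalars in {-1, 0, 1} standing for that multiple of identity
    Jn1 <- -sb2 * Jb1 + sb1 * Jb2
    Jn2 <- -sb3 * Jb2 + sb2 * Jb3
    Jm <- -sn2 %*% Jn1 + sn1 %*% Jn2
    grad_c <- t(Jn1) %*% n2 + t(Jn2) %*% n1
    grad_y <- t(Jm) %*% (b2 / lb2) + Jb2 * my
    as.vector((cc * grad_y - y * grad_c) / denom)
  }
  list(phi = phi,
       d_i = grad_at(-1, 0, 0),
       d_j = grad_at(1, -1, 0),
       d_k = grad_at(0, 1, -1),
       d_l = grad_at(0, 0, 1),
       degenerate = degenerate)
}

#' Total potential energy of a configuration
#'
#' @param system a `molecular_system`.
#' @param frame coordinates, nm.
#' @param cutoff nonbonded cutoff, nm.
#' @param pairs optional precomputed candidate pair list (see
#'   [nonbonded_pairs()]); pairs beyond the cutoffs at this frame
#'   contribute 0.
#' @param lj_cutoff Lennard-Jones cutoff, nm (defaults to `cutoff`).
#' @return energy in kJ/mol, with per-kind breakdown in attributes.
#' @export
system_energy <- function(system, frame, cutoff = 1.2, pairs = NULL,
                          lj_cutoff = cutoff) {
  x <- as.matrix(frame)
  e <- c(bond = 0, angle = 0, dihedral = 0, coulomb = 0, lj = 0)
  b <- system$bonds
  if (nrow(b)) {
    r <- vnorm(x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE])
    e["bond"] <- sum(0.5 * b$k_b * (r - b$r0)^2)
  }
  an <- system$angles
  if (nrow(an)) {
    for (t in seq_len(nrow(an))) {
      g <- angle_kernel(x[an$i[t], ], x[an$j[t], ], x[an$k[t], ])
      e["angle"] <- e["angle"] +
        0.5 * an$k_theta[t] * (g$theta - deg2rad(an$theta0[t]))^2
    }
  }
  dh <- system$dihedrals
  if (nrow(dh)) {
    for (t in seq_len(nrow(dh))) {
      g <- dihedral_kernel(x[dh$i[t], ], x[dh$j[t], ], x[dh$k[t], ], x[dh$l[t], ])
      e["dihedral"] <- e["dihedral"] +
        dh$k_phi[t] * (1 + cos(dh$mult[t] * g$phi - deg2rad(dh$phase[t])))
    }
  }
  if (is.null(pairs)) {
    pairs <- nonbonded_pairs(system, frame, cutoff, lj_cutoff = lj_cutoff)
  }
  if (nrow(pairs)) {
    r <- vnorm(x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE])
    if (any(r < MIN_DIST)) stop("overlapping atoms in a nonbonded pair")
    nb <- nonbonded_kernel(system, pairs, r)
    e["coulomb"] <- sum(nb$e_coul[r <= cutoff & nb$e_coul != 0])
    e["lj"] <- sum(nb$e_lj[r <= lj_cutoff])
  }
  structure(sum(e), breakdown = e)
}

#' Analytic atomic forces
#'
#' @inheritParams system_energy
#' @param cache optional [nb_cache()]-style precomputed pair parameters
#'   (inner-loop use; implies `pairs`).
#' @return n x 3 matrix of forces (kJ/mol/nm), the negative energy gradient.
#' @export
system_forces <- function(system, frame, cutoff = 1.2, pairs = NULL,
                          lj_cutoff = cutoff, cache = NULL) {
  x <- as.matrix(frame)
  n <- nrow(x)
  f <- matrix(0, n, 3)
  add_pair_forces <- function(f, idx_i, idx_j, dudr, dx, r) {
    # force on i along +dx (dx = x_i - x_j) with magnitude -dudr
    fv <- dx * (-dudr / r)
    s <- rowsum(rbind(fv, -fv), c(idx_i, idx_j))
    who <- as.integer(rownames(s))
    f[who, ] <- f[who, ] + s
    f
  }
  b <- system$bonds
  if (nrow(b)) {
    dx <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
    r <- vnorm(dx)
    f <- add_pair_forces(f, b$i, b$j, b$k_b * (r - b$r0), dx, r)
  }
  an <- system$angles
  if (nrow(an)) {
    for (t in seq_len(nrow(an))) {
      g <- angle_kernel(x[an$i[t], ], x[an$j[t], ], x[an$k[t], ])
      coef <- -an$k_theta[t] * (g$theta - deg2rad(an$theta0[t]))
      f[an$i[t], ] <- f[an$i[t], ] + coef * g$d_i
      f[an$j[t], ] <- f[an$j[t], ] + coef * g$d_j
      f[an$k[t], ] <- f[an$k[t], ] + coef * g$d_k
    }
  }
  dh <- system$dihedrals
  if (nrow(dh)) {
    for (t in seq_len(nrow(dh))) {
      g <- dihedral_kernel(x[dh$i[t], ], x[dh$j[t], ], x[dh$k[t], ], x[dh$l[t], ])
      coef <- dh$k_phi[t] * dh$mult[t] *
        sin(dh$mult[t] * g$phi - deg2rad(dh$phase[t]))
      f[dh$i[t], ] <- f[dh$i[t], ] + coef * g$d_i
      f[dh$j[t], ] <- f[dh$j[t], ] + coef * g$d_j
      f[dh$k[t], ] <- f[dh$k[t], ] + coef * g$d_k
      f[dh$l[t], ] <- f[dh$l[t], ] + coef * g$d_l
    }
  }
  if (is.null(cache)) {
    if (is.null(pairs)) {
      pairs <- nonbonded_pairs(system, frame, cutoff, lj_cutoff = lj_cutoff)
    }
    cache <- nb_cache(system, pairs)
  }
  pairs <- cache$pairs
  if (nrow(pairs)) {
    dx <- x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE]
    r <- vnorm(dx)
    if (any(r < MIN_DIST)) stop("overlapping atoms in a nonbonded pair")
    dudr <- nb_dudr_cached(cache, r, cutoff, lj_cutoff)
    nz <- dudr != 0
    if (any(nz)) {
      f <- add_pair_forces(f, pairs[nz, 1], pairs[nz, 2], dudr[nz],
                           dx[nz, , drop = FALSE], r[nz])
    }
  }
  f
}

#' Minimize the potential energy of a configuration
#'
#' L-BFGS-B on the analytic gradient; adequate for the bead models this
#' package generates (a few hundred degrees of freedom).
#'
#' @inheritParams system_energy
#' @param maxit iteration cap.
#' @return list with `frame` (minimized coordinates), `energy`, `converged`.
#' @export
minimize_energy <- function(system, frame, cutoff = 1.2, maxit = 20000,
                            lj_cutoff = cutoff) {
  x0 <- as.vector(as.matrix(frame))
  n <- n_atoms(system)
  pairs <- nonbonded_pairs(system, frame, cutoff, skin = 0.5,
                           lj_cutoff = lj_cutoff)
  cache <- nb_cache(system, pairs)
  fn <- function(p) as.numeric(system_energy(system, matrix(p, n, 3),
                                             cutoff, pairs, lj_cutoff))
  gr <- function(p) -as.vector(system_forces(system, matrix(p, n, 3),
                                             cutoff, lj_cutoff = lj_cutoff,
                                             cache = cache))
  opt <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10))
  list(frame = make_frame(matrix(opt$par, n, 3)), energy = opt$value,
       converged = opt$convergence == 0)
}
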