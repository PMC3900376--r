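# Pairwise force computation: every interaction term is attributed to atom
# pairs. Two-body terms (bonds, Coulomb, LJ) are central by nature; angle and
# dihedral forces are decomposed into central forces on all atom pairs of the
# term such that the per-atom sums reproduce the analytic atomic forces
# (exact for 3-body, least-squares for 4-body; both are generically exact
# since a torque-free, translation-free force set on m atoms has as many
# degrees of freedom as the m(m-1)/2 pair axes for m = 3, 4).
#
# Scalarization follows the FDA convention: the stored value is the force
# norm with a sign from the projection on the interatomic axis - positive
# repulsive, negative attractive.

#' Decompose a multi-atom force set into central pair forces
#'
#' Given atom positions and the analytic forces a single interaction term
#' exerts on them, finds signed magnitudes on every atom pair axis whose
#' per-atom sums reproduce those forces. Degenerate (collinear/planar)
#' geometries fall back to the minimum-norm solution and are flagged.
#'
#' @param idx atom indices of the term (length 3 or 4).
#' @param x full coordinate matrix, nm.
#' @param forces per-atom force matrix for the term (rows follow `idx`).
#' @return data.frame (i, j, scalar, fx, fy, fz, degenerate) where scalar is
#'   the signed central magnitude (kJ/mol/nm, positive repulsive) and
#'   (fx,fy,fz) the force on i from j.
#' @export
decompose_central <- function(idx, x, forces) {
  m <- length(idx)
  pr <- t(utils::combn(m, 2L))
  np <- nrow(pr)
  A <- matrix(0, 3L * m, np)
  uh <- matrix(0, np, 3)
  for (p in seq_len(np)) {
    a <- pr[p, 1]; b <- pr[p, 2]
    d <- x[idx[a], ] - x[idx[b], ]
    r <- sqrt(sum(d * d))
    if (r < MIN_DIST) stop("coincident atoms in multi-body term")
    u <- d / r
    uh[p, ] <- u
    A[(3 * a - 2):(3 * a), p] <- u
    A[(3 * b - 2):(3 * b), p] <- -u
  }
  rhs <- as.vector(t(forces))
  qrA <- qr(A)
  degenerate <- qrA$rank < np
  if (!degenerate) {
    mag <- qr.coef(qrA, rhs)
    resid <- sqrt(sum((A %*% mag - rhs)^2))
    if (resid > 1e-8 * max(1, sqrt(sum(rhs^2)))) degenerate <- TRUE
  }
  if (degenerate) {
    sv <- svd(A)
    keep <- sv$d > 1e-10 * max(sv$d)
    mag <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% rhs) / sv$d[keep])
    mag <- as.vector(mag)
  }
  data.frame(i = idx[pr[, 1]], j = idx[pr[, 2]], scalar = mag,
             fx = mag * uh[, 1], fy = mag * uh[, 2], fz = mag * uh[, 3],
             degenerate = degenerate)
}

#' Signed scalar from a pair force vector
#'
#' Norm of the force on atom i, with positive sign when the projection on the
#' i<-j axis is repulsive and negative when attractive. Returned in pN.
#'
#' @param force 3-vector, force on i from j (kJ/mol/nm).
#' @param xi,xj positions of i and j (nm).
#' @export
scalarize_pair_force <- function(force, xi, xj) {
  d <- xi - xj
  r <- sqrt(sum(d * d))
  if (r <= 0) stop("pair distance must be positive")
  proj <- sum(force * d) / r
  convert_force(sign(proj) * sqrt(sum(force * force)), "kJ/mol/nm", "pN")
}

# identity of atoms three bonds apart (1-4 pairs), used for nonbonded scaling
pairs_14 <- function(bonds, n) {
  if (!nrow(bonds)) return(character())
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], bonds$j[r])
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], bonds$i[r])
  }
  out <- character()
  for (a in seq_len(n)) {
    for (b in adj[[a]]) for (cc in adj[[b]]) for (d in adj[[cc]]) {
      if (d > a && d != b && cc != a) out <- c(out, paste(a, d))
    }
  }
  unique(out)
}

#' Per-frame pairwise forces over all interaction types
#'
#' Computes vector pair forces from every bonded term (with multi-body
#' decomposition) and from Coulomb/LJ interactions within the cutoff
#' (exclusions applied to nonbonded terms only), then scalarizes them.
#'
#' @param system a `molecular_system`.
#' @param frame coordinates, nm.
#' @param cutoff nonbonded cutoff, nm.
#' @param vectors keep the vector stage (one row per term contribution) in
#'   `attr(, "vectors")` for validation work.
#' @param scale14 scaling factor for 1-4 nonbonded pairs (default 1: full
#'   strength).
#' @param pairs optional precomputed nonbonded candidate list.
#' @param lj_cutoff Lennard-Jones cutoff, nm (defaults to `cutoff`).
#' @return a `pair_force_matrix`: data.frame (i, j, f_pn) of total signed
#'   scalar pair forces, with per-kind breakdown in `attr(, "breakdown")` and
#'   the count of degenerate multi-body terms in `attr(, "n_degenerate")`.
#' @export
pair_forces_frame <- function(system, frame, cutoff = 1.2, vectors = FALSE,
                              scale14 = 1, pairs = NULL,
                              lj_cutoff = cutoff) {
  stopifnot(cutoff > 0)
  x <- as.matrix(frame)
  rows <- list()
  n_degenerate <- 0L
  b <- system$bonds
  if (nrow(b)) {
    dx <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
    r <- vnorm(dx)
    s <- -b$k_b * (r - b$r0)  # -dU/dr: positive repulsive
    rows$bond <- data.frame(i = b$i, j = b$j, kind = "bond", scalar = s,
                            fx = s * dx[, 1] / r, fy = s * dx[, 2] / r,
                            fz = s * dx[, 3] / r)
  }
  an <- system$angles
  if (nrow(an)) {
    out <- vector("list", nrow(an))
    for (t in seq_len(nrow(an))) {
      idx <- c(an$i[t], an$j[t], an$k[t])
      g <- angle_kernel(x[idx[1], ], x[idx[2], ], x[idx[3], ])
      coef <- -an$k_theta[t] * (g$theta - deg2rad(an$theta0[t]))
      fterm <- rbind(coef * g$d_i, coef * g$d_j, coef * g$d_k)
      dec <- decompose_central(idx, x, fterm)
      if (dec$degenerate[1]) n_degenerate <- n_degenerate + 1L
      out[[t]] <- dec
    }
    ang <- do.call(rbind, out)
    ang$kind <- "angle"
    rows$angle <- ang[, c("i", "j", "kind", "scalar", "fx", "fy", "fz")]
  }
  dh <- system$dihedrals
  if (nrow(dh)) {
    out <- vector("list", nrow(dh))
    for (t in seq_len(nrow(dh))) {
      idx <- c(dh$i[t], dh$j[t], dh$k[t], dh$l[t])
      g <- dihedral_kernel(x[idx[1], ], x[idx[2], ], x[idx[3], ], x[idx[4], ])
      coef <- dh$k_phi[t] * dh$mult[t] *
        sin(dh$mult[t] * g$phi - deg2rad(dh$phase[t]))
      fterm <- rbind(coef * g$d_i, coef * g$d_j, coef * g$d_k, coef * g$d_l)
      dec <- decompose_central(idx, x, fterm)
      if (dec$degenerate[1] || g$degenerate) n_degenerate <- n_degenerate + 1L
      out[[t]] <- dec
    }
    dhh <- do.call(rbind, out)
    dhh$kind <- "dihedral"
    rows$dihedral <- dhh[, c("i", "j", "kind", "scalar", "fx", "fy", "fz")]
  }
  if (is.null(pairs)) {
    pairs <- nonbonded_pairs(system, frame, cutoff, lj_cutoff = lj_cutoff)
  }
  if (nrow(pairs)) {
    dx <- x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE]
    r <- vnorm(dx)
    if (any(r < MIN_DIST)) stop("overlapping atoms in a nonbonded pair")
    nb <- nonbonded_kernel(system, pairs, r)
    scale <- rep(1, nrow(pairs))
    if (scale14 != 1) {
      in14 <- paste(pairs[, 1], pairs[, 2]) %in%
        pairs_14(chemical_bonds(system), n_atoms(system))
      scale[in14] <- scale14
    }
    ux <- dx / r
    masks <- list(coulomb = r <= cutoff, lj = r <= lj_cutoff)
    for (kind in c("coulomb", "lj")) {
      s <- -scale * (if (kind == "coulomb") nb$dudr_coul else nb$dudr_lj)
      nz <- s != 0 & masks[[kind]]
      if (any(nz)) {
        rows[[kind]] <- data.frame(
          i = pairs[nz, 1], j = pairs[nz, 2], kind = kind, scalar = s[nz],
          fx = s[nz] * ux[nz, 1], fy = s[nz] * ux[nz, 2],
          fz = s[nz] * ux[nz, 3])
      }
    }
  }
  all_rows <- do.call(rbind, unname(rows))
  if (is.null(all_rows)) {
    all_rows <- data.frame(i = integer(), j = integer(), kind = character(),
                           scalar = numeric(), fx = numeric(), fy = numeric(),
                           fz = numeric())
  }
  # canonical i < j; flipping the pair negates the vector but not the scalar
  flip <- all_rows$i > all_rows$j
  if (any(flip)) {
    tmp <- all_rows$i[flip]
    all_rows$i[flip] <- all_rows$j[flip]
    all_rows$j[flip] <- tmp
    all_rows[flip, c("fx", "fy", "fz")] <- -all_rows[flip, c("fx", "fy", "fz")]
  }
  all_rows$f_pn <- convert_force(all_rows$scalar, "kJ/mol/nm", "pN")
  key <- paste(all_rows$i, all_rows$j)
  tot <- rowsum(all_rows$f_pn, key)
  ij <- do.call(rbind, strsplit(rownames(tot), " "))
  pfm <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    f_pn = as.vector(tot))
  pfm <- pfm[order(pfm$i, pfm$j), , drop = FALSE]
  rownames(pfm) <- NULL
  structure(pfm, class = c("pair_force_matrix", "data.frame"),
            n_atoms = n_atoms(system),
            breakdown = all_rows[, c("i", "j", "kind", "f_pn")],
            vectors = if (vectors)
              all_rows[, c("i", "j", "kind", "fx", "fy", "fz")],
            n_degenerate = n_degenerate)
}

#' Sum signed pair forces between two atom groups
#'
#' The group-group force F_uv is the sum of signed scalar pair forces over
#' atom pairs spanning the two (disjoint) groups, in pN.
#'
#' @param pfm a `pair_force_matrix`.
#' @param group_u,group_v integer atom-index vectors.
#' @export
group_pair_forces <- function(pfm, group_u, group_v) {
  if (length(intersect(group_u, group_v))) {
    stop("groups must be disjoint at the atom level")
  }
  span <- (pfm$i %in% group_u & pfm$j %in% group_v) |
    (pfm$i %in% group_v & pfm$j %in% group_u)
  sum(pfm$f_pn[span])
}

as_fda_ensemble <- function(traj) {
  if (inherits(traj, "trajectory_ensemble")) return(traj)
  if (inherits(traj, "fda_frame") || is.matrix(traj)) {
    return(trajectory_ensemble(list(list(make_frame(traj)))))
  }
  if (is.list(traj)) return(trajectory_ensemble(list(traj)))
  stop("cannot interpret trajectory input")
}

#' Nonbonded interaction energy between two groups
#'
#' Sum of Coulomb and Lennard-Jones pair energies across the two disjoint
#' groups, averaged per replica and then across replicas.
#'
#' @param system a `molecular_system`.
#' @param traj a frame, list of frames, or `trajectory_ensemble`.
#' @param group_a,group_b atom-index vectors.
#' @param cutoff nonbonded cutoff, nm.
#' @return list with `mean`, `sd` (across replicas; NA for one replica),
#'   `per_replica`, and mean per-kind `breakdown` (kJ/mol).
#' @export
interaction_energy <- function(system, traj, group_a, group_b, cutoff = 1.2) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  ens <- as_fda_ensemble(traj)
  per_rep <- matrix(0, length(ens$replicas), 2,
                    dimnames = list(NULL, c("coulomb", "lj")))
  for (rp in seq_along(ens$replicas)) {
    arr <- ens$replicas[[rp]]
    acc <- c(coulomb = 0, lj = 0)
    for (fr in seq_len(dim(arr)[1])) {
      x <- arr[fr, , ]
      pairs <- nonbonded_pairs(system, x, cutoff)
      span <- (pairs[, 1] %in% group_a & pairs[, 2] %in% group_b) |
        (pairs[, 1] %in% group_b & pairs[, 2] %in% group_a)
      pairs <- pairs[span, , drop = FALSE]
      if (nrow(pairs)) {
        r <- vnorm(x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE])
        nb <- nonbonded_kernel(system, pairs, r)
        acc <- acc + c(coulomb = sum(nb$e_coul), lj = sum(nb$e_lj))
      }
    }
    per_rep[rp, ] <- acc / dim(arr)[1]
  }
  totals <- rowSums(per_rep)
  list(mean = mean(totals),
       sd = if (length(totals) > 1) stats::sd(totals) else NA_real_,
       per_replica = totals,
       breakdown = colMeans(per_rep))
}
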