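# Replica-aware averaging of pairwise forces, state differencing, punctual
# stress and binding-pocket profiles. Averaging is replica-first: a pair
# absent from a frame contributes 0 for that frame, the per-replica mean is
# the frame average, the grand mean is the unweighted mean of replica means
# and the SD is taken across replica means.

pair_key <- function(i, j) paste(i, j)

new_averaged_pair_forces <- function(i, j, replica_means, n_frames, n_atoms,
                                     state = "state") {
  rm <- as.matrix(replica_means)
  mean_pn <- rowMeans(rm)
  sd_pn <- if (ncol(rm) > 1) apply(rm, 1, stats::sd) else rep(NA_real_, nrow(rm))
  keep <- apply(rm != 0, 1, any)
  df <- data.frame(i = i, j = j, mean_pn = mean_pn, sd_pn = sd_pn)[keep, ,
                                                                   drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("averaged_pair_forces", "data.frame"),
            replica_means = rm[keep, , drop = FALSE],
            n_frames = n_frames, n_atoms = n_atoms, state = state)
}

#' Average pairwise forces over frames and replicas
#'
#' @param matrices_by_replica list with one entry per replica, each a list of
#'   `pair_force_matrix` objects (one per frame).
#' @param state state label attached to the result.
#' @return an `averaged_pair_forces` data.frame (i, j, mean_pn, sd_pn) with
#'   per-replica means in `attr(, "replica_means")`.
#' @export
average_pair_forces <- function(matrices_by_replica, state = "state") {
  if (!length(matrices_by_replica)) stop("need at least one replica")
  if (any(vapply(matrices_by_replica, length, integer(1)) == 0L)) {
    stop("every replica must contain at least one frame")
  }
  nat <- unique(unlist(lapply(matrices_by_replica, function(rep)
    vapply(rep, function(m) attr(m, "n_atoms"), integer(1)))))
  if (length(nat) != 1L) stop("inconsistent atom count across frames")
  keys <- unique(unlist(lapply(matrices_by_replica, function(rep)
    lapply(rep, function(m) pair_key(m$i, m$j)))))
  keys <- sort(keys)
  nr <- length(matrices_by_replica)
  rm <- matrix(0, length(keys), nr)
  nf <- integer(nr)
  for (rp in seq_len(nr)) {
    acc <- stats::setNames(numeric(length(keys)), keys)
    frames <- matrices_by_replica[[rp]]
    nf[rp] <- length(frames)
    for (m in frames) {
      k <- pair_key(m$i, m$j)
      acc[k] <- acc[k] + m$f_pn
    }
    rm[, rp] <- acc / nf[rp]
  }
  ij <- do.call(rbind, strsplit(keys, " "))
  ord <- order(as.integer(ij[, 1]), as.integer(ij[, 2]))
  new_averaged_pair_forces(as.integer(ij[ord, 1]), as.integer(ij[ord, 2]),
                           rm[ord, , drop = FALSE], nf, nat, state)
}

# ---- streaming ensemble averaging over a fixed pair universe --------------

#' Precompute the pair universe of a system near a reference geometry
#'
#' All pairs that can carry force: pairs of every bonded term plus nonbonded
#' candidates within cutoff + skin of the reference frame. Used to stream
#' per-frame scalar forces without materializing per-frame tables.
#'
#' @param system a `molecular_system`.
#' @param frame reference coordinates, nm.
#' @param cutoff nonbonded cutoff, nm.
#' @param skin candidate-list margin, nm (must exceed typical per-atom
#'   excursions from the reference geometry).
#' @export
pair_universe <- function(system, frame, cutoff = 1.2, skin = 0.4,
                          lj_cutoff = cutoff) {
  keys <- character()
  add <- function(i, j) paste(pmin(i, j), pmax(i, j))
  if (nrow(system$bonds)) keys <- c(keys, add(system$bonds$i, system$bonds$j))
  if (nrow(system$angles)) {
    a <- system$angles
    keys <- c(keys, add(a$i, a$j), add(a$j, a$k), add(a$i, a$k))
  }
  if (nrow(system$dihedrals)) {
    d <- system$dihedrals
    for (cols in list(c("i", "j"), c("i", "k"), c("i", "l"),
                      c("j", "k"), c("j", "l"), c("k", "l"))) {
      keys <- c(keys, add(d[[cols[1]]], d[[cols[2]]]))
    }
  }
  nb <- nonbonded_pairs(system, frame, cutoff, skin = skin,
                        lj_cutoff = lj_cutoff)
  keys <- unique(c(keys, add(nb[, 1], nb[, 2])))
  ij <- do.call(rbind, strsplit(keys, " "))
  ij <- cbind(as.integer(ij[, 1]), as.integer(ij[, 2]))
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  lookup <- stats::setNames(seq_len(nrow(ij)), paste(ij[, 1], ij[, 2]))
  structure(list(pairs = ij, lookup = lookup, nonbonded = nb,
                 nb_pos = unname(lookup[paste(nb[, 1], nb[, 2])]),
                 bond_pos = if (nrow(system$bonds))
                   unname(lookup[paste(pmin(system$bonds$i, system$bonds$j),
                                       pmax(system$bonds$i, system$bonds$j))]),
                 nb_cache = nb_cache(system, nb),
                 cutoff = cutoff, lj_cutoff = lj_cutoff,
                 n_atoms = n_atoms(system)),
            class = "pair_universe")
}

# scalar force vector (pN) over the universe for one frame
scalar_forces_frame <- function(system, x, uni) {
  out <- numeric(nrow(uni$pairs))
  b <- system$bonds
  if (nrow(b)) {
    dx <- x[b$i, , drop = FALSE] - x[b$j, , drop = FALSE]
    r <- vnorm(dx)
    out[uni$bond_pos] <- out[uni$bond_pos] - b$k_b * (r - b$r0)
  }
  an <- system$angles
  if (nrow(an)) {
    for (t in seq_len(nrow(an))) {
      idx <- c(an$i[t], an$j[t], an$k[t])
      g <- angle_kernel(x[idx[1], ], x[idx[2], ], x[idx[3], ])
      coef <- -an$k_theta[t] * (g$theta - deg2rad(an$theta0[t]))
      dec <- decompose_central(idx, x,
                               rbind(coef * g$d_i, coef * g$d_j, coef * g$d_k))
      pos <- uni$lookup[paste(pmin(dec$i, dec$j), pmax(dec$i, dec$j))]
      out[pos] <- out[pos] + dec$scalar
    }
  }
  dh <- system$dihedrals
  if (nrow(dh)) {
    for (t in seq_len(nrow(dh))) {
      idx <- c(dh$i[t], dh$j[t], dh$k[t], dh$l[t])
      g <- dihedral_kernel(x[idx[1], ], x[idx[2], ], x[idx[3], ], x[idx[4], ])
      coef <- dh$k_phi[t] * dh$mult[t] *
        sin(dh$mult[t] * g$phi - deg2rad(dh$phase[t]))
      dec <- decompose_central(idx, x, rbind(coef * g$d_i, coef * g$d_j,
                                             coef * g$d_k, coef * g$d_l))
      pos <- uni$lookup[paste(pmin(dec$i, dec$j), pmax(dec$i, dec$j))]
      out[pos] <- out[pos] + dec$scalar
    }
  }
  nb <- uni$nonbonded
  if (nrow(nb)) {
    dx <- x[nb[, 1], , drop = FALSE] - x[nb[, 2], , drop = FALSE]
    r <- vnorm(dx)
    dudr <- nb_dudr_cached(uni$nb_cache, r, uni$cutoff, uni$lj_cutoff)
    nz <- dudr != 0
    if (any(nz)) {
      pos <- uni$nb_pos[nz]
      out[pos] <- out[pos] - dudr[nz]
    }
  }
  convert_force(out, "kJ/mol/nm", "pN")
}

#' Average pairwise forces of a replica ensemble (streaming)
#'
#' Equivalent to running [pair_forces_frame()] on every frame and
#' [average_pair_forces()] on the result, but accumulates running sums over a
#' fixed pair universe instead of materializing per-frame tables.
#'
#' @param system a `molecular_system`.
#' @param ensemble a `trajectory_ensemble`.
#' @param cutoff nonbonded cutoff, nm.
#' @param skin candidate-list margin, nm.
#' @return an `averaged_pair_forces` object.
#' @export
ensemble_average_forces <- function(system, ensemble, cutoff = 1.2,
                                    skin = 0.4, lj_cutoff = cutoff) {
  ens <- as_fda_ensemble(ensemble)
  if (dim(ens$replicas[[1]])[2] != n_atoms(system)) {
    stop("ensemble atom count does not match the system")
  }
  uni <- pair_universe(system, ensemble_frame(ens, 1, 1), cutoff, skin,
                       lj_cutoff = lj_cutoff)
  nr <- length(ens$replicas)
  rm <- matrix(0, nrow(uni$pairs), nr)
  nf <- integer(nr)
  for (rp in seq_len(nr)) {
    arr <- ens$replicas[[rp]]
    nf[rp] <- dim(arr)[1]
    acc <- numeric(nrow(uni$pairs))
    for (fr in seq_len(nf[rp])) {
      acc <- acc + scalar_forces_frame(system, arr[fr, , ], uni)
    }
    rm[, rp] <- acc / nf[rp]
  }
  new_averaged_pair_forces(uni$pairs[, 1], uni$pairs[, 2], rm, nf,
                           n_atoms(system), ens$state)
}

#' Restrict averaged pair forces to a subset of atoms
#'
#' Keeps only pairs with both atoms in `keep_atoms`. Used to reduce a
#' ligand-bound state to its protein-protein pair subset before differencing
#' against a ligand-free state with fewer atoms.
#'
#' @param avg an `averaged_pair_forces` object.
#' @param keep_atoms atom indices to keep.
#' @param n_atoms atom count to declare for the restricted object (defaults
#'   to `max(keep_atoms)`).
#' @export
restrict_pairs <- function(avg, keep_atoms, n_atoms = max(keep_atoms)) {
  sel <- avg$i %in% keep_atoms & avg$j %in% keep_atoms
  new_averaged_pair_forces(avg$i[sel], avg$j[sel],
                           attr(avg, "replica_means")[sel, , drop = FALSE],
                           attr(avg, "n_frames"), n_atoms,
                           attr(avg, "state"))
}

#' Difference of averaged pairwise forces between two states
#'
#' delta = mean(state a) - mean(state b); a pair missing from one state is
#' treated as zero-mean there. Conventionally a = apo, b = holo/complex.
#'
#' @param avg_a,avg_b `averaged_pair_forces` objects on the same atom
#'   indexing.
#' @return a `force_difference` data.frame (i, j, delta_pn).
#' @export
force_difference <- function(avg_a, avg_b) {
  na <- attr(avg_a, "n_atoms"); nb <- attr(avg_b, "n_atoms")
  if (na != nb) stop("atom count mismatch between states (", na, " vs ", nb, ")")
  ka <- pair_key(avg_a$i, avg_a$j); kb <- pair_key(avg_b$i, avg_b$j)
  keys <- union(ka, kb)
  va <- stats::setNames(numeric(length(keys)), keys)
  vb <- va
  va[ka] <- avg_a$mean_pn
  vb[kb] <- avg_b$mean_pn
  ij <- do.call(rbind, strsplit(keys, " "))
  df <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                   delta_pn = unname(va - vb))
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("force_difference", "data.frame"), n_atoms = na,
            states = c(attr(avg_a, "state"), attr(avg_b, "state")))
}

#' Punctual stress profile
#'
#' Per-atom perturbation measure: the absolute sum of pairwise force
#' differences sensed by each atom, `dF_i = sum_j |dF_ij|`. A per-residue
#' aggregate (sum over member atoms by default, or max) is attached when a
#' residue map is available.
#'
#' @param diff a `force_difference`.
#' @param residues optional integer residue index per atom (see
#'   [residue_map()]).
#' @param residue_mode `"sum"` or `"max"` aggregation over member atoms.
#' @return list with `atom` (pN per atom), `residue` (named vector or NULL)
#'   and `mode`.
#' @export
punctual_stress <- function(diff, residues = NULL, residue_mode = c("sum", "max")) {
  residue_mode <- match.arg(residue_mode)
  n <- attr(diff, "n_atoms")
  atom <- numeric(n)
  av <- abs(diff$delta_pn)
  acc <- rowsum(c(av, av), c(diff$i, diff$j))
  atom[as.integer(rownames(acc))] <- as.vector(acc)
  res <- NULL
  if (!is.null(residues)) {
    if (length(residues) != n) stop("residue map length must equal atom count")
    res <- if (residue_mode == "sum") {
      tapply(atom, residues, sum)
    } else {
      tapply(atom, residues, max)
    }
    res <- stats::setNames(as.vector(res), names(res))
  }
  list(atom = atom, residue = res, mode = residue_mode)
}

#' Residue-wise ligand binding profile
#'
#' For each protein residue u, the absolute residue-wise force |F_uv| between
#' u and the whole ligand group (sum of signed scalar atom-pair forces, then
#' absolute value), ranked in decreasing order.
#'
#' @param avg `averaged_pair_forces` of the ligand-bound state.
#' @param system the matching `molecular_system` (for the residue map).
#' @param ligand_group atom indices of the ligand.
#' @return data.frame (residue, f_pn, abs_pn) sorted by `abs_pn` decreasing.
#' @export
ligand_binding_profile <- function(avg, system, ligand_group) {
  if (!length(ligand_group)) stop("ligand group is empty")
  res <- residue_map(system)
  prot_atoms <- setdiff(seq_len(n_atoms(system)), ligand_group)
  prot_res <- sort(unique(res[prot_atoms]))
  span <- (avg$i %in% ligand_group) != (avg$j %in% ligand_group)
  sp <- avg[span, , drop = FALSE]
  other <- ifelse(sp$i %in% ligand_group, sp$j, sp$i)
  per_res <- rowsum(sp$mean_pn, res[other])
  f <- stats::setNames(numeric(length(prot_res)), prot_res)
  hit <- intersect(rownames(per_res), names(f))
  f[hit] <- per_res[hit, 1]
  out <- data.frame(residue = as.integer(names(f)), f_pn = unname(f),
                    abs_pn = abs(unname(f)))
  out <- out[order(-out$abs_pn, out$residue), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Running-mean convergence diagnostics for a pair force series
#'
#' @param series numeric per-frame force values of one pair.
#' @param tol absolute tolerance (same unit as `series`) on the difference
#'   between first-half and second-half means.
#' @return list with `running_mean`, `half_difference`, `converged`.
#' @export
convergence_profile <- function(series, tol = NULL) {
  n <- length(series)
  if (n < 2) stop("need at least 2 frames")
  run <- cumsum(series) / seq_len(n)
  h1 <- mean(series[seq_len(n %/% 2)])
  h2 <- mean(series[(n %/% 2 + 1):n])
  if (is.null(tol)) tol <- 3 * stats::sd(series) / sqrt(n)
  list(running_mean = run, half_difference = h2 - h1,
       converged = abs(h2 - h1) <= tol, tol = tol)
}
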