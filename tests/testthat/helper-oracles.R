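# Independent oracles and fixture builders shared across the suite. These
# deliberately avoid the package's own computational paths: finite
# differences for gradients, hand-rolled BFS for components, direct
# double loops for stress and group forces, quaternion grid search for
# superposition.

KJNM_TO_PN <- 1e3 / (6.02214076e23 * 1e-9) * 1e12

# ---- random molecular systems ---------------------------------------------

# Random system with all interaction types and non-degenerate geometry.
random_system <- function(n = 20, seed = 1, charged = TRUE, lj = TRUE,
                          bonded = TRUE) {
  set.seed(seed)
  # positions: sequential random walk, guarantees bonded neighbours are near
  # and no two atoms coincide
  x <- matrix(0, n, 3)
  for (i in 2:n) {
    repeat {
      cand <- x[i - 1, ] + stats::rnorm(3, 0, 0.25)
      d <- sqrt(rowSums((x[seq_len(i - 1), , drop = FALSE] -
                           matrix(cand, i - 1, 3, byrow = TRUE))^2))
      if (min(d) > 0.12) break
    }
    x[i, ] <- cand
  }
  atoms <- atom_table(rep("X", n), seq_len(n),
                      charge = if (charged) round(stats::runif(n, -1, 1), 2)
                      else 0,
                      lj_sigma = if (lj) stats::runif(n, 0.1, 0.2) else 0,
                      lj_epsilon = if (lj) stats::runif(n, 0.05, 0.3) else 0)
  bonds <- angles <- dihedrals <- NULL
  if (bonded) {
    bi <- seq_len(n - 1)
    d <- sqrt(rowSums((x[bi, , drop = FALSE] - x[bi + 1, , drop = FALSE])^2))
    bonds <- data.frame(i = bi, j = bi + 1,
                        k_b = stats::runif(n - 1, 200, 800), r0 = d * 0.95)
    ai <- seq_len(n - 2)
    angles <- data.frame(i = ai, j = ai + 1, k = ai + 2,
                         k_theta = stats::runif(n - 2, 20, 120),
                         theta0 = stats::runif(n - 2, 80, 150))
    di <- seq_len(n - 3)
    dihedrals <- data.frame(i = di, j = di + 1, k = di + 2, l = di + 3,
                            k_phi = stats::runif(n - 3, 1, 8),
                            mult = sample(1:3, n - 3, replace = TRUE),
                            phase = stats::runif(n - 3, 0, 360))
  }
  list(system = molecular_system(atoms, bonds, angles, dihedrals),
       frame = make_frame(x))
}

# ---- gradient oracle -------------------------------------------------------

fd_gradient <- function(system, x, cutoff, h = 1e-6) {
  g <- matrix(0, nrow(x), 3)
  for (i in seq_len(nrow(x))) {
    for (d in 1:3) {
      xp <- x; xp[i, d] <- xp[i, d] + h
      xm <- x; xm[i, d] <- xm[i, d] - h
      g[i, d] <- (as.numeric(system_energy(system, xp, cutoff)) -
                    as.numeric(system_energy(system, xm, cutoff))) / (2 * h)
    }
  }
  -g
}

# net per-atom force reconstructed from the vector stage of a pair table
atom_forces_from_pairs <- function(pfm, n) {
  v <- attr(pfm, "vectors")
  f <- matrix(0, n, 3)
  for (r in seq_len(nrow(v))) {
    f[v$i[r], ] <- f[v$i[r], ] + c(v$fx[r], v$fy[r], v$fz[r])
    f[v$j[r], ] <- f[v$j[r], ] - c(v$fx[r], v$fy[r], v$fz[r])
  }
  f
}

# ---- graph oracle ----------------------------------------------------------

# components via hand-rolled BFS on an edge list; returns list of sorted
# node vectors (only nodes with at least one incident edge)
bfs_components <- function(edges) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  adj <- lapply(stats::setNames(nodes, nodes), function(v) integer())
  for (r in seq_len(nrow(edges))) {
    u <- as.character(edges[r, 1]); v <- as.character(edges[r, 2])
    adj[[u]] <- c(adj[[u]], edges[r, 2])
    adj[[v]] <- c(adj[[v]], edges[r, 1])
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (s in nodes) {
    if (seen[as.character(s)]) next
    queue <- s; members <- integer()
    seen[as.character(s)] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      for (w in adj[[as.character(v)]]) {
        if (!seen[as.character(w)]) {
          seen[as.character(w)] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# brute-force punctual stress: double loop over the difference table
brute_stress <- function(diff, n) {
  out <- numeric(n)
  for (a in seq_len(n)) {
    for (r in seq_len(nrow(diff))) {
      if (diff$i[r] == a || diff$j[r] == a) {
        out[a] <- out[a] + abs(diff$delta_pn[r])
      }
    }
  }
  out
}

# random sparse force-difference object
random_diff <- function(n = 30, m = 60, seed = 1) {
  set.seed(seed)
  pr <- unique(t(replicate(m, sort(sample.int(n, 2)))))
  structure(data.frame(i = pr[, 1], j = pr[, 2],
                       delta_pn = stats::rnorm(nrow(pr), 0, 50)),
            class = c("force_difference", "data.frame"), n_atoms = n)
}

# averaged-pair-forces object straight from a mean table (test plumbing)
avg_from_table <- function(i, j, mean_pn, n_atoms, state = "s") {
  fdanet:::new_averaged_pair_forces(i, j, matrix(mean_pn, ncol = 1),
                                    1L, n_atoms, state)
}

# ---- superposition oracle --------------------------------------------------

quat_to_mat <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# global search over random quaternions plus Nelder-Mead polish;
# fully independent of the Kabsch/SVD route
quaternion_grid_rmsd <- function(a, b, n_grid = 3000, seed = 7) {
  a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
  rmsd_for <- function(R) sqrt(mean(rowSums((a0 %*% R - b0)^2)))
  set.seed(seed)
  best <- Inf; best_q <- c(1, 0, 0, 0)
  for (k in seq_len(n_grid)) {
    q <- stats::rnorm(4)
    r <- rmsd_for(quat_to_mat(q))
    if (r < best) { best <- r; best_q <- q }
  }
  opt <- stats::optim(best_q, function(q) rmsd_for(quat_to_mat(q)),
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt$value
}

# random rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  quat_to_mat(stats::rnorm(4))
}
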