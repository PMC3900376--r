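# Synthetic two-state benchmark: a two-domain Calpha-bead model with a
# designed binding-site -> hinge force pathway and a designed hinge-angle
# change on ligand binding. The generator provides ground truth (pathway
# residues, binding residues, hinge pair, designed angle change) for
# end-to-end validation of the force-distribution pipeline.
#
# Mechanical design (sized statically, see the methods vignette): each domain
# is a helical bead rod stiffened by an intra-domain i+-2..4 elastic network;
# the two rods meet at one interdomain joint held by a stiff three-point
# angle restraint. The designed pathway is a chain of springs stiffened
# `stiffening`-fold over the network, running from the binding residues on
# domain A across the hinge pair into domain B, decorated with alternating
# partial charges. The two single-bead ligands are substrate analogues with
# large opposite-domain charges: bound on opposite faces of the cleft, their
# mutual Coulomb repulsion is a force dipole whose two poles sit on the two
# domains, so a conserved stress flux must cross the interdomain joint; the
# stiff chain carries almost all of it, which is what lights up every
# designed pathway edge in the holo-minus-apo force difference, far above
# the thermal noise floor of the replica averages. Ligand binding also
# shifts the hinge equilibrium angle by the designed opening.

#' Specification of the synthetic two-domain system
#'
#' Defaults are the package's standard benchmark: 2 domains x 30 beads,
#' 5 replicas x 2000 frames per state, a 13-residue pathway (every fourth
#' bead from 3 to 51) through the hinge pair 27/31, two repelling
#' substrate-analogue ligands anchored at residues 7/11 and 43/47, and a
#' designed apo->holo hinge opening of 20 degrees.
#'
#' @param n_per_domain beads per domain.
#' @param spacing backbone bead spacing target, nm.
#' @param helix_radius,helix_rise,helix_turn_deg helical bead arrangement.
#' @param bend_deg rigid rotation applied to domain B at build time; sets the
#'   apo hinge geometry.
#' @param k_bond backbone spring constant, kJ/mol/nm^2.
#' @param k_en,en_cutoff elastic-network spring constant and cutoff.
#' @param pathway_chain ordered residue chain from the binding region across
#'   the hinge into the far domain.
#' @param stiffening pathway springs get `stiffening * k_en`; 0 disables the
#'   designed pathway (negative control).
#' @param pathway_charge alternating +/- charge on chain beads, e.
#' @param hinge_triplet Calpha triplet whose angle is restrained and
#'   measured (outer beads on the pathway so the restraint's residual forces
#'   stay on designed residues).
#' @param hinge_pair the two hinge-point residues (one per domain).
#' @param k_hinge hinge angle stiffness, kJ/mol/rad^2 (stiff by design so the
#'   minimum-energy hinge angle tracks theta0 despite network resistance).
#' @param delta_angle designed |apo - holo| hinge angle change, degrees; the
#'   holo angle opens by this amount (the reported apo - holo difference is
#'   negative, as for a straightening secondary-structure element).
#' @param ligand_n,ligand_charges,anchor_residues,k_ligand,ligand_pretension,ligand_offset
#'   number of single-bead ligands, their charges (e; large and like-signed
#'   so the ligands repel across the cleft), a list of anchor-residue sets
#'   (one per ligand), anchor spring constant, anchor rest-length shortening
#'   (nm) and placement offset from the anchor centroid toward the other
#'   ligand, nm.
#' @param lj_sigma,lj_epsilon bead Lennard-Jones parameters.
#' @param cutoff Coulomb cutoff, nm (beyond the system extent by default so
#'   the designed inter-ligand repulsion is never truncated); `lj_cutoff`
#'   Lennard-Jones cutoff, nm.
#' @param temperature K; `gamma` friction (kJ ps/mol/nm^2), `dt` time step
#'   (ps), `stride` steps per recorded frame, `burn_in` discarded steps.
#' @param n_replicas,n_frames ensemble size per state.
#' @param seed base seed fixing all stochastic draws.
#' @return list of class `two_domain_spec`.
#' @export
two_domain_spec <- function(n_per_domain = 30, spacing = 0.38,
                            helix_radius = 0.23, helix_rise = 0.15,
                            helix_turn_deg = 90, bend_deg = 140,
                            k_bond = 500, k_en = 100, en_cutoff = 0.75,
                            pathway_chain = seq(3, 51, by = 4),
                            stiffening = 150, pathway_charge = 0.1,
                            hinge_triplet = c(3, 27, 51),
                            hinge_pair = c(27, 31), k_hinge = 4e5,
                            delta_angle = 20,
                            ligand_n = 2, ligand_charges = c(-4, -3),
                            anchor_residues = list(c(7, 11), c(43, 47)),
                            k_ligand = 3000,
                            ligand_pretension = 0.15, ligand_offset = 0.5,
                            lj_sigma = 0.33, lj_epsilon = 0.25,
                            cutoff = 6, lj_cutoff = 1.2,
                            temperature = 300, gamma = 50,
                            dt = 5e-4, stride = 10, burn_in = 2000,
                            n_replicas = 5, n_frames = 2000, seed = 1) {
  spec <- as.list(environment())
  n <- 2 * n_per_domain
  stopifnot(all(pathway_chain >= 1), all(pathway_chain <= n),
            !anyDuplicated(pathway_chain),
            all(diff(pathway_chain) > 1),  # chain hops must not be backbone bonds
            all(unlist(anchor_residues) %in% seq_len(n)),
            ligand_n == 0 || length(anchor_residues) == ligand_n,
            all(hinge_pair %in% pathway_chain) || stiffening == 0,
            delta_angle >= 0)
  class(spec) <- "two_domain_spec"
  spec
}

#' Negative-control spec
#'
#' Same architecture with the designed signal removed: no pathway stiffening,
#' no pathway charges, no ligand, no hinge-angle change. The pipeline must
#' report a broken path on this system.
#'
#' @param ... overrides forwarded to [two_domain_spec()].
#' @export
negative_control_spec <- function(...) {
  two_domain_spec(stiffening = 0, pathway_charge = 0, ligand_n = 0,
                  delta_angle = 0, ...)
}

rotate_about_axis <- function(x, axis, angle_rad, pivot) {
  a <- axis / sqrt(sum(axis^2))
  ca <- cos(angle_rad); sa <- sin(angle_rad)
  xc <- sweep(x, 2, pivot)
  # Rodrigues rotation, row-vector form
  cross <- cbind(a[2] * xc[, 3] - a[3] * xc[, 2],
                 a[3] * xc[, 1] - a[1] * xc[, 3],
                 a[1] * xc[, 2] - a[2] * xc[, 1])
  dot <- as.vector(xc %*% a)
  sweep(ca * xc + sa * cross + (1 - ca) * outer(dot, a), 2, pivot, `+`)
}

#' Build the apo two-domain bead system
#'
#' @param spec a [two_domain_spec()].
#' @return list with `system` (a `molecular_system`), `frame` (built
#'   geometry, which is the exact apo energy minimum since every term is at
#'   rest there) and `truth` (ground-truth sets).
#' @export
build_two_domain_system <- function(spec) {
  n <- 2 * spec$n_per_domain
  om <- deg2rad(spec$helix_turn_deg)
  t <- seq_len(n)
  x <- cbind(spec$helix_radius * cos(om * t),
             spec$helix_radius * sin(om * t),
             spec$helix_rise * t)
  # scale backbone steps to the requested spacing
  step <- sqrt(sum((x[2, ] - x[1, ])^2))
  x <- x * (spec$spacing / step)
  nd <- spec$n_per_domain
  pivot <- (x[nd, ] + x[nd + 1, ]) / 2
  axisd <- x[nd + 1, ] - x[nd, ]
  perp <- c(-axisd[2], axisd[1], 0)
  if (sqrt(sum(perp^2)) < 1e-8) perp <- c(1, 0, 0)
  x[(nd + 1):n, ] <- rotate_about_axis(x[(nd + 1):n, , drop = FALSE], perp,
                                       deg2rad(spec$bend_deg), pivot)
  dist <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  bonds <- data.frame(i = seq_len(n - 1), j = 2:n, k_b = spec$k_bond,
                      r0 = vapply(seq_len(n - 1), function(k) dist(k, k + 1),
                                  numeric(1)),
                      chemical = TRUE)
  # intra-domain elastic network: non-backbone pairs within cutoff, springs
  # at rest; the hinge region is crossed only by the backbone bond, the
  # hinge angle term and (when designed) the pathway chain
  cmb <- t(utils::combn(n, 2))
  sep <- cmb[, 2] - cmb[, 1]
  same_domain <- (cmb[, 2] <= nd) | (cmb[, 1] > nd)
  d_all <- vnorm(x[cmb[, 1], , drop = FALSE] - x[cmb[, 2], , drop = FALSE])
  en_sel <- sep >= 2 & d_all <= spec$en_cutoff & same_domain
  en <- data.frame(i = cmb[en_sel, 1], j = cmb[en_sel, 2], k_b = spec$k_en,
                   r0 = d_all[en_sel], chemical = FALSE)
  # pathway chain: stiffened springs between consecutive chain residues,
  # plus redundant intra-domain skip springs between next-nearest chain
  # residues so the designed force route does not hinge on a single spring;
  # skips never cross the domain boundary, keeping the hinge crossed by one
  # designed spring only
  ch <- spec$pathway_chain
  if (spec$stiffening > 0) {
    k_path <- spec$stiffening * spec$k_en
    hops <- cbind(ch[-length(ch)], ch[-1], k_path)
    if (length(ch) > 2) {
      # half-stiffness skips: redundancy without starving the direct hops
      skips <- cbind(ch[seq_len(length(ch) - 2)], ch[-(1:2)], k_path / 2)
      same_dom <- (skips[, 1] <= nd & skips[, 2] <= nd) |
        (skips[, 1] > nd & skips[, 2] > nd)
      hops <- rbind(hops, skips[same_dom, , drop = FALSE])
    }
    for (h in seq_len(nrow(hops))) {
      i <- min(hops[h, 1:2]); j <- max(hops[h, 1:2])
      d <- dist(i, j)
      if (d > 8 * spec$spacing) {
        stop(sprintf("pathway chain hop %d-%d spans %.2f nm: broken under the network geometry",
                     i, j, d))
      }
      hit <- which(en$i == i & en$j == j)
      if (length(hit)) {
        en$k_b[hit] <- hops[h, 3]
      } else {
        en <- rbind(en, data.frame(i = i, j = j, k_b = hops[h, 3], r0 = d,
                                   chemical = FALSE))
      }
    }
  }
  charges <- numeric(n)
  if (spec$stiffening > 0 && spec$pathway_charge != 0) {
    # alternating charges decorate the chain so the nonbonded channel is
    # exercised; anchor residues stay neutral so the (large) ligand charges
    # do not distort the binding-site geometry
    charges[ch] <- spec$pathway_charge * (-1)^(seq_along(ch) - 1)
    charges[unlist(spec$anchor_residues)] <- 0
  }
  atoms <- atom_table(rep("CA", n), seq_len(n), residue_name = "BEA",
                      element = "C", charge = charges,
                      lj_sigma = spec$lj_sigma, lj_epsilon = spec$lj_epsilon)
  ht <- spec$hinge_triplet
  theta0 <- bending_angle(x, ht)
  angles <- data.frame(i = ht[1], j = ht[2], k = ht[3],
                       k_theta = spec$k_hinge, theta0 = theta0)
  binding <- sort(unique(unlist(spec$anchor_residues)))
  groups <- list(protein = seq_len(n), binding = binding,
                 hinge = spec$hinge_pair)
  sys <- molecular_system(atoms, bonds = rbind(bonds, en), angles = angles,
                          groups = groups)
  truth <- list(
    pathway = sort(unique(c(binding, ch))),
    binding = binding,
    hinge_pair = sort(spec$hinge_pair),
    hinge_triplet = ht,
    delta_angle = spec$delta_angle,
    apo_angle = theta0
  )
  list(system = sys, frame = make_frame(x),
       hinge_geometry = list(pivot = pivot, axis = perp, domain_b = (nd + 1):n),
       truth = truth)
}

#' Derive the ligand-bound (holo) system from the apo build
#'
#' Shifts the hinge equilibrium angle by the designed opening and adds one
#' bead per ligand, each bound to its own anchor residues with pre-tensioned
#' springs and carrying a (typically large, substrate-like) charge so the two
#' ligands repel each other across the interdomain cleft. All other terms are
#' bit-identical to the apo system. The returned starting frame is the apo
#' geometry with domain B pre-rotated to the holo equilibrium angle and the
#' ligands placed in the opened cleft.
#'
#' @param built result of [build_two_domain_system()].
#' @param spec the same [two_domain_spec()].
#' @return list with `system`, `frame` and `truth`.
#' @export
make_holo <- function(built, spec) {
  sys <- built$system
  x <- as.matrix(built$frame)
  n <- nrow(x)
  sys$angles$theta0[1] <- sys$angles$theta0[1] + spec$delta_angle
  hg <- built$hinge_geometry
  x[hg$domain_b, ] <- rotate_about_axis(x[hg$domain_b, , drop = FALSE],
                                        hg$axis, -deg2rad(spec$delta_angle),
                                        hg$pivot)
  if (spec$ligand_n > 0) {
    anchor_sets <- spec$anchor_residues
    centroids <- lapply(anchor_sets, function(a) colMeans(x[a, , drop = FALSE]))
    lig_xyz <- t(vapply(seq_len(spec$ligand_n), function(m) {
      towards <- Reduce(`+`, centroids[-m]) / (length(centroids) - 1) -
        centroids[[m]]
      towards <- towards / sqrt(sum(towards^2))
      centroids[[m]] + towards * spec$ligand_offset
    }, numeric(3)))
    lig_idx <- n + seq_len(spec$ligand_n)
    atoms <- rbind(sys$atoms,
                   atom_table(rep("LIG", spec$ligand_n),
                              max(sys$atoms$residue_index) + seq_len(spec$ligand_n),
                              residue_name = "LIG", element = "P",
                              charge = rep_len(spec$ligand_charges, spec$ligand_n),
                              lj_sigma = spec$lj_sigma,
                              lj_epsilon = spec$lj_epsilon))
    atoms$atom_index <- seq_len(nrow(atoms))
    anchor_bonds <- do.call(rbind, lapply(seq_len(spec$ligand_n), function(m) {
      anch <- anchor_sets[[m]]
      data.frame(
        i = rep(lig_idx[m], length(anch)), j = anch,
        k_b = spec$k_ligand,
        r0 = pmax(vnorm(sweep(x[anch, , drop = FALSE], 2, lig_xyz[m, ])) -
                    spec$ligand_pretension, 0.05),
        chemical = FALSE)
    }))
    groups <- sys$groups
    groups$ligand <- lig_idx
    holo <- molecular_system(atoms,
                             bonds = rbind(sys$bonds, anchor_bonds),
                             angles = sys$angles, dihedrals = sys$dihedrals,
                             groups = groups)
    frame <- make_frame(rbind(x, lig_xyz))
  } else {
    holo <- sys
    frame <- make_frame(x)
  }
  list(system = holo, frame = frame, truth = built$truth)
}

#' Sample a replica ensemble with overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of `dx = F/gamma dt + sqrt(2 kT dt / gamma) dW`
#' from the energy-minimized start. Replicas draw independent noise from one
#' seeded stream, so the whole ensemble is an exact function of the seed.
#'
#' @param system a `molecular_system`.
#' @param frame starting coordinates (minimized internally by default).
#' @param spec a [two_domain_spec()] supplying integrator parameters.
#' @param n_replicas,n_frames override the spec ensemble size.
#' @param seed RNG seed (defaults to `spec$seed`).
#' @param state state label for the ensemble.
#' @param minimize minimize the start before sampling.
#' @return a `trajectory_ensemble`.
#' @export
sample_ensemble <- function(system, frame, spec, n_replicas = NULL,
                            n_frames = NULL, seed = NULL, state = "apo",
                            minimize = TRUE) {
  n_replicas <- n_replicas %||% spec$n_replicas
  n_frames <- n_frames %||% spec$n_frames
  seed <- seed %||% spec$seed
  if (minimize) {
    frame <- minimize_energy(system, frame, cutoff = spec$cutoff,
                             lj_cutoff = spec$lj_cutoff)$frame
  }
  x0 <- as.matrix(frame)
  n <- nrow(x0)
  pairs <- nonbonded_pairs(system, x0, spec$cutoff, skin = 0.6,
                           lj_cutoff = spec$lj_cutoff)
  cache <- nb_cache(system, pairs)
  kt <- .fda_const$kb * spec$temperature
  noise_scale <- sqrt(2 * kt * spec$dt / spec$gamma)
  mob <- spec$dt / spec$gamma
  set.seed(seed)
  replicas <- vector("list", n_replicas)
  use_cpp <- nrow(system$dihedrals) == 0L
  for (rp in seq_len(n_replicas)) {
    if (use_cpp) {
      run <- cpp_langevin_run(
        x0, system$bonds$i, system$bonds$j, system$bonds$k_b,
        system$bonds$r0, system$angles$i, system$angles$j, system$angles$k,
        system$angles$k_theta, deg2rad(system$angles$theta0),
        pairs[, 1], pairs[, 2], cache$qq, cache$sig, cache$eps,
        spec$cutoff, spec$lj_cutoff, mob, noise_scale,
        as.integer(spec$burn_in), as.integer(n_frames),
        as.integer(spec$stride))
      if (run$diverged) {
        stop("integrator diverged; reduce dt")
      }
      replicas[[rp]] <- run$frames
    } else {
      x <- x0
      arr <- array(0, dim = c(n_frames, n, 3))
      total <- spec$burn_in + n_frames * spec$stride
      rec <- 0L
      for (s in seq_len(total)) {
        f <- system_forces(system, x, spec$cutoff, lj_cutoff = spec$lj_cutoff,
                           cache = cache)
        x <- x + f * mob +
          if (spec$temperature > 0)
            noise_scale * matrix(stats::rnorm(3 * n), n, 3)
          else 0
        if (s %% 500L == 0L &&
            as.numeric(system_energy(system, x, spec$cutoff, pairs,
                                     spec$lj_cutoff)) > 1e7) {
          stop("integrator diverged (energy > 1e7 kJ/mol); reduce dt")
        }
        if (s > spec$burn_in && (s - spec$burn_in) %% spec$stride == 0L) {
          rec <- rec + 1L
          arr[rec, , ] <- x
        }
      }
      replicas[[rp]] <- arr
    }
  }
  trajectory_ensemble(replicas, state = state)
}

#' Score pathway recovery against the designed ground truth
#'
#' @param detected integer residue set (e.g. the largest-component nodes), or
#'   a [largest_component()] result, or a graph.
#' @param truth ground-truth list from [build_two_domain_system()].
#' @param hinge_angle_error optional measured - designed hinge angle change,
#'   degrees, carried through for reporting.
#' @return list with `precision`, `recall`, `empty_detection` flag, and the
#'   residue sets compared.
#' @export
score_recovery <- function(detected, truth, hinge_angle_error = NA_real_) {
  nodes <- if (is.numeric(detected)) as.integer(detected)
  else if (is.list(detected) && !is.null(detected$nodes)) detected$nodes
  else if (inherits(detected, "igraph")) graph_nodes(detected)
  else stop("cannot interpret 'detected'")
  tp <- intersect(nodes, truth$pathway)
  empty <- length(nodes) == 0L
  list(precision = if (empty) 0 else length(tp) / length(nodes),
       recall = length(tp) / length(truth$pathway),
       empty_detection = empty,
       detected = sort(nodes), truth = sort(truth$pathway),
       hinge_angle_error = hinge_angle_error)
}
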