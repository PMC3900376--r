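# Hinge bending angles with replica-level error propagation, geometric
# hydrogen-bond detection with occupancy, and Kabsch least-squares
# superposition.

#' Three-point bending angle
#'
#' Angle at the middle atom of a triplet, in degrees within [0, 180].
#' Invariant under global rotation/translation and under swapping the two
#' outer atoms.
#'
#' @param frame coordinates, nm (or any consistent unit).
#' @param triplet integer vector (a, b, c); the angle is at b.
#' @export
bending_angle <- function(frame, triplet) {
  stopifnot(length(triplet) == 3, length(unique(triplet)) == 3)
  x <- as.matrix(frame)
  g <- angle_kernel(x[triplet[1], ], x[triplet[2], ], x[triplet[3], ])
  rad2deg(g$theta)
}

#' Bending-angle profile of a replica ensemble
#'
#' Per-replica frame mean, then ensemble mean and SD across the replica
#' means. Values in degrees.
#'
#' @param ensemble a `trajectory_ensemble` (or frame / list of frames).
#' @param triplet atom triplet, see [bending_angle()].
#' @param label descriptive label (e.g. `"helix 7"`).
#' @return object of class `angle_profile`: list with `mean`, `sd`,
#'   `per_replica`, `triplet`, `label`, `state`.
#' @export
angle_profile <- function(ensemble, triplet, label = NULL) {
  ens <- as_fda_ensemble(ensemble)
  per_rep <- vapply(ens$replicas, function(arr) {
    mean(vapply(seq_len(dim(arr)[1]), function(fr) {
      bending_angle(arr[fr, , ], triplet)
    }, numeric(1)))
  }, numeric(1))
  structure(list(mean = mean(per_rep),
                 sd = if (length(per_rep) > 1) stats::sd(per_rep) else NA_real_,
                 per_replica = per_rep, triplet = triplet,
                 label = label %||% paste(triplet, collapse = "-"),
                 state = ens$state),
            class = "angle_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an angle profile from summary statistics
#'
#' For worked-example arithmetic on reported per-state angle tables: wraps a
#' printed mean +/- SD into an `angle_profile` so it can be differenced with
#' [angle_difference()].
#'
#' @param mean,sd degrees.
#' @param triplet,label,state as in [angle_profile()].
#' @export
angle_profile_from_stats <- function(mean, sd, triplet = c(NA, NA, NA),
                                     label = NULL, state = "state") {
  structure(list(mean = mean, sd = sd, per_replica = NULL, triplet = triplet,
                 label = label %||% "angle", state = state),
            class = "angle_profile")
}

#' @export
print.angle_profile <- function(x, ...) {
  cat(sprintf("<angle_profile> %s [%s] %s: %.1f +/- %.1f deg\n", x$label,
              paste(x$triplet, collapse = "-"), x$state, x$mean, x$sd))
  invisible(x)
}

#' Difference of two angle profiles with quadrature error propagation
#'
#' delta = mean_a - mean_b, SD propagated as sqrt(sd_a^2 + sd_b^2)
#' (independent states). Values are computed at full precision; reports
#' conventionally round to 0.1 degree.
#'
#' @param profile_a,profile_b `angle_profile` objects on the same triplet.
#' @return list with `delta`, `sd`, `label`.
#' @export
angle_difference <- function(profile_a, profile_b) {
  ta <- profile_a$triplet; tb <- profile_b$triplet
  if (!all(is.na(ta)) && !all(is.na(tb)) && !identical(ta, tb)) {
    stop("angle profiles are for different triplets")
  }
  list(delta = profile_a$mean - profile_b$mean,
       sd = sqrt(profile_a$sd^2 + profile_b$sd^2),
       label = profile_a$label)
}

#' Detect hydrogen bonds with a geometric criterion
#'
#' A donor/acceptor pair is counted in a frame when the donor-acceptor
#' distance is at most `d_max` and, when a hydrogen atom is supplied for the
#' donor, the D-H...A angle is at least `angle_min`. Occupancy is the
#' fraction of frames satisfying the criterion; bonds below `occ_min` are
#' dropped.
#'
#' @param ensemble a `trajectory_ensemble` (coordinates in nm).
#' @param donors integer vector of donor heavy atoms.
#' @param acceptors integer vector of acceptor atoms.
#' @param hydrogens optional vector parallel to `donors` giving each donor's
#'   hydrogen (NA = no angular test for that donor).
#' @param d_max distance cutoff in Angstrom (default 3.5).
#' @param angle_min D-H...A angle cutoff in degrees (default 120).
#' @param occ_min occupancy threshold (default 0.5).
#' @return data.frame (donor, acceptor, mean_distance_A, occupancy).
#' @export
detect_hbonds <- function(ensemble, donors, acceptors, hydrogens = NULL,
                          d_max = 3.5, angle_min = 120, occ_min = 0.5) {
  if (!length(donors) || !length(acceptors)) {
    stop("donor and acceptor selections must be nonempty")
  }
  ens <- as_fda_ensemble(ensemble)
  if (is.null(hydrogens)) hydrogens <- rep(NA_integer_, length(donors))
  cand <- expand.grid(di = seq_along(donors), acceptor = acceptors)
  cand$donor <- donors[cand$di]
  cand <- cand[cand$donor != cand$acceptor, , drop = FALSE]
  nfr_total <- 0L
  hits <- numeric(nrow(cand))
  dsum <- numeric(nrow(cand))
  for (arr in ens$replicas) {
    for (fr in seq_len(dim(arr)[1])) {
      x <- arr[fr, , ] * 10  # nm -> A
      d <- vnorm(x[cand$donor, , drop = FALSE] -
                   x[cand$acceptor, , drop = FALSE])
      ok <- d <= d_max
      h <- hydrogens[cand$di]
      for (rw in which(ok & !is.na(h))) {
        ang <- rad2deg(angle_kernel(x[cand$donor[rw], ], x[h[rw], ],
                                    x[cand$acceptor[rw], ])$theta)
        if (ang < angle_min) ok[rw] <- FALSE
      }
      hits <- hits + ok
      dsum <- dsum + ifelse(ok, d, 0)
      nfr_total <- nfr_total + 1L
    }
  }
  occ <- hits / nfr_total
  keep <- occ >= occ_min & hits > 0
  out <- data.frame(donor = cand$donor[keep], acceptor = cand$acceptor[keep],
                    mean_distance_A = dsum[keep] / hits[keep],
                    occupancy = occ[keep])
  out[order(-out$occupancy, out$donor), , drop = FALSE]
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the rotation and translation minimizing the RMSD of the selected
#' atoms of `mobile` onto `reference`.
#'
#' @param mobile,reference frames (nm) with equal atom counts.
#' @param selection atom indices used for the fit (default: all).
#' @return list with `rotation` (3x3, applied on the right of row vectors),
#'   `translation`, `rmsd_A`, and `fitted` (all mobile atoms transformed).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  xm <- as.matrix(mobile); xr <- as.matrix(reference)
  if (is.null(selection)) selection <- seq_len(nrow(xm))
  if (length(selection) < 3) stop("need at least 3 atoms for superposition")
  a <- xm[selection, , drop = FALSE]
  b <- xr[selection, , drop = FALSE]
  if (nrow(a) != nrow(b)) stop("selection counts differ between frames")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  sv <- svd(crossprod(a0, b0))
  if (sv$d[2] < 1e-12 * max(sv$d, 1)) {
    stop("selection is (near-)collinear; superposition is underdetermined")
  }
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted_sel <- a0 %*% R
  rmsd_nm <- sqrt(mean(rowSums((fitted_sel - b0)^2)))
  fitted <- sweep(sweep(xm, 2, ca) %*% R, 2, cb, `+`)
  list(rotation = R, translation = cb - ca %*% R, rmsd_A = rmsd_nm * 10,
       fitted = make_frame(fitted))
}
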