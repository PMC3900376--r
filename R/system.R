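# Core containers: molecular_system, frame, trajectory_ensemble.
# Indices are 1-based everywhere user-facing; atoms are stored in a
# data.frame in file order with contiguous atom_index.

#' Build an atom table
#'
#' @param atom_name,element,residue_name character vectors.
#' @param residue_index integer vector, nondecreasing.
#' @param charge partial charges (e), `lj_sigma` (nm), `lj_epsilon` (kJ/mol).
#' @return data.frame with one row per atom and a contiguous `atom_index`.
#' @export
atom_table <- function(atom_name, residue_index,
                       residue_name = "RES", element = "C",
                       charge = 0, lj_sigma = 0, lj_epsilon = 0) {
  n <- length(atom_name)
  df <- data.frame(
    atom_index = seq_len(n),
    atom_name = as.character(atom_name),
    element = rep_len(as.character(element), n),
    residue_index = as.integer(residue_index),
    residue_name = rep_len(as.character(residue_name), n),
    charge = rep_len(as.numeric(charge), n),
    lj_sigma = rep_len(as.numeric(lj_sigma), n),
    lj_epsilon = rep_len(as.numeric(lj_epsilon), n),
    stringsAsFactors = FALSE
  )
  df
}

empty_terms <- function() {
  list(
    bonds = data.frame(i = integer(), j = integer(),
                       k_b = numeric(), r0 = numeric()),
    angles = data.frame(i = integer(), j = integer(), k = integer(),
                        k_theta = numeric(), theta0 = numeric()),
    dihedrals = data.frame(i = integer(), j = integer(), k = integer(),
                           l = integer(), k_phi = numeric(),
                           mult = integer(), phase = numeric())
  )
}

#' Construct a molecular system
#'
#' Holds the atom table, bonded interaction terms (harmonic bonds, harmonic
#' angles, periodic dihedrals), nonbonded exclusions and named atom groups.
#' Bond force constants are kJ/mol/nm^2 with rest length r0 in nm; angle
#' constants kJ/mol/rad^2 with theta0 in degrees; dihedrals
#' `k_phi * (1 + cos(mult * phi - phase))` with k_phi in kJ/mol and phase in
#' degrees.
#'
#' @param atoms data.frame from [atom_table()].
#' @param bonds,angles,dihedrals data.frames of bonded terms (may be NULL).
#' @param exclusions two-column matrix of excluded nonbonded pairs; the 1-2
#'   and 1-3 exclusions implied by the bond list are always added.
#' @param groups named list of integer atom-index vectors.
#' @return object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, bonds = NULL, angles = NULL,
                             dihedrals = NULL, exclusions = NULL,
                             groups = list()) {
  terms <- empty_terms()
  if (!is.null(bonds) && nrow(bonds)) terms$bonds <- as.data.frame(bonds)
  if (!is.null(angles) && nrow(angles)) terms$angles <- as.data.frame(angles)
  if (!is.null(dihedrals) && nrow(dihedrals)) {
    terms$dihedrals <- as.data.frame(dihedrals)
  }
  if (nrow(terms$bonds) && is.null(terms$bonds$chemical)) {
    terms$bonds$chemical <- TRUE
  }
  sys <- structure(
    list(atoms = atoms, bonds = terms$bonds, angles = terms$angles,
         dihedrals = terms$dihedrals,
         exclusions = matrix(integer(), ncol = 2), groups = groups),
    class = "molecular_system"
  )
  validate_system(sys)
  sys$exclusions <- make_exclusions(chemical_bonds(sys), n_atoms(sys),
                                    extra = exclusions)
  sys
}

# Springs marked chemical = FALSE (elastic-network restraints) do not
# generate 1-2/1-3 exclusions or count as bonds for the 1-4 rule.
chemical_bonds <- function(sys) {
  b <- sys$bonds
  if (!nrow(b)) return(b)
  if (is.null(b$chemical)) return(b)
  b[b$chemical, , drop = FALSE]
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf(
    "<molecular_system> %d atoms, %d residues | %d bonds, %d angles, %d dihedrals | groups: %s\n",
    n_atoms(x), length(unique(x$atoms$residue_index)), nrow(x$bonds),
    nrow(x$angles), nrow(x$dihedrals),
    if (length(x$groups)) paste(names(x$groups), collapse = ", ") else "none"))
  invisible(x)
}

#' Number of atoms in a system
#' @param system a `molecular_system`.
#' @export
n_atoms <- function(system) nrow(system$atoms)

validate_system <- function(sys) {
  a <- sys$atoms
  if (nrow(a) == 0L) stop("system has zero atoms")
  if (!identical(a$atom_index, seq_len(nrow(a)))) {
    stop("atom_index must be contiguous from 1")
  }
  if (is.unsorted(a$residue_index)) {
    stop("residue_index must be nondecreasing with atom_index")
  }
  if (any(a$lj_sigma < 0) || any(a$lj_epsilon < 0)) {
    stop("lj_sigma and lj_epsilon must be >= 0")
  }
  n <- nrow(a)
  check_idx <- function(df, cols, what) {
    for (cl in cols) {
      bad <- which(df[[cl]] < 1L | df[[cl]] > n)
      if (length(bad)) {
        stop(sprintf("%s term %d references atom %d outside 1..%d",
                     what, bad[1], df[[cl]][bad[1]], n))
      }
    }
  }
  check_idx(sys$bonds, c("i", "j"), "bond")
  check_idx(sys$angles, c("i", "j", "k"), "angle")
  check_idx(sys$dihedrals, c("i", "j", "k", "l"), "dihedral")
  if (nrow(sys$bonds)) {
    key <- paste(pmin(sys$bonds$i, sys$bonds$j),
                 pmax(sys$bonds$i, sys$bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
  }
  for (g in names(sys$groups)) {
    idx <- sys$groups[[g]]
    if (length(idx) && (min(idx) < 1L || max(idx) > n)) {
      stop("group '", g, "' references atoms outside the system")
    }
  }
  invisible(sys)
}

#' Generate nonbonded exclusions from the bond list
#'
#' Applies the 1-2 rule (bonded pairs) and 1-3 rule (pairs separated by two
#' bonds), plus any explicit extra pairs. The result is stored with i < j and
#' is symmetric by convention and idempotent.
#'
#' @param bonds bond data.frame with columns i, j.
#' @param n total atom count (for validation).
#' @param extra optional two-column matrix of additional excluded pairs.
#' @return two-column integer matrix, rows unique, i < j.
#' @export
make_exclusions <- function(bonds, n, extra = NULL) {
  pairs <- matrix(integer(), ncol = 2)
  if (!is.null(bonds) && nrow(bonds)) {
    b12 <- cbind(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    # 1-3: atoms bonded to a common center
    adj <- split(c(bonds$j, bonds$i), c(bonds$i, bonds$j))
    b13 <- list()
    for (center in names(adj)) {
      nb <- unique(adj[[center]])
      if (length(nb) >= 2) {
        cmb <- utils::combn(sort(nb), 2)
        b13[[center]] <- t(cmb)
      }
    }
    b13 <- do.call(rbind, b13)
    pairs <- rbind(b12, b13)
  }
  if (!is.null(extra) && NROW(extra)) {
    extra <- cbind(pmin(extra[, 1], extra[, 2]), pmax(extra[, 1], extra[, 2]))
    pairs <- rbind(pairs, extra)
  }
  if (nrow(pairs)) {
    storage.mode(pairs) <- "integer"
    if (any(pairs < 1L) || any(pairs > n)) {
      stop("exclusion references atom outside 1..", n)
    }
    pairs <- unique(pairs[pairs[, 1] != pairs[, 2], , drop = FALSE])
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  }
  pairs
}

#' Construct a coordinate frame
#'
#' @param coordinates n x 3 numeric matrix in nm.
#' @param box optional orthorhombic box lengths (nm, length 3).
#' @return object of class `fda_frame` (an n x 3 matrix with attributes).
#' @export
make_frame <- function(coordinates, box = NULL) {
  coordinates <- as.matrix(coordinates)
  dimnames(coordinates) <- NULL
  if (ncol(coordinates) != 3L) stop("coordinates must be an n x 3 matrix")
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  if (!is.null(box)) {
    if (length(box) != 3L || any(box <= 0)) stop("box must be 3 positive lengths")
  }
  structure(coordinates, box = box, class = c("fda_frame", "matrix", "array"))
}

#' Bundle replica trajectories of one state
#'
#' @param replicas list, one entry per replica; each entry either a list of
#'   frames or a `n_frames x n_atoms x 3` array.
#' @param state state label, conventionally `"apo"` or `"holo"`.
#' @return object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(replicas, state = "apo") {
  if (!length(replicas)) stop("ensemble needs at least one replica")
  replicas <- lapply(replicas, function(r) {
    if (is.array(r) && length(dim(r)) == 3L) return(r)
    if (is.list(r) && length(r)) {
      arr <- array(0, dim = c(length(r), nrow(r[[1]]), 3L))
      for (f in seq_along(r)) arr[f, , ] <- r[[f]]
      return(arr)
    }
    stop("each replica must be a nonempty list of frames or a 3-d array")
  })
  nat <- vapply(replicas, function(r) dim(r)[2], integer(1))
  if (length(unique(nat)) != 1L) {
    stop("all replicas must share one atom count")
  }
  if (any(vapply(replicas, function(r) dim(r)[1], integer(1)) == 0L)) {
    stop("every replica must contain at least one frame")
  }
  structure(list(replicas = replicas, state = state),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$replicas, function(r) dim(r)[1], integer(1))
  cat(sprintf("<trajectory_ensemble> state=%s, %d replicas x %s frames, %d atoms\n",
              x$state, length(x$replicas),
              paste(unique(nf), collapse = "/"), dim(x$replicas[[1]])[2]))
  invisible(x)
}

#' Extract one frame from an ensemble
#' @param ensemble a `trajectory_ensemble`.
#' @param replica,frame 1-based indices.
#' @export
ensemble_frame <- function(ensemble, replica, frame) {
  make_frame(ensemble$replicas[[replica]][frame, , ])
}

n_frames <- function(ensemble) {
  vapply(ensemble$replicas, function(r) dim(r)[1], integer(1))
}

#' Map atoms to residues
#' @param system a `molecular_system`.
#' @return integer vector: residue index per atom.
#' @export
residue_map <- function(system) system$atoms$residue_index
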