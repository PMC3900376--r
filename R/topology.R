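# Minimal text topology dialect. This package deliberately defines its own
# format instead of parsing CHARMM/AMBER/GROMACS files: the analysis layer,
# not the force field, is the point. Sections:
#
#   [atoms]       index name element residue_index residue_name charge sigma epsilon
#   [bonds]       i j k_b(kJ/mol/nm^2) r0(nm) [chemical 0/1, default 1]
#                 (chemical=0 marks elastic-network restraint springs, which
#                  do not generate 1-2/1-3 exclusions)
#   [angles]      i j k k_theta(kJ/mol/rad^2) theta0(deg)
#   [dihedrals]   i j k l k_phi(kJ/mol) mult phase(deg)
#   [exclusions]  i j          (extra pairs; 1-2/1-3 are always generated)
#   [groups]      name i1 i2 ...
#
# ';' starts a comment; blank lines ignored.

#' Read the package topology dialect
#'
#' @param path topology file.
#' @return a [molecular_system()] with all bonded terms, nonbonded parameters,
#'   groups and auto-generated exclusions attached.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  lines <- lines[keep]; line_no <- which(keep)
  section <- NA_character_
  buf <- list(atoms = list(), bonds = list(), angles = list(),
              dihedrals = list(), exclusions = list(), groups = list())
  for (k in seq_along(lines)) {
    ln <- lines[k]
    if (grepl("^\\[", ln)) {
      section <- tolower(gsub("[][ ]", "", ln))
      if (!section %in% names(buf)) {
        stop(sprintf("unknown topology section '%s' at line %d", section, line_no[k]))
      }
      next
    }
    if (is.na(section)) stop("topology content before any [section] header")
    toks <- strsplit(ln, "\\s+")[[1]]
    buf[[section]][[length(buf[[section]]) + 1L]] <- list(toks = toks, line = line_no[k])
  }
  req <- function(entry, n, what) {
    if (length(entry$toks) < n) {
      stop(sprintf("%s entry at line %d needs %d fields", what, entry$line, n))
    }
    entry$toks
  }
  if (!length(buf$atoms)) stop("topology has no [atoms] section")
  am <- t(vapply(buf$atoms, function(e) req(e, 8, "atom"), character(8)))
  atoms <- atom_table(am[, 2], as.integer(am[, 4]), residue_name = am[, 5],
                      element = am[, 3], charge = as.numeric(am[, 6]),
                      lj_sigma = as.numeric(am[, 7]),
                      lj_epsilon = as.numeric(am[, 8]))
  if (!identical(as.integer(am[, 1]), seq_len(nrow(am)))) {
    stop("[atoms] indices must be contiguous from 1")
  }
  num_rows <- function(entries, n, what) {
    if (!length(entries)) return(NULL)
    m <- t(vapply(entries, function(e) as.numeric(req(e, n, what)[1:n]),
                  numeric(n)))
    if (any(!is.finite(m))) stop("non-numeric field in [", what, "] section")
    m
  }
  bonds <- NULL
  if (length(buf$bonds)) {
    brows <- lapply(buf$bonds, function(e) {
      toks <- req(e, 4, "bond")
      v <- suppressWarnings(as.numeric(toks[1:min(5, length(toks))]))
      if (any(!is.finite(v))) stop("non-numeric field in [bonds] at line ", e$line)
      c(v, 1)[1:5]
    })
    b <- do.call(rbind, brows)
    bonds <- data.frame(i = as.integer(b[, 1]), j = as.integer(b[, 2]),
                        k_b = b[, 3], r0 = b[, 4], chemical = b[, 5] != 0)
  }
  an <- num_rows(buf$angles, 5, "angles")
  angles <- if (is.null(an)) NULL else
    data.frame(i = as.integer(an[, 1]), j = as.integer(an[, 2]),
               k = as.integer(an[, 3]), k_theta = an[, 4], theta0 = an[, 5])
  dh <- num_rows(buf$dihedrals, 7, "dihedrals")
  dihedrals <- if (is.null(dh)) NULL else
    data.frame(i = as.integer(dh[, 1]), j = as.integer(dh[, 2]),
               k = as.integer(dh[, 3]), l = as.integer(dh[, 4]),
               k_phi = dh[, 5], mult = as.integer(dh[, 6]), phase = dh[, 7])
  ex <- num_rows(buf$exclusions, 2, "exclusions")
  groups <- list()
  for (e in buf$groups) {
    toks <- req(e, 2, "group")
    groups[[toks[1]]] <- as.integer(toks[-1])
  }
  molecular_system(atoms, bonds = bonds, angles = angles,
                   dihedrals = dihedrals, exclusions = ex, groups = groups)
}

#' Write a system in the package topology dialect
#' @param system a `molecular_system`.
#' @param path output file.
#' @export
write_topology <- function(system, path) {
  a <- system$atoms
  out <- c("[atoms]", sprintf("%d %s %s %d %s %.8g %.8g %.8g",
                              a$atom_index, a$atom_name, a$element,
                              a$residue_index, a$residue_name, a$charge,
                              a$lj_sigma, a$lj_epsilon))
  if (nrow(system$bonds)) {
    chem <- if (is.null(system$bonds$chemical)) rep(1, nrow(system$bonds)) else
      as.integer(system$bonds$chemical)
    out <- c(out, "[bonds]", sprintf("%d %d %.8g %.8g %d", system$bonds$i,
                                     system$bonds$j, system$bonds$k_b,
                                     system$bonds$r0, chem))
  }
  if (nrow(system$angles)) {
    out <- c(out, "[angles]",
             sprintf("%d %d %d %.8g %.8g", system$angles$i, system$angles$j,
                     system$angles$k, system$angles$k_theta,
                     system$angles$theta0))
  }
  if (nrow(system$dihedrals)) {
    out <- c(out, "[dihedrals]",
             sprintf("%d %d %d %d %.8g %d %.8g", system$dihedrals$i,
                     system$dihedrals$j, system$dihedrals$k,
                     system$dihedrals$l, system$dihedrals$k_phi,
                     system$dihedrals$mult, system$dihedrals$phase))
  }
  auto <- make_exclusions(chemical_bonds(system), n_atoms(system))
  extra <- setdiff(paste(system$exclusions[, 1], system$exclusions[, 2]),
                   paste(auto[, 1], auto[, 2]))
  if (length(extra)) {
    out <- c(out, "[exclusions]", extra)
  }
  if (length(system$groups)) {
    out <- c(out, "[groups]",
             vapply(names(system$groups), function(g) {
               paste(c(g, system$groups[[g]]), collapse = " ")
             }, character(1)))
  }
  writeLines(out, path)
  invisible(path)
}
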