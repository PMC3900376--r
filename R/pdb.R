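# Minimal fixed-width PDB I/O. Coordinates are converted A -> nm on read and
# nm -> A on write. Residues are renumbered consecutively across chain breaks
# so every downstream module works with a single integer residue key; the
# original (chain, resSeq) labels are retained in an audit map.

pdb_num <- function(s) {
  s <- trimws(s)
  ifelse(nzchar(s), suppressWarnings(as.numeric(s)), NA_real_)
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records of the first MODEL (or the whole file when no
#' MODEL records are present). Chains are renumbered into one consecutive
#' residue numbering; the original labels are kept in
#' `attr(system, "residue_audit")`.
#'
#' @param path PDB file.
#' @return list with `system` (a [molecular_system()] without bonded terms)
#'   and `frame` (coordinates in nm).
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  models <- split_pdb_models(lines)
  parsed <- parse_pdb_atoms(models$records[[1]], models$line_no[[1]])
  sys <- pdb_system(parsed)
  list(system = sys, frame = make_frame(parsed$xyz / 10))
}

#' Read a multi-model PDB trajectory
#'
#' @param path PDB file with MODEL/ENDMDL blocks.
#' @return list with `system` (from the first model) and `frames`, a list of
#'   frames in nm.
#' @export
read_pdb_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  models <- split_pdb_models(lines)
  first <- parse_pdb_atoms(models$records[[1]], models$line_no[[1]])
  sys <- pdb_system(first)
  frames <- lapply(seq_along(models$records), function(m) {
    p <- parse_pdb_atoms(models$records[[m]], models$line_no[[m]])
    if (nrow(p$xyz) != n_atoms(sys)) {
      stop("model ", m, " atom count differs from model 1")
    }
    make_frame(p$xyz / 10)
  })
  list(system = sys, frames = frames)
}

split_pdb_models <- function(lines) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (!length(model_starts)) {
    if (!any(is_atom)) stop("no ATOM/HETATM records found")
    return(list(records = list(lines[is_atom]),
                line_no = list(which(is_atom))))
  }
  ends <- c(model_starts[-1] - 1L, length(lines))
  recs <- list(); lns <- list()
  for (m in seq_along(model_starts)) {
    rng <- model_starts[m]:ends[m]
    sel <- rng[is_atom[rng]]
    if (length(sel)) {
      recs[[length(recs) + 1L]] <- lines[sel]
      lns[[length(lns) + 1L]] <- sel
    }
  }
  if (!length(recs)) stop("no ATOM/HETATM records found")
  list(records = recs, line_no = lns)
}

parse_pdb_atoms <- function(rec, line_no) {
  n <- length(rec)
  get <- function(a, b) substr(rec, a, b)
  x <- pdb_num(get(31, 38)); y <- pdb_num(get(39, 46)); z <- pdb_num(get(47, 54))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | nchar(rec) < 54)
  if (length(bad)) {
    stop(sprintf("malformed ATOM/HETATM record at line %d", line_no[bad[1]]))
  }
  list(
    atom_name = trimws(get(13, 16)),
    alt = get(17, 17),
    residue_name = trimws(get(18, 20)),
    chain = get(22, 22),
    res_seq = trimws(get(23, 27)),  # includes insertion code column
    xyz = cbind(x, y, z),
    occupancy = pdb_num(get(55, 60)),
    bfactor = pdb_num(get(61, 66)),
    element = trimws(get(77, 78)),
    hetatm = startsWith(rec, "HETATM")
  )
}

pdb_system <- function(p) {
  key <- paste(p$chain, p$res_seq)
  resi <- cumsum(c(TRUE, key[-1] != key[-length(key)]))
  el <- ifelse(nzchar(p$element), p$element,
               substr(gsub("[^A-Za-z].*", "", p$atom_name), 1, 1))
  atoms <- atom_table(p$atom_name, resi, residue_name = p$residue_name,
                      element = el)
  groups <- list(protein = which(!p$hetatm))
  if (any(p$hetatm)) groups$ligand <- which(p$hetatm)
  for (ch in unique(p$chain)) {
    if (nzchar(trimws(ch))) groups[[paste0("chain_", ch)]] <- which(p$chain == ch)
  }
  sys <- molecular_system(atoms, groups = groups)
  audit <- unique(data.frame(residue_index = resi, chain = p$chain,
                             pdb_res = p$res_seq, stringsAsFactors = FALSE))
  attr(sys, "residue_audit") <- audit
  sys
}

format_pdb_atom <- function(serial, name, resname, chain, resseq, xyz,
                            occ = 1, bfac = 0, element = "") {
  nm <- ifelse(nchar(name) < 4, paste0(" ", name), name)
  sprintf("ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, substr(nm, 1, 4), substr(resname, 1, 4),
          substr(chain, 1, 1), resseq %% 10000,
          xyz[1], xyz[2], xyz[3], occ, bfac, substr(element, 1, 2))
}

#' Write a system/frame to PDB
#'
#' @param system a `molecular_system`.
#' @param frames a single frame or list of frames (nm); multiple frames are
#'   written as MODEL blocks.
#' @param path output file.
#' @param bfactor optional per-atom values for the B-factor column.
#' @export
write_pdb <- function(system, frames, path, bfactor = NULL) {
  if (inherits(frames, "fda_frame") || (is.matrix(frames) && !is.list(frames))) {
    frames <- list(frames)
  }
  a <- system$atoms
  if (is.null(bfactor)) bfactor <- rep(0, nrow(a))
  if (length(bfactor) != nrow(a)) {
    stop("bfactor length must equal the atom count")
  }
  con <- file(path, "w"); on.exit(close(con))
  multi <- length(frames) > 1L
  for (m in seq_along(frames)) {
    xyz <- as.matrix(frames[[m]]) * 10  # nm -> A
    if (nrow(xyz) != nrow(a)) stop("frame atom count mismatch")
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(vapply(seq_len(nrow(a)), function(i) {
      format_pdb_atom(a$atom_index[i], a$atom_name[i], a$residue_name[i], "A",
                      a$residue_index[i], xyz[i, ], bfac = bfactor[i],
                      element = a$element[i])
    }, character(1)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write per-atom stress values into the PDB B-factor column
#'
#' Values are rescaled linearly to `[0, 99.99]` so they survive the
#' fixed-width `%6.2f` B-factor field; the scale factor is recorded in a
#' REMARK line (`stress_pN = bfactor * scale`).
#'
#' @param system a `molecular_system`.
#' @param frame coordinates in nm.
#' @param values one finite nonnegative value per atom (pN).
#' @param path output file.
#' @return invisibly, the scale factor used.
#' @export
write_stress_pdb <- function(system, frame, values, path) {
  if (length(values) != n_atoms(system)) {
    stop("need exactly one stress value per atom")
  }
  if (!all(is.finite(values))) stop("stress values must be finite")
  vmax <- max(values)
  scale <- if (vmax > 0) vmax / 99.99 else 1
  rescaled <- values / scale
  tmp <- tempfile()
  write_pdb(system, frame, tmp, bfactor = rescaled)
  body <- readLines(tmp); unlink(tmp)
  writeLines(c(sprintf("REMARK 999 PUNCTUAL STRESS IN B-FACTOR; SCALE_PN_PER_UNIT %.8g",
                       scale), body), path)
  invisible(scale)
}

#' Read back B-factor values from a PDB file
#' @param path PDB file.
#' @return numeric vector of B-factor column values (first model).
#' @export
read_pdb_bfactors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  models <- split_pdb_models(lines)
  parse_pdb_atoms(models$records[[1]], models$line_no[[1]])$bfactor
}
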