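# Extended XYZ trajectory I/O (coordinates stored in Angstrom in the file,
# nm in memory). Frame comment line carries 'state=<label>' when written by
# this package. Binary MD formats are out of scope; readers are pluggable
# through read_trajectory().

#' Read an (extended) XYZ trajectory
#' @param path xyz file; repeated blocks of `n`, comment, `n` atom lines.
#' @return list with `elements` and `frames` (list of frames, nm).
#' @export
read_xyz_trajectory <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  frames <- list(); elements <- NULL; pos <- 1L
  while (pos <= length(lines) && nzchar(trimws(lines[pos]))) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("malformed xyz atom count at line ", pos)
    block <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    el <- vapply(toks, `[[`, character(1), 1)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) stop("malformed xyz coordinates near line ", pos)
    if (is.null(elements)) elements <- el
    frames[[length(frames) + 1L]] <- make_frame(xyz / 10)
    pos <- pos + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  list(elements = elements, frames = frames)
}

#' Write an (extended) XYZ trajectory
#' @param system a `molecular_system` (elements taken from the atom table).
#' @param frames list of frames (nm).
#' @param path output file.
#' @param state comment-line state label.
#' @export
write_xyz_trajectory <- function(system, frames, path, state = "apo") {
  if (!is.list(frames)) frames <- list(frames)
  con <- file(path, "w"); on.exit(close(con))
  el <- system$atoms$element
  for (f in seq_along(frames)) {
    xyz <- as.matrix(frames[[f]]) * 10
    writeLines(c(as.character(nrow(xyz)),
                 sprintf("frame=%d state=%s", f, state),
                 sprintf("%s %.6f %.6f %.6f", el, xyz[, 1], xyz[, 2], xyz[, 3])),
               con)
  }
  invisible(path)
}

#' Read a trajectory through a pluggable reader registry
#'
#' Dispatches on file extension: `.pdb` to [read_pdb_trajectory()], `.xyz` to
#' [read_xyz_trajectory()]. Additional readers (e.g. wrappers around binary MD
#' formats) can be registered for an extension.
#'
#' @param path trajectory file.
#' @param reader optional function(path) returning a list with `frames`.
#' @export
read_trajectory <- function(path, reader = NULL) {
  if (!is.null(reader)) return(reader(path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pdb = read_pdb_trajectory(path),
    xyz = read_xyz_trajectory(path),
    stop("no registered reader for extension '.", ext,
         "'; pass a reader function")
  )
}
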