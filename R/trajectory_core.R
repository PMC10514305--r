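# Structure / trajectory input and per-molecule center-of-geometry tracks.
# All coordinates are stored in nm, times in ns.

#' Load a reference structure
#'
#' Reads a structure with atom and residue annotations from PDB or GRO.
#' PDB coordinates (Angstrom) are converted to nm on load; GRO files are
#' already in nm.  Box vectors are taken from CRYST1 (PDB) or the final
#' box line (GRO) when present.
#'
#' @param path Path to the structure file.
#' @param dialect Format, `"pdb"` or `"gro"`.  Defaults to the file
#'   extension.
#' @return A `pw_structure`: list with `atoms` (data.frame with columns
#'   `elety`, `resid`, `resno`, `chain`, `x`, `y`, `z` in nm) and `box`
#'   (length-3 numeric in nm, or `NULL`).
#' @export
load_structure <- function(path, dialect = c("auto", "pdb", "gro")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, pdb = "pdb", gro = "gro",
                      stop("cannot infer structure dialect from extension '",
                           ext, "'; pass dialect explicitly"))
  }
  st <- switch(dialect, pdb = read_structure_pdb(path),
               gro = read_structure_gro(path))
  validate_structure(st, path)
  st
}

read_structure_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  a <- pdb$atom
  if (nrow(a) < 1L) stop("PDB file '", path, "' contains no ATOM/HETATM records")
  atoms <- data.frame(
    elety = a$elety, resid = a$resid, resno = a$resno,
    chain = ifelse(is.na(a$chain), "", a$chain),
    x = a$x / 10, y = a$y / 10, z = a$z / 10,
    stringsAsFactors = FALSE)
  box <- NULL
  cr <- grep("^CRYST1", readLines(path, warn = FALSE), value = TRUE)
  if (length(cr) >= 1L) {
    abc <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                         substr(cr[1], 16, 24),
                                         substr(cr[1], 25, 33))))
    if (!anyNA(abc) && all(abc > 0)) box <- abc / 10
  }
  structure(list(atoms = atoms, box = box), class = "pw_structure")
}

read_structure_gro <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (length(ln) < 3L) stop("GRO file '", path, "' truncated: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(ln[2])))
  if (is.na(n) || n < 1L)
    stop("GRO file '", path, "': line 2 is not a valid atom count")
  if (length(ln) < 2L + n + 1L)
    stop("GRO file '", path, "' truncated at line ", length(ln),
         ": expected ", 2L + n + 1L, " lines for ", n, " atoms")
  al <- ln[3:(2 + n)]
  bad <- which(nchar(al) < 44)
  if (length(bad))
    stop("GRO file '", path, "': atom line ", bad[1] + 2L, " too short")
  atoms <- data.frame(
    resno = as.integer(substr(al, 1, 5)),
    resid = trimws(substr(al, 6, 10)),
    elety = trimws(substr(al, 11, 15)),
    chain = "",
    x = as.numeric(substr(al, 21, 28)),
    y = as.numeric(substr(al, 29, 36)),
    z = as.numeric(substr(al, 37, 44)),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) || anyNA(atoms$resno))
    stop("GRO file '", path, "': unparseable coordinate field in atom records")
  atoms <- atoms[, c("elety", "resid", "resno", "chain", "x", "y", "z")]
  bx <- suppressWarnings(as.numeric(strsplit(trimws(ln[2 + n + 1L]), "\\s+")[[1]]))
  box <- if (length(bx) >= 3 && !anyNA(bx[1:3])) bx[1:3] else NULL
  structure(list(atoms = atoms, box = box), class = "pw_structure")
}

validate_structure <- function(st, path) {
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("structure '", path, "' contains non-finite coordinates")
  if (any(st$atoms$resno < 0, na.rm = TRUE))
    stop("structure '", path, "' contains negative residue indices")
  invisible(st)
}

#' @export
print.pw_structure <- function(x, ...) {
  cat("pw_structure:", nrow(x$atoms), "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues")
  if (!is.null(x$box)) cat(sprintf("; box %.3f x %.3f x %.3f nm",
                                   x$box[1], x$box[2], x$box[3]))
  cat("\n")
  invisible(x)
}

#' Load a coordinate trajectory
#'
#' Reads a multi-frame trajectory against a topology structure.  Supported
#' dialects: `"dcd"` (via bio3d, Angstrom converted to nm), `"xyz"`
#' (multi-frame XYZ; unit controlled by `unit`), and `"pdb"` (multi-MODEL
#' PDB, Angstrom).  Frame times are read from the file when the format
#' carries them (none of these do) or synthesized as
#' `(0, stride_ns, 2*stride_ns, ...)`.
#'
#' @param path Trajectory file.
#' @param topology A `pw_structure` whose atom count must match each frame.
#' @param dialect `"dcd"`, `"xyz"` or `"pdb"` (default from extension).
#' @param stride_ns Time between saved frames in ns; required unless
#'   `times_ns` is given.
#' @param times_ns Optional explicit per-frame times (ns), strictly
#'   increasing.
#' @param unit Coordinate unit for XYZ input, `"angstrom"` (conventional)
#'   or `"nm"`.
#' @param box Optional length-3 box vector (nm) applied to every frame when
#'   the file has none; the first frame must have a box from one source.
#' @return A `pw_trajectory`: list with `coords` (array frames x atoms x 3,
#'   nm), `times` (ns), `box` (matrix frames x 3, nm), `natoms`.
#' @export
load_trajectory <- function(path, topology, dialect = c("auto", "dcd", "xyz", "pdb"),
                            stride_ns = NULL, times_ns = NULL,
                            unit = c("angstrom", "nm"), box = NULL) {
  dialect <- match.arg(dialect)
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (!inherits(topology, "pw_structure")) stop("topology must be a pw_structure")
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, dcd = "dcd", xyz = "xyz", pdb = "pdb",
                      stop("cannot infer trajectory dialect from extension '", ext, "'"))
  }
  res <- switch(dialect,
    dcd = read_traj_dcd(path),
    xyz = read_traj_xyz(path, scale = if (unit == "angstrom") 0.1 else 1),
    pdb = read_traj_pdb(path))
  coords <- res$coords
  nf <- dim(coords)[1]; na <- dim(coords)[2]
  if (na != nrow(topology$atoms))
    stop("atom-count mismatch: trajectory has ", na, " atoms, topology has ",
         nrow(topology$atoms))
  if (!all(is.finite(coords)))
    stop("trajectory '", path, "' contains non-finite coordinates")
  if (is.null(times_ns)) {
    if (is.null(stride_ns))
      stop("trajectory carries no frame times; supply stride_ns or times_ns")
    times_ns <- (seq_len(nf) - 1) * stride_ns
  }
  if (length(times_ns) != nf) stop("times_ns length must equal frame count")
  if (nf > 1 && any(diff(times_ns) <= 0))
    stop("frame times must be strictly increasing")
  boxm <- res$box
  if (is.null(boxm)) {
    if (is.null(box)) box <- topology$box
    if (is.null(box))
      stop("no box vectors in trajectory, topology, or `box` argument")
    boxm <- matrix(rep(box, each = nf), nrow = nf)
  }
  # frames lacking a box inherit the previous frame's; first must have one
  for (f in seq_len(nf)) {
    if (anyNA(boxm[f, ])) {
      if (f == 1L) stop("first trajectory frame has no box vectors")
      boxm[f, ] <- boxm[f - 1L, ]
    }
  }
  new_trajectory(coords, times_ns, boxm)
}

new_trajectory <- function(coords, times, box) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  structure(list(coords = coords, times = as.numeric(times),
                 box = box, natoms = dim(coords)[2]),
            class = "pw_trajectory")
}

read_traj_dcd <- function(path) {
  m <- tryCatch(bio3d::read.dcd(path, verbose = FALSE),
                error = function(e) stop("failed to parse DCD '", path, "': ",
                                         conditionMessage(e)))
  m <- as.matrix(m)
  nf <- nrow(m); na <- ncol(m) / 3L
  coords <- aperm(array(t(m), dim = c(3, na, nf)), c(3, 2, 1)) / 10
  list(coords = coords, box = NULL)
}

read_traj_xyz <- function(path, scale = 0.1) {
  ln <- readLines(path, warn = FALSE)
  if (!length(ln)) stop("XYZ file '", path, "' is empty")
  frames <- list(); i <- 1L; nl <- length(ln)
  while (i <= nl) {
    if (!nzchar(trimws(ln[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(ln[i])))
    if (is.na(n) || n < 1L)
      stop("XYZ file '", path, "': line ", i, " is not a valid atom count")
    if (i + 1L + n > nl)
      stop("XYZ file '", path, "' truncated in frame starting at line ", i)
    block <- ln[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(lengths(parts) < 4L)
    if (length(bad))
      stop("XYZ file '", path, "': malformed atom line ", i + 1L + bad[1])
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + n
  }
  na <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, 1L) != na))
    stop("XYZ file '", path, "': atom count varies across frames")
  coords <- array(0, dim = c(length(frames), na, 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]] * scale
  list(coords = coords, box = NULL)
}

read_traj_pdb <- function(path) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB trajectory '",
                                           path, "': ", conditionMessage(e)))
  m <- pdb$xyz
  nf <- nrow(m); na <- ncol(m) / 3L
  coords <- aperm(array(t(as.matrix(m)), dim = c(3, na, nf)), c(3, 2, 1)) / 10
  list(coords = coords, box = NULL)
}

#' @export
print.pw_trajectory <- function(x, ...) {
  cat(sprintf("pw_trajectory: %d frames x %d atoms, t = %.4g..%.4g ns\n",
              dim(x$coords)[1], x$natoms, x$times[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' Resolve a species selection
#'
#' Maps atoms of a topology to disjoint molecules of one permeant species,
#' selecting by residue name and grouping atoms into molecules by
#' (chain, residue index).
#'
#' @param topology A `pw_structure`.
#' @param resid Residue name(s) to select (e.g. `"PDO"`, `"CLA"`, `"SOD"`,
#'   `"TIP3"`).
#' @param label Species label; defaults to the first `resid`.
#' @return A `pw_selection`: list with `label` and `molecules`, a named
#'   list of integer atom-index vectors (one per molecule).
#' @export
select_species <- function(topology, resid, label = resid[1]) {
  stopifnot(inherits(topology, "pw_structure"))
  keep <- which(topology$atoms$resid %in% resid)
  if (!length(keep))
    stop("selection error: no atoms with residue name(s) ",
         paste(resid, collapse = ", "))
  key <- paste(topology$atoms$chain[keep], topology$atoms$resno[keep], sep = "/")
  molecules <- split(keep, factor(key, levels = unique(key)))
  structure(list(label = label, molecules = molecules), class = "pw_selection")
}

#' Per-molecule center-of-geometry tracks
#'
#' Computes the unweighted mean of member-atom coordinates per molecule and
#' frame.  Molecules split across a periodic boundary are made whole first:
#' every atom is shifted by integer box vectors to its minimum-image
#' position relative to the molecule's first atom, so the center is never
#' an artefact of wrapping (it may lie just outside the primary box, one
#' image away, which is equivalent under periodicity).
#'
#' @param traj A `pw_trajectory`.
#' @param sel A `pw_selection`.
#' @return A `pw_tracks`: list with `label`, `coords` (array frames x
#'   molecules x 3, nm), `ids`, `times`, `box`.
#' @export
centers_of_geometry <- function(traj, sel) {
  stopifnot(inherits(traj, "pw_trajectory"), inherits(sel, "pw_selection"))
  if (!length(sel$molecules)) stop("selection error: selection resolves no molecules")
  nf <- dim(traj$coords)[1]
  nm <- length(sel$molecules)
  out <- array(0, dim = c(nf, nm, 3))
  for (m in seq_len(nm)) {
    idx <- sel$molecules[[m]]
    first <- traj$coords[, idx[1], , drop = FALSE]
    dim(first) <- c(nf, 3)
    acc <- first
    if (length(idx) > 1L) {
      for (a in idx[-1]) {
        at <- traj$coords[, a, , drop = FALSE]
        dim(at) <- c(nf, 3)
        disp <- at - first
        disp <- disp - traj$box * round(disp / traj$box)
        acc <- acc + (first + disp)
      }
    }
    out[, m, ] <- acc / length(idx)
  }
  new_tracks(sel$label, out, names(sel$molecules), traj$times, traj$box)
}

new_tracks <- function(label, coords, ids, times, box) {
  structure(list(label = label, coords = coords, ids = ids,
                 times = as.numeric(times), box = box),
            class = "pw_tracks")
}

#' @export
print.pw_tracks <- function(x, ...) {
  cat(sprintf("pw_tracks [%s]: %d molecules x %d frames\n",
              x$label, dim(x$coords)[2], dim(x$coords)[1]))
  invisible(x)
}

#' Write molecule tracks as delimited text
#'
#' One row per molecule per frame: `molecule, frame, t_ns, x, y, z`.
#'
#' @param tracks A `pw_tracks`.
#' @param path Output file.
#' @param sep Field separator.
#' @export
write_tracks <- function(tracks, path, sep = "\t") {
  stopifnot(inherits(tracks, "pw_tracks"))
  nf <- dim(tracks$coords)[1]; nm <- dim(tracks$coords)[2]
  df <- data.frame(
    molecule = rep(tracks$ids, each = nf),
    frame = rep(seq_len(nf), nm),
    t_ns = rep(tracks$times, nm),
    x = as.vector(tracks$coords[, , 1]),
    y = as.vector(tracks$coords[, , 2]),
    z = as.vector(tracks$coords[, , 3]))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read molecule tracks written by [write_tracks()]
#' @param label Species label to attach.
#' @inheritParams write_tracks
#' @return A `pw_tracks` (with `box` set to `NA`, unknown from the file).
#' @export
read_tracks <- function(path, label = "species", sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("molecule", "frame", "t_ns", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("track file '", path, "' missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  ids <- unique(df$molecule)
  frames <- sort(unique(df$frame))
  nf <- length(frames); nm <- length(ids)
  coords <- array(NA_real_, dim = c(nf, nm, 3))
  mi <- match(df$molecule, ids); fi <- match(df$frame, frames)
  coords[cbind(fi, mi, 1L)] <- df$x
  coords[cbind(fi, mi, 2L)] <- df$y
  coords[cbind(fi, mi, 3L)] <- df$z
  times <- df$t_ns[match(frames, df$frame)]
  new_tracks(label, coords, as.character(ids), times,
             matrix(NA_real_, nf, 3))
}
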