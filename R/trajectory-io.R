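#' Construct a Trajectory from a coordinate array
#'
#' Low-level constructor used by the readers and by the synthetic generator.
#'
#' @param coords frames x residues x 3 numeric array (Angstrom).
#' @param residueIds author residue numbers (one per residue column).
#' @param atomName representative atom name.
#' @param frameTimes optional frame times (ns).
#' @return a [Trajectory-class] object.
#' @export
Trajectory <- function(coords, residueIds, atomName = "CA",
                       frameTimes = numeric(0)) {
  o <- order(residueIds)
  new("Trajectory", coords = coords[, o, , drop = FALSE],
      residueIds = as.integer(residueIds)[o], atomName = atomName,
      frameTimes = as.numeric(frameTimes))
}

#' Read a trajectory with one representative atom per residue
#'
#' Supported dialects:
#' \describe{
#'   \item{`pdb`}{multi-model PDB (`MODEL`/`ENDMDL` records), read through
#'     bio3d; one frame per model.}
#'   \item{`table`}{whitespace-separated rows `frame residue x y z`, one line
#'     per residue per frame, `#` comment lines allowed; hand-writable.}
#'   \item{`dcd`}{CHARMM/NAMD DCD, read through bio3d; requires a PDB
#'     `topology` for atom names and residue numbering.}
#' }
#' XTC is not supported and raises an error. Residues lacking the selected
#' atom are dropped with a warning. Author residue numbering is preserved.
#'
#' @param path input file.
#' @param format one of `"auto"`, `"pdb"`, `"table"`, `"dcd"`, `"xtc"`.
#'   `"auto"` picks by file extension (`.pdb`, `.dcd`, anything else = table).
#' @param selection representative atom name (default `"CA"`).
#' @param topology PDB file defining atoms for `dcd` input.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, format = c("auto", "pdb", "table", "dcd", "xtc"),
                           selection = "CA", topology = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", dcd = "dcd", xtc = "xtc",
                     "table")
  }
  switch(format,
    pdb = .readTrajectoryPDB(path, selection),
    table = .readTrajectoryTable(path),
    dcd = .readTrajectoryDCD(path, topology, selection),
    xtc = stop("XTC input is not supported; convert to multi-model PDB or DCD"))
}

.selectOnePerResidue <- function(pdb, selection, path) {
  sel <- pdb$atom$elety == selection &
    !duplicated(paste(pdb$atom$chain, pdb$atom$resno, pdb$atom$elety))
  if (!any(sel))
    stop("no '", selection, "' atoms found in ", path)
  dropped <- setdiff(unique(pdb$atom$resno), pdb$atom$resno[sel])
  if (length(dropped))
    warning("residues lacking atom '", selection, "' dropped: ",
            paste(dropped, collapse = ", "))
  which(sel)
}

.readTrajectoryPDB <- function(path, selection) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("unparseable PDB file ", path, ": ",
                                           conditionMessage(e)))
  idx <- .selectOnePerResidue(pdb, selection, path)
  ids <- pdb$atom$resno[idx]
  if (anyDuplicated(ids))
    stop("duplicate residue numbers across chains in ", path,
         "; single-chain input required")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  if (nf == 0L) stop("empty input: no frames (MODEL records) in ", path)
  ci <- as.vector(rbind(3 * (idx - 1) + 1, 3 * (idx - 1) + 2, 3 * idx))
  coords <- array(NA_real_, c(nf, length(idx), 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ci], ncol = 3, byrow = TRUE)
  Trajectory(coords, ids, atomName = selection)
}

.readTrajectoryTable <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("empty input: no coordinate rows in ", path)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  lineno <- which(keep)
  bad <- which(lengths(fields) != 5L)
  if (length(bad))
    stop("format error in ", path, " line ", lineno[bad[1]],
         ": expected 'frame residue x y z'")
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 5, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("format error in ", path, " line ", lineno[bad], ": non-numeric field")
  }
  frames <- sort(unique(m[, 1]))
  ids <- sort(unique(m[, 2]))
  if (length(frames) < 2L) stop("a trajectory needs at least 2 frames, got ",
                                length(frames))
  coords <- array(NA_real_, c(length(frames), length(ids), 3))
  fi <- match(m[, 1], frames); ri <- match(m[, 2], ids)
  if (anyDuplicated(cbind(fi, ri)))
    stop("format error in ", path, ": duplicate residue within a frame")
  coords[cbind(fi, ri, 1)] <- m[, 3]
  coords[cbind(fi, ri, 2)] <- m[, 4]
  coords[cbind(fi, ri, 3)] <- m[, 5]
  if (anyNA(coords)) {
    miss <- which(is.na(coords[, , 1]), arr.ind = TRUE)
    stop("frame ", frames[miss[1, 1]], " is missing residue ",
         ids[miss[1, 2]], " in ", path)
  }
  Trajectory(coords, ids, atomName = "CA")
}

.readTrajectoryDCD <- function(path, topology, selection) {
  if (is.null(topology))
    stop("dcd input requires a PDB 'topology' file")
  pdb <- bio3d::read.pdb(topology, verbose = FALSE)
  idx <- .selectOnePerResidue(pdb, selection, topology)
  ids <- pdb$atom$resno[idx]
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(pdb$atom))
    stop("format error: dcd atom count does not match topology ", topology)
  nf <- nrow(xyz)
  ci <- as.vector(rbind(3 * (idx - 1) + 1, 3 * (idx - 1) + 2, 3 * idx))
  coords <- array(NA_real_, c(nf, length(idx), 3))
  for (f in seq_len(nf))
    coords[f, , ] <- matrix(xyz[f, ci], ncol = 3, byrow = TRUE)
  Trajectory(coords, ids, atomName = selection)
}

#' Write a trajectory as a plain coordinate table
#'
#' Writes the whitespace-separated `frame residue x y z` dialect read back by
#' [readTrajectory()] (`format = "table"`). Coordinates are printed with full
#' double precision so that write/read round-trips are exact.
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectoryTable <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  d <- dim(traj@coords)
  fr <- rep(seq_len(d[1]), each = d[2])
  rs <- rep(traj@residueIds, d[1])
  x <- as.vector(t(traj@coords[, , 1]))
  y <- as.vector(t(traj@coords[, , 2]))
  z <- as.vector(t(traj@coords[, , 3]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# frame residue x y z",
               sprintf("%d %d %.17g %.17g %.17g", fr, rs, x, y, z)), con)
  invisible(path)
}
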