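#' @include AllClasses.R utils.R
NULL

#' Construct a Trajectory from a coordinate array
#'
#' @param coords numeric array frames x atoms x 3 (Angstrom).
#' @param residueIds per-atom residue identifiers (e.g. "GLN149"); defaults
#'   to one residue per atom.
#' @return a \linkS4class{Trajectory}.
#' @export
trajectory <- function(coords, residueIds = NULL) {
  coords <- as.array(coords)
  if (is.null(residueIds)) {
    residueIds <- as.character(seq_len(dim(coords)[2]))
  }
  new("Trajectory", coords = coords, residueIds = as.character(residueIds))
}

#' Read a multi-model PDB file as a Trajectory
#'
#' Frames are the MODEL/ENDMDL records of the file; the atom-to-residue
#' mapping combines the residue name and number (e.g. "GLN149").
#'
#' @param path PDB file path.
#' @return a \linkS4class{Trajectory}.
#' @export
readTrajectoryPDB <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  natoms <- ncol(xyz) / 3L
  arr <- array(NA_real_, c(nrow(xyz), natoms, 3L))
  for (f in seq_len(nrow(xyz))) {
    arr[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  rid <- paste0(pdb$atom$resid, pdb$atom$resno)
  trajectory(arr, rid)
}

#' Per-frame RMSD against the initial conformation
#'
#' \code{RMSD_t = sqrt(mean_i |x_i(t) - x_i(0)|^2)} with frame 1 as the
#' reference; optionally each frame is first rigidly superposed onto the
#' reference (Kabsch).
#'
#' @param traj a \linkS4class{Trajectory} with at least one frame.
#' @param superpose superpose each frame on the reference first (default
#'   FALSE).
#' @return numeric RMSD per frame (Angstrom); the first entry is 0.
#' @export
rmsdSeries <- function(traj, superpose = FALSE) {
  stopifnot(is(traj, "Trajectory"))
  d <- dim(traj@coords)
  ref <- traj@coords[1, , , drop = TRUE]
  if (is.null(dim(ref))) ref <- matrix(ref, ncol = 3)
  vapply(seq_len(d[1]), function(f) {
    fr <- traj@coords[f, , , drop = TRUE]
    if (is.null(dim(fr))) fr <- matrix(fr, ncol = 3)
    if (superpose) {
      k <- kabsch(fr, ref)
      fr <- applyRigid(fr, k$rotation, k$translation)
    }
    sqrt(mean(rowSums((fr - ref)^2)))
  }, numeric(1))
}

#' Per-residue RMSF over a trajectory
#'
#' Per atom, \code{sqrt(mean_t |x_i(t) - xbar_i|^2)} about the time-mean
#' position; per residue, the mean over its atoms.
#'
#' @param traj a \linkS4class{Trajectory} with at least two frames.
#' @return named numeric RMSF per residue (Angstrom), in order of first
#'   appearance.
#' @export
rmsfPerResidue <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  d <- dim(traj@coords)
  if (d[1] < 2L) stop("RMSF needs at least two frames", call. = FALSE)
  xbar <- apply(traj@coords, c(2, 3), mean)
  dev2 <- sapply(seq_len(d[2]), function(i) {
    mean(rowSums(sweep(traj@coords[, i, , drop = TRUE], 2, xbar[i, ])^2))
  })
  atomRmsf <- sqrt(dev2)
  res <- factor(traj@residueIds, levels = unique(traj@residueIds))
  out <- tapply(atomRmsf, res, mean)
  stats::setNames(as.numeric(out), names(out))
}
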