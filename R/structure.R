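# Domain types: Conformation, Trajectory, AtomSelection.
#
# A Conformation couples an atom table (name, residue, chain, element) with an
# n x 3 coordinate matrix in Angstrom.  Residue indices are the PDB's own
# (1-based, possibly gapped); selections hold positions into the atom table.

#' Create a Conformation
#'
#' The universal currency of the package: an ordered atom list with one 3D
#' coordinate per atom (Angstrom).
#'
#' @param atoms data.frame with columns `atom_name`, `residue_name`,
#'   `residue_index` (integer, as in the source PDB), `chain_id`, `element`.
#' @param xyz numeric matrix, `nrow(atoms)` x 3, finite.
#' @return An object of class `Conformation`.
#' @export
conformation <- function(atoms, xyz) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("atom_name", "residue_name", "residue_index", "chain_id", "element")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    stop("atoms table lacks column(s): ", paste(missing_cols, collapse = ", "))
  xyz <- as.matrix(xyz)
  if (is.null(dim(xyz)) || ncol(xyz) != 3)
    stop("xyz must be an n x 3 matrix")
  if (nrow(xyz) != nrow(atoms))
    stop("coordinate count (", nrow(xyz), ") does not match atom count (",
         nrow(atoms), ")")
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in Conformation")
  if (any(!nzchar(atoms$atom_name)))
    stop("empty atom_name in atoms table")
  if (any(atoms$residue_index < 1))
    stop("residue_index must be >= 1")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, xyz = xyz), class = "Conformation")
}

#' @export
print.Conformation <- function(x, ...) {
  nres <- length(unique(paste(x$atoms$chain_id, x$atoms$residue_index)))
  cat("Conformation:", nrow(x$atoms), "atoms,", nres, "residues\n")
  invisible(x)
}

#' Number of atoms in a Conformation
#' @param conf a [conformation()].
#' @return Integer atom count.
#' @export
n_atoms <- function(conf) nrow(conf$atoms)

#' Create a Trajectory
#'
#' Ordered coordinate frames sharing one atom list, with strictly increasing
#' frame times in ps.
#'
#' @param atoms atom table as in [conformation()] (residue metadata may be
#'   absent when read back from a plain XYZ file).
#' @param frames list of n x 3 coordinate matrices.
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @return An object of class `Trajectory`.
#' @export
trajectory <- function(atoms, frames, times) {
  if (length(frames) == 0) stop("trajectory must contain at least one frame")
  if (length(frames) != length(times))
    stop("frame count does not match time count")
  n <- nrow(frames[[1]])
  for (i in seq_along(frames)) {
    frames[[i]] <- as.matrix(frames[[i]])
    if (nrow(frames[[i]]) != n || ncol(frames[[i]]) != 3)
      stop("frame ", i, " has inconsistent dimensions")
  }
  if (nrow(atoms) != n)
    stop("atom table does not match frame atom count")
  if (any(diff(times) <= 0))
    stop("frame_times must be strictly increasing")
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 frames = frames, times = as.numeric(times)),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames,", nrow(x$atoms), "atoms, t =",
      format(x$times[1]), "..", format(x$times[length(x$times)]), "ps\n")
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj a [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Create an AtomSelection
#'
#' Positions into a Conformation's atom table (1-based), unique and in range
#' for the structure they were built against.
#'
#' @param indices integer vector of 1-based atom positions.
#' @param label short description of the selection.
#' @return An object of class `AtomSelection`.
#' @export
atom_selection <- function(indices, label = "") {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  if (length(indices) > 0 && any(indices < 1))
    stop("selection indices must be >= 1")
  structure(list(indices = indices, label = as.character(label)),
            class = "AtomSelection")
}

#' @export
print.AtomSelection <- function(x, ...) {
  cat("AtomSelection '", x$label, "': ", length(x$indices), " atoms\n",
      sep = "")
  invisible(x)
}

# Resolve a selection argument (AtomSelection | integer vector | NULL = all).
resolve_selection <- function(sel, n) {
  if (is.null(sel)) return(seq_len(n))
  idx <- if (inherits(sel, "AtomSelection")) sel$indices else as.integer(sel)
  if (length(idx) > 0 && (max(idx) > n || min(idx) < 1))
    stop("selection index out of range (structure has ", n, " atoms)")
  idx
}

# Locate one atom by (residue_index, atom_name); chain optional.
find_atom <- function(conf, residue_index, atom_name, chain_id = NULL) {
  hit <- conf$atoms$residue_index == residue_index &
    conf$atoms$atom_name == atom_name
  if (!is.null(chain_id)) hit <- hit & conf$atoms$chain_id == chain_id
  which(hit)
}
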