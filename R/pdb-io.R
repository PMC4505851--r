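# PDB reading/writing (bio3d-backed) and the plain-text multi-frame XYZ
# trajectory dialect.

#' Read a PDB file into a Conformation
#'
#' Parses ATOM/HETATM records (PDB v3.3 columns) via [bio3d::read.pdb()].
#' Alternate locations are resolved to the highest occupancy, ties broken
#' alphabetically by altloc code.  Only one MODEL of a multi-model file is
#' returned (the first by default): the crystal structures this package
#' targets are single-model.
#'
#' @param path path to a PDB file.
#' @param model 1-based model index for multi-model files.
#' @param hetatm keep HETATM records (default TRUE).
#' @return A [conformation()]; coordinates in Angstrom, original residue
#'   numbering preserved.
#' @export
read_pdb <- function(path, model = 1L, hetatm = TRUE) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom))
    stop("empty structure: no ATOM/HETATM records in ", path)
  # Validate coordinate fields up front so a malformed line is reported by
  # line number rather than surfacing as an opaque parse failure downstream.
  for (ln in which(is_atom)) {
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      txt <- trimws(substr(lines[ln], fld[1], fld[2]))
      if (is.na(suppressWarnings(as.numeric(txt))))
        stop("malformed coordinate field at line ", ln, " of ", path,
             ": '", txt, "'")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  if (!hetatm) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no ATOM records in ", path)

  nmodels <- max(1L, nrow(pdb$xyz))
  if (model < 1 || model > nmodels)
    stop("model index ", model, " out of range (file has ", nmodels, ")")
  xyz_row <- pdb$xyz[model, ]
  xyz <- matrix(xyz_row, ncol = 3, byrow = TRUE)[seq_len(nrow(pdb$atom)), ,
                                                 drop = FALSE]
  keep_type <- if (hetatm) rep(TRUE, nrow(pdb$atom)) else pdb$atom$type == "ATOM"

  # altloc resolution: within each (chain, resno, insert, atom name) group
  # keep the record with highest occupancy; ties alphabetical by alt code.
  alt <- pdb$atom$alt
  alt[is.na(alt)] <- ""
  occ <- pdb$atom$o
  occ[is.na(occ)] <- 1
  key <- paste(pdb$atom$chain, pdb$atom$resno, pdb$atom$insert,
               pdb$atom$elety, sep = "\r")
  keep_alt <- rep(TRUE, nrow(pdb$atom))
  for (g in split(seq_len(nrow(pdb$atom)), key)) {
    if (length(g) > 1) {
      ord <- order(-occ[g], alt[g])
      keep_alt[g[-ord[1]]] <- FALSE
    }
  }
  keep <- keep_type & keep_alt
  at <- pdb$atom[keep, , drop = FALSE]
  xyz <- xyz[keep, , drop = FALSE]

  elem <- at$elesy
  elem[is.na(elem) | !nzchar(elem)] <- substr(trimws(at$elety[is.na(elem) | !nzchar(elem)]), 1, 1)
  chain <- at$chain
  chain[is.na(chain)] <- ""
  conformation(
    atoms = data.frame(atom_name = trimws(at$elety),
                       residue_name = trimws(at$resid),
                       residue_index = as.integer(at$resno),
                       chain_id = chain,
                       element = trimws(elem),
                       stringsAsFactors = FALSE),
    xyz = xyz)
}

#' Write a Conformation to a PDB file
#'
#' @param conf a [conformation()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(conf, path) {
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(conf$xyz)),
                   resno = conf$atoms$residue_index,
                   resid = conf$atoms$residue_name,
                   eleno = seq_len(n_atoms(conf)),
                   elety = conf$atoms$atom_name,
                   chain = ifelse(nzchar(conf$atoms$chain_id),
                                  conf$atoms$chain_id, "A"),
                   elesy = conf$atoms$element)
  invisible(path)
}

#' Select the representative backbone atoms of a loop
#'
#' For every residue in `first_res:last_res` (by `residue_index`): the
#' backbone amide hydrogen `H` (skipped for prolines, which have none), the
#' carbonyl oxygen `O`, and `CA`.  These Cartesian coordinates pin down both
#' the position and the orientation of each peptide plane.  Selected
#' side-chain atoms (e.g. one CB) can be added through `extra_atoms`.
#' Ordering is deterministic: by residue, then H, O, CA, then that residue's
#' extras.
#'
#' @param conf a [conformation()].
#' @param first_res,last_res residue range (PDB numbering, inclusive).
#' @param extra_atoms list of `c(residue_index, atom_name)` pairs (or a
#'   2-column data.frame) appended per residue.
#' @return An [atom_selection()].
#' @export
select_representative_atoms <- function(conf, first_res, last_res,
                                        extra_atoms = list()) {
  resids <- sort(unique(conf$atoms$residue_index[
    conf$atoms$residue_index >= first_res &
    conf$atoms$residue_index <= last_res]))
  if (length(resids) == 0)
    stop("residue range ", first_res, ":", last_res, " not present")
  if (is.data.frame(extra_atoms))
    extra_atoms <- lapply(seq_len(nrow(extra_atoms)),
                          function(i) c(extra_atoms[i, 1], extra_atoms[i, 2]))
  extra_res <- vapply(extra_atoms, function(e) as.integer(e[[1]]), integer(1))
  extra_name <- vapply(extra_atoms, function(e) as.character(e[[2]]),
                       character(1))
  for (k in seq_along(extra_atoms)) {
    if (length(find_atom(conf, extra_res[k], extra_name[k])) == 0)
      stop("missing atom: requested extra atom ", extra_name[k],
           " in residue ", extra_res[k], " is absent")
  }
  idx <- integer(0)
  for (r in resids) {
    is_pro <- any(conf$atoms$residue_index == r &
                  conf$atoms$residue_name == "PRO")
    if (!is_pro) idx <- c(idx, find_atom(conf, r, "H")[1])
    idx <- c(idx, find_atom(conf, r, "O")[1], find_atom(conf, r, "CA")[1])
    for (k in which(extra_res == r))
      idx <- c(idx, find_atom(conf, r, extra_name[k])[1])
  }
  idx <- idx[!is.na(idx)]
  atom_selection(idx, label = sprintf("representative %d-%d", first_res,
                                      last_res))
}

#' Place backbone amide hydrogens
#'
#' Crystal structures usually lack hydrogens; H-bond distance monitors need
#' the amide H.  For every non-proline, non-N-terminal residue lacking an H,
#' one is placed 1.00 Angstrom from N, in the C(prev)-N-CA plane, along the
#' exterior-angle bisector (standard ideal amide geometry).  Existing
#' hydrogens are untouched; residues with missing backbone atoms are skipped
#' with a warning.
#'
#' @param conf a [conformation()].
#' @return A new [conformation()] with hydrogens inserted after each N.
#' @export
place_amide_hydrogens <- function(conf) {
  at <- conf$atoms
  keys <- unique(data.frame(chain = at$chain_id, res = at$residue_index,
                            stringsAsFactors = FALSE))
  keys <- keys[order(keys$chain, keys$res), ]
  new_atoms <- list()
  new_xyz <- list()
  for (i in seq_len(nrow(keys))) {
    ch <- keys$chain[i]; r <- keys$res[i]
    rows <- which(at$chain_id == ch & at$residue_index == r)
    resname <- at$residue_name[rows[1]]
    block_atoms <- at[rows, , drop = FALSE]
    block_xyz <- conf$xyz[rows, , drop = FALSE]
    needs_h <- resname != "PRO" && !any(block_atoms$atom_name == "H")
    prev_rows <- which(at$chain_id == ch & at$residue_index < r)
    is_nterm <- length(prev_rows) == 0
    if (needs_h && is_nterm) {
      warning("no amide H placed for N-terminal residue ", resname, r)
      needs_h <- FALSE
    }
    if (needs_h) {
      iN <- rows[block_atoms$atom_name == "N"][1]
      iCA <- rows[block_atoms$atom_name == "CA"][1]
      prev_res <- max(at$residue_index[prev_rows])
      iC <- which(at$chain_id == ch & at$residue_index == prev_res &
                  at$atom_name == "C")[1]
      if (is.na(iN) || is.na(iCA) || is.na(iC)) {
        warning("missing backbone atom; no amide H placed for residue ",
                resname, r)
      } else {
        vC <- conf$xyz[iC, ] - conf$xyz[iN, ]
        vCA <- conf$xyz[iCA, ] - conf$xyz[iN, ]
        u <- -(vC / sqrt(sum(vC^2)) + vCA / sqrt(sum(vCA^2)))
        u <- u / sqrt(sum(u^2))
        h_xyz <- conf$xyz[iN, ] + 1.00 * u
        pos <- which(block_atoms$atom_name == "N")[1]
        h_row <- block_atoms[pos, , drop = FALSE]
        h_row$atom_name <- "H"
        h_row$element <- "H"
        block_atoms <- rbind(block_atoms[seq_len(pos), , drop = FALSE], h_row,
                             if (pos < nrow(block_atoms))
                               block_atoms[(pos + 1):nrow(block_atoms), ,
                                           drop = FALSE])
        block_xyz <- rbind(block_xyz[seq_len(pos), , drop = FALSE],
                           matrix(h_xyz, 1, 3),
                           if (pos < nrow(block_xyz))
                             block_xyz[(pos + 1):nrow(block_xyz), ,
                                       drop = FALSE])
      }
    }
    new_atoms[[i]] <- block_atoms
    new_xyz[[i]] <- block_xyz
  }
  conformation(do.call(rbind, new_atoms), do.call(rbind, new_xyz))
}

#' Write a Trajectory as multi-frame plain-text XYZ
#'
#' Dialect: per frame an atom-count line, a comment line `t=<ps>`, then one
#' `name x y z` row per atom where `name` is
#' `atom_name/residue_name/residue_index`.  Coordinates carry 6 decimal
#' places, losslessly round-tripping to well under 1e-5 Angstrom.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "Trajectory")) stop("not a Trajectory")
  if (length(traj$frames) == 0) stop("cannot write an empty trajectory")
  at <- traj$atoms
  nm <- paste(at$atom_name,
              if (!is.null(at$residue_name)) at$residue_name else "UNK",
              if (!is.null(at$residue_index)) at$residue_index else 1,
              sep = "/")
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    writeLines(as.character(nrow(at)), con)
    writeLines(sprintf("t=%.6f", traj$times[f]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", nm,
                       traj$frames[[f]][, 1], traj$frames[[f]][, 2],
                       traj$frames[[f]][, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame plain-text XYZ trajectory
#'
#' @param path path written by [write_trajectory()].
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pos <- 1L
  frames <- list()
  times <- numeric(0)
  atoms <- NULL
  fidx <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    fidx <- fidx + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n)) stop("format error at frame ", fidx, ": bad atom count line")
    if (!is.null(atoms) && n != nrow(atoms))
      stop("format error at frame ", fidx, ": atom count ", n,
           " differs from first frame (", nrow(atoms), ")")
    tline <- lines[pos + 1L]
    t <- suppressWarnings(as.numeric(sub("^\\s*t=", "", tline)))
    if (is.na(t)) stop("format error at frame ", fidx, ": bad time line")
    rows <- lines[(pos + 2L):(pos + 1L + n)]
    if (length(rows) < n || any(is.na(rows)))
      stop("format error at frame ", fidx, ": truncated frame")
    parts <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) != 4)
    if (length(bad) > 0)
      stop("format error at frame ", fidx, ", row ", bad[1])
    nm <- vapply(parts, `[[`, character(1), 1)
    xyz <- matrix(as.numeric(t(vapply(parts, function(p) p[2:4],
                                      character(3)))), ncol = 3)
    if (is.null(atoms)) {
      fields <- strsplit(nm, "/", fixed = TRUE)
      atoms <- data.frame(
        atom_name = vapply(fields, `[[`, character(1), 1),
        residue_name = vapply(fields, function(f)
          if (length(f) >= 2) f[[2]] else "UNK", character(1)),
        residue_index = vapply(fields, function(f)
          if (length(f) >= 3) as.integer(f[[3]]) else 1L, integer(1)),
        chain_id = "A", stringsAsFactors = FALSE)
      atoms$element <- substr(atoms$atom_name, 1, 1)
    }
    frames[[fidx]] <- xyz
    times[fidx] <- t
    pos <- pos + 2L + n
  }
  if (fidx == 0L) stop("format error: no frames in ", path)
  trajectory(atoms, frames, times)
}

#' Extract one frame of a Trajectory as a Conformation
#' @param traj a [trajectory()].
#' @param frame 1-based frame index.
#' @return A [conformation()].
#' @export
frame_conformation <- function(traj, frame) {
  conformation(traj$atoms, traj$frames[[frame]])
}
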