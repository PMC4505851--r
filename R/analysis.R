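# Structural statistics: torsion (Ramachandran) profiles and deviations,
# RMSD series, dynamic cross-correlation, H-bond distances, layer thickness,
# per-residue displacement.

#' Dihedral angle of four points
#'
#' IUPAC sign convention: cis = 0, trans = 180, right-handed rotations
#' positive.  Angles are reported in degrees in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @return Dihedral angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-18 || sum(n2^2) < 1e-18)
    stop("undefined dihedral: three consecutive points are collinear")
  b2n <- b2 / sqrt(sum(b2^2))
  n1xn2 <- c(n1[2] * n2[3] - n1[3] * n2[2],
             n1[3] * n2[1] - n1[1] * n2[3],
             n1[1] * n2[2] - n1[2] * n2[1])
  ang <- atan2(sum(n1xn2 * b2n), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Wrap an angle (degrees) into (-180, 180].
wrap180 <- function(a) {
  a <- a %% 360
  hi <- which(a > 180)
  a[hi] <- a[hi] - 360
  a
}

#' Smallest periodic difference between two angles
#' @param a,b angles in degrees.
#' @return Deviation in `[0, 180]` degrees.
#' @export
angle_deviation <- function(a, b) abs(wrap180(a - b))

#' Backbone phi/psi torsion profile of a conformation
#'
#' phi(i) = C(i-1)-N(i)-CA(i)-C(i); psi(i) = N(i)-CA(i)-C(i)-N(i+1).
#' Terminal residues carry `NA` for the torsion that is undefined.
#'
#' @param conf a [conformation()].
#' @return data.frame with `residue_index`, `residue_name`, `phi`, `psi`
#'   (degrees in `(-180, 180]`).
#' @export
torsion_profile <- function(conf) {
  resids <- sort(unique(conf$atoms$residue_index))
  get1 <- function(r, nm) {
    i <- find_atom(conf, r, nm)[1]
    if (is.na(i) || length(i) == 0) NULL else conf$xyz[i, ]
  }
  out <- data.frame(residue_index = resids,
                    residue_name = vapply(resids, function(r)
                      conf$atoms$residue_name[
                        which(conf$atoms$residue_index == r)[1]],
                      character(1)),
                    phi = NA_real_, psi = NA_real_)
  for (k in seq_along(resids)) {
    r <- resids[k]
    N <- get1(r, "N"); CA <- get1(r, "CA"); C <- get1(r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (k > 1) {
      Cprev <- get1(resids[k - 1], "C")
      if (!is.null(Cprev)) out$phi[k] <- dihedral(Cprev, N, CA, C)
    }
    if (k < length(resids)) {
      Nnext <- get1(resids[k + 1], "N")
      if (!is.null(Nnext)) out$psi[k] <- dihedral(N, CA, C, Nnext)
    }
  }
  out
}

#' Per-residue torsion deviation between two conformations
#'
#' For each shared residue, the smallest periodic differences
#' `delta_phi`, `delta_psi` (degrees, in `[0, 180]`) and the combined
#' deviation `sqrt(delta_phi^2 + delta_psi^2)`.  A torsion undefined in
#' either structure (chain terminus) is excluded from the combination and
#' marked `NA`.
#'
#' @param a,b two [conformation()]s sharing a residue sequence over the
#'   compared range.
#' @return data.frame with `residue_index`, `delta_phi`, `delta_psi`,
#'   `combined`.
#' @export
torsion_deviation_profile <- function(a, b) {
  ta <- torsion_profile(a)
  tb <- torsion_profile(b)
  shared <- intersect(ta$residue_index, tb$residue_index)
  if (length(shared) == 0) stop("alignment error: no shared residues")
  ta <- ta[match(shared, ta$residue_index), ]
  tb <- tb[match(shared, tb$residue_index), ]
  mismatch <- ta$residue_name != tb$residue_name
  if (any(mismatch))
    stop("alignment error: residue name mismatch at residue ",
         shared[which(mismatch)[1]])
  dphi <- ifelse(is.na(ta$phi) | is.na(tb$phi), NA_real_,
                 angle_deviation(ta$phi, tb$phi))
  dpsi <- ifelse(is.na(ta$psi) | is.na(tb$psi), NA_real_,
                 angle_deviation(ta$psi, tb$psi))
  comb <- sqrt(ifelse(is.na(dphi), 0, dphi^2) +
               ifelse(is.na(dpsi), 0, dpsi^2))
  comb[is.na(dphi) & is.na(dpsi)] <- NA_real_
  data.frame(residue_index = shared, delta_phi = dphi, delta_psi = dpsi,
             combined = comb)
}

#' RMSD time series of a trajectory against a reference
#'
#' @param traj a [trajectory()].
#' @param ref reference [conformation()] (or coordinate matrix).
#' @param sel selection applied to both (default all atoms).
#' @param superpose superpose each frame onto the reference on the same
#'   selection before measuring (default TRUE).
#' @return data.frame with `time` (ps) and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(traj, ref, sel = NULL, superpose = TRUE) {
  xr <- if (inherits(ref, "Conformation")) ref$xyz else as.matrix(ref)
  idx <- resolve_selection(sel, nrow(traj$frames[[1]]))
  refc <- xr[idx, , drop = FALSE]
  vals <- vapply(traj$frames, function(fr) {
    m <- fr[idx, , drop = FALSE]
    if (superpose) kabsch_superpose(m, refc)$rmsd else rmsd_raw(m, refc)
  }, numeric(1))
  data.frame(time = traj$times, rmsd = vals)
}

#' Dynamic cross-correlation between two residue sets
#'
#' C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>), with dr the displacement
#' of a residue's CA from its trajectory mean and averages over frames.
#' Frames are first aligned to the first frame on all CA atoms, removing
#' rigid-body drift that would otherwise inflate correlations.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param set_a,set_b residue index vectors (each residue represented by its
#'   CA atom).
#' @param align align frames to the first frame on all CA before computing
#'   displacements (default TRUE).
#' @return Matrix of correlations in `[-1, 1]`, rows = `set_a`, cols =
#'   `set_b`; `NA` marks a residue with zero fluctuation.
#' @export
dynamic_cross_correlation <- function(traj, set_a, set_b, align = TRUE) {
  if (length(traj$frames) < 2) stop("need at least 2 frames")
  ca_all <- which(traj$atoms$atom_name == "CA")
  ca_of <- function(r) {
    i <- which(traj$atoms$atom_name == "CA" & traj$atoms$residue_index == r)
    if (length(i) == 0) stop("no CA atom for residue ", r)
    i[1]
  }
  ia <- vapply(set_a, ca_of, integer(1))
  ib <- vapply(set_b, ca_of, integer(1))
  frames <- traj$frames
  if (align && length(ca_all) >= 3) {
    ref <- frames[[1]][ca_all, , drop = FALSE]
    frames <- lapply(frames, function(fr) {
      fit <- kabsch_superpose(fr[ca_all, , drop = FALSE], ref)
      cm <- colMeans(fr[ca_all, , drop = FALSE])
      sweep(sweep(fr, 2, cm) %*% t(fit$rotation), 2, colMeans(ref),
            FUN = "+")
    })
  }
  nf <- length(frames)
  idx <- unique(c(ia, ib))
  pos <- array(0, dim = c(nf, length(idx), 3))
  for (f in seq_len(nf)) pos[f, , ] <- frames[[f]][idx, , drop = FALSE]
  mu <- apply(pos, c(2, 3), mean)
  dev <- sweep(pos, c(2, 3), mu)
  var_i <- apply(dev^2, 2, sum) / nf      # <dr^2> per residue
  cmat <- matrix(NA_real_, length(ia), length(ib),
                 dimnames = list(set_a, set_b))
  for (u in seq_along(ia)) {
    ku <- match(ia[u], idx)
    for (v in seq_along(ib)) {
      kv <- match(ib[v], idx)
      denom <- sqrt(var_i[ku] * var_i[kv])
      if (denom < 1e-12) next   # zero fluctuation: undefined, stays NA
      cmat[u, v] <- sum(dev[, ku, ] * dev[, kv, ]) / nf / denom
    }
  }
  cmat
}

#' H-bond donor-acceptor distance(s)
#'
#' Euclidean distance between a named donor atom (typically a backbone amide
#' H) and acceptor atom (typically a carbonyl O), per frame for a
#' trajectory, or a single value for a conformation.
#'
#' @param x a [conformation()] or [trajectory()].
#' @param donor `c(residue_index, atom_name)` of the donor atom.
#' @param acceptor `c(residue_index, atom_name)` of the acceptor atom.
#' @return Numeric vector of distances (Angstrom), one per frame.
#' @export
hbond_distance_series <- function(x, donor, acceptor) {
  atoms <- x$atoms
  look <- function(spec) {
    i <- which(atoms$residue_index == as.integer(spec[[1]]) &
               atoms$atom_name == as.character(spec[[2]]))
    if (length(i) == 0)
      stop("missing atom ", spec[[2]], " in residue ", spec[[1]],
           if (spec[[2]] %in% c("H", "HN"))
         " (crystal structures lack hydrogens; run place_amide_hydrogens first)"
           else "")
    i[1]
  }
  id <- look(donor); ia <- look(acceptor)
  frames <- if (inherits(x, "Trajectory")) x$frames else list(x$xyz)
  vapply(frames, function(fr) sqrt(sum((fr[id, ] - fr[ia, ])^2)), numeric(1))
}

#' Layer thickness time series
#'
#' Difference between the mean z coordinates of two atom groups per frame
#' (e.g. the phosphorus atoms of the two leaflets of a bilayer whose normal
#' is the z axis).
#'
#' @param traj a [trajectory()].
#' @param group_upper,group_lower [atom_selection()]s (or index vectors),
#'   non-empty.
#' @return data.frame with `time` and `thickness` (Angstrom).
#' @export
layer_thickness <- function(traj, group_upper, group_lower) {
  iu <- resolve_selection(group_upper, nrow(traj$frames[[1]]))
  il <- resolve_selection(group_lower, nrow(traj$frames[[1]]))
  if (length(iu) == 0 || length(il) == 0) stop("empty atom group")
  th <- vapply(traj$frames, function(fr)
    mean(fr[iu, 3]) - mean(fr[il, 3]), numeric(1))
  data.frame(time = traj$times, thickness = th)
}

#' Per-residue CA displacement after alignment
#'
#' Superposes `final` onto `target` on `align_sel` (Kabsch), then reports
#' the distance between the CA positions of each shared residue.
#'
#' @param final,target [conformation()]s sharing a residue range.
#' @param align_sel selection used for the superposition (default: all CA).
#' @return data.frame with `residue_index` and `displacement` (Angstrom).
#' @export
per_residue_displacement <- function(final, target, align_sel = NULL) {
  if (is.null(align_sel))
    align_sel <- which(final$atoms$atom_name == "CA")
  idx <- resolve_selection(align_sel, n_atoms(final))
  fit <- kabsch_superpose(final$xyz[idx, , drop = FALSE],
                          target$xyz[idx, , drop = FALSE])
  cm <- colMeans(final$xyz[idx, , drop = FALSE])
  cr <- colMeans(target$xyz[idx, , drop = FALSE])
  moved <- sweep(sweep(final$xyz, 2, cm) %*% t(fit$rotation), 2, cr,
                 FUN = "+")
  shared <- intersect(unique(final$atoms$residue_index),
                      unique(target$atoms$residue_index))
  disp <- vapply(shared, function(r) {
    i1 <- which(final$atoms$residue_index == r &
                final$atoms$atom_name == "CA")[1]
    i2 <- which(target$atoms$residue_index == r &
                target$atoms$atom_name == "CA")[1]
    if (is.na(i1) || is.na(i2)) return(NA_real_)
    sqrt(sum((moved[i1, ] - target$xyz[i2, ])^2))
  }, numeric(1))
  data.frame(residue_index = shared, displacement = disp)
}
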