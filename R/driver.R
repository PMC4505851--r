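# Loop-driven protocol: combine the refined internal pathway with linear
# centre interpolation and quaternion slerp of orientation into a driving
# pathway of restraint frames, advance the frames stepwise while the global
# pose is pinned, and quantify how the undriven remainder follows.

#' Build the combined driving pathway for a loop
#'
#' At progression t_f = f / (n_frames - 1): the internal conformation is
#' the even-arc-length point t_f along `internal_path`, the centre is
#' `lerp_center(pose_a, pose_b, t_f)`, the orientation is
#' `slerp(q_a, q_b, t_f)`; the frame coordinates are the centred internal
#' conformation transformed into the interpolated pose.  Frames 0 and
#' n_frames - 1 therefore reproduce the loop coordinates in states A and B
#' exactly.
#'
#' @param internal_path a [string_path()] over the loop's representative
#'   atoms, in the aligned internal frame.
#' @param pose_a,pose_b [rigid_pose()]s of the loop in the two endpoint
#'   structures (e.g. from [pose_of()] against the aligned internal
#'   endpoint).
#' @param n_frames number of restraint frames (default 60).
#' @param state_a,state_b optional actual endpoint loop coordinates; if
#'   given, frame 0 / n-1 reconstruction is checked against them (0.1 A
#'   RMSD) and a consistency error raised on mismatch.
#' @return Object of class `DrivingPath`: `frames` (list of coordinate
#'   matrices), `poses`, `progress`.
#' @export
build_driving_path <- function(internal_path, pose_a, pose_b,
                               n_frames = 60, state_a = NULL,
                               state_b = NULL) {
  stopifnot(n_frames >= 2)
  arc <- path_arc_lengths(internal_path)
  total <- arc[length(arc)]
  m <- length(internal_path$images)
  internal_at <- function(t) {
    if (total < 1e-12) return(internal_path$images[[1]])
    s <- t * total
    k <- findInterval(s, arc, rightmost.closed = TRUE)
    k <- min(max(k, 1), m - 1)
    f <- (s - arc[k]) / max(arc[k + 1] - arc[k], 1e-12)
    (1 - f) * internal_path$images[[k]] + f * internal_path$images[[k + 1]]
  }
  frames <- vector("list", n_frames)
  poses <- vector("list", n_frames)
  ts <- seq(0, 1, length.out = n_frames)
  for (f in seq_len(n_frames)) {
    t <- ts[f]
    pose_t <- rigid_pose(lerp_center(pose_a$center, pose_b$center, t),
                         slerp(pose_a$q, pose_b$q, t))
    xint <- internal_at(t)
    xc <- sweep(xint, 2, colMeans(xint))
    frames[[f]] <- apply_pose(xc, pose_t)
    poses[[f]] <- pose_t
  }
  check <- function(frame, target, which) {
    if (!is.null(target)) {
      tgt <- if (inherits(target, "Conformation")) target$xyz
             else as.matrix(target)
      r <- rmsd_raw(frame, tgt)
      if (r > 0.1)
        stop("driving-path consistency error: frame ", which,
             " differs from the endpoint by ", signif(r, 3), " A RMSD")
    }
  }
  check(frames[[1]], state_a, "0")
  check(frames[[n_frames]], state_b, paste0(n_frames - 1))
  structure(list(frames = frames, poses = poses, progress = ts,
                 sel = internal_path$sel), class = "DrivingPath")
}

#' @export
print.DrivingPath <- function(x, ...) {
  cat("DrivingPath:", length(x$frames), "frames,", nrow(x$frames[[1]]),
      "driven atoms\n")
  invisible(x)
}

#' Configuration of a loop-driven run
#'
#' Defaults follow the driven-loop protocol: loop restraints at
#' 2 kcal/mol/A^2 advanced frame by frame, the whole-system centre pinned
#' at 1000 kcal/mol/A^2 and the orientation angle at 200 kcal/mol/degree^2.
#'
#' @param loop_spring per-atom spring on the driven loop atoms
#'   (kcal/mol/A^2).
#' @param center_spring global centre spring (kcal/mol/A^2).
#' @param orientation_spring global orientation spring
#'   (kcal/mol/degree^2).
#' @param time_per_frame how long each restraint frame is held (ps).
#' @param seed integer seed.
#' @return List of class `DrivenConfig`.
#' @export
driven_config <- function(loop_spring = 2, center_spring = 1000,
                          orientation_spring = 200, time_per_frame = 1,
                          seed = 1) {
  stopifnot(loop_spring >= 0, center_spring >= 0, orientation_spring >= 0,
            time_per_frame > 0)
  structure(list(loop_spring = loop_spring, center_spring = center_spring,
                 orientation_spring = orientation_spring,
                 time_per_frame = time_per_frame, seed = as.integer(seed)),
            class = "DrivenConfig")
}

#' Run a loop-driven simulation
#'
#' The loop atoms feel Cartesian restraints advanced stepwise through the
#' driving-path frames (each held for `config$time_per_frame`); the whole
#' system is pinned to `global_ref` by centre and orientation-angle
#' restraints so Cartesian coordinates unambiguously represent internal
#' conformation.  Only loop atoms feel driving forces.
#'
#' @param model model containing the loop atoms plus undriven followers.
#' @param start full-system starting [conformation()] or matrix.
#' @param dpath a [build_driving_path()].
#' @param config a [driven_config()].
#' @param global_ref full-system reference coordinates (matrix or
#'   [conformation()]) defining the pinned centre and orientation.
#' @param params a [langevin_params()] (its seed is overridden by
#'   `config$seed`).
#' @param save_every frame stride in steps.
#' @return As [run_restrained()].
#' @export
run_loop_driven <- function(model, start, dpath, config, global_ref,
                            params = langevin_params(), save_every = 25L) {
  xs <- if (inherits(start, "Conformation")) start$xyz else as.matrix(start)
  xg <- if (inherits(global_ref, "Conformation")) global_ref$xyz
        else as.matrix(global_ref)
  n_frames <- length(dpath$frames)
  duration <- n_frames * config$time_per_frame
  frame_times <- (seq_len(n_frames) - 1) * config$time_per_frame
  all_idx <- seq_len(nrow(xs))
  restraints <- list(
    restraint_cartesian(dpath$sel, config$loop_spring,
                        frames = dpath$frames, frame_times = frame_times),
    restraint_center(all_idx, config$center_spring, colMeans(xg)),
    restraint_orientation(all_idx, config$orientation_spring, xg))
  params$seed <- config$seed
  run_restrained(model, xs, duration, params, restraints = restraints,
                 collect = dpath$sel, save_every = save_every)
}

#' Quantify how the undriven remainder followed a driven transition
#'
#' Time series of the follower selection's RMSD to both endpoint
#' structures, the final per-atom displacement to the target, and the
#' residues whose followers failed to reach it.
#'
#' @param traj loop-driven [trajectory()].
#' @param target_a,target_b full-system endpoint coordinates
#'   ([conformation()] or matrix); `target_b` is the driven-to target.
#' @param driven_sel,follower_sel selections of the driven and follower
#'   atoms.
#' @param threshold displacement (A) above which a follower counts as
#'   failed.
#' @return List: `series` (time, rmsd_to_a, rmsd_to_b for the followers),
#'   `final_displacement` (per follower atom), `failed_residues`,
#'   `moved_closer_to_target`.
#' @export
follower_response <- function(traj, target_a, target_b, driven_sel,
                              follower_sel, threshold = 1.0) {
  xa <- if (inherits(target_a, "Conformation")) target_a$xyz
        else as.matrix(target_a)
  xb <- if (inherits(target_b, "Conformation")) target_b$xyz
        else as.matrix(target_b)
  fi <- resolve_selection(follower_sel, nrow(xa))
  sa <- vapply(traj$frames, function(fr)
    rmsd_raw(fr[fi, , drop = FALSE], xa[fi, , drop = FALSE]), numeric(1))
  sb <- vapply(traj$frames, function(fr)
    rmsd_raw(fr[fi, , drop = FALSE], xb[fi, , drop = FALSE]), numeric(1))
  last <- traj$frames[[length(traj$frames)]]
  disp <- sqrt(rowSums((last[fi, , drop = FALSE] -
                        xb[fi, , drop = FALSE])^2))
  res <- traj$atoms$residue_index[fi]
  failed <- sort(unique(res[disp > threshold]))
  list(series = data.frame(time = traj$times, rmsd_to_a = sa,
                           rmsd_to_b = sb),
       final_displacement = data.frame(residue_index = res,
                                       displacement = disp),
       failed_residues = failed,
       moved_closer_to_target = tail(sb, 1) < tail(sa, 1))
}
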