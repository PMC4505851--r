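# Restraint constructors and Langevin dynamics wrappers (BAOAB integrator
# in compiled code).  Restraint kinds:
#   cartesian  U = k/2 * sum_a |x_a - ref_a|^2          (per-atom springs)
#   rmsd       U = k/2 * (RMS - r0)^2                   (best-fit RMSD, TMD)
#   center     U = k/2 * |centroid - c_ref|^2
#   orientation U = k/2 * theta^2, theta the best-fit rotation angle
#               (degrees) relative to a reference pose.
# All forces are exact negative gradients (the RMSD and orientation kinds
# differentiate through the optimal superposition).

#' Langevin dynamics parameters
#'
#' @param temperature K.
#' @param friction damping coefficient, ps^-1.
#' @param timestep ps.
#' @param seed integer; fixes the noise stream exactly.
#' @return List of class `LangevinParams`.
#' @export
langevin_params <- function(temperature = 300, friction = 0.1,
                            timestep = 0.004, seed = 1) {
  stopifnot(temperature >= 0, friction > 0, timestep > 0)
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, seed = as.integer(seed)),
            class = "LangevinParams")
}

#' Boltzmann constant in kcal/mol/K
#' @export
KB_KCAL <- 0.0019872041

#' Cartesian-harmonic restraint
#' @param sel selection (indices or [atom_selection()]).
#' @param k spring constant per atom, kcal/mol/A^2.
#' @param ref n_sel x 3 reference coordinates (static reference).
#' @param frames optional list of n_sel x 3 references advanced stepwise.
#' @param frame_times start time (ps) of each frame (piecewise-constant).
#' @return Restraint object.
#' @export
restraint_cartesian <- function(sel, k, ref = NULL, frames = NULL,
                                frame_times = NULL) {
  stopifnot(k >= 0)
  if (is.null(ref) && is.null(frames))
    stop("cartesian restraint needs a reference (ref or frames)")
  if (!is.null(frames)) {
    stopifnot(length(frames) == length(frame_times),
              !is.unsorted(frame_times))
    ref <- frames[[1]]
  }
  structure(list(kind = 1L, sel = resolve_indices(sel), k = k,
                 ref = as.matrix(ref), frames = frames,
                 frame_times = frame_times), class = "Restraint")
}

#' RMSD (targeted-dynamics) restraint
#'
#' U = k/2 (RMS - r0)^2, with RMS the best-fit RMSD of the selection to the
#' target structure.  r0 may move linearly in time, the targeted-MD
#' schedule.
#'
#' @param sel selection (>= 3 atoms).
#' @param k spring constant, kcal/mol/A^2.
#' @param target n_sel x 3 target coordinates.
#' @param r0 static reference value (A), used when no schedule is given.
#' @param r0_schedule optional `c(start, end)` for a linear schedule.
#' @param t_window `c(t0, t1)` times (ps) over which the schedule runs.
#' @return Restraint object.
#' @export
restraint_rmsd <- function(sel, k, target, r0 = 0, r0_schedule = NULL,
                           t_window = c(0, 0)) {
  idx <- resolve_indices(sel)
  if (length(idx) < 3) stop("rmsd restraint needs at least 3 atoms")
  stopifnot(k >= 0)
  if (is.null(r0_schedule)) r0_schedule <- c(r0, r0)
  structure(list(kind = 2L, sel = idx, k = k, ref = as.matrix(target),
                 r0_start = r0_schedule[1], r0_end = r0_schedule[2],
                 t_start = t_window[1], t_end = t_window[2]),
            class = "Restraint")
}

#' Centre restraint
#' @param sel selection.
#' @param k spring constant on the centroid, kcal/mol/A^2.
#' @param cref reference centre, 3-vector.
#' @return Restraint object.
#' @export
restraint_center <- function(sel, k, cref) {
  stopifnot(k >= 0, length(cref) == 3)
  structure(list(kind = 3L, sel = resolve_indices(sel), k = k,
                 cref = as.numeric(cref)), class = "Restraint")
}

#' Orientation-angle restraint
#'
#' U = k/2 theta^2 with theta (degrees) the angle of the best-fit rotation
#' of the selection onto `ref_coords`, measured relative to the reference
#' orientation `q_ref`.
#'
#' @param sel selection (>= 3 atoms, not collinear).
#' @param k spring constant, kcal/mol/degree^2.
#' @param ref_coords n_sel x 3 reference conformation defining the frame.
#' @param q_ref reference orientation quaternion (default identity).
#' @return Restraint object.
#' @export
restraint_orientation <- function(sel, k, ref_coords,
                                  q_ref = c(1, 0, 0, 0)) {
  idx <- resolve_indices(sel)
  if (length(idx) < 3) stop("orientation restraint needs at least 3 atoms")
  stopifnot(k >= 0)
  structure(list(kind = 4L, sel = idx, k = k, ref = as.matrix(ref_coords),
                 qref = quat_normalize(q_ref)), class = "Restraint")
}

resolve_indices <- function(sel) {
  if (inherits(sel, "AtomSelection")) sel$indices else as.integer(sel)
}

as_engine_restraint <- function(r) {
  list(kind = r$kind, sel = r$sel, k = r$k, ref = r$ref,
       frames = r$frames, frame_times = r$frame_times,
       r0_start = r$r0_start, r0_end = r$r0_end, t_start = r$t_start,
       t_end = r$t_end, cref = r$cref, qref = r$qref)
}

#' Restraint energy and exact forces at a configuration
#'
#' @param restraint a restraint object.
#' @param coords full-system n x 3 coordinates.
#' @param t time (ps) at which time-dependent references are evaluated.
#' @return List with `energy` (kcal/mol), `forces` (n x 3, kcal/mol/A),
#'   and for the rmsd kind `rms`/`r0`, for the orientation kind `theta`
#'   (degrees).
#' @export
restraint_energy_forces <- function(restraint, coords, t = 0) {
  coords <- if (inherits(coords, "Conformation")) coords$xyz
            else as.matrix(coords)
  out <- cpp_energy_forces(list(natoms = nrow(coords)), coords,
                           list(as_engine_restraint(restraint)), t)
  list(energy = out$U_restraints[1], forces = out$forces_restraints,
       rms = out$rms[1], r0 = out$r0[1], theta = out$theta[1])
}

#' Total model + restraint energy and forces
#' @param model a model object.
#' @param coords n x 3 coordinates.
#' @param restraints list of restraint objects.
#' @param t time (ps).
#' @return List with `energy`, `forces`, `U_model`, `U_restraints`.
#' @export
energy_forces <- function(model, coords, restraints = list(), t = 0) {
  coords <- if (inherits(coords, "Conformation")) coords$xyz
            else as.matrix(coords)
  out <- cpp_energy_forces(as_engine_model(model), coords,
                           lapply(restraints, as_engine_restraint), t)
  list(energy = out$U_model + sum(out$U_restraints), forces = out$forces,
       U_model = out$U_model, U_restraints = out$U_restraints)
}

#' One (or a few) BAOAB Langevin steps
#'
#' Advances the state by `nsteps` BAOAB updates.  The noise stream is drawn
#' from R's RNG: callers wanting exact reproducibility call
#' `set.seed(params$seed)` (as the `run_*` drivers do).
#'
#' @param model a model object.
#' @param state list with `coords` (n x 3), optional `vel`, optional `t`.
#' @param params a [langevin_params()].
#' @param restraints list of restraint objects.
#' @param nsteps number of steps (default 1).
#' @return Updated state list (`coords`, `vel`, `t`).
#' @export
langevin_step <- function(model, state, params, restraints = list(),
                          nsteps = 1L) {
  em <- as_engine_model(model)
  mass <- model_masses(model, nrow(state$coords))
  out <- cpp_run(em, as.matrix(state$coords),
                 if (is.null(state$vel)) NULL else as.matrix(state$vel),
                 lapply(restraints, as_engine_restraint), mass,
                 params$temperature, params$friction, params$timestep,
                 as.integer(nsteps), if (is.null(state$t)) 0 else state$t,
                 0L, integer(0), 0L)
  list(coords = out$coords, vel = out$vel,
       t = (if (is.null(state$t)) 0 else state$t) +
         nsteps * params$timestep)
}

model_masses <- function(model, natoms) {
  m <- attr(as_engine_model(model), "mass")
  if (is.null(m)) m <- rep(12, natoms)
  if (length(m) == 1) m <- rep(m, natoms)
  m
}

model_atoms <- function(model, natoms = NULL) {
  at <- attr(as_engine_model(model), "atoms")
  if (is.null(at)) {
    at <- data.frame(atom_name = "X", residue_name = "UNK",
                     residue_index = seq_len(natoms), chain_id = "A",
                     element = "X", stringsAsFactors = FALSE)
  }
  at
}

#' Run restrained Langevin dynamics
#'
#' @param model a model object.
#' @param coords starting n x 3 coordinates (or [conformation()]).
#' @param duration run length (ps).
#' @param params a [langevin_params()]; `params$seed` fixes the noise.
#' @param restraints list of restraint objects.
#' @param collect selection whose time-averaged positions and restraint
#'   forces are accumulated (default: all atoms).
#' @param save_every save a frame every this many steps (0 = only means).
#' @param equil_fraction fraction of steps discarded before averaging.
#' @param vel optional starting velocities (default: Maxwell-Boltzmann).
#' @param t0 start time (ps).
#' @return List with `trajectory` (a [trajectory()], if frames were saved),
#'   `mean_positions`, `mean_restraint_force` (collect x 3),
#'   `log` (data.frame: time, U_model, U_restraint, rms, r0), `coords`,
#'   `vel`, `nsamples`.
#' @export
run_restrained <- function(model, coords, duration, params,
                           restraints = list(), collect = NULL,
                           save_every = 0L, equil_fraction = 0.2,
                           vel = NULL, t0 = 0) {
  if (inherits(coords, "Conformation")) coords <- coords$xyz
  coords <- as.matrix(coords)
  nsteps <- max(1L, as.integer(round(duration / params$timestep)))
  col_idx <- resolve_selection(collect, nrow(coords))
  set.seed(params$seed)
  out <- cpp_run(as_engine_model(model), coords,
                 if (is.null(vel)) NULL else as.matrix(vel),
                 lapply(restraints, as_engine_restraint),
                 model_masses(model, nrow(coords)),
                 params$temperature, params$friction, params$timestep,
                 nsteps, t0, as.integer(save_every), as.integer(col_idx),
                 as.integer(floor(equil_fraction * nsteps)))
  traj <- NULL
  if (save_every > 0) {
    traj <- trajectory(model_atoms(model, nrow(coords)), out$frames,
                       out$times)
  }
  logdf <- as.data.frame(out$log)
  if (nrow(logdf) > 0)
    names(logdf) <- c("time", "U_model", "U_restraint", "rms", "r0")
  list(trajectory = traj, mean_positions = out$mean_pos,
       mean_restraint_force = out$mean_restraint_force, log = logdf,
       coords = out$coords, vel = out$vel, nsamples = out$nsamples)
}

#' Targeted molecular dynamics on a toy model
#'
#' Applies a moving RMSD restraint on `selection`: the reference value r0
#' decreases linearly from the initial best-fit RMSD between start and
#' target to zero over the run, dragging the selection toward the target
#' conformation.
#'
#' @param model a model object.
#' @param start starting [conformation()] (or matrix).
#' @param target target [conformation()] (or matrix).
#' @param selection atoms defining the RMSD (>= 3).
#' @param k spring constant on the RMSD, kcal/mol/A^2.
#' @param duration ps.
#' @param params a [langevin_params()].
#' @param save_every frame stride in steps.
#' @return As [run_restrained()], with the per-frame `(rms, r0)` log; the
#'   log's r0 endpoints are the initial RMSD and 0.
#' @export
run_tmd <- function(model, start, target, selection, k, duration, params,
                    save_every = 25L) {
  xs <- if (inherits(start, "Conformation")) start$xyz else as.matrix(start)
  xt <- if (inherits(target, "Conformation")) target$xyz
        else as.matrix(target)
  idx <- resolve_selection(selection, nrow(xs))
  rms0 <- kabsch_superpose(xs[idx, , drop = FALSE],
                           xt[idx, , drop = FALSE])$rmsd
  r <- restraint_rmsd(idx, k, xt[idx, , drop = FALSE],
                      r0_schedule = c(rms0, 0), t_window = c(0, duration))
  run_restrained(model, xs, duration, params, restraints = list(r),
                 collect = idx, save_every = save_every)
}
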