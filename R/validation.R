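# Self-contained validation protocols with independent oracles: the string
# method against the grid/Newton critical points of a two-well 2D
# potential, and mean-force integration against the closed form of a
# harmonic system.

#' String-method validation on the two-well 2D potential
#'
#' Builds a [make_two_well_potential()], locates its minima and saddle with
#' the grid/Newton oracle, refines a straight initial string between the
#' two minima with two independently seeded sampling groups, and compares:
#' the distance from the converged path to the saddle, the recovered
#' barrier against the oracle's saddle-minus-minimum gap, and the two
#' groups' profiles against their combined standard errors.
#'
#' Protocol (chosen for a barrier of ~5 kcal/mol): 30 images, refinement
#' springs 8 kcal/mol/A^2 with a stiffer 16 kcal/mol/A^2 final pass,
#' sampling at 120 K (barrier / kT of about 20, so the free-energy barrier
#' approximates the potential-energy gap), 30 iterations of 30 sweeps x 50
#' steps, final pass 60 sweeps x 150 steps.
#'
#' @param seed master seed; the two group seeds derive from it.
#' @param barrier_height,well_separation passed to
#'   [make_two_well_potential()].
#' @param n_images images on the string.
#' @param n_iterations refinement iterations.
#' @return List: `potential`, `critical_points`, `path`, `profiles`,
#'   `saddle_distance`, `barrier` (per group), `barrier_oracle`,
#'   `barrier_rel_err`, `max_group_discrepancy_se` (max |dG| over combined
#'   SE), `displacement`.
#' @export
run_two_well_validation <- function(seed = 1, barrier_height = 5,
                                    well_separation = 4, n_images = 30,
                                    n_iterations = 30) {
  pot <- make_two_well_potential(barrier_height, well_separation,
                                 seed = seed)
  cp <- locate_critical_points(pot, grid_resolution = 0.1)
  mins <- cp[cp$type == "minimum", ]
  mins <- mins[order(mins$x), ]
  sad <- cp[cp$type == "saddle", ]
  if (nrow(mins) != 2 || nrow(sad) != 1)
    stop("two-well potential did not produce 2 minima and 1 saddle")
  a <- matrix(c(mins$x[1], mins$y[1], 0), 1, 3)
  b <- matrix(c(mins$x[2], mins$y[2], 0), 1, 3)
  path0 <- init_path_linear(a, b, n_images, k = 8, align = FALSE)
  path0$alignment_reference <- NULL  # a point particle has no pose to remove
  params <- langevin_params(temperature = 120, friction = 5,
                            timestep = 0.01)
  ref <- refine(pot, path0, config = list(
    n_iterations = n_iterations,
    sampling = list(steps_per_sweep = 50, n_sweeps = 30, params = params),
    final_sampling = list(steps_per_sweep = 150, n_sweeps = 60,
                          params = params),
    seeds = c(seed * 13L + 101L, seed * 17L + 202L),
    df_frac = 0.7, k_final = 16))
  pts <- t(vapply(ref$path$images, function(im) im[1, 1:2], numeric(2)))
  s <- c(sad$x[1], sad$y[1])
  seg_dist <- function(p, u, v) {
    uv <- v - u
    t <- sum((p - u) * uv) / sum(uv^2)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (u + t * uv))^2))
  }
  saddle_distance <- min(vapply(seq_len(nrow(pts) - 1), function(i)
    seg_dist(s, pts[i, ], pts[i + 1, ]), numeric(1)))
  g1 <- ref$profiles[[1]]
  g2 <- ref$profiles[[2]]
  barrier <- c(max(g1$free_energy), max(g2$free_energy))
  barrier_oracle <- sad$value[1] - mins$value[1]
  comb_se <- pmax(sqrt(g1$se^2 + g2$se^2), 1e-12)
  list(potential = pot, critical_points = cp, path = ref$path,
       profiles = ref$profiles, saddle_distance = saddle_distance,
       barrier = barrier, barrier_oracle = barrier_oracle,
       barrier_rel_err = abs(mean(barrier) - barrier_oracle) /
         barrier_oracle,
       max_group_discrepancy_se =
         max(abs(g1$free_energy - g2$free_energy) / comb_se),
       displacement = ref$displacement)
}

#' Mean-force integration exactness on a harmonic system
#'
#' A particle in the bowl U = kappa/2 |r|^2 is sampled on a straight string
#' of images along x.  The restrained means of a harmonic system are
#' temperature independent (<x> = k s / (kappa + k)), so the check runs in
#' the deterministic low-temperature limit; the recovered profile must
#' match kappa/2 s^2 up to the known stiff-spring factor k / (kappa + k)
#' (about 2 percent at the default springs).  With kappa = 0 the profile
#' must be identically zero.
#'
#' @param kappa bowl constant (kcal/mol/A^2).
#' @param k image spring constant.
#' @param n_images images along the string.
#' @param smax arc length of the string (A).
#' @param seed integer seed.
#' @return List: `profile`, `reference` (kappa/2 s^2), `max_rel_err`
#'   (worst relative error over interior images), `flat_max_abs` (max
#'   |dG| of the kappa = 0 control).
#' @export
run_harmonic_profile_check <- function(kappa = 1, k = 50, n_images = 12,
                                       smax = 2, seed = 1) {
  params <- langevin_params(temperature = 1e-8, friction = 20,
                            timestep = 0.01, seed = seed)
  run_one <- function(kap) {
    pot <- toy_potential_2d(amps = numeric(0),
                            centers = matrix(0, 0, 2), precs = list(),
                            kconf = kap)
    ss <- seq(0, smax, length.out = n_images)
    path <- string_path(lapply(ss, function(s) matrix(c(s, 0, 0), 1, 3)),
                        k = k)
    means <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      r <- restraint_cartesian(1, k, path$images[[i]])
      out <- run_restrained(pot, path$images[[i]], duration = 30,
                            params = params, restraints = list(r),
                            collect = 1, equil_fraction = 0.5)
      means[[i]] <- out$mean_positions
    }
    integrate_mean_forces(means, path)
  }
  prof <- run_one(kappa)
  ss <- prof$arc_length
  reference <- 0.5 * kappa * ss^2
  interior <- which(ss > 0)
  max_rel_err <- max(abs(prof$free_energy[interior] -
                         reference[interior]) / reference[interior])
  flat <- run_one(0)
  list(profile = prof, reference = reference, max_rel_err = max_rel_err,
       flat_max_abs = max(abs(flat$free_energy)))
}
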