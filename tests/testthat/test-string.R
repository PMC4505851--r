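# String-method machinery: path initialisation, replica exchange,
# path updates, metastable-state detection, mean-force integration, and
# the two-group hysteresis check.

test_that("linear initialisation interpolates between superposed ends", {
  pair <- toy_pair()
  sel <- select_representative_atoms(pair$state_a, 1, 11)
  xa <- pair$state_a$xyz[sel$indices, ]
  xb <- pair$state_b$xyz[sel$indices, ]
  p3 <- init_path_linear(xa, xb, 3, sel = sel)
  xb_fit <- kabsch_superpose(xb, xa)$xyz_fit
  expect_equal(p3$images[[2]], (xa + xb_fit) / 2, tolerance = 1e-9)
  p2 <- init_path_linear(xa, xb, 2, sel = sel)
  expect_equal(p2$images[[1]], xa)
  expect_equal(p2$images[[2]], xb_fit, tolerance = 1e-9)
  gaps <- diff(path_arc_lengths(init_path_linear(xa, xb, 12, sel = sel)))
  expect_lt(max(gaps) - min(gaps), 1e-6)
})

test_that("image starts come from the nearest trajectory frames", {
  pair <- toy_pair()
  sel <- select_representative_atoms(pair$state_a, 1, 11)
  xa <- pair$state_a$xyz
  xb <- pair$state_b$xyz
  path <- init_path_linear(xa[sel$indices, ], xb[sel$indices, ], 5,
                           sel = sel, align = FALSE)
  path$alignment_reference <- NULL
  # a monotone morph trajectory containing each image's exact coordinates
  ts <- seq(0, 1, length.out = 9)
  frames <- lapply(ts, function(t) (1 - t) * xa + t * xb)
  tr <- trajectory(pair$state_a$atoms, frames, seq_along(ts))
  init <- init_images_from_trajectory(tr, path)
  expect_equal(init$frame_indices, c(1, 3, 5, 7, 9))
  expect_true(!is.unsorted(init$frame_indices))
  for (i in 1:5)
    expect_lt(max(abs(init$coords[[i]][sel$indices, ] -
                      path$images[[i]])), 1e-9)
  # brute-force cross-check of the argmin over all frame x image pairs
  for (i in 1:5) {
    d <- vapply(frames, function(fr)
      sqrt(mean(rowSums((fr[sel$indices, ] - path$images[[i]])^2))),
      numeric(1))
    expect_equal(init$frame_indices[i], which.min(d))
  }
  # tie broken by the earliest frame
  tr2 <- trajectory(pair$state_a$atoms, list(xa, xa, xb), 1:3)
  init2 <- init_images_from_trajectory(tr2, path)
  expect_equal(init2$frame_indices[1], 1)
  expect_error(init_images_from_trajectory(
    structure(list(frames = list(), atoms = pair$state_a$atoms,
                   times = numeric(0)), class = "Trajectory"), path),
    "empty")
})

test_that("identical image references always accept exchanges", {
  bowl <- toy_potential_2d(numeric(0), matrix(0, 0, 2), list(), kconf = 2)
  path <- string_path(list(matrix(c(0.4, 0, 0), 1, 3),
                           matrix(c(0.4, 0, 0), 1, 3)), k = 8)
  res <- sample_images_with_exchange(
    bowl, path, list(steps_per_sweep = 10, n_sweeps = 40,
                     params = langevin_params(300, 5, 0.01)), 7)
  expect_equal(res$exchange$rate, 1.0)
})

test_that("frozen-configuration acceptance matches exp(-beta Delta)", {
  # particles frozen at their own references: Delta = U_1(x_2) + U_2(x_1)
  # = k d^2 > 0 on every attempt (states are re-frozen each trial, since
  # an accepted swap would otherwise carry configurations over)
  bowl <- toy_potential_2d(numeric(0), matrix(0, 0, 2), list(), kconf = 2)
  d <- 0.3; k <- 4
  path <- string_path(list(matrix(0, 1, 3), matrix(c(d, 0, 0), 1, 3)),
                      k = k)
  states0 <- lapply(path$images, function(im) list(coords = im))
  n_trials <- 400
  acc <- 0L
  for (s in seq_len(n_trials)) {
    res <- sample_images_with_exchange(
      bowl, path, list(steps_per_sweep = 0, n_sweeps = 1,
                       equil_sweeps = 0, freeze = TRUE,
                       params = langevin_params(300, 5, 0.01)),
      1000 + s, states0 = states0)
    acc <- acc + res$exchange$accepts
  }
  p_exact <- exp(-k * d^2 / (KB_KCAL * 300))
  expect_lt(abs(acc / n_trials - p_exact),
            4 * sqrt(p_exact * (1 - p_exact) / n_trials))
})

test_that("exchange occupancies match direct Boltzmann sampling", {
  kappa <- 2; k <- 8
  bowl <- toy_potential_2d(numeric(0), matrix(0, 0, 2), list(),
                           kconf = kappa)
  refs <- c(0.3, 0.6)
  path <- string_path(lapply(refs, function(x) matrix(c(x, 0, 0), 1, 3)),
                      k = k)
  res <- sample_images_with_exchange(
    bowl, path, list(steps_per_sweep = 50, n_sweeps = 320,
                     equil_sweeps = 20, record_snapshots = TRUE,
                     params = langevin_params(300, 5, 0.01)), 29)
  xs <- vapply(res$snapshots[[1]], function(s) s[1, 1], numeric(1))
  mu <- k * refs[1] / (kappa + k)
  sdv <- sqrt(KB_KCAL * 300 / (kappa + k))
  set.seed(30)
  ks <- stats::ks.test(xs, rnorm(5000, mu, sdv))
  expect_gt(ks$p.value, 0.01)
})

test_that("update_path is a fixed point on straight means and pins ends", {
  pair <- toy_pair()
  sel <- select_representative_atoms(pair$state_a, 1, 11)
  path <- init_path_linear(pair$state_a$xyz[sel$indices, ],
                           pair$state_b$xyz[sel$indices, ], 12, sel = sel)
  upd <- update_path(path$images, path)
  for (i in 1:12)
    expect_lt(max(abs(upd$images[[i]] - path$images[[i]])), 1e-6)
  expect_identical(upd$images[[1]], path$images[[1]])
  expect_identical(upd$images[[12]], path$images[[12]])
  expect_error(update_path(path$images, path, minima_breaks = c(8, 3)),
               "breaks out of order")
  expect_error(update_path(path$images, path, minima_breaks = c(1, 3)),
               "breaks out of order")
})

test_that("update_path smooths noise toward the underlying curve", {
  set.seed(45)
  ts <- seq(0, 1, length.out = 40)
  truth <- lapply(ts, function(t)
    matrix(c(3 * t, 0.6 * sin(pi * t), 0), 1, 3))
  path <- string_path(truth, k = 5)
  sigma <- 0.05
  noisy <- lapply(truth, function(m) m + matrix(rnorm(3, 0, sigma), 1, 3))
  upd <- update_path(noisy, path, df_frac = 0.3)
  err_fit <- sqrt(mean(vapply(seq_along(ts), function(i)
    sum((upd$images[[i]] - truth[[i]])^2), numeric(1))))
  err_raw <- sqrt(mean(vapply(seq_along(ts), function(i)
    sum((noisy[[i]] - truth[[i]])^2), numeric(1))))
  expect_lt(err_fit, err_raw)
  expect_lt(err_fit, 1.5 * sigma / sqrt(2))
  # reparametrisation: consecutive gaps equal within 2 percent
  gaps <- diff(path_arc_lengths(upd))
  expect_lt((max(gaps) - min(gaps)) / mean(gaps), 0.02)
})

test_that("metastable minima are found by prominence", {
  expect_length(detect_metastable_states(c(0, 1, 2, 3, 4), 0.5), 0)
  w <- c(0, 3, 1, 3.5, 0.5)  # interior minimum at 3, prominence 2
  expect_equal(detect_metastable_states(w, 1), 3L)
  expect_length(detect_metastable_states(w, 2.5), 0)
  expect_error(detect_metastable_states(c(0, 1), 1), "at least 3")
})

test_that("a three-well landscape yields one interior free-energy
           minimum where the oracle puts it", {
  pot <- toy_potential_2d(
    amps = c(-5, -4, -5), centers = rbind(c(-3, 0), c(0, 0), c(3, 0)),
    precs = list(diag(2) / 0.64, diag(2) / 0.64, diag(2) / 0.64),
    kconf = 0.05)
  cp <- locate_critical_points(pot, 0.1)
  expect_equal(sum(cp$type == "minimum"), 3)
  mid <- cp[cp$type == "minimum" & abs(cp$x) < 0.5, ]
  path <- string_path(lapply(seq(-3, 3, length.out = 31), function(x)
    matrix(c(x, 0, 0), 1, 3)), k = 10)
  res <- sample_images_with_exchange(
    pot, path, list(steps_per_sweep = 60, n_sweeps = 60,
                    params = langevin_params(120, 5, 0.01)), 51)
  prof <- integrate_mean_forces(res$mean_positions, path)
  found <- detect_metastable_states(prof, min_depth = 1)
  expect_length(found, 1)
  expect_lt(abs(path$images[[found]][1, 1] - mid$x), 0.5)
})

test_that("mean-force integration is exact for flat and harmonic cases", {
  # flat: means identical to references give an all-zero profile
  path <- string_path(lapply(seq(0, 2, length.out = 8), function(x)
    matrix(c(x, 0, 0), 1, 3)), k = 50)
  prof0 <- integrate_mean_forces(path$images, path)
  expect_identical(prof0$free_energy, rep(0, 8))
  # harmonic: recovered profile matches kappa/2 s^2 within 5 percent
  h <- run_harmonic_profile_check(kappa = 1, k = 50, seed = 3)
  expect_lt(h$max_rel_err, 0.05)
  expect_lt(h$flat_max_abs, 1e-4)
})

test_that("two independent groups agree on a converged single-flip
           transition", {
  model <- toy_model()
  pair <- toy_pair_single()
  sel <- select_representative_atoms(pair$state_a, 1, 11)
  xa <- pair$state_a$xyz[sel$indices, ]
  xb <- pair$state_b$xyz[sel$indices, ]
  params <- toy_params()
  path0 <- init_path_linear(xa, xb, 24, k = 2, sel = sel)
  params$seed <- 11
  tmd_ab <- run_tmd(model, pair$state_a, pair$state_b, sel, 500, 40,
                    params)
  params$seed <- 12
  tmd_ba <- run_tmd(model, pair$state_b, pair$state_a, sel, 500, 40,
                    params)
  ia <- init_images_from_trajectory(tmd_ab$trajectory, path0)
  ib <- init_images_from_trajectory(tmd_ba$trajectory, path0)
  ref <- refine(model, path0, config = list(
    n_iterations = 6,
    sampling = list(steps_per_sweep = 60, n_sweeps = 12, params = params),
    final_sampling = list(steps_per_sweep = 400, n_sweeps = 40,
                          params = params),
    seeds = c(101, 202)),
    states0_a = lapply(ia$coords, function(x) list(coords = x)),
    states0_b = lapply(ib$coords, function(x) list(coords = x)))
  g1 <- ref$profiles[[1]]
  g2 <- ref$profiles[[2]]
  comb <- pmax(sqrt(g1$se^2 + g2$se^2), 1e-12)
  # pointwise agreement at a Bonferroni-corrected 1 percent level (the
  # max of |z| over ~24 images exceeds 3 regularly even for identical
  # underlying profiles)
  z_crit <- qnorm(1 - 0.005 / nrow(g1))
  expect_lt(max(abs(g1$free_energy - g2$free_energy) / comb), z_crit)
  expect_lt(abs(max(g1$free_energy) - max(g2$free_energy)),
            0.15 * max(g1$free_energy))
  # endpoints never move
  expect_identical(ref$path$images[[1]], path0$images[[1]])
  expect_identical(ref$path$images[[24]], path0$images[[24]])
  # arc gaps stay even
  gaps <- diff(path_arc_lengths(ref$path))
  expect_lt((max(gaps) - min(gaps)) / mean(gaps), 0.02)
})

test_that("a refinement whose path stops improving triggers the
           convergence warning", {
  # frozen, perturbed states: the sampled means never change, so the path
  # displacement plateaus instead of decreasing -- the negative control
  # for the convergence diagnostic
  pot <- make_two_well_potential(5, 4, seed = 2)
  cp <- locate_critical_points(pot, 0.1)
  mins <- cp[cp$type == "minimum", ]
  mins <- mins[order(mins$x), ]
  path0 <- init_path_linear(matrix(c(mins$x[1], mins$y[1], 0), 1, 3),
                            matrix(c(mins$x[2], mins$y[2], 0), 1, 3),
                            12, k = 40, align = FALSE)
  path0$alignment_reference <- NULL
  set.seed(9)
  frozen <- lapply(path0$images, function(im)
    list(coords = im + matrix(c(rnorm(2, 0, 0.02), 0), 1, 3)))
  expect_warning(
    refine(pot, path0, config = list(
      n_iterations = 5,
      sampling = list(steps_per_sweep = 0, n_sweeps = 2,
                      equil_sweeps = 0, freeze = TRUE,
                      params = langevin_params(300, 5, 0.01)),
      seeds = c(5, 6)),
      states0_a = frozen, states0_b = frozen),
    "not be converged")
})
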