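# Restraint energies/forces (all four kinds, exact gradients through the
# optimal superposition) and the BAOAB Langevin integrator.

make_kind_restraints <- function(pair, sel) {
  xa <- pair$state_a$xyz
  xb <- pair$state_b$xyz
  list(
    cartesian = restraint_cartesian(sel, 2, xb[sel$indices, ]),
    rmsd = restraint_rmsd(sel, 2, xb[sel$indices, ], r0 = 1.0),
    center = restraint_center(seq_len(nrow(xa)), 1000,
                              colMeans(xa) + c(0.3, -0.1, 0.2)),
    orientation = restraint_orientation(seq_len(nrow(xa)), 200, xa))
}

test_that("all four restraint kinds pass finite-difference force checks", {
  pair <- toy_pair()
  sel <- select_representative_atoms(pair$state_a, 1, 11)
  set.seed(105)
  for (rep in 1:2) {
    x <- pair$state_a$xyz + matrix(rnorm(165, 0, 0.08), 55)
    for (nm in names(make_kind_restraints(pair, sel))) {
      r <- make_kind_restraints(pair, sel)[[nm]]
      out <- restraint_energy_forces(r, x)
      g <- -out$forces
      h <- 1e-5
      for (k in sample(length(x), 25)) {
        xp <- x; xp[k] <- xp[k] + h
        xm <- x; xm[k] <- xm[k] - h
        gn <- (restraint_energy_forces(r, xp)$energy -
               restraint_energy_forces(r, xm)$energy) / (2 * h)
        expect_lt(abs(gn - g[k]) / max(abs(gn), 1e-6), 1e-4)
      }
    }
  }
})

test_that("the RMSD restraint energy is k/2 (RMS - r0)^2 exactly", {
  pair <- toy_pair()
  sel <- select_representative_atoms(pair$state_a, 1, 11)
  xa <- pair$state_a$xyz
  # at the target: RMS = 0, so r0 = 1 gives U = 1/2 * 2 * 1^2 = 1 exactly
  r <- restraint_rmsd(sel, 2, xa[sel$indices, ], r0 = 1.0)
  out <- restraint_energy_forces(r, xa)
  expect_equal(out$energy, 1.0, tolerance = 1e-12)
  expect_equal(out$rms, 0, tolerance = 1e-12)
  # a configuration with known nonzero best-fit RMS: set r0 = RMS - 1
  set.seed(115)
  x <- xa + matrix(rnorm(165, 0, 0.2), 55)
  rms <- kabsch_superpose(x[sel$indices, ], xa[sel$indices, ])$rmsd
  r2 <- restraint_rmsd(sel, 2, xa[sel$indices, ], r0 = rms - 1)
  expect_equal(restraint_energy_forces(r2, x)$energy, 1.0,
               tolerance = 1e-9)
  # and U = 0 with zero net force when RMS == r0
  r3 <- restraint_rmsd(sel, 2, xa[sel$indices, ], r0 = rms)
  out3 <- restraint_energy_forces(r3, x)
  expect_equal(out3$energy, 0, tolerance = 1e-12)
  expect_lt(max(abs(out3$forces)), 1e-9)
})

test_that("the RMSD restraint is invariant to rigid motion of the target", {
  pair <- toy_pair()
  sel <- select_representative_atoms(pair$state_a, 1, 11)
  tgt <- pair$state_b$xyz[sel$indices, ]
  set.seed(125)
  x <- pair$state_a$xyz
  rot <- rand_rotation(67)
  tgt2 <- sweep(tgt %*% t(rot$R), 2, c(4, -2, 9), FUN = "+")
  e1 <- restraint_energy_forces(restraint_rmsd(sel, 2, tgt, r0 = 0.5),
                                x)$energy
  e2 <- restraint_energy_forces(restraint_rmsd(sel, 2, tgt2, r0 = 0.5),
                                x)$energy
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("a harmonic mode equilibrates to kT/2 (equipartition)", {
  bowl <- toy_potential_2d(numeric(0), matrix(0, 0, 2), list(),
                           kconf = 2)
  p <- langevin_params(temperature = 300, friction = 5, timestep = 0.01,
                       seed = 11)
  res <- run_restrained(bowl, matrix(0, 1, 3), duration = 4000,
                        params = p, save_every = 5)
  fr <- do.call(rbind, lapply(res$trajectory$frames, function(f) f[1, ]))
  fr <- fr[-seq_len(2000), ]
  kT <- KB_KCAL * 300
  expect_lt(abs(mean(0.5 * 2 * fr[, 1]^2) - kT / 2), 0.03 * kT / 2)
  expect_lt(abs(mean(0.5 * 2 * fr[, 2]^2) - kT / 2), 0.03 * kT / 2)
})

test_that("zero-temperature dynamics relaxes monotonically to the
           minimum", {
  bowl <- toy_potential_2d(numeric(0), matrix(0, 0, 2), list(),
                           kconf = 2)
  p0 <- langevin_params(temperature = 0, friction = 20, timestep = 0.01,
                        seed = 1)
  r0 <- run_restrained(bowl, matrix(2, 1, 3), 20, p0, save_every = 10,
                       vel = matrix(0, 1, 3))
  U <- vapply(r0$trajectory$frames, function(f)
    pot2d_value(bowl, f[1, 1:2]), numeric(1))
  expect_true(all(diff(U) <= 1e-9))
  expect_lt(sqrt(sum(r0$coords[1, 1:2]^2)), 1e-6)
})

test_that("the same seed reproduces a trajectory bitwise", {
  model <- toy_model()
  pair <- toy_pair()
  p <- toy_params(seed = 77)
  r1 <- run_restrained(model, pair$state_a, 2, p, save_every = 20)
  r2 <- run_restrained(model, pair$state_a, 2, p, save_every = 20)
  expect_identical(r1$coords, r2$coords)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  p2 <- toy_params(seed = 78)
  r3 <- run_restrained(model, pair$state_a, 2, p2, save_every = 20)
  expect_false(identical(r1$coords, r3$coords))
})

test_that("a blown-up integration reports a step-size error", {
  bowl <- toy_potential_2d(numeric(0), matrix(0, 0, 2), list(),
                           kconf = 2)
  p <- langevin_params(temperature = 300, friction = 0.1, timestep = 50,
                       seed = 1)
  expect_error(run_restrained(bowl, matrix(1e3, 1, 3), 5000, p),
               "timestep")
})

test_that("restrained means match the harmonic closed form", {
  # U = kappa/2 x^2 with a Cartesian restraint k/2 (x - x0)^2:
  # <x> = k x0 / (kappa + k), at any temperature
  bowl <- toy_potential_2d(numeric(0), matrix(0, 0, 2), list(),
                           kconf = 2)
  restr <- restraint_cartesian(1, 8, matrix(c(1, 0, 0), 1, 3))
  p <- langevin_params(temperature = 300, friction = 5, timestep = 0.01,
                       seed = 21)
  rr <- run_restrained(bowl, matrix(0, 1, 3), 3000, p,
                       restraints = list(restr), collect = 1)
  analytic <- 8 * 1 / (2 + 8)
  # 3 sigma of the mean: stationary sd / sqrt(effective samples)
  sd_x <- sqrt(KB_KCAL * 300 / (2 + 8))
  tol <- 3 * sd_x / sqrt(rr$nsamples / 50)  # conservative decorrelation
  expect_lt(abs(rr$mean_positions[1, 1] - analytic), tol)
  expect_lt(abs(rr$mean_restraint_force[1, 1] - (-8 * (analytic - 1))),
            3 * tol * 8)
  # two seeds agree within combined tolerance
  p2 <- langevin_params(temperature = 300, friction = 5, timestep = 0.01,
                        seed = 22)
  rr2 <- run_restrained(bowl, matrix(0, 1, 3), 3000, p2,
                        restraints = list(restr), collect = 1)
  expect_lt(abs(rr2$mean_positions[1, 1] - rr$mean_positions[1, 1]),
            2 * tol)
})

test_that("unbiased runs from each endpoint keep their loop state", {
  # the chain is thermally floppy (soft torsions, long lever arms), so
  # "no major transition toward the opposite state" is judged by the
  # bistable torsions staying in their starting basin and by the run
  # remaining closer to its start than to the opposite state on average
  model <- toy_model()
  pair <- toy_pair()
  sel <- select_representative_atoms(pair$state_a, 1, 11)
  p <- toy_params(seed = 135)
  states <- list(list(pair$state_a, pair$state_b),
                 list(pair$state_b, pair$state_a))
  for (st in states) {
    run <- run_restrained(model, st[[1]], 40, p, save_every = 100)
    for (i in seq_len(nrow(pair$flipped_torsions))) {
      fl <- pair$flipped_torsions[i, ]
      t_end <- toy_torsion(model, run$coords, fl$residue, fl$torsion)
      t_start <- toy_torsion(model, st[[1]]$xyz, fl$residue, fl$torsion)
      expect_lt(angle_deviation(t_end, t_start), 90)
    }
    to_start <- mean(rmsd_series(run$trajectory, st[[1]], sel)$rmsd)
    to_other <- mean(rmsd_series(run$trajectory, st[[2]], sel)$rmsd)
    expect_lt(to_start, to_other)
  }
})

test_that("targeted MD drives the toy loop to its target", {
  model <- toy_model()
  pair <- toy_pair()
  sel <- select_representative_atoms(pair$state_a, 1, 11)
  p <- toy_params(seed = 31)
  tm <- run_tmd(model, pair$state_a, pair$state_b, sel, k = 500,
                duration = 60, params = p)
  n <- nrow(tm$log)
  rms0 <- kabsch_superpose(pair$state_a$xyz[sel$indices, ],
                           pair$state_b$xyz[sel$indices, ])$rmsd
  expect_equal(tm$log$r0[1], rms0, tolerance = 1e-9)
  expect_equal(tm$log$r0[n], 0, tolerance = 1e-9)
  final <- kabsch_superpose(tm$coords[sel$indices, ],
                            pair$state_b$xyz[sel$indices, ])$rmsd
  expect_lt(final, 0.5)
  # degenerate schedule: target == start keeps r0 at zero and stays close
  tm0 <- run_tmd(model, pair$state_a, pair$state_a, sel, k = 500,
                 duration = 4, params = p)
  expect_true(all(abs(tm0$log$r0) < 1e-9))
  expect_lt(max(tm0$log$rms, na.rm = TRUE), 0.8)
})

test_that("langevin_step advances a state reproducibly", {
  model <- toy_model()
  pair <- toy_pair()
  p <- toy_params(seed = 3)
  set.seed(p$seed)
  s1 <- langevin_step(model, list(coords = pair$state_a$xyz), p,
                      nsteps = 10)
  set.seed(p$seed)
  s2 <- langevin_step(model, list(coords = pair$state_a$xyz), p,
                      nsteps = 10)
  expect_identical(s1$coords, s2$coords)
  expect_equal(s1$t, 10 * p$timestep)
})
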