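# The two synthetic systems: the 2D multi-well potential with its
# critical-point oracle, and the toy loop-chain with designed
# wrapped/unwrapped endpoints.

test_that("the two-well potential has exactly 2 minima and 1 saddle", {
  pot <- make_two_well_potential(5, 4, seed = 1)
  cp <- locate_critical_points(pot, grid_resolution = 0.1)
  expect_equal(sum(cp$type == "minimum"), 2)
  expect_equal(sum(cp$type == "saddle"), 1)
  sad <- cp[cp$type == "saddle", ]
  mins <- cp[cp$type == "minimum", ]
  expect_gt(sad$value - max(mins$value), 1)  # a real barrier
  expect_error(make_two_well_potential(0), "positive")
})

test_that("symmetric wells put the saddle on the symmetry axis", {
  pot <- make_two_well_potential(5, 4, asymmetry = 0)
  cp <- locate_critical_points(pot, grid_resolution = 0.1)
  sad <- cp[cp$type == "saddle", ]
  expect_lt(abs(sad$x), 1e-6)
  mins <- cp[cp$type == "minimum", ]
  expect_equal(mins$value[1], mins$value[2], tolerance = 1e-9)
})

test_that("the critical-point oracle handles elementary landscapes", {
  bowl <- toy_potential_2d(numeric(0), matrix(0, 0, 2), list(),
                           kconf = 1.5)
  cp <- locate_critical_points(bowl, 0.2, xlim = c(-2, 2),
                               ylim = c(-2, 2))
  expect_equal(nrow(cp), 1)
  expect_equal(cp$type, "minimum")
  expect_lt(abs(cp$x) + abs(cp$y), 1e-8)
  expect_equal(cp$value, 0, tolerance = 1e-12)

  well <- toy_potential_2d(-3, matrix(c(0.7, -0.4), 1, 2), list(diag(2)),
                           kconf = 0)
  cpw <- locate_critical_points(well, 0.2, xlim = c(-2, 3),
                                ylim = c(-3, 2))
  cpw <- cpw[cpw$type == "minimum", ]
  expect_equal(c(cpw$x, cpw$y), c(0.7, -0.4), tolerance = 1e-6)
})

test_that("potential value, gradient and Hessian are consistent", {
  pot <- make_two_well_potential(5, 4, seed = 3)
  set.seed(5)
  h <- 1e-6
  for (i in 1:5) {
    p <- runif(2, -3, 3)
    g <- pot2d_grad(pot, p)
    gn <- c((pot2d_value(pot, p + c(h, 0)) -
             pot2d_value(pot, p - c(h, 0))) / (2 * h),
            (pot2d_value(pot, p + c(0, h)) -
             pot2d_value(pot, p - c(0, h))) / (2 * h))
    expect_equal(g, gn, tolerance = 1e-6)
    H <- pot2d_hessian(pot, p)
    Hn <- cbind((pot2d_grad(pot, p + c(h, 0)) -
                 pot2d_grad(pot, p - c(h, 0))) / (2 * h),
                (pot2d_grad(pot, p + c(0, h)) -
                 pot2d_grad(pot, p - c(0, h))) / (2 * h))
    expect_equal(H, Hn, tolerance = 1e-5)
  }
})

test_that("the toy loop has the right site count and is reproducible", {
  model <- toy_model()
  expect_equal(nrow(model$atoms), 55)                 # 5 sites x 11
  modp <- build_toy_loop(11, proline_like = c(3, 5), seed = 1)
  expect_equal(nrow(modp$atoms), 53)                  # two H sites absent
  m2 <- build_toy_loop(11, seed = 1)
  expect_identical(model$targets, m2$targets)
  expect_identical(model$coords_ideal, m2$coords_ideal)
  m3 <- build_toy_loop(11, seed = 99)
  expect_gt(max(abs(m3$targets$phi0 - model$targets$phi0)), 0.1)
  expect_error(build_toy_loop(4), "at least 5")
})

test_that("the analytic gradient matches central finite differences", {
  model <- toy_model()
  set.seed(15)
  x <- model$coords_ideal + matrix(rnorm(165, 0, 0.06), 55)
  ef <- toy_energy_forces(model, x)
  g <- -ef$forces
  h <- 1e-5
  for (k in sample(165, 30)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    gn <- (toy_energy_forces(model, xp)$energy -
           toy_energy_forces(model, xm)$energy) / (2 * h)
    expect_lt(abs(gn - g[k]) / max(abs(gn), 1e-6), 1e-4)
  }
})

test_that("toy energy is invariant under rigid-body motion", {
  model <- toy_model()
  pair <- toy_pair()
  e0 <- toy_energy_forces(model, pair$state_a$xyz)$energy
  set.seed(25)
  for (i in 1:3) {
    rot <- rand_rotation(runif(1, 0, 180))
    moved <- sweep(pair$state_a$xyz %*% t(rot$R), 2, rnorm(3, 0, 10),
                   FUN = "+")
    expect_lt(abs(toy_energy_forces(model, moved)$energy - e0), 1e-8)
  }
})

test_that("endpoint generation realises the designed flips as minima", {
  model <- toy_model()
  pair <- toy_pair()
  # both states are local minima of the full model
  for (st in list(pair$state_a, pair$state_b)) {
    g <- -toy_energy_forces(model, st$xyz)$forces
    expect_lt(max(sqrt(rowSums(g^2))), 1e-3)
  }
  # prescribed torsion differences within 10 degrees
  for (i in seq_len(nrow(pair$flipped_torsions))) {
    fl <- pair$flipped_torsions[i, ]
    ta <- toy_torsion(model, pair$state_a$xyz, fl$residue, fl$torsion)
    tb <- toy_torsion(model, pair$state_b$xyz, fl$residue, fl$torsion)
    expect_lt(angle_deviation(tb, ta + fl$delta), 10)
  }
  # deviation profile peaks exactly at the flipped residues
  dev <- torsion_deviation_profile(pair$state_a, pair$state_b)
  top2 <- dev$residue_index[order(-dev$combined)][1:2]
  expect_setequal(top2, pair$flipped_torsions$residue)
  # helical contact engaged in A, broken in B
  don <- model$contact$donor_res
  acc <- model$contact$acceptor_res
  expect_lt(hbond_distance_series(pair$state_a, c(don, "H"),
                                  c(acc, "O")), 2.5)
  expect_gt(hbond_distance_series(pair$state_b, c(don, "H"),
                                  c(acc, "O")), 5)
})

test_that("an empty flip list returns two copies of the same minimum", {
  model <- toy_model()
  pair0 <- generate_endpoint_conformations(
    model, data.frame(residue = integer(0), torsion = character(0),
                      delta = numeric(0)))
  expect_lt(max(abs(pair0$state_a$xyz - pair0$state_b$xyz)), 1e-3)
})

test_that("linear interpolation between endpoints crosses a barrier", {
  model <- toy_model()
  pair <- toy_pair()
  emax <- max(vapply(seq(0, 1, 0.02), function(t)
    toy_energy_forces(model, (1 - t) * pair$state_a$xyz +
                      t * pair$state_b$xyz)$energy, numeric(1)))
  expect_gt(emax, max(pair$energies) + 1)
})

test_that("flip requests are validated", {
  model <- toy_model()
  expect_error(generate_endpoint_conformations(
    model, data.frame(residue = 7, torsion = "psi", delta = 270)),
    "<= 180")
  expect_error(generate_endpoint_conformations(
    model, data.frame(residue = 40, torsion = "psi", delta = 180)),
    "out of range")
})
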