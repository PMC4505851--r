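# Dihedrals and torsion deviations, Kabsch superposition, RMSD series,
# cross-correlation, H-bond distances, layer thickness, per-residue
# displacement, quaternions and slerp.

test_that("dihedral follows the IUPAC convention and matches oracles", {
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)), 0)
  expect_equal(dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)),
               180)
  # constructed +-90 twist about z
  ninety <- dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0, -1, 1))
  expect_equal(abs(ninety), 90, tolerance = 1e-6)
  expect_equal(ninety,
               dihedral_oracle(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1),
                               c(0, -1, 1)), tolerance = 1e-6)
  set.seed(31)
  for (i in 1:20) {
    p <- matrix(rnorm(12), 4, 3)
    mine <- dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
    expect_equal(mine, dihedral_oracle(p[1, ], p[2, ], p[3, ], p[4, ]),
                 tolerance = 1e-6)
    b3d <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
    expect_equal(mine, b3d[!is.na(b3d)][1], tolerance = 1e-4)
  }
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("torsion deviations respect periodicity and combine as RSS", {
  expect_equal(angle_deviation(10, 370), 0)
  expect_equal(angle_deviation(179, -179), 2)
  expect_equal(sqrt(angle_deviation(0, 3)^2 + angle_deviation(0, 4)^2), 5)
  pair <- toy_pair()
  dev <- torsion_deviation_profile(pair$state_a, pair$state_a)
  expect_true(all(dev$combined[!is.na(dev$combined)] == 0))
})

test_that("kabsch superposition recovers translations and rotations", {
  pair <- toy_pair()
  x <- pair$state_a$xyz
  fit0 <- kabsch_superpose(x, x)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  expect_equal(quat_angle(fit0$pose$q), 0, tolerance = 1e-6)

  shifted <- sweep(x, 2, c(5, 0, 0), FUN = "+")
  fit1 <- kabsch_superpose(shifted, x)
  expect_equal(fit1$rmsd, 0, tolerance = 1e-9)
  expect_equal(unname(fit1$pose$center - colMeans(x)), c(5, 0, 0),
               tolerance = 1e-9)

  # rotated noisy cloud: angle must match a 1D grid-search oracle
  set.seed(41)
  cloud <- matrix(rnorm(60), 20, 3)
  rot <- rand_rotation(37)
  noisy <- cloud %*% t(rot$R) + matrix(rnorm(60, 0, 0.1), 20, 3)
  fit <- kabsch_superpose(noisy, cloud)
  expect_lt(abs(fit$rmsd - 0.1 * sqrt(3)), 0.15 * 0.1 * sqrt(3) + 0.05)
  grid <- seq(0, 360, by = 0.5)
  rms_at <- vapply(grid, function(a) {
    R <- rand_rotation(a, rot$axis)$R
    rmsd_raw(sweep(cloud %*% t(R), 2, colMeans(cloud %*% t(R))),
             sweep(noisy, 2, colMeans(noisy)))
  }, numeric(1))
  best <- grid[which.min(rms_at)]
  expect_lt(abs(quat_angle(fit$pose$q) - min(best, 360 - best)), 1)

  # never worse than no superposition, and matches bio3d
  for (i in 1:5) {
    a <- matrix(rnorm(30), 10, 3)
    b <- matrix(rnorm(30), 10, 3)
    fit <- kabsch_superpose(a, b)
    expect_lte(fit$rmsd, rmsd_raw(a, b) + 1e-12)
    expect_equal(fit$rmsd,
                 bio3d::rmsd(as.vector(t(b)), as.vector(t(a)),
                             fit = TRUE), tolerance = 1e-3)
  }
  expect_error(kabsch_superpose(matrix(0, 2, 3), matrix(0, 2, 3)),
               "degenerate")
  line <- cbind(1:5, 2 * (1:5), -(1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("rmsd_series handles superposed and raw modes", {
  pair <- toy_pair()
  x <- pair$state_a$xyz
  tr <- trajectory(pair$state_a$atoms, list(x, x, x), c(0, 1, 2))
  expect_equal(rmsd_series(tr, pair$state_a)$rmsd, rep(0, 3),
               tolerance = 1e-12)
  shifted <- sweep(x, 2, c(1, 0, 0), FUN = "+")
  tr2 <- trajectory(pair$state_a$atoms, list(shifted), 0)
  expect_equal(rmsd_series(tr2, pair$state_a)$rmsd, 0, tolerance = 1e-9)
  expect_equal(rmsd_series(tr2, pair$state_a, superpose = FALSE)$rmsd, 1.0,
               tolerance = 1e-12)
})

test_that("cross-correlation normalises, detects mirrors, vanishes for
           independent motion", {
  set.seed(51)
  nres <- 4
  atoms <- data.frame(atom_name = "CA", residue_name = "GLY",
                      residue_index = 1:nres, chain_id = "A",
                      element = "C")
  base <- matrix(10 * (1:nres), nres, 3)
  nf <- 10000
  frames <- vector("list", nf)
  for (f in seq_len(nf)) {
    d <- matrix(rnorm(nres * 3, 0, 0.3), nres, 3)
    d[2, ] <- -d[1, ]          # residue 2 mirrors residue 1
    frames[[f]] <- base + d
  }
  tr <- trajectory(atoms, frames, seq_len(nf))
  cm <- dynamic_cross_correlation(tr, 1:nres, 1:nres, align = FALSE)
  expect_equal(unname(diag(cm)), rep(1, nres), tolerance = 1e-12)
  expect_equal(cm[1, 2], -1, tolerance = 1e-12)
  expect_lt(abs(cm[3, 4]), 0.05)       # independent, 1e4 frames
  expect_true(all(abs(cm) <= 1 + 1e-10))
  expect_equal(cm, t(cm), tolerance = 1e-12)
  # brute-force oracle on one off-diagonal entry
  d3 <- t(vapply(frames, function(fr) fr[3, ] - base[3, ], numeric(3)))
  d4 <- t(vapply(frames, function(fr) fr[4, ] - base[4, ], numeric(3)))
  d3 <- sweep(d3, 2, colMeans(d3)); d4 <- sweep(d4, 2, colMeans(d4))
  oracle <- mean(rowSums(d3 * d4)) /
    sqrt(mean(rowSums(d3^2)) * mean(rowSums(d4^2)))
  expect_equal(cm[3, 4], oracle, tolerance = 1e-10)
  # zero-fluctuation residue is marked undefined
  frames0 <- lapply(frames, function(fr) { fr[4, ] <- base[4, ]; fr })
  cm0 <- dynamic_cross_correlation(trajectory(atoms, frames0[1:50], 1:50),
                                   1:nres, 1:nres, align = FALSE)
  expect_true(all(is.na(cm0[4, ])))
})

test_that("H-bond distances are plain euclidean distances", {
  atoms <- data.frame(atom_name = c("H", "O"), residue_name = "GLY",
                      residue_index = c(2L, 1L), chain_id = "A",
                      element = c("H", "O"))
  conf <- conformation(atoms, rbind(c(0, 0, 0), c(0, 0, 2)))
  expect_equal(hbond_distance_series(conf, c(2, "H"), c(1, "O")), 2.0)
  expect_error(hbond_distance_series(conf, c(3, "H"), c(1, "O")),
               "place_amide_hydrogens")
})

test_that("layer thickness is the difference of mean z", {
  atoms <- data.frame(atom_name = "P", residue_name = "POP",
                      residue_index = 1:4, chain_id = "A", element = "P")
  up <- 1:2; lo <- 3:4
  f1 <- cbind(0, 0, c(19, 19, -19, -19))
  tr <- trajectory(atoms, list(f1), 0)
  expect_equal(layer_thickness(tr, up, lo)$thickness, 38.0)
  set.seed(61)
  frames <- lapply(1:1000, function(i) f1 + cbind(0, 0, rnorm(4, 0, 1)))
  trn <- trajectory(atoms, frames, 1:1000)
  expect_lt(abs(mean(layer_thickness(trn, up, lo)$thickness) - 38), 0.2)
  expect_equal(layer_thickness(tr, 1, 3)$thickness, 38.0)  # single atoms
  expect_error(layer_thickness(tr, integer(0), lo), "empty")
})

test_that("per-residue displacement localises a moved CA and is
           rigid-motion invariant", {
  pair <- toy_pair()
  conf <- pair$state_a
  expect_true(all(per_residue_displacement(conf, conf)$displacement <
                  1e-9))
  ca7 <- find_atom(conf, 7, "CA")
  moved_xyz <- conf$xyz
  moved_xyz[ca7, ] <- moved_xyz[ca7, ] + c(0, 0, 2)
  moved <- conformation(conf$atoms, moved_xyz)
  align <- setdiff(which(conf$atoms$atom_name == "CA"), ca7)
  d <- per_residue_displacement(moved, conf, align)
  expect_equal(d$displacement[d$residue_index == 7], 2, tolerance = 1e-6)
  set.seed(71)
  rot <- rand_rotation(83)
  rigid <- conformation(conf$atoms,
                        sweep(moved_xyz %*% t(rot$R), 2, c(3, -1, 2),
                              FUN = "+"))
  d2 <- per_residue_displacement(rigid, conf, align)
  expect_equal(d2$displacement, d$displacement, tolerance = 1e-6)
})

test_that("slerp interpolates at constant angular velocity", {
  q90 <- c(cos(pi / 4), 0, 0, sin(pi / 4))   # 90 deg about z
  expect_equal(slerp(q90, q90, 0.37), q90, tolerance = 1e-12)
  half <- slerp(c(1, 0, 0, 0), q90, 0.5)
  expect_equal(quat_angle(half), 45, tolerance = 1e-8)
  expect_equal(half[2:3], c(0, 0), tolerance = 1e-12)
  set.seed(81)
  qa <- quat_normalize(rnorm(4))
  qb <- quat_normalize(rnorm(4))
  ts <- seq(0, 1, length.out = 100)
  qs <- lapply(ts, function(t) slerp(qa, qb, t))
  steps <- vapply(seq_len(99), function(i)
    quat_angle_between(qs[[i]], qs[[i + 1]]), numeric(1))
  expect_lt(max(steps) - min(steps), 1e-6)
  expect_equal(qs[[1]], qa, tolerance = 1e-12)
  expect_equal(quat_angle_between(qs[[100]], qb), 0, tolerance = 1e-8)
  # antipodal pair goes the short way
  expect_lt(quat_angle_between(slerp(qa, -qb, 0.5), slerp(qa, qb, 0.5)),
            1e-8)
  expect_error(slerp(c(0, 0, 0, 0), qb, 0.5), "zero-norm")
  expect_equal(lerp_center(c(0, 0, 0), c(2, 4, 6), 0.25), c(0.5, 1, 1.5))
})

test_that("pose composition closes: re-posing gives the identity", {
  pair <- toy_pair()
  set.seed(91)
  for (i in 1:3) {
    rot <- rand_rotation(runif(1, 10, 170))
    moved <- sweep(pair$state_a$xyz %*% t(rot$R), 2, rnorm(3, 0, 5),
                   FUN = "+")
    p <- pose_of(moved, pair$state_a)
    rebuilt <- apply_pose(sweep(pair$state_a$xyz, 2,
                                colMeans(pair$state_a$xyz)), p)
    expect_lt(max(abs(rebuilt - moved)), 1e-8)
    p2 <- pose_of(rebuilt, moved)
    expect_lt(quat_angle(p2$q), 1e-6)
  }
})
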