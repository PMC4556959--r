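test_that("Kabsch superposition recovers rigid motions and minimises RMSD", {
  set.seed(4)
  ref <- matrix(rnorm(24), 8, 3)
  # identity case
  f0 <- kabsch_superpose(ref, ref)
  expect_equal(f0$rmsd, 0, tolerance = 1e-12)
  expect_equal(f0$rotation, diag(3), tolerance = 1e-8)
  # 90-degree rotation about z plus translation is removed exactly
  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  mob <- sweep(ref %*% rz, 2, c(5, 0, 0), `+`)
  f1 <- kabsch_superpose(mob, ref)
  expect_lt(f1$rmsd, 1e-8)
  expect_equal(det(f1$rotation), 1, tolerance = 1e-10)
  # displaced-atom case matches an exhaustive minimisation oracle
  base <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  mob2 <- base; mob2[1, 1] <- mob2[1, 1] + 1
  f2 <- kabsch_superpose(mob2, base)
  expect_equal(f2$rmsd, oracle_min_rmsd(mob2, base), tolerance = 1e-6)
  # weighted case against the same oracle
  w <- c(4, 1, 1, 2)
  f3 <- kabsch_superpose(mob2, base, weights = w)
  expect_equal(f3$rmsd, oracle_min_rmsd(mob2, base, weights = w),
               tolerance = 1e-6)
  expect_error(kabsch_superpose(base[1:2, ], base[1:2, ]), "N >= 3")
  coll <- cbind(1:4, 0, 0)
  expect_error(kabsch_superpose(coll, coll), "degenerate")
})

test_that("Kabsch RMSD agrees with an established superposition routine", {
  set.seed(31)
  for (k in 1:5) {
    ref <- matrix(rnorm(36, sd = 3), 12, 3)
    mob <- ref + 0.4 * matrix(rnorm(36), 12, 3)
    ours <- kabsch_superpose(mob, ref)
    xyz_fit <- bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                              mobile = as.numeric(t(mob)),
                              fixed.inds = 1:36, mobile.inds = 1:36)
    theirs <- sqrt(mean(rowSums(
      (matrix(xyz_fit, ncol = 3, byrow = TRUE) - ref)^2)))
    expect_equal(ours$rmsd, theirs, tolerance = 1e-6)
  }
})

test_that("Kabsch RMSD is invariant under joint rigid transforms", {
  set.seed(7)
  a <- matrix(rnorm(30), 10, 3)
  b <- a + 0.3 * matrix(rnorm(30), 10, 3)
  r0 <- kabsch_superpose(a, b)$rmsd
  for (k in 1:5) {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    rot <- matrix(c(
      q[1]^2 + q[2]^2 - q[3]^2 - q[4]^2, 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), q[1]^2 - q[2]^2 + q[3]^2 - q[4]^2,
      2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      q[1]^2 - q[2]^2 - q[3]^2 + q[4]^2), 3, byrow = TRUE)
    tr <- rnorm(3, 0, 5)
    expect_equal(kabsch_superpose(sweep(a %*% rot, 2, tr, `+`),
                                  sweep(b %*% rot, 2, tr, `+`))$rmsd,
                 r0, tolerance = 1e-9)
  }
})

test_that("fitting a tumbling rigid body removes all apparent motion", {
  set.seed(12)
  base <- matrix(rnorm(45, sd = 4), 15, 3)
  traj <- gen_rigid_tumble(base, 30, seed = 5)
  fitted <- fit_trajectory(traj, selection = "all")
  expect_lt(max(rmsd_series(fitted)$rmsd), 1e-8)
  # per-atom variance essentially zero
  v <- apply(fitted$coords, c(2, 3), var)
  expect_lt(max(v), 1e-10)
  # 1-frame trajectory passes through up to a rigid transform
  one <- new_trajectory(traj$topology, traj$coords[1, , , drop = FALSE])
  f1 <- fit_trajectory(one, selection = "all")
  expect_lt(kabsch_superpose(frame_coords(f1, 1), frame_coords(one, 1))$rmsd,
            1e-10)
})

test_that("rmsd_series reports plain per-frame deviations", {
  base <- matrix(rnorm(30), 10, 3)
  coords <- array(0, c(2, 10, 3))
  coords[1, , ] <- base
  coords[2, , ] <- base + matrix(rep(c(1, 0, 0), each = 10), 10)
  top <- topology_from_atoms(
    data.frame(name = "CA", element = "C", resname = "GLY",
               resid = 1:10, chain = "A"), base)
  tr <- new_trajectory(top, coords)
  s <- rmsd_series(tr)
  expect_equal(s$rmsd, c(0, 1))
})

test_that("stationary_value averages the trailing window", {
  expect_equal(stationary_value(rep(3.2, 50), seq(0, 49), window = 10), 3.2)
  expect_equal(stationary_value(1:10, 1:10, window = 2), 9.5)
  # full-span window reproduces the global mean
  expect_equal(stationary_value(1:10, 1:10, window = 9), mean(1:10))
  expect_error(stationary_value(1:10, 1:10, window = 20), "exceeds")
  # CLT bound on a noisy plateau
  set.seed(3)
  y <- 5 + rnorm(400, sd = 0.5)
  est <- stationary_value(y, seq_along(y), window = 99)
  expect_lt(abs(est - mean(y[302:400])), 1e-12)
  expect_lt(abs(est - 5), 3 * 0.5 / sqrt(99))
})

test_that("RMSF matches the isotropic-jitter closed form sigma*sqrt(3)", {
  sigma <- 0.4
  g <- gen_gaussian_trajectory(covariance_spec(3, sigma = sigma), 1e4, seed = 21)
  prof <- rmsf(g$traj, selection = "all")
  expect_equal(prof$rmsf, rep(sigma * sqrt(3), 3), tolerance = 0.02)
  # static trajectory gives zeros; mobile atom ranks above static atom
  g0 <- gen_gaussian_trajectory(covariance_spec(2, sigma = c(0, 0.5)), 200,
                                seed = 2)
  p0 <- rmsf(g0$traj, selection = "all")
  expect_equal(p0$rmsf[1], 0, tolerance = 1e-12)
  expect_gt(p0$rmsf[2], p0$rmsf[1])
})

test_that("RMSF is unchanged by duplicating the trajectory", {
  g <- gen_gaussian_trajectory(covariance_spec(2, sigma = 0.3), 50, seed = 8)
  tr <- g$traj
  dup <- new_trajectory(tr$topology,
                        array(tr$coords[rep(1:50, 2), , ], c(100, 2, 3)))
  expect_equal(rmsf(dup, "all")$rmsf, rmsf(tr, "all")$rmsf, tolerance = 1e-12)
})

test_that("radius of gyration: point masses, symmetry, cube, invariances", {
  mk <- function(xyz) {
    top <- topology_from_atoms(
      data.frame(name = "CA", element = "C", resname = "GLY",
                 resid = seq_len(nrow(xyz)), chain = "A"), xyz)
    new_trajectory(top, array(xyz, c(1, nrow(xyz), 3)))
  }
  expect_equal(radius_of_gyration(mk(matrix(c(1, 2, 3), 1)))$rg, 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(mk(two), mass_weighted = FALSE)$rg, 1.0)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(radius_of_gyration(mk(cube), mass_weighted = FALSE)$rg, sqrt(3))
  # rigid-transform invariance and linear scaling
  tum <- gen_rigid_tumble(cube, 10, seed = 3)
  rgs <- radius_of_gyration(tum, mass_weighted = FALSE)$rg
  expect_equal(rgs, rep(sqrt(3), 10), tolerance = 1e-10)
  expect_equal(radius_of_gyration(mk(2 * cube), mass_weighted = FALSE)$rg,
               2 * sqrt(3))
})
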