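test_that("multi-model PDB files round-trip through write/read", {
  g <- gen_trajectory(n_frames = 3, sigma = 0.5,
                      reference = helical_reference(8, backbone = TRUE),
                      seed = 21)
  f <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(g$traj, f)
  back <- read_multimodel_pdb(f)
  expect_equal(nrow(back$xyz), 3)
  expect_equal(back$atoms$elety, g$traj$atoms$elety)
  expect_equal(back$atoms$resno, g$traj$atoms$resno)
  # PDB coordinates carry 3 decimals
  expect_equal(back$xyz, g$traj$xyz, tolerance = 1e-3)

  single <- gen_trajectory(n_frames = 1, sigma = 0,
                           reference = helical_reference(5), seed = 1)
  f1 <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(single$traj, f1)
  expect_equal(nrow(read_multimodel_pdb(f1)$xyz), 1)

  # drop one atom from model 2 -> integrity error naming the atom
  lines <- readLines(f)
  idx <- grep("^MODEL", lines)
  atom2 <- grep("^ATOM", lines)
  drop <- atom2[atom2 > idx[2]][5]
  writeLines(lines[-drop], f1)
  expect_error(read_multimodel_pdb(f1), "inconsistent atom set")

  writeLines(c("HEADER junk", "END"), f1)
  expect_error(read_multimodel_pdb(f1), "no ATOM records")
})

test_that("Kabsch superposition recovers exact rigid transforms", {
  set.seed(31)
  x <- random_coords(12)
  same <- kabsch_superpose(x, x)
  expect_equal(same$rmsd, 0, tolerance = 1e-10)
  expect_equal(same$rotation, diag(3), tolerance = 1e-8)

  R <- varstab:::rotation_matrix(c(1, -2, 0.5), 1.1)
  moved <- x %*% t(R) + matrix(c(3, -1, 7), nrow(x), 3, byrow = TRUE)
  fit <- kabsch_superpose(moved, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate")
})

test_that("superposed RMSD never exceeds the unsuperposed RMSD", {
  set.seed(32)
  for (i in 1:20) {
    a <- random_coords(8)
    b <- a + matrix(rnorm(24, sd = runif(1, 0.1, 3)), ncol = 3)
    raw <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(kabsch_superpose(a, b)$rmsd, raw + 1e-12)
  }
})

test_that("Kabsch agrees with the rotation-search oracle", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    a <- random_coords(n)
    b <- random_coords(n)
    w <- if (i %% 2 == 0) runif(n, 0.5, 2) else NULL
    expect_equal(kabsch_superpose(a, b, w)$rmsd,
                 oracle_superpose_rmsd(a, b, w), tolerance = 1e-3)
  }
})

test_that("RMSD series vanish for static and rigidly-moved trajectories", {
  tr <- static_traj(5, 10)
  expect_equal(rmsd_series(tr, "calpha")$rmsd, rep(0, 5), tolerance = 1e-10)
  # rigid-body motion only: superposition removes it entirely
  g <- gen_trajectory(n_frames = 6, sigma = 0, rigid_motion = TRUE,
                      reference = helical_reference(12), seed = 2)
  expect_equal(rmsd_series(g$traj, "calpha")$rmsd, rep(0, 6),
               tolerance = 1e-8)
  expect_error(rmsd_series(tr, function(e, r) rep(FALSE, length(e))),
               "empty")
})

test_that("per-frame RMSD matches the oracle on noisy small systems", {
  g <- gen_trajectory(n_frames = 4, sigma = 1,
                      reference = helical_reference(5), seed = 13)
  set.seed(14)
  series <- rmsd_series(g$traj, "calpha", reference = 1)
  for (f in 2:4) {
    mob <- matrix(g$traj$xyz[f, ], ncol = 3, byrow = TRUE)
    ref <- matrix(g$traj$xyz[1, ], ncol = 3, byrow = TRUE)
    expect_equal(series$rmsd[f], oracle_superpose_rmsd(mob, ref),
                 tolerance = 1e-3)
  }
})

test_that("mean RMSD grows with the injected noise amplitude", {
  means <- vapply(c(0.3, 0.8, 1.5, 3), function(s) {
    g <- gen_trajectory(n_frames = 30, sigma = s,
                        reference = helical_reference(40), seed = 8)
    mean(rmsd_series(g$traj, "calpha")$rmsd[-1])
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("RMSF recovers closed-form fluctuation amplitudes", {
  tr <- static_traj(4, 8)
  expect_equal(rmsf_profile(tr, "calpha")$rmsf, rep(0, 8), tolerance = 1e-10)

  # one atom alternating between two points 2a apart: RMSF = a
  # (many fixed atoms, so the rigid-body fit cannot absorb the motion)
  ref <- helical_reference(200)
  xyz <- rbind(as.numeric(t(ref$coords)), as.numeric(t(ref$coords)))
  a <- 0.4
  # move atom 3 along +z then -z around its mean; other atoms fixed
  xyz[1, 9] <- xyz[1, 9] + a
  xyz[2, 9] <- xyz[2, 9] - a
  tr2 <- trajectory(ref$atoms, xyz)
  prof <- rmsf_profile(tr2, "calpha", reference = "first")
  expect_equal(prof$rmsf[3], a, tolerance = 0.02)

  # isotropic Gaussian: RMSF ~ sigma * sqrt(3) (moderate n here)
  g <- gen_trajectory(n_frames = 400, sigma = 1,
                      reference = helical_reference(30), seed = 17)
  prof3 <- rmsf_profile(g$traj, "calpha")
  expect_equal(median(prof3$rmsf), sqrt(3), tolerance = 0.08)
  expect_error(rmsf_profile(g$traj, "calpha", equil_start_ns = 10^6),
               ">= 2 frames")
})

test_that("elevated loop fluctuations appear exactly at planted residues", {
  sig <- rep(0.5, 30)
  loop <- 12:18
  sig[loop] <- 1.5
  g <- gen_trajectory(n_frames = 300, sigma = sig,
                      reference = helical_reference(30), seed = 23)
  prof <- rmsf_profile(g$traj, "calpha")
  expect_true(all(prof$rmsf[loop] > max(prof$rmsf[-loop])))
})

test_that("radius of gyration follows its closed form and invariances", {
  d <- 6
  two <- rbind(c(0, 0, 0), c(d, 0, 0))
  expect_equal(radius_of_gyration(two, c(2, 2)), d / 2)
  set.seed(41)
  x <- random_coords(50)
  m <- runif(50, 1, 16)
  # independent direct evaluation of the definition
  com <- apply(x * m, 2, sum) / sum(m)
  direct <- sqrt(sum(m * ((x[, 1] - com[1])^2 + (x[, 2] - com[2])^2 +
                          (x[, 3] - com[3])^2)) / sum(m))
  expect_equal(radius_of_gyration(x, m), direct, tolerance = 1e-10)
  R <- varstab:::rotation_matrix(c(0.3, 1, -2), 0.77)
  moved <- x %*% t(R) + matrix(c(5, 6, 7), 50, 3, byrow = TRUE)
  expect_equal(radius_of_gyration(moved, m), radius_of_gyration(x, m),
               tolerance = 1e-8)
  expect_error(radius_of_gyration(x, rep(0, 50)), "mass")
})

test_that("equilibrium statistics cover only the analysis window", {
  vals <- rep(3.3, 10)
  times <- (0:9) * 1000
  s <- equilibrium_stats(vals, times, equil_start_ns = 4)
  expect_equal(s$mean, 3.3)
  expect_equal(s$sd, 0)
  expect_equal(s$n, 6)
  set.seed(5)
  noisy <- rnorm(4000, mean = 3.27, sd = 0.29)
  s2 <- equilibrium_stats(noisy, seq_along(noisy), equil_start_ns = 0)
  expect_equal(s2$mean, 3.27, tolerance = 3 * 0.29 / sqrt(4000))
  expect_equal(s2$sd, 0.29, tolerance = 0.02)
  expect_error(equilibrium_stats(vals, times, equil_start_ns = 100), "fewer")
})

test_that("group comparison gates on normality and flags separated groups", {
  x <- c(1.1, 1.2, 1.3, 1.1, 1.2)
  expect_false(compare_groups(x, x)$significant)
  set.seed(6)
  a <- rnorm(50, 3.27, 0.29)
  b <- rnorm(50, 5.14, 0.63)
  cmp <- compare_groups(a, b)
  expect_true(cmp$significant)
  expect_lt(cmp$p_value, 0.05)
  # heavy-tailed data routes to the rank-based test
  skew <- exp(rnorm(30, 0, 2))
  cmp2 <- compare_groups(skew, skew + 0.001)
  expect_equal(cmp2$test, "wilcoxon")
  expect_error(compare_groups(1:2, 1:5), ">= 3")
})

test_that("model quality Z-scores combine with the published weights", {
  expect_equal(model_zscore(0, 0, 0), 0)
  expect_equal(model_zscore(1, 1, 1), 1.0018)
  expect_equal(model_zscore(1, 0, 0), 0.1456)
  expect_equal(model_zscore(0, 1, 0), 0.3906)
  expect_equal(model_zscore(0, 0, 1), 0.4656)
  expect_equal(model_zscore(-1.2, 0.4, -0.5), 0.1456 * -1.2 + 0.3906 * 0.4 +
                 0.4656 * -0.5)
})
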