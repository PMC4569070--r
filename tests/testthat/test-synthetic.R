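# Determinism, statistical convergence and validation of the generators.

test_that("all generators are bit-reproducible under a fixed seed", {
  g <- seq(150, 120, length.out = 6); p <- rep(15, 6)
  expect_identical(gen_hinged_trajectory(g, p, sigma = 0.4, seed = 7)$traj$xyz,
                   gen_hinged_trajectory(g, p, sigma = 0.4, seed = 7)$traj$xyz)
  cv <- diag(1, 9)
  expect_identical(gen_gaussian_trajectory(50, cv, seed = 8)$xyz,
                   gen_gaussian_trajectory(50, cv, seed = 8)$xyz)
  pij <- toy_pij()
  w <- two_peak_weight(pij)
  expect_identical(gen_alpha_histogram(w, pij, 500, "independent", seed = 9)$counts,
                   gen_alpha_histogram(w, pij, 500, "independent", seed = 9)$counts)
})

test_that("jittered hinge recovery is unbiased and tightens with larger domains", {
  g <- rep(130, 400); p <- rep(40, 400)
  err_for <- function(atoms) {
    ht <- gen_hinged_trajectory(g, p, sigma = 1, seed = 10, cloud_atoms = atoms)
    ts <- angle_timeseries(ht$traj, ht$hinges)
    ts$gamma - g
  }
  e4 <- err_for(4); e32 <- err_for(32)
  expect_lt(abs(mean(e4)), 3 * stats::sd(e4) / sqrt(length(e4)))
  expect_lt(stats::sd(e32), stats::sd(e4))
})

test_that("invalid hinge scripts are rejected", {
  expect_error(gen_hinged_trajectory(c(150, 181), c(0, 0)), "inside")
  expect_error(gen_hinged_trajectory(150, c(0, 10)), "equal length")
  # gamma = 180 is only reachable at zero torsion
  expect_error(gen_hinged_trajectory(180, 90), "reachable")
})

test_that("Gaussian trajectories converge to the specified covariance", {
  cv <- gaussian_cov_recipe(3, 2, data.frame(i = 1, j = 3, rho = 0.5))
  tr <- gen_gaussian_trajectory(20000, cv, seed = 11)
  emp <- stats::cov(tr$xyz)
  expect_lt(max(abs(emp - cv)), 0.12)
  # diagonal spec: empirical cross-covariances near zero
  tr0 <- gen_gaussian_trajectory(5000, diag(1, 6), seed = 12)
  emp0 <- stats::cov(tr0$xyz)
  expect_lt(max(abs(emp0[upper.tri(emp0)])), 0.08)
  bad <- diag(1, 6); bad[1, 6] <- bad[6, 1] <- 2
  expect_error(gen_gaussian_trajectory(10, bad), "semi-definite")
  expect_error(gen_gaussian_trajectory(10, matrix(1:36, 6)), "symmetric")
})

test_that("multinomial histograms have the right size, law and provenance", {
  pij <- toy_pij()
  w <- rep(1 / 12, 12)
  h1 <- gen_alpha_histogram(w, pij, 1, model = "independent", seed = 13)
  expect_equal(sum(h1$counts), 1)
  expect_equal(sum(h1$counts > 0), 1)
  # law of large numbers at N_tot = 1e6: every bin within 3 sigma
  big <- gen_alpha_histogram(w, pij, 1e6, model = "independent", seed = 14)
  p <- attr(big, "p_true")
  sd3 <- 3 * sqrt(1e6 * p * (1 - p))
  expect_true(all(abs(big$counts - 1e6 * p) <= pmax(sd3, 3)))
  expect_equal(attr(big, "provenance")$seed, 14)
  # weight/mask mismatch propagates as a validation error
  a_bad <- matrix(1 / 144, 12, 12)
  pij_masked <- pij; pij_masked$mask[1, 2] <- pij_masked$mask[2, 1] <- TRUE
  expect_error(gen_alpha_histogram(a_bad, pij_masked, 10, model = "general"),
               "masked")
})

test_that("anti-correlated and independent two-hinge scripts are distinguishable", {
  set.seed(15)
  n <- 400
  g1 <- stats::runif(n, 70, 170)
  anti <- gen_hinged_trajectory(g1, rep(0, n), gamma2 = 240 - g1, phi2 = rep(0, n))
  indep <- gen_hinged_trajectory(g1, rep(0, n),
                                 gamma2 = stats::runif(n, 70, 170), phi2 = rep(0, n))
  cor_of <- function(ht) {
    ts <- angle_timeseries(ht$traj, ht$hinges)
    stats::cor(ts$gamma[ts$hinge == "hinge1"], ts$gamma[ts$hinge == "hinge2"])
  }
  expect_lt(cor_of(anti), -0.95)
  expect_lt(abs(cor_of(indep)), 0.2)
})

test_that("trajectory containers validate and round-trip through PDB files", {
  expect_error(ca_trajectory(matrix(0, 2, 7), ca_topology("A", 1:2)), "columns")
  ht <- gen_hinged_trajectory(c(150, 140), c(10, 20))
  pdb_file <- tempfile(fileext = ".pdb")
  m <- matrix(ht$traj$xyz[1, ], ncol = 3, byrow = TRUE)
  bio3d::write.pdb(file = pdb_file, xyz = ht$traj$xyz[1, ],
                   chain = ht$traj$top$chain, resno = ht$traj$top$resno,
                   elety = rep("CA", nrow(ht$traj$top)),
                   resid = rep("ALA", nrow(ht$traj$top)))
  back <- read_ca_trajectory(pdb_file)
  expect_equal(back$xyz[1, ], ht$traj$xyz[1, ], ignore_attr = TRUE, tolerance = 1e-3)
  expect_equal(back$top$chain, ht$traj$top$chain)
})
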