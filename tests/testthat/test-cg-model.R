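# Rod-and-sphere model: geometry extraction, embedding, adsorption, alpha.

test_that("geometry construction validates its lengths", {
  expect_error(cg_geometry(-1, 9, 1.3, 2.7), "positive")
  expect_error(cg_geometry(8, 9, 0, 2.7), "positive")
  geo <- cg_geometry(8, 9, 1.3, 2.7)
  expect_equal(geo$h_max, 1.1 * 2.7)
})

test_that("geometry extracted from a structure matches centroid distances", {
  # toy structure: 2-atom groups with hand-set centers (Angstrom)
  top <- ca_topology(chain = rep(c("E", "H", "D"), each = 2), resno = rep(1:2, 3))
  mk <- function(center, d) rbind(center + c(d, 0, 0), center - c(d, 0, 0))
  pts <- rbind(mk(c(0, 0, 0), 5), mk(c(30, 0, 0), 5), mk(c(30, 40, 0), 10))
  tr <- ca_trajectory(as.vector(t(pts)), top)
  grp <- function(ch) do.call(atom_group, stats::setNames(list("g", 1:2), c("label", ch)))
  geo <- build_cg_geometry(tr, grp("E"), grp("H"), grp("D"))
  expect_equal(geo$rod_half, 3)  # nm
  expect_equal(geo$arm, 4)
  expect_equal(geo$r_e, 0.5)
  expect_equal(geo$r_d, 1.0)
  expect_equal(geo$h_max, 1.1)
})

test_that("the fully extended conformation is collinear with alpha = 180", {
  geo <- fg_default_geometry()
  conf <- place_conformation(c(180, 0, 180, 0), geo)
  expect_lt(max(abs(conf$points[, 2])), 1e-9)
  expect_lt(diff(range(conf$points[, 3])), 1e-9)
  expect_equal(measure_alpha(conf), 180)
})

test_that("a quarter-turn arm with zero torsion stays in the x0 plane", {
  geo <- fg_default_geometry()
  conf <- place_conformation(c(90, 0, 180, 0), geo)
  d1 <- conf$points["d1", ] - conf$points["hinge1", ]
  expect_equal(abs(d1[2]), 0, tolerance = 1e-12)          # no out-of-plane component
  expect_equal(d1[3], geo$arm, tolerance = 1e-12)         # perpendicular, toward x0
})

test_that("angle -> embedding -> measurement is the identity", {
  geo <- fg_default_geometry()
  set.seed(17)
  worst <- 0
  for (k in 1:1000) {
    ang <- c(stats::runif(1, 5, 175), stats::runif(1, -179.9, 180),
             stats::runif(1, 5, 175), stats::runif(1, -179.9, 180))
    conf <- place_conformation(ang, geo, roll = stats::runif(1, -180, 180),
                               height = stats::runif(1, 0, 4))
    worst <- max(worst, max(abs(measure_hinge_angles(conf) - ang)))
  }
  expect_lt(worst, 1e-6)
})

test_that("adsorption requires all regions low and both hinges above the plane", {
  geo <- fg_default_geometry()
  # contact placement: E at r_e, both D at r_d via the MC solution
  s <- suppressWarnings(mc_generate(50, geo, seed = 2))
  conf <- place_conformation(c(s$gamma1[1], s$phi1[1], s$gamma2[1], s$phi2[1]),
                             geo, roll = s$roll[1])
  expect_true(is_adsorbed(conf))
  # D2 hoisted high: extended arm pointing up
  up <- place_conformation(c(170, 0, 90, 0), geo, roll = 0)
  expect_gt(up$points["d2", 3], 2 * geo$h_max)
  expect_false(is_adsorbed(up))
  # hinge below the plane fails even with all regions low
  low <- place_conformation(c(90, 180, 90, 180), geo, roll = 0, height = -0.1)
  expect_true(all(low$points[c("e", "d1", "d2"), 3] < geo$h_max))
  expect_false(is_adsorbed(low))
})

test_that("alpha is the planar angle of the projected nodules", {
  geo <- fg_default_geometry()
  # hand-built conformation: projections at right angles around E
  conf <- structure(list(points = rbind(e = c(0, 0, 1), hinge1 = c(-8, 0, 1),
                                        hinge2 = c(8, 0, 1), d1 = c(9, 0, 0.5),
                                        d2 = c(0, 7, 0.5)),
                         geometry = geo), class = "cg_conformation")
  expect_equal(measure_alpha(conf), 90)
  conf$points["d1", ] <- c(0, 0, 2) # projects onto E
  expect_error(measure_alpha(conf), "degenerate projection")
})

test_that("alpha is mirror-symmetric and within range", {
  geo <- fg_default_geometry()
  s <- suppressWarnings(mc_generate(500, geo, seed = 23))
  expect_true(all(s$alpha >= 0 & s$alpha <= 180))
  set.seed(5)
  for (k in 1:50) {
    ang <- c(stats::runif(1, 20, 170), stats::runif(1, -179, 180),
             stats::runif(1, 20, 170), stats::runif(1, -179, 180))
    a1 <- measure_alpha(place_conformation(ang, geo))
    mirrored <- c(ang[1], -ang[2], ang[3], -ang[4])
    a2 <- measure_alpha(place_conformation(mirrored, geo))
    expect_equal(a1, a2, tolerance = 1e-9)
  }
})
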