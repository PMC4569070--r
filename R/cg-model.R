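#' Rod-and-sphere coarse-grained fibrinogen geometry
#'
#' The molecule is reduced to a stiff central rod carrying the E sphere at its
#' center and one hinge at each end; a rigid arm connects each hinge to a D
#' sphere. The four hinge angles (gamma1, phi1, gamma2, phi2) are the only
#' degrees of freedom. All lengths are in nm.
#'
#' @param rod_half rod half-length, E center to either hinge (nm).
#' @param arm hinge to D-sphere center distance (nm).
#' @param r_e,r_d radii of the E and D spheres (nm).
#' @param h_max adsorption height threshold (nm); default `1.1 * r_d`.
#' @return object of class `cg_geometry`.
#' @export
cg_geometry <- function(rod_half, arm, r_e, r_d, h_max = 1.1 * r_d) {
  vals <- c(rod_half = rod_half, arm = arm, r_e = r_e, r_d = r_d, h_max = h_max)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all coarse-grained lengths must be positive and finite", call. = FALSE)
  }
  structure(as.list(vals), class = "cg_geometry")
}

#' @export
print.cg_geometry <- function(x, ...) {
  cat(sprintf("<cg_geometry> rod half %.2f nm, arm %.2f nm, r_E %.2f nm, r_D %.2f nm, h_max %.2f nm\n",
              x$rod_half, x$arm, x$r_e, x$r_d, x$h_max))
  invisible(x)
}

#' Default fibrinogen coarse-grained geometry
#'
#' Dimensions consistent with the ~45 nm fibrinogen architecture: the hinge
#' sits mid coiled-coil about 8 nm from the E center, the D-region center
#' about 9 nm beyond it; sphere radii approximate the radii of gyration of the
#' E and D globules.
#'
#' @return a [cg_geometry()].
#' @export
fg_default_geometry <- function() {
  cg_geometry(rod_half = 8, arm = 9, r_e = 1.3, r_d = 2.7)
}

#' Extract a coarse-grained geometry from a structure
#'
#' Rod lengths are centroid-centroid distances; sphere radii are radii of
#' gyration of the globular groups about their centroid. Coordinates are
#' assumed to be in Angstrom (PDB convention) and are converted to nm.
#'
#' @param traj a one-frame [ca_trajectory()] (e.g. a crystal structure).
#' @param e_group,hinge_group,d_group [atom_group()]s of one protomer.
#' @param h_max_factor `h_max = h_max_factor * r_d` (default 1.1).
#' @return a [cg_geometry()]. The symmetric protomer is assumed, so one
#'   protomer's groups determine both halves.
#' @export
build_cg_geometry <- function(traj, e_group, hinge_group, d_group, h_max_factor = 1.1) {
  ce <- group_centroid(traj, e_group)[1, ]
  ch <- group_centroid(traj, hinge_group)[1, ]
  cd <- group_centroid(traj, d_group)[1, ]
  rg <- function(group, cen) {
    inds <- resolve_group(group, traj$top)
    pts <- xyz_to_mat(traj$xyz[1, ])[inds, , drop = FALSE]
    sqrt(mean(rowSums(sweep(pts, 2, cen)^2)))
  }
  rod_half <- sqrt(sum((ce - ch)^2)) / 10
  arm <- sqrt(sum((ch - cd)^2)) / 10
  r_e <- rg(e_group, ce) / 10
  r_d <- rg(d_group, cd) / 10
  cg_geometry(rod_half, arm, r_e, r_d, h_max = h_max_factor * r_d)
}

# Internal: molecule-frame arm directions for the two hinges.
# Frame: E center at origin, rod along x (hinge1 at -rod_half, hinge2 at
# +rod_half), torsion reference point x0 on the E sphere surface along +z.
# phi_k is the IUPAC dihedral x0-E-hinge_k-D_k; gamma_k the interior angle
# E-hinge_k-D_k. Derived unit arm vectors:
#   d1 = ( cos g1,  sin g1 sin p1, sin g1 cos p1)
#   d2 = (-cos g2, -sin g2 sin p2, sin g2 cos p2)
arm_dirs <- function(gamma1, phi1, gamma2, phi2) {
  g1 <- gamma1 * pi / 180; p1 <- phi1 * pi / 180
  g2 <- gamma2 * pi / 180; p2 <- phi2 * pi / 180
  list(d1 = cbind(cos(g1), sin(g1) * sin(p1), sin(g1) * cos(p1)),
       d2 = cbind(-cos(g2), -sin(g2) * sin(p2), sin(g2) * cos(p2)))
}

rot_x <- function(chi) {
  c <- cos(chi * pi / 180); s <- sin(chi * pi / 180)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' Embed a coarse-grained conformation in 3-D
#'
#' Deterministic embedding of the four hinge angles: the central rod lies
#' along the x axis, the E center at `(0, 0, height)`, the torsion reference
#' x0 on the E-sphere surface initially along +z; each D arm leaves its hinge
#' at `gamma` to the rod and is swung about the rod axis by the torsion `phi`
#' measured against x0. An optional rigid roll about the rod axis (applied to
#' the whole molecule, x0 included) orients the molecule over the surface
#' plane z = 0; internal angles are unaffected by it.
#'
#' @param angles numeric of length 4: `c(gamma1, phi1, gamma2, phi2)` in
#'   degrees, `gamma` in `[0, 180]`, `phi` in `(-180, 180]`.
#' @param geometry a [cg_geometry()].
#' @param roll rigid rotation about the rod axis, degrees (default 0).
#' @param height z of the E center (default `geometry$r_e`, the contact
#'   height).
#' @return object of class `cg_conformation`: list with `angles`, `points`
#'   (5 x 3 matrix: rows `e`, `hinge1`, `hinge2`, `d1`, `d2`), `x0`, `roll`,
#'   `height`, `geometry`.
#' @export
place_conformation <- function(angles, geometry, roll = 0, height = geometry$r_e) {
  stopifnot(length(angles) == 4)
  g1 <- angles[1]; p1 <- angles[2]; g2 <- angles[3]; p2 <- angles[4]
  if (g1 < 0 || g1 > 180 || g2 < 0 || g2 > 180) {
    stop("bending angles must lie in [0, 180] degrees", call. = FALSE)
  }
  if (p1 <= -180 || p1 > 180 || p2 <= -180 || p2 > 180) {
    stop("torsion angles must lie in (-180, 180] degrees", call. = FALSE)
  }
  d <- arm_dirs(g1, p1, g2, p2)
  r <- rot_x(roll)
  lift <- c(0, 0, height)
  e <- lift
  h1 <- c(-geometry$rod_half, 0, 0) + lift
  h2 <- c(geometry$rod_half, 0, 0) + lift
  d1 <- h1 + geometry$arm * drop(r %*% d$d1[1, ])
  d2 <- h2 + geometry$arm * drop(r %*% d$d2[1, ])
  x0 <- geometry$r_e * drop(r %*% c(0, 0, 1)) + lift
  pts <- rbind(e = e, hinge1 = h1, hinge2 = h2, d1 = d1, d2 = d2)
  structure(list(angles = c(gamma1 = g1, phi1 = p1, gamma2 = g2, phi2 = p2),
                 points = pts, x0 = x0, roll = roll, height = height,
                 geometry = geometry),
            class = "cg_conformation")
}

#' Re-measure the hinge angles of an embedded conformation
#'
#' Recovers (gamma1, phi1, gamma2, phi2) from the embedded points and the x0
#' torsion reference; inverse of [place_conformation()] to numerical
#' precision.
#'
#' @param conf a `cg_conformation`.
#' @return named numeric of length 4.
#' @export
measure_hinge_angles <- function(conf) {
  p <- conf$points
  c(gamma1 = angle_at(p["e", ], p["hinge1", ], p["d1", ]),
    phi1 = dihedral_at(conf$x0, p["e", ], p["hinge1", ], p["d1", ]),
    gamma2 = angle_at(p["e", ], p["hinge2", ], p["d2", ]),
    phi2 = dihedral_at(conf$x0, p["e", ], p["hinge2", ], p["d2", ]))
}

#' Adsorption test for an embedded conformation
#'
#' A conformation counts as adsorbed when the E and both D sphere centers sit
#' below the height threshold `h_max` while both hinges stay above the
#' surface plane z = 0.
#'
#' @param conf a `cg_conformation`.
#' @param geometry a [cg_geometry()] (default: the one stored in `conf`).
#' @return logical flag.
#' @export
is_adsorbed <- function(conf, geometry = conf$geometry) {
  z <- conf$points[, 3]
  (z[["e"]] < geometry$h_max &&
     z[["d1"]] < geometry$h_max &&
     z[["d2"]] < geometry$h_max &&
     z[["hinge1"]] >= 0 &&
     z[["hinge2"]] >= 0)
}

#' AFM-style alpha angle of an adsorbed conformation
#'
#' Projects the E and D sphere centers onto the surface plane and measures the
#' angle at the projected E center between the rays to the two projected D
#' centers -- the angle an AFM image of the tri-nodular molecule would show.
#'
#' @param conf a `cg_conformation`.
#' @return alpha in `[0, 180]` degrees.
#' @export
measure_alpha <- function(conf) {
  p <- conf$points
  e <- c(p["e", 1:2], 0)
  d1 <- c(p["d1", 1:2], 0)
  d2 <- c(p["d2", 1:2], 0)
  if (sqrt(sum((d1 - e)^2)) < 1e-9 || sqrt(sum((d2 - e)^2)) < 1e-9) {
    stop("degenerate projection: a D center projects onto the E center", call. = FALSE)
  }
  angle_at(d1, e, d2)
}
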