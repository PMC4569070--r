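#' Hinge bending angle
#'
#' Interior angle gamma (degrees) at the hinge-group centroid between rays to
#' the E-group and D-group centroids. 180 degrees is the fully extended
#' conformation; the crystal conformation of fibrinogen sits near 160 degrees.
#'
#' @param traj a [ca_trajectory()] (or bare xyz matrix plus `top`).
#' @param e_group,hinge_group,d_group [atom_group()]s for the three regions.
#' @param top topology when `traj` is a bare matrix.
#' @return numeric vector of gamma per frame, in `[0, 180]`.
#' @export
bending_angle <- function(traj, e_group, hinge_group, d_group, top = NULL) {
  e <- group_centroid(traj, e_group, top)
  h <- group_centroid(traj, hinge_group, top)
  d <- group_centroid(traj, d_group, top)
  angle_at(e, h, d)
}

#' Hinge torsion angle
#'
#' Signed dihedral phi (degrees, IUPAC convention) of the four group
#' centroids; for the fibrinogen hinge these are two E sub-groups, the hinge
#' group and the D group.
#'
#' @param traj a [ca_trajectory()] (or bare xyz matrix plus `top`).
#' @param g1,g2,g3,g4 the four [atom_group()]s, in order.
#' @param top topology when `traj` is a bare matrix.
#' @return numeric vector of phi per frame, in `(-180, 180]`.
#' @export
torsion_angle <- function(traj, g1, g2, g3, g4, top = NULL) {
  p1 <- group_centroid(traj, g1, top)
  p2 <- group_centroid(traj, g2, top)
  p3 <- group_centroid(traj, g3, top)
  p4 <- group_centroid(traj, g4, top)
  dihedral_at(p1, p2, p3, p4)
}

#' Hinge-angle time series
#'
#' Computes the (gamma, phi) pair for one or more hinges along a trajectory.
#'
#' @param traj a [ca_trajectory()].
#' @param hinges either a single hinge definition (a list with elements
#'   `gamma` = list(e, hinge, d) and `phi` = list(e1, e2, hinge, d), as
#'   returned by [fg_atom_groups()]) or a named list of such definitions.
#' @return a data.frame with columns `frame`, `hinge`, `gamma`, `phi`.
#' @export
angle_timeseries <- function(traj, hinges) {
  if (!is.null(hinges$gamma) && !is.null(hinges$phi)) hinges <- list(hinge1 = hinges)
  if (is.null(names(hinges))) names(hinges) <- paste0("hinge", seq_along(hinges))
  out <- lapply(names(hinges), function(nm) {
    hg <- hinges[[nm]]
    g <- bending_angle(traj, hg$gamma$e, hg$gamma$hinge, hg$gamma$d)
    p <- torsion_angle(traj, hg$phi$e1, hg$phi$e2, hg$phi$hinge, hg$phi$d)
    data.frame(frame = seq_len(n_frames(traj)), hinge = nm, gamma = g, phi = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
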