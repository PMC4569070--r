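# Vectorized point-geometry primitives shared by the angle and coarse-grained
# modules. All inputs are n x 3 matrices (or length-3 vectors, recycled to one
# row); all angles are in degrees.

as_row3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  p
}

row_norm <- function(m) sqrt(rowSums(m * m))

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Interior angle at a vertex
#'
#' Angle in degrees at `b` between the rays `b -> a` and `b -> c`. Inputs may
#' be single points or n x 3 matrices of points (one angle per row).
#'
#' @param a,b,c points (length-3 vectors or n x 3 matrices).
#' @return numeric vector of angles in `[0, 180]` degrees.
#' @export
angle_at <- function(a, b, c) {
  a <- as_row3(a); b <- as_row3(b); c <- as_row3(c)
  u <- a - b
  v <- c - b
  nu <- row_norm(u); nv <- row_norm(v)
  if (any(nu < 1e-12) || any(nv < 1e-12)) {
    stop("degenerate geometry: coincident points in angle computation", call. = FALSE)
  }
  # atan2 form is numerically stable near 0 and 180 degrees
  cr <- row_norm(row_cross(u, v))
  dt <- rowSums(u * v)
  atan2(cr, dt) * 180 / pi
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking down the `b -> c` axis, a clockwise rotation
#' of the far bond relative to the near bond is positive. The cis arrangement
#' gives 0 degrees. Values fall in `(-180, 180]`.
#'
#' @param a,b,c,d points (length-3 vectors or n x 3 matrices).
#' @return numeric vector of dihedral angles in degrees.
#' @export
dihedral_at <- function(a, b, c, d) {
  a <- as_row3(a); b <- as_row3(b); c <- as_row3(c); d <- as_row3(d)
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- row_cross(b1, b2)
  n2 <- row_cross(b2, b3)
  if (any(row_norm(n1) < 1e-12) || any(row_norm(n2) < 1e-12)) {
    stop("degenerate geometry: collinear triple in dihedral computation", call. = FALSE)
  }
  m1 <- row_cross(n1, b2 / row_norm(b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  phi <- -atan2(y, x) * 180 / pi
  # map -180 to +180 so the range is (-180, 180]
  phi[phi <= -180 + 1e-12 & phi >= -180 - 1e-12] <- 180
  phi
}

# Internal: Kabsch rotation aligning `mobile` (N x 3) onto `fixed` (N x 3),
# both already centered. Returns the 3 x 3 rotation matrix.
kabsch_rotation <- function(mobile, fixed) {
  h <- crossprod(mobile, fixed) # maximise tr(R' H): R = U diag(1,1,d) V'
  s <- svd(h)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Internal: rigid-body superposition of every frame of `xyz` onto `ref`
# (a single frame row-vector), least-squares over `fit_atoms` (indices).
superpose_onto <- function(xyz, ref, fit_atoms = NULL) {
  n_atoms <- ncol(xyz) / 3
  if (is.null(fit_atoms)) fit_atoms <- seq_len(n_atoms)
  ref_m <- xyz_to_mat(ref)
  ref_fit <- ref_m[fit_atoms, , drop = FALSE]
  ref_cen <- colMeans(ref_fit)
  ref_fit <- sweep(ref_fit, 2, ref_cen)
  out <- xyz
  for (f in seq_len(nrow(xyz))) {
    m <- xyz_to_mat(xyz[f, ])
    fit <- m[fit_atoms, , drop = FALSE]
    cen <- colMeans(fit)
    r <- kabsch_rotation(sweep(fit, 2, cen), ref_fit)
    moved <- sweep(m, 2, cen) %*% r
    moved <- sweep(moved, 2, ref_cen, `+`)
    out[f, ] <- as.vector(t(moved))
  }
  out
}

#' Iterated least-squares superposition of a trajectory
#'
#' Removes overall rotation and translation by fitting every frame onto the
#' running mean structure (Kabsch fit), recomputing the mean, and iterating to
#' self-consistency. Required before PCA or covariance analysis of internal
#' motion.
#'
#' @param traj a [ca_trajectory()] or a bare xyz matrix.
#' @param fit_atoms atom indices used for the fit (default: all atoms).
#' @param tol convergence threshold on the RMS change of the mean structure,
#'   in the coordinate units (default `1e-5` Angstrom, i.e. `1e-6` nm).
#' @param max_iter iteration cap.
#' @return an object of the same type as `traj` with superposed coordinates;
#'   the converged mean structure is attached as attribute `"mean"`.
#' @export
superpose_trajectory <- function(traj, fit_atoms = NULL, tol = 1e-5, max_iter = 50) {
  xyz <- if (inherits(traj, "fib_traj")) traj$xyz else as.matrix(traj)
  if (nrow(xyz) < 2) stop("superposition needs at least 2 frames", call. = FALSE)
  ref <- xyz[1, ]
  for (it in seq_len(max_iter)) {
    xyz <- superpose_onto(xyz, ref, fit_atoms)
    new_ref <- colMeans(xyz)
    delta <- sqrt(mean((new_ref - ref)^2))
    ref <- new_ref
    if (delta < tol) break
  }
  if (inherits(traj, "fib_traj")) {
    out <- ca_trajectory(xyz, traj$top)
  } else {
    out <- xyz
  }
  attr(out, "mean") <- ref
  out
}
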