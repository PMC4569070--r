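#' Principal component analysis of a C-alpha trajectory
#'
#' Eigendecomposition of the coordinate covariance matrix after iterated
#' least-squares superposition onto the mean structure. Modes are orthonormal
#' displacement vectors sorted by decreasing variance; projections are the
#' per-frame scores along each mode and have zero mean by construction.
#'
#' @param traj a [ca_trajectory()] or bare xyz matrix.
#' @param fit_atoms atom indices used for superposition (default all).
#' @param superpose superpose frames first (default TRUE); set FALSE when the
#'   input is already free of rigid-body motion (e.g. synthetic Gaussian
#'   fluctuations drawn in a fixed frame).
#' @param n_modes number of modes to retain (default: all with nonzero
#'   variance, capped at `n_frames - 1`).
#' @return object of class `fib_pca`: list with `mean` (coordinate vector),
#'   `modes` (3N x k orthonormal matrix), `eigenvalues` (variances, length k,
#'   non-increasing), `projections` (frames x k matrix).
#' @export
ca_pca <- function(traj, fit_atoms = NULL, superpose = TRUE, n_modes = NULL) {
  xyz <- if (inherits(traj, "fib_traj")) traj$xyz else as.matrix(traj)
  if (nrow(xyz) < 2) stop("PCA needs at least 2 frames", call. = FALSE)
  if (superpose) xyz <- superpose_trajectory(xyz, fit_atoms = fit_atoms)
  max_rank <- min(nrow(xyz) - 1L, ncol(xyz))
  if (!is.null(n_modes) && n_modes > max_rank) {
    warning(sprintf("requested %d modes but rank is at most %d; truncating",
                    n_modes, max_rank))
    n_modes <- max_rank
  }
  pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
  k <- if (is.null(n_modes)) min(max_rank, ncol(pc$rotation)) else n_modes
  structure(list(
    mean = pc$center,
    modes = pc$rotation[, seq_len(k), drop = FALSE],
    eigenvalues = pc$sdev[seq_len(k)]^2,
    projections = pc$x[, seq_len(k), drop = FALSE]
  ), class = "fib_pca")
}

#' @export
print.fib_pca <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("<fib_pca> %d modes, %d frames; leading modes explain %s of variance\n",
              ncol(x$modes), nrow(x$projections),
              paste(sprintf("%.1f%%", 100 * x$eigenvalues[seq_len(min(3, length(x$eigenvalues)))] / tot),
                    collapse = ", ")))
  invisible(x)
}

#' Overlap between two PCA subspaces
#'
#' Measures the similarity of the essential dynamics captured by two mode
#' sets: `O = (1/n) * sum_i sum_j (x_i . y_j)^2` over the first `n` modes of
#' each set. Equals 1 when the two n-dimensional spans coincide and 0 when
#' they are mutually orthogonal; symmetric in its arguments and invariant
#' under orthonormal re-basing of either subspace.
#'
#' @param x_modes,y_modes matrices whose columns are orthonormal modes in the
#'   same ambient dimension (or `fib_pca` objects).
#' @param n number of leading modes to compare (default: all shared columns).
#' @param tol orthonormality validation tolerance.
#' @return overlap in `[0, 1]`.
#' @export
subspace_overlap <- function(x_modes, y_modes, n = NULL, tol = 1e-8) {
  if (inherits(x_modes, "fib_pca")) x_modes <- x_modes$modes
  if (inherits(y_modes, "fib_pca")) y_modes <- y_modes$modes
  x_modes <- as.matrix(x_modes); y_modes <- as.matrix(y_modes)
  if (nrow(x_modes) != nrow(y_modes)) {
    stop("mode sets live in different ambient dimensions", call. = FALSE)
  }
  if (is.null(n)) n <- min(ncol(x_modes), ncol(y_modes))
  if (ncol(x_modes) < n || ncol(y_modes) < n) {
    stop(sprintf("need at least %d modes in each set", n), call. = FALSE)
  }
  x <- x_modes[, seq_len(n), drop = FALSE]
  y <- y_modes[, seq_len(n), drop = FALSE]
  check_on <- function(m, nm) {
    g <- crossprod(m)
    if (max(abs(g - diag(n))) > tol) {
      stop(sprintf("%s modes are not orthonormal (max deviation %.2e)",
                   nm, max(abs(g - diag(n)))), call. = FALSE)
    }
  }
  check_on(x, "x"); check_on(y, "y")
  sum(crossprod(x, y)^2) / n
}

#' Correlation of a linear combination of PCA projections with an angle series
#'
#' Forms `CP(t) = sum_j a_j P_j(t)` from the projection matrix and returns the
#' Pearson linear correlation coefficient between `CP(t)` and the supplied
#' angle time series. Used to show that hinge angles track the dominant
#' collective modes (e.g. gamma vs modes 1-3 with coefficients
#' `c(1, -1, -0.1)`).
#'
#' @param projections frames x modes matrix (or a `fib_pca`).
#' @param coefficients numeric coefficients `a_j`, recycled with zeros to the
#'   number of modes.
#' @param angle_series numeric vector, one value per frame.
#' @return Pearson correlation coefficient.
#' @export
projection_combination_correlation <- function(projections, coefficients, angle_series) {
  if (inherits(projections, "fib_pca")) projections <- projections$projections
  projections <- as.matrix(projections)
  if (nrow(projections) != length(angle_series)) {
    stop("projection and angle series lengths differ", call. = FALSE)
  }
  a <- rep(0, ncol(projections))
  a[seq_along(coefficients)] <- coefficients
  cp <- drop(projections %*% a)
  if (stats::sd(cp) < 1e-14 || stats::sd(angle_series) < 1e-14) {
    stop("undefined correlation: a series has zero variance", call. = FALSE)
  }
  stats::cor(cp, angle_series)
}
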