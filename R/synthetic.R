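# Synthetic-data generators. These produce inputs with exactly the
# statistical structure the estimators assume -- rigid domains with
# prescribed hinge angles, stationary Gaussian fluctuations, multinomial
# histograms -- so each analysis stage can be validated against a known
# ground truth without molecular-dynamics output or experimental data.

# Fixed zero-mean, non-coplanar point-cloud shape (>= 4 atoms); groups are
# this cloud scaled and translated to the group centroid, so centroids are
# exact. Larger clouds are stacked scaled tetrahedra, still zero-mean.
unit_cloud <- function(n_atoms = 4) {
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  reps <- ceiling(n_atoms / 4)
  v <- do.call(rbind, lapply(seq_len(reps), function(k) tet * (1 + 0.3 * (k - 1))))
  v <- v[seq_len(n_atoms), , drop = FALSE]
  sweep(v, 2, colMeans(v))
}

# Internal: centroid layout of one hinge given (gamma, phi), vectorized over
# frames. The E sub-group centroids sit at (0, +off, 0) and (0, -off, 0) (so
# the full E centroid is the origin); the hinge of interest sits at
# side * (rod, 0, 0). Returns the unit arm direction from the hinge to the D
# centroid such that the measured angle E-hinge-D equals gamma and the
# measured dihedral E1-E2-hinge-D equals phi.
hinge_arm_direction <- function(gamma, phi, rod, off, side) {
  # direction from the hinge to the full-E centroid
  ue <- c(-side * rod, off / 2, 0)
  ue <- ue / sqrt(sum(ue^2))
  g <- gamma * pi / 180
  # azimuth about the x axis fixed by the dihedral (beta = side-corrected phi)
  beta <- side * phi * pi / 180
  a <- ue[1]; b <- ue[2] * cos(beta)
  rr <- sqrt(a^2 + b^2)
  cosg <- cos(g)
  if (any(abs(cosg) > rr + 1e-12)) {
    stop("gamma outside the reachable range for this layout; reduce the E sub-group offset",
         call. = FALSE)
  }
  delta <- atan2(b, a)
  th1 <- delta + acos(pmin(pmax(cosg / rr, -1), 1))
  th2 <- delta - acos(pmin(pmax(cosg / rr, -1), 1))
  theta <- ifelse(sin(th1) >= 0, th1, th2)
  cbind(cos(theta), sin(theta) * cos(beta), sin(theta) * sin(beta))
}

#' Synthetic rigid-domain hinged trajectory
#'
#' Builds a C-alpha trajectory of rigid domains (two E sub-groups, one or two
#' hinge groups, one or two D groups) whose group-centroid geometry follows a
#' prescribed bending/torsion script exactly; optional isotropic per-atom
#' jitter is added afterwards. At zero jitter the measured (gamma, phi)
#' reproduce the script to numerical precision, which makes the generator its
#' own oracle for the angle machinery.
#'
#' Chains: `A`/`B` are the two E sub-groups, `H`/`I` the hinge groups,
#' `X`/`Y` the D groups; 4 atoms (residues 1-4) each.
#'
#' @param gamma,phi numeric vectors (degrees, one value per frame) scripting
#'   hinge 1. `gamma` in roughly `(5, 175)`; see Details on reachability.
#' @param gamma2,phi2 optional script for a second hinge on the opposite rod
#'   end; `NULL` (default) builds a single-hinge, three-domain chain.
#' @param sigma isotropic per-atom Gaussian jitter, same units as the
#'   coordinates (Angstrom), applied independently per frame.
#' @param seed seed for the jitter.
#' @param rod hinge to E-centroid distance (Angstrom).
#' @param arm hinge to D-centroid distance (Angstrom).
#' @param off separation of the two E sub-group centroids (Angstrom); small
#'   against `rod` so the full bending range stays reachable.
#' @param cloud_scale size of the rigid 4-atom domain clouds (Angstrom).
#' @return list of class `hinged_traj`: `traj` (a [ca_trajectory()]),
#'   `hinges` (named list of group definitions, each directly usable with
#'   [angle_timeseries()]), `angles` (data.frame of the prescribed script).
#' @export
gen_hinged_trajectory <- function(gamma, phi, gamma2 = NULL, phi2 = NULL,
                                  sigma = 0, seed = 1, rod = 30, arm = 35,
                                  off = 2, cloud_scale = 1.5, cloud_atoms = 4) {
  nf <- length(gamma)
  if (length(phi) != nf) stop("gamma and phi scripts must have equal length", call. = FALSE)
  two <- !is.null(gamma2)
  if (two && (length(gamma2) != nf || length(phi2) != nf)) {
    stop("second-hinge script must match the frame count", call. = FALSE)
  }
  if (any(gamma <= 0 | gamma > 180) || (two && any(gamma2 <= 0 | gamma2 > 180))) {
    stop("bending script must stay inside (0, 180] degrees", call. = FALSE)
  }
  if (cloud_atoms < 4) stop("domains need at least 4 atoms to be non-coplanar", call. = FALSE)
  # E sub-group 2 sits on the rod axis so the dihedral reference plane is the
  # xy-plane; the full-E centroid (equal-size sub-groups) is at (0, off/2, 0)
  ce1 <- c(0, off, 0); ce2 <- c(0, 0, 0)
  h1 <- c(-rod, 0, 0); h2 <- c(rod, 0, 0)
  d1_dir <- hinge_arm_direction(gamma, phi, rod, off, side = -1)
  cd1 <- sweep(arm * d1_dir, 2, h1, `+`)
  if (two) {
    d2_dir <- hinge_arm_direction(gamma2, phi2, rod, off, side = 1)
    cd2 <- sweep(arm * d2_dir, 2, h2, `+`)
  }
  cloud <- cloud_scale * unit_cloud(cloud_atoms)
  chains <- c("A", "B", "H", "X", if (two) c("I", "Y"))
  top <- ca_topology(chain = rep(chains, each = cloud_atoms),
                     resno = rep(seq_len(cloud_atoms), times = length(chains)))
  xyz <- matrix(0, nf, 3L * nrow(top))
  for (f in seq_len(nf)) {
    cs <- rbind(ce1, ce2, h1, cd1[f, ])
    if (two) cs <- rbind(cs, h2, cd2[f, ])
    pts <- do.call(rbind, lapply(seq_len(nrow(cs)), function(k) sweep(cloud, 2, cs[k, ], `+`)))
    xyz[f, ] <- as.vector(t(pts))
  }
  if (sigma > 0) {
    set.seed(seed)
    xyz <- xyz + stats::rnorm(length(xyz), sd = sigma)
  }
  rr <- seq_len(cloud_atoms)
  e_full <- atom_group("E", A = rr, B = rr)
  e1 <- atom_group("E part 1", A = rr)
  e2 <- atom_group("E part 2", B = rr)
  hinge_def <- function(hg, dg) {
    list(gamma = list(e = e_full, hinge = hg, d = dg),
         phi = list(e1 = e1, e2 = e2, hinge = hg, d = dg))
  }
  hinges <- list(hinge1 = hinge_def(atom_group("hinge 1", H = rr),
                                    atom_group("D 1", X = rr)))
  angles <- data.frame(frame = seq_len(nf), gamma1 = gamma, phi1 = phi)
  if (two) {
    hinges$hinge2 <- hinge_def(atom_group("hinge 2", I = rr),
                               atom_group("D 2", Y = rr))
    angles$gamma2 <- gamma2; angles$phi2 <- phi2
  }
  structure(list(traj = ca_trajectory(xyz, top), hinges = hinges, angles = angles,
                 sigma = sigma, seed = seed),
            class = "hinged_traj")
}

#' Synthetic multivariate-Gaussian C-alpha trajectory
#'
#' Draws frames independently from a specified `3R x 3R` Gaussian over the
#' residue coordinates. The empirical covariance converges to the
#' specification, so closed-form linear-mutual-information values computed
#' from the generating covariance serve as oracles for [lmi_matrix()].
#'
#' @param n_frames number of frames.
#' @param covariance symmetric positive semi-definite `3R x 3R` matrix.
#' @param mean optional mean coordinate vector (default 0).
#' @param seed seed; output is bit-reproducible given the seed.
#' @return a [ca_trajectory()] (chain `A`, residues `1..R`).
#' @export
gen_gaussian_trajectory <- function(n_frames, covariance, mean = NULL, seed = 1) {
  covariance <- as.matrix(covariance)
  if (!isSymmetric(covariance, tol = 1e-8)) {
    stop("covariance must be symmetric", call. = FALSE)
  }
  eg <- eigen(covariance, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(abs(eg$values))) {
    stop("covariance must be positive semi-definite", call. = FALSE)
  }
  d <- ncol(covariance)
  if (d %% 3 != 0) stop("covariance dimension must be a multiple of 3", call. = FALSE)
  root <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  set.seed(seed)
  z <- matrix(stats::rnorm(n_frames * d), n_frames, d)
  xyz <- z %*% root
  if (!is.null(mean)) xyz <- sweep(xyz, 2, mean, `+`)
  ca_trajectory(xyz, ca_topology(chain = rep("A", d / 3), resno = seq_len(d / 3)))
}

#' Block-recipe covariance for Gaussian trajectories
#'
#' Convenience builder: isotropic per-residue variance plus selected
#' isotropic cross-covariances `rho * var` between residue pairs.
#'
#' @param n_res residue count.
#' @param variance per-residue coordinate variance.
#' @param pairs optional data.frame with columns `i`, `j`, `rho`.
#' @return `3R x 3R` covariance matrix.
#' @export
gaussian_cov_recipe <- function(n_res, variance = 1, pairs = NULL) {
  cv <- diag(variance, 3 * n_res)
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      bi <- (3 * pairs$i[r] - 2):(3 * pairs$i[r])
      bj <- (3 * pairs$j[r] - 2):(3 * pairs$j[r])
      cv[bi, bj] <- cv[bj, bi] <- diag(pairs$rho[r] * variance, 3)
    }
  }
  cv
}

#' Closed-form LMI of an isotropically correlated residue pair
#'
#' For two residues with isotropic variance `v` and isotropic
#' cross-covariance `rho * v`, the linear mutual information is
#' `-(3/2) * log(1 - rho^2)` nats.
#'
#' @param rho isotropic cross-correlation.
#' @return LMI in nats.
#' @export
lmi_isotropic_pair <- function(rho) -1.5 * log(1 - rho^2)

#' Synthetic multinomial alpha-angle histogram
#'
#' Draws `n_tot` counts from the alpha distribution of a hinge-weight model
#' evaluated on a `pij_table` -- a stand-in for an experimental AFM histogram
#' with known generating weights.
#'
#' @param weights general pair-weight matrix or independent single-hinge
#'   vector, per `model`.
#' @param pij a `pij_table`.
#' @param n_tot total count.
#' @param model `"general"` or `"independent"`.
#' @param seed seed.
#' @return an [alpha_histogram()]; the generating distribution is attached as
#'   attribute `"p_true"`, the provenance (model, n_tot, seed) as
#'   `"provenance"`.
#' @export
gen_alpha_histogram <- function(weights, pij, n_tot, model = c("general", "independent"),
                                seed = 1) {
  model <- match.arg(model)
  if (n_tot < 1) stop("n_tot must be at least 1", call. = FALSE)
  p <- switch(model,
              general = model_alpha_general(weights, pij),
              independent = model_alpha_independent(weights, pij))
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, size = n_tot, prob = p))
  h <- alpha_histogram(pij$alpha_edges, counts)
  attr(h, "p_true") <- p
  attr(h, "provenance") <- list(model = model, n_tot = n_tot, seed = seed)
  h
}

# --- backbone builder ------------------------------------------------------

# Internal NeRF atom placement: position of atom D given A, B, C and the
# internal coordinates bond |CD|, angle B-C-D, torsion A-B-C-D (degrees).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Synthetic peptide backbone from phi/psi scripts
#'
#' Builds N-CA-C backbone coordinates with ideal bond geometry and the given
#' backbone dihedrals (omega fixed at 180), per frame. Used to exercise the
#' helicity assignment on conformations with known secondary structure.
#'
#' @param phi,psi matrices (frames x residues) or vectors (one frame) of
#'   backbone dihedrals in degrees; `phi[, 1]` is ignored (undefined at the
#'   N terminus).
#' @return a [ca_trajectory()] with N/CA/C atoms, chain `A`.
#' @export
gen_backbone_trajectory <- function(phi, psi) {
  if (is.null(dim(phi))) phi <- matrix(phi, nrow = 1)
  if (is.null(dim(psi))) psi <- matrix(psi, nrow = 1)
  stopifnot(all(dim(phi) == dim(psi)))
  nf <- nrow(phi); nres <- ncol(phi)
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7
  top <- ca_topology(chain = rep("A", 3 * nres),
                     resno = rep(seq_len(nres), each = 3),
                     elety = rep(c("N", "CA", "C"), nres))
  xyz <- matrix(0, nf, 9 * nres)
  for (f in seq_len(nf)) {
    pts <- matrix(0, 3 * nres, 3)
    pts[1, ] <- c(0, 0, 0)
    pts[2, ] <- c(b_nca, 0, 0)
    pts[3, ] <- place_atom(c(-1, 1, 0), pts[1, ], pts[2, ], b_cac, a_ncac, phi[f, 1] %||% -60)
    for (r in 2:nres) {
      iN <- 3 * r - 2
      pts[iN, ] <- place_atom(pts[iN - 3, ], pts[iN - 2, ], pts[iN - 1, ],
                              b_cn, a_cacn, psi[f, r - 1])
      pts[iN + 1, ] <- place_atom(pts[iN - 2, ], pts[iN - 1, ], pts[iN, ],
                                  b_nca, a_cnca, 180) # omega
      pts[iN + 2, ] <- place_atom(pts[iN - 1, ], pts[iN, ], pts[iN + 1, ],
                                  b_cac, a_ncac, phi[f, r])
    }
    xyz[f, ] <- as.vector(t(pts))
  }
  ca_trajectory(xyz, top)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Synthetic fibrinogen-protomer stand-in structure
#'
#' A single-frame C-alpha structure carrying the fibrinogen chain and residue
#' numbering of one protomer (chains A-alpha, B-beta, gamma as `A`, `B`,
#' `C`), with the E, hinge and D measurement groups laid out at a prescribed
#' bending angle -- by default the near-extended ~160-degree conformation the
#' crystal structure adopts. This is a synthetic stand-in (the group residues
#' are placed as compact clouds around the intended group centroids, not real
#' crystal coordinates); it exercises selection and angle measurement on
#' realistic numbering.
#'
#' @param gamma built-in bending angle, degrees (default 160).
#' @param seed seed for the intra-group cloud placement.
#' @return a [ca_trajectory()] on which [fg_atom_groups()] selections resolve.
#' @export
gen_synthetic_protomer <- function(gamma = 160, seed = 1) {
  set.seed(seed)
  e0 <- c(0, 0, 0)
  h <- c(80, 0, 0)
  g <- gamma * pi / 180
  d <- h + 90 * c(-cos(g), sin(g), 0) # angle(E, hinge, D) = gamma by construction
  clusters <- list(
    list(chain = "A", resno = 50:58, center = e0 + c(0, 5, 0), spread = 6),
    list(chain = "B", resno = 82:90, center = e0 - c(0, 5, 0), spread = 6),
    list(chain = "C", resno = 23:31, center = e0, spread = 6),
    list(chain = "A", resno = 99:110, center = h, spread = 8),
    list(chain = "B", resno = 130:155, center = h, spread = 8),
    list(chain = "C", resno = 70:100, center = h, spread = 8),
    list(chain = "B", resno = 200:458, center = d, spread = 22),
    list(chain = "C", resno = 140:394, center = d, spread = 22)
  )
  pts <- list(); ch <- character(0); rn <- integer(0)
  for (cl in clusters) {
    n <- length(cl$resno)
    p <- matrix(stats::rnorm(3 * n, sd = cl$spread), n, 3)
    p <- sweep(p, 2, colMeans(p)) # exact cluster centroid
    p <- sweep(p, 2, cl$center, `+`)
    pts[[length(pts) + 1L]] <- p
    ch <- c(ch, rep(cl$chain, n)); rn <- c(rn, cl$resno)
  }
  # the three E clusters and three hinge clusters each contribute unequal
  # atom counts; recenter each measurement group so its pooled centroid hits
  # the intended point exactly
  all_pts <- do.call(rbind, pts)
  top <- ca_topology(ch, rn)
  fix_group <- function(pts, sel, target) {
    shift <- target - colMeans(pts[sel, , drop = FALSE])
    pts[sel, ] <- sweep(pts[sel, , drop = FALSE], 2, shift, `+`)
    pts
  }
  groups <- fg_atom_groups()
  all_pts <- fix_group(all_pts, resolve_group(groups$gamma$e, top), e0)
  all_pts <- fix_group(all_pts, resolve_group(groups$gamma$hinge, top), h)
  all_pts <- fix_group(all_pts, resolve_group(groups$gamma$d, top), d)
  ca_trajectory(as.vector(t(all_pts)), top)
}
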