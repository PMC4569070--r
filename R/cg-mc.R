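#' Rectangular binning of the single-hinge (gamma, phi) plane
#'
#' Default: 3 gamma bins with edges 60/100/140/180 degrees by 4 phi bins of 90
#' degrees, the 12-bin discretization used to index adsorbed conformations by
#' the bins of their two hinges.
#'
#' @param gamma_edges strictly increasing bin edges for gamma (degrees).
#' @param phi_edges strictly increasing bin edges for phi (degrees).
#' @return object of class `bin_grid` with `n_bins = (gamma bins) * (phi
#'   bins)`; bins are numbered gamma-major: bin = (gamma bin - 1) * n_phi +
#'   phi bin.
#' @export
bin_grid <- function(gamma_edges = c(60, 100, 140, 180),
                     phi_edges = seq(-180, 180, by = 90)) {
  if (any(diff(gamma_edges) <= 0) || any(diff(phi_edges) <= 0)) {
    stop("bin edges must be strictly increasing", call. = FALSE)
  }
  structure(list(gamma_edges = gamma_edges, phi_edges = phi_edges,
                 n_gamma = length(gamma_edges) - 1L,
                 n_phi = length(phi_edges) - 1L,
                 n_bins = (length(gamma_edges) - 1L) * (length(phi_edges) - 1L)),
            class = "bin_grid")
}

#' @export
print.bin_grid <- function(x, ...) {
  cat(sprintf("<bin_grid> %d gamma x %d phi = %d bins; gamma edges %s; phi edges %s\n",
              x$n_gamma, x$n_phi, x$n_bins,
              paste(x$gamma_edges, collapse = "/"),
              paste(x$phi_edges, collapse = "/")))
  invisible(x)
}

#' Bin index of (gamma, phi) pairs
#'
#' Intervals are left-open, right-closed (`60 < gamma <= 100` style), with the
#' lowest edge included.
#'
#' @param gamma,phi numeric vectors (degrees).
#' @param grid a [bin_grid()].
#' @return integer bin indices (`NA` outside the grid).
#' @export
bin_index <- function(gamma, phi, grid) {
  gi <- findInterval(gamma, grid$gamma_edges, left.open = TRUE, rightmost.closed = FALSE)
  gi[gamma == grid$gamma_edges[1]] <- 1L
  gi[gi < 1 | gi > grid$n_gamma] <- NA_integer_
  pi_ <- findInterval(phi, grid$phi_edges, left.open = TRUE, rightmost.closed = FALSE)
  pi_[phi == grid$phi_edges[1]] <- 1L
  pi_[pi_ < 1 | pi_ > grid$n_phi] <- NA_integer_
  (gi - 1L) * grid$n_phi + pi_
}

# Internal: gamma/phi ranges of one bin.
bin_ranges <- function(bin, grid) {
  gi <- (bin - 1L) %/% grid$n_phi + 1L
  pi_ <- (bin - 1L) %% grid$n_phi + 1L
  list(gamma = grid$gamma_edges[c(gi, gi + 1L)], phi = grid$phi_edges[c(pi_, pi_ + 1L)])
}

wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x <= -180] <- x[x <= -180] + 360
  x
}

#' Monte Carlo generation of adsorbed coarse-grained conformations
#'
#' Creates adsorbed conformations by drawing the first hinge's (gamma1, phi1),
#' rolling the molecule about the (surface-parallel) rod axis so that the E
#' sphere and the first D sphere touch the surface, drawing gamma2, and
#' solving the second torsion phi2 so that the second D sphere also touches.
#' Contact means sphere-center height equals the sphere radius; both contact
#' equations reduce to a `cos(angle) = (r_D - r_E) / (arm * sin gamma)` form
#' whose two roots are chosen uniformly at random. Draws are stratified over
#' ordered bin pairs of the grid so that the accepted per-hinge (gamma, phi)
#' bin occupancy is uniform across bins that admit adsorption; (gamma, phi)
#' are uniform within each stratum. Bin pairs whose quota cannot be filled
#' within the attempt budget are reported as starved (non-adsorbing).
#'
#' @param n total number of conformations to generate.
#' @param geometry a [cg_geometry()]; requires `r_e < h_max` and
#'   `r_d < h_max` so contact conformations are adsorbed.
#' @param grid a [bin_grid()].
#' @param seed integer seed; the sample set is a deterministic function of
#'   `(n, geometry, grid, seed)`.
#' @param attempt_budget multiplier: at most `attempt_budget * quota` raw
#'   draws per bin pair before declaring it starved.
#' @return data.frame of class `cg_samples` with columns `gamma1`, `phi1`,
#'   `gamma2`, `phi2`, `roll`, `alpha`, `bin1`, `bin2`; attributes `grid`,
#'   `geometry`, `starved` (integer matrix of starved pairs, 0 rows if none).
#' @export
mc_generate <- function(n, geometry = fg_default_geometry(), grid = bin_grid(),
                        seed = 1, attempt_budget = 1000) {
  if (geometry$r_e >= geometry$h_max || geometry$r_d >= geometry$h_max) {
    stop("geometry admits no adsorbed contact conformations (h_max <= a sphere radius)",
         call. = FALSE)
  }
  set.seed(seed)
  k_of <- function(gamma) {
    (geometry$r_d - geometry$r_e) / (geometry$arm * sin(gamma * pi / 180))
  }
  nb <- grid$n_bins
  pairs <- expand.grid(i = seq_len(nb), j = seq_len(nb))
  quota <- if (n > 0) ceiling(n / nrow(pairs)) else 0
  res <- vector("list", nrow(pairs))
  starved <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  if (n > 0) {
    for (p in seq_len(nrow(pairs))) {
      i <- pairs$i[p]; j <- pairs$j[p]
      ri <- bin_ranges(i, grid); rj <- bin_ranges(j, grid)
      got <- list(); n_got <- 0L; attempts <- 0L
      while (n_got < quota && attempts < attempt_budget * quota) {
        m <- max(4L * (quota - n_got), 256L)
        attempts <- attempts + m
        g1 <- stats::runif(m, ri$gamma[1], ri$gamma[2])
        p1 <- stats::runif(m, ri$phi[1], ri$phi[2])
        g2 <- stats::runif(m, rj$gamma[1], rj$gamma[2])
        k1 <- k_of(g1); k2 <- k_of(g2)
        ok <- abs(k1) <= 1 & abs(k2) <= 1
        s1 <- sample(c(-1, 1), m, replace = TRUE)
        s2 <- sample(c(-1, 1), m, replace = TRUE)
        # contact heights: z(D1) = r_E + arm sin(g1) cos(p1 - chi),
        #                  z(D2) = r_E + arm sin(g2) cos(p2 + chi)
        chi <- p1 + s1 * acos(pmin(pmax(k1, -1), 1)) * 180 / pi
        p2 <- wrap_angle(-chi + s2 * acos(pmin(pmax(k2, -1), 1)) * 180 / pi)
        in_j <- p2 > rj$phi[1] & p2 <= rj$phi[2]
        if (rj$phi[1] == grid$phi_edges[1]) in_j <- in_j | p2 == rj$phi[1]
        keep <- which(ok & in_j)
        if (length(keep)) {
          keep <- keep[seq_len(min(length(keep), quota - n_got))]
          got[[length(got) + 1L]] <- data.frame(gamma1 = g1[keep], phi1 = p1[keep],
                                                gamma2 = g2[keep], phi2 = p2[keep],
                                                roll = wrap_angle(chi[keep]))
          n_got <- n_got + length(keep)
        }
      }
      if (n_got < quota) starved <- rbind(starved, c(i, j))
      if (n_got > 0) {
        df <- do.call(rbind, got)
        df$bin1 <- i; df$bin2 <- j
        res[[p]] <- df
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else NULL
  if (is.null(out)) {
    out <- data.frame(gamma1 = numeric(0), phi1 = numeric(0), gamma2 = numeric(0),
                      phi2 = numeric(0), roll = numeric(0), alpha = numeric(0),
                      bin1 = integer(0), bin2 = integer(0))
  } else {
    out$alpha <- alpha_from_angles(out$gamma1, out$phi1 - out$roll,
                                   out$gamma2, out$phi2 + out$roll, geometry)
    out <- out[, c("gamma1", "phi1", "gamma2", "phi2", "roll", "alpha", "bin1", "bin2")]
    rownames(out) <- NULL
  }
  if (nrow(starved) > 0) {
    warning(sprintf("%d bin pair(s) starved (no adsorbing conformations found): %s",
                    nrow(starved),
                    paste(apply(starved, 1, paste, collapse = "-"), collapse = ", ")))
  }
  attr(out, "grid") <- grid
  attr(out, "geometry") <- geometry
  attr(out, "starved") <- starved
  class(out) <- c("cg_samples", "data.frame")
  out
}

# Internal, vectorized: projected alpha angle from lab-frame hinge angles
# (torsions already combined with the roll). From the embedding:
#   D1 - E = (-L + arm cos g1,  arm sin g1 sin(a1), .)
#   D2 - E = ( L - arm cos g2, -arm sin g2 sin(a2), .)
# with a1 = phi1 - roll, a2 = phi2 + roll; alpha is the planar angle at E.
alpha_from_angles <- function(gamma1, a1, gamma2, a2, geometry) {
  g1 <- gamma1 * pi / 180; g2 <- gamma2 * pi / 180
  t1 <- a1 * pi / 180; t2 <- a2 * pi / 180
  v1 <- cbind(-geometry$rod_half + geometry$arm * cos(g1),
              geometry$arm * sin(g1) * sin(t1))
  v2 <- cbind(geometry$rod_half - geometry$arm * cos(g2),
              -geometry$arm * sin(g2) * sin(t2))
  dt <- rowSums(v1 * v2)
  cr <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  atan2(abs(cr), dt) * 180 / pi
}

#' Conditional alpha-angle distributions per bin pair
#'
#' Splits the Monte Carlo samples by the (unordered) bin pair of their two
#' hinges and histograms alpha within each pair. Histograms are symmetrized
#' (`P_ij = P_ji`) and normalized to sum to 1; pairs with no samples are
#' masked as non-adsorbing.
#'
#' @param samples a `cg_samples` data.frame from [mc_generate()].
#' @param grid a [bin_grid()] (default: the one stored in `samples`).
#' @param alpha_edges histogram edges for alpha, default 5-degree bins over
#'   `[0, 180]`.
#' @return object of class `pij_table`: list with `hist` (n_bins x n_bins x
#'   n_alpha array of normalized histograms), `counts` (samples per ordered
#'   pair, symmetrized), `mask` (logical matrix, TRUE = non-adsorbing pair),
#'   `alpha_edges`, `alpha_mids`, `grid`.
#' @export
bin_pij <- function(samples, grid = attr(samples, "grid"),
                    alpha_edges = seq(0, 180, by = 5)) {
  if (nrow(samples) == 0) stop("empty sample set", call. = FALSE)
  nb <- grid$n_bins
  na <- length(alpha_edges) - 1L
  ai <- findInterval(samples$alpha, alpha_edges, left.open = TRUE)
  ai[samples$alpha == alpha_edges[1]] <- 1L
  ok <- !is.na(ai) & ai >= 1 & ai <= na
  idx <- (samples$bin1[ok] - 1L) * nb * na + (samples$bin2[ok] - 1L) * na + ai[ok]
  counts3 <- array(tabulate(idx, nbins = nb * nb * na), dim = c(na, nb, nb))
  # dims above are [alpha, j, i] given the index arithmetic; rearrange
  counts3 <- aperm(counts3, c(3, 2, 1))
  # symmetrize over the ordered pair
  counts3 <- counts3 + aperm(counts3, c(2, 1, 3))
  counts <- apply(counts3, c(1, 2), sum)
  mask <- counts == 0
  hist <- counts3
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (!mask[i, j]) hist[i, j, ] <- counts3[i, j, ] / counts[i, j]
  }
  if (all(apply(counts3, 3, sum) == 0)) {
    warning("degenerate binning: all alpha bins empty")
  }
  structure(list(hist = hist, counts = counts, mask = mask,
                 alpha_edges = alpha_edges,
                 alpha_mids = (alpha_edges[-1] + alpha_edges[-length(alpha_edges)]) / 2,
                 grid = grid),
            class = "pij_table")
}

#' @export
print.pij_table <- function(x, ...) {
  cat(sprintf("<pij_table> %d x %d bin pairs (%d adsorbing), %d alpha bins, %d samples\n",
              nrow(x$mask), ncol(x$mask), sum(!x$mask & upper.tri(x$mask, diag = TRUE)),
              length(x$alpha_mids), round(sum(x$counts) / 2)))
  invisible(x)
}

#' Single-hinge bin occupancy of a Monte Carlo sample set
#'
#' Pools both hinges and counts accepted samples per (gamma, phi) bin; under
#' stratified acceptance the occupancy is uniform over admitting bins.
#'
#' @param samples a `cg_samples` data.frame.
#' @param grid a [bin_grid()] (default: stored).
#' @return integer vector of per-bin counts (length `grid$n_bins`).
#' @export
hinge_occupancy <- function(samples, grid = attr(samples, "grid")) {
  tabulate(c(samples$bin1, samples$bin2), nbins = grid$n_bins)
}
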