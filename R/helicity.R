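#' Backbone phi/psi dihedrals along a trajectory
#'
#' Computes per-residue backbone dihedrals from N, CA, C atoms:
#' `phi(i) = C(i-1)-N(i)-CA(i)-C(i)` and `psi(i) = N(i)-CA(i)-C(i)-N(i+1)`.
#' Chain termini, where a neighbour is missing, are `NA`.
#'
#' @param traj a [ca_trajectory()] whose topology contains `N`, `CA` and `C`
#'   atoms (column `elety`).
#' @param residues optional data.frame of `(chain, resno)` restricting the
#'   residues analysed; default all residues with a complete backbone.
#' @return list with `phi` and `psi`: frames x residues matrices (degrees),
#'   plus `residues`, the `(chain, resno)` table of analysed residues.
#' @export
backbone_phi_psi <- function(traj, residues = NULL) {
  top <- traj$top
  key <- paste(top$chain, top$resno)
  res <- unique(data.frame(chain = top$chain, resno = top$resno,
                           stringsAsFactors = FALSE))
  if (!is.null(residues)) {
    res <- merge(res, residues, by = c("chain", "resno"))
    res <- res[order(res$chain, res$resno), ]
    if (nrow(res) == 0) {
      stop("no requested residue is present in the topology", call. = FALSE)
    }
  }
  find_atom <- function(ch, rn, ele) {
    i <- which(top$chain == ch & top$resno == rn & top$elety == ele)
    if (length(i) == 1) i else NA_integer_
  }
  nf <- n_frames(traj)
  phi <- psi <- matrix(NA_real_, nf, nrow(res))
  pts <- function(i) traj$xyz[, c(3 * i - 2, 3 * i - 1, 3 * i), drop = FALSE]
  for (r in seq_len(nrow(res))) {
    ch <- res$chain[r]; rn <- res$resno[r]
    iN <- find_atom(ch, rn, "N"); iCA <- find_atom(ch, rn, "CA"); iC <- find_atom(ch, rn, "C")
    if (is.na(iN) || is.na(iCA) || is.na(iC)) {
      stop(sprintf("residue %s %d lacks a complete N/CA/C backbone", ch, rn), call. = FALSE)
    }
    iCprev <- find_atom(ch, rn - 1L, "C")
    iNnext <- find_atom(ch, rn + 1L, "N")
    if (!is.na(iCprev)) {
      phi[, r] <- dihedral_at(pts(iCprev), pts(iN), pts(iCA), pts(iC))
    }
    if (!is.na(iNnext)) {
      psi[, r] <- dihedral_at(pts(iN), pts(iCA), pts(iC), pts(iNnext))
    }
  }
  list(phi = phi, psi = psi, residues = res)
}

#' Alpha-helical region of the Ramachandran plane
#'
#' A residue is called helical in a frame when its backbone dihedrals fall in
#' the alpha-helical basin: `phi` in `(-100, -30)` and `psi` in `(-80, -5)`
#' degrees. The boundaries are exposed so the assignment can be tightened or
#' relaxed.
#'
#' @param phi,psi numeric (matrices or vectors) of backbone dihedrals, degrees.
#' @param phi_range,psi_range basin boundaries, degrees.
#' @return logical of the same shape (`NA` where a dihedral is `NA`).
#' @export
is_helical <- function(phi, psi, phi_range = c(-100, -30), psi_range = c(-80, -5)) {
  phi > phi_range[1] & phi < phi_range[2] & psi > psi_range[1] & psi < psi_range[2]
}

#' Per-frame helical fraction over a residue window
#'
#' Fraction of the residues in a stated window that are alpha-helical in each
#' frame; for the plasmin-cleavage-site analysis the window is the three
#' residues preceding and following each site.
#'
#' @param traj a backbone [ca_trajectory()].
#' @param residues data.frame of `(chain, resno)` forming the window.
#' @param ... passed to [is_helical()].
#' @return numeric vector in `[0, 1]`, one value per frame.
#' @export
helical_fraction <- function(traj, residues, ...) {
  bb <- backbone_phi_psi(traj, residues = residues)
  h <- is_helical(bb$phi, bb$psi, ...)
  rowMeans(h, na.rm = TRUE)
}

#' Joint distribution of helical fraction and bending angle
#'
#' Bins a per-frame helical-fraction series against the per-frame bending
#' angle gamma and returns the joint probability table (normalized to 1).
#' The construction used to show that stronger hinge bending disrupts the
#' helix around the plasmin cleavage sites.
#'
#' @param gamma per-frame bending angle, degrees.
#' @param helicity per-frame helical fraction in `[0, 1]`.
#' @param gamma_breaks bin edges for gamma, default 10-degree steps over
#'   `[60, 180]`.
#' @param helicity_breaks bin edges for the helical fraction, default 0.1
#'   steps over `[0, 1]`.
#' @return matrix (gamma bins x helicity bins) of probabilities summing to 1,
#'   with `dimnames` giving the bin intervals.
#' @export
helicity_vs_bending <- function(gamma, helicity,
                                gamma_breaks = seq(60, 180, by = 10),
                                helicity_breaks = seq(0, 1, by = 0.1)) {
  if (length(gamma) != length(helicity)) {
    stop("gamma and helicity series lengths differ", call. = FALSE)
  }
  gi <- cut(gamma, gamma_breaks, include.lowest = TRUE)
  hi <- cut(helicity, helicity_breaks, include.lowest = TRUE)
  keep <- !is.na(gi) & !is.na(hi)
  if (!any(keep)) stop("no frames fall inside the binning ranges", call. = FALSE)
  tab <- table(gamma = gi[keep], helicity = hi[keep])
  tab / sum(tab)
}
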