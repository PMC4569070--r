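#' C-alpha topology table
#'
#' A minimal atom table describing the columns of a coordinate matrix: one row
#' per atom, in atom order. Chain identifiers and residue numbers follow the
#' 1-based, inclusive numbering convention of the fibrinogen literature
#' (chains A-alpha, B-beta, gamma).
#'
#' @param chain character vector of chain identifiers, one per atom.
#' @param resno integer vector of residue numbers, one per atom.
#' @param elety atom-name vector (defaults to `"CA"` for every atom).
#' @return A `data.frame` of class `fib_topology` with columns `chain`,
#'   `resno`, `elety`.
#' @export
ca_topology <- function(chain, resno, elety = "CA") {
  if (length(chain) == 1L) chain <- rep(chain, length(resno))
  if (length(chain) != length(resno)) {
    stop("`chain` and `resno` must have the same length", call. = FALSE)
  }
  elety <- rep_len(elety, length(chain))
  top <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                    elety = as.character(elety), stringsAsFactors = FALSE)
  class(top) <- c("fib_topology", "data.frame")
  top
}

#' Build a topology from a bio3d PDB object
#'
#' Selects atoms (C-alpha by default) from a `bio3d` PDB object and returns the
#' corresponding [ca_topology()] together with the atom indices used.
#'
#' @param pdb a `bio3d` `pdb` object as returned by [bio3d::read.pdb()].
#' @param selection a `bio3d` selection string passed to [bio3d::atom.select()],
#'   default `"calpha"`.
#' @return list with `top` (the topology) and `inds` (the bio3d selection).
#' @export
topology_from_pdb <- function(pdb, selection = "calpha") {
  inds <- bio3d::atom.select(pdb, string = selection, verbose = FALSE)
  at <- pdb$atom[inds$atom, ]
  list(top = ca_topology(at$chain, at$resno, at$elety), inds = inds)
}

#' C-alpha coordinate trajectory
#'
#' Couples a frames-by-coordinates matrix (bio3d layout: columns
#' `x1, y1, z1, x2, ...`) with its topology. Coordinates are in Angstrom, the
#' convention of PDB/DCD files; the coarse-grained adsorption model uses nm and
#' says so in its own documentation.
#'
#' @param xyz numeric matrix, one row per frame, `3 * nrow(top)` columns.
#'   A bare vector is treated as a single frame.
#' @param top a [ca_topology()].
#' @return An object of class `fib_traj`: list with elements `xyz` and `top`.
#' @export
ca_trajectory <- function(xyz, top) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(top)) {
    stop(sprintf("coordinate matrix has %d columns but topology has %d atoms (expected %d columns)",
                 ncol(xyz), nrow(top), 3L * nrow(top)), call. = FALSE)
  }
  structure(list(xyz = xyz, top = top), class = "fib_traj")
}

#' @export
print.fib_traj <- function(x, ...) {
  cat(sprintf("<fib_traj> %d frames, %d atoms, chains: %s\n",
              nrow(x$xyz), nrow(x$top),
              paste(unique(x$top$chain), collapse = " ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `fib_traj`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Read a C-alpha trajectory from PDB (+ optional DCD) files
#'
#' The PDB supplies the topology (and, for a multi-model PDB, the frames); a
#' DCD file, when given, supplies the frames instead. Reading is delegated to
#' bio3d.
#'
#' @param pdb_file path to a PDB file.
#' @param dcd_file optional path to a DCD trajectory matching the PDB topology.
#' @param selection bio3d selection string, default `"calpha"`.
#' @return a [ca_trajectory()].
#' @export
read_ca_trajectory <- function(pdb_file, dcd_file = NULL, selection = "calpha") {
  pdb <- bio3d::read.pdb(pdb_file, multi = TRUE)
  sel <- topology_from_pdb(pdb, selection)
  if (is.null(dcd_file)) {
    xyz <- pdb$xyz[, sel$inds$xyz, drop = FALSE]
  } else {
    full <- bio3d::read.dcd(dcd_file, verbose = FALSE)
    if (ncol(full) != ncol(pdb$xyz)) {
      stop("DCD frame size does not match the PDB topology", call. = FALSE)
    }
    xyz <- full[, sel$inds$xyz, drop = FALSE]
  }
  ca_trajectory(xyz, sel$top)
}

# Internal: reshape one xyz row-vector to an N x 3 matrix.
xyz_to_mat <- function(v) matrix(v, ncol = 3, byrow = TRUE)

# Internal: columns of the xyz matrix belonging to 1-based atom indices.
xyz_cols <- function(atom_inds) {
  as.vector(rbind(3L * atom_inds - 2L, 3L * atom_inds - 1L, 3L * atom_inds))
}
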