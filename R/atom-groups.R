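#' Define a named atom group by chain/residue ranges
#'
#' An atom group is a set of residues used to compute a single representative
#' point (centroid). Groups are specified as `(chain, residue-range)` pairs in
#' the 1-based inclusive numbering of the structure, e.g. the fibrinogen
#' E-region group is alpha 50-58 + beta 82-90 + gamma 23-31.
#'
#' @param label short name for the group.
#' @param ... named residue-number vectors; names are chain identifiers, e.g.
#'   `atom_group("E", A = 50:58, B = 82:90, C = 23:31)`.
#' @return object of class `atom_group`: list with `label` and a `selections`
#'   data.frame of `(chain, resno)` rows.
#' @export
atom_group <- function(label, ...) {
  sels <- list(...)
  if (length(sels) == 0 || is.null(names(sels)) || any(!nzchar(names(sels)))) {
    stop("atom_group() needs named residue ranges, e.g. A = 50:58", call. = FALSE)
  }
  if (any(lengths(sels) == 0)) {
    stop(sprintf("atom group '%s': empty residue range", label), call. = FALSE)
  }
  selections <- do.call(rbind, lapply(seq_along(sels), function(i) {
    data.frame(chain = names(sels)[i], resno = as.integer(sels[[i]]),
               stringsAsFactors = FALSE)
  }))
  structure(list(label = label, selections = selections), class = "atom_group")
}

#' @export
print.atom_group <- function(x, ...) {
  rng <- vapply(split(x$selections$resno, x$selections$chain), function(r) {
    sprintf("%d-%d", min(r), max(r))
  }, character(1))
  cat(sprintf("<atom_group> %s: %s\n", x$label,
              paste(names(rng), rng, sep = " ", collapse = ", ")))
  invisible(x)
}

#' Resolve an atom group to atom indices in a topology
#'
#' @param group an [atom_group()].
#' @param top a [ca_topology()].
#' @param elety atom names to keep, default `"CA"`; `NULL` keeps all.
#' @return integer vector of atom indices (rows of `top`).
#' @export
resolve_group <- function(group, top, elety = "CA") {
  key_top <- paste(top$chain, top$resno)
  if (!is.null(elety)) {
    keep <- top$elety %in% elety
  } else {
    keep <- rep(TRUE, nrow(top))
  }
  key_sel <- paste(group$selections$chain, group$selections$resno)
  hit <- keep & (key_top %in% key_sel)
  # fail loudly per selection: every (chain, range) must resolve to >= 1 atom
  by_chain <- split(group$selections$resno, group$selections$chain)
  for (ch in names(by_chain)) {
    found <- any(hit & top$chain == ch)
    if (!found) {
      r <- by_chain[[ch]]
      stop(sprintf("atom group '%s': selection chain %s %d-%d matches no atom",
                   group$label, ch, min(r), max(r)), call. = FALSE)
    }
  }
  which(hit)
}

#' Centroid of an atom group
#'
#' Unweighted mean of the selected C-alpha coordinates, per frame.
#'
#' @param traj a [ca_trajectory()], or a bare xyz matrix plus `top`.
#' @param group an [atom_group()].
#' @param top topology (only needed when `traj` is a bare matrix).
#' @return n x 3 matrix of centroid coordinates (one row per frame).
#' @export
group_centroid <- function(traj, group, top = NULL) {
  if (inherits(traj, "fib_traj")) {
    xyz <- traj$xyz
    top <- traj$top
  } else {
    xyz <- as_xyz_matrix(traj)
    if (is.null(top)) stop("`top` is required with a bare coordinate matrix", call. = FALSE)
  }
  inds <- resolve_group(group, top)
  xs <- xyz[, 3 * inds - 2, drop = FALSE]
  ys <- xyz[, 3 * inds - 1, drop = FALSE]
  zs <- xyz[, 3 * inds, drop = FALSE]
  cbind(rowMeans(xs), rowMeans(ys), rowMeans(zs))
}

as_xyz_matrix <- function(xyz) {
  if (is.null(dim(xyz))) matrix(xyz, nrow = 1) else as.matrix(xyz)
}

#' Fibrinogen hinge atom groups
#'
#' The group definitions used to measure the bending angle gamma (three
#' groups: E region, hinge region, D region) and the torsion angle phi (four
#' groups: two E sub-groups, hinge, D) of one fibrinogen protomer. Residue
#' ranges: E = alpha 50-58, beta 82-90, gamma 23-31; hinge = alpha 99-110,
#' beta 130-155, gamma 70-100; D = beta 200-458, gamma 140-394. The two phi
#' E sub-groups are (alpha 50-58 + gamma 23-31) and (beta 82-90 + gamma
#' 23-31); the shared gamma 23-31 stretch is intentional.
#'
#' @param chains named character vector mapping the three fibrinogen chains to
#'   chain identifiers in the structure; default `c(alpha = "A", beta = "B",
#'   gamma = "C")` as in PDB entry 3GHG (first protomer).
#' @return list with elements `gamma` (list of 3 [atom_group()]s: `e`,
#'   `hinge`, `d`) and `phi` (list of 4: `e1`, `e2`, `hinge`, `d`).
#' @export
fg_atom_groups <- function(chains = c(alpha = "A", beta = "B", gamma = "C")) {
  a <- chains[["alpha"]]; b <- chains[["beta"]]; g <- chains[["gamma"]]
  grp <- function(label, ...) {
    args <- list(...)
    names(args) <- vapply(names(args), function(nm) chains[[nm]], character(1))
    do.call(atom_group, c(list(label = label), args))
  }
  list(
    gamma = list(
      e     = grp("E region", alpha = 50:58, beta = 82:90, gamma = 23:31),
      hinge = grp("hinge region", alpha = 99:110, beta = 130:155, gamma = 70:100),
      d     = grp("D region", beta = 200:458, gamma = 140:394)
    ),
    phi = list(
      e1    = grp("E region part 1", alpha = 50:58, gamma = 23:31),
      e2    = grp("E region part 2", beta = 82:90, gamma = 23:31),
      hinge = grp("hinge region", alpha = 99:110, beta = 130:155, gamma = 70:100),
      d     = grp("D region", beta = 200:458, gamma = 140:394)
    )
  )
}
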