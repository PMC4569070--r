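#' Linear mutual information between residue fluctuations
#'
#' For each residue pair, the linear (Gaussian) mutual information of the two
#' C-alpha position fluctuations:
#' `LMI(i, j) = (ln det C_i + ln det C_j - ln det C_ij) / 2` (nats), where
#' `C_i` is the mean-subtracted 3x3 covariance of residue i and `C_ij` the
#' joint 6x6 covariance. Zero for independent residues; diverges as the two
#' motions become deterministically related.
#'
#' @param traj a [ca_trajectory()] or bare xyz matrix (frames x 3N).
#' @param superpose remove rigid-body motion first (default TRUE); set FALSE
#'   for synthetic fluctuations drawn in a fixed frame.
#' @param fit_atoms atom subset for the superposition fit.
#' @param min_frames_factor minimum frames required, as a multiple of the 6
#'   joint dimensions (default 10).
#' @return object of class `lmi_matrix`: list with `lmi` (R x R symmetric
#'   matrix, nats, `NA` diagonal, `Inf` marks singular pairs), `logdet`
#'   (per-residue log-determinants), `cov` (3R x 3R covariance),
#'   `residues` (chain/resno labels), `infinite_pairs`.
#' @export
lmi_matrix <- function(traj, superpose = TRUE, fit_atoms = NULL,
                       min_frames_factor = 10) {
  if (inherits(traj, "fib_traj")) {
    xyz <- traj$xyz
    labels <- paste(traj$top$chain, traj$top$resno, sep = "_")
  } else {
    xyz <- as.matrix(traj)
    labels <- paste0("res_", seq_len(ncol(xyz) / 3))
  }
  nr <- ncol(xyz) / 3
  if (nrow(xyz) < min_frames_factor * 6) {
    stop(sprintf("need at least %d frames for stable 6x6 covariances (got %d)",
                 min_frames_factor * 6, nrow(xyz)), call. = FALSE)
  }
  if (superpose) xyz <- superpose_trajectory(xyz, fit_atoms = fit_atoms)
  cv <- stats::cov(xyz)
  block <- function(i) (3 * i - 2):(3 * i)
  ld <- vapply(seq_len(nr), function(i) {
    d <- determinant(cv[block(i), block(i)], logarithm = TRUE)
    if (d$sign <= 0) -Inf else as.numeric(d$modulus)
  }, numeric(1))
  lmi <- matrix(NA_real_, nr, nr, dimnames = list(labels, labels))
  inf_pairs <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j")))
  for (i in seq_len(nr - 1)) {
    bi <- block(i)
    for (j in (i + 1):nr) {
      idx <- c(bi, block(j))
      m6 <- cv[idx, idx]
      d <- determinant(m6, logarithm = TRUE)
      if (d$sign <= 0 || !is.finite(as.numeric(d$modulus)) ||
          !is.finite(ld[i]) || !is.finite(ld[j]) || kappa(m6) > 1e12) {
        lmi[i, j] <- lmi[j, i] <- Inf
        inf_pairs <- rbind(inf_pairs, c(i, j))
      } else {
        val <- 0.5 * (ld[i] + ld[j] - as.numeric(d$modulus))
        lmi[i, j] <- lmi[j, i] <- max(val, 0)
      }
    }
  }
  if (nrow(inf_pairs) > 0) {
    warning(sprintf("%d residue pair(s) have singular joint covariance (deterministically coupled); flagged infinite and excluded from networks",
                    nrow(inf_pairs)))
  }
  structure(list(lmi = lmi, logdet = ld, cov = cv, residues = labels,
                 infinite_pairs = inf_pairs),
            class = "lmi_matrix")
}

#' @export
print.lmi_matrix <- function(x, ...) {
  v <- x$lmi[upper.tri(x$lmi)]
  v <- v[is.finite(v)]
  cat(sprintf("<lmi_matrix> %d residues; finite LMI range %.3f-%.3f nats; %d singular pairs\n",
              length(x$residues), min(v), max(v), nrow(x$infinite_pairs)))
  invisible(x)
}

#' Correlation network from an LMI matrix
#'
#' Undirected, unweighted residue graph with an edge wherever the pair's LMI
#' exceeds the threshold `r_crit`. Singular (infinite-LMI) pairs are excluded.
#'
#' @param lmi an [lmi_matrix()] (or a bare symmetric matrix).
#' @param r_crit positive LMI threshold.
#' @return an [igraph::graph] with one vertex per residue (named).
#' @export
build_network <- function(lmi, r_crit) {
  if (r_crit <= 0) stop("r_crit must be positive", call. = FALSE)
  m <- if (inherits(lmi, "lmi_matrix")) lmi$lmi else as.matrix(lmi)
  adj <- !is.na(m) & is.finite(m) & m > r_crit
  diag(adj) <- FALSE
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Maximum pathway length implied by the threshold
#'
#' Pathways are truncated at the largest integer number of edges `N` with
#' `r_crit^N > p_min` (default floor 0.025): links are only trusted while the
#' compounded correlation stays above the floor.
#'
#' @param r_crit LMI threshold (must be below 1 for a finite bound).
#' @param p_min compounded-correlation floor.
#' @return integer maximum path length in edges (`Inf` when `r_crit >= 1`).
#' @export
max_pathway_length <- function(r_crit, p_min = 0.025) {
  if (r_crit >= 1) return(Inf)
  n <- floor(log(p_min) / log(r_crit))
  # strict inequality: back off if r_crit^n has already hit the floor
  while (n > 0 && r_crit^n <= p_min) n <- n - 1
  n
}
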