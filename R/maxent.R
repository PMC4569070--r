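#' Alpha-angle histogram
#'
#' Experimental-style histogram of the AFM alpha angle: bin edges over
#' `[0, 180]` degrees and non-negative counts.
#'
#' @param edges increasing bin edges (degrees).
#' @param counts counts per bin (`length(edges) - 1`).
#' @return object of class `alpha_histogram` with `edges`, `counts`, `mids`,
#'   `n_tot`.
#' @export
alpha_histogram <- function(edges, counts) {
  if (length(counts) != length(edges) - 1L) {
    stop("need one count per bin (length(edges) - 1)", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(diff(edges) <= 0)) stop("edges must be strictly increasing", call. = FALSE)
  structure(list(edges = edges, counts = as.numeric(counts),
                 mids = (edges[-1] + edges[-length(edges)]) / 2,
                 n_tot = sum(counts)),
            class = "alpha_histogram")
}

#' Single-hinge prior weights for the maximum-entropy fit
#'
#' The prior encodes what the solution simulations say about single-hinge
#' (gamma, phi) bin occupancy before any adsorption data are seen. The pair
#' bias is the product `m_ij = w_i * w_j`, restricted to adsorbing pairs and
#' renormalized.
#'
#' @param w per-bin single-hinge weights (non-negative; normalized
#'   internally over bins that touch at least one adsorbing pair).
#' @param pij a `pij_table` supplying the adsorbing-pair mask.
#' @return object of class `prior_weights`: list with `w` (length n_bins,
#'   normalized) and `m` (n_bins x n_bins matrix, zero on masked pairs,
#'   summing to 1).
#' @export
prior_weights <- function(w, pij) {
  nb <- nrow(pij$mask)
  if (length(w) != nb) stop("prior length must equal the number of grid bins", call. = FALSE)
  if (any(w < 0)) stop("prior weights must be non-negative", call. = FALSE)
  admit <- admitting_bins(pij)
  w <- ifelse(seq_len(nb) %in% admit, w, 0)
  if (sum(w) <= 0) stop("prior has no mass on admitting bins", call. = FALSE)
  w <- w / sum(w)
  m <- outer(w, w)
  m[pij$mask] <- 0
  if (sum(m) <= 0) stop("prior bias has no mass on adsorbing pairs", call. = FALSE)
  m <- m / sum(m)
  structure(list(w = w, m = m), class = "prior_weights")
}

#' Bins that participate in at least one adsorbing pair
#' @param pij a `pij_table`.
#' @return integer vector of bin indices.
#' @export
admitting_bins <- function(pij) which(apply(!pij$mask, 1, any))

# Internal: flatten the histogram array to an (n_bins^2 x n_alpha) matrix.
pij_flat <- function(pij) {
  d <- dim(pij$hist)
  matrix(pij$hist, nrow = d[1] * d[2], ncol = d[3])
}

#' Model alpha distribution, general (correlated-hinge) weights
#'
#' `P(alpha) = sum_ij a_ij P_ij(alpha)`: the discretized general superposition
#' in which each adsorbing bin pair carries its own weight.
#'
#' @param a symmetric n_bins x n_bins weight matrix, zero on masked pairs,
#'   summing to 1 (weight of an unordered pair is split over its two ordered
#'   entries).
#' @param pij a `pij_table`.
#' @return numeric vector: probability per alpha bin, summing to 1.
#' @export
model_alpha_general <- function(a, pij) {
  a <- as.matrix(a)
  if (any(a[pij$mask] != 0)) {
    stop("weight placed on a non-adsorbing (masked) bin pair", call. = FALSE)
  }
  if (abs(sum(a) - 1) > 1e-8) stop("general weights must sum to 1", call. = FALSE)
  drop(crossprod(pij_flat(pij), as.vector(a)))
}

#' Model alpha distribution, independent-hinge weights
#'
#' `P(alpha) proportional to sum_ij a_i a_j P_ij(alpha)` over adsorbing pairs,
#' renormalized over the admissible pair mass: the factorized model in which
#' the two hinges draw their bins independently from the same single-hinge
#' weight vector.
#'
#' @param a_i per-bin single-hinge weights, summing to 1 over admitting bins.
#' @param pij a `pij_table`.
#' @return numeric vector: probability per alpha bin, summing to 1.
#' @export
model_alpha_independent <- function(a_i, pij) {
  nb <- nrow(pij$mask)
  if (length(a_i) != nb) stop("need one weight per grid bin", call. = FALSE)
  if (abs(sum(a_i) - 1) > 1e-8) stop("independent weights must sum to 1", call. = FALSE)
  pair_w <- outer(a_i, a_i)
  pair_w[pij$mask] <- 0
  z <- sum(pair_w)
  if (z <= 0) stop("no weight on adsorbing pairs", call. = FALSE)
  drop(crossprod(pij_flat(pij), as.vector(pair_w))) / z
}

#' Reduced chi-squared between a histogram and a model distribution
#'
#' `chi2 = sum_alpha (N(alpha) - N_tot P(alpha))^2 / (N_tot P(alpha))`,
#' divided by the number of degrees of freedom. The dof convention is
#' configurable; the default counts the alpha bins on which the model puts
#' mass, because the weight models typically carry more free parameters than
#' there are bins, which makes the textbook `bins - parameters - 1` count
#' non-positive.
#'
#' @param hist an [alpha_histogram()] (or a bare counts vector).
#' @param p model probability per alpha bin.
#' @param dof degrees of freedom (default `sum(p > 0)`).
#' @return the reduced chi-squared; `Inf` when the model has zero mass on a
#'   bin with counts.
#' @export
reduced_chi2 <- function(hist, p, dof = NULL) {
  counts <- if (inherits(hist, "alpha_histogram")) hist$counts else as.numeric(hist)
  if (length(counts) != length(p)) stop("histogram and model lengths differ", call. = FALSE)
  n_tot <- sum(counts)
  if (any(p <= 0 & counts > 0)) return(Inf)
  if (is.null(dof)) dof <- sum(p > 0)
  nz <- p > 0
  sum((counts[nz] - n_tot * p[nz])^2 / (n_tot * p[nz])) / dof
}

# Internal: d(chi2_reduced)/dP(alpha). With M = N_tot, per-bin term
# f = (N - M P)^2 / (M P) has df/dP = M - N^2 / (M P^2).
chi2_grad_p <- function(counts, p, dof) {
  n_tot <- sum(counts)
  g <- rep(0, length(p))
  nz <- p > 0
  # floor p so near-empty model bins give a large finite pull, not Inf
  g[nz] <- (n_tot - counts[nz]^2 / (n_tot * pmax(p[nz], 1e-12)^2)) / dof
  pmin(pmax(g, -1e12), 1e12)
}

# Internal: inner solve at fixed lambda. Maximizes the concave dual
# F(a) = -sum a log(a/prior) - lambda * chi2(a) over the probability simplex
# by mirror ascent (multiplicative exponentiated-gradient updates) with
# backtracking line search; the full step (eta = 1) is the entropy
# fixed-point update a <- normalize(prior * exp(-lambda * grad)).
maxent_inner <- function(prior, chi2_fn, grad_fn, lambda, init = prior,
                         tol = 1e-10, max_iter = 5000) {
  clamp_log <- function(a) log(pmax(a, 1e-300))
  obj <- function(a) {
    c2 <- chi2_fn(a)
    if (!is.finite(c2)) return(-Inf)
    -sum(a * (clamp_log(a) - clamp_log(prior))) - lambda * c2
  }
  a <- init / sum(init)
  f <- obj(a)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    g <- -(clamp_log(a) - clamp_log(prior)) - 1 -
      lambda * pmin(pmax(grad_fn(a), -1e12), 1e12)
    eta <- 1
    repeat {
      la <- clamp_log(a) + eta * g
      a_new <- exp(la - max(la))
      a_new <- a_new / sum(a_new)
      f_new <- obj(a_new)
      if (f_new >= f || eta < 1e-12) break
      eta <- eta / 2
    }
    if (f_new < f) break # no ascent direction left: at the optimum
    delta <- max(abs(a_new - a))
    a <- a_new
    f <- f_new
    if (delta < tol) break
  }
  list(a = a, iterations = it, converged = delta < tol, objective = f)
}

# Internal shared driver for both model fits. `free` indexes the free weight
# entries; model_fn(a_free) -> P(alpha); grad_fn(a_free) -> d chi2/d a_free.
maxent_fit_driver <- function(counts, prior_free, model_fn, grad_fn, config) {
  cfg <- list(tol_chi2 = 1e-3, tol_w = 1e-8, max_iter = 5000,
              lambda_max = 1e8, dof = NULL, multi_start = FALSE)
  cfg[names(config)] <- config
  dof <- cfg$dof
  chi2_of <- function(a) reduced_chi2(counts, model_fn(a), dof)
  g_of <- function(a) grad_fn(a, dof)
  prior_free <- prior_free / sum(prior_free)
  chi2_prior <- chi2_of(prior_free)
  iters <- 0L
  # normalization multiplier from the stationarity conditions:
  # a = prior * exp(-lambda g - 1 - alpha_N)  =>  alpha_N = log Z - 1
  norm_mult <- function(a, lambda) {
    log(sum(prior_free * exp(-lambda * (g_of(a) - min(g_of(a)))))) - 1
  }
  if (chi2_prior <= 1) {
    return(list(a = prior_free, lambda = 0, chi2 = chi2_prior,
                norm_multiplier = norm_mult(prior_free, 0),
                converged = TRUE, iterations = 0L))
  }
  # deterministic init battery for the non-convex (factorized) inner
  # problem: the warm start, the prior, and smoothed simplex corners
  first_solve <- TRUE
  inits_for <- function(init) {
    if (!cfg$multi_start || !first_solve) return(list(init))
    k <- length(prior_free)
    corners <- lapply(seq_len(k), function(i) {
      a <- 0.1 * prior_free / sum(prior_free)
      a[i] <- a[i] + 0.9
      a
    })
    c(list(init, prior_free), corners)
  }
  solve_at <- function(lambda, init) {
    best <- NULL
    for (a0 in inits_for(init)) {
      r <- maxent_inner(prior_free, chi2_of, g_of, lambda, init = a0,
                        tol = cfg$tol_w, max_iter = cfg$max_iter)
      if (is.null(best) || r$objective > best$objective) best <- r
    }
    first_solve <<- FALSE
    best$chi2 <- chi2_of(best$a)
    best
  }
  # bracket: chi2(0) > 1, expand lambda until chi2 <= 1 or the family floor
  # is reached (chi2 stops improving)
  lo <- 0; chi2_lo <- chi2_prior
  a_cur <- prior_free
  hi <- 1
  prev_chi2 <- Inf
  repeat {
    r <- solve_at(hi, a_cur); iters <- iters + r$iterations
    a_cur <- r$a
    if (r$chi2 <= 1) break
    # stop expanding only when the fit is both stuck and clearly unable to
    # reach the constraint (the slow tail near chi2 = 1 must keep going)
    plateau <- is.finite(prev_chi2) && r$chi2 > 1.1 &&
      abs(prev_chi2 - r$chi2) / max(r$chi2, 1) < 1e-4
    prev_chi2 <- r$chi2
    if (hi >= cfg$lambda_max || plateau) {
      # constraint unreachable: the weight family cannot fit this histogram
      return(list(a = r$a, lambda = hi, chi2 = r$chi2,
                  norm_multiplier = norm_mult(r$a, hi),
                  converged = FALSE, iterations = iters))
    }
    lo <- hi; chi2_lo <- r$chi2
    hi <- hi * 4
  }
  # bisect for chi2 = 1
  for (b in seq_len(100)) {
    mid <- (lo + hi) / 2
    r <- solve_at(mid, a_cur); iters <- iters + r$iterations
    a_cur <- r$a
    if (abs(r$chi2 - 1) < cfg$tol_chi2) {
      return(list(a = r$a, lambda = mid, chi2 = r$chi2,
                  norm_multiplier = norm_mult(r$a, mid),
                  converged = TRUE, iterations = iters))
    }
    if (r$chi2 > 1) lo <- mid else hi <- mid
  }
  list(a = a_cur, lambda = (lo + hi) / 2, chi2 = chi2_of(a_cur),
       norm_multiplier = norm_mult(a_cur, (lo + hi) / 2),
       converged = abs(chi2_of(a_cur) - 1) < cfg$tol_chi2, iterations = iters)
}

finish_fit <- function(kind, weights, prior_ref, fit, p, counts, dof_used) {
  ent <- -sum(ifelse(weights > 0, weights * log(weights / prior_ref), 0))
  structure(list(model = kind, weights = weights, lambda = fit$lambda,
                 norm_multiplier = fit$norm_multiplier, chi2 = fit$chi2,
                 entropy = ent, converged = fit$converged,
                 iterations = fit$iterations, p_alpha = p,
                 dof = dof_used, n_tot = sum(counts)),
            class = "fib_fit")
}

#' @export
print.fib_fit <- function(x, ...) {
  cat(sprintf("<fib_fit> %s model: reduced chi2 = %.4f (dof %d), lambda = %.3g, entropy = %.4f, %sconverged\n",
              x$model, x$chi2, x$dof, x$lambda, x$entropy,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' Maximum-entropy fit of the general (correlated-hinge) model
#'
#' Maximizes the relative entropy `-sum_ij a_ij log(a_ij / m_ij)` of the pair
#' weights against the simulation-derived bias, subject to normalization and
#' to the reduced chi-squared of the fitted alpha distribution reaching 1.
#' The chi-squared equality is enforced as an inequality: when the prior
#' already fits (`chi2 <= 1`) the prior is returned unchanged; otherwise the
#' Lagrange multiplier `lambda` is raised until `chi2 = 1`. Weights stay
#' positive by the exponential form of the stationarity conditions; the fit
#' is deterministic given its inputs.
#'
#' @param hist an [alpha_histogram()].
#' @param pij a `pij_table`.
#' @param prior a [prior_weights()].
#' @param config optional list overriding `tol_chi2` (1e-3), `tol_w` (1e-8),
#'   `max_iter`, `lambda_max`, `dof`.
#' @return object of class `fib_fit` with the fitted `weights` (n_bins x
#'   n_bins matrix), `lambda`, achieved `chi2`, relative `entropy`,
#'   `converged`, `iterations`, and the fitted distribution `p_alpha`.
#' @export
fit_general <- function(hist, pij, prior, config = list()) {
  check_hist_pij(hist, pij)
  counts <- hist$counts
  free <- which(!pij$mask)
  if (!length(free)) stop("no adsorbing bin pairs to fit", call. = FALSE)
  m_free <- prior$m[free]
  if (any(m_free <= 0)) stop("prior must be positive on adsorbing pairs", call. = FALSE)
  h_free <- pij_flat(pij)[free, , drop = FALSE]
  dof_used <- config$dof
  if (is.null(dof_used)) dof_used <- sum(colSums(h_free) > 0)
  config$dof <- dof_used
  model_fn <- function(a) drop(crossprod(h_free, a))
  grad_fn <- function(a, dof) {
    drop(h_free %*% chi2_grad_p(counts, model_fn(a), dof))
  }
  fit <- maxent_fit_driver(counts, m_free, model_fn, grad_fn, config)
  a_mat <- matrix(0, nrow(pij$mask), ncol(pij$mask))
  a_mat[free] <- fit$a
  a_mat <- (a_mat + t(a_mat)) / 2
  m_ref <- prior$m / sum(prior$m)
  finish_fit("general", a_mat, m_ref, fit,
             model_alpha_general(a_mat, pij), counts, dof_used)
}

#' Maximum-entropy fit of the independent-hinge model
#'
#' As [fit_general()], but the pair weights factorize as `a_i a_j` and the
#' entropy is taken on the single-hinge weights against the single-hinge
#' occupancy prior: `-sum_i a_i log(a_i / w_i)`.
#'
#' @inheritParams fit_general
#' @return a `fib_fit` whose `weights` is the single-hinge vector `a_i`.
#' @export
fit_independent <- function(hist, pij, prior, config = list()) {
  check_hist_pij(hist, pij)
  counts <- hist$counts
  admit <- admitting_bins(pij)
  w_free <- prior$w[admit]
  if (any(w_free <= 0)) stop("prior must be positive on admitting bins", call. = FALSE)
  nb <- nrow(pij$mask)
  hmat <- pij_flat(pij)
  u <- 1 - pij$mask[admit, admit, drop = FALSE] # admissible-pair indicator
  dof_used <- config$dof
  if (is.null(dof_used)) dof_used <- sum(colSums(hmat) > 0)
  config$dof <- dof_used
  expand <- function(a) { full <- rep(0, nb); full[admit] <- a; full }
  model_fn <- function(a) model_alpha_independent(expand(a / sum(a)), pij)
  grad_fn <- function(a, dof) {
    a <- a / sum(a)
    pw <- outer(a, a) * u
    z <- sum(pw)
    full_pw <- matrix(0, nb, nb)
    full_pw[admit, admit] <- pw
    s_alpha <- drop(crossprod(hmat, as.vector(full_pw)))
    p <- s_alpha / z
    gp <- chi2_grad_p(counts, p, dof)
    # dP/da_i = (dS_i - P dZ_i)/Z with dS_i(alpha) = 2 sum_j a_j P_ij(alpha)
    g <- numeric(length(a))
    for (ii in seq_along(a)) {
      rows <- (admit[ii] - 1L) * nb + admit # ordered pairs (i, j), j admitting
      ds <- 2 * drop(crossprod(hmat[rows, , drop = FALSE], a * u[ii, ]))
      dz <- 2 * sum(a * u[ii, ])
      g[ii] <- sum(gp * (ds - p * dz) / z)
    }
    g
  }
  if (is.null(config$multi_start)) config$multi_start <- TRUE
  fit <- maxent_fit_driver(counts, w_free, model_fn, grad_fn, config)
  a_full <- expand(fit$a)
  finish_fit("independent", a_full, expand(w_free / sum(w_free)), fit,
             model_alpha_independent(a_full, pij), counts, dof_used)
}

check_hist_pij <- function(hist, pij) {
  if (!inherits(hist, "alpha_histogram")) stop("`hist` must be an alpha_histogram", call. = FALSE)
  if (length(hist$counts) != length(pij$alpha_mids)) {
    stop("histogram binning does not match the P_ij alpha binning", call. = FALSE)
  }
}

#' Chi-squared confidence threshold for a fit
#'
#' The reduced chi-squared value above which a fit is rejected at the given
#' confidence level for its degrees of freedom (upper-tail test).
#'
#' @param dof degrees of freedom.
#' @param level rejection level, default 0.05.
#' @return reduced chi-squared threshold.
#' @export
chi2_threshold <- function(dof, level = 0.05) {
  stats::qchisq(1 - level, df = dof) / dof
}

#' Mode of the factorized alpha distribution over sampled weight functions
#'
#' The impossibility argument for independent hinges: whatever the
#' single-hinge weight function, the factorized model's alpha distribution
#' peaks at full extension, because both hinges sampling the same weight
#' maximum align the two arms and the 180-degree peak accumulates symmetric
#' contributions on its single tail. This routine evaluates the factorized
#' model for a battery of weight vectors (Dirichlet-random draws plus any
#' explicitly supplied constructions, e.g. symmetric two-peak weights) and
#' reports the modal alpha bin of each.
#'
#' @param pij a `pij_table` from a converged Monte Carlo run.
#' @param n_draws number of Dirichlet(1) random weight draws.
#' @param seed seed for the draws.
#' @param extra_weights optional list of weight vectors (length n_bins) to
#'   include, e.g. two-peak constructions.
#' @return data.frame with one row per weight sample: `draw` (label),
#'   `mode_deg` (alpha-bin center of the maximum), `p_max`.
#' @export
independent_peak_check <- function(pij, n_draws = 100, seed = 1, extra_weights = list()) {
  set.seed(seed)
  nb <- nrow(pij$mask)
  admit <- admitting_bins(pij)
  draws <- list()
  for (d in seq_len(n_draws)) {
    w <- rep(0, nb)
    g <- -log(stats::runif(length(admit))) # Dirichlet(1) via exponentials
    w[admit] <- g / sum(g)
    draws[[paste0("dirichlet_", d)]] <- w
  }
  for (nm in names(extra_weights)) draws[[nm]] <- extra_weights[[nm]]
  if (length(extra_weights) && is.null(names(extra_weights))) {
    names(draws)[n_draws + seq_along(extra_weights)] <- paste0("extra_", seq_along(extra_weights))
  }
  out <- lapply(names(draws), function(nm) {
    p <- model_alpha_independent(draws[[nm]] / sum(draws[[nm]]), pij)
    k <- which.max(p)
    data.frame(draw = nm, mode_deg = pij$alpha_mids[k], p_max = p[k],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Symmetric two-peak single-hinge weight
#'
#' Builds a weight vector with equal mass on two (gamma, phi) bins chosen
#' from different gamma ranges -- the construction showing that even
#' multi-peaked hinge weights produce a factorized alpha distribution peaked
#' at 180 degrees.
#'
#' @param pij a `pij_table`.
#' @param bins optional integer pair of bins; default: two admitting bins in
#'   the lowest and highest gamma rows sharing a phi column.
#' @return weight vector (length n_bins).
#' @export
two_peak_weight <- function(pij, bins = NULL) {
  grid <- pij$grid
  admit <- admitting_bins(pij)
  if (is.null(bins)) {
    rows <- (admit - 1L) %/% grid$n_phi + 1L
    lo <- admit[rows == min(rows)]
    hi <- admit[rows == max(rows)]
    common_phi <- intersect((lo - 1L) %% grid$n_phi, (hi - 1L) %% grid$n_phi)
    if (!length(common_phi)) stop("no shared phi column between extreme gamma rows", call. = FALSE)
    ph <- common_phi[1]
    bins <- c(lo[(lo - 1L) %% grid$n_phi == ph][1], hi[(hi - 1L) %% grid$n_phi == ph][1])
  }
  w <- rep(0, grid$n_bins)
  w[bins] <- 0.5
  w
}
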