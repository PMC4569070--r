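# Weight models, reduced chi-squared, and the maximum-entropy fits.

test_that("the general mixture reproduces its components", {
  pij <- two_pair_pij()
  a <- matrix(0, 2, 2); a[1, 1] <- 1
  expect_equal(model_alpha_general(a, pij), pij$hist[1, 1, ])
  a2 <- matrix(0, 2, 2); a2[1, 1] <- 0.5; a2[2, 2] <- 0.5
  expect_equal(model_alpha_general(a2, pij), (pij$hist[1, 1, ] + pij$hist[2, 2, ]) / 2)
  bad <- matrix(0.25, 2, 2)
  expect_error(model_alpha_general(bad, pij), "masked")
})

test_that("random general weights match a direct weighted sum", {
  pij <- toy_pij()
  set.seed(41)
  a <- matrix(stats::runif(144), 12, 12)
  a <- (a + t(a)) / 2
  a[pij$mask] <- 0
  a <- a / sum(a)
  direct <- rep(0, length(pij$alpha_mids))
  for (i in 1:12) for (j in 1:12) direct <- direct + a[i, j] * pij$hist[i, j, ]
  expect_equal(model_alpha_general(a, pij), direct, tolerance = 1e-12)
})

test_that("the independent model factorizes into the general model", {
  pij <- toy_pij()
  w <- rep(0, 12); w[3] <- 1
  expect_equal(model_alpha_independent(w, pij), pij$hist[3, 3, ])
  # two bins at 0.5/0.5: pair weights 0.25 / 0.5 / 0.25 on (i,i)/(i,j)/(j,j)
  w2 <- rep(0, 12); w2[c(2, 7)] <- 0.5
  byhand <- 0.25 * pij$hist[2, 2, ] + 0.5 * pij$hist[2, 7, ] + 0.25 * pij$hist[7, 7, ]
  expect_equal(model_alpha_independent(w2, pij), byhand)
  # general evaluated at a_ij = a_i a_j (renormalized over unmasked mass)
  set.seed(42)
  w3 <- stats::runif(12); w3 <- w3 / sum(w3)
  pair <- outer(w3, w3); pair[pij$mask] <- 0; pair <- pair / sum(pair)
  expect_equal(model_alpha_independent(w3, pij), model_alpha_general(pair, pij),
               tolerance = 1e-12)
})

test_that("reduced chi-squared follows the printed per-bin formula", {
  # per-bin oracle: N = 10, N_tot = 10, P = 0.5 -> (10 - 5)^2 / 5 = 5
  expect_equal(reduced_chi2(10, 1 * 0.5, dof = 1) * 1, 5)
  # exact model: zero
  p <- c(0.2, 0.3, 0.5)
  expect_equal(reduced_chi2(100 * p, p), 0)
  # homogeneity: doubling all counts doubles the unreduced sum
  n1 <- c(12, 30, 58)
  expect_equal(reduced_chi2(2 * n1, p, dof = 3), 2 * reduced_chi2(n1, p, dof = 3))
  # zero model mass under observed counts signals infinity
  expect_equal(reduced_chi2(c(5, 5, 0), c(0.5, 0, 0.5)), Inf)
})

test_that("relative entropy is non-positive with equality at the prior", {
  pij <- toy_pij()
  pr <- prior_weights(rep(1, 12), pij)
  ent <- function(a, m) -sum(ifelse(a > 0, a * log(a / m), 0))
  expect_equal(ent(pr$m, pr$m), 0)
  set.seed(43)
  for (k in 1:20) {
    a <- matrix(stats::rexp(144), 12, 12); a <- (a + t(a)) / 2
    a[pij$mask] <- 0; a <- a / sum(a)
    expect_lte(ent(a, pr$m), 1e-12)
  }
})

test_that("fits are invariant to uniform prior rescaling and reproducible", {
  pij <- toy_pij()
  h <- gen_alpha_histogram(two_peak_weight(pij), pij, 800, model = "independent",
                           seed = 3)
  f1 <- fit_general(h, pij, prior_weights(rep(1, 12), pij))
  f2 <- fit_general(h, pij, prior_weights(rep(7, 12), pij))
  expect_equal(f1$weights, f2$weights, tolerance = 1e-12)
  f3 <- fit_general(h, pij, prior_weights(rep(1, 12), pij))
  expect_identical(f1$weights, f3$weights)
})

test_that("prior-consistent data returns the prior untouched", {
  pij <- toy_pij()
  pr <- prior_weights(rep(1, 12), pij)
  p0 <- model_alpha_general(pr$m, pij)
  h0 <- alpha_histogram(pij$alpha_edges, round(1e6 * p0))
  f0 <- fit_general(h0, pij, pr)
  expect_equal(f0$weights, pr$m)
  expect_equal(f0$lambda, 0)
  expect_lt(f0$chi2, 1)
})

test_that("the general fit reaches chi2 = 1 and recovers the distribution", {
  pij <- toy_pij()
  a_true <- matrix(0, 12, 12)
  a_true[1, 12] <- a_true[12, 1] <- 0.25
  a_true[2, 9] <- a_true[9, 2] <- 0.15
  a_true[5, 11] <- a_true[11, 5] <- 0.1
  a_true <- a_true / sum(a_true)
  h <- gen_alpha_histogram(a_true, pij, 1000, model = "general", seed = 5)
  fit <- fit_general(h, pij, prior_weights(rep(1, 12), pij))
  expect_true(fit$converged)
  expect_equal(fit$chi2, 1, tolerance = 1e-3)
  # fitted mixture close to the generating one (multinomial noise scale)
  expect_lt(max(abs(fit$p_alpha - attr(h, "p_true"))), 0.03)
})

test_that("two-pair toy fit matches a brute-force one-parameter grid search", {
  pij <- two_pair_pij()
  # data from an uneven mix of the two adsorbing pairs
  a_true <- matrix(0, 2, 2); a_true[1, 1] <- 0.8; a_true[2, 2] <- 0.2
  h <- gen_alpha_histogram(a_true, pij, 600, model = "general", seed = 6)
  pr <- prior_weights(rep(1, 2), pij)
  fit <- fit_general(h, pij, pr)
  # brute force over t = weight of pair (1,1): the dual maximizes
  # J(t) = entropy(t) - lambda (chi2(t) - 1) at the fitted lambda
  ts <- seq(1e-4, 1 - 1e-4, length.out = 20001)
  jval <- vapply(ts, function(t) {
    a <- matrix(0, 2, 2); a[1, 1] <- t; a[2, 2] <- 1 - t
    p <- model_alpha_general(a, pij)
    ent <- -sum(a[a > 0] * log(a[a > 0] / pr$m[a > 0]))
    ent - fit$lambda * (reduced_chi2(h, p, dof = fit$dof) - 1)
  }, numeric(1))
  t_grid <- ts[which.max(jval)]
  expect_equal(fit$weights[1, 1], t_grid, tolerance = 1e-4)
})

test_that("factorized data is fit by the independent model at chi2 <= 1", {
  pij <- toy_pij()
  w_true <- rep(0, 12); w_true[c(3, 7, 10)] <- c(0.5, 0.3, 0.2)
  h <- gen_alpha_histogram(w_true, pij, 1000, model = "independent", seed = 8)
  fit <- fit_independent(h, pij, prior_weights(rep(1, 12), pij))
  expect_true(fit$converged)
  expect_lte(fit$chi2, 1 + 1e-3)
  expect_lt(max(abs(fit$p_alpha - attr(h, "p_true"))), 0.03)
})

test_that("correlated-hinge data defeats the independent model but not the general", {
  pij <- toy_pij()
  a_anti <- matrix(0, 12, 12)
  a_anti[1, 12] <- a_anti[12, 1] <- 0.3
  a_anti[2, 11] <- a_anti[11, 2] <- 0.2
  a_anti <- a_anti / sum(a_anti)
  h <- gen_alpha_histogram(a_anti, pij, 1000, model = "general", seed = 9)
  pr <- prior_weights(rep(1, 12), pij)
  f_ind <- fit_independent(h, pij, pr)
  f_gen <- fit_general(h, pij, pr)
  expect_false(f_ind$converged)
  expect_gt(f_ind$chi2, chi2_threshold(f_ind$dof, 0.05))
  expect_true(f_gen$converged)
  expect_equal(f_gen$chi2, 1, tolerance = 1e-3)
  # nested families: the general fit is never worse
  expect_lte(f_gen$chi2, f_ind$chi2 + 1e-6)
})

test_that("a single-bin grid pins the independent weights to one", {
  pij <- two_pair_pij()
  # restrict to one adsorbing pair
  pij$mask[2, 2] <- TRUE
  pij$hist[2, 2, ] <- 0
  h <- gen_alpha_histogram(matrix(c(1, 0, 0, 0), 2, 2), pij, 400,
                           model = "general", seed = 10)
  fit <- fit_independent(h, pij, prior_weights(c(1, 0), pij))
  expect_equal(as.numeric(fit$weights), c(1, 0))
})

test_that("every factorized weight function peaks at full extension", {
  pij <- toy_pij()
  # delta weight on an unbent (gamma in (140, 180]) bin
  unbent <- rep(0, 12); unbent[bin_index(170, 45, pij$grid)] <- 1
  extremes <- independent_peak_check(pij, n_draws = 0,
                                     extra_weights = list(unbent = unbent,
                                                          two_peak = two_peak_weight(pij)))
  expect_true(all(extremes$mode_deg > 175))
  draws <- independent_peak_check(pij, n_draws = 100, seed = 12)
  expect_true(all(draws$mode_deg > 175))
})
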