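test_that("Wald intervals follow normal-quantile arithmetic", {
  set.seed(1)
  eic <- rnorm(100)
  eic <- (eic - mean(eic)) / sd(eic)  # exactly mean 0, sd 1
  ci <- wald_ci(0, eic, 0.95)
  expect_equal(unname(ci), c(-1, 1) * qnorm(0.975) / 10, tolerance = 1e-12)
  expect_warning(ci0 <- wald_ci(0.3, rep(0, 50)), "degenerate")
  expect_equal(unname(ci0), c(0.3, 0.3))
  expect_error(wald_ci(0, eic, 1.2), class = "halcausal_invalid_argument")
})

test_that("interval nesting follows the nominal level ordering", {
  set.seed(2)
  eic <- rnorm(200)
  c90 <- wald_ci(1, eic, 0.90)
  c95 <- wald_ci(1, eic, 0.95)
  c99 <- wald_ci(1, eic, 0.99)
  expect_true(c99[1] <= c95[1] && c95[1] <= c90[1])
  expect_true(c90[2] <= c95[2] && c95[2] <= c99[2])
})

test_that("the plateau selector finds the curvature point", {
  lam <- c(0.5, 0.3, 0.2, 0.1, 0.05)
  # second differences (0, -0.95, -0.04): onset at the 3rd grid point
  sel <- plateau_select(c(1, 2, 3, 3.05, 3.06), lam)
  expect_equal(sel$index, 3L)
  expect_equal(sel$lambda, 0.2)
  expect_true(sel$plateau_found)
  # exactly linear widths: no curvature anywhere
  expect_warning(sel_lin <- plateau_select(c(1, 2, 3, 4, 5), lam),
                 "no curvature")
  expect_equal(sel_lin$index, 1L)
  expect_false(sel_lin$plateau_found)
  # constant widths: already plateaued
  expect_warning(sel_c <- plateau_select(rep(2, 5), lam), "no curvature")
  expect_equal(sel_c$lambda, 0.5)
  expect_error(plateau_select(c(1, 2, 3), lam[1:3]),
               class = "halcausal_invalid_argument")
})

test_that("the plateau selector is scale-equivariant", {
  set.seed(3)
  lam <- exp(seq(0, -3, length.out = 12))
  w <- cumsum(abs(rnorm(12)))
  s1 <- plateau_select(w, lam)
  s2 <- plateau_select(7.3 * w, lam)
  expect_equal(s1$index, s2$index)
})

test_that("working-model covariance matches the robust simple-regression formula", {
  set.seed(4)
  X <- matrix(runif(80), ncol = 1)
  Y <- rnorm(80, 2 * (X[, 1] > 0.4))
  dict <- enumerate_knots(X, max_degree = 1)
  fit <- fit_hal(X, Y, dict = dict, lambda = c(1, 0.05))
  f <- hal_fit_at(fit, 0.05)
  f$support <- f$support[1]
  rel <- relaxed_fit(f, X, Y)
  V <- working_model_covariance(rel, X, Y)
  z <- as.numeric(evaluate_basis(subset_dictionary(dict, rel$support), X))
  Z <- cbind(1, z)
  r <- Y - Z %*% c(rel$beta0, rel$beta[rel$support])
  bread <- solve(crossprod(Z))
  V_hand <- bread %*% crossprod(Z * as.numeric(r)) %*% bread
  expect_equal(unclass(V), V_hand, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("working-model covariances are symmetric PSD across random fits", {
  set.seed(5)
  for (r in 1:5) {
    n <- 80
    X <- matrix(runif(2 * n), ncol = 2)
    Y <- rnorm(n, X[, 1])
    fit <- fit_hal(X, Y, max_degree = 2, knot_reduction = "quantiles",
                   m = 6, cv_folds = 5, nlambda = 20)
    rel <- relaxed_fit(fit, X, Y)
    V <- working_model_covariance(rel, X, Y)
    expect_lt(max(abs(V - t(V))), 1e-10)
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("CATE inference covers a constant effect and orders its bands", {
  dat <- gen_ate_dgp("linear", 600, seed = 6)  # true CATE constant at 0.5
  XA <- cbind(dat$W, A = dat$A)
  fit <- fit_hal(XA, dat$Y, max_degree = 2, knot_reduction = "quantiles",
                 m = 8, cv_folds = 5, nlambda = 40)
  rel <- relaxed_fit(fit, XA, dat$Y)
  V <- working_model_covariance(rel, XA, dat$Y)
  wg <- cbind(seq(0.1, 0.9, length.out = 15), 0.5)
  cc <- cate_curve(rel, V, wg, data = dat)
  expect_length(cc$estimates, 15)
  # simultaneous band at least as wide as pointwise everywhere
  expect_true(all(cc$band_hi - cc$band_lo >= cc$ci_hi - cc$ci_lo - 1e-12))
  # the band should contain the constant truth at most points
  expect_gte(mean(cc$band_lo <= 0.5 & cc$band_hi >= 0.5), 0.8)
  # extrapolation warning
  expect_warning(cate_curve(rel, V, cbind(2, 0.5), data = dat),
                 "extrapolates")
})

test_that("a fit with no treatment terms gives an identically-zero CATE", {
  dat <- gen_ate_dgp("null", 200, seed = 7)
  XA <- cbind(dat$W, A = dat$A)
  fit <- fit_hal(XA, dat$Y, max_degree = 1, knot_reduction = "quantiles",
                 m = 6, cv_folds = 5, nlambda = 20)
  rel <- relaxed_fit(fit, XA, dat$Y)
  # strip any treatment bases from the support (A is column 3)
  a_terms <- which(vapply(seq_len(rel$dict$p), function(j) {
    3L %in% dict_term_subset(rel$dict, j)
  }, logical(1)))
  rel$support <- setdiff(rel$support, a_terms)
  rel$beta[a_terms] <- 0
  V <- working_model_covariance(rel, XA, dat$Y)
  cc <- cate_curve(rel, V, cbind(seq(0.2, 0.8, length.out = 8), 0.5))
  expect_equal(cc$estimates, rep(0, 8))
  expect_true(all(abs(cc$ci_lo + cc$ci_hi) < 1e-10))  # centered at zero
})

test_that("dose-response at a binary treatment reproduces the plug-in ATE", {
  dat <- gen_ate_dgp("linear", 300, seed = 8)
  XA <- cbind(dat$W, A = dat$A)
  fit <- fit_hal(XA, dat$Y, max_degree = 2, knot_reduction = "quantiles",
                 m = 8, cv_folds = 5, nlambda = 30)
  rel <- relaxed_fit(fit, XA, dat$Y)
  V <- working_model_covariance(rel, XA, dat$Y)
  dr <- dose_response_curve(rel, V, c(0, 1), dat)
  est_plugin <- plugin_ate(rel, dat, g = function(W) rep(0.5, nrow(W)))
  expect_equal(dr$estimates[2] - dr$estimates[1], est_plugin$psi,
               tolerance = 1e-10)
  # deterministic under identical seeds
  dr2 <- dose_response_curve(rel, V, c(0, 1), dat)
  expect_identical(dr$band_lo, dr2$band_lo)
  expect_warning(dose_response_curve(rel, V, c(-0.5, 1), dat),
                 "extrapolates")
})

test_that("bootstrap paths are reproducible and degenerate without noise", {
  dat <- gen_ate_dgp("linear", 200, seed = 9,
                     params = list(sigma = 0, a1 = 0))
  nuis <- fit_nuisances(dat, max_degree = 1, knot_reduction = "quantiles",
                        m = 6, cv_folds = 5, nlambda = 30)
  bp1 <- bootstrap_ci_path(dat, nuisances = nuis, B = 15, grid_size = 5,
                           seed = 11)
  bp2 <- bootstrap_ci_path(dat, nuisances = nuis, B = 15, grid_size = 5,
                           seed = 11)
  expect_identical(bp1$psi_boot, bp2$psi_boot)
  expect_identical(bp1$final_interval, bp2$final_interval)
  # noiseless constant-effect data: widths collapse
  expect_lt(max(bp1$widths), 0.05)
})

test_that("bootstrap widths grow toward smaller penalties", {
  hits <- 0L
  for (r in 1:3) {
    dat <- gen_ate_dgp("linear", 250, seed = 20 + r)
    nuis <- fit_nuisances(dat, max_degree = 1, knot_reduction = "quantiles",
                          m = 6, cv_folds = 5, nlambda = 30)
    bp <- bootstrap_ci_path(dat, nuisances = nuis, B = 40, grid_size = 6,
                            seed = r)
    # grid restricted to variation norms >= the CV-selected norm
    expect_true(all(bp$lambda_grid <= nuis$Qbar$lambda_cv + 1e-12))
    expect_true(all(diff(bp$variation_norms) >= -1e-8))
    if (bp$widths[length(bp$widths)] >= bp$widths[1] - 1e-9) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})
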