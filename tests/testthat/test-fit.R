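test_that("an overwhelming penalty shrinks to the marginal mean", {
  set.seed(1)
  X <- matrix(runif(30), ncol = 1)
  Y <- rnorm(30, 2)
  fit <- fit_hal(X, Y, lambda = c(1e6, 1e5, 1e4, 1e3))
  f_big <- hal_fit_at(fit, 1e6)
  expect_equal(sum(abs(f_big$beta)), 0)
  expect_equal(unique(predict(f_big, X)), mean(Y), tolerance = 1e-10)

  Yb <- rbinom(30, 1, 0.7)
  fitb <- fit_hal(X, Yb, family = "binomial", lambda = c(1e6, 1e5, 1e4, 1e3))
  f_bigb <- hal_fit_at(fitb, 1e6)
  expect_equal(sum(abs(f_bigb$beta)), 0)
  expect_equal(unique(predict(f_bigb, X)), mean(Yb), tolerance = 1e-8)
})

test_that("the solver matches a brute-force lasso oracle on a tiny instance", {
  set.seed(2)
  d <- gen_sinusoid(15, seed = 2)
  X <- matrix(d$X)
  dict <- enumerate_knots(X, max_degree = 1)
  Phi <- as.matrix(evaluate_basis(dict, X))
  lam <- 0.01
  fit <- fit_hal(X, d$Y, dict = dict, lambda = c(1, 0.1, lam),
                 thresh = 1e-12)
  f <- hal_fit_at(fit, lam)
  oracle <- ista_lasso(Phi, d$Y, lam, iters = 5e5)
  expect_lt(max(abs(c(f$beta0 - oracle$b0, f$beta - oracle$b))), 1e-4)
  obj_fit <- lasso_objective(Phi, d$Y, f$beta0, f$beta, lam)
  expect_lt(abs(obj_fit - oracle$objective) / abs(oracle$objective), 1e-6)
})

test_that("random tiny instances agree with the oracle objective (both families)", {
  set.seed(3)
  for (r in 1:10) {
    n <- sample(12:20, 1)
    p_dim <- sample(1:2, 1)
    X <- matrix(runif(n * p_dim), n, p_dim)
    fam <- if (r %% 2 == 0) "binomial" else "gaussian"
    Y <- if (fam == "binomial") rbinom(n, 1, plogis(2 * X[, 1] - 1)) else
      rnorm(n, X[, 1])
    dict <- enumerate_knots(X, max_degree = p_dim)
    Phi <- as.matrix(evaluate_basis(dict, X))
    lam <- runif(1, 0.005, 0.1)
    fit <- suppressWarnings(fit_hal(X, Y, family = fam, dict = dict,
                                    lambda = c(10 * lam, lam), thresh = 1e-12))
    f <- hal_fit_at(fit, lam)
    oracle <- ista_lasso(Phi, Y, lam, family = fam, iters = 3e5)
    obj_fit <- lasso_objective(Phi, Y, f$beta0, f$beta, lam, fam)
    expect_lt(abs(obj_fit - oracle$objective) /
                max(abs(oracle$objective), 1e-10), 1e-6)
  }
})

test_that("the variation-norm identity and path monotonicity hold", {
  d <- gen_sinusoid(80, seed = 4)
  fit <- fit_hal(d$X, d$Y, cv_folds = 5, nlambda = 40)
  # identity |b0| + ||b||_1 at every path point
  for (i in seq(1, length(fit$lambda), by = 8)) {
    f <- hal_fit_at(fit, fit$lambda[i])
    expect_equal(variation_norm(f),
                 abs(f$beta0) + sum(abs(f$beta)), tolerance = 1e-12)
  }
  # variation norm nonincreasing in lambda; training risk nonincreasing
  norms <- vapply(fit$lambda, function(l) {
    variation_norm(hal_fit_at(fit, l), include_intercept = FALSE)
  }, numeric(1))
  risks <- vapply(fit$lambda, function(l) {
    mean((d$Y - predict(hal_fit_at(fit, l), matrix(d$X)))^2)
  }, numeric(1))
  expect_true(all(diff(norms) >= -1e-6))
  expect_true(all(diff(risks) <= 1e-6))
  # the intercept-exclusion switch
  expect_equal(variation_norm(fit) - variation_norm(fit, FALSE),
               abs(fit$beta0))
})

test_that("cross-validation beats gross under- and over-fitting", {
  wins <- 0L
  for (r in 1:8) {
    d <- gen_sinusoid(300, seed = 100 + r)
    test_d <- gen_sinusoid(2000, seed = 900 + r)
    fit <- fit_hal(d$X, d$Y, cv_folds = 10, seed = r)
    mse <- function(f) mean((test_d$Y - predict(f, matrix(test_d$X)))^2)
    m_cv <- mse(fit)
    m_over <- mse(hal_fit_at(fit, min(fit$lambda)))
    m_under <- mse(hal_fit_at(fit, max(fit$lambda)))
    if (m_cv < m_over && m_cv < m_under) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("CV risk selection breaks ties toward the larger penalty", {
  d <- gen_sinusoid(50, seed = 6)
  fit <- fit_hal(d$X, d$Y, cv_folds = 5)
  sel <- fit$sel
  expect_equal(fit$cv$cv_risk[sel], min(fit$cv$cv_risk))
  if (sel > 1) expect_gt(fit$cv$cv_risk[sel - 1], fit$cv$cv_risk[sel])
})

test_that("predictions reproduce the linear-combination definition", {
  d <- gen_sinusoid(60, seed = 7)
  fit <- fit_hal(d$X, d$Y, cv_folds = 5, nlambda = 30)
  Phi <- evaluate_basis(fit$dict, matrix(d$X))
  manual <- fit$beta0 + as.numeric(Phi %*% fit$beta)
  expect_equal(predict(fit, matrix(d$X)), manual, tolerance = 1e-12)
  # identical indicator profiles give identical predictions
  x_lo <- min(d$X)
  expect_equal(predict(fit, matrix(x_lo - 1)), predict(fit, matrix(x_lo - 9)))
})

test_that("binomial fits return probabilities in (0,1)", {
  set.seed(8)
  X <- matrix(runif(120), ncol = 2)
  Y <- rbinom(60, 1, plogis(3 * X[, 1] - 1))
  fit <- fit_hal(X, Y, family = "binomial", cv_folds = 5, nlambda = 30)
  p <- predict(fit, X)
  expect_true(all(p > 0 & p < 1))
  expect_error(fit_hal(X, rnorm(60), family = "binomial"),
               class = "halcausal_invalid_argument")
  expect_warning(fit_hal(X, rep(1, 60), family = "binomial"),
                 "intercept-only")
})

test_that("penalty factors exempt chosen columns from shrinkage", {
  set.seed(9)
  d <- gen_sinusoid(50, seed = 9)
  dict <- enumerate_knots(matrix(d$X), max_degree = 1)
  pf <- rep(1, dict$p)
  pf[3] <- 0  # this basis is known a priori; never penalized
  fit <- fit_hal(d$X, d$Y, dict = dict, penalty_factor = pf,
                 lambda = c(10, 1))
  f <- hal_fit_at(fit, 10)
  expect_true(f$beta[3] != 0)
  expect_equal(sum(f$beta[-3] != 0), 0L)
})

test_that("relaxed fits solve the unpenalized normal equations", {
  set.seed(10)
  d <- gen_sinusoid(100, seed = 10)
  fit <- fit_hal(d$X, d$Y, cv_folds = 5)
  rel <- relaxed_fit(fit, matrix(d$X), d$Y)
  expect_true(rel$relaxed)
  expect_true(all(rel$support %in% fit$support))
  Phi <- as.matrix(evaluate_basis(subset_dictionary(fit$dict, rel$support),
                                  matrix(d$X)))
  r <- d$Y - predict(rel, matrix(d$X))
  expect_lt(max(abs(crossprod(cbind(1, Phi), r))), 1e-8 * length(d$Y))
})

test_that("relaxed fit with a single support column is simple regression", {
  set.seed(11)
  X <- matrix(runif(40), ncol = 1)
  Y <- rnorm(40, 2 * (X[, 1] > 0.5))
  dict <- enumerate_knots(X, max_degree = 1)
  fit <- fit_hal(X, Y, dict = dict, lambda = c(1, 0.15))
  f <- hal_fit_at(fit, 0.15)
  # force a single-column support if the penalty kept several
  f$support <- f$support[1]
  rel <- relaxed_fit(f, X, Y)
  z <- as.numeric(evaluate_basis(subset_dictionary(dict, f$support), X))
  ls <- lm(Y ~ z)
  expect_equal(rel$beta0, unname(coef(ls)[1]), tolerance = 1e-10)
  expect_equal(rel$beta[f$support], unname(coef(ls)[2]), tolerance = 1e-10)
})

test_that("relaxed fit with empty support is intercept-only", {
  d <- gen_sinusoid(40, seed = 12)
  fit <- fit_hal(d$X, d$Y, lambda = c(1e5, 1e4))
  f <- hal_fit_at(fit, 1e5)
  rel <- relaxed_fit(f, matrix(d$X), d$Y)
  expect_equal(rel$beta0, mean(d$Y))
  expect_length(rel$support, 0)
})

test_that("relaxed fit drops exactly collinear columns with a warning", {
  set.seed(13)
  X <- matrix(runif(30), ncol = 1)
  Y <- rnorm(30, X[, 1])
  # two terms with identical columns cannot survive enumerate_knots, so
  # build the degeneracy by hand
  u <- sort(X[, 1])[c(10, 10)]
  dict <- dict_fixture(list(1L), list(matrix(u, ncol = 1)), d = 1)
  fit <- fit_hal(X, Y, dict = dict, lambda = c(1, 0.01))
  f <- hal_fit_at(fit, 0.01)
  f$support <- 1:2
  expect_warning(rel <- relaxed_fit(f, X, Y), "collinear")
  expect_length(rel$support, 1)
})

test_that("undersmoothing scans the path like a linear search", {
  d <- gen_sinusoid(80, seed = 14)
  fit <- fit_hal(d$X, d$Y, cv_folds = 5, nlambda = 30)
  # synthetic score decreasing in lambda index; oracle = first grid point
  # past lambda_cv whose |mean| crosses sigma_n/(sqrt(n) log n)
  ms <- seq(0.5, 0, length.out = length(fit$lambda))
  score_fn <- function(f) list(mean = ms[f$sel], var = 1)
  thr <- 1 / (sqrt(fit$n) * log(fit$n))
  oracle_idx <- which(ms <= thr & seq_along(ms) >= fit$sel)[1]
  us <- undersmooth_select(fit, score_fn)
  expect_equal(us$index, oracle_idx)
  expect_true(us$achieved)

  # criterion already satisfied at lambda_cv
  us0 <- undersmooth_select(fit, function(f) list(mean = 0, var = 0))
  expect_equal(us0$lambda, fit$lambda_cv)
  # never satisfied: smallest lambda with achieved = FALSE
  us1 <- undersmooth_select(fit, function(f) list(mean = 1, var = 1e-12))
  expect_false(us1$achieved)
  expect_equal(us1$lambda, min(fit$lambda))
})

test_that("bounded-form CV selects a norm bound and respects it", {
  d <- gen_sinusoid(120, seed = 15)
  fit <- fit_hal_bounded(d$X, d$Y, cv_folds = 5, nlambda = 40,
                         bounds = seq(0, 40, length.out = 50))
  expect_lte(variation_norm(fit), fit$bound + 1e-8)
  expect_equal(fit$cv$cv_risk[which(fit$cv$bound_grid == fit$bound)],
               min(fit$cv$cv_risk))
})
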