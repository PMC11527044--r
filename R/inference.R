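# Inference layers on top of HAL fits: influence-curve Wald intervals, the
# nonparametric bootstrap along the lasso path with plateau penalty
# selection, and delta-method inference on the data-adaptively selected
# working model (CATE and dose-response curves with simultaneous bands).

#' Influence-curve Wald confidence interval
#'
#' @param psi Point estimate.
#' @param eic_values Influence-curve values, length n.
#' @param level Confidence level in (0, 1).
#' @return Length-2 vector `(lo, hi)`:
#'   `psi +/- z_(1+level)/2 * sd(eic) / sqrt(n)`.
#' @export
wald_ci <- function(psi, eic_values, level = 0.95) {
  n <- length(eic_values)
  if (n < 2L) stop_invalid("need at least two influence-curve values")
  if (level <= 0 || level >= 1) stop_invalid("level must be in (0,1)")
  s <- stats::sd(eic_values)
  if (s == 0) {
    warning("degenerate (constant) influence curve: zero-width interval",
            call. = FALSE)
  }
  half <- zcrit(level) * s / sqrt(n)
  c(lo = psi - half, hi = psi + half)
}

#' Plateau penalty selection from bootstrap interval widths
#'
#' Along a decreasing penalty grid, bootstrap confidence interval widths
#' grow as the penalty shrinks and flatten once the fit approximates the
#' target function well. The plateau onset is located at the grid point of
#' extremal discrete second difference (curvature) of the width sequence,
#' optionally after moving-average smoothing. Ties resolve to the larger
#' penalty.
#'
#' @param widths Interval widths, ordered along `lambda_grid`.
#' @param lambda_grid Decreasing penalties (>= 4 points).
#' @param window Odd moving-average window applied to `widths` before
#'   differencing; 1 (default) disables smoothing.
#' @return List with `lambda`, grid `index`, and `plateau_found` (FALSE
#'   when the width curve has no curvature, in which case the largest
#'   penalty is returned with a warning).
#' @export
plateau_select <- function(widths, lambda_grid, window = 1L) {
  m <- length(widths)
  if (m < 4L) stop_invalid("need at least 4 grid points")
  if (length(lambda_grid) != m) stop_invalid("widths and grid lengths differ")
  if (!all(is.finite(widths))) stop_invalid("widths must be finite")
  w <- widths
  if (window > 1L) {
    k <- rep(1 / window, window)
    sm <- stats::filter(w, k, sides = 2)
    w[!is.na(sm)] <- sm[!is.na(sm)]
  }
  d2 <- w[-c(1, 2)] - 2 * w[-c(1, m)] + w[-c(m - 1, m)]
  scale <- max(abs(w), 1e-300)
  if (all(abs(d2) <= 1e-10 * scale)) {
    warning("interval widths show no curvature (no plateau found); ",
            "returning the largest penalty", call. = FALSE)
    return(list(lambda = lambda_grid[1], index = 1L, plateau_found = FALSE))
  }
  j <- which.max(abs(d2)) + 1L  # interior index; first max -> larger lambda
  list(lambda = lambda_grid[j], index = j, plateau_found = TRUE)
}

#' Nonparametric bootstrap confidence intervals along the lasso path
#'
#' For each penalty in a grid restricted to fits whose variation norm is at
#' least the cross-validated one, draws `B` nonparametric resamples, refits
#' HAL at that penalty, relaxes on the re-selected support, reruns the TMLE
#' targeting step and records the bootstrap ATE. Intervals are centered at
#' the original per-penalty TMLE; the final interval is the one at the
#' plateau-selected penalty.
#'
#' @param data A [causal_dataset].
#' @param nuisances Optional `nuisance_fits` from [fit_nuisances()] (fitted
#'   here when missing; fitting options pass through `...`).
#' @param lambda_grid Penalties to scan; defaults to `grid_size` values of
#'   the outcome-regression path from its CV selection downwards.
#' @param grid_size Default grid length (>= 4).
#' @param B Bootstrap replicates (>= 200 recommended).
#' @param seed RNG seed for resampling and targeting.
#' @param level Confidence level.
#' @param interval `"normal"` (original estimate +/- z * bootstrap sd) or
#'   `"percentile"`.
#' @param window Smoothing window for [plateau_select()].
#' @param ... Passed to [fit_nuisances()].
#' @return An object of class `bootstrap_path`: `lambda_grid`, per-penalty
#'   `widths` and `intervals`, bootstrap draws `psi_boot`, original
#'   per-penalty estimates `psi_orig`, `lambda_plateau`, `final_interval`,
#'   `B`, `seed`.
#' @export
bootstrap_ci_path <- function(data, nuisances = NULL, lambda_grid = NULL,
                              grid_size = 10L, B = 200L, seed = 1L,
                              level = 0.95, interval = c("normal", "percentile"),
                              window = 1L, ...) {
  stopifnot(inherits(data, "causal_dataset"))
  interval <- match.arg(interval)
  if (B < 1L) stop_invalid("B must be positive")
  n <- length(data$Y)
  binary_y <- all(data$Y %in% c(0, 1))
  if (is.null(nuisances)) {
    nuisances <- fit_nuisances(
      data, family = if (binary_y) "binomial" else "gaussian", ...)
  }
  Qbar <- nuisances$Qbar
  gfit <- nuisances$g
  g_bounds <- nuisances$g_bounds %||% c(0.005, 0.995)

  # penalties at or below the CV choice <=> variation norms >= the CV norm
  if (is.null(lambda_grid)) {
    idx_lo <- Qbar$sel
    idx_hi <- length(Qbar$lambda)
    if (idx_hi - idx_lo + 1L < 4L) idx_lo <- max(1L, idx_hi - 3L)
    take <- unique(round(seq(idx_lo, idx_hi, length.out = min(grid_size,
                                                              idx_hi - idx_lo + 1L))))
    lambda_grid <- Qbar$lambda[take]
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  L <- length(lambda_grid)
  if (L < 4L) stop_invalid("lambda_grid needs at least 4 points")

  XA <- cbind(data$W, A = data$A)
  PhiQ <- evaluate_basis(Qbar$dict, XA)
  PhiQ1 <- evaluate_basis(Qbar$dict, cbind(data$W, 1))
  PhiQ0 <- evaluate_basis(Qbar$dict, cbind(data$W, 0))
  Phig <- evaluate_basis(gfit$dict, data$W)
  qfam <- Qbar$family

  grel <- relaxed_fit(gfit, data$W, data$A)
  gW_orig <- predict(grel, data$W, type = "response")

  # original (non-bootstrap) per-penalty relaxed TMLE estimates
  psi_orig <- vapply(lambda_grid, function(l) {
    qb <- relaxed_fit(hal_fit_at(Qbar, l), XA, data$Y)
    tmle_ate(data, nuisances = list(
      Q1 = predict_hal_rows(qb, PhiQ1), Q0 = predict_hal_rows(qb, PhiQ0),
      gW = gW_orig, g_bounds = g_bounds))$psi
  }, numeric(1))
  norms_orig <- vapply(lambda_grid, function(l) {
    variation_norm(hal_fit_at(Qbar, l))
  }, numeric(1))

  qpath_lambda <- Qbar$lambda[Qbar$lambda >= min(lambda_grid)]
  gpath_lambda <- gfit$lambda[gfit$lambda >= gfit$lambda_cv]
  psi_boot <- matrix(NA_real_, B, L)
  draws_used <- 0L

  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- NULL
      repeat {
        draws_used <- draws_used + 1L
        if (draws_used > 10L * B) {
          stop_numeric("too many bootstrap resamples rejected ",
                       "(single treatment arm)")
        }
        cand <- sample.int(n, n, replace = TRUE)
        if (length(unique(data$A[cand])) == 2L) { idx <- cand; break }
      }
      Yb <- data$Y[idx]
      Ab <- data$A[idx]
      datb <- structure(list(W = data$W[idx, , drop = FALSE], A = Ab, Y = Yb),
                        class = "causal_dataset")
      qfit_b <- glmnet::glmnet(PhiQ[idx, , drop = FALSE], Yb, family = qfam,
                               standardize = FALSE, lambda = qpath_lambda,
                               thresh = 1e-9, maxit = 1e5)
      gfit_b <- glmnet::glmnet(Phig[idx, , drop = FALSE], Ab,
                               family = "binomial", standardize = FALSE,
                               lambda = gpath_lambda, thresh = 1e-9,
                               maxit = 1e5)
      gW_b <- relaxed_predict_boot(gfit_b, gfit$lambda_cv,
                                   Phig[idx, , drop = FALSE], Ab, "binomial",
                                   list(Phig[idx, , drop = FALSE]))[[1]]
      for (l in seq_len(L)) {
        preds <- relaxed_predict_boot(
          qfit_b, lambda_grid[l], PhiQ[idx, , drop = FALSE], Yb, qfam,
          list(PhiQ1[idx, , drop = FALSE], PhiQ0[idx, , drop = FALSE]))
        est <- try(tmle_ate(datb, nuisances = list(
          Q1 = preds[[1]], Q0 = preds[[2]], gW = gW_b,
          g_bounds = g_bounds)), silent = TRUE)
        if (!inherits(est, "try-error")) psi_boot[b, l] <- est$psi
      }
    }
  })

  z <- zcrit(level)
  intervals <- matrix(NA_real_, 2, L, dimnames = list(c("lo", "hi"), NULL))
  for (l in seq_len(L)) {
    ps <- psi_boot[, l]
    ps <- ps[is.finite(ps)]
    if (interval == "normal") {
      s <- stats::sd(ps)
      intervals[, l] <- psi_orig[l] + c(-1, 1) * z * s
    } else {
      intervals[, l] <- stats::quantile(ps, c((1 - level) / 2,
                                              (1 + level) / 2), names = FALSE)
    }
  }
  widths <- intervals[2, ] - intervals[1, ]
  pl <- plateau_select(widths, lambda_grid, window = window)

  structure(
    list(lambda_grid = lambda_grid, widths = widths, intervals = intervals,
         psi_orig = psi_orig, variation_norms = norms_orig,
         psi_boot = psi_boot, B = B, seed = seed, level = level,
         interval = interval, lambda_plateau = pl$lambda,
         plateau_index = pl$index, plateau_found = pl$plateau_found,
         final_interval = intervals[, pl$index]),
    class = "bootstrap_path")
}

#' @export
print.bootstrap_path <- function(x, ...) {
  cat("Bootstrap CI path (B =", x$B, ",", length(x$lambda_grid),
      "penalties )\n")
  cat(sprintf("  plateau at lambda = %.4g (grid index %d)\n",
              x$lambda_plateau, x$plateau_index))
  cat(sprintf("  final %g%% interval: [%.4f, %.4f]\n", 100 * x$level,
              x$final_interval[1], x$final_interval[2]))
  invisible(x)
}

# refit on the lasso-selected support at `lambda` within a bootstrap sample
# and predict on precomputed basis rows; rank-deficient refits fall back to
# the pivoted least-squares solution (aliased coefficients zero).
relaxed_predict_boot <- function(path_fit, lambda, Phi_b, y_b, family,
                                 newx_list) {
  cf <- predict(path_fit, s = lambda, type = "coefficients",
                exact = FALSE)
  beta <- as.numeric(cf)[-1]
  support <- which(beta != 0)
  if (length(support) == 0L) {
    mu <- mean(y_b)
    eta <- if (family == "binomial") qlogis(pmin(pmax(mu, 1e-12), 1 - 1e-12)) else mu
    return(lapply(newx_list, function(nx) {
      v <- rep(eta, nrow(nx))
      if (family == "binomial") plogis(v) else v
    }))
  }
  Z <- as.matrix(cbind(1, Phi_b[, support, drop = FALSE]))
  coefs <- if (family == "gaussian") {
    stats::lm.fit(Z, y_b)$coefficients
  } else {
    suppressWarnings(stats::glm.fit(Z, y_b,
                                    family = stats::binomial())$coefficients)
  }
  coefs[is.na(coefs)] <- 0
  lapply(newx_list, function(nx) {
    eta <- coefs[1] + as.numeric(nx[, support, drop = FALSE] %*% coefs[-1])
    if (family == "binomial") plogis(eta) else eta
  })
}

predict_hal_rows <- function(fit, Phi_full) {
  eta <- fit$beta0
  if (length(fit$support) > 0L) {
    eta <- eta + as.numeric(Phi_full[, fit$support, drop = FALSE] %*%
                              fit$beta[fit$support])
  } else {
    eta <- rep(eta, nrow(Phi_full))
  }
  if (fit$family == "binomial") plogis(eta) else eta
}

#' Heteroscedasticity-robust covariance of a relaxed HAL fit
#'
#' Treats the lasso-selected support as a fixed working model and returns
#' the sandwich (HC0) covariance of the unpenalized coefficients
#' (intercept first). Rank-deficient supports are pruned with a warning.
#'
#' @param relaxed A relaxed `hal_fit` (see [relaxed_fit()]).
#' @param X,Y Training data.
#' @param family Loss family; defaults to the fit's.
#' @return Symmetric PSD matrix over `(intercept, support)`, with attribute
#'   `"support"` giving the dictionary column indices of the rows/columns
#'   after the intercept.
#' @export
working_model_covariance <- function(relaxed, X, Y, family = relaxed$family) {
  stopifnot(inherits(relaxed, "hal_fit"))
  X <- as_matrix_input(X)
  Y <- as.numeric(Y)
  support <- relaxed$support
  if (length(support) == 0L) {
    Z <- matrix(1, length(Y), 1L)
  } else {
    Phi <- as.matrix(evaluate_basis(subset_dictionary(relaxed$dict, support), X))
    Z <- cbind(1, Phi)
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      keep <- sort(qrz$pivot[seq_len(qrz$rank)])
      warning("pruning ", ncol(Z) - qrz$rank,
              " rank-deficient working-model columns", call. = FALSE)
      support <- support[keep[keep > 1L] - 1L]
      Z <- Z[, keep, drop = FALSE]
    }
  }
  mod <- if (family == "gaussian") {
    stats::lm(Y ~ 0 + Z)
  } else {
    stats::glm(Y ~ 0 + Z, family = stats::binomial())
  }
  V <- sandwich::vcovHC(mod, type = "HC0")
  dimnames(V) <- NULL
  V <- (V + t(V)) / 2
  attr(V, "support") <- support
  V
}

# shared delta-method machinery: estimates, pointwise CIs and a
# Gaussian-multiplier simultaneous band over the evaluation grid
wm_inference <- function(C, beta_vec, V, grid, level, band_draws, seed,
                         fit, type) {
  est <- as.numeric(C %*% beta_vec)
  G <- C %*% V %*% t(C)
  se <- sqrt(pmax(diag(G), 0))
  z <- zcrit(level)
  pos <- se > 1e-12 * max(se, 1)
  if (any(pos)) {
    Gp <- G[pos, pos, drop = FALSE]
    E <- eigen((Gp + t(Gp)) / 2, symmetric = TRUE)
    Lm <- E$vectors %*% diag(sqrt(pmax(E$values, 0)), nrow(Gp))
    maxstat <- with_seed(seed, {
      Zs <- Lm %*% matrix(rnorm(nrow(Gp) * band_draws), nrow(Gp), band_draws)
      apply(abs(Zs) / se[pos], 2, max)
    })
    q_band <- max(stats::quantile(maxstat, level, names = FALSE), z)
  } else {
    q_band <- z
  }
  structure(
    list(fit = fit, cov_beta = V, target_grid = grid, estimates = est,
         se = se, ci_lo = est - z * se, ci_hi = est + z * se,
         band_lo = est - q_band * se, band_hi = est + q_band * se,
         q_band = q_band, level = level, type = type),
    class = "working_model_inference")
}

#' @export
print.working_model_inference <- function(x, ...) {
  cat("Working-model inference (", x$type, "), ",
      length(x$estimates), " grid points\n", sep = "")
  cat(sprintf("  level %g%%; simultaneous-band multiplier %.3f (z = %.3f)\n",
              100 * x$level, x$q_band, zcrit(x$level)))
  invisible(x)
}

#' CATE curve with delta-method working-model inference
#'
#' On the working model implied by a relaxed HAL outcome regression, the
#' conditional average treatment effect at covariate point `w` is the
#' linear contrast `tau(w) = Q(w, 1) - Q(w, 0) = c(w)' beta`; pointwise
#' intervals use the delta method and the simultaneous band a seeded
#' Gaussian-multiplier max statistic over the grid.
#'
#' @param relaxed Relaxed `hal_fit` of `Y` on `(W, A)`, treatment last.
#' @param cov_beta Covariance from [working_model_covariance()].
#' @param w_grid Matrix of covariate points (one row per evaluation point).
#' @param level Confidence level.
#' @param band_draws Gaussian draws for the max-statistic quantile.
#' @param seed Seed for the band draws.
#' @param data Optional [causal_dataset] used to warn on extrapolation
#'   beyond the observed covariate ranges.
#' @return A `working_model_inference` object.
#' @export
cate_curve <- function(relaxed, cov_beta, w_grid, level = 0.95,
                       band_draws = 1e4, seed = 1L, data = NULL) {
  stopifnot(inherits(relaxed, "hal_fit"))
  w_grid <- as_matrix_input(w_grid)
  if (ncol(w_grid) != relaxed$dict$d - 1L) {
    stop_invalid("w_grid must have d - 1 = ", relaxed$dict$d - 1L, " columns")
  }
  if (!is.null(data)) {
    rng <- apply(data$W, 2, range)
    if (any(sweep(w_grid, 2, rng[1, ], `<`)) ||
        any(sweep(w_grid, 2, rng[2, ], `>`))) {
      warning("w_grid extrapolates beyond observed covariate ranges",
              call. = FALSE)
    }
  }
  support <- attr(cov_beta, "support") %||% relaxed$support
  C1 <- contrast_rows(relaxed$dict, support, cbind(w_grid, 1))
  C0 <- contrast_rows(relaxed$dict, support, cbind(w_grid, 0))
  C <- C1 - C0  # intercept column cancels
  beta_vec <- c(relaxed$beta0, relaxed$beta[support])
  wm_inference(C, beta_vec, cov_beta, w_grid, level, band_draws, seed,
               relaxed, "cate")
}

#' Dose-response curve with delta-method working-model inference
#'
#' For a continuous treatment, the marginal adjusted response at dose `a`
#' on the working model is `theta(a) = (1/n) sum_i Q(W_i, a)`, a linear
#' functional `cbar(a)' beta` of the relaxed coefficients; inference is as
#' in [cate_curve()].
#'
#' @param relaxed Relaxed `hal_fit` of `Y` on `(W, A)`, treatment last.
#' @param cov_beta Covariance from [working_model_covariance()].
#' @param a_grid Numeric vector of treatment values.
#' @param data A [causal_dataset] (or list with `W` and `A`) supplying the
#'   covariate sample to average over.
#' @param level,band_draws,seed As in [cate_curve()].
#' @return A `working_model_inference` object.
#' @export
dose_response_curve <- function(relaxed, cov_beta, a_grid, data,
                                level = 0.95, band_draws = 1e4, seed = 1L) {
  stopifnot(inherits(relaxed, "hal_fit"))
  W <- as_matrix_input(data$W)
  if (!is.null(data$A) && (min(a_grid) < min(data$A) ||
                           max(a_grid) > max(data$A))) {
    warning("a_grid extrapolates beyond the observed treatment range",
            call. = FALSE)
  }
  support <- attr(cov_beta, "support") %||% relaxed$support
  C <- do.call(rbind, lapply(a_grid, function(a) {
    colMeans(contrast_rows(relaxed$dict, support, cbind(W, a)))
  }))
  beta_vec <- c(relaxed$beta0, relaxed$beta[support])
  wm_inference(C, beta_vec, cov_beta, a_grid, level, band_draws, seed,
               relaxed, "dose_response")
}

# design rows (intercept + support basis evaluations) at arbitrary points
contrast_rows <- function(dict, support, X) {
  X <- as_matrix_input(X)
  if (length(support) == 0L) {
    return(matrix(1, nrow(X), 1L))
  }
  Phi <- as.matrix(evaluate_basis(subset_dictionary(dict, support), X))
  cbind(1, Phi)
}
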