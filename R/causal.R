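# Average treatment effect estimation with HAL nuisance estimators:
# g-computation plug-in, (undersmoothed) IPTW, and TMLE with a logistic
# fluctuation, together with the efficient influence curve and the exact
# second-order remainder used to analyse these estimators.

#' Efficient influence curve of the average treatment effect
#'
#' For the nonparametric-model ATE the canonical gradient at nuisances
#' `(Qbar, g)` and parameter value `psi` is
#' `D*(O) = Qbar(W,1) - Qbar(W,0) - psi
#'          + (A/g(1|W) - (1-A)/g(0|W)) (Y - Qbar(W,A))`.
#'
#' @param Qbar1,Qbar0,QbarA Predicted outcomes at `A = 1`, `A = 0` and the
#'   observed treatment, length n.
#' @param gW Predicted probabilities `g(1|W)`, strictly inside (0, 1).
#' @param A Binary treatment vector.
#' @param Y Outcome vector.
#' @param psi Parameter value at which the gradient is evaluated.
#' @return Length-n vector of influence-curve values.
#' @export
eic_ate <- function(Qbar1, Qbar0, QbarA, gW, A, Y, psi) {
  A <- check_binary(A)
  if (any(gW <= 0 | gW >= 1)) {
    stop_numeric("g(1|W) must lie strictly in (0,1); truncate first ",
                 "(see g_bounds)")
  }
  H <- A / gW - (1 - A) / (1 - gW)
  Qbar1 - Qbar0 - psi + H * (Y - QbarA)
}

truncate_g <- function(gW, g_bounds) {
  lo <- g_bounds[1]
  hi <- g_bounds[2]
  n_trunc <- sum(gW < lo | gW > hi)
  structure(pmin(pmax(gW, lo), hi), n_truncated = n_trunc)
}

ate_estimate <- function(psi, eic, method, level = 0.95, epsilon = NULL,
                         diagnostics = list()) {
  n <- length(eic)
  se <- stats::sd(eic) / sqrt(n)
  z <- zcrit(level)
  structure(
    list(psi = psi, eic_values = eic, se = se,
         ci = c(lo = psi - z * se, hi = psi + z * se),
         level = level, method = method, epsilon = epsilon,
         pn_eic = mean(eic), n = n, diagnostics = diagnostics),
    class = "ate_estimate")
}

#' @export
print.ate_estimate <- function(x, ...) {
  cat(sprintf("ATE (%s): %.4f  se %.4f  %g%% CI [%.4f, %.4f]\n",
              x$method, x$psi, x$se, 100 * x$level, x$ci[1], x$ci[2]))
  cat(sprintf("  Pn D* = %.3g  (n = %d)\n", x$pn_eic, x$n))
  invisible(x)
}

# predictions of the outcome regression at A = a; Qbar is either a fit on
# (W, A) with treatment as the last column, or a plain function (W, a) ->
# E(Y | W, A = a) (e.g. a known truth in simulations)
predict_Q <- function(Qbar, W, a) {
  if (is.function(Qbar)) {
    Qbar(W, a)
  } else {
    predict(Qbar, cbind(W, rep(a, nrow(W))), type = "response")
  }
}

#' Fit HAL nuisance estimators for ATE estimation
#'
#' The outcome regression is a single HAL fit on `(W, A)` (treatment enters
#' as an ordinary covariate so treatment-covariate interaction bases are
#' available up to `max_degree`); the propensity is a binomial HAL fit on
#' `W`.
#'
#' @param data A [causal_dataset].
#' @param family Outcome family for the regression of `Y` on `(W, A)`.
#' @param g_bounds Truncation interval for the predicted propensities.
#' @param max_degree,cv_folds,seed,... Passed to [fit_hal()].
#' @return List of class `nuisance_fits` with elements `Qbar`, `g`,
#'   `g_bounds`.
#' @export
fit_nuisances <- function(data, family = c("gaussian", "binomial"),
                          g_bounds = c(0.005, 0.995), max_degree = NULL,
                          cv_folds = 10L, seed = 1L, ...) {
  stopifnot(inherits(data, "causal_dataset"))
  family <- match.arg(family)
  XA <- cbind(data$W, A = data$A)
  Qbar <- fit_hal(XA, data$Y, family = family, max_degree = max_degree,
                  cv_folds = cv_folds, seed = seed, ...)
  g <- fit_hal(data$W, data$A, family = "binomial", max_degree = max_degree,
               cv_folds = cv_folds, seed = seed + 1L, ...)
  structure(list(Qbar = Qbar, g = g, g_bounds = g_bounds),
            class = "nuisance_fits")
}

#' Plug-in (g-computation) ATE estimator
#'
#' Averages the difference of outcome-regression predictions at `A = 1` and
#' `A = 0`. No targeting is applied; the influence-curve-based standard
#' error (computed with a supplied or HAL-fitted propensity) is reported
#' for reference, and is reliable only when the regression is undersmoothed
#' enough to solve the efficient score equation.
#'
#' @param Qbar `hal_fit` of `Y` on `(W, A)` with treatment last.
#' @param data A [causal_dataset].
#' @param g Optional propensity `hal_fit` or vector of probabilities
#'   `g(1|W)`; fitted by HAL when missing.
#' @param g_bounds Propensity truncation interval.
#' @param level Confidence level.
#' @return An `ate_estimate` with `method = "plugin"`.
#' @export
plugin_ate <- function(Qbar, data, g = NULL, g_bounds = c(0.005, 0.995),
                       level = 0.95) {
  stopifnot(inherits(data, "causal_dataset"))
  Q1 <- predict_Q(Qbar, data$W, 1)
  Q0 <- predict_Q(Qbar, data$W, 0)
  QA <- ifelse(data$A == 1, Q1, Q0)
  psi <- mean(Q1 - Q0)
  gW <- resolve_g(g, data)
  gW <- truncate_g(gW, g_bounds)
  eic <- eic_ate(Q1, Q0, QA, as.numeric(gW), data$A, data$Y, psi)
  ate_estimate(psi, eic, "plugin", level,
               diagnostics = list(n_g_truncated = attr(gW, "n_truncated")))
}

# g may be a binomial hal_fit, a function W -> P(A=1|W), a vector of
# probabilities, or NULL (HAL-fitted here)
resolve_g <- function(g, data) {
  if (is.null(g)) {
    g <- fit_hal(data$W, data$A, family = "binomial")
  }
  if (inherits(g, "hal_fit")) {
    predict(g, data$W, type = "response")
  } else if (is.function(g)) {
    g(data$W)
  } else {
    as.numeric(g)
  }
}

#' Inverse-probability-of-treatment-weighted ATE estimator
#'
#' `psi = (1/n) sum [A_i Y_i / g(1|W_i) - (1-A_i) Y_i / g(0|W_i)]`. With
#' `undersmooth = TRUE` the propensity penalty is re-selected along its
#' lasso path by [undersmooth_select()] using the ATE efficient influence
#' curve as the score, which restores asymptotic efficiency of IPTW.
#'
#' @param g Binomial `hal_fit` of `A` on `W` (a path fit).
#' @param data A [causal_dataset].
#' @param undersmooth Re-select the propensity penalty by undersmoothing.
#' @param Qbar Optional outcome-regression `hal_fit` used in the
#'   undersmoothing score and the reported influence curve; fitted by HAL
#'   when missing and needed.
#' @param g_bounds Propensity truncation interval.
#' @param weight_cap Warn when any post-truncation weight exceeds this.
#' @param level Confidence level.
#' @return An `ate_estimate` with `method = "iptw"`; diagnostics record the
#'   selected penalty and truncation counts.
#' @export
iptw_ate <- function(g, data, undersmooth = FALSE, Qbar = NULL,
                     g_bounds = c(0.005, 0.995), weight_cap = 100,
                     level = 0.95) {
  stopifnot(inherits(data, "causal_dataset"))
  A <- data$A
  Y <- data$Y
  n <- length(Y)
  needs_Q <- undersmooth || TRUE  # EIC reporting always uses a Qbar
  if (needs_Q && is.null(Qbar)) {
    Qbar <- fit_hal(cbind(data$W, A = A), Y,
                    family = if (all(Y %in% c(0, 1))) "binomial" else "gaussian")
  }
  Q1 <- predict_Q(Qbar, data$W, 1)
  Q0 <- predict_Q(Qbar, data$W, 0)
  QA <- ifelse(A == 1, Q1, Q0)

  iptw_psi <- function(gW) mean(A * Y / gW - (1 - A) * Y / (1 - gW))
  lambda_sel <- if (inherits(g, "hal_fit")) g$lambda_sel else NA_real_
  achieved <- NA
  if (undersmooth && inherits(g, "hal_fit")) {
    score_fn <- function(gfit) {
      gW <- as.numeric(truncate_g(predict(gfit, data$W, type = "response"),
                                  g_bounds))
      psi_l <- iptw_psi(gW)
      d <- eic_ate(Q1, Q0, QA, gW, A, Y, psi_l)
      list(mean = mean(d), var = stats::var(d))
    }
    us <- undersmooth_select(g, score_fn)
    g <- hal_fit_at(g, us$lambda)
    lambda_sel <- us$lambda
    achieved <- us$achieved
  }
  gW <- truncate_g(resolve_g(g, data), g_bounds)
  w <- ifelse(A == 1, 1 / as.numeric(gW), 1 / (1 - as.numeric(gW)))
  if (any(w > weight_cap)) {
    warning(sum(w > weight_cap), " IPTW weights exceed cap ", weight_cap,
            " (max ", signif(max(w), 3), ")", call. = FALSE)
  }
  psi <- iptw_psi(as.numeric(gW))
  eic <- eic_ate(Q1, Q0, QA, as.numeric(gW), A, Y, psi)
  ate_estimate(psi, eic, "iptw", level,
               diagnostics = list(lambda_g = lambda_sel,
                                  undersmooth_achieved = achieved,
                                  n_g_truncated = attr(gW, "n_truncated"),
                                  max_weight = max(w)))
}

#' Targeted maximum likelihood estimation of the ATE
#'
#' Starting from initial nuisance fits, updates the outcome regression
#' along the one-dimensional logistic fluctuation
#' `logit Qbar* = logit Qbar + eps * H` with clever covariate
#' `H(A, W) = A / g(1|W) - (1-A) / g(0|W)`, with `eps` fitted by maximum
#' likelihood, so that the empirical mean of the efficient influence curve
#' is (numerically) exactly zero. Continuous outcomes are affinely mapped
#' to `[0, 1]` for the fluctuation and mapped back.
#'
#' @param data A [causal_dataset].
#' @param nuisances A `nuisance_fits` list (see [fit_nuisances()]); fitted
#'   by HAL when missing. A list with plain numeric elements `Q1`, `Q0`
#'   and `gW` is also accepted (useful in simulations with known truth).
#' @param level Confidence level for the Wald interval.
#' @param y_bounds Bounds used to rescale a continuous outcome; defaults to
#'   the observed range of `Y`.
#' @param ... Passed to [fit_nuisances()] when nuisances are fitted here.
#' @return An `ate_estimate` with `method = "tmle"`, fluctuation
#'   coefficient `epsilon` and `pn_eic` (numerically zero).
#' @export
tmle_ate <- function(data, nuisances = NULL, level = 0.95, y_bounds = NULL,
                     ...) {
  stopifnot(inherits(data, "causal_dataset"))
  A <- data$A
  Y <- data$Y
  n <- length(Y)
  binary_y <- all(Y %in% c(0, 1))
  if (is.null(nuisances)) {
    nuisances <- fit_nuisances(
      data, family = if (binary_y) "binomial" else "gaussian", ...)
  }
  g_bounds <- nuisances$g_bounds %||% c(0.005, 0.995)
  if (!is.null(nuisances$Q1)) {
    Q1 <- nuisances$Q1
    Q0 <- nuisances$Q0
    gW <- nuisances$gW
  } else {
    Q1 <- predict_Q(nuisances$Qbar, data$W, 1)
    Q0 <- predict_Q(nuisances$Qbar, data$W, 0)
    gW <- resolve_g(nuisances$g, data)
  }
  gW <- truncate_g(gW, g_bounds)
  n_trunc <- attr(gW, "n_truncated")
  gW <- as.numeric(gW)

  # map everything to [0, 1] for the logistic fluctuation
  if (binary_y) {
    a <- 0; b <- 1
  } else {
    yb <- y_bounds %||% range(Y)
    a <- yb[1]; b <- yb[2]
    if (b <= a) stop_numeric("degenerate outcome range")
  }
  sc <- function(v) pmin(pmax((v - a) / (b - a), 1e-8), 1 - 1e-8)
  Ys <- (Y - a) / (b - a)
  Q1s <- sc(Q1)
  Q0s <- sc(Q0)
  QAs <- ifelse(A == 1, Q1s, Q0s)
  H <- A / gW - (1 - A) / (1 - gW)
  eta <- qlogis(QAs)

  # one-dimensional MLE for eps: solve sum H (Ys - expit(eta + eps H)) = 0
  score <- function(eps) sum(H * (Ys - plogis(eta + eps * H)))
  eps <- 0
  converged <- FALSE
  for (it in 1:100) {
    mu <- plogis(eta + eps * H)
    s <- sum(H * (Ys - mu))
    info <- sum(H^2 * mu * (1 - mu))
    if (abs(s) < 1e-11 * n) { converged <- TRUE; break }
    if (info <= 0) break
    step <- s / info
    eps <- eps + sign(step) * min(abs(step), 5)
  }
  if (!converged) {
    lohi <- c(-20, 20)
    if (score(lohi[1]) * score(lohi[2]) < 0) {
      eps <- stats::uniroot(score, lohi, tol = 1e-14)$root
      converged <- TRUE
    }
  }
  if (!converged && abs(score(eps)) > 1e-6 * n) {
    stop_numeric("TMLE fluctuation did not converge (score ",
                 signif(score(eps) / n, 3), "); check positivity/truncation")
  }

  Q1s_star <- plogis(qlogis(Q1s) + eps / gW)
  Q0s_star <- plogis(qlogis(Q0s) - eps / (1 - gW))
  QAs_star <- ifelse(A == 1, Q1s_star, Q0s_star)
  psi <- mean(Q1s_star - Q0s_star) * (b - a)
  eic <- eic_ate((b - a) * Q1s_star + a, (b - a) * Q0s_star + a,
                 (b - a) * QAs_star + a, gW, A, Y, psi)
  ate_estimate(psi, eic, "tmle", level, epsilon = eps,
               diagnostics = list(n_g_truncated = n_trunc,
                                  y_bounds = c(a, b)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Exact second-order remainder of the ATE expansion
#'
#' Monte-Carlo approximation of
#' `R2 = E0[ ((g0-g)/g)(1|W) (Qbar0-Qbar)(W,1)
#'          - ((g0-g)/g)(0|W) (Qbar0-Qbar)(W,0) ]`,
#' the term controlling the bias of influence-curve-based estimators. It is
#' identically zero when either nuisance equals its truth.
#'
#' @param Qbar_hat,Qbar0 Functions `(W, a) -> E(Y | W, A = a)` (estimate and
#'   truth).
#' @param g_hat,g0 Functions `W -> P(A = 1 | W)` (estimate and truth).
#' @param W_sample Large matrix of covariate draws from the truth.
#' @return Scalar Monte-Carlo estimate of `R2`.
#' @export
exact_remainder_ate <- function(Qbar_hat, g_hat, Qbar0, g0, W_sample) {
  W <- as_matrix_input(W_sample)
  g1h <- g_hat(W)
  g1o <- g0(W)
  if (any(g1h <= 0 | g1h >= 1)) {
    stop_numeric("estimated g must lie strictly in (0,1)")
  }
  t1 <- (g1o - g1h) / g1h * (Qbar0(W, 1) - Qbar_hat(W, 1))
  t0 <- ((1 - g1o) - (1 - g1h)) / (1 - g1h) * (Qbar0(W, 0) - Qbar_hat(W, 0))
  mean(t1 - t0)
}
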