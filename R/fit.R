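# Variation-norm-penalized empirical risk minimization over the HAL basis.
#
# The constrained problem (empirical risk over fits with sectional variation
# norm at most M) is solved in its Lagrangian form: for each penalty lambda,
#   gaussian:  (1/2n) sum (y_i - b0 - Phi_i b)^2 + lambda ||b||_1
#   binomial: -(1/n) log-likelihood (logit link)  + lambda ||b||_1
# with an unpenalized intercept. The achieved |b0| + ||b||_1 is reported as
# the variation-norm bound of the fit. Columns are never standardized: the
# identity "L1 norm of coefficients = sectional variation norm" only holds
# on the raw indicator/hinge scale.

#' Fit the highly adaptive lasso
#'
#' Builds (or accepts) a HAL basis dictionary, solves the L1-penalized
#' regression along a decreasing penalty grid, and selects the penalty by
#' V-fold cross-validation.
#'
#' @param X Covariate matrix or data frame (n x d).
#' @param Y Outcome vector; in `{0,1}` for `family = "binomial"`.
#' @param family `"gaussian"` (squared-error loss) or `"binomial"`
#'   (log-likelihood loss with logit link).
#' @param dict Optional pre-built [enumerate_knots()] dictionary; when
#'   supplied the basis arguments are ignored.
#' @param max_degree,order,knot_reduction,m,column_budget Passed to
#'   [enumerate_knots()].
#' @param lambda Optional decreasing penalty grid; by default `nlambda`
#'   log-spaced values from the smallest penalty that zeroes every
#'   coefficient down to `lambda_min_ratio` times it.
#' @param nlambda,lambda_min_ratio Grid size and span (defaults 100, 1e-4).
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Seed for the deterministic fold assignment.
#' @param penalty_factor Optional per-column penalty multipliers; 0 leaves a
#'   column unpenalized (for bases known a priori to belong in the model).
#' @param thresh,maxit Solver convergence tolerance and iteration cap.
#' @return An object of class `hal_fit`: the dictionary, the coefficient
#'   path (`a0`, sparse `beta_path` over the grid), the CV summary `cv`
#'   (grid, per-lambda mean validation risk, fold assignment, selected
#'   `lambda_cv`), and the selected fit's `beta0`, `beta`, `support` and
#'   `lambda`. Ties in CV risk resolve to the larger penalty.
#' @examples
#' d <- gen_sinusoid(100, seed = 1)
#' fit <- fit_hal(d$X, d$Y, cv_folds = 5)
#' variation_norm(fit)
#' @export
fit_hal <- function(X, Y, family = c("gaussian", "binomial"), dict = NULL,
                    max_degree = NULL, order = 0L,
                    knot_reduction = "auto", m = NULL, column_budget = 1e5,
                    lambda = NULL, nlambda = 100L, lambda_min_ratio = 1e-4,
                    cv_folds = 10L, seed = 1L, penalty_factor = NULL,
                    thresh = 1e-7, maxit = 1e5) {
  family <- match.arg(family)
  X <- as_matrix_input(X)
  Y <- as.numeric(Y)
  n <- nrow(X)
  if (n != length(Y)) stop_invalid("X and Y must have the same length")
  if (n < 10L) stop_invalid("need n >= 10 observations")
  if (!all(is.finite(Y))) stop_invalid("Y must be finite")
  if (family == "binomial" && !all(Y %in% c(0, 1))) {
    stop_invalid("binomial family requires Y in {0,1}")
  }

  if (is.null(dict)) {
    dict <- enumerate_knots(X, max_degree = max_degree, order = order,
                            knot_reduction = knot_reduction, m = m,
                            column_budget = column_budget)
  }
  Phi <- evaluate_basis(dict, X)
  p <- ncol(Phi)
  if (is.null(penalty_factor)) penalty_factor <- rep(1, p)
  if (length(penalty_factor) != p) {
    stop_invalid("penalty_factor must have one entry per basis column")
  }

  if (family == "binomial" && length(unique(Y)) == 1L) {
    warning("constant binomial outcome: returning intercept-only fit",
            call. = FALSE)
    return(intercept_only_fit(dict, Y, family, n))
  }

  # zero-padding lets glmnet run when the dictionary collapses to < 2 columns
  pad <- max(0L, 2L - p)
  Phi_fit <- if (pad > 0L) {
    cbind(Phi, Matrix::sparseMatrix(i = integer(), j = integer(), x = double(),
                                    dims = c(n, pad)))
  } else Phi
  pf_fit <- c(penalty_factor, rep(1, pad))

  glmnet_args <- list(x = Phi_fit, y = Y, family = family,
                      standardize = FALSE, intercept = TRUE,
                      penalty.factor = pf_fit, thresh = thresh, maxit = maxit)
  if (is.null(lambda)) {
    probe <- do.call(glmnet::glmnet,
                     c(glmnet_args, list(nlambda = 3L, lambda.min.ratio = 0.5)))
    lmax <- probe$lambda[1]
    if (!is.finite(lmax) || lmax <= 0) lmax <- 1
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  lambda <- sort(as.numeric(lambda), decreasing = TRUE)

  fit <- do.call(glmnet::glmnet, c(glmnet_args, list(lambda = lambda)))
  beta_path <- fit$beta[seq_len(p), , drop = FALSE]
  a0 <- as.numeric(fit$a0)

  # V-fold cross-validation over the same fixed grid
  folds <- with_seed(seed, sample(rep(seq_len(cv_folds), length.out = n)))
  loss <- matrix(NA_real_, n, length(lambda))
  for (v in seq_len(cv_folds)) {
    hold <- folds == v
    fold_fit <- do.call(glmnet::glmnet, c(
      list(x = Phi_fit[!hold, , drop = FALSE], y = Y[!hold], family = family,
           standardize = FALSE, intercept = TRUE, penalty.factor = pf_fit,
           thresh = thresh, maxit = maxit, lambda = lambda)))
    eta <- predict(fold_fit, Phi_fit[hold, , drop = FALSE], s = lambda)
    loss[hold, ] <- pointwise_loss(Y[hold], eta, family)
  }
  cv_risk <- colMeans(loss)
  sel <- which(cv_risk <= min(cv_risk) + 1e-12)[1]  # ties -> larger lambda

  out <- structure(
    list(dict = dict, family = family, n = n,
         lambda = lambda, a0 = a0, beta_path = beta_path,
         penalty_factor = penalty_factor,
         cv = list(lambda_grid = lambda, cv_risk = cv_risk, folds = folds,
                   lambda_cv = lambda[sel]),
         lambda_cv = lambda[sel], sel = sel, relaxed = FALSE),
    class = "hal_fit")
  set_selected(out, sel)
}

pointwise_loss <- function(y, eta, family) {
  if (family == "gaussian") {
    (y - eta)^2
  } else {
    p <- pmin(pmax(plogis(eta), 1e-12), 1 - 1e-12)
    -(y * log(p) + (1 - y) * log(1 - p))
  }
}

set_selected <- function(fit, idx) {
  fit$sel <- idx
  fit$lambda_sel <- fit$lambda[idx]
  fit$beta0 <- fit$a0[idx]
  fit$beta <- as.numeric(fit$beta_path[, idx])
  fit$support <- which(fit$beta != 0)
  fit
}

intercept_only_fit <- function(dict, Y, family, n) {
  mu <- mean(Y)
  beta0 <- if (family == "binomial") qlogis(pmin(pmax(mu, 1e-12), 1 - 1e-12)) else mu
  structure(
    list(dict = dict, family = family, n = n, lambda = 1, a0 = beta0,
         beta_path = Matrix::sparseMatrix(i = integer(), j = integer(),
                                          x = double(), dims = c(dict$p, 1L)),
         penalty_factor = rep(1, dict$p),
         cv = list(lambda_grid = 1, cv_risk = NA_real_, folds = NULL,
                   lambda_cv = 1),
         lambda_cv = 1, sel = 1L, lambda_sel = 1, beta0 = beta0,
         beta = rep(0, dict$p), support = integer(), relaxed = FALSE),
    class = "hal_fit")
}

#' Fit HAL with cross-validation over variation-norm bounds
#'
#' Solves the constrained form of the problem directly: candidate bounds
#' `M` on the sectional variation norm are compared by V-fold
#' cross-validation, where the fit under bound `M` is the lasso-path
#' solution with the largest variation norm not exceeding `M` (the
#' path-equivalence of the constrained and Lagrangian problems). This
#' mirrors selecting "a bound on the variation norm" rather than a penalty.
#'
#' @inheritParams fit_hal
#' @param bounds Increasing candidate bounds; default `nbounds` equally
#'   spaced values from 0 to the largest norm on the path.
#' @param nbounds Number of default bounds.
#' @return A `hal_fit` at the selected bound; `cv` carries the bound grid
#'   and risks, and `bound` the selected bound. Ties resolve to the
#'   smaller bound.
#' @export
fit_hal_bounded <- function(X, Y, family = c("gaussian", "binomial"),
                            dict = NULL, max_degree = NULL, order = 0L,
                            knot_reduction = "auto", m = NULL,
                            column_budget = 1e5, bounds = NULL,
                            nbounds = 100L, nlambda = 100L,
                            lambda_min_ratio = 1e-4, cv_folds = 10L,
                            seed = 1L, thresh = 1e-7, maxit = 1e5) {
  family <- match.arg(family)
  fit <- fit_hal(X, Y, family = family, dict = dict, max_degree = max_degree,
                 order = order, knot_reduction = knot_reduction, m = m,
                 column_budget = column_budget, nlambda = nlambda,
                 lambda_min_ratio = lambda_min_ratio, cv_folds = cv_folds,
                 seed = seed, thresh = thresh, maxit = maxit)
  X <- as_matrix_input(X)
  Y <- as.numeric(Y)
  n <- nrow(X)
  Phi <- evaluate_basis(fit$dict, X)
  norms_full <- abs(fit$a0) + Matrix::colSums(abs(fit$beta_path))
  if (is.null(bounds)) {
    bounds <- seq(0, max(norms_full), length.out = nbounds)
  }
  bounds <- sort(bounds)

  folds <- fit$cv$folds
  loss <- matrix(NA_real_, n, length(bounds))
  for (v in seq_len(max(folds))) {
    hold <- folds == v
    ff <- glmnet::glmnet(Phi[!hold, , drop = FALSE], Y[!hold],
                         family = family, standardize = FALSE,
                         lambda = fit$lambda, thresh = thresh, maxit = maxit)
    nf <- abs(as.numeric(ff$a0)) +
      Matrix::colSums(abs(ff$beta))[seq_along(ff$lambda)]
    eta <- predict(ff, Phi[hold, , drop = FALSE], s = fit$lambda)
    for (bi in seq_along(bounds)) {
      ok <- which(nf <= bounds[bi])
      j <- if (length(ok) == 0L) 1L else ok[which.max(nf[ok])]
      loss[hold, bi] <- pointwise_loss(Y[hold], eta[, j], family)
    }
  }
  risk <- colMeans(loss)
  bsel <- which(risk <= min(risk) + 1e-12)[1]  # ties -> smaller bound
  ok <- which(norms_full <= bounds[bsel])
  j <- if (length(ok) == 0L) 1L else ok[which.max(norms_full[ok])]
  out <- set_selected(fit, j)
  out$bound <- bounds[bsel]
  out$cv <- list(bound_grid = bounds, cv_risk = risk, folds = folds,
                 bound_cv = bounds[bsel], lambda_grid = fit$lambda)
  out$lambda_cv <- fit$lambda[j]
  out
}

#' Extract the fit at another penalty on the path
#'
#' @param fit A `hal_fit` with a coefficient path.
#' @param lambda Penalty value; snapped to the nearest grid point.
#' @return A `hal_fit` whose selected coefficients correspond to `lambda`.
#' @export
hal_fit_at <- function(fit, lambda) {
  stopifnot(inherits(fit, "hal_fit"))
  idx <- which.min(abs(log(fit$lambda) - log(lambda)))
  set_selected(fit, idx)
}

#' Sectional variation norm of a fitted HAL function
#'
#' The L1 norm of the coefficients equals the sectional variation norm of
#' the fitted cadlag function; the intercept term houses the value of the
#' function at the lower corner of the covariate space and is included by
#' default.
#'
#' @param fit A `hal_fit`.
#' @param include_intercept Include `|beta0|` in the norm (default TRUE).
#' @return Nonnegative scalar.
#' @export
variation_norm <- function(fit, include_intercept = TRUE) {
  stopifnot(inherits(fit, "hal_fit"))
  sum(abs(fit$beta)) + if (include_intercept) abs(fit$beta0) else 0
}

#' Predict from a HAL fit
#'
#' @param object A `hal_fit`.
#' @param newx Covariate matrix with `d` columns.
#' @param lambda Optional penalty at which to predict (path fits only).
#' @param type `"response"` (probability scale for binomial) or `"link"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.hal_fit <- function(object, newx, lambda = NULL,
                            type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (!is.null(lambda)) object <- hal_fit_at(object, lambda)
  newx <- as_matrix_input(newx)
  if (ncol(newx) != object$dict$d) {
    stop_invalid("newx has ", ncol(newx), " columns; fit expects ",
                 object$dict$d)
  }
  eta <- object$beta0
  if (length(object$support) > 0L) {
    Phi <- evaluate_basis(subset_dictionary(object$dict, object$support), newx)
    eta <- eta + as.numeric(Phi %*% object$beta[object$support])
  } else {
    eta <- rep(eta, nrow(newx))
  }
  if (object$family == "binomial" && type == "response") plogis(eta) else eta
}

#' @export
print.hal_fit <- function(x, ...) {
  cat("HAL fit (", x$family, ", order ", x$dict$order,
      if (isTRUE(x$relaxed)) ", relaxed" else "", ")\n", sep = "")
  cat("  n =", x$n, " basis terms =", x$dict$p,
      " support size =", length(x$support), "\n")
  cat("  lambda =", signif(x$lambda_sel, 4),
      " variation norm =", signif(variation_norm(x), 4), "\n")
  invisible(x)
}

#' Unpenalized refit on the selected support (relaxed HAL)
#'
#' Refits the family's maximum-likelihood regression using only the basis
#' functions with nonzero lasso coefficients. Exactly collinear columns are
#' dropped (first kept) with a warning.
#'
#' @param fit A `hal_fit`.
#' @param X,Y The training data.
#' @return A `hal_fit` with `relaxed = TRUE`; its support never grows.
#' @export
relaxed_fit <- function(fit, X, Y) {
  stopifnot(inherits(fit, "hal_fit"))
  X <- as_matrix_input(X)
  Y <- as.numeric(Y)
  support <- fit$support
  out <- fit
  if (length(support) == 0L) {
    mu <- mean(Y)
    out$beta0 <- if (fit$family == "binomial") {
      qlogis(pmin(pmax(mu, 1e-12), 1 - 1e-12))
    } else mu
    out$beta <- rep(0, fit$dict$p)
    out$support <- integer()
    out$relaxed <- TRUE
    return(out)
  }
  Phi <- as.matrix(evaluate_basis(subset_dictionary(fit$dict, support), X))
  Z <- cbind(1, Phi)
  qrz <- qr(Z)
  keep_z <- sort(qrz$pivot[seq_len(qrz$rank)])
  if (length(keep_z) < ncol(Z)) {
    warning("dropping ", ncol(Z) - length(keep_z),
            " exactly collinear columns in relaxed refit", call. = FALSE)
  }
  if (!1L %in% keep_z) keep_z <- c(1L, keep_z[-length(keep_z)])
  Zk <- Z[, keep_z, drop = FALSE]
  coefs <- if (fit$family == "gaussian") {
    stats::lm.fit(Zk, Y)$coefficients
  } else {
    suppressWarnings(
      stats::glm.fit(Zk, Y, family = stats::binomial())$coefficients)
  }
  coefs <- unname(coefs)
  coefs[is.na(coefs)] <- 0
  beta <- rep(0, fit$dict$p)
  kept_cols <- keep_z[keep_z > 1L] - 1L  # positions within `support`
  beta[support[kept_cols]] <- coefs[-1]
  out$beta0 <- coefs[1]
  out$beta <- beta
  out$support <- support[kept_cols]
  out$relaxed <- TRUE
  out$relax_dropped <- setdiff(support, out$support)
  out
}

#' Undersmooth the penalty along a HAL path
#'
#' Scans penalties at or below the cross-validated one and returns the
#' largest penalty whose fit (approximately) solves the target score
#' equation: `|Pn score| <= sigma_n / (sqrt(n) log n)`, where `sigma_n^2` is
#' the empirical variance of the score. When no grid point satisfies the
#' criterion the smallest penalty is returned with `achieved = FALSE`.
#'
#' @param fit A `hal_fit` with a coefficient path.
#' @param score_fn Function mapping a `hal_fit` (at one penalty) to a list
#'   or vector with components `mean` (the empirical mean of the score) and
#'   `var` (its empirical variance).
#' @param lambda_cv Starting penalty; defaults to the fit's CV selection.
#' @return List with `lambda`, grid `index`, `achieved` flag, and the
#'   per-penalty score `mean`s examined.
#' @export
undersmooth_select <- function(fit, score_fn, lambda_cv = fit$lambda_cv) {
  stopifnot(inherits(fit, "hal_fit"))
  if (length(fit$lambda) == 0L) stop_invalid("empty penalty path")
  n <- fit$n
  start <- which.min(abs(log(fit$lambda) - log(lambda_cv)))
  idxs <- start:length(fit$lambda)
  means <- rep(NA_real_, length(idxs))
  for (k in seq_along(idxs)) {
    s <- score_fn(set_selected(fit, idxs[k]))
    s <- as.list(s)
    means[k] <- s$mean
    if (abs(s$mean) <= sqrt(max(s$var, 0)) / (sqrt(n) * log(n))) {
      return(list(lambda = fit$lambda[idxs[k]], index = idxs[k],
                  achieved = TRUE, score_means = means[seq_len(k)]))
    }
  }
  list(lambda = fit$lambda[length(fit$lambda)], index = length(fit$lambda),
       achieved = FALSE, score_means = means)
}
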