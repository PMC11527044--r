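# Independent oracles used across the suite. These deliberately avoid the
# package's solver path: the lasso oracle is a plain proximal-gradient
# (ISTA) loop, basis counting is brute-force enumeration, and truths are
# quadrature or Monte-Carlo.

# penalized objective on the solver's scale:
#  gaussian:  (1/2n) sum (y - b0 - X b)^2 + lambda * sum(pf * |b|)
#  binomial: -(1/n) loglik(logit)        + lambda * sum(pf * |b|)
lasso_objective <- function(X, y, b0, b, lambda, family = "gaussian",
                            pf = rep(1, length(b))) {
  eta <- b0 + as.numeric(X %*% b)
  n <- length(y)
  fit <- if (family == "gaussian") {
    sum((y - eta)^2) / (2 * n)
  } else {
    p <- plogis(eta)
    -mean(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  }
  fit + lambda * sum(pf * abs(b))
}

# brute-force proximal gradient with unpenalized intercept
ista_lasso <- function(X, y, lambda, family = "gaussian",
                       pf = rep(1, ncol(X)), iters = 2e5, tol = 1e-12) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  Z <- cbind(1, X)
  L <- max(eigen(crossprod(Z) / n, symmetric = TRUE,
                 only.values = TRUE)$values)
  if (family == "binomial") L <- L / 4 + 1e-8  # hessian bound p(1-p) <= 1/4
  step <- 1 / L
  b0 <- 0
  b <- rep(0, p)
  obj_old <- Inf
  for (it in seq_len(iters)) {
    eta <- b0 + as.numeric(X %*% b)
    grad_common <- if (family == "gaussian") -(y - eta) / n else -(y - plogis(eta)) / n
    g0 <- sum(grad_common)
    gb <- as.numeric(crossprod(X, grad_common))
    b0 <- b0 - step * g0
    u <- b - step * gb
    b <- sign(u) * pmax(abs(u) - step * lambda * pf, 0)
    if (it %% 200 == 0) {
      obj <- lasso_objective(X, y, b0, b, lambda, family, pf)
      if (abs(obj_old - obj) < tol * max(1, abs(obj))) break
      obj_old <- obj
    }
  }
  list(b0 = b0, b = b,
       objective = lasso_objective(X, y, b0, b, lambda, family, pf))
}

# brute-force order-0 HAL column count: build every (subset, observed knot)
# indicator column densely and count exact distinct columns
brute_force_hal_columns <- function(X, max_degree) {
  n <- nrow(X)
  d <- ncol(X)
  cols <- list()
  for (k in seq_len(max_degree)) {
    subsets <- utils::combn(d, k)
    for (j in seq_len(ncol(subsets))) {
      s <- subsets[, j]
      for (i in seq_len(n)) {
        u <- X[i, s]
        col <- rep(TRUE, n)
        for (l in seq_along(s)) col <- col & (X[, s[l]] >= u[l])
        cols[[length(cols) + 1L]] <- as.integer(col)
      }
    }
  }
  M <- do.call(cbind, cols)
  sum(!duplicated(as.data.frame(t(M))))
}

# variance of Y = 2 sin((pi/2)|X|) + eps, X ~ U(-4,4), eps ~ N(0,1),
# by numerical quadrature (independent of the generator)
sinusoid_variance_oracle <- function() {
  f <- function(x) 2 * sin(pi / 2 * abs(x))
  m1 <- integrate(function(x) f(x) / 8, -4, 4, rel.tol = 1e-10)$value
  m2 <- integrate(function(x) f(x)^2 / 8, -4, 4, rel.tol = 1e-10)$value
  1 + (m2 - m1^2)
}
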