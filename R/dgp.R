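# Synthetic data-generating processes with known truth.
#
# Every generator draws from a local, seeded RNG stream so that identical
# (scenario, n, seed) calls produce identical datasets and library calls
# never disturb the caller's RNG.

#' Causal dataset container
#'
#' Bundles covariates, a binary treatment and an outcome with alignment and
#' missingness checks.
#'
#' @param W Numeric matrix (or data frame) of covariates, n x d.
#' @param A Binary treatment vector, coded 0/1.
#' @param Y Numeric outcome vector.
#' @return An object of class `causal_dataset` with elements `W`, `A`, `Y`.
#' @export
causal_dataset <- function(W, A, Y) {
  W <- as_matrix_input(W)
  if (is.null(colnames(W))) colnames(W) <- paste0("W", seq_len(ncol(W)))
  A <- check_binary(A)
  Y <- as.numeric(Y)
  if (nrow(W) != length(A) || length(A) != length(Y)) {
    stop_invalid("W, A and Y must have aligned rows")
  }
  if (anyNA(W) || anyNA(A) || anyNA(Y)) stop_invalid("missing values not allowed")
  structure(list(W = W, A = A, Y = Y), class = "causal_dataset")
}

#' @export
as.data.frame.causal_dataset <- function(x, ...) {
  data.frame(x$W, A = x$A, Y = x$Y)
}

#' @export
print.causal_dataset <- function(x, ...) {
  cat("causal_dataset: n =", length(x$Y), ", d =", ncol(x$W),
      ", treated =", sum(x$A), "\n")
  invisible(x)
}

#' Draw the univariate sinusoid regression experiment
#'
#' Samples `X ~ Uniform(-4, 4)` and `Y = 2 sin((pi/2) |X|) + eps` with
#' standard normal noise. The true regression function has sectional
#' variation norm 16 on `[-4, 4]`, making this a canonical test bed for
#' variation-norm-penalized regression.
#'
#' @param n Number of observations (>= 1).
#' @param seed Integer RNG seed.
#' @return A data frame with columns `X` and `Y`.
#' @export
gen_sinusoid <- function(n, seed = 1L) {
  if (n < 1) stop_invalid("n must be >= 1")
  with_seed(seed, {
    X <- runif(n, -4, 4)
    Y <- 2 * sin(pi / 2 * abs(X)) + rnorm(n)
    data.frame(X = X, Y = Y)
  })
}

# ---------------------------------------------------------------------------
# registered causal scenarios

dgp_registry <- function() {
  list(
    # W ~ U(0,1)^2, logistic treatment assignment depending on W1,
    # outcome linear in (W, A) with an optional A x W1 interaction so the
    # true ATE is closed-form: psi0 = a0 + a1 * E[W1] = a0 + a1 / 2.
    linear = function(params) {
      p <- modifyList(list(d = 2L, gamma = 2, b0 = 0.2, b1 = 1, b2 = 0.5,
                           a0 = 0.5, a1 = 0, sigma = 0.5), params)
      g1 <- function(W) plogis(p$gamma * (W[, 1] - 0.5))
      Qbar <- function(W, a) {
        b2w <- if (ncol(W) >= 2L) p$b2 * W[, 2] else 0
        p$b0 + p$b1 * W[, 1] + b2w + (p$a0 + p$a1 * W[, 1]) * a
      }
      list(params = p, g1 = g1, Qbar = Qbar,
           cate = function(W) p$a0 + p$a1 * W[, 1],
           psi0 = p$a0 + p$a1 / 2,
           draw_y = function(W, A, rngless_mean) rngless_mean + p$sigma * rnorm(nrow(W)))
    },
    # treatment depends on W1 but the outcome only on W2, so Y is fully
    # independent of A and psi0 = 0
    null = function(params) {
      p <- modifyList(list(d = 2L, gamma = 2, b0 = 0.2, b2 = 1,
                           sigma = 0.5), params)
      g1 <- function(W) plogis(p$gamma * (W[, 1] - 0.5))
      Qbar <- function(W, a) {
        p$b0 + if (ncol(W) >= 2L) p$b2 * W[, 2] else 0
      }
      list(params = p, g1 = g1, Qbar = Qbar,
           cate = function(W) rep(0, nrow(W)),
           psi0 = 0,
           draw_y = function(W, A, m) m + p$sigma * rnorm(nrow(W)))
    },
    # practical positivity violation: the treatment probability dips into
    # [0.001, 0.02] for W1 below ~0.3 (g1 = 0.001 + 0.999 expit(8 (W1 - 0.8)))
    near_positivity = function(params) {
      p <- modifyList(list(d = 2L, b0 = 0.2, b1 = 1, b2 = 0.5,
                           a0 = 0.5, a1 = 0, sigma = 0.5), params)
      g1 <- function(W) 0.001 + 0.999 * plogis(8 * (W[, 1] - 0.8))
      Qbar <- function(W, a) {
        b2w <- if (ncol(W) >= 2L) p$b2 * W[, 2] else 0
        p$b0 + p$b1 * W[, 1] + b2w + (p$a0 + p$a1 * W[, 1]) * a
      }
      list(params = p, g1 = g1, Qbar = Qbar,
           cate = function(W) p$a0 + p$a1 * W[, 1],
           psi0 = p$a0 + p$a1 / 2,
           draw_y = function(W, A, m) m + p$sigma * rnorm(nrow(W)))
    },
    # binary outcome through an expit link; psi0 obtained by integrating the
    # risk difference over W1 ~ U(0,1) (one-dimensional quadrature)
    binary = function(params) {
      p <- modifyList(list(d = 2L, gamma = 2, b0 = -0.5, b1 = 1, a0 = 1),
                      params)
      g1 <- function(W) plogis(p$gamma * (W[, 1] - 0.5))
      Qbar <- function(W, a) plogis(p$b0 + p$b1 * W[, 1] + p$a0 * a)
      psi0 <- stats::integrate(function(w) {
        plogis(p$b0 + p$b1 * w + p$a0) - plogis(p$b0 + p$b1 * w)
      }, 0, 1, rel.tol = 1e-10)$value
      list(params = p, g1 = g1, Qbar = Qbar,
           cate = function(W) {
             plogis(p$b0 + p$b1 * W[, 1] + p$a0) - plogis(p$b0 + p$b1 * W[, 1])
           },
           psi0 = psi0,
           draw_y = function(W, A, m) rbinom(nrow(W), 1L, m))
    }
  )
}

#' Specify a registered synthetic scenario
#'
#' @param name One of `"linear"`, `"null"`, `"near_positivity"`, `"binary"`.
#' @param params Named list overriding scenario parameters (coefficients,
#'   noise standard deviation `sigma`, treatment-assignment slope `gamma`,
#'   dimension `d`).
#' @return An object of class `dgp_spec` carrying the scenario name, the
#'   resolved parameters, and `truth`: the true ATE `psi0`, the outcome
#'   regression `Qbar(W, a)`, the propensity `g1(W)` and the CATE function.
#' @export
dgp_spec <- function(name, params = list()) {
  reg <- dgp_registry()
  if (!name %in% names(reg)) {
    stop_invalid("unknown scenario '", name, "'; registered: ",
                 paste(names(reg), collapse = ", "))
  }
  sc <- reg[[name]](params)
  structure(
    list(name = name, params = sc$params,
         truth = list(psi0 = sc$psi0, Qbar = sc$Qbar, g1 = sc$g1,
                      cate = sc$cate),
         draw_y = sc$draw_y),
    class = "dgp_spec")
}

#' Generate a causal dataset from a registered scenario
#'
#' @param spec A `dgp_spec` or a scenario name.
#' @param n Sample size (>= 1).
#' @param seed Integer RNG seed; identical `(spec, n, seed)` give identical
#'   datasets.
#' @param params Parameter overrides when `spec` is given by name.
#' @return A [causal_dataset] with attribute `spec` (the resolved
#'   `dgp_spec`, carrying the known truth).
#' @export
gen_ate_dgp <- function(spec, n, seed = 1L, params = list()) {
  if (is.character(spec)) spec <- dgp_spec(spec, params)
  stopifnot(inherits(spec, "dgp_spec"))
  if (n < 1) stop_invalid("n must be >= 1")
  dat <- with_seed(seed, {
    d <- spec$params$d
    W <- matrix(runif(n * d), n, d, dimnames = list(NULL, paste0("W", 1:d)))
    A <- rbinom(n, 1L, spec$truth$g1(W))
    Y <- spec$draw_y(W, A, spec$truth$Qbar(W, A))
    causal_dataset(W, A, Y)
  })
  attr(dat, "spec") <- spec
  dat
}

#' Grid approximation to the one-dimensional sectional variation norm
#'
#' For a univariate function the sectional variation norm reduces to
#' `|f(a)| + TV(f)` on the domain `[a, b]`; this routine approximates the
#' total variation by summing absolute increments over a fine regular grid,
#' converging to the true norm for cadlag `f` as `grid_size` grows. It
#' serves as an analytic oracle for variation norms of known functions.
#'
#' @param f Univariate function, vectorized over a numeric vector.
#' @param domain Length-2 numeric interval `c(a, b)`.
#' @param grid_size Number of grid points (>= 2).
#' @return Nonnegative scalar: `|f(a)| + sum |f(x_{i+1}) - f(x_i)|`.
#' @examples
#' true_variation_norm_1d(function(x) 2 * sin(pi / 2 * abs(x)), c(-4, 4))
#' @export
true_variation_norm_1d <- function(f, domain, grid_size = 1e5) {
  if (grid_size < 2) stop_invalid("grid_size must be >= 2")
  if (length(domain) != 2L || domain[2] <= domain[1]) {
    stop_invalid("domain must be an increasing length-2 interval")
  }
  x <- seq(domain[1], domain[2], length.out = grid_size)
  v <- f(x)
  if (!all(is.finite(v))) stop_numeric("f returned non-finite values")
  abs(v[1]) + sum(abs(diff(v)))
}
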