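# internal helpers shared across modules

#' @importFrom stats plogis qlogis rnorm runif quantile sd var coef
#' @importFrom stats binomial gaussian glm lm qnorm predict kmeans integrate
#' @importFrom stats glm.fit lm.fit rbinom
#' @importFrom utils modifyList combn head read.csv write.csv packageVersion
#' @importFrom methods as
NULL

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

# Run code with a local, seeded RNG stream; the global RNG state is
# untouched so library calls never perturb user simulations.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("halcausal_invalid_argument", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_numeric <- function(...) {
  stop(structure(
    class = c("halcausal_numeric_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

as_matrix_input <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  X
}

check_binary <- function(a, name = "A") {
  if (!all(a %in% c(0, 1))) {
    stop_invalid(name, " must be coded 0/1")
  }
  as.integer(a)
}

zcrit <- function(level) stats::qnorm((1 + level) / 2)
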