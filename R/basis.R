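# HAL basis construction: data-dependent knots and tensor-product spline
# design matrices.
#
# A zeroth-order basis function is an indicator I(x_s >= u) over a subset s
# of coordinates (closed at the knot, so fits are right-continuous step
# functions); a first-order basis function is the tensor product of hinges
# max(x_l - u_l, 0).  Knots are tabulated at observed data points, so the
# linear span of the dictionary is the sieve of cadlag functions with
# discrete support and the L1 norm of the coefficients is the sectional
# variation norm of the fitted function.

#' Enumerate a HAL basis dictionary from data
#'
#' Tabulates knot points for every nonempty subset of covariates up to
#' `max_degree`, forms the corresponding tensor-product basis functions and
#' removes terms that produce duplicated columns on the training data.
#'
#' @param X Numeric matrix or data frame of covariates (n rows, d columns).
#' @param max_degree Maximum interaction degree: only subsets `s` with
#'   `|s| <= max_degree` are used. Defaults to `min(d, 3)`.
#' @param knot_reduction Knot tabulation policy. `"all"` places knots at
#'   every observed data point (the canonical HAL dictionary, up to
#'   `n * (2^d - 1)` columns); `"quantiles"` uses `m` per-coordinate
#'   empirical quantiles before forming tensor products; `"kmeans"` uses `m`
#'   cluster centroids per subset; `"auto"` (default) uses `"all"` unless the
#'   candidate column count exceeds `column_budget`, in which case it falls
#'   back to `"quantiles"` with `m` chosen to respect the budget.
#' @param m Number of knots per coordinate (quantiles) or centroids per
#'   subset (kmeans). Must not exceed `n`.
#' @param order Spline order: `0` for indicator bases, `1` for first-order
#'   (hinge) splines.
#' @param column_budget Maximum number of candidate columns tolerated before
#'   `"auto"` switches to quantile knots.
#' @param seed Seed for the k-means initialization (ignored otherwise).
#' @return An object of class `hal_dictionary` with elements `order`, `d`,
#'   `groups` (one entry per subset: integer indices `s` and a knot matrix
#'   with `|s|` columns), `p` (number of retained terms), and `dedup`
#'   (candidate count and a map from removed duplicate terms to their
#'   retained representative).
#' @examples
#' X <- matrix(runif(40), ncol = 2)
#' dict <- enumerate_knots(X, max_degree = 2)
#' dim(evaluate_basis(dict, X))
#' @export
enumerate_knots <- function(X, max_degree = NULL,
                            knot_reduction = c("auto", "all", "quantiles", "kmeans"),
                            m = NULL, order = 0L, column_budget = 1e5,
                            seed = 1L) {
  X <- as_matrix_input(X)
  n <- nrow(X)
  d <- ncol(X)
  knot_reduction <- match.arg(knot_reduction)
  if (n < 1L || d < 1L) stop_invalid("X must have at least one row and column")
  if (is.null(max_degree)) max_degree <- min(d, 3L)
  if (max_degree < 1L || max_degree > d) {
    stop_invalid("max_degree must lie in [1, d]")
  }
  if (!order %in% c(0L, 1L)) stop_invalid("order must be 0 or 1")
  if (!is.null(m) && m > n) stop_invalid("m must not exceed n")

  subsets <- unlist(lapply(seq_len(max_degree), function(k) {
    asplit(utils::combn(d, k), 2L)
  }), recursive = FALSE)

  if (knot_reduction == "auto") {
    n_cand <- sum(vapply(subsets, function(s) {
      nrow(unique(X[, s, drop = FALSE]))
    }, numeric(1)))
    if (n_cand <= column_budget) {
      knot_reduction <- "all"
    } else {
      knot_reduction <- "quantiles"
      if (is.null(m)) {
        m <- n
        repeat {
          tot <- sum(vapply(subsets, function(s) {
            min(n, m^length(s))
          }, numeric(1)))
          if (tot <= column_budget || m <= 2L) break
          m <- max(2L, floor(m * 0.8))
        }
      }
    }
  }
  if (knot_reduction %in% c("quantiles", "kmeans") && is.null(m)) {
    stop_invalid("m must be supplied for knot_reduction = '", knot_reduction, "'")
  }

  groups <- lapply(subsets, function(s) {
    Xs <- X[, s, drop = FALSE]
    knots <- switch(knot_reduction,
      all = unique(Xs),
      quantiles = {
        qs <- lapply(seq_along(s), function(l) {
          unique(stats::quantile(Xs[, l], probs = seq(0, 1, length.out = m),
                                 type = 1, names = FALSE))
        })
        as.matrix(do.call(expand.grid, qs))
      },
      kmeans = {
        uniq <- unique(Xs)
        if (nrow(uniq) <= m) {
          uniq
        } else {
          km <- with_seed(seed, stats::kmeans(Xs, centers = m, nstart = 1L))
          km$centers
        }
      })
    knots <- as.matrix(knots)
    dimnames(knots) <- NULL
    storage.mode(knots) <- "double"
    # lexicographic row order => deterministic builds and dedup tie-breaks
    knots <- knots[do.call(base::order, asplit(knots, 2L)), , drop = FALSE]
    list(s = as.integer(s), knots = knots)
  })
  groups <- groups[vapply(groups, function(g) nrow(g$knots) > 0L, logical(1))]

  dict <- structure(
    list(order = as.integer(order), d = d, groups = groups,
         p = sum(vapply(groups, function(g) nrow(g$knots), numeric(1))),
         dedup = NULL),
    class = "hal_dictionary")

  # drop candidates whose training columns duplicate an earlier term;
  # candidate order (subset size, then lexicographic s, then lexicographic
  # knots) makes "keep the first" equal "keep the smallest (s, u)"
  Phi <- evaluate_basis(dict, X)
  keys <- design_column_keys(Phi)
  keep <- !duplicated(keys)
  removed_map <- NULL
  if (!all(keep)) {
    labels <- dict_term_labels(dict)
    rep_of <- match(keys, keys[keep])
    removed_map <- data.frame(
      removed = labels[!keep],
      retained = labels[which(keep)[rep_of[!keep]]],
      stringsAsFactors = FALSE)
  }
  dict <- subset_dictionary(dict, which(keep))
  dict$dedup <- list(n_candidates = length(keys),
                     n_retained = sum(keep),
                     map = removed_map)
  dict
}

#' Evaluate a HAL dictionary on new data
#'
#' @param dict A `hal_dictionary`.
#' @param X Numeric matrix with `dict$d` columns.
#' @return A sparse `dgCMatrix` with one row per row of `X` and one column
#'   per basis function. Entries are in `{0, 1}` for order 0 and nonnegative
#'   for order 1; the value at a knot itself is 1 for order 0 (right-closed
#'   convention).
#' @export
evaluate_basis <- function(dict, X) {
  stopifnot(inherits(dict, "hal_dictionary"))
  X <- as_matrix_input(X)
  if (ncol(X) != dict$d) {
    stop_invalid("X has ", ncol(X), " columns; dictionary expects ", dict$d)
  }
  chunks <- lapply(dict$groups, function(g) {
    out <- matrix(1, nrow(X), nrow(g$knots))
    for (l in seq_along(g$s)) {
      x <- X[, g$s[l]]
      if (dict$order == 0L) {
        out <- out * outer(x, g$knots[, l], `>=`)
      } else {
        out <- out * pmax(outer(x, g$knots[, l], `-`), 0)
      }
    }
    methods::as(methods::as(Matrix::Matrix(out, sparse = TRUE), "generalMatrix"),
                "CsparseMatrix")
  })
  if (length(chunks) == 0L) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = double(),
                                dims = c(nrow(X), 0L)))
  }
  do.call(cbind, chunks)
}

# keys identifying identical design columns (sparsity pattern + values)
design_column_keys <- function(Phi) {
  pp <- Phi@p
  ii <- Phi@i
  xx <- signif(Phi@x, 12)
  vapply(seq_len(ncol(Phi)), function(j) {
    if (pp[j + 1L] == pp[j]) return("<empty>")
    idx <- (pp[j] + 1L):pp[j + 1L]
    paste(ii[idx], xx[idx], sep = ":", collapse = ";")
  }, character(1))
}

dict_term_labels <- function(dict) {
  unlist(lapply(dict$groups, function(g) {
    vapply(seq_len(nrow(g$knots)), function(r) {
      paste0("s=", paste(g$s, collapse = ","),
             ";u=", paste(signif(g$knots[r, ], 12), collapse = ","))
    }, character(1))
  }))
}

# restrict a dictionary to a subset of its (global) column indices,
# preserving column order
subset_dictionary <- function(dict, cols) {
  stopifnot(inherits(dict, "hal_dictionary"))
  cols <- sort(unique(as.integer(cols)))
  sizes <- vapply(dict$groups, function(g) nrow(g$knots), integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  groups <- list()
  for (gi in seq_along(dict$groups)) {
    local <- cols[cols >= starts[gi] & cols <= ends[gi]] - starts[gi] + 1L
    if (length(local) > 0L) {
      g <- dict$groups[[gi]]
      groups[[length(groups) + 1L]] <-
        list(s = g$s, knots = g$knots[local, , drop = FALSE])
    }
  }
  out <- dict
  out$groups <- groups
  out$p <- length(cols)
  out$dedup <- NULL
  out
}

#' @export
print.hal_dictionary <- function(x, ...) {
  cat("HAL basis dictionary\n")
  cat("  covariates:", x$d, " order:", x$order, "\n")
  cat("  terms:", x$p, "in", length(x$groups), "coordinate subsets\n")
  if (!is.null(x$dedup)) {
    cat("  candidates:", x$dedup$n_candidates,
        "(", x$dedup$n_candidates - x$dedup$n_retained,
        "duplicate columns removed )\n")
  }
  invisible(x)
}
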