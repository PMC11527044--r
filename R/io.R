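# Dataset, model and result I/O: CSV in, JSON out.

#' Read a causal dataset from delimited text
#'
#' @param path CSV file with a header row.
#' @param outcome,treatment Column names of the outcome and treatment.
#' @param covariates Covariate column names; defaults to every other column.
#' @param treatment_map Optional length-2 character vector
#'   `c(control, treated)` mapping a non-numeric treatment column to 0/1.
#' @return A [causal_dataset].
#' @export
read_causal_data <- function(path, outcome = "Y", treatment = "A",
                             covariates = NULL, treatment_map = NULL) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c(outcome, treatment, covariates)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop_invalid("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(covariates)) {
    covariates <- setdiff(names(df), c(outcome, treatment))
  }
  if (length(covariates) == 0L) stop_invalid("no covariate columns")
  sub <- df[, c(covariates, treatment, outcome)]
  if (anyNA(sub)) {
    bad <- which(rowSums(is.na(sub)) > 0)
    stop_invalid("missing values in rows: ",
                 paste(utils::head(bad, 20), collapse = ", "))
  }
  a <- df[[treatment]]
  if (!is.null(treatment_map)) {
    if (!all(a %in% treatment_map)) {
      stop_invalid("treatment values outside mapping: ",
                   paste(setdiff(unique(a), treatment_map), collapse = ", "))
    }
    message("treatment mapping: ", treatment_map[1], " -> 0, ",
            treatment_map[2], " -> 1")
    a <- as.integer(a == treatment_map[2])
  }
  if (!all(a %in% c(0, 1))) {
    stop_invalid("treatment column must be 0/1 (or supply treatment_map)")
  }
  causal_dataset(as.matrix(df[, covariates, drop = FALSE]), a, df[[outcome]])
}

#' Write an analysis result to JSON
#'
#' Serializes estimates, uncertainty and diagnostics together with a config
#' echo, the seed and the package version so every run is reproducible from
#' its output artifact. Numbers are written at full precision, so re-reading
#' the file reproduces them exactly.
#'
#' @param result An `ate_estimate`, `bootstrap_path`,
#'   `working_model_inference`, `hal_fit` or plain list.
#' @param path Output file path.
#' @param config Optional named list echoed into the output.
#' @return Invisibly, the list that was written.
#' @export
write_result <- function(result, path, config = list()) {
  out <- c(result_payload(result),
           list(config = config,
                software = list(
                  package = "halcausal",
                  version = as.character(utils::packageVersion("halcausal")))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(out)
}

result_payload <- function(result) {
  if (inherits(result, "ate_estimate")) {
    list(type = "ate_estimate", method = result$method, psi = result$psi,
         se = result$se, ci = as.list(result$ci), level = result$level,
         pn_eic = result$pn_eic, epsilon = result$epsilon, n = result$n,
         diagnostics = result$diagnostics)
  } else if (inherits(result, "bootstrap_path")) {
    list(type = "bootstrap_path", lambda_grid = result$lambda_grid,
         widths = result$widths,
         intervals = list(lo = result$intervals[1, ],
                          hi = result$intervals[2, ]),
         variation_norms = result$variation_norms, B = result$B,
         seed = result$seed, level = result$level,
         lambda_plateau = result$lambda_plateau,
         plateau_found = result$plateau_found,
         final_interval = as.list(result$final_interval))
  } else if (inherits(result, "working_model_inference")) {
    list(type = "working_model_inference", target = result$type,
         grid = result$target_grid, estimates = result$estimates,
         se = result$se, ci_lo = result$ci_lo, ci_hi = result$ci_hi,
         band_lo = result$band_lo, band_hi = result$band_hi,
         q_band = result$q_band, level = result$level)
  } else if (inherits(result, "hal_fit")) {
    list(type = "hal_fit_summary", family = result$family, n = result$n,
         lambda = result$lambda_sel,
         support_size = length(result$support),
         variation_norm = variation_norm(result))
  } else if (is.list(result)) {
    result
  } else {
    stop_invalid("unsupported result type: ", class(result)[1])
  }
}

#' Save a HAL model (dictionary and coefficients) as portable JSON
#'
#' @param fit A `hal_fit`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_hal_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hal_fit"))
  obj <- list(
    format = "halcausal_model_v1",
    family = fit$family, order = fit$dict$order, d = fit$dict$d,
    lambda = fit$lambda_sel, relaxed = isTRUE(fit$relaxed), n = fit$n,
    beta0 = fit$beta0,
    groups = lapply(fit$dict$groups, function(g) {
      list(s = g$s, knots = apply(g$knots, 1, function(r) as.list(r),
                                  simplify = FALSE))
    }),
    beta = fit$beta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a HAL model saved by [save_hal_fit()]
#'
#' @param path JSON file path.
#' @return A `hal_fit` usable with [predict.hal_fit()].
#' @export
load_hal_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "halcausal_model_v1")) {
    stop_invalid("not a halcausal model file: ", path)
  }
  groups <- lapply(obj$groups, function(g) {
    knots <- do.call(rbind, lapply(g$knots, function(r) unlist(r)))
    dimnames(knots) <- NULL
    list(s = as.integer(unlist(g$s)), knots = knots)
  })
  dict <- structure(
    list(order = as.integer(obj$order), d = as.integer(obj$d),
         groups = groups,
         p = sum(vapply(groups, function(g) nrow(g$knots), numeric(1))),
         dedup = NULL),
    class = "hal_dictionary")
  beta <- as.numeric(unlist(obj$beta))
  structure(
    list(dict = dict, family = obj$family, n = as.integer(obj$n),
         lambda = obj$lambda, a0 = obj$beta0,
         beta_path = Matrix::Matrix(beta, ncol = 1, sparse = TRUE),
         penalty_factor = rep(1, length(beta)),
         cv = NULL, lambda_cv = obj$lambda, sel = 1L,
         lambda_sel = obj$lambda, beta0 = obj$beta0, beta = beta,
         support = which(beta != 0), relaxed = isTRUE(obj$relaxed)),
    class = "hal_fit")
}

#' Write a dataset to CSV
#'
#' @param data A [causal_dataset] or data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(data, path) {
  df <- if (inherits(data, "causal_dataset")) as.data.frame(data) else data
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
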