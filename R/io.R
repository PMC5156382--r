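#' Read a daily climate CSV
#'
#' Expects a header row with a `Date` column in `dd/mm/yyyy` and one
#' numeric climate column.
#'
#' @param path CSV file path.
#' @param xvar name of the climate column; default: the single non-date
#'   column.
#' @return a [climate_series()].
#' @export
read_climate_csv <- function(path, xvar = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  dcol <- grep("^date$", names(df), ignore.case = TRUE, value = TRUE)
  if (length(dcol) != 1L) stop("need exactly one Date column", call. = FALSE)
  if (is.null(xvar)) {
    others <- setdiff(names(df), dcol)
    if (length(others) != 1L) {
      stop("multiple candidate climate columns; specify xvar", call. = FALSE)
    }
    xvar <- others
  }
  climate_series(df[[dcol]], df[[xvar]], varname = xvar)
}

#' Read a biological response CSV
#'
#' Expects a header row with a `Date` column (`dd/mm/yyyy`), the response
#' column, and optional covariate/group columns.
#'
#' @param path CSV file path.
#' @param response name of the response column.
#' @param covariates character vector of covariate column names.
#' @param group optional group column name.
#' @return a [biol_table()].
#' @export
read_biol_csv <- function(path, response, covariates = NULL, group = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  dcol <- grep("^date$", names(df), ignore.case = TRUE, value = TRUE)
  if (length(dcol) != 1L) stop("need exactly one Date column", call. = FALSE)
  if (!response %in% names(df)) {
    stop("response column '", response, "' not found", call. = FALSE)
  }
  covs <- if (!is.null(covariates)) df[covariates]
  grp <- if (!is.null(group)) df[[group]]
  bt <- biol_table(df[[dcol]], df[[response]], covariates = covs,
                   group = grp)
  names(bt)[2L] <- response
  bt
}

#' Serialize a sliding-window model set to CSV
#'
#' Writes the ranked candidate table (window_start, window_end,
#' delta_aicc, beta, se, mod_weight, ...) and can be read back with
#' [read_modelset_csv()].
#'
#' @param modelset a `window_modelset`.
#' @param path output CSV path.
#' @export
write_modelset_csv <- function(modelset, path) {
  utils::write.csv(modelset_dataset(modelset), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modelset_csv
#' @return `read_modelset_csv` returns the candidate table as a data
#'   frame ordered as written.
#' @export
read_modelset_csv <- function(path) {
  utils::read.csv(path)
}

#' Serialize a weighted-window result
#'
#' Writes a one-row summary CSV (delta_aicc, shape, scale, location,
#' beta, se, convergence) and, optionally, the (offset, weight) table.
#'
#' @param result a `weighted_result` from [weightwin()].
#' @param path summary CSV path.
#' @param weights_path optional CSV path for the weight curve.
#' @export
write_weighted_csv <- function(result, path, weights_path = NULL) {
  summ <- data.frame(delta_aicc = result$delta_aicc,
                     shape = result$par[["shape"]],
                     scale = result$par[["scale"]],
                     location = result$par[["location"]],
                     beta = result$beta, se = result$se,
                     converged = result$report$convergence)
  utils::write.csv(summ, path, row.names = FALSE)
  if (!is.null(weights_path)) {
    utils::write.csv(result$weights, weights_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a resolved run configuration as YAML
#'
#' Every analysis run can record its full configuration (paths,
#' window settings, seed) next to its outputs for reproducibility.
#'
#' @param config named list of settings.
#' @param path output YAML path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
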