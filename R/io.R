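# Series / result I/O: CSV for time series and study tables, JSON for fit
# results and designs. CSV dialect: comma-separated, header, UTF-8, '.'
# decimal, floats at 10 significant digits.

.schema_version <- "1.0"

#' Read a binomial time series from CSV
#'
#' Required columns `y` (successes) and `n` (trials); every remaining
#' numeric column is treated as a covariate in header order, and an
#' intercept column is added automatically. Row order is time order.
#'
#' @param path Path to a CSV file with a header.
#' @return A [binomial_series()] with covariate names from the header.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("y", "n") %in% names(df)))
    stop("CSV must contain columns 'y' and 'n'")
  if (anyNA(df)) stop("missing values in input CSV")
  covars <- setdiff(names(df), c("y", "n", "t"))
  if (any(df$y != floor(df$y)) || any(df$n != floor(df$n)))
    stop("non-integer y or n in input CSV")
  bad <- which(df$y > df$n)
  if (length(bad)) stop(sprintf("y exceeds n at row %d", bad[1]))
  X <- if (length(covars)) as.matrix(df[covars]) else
    matrix(numeric(0), nrow(df), 0)
  binomial_series(df$y, df$n, cbind(`(Intercept)` = 1, X))
}

#' Write a binomial time series to CSV
#'
#' Columns `t, y, n, <covariates>`; inverse of [read_series_csv()].
#'
#' @param series A [binomial_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (!inherits(series, "binomial_series")) stop("`series` must be a binomial_series")
  X <- series$X[, -1, drop = FALSE]
  cn <- colnames(X)
  if (is.null(cn) || !all(nzchar(cn))) cn <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(t = seq_len(series$T), y = series$y, n = series$n)
  for (j in seq_len(ncol(X))) df[[cn[j]]] <- signif(X[, j], 10)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a fit result to JSON
#'
#' Fixed field names: `beta_hat`, `alpha_hat`, `se`, `loglik`, `converged`,
#' `family`, `n_iter`, plus `schema_version`.
#'
#' @param fit A [cmc_fit()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  if (!inherits(fit, "cmc_fit")) stop("`fit` must be a cmc_fit")
  obj <- list(schema_version = .schema_version,
              family = fit$family,
              beta_hat = unname(fit$beta_hat),
              alpha_hat = fit$alpha_hat,
              se = unname(fit$se),
              loglik = fit$loglik,
              converged = fit$converged,
              n_iter = fit$n_iter)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a fit result from JSON
#'
#' @param path Path written by [write_fit_json()].
#' @return A `"cmc_fit"` object.
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("fit file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(beta_hat = obj$beta_hat, alpha_hat = obj$alpha_hat,
                 se = obj$se, loglik = obj$loglik,
                 converged = isTRUE(obj$converged),
                 n_iter = obj$n_iter, family = obj$family,
                 include_first = TRUE,
                 tau_hat = param_to_tau(copula_spec(obj$family, obj$alpha_hat))),
            class = "cmc_fit")
}
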