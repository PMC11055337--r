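#' Tidy a spatial Durbin model fit
#'
#' @param x An `sdm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`rho`/`phi`, the
#'   covariates, and the `W.`-prefixed spatially lagged covariates):
#'   `term`, `estimate`, `std.error`, `statistic`, `p.value`. Standard
#'   errors come from the QML coefficient covariance when available.
#' @export
tidy.sdm_fit <- function(x, ...) {
  terms <- c(
    if (x$constraint %in% c("none", "sar")) stats::setNames(x$rho, "rho"),
    if (x$constraint == "sem") stats::setNames(x$phi, "phi"),
    if (!is.null(x$intercept)) stats::setNames(x$intercept, "(intercept)"),
    stats::setNames(x$beta, x$covariates),
    if (x$constraint == "none") stats::setNames(x$theta, paste0("W.", x$covariates))
  )
  se <- rep(NA_real_, length(terms))
  names(se) <- names(terms)
  if (!is.null(x$vcov)) {
    avail <- intersect(names(terms), rownames(x$vcov))
    se[avail] <- sqrt(pmax(diag(x$vcov)[avail], 0))
  }
  stat <- unname(terms) / se
  tibble::tibble(
    term = names(terms),
    estimate = unname(terms),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * stats::pnorm(-abs(unname(stat)))
  )
}

#' Glance at a spatial Durbin model fit
#'
#' @param x An `sdm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `rho`, `phi`, `sigma2`, `logLik`,
#'   `r.squared`, `nobs`, `n.provinces`, `n.years`, `fixed.effects`,
#'   `constraint`.
#' @export
glance.sdm_fit <- function(x, ...) {
  tibble::tibble(
    rho = x$rho, phi = x$phi, sigma2 = x$sigma2, logLik = x$loglik,
    r.squared = x$r_squared, nobs = x$N,
    n.provinces = x$n, n.years = x$T,
    fixed.effects = x$fixed_effects, constraint = x$constraint
  )
}

#' Tidy an LSTM fit
#'
#' @param x An `lstm_fit` object.
#' @param ... Unused.
#' @return A tibble of per-year observed and predicted values over the
#'   train and test spans, with a `span` column.
#' @export
tidy.lstm_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$fitted, span = "train"),
    dplyr::mutate(x$test, span = "test")
  )
}

#' Glance at an LSTM fit
#'
#' @param x An `lstm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: `train_rmse`, `test_rmse`, `final_loss`,
#'   `epochs`, `hidden_units`, `lookback`.
#' @export
glance.lstm_fit <- function(x, ...) {
  tibble::tibble(
    train_rmse = x$train_rmse, test_rmse = x$test_rmse,
    final_loss = x$loss_history[length(x$loss_history)],
    epochs = x$config$epochs, hidden_units = x$config$hidden_units,
    lookback = x$config$lookback
  )
}

#' @importFrom stats pnorm
NULL
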