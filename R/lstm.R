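#' LSTM training configuration
#'
#' The forecasting protocol for the national mean cost series: a single
#' LSTM layer of 50 units trained for 150 epochs with a 5% dropout rate
#' (the "forget rate" of the protocol, read as dropout on the layer
#' output; the forget gate itself stays fully parameterised), a 2:1
#' train/test split realised as the explicit year spans 1992-2011 and
#' 2012-2021, min-max scaling of the series to [0, 1], a sliding lookback
#' window of 3 years, and recursive multi-step forecasting to 2030.
#'
#' @param hidden_units LSTM state size; default 50.
#' @param epochs Training iterations (full-batch); default 150.
#' @param dropout_rate Dropout probability on the layer output during
#'   training; default 0.05. Inference is always deterministic.
#' @param train_span,test_span Length-2 year ranges; must be disjoint,
#'   contiguous and ordered. Defaults 1992-2011 and 2012-2021.
#' @param horizon_end Last year of the recursive forecast; default 2030.
#' @param lookback Window length in years; default 3.
#' @param seed Mandatory seed (weight initialisation and dropout masks).
#' @param learning_rate Adam step size; default 0.02.
#'
#' @return An `lstm_config` list.
#' @export
lstm_config <- function(hidden_units = 50, epochs = 150, dropout_rate = 0.05,
                        train_span = c(1992, 2011), test_span = c(2012, 2021),
                        horizon_end = 2030, lookback = 3, seed,
                        learning_rate = 0.02) {
  if (missing(seed)) abort("A `seed` is mandatory for LSTM training.")
  assert_number(hidden_units, "hidden_units", lower = 1)
  assert_number(epochs, "epochs", lower = 1)
  assert_number(dropout_rate, "dropout_rate", lower = 0, upper = 1,
                strict_upper = TRUE)
  assert_number(lookback, "lookback", lower = 1)
  if (train_span[2] + 1 != test_span[1] || train_span[1] > train_span[2] ||
      test_span[1] > test_span[2]) {
    abort("Train and test spans must be ordered, disjoint and contiguous.")
  }
  structure(
    list(hidden_units = as.integer(hidden_units), epochs = as.integer(epochs),
         dropout_rate = dropout_rate, train_span = train_span,
         test_span = test_span, horizon_end = horizon_end,
         lookback = as.integer(lookback), seed = as.integer(seed),
         learning_rate = learning_rate),
    class = "lstm_config"
  )
}

# --- parameter container -----------------------------------------------------

init_lstm_params <- function(n_h) {
  u <- function(r, c) matrix(runif(r * c, -0.08, 0.08), r, c)
  list(
    Wf = u(n_h, 1), Uf = u(n_h, n_h), bf = rep(1, n_h), # forget bias at 1
    Wg = u(n_h, 1), Ug = u(n_h, n_h), bg = rep(0, n_h),
    Wo = u(n_h, 1), Uo = u(n_h, n_h), bo = rep(0, n_h),
    Wc = u(n_h, 1), Uc = u(n_h, n_h), bc = rep(0, n_h),
    w_out = u(n_h, 1), b_out = 0
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass over a batch of windows. X: lookback x B matrix of scaled
# inputs. Returns the cache needed for backpropagation through time.
lstm_forward <- function(params, X, drop_mask = NULL) {
  L <- nrow(X); B <- ncol(X); n_h <- nrow(params$Uf)
  H <- matrix(0, n_h, B); C <- matrix(0, n_h, B)
  cache <- vector("list", L)
  for (t in seq_len(L)) {
    xt <- matrix(X[t, ], 1, B)
    af <- params$Wf %*% xt + params$Uf %*% H + params$bf
    ag <- params$Wg %*% xt + params$Ug %*% H + params$bg
    ao <- params$Wo %*% xt + params$Uo %*% H + params$bo
    ac <- params$Wc %*% xt + params$Uc %*% H + params$bc
    f <- sigmoid(af); g <- sigmoid(ag); o <- sigmoid(ao); ct <- tanh(ac)
    C_prev <- C; H_prev <- H
    C <- f * C_prev + g * ct
    H <- o * tanh(C)
    cache[[t]] <- list(xt = xt, f = f, g = g, o = o, ct = ct,
                       C = C, C_prev = C_prev, H_prev = H_prev)
  }
  H_out <- if (is.null(drop_mask)) H else H * drop_mask
  yhat <- as.vector(crossprod(params$w_out, H_out)) + params$b_out
  list(yhat = yhat, H = H, H_out = H_out, cache = cache)
}

# Backpropagation through time for the squared-error loss.
lstm_backward <- function(params, fw, X, target, drop_mask = NULL) {
  B <- ncol(X); L <- nrow(X); n_h <- nrow(params$Uf)
  dyhat <- matrix(2 * (fw$yhat - target) / B, 1, B)
  grads <- lapply(params, function(p) if (is.matrix(p)) p * 0 else p * 0)
  grads$w_out <- fw$H_out %*% t(dyhat)
  grads$b_out <- sum(dyhat)
  dH <- params$w_out %*% dyhat
  if (!is.null(drop_mask)) dH <- dH * drop_mask
  dC <- matrix(0, n_h, B)
  for (t in rev(seq_len(L))) {
    cc <- fw$cache[[t]]
    tanhC <- tanh(cc$C)
    do_ <- dH * tanhC
    dC <- dC + dH * cc$o * (1 - tanhC^2)
    df <- dC * cc$C_prev
    dg <- dC * cc$ct
    dct <- dC * cc$g
    daf <- df * cc$f * (1 - cc$f)
    dag <- dg * cc$g * (1 - cc$g)
    dao <- do_ * cc$o * (1 - cc$o)
    dac <- dct * (1 - cc$ct^2)
    grads$Wf <- grads$Wf + daf %*% t(cc$xt)
    grads$Wg <- grads$Wg + dag %*% t(cc$xt)
    grads$Wo <- grads$Wo + dao %*% t(cc$xt)
    grads$Wc <- grads$Wc + dac %*% t(cc$xt)
    grads$Uf <- grads$Uf + daf %*% t(cc$H_prev)
    grads$Ug <- grads$Ug + dag %*% t(cc$H_prev)
    grads$Uo <- grads$Uo + dao %*% t(cc$H_prev)
    grads$Uc <- grads$Uc + dac %*% t(cc$H_prev)
    grads$bf <- grads$bf + rowSums(daf)
    grads$bg <- grads$bg + rowSums(dag)
    grads$bo <- grads$bo + rowSums(dao)
    grads$bc <- grads$bc + rowSums(dac)
    dH <- t(params$Uf) %*% daf + t(params$Ug) %*% dag +
      t(params$Uo) %*% dao + t(params$Uc) %*% dac
    dC <- dC * cc$f
  }
  grads
}

# --- public API --------------------------------------------------------------

#' Fit an LSTM to an annual series
#'
#' Trains the LSTM on one-step-ahead prediction over sliding windows of
#' the min-max-scaled series (the scaler is fitted on the full observed
#' series) by full-batch Adam on the squared error, with seeded
#' initialisation and seeded per-epoch dropout masks so that a fixed seed
#' reproduces the fit bit for bit. Fitted values over the training span
#' and one-step predictions over the test span (windows containing
#' observed values) are reported with their RMSE on the original scale.
#'
#' @param series Data frame with columns `year` and `value`, covering the
#'   configured train and test spans without gaps.
#' @param config An [lstm_config()].
#'
#' @return An `lstm_fit` object: trained parameters, scaler, per-epoch
#'   loss history, `fitted` and `test` tibbles, `train_rmse` and
#'   `test_rmse`.
#' @export
fit_lstm <- function(series, config) {
  stopifnot(inherits(config, "lstm_config"))
  if (!all(c("year", "value") %in% names(series))) {
    abort("`series` needs `year` and `value` columns.")
  }
  series <- dplyr::arrange(tibble::as_tibble(series), .data$year)
  span_years <- seq(config$train_span[1], config$test_span[2])
  if (!all(span_years %in% series$year)) {
    abort("`series` must cover the train and test spans with no missing years.")
  }
  series <- dplyr::filter(series, .data$year %in% span_years)
  if (anyNA(series$value)) abort("`series` has missing values in the spans.")

  rng <- range(series$value)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)  # constant series
  scaler <- list(min = rng[1], max = rng[2])
  scaled <- (series$value - scaler$min) / (scaler$max - scaler$min)
  names(scaled) <- series$year

  L <- config$lookback
  train_targets <- seq(config$train_span[1] + L, config$train_span[2])
  test_targets <- seq(config$test_span[1], config$test_span[2])
  make_batch <- function(targets) {
    X <- vapply(targets, function(y) {
      scaled[as.character(seq(y - L, y - 1))]
    }, numeric(L))
    list(X = matrix(X, nrow = L), y = scaled[as.character(targets)])
  }
  train <- make_batch(train_targets)
  test <- make_batch(test_targets)

  set.seed(derive_seed(config$seed, "lstm"))
  params <- init_lstm_params(config$hidden_units)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate
  loss_history <- numeric(config$epochs)
  B <- ncol(train$X)
  for (epoch in seq_len(config$epochs)) {
    mask <- if (config$dropout_rate > 0) {
      keep <- (matrix(runif(config$hidden_units * B), config$hidden_units, B) >=
                 config$dropout_rate) * 1
      keep / (1 - config$dropout_rate)
    } else NULL
    fw <- lstm_forward(params, train$X, drop_mask = mask)
    loss <- mean((fw$yhat - train$y)^2)
    if (!is.finite(loss)) {
      abort(paste0("Training loss became non-finite at epoch ", epoch,
                   "; lower `learning_rate` (current ", lr, ")."))
    }
    loss_history[epoch] <- loss
    grads <- lstm_backward(params, fw, train$X, train$y, drop_mask = mask)
    for (nm in names(params)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grads[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * grads[[nm]]^2
      mh <- m[[nm]] / (1 - b1^epoch)
      vh <- v[[nm]] / (1 - b2^epoch)
      params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    }
  }

  unscale <- function(z) z * (scaler$max - scaler$min) + scaler$min
  pred_train <- unname(unscale(lstm_forward(params, train$X)$yhat))
  pred_test <- unname(unscale(lstm_forward(params, test$X)$yhat))
  obs_train <- unname(unscale(train$y))
  obs_test <- unname(unscale(test$y))

  structure(
    list(
      params = params, config = config, scaler = scaler,
      series = series, loss_history = loss_history,
      fitted = tibble::tibble(year = train_targets, observed = obs_train,
                              predicted = pred_train),
      test = tibble::tibble(year = test_targets, observed = obs_test,
                            predicted = pred_test),
      train_rmse = sqrt(mean((pred_train - obs_train)^2)),
      test_rmse = sqrt(mean((pred_test - obs_test)^2))
    ),
    class = "lstm_fit"
  )
}

#' Recursive multi-step forecast from a trained LSTM
#'
#' Rolls the trained network forward past the last observed year: each
#' new year is predicted from a window that contains earlier predictions
#' once observations run out, and results are inverse-scaled to the
#' original units. Inference uses no dropout and is deterministic for a
#' fixed fitted state.
#'
#' @param fit An `lstm_fit` from [fit_lstm()].
#' @param horizon_end Last forecast year; defaults to the configured
#'   horizon. Equal to the last observed year gives an empty forecast;
#'   earlier is an error.
#'
#' @return A `forecast_result` tibble with columns `year`, `value`,
#'   `segment` (`observed` / `fitted` / `test_prediction` / `forecast`).
#' @export
forecast_recursive <- function(fit, horizon_end = NULL) {
  stopifnot(inherits(fit, "lstm_fit"))
  config <- fit$config
  horizon_end <- horizon_end %||% config$horizon_end
  last_obs <- max(fit$series$year)
  if (horizon_end < last_obs) {
    abort(sprintf("`horizon_end` (%d) is before the last observed year (%d).",
                  horizon_end, last_obs))
  }
  scaler <- fit$scaler
  scaled <- (fit$series$value - scaler$min) / (scaler$max - scaler$min)
  names(scaled) <- fit$series$year
  L <- config$lookback
  horizon_years <- if (horizon_end > last_obs) {
    seq(last_obs + 1, horizon_end)
  } else {
    integer(0)
  }
  values <- scaled
  for (y in horizon_years) {
    window <- values[as.character(seq(y - L, y - 1))]
    pred <- lstm_forward(fit$params, matrix(window, ncol = 1))$yhat
    values[as.character(y)] <- pred
  }
  unscale <- function(z) z * (scaler$max - scaler$min) + scaler$min
  out <- dplyr::bind_rows(
    tibble::tibble(year = fit$series$year, value = fit$series$value,
                   segment = "observed"),
    tibble::tibble(year = fit$fitted$year, value = fit$fitted$predicted,
                   segment = "fitted"),
    tibble::tibble(year = fit$test$year, value = fit$test$predicted,
                   segment = "test_prediction"),
    tibble::tibble(year = horizon_years,
                   value = unscale(values[as.character(horizon_years)]),
                   segment = "forecast")
  )
  structure(out, train_rmse = fit$train_rmse, test_rmse = fit$test_rmse,
            class = c("forecast_result", "tbl_df", "tbl", "data.frame"))
}

#' Plot an LSTM forecast
#'
#' @param result A `forecast_result` from [forecast_recursive()].
#' @return A ggplot: observed series, in-sample fit, test predictions and
#'   the recursive forecast.
#' @export
plot_forecast <- function(result) {
  ggplot2::ggplot(result, ggplot2::aes(x = .data$year, y = .data$value,
                                       colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = NULL, y = "carbon cost (CNY/tCO2e)") +
    ggplot2::theme_minimal()
}

#' @export
print.lstm_fit <- function(x, ...) {
  cat(sprintf("<lstm_fit> %d units, %d epochs, lookback %d\n",
              x$config$hidden_units, x$config$epochs, x$config$lookback))
  cat(sprintf("  train RMSE %.4f, test RMSE %.4f (original units)\n",
              x$train_rmse, x$test_rmse))
  invisible(x)
}
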