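# Spatial panel econometrics: balanced-panel layout, within transformations,
# Lagrange-multiplier dependence tests, and quasi-maximum-likelihood
# estimation of the spatial Durbin model and its SAR / SEM / OLS limits.

# Reshape a balanced panel into n x T outcome and covariate matrices whose
# row order matches the weight matrix.
panel_arrays <- function(panel, W, outcome, covariates) {
  if (!inherits(W, "spatial_weights")) abort("`W` must be a spatial_weights object.")
  need <- c("province", "year", outcome, covariates)
  missing_cols <- setdiff(need, names(panel))
  if (length(missing_cols)) {
    abort(paste0("Panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  provs <- W$provinces
  if (!setequal(unique(as.character(panel$province)), provs)) {
    abort("Panel provinces do not match the weight matrix units.")
  }
  years <- sort(unique(panel$year))
  n <- length(provs); T_ <- length(years)
  if (nrow(panel) != n * T_) {
    abort(sprintf("Panel is not balanced: %d rows != %d provinces x %d years.",
                  nrow(panel), n, T_))
  }
  idx <- order(match(as.character(panel$province), provs), panel$year)
  panel <- panel[idx, ]
  shape <- function(col) {
    matrix(panel[[col]], nrow = n, ncol = T_, byrow = TRUE,
           dimnames = list(provs, years))
  }
  vals <- lapply(c(outcome, covariates), shape)
  names(vals) <- c(outcome, covariates)
  for (col in c(outcome, covariates)) {
    if (anyNA(vals[[col]])) abort(sprintf("Column `%s` has missing values.", col))
  }
  list(Y = vals[[outcome]], X = vals[covariates],
       provinces = provs, years = years, n = n, T = T_)
}

# Within transformation for an n x T matrix.
demean_matrix <- function(M, fixed_effects) {
  switch(fixed_effects,
    none = M,
    province = M - rowMeans(M),
    year = sweep(M, 2, colMeans(M)),
    twoway = sweep(M - rowMeans(M), 2, colMeans(M - rowMeans(M)))
  )
}

# Effective sample size, log-determinant multiplicity and eigenvalue set for
# the transformed QML likelihood. Cross-sectional demeaning removes the
# constant eigenvector of a row-standardised W, so its unit eigenvalue is
# dropped from the log-determinant in the year and two-way cases.
fe_likelihood_parts <- function(fixed_effects, n, T_, eigenvalues) {
  switch(fixed_effects,
    none = list(N = n * T_, mult = T_, eig = eigenvalues),
    province = list(N = n * (T_ - 1), mult = T_ - 1, eig = eigenvalues),
    year = list(N = (n - 1) * T_, mult = T_,
                eig = drop_unit_eigenvalue(eigenvalues)),
    twoway = list(N = (n - 1) * (T_ - 1), mult = T_ - 1,
                  eig = drop_unit_eigenvalue(eigenvalues))
  )
}

drop_unit_eigenvalue <- function(eigenvalues) {
  i <- which.min(abs(eigenvalues - 1))
  eigenvalues[-i]
}

real_eigenvalues <- function(W) {
  ev <- eigen(W$W, only.values = TRUE)$values
  Re(ev)
}

#' Lagrange-multiplier tests for spatial dependence
#'
#' Classical score tests on (pooled, optionally within-transformed) OLS
#' residuals for spatial error and spatial lag dependence, with the robust
#' variants that adjust each statistic for local presence of the other
#' alternative. With residuals `e`, fitted values from `X`, and
#' `T1 = tr(W'W + WW)` accumulated over time periods, the error statistic
#' is `(e'We / sigma2)^2 / T1` and the lag statistic divides the score
#' `e'Wy / sigma2` by `J = (WXb)'M(WXb)/sigma2 + T1`. All four are
#' referred to a chi-squared distribution with one degree of freedom.
#'
#' @param panel Balanced panel tibble.
#' @param W Row-standardised `spatial_weights`.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of covariate columns.
#' @param fixed_effects `"none"`, `"province"`, `"year"` or `"twoway"`;
#'   the within transformation applied before the OLS fit.
#'
#' @return An `lm_test_report` tibble with columns `test`, `statistic`,
#'   `p_value` for `lm_error`, `robust_lm_error`, `lm_lag`,
#'   `robust_lm_lag`.
#' @export
lm_tests <- function(panel, W, outcome, covariates,
                     fixed_effects = c("none", "province", "year", "twoway")) {
  fixed_effects <- match.arg(fixed_effects)
  arr <- panel_arrays(panel, W, outcome, covariates)
  Wm <- W$W
  n <- arr$n; T_ <- arr$T

  # spatial lags are formed on the raw data and the within transformation
  # is applied afterwards: Q(Wy) != W(Qy) once cross-sectional demeaning
  # is involved (1'W != 1' even for a row-standardised W)
  Y <- demean_matrix(arr$Y, fixed_effects)
  Xs <- lapply(arr$X, demean_matrix, fixed_effects = fixed_effects)

  y <- as.vector(Y)
  Z <- do.call(cbind, lapply(Xs, as.vector))
  if (fixed_effects == "none") Z <- cbind(`(intercept)` = 1, Z)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) abort("Covariate matrix is rank deficient.")
  e <- qr.resid(qrz, y)
  N <- length(y)
  sigma2 <- sum(e^2) / N

  Wy <- as.vector(demean_matrix(Wm %*% arr$Y, fixed_effects))
  E <- matrix(e, nrow = n)
  We <- as.vector(demean_matrix(Wm %*% E, fixed_effects))
  fitted <- qr.fitted(qrz, y)
  WXb <- as.vector(demean_matrix(Wm %*% matrix(fitted, nrow = n),
                                 fixed_effects))
  MWXb <- qr.resid(qrz, WXb)

  T1 <- T_ * sum(Wm * (Wm + t(Wm)))   # tr(W'W + WW) per period, summed
  d_err <- sum(e * We) / sigma2
  d_lag <- sum(e * Wy) / sigma2
  J <- sum(MWXb^2) / sigma2 + T1

  stats <- c(
    lm_error = d_err^2 / T1,
    robust_lm_error = (d_err - (T1 / J) * d_lag)^2 / (T1 * (1 - T1 / J)),
    lm_lag = d_lag^2 / J,
    robust_lm_lag = (d_lag - d_err)^2 / (J - T1)
  )
  structure(
    tibble::tibble(
      test = names(stats),
      statistic = unname(stats),
      p_value = stats::pchisq(unname(stats), df = 1, lower.tail = FALSE)
    ),
    class = c("lm_test_report", "tbl_df", "tbl", "data.frame")
  )
}

#' Fit a spatial Durbin model (or a constrained special case) by QML
#'
#' Estimates, on a balanced province-year panel,
#' \deqn{y_t = \rho W y_t + X_t \beta + W X_t \theta + \nu + \gamma_t + \varepsilon_t,}
#' by quasi-maximum likelihood: fixed effects are removed by the within
#' transformation (with the degrees-of-freedom and log-determinant
#' adjustments of the orthonormal-transform likelihood, so that sigma^2
#' remains consistent), the likelihood is concentrated in the spatial
#' coefficient and maximised by bounded scalar search over the admissible
#' interval, with the Jacobian term computed from the precomputed
#' eigenvalues of `W`. Constraints give the nested special cases:
#' `"sar"` drops the `WX` terms, `"sem"` moves the spatial term to the
#' error (`u = phi W u + e`), `"ols"` drops all spatial terms.
#'
#' @param panel Balanced panel tibble.
#' @param W Row-standardised `spatial_weights` whose units match the
#'   panel's provinces.
#' @param outcome Outcome column name (conventionally a log cost).
#' @param covariates Character vector of covariate column names.
#' @param fixed_effects `"none"`, `"province"`, `"year"` or `"twoway"`.
#' @param constraint `"none"` (SDM), `"sar"`, `"sem"` or `"ols"`.
#' @param compute_vcov Compute the coefficient covariance (numerical
#'   Hessian of the transformed likelihood); needed for effect t-values.
#'   Default `TRUE`.
#'
#' @return An `sdm_fit` object: coefficients (`rho`, `phi`, `beta`,
#'   `theta`), `sigma2`, `loglik`, `vcov`, pseudo R-squared and fit
#'   metadata.
#' @export
fit_sdm <- function(panel, W, outcome, covariates,
                    fixed_effects = c("twoway", "province", "year", "none"),
                    constraint = c("none", "sar", "sem", "ols"),
                    compute_vcov = TRUE) {
  fixed_effects <- match.arg(fixed_effects)
  constraint <- match.arg(constraint)
  if (!W$row_standardized) {
    abort("fit_sdm() requires a row-standardised weight matrix.")
  }
  arr <- panel_arrays(panel, W, outcome, covariates)
  Wm <- W$W
  n <- arr$n; T_ <- arr$T
  eigs <- real_eigenvalues(W)
  parts <- fe_likelihood_parts(fixed_effects, n, T_, eigs)
  interval <- c(1 / min(parts$eig), 1 / max(parts$eig))

  # within-transform after forming spatial lags: Q(WX) != W(QX) under
  # cross-sectional demeaning, since 1'W != 1'
  Y <- demean_matrix(arr$Y, fixed_effects)
  Xs <- lapply(arr$X, demean_matrix, fixed_effects = fixed_effects)
  WY <- demean_matrix(Wm %*% arr$Y, fixed_effects)
  WXs <- lapply(arr$X, function(M) demean_matrix(Wm %*% M, fixed_effects))
  y <- as.vector(Y)

  has_wx <- constraint == "none"
  Zx <- do.call(cbind, lapply(Xs, as.vector))
  colnames(Zx) <- covariates
  if (has_wx) {
    Zwx <- do.call(cbind, lapply(WXs, as.vector))
    colnames(Zwx) <- paste0("W.", covariates)
    Z <- cbind(Zx, Zwx)
  } else {
    Z <- Zx
  }
  if (fixed_effects == "none") Z <- cbind(`(intercept)` = 1, Z)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) abort("Covariate matrix is rank deficient.")

  logdet <- function(a) sum(log(1 - a * parts$eig))
  Ns <- parts$N
  const <- -(Ns / 2) * (log(2 * pi) + 1)

  # sigma^2 is reported with a degrees-of-freedom correction for the
  # estimated coefficients (QML's /N variant is biased by O(K/N) at panel
  # size); the likelihood itself uses the uncorrected ML value
  df_resid <- function(extra) Ns - ncol(Z) - extra
  if (constraint == "ols") {
    delta <- qr.coef(qrz, y)
    e <- qr.resid(qrz, y)
    S <- sum(e^2)
    sigma2 <- S / df_resid(0)
    loglik <- const - (Ns / 2) * log(S / Ns)
    rho <- 0; phi <- 0
    fitted_vec <- qr.fitted(qrz, y)
    opt <- NULL
  } else if (constraint == "sem") {
    sem_fit <- function(a) {
      Ystar <- Y - a * WY
      Zstar <- do.call(cbind, lapply(seq_along(Xs), function(k) {
        as.vector(Xs[[k]] - a * WXs[[k]])
      }))
      colnames(Zstar) <- covariates
      if (fixed_effects == "none") {
        Zstar <- cbind(`(intercept)` = 1 - a, Zstar)
      }
      q2 <- qr(Zstar)
      es <- qr.resid(q2, as.vector(Ystar))
      list(S = sum(es^2), qr = q2, ystar = as.vector(Ystar))
    }
    cll <- function(a) {
      -(Ns / 2) * log(sem_fit(a)$S / Ns) + parts$mult * logdet(a)
    }
    opt <- stats::optimize(cll, interval = interval + c(1e-6, -1e-6),
                           maximum = TRUE, tol = 1e-10)
    phi <- opt$maximum
    sf <- sem_fit(phi)
    delta <- qr.coef(sf$qr, sf$ystar)
    sigma2 <- sf$S / df_resid(1)
    loglik <- const - (Ns / 2) * log(sf$S / Ns) + parts$mult * logdet(phi)
    rho <- 0
    fitted_vec <- as.vector(Z %*% ifelse(is.na(delta), 0, delta))
  } else {
    Wy <- as.vector(WY)
    e0 <- qr.resid(qrz, y)
    e1 <- qr.resid(qrz, Wy)
    Sfun <- function(a) sum((e0 - a * e1)^2)
    cll <- function(a) -(Ns / 2) * log(Sfun(a) / Ns) + parts$mult * logdet(a)
    opt <- stats::optimize(cll, interval = interval + c(1e-6, -1e-6),
                           maximum = TRUE, tol = 1e-10)
    rho <- opt$maximum
    if (min(rho - interval[1], interval[2] - rho) < 1e-4) {
      warn(sprintf("rho estimate %.4f is at the admissible boundary.", rho))
    }
    phi <- 0
    delta <- qr.coef(qrz, y - rho * Wy)
    sigma2 <- Sfun(rho) / df_resid(1)
    loglik <- const - (Ns / 2) * log(Sfun(rho) / Ns) + parts$mult * logdet(rho)
    fitted_vec <- rho * Wy + as.vector(Z %*% delta)
  }

  beta <- delta[covariates]
  theta <- if (has_wx) {
    stats::setNames(delta[paste0("W.", covariates)], covariates)
  } else {
    stats::setNames(rep(0, length(covariates)), covariates)
  }
  r2 <- stats::cor(fitted_vec, y)^2

  fit <- structure(
    list(
      rho = unname(rho), phi = unname(phi),
      beta = beta, theta = theta, sigma2 = sigma2,
      intercept = if (fixed_effects == "none") unname(delta["(intercept)"]) else NULL,
      loglik = loglik, r_squared = r2,
      fixed_effects = fixed_effects, constraint = constraint,
      outcome = outcome, covariates = covariates,
      n = n, T = T_, N = Ns,
      rho_interval = interval,
      convergence = list(
        objective = if (is.null(opt)) NA_real_ else opt$objective
      ),
      vcov = NULL
    ),
    class = "sdm_fit"
  )
  if (compute_vcov) {
    fit$vcov <- sdm_vcov(fit, Y, WY, WXs, Z, parts, has_wx)
  }
  fit
}

# Numerical-Hessian covariance of the transformed-likelihood parameters.
sdm_vcov <- function(fit, Y, WY, WXs, Z, parts, has_wx) {
  Ns <- parts$N
  logdet <- function(a) sum(log(1 - a * parts$eig))
  y <- as.vector(Y)
  covariates <- fit$covariates
  if (fit$constraint == "sem") {
    par <- c(fit$phi, fit$beta, fit$sigma2)
    nm <- c("phi", covariates, "sigma2")
    WZ <- do.call(cbind, lapply(WXs, as.vector))
    nll <- function(p) {
      a <- p[1]; b <- p[2:(1 + length(covariates))]; s2 <- p[length(p)]
      if (s2 <= 0 || a <= 1 / min(parts$eig) || a >= 1 / max(parts$eig)) {
        return(1e10)
      }
      Rs <- (y - a * as.vector(WY)) - as.vector((Z - a * WZ) %*% b)
      S <- sum(Rs^2)
      -((-Ns / 2) * log(2 * pi * s2) + parts$mult * logdet(a) - S / (2 * s2))
    }
  } else if (fit$constraint == "ols") {
    delta <- c(if (!is.null(fit$intercept)) fit$intercept, fit$beta)
    par <- c(delta, fit$sigma2)
    nm <- c(colnames(Z), "sigma2")
    nll <- function(p) {
      d <- p[-length(p)]; s2 <- p[length(p)]
      if (s2 <= 0) return(1e10)
      S <- sum((y - as.vector(Z %*% d))^2)
      -((-Ns / 2) * log(2 * pi * s2) - S / (2 * s2))
    }
  } else {
    Wy <- as.vector(WY)
    delta <- c(if (!is.null(fit$intercept)) fit$intercept,
               fit$beta, if (has_wx) fit$theta)
    par <- c(fit$rho, delta, fit$sigma2)
    nm <- c("rho", colnames(Z), "sigma2")
    nll <- function(p) {
      a <- p[1]; d <- p[2:(length(p) - 1)]; s2 <- p[length(p)]
      if (s2 <= 0 || a <= 1 / min(parts$eig) || a >= 1 / max(parts$eig)) {
        return(1e10)
      }
      S <- sum((y - a * Wy - as.vector(Z %*% d))^2)
      -((-Ns / 2) * log(2 * pi * s2) + parts$mult * logdet(a) - S / (2 * s2))
    }
  }
  H <- stats::optimHess(par, nll)
  V <- tryCatch(solve(H), error = function(e) {
    warn("Hessian is singular; coefficient covariance unavailable.")
    NULL
  })
  if (!is.null(V)) dimnames(V) <- list(nm, nm)
  V
}

#' @export
print.sdm_fit <- function(x, ...) {
  cat(sprintf("<sdm_fit> %s, %s fixed effects; n = %d, T = %d\n",
              toupper(ifelse(x$constraint == "none", "sdm", x$constraint)),
              x$fixed_effects, x$n, x$T))
  if (x$constraint %in% c("none", "sar")) {
    cat(sprintf("  rho = %.4f\n", x$rho))
  }
  if (x$constraint == "sem") cat(sprintf("  phi = %.4f\n", x$phi))
  cat("  beta:\n")
  print(round(x$beta, 4))
  if (x$constraint == "none") {
    cat("  theta (W x covariate):\n")
    print(round(x$theta, 4))
  }
  cat(sprintf("  sigma2 = %.4f, logLik = %.2f, pseudo-R2 = %.3f\n",
              x$sigma2, x$loglik, x$r_squared))
  invisible(x)
}
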