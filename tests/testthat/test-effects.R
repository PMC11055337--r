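# minimal sdm_fit stub for identity checks at fixed parameters
stub_fit <- function(rho, beta, theta, n, vcov = NULL) {
  structure(
    list(rho = rho, phi = 0, beta = beta, theta = theta, sigma2 = 1,
         loglik = 0, r_squared = NA, fixed_effects = "twoway",
         constraint = "none", covariates = names(beta), n = n, T = 1,
         N = n, vcov = vcov, intercept = NULL),
    class = "sdm_fit"
  )
}

test_that("with rho = 0 direct and indirect effects are beta and theta", {
  w <- test_weights(11, seed = 7)
  beta <- c(a = 1.3, b = -0.4); theta <- c(a = 0.6, b = 0.2)
  eff <- decompose_effects(stub_fit(0, beta, theta, 11), w)
  # identity inverse: zero diagonal of W gives direct = beta exactly,
  # unit row sums give total = beta + theta
  expect_equal(eff$direct, unname(beta))
  expect_equal(eff$indirect, unname(theta))
  expect_equal(eff$total, unname(beta + theta))
})

test_that("decomposition agrees with a truncated Neumann series", {
  w <- test_weights(13, seed = 18)
  set.seed(6)
  for (i in 1:5) {
    rho <- runif(1, -0.3, 0.6)
    beta <- c(x = rnorm(1)); theta <- c(x = rnorm(1))
    eff <- decompose_effects(stub_fit(rho, beta, theta, 13), w)
    # series oracle: (I - rho W)^{-1} = sum_m rho^m W^m
    S <- matrix(0, 13, 13)
    Wp <- diag(13)
    for (m in 0:50) {
      S <- S + rho^m * Wp %*% (beta * diag(13) + theta * w$W)
      Wp <- Wp %*% w$W
    }
    expect_equal(eff$direct, mean(diag(S)), tolerance = 1e-8)
    expect_equal(eff$total, mean(rowSums(S)), tolerance = 1e-8)
    # definitional identity holds to numerical exactness
    expect_equal(eff$total - (eff$direct + eff$indirect), 0,
                 tolerance = 1e-10)
  }
})

test_that("simulated t-values are reproducible and finite", {
  w <- test_weights(12, seed = 25)
  sim <- generate_sdm_panel(w, default_truth(),
                            generator_config(seed = 5, n_provinces = 12,
                                             years = 1995:2014))
  fit <- fit_sdm(sim$panel, w, "lncc", names(default_truth()$beta),
                 fixed_effects = "twoway")
  e1 <- decompose_effects(fit, w, draws = 400, seed = 31)
  e2 <- decompose_effects(fit, w, draws = 400, seed = 31)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1$direct_t)))
  # strong true coefficients should show up as large |t|
  expect_gt(abs(e1$direct_t[e1$covariate == "social"]), 3)
  expect_equal(e1$total, e1$direct + e1$indirect, tolerance = 1e-10)
})

test_that("effects rescale inversely under covariate scaling", {
  w <- test_weights(10, seed = 33)
  sim <- generate_sdm_panel(w, default_truth(),
                            generator_config(seed = 8, n_provinces = 10,
                                             years = 2000:2014))
  covs <- names(default_truth()$beta)
  fit1 <- fit_sdm(sim$panel, w, "lncc", covs, fixed_effects = "twoway",
                  compute_vcov = FALSE)
  scaled <- dplyr::mutate(sim$panel, tech = .data$tech * 10)
  fit2 <- fit_sdm(scaled, w, "lncc", covs, fixed_effects = "twoway",
                  compute_vcov = FALSE)
  e1 <- decompose_effects(fit1, w)
  e2 <- decompose_effects(fit2, w)
  expect_equal(e2$direct[e2$covariate == "tech"],
               e1$direct[e1$covariate == "tech"] / 10, tolerance = 1e-8)
  expect_equal(e2$total[e2$covariate == "tech"],
               e1$total[e1$covariate == "tech"] / 10, tolerance = 1e-8)
  expect_equal(e2$direct[e2$covariate == "social"],
               e1$direct[e1$covariate == "social"], tolerance = 1e-8)
})

test_that("robustness sweep reproduces the single-matrix decomposition", {
  w <- test_weights(10, seed = 41)
  sim <- generate_sdm_panel(w, default_truth(),
                            generator_config(seed = 12, n_provinces = 10,
                                             years = 2000:2014))
  covs <- names(default_truth()$beta)
  single <- robustness_sweep(sim$panel, list(contiguity = w), "lncc", covs,
                             draws = 200, seed = 3)
  fit <- fit_sdm(sim$panel, w, "lncc", covs, fixed_effects = "twoway")
  direct <- decompose_effects(fit, w, draws = 200, seed = 3)
  expect_equal(single$direct, direct$direct)
  expect_equal(single$total, direct$total)
  expect_s3_class(attr(single, "sign_table"), "tbl_df")

  expect_error(robustness_sweep(sim$panel, list(), "lncc", covs),
               "at least one")
})

test_that("direct-effect signs are stable across matrices of one geography", {
  w <- generate_adjacency(14, "random_planar", seed = 51)
  ws <- sylvacost:::new_spatial_weights(w$W, "contiguity", TRUE)
  coords <- attr(w, "coordinates")
  geo <- build_weights(
    tibble::tibble(province = ws$provinces,
                   lat = coords[, 2] * 10 + 25, lon = coords[, 1] * 20 + 95),
    kind = "geographic")
  sim <- generate_sdm_panel(ws, default_truth(),
                            generator_config(seed = 23, n_provinces = 14,
                                             years = 1992:2011))
  covs <- names(default_truth()$beta)
  sweep <- robustness_sweep(sim$panel, list(contiguity = ws, geographic = geo),
                            "lncc", covs, draws = 100, seed = 2)
  signs <- attr(sweep, "sign_table")
  by_cov <- split(signs$direct, signs$covariate)
  expect_true(all(vapply(by_cov, function(s) length(unique(s)) == 1,
                         logical(1))))
})
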