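# Shared fixtures, generated in code at test time.

# small row-standardised weight matrix
test_weights <- function(n = 5, seed = 3, topology = "random_planar") {
  w <- generate_adjacency(n, topology, seed = seed)
  sylvacost:::new_spatial_weights(w$W, "contiguity", standardize = TRUE)
}

# balanced panel of pure-noise covariates for null-model tests
null_panel <- function(n = 29, T_ = 30, k = 3, seed = 1) {
  set.seed(seed)
  p <- tidyr::expand_grid(province = sprintf("P%02d", seq_len(n)),
                          year = seq_len(T_))
  for (j in seq_len(k)) p[[paste0("x", j)]] <- rnorm(n * T_)
  p$y <- 1 + rowSums(as.matrix(p[paste0("x", seq_len(k))]) %*%
                       seq(0.5, by = -0.2, length.out = k)) + rnorm(n * T_)
  p
}

default_truth <- function(rho = 0.3) {
  sdm_ground_truth(
    rho = rho,
    beta = c(tech = -0.8, social = 0.9, nature = -0.4),
    theta = c(tech = 0.3, social = 0.4, nature = 0.2),
    sigma2 = 1
  )
}

linear_series <- function(from = 20, to = 120) {
  tibble::tibble(year = 1992:2021, value = seq(from, to, length.out = 30))
}

random_stand_draw <- function() {
  list(
    A = runif(1, 1000, 20000), ca = runif(1, 1000, 15000),
    pw = runif(1, 100, 900), v = runif(1, 10, 120),
    r = runif(1, 0.005, 0.10), U = sample(c(20, 25, 30), 1),
    om = runif(1, 0.2, 3), th = runif(1, 0, 1), e = runif(1, 0, 0.9)
  )
}
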