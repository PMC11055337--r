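test_that("NPP carbon uptake follows the saturating conversion form", {
  # zero volume gives zero uptake
  expect_equal(npp_carbon_uptake(0, 25, 0.6, 1.02, 0.5, 0.02, 0.25), 0)

  # hand evaluation of the closed form with unit constants:
  # biomass = 2, denom = 1, so omega = 2 * 1.63 * (12/44) * 0.5
  expect_equal(
    npp_carbon_uptake(volume = 2, age = 1, biomass_coeff = 1,
                      biomass_exponent = 1, species_c = 1, species_d = 0,
                      root_stem_ratio = 0),
    2 * 1.63 * (12 / 44) * 0.5
  )

  # monotone in volume (x / (q + d x) increases for q > 0)
  v <- seq(10, 200, by = 10)
  om <- npp_carbon_uptake(v, 25, 0.6, 1.02, 0.5, 0.02, 0.25)
  expect_true(all(diff(om) > 0))

  # bounded above by the saturation limit as V grows
  lim <- 1.63 * (12 / 44) * 0.5 / 0.02
  expect_true(all(om < lim))
  expect_lt(lim - npp_carbon_uptake(1e9, 25, 0.6, 1.02, 0.5, 0.02, 0.25),
            1e-3 * lim)

  expect_error(npp_carbon_uptake(10, 0, 0.6, 1.02, 0.5, 0.02, 0.25), "age")
})

test_that("carbon NPV closed-form annuity equals the explicit sum", {
  expect_equal(carbon_npv(0, 1.5, 0.03, 25), 0)            # linear in price
  expect_equal(carbon_npv(100, 1.5, 0.03, 25, baseline_deduction = 1), 0)

  set.seed(42)
  for (i in 1:1000) {
    p <- random_stand_draw()
    closed <- carbon_npv(p$A, p$om, p$r, p$U, p$th, p$e)
    tsum <- p$A * (1 - p$e) * p$om * sum((1 + p$r)^(-(1:p$U))) -
      (1 - p$th) * (1 - p$e) * p$A * p$om * p$U * (1 + p$r)^(-p$U)
    expect_equal(closed, tsum, tolerance = 1e-10)
  }
})

test_that("stand NPV assembles cost, timber and carbon components", {
  # only the afforestation cost survives with no income
  expect_equal(stand_npv(5000, 0, 40, 0.03, 25, 0, 1.5), -5000)
  # extreme discounting removes all future income
  expect_equal(stand_npv(5000, 650, 90, 1e9, 25, 200, 1.5), -5000,
               tolerance = 1e-6)

  set.seed(7)
  for (i in 1:50) {
    p <- random_stand_draw()
    f <- stand_npv(p$ca, p$pw, p$v, p$r, p$U, p$A, p$om, p$th, p$e)
    direct <- -p$ca + p$pw * p$v * (1 + p$r)^(-p$U) +
      carbon_npv(p$A, p$om, p$r, p$U, p$th, p$e)
    expect_equal(f, direct, tolerance = 1e-10)
  }
})

test_that("infinite rotation value is the geometric-series limit", {
  expect_equal(infinite_rotation_value(0, 0.03, 25), 0)

  set.seed(11)
  for (i in 1:20) {
    f <- runif(1, -5000, 5000); r <- runif(1, 0.01, 0.1)
    U <- sample(c(20, 25, 30), 1)
    Fv <- infinite_rotation_value(f, r, U)
    partial <- sum(f * (1 + r)^(-U * (0:199)))
    expect_equal(Fv, partial, tolerance = 1e-8)
  }

  # a very long rotation leaves just the single-rotation value
  expect_equal(infinite_rotation_value(1234, 0.05, 5000), 1234)
  expect_error(infinite_rotation_value(10, 0, 25), "positive")
})

test_that("Cobb-Douglas opportunity cost has the right homogeneity", {
  expect_equal(cobb_douglas_opportunity_cost(1, 1, 1, 0.4, 0.6), 1)
  a <- cobb_douglas_opportunity_cost(2.5, 30, 70, 0.35, 0.6)
  expect_equal(cobb_douglas_opportunity_cost(2.5, 60, 70, 0.35, 0.6),
               a * 2^0.35)
  expect_equal(a, 2.5 * 30^0.35 * 70^0.6)
  expect_error(cobb_douglas_opportunity_cost(1, 1, 1, 0.9, 0.9), "bound")
})

test_that("equilibrium price closed form solves the NPV balance", {
  # constructed zero numerator gives a zero price
  r <- 0.04; U <- 25; disc <- (1 + r)^(-U)
  pc0 <- equilibrium_carbon_price(
    opportunity_cost = 0, afforestation_cost = 650 * 90 * disc,
    timber_price = 650, timber_volume = 90,
    discount_rate = r, rotation = U, uptake = 1.5, basis = "tC")
  expect_equal(as.numeric(pc0), 0, tolerance = 1e-12)

  # oracle equivalence: the closed form is the root of F(p) - A = 0,
  # the perpetual-rotation forest value balancing the opportunity cost
  set.seed(5)
  for (i in 1:200) {
    p <- random_stand_draw()
    pc <- as.numeric(equilibrium_carbon_price(
      p$A, p$ca, p$pw, p$v, p$r, p$U, p$om, p$th, p$e, basis = "tC"))
    g <- function(price) {
      infinite_rotation_value(
        stand_npv(p$ca, p$pw, p$v, p$r, p$U, price, p$om, p$th, p$e),
        p$r, p$U) - p$A
    }
    root <- uniroot(g, interval = pc + c(-1, 1) * (abs(pc) + 1e4),
                    tol = 1e-13)$root
    expect_equal(pc, root, tolerance = 1e-8)
  }

  # tCO2e basis is the tC price converted by the molecular-weight ratio
  p <- random_stand_draw()
  expect_equal(
    as.numeric(equilibrium_carbon_price(p$A, p$ca, p$pw, p$v, p$r, p$U,
                                        p$om, p$th, p$e, basis = "tCO2e")),
    as.numeric(equilibrium_carbon_price(p$A, p$ca, p$pw, p$v, p$r, p$U,
                                        p$om, p$th, p$e, basis = "tC")) * 12 / 44
  )

  # negative prices are flagged, not clamped
  pn <- equilibrium_carbon_price(0, 0, 650, 90, 0.03, 25, 1.5, basis = "tC")
  expect_lt(as.numeric(pn), 0)
  expect_true(attr(pn, "negative"))

  # degenerate denominator is a named failure
  expect_error(
    equilibrium_carbon_price(1000, 5000, 0, 0, 0.05, 30, 1e-14),
    "positive|Degenerate"
  )
})

test_that("price is monotone in opportunity and afforestation costs", {
  p <- list(ca = 5000, pw = 400, v = 40, r = 0.03, U = 25, om = 1.2)
  base <- as.numeric(equilibrium_carbon_price(7000, p$ca, p$pw, p$v, p$r,
                                              p$U, p$om, basis = "tC"))
  upA <- as.numeric(equilibrium_carbon_price(9000, p$ca, p$pw, p$v, p$r,
                                             p$U, p$om, basis = "tC"))
  upC <- as.numeric(equilibrium_carbon_price(7000, 8000, p$pw, p$v, p$r,
                                             p$U, p$om, basis = "tC"))
  dnT <- as.numeric(equilibrium_carbon_price(7000, p$ca, 600, p$v, p$r,
                                             p$U, p$om, basis = "tC"))
  expect_gt(upA, base)
  expect_gt(upC, base)
  expect_lt(dnT, base)
})

test_that("panel_costs matches the scalar path and is order-equivariant", {
  cfg <- generator_config(seed = 21, n_provinces = 6, years = 2000:2004)
  inputs <- generate_cost_inputs(cfg)
  out <- panel_costs(inputs)
  expect_equal(nrow(out), 30)

  # record-by-record scalar loop oracle
  for (i in sample(nrow(out), 5)) {
    row <- out[i, ]
    om <- npp_carbon_uptake(row$volume, row$age, row$biomass_coeff,
                            row$biomass_exponent, row$species_c,
                            row$species_d, row$root_stem_ratio, row$area)
    pc <- as.numeric(equilibrium_carbon_price(
      row$opportunity_cost, row$afforestation_cost, row$timber_price,
      row$timber_volume, row$discount_rate, row$rotation, om,
      row$product_share, row$baseline_deduction, basis = "tCO2e"))
    expect_equal(row$carbon_cost, pc, tolerance = 1e-12)
    expect_equal(row$uptake, om, tolerance = 1e-12)
  }

  # permuting input rows leaves the (sorted) result unchanged
  shuffled <- panel_costs(inputs[sample(nrow(inputs)), ])
  expect_equal(shuffled, out)

  expect_error(panel_costs(inputs[setdiff(names(inputs), "volume")]),
               "missing columns")
})
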