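#' Annual carbon uptake from the volume-biomass-NPP conversion
#'
#' Converts standing timber volume to an annual carbon uptake rate via the
#' saturating volume-biomass-NPP chain: volume is expanded to total biomass
#' with a species-specific allometric term `a * V^b` and the root-stem ratio
#' `k`, biomass is converted to net primary productivity through the
#' species constants `c` and `d` and the stand age, NPP is converted to CO2
#' with the factor 1.63 and back to elemental carbon with 12/44, and a fixed
#' fraction of NPP (default 50%) is counted as realised carbon uptake.
#'
#' @param volume Standing volume per unit area, m^3/ha (`V`).
#' @param age Stand age in years (`Y`); must be positive.
#' @param biomass_coeff,biomass_exponent Allometric coefficients `a` (> 0)
#'   and `b` (> 0) of the volume-to-biomass expansion.
#' @param species_c,species_d Species-specific NPP constants `c` (> 0) and
#'   `d` (>= 0).
#' @param root_stem_ratio Root-to-stem biomass ratio `k` (fraction, >= 0).
#' @param area Stand area in ha (`S`); appears in both numerator and
#'   denominator of the conversion and is kept for fidelity to the
#'   published form (see the methods vignette for the unit audit).
#' @param co2_factor NPP-to-CO2 conversion factor; fixed default 1.63.
#' @param carbon_factor CO2-to-carbon conversion; fixed default 12/44.
#' @param npp_fraction Fraction of NPP counted as carbon uptake;
#'   default 0.5.
#'
#' @return Annual carbon uptake `omega` in tC/ha/yr, same length as
#'   `volume`.
#' @export
#'
#' @examples
#' npp_carbon_uptake(volume = 80, age = 25, biomass_coeff = 0.61,
#'                   biomass_exponent = 1.02, species_c = 250,
#'                   species_d = 0.7, root_stem_ratio = 0.25)
npp_carbon_uptake <- function(volume, age,
                              biomass_coeff, biomass_exponent,
                              species_c, species_d,
                              root_stem_ratio,
                              area = 1,
                              co2_factor = 1.63,
                              carbon_factor = 12 / 44,
                              npp_fraction = 0.5) {
  if (any(volume < 0)) abort("`volume` must be non-negative.")
  if (any(age <= 0)) abort("`age` must be positive.")
  if (any(biomass_coeff <= 0) || any(biomass_exponent <= 0)) {
    abort("`biomass_coeff` and `biomass_exponent` must be positive.")
  }
  if (any(species_c <= 0)) abort("`species_c` must be positive.")
  if (any(species_d < 0)) abort("`species_d` must be non-negative.")
  if (any(root_stem_ratio < 0)) abort("`root_stem_ratio` must be non-negative.")
  if (any(area <= 0)) abort("`area` must be positive.")

  biomass <- biomass_coeff * volume^biomass_exponent * (1 + root_stem_ratio) * area
  denom <- species_c * age + species_d * biomass
  if (any(denom == 0)) {
    abort("Degenerate NPP denominator: species_c * age + species_d * biomass = 0.")
  }
  biomass / denom * co2_factor * carbon_factor * npp_fraction
}

#' Net present value of carbon sequestration income over one rotation
#'
#' Discounted carbon-payment stream over a rotation of `rotation` years,
#' assuming linear forest growth (constant annual uptake `uptake`), with a
#' baseline (additionality) deduction `baseline_deduction` applied to every
#' payment and the non-retained share `1 - product_share` of the
#' accumulated stock charged back at harvest:
#' \deqn{B = p_c (1-e)\,\omega \sum_{t=1}^{U} (1+r)^{-t}
#'        - (1-\theta)(1-e)\, p_c\, \omega\, U\, (1+r)^{-U}.}
#' The annuity sum is evaluated in closed form,
#' \eqn{r^{-1}[1-(1+r)^{-U}]}.
#'
#' @param carbon_price Carbon price `p_c`, CNY/tC.
#' @param uptake Annual carbon uptake `omega`, tC/ha/yr.
#' @param discount_rate Annual discount rate `r` (fraction, > 0).
#' @param rotation Rotation length `U` in years (>= 1).
#' @param product_share Fraction `theta` of harvested carbon retained in
#'   wood products; default 0.8243.
#' @param baseline_deduction Baseline deduction `e` (fraction of carbon not
#'   counted as additional); default 0.05.
#'
#' @return Carbon NPV in CNY/ha (vectorised).
#' @export
carbon_npv <- function(carbon_price, uptake, discount_rate, rotation,
                       product_share = 0.8243, baseline_deduction = 0.05) {
  if (any(discount_rate <= 0)) abort("`discount_rate` must be positive.")
  if (any(rotation < 1)) abort("`rotation` must be at least one year.")
  if (any(product_share < 0 | product_share > 1)) {
    abort("`product_share` must lie in [0, 1].")
  }
  if (any(baseline_deduction < 0 | baseline_deduction > 1)) {
    abort("`baseline_deduction` must lie in [0, 1].")
  }
  disc <- discount_factor(discount_rate, rotation)
  annuity <- (1 - disc) / discount_rate
  carbon_price * (1 - baseline_deduction) * uptake * annuity -
    (1 - product_share) * (1 - baseline_deduction) *
      carbon_price * uptake * rotation * disc
}

#' Net present value of one forest rotation
#'
#' Single-rotation stand NPV: the one-off afforestation cost, discounted
#' timber income at harvest, and the carbon-payment NPV from
#' [carbon_npv()]:
#' \deqn{f = -c_a + p_w v (1+r)^{-U} + B.}
#'
#' @inheritParams carbon_npv
#' @param afforestation_cost One-off establishment cost `c_a`, CNY/ha.
#' @param timber_price Timber price at harvest `p_w`, CNY/m^3.
#' @param timber_volume Harvest volume `v`, m^3/ha.
#'
#' @return Stand NPV `f` in CNY/ha (vectorised).
#' @export
stand_npv <- function(afforestation_cost, timber_price, timber_volume,
                      discount_rate, rotation,
                      carbon_price, uptake,
                      product_share = 0.8243, baseline_deduction = 0.05) {
  if (any(afforestation_cost < 0) || any(timber_price < 0) ||
      any(timber_volume < 0)) {
    abort("Costs, prices and volumes must be non-negative.")
  }
  disc <- discount_factor(discount_rate, rotation)
  -afforestation_cost + timber_price * timber_volume * disc +
    carbon_npv(carbon_price, uptake, discount_rate, rotation,
               product_share, baseline_deduction)
}

#' Value of an infinite chain of identical rotations
#'
#' Capitalises the single-rotation NPV `f` over an infinite sequence of
#' identical rotations (the Faustmann-style perpetual-rotation value):
#' \deqn{F = f\,[1-(1+r)^{-U}]^{-1},}
#' the limit of the geometric series \eqn{\sum_{j \ge 0} f (1+r)^{-jU}}.
#'
#' @param f Single-rotation NPV, CNY/ha.
#' @param discount_rate Annual discount rate `r` (> 0; the series diverges
#'   otherwise).
#' @param rotation Rotation length `U` in years (>= 1).
#'
#' @return Perpetual-rotation value `F` in CNY/ha (vectorised).
#' @export
infinite_rotation_value <- function(f, discount_rate, rotation) {
  if (any(discount_rate <= 0)) {
    abort("`discount_rate` must be positive: the rotation series diverges otherwise.")
  }
  if (any(rotation < 1)) abort("`rotation` must be at least one year.")
  f / (1 - discount_factor(discount_rate, rotation))
}

#' Agricultural opportunity cost from a Cobb-Douglas production function
#'
#' Annual profit forgone by keeping the land in forest rather than
#' agriculture, modelled as \eqn{A = tech \cdot K^\alpha L^\beta}.
#'
#' @param tech Total factor productivity (> 0).
#' @param capital,labor Factor inputs `K` and `L` (> 0).
#' @param alpha,beta Output elasticities (> 0). Their sum is sanity-checked
#'   against `elasticity_bound`.
#' @param elasticity_bound Upper bound on `alpha + beta`; default 1.5.
#'
#' @return Opportunity cost `A` in CNY/ha/yr (vectorised).
#' @export
cobb_douglas_opportunity_cost <- function(tech, capital, labor, alpha, beta,
                                          elasticity_bound = 1.5) {
  if (any(tech <= 0) || any(capital <= 0) || any(labor <= 0)) {
    abort("`tech`, `capital` and `labor` must be positive.")
  }
  if (any(alpha <= 0) || any(beta <= 0)) {
    abort("`alpha` and `beta` must be positive.")
  }
  if (any(alpha + beta > elasticity_bound)) {
    abort(sprintf("alpha + beta exceeds the sanity bound %g.", elasticity_bound))
  }
  tech * capital^alpha * labor^beta
}

#' Equilibrium carbon sequestration price
#'
#' The break-even carbon price at which the perpetual-rotation forest value
#' equals the capitalised agricultural opportunity cost of the same land —
#' the minimum theoretical cost of carbon sequestration management. In
#' closed form:
#' \deqn{p_c = \frac{A[1-(1+r)^{-U}] + c_a - p_w v (1+r)^{-U}}
#'   {\omega(1-e)\{r^{-1}[1-(1+r)^{-U}] - U(1-\theta)(1+r)^{-U}\}}.}
#' The price may legitimately be negative (timber income alone beats
#' agriculture); negative values are returned as-is and flagged through the
#' `"negative"` attribute rather than clamped.
#'
#' @inheritParams stand_npv
#' @param opportunity_cost Annual agricultural profit `A`, CNY/ha/yr.
#' @param basis Price basis: `"tC"` (per ton of carbon, the model's native
#'   unit) or `"tCO2e"` (per ton of CO2-equivalent, i.e. multiplied by
#'   12/44).
#'
#' @return Equilibrium price, CNY per tC (or per tCO2e), vectorised, with a
#'   logical attribute `"negative"` marking records where the price is
#'   below zero.
#' @export
#'
#' @examples
#' equilibrium_carbon_price(
#'   opportunity_cost = 9000, afforestation_cost = 5000,
#'   timber_price = 650, timber_volume = 90,
#'   discount_rate = 0.03, rotation = 25, uptake = 1.2
#' )
equilibrium_carbon_price <- function(opportunity_cost,
                                     afforestation_cost,
                                     timber_price, timber_volume,
                                     discount_rate, rotation, uptake,
                                     product_share = 0.8243,
                                     baseline_deduction = 0.05,
                                     basis = c("tC", "tCO2e")) {
  basis <- match.arg(basis)
  if (any(uptake <= 0)) {
    abort("`uptake` must be positive to solve for an equilibrium price.")
  }
  if (any(baseline_deduction >= 1)) {
    abort("`baseline_deduction` must be below 1 (full deduction leaves no priced carbon).")
  }
  if (any(discount_rate <= 0)) abort("`discount_rate` must be positive.")

  disc <- discount_factor(discount_rate, rotation)
  one_minus_disc <- 1 - disc
  numer <- opportunity_cost * one_minus_disc + afforestation_cost -
    timber_price * timber_volume * disc
  denom <- uptake * (1 - baseline_deduction) *
    (one_minus_disc / discount_rate -
       rotation * (1 - product_share) * disc)
  bad <- abs(denom) < 1e-12 * pmax(1, abs(uptake))
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      paste0("Degenerate equilibrium-price denominator (record %d): ",
             "uptake = %g, rotation = %g, discount_rate = %g, ",
             "product_share = %g make the discounted-uptake term vanish."),
      i, uptake[min(i, length(uptake))], rotation[min(i, length(rotation))],
      discount_rate[min(i, length(discount_rate))],
      product_share[min(i, length(product_share))]
    ))
  }
  price <- numer / denom
  if (basis == "tCO2e") price <- price * 12 / 44
  structure(price, negative = price < 0)
}

#' Compute equilibrium carbon costs for a panel of stand inputs
#'
#' Vectorised driver over a per-(province, year) table of stand and NPP
#' parameters: computes the annual uptake with [npp_carbon_uptake()] and
#' the equilibrium price with [equilibrium_carbon_price()] for every
#' record. Records whose parameters make either step fail are collected
#' and reported in one error rather than dropped silently.
#'
#' @param inputs A data frame with one row per (province, year) and the
#'   columns `province`, `year`, `afforestation_cost`, `timber_price`,
#'   `timber_volume`, `discount_rate`, `rotation`, `opportunity_cost`,
#'   `volume`, `age`, `biomass_coeff`, `biomass_exponent`, `species_c`,
#'   `species_d`, `root_stem_ratio` and optionally `area`,
#'   `product_share`, `baseline_deduction`.
#' @param basis Price basis passed to [equilibrium_carbon_price()];
#'   default `"tCO2e"`, the unit in which cross-province cost tables are
#'   conventionally reported.
#'
#' @return The input tibble with columns `uptake`, `carbon_cost` and
#'   `negative_price` appended, sorted by (province, year).
#' @export
panel_costs <- function(inputs, basis = c("tCO2e", "tC")) {
  basis <- match.arg(basis)
  required <- c("province", "year", "afforestation_cost", "timber_price",
                "timber_volume", "discount_rate", "rotation",
                "opportunity_cost", "volume", "age", "biomass_coeff",
                "biomass_exponent", "species_c", "species_d",
                "root_stem_ratio")
  missing_cols <- setdiff(required, names(inputs))
  if (length(missing_cols)) {
    abort(paste0("`inputs` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  inputs <- dplyr::arrange(tibble::as_tibble(inputs), .data$province, .data$year)
  n <- nrow(inputs)
  area <- inputs$area %||% rep(1, n)
  theta <- inputs$product_share %||% rep(0.8243, n)
  e <- inputs$baseline_deduction %||% rep(0.05, n)

  uptake <- rep(NA_real_, n)
  price <- rep(NA_real_, n)
  failures <- character()
  for (i in seq_len(n)) {
    res <- tryCatch({
      w <- npp_carbon_uptake(
        volume = inputs$volume[i], age = inputs$age[i],
        biomass_coeff = inputs$biomass_coeff[i],
        biomass_exponent = inputs$biomass_exponent[i],
        species_c = inputs$species_c[i], species_d = inputs$species_d[i],
        root_stem_ratio = inputs$root_stem_ratio[i], area = area[i]
      )
      p <- equilibrium_carbon_price(
        opportunity_cost = inputs$opportunity_cost[i],
        afforestation_cost = inputs$afforestation_cost[i],
        timber_price = inputs$timber_price[i],
        timber_volume = inputs$timber_volume[i],
        discount_rate = inputs$discount_rate[i],
        rotation = inputs$rotation[i], uptake = w,
        product_share = theta[i], baseline_deduction = e[i],
        basis = basis
      )
      list(w = w, p = as.numeric(p))
    }, error = function(cnd) cnd)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf(
        "(%s, %s): %s", inputs$province[i], inputs$year[i],
        conditionMessage(res)
      ))
    } else {
      uptake[i] <- res$w
      price[i] <- res$p
    }
  }
  if (length(failures)) {
    abort(paste0(
      length(failures), " record(s) failed cost computation:\n",
      paste(utils::head(failures, 10), collapse = "\n"),
      if (length(failures) > 10) "\n..." else ""
    ))
  }
  dplyr::mutate(inputs, uptake = uptake, carbon_cost = price,
                negative_price = price < 0)
}
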