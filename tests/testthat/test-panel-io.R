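make_toy_panel <- function() {
  tibble::tibble(
    province = c("P1", "P1", "P2"),
    year = c(1992L, 1993L, 1992L),
    carbon_cost = c(10.5, 11.25, 30.125),
    forestry_gdp = c(80, 85, 90),
    wood_production = c(250, 255, 260),
    afforestation_area = c(200, 210, 190),
    labor_price = c(4000, 4100, 3900),
    land_opportunity_cost = c(26000, 26500, 25000),
    rural_consumption = c(6476, 6500, 6400),
    forest_stock = c(20000, 20100, 19000),
    population_density = c(420, 421, 300),
    region = c("eastern", "eastern", "western")
  )
}

test_that("panel CSV round-trip preserves values and sorting", {
  p <- make_toy_panel()
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(p, path)
  back <- read_panel(path)
  expect_equal(nrow(back), 3)
  expect_equal(back$carbon_cost, p$carbon_cost)
  expect_equal(back$year, p$year)
  # numeric content survives a second round trip byte-for-byte
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_panel(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("panel validation names the offending record", {
  p <- make_toy_panel()
  dup <- dplyr::bind_rows(p, p[1, ])
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dup, path)
  expect_error(read_panel(path), "P1.*1992")

  bad <- p
  bad$forestry_gdp <- as.character(bad$forestry_gdp)
  bad$forestry_gdp[2] <- "n/a"
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path2)
  expect_error(read_panel(path2), "forestry_gdp")

  expect_error(validate_panel(dplyr::mutate(p, population_density = 0)),
               "population_density")
  expect_error(validate_panel(dplyr::mutate(p, region = "north")), "region")
  expect_error(read_panel(path, year_range = c(1993, 2000)), "1992")
})

test_that("schema remaps column names and converts units", {
  p <- make_toy_panel()[, c("province", "year", "carbon_cost")]
  names(p) <- c("prov", "yr", "cost_e4")
  p$cost_e4 <- p$cost_e4 / 1e4
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(p, path)
  sch <- panel_schema(
    columns = c(province = "prov", year = "yr", carbon_cost = "cost_e4"),
    scale = c(carbon_cost = 1e4)
  )
  back <- read_panel(path, schema = sch)
  expect_equal(back$carbon_cost, make_toy_panel()$carbon_cost)

  # the YAML on-disk form round-trips into the same schema
  ypath <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("columns:", "  province: prov", "  year: yr",
               "  carbon_cost: cost_e4", "scale:", "  carbon_cost: 1.0e4"),
             ypath)
  sch_y <- read_panel_schema(ypath)
  expect_equal(sch_y$columns, sch$columns)
  expect_equal(read_panel(path, schema = sch_y)$carbon_cost,
               make_toy_panel()$carbon_cost)

  expect_error(panel_schema(columns = c(foo = "bar")), "Unknown canonical")
  expect_error(read_panel(path, panel_schema(
    columns = c(province = "prov", year = "yr", carbon_cost = "nope"))),
    "absent")
})

test_that("missing cells are flagged, not imputed", {
  p <- make_toy_panel()
  p$forest_stock[2] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(p, path)
  expect_warning(back <- read_panel(path), "missing cell")
  expect_true(is.na(back$forest_stock[back$province == "P1" &
                                        back$year == 1993]))
})

test_that("region maps must cover every province", {
  p <- make_toy_panel()
  rm_ <- tibble::tibble(province = c("P1", "P2"),
                        region = c("central", "western"))
  out <- assign_regions(p, rm_)
  expect_equal(out$region[out$province == "P1"], c("central", "central"))
  expect_error(assign_regions(p, rm_[1, ]), "P2")
})

test_that("deflation rescales by the index ratio and is idempotent", {
  idx_flat <- tibble::tibble(year = 1992:1995, index = rep(100, 4))
  df <- tibble::tibble(year = 1992:1995, v = c(10, 20, 30, 40))
  expect_equal(deflate_to_base(df, "v", idx_flat)$v, df$v)

  idx <- tibble::tibble(year = 1992:1993, index = c(100, 110))
  d2 <- tibble::tibble(year = 1993, v = 110)
  expect_equal(deflate_to_base(d2, "v", idx)$v, 100)

  # element-wise ratio oracle on random input
  set.seed(31)
  yrs <- 1992:2011
  idx_r <- tibble::tibble(year = yrs, index = runif(20, 80, 160))
  dr <- tibble::tibble(year = yrs, v = runif(20, 1, 1e4))
  got <- deflate_to_base(dr, "v", idx_r, base_year = 1992)$v
  want <- dr$v * idx_r$index[1] / idx_r$index
  expect_equal(got, want, tolerance = 1e-12)

  # already at base prices: a flat rebased index changes nothing
  rebased <- tibble::tibble(year = yrs, index = rep(idx_r$index[1], 20))
  again <- deflate_to_base(tibble::tibble(year = yrs, v = got), "v", rebased)$v
  expect_equal(again, got, tolerance = 1e-12)

  expect_error(deflate_to_base(tibble::tibble(year = 2050, v = 1), "v", idx_r),
               "2050")
  expect_error(deflate_to_base(dr, "v", idx_r, base_year = 1800), "1800")
})

test_that("interpolation fills gaps without touching observations", {
  lin <- tibble::tibble(year = 2000:2002, value = c(10, NA, 30))
  expect_equal(interpolate_missing(lin, method = "linear")$value,
               c(10, 20, 30))

  geo <- tibble::tibble(year = 2000:2002, value = c(100, NA, 121))
  expect_equal(interpolate_missing(geo, method = "growth")$value,
               c(100, 110, 121))

  # longer gap against the closed-form geometric fill
  long <- tibble::tibble(year = 2000:2006,
                         value = c(50, NA, NA, NA, NA, NA, 50 * 1.07^6))
  got <- interpolate_missing(long, method = "growth")$value
  expect_equal(got, 50 * 1.07^(0:6), tolerance = 1e-10)
  expect_identical(got[c(1, 7)], long$value[c(1, 7)])  # observed untouched

  # trailing gap continues the last observed trend
  trail <- tibble::tibble(year = 2000:2003, value = c(10, 12, 14, NA))
  expect_equal(interpolate_missing(trail, method = "linear")$value[4], 16)

  # leading gaps stay NA; all-missing fails
  lead <- tibble::tibble(year = 2000:2002, value = c(NA, 5, 10))
  expect_warning(out <- interpolate_missing(lead, method = "linear"),
                 "leading")
  expect_true(is.na(out$value[1]))
  expect_error(
    interpolate_missing(tibble::tibble(year = 1:3, value = rep(NA_real_, 3))),
    "two observed"
  )
})

test_that("price index files are validated on read", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(year = 1992:1994, index = c(100, 104, 109)),
                   path)
  idx <- read_price_index(path)
  expect_equal(idx$index, c(100, 104, 109))
  readr::write_csv(tibble::tibble(year = 1992:1993, index = c(100, -4)), path)
  expect_error(read_price_index(path), "positive")
})
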