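#' Canonical panel columns
#'
#' The internal column vocabulary of a province-year panel: the outcome
#' (`carbon_cost`, CNY/tCO2e), three forestry-technology covariates
#' (`forestry_gdp` in billion CNY, `wood_production` in 10^4 tons,
#' `afforestation_area` in ha), three socio-economic covariates
#' (`labor_price`, `land_opportunity_cost`, `rural_consumption`, all CNY),
#' two natural-endowment covariates (`forest_stock` in 10^4 m^3,
#' `population_density` in people/km^2), plus identifiers `province`,
#' `year` and an optional `region` tag.
#'
#' @return Character vector of canonical column names.
#' @export
panel_columns <- function() {
  c("province", "year", "carbon_cost", "forestry_gdp", "wood_production",
    "afforestation_area", "labor_price", "land_opportunity_cost",
    "rural_consumption", "forest_stock", "population_density", "region")
}

#' Describe how a CSV maps onto the canonical panel
#'
#' Yearbook exports differ in column naming and monetary units; a schema
#' records, per canonical column, the file column it comes from and an
#' optional multiplicative unit conversion applied at load (e.g. 1e4 for a
#' column recorded in 10^4 CNY, so that all monetary values are held in
#' CNY internally).
#'
#' @param columns Named character vector mapping canonical names (see
#'   [panel_columns()]) to file column names. Defaults to the identity
#'   mapping.
#' @param scale Named numeric vector of per-column multipliers applied
#'   after reading; names are canonical column names.
#'
#' @return A `panel_schema` list.
#' @export
panel_schema <- function(columns = NULL, scale = NULL) {
  canonical <- panel_columns()
  if (is.null(columns)) {
    columns <- stats::setNames(canonical, canonical)
  }
  unknown <- setdiff(names(columns), canonical)
  if (length(unknown)) {
    abort(paste0("Unknown canonical column(s) in schema: ",
                 paste(unknown, collapse = ", ")))
  }
  if (!all(c("province", "year") %in% names(columns))) {
    abort("Schema must map at least `province` and `year`.")
  }
  if (!is.null(scale)) {
    bad <- setdiff(names(scale), names(columns))
    if (length(bad)) {
      abort(paste0("Scale given for unmapped column(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(list(columns = columns, scale = scale), class = "panel_schema")
}

#' Read a panel schema from a YAML file
#'
#' The on-disk form of [panel_schema()]: a YAML mapping with a `columns`
#' block (canonical name -> file column) and an optional `scale` block
#' (canonical name -> multiplier applied at load).
#'
#' @param path Path to the YAML file.
#' @return A `panel_schema`.
#' @export
read_panel_schema <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$columns)) abort("Schema YAML needs a `columns` mapping.")
  scale <- NULL
  if (!is.null(cfg$scale)) {
    raw <- unlist(cfg$scale)
    # YAML only reads exponents with an explicit sign as numbers;
    # accept "1.0e4" style too
    scale <- stats::setNames(suppressWarnings(as.numeric(raw)), names(raw))
    if (anyNA(scale)) {
      abort(sprintf("Non-numeric scale entry for `%s`.",
                    names(raw)[which(is.na(scale))[1]]))
    }
  }
  panel_schema(columns = unlist(cfg$columns), scale = scale)
}

#' Read a province-year panel from CSV
#'
#' Reads, renames and unit-converts the panel per a [panel_schema()],
#' validates it with [validate_panel()], and returns it sorted by
#' (province, year). Missing cells are kept as `NA` and counted in a
#' warning, never imputed here (see [interpolate_missing()]).
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema A [panel_schema()]; defaults to the identity mapping.
#' @param year_range Optional length-2 integer vector; years outside it are
#'   a validation error.
#'
#' @return A validated tibble of panel records.
#' @export
read_panel <- function(path, schema = panel_schema(), year_range = NULL) {
  if (!inherits(schema, "panel_schema")) abort("`schema` must be a panel_schema().")
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  file_cols <- unname(schema$columns)
  present <- file_cols %in% names(raw)
  if (!all(present)) {
    abort(paste0("Column(s) named in schema but absent from ", path, ": ",
                 paste(file_cols[!present], collapse = ", ")))
  }
  panel <- raw[file_cols]
  names(panel) <- names(schema$columns)

  numeric_cols <- setdiff(names(panel), c("province", "region"))
  for (col in numeric_cols) {
    v <- panel[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(parsed))
      if (length(bad)) {
        abort(sprintf("Non-numeric cell in column `%s`, row %d: \"%s\".",
                      col, bad[1], v[bad[1]]))
      }
      panel[[col]] <- parsed
    }
  }
  if (!is.null(schema$scale)) {
    for (col in names(schema$scale)) {
      panel[[col]] <- panel[[col]] * schema$scale[[col]]
    }
  }
  panel <- dplyr::arrange(tibble::as_tibble(panel), .data$province, .data$year)
  validate_panel(panel, year_range = year_range)
  n_missing <- sum(is.na(panel[numeric_cols]))
  if (n_missing > 0) {
    warn(sprintf("%d missing cell(s) in %s; left as NA (use interpolate_missing()).",
                 n_missing, path))
  }
  panel
}

#' Write a panel to CSV
#'
#' Full-precision CSV output; a round trip through [read_panel()] restores
#' numeric content exactly.
#'
#' @param panel A panel tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path, progress = FALSE)
  invisible(path)
}

#' Validate a province-year panel
#'
#' Checks the panel invariants: unique (province, year) keys, finite
#' observed numeric cells, non-negative forest stock, strictly positive
#' population density, years inside `year_range` when given, and region
#' labels drawn from eastern/central/western/national when a `region`
#' column is present.
#'
#' @param panel A data frame of panel records.
#' @param year_range Optional length-2 vector of admissible years.
#' @return `panel`, invisibly, or an error naming the offending record.
#' @export
validate_panel <- function(panel, year_range = NULL) {
  if (!all(c("province", "year") %in% names(panel))) {
    abort("A panel needs `province` and `year` columns.")
  }
  key <- paste(panel$province, panel$year, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    d <- strsplit(d, "\r", fixed = TRUE)[[1]]
    abort(sprintf("Duplicate panel record for province \"%s\", year %s.",
                  d[1], d[2]))
  }
  if (!is.null(year_range)) {
    out <- panel$year < min(year_range) | panel$year > max(year_range)
    if (any(out)) {
      abort(sprintf("Year %s outside the configured span [%s, %s].",
                    panel$year[which(out)[1]], min(year_range), max(year_range)))
    }
  }
  numeric_cols <- intersect(setdiff(panel_columns(), c("province", "region")),
                            names(panel))
  for (col in numeric_cols) {
    v <- panel[[col]]
    if (any(!is.na(v) & !is.finite(v))) {
      abort(sprintf("Non-finite value in column `%s`, row %d.",
                    col, which(!is.na(v) & !is.finite(v))[1]))
    }
  }
  if ("forest_stock" %in% names(panel) &&
      any(panel$forest_stock < 0, na.rm = TRUE)) {
    abort("`forest_stock` must be non-negative.")
  }
  if ("population_density" %in% names(panel) &&
      any(panel$population_density <= 0, na.rm = TRUE)) {
    abort("`population_density` must be strictly positive.")
  }
  if ("region" %in% names(panel)) {
    ok <- c("eastern", "central", "western", "national")
    bad <- setdiff(stats::na.omit(unique(panel$region)), ok)
    if (length(bad)) {
      abort(paste0("Unknown region label(s): ", paste(bad, collapse = ", "),
                   "; expected ", paste(ok, collapse = "/"), "."))
    }
  }
  invisible(panel)
}

#' Read a province-to-region map
#'
#' A two-column CSV (`province,region`) assigning every province to an
#' eastern/central/western belt. Shipped as an editable configuration
#' rather than a hard-coded list; a synthetic template for generated
#' panels is included under `inst/extdata/`.
#'
#' @param path Path to the CSV.
#' @return A tibble with columns `province` and `region`.
#' @export
read_region_map <- function(path) {
  rm_ <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("province", "region") %in% names(rm_))) {
    abort("A region map needs `province` and `region` columns.")
  }
  ok <- c("eastern", "central", "western", "national")
  bad <- setdiff(unique(rm_$region), ok)
  if (length(bad)) {
    abort(paste0("Unknown region label(s): ", paste(bad, collapse = ", ")))
  }
  tibble::as_tibble(rm_[c("province", "region")])
}

#' Attach region labels to a panel
#'
#' @param panel A panel tibble.
#' @param region_map A tibble from [read_region_map()] (or equivalent).
#' @return The panel with a `region` column; an error if any panel
#'   province is unmapped.
#' @export
assign_regions <- function(panel, region_map) {
  unmapped <- setdiff(unique(panel$province), region_map$province)
  if (length(unmapped)) {
    abort(paste0("Province(s) missing from region map: ",
                 paste(unmapped, collapse = ", ")))
  }
  panel$region <- NULL
  dplyr::left_join(panel, region_map, by = "province")
}
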