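#' Read a price index series
#'
#' A two-column CSV (`year,index`) holding a price index on a base-100
#' scale. The index must be strictly positive.
#'
#' @param path Path to the CSV.
#' @return A tibble with columns `year` and `index`.
#' @export
read_price_index <- function(path) {
  idx <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("year", "index") %in% names(idx))) {
    abort("A price index needs `year` and `index` columns.")
  }
  if (any(!is.finite(idx$index)) || any(idx$index <= 0)) {
    abort("Price index values must be strictly positive and finite.")
  }
  if (anyDuplicated(idx$year)) abort("Duplicate year in price index.")
  tibble::as_tibble(idx[c("year", "index")])
}

#' Deflate monetary columns to base-year prices
#'
#' Converts nominal CNY series to constant prices of `base_year` using a
#' price index: `value_out(y) = value_in(y) * index(base_year) / index(y)`.
#' The convention follows cost studies that express three decades of
#' monetary variables at the prices of the first panel year. Deflation is
#' idempotent: once a column is at base prices (index identically equal to
#' its base value), a second pass leaves it unchanged.
#'
#' @param data A data frame with a `year` column.
#' @param cols Character vector of column names to deflate.
#' @param index A price index tibble (`year`, `index`), e.g. from
#'   [read_price_index()].
#' @param base_year Base year; must be present in `index`. Default 1992.
#'
#' @return `data` with the named columns deflated.
#' @export
#'
#' @examples
#' idx <- tibble::tibble(year = 1992:1994, index = c(100, 110, 121))
#' df <- tibble::tibble(year = 1992:1994, cost = c(50, 55, 60.5))
#' deflate_to_base(df, "cost", idx) # constant 50, 50, 50 at 1992 prices
deflate_to_base <- function(data, cols, index, base_year = 1992) {
  if (!"year" %in% names(data)) abort("`data` needs a `year` column.")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("Column(s) not in `data`: ", paste(missing_cols, collapse = ", ")))
  }
  if (!base_year %in% index$year) {
    abort(sprintf("Base year %s is missing from the price index.", base_year))
  }
  missing_years <- setdiff(unique(data$year), index$year)
  if (length(missing_years)) {
    abort(paste0("Price index has no entry for year(s): ",
                 paste(sort(missing_years), collapse = ", ")))
  }
  base_value <- index$index[match(base_year, index$year)]
  factor <- base_value / index$index[match(data$year, index$year)]
  for (col in cols) data[[col]] <- data[[col]] * factor
  data
}

#' Fill missing years of an annual series
#'
#' Completes an annual series with interior or trailing gaps. `"linear"`
#' draws a straight line between the bracketing observations;
#' `"growth"` fits a constant geometric (natural) growth rate to the
#' bracketing observations and fills along it — the convention for stock
#' variables such as standing forest volume. Trailing gaps are extended
#' from the last two observations (same rule, no right bracket). Leading
#' gaps are deliberately not back-extrapolated and stay `NA` with a
#' warning. Observed values are never altered.
#'
#' @param data A data frame with columns `year` and the series column.
#' @param col Name of the value column; default `"value"`.
#' @param method `"linear"` or `"growth"`.
#'
#' @return `data` with the gap years of `col` filled.
#' @export
#'
#' @examples
#' df <- tibble::tibble(year = 2000:2002, value = c(100, NA, 121))
#' interpolate_missing(df, method = "growth") # 2001 -> 110
interpolate_missing <- function(data, col = "value",
                                method = c("linear", "growth")) {
  method <- match.arg(method)
  if (!all(c("year", col) %in% names(data))) {
    abort(sprintf("`data` needs `year` and `%s` columns.", col))
  }
  data <- dplyr::arrange(data, .data$year)
  v <- data[[col]]
  obs <- which(!is.na(v))
  if (length(obs) < 2) {
    abort("Interpolation needs at least two observed years.")
  }
  yrs <- data$year
  fill_one <- function(y, y1, v1, y2, v2) {
    if (method == "linear") {
      v1 + (v2 - v1) * (y - y1) / (y2 - y1)
    } else {
      if (v1 <= 0 || v2 <= 0) {
        abort("Growth-rate interpolation needs strictly positive observations.")
      }
      rate <- (v2 / v1)^(1 / (y2 - y1))
      v1 * rate^(y - y1)
    }
  }
  for (i in which(is.na(v))) {
    left <- obs[obs < i]
    right <- obs[obs > i]
    if (!length(left)) next  # leading gap: not back-extrapolated
    if (length(right)) {
      l <- max(left); r <- min(right)
      v[i] <- fill_one(yrs[i], yrs[l], v[l], yrs[r], v[r])
    } else {
      # trailing gap: continue the trend of the last two observations
      l2 <- tail(left, 2)
      v[i] <- fill_one(yrs[i], yrs[l2[1]], v[l2[1]], yrs[l2[2]], v[l2[2]])
    }
  }
  if (anyNA(v)) {
    warn(sprintf("%d leading year(s) left NA (no back-extrapolation).",
                 sum(is.na(v))))
  }
  data[[col]] <- v
  data
}
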