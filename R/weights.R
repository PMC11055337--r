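#' Spatial weight matrices
#'
#' Constructs the n-by-n spatial weight matrix used by the spatial panel
#' models, from one of three sources: a binary contiguity structure (an
#' adjacency edge list), inverse great-circle distance between province
#' coordinates, or inverse absolute difference of a period-mean economic
#' indicator ("economic distance"). The diagonal is always zero; row
#' standardisation (each nonzero row rescaled to sum to one) is the
#' convention assumed by the model-fitting functions. The eigenvalue range
#' of the (standardised) matrix is cached because it bounds the admissible
#' spatial autoregressive coefficient: rho must lie in
#' (1/lambda_min, 1/lambda_max).
#'
#' @param source For `kind = "contiguity"`: a data frame with columns
#'   `i`, `j` naming neighbouring provinces (undirected edges), or a
#'   square 0/1 matrix with dimnames. For `"geographic"`: a data frame
#'   with `province`, `lat`, `lon` (degrees). For `"economic"`: a data
#'   frame with `province`, `value` (a period-mean indicator) or
#'   `province`, `year`, `value` (averaged over years here).
#' @param kind One of `"contiguity"`, `"geographic"`, `"economic"`.
#' @param standardize Row-standardise the matrix (default `TRUE`).
#'
#' @return A `spatial_weights` object: list with the matrix `W`, the
#'   `provinces` ordering, `kind`, `row_standardized`, and the cached
#'   `eig_range`.
#' @export
build_weights <- function(source,
                          kind = c("contiguity", "geographic", "economic"),
                          standardize = TRUE) {
  kind <- match.arg(kind)
  W <- switch(kind,
    contiguity = weights_from_contiguity(source),
    geographic = weights_from_coordinates(source),
    economic = weights_from_indicator(source)
  )
  new_spatial_weights(W, kind = kind, standardize = standardize)
}

new_spatial_weights <- function(W, kind, standardize) {
  if (nrow(W) < 2) abort("A weight matrix needs at least 2 units.")
  diag(W) <- 0
  if (any(W < 0)) abort("Weights must be non-negative.")
  provinces <- rownames(W) %||% as.character(seq_len(nrow(W)))
  if (standardize) {
    rs <- rowSums(W)
    if (any(rs == 0)) {
      warn(paste0("Isolated unit(s) with no neighbours: ",
                  paste(provinces[rs == 0], collapse = ", ")))
      rs[rs == 0] <- 1
    }
    W <- W / rs
  }
  ev <- eigen(W, only.values = TRUE)$values
  ev <- Re(ev[abs(Im(ev)) < 1e-8])
  structure(
    list(W = W, provinces = provinces, kind = kind,
         row_standardized = standardize,
         eig_range = c(min(ev), max(ev))),
    class = "spatial_weights"
  )
}

weights_from_contiguity <- function(source) {
  if (is.matrix(source)) {
    if (nrow(source) != ncol(source)) abort("Adjacency matrix must be square.")
    if (!isSymmetric(unname(source))) abort("Adjacency matrix must be symmetric.")
    W <- (source != 0) * 1
    return(W)
  }
  if (!all(c("i", "j") %in% names(source))) {
    abort("A contiguity edge list needs columns `i` and `j`.")
  }
  units <- sort(unique(c(as.character(source$i), as.character(source$j))))
  W <- matrix(0, length(units), length(units), dimnames = list(units, units))
  for (r in seq_len(nrow(source))) {
    a <- as.character(source$i[r]); b <- as.character(source$j[r])
    if (a == b) abort(sprintf("Self-edge for unit \"%s\".", a))
    W[a, b] <- 1; W[b, a] <- 1
  }
  W
}

weights_from_coordinates <- function(source) {
  if (!all(c("province", "lat", "lon") %in% names(source))) {
    abort("Coordinates need columns `province`, `lat`, `lon`.")
  }
  n <- nrow(source)
  # great-circle distances in km
  D <- geosphere::distm(cbind(source$lon, source$lat)) / 1000
  dimnames(D) <- list(source$province, source$province)
  off <- D[upper.tri(D)]
  if (any(off == 0)) {
    idx <- which(D == 0 & upper.tri(D), arr.ind = TRUE)[1, ]
    abort(sprintf("Zero distance between distinct units \"%s\" and \"%s\".",
                  source$province[idx[1]], source$province[idx[2]]))
  }
  W <- 1 / D
  diag(W) <- 0
  W
}

weights_from_indicator <- function(source) {
  if (!all(c("province", "value") %in% names(source))) {
    abort("An economic indicator needs columns `province` and `value`.")
  }
  means <- dplyr::summarise(dplyr::group_by(source, .data$province),
                            value = mean(.data$value), .groups = "drop")
  v <- means$value
  names(v) <- means$province
  D <- abs(outer(v, v, "-"))
  bad <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  if (nrow(bad)) {
    abort(sprintf(
      "Identical period-mean indicator for \"%s\" and \"%s\" (infinite weight).",
      names(v)[bad[1, 1]], names(v)[bad[1, 2]]))
  }
  W <- 1 / D
  diag(W) <- 0
  dimnames(W) <- list(names(v), names(v))
  W
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("<spatial_weights> %d units, kind = %s, %s\n",
              nrow(x$W), x$kind,
              if (x$row_standardized) "row-standardized" else "raw"))
  cat(sprintf("  eigenvalue range [%.4f, %.4f]; admissible rho (%.4f, %.4f)\n",
              x$eig_range[1], x$eig_range[2],
              1 / x$eig_range[1], 1 / x$eig_range[2]))
  invisible(x)
}

#' Admissible interval for the spatial autoregressive coefficient
#'
#' @param W A `spatial_weights` object.
#' @return Length-2 numeric: (1/lambda_min, 1/lambda_max).
#' @export
rho_interval <- function(W) {
  c(1 / W$eig_range[1], 1 / W$eig_range[2])
}
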