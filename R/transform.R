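#' Transform and z-standardize life-history traits
#'
#' Applies the per-variable variance-stabilizing transforms used throughout
#' the life-history models -- log10 for lengths and weights, square root for
#' fecundity, arcsine square root for proportions -- followed by
#' z-standardization of each transformed column. The mapping and the
#' centering/scaling constants are stored in the `transform_map` attribute
#' so they can be inverted or re-applied to new individuals (see
#' [apply_transform()]).
#'
#' @param table A raw trait tibble (attribute `transform_state = "raw"`).
#' @param mapping Named list with elements `log10`, `sqrt`, `asinsqrt`,
#'   each a character vector of column names. Defaults to the standard
#'   assignment for the bundled trait set.
#' @param z Standardize after transforming (default `TRUE`).
#' @return The transformed tibble, `transform_state = "transformed"`.
#' @export
transform_traits <- function(table, mapping = NULL, z = TRUE) {
  state <- attr(table, "transform_state") %||% "raw"
  if (identical(state, "transformed")) {
    stop("table is already transformed")
  }
  mapping <- mapping %||% list(
    log10 = intersect(c("sl_mm", "lean_weight_g", "embryo_lean_weight_mg"),
                      names(table)),
    sqrt = intersect("fecundity", names(table)),
    asinsqrt = intersect(c("fat_content", "gsi_or_ra", "embryo_fat"),
                         names(table))
  )
  map <- list()
  out <- table
  fns <- list(
    log10 = function(x, col) {
      if (any(x <= 0, na.rm = TRUE)) {
        stop("log10 transform of non-positive values in ", col)
      }
      log10(x)
    },
    sqrt = function(x, col) {
      if (any(x < 0, na.rm = TRUE)) stop("sqrt of negative values in ", col)
      sqrt(x)
    },
    asinsqrt = function(x, col) {
      if (any(x < 0 | x > 1, na.rm = TRUE)) {
        stop("arcsine-sqrt requires proportions in [0, 1]: ", col)
      }
      asin(sqrt(x))
    }
  )
  for (kind in names(mapping)) {
    for (col in mapping[[kind]]) {
      v <- fns[[kind]](out[[col]], col)
      ctr <- 0
      scl <- 1
      if (z) {
        ctr <- mean(v, na.rm = TRUE)
        scl <- sd(v, na.rm = TRUE)
        if (!is.finite(scl) || scl == 0) scl <- 1
        v <- (v - ctr) / scl
      }
      out[[col]] <- v
      map[[col]] <- list(kind = kind, center = ctr, scale = scl)
    }
  }
  attr(out, "transform_state") <- "transformed"
  attr(out, "transform_map") <- map
  out
}

#' Apply a stored transformation to new individuals
#'
#' Re-applies the transforms and z-scalings recorded by [transform_traits()]
#' on a training table, so individuals measured later (or from another
#' genus) land on the same scale before projection onto a divergence vector.
#'
#' @param table A raw trait tibble.
#' @param map A `transform_map` attribute from a transformed table.
#' @return The transformed tibble.
#' @export
apply_transform <- function(table, map) {
  out <- table
  for (col in names(map)) {
    if (!col %in% names(out)) next
    m <- map[[col]]
    v <- switch(m$kind,
      log10 = log10(out[[col]]),
      sqrt = sqrt(out[[col]]),
      asinsqrt = asin(sqrt(out[[col]]))
    )
    out[[col]] <- (v - m$center) / m$scale
  }
  attr(out, "transform_state") <- "transformed"
  attr(out, "transform_map") <- map
  out
}
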