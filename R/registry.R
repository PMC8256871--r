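#' Image feature registry
#'
#' The per-view feature set extracted from each plant silhouette. Fourteen
#' geometric descriptors are computed per view; with three views (top, side0,
#' side90) the geometry-only predictor block used for biomass modelling has
#' 14 x 3 = 42 columns. One additional near-infrared feature (`mean_gray`,
#' 8-bit mean intensity under the plant mask; higher = drier tissue) is kept
#' alongside but excluded from the geometry-only subset.
#'
#' Column names in a feature table are `<feature>.<view>`, e.g. `area.top`.
#'
#' @return `pg_feature_registry()` returns a list with elements `geometric`
#'   (character vector of the 14 geometric feature names), `nir` (the NIR
#'   feature names) and `views` (the three view labels).
#' @examples
#' reg <- pg_feature_registry()
#' length(reg$geometric) * length(reg$views)  # 42 geometry-only columns
#' @export
pg_feature_registry <- function() {
  list(
    geometric = c(
      "area",            # projected (foreground) area, px
      "hull_area",       # convex hull area, px
      "perimeter",       # silhouette perimeter, px
      "hull_perimeter",  # convex hull perimeter, px
      "width",           # bounding-box width, px
      "height",          # bounding-box height, px
      "caliper",         # maximum caliper (Feret) length, px
      "compactness",     # 4*pi*area / perimeter^2, dimensionless in (0, 1]
      "eccentricity",    # ellipse eccentricity from second moments, [0, 1)
      "centroid_y",      # foreground centroid row coordinate, px
      "solidity",        # area / hull_area, (0, 1]
      "aspect_ratio",    # width / height
      "extent",          # area / bounding-box area, (0, 1]
      "eq_diameter"      # diameter of the circle with equal area, px
    ),
    nir = "mean_gray",
    views = c("top", "side0", "side90")
  )
}

#' Registered feature-table column names
#'
#' @param geometry_only if `TRUE`, return only the 42 geometric columns used
#'   as biomass predictors; otherwise include NIR columns as well.
#' @return character vector of `<feature>.<view>` column names.
#' @export
pg_feature_columns <- function(geometry_only = FALSE) {
  reg <- pg_feature_registry()
  feats <- if (geometry_only) reg$geometric else c(reg$geometric, reg$nir)
  as.vector(vapply(reg$views, function(v) paste(feats, v, sep = "."),
                   character(length(feats))))
}
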