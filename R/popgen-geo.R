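#' Pairwise great-circle distances between populations
#'
#' Haversine distances on a sphere of mean Earth radius 6371.0088 km,
#' optionally natural-log transformed (isolation-by-distance against
#' log distance accommodates non-linear expansion). A Euclidean
#' distance on raw decimal degrees is available for sensitivity checks.
#'
#' @param table population table with `latitude` and `longitude` in
#'   decimal degrees (see [parse_population_table()]).
#' @param transform `"linear"` or `"log"` (natural log of km; requires
#'   all off-diagonal distances positive).
#' @param method `"haversine"` (default) or `"euclidean_degrees"`.
#' @return symmetric matrix of km (or ln km), zero diagonal.
#' @export
geo_distances <- function(table, transform = c("linear", "log"),
                          method = c("haversine", "euclidean_degrees")) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  pt <- parse_population_table(table)
  if (is.null(pt$coords)) abort("population table lacks coordinates")
  lat <- pt$coords$latitude
  lon <- pt$coords$longitude
  n <- length(lat)
  m <- matrix(0, n, n, dimnames = list(pt$coords$population,
                                       pt$coords$population))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- if (method == "haversine") {
        haversine_km(lat[i], lon[i], lat[j], lon[j])
      } else {
        sqrt((lat[i] - lat[j])^2 + (lon[i] - lon[j])^2)
      }
      m[i, j] <- m[j, i] <- d
    }
  }
  if (transform == "log") {
    off <- m[lower.tri(m)]
    if (any(off <= 0)) {
      abort("log transform undefined: duplicate coordinates give zero distance")
    }
    m[lower.tri(m)] <- log(m[lower.tri(m)])
    m[upper.tri(m)] <- t(m)[upper.tri(m)]
  }
  attr(m, "transform") <- transform
  m
}

#' Haversine great-circle distance in kilometres
#' @param lat1,lon1,lat2,lon2 decimal degrees.
#' @param radius_km sphere radius (default: mean Earth radius).
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0088) {
  rad <- pi / 180
  a <- sin((lat2 - lat1) * rad / 2)^2 +
    cos(lat1 * rad) * cos(lat2 * rad) * sin((lon2 - lon1) * rad / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}
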