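#' Round site coordinates to the nearest integer degree
#'
#' Nearest-integer rounding with halves rounded away from zero (10.65 -> 11,
#' 0.5 -> 1, -0.5 -> -1), used to pool nearby sites before building the
#' spatial proximity matrix.
#'
#' @param latitude,longitude Coordinates in degrees (vectorised).
#' @return A tibble with integer `latitude` and `longitude` columns.
#' @export
round_coordinates <- function(latitude, longitude) {
  if (any(abs(latitude) > 90, na.rm = TRUE)) {
    abort("latitude outside [-90, 90]")
  }
  if (any(abs(longitude) > 180, na.rm = TRUE)) {
    abort("longitude outside [-180, 180]")
  }
  half_away <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))
  tibble::tibble(latitude = half_away(latitude),
                 longitude = half_away(longitude))
}

#' Haversine great-circle distance
#'
#' Spherical distance between two points (or two vectors of points) given as
#' latitude/longitude in degrees.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees (vectorised).
#' @param radius_km Sphere radius in kilometres, default 6371 (mean Earth
#'   radius).
#' @return Distance(s) in kilometres.
#' @export
#' @examples
#' haversine_distance(0, 0, 0, 180) # half the circumference, ~20015 km
haversine_distance <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(1, pmax(0, a))
  2 * radius_km * asin(sqrt(a))
}

#' Build the normalised site proximity matrix
#'
#' Rounds coordinates to integer degrees, computes pairwise Haversine
#' distances D, and maps them to proximities on \[0, 1\] with 1 for
#' coincident sites and 0 for the most distant pair (`1 - D/max(D)`, the
#' default transform). Because this transform is not guaranteed positive
#' semidefinite, negative eigenvalues are clipped to zero and the matrix is
#' rescaled to unit diagonal before a small nugget is added, so the result
#' is usable as a covariance for the correlated site slopes.
#'
#' @param sites A tibble/data.frame with `site_id`, `latitude`, `longitude`
#'   (one row per site), or a long observation table from
#'   [prepare_series()] (unique sites are extracted).
#' @param nugget Small positive value added to the diagonal, default 1e-6.
#' @param transform `"linear"` (default, `1 - D/max(D)`) or `"exponential"`
#'   (`exp(-D / length_scale)`).
#' @param length_scale Kilometres; only for the exponential transform
#'   (default 2000).
#' @return An object of class `spatial_covariance`: a list with `site_ids`,
#'   `proximity` (diagonal `1 + nugget`), `nugget`, `chol` (lower Cholesky
#'   factor) and `min_eigenvalue_raw` (smallest eigenvalue before repair).
#' @export
build_site_proximity <- function(sites, nugget = 1e-6,
                                 transform = c("linear", "exponential"),
                                 length_scale = 2000) {
  transform <- match.arg(transform)
  if (!"site_id" %in% names(sites)) {
    abort("`sites` must contain a site_id column")
  }
  sites <- dplyr::distinct(
    tibble::as_tibble(sites)[, c("site_id", "latitude", "longitude")],
    .data$site_id, .keep_all = TRUE
  )
  n <- nrow(sites)
  if (n < 1) abort("at least one site is required")
  rc <- round_coordinates(sites$latitude, sites$longitude)
  D <- outer(seq_len(n), seq_len(n), function(i, j) {
    haversine_distance(rc$latitude[i], rc$longitude[i],
                       rc$latitude[j], rc$longitude[j])
  })
  D <- (D + t(D)) / 2
  if (max(D) > 0) {
    P <- switch(transform,
      linear = 1 - D / max(D),
      exponential = exp(-D / length_scale)
    )
  } else {
    # all sites coincide after rounding: identity avoids a singular
    # all-ones matrix
    P <- diag(n)
  }
  diag(P) <- 1
  ev <- eigen(P, symmetric = TRUE)
  min_raw <- min(ev$values)
  if (min_raw < 0) {
    lam <- pmax(ev$values, 0)
    P <- ev$vectors %*% (lam * t(ev$vectors))
    d <- sqrt(pmax(diag(P), .Machine$double.eps))
    P <- P / outer(d, d)
    P <- pmin(pmax(P, 0), 1)
    P <- (P + t(P)) / 2
  }
  diag(P) <- 1 + nugget
  ch <- NULL
  jitter <- nugget
  for (k in 1:6) {
    ch <- tryCatch(t(chol(P)), error = function(e) NULL)
    if (!is.null(ch)) break
    jitter <- jitter * 10
    diag(P) <- 1 + nugget + jitter
  }
  if (is.null(ch)) abort("proximity matrix could not be factorised")
  dimnames(P) <- list(sites$site_id, sites$site_id)
  structure(
    list(site_ids = sites$site_id, proximity = P, nugget = nugget,
         chol = ch, min_eigenvalue_raw = min_raw),
    class = "spatial_covariance"
  )
}

#' @export
print.spatial_covariance <- function(x, ...) {
  cat(sprintf("<spatial_covariance> %d sites, nugget %.1e, min raw eigenvalue %.3g\n",
              length(x$site_ids), x$nugget, x$min_eigenvalue_raw))
  invisible(x)
}
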