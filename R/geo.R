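# Coordinate reference systems and ellipsoidal geodesy.
#
# Native grids of environmental datasets come in a handful of projections
# (geographic lon/lat, sinusoidal, Lambert conformal conic, plate carree,
# Albers equal area). Forward/inverse formulas follow Snyder's "Map
# Projections: A Working Manual"; geodesic distance and azimuth delegate to
# geosphere (Karney's algorithms on the WGS84 ellipsoid).

WGS84_A <- 6378137
WGS84_F <- 1 / 298.257223563
# Authalic sphere radius used by the MODIS sinusoidal grid definition.
MODIS_SPHERE_R <- 6371007.181

#' Coordinate reference system descriptors
#'
#' Construct a CRS descriptor for one of the projections supported by the
#' annotation engine. All angular parameters are degrees; ellipsoidal
#' projections default to WGS84 (a = 6378137 m, 1/f = 298.257223563).
#' The sinusoidal projection defaults to the authalic sphere radius
#' 6371007.181 m used by the MODIS land grids.
#'
#' @param lon0 central meridian (degrees)
#' @param lat0 latitude of origin (degrees)
#' @param lat1,lat2 standard parallels (degrees)
#' @param radius sphere radius in meters (spherical projections)
#' @param a,f ellipsoid semi-major axis (m) and flattening
#' @return an object of class `crs_id`
#' @export
crs_wgs84 <- function() {
  structure(list(name = "wgs84_lonlat"), class = "crs_id")
}

#' @rdname crs_wgs84
#' @export
crs_sinusoidal <- function(lon0 = 0, radius = MODIS_SPHERE_R) {
  structure(list(name = "sinusoidal", lon0 = lon0, radius = radius),
            class = "crs_id")
}

#' @rdname crs_wgs84
#' @export
crs_plate_carree <- function(lon0 = 0, radius = MODIS_SPHERE_R) {
  structure(list(name = "plate_carree", lon0 = lon0, radius = radius),
            class = "crs_id")
}

#' @rdname crs_wgs84
#' @export
crs_lambert_conformal_conic <- function(lat1 = 33, lat2 = 45, lat0 = 40,
                                        lon0 = -97, a = WGS84_A, f = WGS84_F) {
  structure(list(name = "lambert_conformal_conic", lat1 = lat1, lat2 = lat2,
                 lat0 = lat0, lon0 = lon0, a = a, f = f),
            class = "crs_id")
}

#' @rdname crs_wgs84
#' @export
crs_albers_equal_area <- function(lat1 = 29.5, lat2 = 45.5, lat0 = 23,
                                  lon0 = -96, a = WGS84_A, f = WGS84_F) {
  structure(list(name = "albers_equal_area", lat1 = lat1, lat2 = lat2,
                 lat0 = lat0, lon0 = lon0, a = a, f = f),
            class = "crs_id")
}

#' @export
print.crs_id <- function(x, ...) {
  pars <- x[setdiff(names(x), "name")]
  cat("<crs_id>", x$name,
      if (length(pars)) paste0("(", paste(names(pars), unlist(pars),
                                          sep = "=", collapse = ", "), ")"),
      "\n")
  invisible(x)
}

is_lonlat <- function(crs) inherits(crs, "crs_id") && crs$name == "wgs84_lonlat"

#' Build a CRS from a manifest entry
#'
#' @param spec a string naming the CRS, or a list with a `name` element and
#'   projection parameters.
#' @return a `crs_id`
#' @export
as_crs <- function(spec) {
  if (inherits(spec, "crs_id")) return(spec)
  if (is.character(spec)) spec <- list(name = spec)
  if (!is.list(spec) || is.null(spec$name))
    et_validation_error("CRS spec must be a name or a list with $name")
  nm <- spec$name
  args <- spec[setdiff(names(spec), "name")]
  ctor <- switch(nm,
    wgs84_lonlat = crs_wgs84,
    sinusoidal = crs_sinusoidal,
    plate_carree = crs_plate_carree,
    lambert_conformal_conic = crs_lambert_conformal_conic,
    albers_equal_area = crs_albers_equal_area,
    et_validation_error(sprintf("unknown CRS name '%s'", nm))
  )
  do.call(ctor, args)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# -- projection kernels (lon/lat degrees <-> projected meters) ---------------

proj_forward <- function(lon, lat, crs) {
  switch(crs$name,
    wgs84_lonlat = list(x = lon, y = lat),
    plate_carree = list(x = crs$radius * deg2rad(lon - crs$lon0),
                        y = crs$radius * deg2rad(lat)),
    sinusoidal = list(
      x = crs$radius * deg2rad(lon - crs$lon0) * cos(deg2rad(lat)),
      y = crs$radius * deg2rad(lat)
    ),
    lambert_conformal_conic = lcc_forward(lon, lat, crs),
    albers_equal_area = aea_forward(lon, lat, crs),
    et_validation_error(sprintf("unknown CRS '%s'", crs$name))
  )
}

proj_inverse <- function(x, y, crs) {
  switch(crs$name,
    wgs84_lonlat = list(lon = x, lat = y),
    plate_carree = list(lon = rad2deg(x / crs$radius) + crs$lon0,
                        lat = rad2deg(y / crs$radius)),
    sinusoidal = {
      phi <- y / crs$radius
      cphi <- cos(phi)
      lam <- ifelse(abs(cphi) < 1e-12, 0, x / (crs$radius * cphi))
      list(lon = rad2deg(lam) + crs$lon0, lat = rad2deg(phi))
    },
    lambert_conformal_conic = lcc_inverse(x, y, crs),
    albers_equal_area = aea_inverse(x, y, crs),
    et_validation_error(sprintf("unknown CRS '%s'", crs$name))
  )
}

# Lambert conformal conic, ellipsoidal (Snyder 1987, eqs 15-1..15-11).
lcc_consts <- function(crs) {
  e <- sqrt(crs$f * (2 - crs$f))
  msnyder <- function(phi) cos(phi) / sqrt(1 - (e * sin(phi))^2)
  tsnyder <- function(phi) {
    tan(pi / 4 - phi / 2) /
      ((1 - e * sin(phi)) / (1 + e * sin(phi)))^(e / 2)
  }
  p1 <- deg2rad(crs$lat1); p2 <- deg2rad(crs$lat2); p0 <- deg2rad(crs$lat0)
  n <- if (abs(p1 - p2) < 1e-12) sin(p1) else
    (log(msnyder(p1)) - log(msnyder(p2))) / (log(tsnyder(p1)) - log(tsnyder(p2)))
  F <- msnyder(p1) / (n * tsnyder(p1)^n)
  list(e = e, n = n, F = F, rho0 = crs$a * F * tsnyder(p0)^n,
       tsnyder = tsnyder)
}

lcc_forward <- function(lon, lat, crs) {
  k <- lcc_consts(crs)
  # the pole on the far side of the cone is a singularity
  bad <- if (k$n > 0) lat <= -89.5 else lat >= 89.5
  if (any(bad))
    et_domain_error("latitude outside Lambert conformal conic domain")
  rho <- crs$a * k$F * k$tsnyder(deg2rad(lat))^k$n
  th <- k$n * deg2rad(lon - crs$lon0)
  list(x = rho * sin(th), y = k$rho0 - rho * cos(th))
}

lcc_inverse <- function(x, y, crs) {
  k <- lcc_consts(crs)
  rho <- sign(k$n) * sqrt(x^2 + (k$rho0 - y)^2)
  th <- atan2(sign(k$n) * x, sign(k$n) * (k$rho0 - y))
  tt <- (rho / (crs$a * k$F))^(1 / k$n)
  phi <- pi / 2 - 2 * atan(tt)
  for (i in 1:25) {
    phi_new <- pi / 2 - 2 * atan(
      tt * ((1 - k$e * sin(phi)) / (1 + k$e * sin(phi)))^(k$e / 2)
    )
    if (all(abs(phi_new - phi) < 1e-13)) { phi <- phi_new; break }
    phi <- phi_new
  }
  list(lon = rad2deg(th / k$n) + crs$lon0, lat = rad2deg(phi))
}

# Albers equal area, ellipsoidal (Snyder 1987, eqs 14-1..14-21).
aea_consts <- function(crs) {
  e <- sqrt(crs$f * (2 - crs$f)); e2 <- e^2
  msnyder <- function(phi) cos(phi) / sqrt(1 - e2 * sin(phi)^2)
  qsnyder <- function(phi) {
    s <- sin(phi)
    (1 - e2) * (s / (1 - e2 * s^2) - (1 / (2 * e)) *
                  log((1 - e * s) / (1 + e * s)))
  }
  p1 <- deg2rad(crs$lat1); p2 <- deg2rad(crs$lat2); p0 <- deg2rad(crs$lat0)
  n <- if (abs(p1 - p2) < 1e-12) sin(p1) else
    (msnyder(p1)^2 - msnyder(p2)^2) / (qsnyder(p2) - qsnyder(p1))
  C <- msnyder(p1)^2 + n * qsnyder(p1)
  list(e = e, e2 = e2, n = n, C = C,
       rho0 = crs$a * sqrt(C - n * qsnyder(p0)) / n, qsnyder = qsnyder)
}

aea_forward <- function(lon, lat, crs) {
  k <- aea_consts(crs)
  q <- k$qsnyder(deg2rad(lat))
  under <- k$C - k$n * q
  if (any(under < 0))
    et_domain_error("latitude outside Albers equal-area domain")
  rho <- crs$a * sqrt(under) / k$n
  th <- k$n * deg2rad(lon - crs$lon0)
  list(x = rho * sin(th), y = k$rho0 - rho * cos(th))
}

aea_inverse <- function(x, y, crs) {
  k <- aea_consts(crs)
  rho <- sqrt(x^2 + (k$rho0 - y)^2)
  th <- atan2(sign(k$n) * x, sign(k$n) * (k$rho0 - y))
  q <- (k$C - (rho * k$n / crs$a)^2) / k$n
  phi <- asin(pmin(1, pmax(-1, q / 2)))
  for (i in 1:25) {
    s <- sin(phi)
    delta <- (1 - k$e2 * s^2)^2 / (2 * cos(phi)) *
      (q / (1 - k$e2) - s / (1 - k$e2 * s^2) +
         (1 / (2 * k$e)) * log((1 - k$e * s) / (1 + k$e * s)))
    phi <- phi + delta
    if (all(abs(delta) < 1e-13)) break
  }
  list(lon = rad2deg(th / k$n) + crs$lon0, lat = rad2deg(phi))
}

#' Transform points between coordinate reference systems
#'
#' Transforms coordinates from one CRS to another through WGS84 lon/lat.
#' Inputs and outputs are 2-column matrices (or length-2 vectors); columns
#' are (lon, lat) degrees for geographic CRSs and (x, y) meters otherwise.
#'
#' @param pts numeric vector `c(x, y)` or an n x 2 matrix
#' @param from,to `crs_id` objects (see [crs_wgs84()])
#' @return an n x 2 matrix of transformed coordinates
#' @export
#' @examples
#' transform_point(c(10, 0), crs_wgs84(), crs_sinusoidal())
transform_point <- function(pts, from, to) {
  from <- as_crs(from); to <- as_crs(to)
  m <- if (is.matrix(pts)) pts else matrix(pts, ncol = 2)
  ll <- proj_inverse(m[, 1], m[, 2], from)
  if (any(!is.finite(ll$lon)) || any(abs(ll$lat) > 90 + 1e-9))
    et_domain_error("point outside projection domain")
  out <- proj_forward(ll$lon, ll$lat, to)
  cbind(out$x, out$y, deparse.level = 0)
}

#' Ellipsoidal geodesic distance
#'
#' Distance in meters between two points given as (lon, lat) degrees.
#' The default is the exact geodesic on the WGS84 ellipsoid; a spherical
#' haversine alternative (radius 6371 km) is available.
#'
#' @param p1,p2 length-2 vectors or n x 2 matrices of (lon, lat) degrees
#' @param method `"ellipsoidal"` (WGS84 geodesic, default) or `"haversine"`
#' @return distance(s) in meters
#' @export
geodesic_distance <- function(p1, p2, method = c("ellipsoidal", "haversine")) {
  method <- match.arg(method)
  if (method == "ellipsoidal") geosphere::distGeo(p1, p2)
  else geosphere::distHaversine(p1, p2, r = 6371000)
}

#' Initial bearing of the geodesic from p1 to p2
#'
#' Azimuth at `p1` toward `p2`, degrees clockwise from true north in
#' `[0, 360)`. Uses the WGS84 ellipsoidal geodesic by default; the
#' spherical great-circle azimuth is available for comparison (the two can
#' differ by a few tenths of a degree away from the cardinal directions).
#'
#' @inheritParams geodesic_distance
#' @param method `"ellipsoidal"` or `"spherical"`
#' @return bearing(s) in degrees, `[0, 360)`
#' @export
initial_bearing <- function(p1, p2, method = c("ellipsoidal", "spherical")) {
  method <- match.arg(method)
  m1 <- if (is.matrix(p1)) p1 else matrix(p1, ncol = 2)
  m2 <- if (is.matrix(p2)) p2 else matrix(p2, ncol = 2)
  same <- abs(m1[, 1] - m2[, 1]) < 1e-12 & abs(m1[, 2] - m2[, 2]) < 1e-12
  if (any(same))
    et_validation_error("bearing undefined for coincident points")
  b <- if (method == "ellipsoidal") {
    geosphere::bearing(m1, m2)
  } else {
    l1 <- deg2rad(m1[, 1]); f1 <- deg2rad(m1[, 2])
    l2 <- deg2rad(m2[, 1]); f2 <- deg2rad(m2[, 2])
    dl <- l2 - l1
    rad2deg(atan2(sin(dl) * cos(f2),
                  cos(f1) * sin(f2) - sin(f1) * cos(f2) * cos(dl)))
  }
  b %% 360
}
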