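# Synthetic gridded fields and tracks with closed-form oracles.
#
# Every non-categorical field form carries an analytic evaluator, so the
# full annotation pipeline can be checked against exact expected values
# without downloading any environmental data. Fields emulate the shapes
# of real sources: regular lon/lat grids at several resolutions, projected
# grids, multi-timestamp scenes, categorical mosaics, u/v wind fields, and
# DEMs with analytic surfaces. All fixtures are deterministic functions of
# (spec, seed).

#' Specification of a synthetic gridded field
#'
#' @param form one of `"affine"` (value = `a + b lon + c lat + d hours`),
#'   `"sinusoidal"` (separable sine field with optional linear drift in
#'   time), `"categorical"` (seeded block mosaic of integer codes),
#'   `"wind_uniform"` (constant u/v component pair),
#'   `"wind_bands"` (easterly band south of `split_lat`, westerly north —
#'   the fixture used to reproduce the qualitative outbound-headwind /
#'   return-tailwind signature of a clockwise foraging loop),
#'   `"dem_plane"` (planar elevation surface), or `"dem_hill"` (Gaussian
#'   hill)
#' @param params named list of form parameters (defaults filled per form)
#' @param lon,lat axis ranges `c(min, max)` in degrees (or native meters
#'   for projected grids)
#' @param spacing grid spacing, degrees (or meters)
#' @param timestamps POSIXct / epoch-second scene times (`NULL` for a
#'   static field)
#' @param crs native CRS (default WGS84 lon/lat)
#' @param tile_shape spatial tile block sizes (x, y)
#' @param mask_fraction fraction of nodes masked missing (seeded)
#' @param seed integer seed for the stochastic pieces (mosaic, mask)
#' @param id variable id prefix
#' @return a `field_spec` list
#' @export
field_spec <- function(form = c("affine", "sinusoidal", "categorical",
                                "wind_uniform", "wind_bands",
                                "dem_plane", "dem_hill"),
                       params = list(), lon = c(-10, 10), lat = c(-10, 10),
                       spacing = 1, timestamps = NULL, crs = crs_wgs84(),
                       tile_shape = NULL, mask_fraction = 0, seed = 1L,
                       id = form) {
  form <- match.arg(form)
  defaults <- switch(form,
    affine = list(a = 2, b = 0.5, c = 0.25, d = 1),   # d per hour
    sinusoidal = list(amplitude = 5, wavelength_x = 8, wavelength_y = 8,
                      offset = 10, drift = 0),        # drift per hour
    categorical = list(block = 3, codes = c(11, 14, 20)),
    wind_uniform = list(u0 = 5, v0 = 0),
    wind_bands = list(amp = 8, split_lat = 0),
    dem_plane = list(z0 = 100, sx = 0.05, sy = 0),    # per meter
    dem_hill = list(z0 = 0, amplitude = 500, sigma = 5000)
  )
  params <- modifyList(defaults, params)
  ts <- if (is.null(timestamps)) NULL else as.numeric(timestamps)
  structure(list(form = form, params = params, lon = lon, lat = lat,
                 spacing = spacing, timestamps = ts, crs = as_crs(crs),
                 tile_shape = tile_shape, mask_fraction = mask_fraction,
                 seed = as.integer(seed), id = id),
            class = "field_spec")
}

field_oracle <- function(spec) {
  p <- spec$params
  t0 <- if (!is.null(spec$timestamps)) spec$timestamps[1] else 0
  hours <- function(t) (t - t0) / 3600
  switch(spec$form,
    affine = function(x, y, t = t0)
      p$a + p$b * x + p$c * y + p$d * hours(t),
    sinusoidal = function(x, y, t = t0)
      p$offset + p$amplitude * sin(2 * pi * x / p$wavelength_x) *
        sin(2 * pi * y / p$wavelength_y) + p$drift * hours(t),
    wind_uniform = function(x, y, t = t0)
      list(u = p$u0 + 0 * x, v = p$v0 + 0 * x),
    wind_bands = function(x, y, t = t0)
      list(u = ifelse(y < p$split_lat, -p$amp, p$amp), v = 0 * x),
    dem_plane = function(x, y, t = t0) {
      m <- meters_per_unit(spec)
      p$z0 + p$sx * x * m$x + p$sy * y * m$y
    },
    dem_hill = function(x, y, t = t0) {
      m <- meters_per_unit(spec)
      p$z0 + p$amplitude * exp(-((x * m$x)^2 + (y * m$y)^2) / (2 * p$sigma^2))
    },
    NULL  # categorical: no closed form, nodes are the oracle
  )
}

# Meters per native unit for DEM forms (so slopes are in m/m even on
# geographic grids; 111.32 km/degree at the equator).
meters_per_unit <- function(spec) {
  if (is_lonlat(spec$crs)) list(x = 111320, y = 111320)
  else list(x = 1, y = 1)
}

#' Generate a synthetic gridded field with its closed-form oracle
#'
#' Builds one or two (for wind forms) `grid_variable`s whose node values
#' equal the form's closed form evaluated at the node coordinates, plus an
#' oracle callable at arbitrary `(x, y, t)`. Categorical mosaics have no
#' analytic oracle; their node values themselves serve as the reference.
#'
#' @param spec a [field_spec()]
#' @return list with `vars` (named list of `grid_variable`s), `oracle`
#'   (function of `x, y, t`, or `NULL` for categorical), and `spec`
#' @export
make_field <- function(spec) {
  stopifnot(inherits(spec, "field_spec"))
  xs <- seq(spec$lon[1], spec$lon[2], by = spec$spacing)
  ys <- seq(spec$lat[1], spec$lat[2], by = spec$spacing)
  axes <- list(grid_axis("x", xs), grid_axis("y", ys))
  ts <- spec$timestamps
  if (!is.null(ts)) axes <- c(axes, list(grid_axis("t", ts)))
  nt <- if (is.null(ts)) 1L else length(ts)
  oracle <- field_oracle(spec)
  grid <- expand.grid(x = xs, y = ys)

  node_array <- function(fun) {
    vals <- vapply(seq_len(nt), function(k) {
      tk <- if (is.null(ts)) 0 else ts[k]
      fun(grid$x, grid$y, tk)
    }, numeric(nrow(grid)))
    dims <- c(length(xs), length(ys), if (!is.null(ts)) nt)
    array(vals, dim = dims)
  }

  mask <- function(values) {
    if (spec$mask_fraction <= 0) return(values)
    set.seed(spec$seed)
    drop <- runif(length(values)) < spec$mask_fraction
    values[drop] <- NA_real_
    values
  }

  build <- function(id, values, kind = "continuous") {
    build_grid_variable(id, axes, mask(values), crs = spec$crs, kind = kind,
                        tile_shape = spec$tile_shape)
  }

  vars <- if (spec$form %in% c("wind_uniform", "wind_bands")) {
    uv_u <- node_array(function(x, y, t) oracle(x, y, t)$u)
    uv_v <- node_array(function(x, y, t) oracle(x, y, t)$v)
    setNames(list(build(paste0(spec$id, ".u"), uv_u),
                  build(paste0(spec$id, ".v"), uv_v)),
             paste0(spec$id, c(".u", ".v")))
  } else if (spec$form == "categorical") {
    set.seed(spec$seed)
    bx <- ceiling(length(xs) / spec$params$block)
    by <- ceiling(length(ys) / spec$params$block)
    codes_by_block <- matrix(sample(spec$params$codes, bx * by, replace = TRUE),
                             nrow = bx)
    vals <- node_array(function(x, y, t) {
      i <- pmin(bx, (match(x, xs) - 1) %/% spec$params$block + 1)
      j <- pmin(by, (match(y, ys) - 1) %/% spec$params$block + 1)
      codes_by_block[cbind(i, j)]
    })
    setNames(list(build(spec$id, vals, kind = "categorical")), spec$id)
  } else {
    setNames(list(build(spec$id, node_array(oracle))), spec$id)
  }

  list(vars = vars, oracle = oracle, spec = spec)
}

#' Specification of a synthetic track
#'
#' @param waypoints n x 2 matrix of (lon, lat) waypoints in degrees
#' @param speed ground speed along the path (m/s)
#' @param interval fix interval in seconds (default 5400 s = 90 min, a
#'   typical seabird GPS duty cycle)
#' @param start_time first fix time (POSIXct or epoch seconds)
#' @param individual individual identifier
#' @param loop close the path back to the first waypoint
#' @return a `track_spec` list
#' @export
track_spec <- function(waypoints, speed = 10, interval = 5400,
                       start_time = as.POSIXct("2008-06-01 00:00:00", tz = "UTC"),
                       individual = "bird01", loop = FALSE) {
  waypoints <- matrix(as.numeric(waypoints), ncol = 2)
  if (nrow(waypoints) < 2) et_validation_error("need at least two waypoints")
  if (speed <= 0 || interval <= 0)
    et_validation_error("speed and interval must be positive")
  if (loop) waypoints <- rbind(waypoints, waypoints[1, ])
  structure(list(waypoints = waypoints, speed = speed, interval = interval,
                 start_time = as.numeric(start_time),
                 individual = individual),
            class = "track_spec")
}

#' Generate a synthetic track along geodesic segments
#'
#' Emits fixes at the spec's cadence along the geodesic path through the
#' waypoints at constant ground speed, clamping the final fix to the last
#' waypoint. Deterministic (no randomness beyond the spec).
#'
#' @param spec a [track_spec()]
#' @return a track data frame with columns `individual`, `timestamp`
#'   (POSIXct UTC), `lon`, `lat`
#' @export
make_track <- function(spec) {
  stopifnot(inherits(spec, "track_spec"))
  wp <- spec$waypoints
  leg_len <- geosphere::distGeo(wp[-nrow(wp), , drop = FALSE],
                                wp[-1, , drop = FALSE])
  cum <- c(0, cumsum(leg_len))
  total <- cum[length(cum)]
  step <- spec$speed * spec$interval
  dists <- seq(0, total, by = step)
  if (dists[length(dists)] < total) dists <- c(dists, total)

  pos <- t(vapply(dists, function(s) {
    leg <- findInterval(s, cum, rightmost.closed = TRUE)
    leg <- min(leg, nrow(wp) - 1)
    offset <- s - cum[leg]
    if (offset <= 0) return(wp[leg, ])
    if (offset >= leg_len[leg]) return(wp[leg + 1, ])
    azi <- geosphere::bearing(wp[leg, ], wp[leg + 1, ])
    as.numeric(geosphere::destPoint(wp[leg, ], azi, offset))
  }, numeric(2)))

  data.frame(
    individual = spec$individual,
    timestamp = as.POSIXct(spec$start_time + spec$interval * (seq_along(dists) - 1),
                           origin = "1970-01-01", tz = "UTC"),
    lon = pos[, 1], lat = pos[, 2]
  )
}
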