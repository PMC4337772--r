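# Derived flight and terrain covariates.
#
# Wind is given by its eastward (u) and northward (v) components in m/s.
# Directions are azimuths in degrees clockwise from true north; wind
# direction is reported as the azimuth TOWARD which the air moves, the
# convention consistent with the tailwind/crosswind decomposition
# (meteorological reports usually give the FROM direction; see
# wind_dir_from_to()). Terrain operators use the Horn 3x3 kernel on DEM
# windows; rugosity is the population standard deviation of the window.

GRAVITY <- 9.80665

#' Wind speed and direction from u/v components
#'
#' @param u eastward wind component (m/s)
#' @param v northward wind component (m/s)
#' @return data frame with `speed` (m/s) and `direction` (degrees from
#'   north, the azimuth toward which air moves; `NA` for calm air)
#' @export
#' @examples
#' wind_speed_direction(3, 4)  # speed 5, direction ~36.87
wind_speed_direction <- function(u, v) {
  if (any(!is.finite(u)) || any(!is.finite(v)))
    et_validation_error("wind components must be finite")
  speed <- sqrt(u^2 + v^2)
  direction <- ifelse(speed == 0, NA_real_,
                      (atan2(u, v) * 180 / pi) %% 360)
  data.frame(speed = speed, direction = direction)
}

#' Convert wind direction between "from" and "to" conventions
#'
#' @param direction azimuth in degrees
#' @return the opposite azimuth (±180°, wrapped to `[0, 360)`)
#' @export
wind_dir_from_to <- function(direction) (direction + 180) %% 360

#' Tail-wind support and crosswind relative to a flight heading
#'
#' Decomposes the horizontal wind vector into the component along the
#' animal's travel direction (tailwind; positive = flow assistance,
#' negative = head wind) and perpendicular to it (crosswind). With
#' heading angle theta, `tailwind = u sin(theta) + v cos(theta)` and
#' `crosswind = u cos(theta) - v sin(theta)`; positive crosswind means
#' wind arriving from the animal's left (set `sign_flip = TRUE` for the
#' opposite convention). The decomposition preserves kinetic energy:
#' `tailwind^2 + crosswind^2 = u^2 + v^2`.
#'
#' @inheritParams wind_speed_direction
#' @param heading flight heading, degrees clockwise from north
#' @param sign_flip flip the crosswind sign convention
#' @return data frame with `tailwind` and `crosswind` (m/s); `NA` rows
#'   where the heading is undefined
#' @export
#' @examples
#' wind_support(5, 0, 90)   # tailwind 5, crosswind 0
#' wind_support(3, 4, 90)   # tailwind 3, crosswind -4
wind_support <- function(u, v, heading, sign_flip = FALSE) {
  if (any(!is.finite(u)) || any(!is.finite(v)))
    et_validation_error("wind components must be finite")
  th <- heading * pi / 180
  tailwind <- u * sin(th) + v * cos(th)
  crosswind <- u * cos(th) - v * sin(th)
  if (sign_flip) crosswind <- -crosswind
  bad <- !is.finite(heading)
  tailwind[bad] <- NA_real_
  crosswind[bad] <- NA_real_
  data.frame(tailwind = tailwind, crosswind = crosswind)
}

#' Slope and aspect from a 3x3 DEM window (Horn kernel)
#'
#' The window is oriented with row 1 to the north and column 1 to the
#' west:
#' ```
#'   a b c
#'   d e f
#'   g h i
#' ```
#' The Horn finite differences are
#' `dz/dx = ((c + 2f + i) - (a + 2d + g)) / (8 dx)` (eastward) and
#' `dz/dy = ((a + 2b + c) - (g + 2h + i)) / (8 dy)` (northward);
#' `slope = atan(sqrt((dz/dx)^2 + (dz/dy)^2))` and the aspect is the
#' downslope azimuth `atan2(-dz/dx, -dz/dy)` in degrees from north. The
#' kernel recovers planar surfaces exactly. A flat window has slope 0 and
#' undefined (`NA`) aspect.
#'
#' @param window 3x3 numeric matrix of elevations (m), row 1 north
#' @param cell_size_x,cell_size_y grid cell size in meters
#' @return list with `slope` (radians), `slope_deg`, and `aspect`
#'   (degrees from north, `NA` when flat); all `NA` if any cell is missing
#' @export
slope_aspect <- function(window, cell_size_x, cell_size_y = cell_size_x) {
  if (!is.matrix(window) || any(dim(window) != 3))
    et_validation_error("slope_aspect needs a 3x3 elevation window")
  if (any(!is.finite(window)))
    return(list(slope = NA_real_, slope_deg = NA_real_, aspect = NA_real_))
  a <- window[1, 1]; b <- window[1, 2]; c <- window[1, 3]
  d <- window[2, 1];                    f <- window[2, 3]
  g <- window[3, 1]; h <- window[3, 2]; i <- window[3, 3]
  dzdx <- ((c + 2 * f + i) - (a + 2 * d + g)) / (8 * cell_size_x)
  dzdy <- ((a + 2 * b + c) - (g + 2 * h + i)) / (8 * cell_size_y)
  slope <- atan(sqrt(dzdx^2 + dzdy^2))
  aspect <- if (slope == 0) NA_real_ else
    (atan2(-dzdx, -dzdy) * 180 / pi) %% 360
  list(slope = slope, slope_deg = slope * 180 / pi, aspect = aspect)
}

#' Terrain rugosity of a DEM window
#'
#' Population standard deviation of the window's elevations, in elevation
#' units. Missing cells are ignored; at least 4 finite cells are required.
#'
#' @param window numeric matrix (k x k) of elevations
#' @return rugosity in elevation units, `NA` if fewer than 4 finite cells
#' @export
rugosity <- function(window) {
  z <- window[is.finite(window)]
  if (length(z) < 4) return(NA_real_)
  sqrt(mean((z - mean(z))^2))
}

#' Orographic uplift from wind and terrain
#'
#' Vertical air velocity induced by horizontal wind meeting sloped
#' terrain: `w_oro = |W| tan(slope) cos(dir_to - upslope)` where `|W|` is
#' the horizontal wind speed, `dir_to` the azimuth toward which the wind
#' blows, and `upslope = aspect + 180` the uphill azimuth. Positive values
#' are rising air on windward slopes; downslope (lee) flow gives negative
#' values unless `clamp = TRUE`.
#'
#' @inheritParams wind_speed_direction
#' @param slope terrain slope in radians
#' @param aspect downslope azimuth in degrees from north
#' @param clamp truncate negative (lee-side) values at 0
#' @return uplift velocity (m/s); 0 on flat cells
#' @export
#' @examples
#' orographic_uplift(10, 0, slope = 10 * pi / 180, aspect = 180) # upslope flow
orographic_uplift <- function(u, v, slope, aspect, clamp = FALSE) {
  if (!is.finite(slope) || slope == 0 || !is.finite(aspect)) return(0)
  w <- wind_speed_direction(u, v)
  if (w$speed == 0) return(0)
  upslope <- (aspect + 180) %% 360
  out <- w$speed * tan(slope) *
    cos((w$direction - upslope) * pi / 180)
  if (clamp) max(out, 0) else out
}

#' Thermal uplift (convective velocity scale)
#'
#' The boundary-layer convective velocity scale
#' `w* = ((g z_i / T) * H / (rho c_p))^(1/3)` for positive surface
#' sensible heat flux `H`, and 0 otherwise.
#'
#' @param H surface sensible heat flux (W/m^2)
#' @param z_i boundary-layer height (m), > 0
#' @param T_surf surface air temperature; Kelvin, or Celsius if < 200
#'   (auto-converted)
#' @param rho air density (kg/m^3)
#' @param c_p specific heat of air (J/kg/K)
#' @return `w*` in m/s
#' @export
#' @examples
#' thermal_uplift(300, 1000, 288)  # ~2.03 m/s
thermal_uplift <- function(H, z_i, T_surf, rho = 1.225, c_p = 1005) {
  if (!is.finite(z_i) || z_i <= 0)
    et_validation_error("boundary-layer height must be positive")
  if (!is.finite(T_surf))
    et_validation_error("temperature must be finite")
  if (T_surf < 200) T_surf <- T_surf + 273.15
  if (T_surf <= 0) et_validation_error("temperature must be positive")
  if (!is.finite(H) || H <= 0) return(0)
  ((GRAVITY * z_i / T_surf) * H / (rho * c_p))^(1 / 3)
}
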