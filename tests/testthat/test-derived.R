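test_that("wind speed and direction from u/v components", {
  w <- wind_speed_direction(3, 4)
  expect_equal(w$speed, 5)
  expect_equal(w$direction, atan2(3, 4) * 180 / pi)  # ~36.87, toward NE
  expect_equal(wind_speed_direction(5, 0)$direction, 90)  # blowing toward east
  calm <- wind_speed_direction(0, 0)
  expect_equal(calm$speed, 0)
  expect_true(is.na(calm$direction))
  expect_equal(wind_dir_from_to(36.87), 216.87)
  expect_error(wind_speed_direction(Inf, 0),
               class = "envtrack_validation_error")
})

test_that("tail-wind / crosswind decomposition: axis cases and energy identity", {
  expect_equal(wind_support(5, 0, 90), data.frame(tailwind = 5, crosswind = 0))
  expect_equal(wind_support(5, 0, 270)$tailwind, -5)  # head wind
  ws <- wind_support(3, 4, 90)
  expect_equal(ws$tailwind, 3)
  expect_equal(ws$crosswind, -4)
  expect_equal(ws$tailwind^2 + ws$crosswind^2, 25)
  # positive crosswind = wind from the animal's left; flag flips it
  expect_equal(wind_support(0, -4, 90)$crosswind, 4)
  expect_equal(wind_support(0, -4, 90, sign_flip = TRUE)$crosswind, -4)

  set.seed(41)
  u <- rnorm(2000, sd = 8); v <- rnorm(2000, sd = 8)
  h <- runif(2000, 0, 360)
  ws <- wind_support(u, v, h)
  expect_lt(max(abs(ws$tailwind^2 + ws$crosswind^2 - (u^2 + v^2))), 1e-9)
})

test_that("wind_support is equivariant under joint rotation", {
  set.seed(43)
  for (i in 1:50) {
    u <- rnorm(1, sd = 6); v <- rnorm(1, sd = 6)
    h <- runif(1, 0, 360)
    rot <- runif(1, 0, 360)
    a <- rot * pi / 180
    # rotate the wind vector clockwise (azimuth sense) by rot
    u2 <- u * cos(a) + v * sin(a)
    v2 <- v * cos(a) - u * sin(a)
    base <- wind_support(u, v, h)
    moved <- wind_support(u2, v2, (h + rot) %% 360)
    expect_equal(moved$tailwind, base$tailwind, tolerance = 1e-9)
    expect_equal(moved$crosswind, base$crosswind, tolerance = 1e-9)
  }
})

test_that("Horn kernel recovers analytic planes exactly", {
  plane_window <- function(sx, sy, d) {
    # [r, c] = sx * x_east + sy * y_north with row 1 = north, col 1 = west
    outer(d * (1:-1) * sy, d * (-1:1) * sx, `+`)
  }
  # z = 0.1 x (east), 30 m cells: slope atan(0.1), downslope faces west
  w <- plane_window(0.1, 0, 30)
  sa <- slope_aspect(w, 30)
  expect_equal(sa$slope, atan(0.1))
  expect_equal(sa$slope_deg, 5.710593, tolerance = 1e-6)
  expect_equal(sa$aspect, 270)
  # z = 0.1 y (north): downslope faces south
  expect_equal(slope_aspect(plane_window(0, 0.1, 30), 30)$aspect, 180)
  # flat: zero slope, undefined aspect
  flat <- slope_aspect(matrix(7, 3, 3), 30)
  expect_equal(flat$slope, 0)
  expect_true(is.na(flat$aspect))
  # random planes, exact recovery
  set.seed(47)
  for (i in 1:100) {
    sx <- rnorm(1, sd = 0.2); sy <- rnorm(1, sd = 0.2)
    d <- runif(1, 10, 90)
    sa <- slope_aspect(plane_window(sx, sy, d) + rnorm(1, sd = 100), d)
    expect_equal(sa$slope, atan(sqrt(sx^2 + sy^2)), tolerance = 1e-12)
    if (sx^2 + sy^2 > 0) {
      want <- (atan2(-sx, -sy) * 180 / pi) %% 360
      expect_equal(sa$aspect, want, tolerance = 1e-9)
    }
  }
  expect_true(is.na(slope_aspect(matrix(c(1:8, NA), 3, 3), 30)$slope))
})

test_that("rugosity is the population SD of the window", {
  expect_equal(rugosity(matrix(5, 3, 3)), 0)
  w <- matrix(c(0, 0, 0, 0, 10, 0, 0, 0, 0), 3, 3)
  expect_equal(rugosity(w), sqrt((8 * (10 / 9)^2 + (10 - 10 / 9)^2) / 9))
  expect_equal(rugosity(w), 3.142697, tolerance = 1e-6)
  expect_equal(rugosity(w * -2.5), 2.5 * rugosity(w))  # |c| homogeneity
  expect_true(is.na(rugosity(matrix(NA_real_, 3, 3))))
})

test_that("orographic uplift: analytic cases and wind-reversal antisymmetry", {
  slope10 <- 10 * pi / 180
  # wind 10 m/s due north onto a north-facing... aspect 180 means
  # downslope south, upslope north: northward wind blows directly upslope
  expect_equal(orographic_uplift(0, 10, slope10, aspect = 180),
               10 * tan(slope10))
  expect_equal(orographic_uplift(0, 10, slope10, aspect = 180),
               1.763270, tolerance = 1e-6)
  # along-slope wind: orthogonal, no uplift
  expect_equal(orographic_uplift(10, 0, slope10, aspect = 180), 0,
               tolerance = 1e-12)
  expect_equal(orographic_uplift(0, 0, slope10, aspect = 180), 0)
  expect_equal(orographic_uplift(3, 4, 0, aspect = NA), 0)
  # reversing the wind flips the sign
  set.seed(53)
  for (i in 1:30) {
    u <- rnorm(1, sd = 5); v <- rnorm(1, sd = 5)
    sl <- runif(1, 0.01, 0.5); asp <- runif(1, 0, 360)
    expect_equal(orographic_uplift(-u, -v, sl, asp),
                 -orographic_uplift(u, v, sl, asp), tolerance = 1e-9)
  }
  # lee-side clamp
  expect_equal(orographic_uplift(0, -10, slope10, aspect = 180, clamp = TRUE), 0)
})

test_that("thermal uplift follows the convective velocity scale", {
  expect_equal(thermal_uplift(0, 1000, 288), 0)
  expect_equal(thermal_uplift(-50, 1000, 288), 0)
  want <- ((9.80665 * 1000 / 288) * 300 / (1.225 * 1005))^(1 / 3)
  expect_equal(thermal_uplift(300, 1000, 288), want)
  expect_equal(want, 2.02, tolerance = 0.005)
  # H^(1/3) homogeneity
  expect_equal(thermal_uplift(600, 1000, 288),
               2^(1 / 3) * thermal_uplift(300, 1000, 288))
  # Celsius auto-conversion
  expect_equal(thermal_uplift(300, 1000, 14.85),
               thermal_uplift(300, 1000, 288))
  expect_error(thermal_uplift(300, -5, 288),
               class = "envtrack_validation_error")
})
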