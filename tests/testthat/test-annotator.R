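mk_track <- function(lon, lat, t, individual = "b1") {
  data.frame(individual = individual,
             timestamp = as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
             lon = lon, lat = lat)
}

test_that("heading and speed from forward differences", {
  # two equator fixes 0.1 degrees apart eastward, 90 min apart
  tr <- compute_heading_speed(mk_track(c(0, 0.1), c(0, 0),
                                       EPOCH_2008 + c(0, 5400)))
  d <- geosphere::distGeo(c(0, 0), c(0.1, 0))
  expect_equal(tr$ground_speed[1], d / 5400)
  expect_equal(tr$ground_speed[1], 2.0615, tolerance = 1e-4)
  expect_equal(tr$heading[1], 90)
  # last fix inherits the previous heading and speed
  expect_equal(tr$heading[2], tr$heading[1])
  expect_equal(tr$ground_speed[2], tr$ground_speed[1])

  # stationary fixes: speed 0, heading undefined
  st <- compute_heading_speed(mk_track(c(5, 5), c(5, 5),
                                       EPOCH_2008 + c(0, 5400)))
  expect_equal(st$ground_speed[1], 0)
  expect_true(all(is.na(st$heading)))

  # reversing a 2-point track flips the heading by 180
  fwd <- compute_heading_speed(mk_track(c(10, 10.4), c(40, 40.3),
                                        EPOCH_2008 + c(0, 5400)))
  rev <- compute_heading_speed(mk_track(c(10.4, 10), c(40.3, 40),
                                        EPOCH_2008 + c(0, 5400)))
  expect_lt(abs(((rev$heading[1] - fwd$heading[1]) %% 360) - 180), 0.5)

  expect_error(
    compute_heading_speed(mk_track(c(0, 1), c(0, 0), EPOCH_2008 + c(0, 0))),
    class = "envtrack_validation_error")
})

test_that("track annotation matches the affine closed form and preserves rows", {
  ts <- EPOCH_2008 + 21600 * 0:3
  f <- make_field(field_spec("affine", lon = c(-95, -75), lat = c(-15, 5),
                             timestamps = ts))
  set.seed(61)
  n <- 100
  track <- mk_track(runif(n, -94, -76), runif(n, -14, 4),
                    sort(EPOCH_2008 + runif(n, 0, 64800)),
                    individual = rep(c("b1", "b2"), length.out = n))
  req <- list(list(id = "affine", method = interp_method()))
  out <- annotate_track(track, req, f$vars)

  col <- "affine.bilinear-idw"
  expect_true(col %in% names(out))
  expect_identical(out[names(track)], track)  # inputs untouched, order kept
  want <- f$oracle(track$lon, track$lat, as.numeric(track$timestamp))
  expect_equal(out[[col]], want, tolerance = 1e-9)

  # permuted input order (per-individual order preserved) annotates each
  # point identically, and a re-run is bit-identical
  tr2 <- track[order(track$individual), ]
  out2 <- annotate_track(tr2, req, f$vars)
  expect_identical(out2[[col]],
                   out[[col]][match(paste(tr2$lon, tr2$lat),
                                    paste(track$lon, track$lat))])
  expect_identical(annotate_track(track, req, f$vars)[[col]], out[[col]])
})

test_that("empty variable lists, unknown variables and illegal methods", {
  f <- make_field(field_spec("affine", timestamps = EPOCH_2008))
  track <- mk_track(c(1, 2), c(1, 2), EPOCH_2008 + c(0, 5400))
  out <- annotate_track(track, list(), f$vars)
  expect_identical(names(out), names(track))

  expect_error(annotate_track(track, list(list(id = "nope")), f$vars),
               class = "envtrack_request_error")

  cat_f <- make_field(field_spec("categorical", timestamps = EPOCH_2008,
                                 id = "landuse"))
  expect_error(
    annotate_track(track,
                   list(list(id = "landuse",
                             method = interp_method("bilinear",
                                                    "nearest_neighbour"))),
                   cat_f$vars),
    "nearest neighbour")
})

test_that("out-of-domain points give missing cells and the run continues", {
  f <- make_field(field_spec("affine", lon = c(0, 10), lat = c(0, 10),
                             timestamps = EPOCH_2008))
  track <- mk_track(c(5, 50, 6), c(5, 50, 6), EPOCH_2008 + c(0, 10, 20))
  out <- suppressWarnings(
    annotate_track(track, list(list(id = "affine")), f$vars))
  col <- "affine.bilinear-idw"
  expect_true(is.na(out[[col]][2]))
  expect_false(anyNA(out[[col]][c(1, 3)]))
  log <- attr(out, "log")
  expect_equal(log$missing_annotations, 1L)
  expect_true(any(grepl("missing", log$warnings)))
})

test_that("column names encode dataset.variable and methods without collisions", {
  ts <- EPOCH_2008 + c(0, 21600)
  f <- make_field(field_spec("affine", id = "ncep.uwind", timestamps = ts))
  track <- mk_track(1, 1, EPOCH_2008 + 100)
  req <- list(
    list(id = "ncep.uwind", method = interp_method("bilinear",
                                                   "inverse_distance_weighted")),
    list(id = "ncep.uwind", method = interp_method("nearest_neighbour",
                                                   "nearest_neighbour")))
  out <- annotate_track(track, req, f$vars)
  added <- setdiff(names(out), names(track))
  expect_identical(added, c("ncep.uwind.bilinear-idw", "ncep.uwind.nn-nn"))
  expect_equal(anyDuplicated(names(out)), 0L)
})

test_that("segmentation labels transit, coastal foraging and other", {
  tr <- data.frame(individual = "b1",
                   timestamp = as.POSIXct(EPOCH_2008 + 5400 * (0:3),
                                          origin = "1970-01-01", tz = "UTC"),
                   lon = c(-85, -80, -85, -95), lat = c(-2, -5, -2, -2),
                   ground_speed = c(8, 1, 3, 8), heading = 90)
  seg <- segment_track(tr)
  expect_equal(as.character(seg$segment),
               c("transit", "coastal_foraging", "other", "other"))
  # the shared boundary belongs to the coastal band only
  b <- segment_track(transform(tr, lon = -82.5))
  expect_equal(as.character(b$segment), rep("coastal_foraging", 4))
})

test_that("area annotation at native resolution with NN is bit-exact", {
  ts <- EPOCH_2008 + c(0, 21600)
  set.seed(67)
  vals <- array(rnorm(11 * 11 * 2), dim = c(11, 11, 2))
  v <- simple_var(values = vals, times = ts, id = "field")
  req <- structure(list(
    mode = "area",
    variables = list(list(id = "field",
                          method = interp_method("nearest_neighbour",
                                                 "nearest_neighbour"))),
    area = list(xmin = -0.5, xmax = 10.5, ymin = -0.5, ymax = 10.5,
                nx = 11L, ny = 11L, crs = "wgs84_lonlat",
                timestamps = ts[1])),
    class = "annotation_request")
  bundle <- annotate_area(req, list(field = v))
  expect_length(bundle, 1)
  expect_identical(bundle[[1]], vals[, , 1])
})

test_that("upsampled bilinear area annotation matches the affine closed form", {
  ts <- EPOCH_2008 + c(0, 21600)
  f <- make_field(field_spec("affine", lon = c(0, 10), lat = c(0, 10),
                             timestamps = ts))
  req <- structure(list(
    mode = "area",
    variables = list(list(id = "affine", method = interp_method())),
    area = list(xmin = 0, xmax = 10, ymin = 0, ymax = 10,
                nx = 20L, ny = 20L, crs = "wgs84_lonlat",
                timestamps = ts)),
    class = "annotation_request")
  bundle <- annotate_area(req, f$vars)
  expect_length(bundle, 2)  # one raster per timestamp, in request order
  px <- 0 + (1:20 - 0.5) * 0.5
  for (k in 1:2) {
    want <- outer(px, px, function(x, y) f$oracle(x, y, ts[k]))
    expect_equal(bundle[[k]], want, tolerance = 1e-12)
  }
  expect_error(
    annotate_area(structure(list(mode = "area", variables = list(),
                                 area = list(xmin = 0, xmax = 0, ymin = 0,
                                             ymax = 1, nx = 1, ny = 1)),
                            class = "annotation_request"),
                  f$vars),
    class = "envtrack_request_error")
})
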