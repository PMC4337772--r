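# The neighborhood used throughout: 1-degree cell of a small grid.
nb_at <- function(fx, fy, v = simple_var()) locate_neighborhood(v, fx, fy)

test_that("bilinear expansion matches hand-computed values", {
  m <- interp_method("bilinear", "nearest_neighbour")
  expect_equal(interp_spatial(nb_at(0.5, 0.5), c(0, 1, 2, 3), m), 1.5)
  # (0.75*0.25)*0 + (0.25*0.25)*1 + (0.75*0.75)*2 + (0.25*0.75)*3 = 1.75
  expect_equal(interp_spatial(nb_at(0.25, 0.75), c(0, 1, 2, 3), m), 1.75)
})

test_that("constant fields are reproduced by every spatial method", {
  for (meth in all_method_combos()) {
    expect_equal(interp_spatial(nb_at(0.3, 0.8), rep(4.2, 4), meth), 4.2)
  }
})

test_that("temporal interpolation: midpoint, asymmetric weights, NN tie", {
  idw <- interp_method("bilinear", "inverse_distance_weighted")
  nn <- interp_method("bilinear", "nearest_neighbour")
  t0 <- 0; t1 <- 21600
  expect_equal(interp_temporal(10, 20, t0, t1, 10800, idw), 15)
  # t = 02:00 -> weights 1/7200, 1/14400: (10/2 + 20/4) / (3/4)
  expect_equal(interp_temporal(10, 20, t0, t1, 7200, idw), 40 / 3)
  expect_equal(interp_temporal(10, 20, t0, t1, 7200, nn), 10)
  # tie at the exact midpoint resolves to the earlier scene
  expect_equal(interp_temporal(10, 20, t0, t1, 10800, nn), 10)
  # a scene timestamp returns that scene's value exactly
  expect_identical(interp_temporal(10, 20, t0, t1, t1, idw), 20)
  expect_error(interp_temporal(10, 20, t0, t1, -5, idw),
               class = "envtrack_validation_error")
})

test_that("affine fields are annotated exactly by bilinear + temporal IDW", {
  f <- make_field(field_spec("affine", timestamps = EPOCH_2008 + 21600 * 0:3))
  v <- f$vars$affine
  # the spec'd plug-in example: 2 + 0.5*0.5 + 0.25*0.5 + 3
  expect_equal(
    as.numeric(annotate_point(v, 0.5, 0.5, EPOCH_2008 + 10800)),
    5.375, tolerance = 1e-12)
  set.seed(23)
  pts <- random_points_in(v, 200)
  m <- interp_method("bilinear", "inverse_distance_weighted")
  for (i in seq_len(nrow(pts))) {
    got <- as.numeric(annotate_point(v, pts$x[i], pts$y[i], pts$t[i], m))
    want <- f$oracle(pts$x[i], pts$y[i], pts$t[i])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("a point on a node at a scene time returns the stored value for all methods", {
  v <- simple_var(times = c(0, 21600))
  for (meth in all_method_combos()) {
    expect_equal(as.numeric(annotate_point(v, 4, 7, 21600, meth)),
                 node_value(v, 5, 8, 2))
  }
})

test_that("every method yields convex combinations of the nodes", {
  v <- simple_var(values = array(rnorm(11 * 11 * 2, sd = 10),
                                 dim = c(11, 11, 2)),
                  times = c(0, 21600))
  set.seed(29)
  pts <- random_points_in(v, 300)
  methods <- all_method_combos()
  for (i in seq_len(nrow(pts))) {
    nb <- locate_neighborhood(v, pts$x[i], pts$y[i], pts$t[i])
    nodes <- c(vapply(c(nb$k1, nb$k2), function(k)
      as.numeric(nb_values_at(v, nb, k)), numeric(4)))
    for (meth in methods) {
      val <- as.numeric(annotate_point(v, pts$x[i], pts$y[i], pts$t[i], meth))
      expect_gte(val, min(nodes) - 1e-12)
      expect_lte(val, max(nodes) + 1e-12)
    }
  }
})

test_that("IDW with k = 1 equals nearest neighbour; p -> Inf converges to it", {
  v <- simple_var(values = matrix(rnorm(121), 11, 11))
  set.seed(31)
  pts <- random_points_in(v, 300)
  nn <- interp_method("nearest_neighbour", "nearest_neighbour")
  k1 <- interp_method("inverse_distance_weighted", "nearest_neighbour",
                      idw_k = 1)
  p64 <- interp_method("inverse_distance_weighted", "nearest_neighbour",
                       idw_power_space = 64)
  n_checked <- 0L
  for (i in seq_len(nrow(pts))) {
    a <- as.numeric(annotate_point(v, pts$x[i], pts$y[i], method = nn))
    expect_identical(as.numeric(annotate_point(v, pts$x[i], pts$y[i],
                                               method = k1)), a)
    # quantitative convergence at p = 64 requires a clearly-unique
    # nearest node: (d1/d2)^64 <= 1e-6 iff d2/d1 >= ~1.24
    nodes <- expand.grid(x = floor(pts$x[i]) + 0:1,
                         y = floor(pts$y[i]) + 0:1)
    d <- sort(geosphere::distGeo(c(pts$x[i], pts$y[i]),
                                 as.matrix(nodes)))
    if (d[2] / d[1] < 1.3) next
    n_checked <- n_checked + 1L
    expect_equal(as.numeric(annotate_point(v, pts$x[i], pts$y[i],
                                           method = p64)), a,
                 tolerance = 1e-6)
  }
  expect_gt(n_checked, 50)
})

test_that("IDW with k > 4 extends the neighborhood and stays convex", {
  v <- simple_var(values = matrix(rnorm(121), 11, 11))
  m9 <- interp_method("inverse_distance_weighted", "nearest_neighbour",
                      idw_k = 9)
  val <- as.numeric(annotate_point(v, 5.4, 5.6, method = m9))
  expect_gte(val, min(v$values))
  expect_lte(val, max(v$values))
})

test_that("missing nodes are dropped with renormalized weights", {
  v <- simple_var()
  nb <- nb_at(0.5, 0.5, v)
  for (meth in all_method_combos()) {
    vals <- c(NA, 1, 2, 3)
    out <- interp_spatial(nb, vals, meth)
    expect_gte(out, 1)
    expect_lte(out, 3)
    # all nodes missing -> missing result, not an exception
    expect_true(is.na(interp_spatial(nb, rep(NA_real_, 4), meth)))
  }
  # nearest neighbour falls through to the next-nearest node (v1 at the
  # lower-left corner is nearest but missing; v2 due east is next)
  nnb <- locate_neighborhood(v, 0.4, 0.05)
  nn <- interp_method("nearest_neighbour", "nearest_neighbour")
  expect_equal(interp_spatial(nnb, c(NA, 5, 6, 7), nn), 5)
})

test_that("categorical annotation always returns a member of the code set", {
  set.seed(37)
  codes <- matrix(sample(c(11, 14, 20), 121, replace = TRUE), 11, 11)
  v <- simple_var(values = codes, kind = "categorical")
  pts <- random_points_in(v, 50)
  m <- interp_method("bilinear", "inverse_distance_weighted")  # forced to NN
  for (i in seq_len(nrow(pts))) {
    val <- as.numeric(annotate_point(v, pts$x[i], pts$y[i], method = m))
    expect_true(val %in% v$codes)
  }
})
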