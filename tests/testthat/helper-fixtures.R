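# Shared fixtures and independent oracles for the test suite.

EPOCH_2008 <- as.numeric(as.POSIXct("2008-06-01 00:00:00", tz = "UTC"))

# Small regular lon/lat grid variable with explicit node values.
simple_var <- function(values = NULL, lon = 0:10, lat = 0:10,
                       times = NULL, tile_shape = NULL, kind = "continuous",
                       id = "test.var", crs = crs_wgs84()) {
  axes <- list(grid_axis("x", lon), grid_axis("y", lat))
  dims <- c(length(lon), length(lat))
  if (!is.null(times)) {
    axes <- c(axes, list(grid_axis("t", times)))
    dims <- c(dims, length(times))
  }
  if (is.null(values)) values <- array(seq_len(prod(dims)), dim = dims)
  build_grid_variable(id, axes, values, crs = crs, kind = kind,
                      tile_shape = tile_shape)
}

# Independent brute-force enumeration of the scenes a set of points
# needs on a REGULAR lon/lat grid: neighbor indices from closed-form
# fractional positions, tiles from integer division, times from a scan of
# the timestamp vector. Shares no code with scenes_required().
brute_force_scenes <- function(points, lon, lat, times, tile_shape, id) {
  dx <- lon[2] - lon[1]; dy <- lat[2] - lat[1]
  keys <- character()
  for (r in seq_len(nrow(points))) {
    fx <- (points$x[r] - lon[1]) / dx
    fy <- (points$y[r] - lat[1]) / dy
    # 0-based lower node of the bracketing cell (last node joins the
    # cell below it)
    lx <- max(0, min(floor(fx), length(lon) - 2))
    ly <- max(0, min(floor(fy), length(lat) - 2))
    is <- lx:(lx + 1)
    js <- ly:(ly + 1)
    ks <- if (is.null(times)) 0 else {
      after <- which(times >= points$t[r])[1]
      before <- max(which(times <= points$t[r]))
      unique(c(before, after))
    }
    for (i in is) for (j in js) for (k in ks) {
      keys <- c(keys, sprintf("%s|t%03d|x%03d.y%03d", id, k,
                              i %/% tile_shape[1], j %/% tile_shape[2]))
    }
  }
  sort(unique(keys))
}

# Independent cache-policy simulator: replays a get() sequence over a
# plain data frame and returns the surviving key set. Eviction rules are
# re-stated here from scratch (rank by count then recency then key for
# LFU; recency then key for LRU; one eviction per overflowing insert).
simulate_cache <- function(keys, capacity, strategy) {
  st <- data.frame(key = character(), count = integer(), last = integer(),
                   stringsAsFactors = FALSE)
  clock <- 0L
  for (k in keys) {
    clock <- clock + 1L
    hit <- which(st$key == k)
    if (length(hit)) {
      st$count[hit] <- st$count[hit] + 1L
      st$last[hit] <- clock
    } else {
      st <- rbind(st, data.frame(key = k, count = 1L, last = clock))
      while (nrow(st) > capacity) {
        ord <- if (strategy == "lfu") order(st$count, st$last, st$key)
               else order(st$last, st$key)
        st <- st[-ord[1], , drop = FALSE]
      }
    }
  }
  sort(st$key)
}

# Random points strictly inside a variable's space-time domain.
random_points_in <- function(var, n) {
  xr <- range(var$axes$x$coordinates)
  yr <- range(var$axes$y$coordinates)
  out <- data.frame(x = runif(n, xr[1], xr[2]), y = runif(n, yr[1], yr[2]))
  if ("t" %in% names(var$axes)) {
    tr <- range(var$axes$t$coordinates)
    out$t <- runif(n, tr[1], tr[2])
  }
  out
}

all_method_combos <- function(idw_k = 4) {
  sp <- c("nearest_neighbour", "bilinear", "inverse_distance_weighted")
  tm <- c("nearest_neighbour", "inverse_distance_weighted")
  unlist(lapply(sp, function(s) lapply(tm, function(t)
    interp_method(s, t, idw_k = idw_k))), recursive = FALSE)
}
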