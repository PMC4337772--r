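# Data model for n-dimensional gridded environmental variables.
#
# A GridVariable spans 1-4 axes drawn from {x, y, z, t}. Internally all
# axes are stored ascending; geographic longitudes are normalized to
# [-180, 180) (grids published as [0, 360) are re-indexed on load) and a
# global longitude axis wraps across the antimeridian. Grid coordinates
# are cell centers; fractional positions are measured between adjacent
# centers. Spatial tiles plus the timestamp index define scenes, the unit
# of caching and fetching.

AXIS_NAMES <- c("x", "y", "z", "t")

#' Grid axis
#'
#' One coordinate axis of a gridded variable. Coordinates must be strictly
#' monotone; descending axes are reversed to ascending on construction
#' (the parent [build_grid_variable()] flips the value array to match).
#' A scalar spacing is recorded when the axis is regular (successive
#' differences equal within 1e-9 relative tolerance).
#'
#' @param name one of `"x"`, `"y"`, `"z"`, `"t"`
#' @param coordinates strictly monotone numeric vector (degrees, meters,
#'   or epoch seconds)
#' @return a `grid_axis` object with fields `name`, `coordinates`,
#'   `spacing` (NULL if irregular), and `reversed` (TRUE if the input was
#'   descending)
#' @export
grid_axis <- function(name, coordinates) {
  if (!name %in% AXIS_NAMES)
    et_validation_error(sprintf("axis name must be one of %s",
                                paste(AXIS_NAMES, collapse = ", ")))
  coordinates <- as.numeric(coordinates)
  if (length(coordinates) < 1 || anyNA(coordinates))
    et_validation_error("axis coordinates must be non-empty and finite")
  d <- diff(coordinates)
  reversed <- FALSE
  if (length(d)) {
    if (all(d < 0)) {
      coordinates <- rev(coordinates)
      d <- -rev(d)
      reversed <- TRUE
    } else if (any(d <= 0)) {
      et_validation_error(sprintf("axis '%s' coordinates not strictly monotone",
                                  name))
    }
  }
  spacing <- NULL
  if (length(d)) {
    s <- mean(d)
    if (all(abs(d - s) <= 1e-9 * max(abs(s), 1))) spacing <- s
  }
  structure(list(name = name, coordinates = coordinates, spacing = spacing,
                 reversed = reversed),
            class = "grid_axis")
}

axis_len <- function(ax) length(ax$coordinates)

#' Build a gridded environmental variable
#'
#' Assembles an n-dimensional gridded variable (1 <= n <= 4, axes drawn
#' from x, y, z, t in that order) from axes and a value array. Geographic
#' grids published with longitudes in `[0, 360)` are re-indexed to
#' `[-180, 180)`; descending axes are flipped ascending together with the
#' value array. Categorical variables carry an integer code set and are
#' restricted to nearest-neighbour interpolation downstream.
#'
#' @param id dataset+variable identifier, e.g. `"ncep.uwind"`
#' @param axes list of [grid_axis()] objects in x, y, z, t order
#' @param values numeric array with `dim` matching the axis lengths
#'   (a vector is accepted for 1-axis variables)
#' @param crs a [crs_wgs84()]-style `crs_id` (or name / manifest list)
#' @param kind `"continuous"` or `"categorical"`
#' @param tile_shape integer block size per spatial axis (x, y); defaults
#'   to the full axis lengths (one spatial tile)
#' @param units free-text units
#' @param missing_value sentinel value converted to `NA` on load
#'   (`NA` values in `values` are always treated as missing)
#' @return a `grid_variable` object
#' @export
build_grid_variable <- function(id, axes, values, crs = crs_wgs84(),
                                kind = c("continuous", "categorical"),
                                tile_shape = NULL, units = "",
                                missing_value = NULL) {
  kind <- match.arg(kind)
  crs <- as_crs(crs)
  if (!is.list(axes) || !length(axes))
    et_validation_error("axes must be a non-empty list of grid_axis objects")
  if (length(axes) > 4)
    et_validation_error("a grid variable has at most 4 axes (x, y, z, t)")
  axes <- lapply(seq_along(axes), function(i) {
    ax <- axes[[i]]
    if (!inherits(ax, "grid_axis")) et_validation_error("axes must be grid_axis objects")
    ax
  })
  nm <- vapply(axes, `[[`, "", "name")
  if (anyDuplicated(nm))
    et_validation_error("duplicate axis names")
  if (!all(order(match(nm, AXIS_NAMES)) == seq_along(nm)))
    et_validation_error("axes must be given in x, y, z, t order")
  names(axes) <- nm

  dims <- vapply(axes, axis_len, 0L)
  if (is.null(dim(values))) {
    if (length(axes) == 1L && length(values) == dims) {
      values <- array(as.numeric(values), dim = dims)
    } else {
      et_validation_error("values must be an array with dim matching the axes")
    }
  }
  if (length(dim(values)) != length(dims) || !all(dim(values) == dims))
    et_validation_error(sprintf(
      "values shape (%s) does not match axis lengths (%s)",
      paste(dim(values), collapse = "x"), paste(dims, collapse = "x")))
  storage.mode(values) <- "double"
  if (!is.null(missing_value))
    values[values == missing_value] <- NA_real_

  # flip the value array along any axis that was stored descending
  for (i in seq_along(axes)) {
    if (axes[[i]]$reversed) {
      idx <- lapply(dim(values), seq_len)
      idx[[i]] <- rev(idx[[i]])
      values <- do.call(`[`, c(list(values), idx, list(drop = FALSE)))
    }
  }

  # re-index [0, 360) longitude grids to [-180, 180)
  if (is_lonlat(crs) && "x" %in% nm) {
    xc <- axes[["x"]]$coordinates
    if (max(xc) > 180) {
      newx <- ((xc + 180) %% 360) - 180
      ord <- order(newx)
      axes[["x"]]$coordinates <- newx[ord]
      ix <- which(nm == "x")
      idx <- lapply(dim(values), seq_len)
      idx[[ix]] <- ord
      values <- do.call(`[`, c(list(values), idx, list(drop = FALSE)))
    }
  }

  codes <- NULL
  if (kind == "categorical") {
    codes <- sort(unique(values[is.finite(values)]))
    if (length(codes) && any(codes != round(codes)))
      et_validation_error("categorical variables must hold integer codes")
  }

  nx <- if ("x" %in% nm) dims[["x"]] else 1L
  ny <- if ("y" %in% nm) dims[["y"]] else 1L
  if (is.null(tile_shape)) tile_shape <- c(nx, ny)
  tile_shape <- as.integer(tile_shape)
  if (length(tile_shape) != 2L || any(tile_shape < 1L))
    et_validation_error("tile_shape must be two positive integers (x, y)")

  structure(list(id = id, axes = axes, values = values, crs = crs,
                 kind = kind, units = units, tile_shape = tile_shape,
                 codes = codes),
            class = "grid_variable")
}

#' @export
print.grid_variable <- function(x, ...) {
  cat("<grid_variable>", x$id, sprintf("[%s]", x$kind), "\n")
  for (ax in x$axes)
    cat(sprintf("  %s: %d nodes [%g .. %g]%s\n", ax$name, axis_len(ax),
                min(ax$coordinates), max(ax$coordinates),
                if (!is.null(ax$spacing)) sprintf(" step %g", ax$spacing) else ""))
  cat("  crs:", x$crs$name, " tiles:", paste(x$tile_shape, collapse = "x"), "\n")
  invisible(x)
}

var_has_axis <- function(var, name) name %in% names(var$axes)

# TRUE when a lon/lat grid covers the full circle so neighborhoods may
# wrap across the antimeridian.
lon_is_global <- function(var) {
  if (!is_lonlat(var$crs) || !var_has_axis(var, "x")) return(FALSE)
  ax <- var$axes[["x"]]
  if (is.null(ax$spacing)) return(FALSE)
  span <- max(ax$coordinates) - min(ax$coordinates) + ax$spacing
  abs(span - 360) < 1e-6
}

#' Look up a stored node value by integer axis indices
#'
#' @param var a `grid_variable`
#' @param ... one integer index per axis, in axis order
#' @return the stored node value
#' @export
node_value <- function(var, ...) {
  idx <- as.list(as.integer(c(...)))
  if (length(idx) != length(var$axes))
    et_validation_error("node_value needs one index per axis")
  do.call(`[`, c(list(var$values), idx))
}

# -- neighborhood location ---------------------------------------------------

# Bracketing indices + fractional offset along one ascending axis.
# Returns list(i1, i2, frac) or signals a domain error.
bracket_axis <- function(coords, v, what = "coordinate") {
  n <- length(coords)
  if (n == 1L) {
    if (abs(v - coords[1]) > 1e-9)
      et_domain_error(sprintf("%s %g outside grid domain", what, v))
    return(list(i1 = 1L, i2 = 1L, frac = 0))
  }
  if (v < coords[1] || v > coords[n])
    et_domain_error(sprintf("%s %g outside grid domain [%g, %g]",
                            what, v, coords[1], coords[n]))
  i <- findInterval(v, coords)
  if (i >= n) { i <- n - 1L }
  frac <- (v - coords[i]) / (coords[i + 1L] - coords[i])
  list(i1 = i, i2 = i + 1L, frac = frac)
}

# Longitude bracketing with antimeridian wrap for global grids.
bracket_lon <- function(var, lon) {
  ax <- var$axes[["x"]]
  coords <- ax$coordinates
  if (is_lonlat(var$crs)) lon <- ((lon + 180) %% 360) - 180
  n <- length(coords)
  if (lon_is_global(var) && (lon < coords[1] || lon > coords[n])) {
    # between the last and (wrapped) first cell centers
    gap <- coords[1] + 360 - coords[n]
    pos <- if (lon >= coords[n]) lon - coords[n] else lon + 360 - coords[n]
    return(list(i1 = n, i2 = 1L, frac = pos / gap))
  }
  bracket_axis(coords, lon, "x")
}

# Temporal bracketing: inside the domain returns bracketing scene indices;
# up to one scene interval beyond an edge clamps to the edge scene with a
# warning; further out is a domain error.
bracket_time <- function(var, t) {
  if (!var_has_axis(var, "t"))
    return(list(k1 = NA_integer_, k2 = NA_integer_,
                t_before = NA_real_, t_after = NA_real_))
  ts <- var$axes[["t"]]$coordinates
  n <- length(ts)
  step <- if (n > 1) max(diff(ts)) else Inf
  if (t < ts[1] || t > ts[n]) {
    if (t >= ts[1] - step && t <= ts[n] + step) {
      k <- if (t < ts[1]) 1L else n
      warning(sprintf("time %s beyond temporal domain; clamped to edge scene",
                      format(t)), call. = FALSE)
      return(list(k1 = k, k2 = k, t_before = ts[k], t_after = ts[k]))
    }
    et_domain_error("time outside temporal domain by more than one scene interval")
  }
  b <- bracket_axis(ts, t, "t")
  if (b$frac == 0) b$i2 <- b$i1
  if (b$frac == 1) b$i1 <- b$i2
  list(k1 = b$i1, k2 = b$i2, t_before = ts[b$i1], t_after = ts[b$i2])
}

nearest_z_index <- function(var, alt) {
  if (!var_has_axis(var, "z")) return(NA_integer_)
  zc <- var$axes[["z"]]$coordinates
  if (is.null(alt) || is.na(alt)) return(1L)
  which.min(abs(zc - alt))
}

#' Locate the grid-cell neighborhood of a point
#'
#' Finds the four native-grid nodes bracketing a point in space (two per
#' axis) and the two scenes bracketing it in time, together with the
#' fractional position `(fx, fy)` of the point within its cell. Fractions
#' are measured between adjacent cell centers. A point exactly on a node
#' at a scene timestamp collapses to a degenerate bracket (`frac = 0`,
#' identical before/after scenes). Global longitude axes wrap across the
#' antimeridian. No spatial extrapolation: points outside the spatial
#' domain raise a domain error; times up to one scene interval beyond the
#' temporal edge clamp to the edge scene with a warning.
#'
#' @param var a `grid_variable`
#' @param x,y point coordinates in the variable's native CRS
#' @param t query time (UTC epoch seconds); ignored for static variables
#' @param alt altitude for variables with a z axis (nearest level is used)
#' @return a `cell_neighborhood`: list with integer node indices `ix`,
#'   `iy` (each length 2), fractions `fx`, `fy`, time indices `k1`, `k2`,
#'   `t_before`, `t_after`, z index `iz`, native node coordinates
#'   `node_x`, `node_y`, and `wrap` (antimeridian flag)
#' @export
locate_neighborhood <- function(var, x, y, t = NA_real_, alt = NULL) {
  if (!var_has_axis(var, "x") || !var_has_axis(var, "y"))
    et_validation_error("neighborhood location needs both x and y axes")
  bx <- if (is_lonlat(var$crs)) bracket_lon(var, x) else
    bracket_axis(var$axes[["x"]]$coordinates, x, "x")
  by <- bracket_axis(var$axes[["y"]]$coordinates, y, "y")
  bt <- bracket_time(var, t)
  xc <- var$axes[["x"]]$coordinates
  yc <- var$axes[["y"]]$coordinates
  wrap <- bx$i2 < bx$i1
  node_x <- xc[c(bx$i1, bx$i2)]
  if (wrap) node_x[2] <- node_x[2] + 360
  if (is_lonlat(var$crs)) x <- ((x + 180) %% 360) - 180
  structure(list(
    ix = c(bx$i1, bx$i2), iy = c(by$i1, by$i2),
    fx = bx$frac, fy = by$frac,
    k1 = bt$k1, k2 = bt$k2, t_before = bt$t_before, t_after = bt$t_after,
    t = t, iz = nearest_z_index(var, alt),
    node_x = node_x, node_y = yc[c(by$i1, by$i2)],
    px = x, py = y, crs = var$crs,
    wrap = wrap
  ), class = "cell_neighborhood")
}

# -- tiles and scenes --------------------------------------------------------

tile_of <- function(i, tile_len) as.integer((i - 1L) %/% tile_len)

scene_key <- function(var_id, k, tx, ty) {
  k <- ifelse(is.na(k), 0L, as.integer(k))
  sprintf("%s|t%03d|x%03d.y%03d", var_id, k, tx, ty)
}

# Scene keys needed by one located neighborhood.
nb_scene_keys <- function(var, nb) {
  txs <- unique(tile_of(nb$ix, var$tile_shape[1]))
  tys <- unique(tile_of(nb$iy, var$tile_shape[2]))
  ks <- unique(c(nb$k1, nb$k2))
  out <- expand.grid(ty = tys, tx = txs, k = ks)
  data.frame(variable = var$id, time_index = out$k,
             tile_x = out$tx, tile_y = out$ty,
             key = scene_key(var$id, out$k, out$tx, out$ty),
             stringsAsFactors = FALSE)
}

#' Scenes required to annotate a set of points
#'
#' Maps every point's cell neighborhood to the tiles and timestamps that
#' hold its node values, returning the de-duplicated scene keys sorted by
#' (variable, timestamp index, tile index). A point whose four spatial
#' neighbors straddle a tile boundary lists every contributing tile.
#'
#' @param var a `grid_variable`
#' @param points data frame with native coordinates `x`, `y` and a time
#'   column `t` (epoch seconds; optional for static variables)
#' @return data frame with columns `variable`, `time_index`, `tile_x`,
#'   `tile_y`, `key`, one row per scene, sorted
#' @export
scenes_required <- function(var, points) {
  if (!nrow(points)) et_validation_error("points must be non-empty")
  tcol <- if ("t" %in% names(points)) points$t else rep(NA_real_, nrow(points))
  keys <- do.call(rbind, lapply(seq_len(nrow(points)), function(i) {
    nb <- locate_neighborhood(var, points$x[i], points$y[i], tcol[i],
                              points$alt[i] %||% NULL)
    nb_scene_keys(var, nb)
  }))
  keys <- keys[!duplicated(keys$key), , drop = FALSE]
  ord <- order(keys$variable, keys$time_index, keys$tile_x, keys$tile_y)
  keys <- keys[ord, , drop = FALSE]
  rownames(keys) <- NULL
  keys
}

# Materialize one scene payload directly from an in-memory variable:
# the (x, y) tile block at one timestamp, all z levels.
scene_payload <- function(var, time_index, tx, ty) {
  nx <- axis_len(var$axes[["x"]]); ny <- axis_len(var$axes[["y"]])
  irange <- (tx * var$tile_shape[1] + 1L):min((tx + 1L) * var$tile_shape[1], nx)
  jrange <- (ty * var$tile_shape[2] + 1L):min((ty + 1L) * var$tile_shape[2], ny)
  nm <- names(var$axes)
  idx <- list(irange, jrange)
  if ("z" %in% nm) idx <- c(idx, list(seq_len(axis_len(var$axes[["z"]]))))
  if ("t" %in% nm) idx <- c(idx, list(as.integer(time_index)))
  block <- do.call(`[`, c(list(var$values), idx, list(drop = FALSE)))
  list(block = block, i_offset = irange[1] - 1L, j_offset = jrange[1] - 1L)
}

# Read node (i, j) at time k / level iz through a fetch function that
# returns scene payloads (the cache hook). Vectorized over i, j.
nodes_from_scenes <- function(var, i, j, k, iz, fetch) {
  vapply(seq_along(i), function(m) {
    tx <- tile_of(i[m], var$tile_shape[1])
    ty <- tile_of(j[m], var$tile_shape[2])
    sc <- fetch(var, k, tx, ty)
    ii <- i[m] - sc$i_offset
    jj <- j[m] - sc$j_offset
    idx <- list(ii, jj)
    if (var_has_axis(var, "z")) idx <- c(idx, list(if (is.na(iz)) 1L else iz))
    if (var_has_axis(var, "t")) idx <- c(idx, list(1L))
    do.call(`[`, c(list(sc$block), idx))
  }, 0)
}

# 2x2 node-value matrix for one neighborhood at one time index.
# Layout: v1=(i1,j1) v2=(i2,j1) v3=(i1,j2) v4=(i2,j2), matching the
# bilinear weight expansion.
nb_values_at <- function(var, nb, k, fetch = NULL) {
  if (is.null(fetch)) fetch <- function(v, k, tx, ty) scene_payload(v, k, tx, ty)
  i <- nb$ix[c(1, 2, 1, 2)]
  j <- nb$iy[c(1, 1, 2, 2)]
  matrix(nodes_from_scenes(var, i, j, k, nb$iz, fetch), nrow = 2)
}
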