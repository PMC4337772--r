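# Spatial-then-temporal interpolation of a cell neighborhood.
#
# A track point is annotated by interpolating the node values of its cell
# neighborhood in space at the two bracketing scene timestamps, then
# interpolating the two spatial values in time to the point's timestamp.
# Distances for nearest-neighbour and inverse-distance weighting are
# geodesic distances on the WGS84 ellipsoid; missing nodes are dropped and
# the remaining weights renormalized, so every method yields a convex
# combination of the contributing nodes.

#' Interpolation method descriptor
#'
#' Combines a spatial and a temporal interpolation method. Categorical
#' variables are restricted to nearest-neighbour in both dimensions;
#' [parse_request()] and [annotate_track()] enforce this. The temporal IDW
#' power defaults to 1, which for the two bracketing scenes reduces to
#' linear interpolation in time.
#'
#' @param spatial `"nearest_neighbour"`, `"bilinear"`, or
#'   `"inverse_distance_weighted"`
#' @param temporal `"nearest_neighbour"` or `"inverse_distance_weighted"`
#' @param idw_power_space IDW exponent in space (default 2, Shepard)
#' @param idw_power_time IDW exponent in time (default 1, i.e. linear)
#' @param idw_k number of nearest nodes used by spatial IDW (default 4,
#'   the bracketing cell; larger values extend the neighborhood ring by
#'   ring around the cell)
#' @return an `interp_method` object
#' @export
interp_method <- function(spatial = c("bilinear", "nearest_neighbour",
                                      "inverse_distance_weighted"),
                          temporal = c("inverse_distance_weighted",
                                       "nearest_neighbour"),
                          idw_power_space = 2, idw_power_time = 1,
                          idw_k = 4) {
  spatial <- match.arg(spatial)
  temporal <- match.arg(temporal)
  if (idw_power_space <= 0 || idw_power_time <= 0)
    et_validation_error("IDW powers must be positive")
  if (idw_k < 1) et_validation_error("idw_k must be >= 1")
  structure(list(spatial = spatial, temporal = temporal,
                 idw_power_space = idw_power_space,
                 idw_power_time = idw_power_time,
                 idw_k = as.integer(idw_k)),
            class = "interp_method")
}

method_label <- function(m) {
  ab <- c(nearest_neighbour = "nn", bilinear = "bilinear",
          inverse_distance_weighted = "idw")
  paste0(ab[[m$spatial]], "-", ab[[m$temporal]])
}

# lon/lat of neighborhood nodes in v1..v4 order, and of the query point.
nb_lonlat <- function(nb) {
  nx <- nb$node_x[c(1, 2, 1, 2)]
  ny <- nb$node_y[c(1, 1, 2, 2)]
  if (is_lonlat(nb$crs)) {
    list(nodes = cbind(((nx + 180) %% 360) - 180, ny),
         point = c(((nb$px + 180) %% 360) - 180, nb$py))
  } else {
    inv <- proj_inverse(nx, ny, nb$crs)
    p <- proj_inverse(nb$px, nb$py, nb$crs)
    list(nodes = cbind(inv$lon, inv$lat), point = c(p$lon, p$lat))
  }
}

# Geodesic distances (m) from the query point to the four nodes.
nb_node_distances <- function(nb) {
  ll <- nb_lonlat(nb)
  geosphere::distGeo(matrix(ll$point, ncol = 2), ll$nodes)
}

# Shared weighted-mean kernel: drops missing nodes and renormalizes, so
# the result is a convex combination of the surviving values.
weighted_value <- function(values, weights) {
  ok <- is.finite(values) & is.finite(weights)
  if (!any(ok)) return(NA_real_)
  v <- values[ok]; w <- weights[ok]
  if (length(v) == 1L) return(v)
  if (sum(w) <= 0) return(NA_real_)
  sum(v * w) / sum(w)
}

# Inverse-distance weights d^-p, normalized by the minimal distance so
# large powers cannot underflow; distances under 1 m are floored.
idw_weights <- function(d, p) {
  dd <- pmax(d, 1)
  (min(dd) / dd)^p
}

#' Spatial interpolation of one neighborhood at one timestamp
#'
#' Collapses the four node values of a cell neighborhood to a single value
#' at the query point. `nearest_neighbour` returns the value of the node
#' at minimal geodesic distance (falling through to the next-nearest when
#' nodes are missing); `bilinear` expands
#' `(1-fx)(1-fy) v1 + fx(1-fy) v2 + (1-fx)fy v3 + fx fy v4`;
#' `inverse_distance_weighted` uses weights `d^-p` with geodesic `d`. An
#' exact node hit (distance < 1 m) returns that node's stored value. All
#' nodes missing yields `NA` (a missing-value result, not an error).
#'
#' @param nb a `cell_neighborhood` from [locate_neighborhood()]
#' @param values 2 x 2 matrix of node values (v1, v2 in row-major lower
#'   row; as returned internally for one timestamp) or a length-4 vector
#'   in v1..v4 order
#' @param method an [interp_method()]
#' @return the interpolated value, or `NA` if no node contributes
#' @export
interp_spatial <- function(nb, values, method) {
  v <- as.numeric(values)  # v1, v2, v3, v4
  if (length(v) != 4) et_validation_error("values must hold the 4 cell nodes")
  if (all(!is.finite(v))) return(NA_real_)
  d <- nb_node_distances(nb)

  hit <- which(d < 1)
  if (length(hit) && is.finite(v[hit[1]])) return(v[hit[1]])

  switch(method$spatial,
    nearest_neighbour = {
      ord <- order(d)
      v[ord][which(is.finite(v[ord]))[1]]
    },
    bilinear = {
      fx <- nb$fx; fy <- nb$fy
      w <- c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
      out <- weighted_value(v, w)
      # point pinned on a missing corner: fall back to nearest valid node
      if (is.na(out)) {
        ord <- order(d)
        out <- v[ord][which(is.finite(v[ord]))[1]]
      }
      out
    },
    inverse_distance_weighted = {
      ok <- is.finite(v)
      keep <- order(!ok, d)[seq_len(min(method$idw_k, sum(ok)))]
      weighted_value(v[keep], idw_weights(d[keep], method$idw_power_space))
    }
  )
}

#' Temporal interpolation between two bracketing scenes
#'
#' Interpolates the two spatially-interpolated values to the query time.
#' `nearest_neighbour` returns the value at the closer timestamp (ties at
#' the exact midpoint resolve to the earlier scene); IDW uses weights
#' `|t - t_k|^-p` (default power 1, which for two samples equals linear
#' interpolation). A query at a scene timestamp returns that scene's value
#' exactly. A missing endpoint is dropped (the other endpoint is
#' returned); both missing yields `NA`.
#'
#' @param v_before,v_after spatially interpolated values at `t_before`,
#'   `t_after`
#' @param t_before,t_after bracketing scene timestamps (epoch seconds)
#' @param t query time, `t_before <= t <= t_after`
#' @param method an [interp_method()]
#' @return the interpolated value
#' @export
interp_temporal <- function(v_before, v_after, t_before, t_after, t, method) {
  if (is.na(t_before) || t_before == t_after) {
    if (is.finite(v_before)) return(v_before)
    return(if (is.finite(v_after)) v_after else NA_real_)
  }
  if (t < t_before || t > t_after)
    et_validation_error("query time outside the temporal bracket")
  if (t == t_before && is.finite(v_before)) return(v_before)
  if (t == t_after && is.finite(v_after)) return(v_after)
  v <- c(v_before, v_after)
  if (all(!is.finite(v))) return(NA_real_)
  switch(method$temporal,
    nearest_neighbour = {
      db <- t - t_before; da <- t_after - t
      ord <- if (db <= da) c(1L, 2L) else c(2L, 1L)
      v[ord][which(is.finite(v[ord]))[1]]
    },
    inverse_distance_weighted =
      weighted_value(v, abs(t - c(t_before, t_after))^(-method$idw_power_time))
  )
}

# Extended spatial IDW over the k nearest nodes (k > 4): grows the index
# window ring by ring around the bracketing cell, wrapping in longitude on
# global grids, then weights the k nearest finite nodes by geodesic d^-p.
idw_k_spatial <- function(var, nb, k_time, method, fetch) {
  nx <- axis_len(var$axes[["x"]]); ny <- axis_len(var$axes[["y"]])
  wrapx <- lon_is_global(var)
  k <- method$idw_k
  ring <- 0L
  repeat {
    is <- (nb$ix[1] - ring):(if (nb$wrap) nb$ix[2] + nx else nb$ix[2] + ring)
    js <- (nb$iy[1] - ring):(nb$iy[2] + ring)
    if (wrapx) is <- unique(((is - 1L) %% nx) + 1L) else
      is <- is[is >= 1L & is <= nx]
    js <- js[js >= 1L & js <= ny]
    grid <- expand.grid(i = is, j = js)
    if (nrow(grid) >= k || (length(is) == nx && length(js) == ny)) break
    ring <- ring + 1L
  }
  vals <- nodes_from_scenes(var, grid$i, grid$j, k_time, nb$iz, fetch)
  xc <- var$axes[["x"]]$coordinates[grid$i]
  yc <- var$axes[["y"]]$coordinates[grid$j]
  ll <- if (is_lonlat(var$crs)) {
    list(nodes = cbind(xc, yc), point = c(nb$px, nb$py))
  } else {
    inv <- proj_inverse(xc, yc, var$crs)
    p <- proj_inverse(nb$px, nb$py, var$crs)
    list(nodes = cbind(inv$lon, inv$lat), point = c(p$lon, p$lat))
  }
  d <- geosphere::distGeo(matrix(ll$point, ncol = 2), ll$nodes)
  hit <- which(d < 1)
  if (length(hit) && is.finite(vals[hit[1]])) return(vals[hit[1]])
  ok <- is.finite(vals)
  if (!any(ok)) return(NA_real_)
  keep <- order(!ok, d)[seq_len(min(k, sum(ok)))]
  weighted_value(vals[keep], idw_weights(d[keep], method$idw_power_space))
}

# Spatial value at one time index, honoring idw_k > 4.
spatial_value_at <- function(var, nb, k_time, method, fetch = NULL) {
  if (is.null(fetch)) fetch <- function(v, k, tx, ty) scene_payload(v, k, tx, ty)
  if (method$spatial == "inverse_distance_weighted" && method$idw_k > 4)
    return(idw_k_spatial(var, nb, k_time, method, fetch))
  interp_spatial(nb, nb_values_at(var, nb, k_time, fetch), method)
}

#' Annotate a single point with one gridded variable
#'
#' The full space-then-time scheme for one point: the point (WGS84
#' lon/lat + time) is transformed to the variable's native CRS, its cell
#' neighborhood located, node values interpolated in space at the two
#' bracketing scene timestamps, and the two spatial values interpolated in
#' time. Categorical variables are forced to nearest-neighbour in both
#' dimensions, so the output is always a member of the code set.
#'
#' Out-of-domain points yield `NA` with a `"missing"` attribute naming the
#' reason — never a silent zero.
#'
#' @param var a `grid_variable`
#' @param lon,lat WGS84 coordinates of the point (degrees)
#' @param t time as UTC epoch seconds (ignored for static variables)
#' @param method an [interp_method()]
#' @param alt optional altitude (m), used for variables with a z axis
#' @param fetch optional scene accessor `function(var, k, tx, ty)`
#'   returning a scene payload (the cache hook); defaults to direct
#'   in-memory access
#' @return the annotated value (`NA` if missing, with attribute)
#' @export
annotate_point <- function(var, lon, lat, t = NA_real_, method = interp_method(),
                           alt = NULL, fetch = NULL) {
  if (var$kind == "categorical" &&
      (method$spatial != "nearest_neighbour" ||
       method$temporal != "nearest_neighbour")) {
    method <- interp_method("nearest_neighbour", "nearest_neighbour")
  }
  native <- if (is_lonlat(var$crs)) c(lon, lat) else
    as.numeric(transform_point(c(lon, lat), crs_wgs84(), var$crs))
  nb <- tryCatch(
    locate_neighborhood(var, native[1], native[2], t, alt),
    envtrack_domain_error = function(e) e
  )
  if (inherits(nb, "condition"))
    return(structure(NA_real_, missing = conditionMessage(nb)))
  vb <- spatial_value_at(var, nb, nb$k1, method, fetch)
  va <- if (!is.na(nb$k1) && identical(nb$k1, nb$k2)) vb else
    spatial_value_at(var, nb, nb$k2, method, fetch)
  tt <- if (is.na(nb$t_before)) NA_real_ else min(max(t, nb$t_before), nb$t_after)
  out <- interp_temporal(vb, va, nb$t_before, nb$t_after, tt, method)
  if (is.na(out)) structure(NA_real_, missing = "all nodes missing") else out
}
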