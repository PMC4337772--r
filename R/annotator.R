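# End-to-end annotation pipeline: per-point flight heading and speed,
# track segmentation, track annotation, and area annotation.
#
# Tracks are data frames with columns individual, timestamp (POSIXct
# UTC), lon, lat (WGS84 degrees) and optional alt (m). Annotation adds
# one column per requested (variable, method) pair without touching the
# input columns, preserving row order; internally points are processed in
# scene-sorted order so tile caching is effective.

track_epochs <- function(track) as.numeric(track$timestamp)

validate_track <- function(track) {
  need <- c("individual", "timestamp", "lon", "lat")
  miss <- setdiff(need, names(track))
  if (length(miss))
    et_validation_error(paste("track missing columns:",
                              paste(miss, collapse = ", ")))
  if (any(abs(track$lat) > 90))
    et_validation_error("latitudes must be within [-90, 90]")
  ep <- track_epochs(track)
  for (id in unique(track$individual)) {
    ti <- ep[track$individual == id]
    if (any(diff(ti) <= 0))
      et_validation_error(sprintf(
        "timestamps must be strictly increasing per individual ('%s')", id))
  }
  invisible(track)
}

#' Per-point flight heading and ground speed
#'
#' Forward differences per individual: the speed at fix i is the geodesic
#' distance to fix i+1 divided by the elapsed time, and the heading is
#' the initial geodesic bearing toward fix i+1. The last fix of each
#' individual inherits the previous heading and speed. Coincident
#' consecutive fixes give speed 0 and an undefined (`NA`) heading.
#'
#' @param track a track data frame (`individual`, `timestamp`, `lon`,
#'   `lat`)
#' @return the track with added `ground_speed` (m/s) and `heading`
#'   (degrees from north) columns
#' @export
compute_heading_speed <- function(track) {
  validate_track(track)
  ep <- track_epochs(track)
  track$ground_speed <- NA_real_
  track$heading <- NA_real_
  for (id in unique(track$individual)) {
    sel <- which(track$individual == id)
    if (length(sel) < 2) next
    p <- cbind(track$lon[sel], track$lat[sel])
    n <- length(sel)
    d <- geosphere::distGeo(p[-n, , drop = FALSE], p[-1, , drop = FALSE])
    dt <- diff(ep[sel])
    speed <- d / dt
    hd <- rep(NA_real_, n - 1)
    moved <- d > 1e-9
    if (any(moved))
      hd[moved] <- geosphere::bearing(p[which(moved), , drop = FALSE],
                                      p[which(moved) + 1, , drop = FALSE]) %% 360
    track$ground_speed[sel] <- c(speed, speed[n - 1])
    track$heading[sel] <- c(hd, hd[n - 1])
  }
  track
}

#' Segment a track into transit / coastal-foraging / other
#'
#' Labels each fix: `transit` when the ground speed strictly exceeds the
#' threshold and the longitude falls in the transit band, and
#' `coastal_foraging` when the longitude falls in the coastal band
#' (regardless of speed); everything else is `other`. Band membership
#' uses half-open intervals `[west, east)`, so the shared boundary
#' belongs to the coastal band only. Defaults follow the Galapagos
#' albatross case study: >5 m/s between 90°W and 82.5°W for transit, and
#' 82.5°W to 75°W for the Peruvian coastal foraging area.
#'
#' @param track a track data frame; `ground_speed` is computed if absent
#' @param speed_threshold transit speed threshold (m/s), strict `>`
#' @param transit_lon,coastal_lon longitude bands `c(west, east)` degrees
#' @return the track with an added `segment` factor column
#' @export
segment_track <- function(track, speed_threshold = 5,
                          transit_lon = c(-90, -82.5),
                          coastal_lon = c(-82.5, -75)) {
  if (!"ground_speed" %in% names(track))
    track <- compute_heading_speed(track)
  in_band <- function(lon, band) lon >= band[1] & lon < band[2]
  lab <- rep("other", nrow(track))
  lab[in_band(track$lon, transit_lon) &
        !is.na(track$ground_speed) &
        track$ground_speed > speed_threshold] <- "transit"
  lab[in_band(track$lon, coastal_lon)] <- "coastal_foraging"
  track$segment <- factor(lab, levels = c("transit", "coastal_foraging", "other"))
  track
}

# Column label for one requested (variable, method) pair.
annotation_column <- function(var_id, method)
  paste0(var_id, ".", method_label(method))

# Internal scene-sorted processing order for one variable: points sorted
# by (first bracketing timestamp index, tile index of the lower-left
# node). Out-of-domain points sort last and are annotated as missing.
scene_order <- function(var, track) {
  ep <- track_epochs(track)
  keyinfo <- t(vapply(seq_len(nrow(track)), function(i) {
    native <- if (is_lonlat(var$crs)) c(track$lon[i], track$lat[i]) else
      as.numeric(transform_point(c(track$lon[i], track$lat[i]),
                                 crs_wgs84(), var$crs))
    nb <- tryCatch(
      suppressWarnings(locate_neighborhood(var, native[1], native[2], ep[i])),
      envtrack_domain_error = function(e) NULL)
    if (is.null(nb)) return(c(NA_real_, NA_real_, NA_real_))
    c(if (is.na(nb$k1)) 0 else nb$k1,
      tile_of(nb$ix[1], var$tile_shape[1]),
      tile_of(nb$iy[1], var$tile_shape[2]))
  }, numeric(3)))
  order(keyinfo[, 1], keyinfo[, 2], keyinfo[, 3], na.last = TRUE)
}

#' Annotate a track with gridded environmental variables
#'
#' For every requested (variable, interpolation method) pair, every track
#' point is annotated by the space-then-time scheme of
#' [annotate_point()]. Scenes are fetched through a cache; points are
#' processed in scene-sorted order internally, but the output preserves
#' the input row order and all input columns. Out-of-domain points yield
#' `NA` cells and a logged warning; the run continues.
#'
#' @param track a track data frame (WGS84 lon/lat, POSIXct timestamps)
#' @param request an `annotation_request` from [parse_request()], or a
#'   list of `list(id =, method =)` entries
#' @param datasets named list of `grid_variable`s (see [load_datasets()]
#'   or [make_field()])
#' @param cache optional [scene_cache()] (default: unbounded LFU)
#' @return the annotated track; attribute `"log"` carries the run
#'   manifest (scene counts, cache statistics, missing-annotation count)
#' @export
annotate_track <- function(track, request, datasets, cache = NULL) {
  validate_track(track)
  vars_req <- request_variables(request)
  if (is.null(cache)) cache <- scene_cache()
  provider <- memory_provider(datasets)
  fetch <- cached_fetch(cache, provider)
  out <- track
  ep <- track_epochs(track)
  n_missing <- 0L
  warnings <- character()

  for (vr in vars_req) {
    var <- datasets[[vr$id]]
    if (is.null(var))
      et_request_error(sprintf("unknown variable '%s'", vr$id))
    method <- vr$method
    if (var$kind == "categorical" &&
        (method$spatial != "nearest_neighbour" ||
         method$temporal != "nearest_neighbour"))
      et_request_error(sprintf(
        "variable '%s' is categorical: only the nearest neighbour interpolation can be applied",
        vr$id))
    ord <- scene_order(var, track)
    vals <- rep(NA_real_, nrow(track))
    for (i in ord) {
      v <- withCallingHandlers(
        annotate_point(var, track$lon[i], track$lat[i], ep[i], method,
                       alt = track$alt[i] %||% NULL, fetch = fetch),
        warning = function(w) {
          warnings <<- c(warnings, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (is.na(v)) {
        n_missing <- n_missing + 1L
        warnings <- c(warnings, sprintf(
          "point %d: %s missing (%s)", i, vr$id,
          attr(v, "missing") %||% "missing"))
      }
      vals[i] <- as.numeric(v)
    }
    out[[annotation_column(vr$id, method)]] <- vals
  }

  structure(out, log = run_manifest(request = request, cache = cache,
                                    n_missing = n_missing,
                                    warnings = unique(warnings)))
}

#' Annotate a rectangular geographic area
#'
#' Resamples each requested variable onto a regular pixel grid spanned by
#' the four corners of a region of interest, one raster per (variable,
#' timestamp). Pixels are registered at cell centers, each computed by
#' the same space-then-time scheme as track annotation, so requesting the
#' native grid with nearest-neighbour reproduces the native scene
#' exactly.
#'
#' @param request an `annotation_request` with `mode = "area"`: corners
#'   (`xmin`, `xmax`, `ymin`, `ymax` of the region in the stated CRS),
#'   `crs`, `timestamps`, and pixel counts `nx`, `ny`
#' @param datasets named list of `grid_variable`s
#' @param cache optional [scene_cache()]
#' @return an `area_bundle`: list of rasters (matrices `nx` x `ny`,
#'   x along rows increasing, y along columns increasing) keyed
#'   `<variable id>@<timestamp>`, with grid metadata attached
#' @export
annotate_area <- function(request, datasets, cache = NULL) {
  area <- request$area
  if (is.null(area)) et_request_error("request has no area block")
  if (area$xmax <= area$xmin || area$ymax <= area$ymin)
    et_request_error("area corners form a zero-area rectangle")
  if (area$nx < 1 || area$ny < 1)
    et_request_error("pixel counts must be positive")
  vars_req <- request_variables(request)
  if (is.null(cache)) cache <- scene_cache()
  fetch <- cached_fetch(cache, memory_provider(datasets))
  crs <- as_crs(area$crs %||% "wgs84_lonlat")

  dx <- (area$xmax - area$xmin) / area$nx
  dy <- (area$ymax - area$ymin) / area$ny
  px <- area$xmin + (seq_len(area$nx) - 0.5) * dx
  py <- area$ymin + (seq_len(area$ny) - 0.5) * dy
  centers <- expand.grid(x = px, y = py)
  ll <- proj_inverse(centers$x, centers$y, crs)

  rasters <- list()
  for (vr in vars_req) {
    var <- datasets[[vr$id]]
    if (is.null(var)) et_request_error(sprintf("unknown variable '%s'", vr$id))
    tss <- if (var_has_axis(var, "t")) area$timestamps else NA_real_
    if (is.null(tss)) et_request_error("area request needs >= 1 timestamp")
    for (tk in tss) {
      vals <- vapply(seq_len(nrow(centers)), function(m) {
        as.numeric(annotate_point(var, ll$lon[m], ll$lat[m], tk,
                                  vr$method, fetch = fetch))
      }, 0)
      key <- paste0(vr$id, "@", if (is.na(tk)) "static" else
        format_epoch(tk))
      rasters[[key]] <- matrix(vals, nrow = area$nx)
    }
  }
  structure(rasters,
            class = "area_bundle",
            grid = list(xmin = area$xmin, ymin = area$ymin, dx = dx, dy = dy,
                        nx = area$nx, ny = area$ny, crs = crs),
            log = run_manifest(request = request, cache = cache,
                               n_missing = sum(vapply(rasters, function(r)
                                 sum(is.na(r)), 0)),
                               warnings = character()))
}

# Normalize the request argument to a list of list(id, method) entries.
request_variables <- function(request) {
  vars <- if (inherits(request, "annotation_request")) request$variables
          else request
  lapply(vars, function(v) {
    if (is.null(v$id)) et_request_error("request variable entry lacks an id")
    m <- v$method %||% interp_method()
    if (!inherits(m, "interp_method"))
      m <- do.call(interp_method, m)
    list(id = v$id, method = m)
  })
}
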