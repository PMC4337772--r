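# Request parsing, dataset manifests, and run logging.
#
# Requests and dataset manifests are YAML. A trajectory request names the
# variables to annotate and an interpolation method (spatial + temporal)
# per variable; an area request additionally gives the region corners,
# CRS, timestamps, and target pixel counts. Validation collects every
# failure, not just the first.

SPATIAL_METHODS <- c("nearest_neighbour", "bilinear", "inverse_distance_weighted")
TEMPORAL_METHODS <- c("nearest_neighbour", "inverse_distance_weighted")

#' Parse timestamps in the request format
#'
#' Accepts `"yyyy-MM-dd HH:mm:ss"` strings (single, vector, or one
#' comma-separated string), interpreted as UTC.
#'
#' @param x character timestamps
#' @return numeric UTC epoch seconds
#' @export
parse_timestamps <- function(x) {
  parts <- trimws(unlist(strsplit(as.character(x), ",")))
  out <- as.numeric(as.POSIXct(parts, tz = "UTC",
                               format = "%Y-%m-%d %H:%M:%S"))
  if (anyNA(out))
    et_validation_error(sprintf(
      "cannot parse timestamp(s): %s (expected yyyy-MM-dd HH:mm:ss)",
      paste(parts[is.na(out)], collapse = ", ")))
  out
}

format_epoch <- function(t)
  format(as.POSIXct(t, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ")

#' Parse and validate an annotation request
#'
#' Reads a YAML request (text or file path) into a validated
#' `annotation_request`. Defaults are filled (bilinear + temporal IDW,
#' Shepard power 2 in space and 1 in time, case-study segmentation
#' bands). All validation failures are collected and reported together.
#' When `datasets` is supplied, variable ids are checked against it and
#' categorical variables reject any method other than nearest neighbour.
#'
#' @param yaml_text YAML string or path to a YAML file
#' @param datasets optional named list of `grid_variable`s to validate
#'   against
#' @return an `annotation_request`
#' @export
parse_request <- function(yaml_text, datasets = NULL) {
  doc <- if (length(yaml_text) == 1 && file.exists(yaml_text))
    yaml::read_yaml(yaml_text) else yaml::yaml.load(yaml_text)
  if (!is.list(doc)) et_request_error("request is not a YAML mapping")
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)

  mode <- doc$mode %||% "trajectory"
  if (!mode %in% c("trajectory", "area"))
    note(sprintf("unknown mode '%s'", mode))

  variables <- lapply(seq_along(doc$variables %||% list()), function(i) {
    v <- doc$variables[[i]]
    if (is.character(v)) v <- list(id = v)
    if (is.null(v$id)) { note(sprintf("variable %d lacks an id", i)); return(NULL) }
    sp <- v$spatial %||% "bilinear"
    tm <- v$temporal %||% "inverse_distance_weighted"
    if (!sp %in% SPATIAL_METHODS)
      note(sprintf("variable '%s': unknown spatial method '%s'", v$id, sp))
    if (!tm %in% TEMPORAL_METHODS)
      note(sprintf("variable '%s': unknown temporal method '%s'", v$id, tm))
    if (!is.null(datasets)) {
      dv <- datasets[[v$id]]
      if (is.null(dv)) {
        note(sprintf("variable '%s' not present in the dataset manifest", v$id))
      } else if (dv$kind == "categorical" &&
                 (sp != "nearest_neighbour" || tm != "nearest_neighbour")) {
        note(sprintf(
          "variable '%s' is categorical: only the nearest neighbor interpolation can be applied",
          v$id))
      }
    }
    if (!sp %in% SPATIAL_METHODS || !tm %in% TEMPORAL_METHODS) return(NULL)
    list(id = v$id,
         method = interp_method(
           spatial = sp, temporal = tm,
           idw_power_space = v$idw_power_space %||% 2,
           idw_power_time = v$idw_power_time %||% 1,
           idw_k = v$idw_k %||% 4))
  })
  variables <- Filter(Negate(is.null), variables)

  area <- NULL
  if (mode == "area") {
    a <- doc$area
    if (is.null(a)) {
      note("area mode requires an 'area' block")
    } else {
      need <- c("xmin", "xmax", "ymin", "ymax", "nx", "ny")
      miss <- setdiff(need, names(a))
      if (length(miss))
        note(paste("area block missing:", paste(miss, collapse = ", ")))
      ts <- NULL
      if (!is.null(a$timestamps))
        ts <- tryCatch(parse_timestamps(a$timestamps),
                       envtrack_validation_error = function(e) {
                         note(conditionMessage(e)); NULL })
      if (!length(miss)) {
        if (a$nx < 1 || a$ny < 1) note("area pixel counts must be positive")
        area <- list(xmin = a$xmin, xmax = a$xmax, ymin = a$ymin,
                     ymax = a$ymax, nx = as.integer(a$nx),
                     ny = as.integer(a$ny), crs = a$crs %||% "wgs84_lonlat",
                     timestamps = ts)
      }
    }
  }

  seg <- doc$segmentation %||% list()
  segmentation <- list(
    speed_threshold = seg$speed_threshold %||% 5,
    transit_lon = unlist(seg$transit_lon %||% c(-90, -82.5)),
    coastal_lon = unlist(seg$coastal_lon %||% c(-82.5, -75)))

  if (length(errs))
    et_request_error(paste0("invalid annotation request:\n  - ",
                            paste(errs, collapse = "\n  - ")),
                     failures = errs)

  structure(list(mode = mode, variables = variables, area = area,
                 segmentation = segmentation),
            class = "annotation_request")
}

#' Load datasets declared in a YAML manifest
#'
#' The manifest declares, per variable: `id`, `kind`
#' (continuous/categorical), `crs` (name + parameters), optional `units`,
#' `missing_value` and `tile_shape`, and the scene files — ESRI ASCII
#' grids, one per timestamp (`scenes: [{time:, file:}, ...]`, or a single
#' `file:` for static variables). Paths are resolved relative to the
#' manifest.
#'
#' @param manifest_path path to the YAML dataset manifest
#' @return named list of `grid_variable`s
#' @export
load_datasets <- function(manifest_path) {
  doc <- yaml::read_yaml(manifest_path)
  base <- dirname(manifest_path)
  vars <- lapply(doc$variables, function(d) {
    if (is.null(d$id)) et_validation_error("manifest variable lacks an id")
    crs <- as_crs(d$crs %||% "wgs84_lonlat")
    scenes <- if (!is.null(d$scenes)) d$scenes else list(list(file = d$file))
    grids <- lapply(scenes, function(s)
      read_ascii_grid(file.path(base, s$file)))
    g1 <- grids[[1]]
    axes <- list(grid_axis("x", g1$x), grid_axis("y", g1$y))
    ts <- NULL
    if (!is.null(scenes[[1]]$time)) {
      ts <- parse_timestamps(vapply(scenes, `[[`, "", "time"))
      axes <- c(axes, list(grid_axis("t", ts)))
      values <- array(unlist(lapply(grids, `[[`, "values")),
                      dim = c(length(g1$x), length(g1$y), length(ts)))
    } else {
      values <- grids[[1]]$values
    }
    build_grid_variable(d$id, axes, values, crs = crs,
                        kind = d$kind %||% "continuous",
                        tile_shape = unlist(d$tile_shape),
                        units = d$units %||% "",
                        missing_value = d$missing_value)
  })
  setNames(vars, vapply(doc$variables, `[[`, "", "id"))
}

# Machine-readable run manifest attached to every annotation result.
run_manifest <- function(request, cache, n_missing, warnings) {
  list(tool = "envtrack",
       version = as.character(utils::packageVersion("envtrack")),
       mode = if (inherits(request, "annotation_request")) request$mode
              else "trajectory",
       variables = vapply(request_variables(request), function(v)
         annotation_column(v$id, v$method), ""),
       scenes = list(requested = cache$stats$hits + cache$stats$misses,
                     fetched = cache$stats$misses,
                     cache_hits = cache$stats$hits,
                     evictions = cache$stats$evictions),
       missing_annotations = n_missing,
       warnings = warnings)
}

#' Write the run manifest of an annotation result as JSON
#'
#' @param annotated result of [annotate_track()] or [annotate_area()]
#' @param path output JSON path
#' @return the path, invisibly
#' @export
write_run_manifest <- function(annotated, path) {
  log <- attr(annotated, "log")
  if (is.null(log)) et_validation_error("object carries no run manifest")
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
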