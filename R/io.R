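# File formats: Movebank-style track CSV, ESRI ASCII grids for scene
# payloads, TIFF + world file and KML ground overlays for area output.
#
# All formats are plain text except the TIFF rasters (32-bit float
# samples, georeferenced by an ESRI world file alongside).

MOVEBANK_COLS <- c(
  individual = "individual-local-identifier",
  timestamp = "timestamp",
  lon = "location-long",
  lat = "location-lat",
  alt = "height-above-ellipsoid"
)

#' Read a track CSV
#'
#' Accepts Movebank-style headers (`individual-local-identifier`,
#' `timestamp`, `location-long`, `location-lat`, optional
#' `height-above-ellipsoid`) or the package's internal names
#' (`individual`, `timestamp`, `lon`, `lat`, `alt`). Timestamps are
#' parsed as UTC (`yyyy-MM-dd HH:mm:ss`, with or without a `T`
#' separator).
#'
#' @param path CSV file path
#' @return a validated track data frame
#' @export
read_track_csv <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (internal in names(MOVEBANK_COLS)) {
    col <- if (MOVEBANK_COLS[[internal]] %in% names(raw))
      raw[[MOVEBANK_COLS[[internal]]]]
    else if (internal %in% names(raw)) raw[[internal]]
    else NULL
    if (!is.null(col)) out[[internal]] <- col
  }
  if (is.null(out$timestamp))
    et_validation_error("track CSV lacks a timestamp column")
  ts <- gsub("T", " ", out$timestamp)
  ts <- sub("Z$", "", ts)
  out$timestamp <- as.POSIXct(ts, tz = "UTC")
  if (anyNA(out$timestamp))
    et_validation_error("unparseable timestamps in track CSV")
  if (is.null(out$individual)) out$individual <- "track"
  validate_track(out)
}

#' Write a track (annotated or not) as CSV
#'
#' RFC 4180 CSV, UTF-8, ISO-8601 UTC timestamps.
#'
#' @param track track data frame
#' @param path output path
#' @return the path, invisibly
#' @export
write_track_csv <- function(track, path) {
  out <- track
  out$timestamp <- format(track$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' Supports `xllcenter`/`yllcenter` and `xllcorner`/`yllcorner`
#' registration. Values equal to `NODATA_value` become `NA`.
#'
#' @param path `.asc` file path
#' @return list with `x`, `y` (cell-center coordinate vectors, ascending)
#'   and `values` (matrix, x along rows increasing, y along columns
#'   increasing)
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  ncols <- hdr$ncols; nrows <- hdr$nrows; cs <- hdr$cellsize
  x0 <- hdr$xllcenter %||% (hdr$xllcorner + cs / 2)
  y0 <- hdr$yllcenter %||% (hdr$yllcorner + cs / 2)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != ncols * nrows)
    et_validation_error(sprintf("ASCII grid '%s': expected %d values, found %d",
                                path, ncols * nrows, length(vals)))
  if (!is.null(hdr$nodata_value)) vals[vals == hdr$nodata_value] <- NA
  # rows are written north to south; flip into ascending-y orientation
  m <- matrix(vals, nrow = ncols, ncol = nrows)[, nrows:1, drop = FALSE]
  list(x = x0 + (seq_len(ncols) - 1) * cs,
       y = y0 + (seq_len(nrows) - 1) * cs,
       values = m)
}

#' Write a matrix as an ESRI ASCII grid
#'
#' @param values matrix, x along rows increasing, y along columns
#'   increasing
#' @param x0,y0 cell-center coordinates of the lower-left cell
#' @param cellsize grid spacing
#' @param path output `.asc` path
#' @param nodata sentinel written for `NA` cells
#' @return the path, invisibly
#' @export
write_ascii_grid <- function(values, x0, y0, cellsize, path, nodata = -9999) {
  nc <- nrow(values); nr <- ncol(values)
  body <- apply(values[, nr:1, drop = FALSE], 2, function(col)
    paste(ifelse(is.na(col), nodata, col), collapse = " "))
  writeLines(c(
    sprintf("ncols %d", nc), sprintf("nrows %d", nr),
    sprintf("xllcenter %.10g", x0), sprintf("yllcenter %.10g", y0),
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %g", nodata),
    body), path)
  invisible(path)
}

#' Write a gridded variable's scenes as ASCII grids plus a manifest
#'
#' One `.asc` per timestamp (or a single file for static variables) and a
#' YAML manifest entry that [load_datasets()] reads back. Requires a
#' regular lon/lat or projected grid.
#'
#' @param vars named list of `grid_variable`s
#' @param dir output directory (created if needed)
#' @return the manifest path, invisibly
#' @export
write_field_ascii <- function(vars, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(vars, function(var) {
    ax <- var$axes
    if (is.null(ax$x$spacing) || is.null(ax$y$spacing))
      et_validation_error("ASCII export needs regular x and y axes")
    cs <- ax$x$spacing
    safe <- gsub("[^A-Za-z0-9_.-]", "_", var$id)
    entry <- list(id = var$id, kind = var$kind,
                  crs = c(list(name = var$crs$name),
                          var$crs[setdiff(names(var$crs), "name")]),
                  tile_shape = as.list(var$tile_shape))
    if (var_has_axis(var, "t")) {
      ts <- ax$t$coordinates
      entry$scenes <- lapply(seq_along(ts), function(k) {
        f <- sprintf("%s_t%03d.asc", safe, k)
        write_ascii_grid(var$values[, , k], ax$x$coordinates[1],
                         ax$y$coordinates[1], cs, file.path(dir, f))
        list(time = format(as.POSIXct(ts[k], origin = "1970-01-01", tz = "UTC"),
                           "%Y-%m-%d %H:%M:%S"),
             file = f)
      })
    } else {
      f <- paste0(safe, ".asc")
      write_ascii_grid(var$values, ax$x$coordinates[1], ax$y$coordinates[1],
                       cs, file.path(dir, f))
      entry$file <- f
    }
    entry
  })
  manifest <- file.path(dir, "datasets.yml")
  yaml::write_yaml(list(variables = unname(entries)), manifest)
  invisible(manifest)
}

#' Write an area bundle as TIFF rasters with world files
#'
#' One 32-bit TIFF per (variable, timestamp) raster, georeferenced by an
#' ESRI world file (`.tfw`) holding the edge-based affine transform.
#' Sample values are stored min/max-scaled to `[0, 1]`; the linear scale
#' (`value_min`, `value_max`) and the missing-cell mask are recorded in a
#' JSON sidecar, so `value = sample * (max - min) + min` reconstructs the
#' raster to 32-bit precision. Optionally a KML ground overlay (with a
#' PNG rendering) per raster for geographic-CRS bundles.
#'
#' @param bundle an `area_bundle` from [annotate_area()]
#' @param dir output directory
#' @param kml also write KML ground overlays (lon/lat bundles only)
#' @return character vector of files written, invisibly
#' @export
write_area_tiff <- function(bundle, dir, kml = FALSE) {
  g <- attr(bundle, "grid")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  for (key in names(bundle)) {
    safe <- gsub("[^A-Za-z0-9_.-]", "_", key)
    m <- bundle[[key]]
    rng <- range(m, finite = TRUE)
    span <- if (diff(rng) > 0) diff(rng) else 1
    norm <- (m - rng[1]) / span
    norm[!is.finite(norm)] <- 0
    # TIFF rows run north to south
    img <- t(norm[, ncol(norm):1, drop = FALSE])
    tif <- file.path(dir, paste0(safe, ".tif"))
    tiff::writeTIFF(img, tif, bits.per.sample = 32L, reduce = FALSE)
    # world file: pixel sizes and the CENTER of the upper-left pixel
    tfw <- file.path(dir, paste0(safe, ".tfw"))
    writeLines(sprintf("%.10f", c(g$dx, 0, 0, -g$dy,
                                  g$xmin + g$dx / 2,
                                  g$ymin + g$dy * (g$ny - 0.5))), tfw)
    meta <- file.path(dir, paste0(safe, ".meta.json"))
    jsonlite::write_json(
      list(layer = key, value_min = rng[1], value_max = rng[2],
           crs = g$crs$name, nx = g$nx, ny = g$ny,
           missing_cells = which(is.na(m)) - 1L),
      meta, auto_unbox = TRUE, digits = NA)
    written <- c(written, tif, tfw, meta)
    if (kml && g$crs$name == "wgs84_lonlat")
      written <- c(written, write_kml_overlay(m, g, key, dir, safe))
  }
  invisible(written)
}

# KML ground overlay: grayscale PNG + KML wrapper with the bounding box.
write_kml_overlay <- function(m, g, key, dir, safe) {
  rng <- range(m, na.rm = TRUE)
  norm <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
  norm[is.na(norm)] <- 0
  png_file <- file.path(dir, paste0(safe, ".png"))
  grDevices::png(png_file, width = nrow(m), height = ncol(m))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), norm,
                  col = grDevices::gray.colors(256, 0, 1),
                  axes = FALSE, xlab = "", ylab = "", useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  kml_file <- file.path(dir, paste0(safe, ".kml"))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<kml xmlns="http://www.opengis.net/kml/2.2"><GroundOverlay>',
    sprintf("  <name>%s</name>", key),
    sprintf("  <Icon><href>%s</href></Icon>", basename(png_file)),
    "  <LatLonBox>",
    sprintf("    <north>%.10f</north><south>%.10f</south>",
            g$ymin + g$ny * g$dy, g$ymin),
    sprintf("    <east>%.10f</east><west>%.10f</west>",
            g$xmin + g$nx * g$dx, g$xmin),
    "  </LatLonBox>",
    "</GroundOverlay></kml>"), kml_file)
  c(png_file, kml_file)
}
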