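#' Construct a slide tile
#'
#' A tile is a square RGB region cut from a digitized smear, carried together
#' with its provenance: the slide it came from and its 0-based pixel offset in
#' the slide frame (x rightward, y downward).
#'
#' @param pixels RGB array of shape (H, W, 3) with values in 0..255.
#' @param slide_id Character scalar.
#' @param origin Integer vector `c(x, y)`, non-negative.
#' @return An object of class `cyto_tile`.
#' @export
tile <- function(pixels, slide_id = "slide", origin = c(0L, 0L)) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (any(origin < 0)) stop("tile origin must be non-negative", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("tile pixel values must lie in [0, 255]", call. = FALSE)
  }
  structure(
    list(pixels = pixels, slide_id = slide_id,
         origin = as.integer(origin), size = dim(pixels)[1:2]),
    class = "cyto_tile"
  )
}

#' @export
print.cyto_tile <- function(x, ...) {
  cat(sprintf("<cyto_tile %s @(%d,%d) %dx%d>\n", x$slide_id,
              x$origin[1], x$origin[2], x$size[2], x$size[1]))
  invisible(x)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("cannot read raster: ", path, call. = FALSE)
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2) stop("raster is not RGB: ", path, call. = FALSE)
  if (dim(img)[3] >= 4) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3] != 3) stop("raster is not RGB: ", path, call. = FALSE)
  round(img * 255)
}

write_raster <- function(pixels, path) {
  png::writePNG(pixels / 255, path)
  invisible(path)
}

#' Cut a raster (or directory of rasters) into fixed-size tiles
#'
#' Tiles are produced in row-major order (x varies fastest) with the given
#' stride; partial tiles at the right/bottom edge are dropped, so an H x W
#' raster yields `floor((H - h)/s + 1) * floor((W - w)/s + 1)` tiles.
#'
#' @param source Path to a PNG/TIFF raster, a directory of such rasters, or an
#'   RGB array already in memory.
#' @param tile_size Tile side in pixels (default 512).
#' @param stride Step between tile origins in pixels (default `tile_size`).
#' @param slide_id Slide identifier; defaults to the file name.
#' @return List of [tile()] objects.
#' @export
read_tiles <- function(source, tile_size = 512L, stride = tile_size,
                       slide_id = NULL) {
  if (is.character(source) && length(source) == 1 && dir.exists(source)) {
    files <- sort(list.files(source, pattern = "\\.(png|tiff?)$",
                             ignore.case = TRUE, full.names = TRUE))
    return(purrr::flatten(purrr::map(files, read_tiles,
                                     tile_size = tile_size, stride = stride)))
  }
  if (is.character(source)) {
    pixels <- read_raster(source)
    slide_id <- slide_id %||% tools::file_path_sans_ext(basename(source))
  } else {
    pixels <- source
    slide_id <- slide_id %||% "slide"
  }
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  if (h < tile_size || w < tile_size) return(list())
  ys <- seq(0L, h - tile_size, by = stride)
  xs <- seq(0L, w - tile_size, by = stride)
  out <- list()
  for (y in ys) {
    for (x in xs) {
      out[[length(out) + 1]] <- tile(
        pixels[(y + 1):(y + tile_size), (x + 1):(x + tile_size), , drop = FALSE],
        slide_id = slide_id, origin = c(x, y))
    }
  }
  out
}

#' Construct a per-cell detection record
#'
#' @param cell_id,slide_id Identifiers.
#' @param cell_type `"WBC"` or `"RBC"`.
#' @param boundary n x 2 matrix of polygon vertices (open ring, 0-based slide
#'   pixel coordinates) with positive signed area.
#' @param nucleus_boundary Optional polygon for the nucleus (WBC only).
#' @param features Named numeric feature vector (42 for RBC, 53 for WBC), or
#'   NULL before feature extraction.
#' @return An object of class `cyto_cell`.
#' @export
cell_record <- function(cell_id, slide_id, cell_type, boundary,
                        nucleus_boundary = NULL, features = NULL) {
  cell_type <- match.arg(cell_type, c("WBC", "RBC"))
  boundary <- as.matrix(boundary)
  if (nrow(boundary) < 3) stop("boundary needs >= 3 vertices", call. = FALSE)
  if (polygon_area_signed(boundary) < 0) boundary <- boundary[nrow(boundary):1, ]
  if (!is.null(features)) {
    expected <- if (cell_type == "WBC") 53L else 42L
    if (length(features) != expected) {
      stop(sprintf("%s feature vector must have length %d, got %d",
                   cell_type, expected, length(features)), call. = FALSE)
    }
  }
  structure(
    list(cell_id = cell_id, slide_id = slide_id, cell_type = cell_type,
         boundary = boundary, nucleus_boundary = nucleus_boundary,
         features = features),
    class = "cyto_cell"
  )
}

#' Export detections as QuPath-compatible GeoJSON
#'
#' Writes a `FeatureCollection` with one closed-ring `Polygon` feature per
#' cell, properties `cell_type` and `cell_id`, coordinates in the slide pixel
#' frame. Suitable for overlay in QuPath and other GeoJSON viewers.
#'
#' @param cells List of [cell_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_qupath_geojson <- function(cells, path) {
  feats <- purrr::map(cells, function(cl) {
    if (!polygon_is_simple(cl$boundary)) {
      stop("self-intersecting boundary for cell ", cl$cell_id, call. = FALSE)
    }
    ring <- rbind(cl$boundary, cl$boundary[1, , drop = FALSE])
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(unname(apply(ring, 1, as.list,
                                                      simplify = FALSE)))),
      properties = list(cell_type = cl$cell_type, cell_id = cl$cell_id)
    )
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GeoJSON detection file back into cell records
#'
#' Inverse of [export_qupath_geojson()]; vertices and properties round-trip
#' exactly.
#'
#' @param path GeoJSON file path.
#' @param slide_id Slide id to attach to the records.
#' @return List of [cell_record()] objects (without features).
#' @export
read_qupath_geojson <- function(path, slide_id = "slide") {
  obj <- jsonlite::read_json(path)
  purrr::map(obj$features, function(f) {
    ring <- do.call(rbind, purrr::map(f$geometry$coordinates[[1]],
                                      ~ unlist(.x, use.names = FALSE)))
    cell_record(cell_id = f$properties$cell_id, slide_id = slide_id,
                cell_type = f$properties$cell_type,
                boundary = ring[-nrow(ring), , drop = FALSE])
  })
}

#' Write / read per-cell feature tables
#'
#' Feature tables hold one row per cell with `slide_id`, `cell_id`,
#' `cell_type` and the named feature columns. Both CSV and Parquet are
#' supported; round-trips are lossless. Mixed WBC/RBC tables are allowed on
#' disk; [split_feature_table()] partitions them back into the 53- and
#' 42-column schemas.
#'
#' @param x Tibble of cell features.
#' @param path Output path ending in `.csv` or `.parquet`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  mandatory <- c("slide_id", "cell_id", "cell_type")
  missing <- setdiff(mandatory, names(x))
  if (length(missing)) {
    stop("feature table missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = readr::write_csv(x, path),
    parquet = arrow::write_parquet(x, path),
    stop("unsupported table format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE),
    parquet = arrow::read_parquet(path),
    stop("unsupported table format: .", ext, call. = FALSE)
  )
  mandatory <- c("slide_id", "cell_id", "cell_type")
  missing <- setdiff(mandatory, names(x))
  if (length(missing)) {
    stop("feature table missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(x)
}

#' @rdname write_feature_table
#' @export
split_feature_table <- function(x) {
  wbc <- dplyr::filter(x, .data$cell_type == "WBC")
  rbc <- dplyr::filter(x, .data$cell_type == "RBC")
  drop_all_na <- function(df) {
    keep <- purrr::map_lgl(df, ~ !all(is.na(.x)))
    df[, keep, drop = FALSE]
  }
  list(wbc = drop_all_na(wbc), rbc = drop_all_na(rbc))
}

#' Read a YAML run configuration
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

# One-line structured log record; quiet unless option cytomorph.verbose is set.
log_stage <- function(stage, slide_id = NA_character_, ...) {
  if (!isTRUE(getOption("cytomorph.verbose", FALSE))) return(invisible(NULL))
  extras <- list(...)
  kv <- if (length(extras)) {
    paste(names(extras), unlist(extras), sep = "=", collapse = " ")
  } else ""
  message(sprintf("[%s] stage=%s slide=%s %s",
                  format(Sys.time(), "%H:%M:%S"), stage, slide_id, kv))
  invisible(NULL)
}
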