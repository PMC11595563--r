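#' Lightweight single-band raster layer
#'
#' A minimal in-memory raster: a numeric matrix with an affine transform
#' (origin, cell sizes), a nodata mask and a CRS tag. Rows run north to
#' south (row 1 is the top of the map), matching the ESRI ASCII grid
#' convention used for I/O.
#'
#' @param values numeric matrix of cell values.
#' @param transform numeric vector `c(x_origin, y_origin, cell_w, cell_h)`;
#'   the origin is the *lower-left* corner of the grid, cell sizes in map
#'   units (km in planar mode, degrees in geographic mode).
#' @param name layer name.
#' @param nodata_mask logical matrix, `TRUE` where the cell is invalid.
#' @param crs_tag free-text coordinate system tag, e.g. `"planar_km"` or
#'   `"EPSG:4326"`.
#' @return an object of class `raster_layer`.
#' @export
raster_layer <- function(values, transform, name = "layer",
                         nodata_mask = NULL, crs_tag = "planar_km") {
  values <- as.matrix(values)
  if (!is.numeric(transform) || length(transform) != 4L)
    stop_ps("transform must be c(x_origin, y_origin, cell_w, cell_h)")
  if (transform[3] <= 0 || transform[4] <= 0)
    stop_ps("cell sizes must be positive")
  if (is.null(nodata_mask)) nodata_mask <- is.na(values)
  nodata_mask <- as.matrix(nodata_mask) | is.na(values)
  if (!identical(dim(values), dim(nodata_mask)))
    stop_ps("values and nodata_mask must share shape")
  structure(
    list(name = name, values = values, transform = as.numeric(transform),
         nodata_mask = nodata_mask, crs_tag = crs_tag),
    class = "raster_layer"
  )
}

#' Stack of aligned raster layers
#'
#' @param layers list of [raster_layer()] objects sharing shape, transform
#'   and CRS tag; names taken from the layers.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(length(layers) >= 1L)
  ref <- layers[[1]]
  for (l in layers) {
    if (!inherits(l, "raster_layer")) stop_ps("all elements must be raster_layer")
    if (!identical(dim(l$values), dim(ref$values)) ||
        !isTRUE(all.equal(l$transform, ref$transform)) ||
        !identical(l$crs_tag, ref$crs_tag))
      stop_ps("layers must share shape, transform and crs_tag")
  }
  nms <- vapply(layers, function(l) l$name, character(1))
  if (anyDuplicated(nms)) stop_ps("layer names must be unique")
  names(layers) <- nms
  structure(list(layers = layers), class = "raster_stack")
}

#' @export
print.raster_layer <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_layer '%s'> %d x %d cells, cell %.4g x %.4g, %s\n",
              x$name, d[1], d[2], x$transform[3], x$transform[4], x$crs_tag))
  v <- x$values[!x$nodata_mask]
  if (length(v)) cat(sprintf("  range [%.4g, %.4g], %d nodata cells\n",
                             min(v), max(v), sum(x$nodata_mask)))
  invisible(x)
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("<raster_stack> %d layers: %s\n", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

n_valid_cells <- function(layer) sum(!layer$nodata_mask)

#' Cell-centre coordinates of every grid cell
#'
#' @param layer a [raster_layer()].
#' @return data.frame with columns `x`, `y`, `row`, `col` (row 1 = top).
#' @export
cell_centers <- function(layer) {
  d <- dim(layer$values)
  tr <- layer$transform
  top <- tr[2] + d[1] * tr[4]                 # y of the grid's top edge
  rows <- rep(seq_len(d[1]), times = d[2])
  cols <- rep(seq_len(d[2]), each = d[1])
  data.frame(
    x = tr[1] + (cols - 0.5) * tr[3],
    y = top - (rows - 0.5) * tr[4],
    row = rows, col = cols
  )
}

#' Map x/y points to raster row/col indices
#'
#' Cells are half-open: a point on a cell's lower/left edge belongs to it.
#'
#' @param layer a [raster_layer()].
#' @param x,y point coordinates in the layer's units.
#' @return data.frame with columns `row`, `col` (NA when outside the grid).
#' @export
point_to_cell <- function(layer, x, y) {
  d <- dim(layer$values)
  tr <- layer$transform
  col <- as.integer(floor((x - tr[1]) / tr[3])) + 1L
  top <- tr[2] + d[1] * tr[4]
  # half-open cells, lower edge inclusive: y in [bottom, bottom + h)
  row <- d[1] - as.integer(floor((y - tr[2]) / tr[4]))
  # points exactly on the top edge fall in row 1
  row[y == top] <- 1L
  bad <- row < 1L | row > d[1] | col < 1L | col > d[2]
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

#' Extract layer values at point locations
#'
#' @param obj a [raster_layer()] or [raster_stack()].
#' @param x,y point coordinates.
#' @return numeric vector (layer) or matrix with one column per layer
#'   (stack); NA outside the grid or on nodata cells.
#' @export
extract_values <- function(obj, x, y) {
  if (inherits(obj, "raster_stack")) {
    out <- sapply(obj$layers, function(l) extract_values(l, x, y))
    if (is.null(dim(out))) out <- matrix(out, nrow = length(x),
                                         dimnames = list(NULL, names(obj$layers)))
    return(out)
  }
  rc <- point_to_cell(obj, x, y)
  idx <- cbind(rc$row, rc$col)
  v <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  v[ok] <- obj$values[idx[ok, , drop = FALSE]]
  v[ok][obj$nodata_mask[idx[ok, , drop = FALSE]]] <- NA_real_
  v
}

#' Pearson correlation between two aligned raster layers
#'
#' Computed over the cells that are valid in both layers, as in whole-layer
#' comparisons of candidate environmental predictors.
#'
#' @param layer_a,layer_b aligned [raster_layer()] objects.
#' @return sample Pearson r in `[-1, 1]`.
#' @export
pearson_r <- function(layer_a, layer_b) {
  if (!identical(dim(layer_a$values), dim(layer_b$values)))
    stop_ps("layers are not aligned")
  ok <- !layer_a$nodata_mask & !layer_b$nodata_mask
  if (sum(ok) < 3L) stop_ps("need at least 3 jointly valid cells")
  a <- layer_a$values[ok]; b <- layer_b$values[ok]
  if (stats::sd(a) == 0) stop_ps("constant layer: '%s' has zero variance", layer_a$name)
  if (stats::sd(b) == 0) stop_ps("constant layer: '%s' has zero variance", layer_b$name)
  stats::cor(a, b)
}

#' Rasterise host-plant occurrence points as per-cell counts
#'
#' Counts the number of points falling in each cell of a template grid.
#' Cells of the valid domain containing no point are 0, not nodata.
#'
#' @param points data.frame with columns `lon`, `lat` (x and y in planar
#'   mode); may have zero rows.
#' @param template a [raster_layer()] defining the grid and valid domain.
#' @param name name of the returned layer.
#' @return a [raster_layer()] of counts.
#' @export
host_counts_to_raster <- function(points, template, name = "host_plant") {
  counts <- matrix(0, nrow(template$values), ncol(template$values))
  if (NROW(points) > 0) {
    rc <- point_to_cell(template, points$lon, points$lat)
    ok <- !is.na(rc$row)
    for (i in which(ok)) {
      counts[rc$row[i], rc$col[i]] <- counts[rc$row[i], rc$col[i]] + 1
    }
  }
  counts[template$nodata_mask] <- NA_real_
  raster_layer(counts, template$transform, name = name,
               nodata_mask = template$nodata_mask, crs_tag = template$crs_tag)
}

#' Write a raster layer as an ESRI ASCII grid
#'
#' @param layer a [raster_layer()]; must be square-celled (the format
#'   carries a single cell size).
#' @param path output file path.
#' @param nodata_value value written for nodata cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(layer, path, nodata_value = -9999) {
  tr <- layer$transform
  if (abs(tr[3] - tr[4]) > 1e-9 * tr[3])
    stop_ps("ESRI ASCII grids require square cells")
  v <- layer$values
  v[layer$nodata_mask] <- nodata_value
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", tr[1]),
    sprintf("yllcorner %.10g", tr[2]),
    sprintf("cellsize %.10g", tr[3]),
    sprintf("NODATA_value %.10g", nodata_value)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(v, trim = TRUE, digits = 15), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file path.
#' @param name layer name to assign.
#' @param crs_tag CRS tag to assign.
#' @return a [raster_layer()].
#' @export
read_ascii_grid <- function(path, name = NULL, crs_tag = "planar_km") {
  lines <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  hdr <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  body <- utils::read.table(path, skip = 6L)
  v <- as.matrix(body)
  dimnames(v) <- NULL
  if (nrow(v) != hdr["nrows"] || ncol(v) != hdr["ncols"])
    stop_ps("grid body does not match header dimensions")
  mask <- v == hdr["nodata_value"]
  v[mask] <- NA_real_
  raster_layer(v, c(hdr["xllcorner"], hdr["yllcorner"],
                    hdr["cellsize"], hdr["cellsize"]),
               name = name %||% sub("\\.[^.]*$", "", basename(path)),
               nodata_mask = mask, crs_tag = crs_tag)
}
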