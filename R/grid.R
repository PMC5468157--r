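#' Raster grid data model
#'
#' A `habgrid` is a single-band raster on a projected equal-area grid: a
#' numeric matrix (rows run north to south, columns west to east), a cell
#' size in km, and the coordinates of the outer (north-west) corner of the
#' top-left cell. Nodata cells are `NA` in `values`. All layers entering the
#' pipeline must share one geometry; nothing is ever resampled silently.
#'
#' @param values numeric matrix; `NA` marks nodata.
#' @param cell_size_km positive cell edge length in km (cell area is its
#'   square).
#' @param origin_xy length-2 numeric, the projected (x, y) of the outer
#'   top-left corner, in km.
#' @param layer_name character scalar naming the layer.
#' @return An object of class `habgrid`.
#' @export
habgrid <- function(values, cell_size_km = 1, origin_xy = c(0, 0),
                    layer_name = "layer") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size_km) || length(cell_size_km) != 1 ||
      !is.finite(cell_size_km) || cell_size_km <= 0) {
    stop("cell_size_km must be a single positive number", call. = FALSE)
  }
  if (length(origin_xy) != 2 || !all(is.finite(origin_xy))) {
    stop("origin_xy must be two finite coordinates", call. = FALSE)
  }
  structure(
    list(values = values, cell_size_km = as.numeric(cell_size_km),
         origin_xy = as.numeric(origin_xy),
         layer_name = as.character(layer_name)[1]),
    class = "habgrid"
  )
}

#' @export
print.habgrid <- function(x, ...) {
  cat(sprintf("<habgrid> '%s': %d x %d cells of %g km, origin (%g, %g), %d nodata\n",
              x$layer_name, nrow(x$values), ncol(x$values), x$cell_size_km,
              x$origin_xy[1], x$origin_xy[2], sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.habgrid <- function(x) dim(x$values)

#' Geometry descriptor of a grid
#'
#' @param g a `habgrid` or `habstack`.
#' @return list with `n_rows`, `n_cols`, `cell_size_km`, `origin_xy`.
#' @export
grid_geometry <- function(g) {
  if (inherits(g, "habstack")) g <- g$layers[[1]]
  list(n_rows = nrow(g$values), n_cols = ncol(g$values),
       cell_size_km = g$cell_size_km, origin_xy = g$origin_xy)
}

#' Validity (non-nodata) mask of a grid
#' @param g a `habgrid`.
#' @return logical matrix, `TRUE` where the cell carries data.
#' @export
valid_mask <- function(g) !is.na(g$values)

#' Area of a boolean mask in km^2
#'
#' Exactly `sum(mask) * cell_size_km^2`; all areas in the pipeline are cell
#' multiples, so two grids agreeing cellwise agree in area exactly.
#'
#' @param mask logical matrix (or `habgrid` whose values are 0/1).
#' @param cell_size_km cell edge in km; taken from the grid if one is given.
#' @return numeric area in km^2.
#' @export
area_km2 <- function(mask, cell_size_km = 1) {
  if (inherits(mask, "habgrid")) {
    cell_size_km <- mask$cell_size_km
    mask <- !is.na(mask$values) & mask$values != 0
  }
  sum(mask, na.rm = TRUE) * cell_size_km^2
}

#' Named stack of aligned grids
#'
#' @param layers named list of `habgrid` objects sharing one geometry.
#' @return object of class `habstack`; `$geometry` is the shared descriptor.
#' @export
habstack <- function(layers) {
  if (length(layers) == 0) stop("empty stack", call. = FALSE)
  if (is.null(names(layers)) || any(names(layers) == "")) {
    names(layers) <- vapply(layers, function(g) g$layer_name, character(1))
  }
  st <- structure(list(layers = layers, geometry = NULL), class = "habstack")
  st$geometry <- assert_aligned(st)
  st
}

#' @export
print.habstack <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("<habstack> %d layers on %d x %d @ %g km: %s\n",
              length(x$layers), g$n_rows, g$n_cols, g$cell_size_km,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Assert that all layers of a stack share one geometry
#'
#' Shape must match exactly; cell size and origin may differ by a relative
#' tolerance of 1e-6 (absolute for origins within a cell of zero).
#'
#' @param stack a `habstack`, or a named list of `habgrid`s.
#' @return the shared geometry descriptor, invisibly usable downstream.
#' @export
assert_aligned <- function(stack) {
  layers <- if (inherits(stack, "habstack")) stack$layers else stack
  if (length(layers) == 0) stop("empty stack", call. = FALSE)
  ref <- layers[[1]]
  tol <- 1e-6
  for (i in seq_along(layers)) {
    g <- layers[[i]]
    nm <- names(layers)[i]
    if (is.null(nm) || is.na(nm) || nm == "") nm <- g$layer_name
    if (!identical(dim(g$values), dim(ref$values))) {
      stop(sprintf("layer '%s' misaligned: shape %dx%d vs %dx%d", nm,
                   nrow(g$values), ncol(g$values),
                   nrow(ref$values), ncol(ref$values)), call. = FALSE)
    }
    if (abs(g$cell_size_km - ref$cell_size_km) >
        tol * max(abs(ref$cell_size_km), 1e-12)) {
      stop(sprintf("layer '%s' misaligned: cell size %g vs %g", nm,
                   g$cell_size_km, ref$cell_size_km), call. = FALSE)
    }
    scale <- max(abs(ref$origin_xy), ref$cell_size_km)
    if (any(abs(g$origin_xy - ref$origin_xy) > tol * scale)) {
      stop(sprintf("layer '%s' misaligned: origin (%g, %g) vs (%g, %g)", nm,
                   g$origin_xy[1], g$origin_xy[2],
                   ref$origin_xy[1], ref$origin_xy[2]), call. = FALSE)
    }
  }
  grid_geometry(ref)
}

#' Locate points in grid cells
#'
#' Half-open cell convention: a point on a cell's north or west edge belongs
#' to that cell; a point on the extent's east or south outer edge is outside.
#' Indices are 1-based, row 1 at the north, column 1 at the west.
#'
#' @param xy two-column matrix (or data.frame) of projected point
#'   coordinates, km.
#' @param geom geometry descriptor from [grid_geometry()].
#' @return data.frame with integer `row`, `col` (NA when outside) and
#'   logical `inside`.
#' @export
cell_of <- function(xy, geom) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  cs <- geom$cell_size_km
  col <- floor((xy[, 1] - geom$origin_xy[1]) / cs) + 1L
  row <- floor((geom$origin_xy[2] - xy[, 2]) / cs) + 1L
  inside <- row >= 1L & row <= geom$n_rows & col >= 1L & col <= geom$n_cols
  row[!inside] <- NA_integer_
  col[!inside] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Coordinates of cell centers
#'
#' @param row,col 1-based cell indices.
#' @param geom geometry descriptor.
#' @return two-column matrix of (x, y) center coordinates in km.
#' @export
cell_center <- function(row, col, geom) {
  cs <- geom$cell_size_km
  cbind(x = geom$origin_xy[1] + (col - 0.5) * cs,
        y = geom$origin_xy[2] - (row - 0.5) * cs)
}

#' Extract layer values at points
#'
#' @param stack a `habstack`.
#' @param xy two-column matrix of point coordinates.
#' @return data.frame, one column per layer; rows for points outside the
#'   extent (or on nodata) carry `NA`.
#' @export
extract_at <- function(stack, xy) {
  geom <- stack$geometry
  rc <- cell_of(xy, geom)
  idx <- ifelse(rc$inside, (rc$col - 1L) * geom$n_rows + rc$row, NA_integer_)
  out <- lapply(stack$layers, function(g) g$values[idx])
  as.data.frame(out, optional = TRUE)
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------

#' Read an ESRI ASCII grid
#'
#' Honors the header keywords ncols, nrows, xllcorner/xllcenter,
#' yllcorner/yllcenter, cellsize and NODATA_value case-insensitively. Header
#' coordinates are interpreted in km (the pipeline's working unit); the
#' stored origin is the outer top-left corner, i.e. the lower-left corner
#' shifted north by `nrows * cellsize`.
#'
#' @param path file path to a `.asc` grid.
#' @param layer_name layer name; defaults to the file name without extension.
#' @return a [habgrid()].
#' @export
read_asc <- function(path, layer_name = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(tok) == 2 && grepl("^[a-zA-Z]", tok[1])) {
      hdr[[tolower(tok[1])]] <- suppressWarnings(as.numeric(tok[2]))
      n_hdr <- n_hdr + 1L
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  for (k in need) {
    if (is.null(hdr[[k]]) || is.na(hdr[[k]])) {
      stop(sprintf("malformed ASCII grid header in %s: missing or bad '%s'",
                   path, k), call. = FALSE)
    }
  }
  if (!is.null(hdr$xllcorner)) xll <- hdr$xllcorner
  else if (!is.null(hdr$xllcenter)) xll <- hdr$xllcenter - hdr$cellsize / 2
  else stop(sprintf("malformed ASCII grid header in %s: missing 'xllcorner'",
                    path), call. = FALSE)
  if (!is.null(hdr$yllcorner)) yll <- hdr$yllcorner
  else if (!is.null(hdr$yllcenter)) yll <- hdr$yllcenter - hdr$cellsize / 2
  else stop(sprintf("malformed ASCII grid header in %s: missing 'yllcorner'",
                    path), call. = FALSE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else NA_real_
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  body <- paste(lines[(n_hdr + 1L):length(lines)], collapse = " ")
  vals <- scan(text = body, what = double(), quiet = TRUE)
  if (length(vals) != nr * nc) {
    stop(sprintf("ASCII grid %s: expected %d values, found %d", path,
                 nr * nc, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  if (is.null(layer_name)) layer_name <- sub("\\.[^.]*$", "", basename(path))
  habgrid(m, cell_size_km = hdr$cellsize,
          origin_xy = c(xll, yll + nr * hdr$cellsize),
          layer_name = layer_name)
}

#' Write an ESRI ASCII grid
#'
#' Values are written at full double precision so that
#' `read_asc(write_asc(g))` round-trips bit-exactly, including nodata
#' placement.
#'
#' @param g a `habgrid`.
#' @param path output file path.
#' @param nodata_value number standing in for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(g, path, nodata_value = -9999) {
  m <- g$values
  nr <- nrow(m); nc <- ncol(m)
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.17g", g$origin_xy[1]),
    sprintf("yllcorner %.17g", g$origin_xy[2] - nr * g$cell_size_km),
    sprintf("cellsize %.17g", g$cell_size_km),
    sprintf("NODATA_value %.17g", nodata_value)
  )
  m[is.na(m)] <- nodata_value
  rows <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read occurrence or background points from CSV
#'
#' @param path CSV with header columns `x,y` (extra columns ignored).
#' @return data.frame with numeric `x`, `y`.
#' @export
read_points_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) {
    stop(sprintf("%s: point CSV must have columns 'x' and 'y'", path),
         call. = FALSE)
  }
  data.frame(x = as.numeric(df$x), y = as.numeric(df$y))
}

#' Write points to CSV with header `x,y`
#' @param pts data.frame with `x`, `y`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points_csv <- function(pts, path) {
  utils::write.csv(pts[, c("x", "y")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
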