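#' Minimal aligned raster grid
#'
#' Lightweight grid geometry shared by every raster in an analysis. The grid
#' is regular, axis-aligned, with `x` increasing eastward and `y` increasing
#' northward; matrix row 1 is the northernmost row (the usual raster layout).
#'
#' @param nrow,ncol grid dimensions in cells.
#' @param xmin,ymin coordinates of the lower-left corner.
#' @param cellsize cell edge length (degrees for geographic grids, km for
#'   planar working grids).
#' @param crs free-text note: `"lonlat"` (default) or `"planar_km"`.
#' @return an `env_grid` object.
#' @export
env_grid <- function(nrow, ncol, xmin = 0, ymin = 0, cellsize = 1,
                     crs = "lonlat") {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         xmin = xmin, ymin = ymin, cellsize = cellsize, crs = crs),
    class = "env_grid")
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("<env_grid> %d x %d cells, cellsize %g (%s), origin (%g, %g)\n",
              x$nrow, x$ncol, x$cellsize, x$crs, x$xmin, x$ymin))
  invisible(x)
}

n_cells <- function(grid) grid$nrow * grid$ncol

#' Cell-centre coordinates of every cell (column-major order, matching
#' `as.vector()` on a layer matrix).
#' @param grid an `env_grid`.
#' @return list with numeric vectors `x` and `y`.
#' @export
cell_centers <- function(grid) {
  row <- rep(seq_len(grid$nrow), times = grid$ncol)
  col <- rep(seq_len(grid$ncol), each = grid$nrow)
  list(x = grid$xmin + (col - 0.5) * grid$cellsize,
       y = grid$ymin + (grid$nrow - row + 0.5) * grid$cellsize)
}

#' Locate points on a grid
#'
#' @param grid an `env_grid`.
#' @param x,y point coordinates.
#' @return integer vector of column-major cell indices; `NA` off-grid.
#' @export
cell_from_xy <- function(grid, x, y) {
  col <- floor((x - grid$xmin) / grid$cellsize) + 1L
  row <- grid$nrow - floor((y - grid$ymin) / grid$cellsize)
  # points exactly on the top/right edge belong to the edge cell
  col[x == grid$xmin + grid$ncol * grid$cellsize] <- grid$ncol
  row[y == grid$ymin + grid$nrow * grid$cellsize] <- 1L
  bad <- col < 1L | col > grid$ncol | row < 1L | row > grid$nrow |
    is.na(x) | is.na(y)
  col[bad] <- 1; row[bad] <- 1
  idx <- as.integer((col - 1) * grid$nrow + row)
  idx[bad] <- NA_integer_
  idx
}

#' Multi-layer environmental raster stack
#'
#' Named list of aligned numeric matrices plus a shared validity mask.
#' All layers must share the grid; cells where `mask` is `FALSE` are nodata.
#'
#' @param layers named list of numeric matrices (`grid$nrow` x `grid$ncol`).
#' @param grid an `env_grid`.
#' @param mask logical matrix, `TRUE` = valid. Default: all valid.
#' @return an `env_stack` object.
#' @export
env_stack <- function(layers, grid, mask = NULL) {
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("layers must be uniquely named")
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || nrow(m) != grid$nrow || ncol(m) != grid$ncol)
      stop("layer '", nm, "' does not match the grid")
  }
  if (is.null(mask)) mask <- matrix(TRUE, grid$nrow, grid$ncol)
  stopifnot(is.logical(mask), nrow(mask) == grid$nrow, ncol(mask) == grid$ncol)
  structure(list(layers = layers, grid = grid, mask = mask),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layer(s) [%s] on ", length(x$layers),
              paste(names(x$layers), collapse = ", ")))
  print(x$grid)
  invisible(x)
}

#' Extract layer values at point locations
#'
#' @param env an `env_stack`.
#' @param x,y point coordinates (same system as the grid).
#' @param layers layer names to extract; default all.
#' @return data.frame, one column per layer; `NA` for off-grid/nodata points.
#' @export
extract_env <- function(env, x, y, layers = names(env$layers)) {
  idx <- cell_from_xy(env$grid, x, y)
  valid <- !is.na(idx) & as.vector(env$mask)[ifelse(is.na(idx), 1L, idx)]
  out <- lapply(layers, function(nm) {
    v <- rep(NA_real_, length(idx))
    v[valid] <- env$layers[[nm]][idx[valid]]
    v
  })
  names(out) <- layers
  as.data.frame(out, optional = TRUE)
}

#' Write a layer as an ESRI ASCII grid
#'
#' Plain-text raster interchange format (`.asc`), readable by standard GIS
#' software. Nodata cells are written as `-9999`.
#'
#' @param mat numeric matrix (row 1 = north).
#' @param grid an `env_grid`.
#' @param path output file.
#' @param mask optional logical validity matrix.
#' @export
write_esri_ascii <- function(mat, grid, path, mask = NULL) {
  if (!is.null(mask)) mat[!mask] <- NA
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncol),
    sprintf("nrows %d", grid$nrow),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$cellsize),
    "NODATA_value -9999"), con)
  m <- mat
  m[is.na(m)] <- -9999
  writeLines(apply(m, 1L, function(r) paste(format(r, trim = TRUE,
                                                   digits = 10),
                                            collapse = " ")), con)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path `.asc` file.
#' @param crs coordinate-system note to attach.
#' @return list with `values` (matrix, `NA` at nodata), `grid`, `mask`.
#' @export
read_esri_ascii <- function(path, crs = "lonlat") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA
  grid <- env_grid(nr, nc, hdr$xllcorner, hdr$yllcorner, hdr$cellsize, crs)
  list(values = m, grid = grid, mask = !is.na(m))
}

#' Write an `env_stack` to a directory of ESRI ASCII grids
#' @param env an `env_stack`.
#' @param dir output directory (created if absent).
#' @return invisibly, the files written.
#' @export
write_env_stack <- function(env, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(env$layers), function(nm) {
    write_esri_ascii(env$layers[[nm]], env$grid,
                     file.path(dir, paste0(nm, ".asc")), env$mask)
  }, character(1))
  invisible(paths)
}

#' Read a directory of ESRI ASCII grids into an `env_stack`
#' @param dir directory of `.asc` files (layer name = file name).
#' @param crs coordinate-system note.
#' @export
read_env_stack <- function(dir, crs = "lonlat") {
  files <- sort(list.files(dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(files)) stop("no .asc layers found in ", dir)
  parsed <- lapply(files, read_esri_ascii, crs = crs)
  grid <- parsed[[1]]$grid
  mask <- Reduce(`&`, lapply(parsed, `[[`, "mask"))
  layers <- lapply(parsed, `[[`, "values")
  names(layers) <- sub("\\.asc$", "", basename(files))
  env_stack(layers, grid, mask)
}

#' Great-circle distance in km (haversine, WGS84 mean radius)
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorised).
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

# deterministic per-stage seed derived from a global seed (kept < 2^31)
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 7919 + h) %% 2147483647)
}
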