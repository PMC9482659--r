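#' Regular lon/lat grid specification
#'
#' Defines the rectangular grid on which all climate layers, masks and
#' species ranges live. Cells are indexed 1..`n_rows * n_cols` in row-major
#' order (cell 1 is the top-left / north-west corner). `origin` is the
#' outer corner of cell (1,1): longitudes increase with column, latitudes
#' decrease with row.
#'
#' @param n_rows,n_cols grid dimensions; both must be at least 8.
#' @param cell_size cell edge length in decimal degrees.
#' @param origin length-2 numeric, `c(lon, lat)` of the outer (NW) corner.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 0.5, origin = c(-100, 30)) {
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L)
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 8L || n_cols < 8L)
    stop("grid must be at least 8 x 8 cells")
  if (!is.numeric(cell_size) || cell_size <= 0)
    stop("cell_size must be a positive number of degrees")
  if (length(origin) != 2L)
    stop("origin must be c(lon, lat)")
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         cell_size = as.numeric(cell_size),
         origin = as.numeric(origin)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g deg, NW corner (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2]))
  invisible(x)
}

#' Number of cells in a grid
#' @param grid a [grid_spec()].
#' @return integer cell count.
#' @export
n_cells <- function(grid) grid$n_rows * grid$n_cols

#' Convert cell indices to (row, col)
#' @param grid a [grid_spec()].
#' @param cells integer cell indices.
#' @return two-column integer matrix `row`, `col`.
#' @export
cell_rowcol <- function(grid, cells) {
  stopifnot(all(cells >= 1L), all(cells <= n_cells(grid)))
  cells <- as.integer(cells)
  row <- (cells - 1L) %/% grid$n_cols + 1L
  col <- (cells - 1L) %% grid$n_cols + 1L
  cbind(row = row, col = col)
}

#' Convert (row, col) to cell indices
#' @param grid a [grid_spec()].
#' @param row,col integer vectors.
#' @return integer cell indices.
#' @export
rowcol_cell <- function(grid, row, col) {
  stopifnot(all(row >= 1L), all(row <= grid$n_rows),
            all(col >= 1L), all(col <= grid$n_cols))
  as.integer((row - 1L) * grid$n_cols + col)
}

#' Cell centers in lon/lat
#' @param grid a [grid_spec()].
#' @param cells integer cell indices (default all).
#' @return data.frame with `cell`, `lon`, `lat`.
#' @export
cell_center <- function(grid, cells = seq_len(n_cells(grid))) {
  rc <- cell_rowcol(grid, cells)
  data.frame(
    cell = as.integer(cells),
    lon = grid$origin[1] + (rc[, "col"] - 0.5) * grid$cell_size,
    lat = grid$origin[2] - (rc[, "row"] - 0.5) * grid$cell_size)
}

#' Snap lon/lat coordinates to grid cells
#'
#' Points outside the grid extent yield `NA`.
#'
#' @param grid a [grid_spec()].
#' @param lon,lat numeric coordinate vectors.
#' @return integer cell indices (with `NA` for out-of-extent points).
#' @export
lonlat_to_cell <- function(grid, lon, lat) {
  col <- floor((lon - grid$origin[1]) / grid$cell_size) + 1
  row <- floor((grid$origin[2] - lat) / grid$cell_size) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  out <- rep(NA_integer_, length(lon))
  out[ok] <- rowcol_cell(grid, as.integer(row[ok]), as.integer(col[ok]))
  out
}

#' Dilate a cell set by a Chebyshev radius
#'
#' Morphological dilation on the grid: the result contains every cell within
#' Chebyshev (chessboard) distance `radius` of the input set, clipped to the
#' grid. Used for the endemicity buffer, the accessible-area (M) buffer and
#' the projected-M buffer, with degree buffers converted to whole cells by
#' ceiling.
#'
#' @param grid a [grid_spec()].
#' @param cells integer cell indices.
#' @param radius non-negative integer radius in cells.
#' @return sorted integer cell indices of the dilated set.
#' @export
dilate_cells <- function(grid, cells, radius) {
  radius <- as.integer(radius)
  stopifnot(radius >= 0L)
  if (length(cells) == 0L) return(integer(0))
  if (radius == 0L) return(sort(unique(as.integer(cells))))
  # beyond these radii the dilation saturates at the full grid extent
  radius_r <- min(radius, grid$n_rows - 1L)
  radius_c <- min(radius, grid$n_cols - 1L)
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  rc <- cell_rowcol(grid, cells)
  m[cbind(rc[, "row"], rc[, "col"])] <- TRUE
  out <- matrix(FALSE, grid$n_rows, grid$n_cols)
  for (dr in -radius_r:radius_r) {
    r_src <- max(1L, 1L - dr):min(grid$n_rows, grid$n_rows - dr)
    r_dst <- r_src + dr
    for (dc in -radius_c:radius_c) {
      c_src <- max(1L, 1L - dc):min(grid$n_cols, grid$n_cols - dc)
      c_dst <- c_src + dc
      out[r_dst, c_dst] <- out[r_dst, c_dst] | m[r_src, c_src]
    }
  }
  idx <- which(t(out))  # t(): which() is column-major, cells are row-major
  sort(idx)
}

#' Degrees to whole-cell buffer radius
#'
#' Converts a buffer in decimal degrees to a cell radius by ceiling, so a
#' buffer is never rounded away (conservative inclusion).
#'
#' @param grid a [grid_spec()].
#' @param buffer_deg buffer width in degrees.
#' @return non-negative integer radius in cells.
#' @export
buffer_cells <- function(grid, buffer_deg) {
  stopifnot(buffer_deg >= 0)
  as.integer(ceiling(buffer_deg / grid$cell_size - 1e-9))
}
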