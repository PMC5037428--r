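#' Regular raster lattice
#'
#' A `lattice_grid` describes a regular planar lattice of square cells: the
#' universal carrier for every mapped variable in the pipeline (suitability,
#' accessibility, climate, topography, richness). Coordinates are planar
#' kilometres; the cylindrical-equal-area projection step used to obtain such
#' a grid from geographic data is treated as preprocessing and is out of
#' scope here.
#'
#' Cell indexing is row-major and 0-based with row 0 at the top of the grid.
#' The centre of the cell in (0-based) row `i`, column `j` is at
#' `(x_origin + (j + 0.5) * cell_size, y_origin + (i + 0.5) * cell_size)`;
#' the y axis therefore points "down" the grid, which leaves all distances
#' unaffected.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @param cell_size cell edge length in km (> 0).
#' @param x_origin,y_origin planar coordinates (km) of the grid's top-left
#'   corner.
#' @param land_fraction per-cell fraction of land in `[0, 1]`; either a
#'   single value recycled to all cells or an `n_rows x n_cols` matrix.
#' @return an object of class `lattice_grid`.
#' @seealso [surface()], [land_filter()], [cell_centers()]
#' @export
lattice_grid <- function(n_rows, n_cols, cell_size = 10,
                         x_origin = 0, y_origin = 0, land_fraction = 1) {
  stopifnot(length(n_rows) == 1L, length(n_cols) == 1L)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L)
    stop("n_rows and n_cols must be >= 1")
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive length (km)")
  if (is.matrix(land_fraction)) {
    if (!identical(dim(land_fraction), c(n_rows, n_cols)))
      stop("land_fraction matrix must be n_rows x n_cols")
  } else {
    land_fraction <- matrix(land_fraction, n_rows, n_cols)
  }
  lf <- land_fraction[!is.na(land_fraction)]
  if (any(lf < 0 | lf > 1))
    stop("land_fraction values must lie in [0, 1]")
  structure(
    list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
         x_origin = x_origin, y_origin = y_origin,
         land_fraction = land_fraction),
    class = "lattice_grid")
}

#' @export
print.lattice_grid <- function(x, ...) {
  cat(sprintf("lattice_grid: %d x %d cells of %.6g km (origin %.6g, %.6g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$x_origin, x$y_origin))
  cat(sprintf("  land cells (fraction > 0.5): %d of %d\n",
              sum(x$land_fraction > 0.5, na.rm = TRUE),
              x$n_rows * x$n_cols))
  invisible(x)
}

#' Per-cell value layer on a lattice
#'
#' A `surface` attaches one numeric value per cell to a [lattice_grid()].
#' Missing cells (sea, outside the study region) carry `NA` -- never a silent
#' zero.
#'
#' @param grid a [lattice_grid()].
#' @param values numeric: an `n_rows x n_cols` matrix or a vector in
#'   row-major cell-id order (see [lattice_grid()] for the indexing
#'   convention).
#' @return an object of class `surface` with elements `grid` and `values`
#'   (an `n_rows x n_cols` matrix).
#' @export
surface <- function(grid, values) {
  stopifnot(inherits(grid, "lattice_grid"))
  if (is.matrix(values)) {
    if (!identical(dim(values), c(grid$n_rows, grid$n_cols)))
      stop("values matrix must be n_rows x n_cols")
  } else {
    if (length(values) != grid$n_rows * grid$n_cols)
      stop("value count must equal n_rows * n_cols")
    # row-major vector -> R's column-major matrix
    values <- matrix(values, grid$n_rows, grid$n_cols, byrow = TRUE)
  }
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values), class = "surface")
}

#' @export
print.surface <- function(x, ...) {
  v <- x$values
  cat(sprintf("surface on %d x %d grid: %d missing, range [%.6g, %.6g]\n",
              x$grid$n_rows, x$grid$n_cols, sum(is.na(v)),
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE))))
  invisible(x)
}

#' @export
as.matrix.surface <- function(x, ...) x$values

#' Cell-id arithmetic
#'
#' Convert between 0-based row-major cell ids and (0-based) row/column pairs.
#'
#' @param grid a [lattice_grid()].
#' @param cell_id integer vector of 0-based row-major cell ids.
#' @param row,col integer vectors of 0-based row/column indices.
#' @return `cell_to_rowcol()` returns a two-column integer matrix
#'   (`row`, `col`); `rowcol_to_cell()` returns an integer vector of ids.
#' @export
cell_to_rowcol <- function(grid, cell_id) {
  cell_id <- as.integer(cell_id)
  if (any(cell_id < 0L | cell_id >= grid$n_rows * grid$n_cols, na.rm = TRUE))
    stop("cell_id out of range")
  cbind(row = cell_id %/% grid$n_cols, col = cell_id %% grid$n_cols)
}

#' @rdname cell_to_rowcol
#' @export
rowcol_to_cell <- function(grid, row, col) {
  row <- as.integer(row); col <- as.integer(col)
  if (any(row < 0L | row >= grid$n_rows | col < 0L | col >= grid$n_cols,
          na.rm = TRUE))
    stop("row/col out of range")
  row * grid$n_cols + col
}

#' Planar coordinates of cell centres
#'
#' @param grid a [lattice_grid()].
#' @param cell_id optional 0-based cell ids; default all cells in id order.
#' @return a two-column matrix (`x`, `y`) in km.
#' @export
cell_centers <- function(grid, cell_id = NULL) {
  if (is.null(cell_id)) cell_id <- seq_len(grid$n_rows * grid$n_cols) - 1L
  rc <- cell_to_rowcol(grid, cell_id)
  cbind(x = grid$x_origin + (rc[, "col"] + 0.5) * grid$cell_size,
        y = grid$y_origin + (rc[, "row"] + 0.5) * grid$cell_size)
}

# values of a surface in 0-based row-major cell-id order
surface_values_by_id <- function(s) as.vector(t(s$values))

#' Land filter
#'
#' Cells retained for analysis are those with strictly more than `threshold`
#' land (the conventional ">50% land" rule), so a cell at exactly the
#' threshold is dropped.
#'
#' @param grid a [lattice_grid()] with `land_fraction` populated.
#' @param threshold fraction in `[0, 1]`; default 0.5.
#' @return integer vector of 0-based row-major cell ids, in id order.
#' @export
land_filter <- function(grid, threshold = 0.5) {
  stopifnot(inherits(grid, "lattice_grid"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  lf <- as.vector(t(grid$land_fraction))  # row-major order
  which(!is.na(lf) & lf > threshold) - 1L
}

#' Aggregate a lattice to a coarser resolution
#'
#' Builds the coarse grid corresponding to `factor x factor` blocks of the
#' fine grid; the coarse `land_fraction` is the block mean of the fine one.
#' A ragged final row/column block is averaged over the cells it actually
#' contains.
#'
#' @param grid fine [lattice_grid()].
#' @param factor positive integer block edge.
#' @return a coarse [lattice_grid()].
#' @export
aggregate_grid <- function(grid, factor) {
  stopifnot(inherits(grid, "lattice_grid"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  nr <- as.integer(ceiling(grid$n_rows / factor))
  nc <- as.integer(ceiling(grid$n_cols / factor))
  lf <- block_reduce(grid$land_fraction, factor, mean)
  lattice_grid(nr, nc, cell_size = grid$cell_size * factor,
               x_origin = grid$x_origin, y_origin = grid$y_origin,
               land_fraction = lf)
}

# apply `fun` (with na.rm semantics handled by caller-supplied fun) to each
# factor x factor block of a matrix; ragged trailing blocks use the cells
# available
block_reduce <- function(m, factor, fun) {
  nr <- ceiling(nrow(m) / factor)
  nc <- ceiling(ncol(m) / factor)
  ri <- rep(seq_len(nr), each = factor, length.out = nrow(m))
  ci <- rep(seq_len(nc), each = factor, length.out = ncol(m))
  out <- matrix(NA_real_, nr, nc)
  for (b in seq_len(nc)) {
    sub <- m[, ci == b, drop = FALSE]
    out[, b] <- vapply(seq_len(nr),
                       function(a) fun(sub[ri == a, ]),
                       numeric(1))
  }
  out
}

#' Zonal (block) mean aggregation
#'
#' Averages a fine surface onto the coarse grid: each coarse cell is the
#' arithmetic mean of the non-missing fine cells in its `factor x factor`
#' block (the "mean" zonal statistic). A block with no observed cells is
#' missing. With `factor = 1` the input is returned unchanged.
#'
#' @param fine a [surface()].
#' @param factor positive integer aggregation factor.
#' @return a [surface()] on the [aggregate_grid()] of the input.
#' @export
zonal_mean <- function(fine, factor) {
  stopifnot(inherits(fine, "surface"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be a positive integer")
  if (all(is.na(fine$values)) && length(fine$values) == 0L)
    stop("empty surface")
  if (factor == 1L) return(fine)
  cg <- aggregate_grid(fine$grid, factor)
  vals <- block_reduce(fine$values, factor, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) NA_real_ else mean(x)
  })
  surface(cg, vals)
}

#' Climate anomaly (contemporary minus paleo)
#'
#' Computes the cellwise anomaly `current - mean(past layers)`. Where several
#' paleoclimate simulations exist for an epoch (e.g. two GCMs for the Last
#' Glacial Maximum) the mean across simulations is subtracted. The sign
#' convention is positive where the present is warmer/wetter than the past.
#'
#' @param current a [surface()] of contemporary climate.
#' @param past a [surface()] or list of surfaces of paleoclimate on the same
#'   grid.
#' @return an anomaly [surface()].
#' @export
climate_anomaly <- function(current, past) {
  stopifnot(inherits(current, "surface"))
  if (inherits(past, "surface")) past <- list(past)
  if (!length(past) || !all(vapply(past, inherits, logical(1), "surface")))
    stop("past must be one or more surfaces")
  for (p in past) {
    if (!identical(dim(p$values), dim(current$values)) ||
        !isTRUE(all.equal(p$grid$cell_size, current$grid$cell_size)))
      stop("all surfaces must share the same grid")
  }
  pm <- Reduce(`+`, lapply(past, function(p) p$values)) / length(past)
  surface(current$grid, current$values - pm)
}
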