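#' Read and write ESRI ASCII grids
#'
#' Plain-text raster exchange in the ESRI ASCII ("Arc/Info ASCII") grid
#' format: a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of values, top row first.
#' `NODATA` cells map to `NA`. The grid's planar origin is stored in
#' `xllcorner`/`yllcorner` (see [lattice_grid()] for the axis convention used
#' here: the stored corner is the grid's top-left origin).
#'
#' Values are written with 15 significant digits, so a write/read round trip
#' is exact for integer-valued data and well within 1e-6 for doubles.
#'
#' @param x a [surface()].
#' @param file path to write to / read from.
#' @param nodata sentinel written for missing cells.
#' @param land_fraction optional land-fraction matrix to attach to the grid
#'   of a surface being read (the format itself carries no land mask).
#' @return `read_ascii_grid()` returns a [surface()]; `write_ascii_grid()`
#'   returns `file` invisibly.
#' @export
write_ascii_grid <- function(x, file, nodata = -9999) {
  stopifnot(inherits(x, "surface"))
  g <- x$grid
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.10g", g$x_origin),
           sprintf("yllcorner %.10g", g$y_origin),
           sprintf("cellsize %.10g", g$cell_size),
           sprintf("NODATA_value %.10g", nodata))
  v <- x$values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1L, function(r) paste(format(r, digits = 15, trim = TRUE,
                                                scientific = FALSE),
                                         collapse = " "))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(file, land_fraction = 1) {
  lines <- readLines(file)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ESRI ASCII header")
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc) stop("value count does not match header")
  m <- matrix(vals, nr, nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  g <- lattice_grid(nr, nc, cell_size = hdr$cellsize,
                    x_origin = if (is.null(hdr$xllcorner)) 0 else hdr$xllcorner,
                    y_origin = if (is.null(hdr$yllcorner)) 0 else hdr$yllcorner,
                    land_fraction = land_fraction)
  surface(g, m)
}

#' Export / import a cell table
#'
#' Flattens one or more surfaces on a common grid into a delimited table with
#' one row per cell: `cell_id` (0-based, row-major), `row`, `col` (0-based),
#' `x`, `y` (cell-centre km), `land_fraction`, then one column per surface.
#' This is the exchange format between the raster stages and the regression
#' stage.
#'
#' @param grid a [lattice_grid()].
#' @param surfaces named list of [surface()] objects on `grid`.
#' @param file optional path; when given the table is also written as CSV.
#' @return a `data.frame` (invisibly when `file` is given).
#' @export
export_cell_table <- function(grid, surfaces = list(), file = NULL) {
  stopifnot(inherits(grid, "lattice_grid"))
  if (length(surfaces) && is.null(names(surfaces)))
    stop("surfaces must be a named list")
  n <- grid$n_rows * grid$n_cols
  id <- seq_len(n) - 1L
  rc <- cell_to_rowcol(grid, id)
  xy <- cell_centers(grid, id)
  tab <- data.frame(cell_id = id, row = rc[, "row"], col = rc[, "col"],
                    x = xy[, "x"], y = xy[, "y"],
                    land_fraction = as.vector(t(grid$land_fraction)))
  for (nm in names(surfaces)) {
    s <- surfaces[[nm]]
    stopifnot(inherits(s, "surface"))
    if (!identical(dim(s$values), c(grid$n_rows, grid$n_cols)))
      stop("surface '", nm, "' is not on the given grid")
    tab[[nm]] <- surface_values_by_id(s)
  }
  if (!is.null(file)) {
    utils::write.csv(tab, file, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' @rdname export_cell_table
#' @export
import_cell_table <- function(file) {
  utils::read.csv(file)
}
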