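#' Wing-disc field geometry
#'
#' Describes the rendered epithelial field: a rectangular region of the disc
#' spanning the A/P compartment boundary, with columnar cells of ~2.5 um
#' diameter, a ptc-expression band of 3-4 cells immediately anterior to the
#' boundary, and two optical sections (apical, basolateral). Images are 2D
#' per section; rows index y, columns index x, and x increases from anterior
#' to posterior. Pixel centers sit at `(index - 0.5) * pixel_um`.
#'
#' @param field_um Field size `c(x, y)` in micrometres.
#' @param pixel_um Pixel size in micrometres per pixel.
#' @param cell_um Cell diameter in micrometres (default 2.5).
#' @param band_cells Width of the ptc band in cells; 3 or 4.
#' @param boundary_x_um Position of the A/P boundary along x (um).
#' @return An object of class `disc_geometry`.
#' @export
disc_geometry <- function(field_um = c(64, 48), pixel_um = 0.2,
                          cell_um = 2.5, band_cells = 4,
                          boundary_x_um = 36) {
  stopifnot(length(field_um) == 2, all(field_um > 0), pixel_um > 0,
            cell_um > 0)
  if (!band_cells %in% c(3, 4)) stop("band_cells must be 3 or 4")
  if (boundary_x_um <= band_cells * cell_um || boundary_x_um >= field_um[1])
    stop("boundary_x_um must leave room for the ptc band and both compartments")
  structure(
    list(field_um = field_um, pixel_um = pixel_um, cell_um = cell_um,
         band_cells = band_cells, boundary_x_um = boundary_x_um,
         nx = as.integer(round(field_um[1] / pixel_um)),
         ny = as.integer(round(field_um[2] / pixel_um)),
         sections = c("basolateral", "apical")),
    class = "disc_geometry"
  )
}

#' @export
print.disc_geometry <- function(x, ...) {
  cat(sprintf(
    "<disc_geometry> %g x %g um (%d x %d px @ %g um/px); boundary at x = %g um; %d-cell ptc band\n",
    x$field_um[1], x$field_um[2], x$nx, x$ny, x$pixel_um,
    x$boundary_x_um, x$band_cells))
  invisible(x)
}

# pixel center coordinates along x (columns) and y (rows)
x_centers <- function(geom) (seq_len(geom$nx) - 0.5) * geom$pixel_um
y_centers <- function(geom) (seq_len(geom$ny) - 0.5) * geom$pixel_um

#' Region masks of the disc field
#'
#' Three masks partitioning the field along x: `far_A` (anterior of the ptc
#' band), `ptc_band` (the 3-4 cell strip immediately anterior to the
#' boundary) and `P` (posterior compartment). Masks are logical matrices
#' `(ny, nx)`.
#'
#' @param geom A [disc_geometry()].
#' @return Named list of logical matrices.
#' @export
region_masks <- function(geom) {
  stopifnot(inherits(geom, "disc_geometry"))
  x <- x_centers(geom)
  band_lo <- geom$boundary_x_um - geom$band_cells * geom$cell_um
  col_region <- ifelse(x >= geom$boundary_x_um, "P",
                       ifelse(x >= band_lo, "ptc_band", "far_A"))
  mk <- function(rg) matrix(rep(col_region == rg, each = geom$ny),
                            nrow = geom$ny)
  list(far_A = mk("far_A"), ptc_band = mk("ptc_band"), P = mk("P"))
}

#' Anterior/posterior compartment masks
#'
#' @param geom A [disc_geometry()].
#' @return Named list with logical matrices `A` and `P`.
#' @export
ap_masks <- function(geom) {
  rm <- region_masks(geom)
  list(A = rm$far_A | rm$ptc_band, P = rm$P)
}

#' Cell-outline membrane lattice
#'
#' A brick-like lattice of cell outlines with `cell_um` spacing (rows of
#' cells offset by half a cell, approximating a hexagonal packing), one
#' pixel wide and then dilated by one pixel. Stands in for the junctional /
#' membrane marker signal.
#'
#' @param geom A [disc_geometry()].
#' @return Logical matrix `(ny, nx)`.
#' @export
membrane_lattice <- function(geom) {
  stopifnot(inherits(geom, "disc_geometry"))
  px <- geom$pixel_um; cw <- geom$cell_um
  ny <- geom$ny; nx <- geom$nx
  # horizontal cell walls: rows whose pixel crosses a multiple of cell_um
  hw <- floor(seq_len(ny) * px / cw) > floor((seq_len(ny) - 1) * px / cw)
  lat <- matrix(FALSE, ny, nx)
  lat[hw, ] <- TRUE
  # vertical walls, offset by half a cell on odd rows of cells
  yband <- floor(y_centers(geom) / cw)
  off <- ifelse(yband %% 2 == 1, cw / 2, 0)
  jx <- seq_len(nx)
  for (i in seq_len(ny)) {
    vw <- floor((jx * px - off[i]) / cw) > floor(((jx - 1) * px - off[i]) / cw)
    lat[i, vw] <- TRUE
  }
  k <- EBImage::makeBrush(3, shape = "box")
  as.matrix(EBImage::dilate(EBImage::Image(lat * 1), k)) > 0.5
}

#' Dorsal-half mask (y below the field midline)
#'
#' @param geom A [disc_geometry()].
#' @return Logical matrix `(ny, nx)`.
#' @export
dorsal_mask <- function(geom) {
  stopifnot(inherits(geom, "disc_geometry"))
  matrix(rep(y_centers(geom) < geom$field_um[2] / 2, times = geom$nx),
         nrow = geom$ny)
}
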