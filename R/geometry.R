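#' Subsampling tray geometry
#'
#' Describes the gridded circular subsampling tray: a plate of inner diameter
#' `inner_diameter` cm holding a metal frame with `n_complete_cells` complete
#' square cells of side `cell_side` cm. The plate's total inner area expressed
#' in units of one cell's area is the cell-equivalent count
#' `equivalent_cells`; it is the extrapolation multiplier of the abundance
#' estimator and is stored as a configurable constant rather than recomputed
#' from the other dimensions (the published apparatus rounds it to 63.6, while
#' raw division of the areas gives about 63.9; the rounded value is canonical
#' for the estimator). The area not covered by complete cells — partial cells
#' around the rim — is pooled into a single edge region of
#' `equivalent_cells - n_complete_cells` cell-equivalents, which is never
#' selectable for counting.
#'
#' @param inner_diameter Inner diameter of the plate, cm.
#' @param cell_side Side of one square grid cell, cm.
#' @param n_complete_cells Number of complete cells in the frame.
#' @param equivalent_cells Plate area in units of one cell area (the
#'   extrapolation multiplier). Must be at least `n_complete_cells`; it may
#'   equal it, giving an edge-free tray (useful for small test arenas).
#' @return An object of class `"tray_geometry"`: a list with the four
#'   arguments plus `edge_equivalents = equivalent_cells - n_complete_cells`.
#' @examples
#' tray_geometry()            # the published apparatus
#' tray_geometry(10, 1, 20, 25)
#' @export
tray_geometry <- function(inner_diameter = 22.9, cell_side = 2.54,
                          n_complete_cells = 45L, equivalent_cells = 63.6) {
  stopifnot(is.numeric(inner_diameter), length(inner_diameter) == 1L,
            is.numeric(cell_side), length(cell_side) == 1L,
            is.numeric(n_complete_cells), length(n_complete_cells) == 1L,
            is.numeric(equivalent_cells), length(equivalent_cells) == 1L)
  if (cell_side <= 0)
    stop("'cell_side' must be positive", call. = FALSE)
  if (inner_diameter <= 2 * cell_side)
    stop("'inner_diameter' must exceed twice the cell side", call. = FALSE)
  if (n_complete_cells < 1 || n_complete_cells != round(n_complete_cells))
    stop("'n_complete_cells' must be a positive integer", call. = FALSE)
  if (equivalent_cells < n_complete_cells)
    stop("'equivalent_cells' must be at least 'n_complete_cells'",
         call. = FALSE)
  structure(list(inner_diameter = inner_diameter,
                 cell_side = cell_side,
                 n_complete_cells = as.integer(n_complete_cells),
                 equivalent_cells = equivalent_cells,
                 edge_equivalents = equivalent_cells - n_complete_cells),
            class = "tray_geometry")
}

#' @export
print.tray_geometry <- function(x, ...) {
  cat("Subsampling tray geometry\n")
  cat(sprintf("  inner diameter : %.2f cm (plate area %.1f cm^2)\n",
              x$inner_diameter, plate_area(x$inner_diameter)))
  cat(sprintf("  cell side      : %.2f cm (cell area %.2f cm^2)\n",
              x$cell_side, cell_area(x$cell_side)))
  cat(sprintf("  complete cells : %d\n", x$n_complete_cells))
  cat(sprintf("  cell-equivalents: %.1f (edge region %.1f)\n",
              x$equivalent_cells, x$edge_equivalents))
  invisible(x)
}

#' Area of one grid cell
#'
#' @param cell_side Cell side length, cm.
#' @return Cell area in cm^2 (`cell_side^2`).
#' @examples
#' cell_area(2.54)  # 6.45 cm^2
#' @export
cell_area <- function(cell_side) {
  stopifnot(is.numeric(cell_side))
  if (any(cell_side <= 0)) stop("'cell_side' must be positive", call. = FALSE)
  cell_side^2
}

#' Inner area of the circular plate
#'
#' @param inner_diameter Plate inner diameter, cm.
#' @return Plate area in cm^2 (`pi * (inner_diameter / 2)^2`).
#' @examples
#' plate_area(22.9)  # ~412 cm^2
#' @export
plate_area <- function(inner_diameter) {
  stopifnot(is.numeric(inner_diameter))
  if (any(inner_diameter <= 0))
    stop("'inner_diameter' must be positive", call. = FALSE)
  pi * (inner_diameter / 2)^2
}

#' Percent of plate area covered by k counted cells
#'
#' Only complete cells are selectable, so `k` may not exceed
#' `geometry$n_complete_cells`, and even counting every complete cell covers
#' less than 100% of the circular plate.
#'
#' @param k Number of counted cells (0 to `n_complete_cells`).
#' @param geometry A [tray_geometry()].
#' @return Percent of total plate area, `100 * k / equivalent_cells`.
#' @examples
#' area_fraction(16)  # 25% of the published tray
#' area_fraction(10)  # ~16%
#' @export
area_fraction <- function(k, geometry = tray_geometry()) {
  stopifnot(inherits(geometry, "tray_geometry"), is.numeric(k))
  if (any(k < 0) || any(k > geometry$n_complete_cells))
    stop("'k' must be between 0 and the number of complete cells",
         call. = FALSE)
  100 * k / geometry$equivalent_cells
}
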