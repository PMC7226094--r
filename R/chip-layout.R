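#' Geometric model of a microwell array chip
#'
#' A `chip_layout` describes the regular grid of cylindrical microwells on a
#' PDMS chip, the fiducial (alignment) markers at its corners, and the imaging
#' geometry used when the chip is scanned tile by tile. All physical
#' dimensions are in micrometres. Defaults mirror a production chip:
#' 60 um diameter x 40 um deep wells (113 pL) and a 3328 um square
#' field of view per microscope tile.
#'
#' Well `(row, col)` is centred at
#' `x = margin + (col - 1/2) * pitch`, `y = margin + (row - 1/2) * pitch`,
#' with the chip origin at its top-left corner (x rightward, y downward).
#' Four fiducial markers sit at the chip corners, ordered top-left,
#' top-right, bottom-left, bottom-right; the ordering is stable so that
#' pre- and post-disassembly marker lists correspond element-wise.
#'
#' @param n_rows,n_cols Number of well rows and columns (positive integers).
#' @param pitch Centre-to-centre well spacing (um); must exceed the diameter.
#' @param well_diameter,well_depth Cylindrical well dimensions (um).
#' @param pixel_size Imaging scale (um per pixel).
#' @param tile_fov Side length of one microscope tile (um).
#' @param margin Border between the chip edge and the first well (um);
#'   defaults to one pitch. Markers are centred `margin/2` in from the edge.
#'
#' @return An object of class `chip_layout`: a list with the geometry fields
#'   plus `markers`, a tibble of ordered fiducial coordinates.
#' @examples
#' layout <- chip_layout(10, 10, pitch = 100)
#' n_wells(layout)
#' well_centers(layout)
#' @export
chip_layout <- function(n_rows, n_cols, pitch,
                        well_diameter = 60, well_depth = 40,
                        pixel_size = 3.25, tile_fov = 3328,
                        margin = NULL) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (is.na(n_rows) || is.na(n_cols) || n_rows < 1L || n_cols < 1L) {
    ws_abort("`n_rows` and `n_cols` must be positive integers.", "invalid_geometry")
  }
  for (v in c(pitch = pitch, well_diameter = well_diameter,
              well_depth = well_depth, pixel_size = pixel_size,
              tile_fov = tile_fov)) {
    if (!is.finite(v) || v <= 0) {
      ws_abort("All chip dimensions must be positive and finite.", "invalid_geometry")
    }
  }
  if (pitch <= well_diameter) {
    ws_abort("`pitch` must exceed `well_diameter` (wells may not touch).", "invalid_geometry")
  }
  margin <- margin %||% pitch
  if (!is.finite(margin) || margin <= 0) {
    ws_abort("`margin` must be positive.", "invalid_geometry")
  }
  width  <- 2 * margin + n_cols * pitch
  height <- 2 * margin + n_rows * pitch
  m <- margin / 2
  markers <- tibble(
    marker = c("TL", "TR", "BL", "BR"),
    x_um = c(m, width - m, m, width - m),
    y_um = c(m, m, height - m, height - m)
  )
  structure(
    list(
      n_rows = n_rows, n_cols = n_cols, pitch = pitch,
      well_diameter = well_diameter, well_depth = well_depth,
      pixel_size = pixel_size, tile_fov = tile_fov,
      margin = margin, width = width, height = height,
      markers = markers
    ),
    class = "chip_layout"
  )
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf(
    "<chip_layout> %d x %d wells (%s total), pitch %g um, wells d %g x h %g um (%.1f pL)\n",
    x$n_rows, x$n_cols, format(n_wells(x), big.mark = ","),
    x$pitch, x$well_diameter, x$well_depth,
    well_volume(x$well_diameter, x$well_depth)
  ))
  cat(sprintf("  chip %g x %g um; %d fiducial markers; %g um/px; tile FOV %g um\n",
              x$width, x$height, nrow(x$markers), x$pixel_size, x$tile_fov))
  invisible(x)
}

#' Total number of wells in a layout
#' @param layout A [chip_layout()].
#' @return Integer count `n_rows * n_cols`.
#' @export
n_wells <- function(layout) {
  stopifnot(inherits(layout, "chip_layout"))
  layout$n_rows * layout$n_cols
}

#' Well centre coordinates
#'
#' @param layout A [chip_layout()].
#' @return A tibble with one row per well: `well` (row-major index), `row`,
#'   `col`, and centre coordinates `x_um`, `y_um`.
#' @export
well_centers <- function(layout) {
  stopifnot(inherits(layout, "chip_layout"))
  grid <- expand.grid(col = seq_len(layout$n_cols), row = seq_len(layout$n_rows))
  tibble(
    well = seq_len(nrow(grid)),
    row = grid$row,
    col = grid$col,
    x_um = layout$margin + (grid$col - 0.5) * layout$pitch,
    y_um = layout$margin + (grid$row - 0.5) * layout$pitch
  )
}

#' Volume of a cylindrical microwell
#'
#' Computes `pi * (d/2)^2 * h` and converts cubic micrometres to picolitres
#' (1 um^3 = 1 fL, so divide by 1000). A 60 um x 40 um well holds 113.1 pL.
#'
#' @param diameter,depth Well diameter and depth in micrometres (>= 0).
#' @return Volume in picolitres.
#' @examples
#' well_volume(60, 40) # ~113 pL
#' @export
well_volume <- function(diameter, depth) {
  if (any(!is.finite(diameter)) || any(!is.finite(depth)) ||
      any(diameter < 0) || any(depth < 0)) {
    ws_abort("`diameter` and `depth` must be non-negative.", "invalid_geometry")
  }
  pi * (diameter / 2)^2 * depth / 1000
}
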