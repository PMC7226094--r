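#' Simulate Poisson cell loading of a microwell chip
#'
#' Draws i.i.d. Poisson(`lambda`) cell counts per well and, when a library is
#' supplied, samples a clone identity for every cell from the library's
#' abundance distribution (cells load independently, so a multi-cell well
#' can mix clones).
#'
#' @param layout A [chip_layout()].
#' @param lambda Mean cells per well (>= 0); 0.1 is the standard single-cell
#'   loading condition (10% occupancy, ~95% single-cell purity).
#' @param library Optional [library_spec()] supplying clone ids and
#'   abundances.
#' @param seed Integer RNG seed.
#' @return A tibble (class `occupancy_map`) with one row per well: `well`,
#'   `row`, `col`, `x_um`, `y_um`, `n_cells`, and list-column `clone_ids`
#'   (length `n_cells`, `character(0)` for empty wells). The layout and
#'   lambda are attached as attributes.
#' @examples
#' occ <- simulate_loading(chip_layout(10, 10, 100), lambda = 0.1, seed = 1)
#' mean(occ$n_cells > 0)
#' @export
simulate_loading <- function(layout, lambda, library = NULL, seed = 0) {
  stopifnot(inherits(layout, "chip_layout"))
  if (!is.finite(lambda) || lambda < 0) {
    ws_abort("`lambda` must be non-negative.", "invalid_parameter")
  }
  withr::local_seed(seed)
  occ <- well_centers(layout)
  occ$n_cells <- rpois(nrow(occ), lambda)
  total <- sum(occ$n_cells)
  ids <- if (is.null(library)) {
    rep("cell", total)
  } else {
    sample(library$clones$clone_id, total, replace = TRUE,
           prob = library$clones$abundance)
  }
  occ$clone_ids <- split(ids, rep.int(seq_len(nrow(occ)), occ$n_cells)) |>
    (\(s) {
      out <- rep(list(character(0)), nrow(occ))
      out[as.integer(names(s))] <- s
      out
    })()
  attr(occ, "layout") <- layout
  attr(occ, "lambda") <- lambda
  class(occ) <- c("occupancy_map", class(occ))
  occ
}

# Pixel-centre coordinate helpers: pixel (i, j) of a stitched image covers
# [(j-1) ps, j ps) x [(i-1) ps, i ps) um; its centre is ((j-0.5) ps, (i-0.5) ps).
um_to_px <- function(um, pixel_size) um / pixel_size + 0.5
px_to_um <- function(px, pixel_size) (px - 0.5) * pixel_size

# Background levels of the simulated 16-bit images (arbitrary units).
BG_FLUOR <- 100
BG_BRIGHT <- 500
WELL_BRIGHT <- 350       # well interiors image darker in brightfield
CELL_SPECKLE <- 900      # bright cell bodies inside occupied wells
MARKER_VALUE <- 1000

render_chip_image <- function(layout, occupancy, intensity, channel,
                              noise_sd, combine, seed) {
  ps <- layout$pixel_size
  nx <- max(1L, round(layout$width / ps))
  ny <- max(1L, round(layout$height / ps))
  bg <- if (channel == "fluorescence") BG_FLUOR else BG_BRIGHT
  img <- matrix(bg, nrow = ny, ncol = nx)
  xs <- px_to_um(seq_len(nx), ps)
  ys <- px_to_um(seq_len(ny), ps)
  r <- layout$well_diameter / 2

  well_int <- purrr::map_dbl(occupancy$clone_ids, function(ids) {
    v <- intensity[ids]
    v <- v[!is.na(v)]
    if (!length(v)) 0 else if (combine == "max") max(v) else sum(v)
  })

  withr::local_seed(seed)
  for (w in seq_len(nrow(occupancy))) {
    cx <- occupancy$x_um[w]; cy <- occupancy$y_um[w]
    jj <- which(abs(xs - cx) <= r)
    ii <- which(abs(ys - cy) <= r)
    if (!length(jj) || !length(ii)) next
    dist2 <- outer((ys[ii] - cy)^2, (xs[jj] - cx)^2, `+`)
    disk <- dist2 <= r^2
    if (channel == "fluorescence") {
      img[ii, jj][disk] <- bg + well_int[w]
    } else {
      img[ii, jj][disk] <- WELL_BRIGHT
      nc <- occupancy$n_cells[w]
      if (nc > 0) {
        # cells image as bright speckles; drives the variance-based
        # occupancy call
        idx <- which(disk & dist2 <= (0.7 * r)^2, arr.ind = TRUE)
        if (nrow(idx)) {
          pick <- idx[sample.int(nrow(idx), min(nrow(idx), 8L * nc)), , drop = FALSE]
          img[cbind(ii[pick[, 1]], jj[pick[, 2]])] <- CELL_SPECKLE
        }
      }
    }
  }
  # fiducial crosses at the chip corners, visible in both channels
  arm <- min(40, layout$margin / 2 - ps)
  hw <- max(ps, 4)
  for (m in seq_len(nrow(layout$markers))) {
    mx <- layout$markers$x_um[m]; my <- layout$markers$y_um[m]
    jj <- which(abs(xs - mx) <= arm); ii <- which(abs(ys - my) <= hw)
    img[ii, jj] <- MARKER_VALUE
    jj <- which(abs(xs - mx) <= hw); ii <- which(abs(ys - my) <= arm)
    img[ii, jj] <- MARKER_VALUE
  }
  if (noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow = ny)
  }
  img[img < 0] <- 0
  img[img > 65535] <- 65535
  list(image = img, well_intensity = well_int)
}

tile_starts <- function(n_px, fov_px, step_px) {
  if (n_px <= fov_px) return(0L)
  n <- ceiling((n_px - fov_px) / step_px) + 1L
  pmin((seq_len(n) - 1L) * step_px, n_px - fov_px)
}

#' Render grid-scanned microscope tiles of a chip
#'
#' Renders the whole chip as a 16-bit grayscale image (wells as disks on a
#' flat background, fiducial crosses at the corners, optional Gaussian pixel
#' noise) and cuts it into overlapping tiles the way a motorised stage scans
#' it. The fluorescence signal of a well is the maximum over its clones'
#' intensities (configurable to the sum); brightfield wells image darker
#' than the background with bright cell speckles when occupied. A
#' ground-truth per-well table is returned alongside the tiles.
#'
#' @param layout A [chip_layout()].
#' @param occupancy An [simulate_loading()] occupancy map for `layout`.
#' @param intensity Named numeric vector, clone id -> fluorescence intensity
#'   (a.u. above background); see [clone_intensities()].
#' @param channel `"fluorescence"` or `"brightfield"`.
#' @param noise_sd Gaussian pixel noise SD (a.u., >= 0).
#' @param overlap Tile overlap fraction, in `[0, 0.5]`.
#' @param combine How a multi-clone well combines intensities: `"max"`
#'   (default; mixed phage compete for the antigen surface) or `"sum"`.
#' @param seed Integer RNG seed.
#' @return An object of class `tile_set`: list with `tiles` (named list of
#'   matrices), `manifest` (tibble: `tile_id`, `stage_x_um`, `stage_y_um`,
#'   `channel`), `truth` (per-well tibble with `n_cells`, `occupied`,
#'   `intensity`), `image` (the full mosaic) and `pixel_size`.
#' @export
render_tiles <- function(layout, occupancy, intensity = numeric(),
                         channel = c("fluorescence", "brightfield"),
                         noise_sd = 0, overlap = 0.1,
                         combine = c("max", "sum"), seed = 0) {
  stopifnot(inherits(layout, "chip_layout"))
  channel <- match.arg(channel)
  combine <- match.arg(combine)
  if (!is.finite(overlap) || overlap < 0 || overlap > 0.5) {
    ws_abort("`overlap` must lie in [0, 0.5].", "invalid_parameter")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    ws_abort("`noise_sd` must be >= 0.", "invalid_parameter")
  }
  rend <- render_chip_image(layout, occupancy, intensity, channel,
                            noise_sd, combine, seed)
  ps <- layout$pixel_size
  fov_px <- max(1L, round(layout$tile_fov / ps))
  step_px <- max(1L, round(fov_px * (1 - overlap)))
  xs <- tile_starts(ncol(rend$image), min(fov_px, ncol(rend$image)), step_px)
  ys <- tile_starts(nrow(rend$image), min(fov_px, nrow(rend$image)), step_px)
  w <- min(fov_px, ncol(rend$image)); h <- min(fov_px, nrow(rend$image))
  grid <- expand.grid(x0 = xs, y0 = ys)
  tiles <- purrr::pmap(grid, function(x0, y0) {
    rend$image[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), drop = FALSE]
  })
  names(tiles) <- sprintf("tile_%03d", seq_along(tiles))
  manifest <- tibble(
    tile_id = names(tiles),
    stage_x_um = grid$x0 * ps,
    stage_y_um = grid$y0 * ps,
    channel = channel
  )
  truth <- occupancy[c("well", "row", "col", "x_um", "y_um", "n_cells")]
  truth$occupied <- truth$n_cells > 0
  truth$intensity <- rend$well_intensity
  structure(
    list(tiles = tiles, manifest = manifest, truth = as_tibble(truth),
         image = rend$image, pixel_size = ps, layout = layout),
    class = "tile_set"
  )
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set> %d %s tile(s) of %d x %d px (%g um/px), chip %d x %d px\n",
              length(x$tiles), x$manifest$channel[1],
              nrow(x$tiles[[1]]), ncol(x$tiles[[1]]), x$pixel_size,
              nrow(x$image), ncol(x$image)))
  invisible(x)
}

#' Apply the chip-disassembly distortion to coordinates
#'
#' Maps marker or well coordinates through a known first-order transform
#' (the geometric distortion a peeled elastomer imposes) plus optional
#' isotropic Gaussian jitter, emulating the post-disassembly view of the
#' sample-capturing substrate. The ground-truth transform is recorded as an
#' attribute.
#'
#' @param points Data frame with `x_um`, `y_um`.
#' @param transform A [planar_transform()].
#' @param jitter_sd Isotropic Gaussian jitter SD (um, >= 0), emulating
#'   localisation error.
#' @param seed Integer RNG seed.
#' @return The distorted points tibble, with attribute `true_transform`.
#' @export
apply_disassembly_distortion <- function(points, transform, jitter_sd = 0,
                                         seed = 0) {
  transform <- as_planar_transform(transform)
  if (!is.finite(jitter_sd) || jitter_sd < 0) {
    ws_abort("`jitter_sd` must be >= 0.", "invalid_parameter")
  }
  out <- map_coordinates(transform, points)
  if (jitter_sd > 0) {
    withr::local_seed(seed)
    out$x_um <- out$x_um + rnorm(nrow(out), 0, jitter_sd)
    out$y_um <- out$y_um + rnorm(nrow(out), 0, jitter_sd)
  }
  attr(out, "true_transform") <- transform
  out
}
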