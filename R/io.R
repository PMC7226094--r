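#' Write and read image tiles with a CSV manifest
#'
#' Tiles go to 16-bit grayscale TIFF files named by tile id next to a
#' `manifest.csv` recording stage positions (um) and channel.
#'
#' @param tile_set A [render_tiles()] result.
#' @param dir Output directory (created if needed).
#' @return `write_tiles()` returns `dir` invisibly; `read_tiles()` returns a
#'   list with `tiles` (matrices on the original 16-bit scale), `manifest`
#'   and `pixel_size`.
#' @export
write_tiles <- function(tile_set, dir) {
  stopifnot(inherits(tile_set, "tile_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(tile_set$tiles)) {
    tiff::writeTIFF(tile_set$tiles[[id]] / 65535,
                    file.path(dir, paste0(id, ".tif")),
                    bits.per.sample = 16L, compression = "none")
  }
  manifest <- tile_set$manifest
  manifest$pixel_size_um <- tile_set$pixel_size
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' @rdname write_tiles
#' @export
read_tiles <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
                              show_col_types = FALSE)
  tiles <- lapply(manifest$tile_id, function(id) {
    tiff::readTIFF(file.path(dir, paste0(id, ".tif"))) * 65535
  })
  names(tiles) <- manifest$tile_id
  pixel_size <- manifest$pixel_size_um[1]
  manifest$pixel_size_um <- NULL
  list(tiles = tiles, manifest = manifest, pixel_size = pixel_size)
}

#' Read and write ELISA plate tables
#'
#' Plates are CSV with columns `well`, `role`, `clone_id`, `absorbance`
#' (extra columns such as the simulator's `truth_reactive` pass through).
#'
#' @param plate A plate tibble.
#' @param path CSV file path.
#' @return `read_plate_csv()` returns the plate tibble.
#' @export
write_plate_csv <- function(plate, path) {
  readr::write_csv(plate, path)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(clone_id = readr::col_character()))
}

#' Write the tabular outputs of a screen stage
#'
#' Tab-separated writers for well measurements (`wells.tsv`), retrieval
#' plans (`retrieval_plan.tsv`) and clone tables (`clones.tsv`);
#' list-columns are flattened to comma-separated strings.
#'
#' @param x A tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(x, path) {
  flat <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.list),
    ~ vapply(.x, function(v) paste(v, collapse = ","), "")
  ))
  readr::write_tsv(flat, path)
  invisible(path)
}
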