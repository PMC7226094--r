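# Small, fast fixtures shared across test files. Everything is generated in
# code; chip-scale objects are only built where a test genuinely needs them.

tiny_layout <- function(n = 10, pitch = 100, pixel_size = 2, tile_fov = 1500) {
  chip_layout(n, n, pitch = pitch, well_diameter = 60, well_depth = 40,
              pixel_size = pixel_size, tile_fov = tile_fov)
}

tiny_library <- function(n_clones = 8, n_reactive = 3, seed = 11, ...) {
  library_spec(n_clones = n_clones, n_reactive = n_reactive, seed = seed, ...)
}

# renders both channels of a small chip and returns everything downstream
# tests need for round-trip checks
rendered_chip <- function(layout = tiny_layout(), lambda = 0.3, seed = 5,
                          noise_sd = 0, library = tiny_library()) {
  occ <- simulate_loading(layout, lambda, library, seed = seed)
  intens <- clone_intensities(library)
  list(
    layout = layout, library = library, occupancy = occ, intensity = intens,
    bf = render_tiles(layout, occ, intens, "brightfield", noise_sd = noise_sd,
                      seed = seed + 1),
    fl = render_tiles(layout, occ, intens, "fluorescence", noise_sd = noise_sd,
                      seed = seed + 2)
  )
}

# a segments tibble in the shape locate_anchors() emits, for direct
# validate_chains() tests
manual_segments <- function(vl_nt, vh_nt, vl_qual = strrep("I", nchar(vl_nt)),
                            vh_qual = strrep("I", nchar(vh_nt))) {
  tibble::tibble(
    read_id = sprintf("r%02d", seq_along(vl_nt)),
    orientation = "fwd", anchor_fail = FALSE,
    vl_nt = vl_nt, vh_nt = vh_nt, vl_qual = vl_qual, vh_qual = vh_qual
  )
}
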