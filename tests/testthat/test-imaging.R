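test_that("stitching reconstructs mosaics placed by stage position", {
  # single tile: output identical to input
  tl <- matrix(runif(100 * 120), 100, 120)
  st <- stitch_tiles(list(tile_001 = tl),
                     tibble::tibble(tile_id = "tile_001", stage_x_um = 0,
                                    stage_y_um = 0, channel = "brightfield"),
                     pixel_size = 2)
  expect_identical(st$image, tl)

  # crop-then-restitch oracle: 2x2 tiles with ~10% overlap, pixel-identical
  set.seed(31)
  mosaic <- matrix(runif(200 * 200), 200, 200)
  cut <- function(x0, y0) mosaic[(y0 + 1):(y0 + 110), (x0 + 1):(x0 + 110)]
  grid <- expand.grid(x0 = c(0, 90), y0 = c(0, 90))
  tiles <- Map(cut, grid$x0, grid$y0)
  names(tiles) <- sprintf("tile_%03d", 1:4)
  man <- tibble::tibble(tile_id = names(tiles), stage_x_um = grid$x0 * 2,
                        stage_y_um = grid$y0 * 2, channel = "brightfield")
  re <- stitch_tiles(tiles, man, pixel_size = 2)
  expect_identical(re$image, mosaic)

  # mosaic physical extent equals the bounding box of the tile extents
  fov_px <- round(3328 / 3.25)
  tiles2 <- list(a = matrix(0, fov_px, fov_px), b = matrix(0, fov_px, fov_px))
  man2 <- tibble::tibble(tile_id = c("a", "b"),
                         stage_x_um = c(0, 0.9 * 3328), stage_y_um = 0,
                         channel = "fluorescence")
  st2 <- stitch_tiles(tiles2, man2, pixel_size = 3.25)
  expect_equal(ncol(st2$image), round(0.9 * 3328 / 3.25) + fov_px)
  expect_equal(nrow(st2$image), fov_px)

  expect_error(
    stitch_tiles(list(a = matrix(0, 5, 5), b = matrix(0, 6, 6)),
                 tibble::tibble(tile_id = c("a", "b"), stage_x_um = c(0, 10),
                                stage_y_um = 0, channel = "x"),
                 pixel_size = 2),
    class = "invalid_input"
  )
  # gaps are zero-filled with a warning
  expect_warning(
    gap <- stitch_tiles(list(a = matrix(1, 10, 10), b = matrix(1, 10, 10)),
                        tibble::tibble(tile_id = c("a", "b"),
                                       stage_x_um = c(0, 60), stage_y_um = 0,
                                       channel = "x"),
                        pixel_size = 2)
  )
  expect_true(any(gap$image == 0))
})

test_that("well detection lands within a pixel of rendered centroids", {
  rc <- rendered_chip()
  sb <- stitch_tiles(rc$bf)
  cent <- detect_wells(sb, rc$layout)
  expect_equal(nrow(cent), n_wells(rc$layout))
  truth <- well_centers(rc$layout)
  err_px <- pmax(abs(cent$x_um - truth$x_um),
                 abs(cent$y_um - truth$y_um)) / rc$layout$pixel_size
  expect_lt(max(err_px), 1)

  blank <- matrix(100, 400, 400)
  expect_error(detect_wells(blank, rc$layout, pixel_size = 2),
               class = "grid_fit_failure")
})

test_that("well quantification is background-subtracted and linear", {
  # uniform image measures ~0 everywhere
  flat <- matrix(77, 80, 80)
  cent <- tibble::tibble(x_um = 40, y_um = 40)
  m <- measure_wells(flat, cent, pixel_size = 1, well_radius_um = 8)
  expect_equal(m$fluorescence, 0)

  # planted disk 200 a.u. on background 50 -> 150, within 2%
  img <- matrix(50, 80, 80)
  for (i in 1:80) for (j in 1:80) {
    if ((i - 40.5)^2 + (j - 40.5)^2 <= 100) img[i, j] <- 200
  }
  m1 <- measure_wells(img, tibble::tibble(x_um = 40, y_um = 40),
                      pixel_size = 1, well_radius_um = 8)
  expect_equal(m1$fluorescence, 150, tolerance = 0.02)

  # doubling the planted signal above background doubles the measurement
  img2 <- matrix(50, 80, 80)
  for (i in 1:80) for (j in 1:80) {
    if ((i - 40.5)^2 + (j - 40.5)^2 <= 100) img2[i, j] <- 350
  }
  m2 <- measure_wells(img2, tibble::tibble(x_um = 40, y_um = 40),
                      pixel_size = 1, well_radius_um = 8)
  expect_equal(m2$fluorescence, 2 * m1$fluorescence, tolerance = 1e-9)

  # a disk reaching past the border is flagged edge-truncated
  me <- measure_wells(img, tibble::tibble(x_um = 5, y_um = 40),
                      pixel_size = 1, well_radius_um = 8)
  expect_true(me$edge)
})

test_that("hit calling thresholds at mean + k SD of empty wells", {
  set.seed(77)
  empties <- tibble::tibble(occupied = FALSE,
                            fluorescence = rep(c(95, 100, 105), 4))
  occ <- tibble::tibble(occupied = TRUE, fluorescence = c(120, 130))
  m <- rbind(empties, occ)
  mu <- mean(empties$fluorescence); s <- sd(empties$fluorescence)
  hits <- call_hits(m, k = 5)
  expect_equal(hits$threshold, mu + 5 * s)
  expect_equal(sum(hits$wells$hit), sum(occ$fluorescence >= mu + 5 * s))

  # worked threshold arithmetic: mean 100, SD 5, k 5 -> threshold 125,
  # wells at 120 and 130 -> one hit
  expect_equal(100 + 5 * 5, 125)
  expect_equal(sum(hits$wells$fluorescence[hits$wells$hit] > 125), 1)

  # hit count is non-increasing in k, and vanishes for huge k
  ks <- c(0, 1, 2, 5, 10, 1e6)
  counts <- vapply(ks, function(k) sum(call_hits(m, k)$wells$hit), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0)

  expect_error(call_hits(tibble::tibble(occupied = TRUE, fluorescence = 1)),
               class = "cannot_estimate_threshold")
})

test_that("noiseless render-measure round trip inverts the simulator", {
  rc <- rendered_chip()
  sb <- stitch_tiles(rc$bf)
  sf <- stitch_tiles(rc$fl)
  r_meas <- 0.8 * rc$layout$well_diameter / 2
  cent <- detect_wells(sb, rc$layout)
  cent <- call_occupancy(sb, cent, well_radius_um = r_meas)
  meas <- measure_wells(sf, cent, well_radius_um = r_meas)
  truth <- rc$fl$truth

  # occupancy exact, intensity within 1% relative error
  expect_identical(meas$occupied, truth$occupied)
  rel <- abs(meas$fluorescence - truth$intensity) / pmax(truth$intensity, 1)
  expect_lt(max(rel), 0.01)

  # hit set is exactly the wells holding a reactive clone
  hits <- call_hits(meas, k = 5)
  expect_setequal(hits$wells$well[hits$wells$hit],
                  truth$well[truth$intensity > 0])
})
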