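test_that("Poisson loading honours lambda, abundances and seeds", {
  layout <- tiny_layout()
  lib <- tiny_library()
  expect_error(simulate_loading(layout, -0.1), class = "invalid_parameter")

  empty <- simulate_loading(layout, 0, lib, seed = 1)
  expect_true(all(empty$n_cells == 0))
  expect_true(all(lengths(empty$clone_ids) == 0))

  occ <- simulate_loading(layout, 0.5, lib, seed = 2)
  expect_equal(lengths(occ$clone_ids), occ$n_cells)
  expect_true(all(unlist(occ$clone_ids) %in% lib$clones$clone_id))
  # determinism
  expect_identical(occ, simulate_loading(layout, 0.5, lib, seed = 2))
  expect_false(identical(occ$n_cells,
                         simulate_loading(layout, 0.5, lib, seed = 3)$n_cells))
})

test_that("tile rendering covers the chip and records exact ground truth", {
  rc <- rendered_chip()
  # noiseless rendering: per-well truth equals the per-clone intensity map
  intens <- rc$intensity
  expected <- vapply(rc$occupancy$clone_ids, function(ids) {
    if (!length(ids)) 0 else max(intens[ids])
  }, numeric(1))
  expect_equal(rc$fl$truth$intensity, expected)
  expect_equal(rc$fl$truth$occupied, rc$occupancy$n_cells > 0)

  # chip width 2x tile FOV with 10% overlap -> 3 tiles along x
  wide <- chip_layout(2, 24, pitch = 80, pixel_size = 2, tile_fov = 1000,
                      margin = 40)
  expect_equal(wide$width, 2000)
  occ <- simulate_loading(wide, 0, seed = 1)
  ts <- render_tiles(wide, occ, numeric(), "fluorescence", overlap = 0.1)
  expect_equal(length(unique(ts$manifest$stage_x_um)), 3)

  # empty chip in fluorescence is pure background plus the fiducials
  blank <- render_tiles(rc$layout, simulate_loading(rc$layout, 0, seed = 1),
                        numeric(), "fluorescence")
  expect_true(all(blank$image %in% c(100, 1000)))
  expect_error(render_tiles(rc$layout, rc$occupancy, overlap = 0.7),
               class = "invalid_parameter")
  # determinism of noisy renders
  n1 <- render_tiles(rc$layout, rc$occupancy, rc$intensity, "brightfield",
                     noise_sd = 20, seed = 9)
  n2 <- render_tiles(rc$layout, rc$occupancy, rc$intensity, "brightfield",
                     noise_sd = 20, seed = 9)
  expect_identical(n1$image, n2$image)
})

test_that("disassembly distortion applies the exact transform plus jitter", {
  pts <- well_centers(tiny_layout())[, c("x_um", "y_um")]
  ident <- planar_transform()
  expect_equal(apply_disassembly_distortion(pts, ident)[, c("x_um", "y_um")],
               pts, ignore_attr = TRUE)

  tr <- similarity_transform(scale = 1.01, rotation_deg = 0.5,
                             tx = 12.3, ty = -4.5)
  got <- apply_disassembly_distortion(pts, tr)
  th <- 0.5 * pi / 180
  expect_equal(got$x_um, 1.01 * (cos(th) * pts$x_um - sin(th) * pts$y_um) + 12.3)
  expect_equal(got$y_um, 1.01 * (sin(th) * pts$x_um + cos(th) * pts$y_um) - 4.5)

  # pure translation is an isometry
  shift <- apply_disassembly_distortion(pts, planar_transform(tx = 40, ty = -7))
  expect_equal(c(dist(cbind(shift$x_um, shift$y_um))),
               c(dist(cbind(pts$x_um, pts$y_um))))
  expect_error(planar_transform(1, 1, 1, 1, 0, 0), class = "degenerate_transform")
})

test_that("read simulation plants errors at the configured rates", {
  lib0 <- tiny_library(sub_rate = 0, frameshift_rate = 0, lowq_rate = 0,
                       revcomp_frac = 0)
  reads <- simulate_reads(lib0, c(C001 = 5, C003 = 2), seed = 4)
  expect_equal(nrow(reads), 7)
  cons <- construct_nt(lib0$template,
                       vh_nt = lib0$clones$vh_nt[lib0$clones$clone_id == "C001"])
  expect_true(all(reads$seq[reads$clone_id == "C001"] == cons))
  expect_error(simulate_reads(lib0, c(NOPE = 1)), class = "invalid_input")
  expect_identical(reads, simulate_reads(lib0, c(C001 = 5, C003 = 2), seed = 4))

  # substitution count: binomial with mean L * rate, checked against an
  # independent character-level mismatch count
  lib_sub <- tiny_library(sub_rate = 0.01, revcomp_frac = 0)
  L <- nchar(construct_nt(lib_sub$template))
  n <- 400
  rs <- simulate_reads(lib_sub, c(C001 = n), seed = 5)
  ref <- strsplit(construct_nt(lib_sub$template,
                               vh_nt = lib_sub$clones$vh_nt[1]), "")[[1]]
  mism <- vapply(strsplit(rs$seq, ""), function(s) sum(s != ref), numeric(1))
  expect_equal(mism, rs$n_subs)
  se <- sqrt(L * 0.01 * 0.99 / n)
  expect_lt(abs(mean(mism) - L * 0.01), 3 * se)

  # frameshift fraction: binomial check, and flagged reads change length
  lib_fs <- tiny_library(frameshift_rate = 0.1, revcomp_frac = 0)
  rf <- simulate_reads(lib_fs, c(C001 = 500), seed = 6)
  se_fs <- sqrt(0.1 * 0.9 / 500)
  expect_lt(abs(mean(rf$frameshift) - 0.1), 3 * se_fs)
  expect_true(all(nchar(rf$seq[rf$frameshift]) != L))
  expect_true(all(nchar(rf$seq[!rf$frameshift]) == L))

  # reverse-complemented reads round-trip to the template
  lib_rc <- tiny_library(revcomp_frac = 1)
  rr <- simulate_reads(lib_rc, c(C001 = 3), seed = 7)
  back <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rr$seq)))
  cons_rc <- construct_nt(lib_rc$template, vh_nt = lib_rc$clones$vh_nt[1])
  expect_true(all(back == cons_rc))
})

test_that("simulated ELISA plates separate reactive and non-reactive clones", {
  expect_error(simulate_elisa("A", TRUE, n_negative = 1), class = "invalid_design")

  exact <- simulate_elisa(c("A", "B"), c(TRUE, FALSE), neg_sd = 0, seed = 1)
  expect_true(all(exact$absorbance[exact$role == "negative"] == 0.15))

  # 78 reactive + 21 non-reactive -> confirmation rate 78/99 downstream
  ids <- sprintf("K%03d", 1:99)
  reactive <- c(rep(TRUE, 78), rep(FALSE, 21))
  plate <- simulate_elisa(ids, reactive, seed = 8)
  calls <- call_ar_clones(plate, k = 5)
  expect_equal(calls$n_ar, 78)
  expect_equal(round(100 * calls$confirmation_rate, 1), 78.8)
  expect_identical(calls$calls$ar_call, reactive)

  none <- simulate_elisa(ids[1:5], rep(FALSE, 5), seed = 9)
  expect_equal(call_ar_clones(none)$n_ar, 0)
  expect_identical(plate, simulate_elisa(ids, reactive, seed = 8))
})
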