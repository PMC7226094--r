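#' Stitch scanned tiles into one chip image
#'
#' Places each tile on a zero-initialised canvas at its stage position
#' (converted to pixels); overlapping regions are resolved by the later tile
#' (last-write, no blending, so noiseless reconstructions are pixel-exact).
#' An optional integer-shift cross-correlation refinement nudges each tile
#' within a small search radius to best agree with what is already on the
#' canvas.
#'
#' @param tiles Named list of numeric matrices (or a `tile_set`, in which
#'   case `manifest` and `pixel_size` are taken from it).
#' @param manifest Tibble with `tile_id`, `stage_x_um`, `stage_y_um`,
#'   `channel`.
#' @param pixel_size Micrometres per pixel.
#' @param refine_px Search radius (pixels) for stage-position refinement;
#'   0 (default) trusts the stage positions.
#' @return A list of class `stitched_image`: `image` (matrix), `pixel_size`,
#'   `channel`.
#' @export
stitch_tiles <- function(tiles, manifest = NULL, pixel_size = NULL,
                         refine_px = 0) {
  if (inherits(tiles, "tile_set")) {
    manifest <- manifest %||% tiles$manifest
    pixel_size <- pixel_size %||% tiles$pixel_size
    tiles <- tiles$tiles
  }
  stopifnot(is.list(tiles), !is.null(manifest), !is.null(pixel_size))
  if (length(unique(manifest$channel)) > 1L) {
    ws_abort("All tiles must share one channel.", "invalid_input")
  }
  dims <- vapply(tiles, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    ws_abort("All tiles must have identical dimensions.", "invalid_input")
  }
  h <- dims[1, 1]; w <- dims[2, 1]
  x0 <- round(manifest$stage_x_um / pixel_size)
  y0 <- round(manifest$stage_y_um / pixel_size)
  nx <- max(x0) + w; ny <- max(y0) + h
  canvas <- matrix(NA_real_, ny, nx)
  ord <- order(match(manifest$tile_id, names(tiles)))
  for (k in ord) {
    tl <- tiles[[manifest$tile_id[k]]]
    xo <- x0[k]; yo <- y0[k]
    if (refine_px > 0 && k > ord[1]) {
      best <- c(0, 0); best_err <- Inf
      for (dy in -refine_px:refine_px) for (dx in -refine_px:refine_px) {
        yy <- (yo + dy + 1):(yo + dy + h); xx <- (xo + dx + 1):(xo + dx + w)
        if (min(yy) < 1 || min(xx) < 1 || max(yy) > ny || max(xx) > nx) next
        ref <- canvas[yy, xx]
        ok <- !is.na(ref)
        if (sum(ok) < 100) next
        err <- mean((ref[ok] - tl[ok])^2)
        if (err < best_err) { best_err <- err; best <- c(dy, dx) }
      }
      yo <- yo + best[1]; xo <- xo + best[2]
    }
    canvas[(yo + 1):(yo + h), (xo + 1):(xo + w)] <- tl
  }
  if (anyNA(canvas)) {
    warn("Tile coverage has gaps; uncovered pixels set to 0.")
    canvas[is.na(canvas)] <- 0
  }
  structure(list(image = canvas, pixel_size = pixel_size,
                 channel = manifest$channel[1]),
            class = "stitched_image")
}

#' @export
print.stitched_image <- function(x, ...) {
  cat(sprintf("<stitched_image> %s, %d x %d px at %g um/px (%.0f x %.0f um)\n",
              x$channel, nrow(x$image), ncol(x$image), x$pixel_size,
              ncol(x$image) * x$pixel_size, nrow(x$image) * x$pixel_size))
  invisible(x)
}

as_image_matrix <- function(x) {
  if (inherits(x, "stitched_image")) x$image else x
}

# circular cross-correlation of `img` with a centred disk of radius r_px,
# normalised to the disk mean; FFT-based, O(N log N)
disk_response <- function(img, r_px) {
  ny <- nrow(img); nx <- ncol(img)
  R <- ceiling(r_px)
  d <- expand.grid(di = -R:R, dj = -R:R)
  d <- d[d$di^2 + d$dj^2 <= r_px^2, ]
  K <- matrix(0, ny, nx)
  K[cbind(d$di %% ny + 1, d$dj %% nx + 1)] <- 1
  resp <- Re(stats::fft(stats::fft(img) * Conj(stats::fft(K)), inverse = TRUE)) /
    length(img)
  resp / nrow(d)
}

#' Locate microwell centroids on a stitched brightfield image
#'
#' Detection by grid-phase fitting: the image is correlated with a disk
#' template (wells image darker than the PDMS background, so the negated
#' image is used), the lattice offset that maximises the summed response at
#' the layout's predicted well positions is searched over one pitch, and
#' each well centroid is then refined to the local response peak with
#' sub-pixel quadratic interpolation.
#'
#' @param image A `stitched_image` (brightfield) or plain matrix.
#' @param layout The [chip_layout()] prior (pitch accurate to ~20%).
#' @param pixel_size Micrometres per pixel (taken from `image` when it is a
#'   `stitched_image`).
#' @param min_found Minimum fraction of wells with a clear local response
#'   peak; below this a grid-fit failure is raised.
#' @return A tibble with `well`, `row`, `col`, pixel centroids `x_px`,
#'   `y_px`, physical centroids `x_um`, `y_um`, the template `response` and
#'   a `found` flag.
#' @export
detect_wells <- function(image, layout, pixel_size = NULL, min_found = 0.5) {
  stopifnot(inherits(layout, "chip_layout"))
  if (inherits(image, "stitched_image")) pixel_size <- pixel_size %||% image$pixel_size
  pixel_size <- pixel_size %||% layout$pixel_size
  img <- as_image_matrix(image)
  signal <- mean(img) - img # wells are darker than background
  r_px <- (layout$well_diameter / 2) / pixel_size
  resp <- disk_response(signal, r_px)
  ny <- nrow(img); nx <- ncol(img)

  wells <- well_centers(layout)
  px0 <- round(um_to_px(wells$x_um, pixel_size))
  py0 <- round(um_to_px(wells$y_um, pixel_size))
  p_px <- layout$pitch / pixel_size
  hmax <- max(1L, floor(p_px / 2))
  offs <- expand.grid(dy = -hmax:hmax, dx = -hmax:hmax)
  scores <- vapply(seq_len(nrow(offs)), function(k) {
    yy <- py0 + offs$dy[k]; xx <- px0 + offs$dx[k]
    ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
    if (!any(ok)) return(-Inf)
    mean(resp[cbind(yy[ok], xx[ok])])
  }, numeric(1))
  s_sd <- sd(scores[is.finite(scores)])
  if (!is.finite(s_sd) || s_sd == 0) {
    ws_abort("Grid-phase fit failed: no well lattice detected in the image.",
             "grid_fit_failure")
  }
  best <- offs[which.max(scores), ]
  cx <- px0 + best$dx; cy <- py0 + best$dy

  w <- max(2L, floor(p_px / 4))
  r_sd <- sd(resp); r_mu <- mean(resp)
  out <- purrr::map(seq_len(nrow(wells)), function(i) {
    yy <- max(1, cy[i] - w):min(ny, cy[i] + w)
    xx <- max(1, cx[i] - w):min(nx, cx[i] + w)
    win <- resp[yy, xx, drop = FALSE]
    pk <- which(win == max(win), arr.ind = TRUE)[1, ]
    py <- yy[pk[1]]; px <- xx[pk[2]]
    # separable quadratic sub-pixel refinement at the peak
    sub <- function(m1, m2, m3) {
      den <- m1 - 2 * m2 + m3
      if (den >= 0 || !is.finite(den)) 0 else max(-0.5, min(0.5, 0.5 * (m1 - m3) / den))
    }
    dx <- if (px > 1 && px < nx) sub(resp[py, px - 1], resp[py, px], resp[py, px + 1]) else 0
    dy <- if (py > 1 && py < ny) sub(resp[py - 1, px], resp[py, px], resp[py + 1, px]) else 0
    tibble(x_px = px + dx, y_px = py + dy, response = max(win))
  }) |> purrr::list_rbind()
  wells$x_px <- out$x_px
  wells$y_px <- out$y_px
  wells$x_um <- px_to_um(out$x_px, pixel_size)
  wells$y_um <- px_to_um(out$y_px, pixel_size)
  wells$response <- out$response
  wells$found <- out$response > r_mu + 2 * r_sd
  if (mean(wells$found) < min_found) {
    ws_abort(sprintf("Grid fit found only %.0f%% of expected wells.",
                     100 * mean(wells$found)), "grid_fit_failure")
  }
  wells
}

well_pixel_stats <- function(img, cx_px, cy_px, radii_px) {
  ny <- nrow(img); nx <- ncol(img)
  R <- ceiling(max(radii_px))
  yy <- (round(cy_px) - R):(round(cy_px) + R)
  xx <- (round(cx_px) - R):(round(cx_px) + R)
  edge <- min(yy) < 1 || min(xx) < 1 || max(yy) > ny || max(xx) > nx
  yy <- yy[yy >= 1 & yy <= ny]; xx <- xx[xx >= 1 & xx <= nx]
  d2 <- outer((yy - cy_px)^2, (xx - cx_px)^2, `+`)
  list(window = img[yy, xx, drop = FALSE], d2 = d2, edge = edge)
}

#' Quantify per-well fluorescence
#'
#' For each centroid, the signal is the mean intensity over the well disk
#' minus the median of a surrounding background annulus (the median is
#' robust to bright neighbouring wells). Wells whose annulus extends past
#' the image border are flagged `edge` and should be excluded from hit
#' calling.
#'
#' @param image A fluorescence `stitched_image` or matrix.
#' @param centroids Tibble from [detect_wells()] (`x_um`, `y_um` used).
#' @param pixel_size Micrometres per pixel.
#' @param well_radius_um Radius of the measured disk; defaults to 80% of the
#'   layout well radius (attached to `centroids` calls pass it explicitly)
#'   to avoid partial rim pixels.
#' @param annulus Inner/outer annulus radii as multiples of
#'   `well_radius_um`.
#' @return `centroids` with `fluorescence` and `edge` columns added.
#' @export
measure_wells <- function(image, centroids, pixel_size = NULL,
                          well_radius_um, annulus = c(1.4, 2.0)) {
  if (inherits(image, "stitched_image")) pixel_size <- pixel_size %||% image$pixel_size
  stopifnot(!is.null(pixel_size))
  img <- as_image_matrix(image)
  r <- well_radius_um / pixel_size
  ann <- annulus * r
  out <- purrr::map(seq_len(nrow(centroids)), function(i) {
    st <- well_pixel_stats(img, um_to_px(centroids$x_um[i], pixel_size),
                           um_to_px(centroids$y_um[i], pixel_size),
                           ann[2])
    disk <- st$d2 <= r^2
    ring <- st$d2 > ann[1]^2 & st$d2 <= ann[2]^2
    fl <- if (!any(disk) || !any(ring)) NA_real_ else {
      mean(st$window[disk]) - median(st$window[ring])
    }
    tibble(fluorescence = fl, edge = st$edge)
  }) |> purrr::list_rbind()
  centroids$fluorescence <- out$fluorescence
  centroids$edge <- out$edge
  as_tibble(centroids)
}

#' Call per-well cell occupancy from brightfield
#'
#' A well that trapped cells shows textured content (cell bodies) against
#' the uniform dark well interior; occupancy is called when the interior
#' pixel variance exceeds a multiple of the blank-well variance, estimated
#' robustly as the median interior variance across all wells (valid under
#' dilute loading, where most wells are empty).
#'
#' @param image Brightfield `stitched_image` or matrix.
#' @param centroids Tibble from [detect_wells()].
#' @param pixel_size Micrometres per pixel.
#' @param well_radius_um Interior radius inspected.
#' @param mult Variance multiple over blank wells that calls occupancy.
#' @return `centroids` with `interior_var` and `occupied` columns added.
#' @export
call_occupancy <- function(image, centroids, pixel_size = NULL,
                           well_radius_um, mult = 5) {
  if (inherits(image, "stitched_image")) pixel_size <- pixel_size %||% image$pixel_size
  stopifnot(!is.null(pixel_size))
  img <- as_image_matrix(image)
  r <- well_radius_um / pixel_size
  v <- purrr::map_dbl(seq_len(nrow(centroids)), function(i) {
    st <- well_pixel_stats(img, um_to_px(centroids$x_um[i], pixel_size),
                           um_to_px(centroids$y_um[i], pixel_size), r)
    px <- st$window[st$d2 <= r^2]
    if (length(px) < 4) NA_real_ else var(px)
  })
  blank <- median(v, na.rm = TRUE)
  centroids$interior_var <- v
  centroids$occupied <- !is.na(v) & v > pmax(mult * blank, 1e-9)
  as_tibble(centroids)
}

#' Call antigen-reactive hit wells
#'
#' The fluorescence threshold is estimated from empty (unoccupied) wells as
#' `mean + k * SD` of their background-subtracted intensities; a well is a
#' hit when it is occupied, not edge-truncated, and its fluorescence reaches
#' the threshold.
#'
#' @param measurements Tibble with `occupied`, `fluorescence` and optionally
#'   `edge` columns (see [measure_wells()] / [call_occupancy()]).
#' @param k SD multiplier (default 5, the same rule the ELISA confirmation
#'   step uses).
#' @return An object of class `hit_calls`: list with `wells` (the input plus
#'   `hit`), `threshold`, `empty_mean`, `empty_sd`, `n_empty`, `k`.
#' @examples
#' m <- tibble::tibble(occupied = c(rep(FALSE, 10), TRUE, TRUE),
#'                     fluorescence = c(rnorm(10, 100, 5), 120, 130))
#' call_hits(m, k = 5)
#' @export
call_hits <- function(measurements, k = 5) {
  stopifnot(all(c("occupied", "fluorescence") %in% names(measurements)))
  edge <- if ("edge" %in% names(measurements)) measurements$edge else rep(FALSE, nrow(measurements))
  empty <- !measurements$occupied & !edge & is.finite(measurements$fluorescence)
  if (sum(empty) < 2) {
    ws_abort("Cannot estimate the background threshold: fewer than 2 empty wells.",
             "cannot_estimate_threshold")
  }
  if (sum(empty) < 10) {
    warn("Fewer than 10 empty wells; background statistics are unstable.")
  }
  mu <- mean(measurements$fluorescence[empty])
  s <- sd(measurements$fluorescence[empty])
  thr <- mu + k * s
  # `>= thr` per the mean + k SD rule; the additional strict `> mu` only
  # binds when the empty-well background is noiseless (SD 0), where a
  # signal-free occupied well would otherwise tie the threshold
  measurements$hit <- measurements$occupied & !edge &
    is.finite(measurements$fluorescence) & measurements$fluorescence >= thr &
    measurements$fluorescence > mu
  structure(
    list(wells = as_tibble(measurements), threshold = thr, empty_mean = mu,
         empty_sd = s, n_empty = sum(empty), k = k),
    class = "hit_calls"
  )
}

#' @export
print.hit_calls <- function(x, ...) {
  cat(sprintf("<hit_calls> %d / %d wells above threshold %.2f (empty: mean %.2f, SD %.2f, n %d, k %g)\n",
              sum(x$wells$hit), nrow(x$wells), x$threshold, x$empty_mean,
              x$empty_sd, x$n_empty, x$k))
  invisible(x)
}

#' @export
tidy.hit_calls <- function(x, ...) x$wells

#' @export
glance.hit_calls <- function(x, ...) {
  tibble(n_wells = nrow(x$wells), n_occupied = sum(x$wells$occupied),
         n_hits = sum(x$wells$hit), threshold = x$threshold,
         empty_mean = x$empty_mean, empty_sd = x$empty_sd,
         n_empty = x$n_empty, k = x$k)
}

#' @export
autoplot.hit_calls <- function(object, ...) {
  ggplot2::ggplot(object$wells,
                  ggplot2::aes(x = .data$fluorescence, fill = .data$occupied)) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$threshold,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = "background-subtracted fluorescence (a.u.)", y = "wells",
                  title = sprintf("Hit threshold %.1f (mean + %g SD of empty wells)",
                                  object$threshold, object$k)) +
    ggplot2::theme_minimal()
}
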