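#' First-order (affine) planar transform
#'
#' The six-parameter first-order model used to compensate the distortion an
#' elastomeric chip suffers during disassembly:
#' `x' = a11 x + a12 y + tx`, `y' = a21 x + a22 y + ty`.
#' A full affine is used (rather than a similarity) because a peeled PDMS
#' slab stretches anisotropically; [similarity_transform()] builds the
#' restricted rotation+scale+shift special case.
#'
#' @param a11,a12,a21,a22 Linear part (dimensionless).
#' @param tx,ty Translation (um).
#' @return An object of class `planar_transform` (2x2 matrix `A`, length-2
#'   `t`).
#' @examples
#' planar_transform(1, 0, 0, 1, 5, 0)
#' similarity_transform(scale = 1.01, rotation_deg = 0.5, tx = 12.3, ty = -4.5)
#' @export
planar_transform <- function(a11 = 1, a12 = 0, a21 = 0, a22 = 1, tx = 0, ty = 0) {
  A <- matrix(c(a11, a21, a12, a22), 2, 2)
  if (any(!is.finite(A)) || any(!is.finite(c(tx, ty)))) {
    ws_abort("Transform parameters must be finite.", "degenerate_transform")
  }
  if (abs(det(A)) <= 1e-6) {
    ws_abort("Transform is degenerate (|det| <= 1e-6).", "degenerate_transform")
  }
  structure(list(A = A, t = c(tx, ty)), class = "planar_transform")
}

#' @rdname planar_transform
#' @param scale Isotropic scale factor.
#' @param rotation_deg Rotation angle, degrees counter-clockwise.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0, tx = 0, ty = 0) {
  th <- rotation_deg * pi / 180
  planar_transform(scale * cos(th), -scale * sin(th),
                   scale * sin(th), scale * cos(th), tx, ty)
}

#' @export
print.planar_transform <- function(x, ...) {
  cat(sprintf("<planar_transform> A = [%.6g %.6g; %.6g %.6g], t = (%.6g, %.6g) um, det %.6g\n",
              x$A[1, 1], x$A[1, 2], x$A[2, 1], x$A[2, 2], x$t[1], x$t[2], det(x$A)))
  invisible(x)
}

#' Apply a planar transform to coordinates
#'
#' @param transform A [planar_transform()] (or the `$transform` of a
#'   [fit_transform()] result).
#' @param points A data frame with columns `x_um`, `y_um`.
#' @param inverse Map through the inverse transform instead.
#' @return `points` with `x_um`, `y_um` replaced by their images; all other
#'   columns preserved.
#' @export
map_coordinates <- function(transform, points, inverse = FALSE) {
  transform <- as_planar_transform(transform)
  stopifnot(all(c("x_um", "y_um") %in% names(points)))
  xy <- rbind(points$x_um, points$y_um)
  if (inverse) {
    out <- solve(transform$A, xy - transform$t)
  } else {
    out <- transform$A %*% xy + transform$t
  }
  points$x_um <- out[1, ]
  points$y_um <- out[2, ]
  as_tibble(points)
}

#' @rdname map_coordinates
#' @return `invert_transform()`: the inverse `planar_transform`.
#' @export
invert_transform <- function(transform) {
  transform <- as_planar_transform(transform)
  Ai <- solve(transform$A)
  planar_transform(Ai[1, 1], Ai[1, 2], Ai[2, 1], Ai[2, 2],
                   -(Ai %*% transform$t)[1], -(Ai %*% transform$t)[2])
}

as_planar_transform <- function(x) {
  if (inherits(x, "planar_transform_fit")) x <- x$transform
  if (!inherits(x, "planar_transform")) {
    ws_abort("Expected a `planar_transform`.", "degenerate_transform")
  }
  x
}

#' Fit the first-order transform from fiducial marker pairs
#'
#' Least-squares fit of the 6-parameter affine model mapping pre-disassembly
#' marker coordinates onto their post-disassembly positions. Requires at
#' least 3 non-collinear corresponding pairs (markers correspond by order).
#'
#' @param src_markers,dst_markers Data frames with `x_um`, `y_um`, equal row
#'   counts in corresponding order.
#' @param model `"affine"` (default) or `"similarity"` (rotation + isotropic
#'   scale + translation, fitted by Procrustes-style least squares).
#' @return An object of class `planar_transform_fit`: list with `transform`
#'   (a [planar_transform()]), `residuals` (per-marker tibble with `dx`,
#'   `dy`, `resid` in um) and `rms` residual.
#' @examples
#' src <- tibble::tibble(x_um = c(0, 100, 0, 100), y_um = c(0, 0, 100, 100))
#' dst <- map_coordinates(similarity_transform(1.01, 0.5, 12.3, -4.5), src)
#' fit <- fit_transform(src, dst)
#' glance(fit)
#' @export
fit_transform <- function(src_markers, dst_markers,
                          model = c("affine", "similarity")) {
  model <- match.arg(model)
  stopifnot(all(c("x_um", "y_um") %in% names(src_markers)),
            all(c("x_um", "y_um") %in% names(dst_markers)))
  n <- nrow(src_markers)
  if (n != nrow(dst_markers)) {
    ws_abort("Marker sets must have equal length.", "degenerate_configuration")
  }
  if (n < 3) {
    ws_abort("At least 3 marker pairs are required.", "degenerate_configuration")
  }
  X <- cbind(src_markers$x_um, src_markers$y_um, 1)
  if (qr(X)$rank < 3) {
    ws_abort("Markers are collinear; the transform is unidentifiable.",
             "degenerate_configuration")
  }
  if (model == "affine") {
    beta <- qr.solve(X, cbind(dst_markers$x_um, dst_markers$y_um))
    tr <- planar_transform(beta[1, 1], beta[2, 1], beta[1, 2], beta[2, 2],
                           beta[3, 1], beta[3, 2])
  } else {
    # similarity: closed-form least squares (Umeyama/Procrustes with scale)
    s_c <- c(mean(src_markers$x_um), mean(src_markers$y_um))
    d_c <- c(mean(dst_markers$x_um), mean(dst_markers$y_um))
    S <- cbind(src_markers$x_um - s_c[1], src_markers$y_um - s_c[2])
    D <- cbind(dst_markers$x_um - d_c[1], dst_markers$y_um - d_c[2])
    a <- sum(S * D) / sum(S^2)
    b <- sum(S[, 1] * D[, 2] - S[, 2] * D[, 1]) / sum(S^2)
    A <- matrix(c(a, b, -b, a), 2, 2)
    t <- d_c - A %*% s_c
    tr <- planar_transform(A[1, 1], A[1, 2], A[2, 1], A[2, 2], t[1], t[2])
  }
  pred <- map_coordinates(tr, src_markers[c("x_um", "y_um")])
  res <- tibble(
    marker = if ("marker" %in% names(src_markers)) src_markers$marker else seq_len(n),
    dx = dst_markers$x_um - pred$x_um,
    dy = dst_markers$y_um - pred$y_um
  )
  res$resid <- sqrt(res$dx^2 + res$dy^2)
  structure(
    list(transform = tr, residuals = res,
         rms = sqrt(mean(res$dx^2 + res$dy^2)), model = model, n_markers = n),
    class = "planar_transform_fit"
  )
}

#' @export
print.planar_transform_fit <- function(x, ...) {
  cat(sprintf("<planar_transform_fit> %s from %d markers, RMS residual %.4g um\n",
              x$model, x$n_markers, x$rms))
  print(x$transform)
  invisible(x)
}

#' @export
tidy.planar_transform_fit <- function(x, ...) {
  tibble(
    term = c("a11", "a12", "a21", "a22", "tx", "ty"),
    estimate = c(x$transform$A[1, 1], x$transform$A[1, 2],
                 x$transform$A[2, 1], x$transform$A[2, 2],
                 x$transform$t[1], x$transform$t[2])
  )
}

#' @export
glance.planar_transform_fit <- function(x, ...) {
  tibble(model = x$model, n_markers = x$n_markers, rms_resid_um = x$rms,
         max_resid_um = max(x$residuals$resid), det = det(x$transform$A))
}

#' @export
autoplot.planar_transform_fit <- function(object, ...) {
  r <- object$residuals
  ggplot2::ggplot(r, ggplot2::aes(x = .data$dx, y = .data$dy)) +
    ggplot2::geom_point(colour = "#d7301f") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "residual dx (um)", y = "residual dy (um)",
                  title = sprintf("Marker residuals (RMS %.3g um)", object$rms)) +
    ggplot2::theme_minimal()
}

#' Plan laser-driven retrieval of hit wells
#'
#' Orders the mapped hit positions on the sample-capturing substrate
#' (row-major: by `y_um`, then `x_um`), converts consecutive coordinate
#' differences into stage displacements through the calibration factors, and
#' assigns targets sequentially to pooled collection tubes.
#'
#' @param targets A data frame of substrate positions with `x_um`, `y_um`
#'   (extra columns such as `row`/`col` are carried through). May be empty.
#' @param pool_size Targets collected per tube (>= 1; default 48, one
#'   retrieval batch per sample).
#' @param calibration Length-2 stage calibration (steps per um in x and y);
#'   default identity.
#' @param order `"row_major"` (default) or `"as_is"`.
#' @return A tibble `target_id`, carried columns, `x_um`, `y_um`, stage
#'   displacements `dx`, `dy` (from the previous target; the first is from
#'   the stage origin), and `tube`.
#' @examples
#' plan_retrieval(tibble::tibble(x_um = c(0, 85), y_um = c(0, 0)))
#' @export
plan_retrieval <- function(targets, pool_size = 48, calibration = c(1, 1),
                           order = c("row_major", "as_is")) {
  order <- match.arg(order)
  if (!is.numeric(pool_size) || pool_size < 1) {
    ws_abort("`pool_size` must be >= 1.", "invalid_parameter")
  }
  if (length(calibration) != 2 || any(!is.finite(calibration))) {
    ws_abort("`calibration` must be two finite factors.", "invalid_parameter")
  }
  targets <- as_tibble(targets)
  stopifnot(all(c("x_um", "y_um") %in% names(targets)))
  if (nrow(targets) == 0L) {
    targets$target_id <- integer()
    targets$dx <- numeric()
    targets$dy <- numeric()
    targets$tube <- integer()
    return(dplyr::relocate(targets, "target_id"))
  }
  if (order == "row_major") {
    targets <- dplyr::arrange(targets, .data$y_um, .data$x_um)
  }
  targets$target_id <- seq_len(nrow(targets))
  targets$dx <- c(targets$x_um[1], diff(targets$x_um)) * calibration[1]
  targets$dy <- c(targets$y_um[1], diff(targets$y_um)) * calibration[2]
  targets$tube <- as.integer(ceiling(targets$target_id / pool_size))
  dplyr::relocate(targets, "target_id")
}
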