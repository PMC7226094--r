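#' Poisson single-cell loading statistics
#'
#' When a dilute cell suspension is dispensed over a microwell array, the
#' number of cells trapped per well is Poisson distributed with mean
#' `lambda` (cells/well). These closed forms connect the loading
#' concentration to the occupancy fraction, the single-cell purity among
#' occupied wells, and the expected number of single-cell assays per chip.
#'
#' * occupied fraction: `P(N > 0) = 1 - exp(-lambda)`
#' * single-cell fraction among occupied wells:
#'   `lambda * exp(-lambda) / (1 - exp(-lambda))`
#'
#' At 10% occupancy (`lambda = -log(0.9) ~ 0.105`) about 95% of occupied
#' wells hold a single cell; at `lambda = 0.1` roughly 5% of non-empty wells
#' are multi-cell.
#'
#' @param lambda Mean cells per well (>= 0).
#' @return `loading_model()` returns a one-row tibble with `lambda`,
#'   `p_occupied`, `p_single_given_occupied` and `p_multi_given_occupied`.
#' @examples
#' loading_model(lambda_for_occupancy(0.10))
#' @export
loading_model <- function(lambda) {
  check_lambda(lambda)
  tibble(
    lambda = lambda,
    p_occupied = occupancy_for_lambda(lambda),
    p_single_given_occupied = single_cell_fraction(lambda),
    p_multi_given_occupied = 1 - single_cell_fraction(lambda)
  )
}

check_lambda <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    ws_abort("`lambda` must be finite and non-negative.", "invalid_parameter")
  }
  invisible(lambda)
}

#' @rdname loading_model
#' @return `occupancy_for_lambda()`: the occupied-well fraction `1 - exp(-lambda)`.
#' @export
occupancy_for_lambda <- function(lambda) {
  check_lambda(lambda)
  1 - exp(-lambda)
}

#' @rdname loading_model
#' @param p_occupied Target occupied-well fraction, in `[0, 1)`.
#' @return `lambda_for_occupancy()`: the loading concentration
#'   `lambda = -log(1 - p_occupied)` achieving that occupancy.
#' @export
lambda_for_occupancy <- function(p_occupied) {
  if (any(!is.finite(p_occupied)) || any(p_occupied < 0) || any(p_occupied >= 1)) {
    ws_abort("`p_occupied` must lie in [0, 1).", "invalid_parameter")
  }
  -log(1 - p_occupied)
}

#' @rdname loading_model
#' @return `single_cell_fraction()`: the fraction of occupied wells holding
#'   exactly one cell. The `lambda -> 0` limit is 1 and is returned (with a
#'   `"limit"` attribute) when `lambda = 0`.
#' @export
single_cell_fraction <- function(lambda) {
  check_lambda(lambda)
  out <- ifelse(lambda == 0, 1, lambda * exp(-lambda) / -expm1(-lambda))
  if (any(lambda == 0)) attr(out, "limit") <- TRUE
  out
}

#' Expected single-cell assays on one chip
#'
#' `n_wells * p_occupied * single_cell_fraction(lambda(p_occupied))`: the
#' expected number of wells that host exactly one cell, i.e. valid
#' single-clone assays. A 113,000-well chip loaded to 10% occupancy yields
#' over 10,000 such assays.
#'
#' @param n_wells Number of wells on the chip (>= 0).
#' @param p_occupied Occupied-well fraction in `[0, 1)`.
#' @return Expected single-cell assay count (not rounded).
#' @examples
#' assays_per_chip(113000, 0.10)
#' @export
assays_per_chip <- function(n_wells, p_occupied) {
  if (any(!is.finite(n_wells)) || any(n_wells < 0)) {
    ws_abort("`n_wells` must be non-negative.", "invalid_parameter")
  }
  lam <- lambda_for_occupancy(p_occupied)
  n_wells * p_occupied * single_cell_fraction(lam)
}

#' Library coverage of a screen
#'
#' Fraction of the library complexity interrogated when `n_screened` clones
#' are screened, treating each screened well as one clone draw (no collision
#' correction). `expected_unique_clones()` gives the collision-corrected
#' expectation `complexity * (1 - exp(-n/complexity))` for comparison.
#'
#' @param n_screened Number of clones screened (>= 0).
#' @param complexity Library complexity (> 0).
#' @return `coverage_fraction()`: `n_screened / complexity` (unrounded).
#' @examples
#' coverage_fraction(70000, 5.21e5)
#' @export
coverage_fraction <- function(n_screened, complexity) {
  if (any(!is.finite(complexity)) || any(complexity <= 0)) {
    ws_abort("`complexity` must be positive.", "invalid_parameter")
  }
  if (any(!is.finite(n_screened)) || any(n_screened < 0)) {
    ws_abort("`n_screened` must be non-negative.", "invalid_parameter")
  }
  n_screened / complexity
}

#' @rdname coverage_fraction
#' @return `expected_unique_clones()`: expected distinct clones drawn.
#' @export
expected_unique_clones <- function(n_screened, complexity) {
  if (any(!is.finite(complexity)) || any(complexity <= 0)) {
    ws_abort("`complexity` must be positive.", "invalid_parameter")
  }
  complexity * (1 - exp(-n_screened / complexity))
}
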