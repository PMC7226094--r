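#' Simulate a phage ELISA plate
#'
#' Builds an absorbance table for a set of tested clones together with
#' negative- and positive-control wells. Negative controls are drawn from a
#' normal distribution truncated at 0; non-reactive target clones share that
#' distribution; reactive clones are drawn well above the
#' mean-plus-five-SD calling threshold (their draws are floored at
#' `neg_mean + 5 * neg_sd + margin`), so with default parameters the
#' distributions do not overlap and downstream calls match ground truth.
#'
#' @param clone_ids Character vector of tested clone ids.
#' @param reactive Logical vector, ground-truth antigen reactivity per clone.
#' @param n_negative Number of negative-control wells (>= 2, so an SD is
#'   estimable).
#' @param n_positive Number of positive-control wells (may be 0; not used by
#'   the caller but standard on a plate).
#' @param neg_mean,neg_sd Negative-control absorbance mean and SD (OD units).
#'   Defaults 0.15 and 0.05 put the 5-SD threshold at OD 0.4.
#' @param reactive_mean,reactive_sd Absorbance distribution of reactive
#'   clones.
#' @param margin Guaranteed gap above the nominal threshold for reactive
#'   draws (OD).
#' @param seed Integer RNG seed.
#' @return A tibble (one row per well): `well`, `role` (`"negative"`,
#'   `"positive"`, `"target"`), `clone_id` (`NA` for controls),
#'   `absorbance`, `truth_reactive`.
#' @examples
#' plate <- simulate_elisa(sprintf("C%03d", 1:5), c(TRUE, TRUE, FALSE, FALSE, TRUE))
#' @export
simulate_elisa <- function(clone_ids, reactive,
                           n_negative = 8, n_positive = 2,
                           neg_mean = 0.15, neg_sd = 0.05,
                           reactive_mean = 1.0, reactive_sd = 0.15,
                           margin = 0.25, seed = 0) {
  if (n_negative < 2) {
    ws_abort("At least 2 negative-control wells are required.", "invalid_design")
  }
  if (!is.finite(neg_sd) || neg_sd < 0) {
    ws_abort("`neg_sd` must be >= 0.", "invalid_parameter")
  }
  stopifnot(length(clone_ids) == length(reactive))
  withr::local_seed(seed)
  thr <- neg_mean + 5 * neg_sd
  neg <- pmax(rnorm(n_negative, neg_mean, neg_sd), 0)
  pos <- pmax(rnorm(n_positive, 1.5, 0.1), 0)
  tgt <- numeric(length(clone_ids))
  tgt[reactive] <- pmax(rnorm(sum(reactive), reactive_mean, reactive_sd),
                        thr + margin)
  tgt[!reactive] <- pmax(rnorm(sum(!reactive), neg_mean, neg_sd), 0)
  out <- tibble(
    role = c(rep("negative", n_negative), rep("positive", n_positive),
             rep("target", length(clone_ids))),
    clone_id = c(rep(NA_character_, n_negative + n_positive), clone_ids),
    absorbance = c(neg, pos, tgt),
    truth_reactive = c(rep(NA, n_negative + n_positive), reactive)
  )
  out$well <- sprintf("W%02d", seq_len(nrow(out)))
  dplyr::relocate(out, "well")
}
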