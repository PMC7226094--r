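#' Call antigen-reactive clones from an ELISA plate
#'
#' The calling threshold is the mean plus `k` (default 5) sample standard
#' deviations (n-1 denominator) of the negative-control absorbances; a
#' tested clone is antigen-reactive (AR) when its absorbance is greater
#' than or equal to the threshold (ties call AR).
#'
#' @param plate Tibble with columns `role` (`"negative"`, `"positive"`,
#'   `"target"`), `clone_id`, `absorbance` — the format written by
#'   [simulate_elisa()] / [read_plate_csv()].
#' @param k SD multiplier.
#' @return An object of class `elisa_calls`: list with `calls` (per tested
#'   clone: `clone_id`, `absorbance`, `ar_call`), `threshold`, `neg_mean`,
#'   `neg_sd`, `n_negative`, `n_tested`, `n_ar`, `confirmation_rate`.
#' @examples
#' plate <- simulate_elisa(c("A", "B"), c(TRUE, FALSE), seed = 1)
#' glance(call_ar_clones(plate))
#' @export
call_ar_clones <- function(plate, k = 5) {
  stopifnot(all(c("role", "absorbance") %in% names(plate)))
  neg <- plate$absorbance[plate$role == "negative"]
  if (length(neg) < 2) {
    ws_abort("Cannot estimate the ELISA threshold: fewer than 2 negative controls.",
             "cannot_estimate_threshold")
  }
  mu <- mean(neg); s <- sd(neg)
  thr <- mu + k * s
  tgt <- plate[plate$role == "target", , drop = FALSE]
  calls <- tibble(
    clone_id = tgt$clone_id,
    absorbance = tgt$absorbance,
    ar_call = tgt$absorbance >= thr
  )
  structure(
    list(calls = calls, threshold = thr, neg_mean = mu, neg_sd = s,
         n_negative = length(neg), n_tested = nrow(calls),
         n_ar = sum(calls$ar_call), k = k,
         confirmation_rate = if (nrow(calls)) mean(calls$ar_call) else NA_real_),
    class = "elisa_calls"
  )
}

#' @export
print.elisa_calls <- function(x, ...) {
  cat(sprintf("<elisa_calls> %d / %d clones AR (%.1f%%) at threshold OD %.3f (mean %.3f + %g x SD %.3f)\n",
              x$n_ar, x$n_tested, 100 * x$confirmation_rate, x$threshold,
              x$neg_mean, x$k, x$neg_sd))
  invisible(x)
}

#' @export
tidy.elisa_calls <- function(x, ...) x$calls

#' @export
glance.elisa_calls <- function(x, ...) {
  tibble(n_tested = x$n_tested, n_ar = x$n_ar,
         confirmation_rate = x$confirmation_rate, threshold = x$threshold,
         neg_mean = x$neg_mean, neg_sd = x$neg_sd,
         n_negative = x$n_negative, k = x$k)
}

#' @export
autoplot.elisa_calls <- function(object, ...) {
  d <- object$calls
  d$clone_id <- factor(d$clone_id, levels = d$clone_id[order(-d$absorbance)])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$clone_id, y = .data$absorbance,
                                  fill = .data$ar_call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$threshold, colour = "red",
                        linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#d7301f", `FALSE` = "grey60")) +
    ggplot2::labs(x = NULL, y = "absorbance (OD)",
                  title = sprintf("ELISA calls: threshold OD %.2f", object$threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
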