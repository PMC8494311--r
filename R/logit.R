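#' Log-odds transform and its inverse
#'
#' All observer models combine evidence in log-odds ("logit") space:
#' `logit(p) = ln(p / (1 - p))`. `inv_logit()` is the logistic function,
#' its exact inverse.
#'
#' @param p Numeric vector of probabilities, strictly inside (0, 1).
#' @param L Numeric vector of log-odds.
#' @return Numeric vector of the same length.
#' @examples
#' logit(0.9)       # ln(9)
#' inv_logit(logit(0.3))
#' @export
logit <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric.")
  bad <- !is.finite(p) | p <= 0 | p >= 1
  if (any(bad)) {
    abort(sprintf(
      "Probabilities must lie strictly in (0, 1); offending value(s): %s",
      paste(utils::head(p[bad], 5), collapse = ", ")
    ))
  }
  log(p / (1 - p))
}

#' @rdname logit
#' @export
inv_logit <- function(L) {
  stats::plogis(L)
}

#' Clip probabilities away from the scale edges
#'
#' Responses clicked at the very edge of the confidence scale correspond to
#' probabilities of exactly 0 or 1, whose logit is infinite. Before taking
#' logits, confidences are clipped into `[eps, 1 - eps]` (default
#' `eps = 0.01`, so edge clicks map to `|logit| = ln(99)`, about 4.595).
#'
#' @param p Numeric vector of probabilities in `[0, 1]`.
#' @param eps Clipping margin, in (0, 0.5).
#' @return `p` with values pushed inside `[eps, 1 - eps]`.
#' @export
clip_confidence <- function(p, eps = 0.01) {
  stopifnot(is.numeric(eps), length(eps) == 1L, eps > 0, eps < 0.5)
  pmin(pmax(p, eps), 1 - eps)
}
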