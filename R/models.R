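#' Reliability-weighting sigmoid F
#'
#' The building block of every observer model below:
#' `F(L, w) = ln((w e^L + 1 - w) / ((1 - w) e^L + w))`,
#' with `L` a log-odds signal and `w` a reliability weight on the true
#' scale `[0.5, 1]`. `F(L, 1) = L` passes the signal unchanged;
#' `F(L, 0.5) = 0` nulls it; for `w < 1` the output saturates at
#' `±ln(w / (1 - w))`. The implementation factors out the exponent so that
#' `|L|` up to 700 neither overflows nor loses the saturation value.
#'
#' @param L Numeric vector of log-odds (finite).
#' @param w Weight(s) on the true scale, in `[0.5, 1]`; values below 0.5
#'   are rejected, not clipped.
#' @return Numeric vector of weighted log-odds.
#' @examples
#' sigmoid_F(2, 0.8)
#' sigmoid_F(3.7, 0.5)  # 0: the signal is fully discounted
#' sigmoid_F(-1.2, 1)   # identity
#' @export
sigmoid_F <- function(L, w) {
  if (!all(is.finite(L))) abort("`L` must be finite.")
  if (any(!is.finite(w) | w < 0.5 | w > 1)) {
    abort(sprintf(
      "Weights must lie in [0.5, 1] on the true scale; offending value(s): %s",
      paste(utils::head(w[!is.finite(w) | w < 0.5 | w > 1], 5), collapse = ", ")
    ))
  }
  log_wexp(L, w) - log_wexp(L, 1 - w)
}

# log(w * exp(L) + (1 - w)), stable for large |L|: for L > 0 factor out
# exp(L) so the argument of exp() is never positive.
log_wexp <- function(L, w) {
  out <- numeric(length(L))
  if (length(w) == 1L) w <- rep(w, length(L))
  up <- L > 0
  out[up] <- L[up] + log(w[up] + (1 - w[up]) * exp(-L[up]))
  out[!up] <- log(w[!up] * exp(L[!up]) + (1 - w[!up]))
  out
}

#' Observer-model parameter sets
#'
#' The four parameters are the prior and likelihood weights `w_p`, `w_s`
#' (true range `[0.5, 1]`) and the prior and likelihood reverberation
#' counts `a_p`, `a_s` (true range `[0, 60]`). Reported values use the
#' rescaled representation, all four mapped to `[0, 1]`:
#' `(w - 0.5) / 0.5` for weights and `a / 60` for reverberation.
#' `model_params()` builds a validated rescaled parameter vector;
#' `unrescale_params()` / `rescale_params()` convert between the two
#' representations (exact inverses).
#'
#' @param w_p,w_s,a_p,a_s Rescaled parameter values in `[0, 1]`.
#' @param params Named numeric vector with elements
#'   `w_p`, `w_s`, `a_p`, `a_s`.
#' @return A named numeric vector of the four parameters.
#' @examples
#' p <- model_params(w_p = 0.8, w_s = 0.06, a_p = 0.02, a_s = 0.05)
#' unrescale_params(p)
#' @export
model_params <- function(w_p = 1, w_s = 1, a_p = 0, a_s = 0) {
  p <- c(w_p = w_p, w_s = w_s, a_p = a_p, a_s = a_s)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort("Rescaled parameters must all lie in [0, 1].")
  }
  p
}

#' @rdname model_params
#' @export
unrescale_params <- function(params) {
  params <- check_params(params)
  c(
    w_p = 0.5 + 0.5 * params[["w_p"]],
    w_s = 0.5 + 0.5 * params[["w_s"]],
    a_p = 60 * params[["a_p"]],
    a_s = 60 * params[["a_s"]]
  )
}

#' @rdname model_params
#' @export
rescale_params <- function(params) {
  c(
    w_p = (params[["w_p"]] - 0.5) / 0.5,
    w_s = (params[["w_s"]] - 0.5) / 0.5,
    a_p = params[["a_p"]] / 60,
    a_s = params[["a_s"]] / 60
  )
}

check_params <- function(params) {
  need <- c("w_p", "w_s", "a_p", "a_s")
  if (is.null(names(params)) || !all(need %in% names(params))) {
    abort("`params` must be a named vector with w_p, w_s, a_p, a_s.")
  }
  params <- params[need]
  if (any(!is.finite(params) | params < 0 | params > 1)) {
    abort("Rescaled parameters must all lie in [0, 1].")
  }
  params
}

#' Predicted logit confidence of the observer models
#'
#' Maps a trial set's cue logits (`L_p` prior, `L_s` likelihood) to the
#' model's noiseless logit confidence `L_c`:
#'
#' * **SB** (Simple Bayes): `L_c = L_p + L_s`.
#' * **WB** (Weighted Bayes): `L_c = F(L_p, w_p) + F(L_s, w_s)` —
#'   either cue may be discounted.
#' * **CII** (circular inference with interference): both signals are
#'   reverberated into a common corruption term
#'   `I = F(a_p L_p, w_p) + F(a_s L_s, w_s)` that re-enters both channels:
#'   `L_c = F(L_p + I, w_p) + F(L_s + I, w_s)`.
#' * **CINI** (no interference): each channel reverberates only itself,
#'   `L_c = F(L_p + F(a_p L_p, w_p), w_p) + F(L_s + F(a_s L_s, w_s), w_s)`,
#'   so the two cues contribute additively.
#'
#' Parameters are supplied rescaled (as reported) and mapped back to the
#' true scale internally. With both weights 1, WB reduces to SB; with both
#' reverberation parameters 0, CII and CINI reduce to WB.
#'
#' @param trials A trial tibble with columns `L_p` and `L_s`
#'   (see [build_trial_set()]).
#' @param model One of `"SB"`, `"WB"`, `"CII"`, `"CINI"`.
#' @param params Rescaled parameters from [model_params()]; ignored by SB,
#'   weights only for WB.
#' @return Numeric vector of predicted logit confidences, one per trial.
#' @examples
#' trials <- build_trial_set(81, seed = 1)
#' p <- model_params(w_p = 0.8, w_s = 0.06, a_p = 0.02, a_s = 0.05)
#' head(predict_confidence(trials, "CINI", p))
#' @export
predict_confidence <- function(trials, model, params = model_params()) {
  model <- match_model(model)
  L_p <- trials$L_p
  L_s <- trials$L_s
  if (is.null(L_p) || is.null(L_s)) {
    abort("`trials` must carry logit columns L_p and L_s.")
  }
  if (model == "SB") return(L_p + L_s)
  tp <- unrescale_params(check_params(params))
  w_p <- tp[["w_p"]]; w_s <- tp[["w_s"]]
  a_p <- tp[["a_p"]]; a_s <- tp[["a_s"]]
  switch(model,
    WB = sigmoid_F(L_p, w_p) + sigmoid_F(L_s, w_s),
    CII = {
      I <- sigmoid_F(a_p * L_p, w_p) + sigmoid_F(a_s * L_s, w_s)
      sigmoid_F(L_p + I, w_p) + sigmoid_F(L_s + I, w_s)
    },
    CINI = {
      sigmoid_F(L_p + sigmoid_F(a_p * L_p, w_p), w_p) +
        sigmoid_F(L_s + sigmoid_F(a_s * L_s, w_s), w_s)
    }
  )
}
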