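#' Simulate responses for one participant
#'
#' Responses follow the generative assumption used at fitting time:
#' Gaussian noise on the logit confidence. For each trial,
#' `L_c = prediction + N(0, noise_sd)`; the confidence is
#' `c = inv_logit(L_c)` clipped into `[eps, 1 - eps]` (edge responses are
#' treated like edge clicks on the scale), and the stored logit is
#' recomputed from the clipped confidence. Reaction times are log-normal
#' with a configurable negative dependence on the absolute noiseless
#' prediction, mimicking slower responses under uncertainty.
#'
#' @param trials Trial tibble (see [build_trial_set()]).
#' @param model,params Generating observer model and rescaled parameters.
#' @param noise_sd Standard deviation of the Gaussian logit noise (> 0).
#' @param seed Integer seed; identical seeds give identical records.
#' @param eps Confidence clipping margin (see [clip_confidence()]).
#' @param participant_id Identifier copied into every record.
#' @param rt_meanlog,rt_slope,rt_sdlog Log-normal reaction-time model:
#'   `log rt ~ N(rt_meanlog + rt_slope * |prediction|, rt_sdlog)`. The
#'   default slope is negative (confident trials are answered faster).
#' @return A tibble with one row per trial: `participant_id`, `trial_id`,
#'   `confidence`, `L_c`, `rt`.
#' @examples
#' trials <- build_trial_set(130, seed = 1)
#' r <- simulate_responses(trials, "CINI",
#'   model_params(0.8, 0.7, 0.1, 0.2),
#'   noise_sd = 1, seed = 7
#' )
#' @export
simulate_responses <- function(trials, model, params = model_params(),
                               noise_sd = 1, seed = 1L, eps = 0.01,
                               participant_id = 1L,
                               rt_meanlog = log(2), rt_slope = -0.12,
                               rt_sdlog = 0.35) {
  stopifnot(noise_sd > 0)
  pred <- predict_confidence(trials, model, params)
  with_seed(seed, {
    L_raw <- pred + rnorm(length(pred), 0, noise_sd)
    rt <- rlnorm(length(pred), rt_meanlog + rt_slope * abs(pred), rt_sdlog)
  })
  confidence <- clip_confidence(inv_logit(L_raw), eps)
  tibble::tibble(
    participant_id = participant_id,
    trial_id = trials$trial_id,
    confidence = confidence,
    L_c = logit(confidence),
    rt = rt
  )
}

#' Cohort-simulation configuration
#'
#' Collects the distributional choices behind [simulate_cohort()]:
#' generating-parameter distribution (rescaled weights uniform on
#' `[0.3, 1]`, reverberation uniform on `[0, 0.3]`, logit-noise SD uniform
#' on `[0.5, 1.5]`), trait-score moments (AQ total mean 22.9, SD 6.5;
#' PDI total mean 6.1, SD 3.1; ASD subgroup AQ mean 28.0, SD 8.0), the
#' fraction of participants carrying an ASD diagnosis, and the
#' trait-to-parameter coupling coefficients. Couplings default to zero —
#' the null cohort, in which traits and generating parameters are
#' independent.
#'
#' A coupling entry `c(a_s = 0.8)` in `coupling_aq` shifts each
#' participant's rescaled `a_s` by `0.8 * 0.1 * standardized AQ` before
#' clipping to `[0, 1]` (the 0.1 factor keeps unit couplings within the
#' rescaled range for typical draws).
#'
#' @param model Generating observer model for every participant.
#' @param w_range,a_range,noise_sd_range Uniform ranges for the rescaled
#'   weights, rescaled reverberation parameters, and logit-noise SD.
#' @param aq_mean,aq_sd,pdi_mean,pdi_sd Trait moments for the general
#'   sample (scores are rounded and truncated to AQ 0-50, PDI 0-21).
#' @param asd_fraction Fraction of participants labelled with an ASD
#'   diagnosis; their AQ is drawn with `asd_aq_mean`/`asd_aq_sd`.
#' @param asd_aq_mean,asd_aq_sd AQ moments of the ASD subgroup.
#' @param coupling_aq,coupling_pdi Named numeric vectors (subset of
#'   `w_p`, `w_s`, `a_p`, `a_s`) of trait-parameter coupling strengths.
#' @param eps Confidence clipping margin passed through to the responses.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(model = "CINI",
                          w_range = c(0.3, 1), a_range = c(0, 0.3),
                          noise_sd_range = c(0.5, 1.5),
                          aq_mean = 22.9, aq_sd = 6.5,
                          pdi_mean = 6.1, pdi_sd = 3.1,
                          asd_fraction = 0.12,
                          asd_aq_mean = 28.0, asd_aq_sd = 8.0,
                          coupling_aq = numeric(0),
                          coupling_pdi = numeric(0),
                          eps = 0.01) {
  cfg <- list(
    model = match_model(model),
    w_range = w_range, a_range = a_range,
    noise_sd_range = noise_sd_range,
    aq_mean = aq_mean, aq_sd = aq_sd,
    pdi_mean = pdi_mean, pdi_sd = pdi_sd,
    asd_fraction = asd_fraction,
    asd_aq_mean = asd_aq_mean, asd_aq_sd = asd_aq_sd,
    coupling_aq = coupling_aq, coupling_pdi = coupling_pdi,
    eps = eps
  )
  structure(cfg, class = "cohort_config")
}

# Truncated-normal integer trait scores via resampling of out-of-range
# draws (moments are preserved closely for the score ranges used here).
draw_trait <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  for (i in 1:50) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  as.integer(round(pmin(pmax(x, lower), upper)))
}

#' Simulate a synthetic cohort
#'
#' Draws a cohort of participant profiles (generating parameters, noise
#' level, AQ and PDI totals, diagnosis label) and their trial-level
#' responses, all as a pure function of `(config, seed)`. With the default
#' null configuration the trait scores are independent of the generating
#' parameters, which is the fixture on which the association battery must
#' show type-I error control.
#'
#' @param n Number of participants (>= 2).
#' @param trials Trial tibble shared by all participants.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @param include_responses Set `FALSE` to draw profiles only (the trait
#'   and parameter layer), e.g. for calibration studies that never touch
#'   trial-level data; `responses` is then `NULL`. The profile draw is
#'   identical either way.
#' @return A list with tibbles `profiles` (one row per participant:
#'   `participant_id`, `model`, rescaled `w_p`, `w_s`, `a_p`, `a_s`,
#'   `noise_sd`, `AQ`, `PDI`, `diagnosis`) and `responses` (stacked
#'   [simulate_responses()] output).
#' @examples
#' trials <- build_trial_set(130, seed = 1)
#' cohort <- simulate_cohort(20, trials, cohort_config(), seed = 3)
#' @export
simulate_cohort <- function(n, trials, config = cohort_config(), seed = 1L,
                            include_responses = TRUE) {
  stopifnot(inherits(config, "cohort_config"), n >= 2)
  with_seed(seed, {
    n_asd <- round(config$asd_fraction * n)
    diagnosis <- sample(c(rep("ASD", n_asd), rep("ND", n - n_asd)))
    AQ <- integer(n)
    is_asd <- diagnosis == "ASD"
    AQ[!is_asd] <- draw_trait(sum(!is_asd), config$aq_mean, config$aq_sd, 0, 50)
    AQ[is_asd] <- draw_trait(sum(is_asd), config$asd_aq_mean, config$asd_aq_sd, 0, 50)
    PDI <- draw_trait(n, config$pdi_mean, config$pdi_sd, 0, 21)

    pars <- tibble::tibble(
      w_p = runif(n, config$w_range[1], config$w_range[2]),
      w_s = runif(n, config$w_range[1], config$w_range[2]),
      a_p = runif(n, config$a_range[1], config$a_range[2]),
      a_s = runif(n, config$a_range[1], config$a_range[2])
    )
    pars <- apply_coupling(pars, AQ, config$coupling_aq)
    pars <- apply_coupling(pars, PDI, config$coupling_pdi)

    noise_sd <- runif(n, config$noise_sd_range[1], config$noise_sd_range[2])
    resp_seeds <- sample.int(.Machine$integer.max, n)
  })

  profiles <- dplyr::bind_cols(
    tibble::tibble(participant_id = seq_len(n), model = config$model),
    pars,
    tibble::tibble(noise_sd = noise_sd, AQ = AQ, PDI = PDI,
                   diagnosis = diagnosis)
  )

  if (!include_responses) {
    return(list(profiles = profiles, responses = NULL))
  }

  responses <- purrr::pmap(
    list(seq_len(n), resp_seeds),
    function(id, s) {
      p <- profiles[id, ]
      simulate_responses(
        trials, config$model,
        model_params(p$w_p, p$w_s, p$a_p, p$a_s),
        noise_sd = p$noise_sd, seed = s, eps = config$eps,
        participant_id = id
      )
    }
  ) |> purrr::list_rbind()

  list(profiles = profiles, responses = responses)
}

# Shift parameters by coupling * 0.1 * standardized trait; out-of-range
# values are clipped into [0, 1] with a warning.
apply_coupling <- function(pars, trait, coupling) {
  if (length(coupling) == 0) return(pars)
  bad <- setdiff(names(coupling), names(pars))
  if (length(bad)) abort(sprintf("Unknown coupling target(s): %s",
                                 paste(bad, collapse = ", ")))
  z <- as.numeric(scale(trait))
  if (any(!is.finite(z))) z[] <- 0
  for (nm in names(coupling)) {
    shifted <- pars[[nm]] + coupling[[nm]] * 0.1 * z
    if (any(shifted < 0 | shifted > 1)) {
      warn(sprintf(
        "Coupling pushed %d value(s) of %s outside [0, 1]; clipped.",
        sum(shifted < 0 | shifted > 1), nm
      ))
    }
    pars[[nm]] <- pmin(pmax(shifted, 0), 1)
  }
  pars
}

#' Flag low-quality response sets
#'
#' Heuristic quality screen for unengaged responding: a participant is
#' flagged when their confidences have standard deviation below `min_sd`
#' (scale barely used) or when more than `max_mid_frac` of clicks fall
#' within `mid_tol` of the scale midpoint. Exclusion is the caller's
#' choice; this function only labels.
#'
#' @param responses Stacked response tibble.
#' @param min_sd,max_mid_frac,mid_tol Screen thresholds.
#' @return Tibble with `participant_id`, the two screen statistics, and
#'   logical `flagged`.
#' @export
flag_low_quality <- function(responses, min_sd = 0.05,
                             max_mid_frac = 0.30, mid_tol = 0.02) {
  responses |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      sd_confidence = stats::sd(.data$confidence),
      mid_frac = mean(abs(.data$confidence - 0.5) <= mid_tol),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      flagged = .data$sd_confidence < min_sd | .data$mid_frac > max_mid_frac
    )
}
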