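#' Parameter recovery for an observer model
#'
#' Draws `n_sim` generating parameter sets, simulates responses on the
#' supplied trial design with Gaussian logit noise, refits the same model,
#' and reports the agreement between generating and recovered parameters
#' (Pearson r and Kendall tau-b per parameter — Pearson is reported
#' alongside the rank statistic because it is sensitive to outliers in the
#' reverberation parameters) together with the cross-correlation matrix of
#' the recovered parameters. With a zero-variance generating parameter the
#' correlation is undefined and reported as `NA` with a warning.
#'
#' @param model `"CII"` or `"CINI"` (the circular-inference variants; the
#'   simpler models are nested within them).
#' @param n_sim Number of simulated participants (>= 10).
#' @param trials Trial tibble; defaults to the 130-trial design.
#' @param param_source Either `NULL` (draw rescaled weights from
#'   `U(w_range)`, reverberation from `U(a_range)`) or a data frame of
#'   rescaled `w_p`, `w_s`, `a_p`, `a_s` resampled with replacement.
#' @param w_range,a_range Uniform generating ranges used when
#'   `param_source` is `NULL`.
#' @param noise_sd Logit-noise SD: a single value or a sampling function
#'   `function(n)`.
#' @param eps Confidence clipping margin for the simulated responses.
#'   Recovery validates the estimator under its own generative assumption
#'   (unbounded Gaussian noise on the logit), so the margin defaults to
#'   1e-9 — effectively inactive — rather than the response-scale margin
#'   used for cohort realism.
#' @param seed Integer seed; the report is a pure function of the inputs.
#' @return A list of class `cf_recovery`: `correlations` (tibble with
#'   `parameter`, `pearson`, `kendall`), `recovered_cor` (4 x 4 Pearson
#'   matrix of recovered parameters), `draws` (tibble of generating and
#'   recovered values), `model`, `n_sim`, `seed`.
#' @export
parameter_recovery <- function(model, n_sim = 200L,
                               trials = build_trial_set(130, seed = 1),
                               param_source = NULL,
                               w_range = c(0.3, 1), a_range = c(0, 0.3),
                               noise_sd = 1, eps = 1e-9, seed = 1L) {
  model <- match_model(model)
  stopifnot(n_sim >= 10)
  par_names <- c("w_p", "w_s", "a_p", "a_s")

  with_seed(seed, {
    gen <- draw_generating_params(n_sim, param_source, w_range, a_range)
    nsd <- if (is.function(noise_sd)) noise_sd(n_sim) else rep(noise_sd, n_sim)
    sim_seeds <- sample.int(.Machine$integer.max, n_sim)
    fit_seeds <- sample.int(.Machine$integer.max, n_sim)
  })

  rec <- purrr::map(seq_len(n_sim), function(i) {
    resp <- simulate_responses(
      trials, model,
      model_params(gen$w_p[i], gen$w_s[i], gen$a_p[i], gen$a_s[i]),
      noise_sd = nsd[i], seed = sim_seeds[i], eps = eps, participant_id = i
    )
    fit_model(resp, trials, model, seed = fit_seeds[i])
  }) |> purrr::list_rbind()

  draws <- dplyr::bind_cols(
    setNames(gen[par_names], paste0("gen_", par_names)),
    setNames(rec[par_names], paste0("rec_", par_names))
  )

  correlations <- purrr::map(par_names, function(p) {
    g <- draws[[paste0("gen_", p)]]
    r <- draws[[paste0("rec_", p)]]
    if (stats::sd(g) == 0 || stats::sd(r) == 0) {
      warn(sprintf("Zero variance in %s; recovery correlation undefined.", p))
      return(tibble::tibble(parameter = p, pearson = NA_real_,
                            kendall = NA_real_))
    }
    tibble::tibble(
      parameter = p,
      pearson = cor(g, r),
      kendall = cor(g, r, method = "kendall")
    )
  }) |> purrr::list_rbind()

  structure(
    list(
      correlations = correlations,
      recovered_cor = cor(as.matrix(draws[paste0("rec_", par_names)])),
      draws = tibble::as_tibble(draws),
      model = model, n_sim = n_sim, seed = seed
    ),
    class = "cf_recovery"
  )
}

draw_generating_params <- function(n, param_source, w_range, a_range) {
  par_names <- c("w_p", "w_s", "a_p", "a_s")
  if (is.null(param_source)) {
    tibble::tibble(
      w_p = runif(n, w_range[1], w_range[2]),
      w_s = runif(n, w_range[1], w_range[2]),
      a_p = runif(n, a_range[1], a_range[2]),
      a_s = runif(n, a_range[1], a_range[2])
    )
  } else {
    if (!all(par_names %in% names(param_source))) {
      abort("`param_source` must have columns w_p, w_s, a_p, a_s.")
    }
    tibble::as_tibble(
      param_source[sample.int(nrow(param_source), n, replace = TRUE),
                   par_names]
    )
  }
}

#' @export
print.cf_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery: %s, %d simulants\n", x$model, x$n_sim))
  print(as.data.frame(x$correlations), digits = 3)
  invisible(x)
}

#' @describeIn parameter_recovery Per-parameter recovery correlations.
#' @param x A `cf_recovery` object.
#' @param ... Unused.
#' @export
tidy.cf_recovery <- function(x, ...) x$correlations

#' Model recovery between two observer models
#'
#' For each of the two candidate generating models, simulates
#' `n_per_model` participants, fits *both* models to each, and assigns
#' every simulant to the model with the lower BIC. Exact BIC ties
#' (|difference| < 1e-9, which arises when the two models coincide at the
#' fitted parameters) are counted for the generating model and logged.
#'
#' @param models Character vector of exactly two model identifiers
#'   (default the two circular-inference variants).
#' @param n_per_model Simulated participants per generating model (>= 10).
#' @inheritParams parameter_recovery
#' @return A list of class `cf_confusion`: `table` (2 x 2 counts,
#'   simulated x recovered), `accuracy` (per generating model),
#'   `mean_accuracy`, `n_ties`, `n_per_model`, `seed`.
#' @export
model_recovery <- function(models = c("CINI", "CII"), n_per_model = 200L,
                           trials = build_trial_set(130, seed = 1),
                           param_source = NULL,
                           w_range = c(0.3, 1), a_range = c(0, 0.3),
                           noise_sd = 1, eps = 1e-9, seed = 1L) {
  models <- match_model(models, several.ok = TRUE)
  stopifnot(length(models) == 2, n_per_model >= 10)

  counts <- matrix(0L, 2, 2, dimnames = list(simulated = models,
                                             recovered = models))
  n_ties <- 0L
  for (gi in 1:2) {
    gen_model <- models[gi]
    with_seed(seed + gi - 1L, {
      gen <- draw_generating_params(n_per_model, param_source,
                                    w_range, a_range)
      nsd <- if (is.function(noise_sd)) noise_sd(n_per_model)
             else rep(noise_sd, n_per_model)
      sim_seeds <- sample.int(.Machine$integer.max, n_per_model)
      fit_seeds <- sample.int(.Machine$integer.max, n_per_model)
    })
    for (i in seq_len(n_per_model)) {
      resp <- simulate_responses(
        trials, gen_model,
        model_params(gen$w_p[i], gen$w_s[i], gen$a_p[i], gen$a_s[i]),
        noise_sd = nsd[i], seed = sim_seeds[i], eps = eps, participant_id = i
      )
      bics <- purrr::map_dbl(models, function(m) {
        fit_model(resp, trials, m, seed = fit_seeds[i])$bic
      })
      if (abs(bics[1] - bics[2]) < 1e-9) {
        n_ties <- n_ties + 1L
        win <- gi
      } else {
        win <- which.min(bics)
      }
      counts[gi, win] <- counts[gi, win] + 1L
    }
  }
  if (n_ties > 0) {
    warn(sprintf("%d BIC tie(s) assigned to the generating model.", n_ties))
  }
  accuracy <- diag(counts) / n_per_model
  structure(
    list(
      table = counts,
      accuracy = setNames(accuracy, models),
      mean_accuracy = mean(accuracy),
      n_ties = n_ties,
      n_per_model = n_per_model,
      seed = seed
    ),
    class = "cf_confusion"
  )
}

#' @export
print.cf_confusion <- function(x, ...) {
  cat(sprintf("Model recovery (%d simulants per generating model)\n",
              x$n_per_model))
  print(x$table)
  cat(sprintf("Correct recovery: %s; mean %.1f%%\n",
              paste(sprintf("%s %.1f%%", names(x$accuracy),
                            100 * x$accuracy), collapse = ", "),
              100 * x$mean_accuracy))
  invisible(x)
}

#' @describeIn model_recovery Long-format confusion counts.
#' @param x A `cf_confusion` object.
#' @param ... Unused.
#' @export
tidy.cf_confusion <- function(x, ...) {
  as.data.frame.table(x$table, responseName = "count") |>
    tibble::as_tibble()
}

#' @describeIn model_recovery One-row accuracy summary.
#' @export
glance.cf_confusion <- function(x, ...) {
  tibble::tibble(
    n_per_model = x$n_per_model,
    mean_accuracy = x$mean_accuracy,
    n_ties = x$n_ties
  )
}
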