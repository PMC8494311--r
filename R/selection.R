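#' Fixed-effects group model comparison (summed delta-BIC)
#'
#' Sums each model's per-participant BIC scores and subtracts the summed
#' BIC of a baseline model (default CII, the winning model of the earlier
#' clinical work this task derives from), so the baseline's delta is 0 by
#' construction and lower values indicate better group-level fit.
#'
#' @param fits Fit tibble from [fit_cohort()] (columns `participant_id`,
#'   `model`, `bic`); every participant must have a row for every model.
#' @param baseline Baseline model identifier.
#' @return Tibble with `model`, `sum_bic`, `delta_bic`, sorted by
#'   `delta_bic`.
#' @export
group_delta_bic <- function(fits, baseline = "CII") {
  baseline <- match_model(baseline)
  cells <- tidyr::expand_grid(
    participant_id = unique(fits$participant_id),
    model = unique(fits$model)
  )
  missing <- dplyr::anti_join(cells, fits, by = c("participant_id", "model"))
  if (nrow(missing) > 0) {
    abort(sprintf(
      "Missing (participant, model) fit cell(s): %s",
      paste(utils::head(
        paste0("(", missing$participant_id, ", ", missing$model, ")"), 10
      ), collapse = ", ")
    ))
  }
  if (!baseline %in% fits$model) {
    abort(sprintf("Baseline model %s has no fits.", baseline))
  }
  sums <- fits |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(sum_bic = sum(.data$bic), .groups = "drop")
  base <- sums$sum_bic[sums$model == baseline]
  sums |>
    dplyr::mutate(delta_bic = .data$sum_bic - base) |>
    dplyr::arrange(.data$delta_bic)
}

#' Random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across participants and
#' estimates the population frequencies of the candidate models with the
#' variational Dirichlet scheme: starting from a symmetric Dirichlet prior
#' `alpha0`, iterate participant-level model responsibilities
#' `u_nk ∝ exp(log_evidence_nk + psi(alpha_k) - psi(sum(alpha)))`
#' (normalized over models within each participant) and concentration
#' updates `alpha_k = alpha0 + sum_n u_nk`, until the largest change in
#' `alpha` falls below `tol`. Expected posterior model probabilities are
#' `r_k = alpha_k / sum(alpha)`; exceedance probabilities (the posterior
#' probability that model k is the most frequent in the population) are
#' estimated by seeded Monte-Carlo sampling from the fitted Dirichlet.
#'
#' Log model evidence is approximated as `-BIC / 2` when a fit table is
#' supplied.
#'
#' @param log_evidence Numeric matrix, participants x models, of
#'   (approximate) log model evidences, with model names as column names;
#'   or a fit tibble from [fit_cohort()], from which the matrix is built
#'   as `-bic / 2`.
#' @param alpha0 Symmetric Dirichlet prior concentration (default 1).
#' @param tol Convergence tolerance on `max |delta alpha|`.
#' @param max_iter Iteration cap; non-convergence is flagged, not fatal.
#' @param n_samples Dirichlet draws for the exceedance estimate.
#' @param seed Seed for the exceedance sampling.
#' @return An object of class `cf_bms`: list with `models`, `alpha`,
#'   `r` (expected posterior model probabilities), `exceedance`,
#'   `iterations`, `converged`, `n_participants`.
#' @examples
#' lev <- cbind(WB = c(-4, -6, -5), CINI = c(-1, -2, -1.5))
#' random_effects_bms(lev)
#' @export
random_effects_bms <- function(log_evidence, alpha0 = 1, tol = 1e-6,
                               max_iter = 10000L, n_samples = 1e6,
                               seed = 1L) {
  if (is.data.frame(log_evidence)) {
    log_evidence <- log_evidence |>
      dplyr::transmute(participant_id = .data$participant_id,
                       model = .data$model, lev = -.data$bic / 2) |>
      tidyr::pivot_wider(names_from = "model", values_from = "lev") |>
      dplyr::select(-"participant_id") |>
      as.matrix()
  }
  if (!all(is.finite(log_evidence))) abort("Log evidences must be finite.")
  stopifnot(alpha0 > 0)
  K <- ncol(log_evidence)
  N <- nrow(log_evidence)
  models <- colnames(log_evidence)
  if (is.null(models)) models <- paste0("model", seq_len(K))

  alpha <- rep(alpha0, K)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- w - apply(w, 1, max)
    u <- exp(w)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }

  exceedance <- with_seed(seed, {
    draws <- matrix(rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
                    ncol = K)
    tabulate(max.col(draws, ties.method = "random"), nbins = K) / n_samples
  })

  structure(
    list(
      models = models,
      alpha = setNames(alpha, models),
      r = setNames(alpha / sum(alpha), models),
      exceedance = setNames(exceedance, models),
      iterations = iter,
      converged = converged,
      n_participants = N
    ),
    class = "cf_bms"
  )
}

#' @export
print.cf_bms <- function(x, ...) {
  cat("Random-effects Bayesian model selection\n")
  cat(sprintf("  %d participants, %d models; %s after %d iterations\n",
              x$n_participants, length(x$models),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(round(rbind(alpha = x$alpha, r = x$r, exceedance = x$exceedance), 4))
  invisible(x)
}

#' @describeIn random_effects_bms One row per model: concentration,
#'   expected posterior probability, exceedance probability.
#' @param x A `cf_bms` object.
#' @param ... Unused.
#' @export
tidy.cf_bms <- function(x, ...) {
  tibble::tibble(
    model = x$models,
    alpha = unname(x$alpha),
    posterior_prob = unname(x$r),
    exceedance_prob = unname(x$exceedance)
  )
}

#' @describeIn random_effects_bms One-row convergence summary.
#' @export
glance.cf_bms <- function(x, ...) {
  tibble::tibble(
    n_participants = x$n_participants,
    n_models = length(x$models),
    iterations = x$iterations,
    converged = x$converged
  )
}

#' @describeIn random_effects_bms Bar chart of posterior model
#'   probabilities with exceedance probabilities annotated.
#' @param object A `cf_bms` object.
#' @method autoplot cf_bms
#' @export
autoplot.cf_bms <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$model, y = .data$posterior_prob)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("EP %.2f", .data$exceedance_prob)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(x = NULL, y = "Posterior model probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
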