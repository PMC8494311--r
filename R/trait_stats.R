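#' Build trial-level regressors for the model-free analysis
#'
#' Joins responses, trial design, and trait scores into the regressor
#' table used by the linear mixed-effects variants:
#'
#' * `abs_confidence = |c - 0.5|` (the response variable),
#' * `abs_likelihood = |like_p - 0.5|`,
#' * `prior_congruency = |prior_p - 0.5| * sgn((prior_p - 0.5) *
#'   (like_p - 0.5))` — how much the prior agreed with the likelihood,
#'   with `sgn(0) = 0` so an uninformative prior contributes nothing.
#'
#' The transformation is purely row-wise: permuting input rows permutes
#' output rows identically.
#'
#' @param responses Response tibble (`participant_id`, `trial_id`,
#'   `confidence`, `rt`).
#' @param trials Trial tibble (`trial_id`, `prior_p`, `like_p`).
#' @param traits Trait tibble (`participant_id`, `AQ`, `PDI`).
#' @return Tibble with `participant_id`, `trial_id`, `abs_confidence`,
#'   `abs_likelihood`, `prior_congruency`, `rt`, `AQ`, `PDI`.
#' @export
build_regressors <- function(responses, trials, traits) {
  dat <- dplyr::inner_join(responses, trials[, c("trial_id", "prior_p", "like_p")],
                           by = "trial_id")
  if (nrow(dat) < nrow(responses)) {
    abort("Some responses have no matching trial_id in `trials`.")
  }
  dat <- dplyr::inner_join(dat, traits[, c("participant_id", "AQ", "PDI")],
                           by = "participant_id")
  if (nrow(dat) < nrow(responses)) {
    abort("Some participants have no trait scores in `traits`.")
  }
  dat |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      trial_id = .data$trial_id,
      abs_confidence = abs(.data$confidence - 0.5),
      abs_likelihood = abs(.data$like_p - 0.5),
      prior_congruency = abs(.data$prior_p - 0.5) *
        sign((.data$prior_p - 0.5) * (.data$like_p - 0.5)),
      rt = .data$rt,
      AQ = .data$AQ,
      PDI = .data$PDI
    )
}

lme_variant_formulas <- function(random_part) {
  list(
    LME_core = sprintf(
      "abs_confidence ~ abs_likelihood * prior_congruency + rt + %s",
      random_part),
    LME_AQ = sprintf(
      "abs_confidence ~ abs_likelihood * prior_congruency * AQ + rt + %s",
      random_part),
    LME_PDI = sprintf(
      "abs_confidence ~ abs_likelihood * prior_congruency * PDI + rt + %s",
      random_part),
    LME_full = sprintf(
      paste0("abs_confidence ~ abs_likelihood * prior_congruency * AQ + ",
             "abs_likelihood * prior_congruency * PDI + rt + %s"),
      random_part),
    LME_rtInteract = sprintf(
      paste0("abs_confidence ~ abs_likelihood * prior_congruency * AQ + ",
             "abs_likelihood * prior_congruency * PDI + rt + rt:AQ + ",
             "rt:PDI + %s"),
      random_part)
  )
}

#' Fit the five linear mixed-effects variants
#'
#' The response is the trial-level absolute confidence; fixed effects are
#' absolute likelihood, prior congruency, their two-way interaction, and
#' reaction time. `LME_core` uses only those; `LME_AQ` adds the AQ main
#' effect and its two- and three-way interactions with the two task
#' regressors; `LME_PDI` does the same with PDI; `LME_full` includes both
#' trait blocks (no AQ x PDI terms); `LME_rtInteract` additionally allows
#' reaction time to interact with each trait. Participants enter as a
#' random factor with intercept and slopes for the two repeated-measures
#' task regressors; when that structure is singular the variant is refit
#' with a random intercept only and flagged. Trait scores are z-scored
#' before fitting for numerical balance; models are fit by maximum
#' likelihood so the BICs are comparable across variants.
#'
#' @param regressors Output of [build_regressors()].
#' @param variants Which of the five variants to fit.
#' @return A list of class `cf_lme`: `coefficients` (tibble with
#'   `variant`, `term`, `estimate`, `std_error`, `statistic` (t),
#'   `p_value`), `bic` (tibble with `variant`, `bic`, `delta_bic`,
#'   `singular_fallback`), and `fits` (the underlying `lmerMod` objects).
#' @export
fit_lme_variants <- function(regressors,
                             variants = c("LME_core", "LME_AQ", "LME_PDI",
                                          "LME_full", "LME_rtInteract")) {
  if (length(unique(regressors$participant_id)) < 2) {
    abort("At least two participants are required for the mixed models.")
  }
  dat <- regressors |>
    dplyr::mutate(
      AQ = as.numeric(scale(.data$AQ)),
      PDI = as.numeric(scale(.data$PDI))
    )
  full_random <- "(1 + abs_likelihood + prior_congruency | participant_id)"
  simple_random <- "(1 | participant_id)"

  res <- purrr::map(variants, function(v) {
    f_full <- lme_variant_formulas(full_random)[[v]]
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(stats::as.formula(f_full), data = dat, REML = FALSE)
    ))
    fallback <- FALSE
    if (lme4::isSingular(fit, tol = 1e-4)) {
      fallback <- TRUE
      f_simple <- lme_variant_formulas(simple_random)[[v]]
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(stats::as.formula(f_simple), data = dat, REML = FALSE)
      ))
    }
    co <- as.data.frame(coef(summary(fit)))
    list(
      fit = fit,
      fallback = fallback,
      bic = BIC(fit),
      coefficients = tibble::tibble(
        variant = v,
        term = rownames(co),
        estimate = co$Estimate,
        std_error = co$`Std. Error`,
        statistic = co$`t value`,
        p_value = co$`Pr(>|t|)`
      )
    )
  })
  names(res) <- variants

  bic <- tibble::tibble(
    variant = variants,
    bic = purrr::map_dbl(res, "bic"),
    singular_fallback = purrr::map_lgl(res, "fallback")
  ) |>
    dplyr::mutate(delta_bic = .data$bic - min(.data$bic))

  structure(
    list(
      coefficients = purrr::list_rbind(purrr::map(res, "coefficients")),
      bic = bic,
      fits = purrr::map(res, "fit")
    ),
    class = "cf_lme"
  )
}

#' @export
print.cf_lme <- function(x, ...) {
  cat("Linear mixed-effects variants (ML fits)\n")
  print(as.data.frame(x$bic), digits = 5)
  invisible(x)
}

#' @describeIn fit_lme_variants All fixed-effect coefficients.
#' @param x A `cf_lme` object.
#' @param ... Unused.
#' @export
tidy.cf_lme <- function(x, ...) x$coefficients

#' @describeIn fit_lme_variants Per-variant BIC comparison.
#' @export
glance.cf_lme <- function(x, ...) x$bic

#' Kendall rank correlation with tie correction
#'
#' Tau-b with a two-sided p-value: exact when the sample is small
#' (n < 50) and tie-free, the tie-corrected normal approximation
#' otherwise (trait totals are integers, so ties are the rule). With zero
#' variance in either input the statistic is undefined and returned as
#' `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return One-row tibble: `statistic_name` (`"tau"`), `statistic`,
#'   `effect_size` (`NA` for correlations), `p_value`.
#' @examples
#' kendall_tau(c(1, 2, 3), c(1, 3, 2))  # tau = 1/3
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warn("Zero variance: Kendall tau undefined.")
    return(tibble::tibble(statistic_name = "tau", statistic = NA_real_,
                          effect_size = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "kendall",
                                  alternative = "two.sided"))
  tibble::tibble(
    statistic_name = "tau",
    statistic = unname(ct$estimate),
    effect_size = NA_real_,
    p_value = ct$p.value
  )
}

#' Mann-Whitney U test with common-language effect size
#'
#' Two-sided Mann-Whitney U, exact for small tie-free samples and by the
#' tie-corrected normal approximation otherwise (the same convention as
#' the Kendall test here; the approximation is noticeably conservative
#' for tail-group sizes around 10), reported with the common-language
#' effect size
#' `f = U_x / (n_x * n_y)`: the probability (counting ties as 1/2) that a
#' random member of `x` exceeds a random member of `y`. `f = 0.5` means
#' no group difference; `f(x, y) + f(y, x) = 1`.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return One-row tibble: `statistic_name` (`"U"`), `statistic`,
#'   `effect_size` (f), `p_value`.
#' @examples
#' mann_whitney_f(c(1, 3), c(2, 4))  # f = 0.25
#' @export
mann_whitney_f <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Both samples must have at least 2 observations.")
  }
  wt <- suppressWarnings(wilcox.test(x, y, correct = TRUE))
  U <- unname(wt$statistic)
  tibble::tibble(
    statistic_name = "U",
    statistic = U,
    effect_size = U / (length(x) * length(y)),
    p_value = wt$p.value
  )
}

#' Define trait and diagnosis contrast groups
#'
#' Splits the sample into low- and high-AQ groups at the bottom and top
#' 15% of AQ scores (thresholds at the 15th/85th order statistics, ties
#' at the threshold included on the extreme side) and carries the
#' diagnosis contrast (ASD vs ND, participants with no diagnosis). Also
#' marks the low-trait ND subgroup (ND participants at or below the
#' low-AQ threshold) used as a stricter comparison group.
#'
#' @param traits Tibble with `participant_id`, `AQ`, and optionally
#'   `diagnosis` (values `"ASD"`, `"ND"`, other).
#' @param tail_fraction Fraction of the sample in each extreme group.
#' @return Tibble with `participant_id`, `AQ`, `aq_group`
#'   (`"low"`/`"middle"`/`"high"`), `diagnosis_group`, `low_nd`.
#' @examples
#' tr <- tibble::tibble(participant_id = 1:100, AQ = 1:100)
#' table(define_groups(tr)$aq_group)
#' @export
define_groups <- function(traits, tail_fraction = 0.15) {
  if (anyNA(traits$AQ)) abort("AQ must be present for every participant.")
  n <- nrow(traits)
  n_tail <- floor(tail_fraction * n)
  if (n_tail < 1 || 2 * n_tail > n) {
    abort("Sample too small for non-empty 15% tail groups.")
  }
  aq_sorted <- sort(traits$AQ)
  lo_thr <- aq_sorted[n_tail]
  hi_thr <- aq_sorted[n - n_tail + 1]
  if (lo_thr >= hi_thr) {
    abort("Degenerate AQ distribution: tail thresholds coincide.")
  }
  diagnosis <- if ("diagnosis" %in% names(traits)) traits$diagnosis
               else rep(NA_character_, n)
  traits |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      AQ = .data$AQ,
      aq_group = dplyr::case_when(
        .data$AQ <= lo_thr ~ "low",
        .data$AQ >= hi_thr ~ "high",
        TRUE ~ "middle"
      ),
      diagnosis_group = diagnosis,
      low_nd = diagnosis == "ND" & .data$AQ <= lo_thr
    )
}

#' Trait-association battery on fitted model parameters
#'
#' Runs the full nonparametric association battery for one model's fitted
#' parameters: Kendall tau-b of each of the four parameters against AQ
#' and against PDI (8 correlations), and Mann-Whitney U with
#' common-language effect size for the two group contrasts — ASD vs ND,
#' and high- vs low-AQ — on each parameter (8 tests). Effect sizes are
#' oriented so that `f > 0.5` means larger parameter values in the ASD or
#' high-AQ group. Within each battery the p-values are
#' Benjamini-Hochberg adjusted across its 8 tests; uncorrected p-values
#' are always reported alongside.
#'
#' @param fits One model's fit tibble (one row per participant, columns
#'   `participant_id`, `w_p`, `w_s`, `a_p`, `a_s`).
#' @param traits Trait tibble (`participant_id`, `AQ`, `PDI`,
#'   optionally `diagnosis`).
#' @param groups Optional [define_groups()] output; computed from
#'   `traits` when absent.
#' @return Tibble with `battery` (`"correlation"` / `"group_contrast"`),
#'   `contrast`, `parameter`, `statistic_name`, `statistic`,
#'   `effect_size`, `p_value`, `p_adjusted`.
#' @export
association_battery <- function(fits, traits, groups = NULL) {
  if (anyDuplicated(fits$participant_id)) {
    abort("`fits` must hold one model only: one row per participant.")
  }
  if (is.null(groups)) groups <- define_groups(traits)
  # keep only the columns each table contributes, so a profiles tibble
  # (which carries both parameters and traits) can play either role
  fits <- fits[, c("participant_id", "w_p", "w_s", "a_p", "a_s")]
  traits <- traits[, c("participant_id", "AQ", "PDI")]
  dat <- fits |>
    dplyr::inner_join(traits, by = "participant_id") |>
    dplyr::inner_join(groups[, c("participant_id", "aq_group",
                                 "diagnosis_group")],
                      by = "participant_id")
  par_names <- c("a_p", "a_s", "w_p", "w_s")

  cors <- tidyr::expand_grid(trait = c("AQ", "PDI"), parameter = par_names) |>
    purrr::pmap(function(trait, parameter) {
      kendall_tau(dat[[parameter]], dat[[trait]]) |>
        dplyr::mutate(battery = "correlation",
                      contrast = trait, parameter = parameter)
    }) |> purrr::list_rbind()

  contrast_sets <- list(
    "ASD_vs_ND" = list(
      x = dat$diagnosis_group %in% "ASD",
      y = dat$diagnosis_group %in% "ND"
    ),
    "highAQ_vs_lowAQ" = list(
      x = dat$aq_group == "high",
      y = dat$aq_group == "low"
    )
  )
  grps <- tidyr::expand_grid(contrast = names(contrast_sets),
                             parameter = par_names) |>
    purrr::pmap(function(contrast, parameter) {
      sel <- contrast_sets[[contrast]]
      mann_whitney_f(dat[[parameter]][sel$x], dat[[parameter]][sel$y]) |>
        dplyr::mutate(battery = "group_contrast",
                      contrast = contrast, parameter = parameter)
    }) |> purrr::list_rbind()

  dplyr::bind_rows(cors, grps) |>
    dplyr::group_by(.data$battery) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::select("battery", "contrast", "parameter", "statistic_name",
                  "statistic", "effect_size", "p_value", "p_adjusted")
}

#' Average logit confidences between mirror-symmetric trials
#'
#' The task grid and every observer model are antisymmetric under joint
#' complementation of the two cues (a trial with prior 0.3 / likelihood
#' 0.8 mirrors one with prior 0.7 / likelihood 0.2, and the noiseless
#' predicted logits flip sign). Averaging `(L_c(t) - L_c(t')) / 2` over
#' each mirror pair therefore halves the noise variance while leaving
#' model predictions unchanged. Results are indexed by the 45
#' representative cells with likelihood >= 0.5. When one side of a pair
#' is missing the available side is used alone and the cell is flagged
#' incomplete.
#'
#' @param responses Response tibble (may hold many participants; the
#'   average is computed within participant and cell).
#' @param trials Trial tibble.
#' @return Tibble with `participant_id`, `prior_p`, `like_p` (the
#'   representative cell), `L_p`, `L_s`, `avg_L_c`, `complete`.
#' @export
symmetric_trial_average <- function(responses, trials) {
  dat <- dplyr::inner_join(
    responses[, c("participant_id", "trial_id", "L_c")],
    trials[, c("trial_id", "prior_p", "like_p")],
    by = "trial_id"
  )
  cell_means <- dat |>
    dplyr::mutate(
      # harmonize binary representations so complemented keys join exactly
      prior_p = round(.data$prior_p, 10),
      like_p = round(.data$like_p, 10)
    ) |>
    dplyr::group_by(.data$participant_id, .data$prior_p, .data$like_p) |>
    dplyr::summarise(L_c = mean(.data$L_c), .groups = "drop")

  # representative cells: likelihood >= 0.5; mirror = both cues complemented
  reps <- cell_means |>
    dplyr::filter(.data$like_p >= 0.5 - 1e-9)
  mirrors <- cell_means |>
    dplyr::transmute(
      participant_id = .data$participant_id,
      prior_p = round(1 - .data$prior_p, 10),
      like_p = round(1 - .data$like_p, 10),
      L_c_mirror = .data$L_c
    )
  out <- dplyr::full_join(
    reps, mirrors |> dplyr::filter(.data$like_p >= 0.5 - 1e-9),
    by = c("participant_id", "prior_p", "like_p")
  )
  out |>
    dplyr::mutate(
      complete = !is.na(.data$L_c) & !is.na(.data$L_c_mirror),
      avg_L_c = dplyr::case_when(
        .data$complete ~ (.data$L_c - .data$L_c_mirror) / 2,
        !is.na(.data$L_c) ~ .data$L_c,
        TRUE ~ -.data$L_c_mirror
      ),
      L_p = logit(.data$prior_p),
      L_s = logit(.data$like_p)
    ) |>
    dplyr::select("participant_id", "prior_p", "like_p", "L_p", "L_s",
                  "avg_L_c", "complete") |>
    dplyr::arrange(.data$participant_id, .data$prior_p, .data$like_p)
}
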