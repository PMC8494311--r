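make_stats_fixture <- function(n = 24, seed = 13, coupling = numeric(0),
                               trials = grid_trials()) {
  # strong couplings may clip a few draws at the box edge; that warning
  # is part of the generator's contract, not a test concern here
  suppressWarnings(
    cohort <- simulate_cohort(n, trials,
                              cohort_config(coupling_aq = coupling),
                              seed = seed)
  )
  list(trials = trials, profiles = cohort$profiles,
       responses = cohort$responses)
}

test_that("regressors follow the printed formulas", {
  responses <- tibble::tibble(
    participant_id = 1L, trial_id = 1:3,
    confidence = c(0.5, 0.9, 0.2), rt = c(1, 2, 3)
  )
  trials <- tibble::tibble(
    trial_id = 1:3,
    prior_p = c(0.8, 0.8, 0.5),
    like_p = c(0.3, 0.7, 0.9)
  )
  traits <- tibble::tibble(participant_id = 1L, AQ = 20L, PDI = 5L)
  reg <- build_regressors(responses, trials, traits)
  expect_equal(reg$abs_confidence, c(0, 0.4, 0.3))
  expect_equal(reg$abs_likelihood, c(0.2, 0.2, 0.4))
  # congruency: sign of the cue-agreement product, scaled by prior strength
  expect_equal(reg$prior_congruency, c(-0.3, 0.3, 0))
  # pure row-wise map: permuting rows permutes outputs
  perm <- c(3, 1, 2)
  reg2 <- build_regressors(responses[perm, ], trials, traits)
  expect_equal(reg2$prior_congruency, reg$prior_congruency[perm])
  # join failure surfaces as an error
  expect_error(
    build_regressors(responses |> dplyr::mutate(trial_id = 7:9),
                     trials, traits),
    "no matching trial_id"
  )
})

test_that("Kendall tau-b matches pair enumeration on tiny samples", {
  expect_equal(kendall_tau(c(1, 2, 3), c(2, 4, 6))$statistic, 1)
  expect_equal(kendall_tau(c(1, 2, 3), c(1, 3, 2))$statistic, 1 / 3,
               tolerance = 1e-12)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(4, 3, 2, 1))$statistic, -1)
  expect_warning(out <- kendall_tau(c(1, 1, 1), c(1, 2, 3)), "Zero variance")
  expect_true(is.na(out$statistic))
})

test_that("common-language effect size counts exceedance pairs", {
  expect_equal(mann_whitney_f(c(5, 6, 7), c(1, 2))$effect_size, 1)
  expect_equal(mann_whitney_f(c(1, 2, 2, 5), c(2, 1, 5, 2))$effect_size, 0.5)
  expect_equal(mann_whitney_f(c(1, 3), c(2, 4))$effect_size, 0.25)
  expect_error(mann_whitney_f(1, c(1, 2)), "at least 2")
  # complementarity f(x, y) + f(y, x) = 1, with and without ties
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- sample(1:6, 8, replace = TRUE)
      y <- sample(1:6, 5, replace = TRUE)
      expect_equal(
        mann_whitney_f(x, y)$effect_size + mann_whitney_f(y, x)$effect_size,
        1, tolerance = 1e-12
      )
    }
  })
})

test_that("AQ groups split at the 15% order statistics with ties outward", {
  tr <- tibble::tibble(participant_id = 1:100, AQ = 1:100)
  g <- define_groups(tr)
  expect_identical(sort(g$participant_id[g$aq_group == "low"]), 1:15)
  expect_identical(sort(g$participant_id[g$aq_group == "high"]), 86:100)
  expect_error(define_groups(tibble::tibble(participant_id = 1:30, AQ = 7)),
               "Degenerate AQ")
  expect_error(define_groups(tibble::tibble(participant_id = 1:3,
                                            AQ = c(1, 2, 3))),
               "too small")
})

test_that("synthetic traits at the cohort moments give plausible AQ tails", {
  tr <- grid_trials()
  cohort <- simulate_cohort(176, tr, cohort_config(), seed = 31,
                            include_responses = FALSE)
  g <- define_groups(cohort$profiles)
  n_low <- sum(g$aq_group == "low")
  n_high <- sum(g$aq_group == "high")
  # integer scores pull threshold ties into the tails; sizes sit near
  # 26-30 out of 176 for samples with these moments
  expect_gte(n_low, 26); expect_lte(n_low, 45)
  expect_gte(n_high, 26); expect_lte(n_high, 45)
  expect_true(all(cohort$profiles$AQ[g$aq_group == "high"] >
                    max(cohort$profiles$AQ[g$aq_group == "low"])))
})

test_that("the association battery reports 16 adjusted tests", {
  fx <- make_stats_fixture(n = 40, seed = 17)
  fits <- fx$profiles   # generating parameters stand in for fitted ones
  out <- association_battery(fits, fx$profiles)
  expect_equal(nrow(out), 16)
  expect_equal(sum(out$battery == "correlation"), 8)
  expect_equal(sum(out$battery == "group_contrast"), 8)
  expect_true(all(out$p_adjusted >= out$p_value - 1e-12, na.rm = TRUE))
  expect_true(all(out$effect_size[out$battery == "group_contrast"] >= 0 &
                    out$effect_size[out$battery == "group_contrast"] <= 1))
})

test_that("an injected AQ coupling is detected after correction", {
  fx <- make_stats_fixture(n = 176, seed = 19, coupling = c(a_s = 0.8))
  out <- association_battery(fx$profiles, fx$profiles)
  row <- out[out$battery == "correlation" & out$contrast == "AQ" &
               out$parameter == "a_s", ]
  expect_gt(row$statistic, 0)
  expect_lt(row$p_adjusted, 0.05)
})

test_that("symmetric-trial averaging is exact on noise-free responses", {
  tr <- grid_trials()
  p <- model_params(0.7, 0.5, 0.1, 0.2)
  resp <- simulate_responses(tr, "CINI", p, noise_sd = 1e-9, seed = 23)
  avg <- symmetric_trial_average(resp, tr)
  expect_equal(nrow(avg), 45)
  expect_true(all(avg$complete))
  pred <- predict_confidence(avg, "CINI", p)
  keep <- abs(pred) < logit(0.99)   # clipping-free cells
  expect_lt(max(abs(avg$avg_L_c[keep] - pred[keep])), 1e-6)
})

test_that("mirror averaging halves the definition and flags missing sides", {
  trials <- tibble::tibble(
    trial_id = 1:3,
    prior_p = c(0.3, 0.7, 0.9),
    like_p = c(0.2, 0.8, 0.9)
  )
  responses <- tibble::tibble(
    participant_id = 1L, trial_id = 1:3,
    confidence = inv_logit(c(-1, 2, 1.2)),
    L_c = c(-1, 2, 1.2), rt = 1
  )
  avg <- symmetric_trial_average(responses, trials)
  pair <- avg[avg$prior_p == 0.7 & avg$like_p == 0.8, ]
  expect_equal(pair$avg_L_c, (2 - (-1)) / 2)
  expect_true(pair$complete)
  lone <- avg[avg$prior_p == 0.9 & avg$like_p == 0.9, ]
  expect_false(lone$complete)
  expect_equal(lone$avg_L_c, 1.2)
})

test_that("averaging mirror pairs shrinks noise by about 1/sqrt(2)", {
  tr <- grid_trials()
  p <- model_params(0.5, 0.5)   # true weights 0.75: predictions stay small
  pred <- predict_confidence(tr, "WB", p)
  rmse <- function(x, y) sqrt(mean((x - y)^2))
  raw_err <- avg_err <- numeric(120)
  for (i in seq_along(raw_err)) {
    resp <- simulate_responses(tr, "WB", p, noise_sd = 0.8, seed = 1000 + i)
    avg <- symmetric_trial_average(resp, tr)
    apred <- predict_confidence(avg, "WB", p)
    raw_err[i] <- rmse(resp$L_c, pred)
    avg_err[i] <- rmse(avg$avg_L_c, apred)
  }
  expect_equal(mean(avg_err) / mean(raw_err), 1 / sqrt(2), tolerance = 0.05)
})

test_that("the five mixed-model variants recover the injected structure", {
  fx <- make_stats_fixture(n = 24, seed = 29)
  reg <- build_regressors(fx$responses, fx$trials, fx$profiles)
  lmes <- fit_lme_variants(reg)
  co <- lmes$coefficients

  core <- co[co$variant == "LME_core", ]
  # responses load on the likelihood cue and on cue agreement
  expect_gt(core$statistic[core$term == "abs_likelihood"], 2)
  expect_gt(core$statistic[core$term == "prior_congruency"], 2)
  # simulated reaction times are slower on uncertain trials
  rt_row <- core[core$term == "rt", ]
  expect_lt(rt_row$estimate, 0)
  expect_lt(rt_row$p_value, 0.05)

  # null cohort: parsimony favours the core variant
  expect_equal(lmes$bic$variant[which.min(lmes$bic$bic)], "LME_core")
  expect_equal(nrow(lmes$bic), 5)
  # trait interaction terms exist where specified
  expect_true("abs_likelihood:AQ" %in% co$term[co$variant == "LME_AQ"])
  expect_true(any(co$term[co$variant == "LME_rtInteract"] %in%
                    c("rt:PDI", "PDI:rt")))
  expect_false(any(grepl("AQ:PDI|PDI:AQ", co$term[co$variant == "LME_full"])))
})
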