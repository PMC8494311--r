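# Frozen reference values computed independently with 40-digit
# arbitrary-precision arithmetic from a literal transcription of the
# model equations.
F_2_08 <- 0.9869155064135507
WB_99 <- 1.6124213194577106     # prior .9, like .9, true w_p=.9, w_s=.53
CII_79 <- 1.3878238411107529    # prior .7, like .9, rescaled (.8,.06,.02,.05)
CINI_99 <- 2.1314176986100540   # prior .9, like .9, same params
FIG2_PARAMS <- model_params(w_p = 0.8, w_s = 0.06, a_p = 0.02, a_s = 0.05)

one_trial <- function(prior_p, like_p) {
  tibble::tibble(prior_p = prior_p, like_p = like_p,
                 L_p = logit(prior_p), L_s = logit(like_p))
}

test_that("the weighting sigmoid hits its anchor values and stays stable", {
  expect_equal(sigmoid_F(3.7, 0.5), 0, tolerance = 1e-12)
  for (L in c(-5, -0.3, 0, 2, 14)) expect_equal(sigmoid_F(L, 1), L)
  expect_equal(sigmoid_F(2, 0.8), F_2_08, tolerance = 1e-12)
  # antisymmetry in L
  expect_equal(sigmoid_F(-2, 0.8), -F_2_08, tolerance = 1e-12)
  # saturation without overflow at |L| = 700
  expect_equal(sigmoid_F(700, 0.9), log(9), tolerance = 1e-9)
  expect_equal(sigmoid_F(-700, 0.9), -log(9), tolerance = 1e-9)
  expect_error(sigmoid_F(1, 0.3), "\\[0.5, 1\\]")
  expect_error(sigmoid_F(1, 1.01), "\\[0.5, 1\\]")
  expect_error(sigmoid_F(Inf, 0.8), "finite")
})

test_that("parameter rescaling is an exact involution pair", {
  for (p in random_params(20)) {
    expect_equal(rescale_params(unrescale_params(p)), p, tolerance = 1e-12)
  }
  expect_error(model_params(w_p = 1.2), "\\[0, 1\\]")
  expect_error(unrescale_params(c(w_p = 0.5, w_s = 0.5)), "named vector")
})

test_that("Simple Bayes adds the two cue logits", {
  expect_equal(predict_confidence(one_trial(0.7, 0.3), "SB"), 0,
               tolerance = 1e-12)
  expect_equal(predict_confidence(one_trial(0.9, 0.9), "SB"), 2 * log(9),
               tolerance = 1e-12)
  expect_equal(predict_confidence(one_trial(0.5, 0.8), "SB"), log(4),
               tolerance = 1e-12)
})

test_that("Weighted Bayes discounts channels and matches the frozen value", {
  g <- grid_trials()
  # w = 1 on both channels reduces WB to SB
  expect_equal(
    predict_confidence(g, "WB", model_params(1, 1)),
    predict_confidence(g, "SB"),
    tolerance = 1e-10
  )
  # rescaled w = 0 (true 0.5) nulls both channels
  expect_equal(predict_confidence(g, "WB", model_params(0, 0)),
               rep(0, 81), tolerance = 1e-12)
  # frozen oracle: true weights 0.9 / 0.53 are rescaled 0.8 / 0.06
  expect_equal(
    predict_confidence(one_trial(0.9, 0.9), "WB", model_params(0.8, 0.06)),
    WB_99, tolerance = 1e-12
  )
})

test_that("circular-inference predictions match the frozen oracle values", {
  expect_equal(
    predict_confidence(one_trial(0.7, 0.9), "CII", FIG2_PARAMS),
    CII_79, tolerance = 1e-12
  )
  expect_equal(
    predict_confidence(one_trial(0.9, 0.9), "CINI", FIG2_PARAMS),
    CINI_99, tolerance = 1e-12
  )
  # fully uninformative cues give zero confidence whatever the parameters
  for (p in random_params(5)) {
    expect_equal(predict_confidence(one_trial(0.5, 0.5), "CII", p), 0,
                 tolerance = 1e-12)
    expect_equal(predict_confidence(one_trial(0.5, 0.5), "CINI", p), 0,
                 tolerance = 1e-12)
  }
})

test_that("reduction chain: SB = WB(1,1); WB = CII(a=0) = CINI(a=0)", {
  g <- grid_trials()
  for (p in random_params(20)) {
    wb <- predict_confidence(g, "WB", p)
    p0 <- p; p0[c("a_p", "a_s")] <- 0
    expect_equal(predict_confidence(g, "CII", p0), wb, tolerance = 1e-10)
    expect_equal(predict_confidence(g, "CINI", p0), wb, tolerance = 1e-10)
  }
})

test_that("all models are antisymmetric under joint cue complementation", {
  g <- grid_trials()
  gm <- g |>
    dplyr::mutate(prior_p = 1 - prior_p, like_p = 1 - like_p,
                  L_p = -L_p, L_s = -L_s)
  expect_equal(predict_confidence(gm, "SB"), -predict_confidence(g, "SB"),
               tolerance = 1e-10)
  for (p in random_params(100)) {
    for (m in c("WB", "CII", "CINI")) {
      expect_equal(
        predict_confidence(gm, m, p), -predict_confidence(g, m, p),
        tolerance = 1e-10
      )
    }
  }
})

test_that("predictions are non-decreasing in each cue logit", {
  levels <- seq(0.1, 0.9, by = 0.1)
  for (p in random_params(25)) {
    for (m in c("SB", "WB", "CII", "CINI")) {
      for (lk in c(0.2, 0.5, 0.8)) {
        along_prior <- predict_confidence(one_trial(levels, rep(lk, 9)), m, p)
        expect_true(all(diff(along_prior) >= -1e-10))
        along_like <- predict_confidence(one_trial(rep(lk, 9), levels), m, p)
        expect_true(all(diff(along_like) >= -1e-10))
      }
    }
  }
})

test_that("CINI is additive across channels; CII is not when reverberating", {
  p <- model_params(0.7, 0.6, 0.15, 0.22)
  g <- grid_trials()
  # CINI: joint prediction = sum of single-channel predictions
  joint <- predict_confidence(g, "CINI", p)
  prior_only <- predict_confidence(g |> dplyr::mutate(L_s = 0), "CINI", p)
  like_only <- predict_confidence(g |> dplyr::mutate(L_p = 0), "CINI", p)
  expect_equal(joint, prior_only + like_only, tolerance = 1e-10)
  # CII and CINI diverge once both channels carry signal and a > 0
  informative <- g$prior_p != 0.5 & g$like_p != 0.5
  diff_models <- abs(predict_confidence(g, "CII", p) - joint)
  expect_true(all(diff_models[informative] > 1e-6))
})

test_that("the compiled fitting objective agrees with the R predictions", {
  tr <- build_trial_set(130, seed = 4)
  withr::with_seed(11, {
    for (i in 1:20) {
      th <- runif(4)
      L_c <- rnorm(130)
      p <- model_params(th[1], th[2], th[3], th[4])
      for (m in c("WB", "CII", "CINI")) {
        code <- c(WB = 1L, CII = 2L, CINI = 3L)[[m]]
        expect_equal(
          circinf:::cf_mse_objective(th, tr$L_p, tr$L_s, L_c, code),
          mean((L_c - predict_confidence(tr, m, p))^2),
          tolerance = 1e-12
        )
      }
    }
  })
})

test_that("model_k reports the free-parameter counts", {
  expect_identical(model_k(c("SB", "WB", "CII", "CINI")), c(0L, 2L, 4L, 4L))
  expect_error(model_k("XX"), "Unknown model")
})
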