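---
title: "Circular-inference models of two-cue probabilistic decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circular-inference models of two-cue probabilistic decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circinf)
```

## The task and the inference problem

The fisher task is a two-alternative probabilistic decision task. On each
trial the participant sees a prior cue (two baskets whose sizes encode the
fisherman's preference for the left or right lake) followed by a likelihood
cue (the proportions of red versus black fish in each lake), and reports a
continuous confidence that a caught red fish came from the left lake. Both
cues take nine values, the probabilities 0.1 to 0.9, and within a trial the
left- and right-lake values are complementary, so a single left-lake
probability per cue describes the trial. The design grid therefore has
9 × 9 = 81 cells; the default session uses 130 trials covering every cell
at least once.

All modelling happens in log-odds (logit) space, `L = ln(p / (1 − p))`. A
trial contributes a prior logit `L_p` and a likelihood logit `L_s`; the
response contributes a confidence logit `L_c`.

## The observer models

Four nested generative observers map `(L_p, L_s)` to a noiseless predicted
confidence:

* **Simple Bayes (SB)** — ideal integration: `L_c = L_p + L_s`. No free
  parameters.
* **Weighted Bayes (WB)** — either cue may be discounted through the
  weighting sigmoid
  `F(L, w) = ln((w e^L + 1 − w) / ((1 − w) e^L + w))`:
  `L_c = F(L_p, w_p) + F(L_s, w_s)`. `F(L, 1) = L` passes a signal
  unchanged; `F(L, 0.5) = 0` silences it; for intermediate weights the
  output saturates at `±ln(w / (1 − w))`.
* **Circular inference with interference (CII)** — both signals are
  reverberated (overcounted) and the reverberated mixture
  `I = F(a_p L_p, w_p) + F(a_s L_s, w_s)` corrupts *both* channels:
  `L_c = F(L_p + I, w_p) + F(L_s + I, w_s)`. The influence of one cue
  therefore depends on the strength of the other.
* **Circular inference without interference (CINI)** — each channel
  overcounts only itself:
  `L_c = F(L_p + F(a_p L_p, w_p), w_p) + F(L_s + F(a_s L_s, w_s), w_s)`,
  which is additive across channels.

Weights live on `[0.5, 1]` and reverberation counts on `[0, 60]` on the
true scale; everything user-facing uses the rescaled representation that
maps all four to `[0, 1]` (`(w − 0.5)/0.5`, `a/60`), which is how such
parameters are conventionally reported and compared. The upper bound of 60
is an arbitrary but generous cap; fitted values stay far below it. With
both rescaled weights at 1, WB collapses to SB; with both reverberation
parameters at 0, CII and CINI collapse to WB. Every model is antisymmetric
under joint complementation of the two cues, which licenses the
mirror-trial averaging used for visualisation.

```{r curves, fig.width = 6, fig.height = 4, eval = FALSE}
plot_model_curves("CINI", model_params(w_p = 0.8, w_s = 0.06,
                                       a_p = 0.02, a_s = 0.05))
```

## Fitting and model comparison

Responses are assumed to carry additive Gaussian noise on the logit
confidence, so per-participant least squares on `L_c` is maximum
likelihood, and model comparison uses `BIC = n ln(σ²) + k ln(n)` with `σ²`
the mean squared logit residual and `k` the free-parameter count (0, 2, 4,
4 for SB, WB, CII, CINI). SB is scored in closed form. The other models
are optimised over the rescaled parameter box with bound-constrained
L-BFGS-B from a deterministic start grid (`{0.25, 0.75}^d`) plus eight
seeded random restarts; the best solution wins and exact ties go to the
smallest `a_p + a_s`, then the lexicographically smallest vector —
preferring the least-reverberant explanation and making refits
bit-reproducible. A zero MSE (possible only on degenerate noise-free
input) is floored at 1e−12 before the logarithm.

Group-level comparison is offered in both flavours used in this
literature: the fixed-effects summed ΔBIC relative to a configurable
baseline (default CII), and random-effects Bayesian model selection, which
treats the model identity as a random effect across participants. The
latter is the standard variational Dirichlet scheme over approximate log
model evidences (`−BIC/2`): responsibilities
`u_nk ∝ exp(lev_nk + ψ(α_k) − ψ(Σα))`, concentration updates
`α_k = α₀ + Σ_n u_nk`, iterated to a 1e−6 fixed point with α₀ = 1
(uniform prior), and exceedance probabilities — the posterior probability
that a model is the most frequent in the population — estimated from 10⁶
seeded Dirichlet draws. Note an algebraic consequence of the uniform
prior: a *single* participant, however decisive, can push a model's
expected posterior probability to at most `(α₀ + 1)/(K α₀ + 1)` (2/3 for
two models); decisiveness shows up in the responsibilities and, with more
participants, in the exceedance probability.

## The synthetic cohort generator

Because no participant-level dataset ships with the package, every
downstream stage is exercised on synthetic cohorts, and the generator is
itself part of the tested surface. Each participant draws

* rescaled weights from U(0.3, 1) and reverberation from U(0, 0.3) — a
  range bracketing published fitted values, whose reported maximum
  rescaled reverberation is about 0.48;
* a logit-noise SD from U(0.5, 1.5);
* integer AQ and PDI totals from truncated normals with the cohort
  moments reported for this task's reference sample (AQ mean 22.9, SD
  6.5 on 0–50; PDI mean 6.1, SD 3.1 on 0–21), with an ASD-labelled
  fraction (default 12%) drawing AQ from mean 28.0, SD 8.0;
* reaction times from a log-normal whose location decreases with the
  absolute noiseless prediction, so the well-known
  slower-when-uncertain pattern is present for the mixed-model stage.

Trait–parameter couplings default to zero: the *null cohort*, on which the
association battery must show type-I error control, mirroring the null
result regime this analysis was designed around. Nonzero couplings shift a
parameter by `coupling × 0.1 ×` the standardised trait, for power checks.

Confidences are stored as probabilities clipped into `[0.01, 0.99]`
(`|L_c| ≤ ln 99 ≈ 4.6`), a stand-in for edge clicks on the bounded
response scale; how the original study handled edge responses is not
documented. Two things the generator deliberately does *not* emulate:
item-level questionnaire structure (only totals are drawn) and any
participant-exclusion process — a heuristic low-quality screen
(`flag_low_quality()`: near-constant confidence, or many midpoint clicks)
is provided but opt-in, since the original exclusion criteria are not
public. Passing tests on these cohorts therefore validates the estimator
and the statistics under the stated generative assumptions, not the
behaviour of real participants.

One definitional consequence matters for validation: response-scale
clipping censors large logits, and noiseless circular-inference
predictions routinely exceed `ln 99` under the generating ranges above.
The recovery suite therefore simulates with an effectively inactive
clipping margin (`eps = 1e-9`, overridable) — it validates the estimator
under its own generative assumption of unbounded Gaussian logit noise —
while cohort simulation keeps the response-scale margin. With the
response-scale margin left in place, zero-noise recovery would measure the
censoring, not the estimator.

## Recovery validation

`parameter_recovery()` draws generating parameter sets, simulates
130-trial responses, refits, and reports generating-vs-recovered Pearson
and Kendall correlations (Pearson is kept alongside the rank statistic
precisely because it is outlier-sensitive for the reverberation
parameters) plus the cross-correlation matrix of recovered parameters.
`model_recovery()` simulates from each of two models, fits both, assigns
by lower BIC, and reports the confusion matrix; exact BIC ties — which
arise when both variants coincide at the boundary `a = 0` — are credited
to the generating model and logged.

One identifiability caveat is intrinsic to the model family: once the
reverberated signal `a·L` is large enough that `F` saturates on every
trial of the design, the likelihood is exactly flat in `a` above that
threshold, so reverberation draws in the saturated region cannot be
recovered even from noiseless data — the fit returns the best-scoring
plateau point. Weights do not suffer from this. Under the wide stand-in
generating range this affects a minority of draws and caps the
zero-noise reverberation recovery correlation slightly below 1.

The validation-level expectations reproduce the published design:
near-perfect recovery at vanishing noise; at noise SD 1,
"excellent" weight recovery (r ≥ 0.85) with weaker but positive
reverberation recovery; and roughly 80% correct model recovery. The last
figure depends on the (unpublished) distribution the original simulants
were drawn from; under this package's stand-in distribution the
CINI-generated row stays in the expected band around 80% while
CII-generated data is *more* identifiable (~95%), because reverberation
values near the top of U(0, 0.3) produce interference signatures the
additive variant cannot imitate. We report this asymmetry rather than re-tuning the
generator to the published cell counts.

## The statistical battery

The model-free stage regresses trial-level absolute confidence
`|c − 0.5|` on absolute likelihood `|like − 0.5|`, prior congruency
`|prior − 0.5| · sgn[(prior − 0.5)(like − 0.5)]` (with `sgn(0) = 0`),
their interaction, and reaction time, with participants as a random
factor (intercept plus slopes for the two task regressors, falling back
to intercept-only — flagged — when that structure is singular). Five
variants add trait terms: none (`LME_core`), AQ, PDI, both
(`LME_full`), and both plus reaction-time-by-trait interactions
(`LME_rtInteract`); all are fitted by maximum likelihood via `lme4` /
`lmerTest` so BICs are comparable, and trait scores are z-scored for
numerical balance.

The model-based battery takes one model's fitted parameters per
participant and runs Kendall tau-b correlations against AQ and PDI and
Mann–Whitney U tests (with the common-language effect size
`f = U/(n₁n₂)`, tie-corrected, oriented so `f > 0.5` means larger values
in the ASD or high-AQ group) across two contrasts: self-reported ASD
diagnosis versus no diagnosis, and the top versus bottom 15% of the AQ
distribution (`floor(0.15 n)` per tail, threshold ties included outward).
Tau-b is used because integer trait totals guarantee ties; p-values are
exact only for small tie-free samples, otherwise the tie-corrected normal
approximation. Each 8-test battery is Benjamini–Hochberg adjusted — the
specific correction behind the original analysis is not named in print,
so BH is the documented stand-in — and unadjusted p-values are always
reported alongside.

## Numerical choices and problem sizes

* `F` is evaluated as a difference of two stabilised
  `log(w e^L + 1 − w)` terms with the exponent factored out, so `|L|` up
  to 700 neither overflows nor loses the saturation limit.
* The MSE objective used inside the optimizer is compiled (Rcpp) and
  tested to agree with the R prediction functions to 1e−12; equivalence
  and reduction-chain tolerances are 1e−10.
* Test-suite problem sizes are chosen to exercise each claim at the scale
  its sampling error requires: 200 simulants per generating model for the
  confusion matrix, 200 (noise SD 1) and 50 (noiseless) for parameter
  recovery, 500 null cohorts of 60 participants for type-I calibration
  of the association battery, and 100 random parameter draws over the
  full 81-cell grid for the algebraic identities.

## Known limitations

* The 130-trial composition, the original exclusion criteria, and the
  generating distribution behind the published recovery figures are all
  unpublished; the package ships documented stand-ins for each.
* Bayes-factor columns of the original result tables are out of scope
  (they depend on a specific GUI tool's default priors); the battery
  reports frequentist statistics with an effect size.
* Reverberation parameters are unidentifiable above the saturation
  threshold of `F` (see the recovery section); fitted values there are
  plateau representatives, not point estimates.
* Fitting is independent per participant; no hierarchical shrinkage.
* Protected exceedance probabilities are not implemented (not used in
  the analysis this package reproduces).
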