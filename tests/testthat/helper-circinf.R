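# Shared fixtures, all generated in code.

# the bare 81-cell design grid, one trial per cell, unshuffled order
grid_trials <- function() {
  levels <- seq(0.1, 0.9, by = 0.1)
  tidyr::expand_grid(prior_p = levels, like_p = levels) |>
    dplyr::mutate(
      trial_id = dplyr::row_number(),
      L_p = logit(prior_p),
      L_s = logit(like_p),
      .before = 1
    )
}

# random rescaled parameter draws on the full box
random_params <- function(n, seed = 42) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n), function(i) {
      model_params(runif(1), runif(1), runif(1), runif(1))
    })
  })
}
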