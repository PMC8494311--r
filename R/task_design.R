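#' Construct a balanced fisher-task trial set
#'
#' The task presents two probabilistic cues per trial: a prior cue (basket
#' sizes, the fisherman's lake preference) and a likelihood cue (red/black
#' fish proportions). Each cue takes one of nine levels, the probabilities
#' 0.1 to 0.9, and within a trial left- and right-lake probabilities are
#' complementary, so only the left-lake value is stored. The full design
#' grid therefore has 9 x 9 = 81 cells.
#'
#' With the default full-coverage policy every grid cell appears at least
#' `floor(n_trials / 81)` times and the remaining trials are spread as
#' evenly as possible: extra cells are chosen along (seeded) cyclic
#' diagonals of the grid, which keeps the nine marginal frequencies of each
#' cue within one count of each other. Trial order is then shuffled by
#' `seed`; the same seed always yields the same sequence.
#'
#' @param n_trials Number of trials; at least 81 so the grid is covered.
#' @param seed Integer seed controlling oversampled-cell choice and order.
#' @param levels Cue probability levels (default the nine levels 0.1-0.9).
#' @return A tibble with one row per trial: `trial_id`, `prior_p`,
#'   `like_p`, and their natural-log odds `L_p`, `L_s`.
#' @examples
#' trials <- build_trial_set(130, seed = 1)
#' dplyr::count(trials, prior_p, like_p)
#' @export
build_trial_set <- function(n_trials = 130L, seed = 1L,
                            levels = seq(0.1, 0.9, by = 0.1)) {
  n_trials <- as.integer(n_trials)
  # snap to shortest-decimal doubles so values survive CSV round trips
  levels <- round(levels, 10)
  nl <- length(levels)
  n_cells <- nl * nl
  if (n_trials < n_cells) {
    abort(sprintf(
      "Full-grid coverage needs at least %d trials; got %d.",
      n_cells, n_trials
    ))
  }
  grid <- tidyr::expand_grid(prior_p = levels, like_p = levels)
  n_full <- n_trials %/% n_cells
  r <- n_trials %% n_cells

  with_seed(seed, {
    extra <- grid[diagonal_cells(nl, r), , drop = FALSE]
    trials <- dplyr::bind_rows(
      purrr::map(seq_len(n_full), function(i) grid),
      extra
    )
    trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  })

  trials |>
    dplyr::mutate(
      trial_id = dplyr::row_number(),
      L_p = logit(.data$prior_p),
      L_s = logit(.data$like_p),
      .before = 1
    )
}

# Pick `r` cells of an `nl` x `nl` grid so that each row and each column is
# used either floor(r/nl) or ceiling(r/nl) times: take whole cyclic
# diagonals {(i, (i + k) mod nl)} for k = 0, ..., q - 1, then a random
# subset of rows from diagonal q. Returns row indices into the grid laid
# out row-major (prior varying slowest).
diagonal_cells <- function(nl, r) {
  stopifnot(r >= 0, r < nl * nl)
  if (r == 0) return(integer(0))
  q <- r %/% nl
  s <- r %% nl
  ks <- rep(seq_len(q) - 1L, each = nl)
  rows <- rep(seq_len(nl) - 1L, times = q)
  if (s > 0) {
    pick <- sort(sample.int(nl, s)) - 1L
    ks <- c(ks, rep(q, s))
    rows <- c(rows, pick)
  }
  cols <- (rows + ks) %% nl
  rows * nl + cols + 1L
}

#' Read and write trial-set CSV files
#'
#' Only `trial_id`, `prior_p` and `like_p` are stored; the logits are
#' recomputed on load so the file never carries stale derived columns.
#'
#' @param trials A trial-set tibble from [build_trial_set()].
#' @param path File path of the trial CSV.
#' @return `read_trials()` returns the trial tibble with logits;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(
    trials[, c("trial_id", "prior_p", "like_p")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path)
  req <- c("trial_id", "prior_p", "like_p")
  if (!all(req %in% names(raw))) {
    abort(sprintf("Trial CSV must have columns %s.", paste(req, collapse = ", ")))
  }
  tibble::as_tibble(raw[, req]) |>
    dplyr::mutate(L_p = logit(.data$prior_p), L_s = logit(.data$like_p))
}
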