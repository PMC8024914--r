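# Explore-trial labelling and novelty-propensity estimation.
#
# Behaviourally, subjects tend to sample a newly introduced stimulus on the
# *second* trial after it appears (lag 2), once they have seen one outcome
# cycle of the incumbent set. Novelty propensity (NP) summarizes how strong
# that pull is: the EV of the best non-novel alternative at which the
# subject is indifferent (50% novel choice) on lag-2 trials.

#' Label explore trials
#'
#' A responded trial is an explore trial when the chosen stimulus is at
#' lag 2 (second trial since its introduction). All other responded trials
#' are non-explore; non-responded trials are neither.
#'
#' @param trajectory An `nb_trajectory` from [derive_trajectory()] (any
#'   tibble with `responded` and `lag_chosen` works).
#' @return The input with a logical `explore` column.
#' @export
label_explore <- function(trajectory) {
  trajectory$explore <- trajectory$responded &
    !is.na(trajectory$lag_chosen) & trajectory$lag_chosen == 2L
  trajectory
}

#' Proportion of novel-stimulus choices by lag
#'
#' For each lag value, the fraction of offers of a stimulus at that lag that
#' were chosen. A trial contributes one offer per offered stimulus. Lags
#' with no offers are absent from the output rather than reported as zero.
#'
#' @param choices A choice dataset, or one covering several subjects
#'   (rows are pooled).
#' @return A tibble of class `nb_lag_curve` with `lag`, `n_offers`,
#'   `n_chosen`, `prop_chosen`.
#' @export
novel_choice_by_lag <- function(choices) {
  if (is.list(choices) && !is.data.frame(choices)) {
    choices <- dplyr::bind_rows(choices)
  }
  dat <- split(choices, choices[["subject_id"]] %||% "all")
  offers <- purrr::map_dfr(dat, function(ch) {
    ch <- compute_lags(dplyr::arrange(ch, .data$trial))
    tidyr::pivot_longer(
      ch,
      cols = c("stim_left", "stim_mid", "stim_right"),
      names_to = "pos", values_to = "stimulus_id"
    ) |>
      dplyr::mutate(
        lag = dplyr::case_when(
          pos == "stim_left" ~ .data$lag_left,
          pos == "stim_mid" ~ .data$lag_mid,
          TRUE ~ .data$lag_right
        ),
        picked = .data$responded & !is.na(.data$chosen) &
          .data$chosen == .data$stimulus_id
      )
  })
  out <- offers |>
    dplyr::filter(.data$responded) |>
    dplyr::group_by(lag = .data$lag) |>
    dplyr::summarise(
      n_offers = dplyr::n(),
      n_chosen = sum(.data$picked),
      prop_chosen = mean(.data$picked),
      .groups = "drop"
    )
  class(out) <- c("nb_lag_curve", class(out))
  out
}

#' Estimate novelty propensity (NP)
#'
#' Restricts to trials on which a lag-2 stimulus is offered and fits a
#' logistic regression of the indicator "chose the novel (minimum-lag)
#' stimulus" on the EV of the best non-novel offered stimulus. NP is the
#' EV at which the fitted probability is 0.5, i.e. `-intercept / slope`.
#' The estimate is reported non-identifiable (NP missing) when the outcome
#' or predictor is constant, the fit separates, or the slope is
#' non-negative (novel choice should fall as the best alternative's value
#' rises).
#'
#' @param trajectory An `nb_trajectory` from [derive_trajectory()].
#' @param min_trials Minimum number of usable lag-2 trials (default 8).
#' @return A one-row tibble of class `nb_np`: `np_value`, `intercept`,
#'   `slope`, `n_lag2`, `identifiable`.
#' @export
estimate_np <- function(trajectory, min_trials = 8L) {
  lag2 <- trajectory$responded &
    (trajectory$lag_left == 2L | trajectory$lag_mid == 2L |
       trajectory$lag_right == 2L) &
    !is.na(trajectory$ev_best_nonnovel)
  d <- trajectory[lag2, ]
  if (nrow(d) < min_trials) {
    abort(sprintf("insufficient data: %d usable lag-2 trials (< %d).",
                  nrow(d), min_trials))
  }
  fit_np_logistic(y = d$chose_novel, x = d$ev_best_nonnovel)
}

# logistic 50%-point fit; shared by estimate_np and tests
fit_np_logistic <- function(y, x) {
  n <- length(y)
  res <- tibble::tibble(np_value = NA_real_, intercept = NA_real_,
                        slope = NA_real_, n_lag2 = n, identifiable = FALSE)
  if (length(unique(y)) < 2L || !isTRUE(sd(x) > 0)) {
    class(res) <- c("nb_np", class(res))
    return(res)
  }
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  co <- coef(fit)
  p <- fitted(fit)
  separated <- !fit$converged || any(abs(co) > 1e3) ||
    all(p > 1 - 1e-8 | p < 1e-8)
  res$intercept <- co[[1L]]
  res$slope <- co[[2L]]
  if (!separated && co[[2L]] < 0) {
    res$np_value <- -co[[1L]] / co[[2L]]
    res$identifiable <- TRUE
  }
  class(res) <- c("nb_np", class(res))
  res
}

#' Novelty propensity for every subject in a cohort
#'
#' Maps [estimate_np()] over subjects; subjects with insufficient lag-2
#' trials or a non-identifiable fit get a missing `np_value` instead of an
#' error.
#'
#' @param trajectories A tibble of trajectories with a `subject_id` column,
#'   or a named list of per-subject trajectories.
#' @param min_trials Passed to [estimate_np()].
#' @return A tibble with one row per subject.
#' @export
estimate_np_cohort <- function(trajectories, min_trials = 8L) {
  if (is.data.frame(trajectories)) {
    trajectories <- split(trajectories, trajectories$subject_id)
  }
  purrr::imap_dfr(trajectories, function(tr, id) {
    out <- tryCatch(estimate_np(tr, min_trials = min_trials),
                    error = function(e) {
                      tibble::tibble(np_value = NA_real_, intercept = NA_real_,
                                     slope = NA_real_, n_lag2 = NA_integer_,
                                     identifiable = FALSE)
                    })
    dplyr::bind_cols(tibble::tibble(subject_id = id), out)
  })
}
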