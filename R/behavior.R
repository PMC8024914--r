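# Subject-level behavioral metrics and their clinical correlations.

#' Proportion of best (or worst) non-novel choices
#'
#' Over responded trials offering at least one non-novel stimulus
#' (lag > `novel_lag_max` in the trajectory), the fraction on which the
#' chosen stimulus was the non-novel stimulus with the maximal (or minimal)
#' current model EV. Trials with no non-novel stimulus on offer are excluded
#' from the denominator. EVs come from the fixed-group-learning-rate
#' trajectory, not from latent payoff rates; pass a trajectory derived with
#' the appropriate `alpha`.
#'
#' @param trajectory An `nb_trajectory` from [derive_trajectory()].
#' @param which `"best"` or `"worst"`.
#' @return One-row tibble: `prop` (NA with a warning if no eligible
#'   trials), `n_eligible`, `n_matched`.
#' @export
prop_best_nonnovel <- function(trajectory, which = c("best", "worst")) {
  which <- match.arg(which)
  evs <- as.matrix(trajectory[, c("ev_left", "ev_mid", "ev_right")])
  lags <- as.matrix(trajectory[, c("lag_left", "lag_mid", "lag_right")])
  ids <- as.matrix(trajectory[, c("stim_left", "stim_mid", "stim_right")])
  novel_lag_max <- infer_novel_lag_max(trajectory, lags)
  nonnovel <- lags > novel_lag_max
  evn <- evs
  evn[!nonnovel] <- NA_real_
  target <- suppressWarnings(
    apply(evn, 1L, if (which == "best") max else min, na.rm = TRUE)
  )
  eligible <- trajectory$responded & is.finite(target)
  if (!any(eligible)) {
    warn("no responded trials with a non-novel stimulus on offer.")
    return(tibble::tibble(prop = NA_real_, n_eligible = 0L, n_matched = 0L))
  }
  chosen_ev <- trajectory$ev_chosen
  chosen_nonnovel <- !is.na(trajectory$lag_chosen) &
    trajectory$lag_chosen > novel_lag_max
  matched <- eligible & chosen_nonnovel & chosen_ev == target
  tibble::tibble(
    prop = sum(matched) / sum(eligible),
    n_eligible = sum(eligible),
    n_matched = sum(matched)
  )
}

# the trajectory's novelty window: smallest lag classed as non-novel minus 1;
# recovered from how ev_best_nonnovel was filled in
infer_novel_lag_max <- function(trajectory, lags) {
  attr(trajectory, "novel_lag_max") %||% 2L
}

#' Model-predicted best/worst non-novel choice proportions
#'
#' The softmax policy's mean probability mass on the best and worst
#' non-novel stimulus over the same eligible trials as
#' [prop_best_nonnovel()]; used for consistency-of-fit diagnostics
#' (predicted vs. observed proportions).
#'
#' @param trajectory An `nb_trajectory`.
#' @param beta Inverse temperature at which to evaluate the policy
#'   (typically the subject's fitted beta).
#' @return One-row tibble: `prop_best_pred`, `prop_worst_pred`,
#'   `n_eligible`.
#' @export
predicted_choice_props <- function(trajectory, beta) {
  evs <- as.matrix(trajectory[, c("ev_left", "ev_mid", "ev_right")])
  lags <- as.matrix(trajectory[, c("lag_left", "lag_mid", "lag_right")])
  novel_lag_max <- infer_novel_lag_max(trajectory, lags)
  nonnovel <- lags > novel_lag_max
  evn <- evs
  evn[!nonnovel] <- NA_real_
  best <- suppressWarnings(apply(evn, 1L, max, na.rm = TRUE))
  worst <- suppressWarnings(apply(evn, 1L, min, na.rm = TRUE))
  eligible <- trajectory$responded & is.finite(best)
  p <- choice_probabilities(evs[eligible, , drop = FALSE], beta)
  is_best <- nonnovel[eligible, , drop = FALSE] &
    evs[eligible, , drop = FALSE] == best[eligible]
  is_worst <- nonnovel[eligible, , drop = FALSE] &
    evs[eligible, , drop = FALSE] == worst[eligible]
  tibble::tibble(
    prop_best_pred = mean(rowSums(p * is_best)),
    prop_worst_pred = mean(rowSums(p * is_worst)),
    n_eligible = sum(eligible)
  )
}

#' Partial correlations of clinical scores with behavioral metrics
#'
#' For each (score, metric) pair, the partial correlation controlling for
#' the given covariates (by default sex), with two-sided p-values on
#' `n - 2 - k` degrees of freedom.
#'
#' @param cohort Subject-level data frame.
#' @param scores,metrics Column names.
#' @param covariates Column names to control for (default `"sex"`).
#' @return Tibble: `score`, `metric`, `r`, `df`, `p_value`, `n`.
#' @export
behavioral_correlations <- function(cohort,
                                    scores = c("audit_rankit_z", "cudit_z"),
                                    metrics = c("prop_best_nonnovel", "np_value"),
                                    covariates = "sex") {
  if (nrow(cohort) < 10L) abort("need >= 10 subjects.")
  grid <- tidyr::expand_grid(score = scores, metric = metrics)
  purrr::pmap_dfr(grid, function(score, metric) {
    keep <- complete.cases(cohort[, c(score, metric, covariates)])
    pc <- partial_correlation(cohort[keep, ], x = score, y = metric,
                              covariates = covariates)
    dplyr::bind_cols(tibble::tibble(score = score, metric = metric), pc,
                     tibble::tibble(n = sum(keep)))
  })
}

#' All behavioral metrics for one subject
#'
#' Convenience wrapper combining [prop_best_nonnovel()], [estimate_np()]
#' and [total_winnings()].
#'
#' @param choices Choice dataset for one subject.
#' @param alpha Learning rate for the trajectory (group value by default).
#' @param ev_init Initial EV for novel stimuli.
#' @param payout_fraction Payout fraction.
#' @return One-row tibble of metrics.
#' @export
behavior_metrics <- function(choices, alpha = 0.692, ev_init = 0.216,
                             payout_fraction = 0.10) {
  tr <- derive_trajectory(choices, alpha = alpha, ev_init = ev_init)
  pb <- prop_best_nonnovel(tr)
  np <- tryCatch(estimate_np(tr), error = function(e) {
    tibble::tibble(np_value = NA_real_, intercept = NA_real_,
                   slope = NA_real_, n_lag2 = NA_integer_,
                   identifiable = FALSE)
  })
  w <- total_winnings(choices, payout_fraction)
  tibble::tibble(
    prop_best_nonnovel = pb$prop,
    n_eligible = pb$n_eligible,
    np_value = np$np_value,
    np_identifiable = np$identifiable,
    n_explore = sum(tr$explore),
    n_trials = sum(tr$responded),
    winnings = w$winnings,
    payout = w$payout
  )
}
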