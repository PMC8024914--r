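# Maximum-likelihood fitting of the delta-rule / softmax model.
#
# Trajectories (EVs, RPEs) depend on the learning rate and the feedback
# history only, never on beta, so fitting profiles the likelihood: for each
# candidate alpha the forward pass is run once and beta is optimized on the
# cached EVs.

# ---- forward pass -----------------------------------------------------------

# pre-choice EV matrix (n x 3, aligned with the offered columns) for one
# subject; chosen may contain NA on non-responded trials
ev_forward_pass <- function(offered, lags, run_trial, chosen, feedback,
                            responded, alpha, ev_init_novel, ev_init_start) {
  n <- nrow(offered)
  ev <- numeric(max(offered))
  out <- matrix(NA_real_, n, 3L)
  for (t in seq_len(n)) {
    off <- offered[t, ]
    new <- lags[t, ] == 1L
    if (any(new)) {
      ev[off[new]] <- if (run_trial[t] == 1L) ev_init_start else ev_init_novel
    }
    out[t, ] <- ev[off]
    if (responded[t] && !is.na(chosen[t])) {
      ch <- chosen[t]
      ev[ch] <- ev[ch] + alpha * (feedback[t] - ev[ch])
    }
  }
  out
}

# unpack a choices tibble into the arrays the forward pass needs
prepare_choices <- function(choices) {
  need <- c("run", "trial", "stim_left", "stim_mid", "stim_right",
            "chosen", "feedback", "responded")
  if (!all(need %in% names(choices))) {
    abort(sprintf("choice data must have columns: %s", paste(need, collapse = ", ")))
  }
  choices <- dplyr::arrange(choices, .data$trial)
  if (!"run_trial" %in% names(choices)) {
    choices <- choices |>
      dplyr::group_by(.data$run) |>
      dplyr::mutate(run_trial = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  choices <- compute_lags(choices)
  offered <- as.matrix(choices[, c("stim_left", "stim_mid", "stim_right")])
  # compact ids so the EV state vector stays small
  uid <- sort(unique(as.vector(offered)))
  omap <- matrix(match(offered, uid), nrow(offered), 3L)
  chosen <- match(choices$chosen, uid)
  resp <- choices$responded & !is.na(choices$chosen)
  k <- integer(nrow(offered))
  for (j in 1:3) k[omap[, j] == chosen & resp] <- j
  if (any(resp & k == 0L)) {
    abort(sprintf("chosen stimulus not among offered on trial row(s): %s",
                  paste(head(which(resp & k == 0L), 5L), collapse = ", ")))
  }
  list(
    offered = omap,
    lags = as.matrix(choices[, c("lag_left", "lag_mid", "lag_right")]),
    run_trial = choices$run_trial,
    chosen = chosen,
    chosen_col = k,
    feedback = choices$feedback,
    responded = resp,
    trials = choices
  )
}

#' Derive the EV/RPE trajectory implied by a choice dataset
#'
#' Deterministic forward pass of the delta rule at a fixed learning rate:
#' only the chosen stimulus's EV is updated, non-responded trials leave all
#' EVs unchanged and have a missing RPE. Newly introduced stimuli start at
#' `ev_init`. EVs reported for a trial are the pre-choice (decision-time)
#' values, so `rpe_chosen = feedback - ev_chosen` on every responded trial.
#'
#' @param choices A choice dataset tibble (see [simulate_agent()]).
#' @param alpha Learning rate in (0, 1\]. The group value 0.692 is the
#'   default used throughout the downstream pipeline.
#' @param ev_init Initial EV (dollars) for newly introduced stimuli (and for
#'   the run-initial stimuli).
#' @param novel_lag_max Largest lag at which a stimulus still counts as
#'   novel; stimuli with lag > `novel_lag_max` are non-novel when computing
#'   `ev_best_nonnovel`. Default 2, matching the explore window.
#' @return A tibble of class `nb_trajectory`: the input rows plus `ev_left`,
#'   `ev_mid`, `ev_right`, `lag_left/mid/right`, `ev_chosen`, `rpe_chosen`,
#'   `ev_best_nonnovel` (max EV over offered non-novel stimuli, NA when all
#'   offered are novel), `novel_stim` (minimum-lag offered stimulus id),
#'   `chose_novel`, and `explore` (responded and chosen stimulus at lag 2).
#' @export
derive_trajectory <- function(choices, alpha = 0.692, ev_init = 0.216,
                              novel_lag_max = 2L) {
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  d <- prepare_choices(choices)
  ev <- ev_forward_pass(d$offered, d$lags, d$run_trial, d$chosen, d$feedback,
                        d$responded, alpha, ev_init, ev_init)
  out <- d$trials
  out$ev_left <- ev[, 1L]
  out$ev_mid <- ev[, 2L]
  out$ev_right <- ev[, 3L]
  idx <- cbind(seq_len(nrow(ev)), pmax(d$chosen_col, 1L))
  out$ev_chosen <- ifelse(d$responded, ev[idx], NA_real_)
  out$rpe_chosen <- ifelse(d$responded, d$feedback - out$ev_chosen, NA_real_)
  nonnovel <- d$lags > novel_lag_max
  evn <- ev
  evn[!nonnovel] <- NA_real_
  out$ev_best_nonnovel <- suppressWarnings(apply(evn, 1L, max, na.rm = TRUE))
  out$ev_best_nonnovel[!is.finite(out$ev_best_nonnovel)] <- NA_real_
  min_lag_col <- max.col(-d$lags, ties.method = "first")
  offered_ids <- as.matrix(out[, c("stim_left", "stim_mid", "stim_right")])
  out$novel_stim <- offered_ids[cbind(seq_len(nrow(out)), min_lag_col)]
  out$chose_novel <- d$responded & d$chosen_col == min_lag_col
  if (!"lag_chosen" %in% names(out)) {
    out$lag_chosen <- ifelse(d$responded, d$lags[idx], NA_integer_)
  }
  out$explore <- d$responded & !is.na(out$lag_chosen) & out$lag_chosen == 2L
  class(out) <- c("nb_trajectory", class(out))
  out
}

# ---- likelihood -------------------------------------------------------------

# nll of beta given cached EVs of responded trials
nll_beta <- function(beta, ev, k) {
  z <- beta * ev
  -sum(z[cbind(seq_len(nrow(ev)), k)] - row_logsumexp(z))
}

# cache (responded-trial EV matrix, chosen column) for one prepared subject
cache_at_alpha <- function(d, alpha, ev_init) {
  ev <- ev_forward_pass(d$offered, d$lags, d$run_trial, d$chosen, d$feedback,
                        d$responded, alpha, ev_init, ev_init)
  list(ev = ev[d$responded, , drop = FALSE], k = d$chosen_col[d$responded])
}

#' Negative log-likelihood of choice data under the softmax/delta-rule model
#'
#' `-sum log P(chosen)` over responded trials, with choice probabilities from
#' the softmax applied to the trajectory EVs at the given learning rate.
#' Computed with log-sum-exp, so large `beta` does not overflow.
#'
#' @param choices A choice dataset tibble.
#' @param params An [agent_params()] object (or list with `alpha`, `beta`,
#'   `ev_init_novel`).
#' @return Scalar negative log-likelihood.
#' @export
#' @examples
#' sched <- generate_schedule(task_config(n_runs = 1, n_novel_introductions = 5), seed = 1)
#' ch <- simulate_agent(sched, agent_params(0.7, 5), seed = 2)
#' negative_log_likelihood(ch, agent_params(0.7, 5))
negative_log_likelihood <- function(choices, params) {
  if (!inherits(params, "nb_agent_params")) params <- do.call(agent_params, params)
  d <- prepare_choices(choices)
  if (!any(d$responded)) abort("no responded trials in the dataset.")
  cc <- cache_at_alpha(d, params$alpha, params$ev_init_novel)
  nll_beta(params$beta, cc$ev, cc$k)
}

# ---- fitting ----------------------------------------------------------------

new_fit_result <- function(alpha_hat, beta_hat, fixed, nll, n_trials,
                           n_subjects, converged, identifiable, n_grid) {
  structure(
    list(alpha_hat = alpha_hat, beta_hat = beta_hat, fixed = fixed,
         nll = nll, n_trials = n_trials, n_subjects = n_subjects,
         converged = converged, identifiable = identifiable,
         n_restarts_used = n_grid),
    class = "nb_fit"
  )
}

#' @export
print.nb_fit <- function(x, ...) {
  bh <- if (length(x$beta_hat) > 1L) {
    sprintf("per-subject (mean %.3f)", mean(x$beta_hat))
  } else {
    sprintf("%.3f", x$beta_hat)
  }
  cat(sprintf(
    "<nb_fit> alpha = %.4f%s, beta = %s%s, nll = %.2f (%d trials, %d subject%s)\n",
    x$alpha_hat, if (x$fixed[["alpha"]]) " [fixed]" else "",
    bh, if (x$fixed[["beta"]]) " [fixed]" else "",
    x$nll, x$n_trials, x$n_subjects, if (x$n_subjects > 1) "s" else ""
  ))
  if (!x$identifiable) cat("  (likelihood flat: parameters not identifiable)\n")
  invisible(x)
}

#' @export
#' @method tidy nb_fit
tidy.nb_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha_hat, mean(x$beta_hat)),
    fixed = c(x$fixed[["alpha"]], x$fixed[["beta"]])
  )
}

#' @export
#' @method glance nb_fit
glance.nb_fit <- function(x, ...) {
  tibble::tibble(
    nll = x$nll, n_trials = x$n_trials, n_subjects = x$n_subjects,
    converged = x$converged, identifiable = x$identifiable
  )
}

# profile fit shared by fit_subject / fit_pooled.
# prepared: list of prepare_choices() outputs; share_beta: one beta for all
# subjects or one per subject.
profile_fit <- function(prepared, fixed_alpha = NULL, fixed_beta = NULL,
                        alpha_bounds = c(0.01, 1), beta_bounds = c(0, 50),
                        n_grid = 21L, ev_init = 0.216, share_beta = TRUE) {
  inner <- function(alpha) {
    caches <- lapply(prepared, cache_at_alpha, alpha = alpha, ev_init = ev_init)
    if (!is.null(fixed_beta)) {
      betas <- rep(fixed_beta, if (share_beta) 1L else length(prepared))
      tot <- sum(vapply(caches, function(cc) nll_beta(fixed_beta, cc$ev, cc$k), 0))
      return(list(nll = tot, beta = betas))
    }
    if (share_beta) {
      f <- function(b) sum(vapply(caches, function(cc) nll_beta(b, cc$ev, cc$k), 0))
      op <- optimize(f, beta_bounds, tol = 1e-5)
      list(nll = op$objective, beta = op$minimum)
    } else {
      ops <- lapply(caches, function(cc) {
        optimize(function(b) nll_beta(b, cc$ev, cc$k), beta_bounds, tol = 1e-5)
      })
      list(nll = sum(vapply(ops, `[[`, 0, "objective")),
           beta = vapply(ops, `[[`, 0, "minimum"))
    }
  }

  if (!is.null(fixed_alpha)) {
    res <- inner(fixed_alpha)
    return(list(alpha = fixed_alpha, beta = res$beta, nll = res$nll,
                identifiable = is.null(fixed_beta) || fixed_beta > 0,
                converged = is.finite(res$nll), n_grid = 1L))
  }

  grid <- seq(alpha_bounds[1], alpha_bounds[2], length.out = n_grid)
  gvals <- vapply(grid, function(a) inner(a)$nll, 0)
  if (diff(range(gvals)) < 1e-8) {
    # flat profile: alpha not identifiable (e.g. beta fixed at 0)
    res <- inner(grid[1L])
    return(list(alpha = NA_real_, beta = res$beta, nll = res$nll,
                identifiable = FALSE, converged = TRUE, n_grid = n_grid))
  }
  i <- which.min(gvals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  op <- optimize(function(a) inner(a)$nll, c(lo, hi), tol = 1e-4)
  best_alpha <- if (op$objective <= gvals[i]) op$minimum else grid[i]
  res <- inner(best_alpha)
  list(alpha = best_alpha, beta = res$beta, nll = res$nll,
       identifiable = TRUE, converged = is.finite(res$nll), n_grid = n_grid)
}

#' Fit the model to one subject's choices by maximum likelihood
#'
#' Minimizes the negative log-likelihood over `alpha` in (0.01, 1\] and
#' `beta` in \[0, 50\] using a profile search: a coarse grid over `alpha`
#' (trajectories recomputed per grid point) refined by golden-section
#' optimization, with `beta` optimized on cached EVs at each `alpha`. Either
#' parameter can be held fixed. When the profile is flat (e.g. `beta` fixed
#' at 0, which makes every choice uniform regardless of `alpha`), the result
#' is flagged non-identifiable rather than reporting an arbitrary optimum.
#'
#' @param choices A choice dataset tibble.
#' @param fixed Optional named list fixing `alpha` and/or `beta`,
#'   e.g. `list(alpha = 0.692)`.
#' @param alpha_bounds,beta_bounds Search bounds.
#' @param n_grid Number of alpha grid points before refinement.
#' @param ev_init Initial EV for novel stimuli used in the trajectories.
#' @return An `nb_fit` object; see [tidy.nb_fit()] / [glance.nb_fit()].
#' @export
fit_subject <- function(choices, fixed = list(),
                        alpha_bounds = c(0.01, 1), beta_bounds = c(0, 50),
                        n_grid = 21L, ev_init = 0.216) {
  d <- prepare_choices(choices)
  if (sum(d$responded) < 2L || length(unique(d$chosen[d$responded])) < 2L) {
    abort("dataset degenerate: need >= 2 responded trials with >= 2 distinct choices.")
  }
  res <- profile_fit(list(d), fixed_alpha = fixed$alpha, fixed_beta = fixed$beta,
                     alpha_bounds = alpha_bounds, beta_bounds = beta_bounds,
                     n_grid = n_grid, ev_init = ev_init, share_beta = TRUE)
  if (!res$converged) abort("fit failed to converge: non-finite likelihood.")
  new_fit_result(res$alpha, res$beta,
                 c(alpha = !is.null(fixed$alpha), beta = !is.null(fixed$beta)),
                 res$nll, sum(d$responded), 1L, res$converged,
                 res$identifiable, res$n_grid)
}

#' Pooled fit with a shared learning rate across subjects
#'
#' Minimizes the summed negative log-likelihood over all subjects with
#' `alpha` shared; `beta` is either shared too (`share = "alpha_beta"`) or
#' fit per subject (`share = "alpha"`, the default). This mirrors the
#' group-learning-rate workflow: the pooled `alpha` is subsequently fixed
#' for all trajectory/RPE derivations.
#'
#' @param choices A tibble with a `subject_id` column covering several
#'   subjects, or a list of choice datasets.
#' @param share `"alpha"` (shared alpha, per-subject beta) or
#'   `"alpha_beta"` (both shared).
#' @param fixed,alpha_bounds,beta_bounds,n_grid,ev_init As in
#'   [fit_subject()].
#' @return An `nb_fit`; `beta_hat` is a vector when betas are per-subject.
#' @export
fit_pooled <- function(choices, share = c("alpha", "alpha_beta"),
                       fixed = list(), alpha_bounds = c(0.01, 1),
                       beta_bounds = c(0, 50), n_grid = 21L, ev_init = 0.216) {
  share <- match.arg(share)
  if (is.data.frame(choices)) {
    choices <- split(choices, choices$subject_id)
  }
  if (length(choices) < 2L) abort("pooled fit needs >= 2 datasets.")
  prepared <- lapply(choices, prepare_choices)
  res <- profile_fit(prepared, fixed_alpha = fixed$alpha,
                     fixed_beta = fixed$beta,
                     alpha_bounds = alpha_bounds, beta_bounds = beta_bounds,
                     n_grid = n_grid, ev_init = ev_init,
                     share_beta = share == "alpha_beta")
  if (!res$converged) abort("pooled fit failed to converge.")
  new_fit_result(res$alpha, res$beta,
                 c(alpha = !is.null(fixed$alpha), beta = !is.null(fixed$beta)),
                 res$nll, sum(vapply(prepared, function(d) sum(d$responded), 0L)),
                 length(prepared), res$converged, res$identifiable, res$n_grid)
}

#' Consistency-of-fit regression diagnostics
#'
#' Regresses observed subject-level choice proportions on model-predicted
#' proportions, optionally with clinical-score interactions, to check that
#' model fit quality is uniform across the cohort (a score-by-prediction
#' interaction would indicate the model fits some symptom strata worse).
#'
#' @param data Subject-level data frame.
#' @param observed,predicted Names of the observed and predicted proportion
#'   columns.
#' @param moderators Optional character vector of clinical-score columns;
#'   one interaction model is fit per moderator.
#' @return A list of class `nb_fit_diag` with `r` (Pearson correlation),
#'   `n`, and `terms`, a tibble of regression coefficients (including
#'   `predicted:moderator` interaction rows per moderator).
#' @export
model_fit_diagnostics <- function(data, observed = "prop_best_obs",
                                  predicted = "prop_best_pred",
                                  moderators = NULL) {
  if (nrow(data) < 10L) abort("need >= 10 subjects for fit diagnostics.")
  x <- data[[predicted]]
  y <- data[[observed]]
  if (!isTRUE(sd(x, na.rm = TRUE) > 0)) {
    abort("degenerate input: predicted proportions have zero variance.")
  }
  r <- cor(x, y, use = "complete.obs")
  terms <- list(tidy_lm_terms(lm(y ~ x), moderator = NA_character_))
  for (m in moderators) {
    z <- data[[m]]
    fit <- lm(y ~ x * z)
    terms <- c(terms, list(tidy_lm_terms(fit, moderator = m)))
  }
  structure(list(r = r, n = sum(complete.cases(x, y)),
                 terms = dplyr::bind_rows(terms)),
            class = "nb_fit_diag")
}

tidy_lm_terms <- function(fit, moderator) {
  s <- summary(fit)$coefficients
  tibble::tibble(
    moderator = moderator,
    term = rownames(s),
    estimate = s[, 1L], std_error = s[, 2L], p_value = s[, 4L]
  )
}

#' @export
print.nb_fit_diag <- function(x, ...) {
  cat(sprintf("<nb_fit_diag> r(predicted, observed) = %.3f over %d subjects\n",
              x$r, x$n))
  invisible(x)
}

#' @export
#' @method tidy nb_fit_diag
tidy.nb_fit_diag <- function(x, ...) x$terms
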