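#' Reinforcement-learning agent parameters
#'
#' The agent learns stimulus expected values (EVs, in dollars) with a
#' delta rule — `EV <- EV + alpha * (feedback - EV)` for the chosen stimulus
#' only — and chooses among the three offered stimuli with a softmax policy
#' of precision `beta`. Newly introduced stimuli start at `ev_init_novel`; a
#' value above the long-run average payoff acts as an optimistic novelty
#' prior that draws early choices toward novel stimuli.
#'
#' @param alpha Learning rate in (0, 1\].
#' @param beta Softmax inverse temperature, >= 0 (0 = random, large = greedy).
#' @param ev_init_novel Initial EV (dollars) assigned to each newly
#'   introduced stimulus. Default 0.216.
#' @param ev_init_start Initial EV for the three stimuli present at the start
#'   of a run. Defaults to `ev_init_novel`.
#' @return A list of class `nb_agent_params`.
#' @export
agent_params <- function(alpha, beta, ev_init_novel = 0.216,
                         ev_init_start = ev_init_novel) {
  stopifnot_scalar_number(alpha, "alpha")
  stopifnot_scalar_number(beta, "beta", lo = 0)
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  stopifnot_scalar_number(ev_init_novel, "ev_init_novel", lo = 0)
  stopifnot_scalar_number(ev_init_start, "ev_init_start", lo = 0)
  structure(
    list(alpha = alpha, beta = beta,
         ev_init_novel = ev_init_novel, ev_init_start = ev_init_start),
    class = "nb_agent_params"
  )
}

#' Softmax choice probabilities
#'
#' `P(i) = exp(beta * EV_i) / sum_j exp(beta * EV_j)` over the offered
#' stimuli, computed stably so large `beta` does not overflow. Invariant
#' under adding a constant to all EVs.
#'
#' @param evs Numeric vector (or matrix, one trial per row) of EVs.
#' @param beta Inverse temperature, >= 0.
#' @return Probabilities with the same shape as `evs`.
#' @export
#' @examples
#' choice_probabilities(c(0.1, 0.2, 0.3), beta = 10)
choice_probabilities <- function(evs, beta) {
  stopifnot_scalar_number(beta, "beta", lo = 0)
  if (any(!is.finite(evs))) abort("`evs` must be finite.")
  if (is.matrix(evs)) {
    z <- beta * evs
    p <- exp(z - row_logsumexp(z))
    return(p)
  }
  z <- beta * evs
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Delta-rule value update
#'
#' Computes the reward prediction error `rpe = feedback - ev` and the updated
#' value `ev + alpha * rpe` for the chosen stimulus.
#'
#' @param ev Current EV (dollars).
#' @param feedback Received feedback (dollars).
#' @param alpha Learning rate in (0, 1\].
#' @return A list with `new_ev` and `rpe`.
#' @export
#' @examples
#' update_value(0.216, 0.30, alpha = 0.692)
update_value <- function(ev, feedback, alpha) {
  if (any(!is.finite(c(ev, feedback, alpha)))) abort("inputs must be finite.")
  rpe <- feedback - ev
  list(new_ev = ev + alpha * rpe, rpe = rpe)
}

#' Simulate an agent on a task schedule
#'
#' Runs the softmax/delta-rule agent forward over a schedule: on each trial a
#' choice is sampled from the softmax over current EVs of the three offered
#' stimuli, Bernoulli feedback is drawn from the chosen stimulus's payoff
#' rate, and the chosen stimulus's EV is updated. EVs of replaced stimuli are
#' dropped; each run restarts value state with its fresh initial stimuli.
#'
#' @param schedule An `nb_schedule` from [generate_schedule()].
#' @param params An [agent_params()] object.
#' @param seed Integer seed; the dataset is reproducible from
#'   `(schedule, params, seed)`.
#' @param subject_id Identifier stored in the output.
#' @return A tibble of class `nb_choices`, one row per trial: `subject_id`,
#'   `run`, `trial`, `stim_left`, `stim_mid`, `stim_right`, `chosen`
#'   (stimulus id), `feedback` (dollars), `responded`, `lag_chosen`, and
#'   `prob_chosen` (model probability of the realized choice).
#' @export
simulate_agent <- function(schedule, params, seed, subject_id = "sim") {
  if (!inherits(schedule, "nb_schedule")) abort("`schedule` must be an nb_schedule.")
  if (!inherits(params, "nb_agent_params")) params <- do.call(agent_params, params)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  trials <- compute_lags(schedule$trials)
  offered <- as.matrix(trials[, c("stim_left", "stim_mid", "stim_right")])
  lags <- as.matrix(trials[, c("lag_left", "lag_mid", "lag_right")])
  rates <- setNames(schedule$stimuli$payoff_rate,
                    as.character(schedule$stimuli$stimulus_id))
  rmag <- schedule$config$reward_magnitude

  n <- nrow(trials)
  ev <- numeric(max(schedule$stimuli$stimulus_id))
  chosen <- integer(n)
  feedback <- numeric(n)
  prob_chosen <- numeric(n)
  lag_chosen <- integer(n)
  for (t in seq_len(n)) {
    off <- offered[t, ]
    new <- lags[t, ] == 1L
    ev[off[new]] <- ifelse(trials$run_trial[t] == 1L,
                           params$ev_init_start, params$ev_init_novel)
    p <- choice_probabilities(ev[off], params$beta)
    k <- sample.int(3L, 1L, prob = p)
    ch <- off[k]
    fb <- rmag * (runif(1L) < rates[as.character(ch)])
    ev[ch] <- ev[ch] + params$alpha * (fb - ev[ch])
    chosen[t] <- ch
    feedback[t] <- fb
    prob_chosen[t] <- p[k]
    lag_chosen[t] <- lags[t, k]
  }
  out <- tibble::tibble(
    subject_id = subject_id,
    run = trials$run,
    trial = trials$trial,
    stim_left = trials$stim_left,
    stim_mid = trials$stim_mid,
    stim_right = trials$stim_right,
    chosen = chosen,
    feedback = feedback,
    responded = TRUE,
    lag_chosen = lag_chosen,
    prob_chosen = prob_chosen
  )
  class(out) <- c("nb_choices", class(out))
  out
}
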