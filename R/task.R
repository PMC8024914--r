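#' Task configuration for the novelty bandit
#'
#' The task is a three-armed bandit in which each stimulus carries a fixed
#' probability of paying out a fixed reward. Every stimulus is offered for a
#' limited number of consecutive trials (its lifetime) before being replaced
#' by a novel stimulus. Participants keep a fraction of their accumulated
#' winnings.
#'
#' @param n_runs Number of task runs (separate scanner runs). Each run starts
#'   with three fresh initial stimuli.
#' @param n_novel_introductions Total number of novel (non-initial) stimuli
#'   introduced across all runs, split as evenly as possible between runs.
#' @param lifetime_min,lifetime_max Bounds (in trials) of the discrete-uniform
#'   stimulus lifetime distribution.
#' @param reward_magnitude Dollar value of a win.
#' @param payout_fraction Fraction of total winnings paid to the participant.
#' @param n_slots Number of simultaneously offered stimuli; fixed at 3.
#' @return A list of class `nb_task_config`.
#' @export
#' @examples
#' task_config()
task_config <- function(n_runs = 2L,
                        n_novel_introductions = 40L,
                        lifetime_min = 5L,
                        lifetime_max = 9L,
                        reward_magnitude = 0.30,
                        payout_fraction = 0.10,
                        n_slots = 3L) {
  if (n_slots != 3L) abort("`n_slots` is fixed at 3 for this task.")
  if (lifetime_min < 1) abort("invalid config: `lifetime_min` must be >= 1.")
  if (lifetime_max < lifetime_min) {
    abort("invalid config: `lifetime_max` must be >= `lifetime_min`.")
  }
  if (n_novel_introductions < 1) {
    abort("invalid config: `n_novel_introductions` must be >= 1.")
  }
  if (payout_fraction <= 0 || payout_fraction > 1) {
    abort("invalid config: `payout_fraction` must be in (0, 1].")
  }
  stopifnot_scalar_number(reward_magnitude, "reward_magnitude", lo = 0)
  structure(
    list(
      n_runs = as.integer(n_runs),
      n_novel_introductions = as.integer(n_novel_introductions),
      lifetime_min = as.integer(lifetime_min),
      lifetime_max = as.integer(lifetime_max),
      reward_magnitude = reward_magnitude,
      payout_fraction = payout_fraction,
      n_slots = 3L
    ),
    class = "nb_task_config"
  )
}

#' Generate a task schedule
#'
#' Builds the full stimulus-introduction plan for a session. Each run starts
#' with three initial stimuli; whenever a stimulus's lifetime (drawn uniformly
#' on `lifetime_min:lifetime_max`) elapses it is replaced in place by the next
#' novel stimulus. A run ends at the first trial on which an expired slot can
#' no longer be refilled, so stimuli still alive at that point have realized
#' lifetimes shorter than their drawn ones. Each stimulus receives an
#' independent payout probability drawn uniformly on (0, 1), so expected
#' payoffs are uniform on (0, `reward_magnitude`).
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the same `(config, seed)` pair always yields an
#'   identical schedule.
#' @return An object of class `nb_schedule`: a list with elements
#'   * `trials`: tibble with `run`, `trial` (1-based, continuous across runs),
#'     `run_trial`, and offered stimulus ids `stim_left`, `stim_mid`,
#'     `stim_right` (position is randomized metadata; the learner is
#'     position-blind);
#'   * `stimuli`: tibble with `stimulus_id`, `payoff_rate`, `expected_payoff`,
#'     `introduced_at` (trial of first offer), `lifetime` (drawn),
#'     `realized_lifetime` (trials actually offered), `initial`, `run`;
#'   * `config`: the configuration used.
#' @export
#' @examples
#' sched <- generate_schedule(task_config(), seed = 1)
#' nrow(sched$stimuli)
generate_schedule <- function(config = task_config(), seed) {
  if (!inherits(config, "nb_task_config")) config <- do.call(task_config, config)
  stopifnot_scalar_number(seed, "seed")
  seeds <- child_seeds(seed, config$n_runs)

  per_run <- rep(config$n_novel_introductions %/% config$n_runs, config$n_runs)
  extra <- config$n_novel_introductions %% config$n_runs
  if (extra > 0) per_run[seq_len(extra)] <- per_run[seq_len(extra)] + 1L

  next_id <- 1L
  trial0 <- 0L
  trials <- vector("list", config$n_runs)
  stimuli <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    run <- generate_run(config, per_run[r], seeds[r], next_id, trial0, r)
    trials[[r]] <- run$trials
    stimuli[[r]] <- run$stimuli
    next_id <- max(run$stimuli$stimulus_id) + 1L
    trial0 <- max(run$trials$trial)
  }
  structure(
    list(
      trials = dplyr::bind_rows(trials),
      stimuli = dplyr::bind_rows(stimuli),
      config = config
    ),
    class = "nb_schedule"
  )
}

# one run: 3 initial stimuli plus n_novel replacements, trial-by-trial.
# In the rare draw where several stimuli expire on the same trial with too
# few novels left to refill every slot, the tail novels could never be
# offered; such draws are regenerated from the next derived seed so every
# run introduces exactly n_novel novel stimuli.
generate_run <- function(config, n_novel, seed, first_id, trial_offset, run_idx) {
  for (attempt in seq_len(100L)) {
    run <- generate_run_once(config, n_novel, seed + (attempt - 1L) * 997L,
                             first_id, trial_offset, run_idx)
    if (!is.null(run)) return(run)
  }
  abort("failed to generate a schedule without stranded stimuli.")
}

generate_run_once <- function(config, n_novel, seed, first_id, trial_offset,
                              run_idx) {
  set.seed(seed %% .Machine$integer.max)
  n_stim <- 3L + n_novel
  ids <- seq.int(first_id, length.out = n_stim)
  life_range <- seq.int(config$lifetime_min, config$lifetime_max)
  lifetimes <- life_range[sample.int(length(life_range), n_stim,
                                     replace = TRUE)]
  rates <- runif(n_stim)

  slot_stim <- 1L:3L            # index into ids (order of introduction)
  introduced <- rep(NA_integer_, n_stim)
  expires <- rep(NA_integer_, n_stim)   # last trial of drawn lifetime
  last_seen <- rep(NA_integer_, n_stim)
  introduced[1:3] <- 1L
  expires[1:3] <- lifetimes[1:3]
  pool <- if (n_novel > 0) seq.int(4L, n_stim) else integer(0)

  rows <- vector("list", n_stim * config$lifetime_max)
  t <- 0L
  repeat {
    t <- t + 1L
    if (t > 1L) {
      # replace expired slots, lowest stimulus id first
      expired <- slot_stim[expires[slot_stim] < t]
      if (length(expired) > 0L && length(pool) == 0L) {
        return(finish_run(rows, t - 1L, ids, rates, lifetimes, introduced,
                          last_seen, config, trial_offset, run_idx))
      }
      if (length(expired) > length(pool)) {
        return(NULL)  # would strand unoffered novels; caller regenerates
      }
      for (s in sort(expired)) {
        nxt <- pool[1L]
        pool <- pool[-1L]
        slot_stim[match(s, slot_stim)] <- nxt
        introduced[nxt] <- t
        expires[nxt] <- t + lifetimes[nxt] - 1L
      }
    }
    last_seen[slot_stim] <- t
    pos <- sample.int(3L)   # randomized left/mid/right assignment
    rows[[t]] <- ids[slot_stim[pos]]
    if (all(expires[slot_stim] <= t) && length(pool) == 0L) {
      return(finish_run(rows, t, ids, rates, lifetimes, introduced,
                        last_seen, config, trial_offset, run_idx))
    }
  }
}

finish_run <- function(rows, n_trials, ids, rates, lifetimes, introduced,
                       last_seen, config, trial_offset, run_idx) {
  offered <- do.call(rbind, rows[seq_len(n_trials)])
  trials <- tibble::tibble(
    run = run_idx,
    trial = trial_offset + seq_len(n_trials),
    run_trial = seq_len(n_trials),
    stim_left = offered[, 1L],
    stim_mid = offered[, 2L],
    stim_right = offered[, 3L]
  )
  used <- !is.na(introduced)
  stimuli <- tibble::tibble(
    stimulus_id = ids[used],
    payoff_rate = rates[used],
    expected_payoff = config$reward_magnitude * rates[used],
    introduced_at = trial_offset + introduced[used],
    lifetime = lifetimes[used],
    realized_lifetime = last_seen[used] - introduced[used] + 1L,
    initial = introduced[used] == 1L,
    run = run_idx
  )
  list(trials = trials, stimuli = stimuli)
}

#' @export
print.nb_schedule <- function(x, ...) {
  cat(sprintf(
    "<nb_schedule> %d runs, %d trials, %d stimuli (%d novel introductions)\n",
    x$config$n_runs, nrow(x$trials), nrow(x$stimuli),
    sum(!x$stimuli$initial)
  ))
  invisible(x)
}

#' @export
#' @method glance nb_schedule
glance.nb_schedule <- function(x, ...) {
  tibble::tibble(
    n_runs = x$config$n_runs,
    n_trials = nrow(x$trials),
    n_stimuli = nrow(x$stimuli),
    n_novel = sum(!x$stimuli$initial),
    mean_lifetime = mean(x$stimuli$lifetime),
    mean_expected_payoff = mean(x$stimuli$expected_payoff)
  )
}

#' Sample feedback for a stimulus
#'
#' Default Bernoulli payoff scheme: the full `reward_magnitude` with
#' probability `payoff_rate`, otherwise zero.
#'
#' @param payoff_rate Win probability in \[0, 1\].
#' @param n Number of draws.
#' @param reward_magnitude Dollar value of a win.
#' @return Numeric vector of dollar feedback values.
#' @export
sample_feedback <- function(payoff_rate, n = 1L, reward_magnitude = 0.30) {
  if (any(!is.finite(payoff_rate)) || any(payoff_rate < 0) || any(payoff_rate > 1)) {
    abort("`payoff_rate` must lie in [0, 1].")
  }
  reward_magnitude * rbinom(n, 1L, payoff_rate)
}

#' Per-trial lags of the offered stimuli
#'
#' The lag of a stimulus on a trial is the number of trials since its
#' introduction, counting the first offered trial as lag 1. A lag-2 offer is
#' the trial on which choosing the (still newest) stimulus counts as an
#' explore decision.
#'
#' @param trials A trials tibble with `run`, `trial`, `stim_left`, `stim_mid`,
#'   `stim_right` (e.g. `schedule$trials` or a choice dataset).
#' @return The input with added integer columns `lag_left`, `lag_mid`,
#'   `lag_right`.
#' @export
compute_lags <- function(trials) {
  need <- c("run", "trial", "stim_left", "stim_mid", "stim_right")
  if (!all(need %in% names(trials))) {
    abort(sprintf("`trials` must have columns: %s", paste(need, collapse = ", ")))
  }
  trials <- dplyr::arrange(trials, .data$trial)
  offered <- as.matrix(trials[, c("stim_left", "stim_mid", "stim_right")])
  first_offer <- tapply(rep(trials$trial, 3L), as.vector(offered), min)
  lag <- matrix(trials$trial, nrow(trials), 3L) -
    matrix(first_offer[as.character(offered)], nrow(trials), 3L) + 1L
  trials$lag_left <- as.integer(lag[, 1L])
  trials$lag_mid <- as.integer(lag[, 2L])
  trials$lag_right <- as.integer(lag[, 3L])
  trials
}

#' Total winnings and payout
#'
#' @param choices A choice dataset (see [simulate_agent()]).
#' @param payout_fraction Fraction of winnings paid out.
#' @return One-row tibble with `winnings` and `payout` in dollars.
#' @export
total_winnings <- function(choices, payout_fraction = 0.10) {
  w <- sum(choices$feedback[choices$responded], na.rm = TRUE)
  tibble::tibble(winnings = w, payout = payout_fraction * w)
}
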