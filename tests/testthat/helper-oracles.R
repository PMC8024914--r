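# Independent oracle implementations used to cross-check the package.
# These are deliberately naive (scalar loops, dictionaries keyed by
# stimulus id) and share no code with the package internals.

# replay a choice table and count, per trial and offered slot, how many
# times each stimulus has been offered so far (lag oracle)
oracle_lags <- function(trials) {
  trials <- trials[order(trials$trial), ]
  seen <- new.env()
  out <- matrix(NA_integer_, nrow(trials), 3L)
  cols <- c("stim_left", "stim_mid", "stim_right")
  for (i in seq_len(nrow(trials))) {
    for (j in 1:3) {
      id <- as.character(trials[[cols[j]]][i])
      cnt <- (get0(id, envir = seen) %||% 0L) + 1L
      assign(id, cnt, envir = seen)
      out[i, j] <- cnt
    }
  }
  out
}

# scalar-loop delta-rule trajectory: returns list with per-trial pre-choice
# EVs of the offered stimuli and the chosen-stimulus RPE
oracle_trajectory <- function(choices, alpha, ev_init) {
  choices <- choices[order(choices$trial), ]
  ev <- new.env()
  cols <- c("stim_left", "stim_mid", "stim_right")
  n <- nrow(choices)
  evs <- matrix(NA_real_, n, 3L)
  rpe <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    for (j in 1:3) {
      id <- as.character(choices[[cols[j]]][i])
      if (is.null(get0(id, envir = ev))) assign(id, ev_init, envir = ev)
      evs[i, j] <- get(id, envir = ev)
    }
    if (isTRUE(choices$responded[i]) && !is.na(choices$chosen[i])) {
      id <- as.character(choices$chosen[i])
      cur <- get(id, envir = ev)
      rpe[i] <- choices$feedback[i] - cur
      assign(id, cur + alpha * rpe[i], envir = ev)
    }
  }
  list(evs = evs, rpe = rpe)
}

# direct softmax, no numerical safeguards
oracle_softmax <- function(evs, beta) {
  exp(beta * evs) / sum(exp(beta * evs))
}

# nll by direct product of softmax probabilities over the oracle trajectory
oracle_nll <- function(choices, alpha, beta, ev_init = 0.216) {
  tr <- oracle_trajectory(choices, alpha, ev_init)
  cols <- c("stim_left", "stim_mid", "stim_right")
  ll <- 0
  for (i in seq_len(nrow(choices))) {
    if (!isTRUE(choices$responded[i])) next
    p <- oracle_softmax(tr$evs[i, ], beta)
    k <- which(c(choices$stim_left[i], choices$stim_mid[i],
                 choices$stim_right[i]) == choices$chosen[i])
    ll <- ll + log(p[k])
  }
  -ll
}

# hand-buildable choice dataset for small worked examples
make_choices <- function(run, trial, offered, chosen, feedback,
                         responded = TRUE, subject_id = "T") {
  off <- do.call(rbind, offered)
  tibble::tibble(
    subject_id = subject_id, run = run, trial = trial,
    stim_left = off[, 1], stim_mid = off[, 2], stim_right = off[, 3],
    chosen = chosen, feedback = feedback,
    responded = rep_len(responded, length(trial)),
    lag_chosen = NA_integer_
  )
}

# simulate a small homogeneous cohort of agents (shared by several tests)
simulate_cohort_choices <- function(n_agents, alpha, beta, seed0,
                                    config = task_config(),
                                    ev_init = 0.216) {
  lapply(seq_len(n_agents), function(i) {
    sched <- generate_schedule(config, seed = seed0 + i)
    simulate_agent(sched, agent_params(alpha, beta, ev_init_novel = ev_init),
                   seed = seed0 + 100000 + i,
                   subject_id = sprintf("A%03d", i))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
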