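test_that("trajectory worked examples and oracle agreement", {
  # single trial at the novelty prior: RPE = 0.30 - 0.216
  ch <- make_choices(1, 1, list(c(1, 2, 3)), chosen = 1, feedback = 0.30)
  tr <- derive_trajectory(ch, alpha = 0.692, ev_init = 0.216)
  expect_equal(tr$rpe_chosen, 0.084)
  expect_equal(tr$ev_chosen, 0.216)

  # alpha = 1: EV equals the most recent feedback
  ch <- make_choices(1, 1:4, rep(list(c(1, 2, 3)), 4),
                     chosen = c(1, 1, 1, 1),
                     feedback = c(0.30, 0, 0.30, 0.30))
  tr <- derive_trajectory(ch, alpha = 1)
  expect_equal(tr$ev_left, c(0.216, 0.30, 0, 0.30))

  # random dataset matches the scalar-loop oracle to 1e-12
  sched <- generate_schedule(task_config(), seed = 61)
  ch <- simulate_agent(sched, agent_params(0.4, 3), seed = 62)
  for (alpha in c(0.2, 0.692, 1)) {
    tr <- derive_trajectory(ch, alpha = alpha)
    want <- oracle_trajectory(ch, alpha, 0.216)
    expect_equal(as.matrix(tr[, c("ev_left", "ev_mid", "ev_right")]), want$evs,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(tr$rpe_chosen, want$rpe, tolerance = 1e-12)
  }
})

test_that("non-responded trials carry EVs forward with missing RPE", {
  ch <- make_choices(1, 1:3, rep(list(c(1, 2, 3)), 3),
                     chosen = c(1, NA, 1), feedback = c(0.30, NA, 0),
                     responded = c(TRUE, FALSE, TRUE))
  tr <- derive_trajectory(ch, alpha = 0.5)
  expect_true(is.na(tr$rpe_chosen[2]))
  expect_equal(tr$ev_left[2], tr$ev_left[3])
})

test_that("chosen stimulus outside the offered set is a data-integrity error", {
  ch <- make_choices(1, 1, list(c(1, 2, 3)), chosen = 9, feedback = 0.30)
  expect_error(derive_trajectory(ch, 0.5), "not among offered")
})

test_that("nll equals n log 3 at beta = 0 and matches hand-computed products", {
  sched <- generate_schedule(task_config(), seed = 71)
  ch <- simulate_agent(sched, agent_params(0.692, 8), seed = 72)
  n <- sum(ch$responded)
  expect_equal(negative_log_likelihood(ch, agent_params(0.5, 0)), n * log(3),
               tolerance = 1e-10)

  # 5-trial toy dataset against the direct product oracle
  toy <- make_choices(1, 1:5, rep(list(c(1, 2, 3)), 5),
                      chosen = c(1, 2, 1, 3, 1),
                      feedback = c(0.30, 0, 0, 0.30, 0.30))
  for (b in c(0.5, 4, 12)) {
    expect_equal(negative_log_likelihood(toy, agent_params(0.692, b)),
                 oracle_nll(toy, 0.692, b), tolerance = 1e-10)
  }
})

test_that("likelihood at generating parameters beats chance in expectation", {
  gaps <- vapply(1:20, function(i) {
    sched <- generate_schedule(task_config(n_runs = 1,
                                           n_novel_introductions = 15),
                               seed = 3000 + i)
    ch <- simulate_agent(sched, agent_params(0.692, 8), seed = 3100 + i)
    negative_log_likelihood(ch, agent_params(0.692, 0)) -
      negative_log_likelihood(ch, agent_params(0.692, 8))
  }, 0)
  expect_gt(mean(gaps), 0)
})

test_that("nll is continuous in beta (finite differences)", {
  sched <- generate_schedule(task_config(), seed = 81)
  ch <- simulate_agent(sched, agent_params(0.692, 8), seed = 82)
  f <- function(b) negative_log_likelihood(ch, agent_params(0.692, b))
  for (b in c(0.01, 1, 8, 30)) {
    expect_lt(abs(f(b + 1e-4) - f(b)), 1)
  }
})

test_that("optimizer matches a brute-force lattice oracle", {
  sched <- generate_schedule(task_config(), seed = 91)
  ch <- simulate_agent(sched, agent_params(0.6, 9), seed = 92)
  fit <- fit_subject(ch)
  # lattice over (alpha, beta); oracle uses the independent nll implementation
  alphas <- seq(0.02, 1, length.out = 60)
  betas <- seq(0, 40, length.out = 60)
  kmat <- vapply(seq_len(nrow(ch)), function(i) {
    which(c(ch$stim_left[i], ch$stim_mid[i], ch$stim_right[i]) == ch$chosen[i])
  }, 0L)
  lattice_min <- min(vapply(alphas, function(a) {
    evs <- oracle_trajectory(ch, a, 0.216)$evs
    min(vapply(betas, function(b) {
      -sum(log(vapply(seq_len(nrow(evs)), function(i) {
        oracle_softmax(evs[i, ], b)[kmat[i]]
      }, 0)))
    }, 0))
  }, 0))
  expect_lte(fit$nll, lattice_min + 1e-3)
})

test_that("subject-level recovery is adequate with long datasets", {
  # 500+ trial sessions at (alpha = 0.5, beta = 10). With both parameters
  # free the likelihood has a learning-rate/temperature ridge, so the
  # identified checks are: alpha recovery at known beta, and pooled
  # recovery across sessions with both parameters free.
  cfg <- task_config(n_runs = 2, n_novel_introductions = 210)
  chs <- lapply(1:12, function(i) {
    sched <- generate_schedule(cfg, seed = 4000 + i)
    simulate_agent(sched, agent_params(0.5, 10), seed = 4100 + i,
                   subject_id = paste0("S", i))
  })
  hits <- vapply(chs, function(ch) {
    abs(fit_subject(ch, fixed = list(beta = 10))$alpha_hat - 0.5) <= 0.1
  }, NA)
  expect_gte(mean(hits), 0.9)
  pooled <- fit_pooled(chs, share = "alpha_beta")
  expect_lt(abs(pooled$alpha_hat - 0.5), 0.1)
})

test_that("beta fixed at 0 flags alpha as non-identifiable", {
  sched <- generate_schedule(task_config(), seed = 95)
  ch <- simulate_agent(sched, agent_params(0.692, 8), seed = 96)
  fit <- fit_subject(ch, fixed = list(beta = 0))
  expect_false(fit$identifiable)
  expect_true(is.na(fit$alpha_hat))
})

test_that("pooled fit nests per-subject fits and collapses for identical data", {
  chs <- simulate_cohort_choices(4, alpha = 0.692, beta = 8, seed0 = 5000)
  pooled <- fit_pooled(chs, share = "alpha")
  per_sub <- sum(vapply(chs, function(ch) fit_subject(ch)$nll, 0))
  expect_gte(pooled$nll, per_sub - 1e-6)

  # two identical datasets: pooled estimate equals the single-subject one
  two <- list(chs[[1]], dplyr::mutate(chs[[1]], subject_id = "B"))
  pooled2 <- fit_pooled(two, share = "alpha_beta")
  single <- fit_subject(chs[[1]])
  expect_equal(pooled2$alpha_hat, single$alpha_hat, tolerance = 0.02)
  expect_equal(pooled2$nll, 2 * single$nll, tolerance = 0.05)
})

test_that("recovery bias shrinks as sessions lengthen", {
  err_at <- function(n_intro, seeds) {
    mean(vapply(seeds, function(i) {
      cfg <- task_config(n_runs = 1, n_novel_introductions = n_intro)
      sched <- generate_schedule(cfg, seed = 6000 + n_intro * 37 + i)
      ch <- simulate_agent(sched, agent_params(0.5, 10),
                           seed = 6500 + n_intro * 37 + i)
      abs(fit_subject(ch)$alpha_hat - 0.5)
    }, 0))
  }
  short <- err_at(40, 1:8)
  long <- err_at(400, 1:8)
  expect_lt(long, short)
})

test_that("fit diagnostics report calibration of predicted vs observed proportions", {
  # heterogeneous choice precision so predicted proportions carry signal
  betas <- exp(seq(log(1), log(20), length.out = 24))
  chs <- lapply(seq_along(betas), function(i) {
    sched <- generate_schedule(task_config(), seed = 7000 + i)
    simulate_agent(sched, agent_params(0.692, betas[i]), seed = 7300 + i,
                   subject_id = sprintf("A%03d", i))
  })
  dat <- purrr::map_dfr(chs, function(ch) {
    tr <- derive_trajectory(ch, 0.692)
    fb <- fit_subject(ch, fixed = list(alpha = 0.692))
    dplyr::bind_cols(
      prop_best_obs = prop_best_nonnovel(tr)$prop,
      predicted_choice_props(tr, fb$beta_hat)[, 1:2]
    )
  })
  dat$score <- rnorm(nrow(dat))
  diag <- model_fit_diagnostics(dat, observed = "prop_best_obs",
                                predicted = "prop_best_pred",
                                moderators = "score")
  expect_gt(diag$r, 0.5)
  expect_true("x:z" %in% diag$terms$term)

  # predictions equal to observations give r = 1
  dat2 <- dat
  dat2$prop_best_pred <- dat2$prop_best_obs
  # perfect agreement trips summary.lm's zero-residual warning; expected here
  expect_equal(suppressWarnings(
    model_fit_diagnostics(dat2, "prop_best_obs", "prop_best_pred")$r), 1)
  # zero-variance predictions are rejected
  dat3 <- dat
  dat3$prop_best_pred <- 0.5
  expect_error(model_fit_diagnostics(dat3, "prop_best_obs", "prop_best_pred"),
               "zero variance")
})
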