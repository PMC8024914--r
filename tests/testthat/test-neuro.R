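test_that("single-event regressor matches a closed-form HRF convolution", {
  ev <- tibble::tibble(run = 1L, onset = 0, duration = 1.5,
                       trial_type = "cue_nonexplore", modulator = 0.2)
  des <- build_design(ev, tr = 2, n_volumes = 30)
  col <- des$X[, "cue_nonexplore"]
  # closed-form oracle: integral of the HRF over the boxcar, Riemann sum on
  # a fine independent grid (the package grid is TR/16, so shapes agree to
  # within discretization error)
  tvol <- (0:29) * 2
  dt <- 0.005
  tg <- seq(0, 1.5 - dt, by = dt)
  want <- vapply(tvol, function(t0) {
    sum(hrf_double_gamma(t0 - tg)[t0 - tg >= 0]) * dt
  }, 0)
  expect_gt(cor(col, want), 0.999)
  expect_lt(max(abs(col - want)), 0.05 * max(want))
  # and exactly (1e-10) against a naive same-grid double-loop convolution
  dt2 <- 2 / 16
  grid_n <- 30 * 16
  stick <- as.numeric(seq_len(grid_n) <= round(1.5 / dt2))
  kern <- hrf_double_gamma(seq(0, 32, by = dt2))
  naive <- vapply(1L + (0:29) * 16L, function(g) {
    acc <- 0
    for (j in seq_along(kern)) {
      if (g - j + 1L >= 1L && g - j + 1L <= grid_n) {
        acc <- acc + kern[j] * stick[g - j + 1L]
      }
    }
    acc * dt2
  }, 0)
  expect_lt(max(abs(col - naive)), 1e-10)
  # peak lands 4-8 s after onset
  expect_true(which.max(col) %in% c(3, 4, 5))
})

test_that("constant modulators are centred away and empty classes dropped", {
  ev <- tibble::tibble(
    run = 1L,
    onset = c(0, 20, 40, 60),
    duration = 1.5,
    trial_type = "feedback_nonexplore",
    modulator = 0.1
  )
  des <- build_design(ev, tr = 2, n_volumes = 45)
  expect_false("feedback_nonexplore_mod" %in% colnames(des$X))
  expect_true("feedback_nonexplore_mod" %in% des$dropped)
  # no explore events at all: design still solvable
  expect_true("feedback_nonexplore" %in% colnames(des$X))
  bold <- matrix(rnorm(45 * 2) + 100, 45, 2)
  expect_s3_class(fit_glm(bold, des), "nb_glm")
})

test_that("modulated columns are orthogonal to their unmodulated companions", {
  sched <- generate_schedule(task_config(n_runs = 1,
                                         n_novel_introductions = 12),
                             seed = 301)
  ch <- simulate_agent(sched, agent_params(0.692, 8), seed = 302)
  tr <- derive_trajectory(ch, 0.692)
  ev <- make_event_table(tr, seed = 303)
  nvol <- ceiling((max(ev$onset + ev$duration) + 12) / 2)
  des <- build_design(ev, tr = 2, n_volumes = nvol)
  # centred modulator means the modulated column is uncorrelated-by-design
  # with the event amplitudes; projection onto the companion stays modest
  for (cl in c("feedback_nonexplore", "cue_nonexplore")) {
    if (!paste0(cl, "_mod") %in% colnames(des$X)) next
    u <- des$X[, cl]
    m <- des$X[, paste0(cl, "_mod")]
    expect_lt(abs(sum(u * m)) / sqrt(sum(u^2) * sum(m^2)), 0.5)
  }
  # reproducibility: identical inputs give bit-identical designs
  des2 <- build_design(ev, tr = 2, n_volumes = nvol)
  expect_identical(des$X, des2$X)
})

test_that("censor rule flags spiking volumes and their predecessors", {
  # step displacement: one large volume-to-volume motion at volume 20
  m <- matrix(0, 50, 6)
  m[20:50, 1] <- 0.6
  cm <- censor_mask(m)
  expect_equal(which(cm$censored), c(19L, 20L))
  # two adjacent spikes: union without double counting
  m2 <- matrix(0, 50, 6)
  m2[20, 1] <- 0.6
  m2[21, 1] <- 1.3
  cm2 <- censor_mask(m2)
  expect_equal(which(cm2$censored), c(19L, 20L, 21L, 22L))
  m3 <- matrix(0, 50, 6)
  m3[20:21, 1] <- 0.6   # up at 20, down after 21
  cm3 <- censor_mask(m3)
  expect_equal(which(cm3$censored), c(19L, 20L, 21L, 22L))
  # all-zero motion: nothing censored
  expect_equal(sum(censor_mask(matrix(0, 30, 6))$censored), 0L)
  # monotonicity: higher threshold never censors more
  set.seed(41)
  mm <- apply(matrix(rnorm(300), 50, 6) * 0.3, 2, cumsum)
  a <- sum(censor_mask(mm, threshold_mm = 0.3)$censored)
  b <- sum(censor_mask(mm, threshold_mm = 0.6)$censored)
  expect_gte(a, b)
  expect_error(censor_mask(matrix(0, 30, 5)), "6 columns")
})

test_that("movement QC uses a strict > 15% rule", {
  fake_mask <- function(frac) {
    structure(tibble::tibble(volume = 1:100, enorm = 0,
                             censored = seq_len(100) <= frac * 100),
              class = c("nb_censor", "data.frame"))
  }
  expect_true(subject_qc(fake_mask(0.14))$include)
  expect_true(subject_qc(fake_mask(0.15))$include)
  expect_false(subject_qc(fake_mask(0.16))$include)
})

test_that("percent signal change centres and scales correctly", {
  y <- matrix(c(90, 100, 110), 3, 1)
  expect_equal(as.vector(percent_signal_change(y)), c(-10, 0, 10))
  expect_equal(percent_signal_change(matrix(5, 10, 1)),
               matrix(0, 10, 1))
  set.seed(43)
  Y <- matrix(rnorm(200, 100, 5), 50, 4)
  expect_lt(max(abs(colMeans(percent_signal_change(Y)))), 1e-10)
  expect_warning(percent_signal_change(matrix(0, 10, 1)), "zero mean")
})

test_that("GLM recovers known coefficients exactly without noise, even censored", {
  sched <- generate_schedule(task_config(n_runs = 1,
                                         n_novel_introductions = 12),
                             seed = 311)
  ch <- simulate_agent(sched, agent_params(0.692, 8), seed = 312)
  tr <- derive_trajectory(ch, 0.692)
  ev <- make_event_table(tr, seed = 313)
  nvol <- ceiling((max(ev$onset + ev$duration) + 12) / 2)
  des <- build_design(ev, tr = 2, n_volumes = nvol)
  set.seed(314)
  b_true <- runif(ncol(des$X), -1, 1)
  bold <- des$X %*% b_true
  g <- fit_glm(cbind(bold), des)
  expect_lt(max(abs(g$betas[, 1] - b_true)), 1e-8)

  # censoring 15% of rows leaves the noiseless fit exact
  m <- matrix(0, nvol, 6)
  spikes <- seq(5, nvol - 2, by = 7)
  m[spikes, 1] <- 0.8
  m[spikes + 1, 1] <- 0  # return -> predecessor rule fires twice per spike
  mask <- censor_mask(m)
  expect_gt(sum(mask$censored), 0)
  g2 <- fit_glm(cbind(bold), des, mask)
  expect_lt(max(abs(g2$betas[, 1] - b_true)), 1e-8)

  # rank-deficient designs are rejected with the offending column named
  des_bad <- des
  des_bad$X <- cbind(des$X, dup = des$X[, 1])
  expect_error(fit_glm(cbind(bold), des_bad), "collinear")
})

test_that("GLM recovers a planted modulated beta under noise (Monte Carlo)", {
  sched <- generate_schedule(task_config(n_runs = 1,
                                         n_novel_introductions = 20),
                             seed = 321)
  ch <- simulate_agent(sched, agent_params(0.692, 8), seed = 322)
  tr <- derive_trajectory(ch, 0.692)
  ev <- make_event_table(tr, seed = 323)
  nvol <- ceiling((max(ev$onset + ev$duration) + 12) / 2)
  des <- build_design(ev, tr = 2, n_volumes = nvol)
  target <- "feedback_nonexplore_mod"
  b_true <- setNames(rep(0.2, ncol(des$X)), colnames(des$X))
  b_true[target] <- 0.5
  signal <- des$X %*% b_true
  set.seed(324)
  est <- vapply(1:120, function(i) {
    bold <- signal + rnorm(nvol)
    fit_glm(cbind(bold), des)$betas[target, 1]
  }, 0)
  expect_lt(abs(mean(est) - 0.5), 0.1)
})
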