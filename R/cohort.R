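# Synthetic-cohort generator with planted effect structure.
#
# Clinical scores come from a Gaussian copula with skewed (gamma-quantile)
# marginals rounded and clipped to the instruments' ranges; agent and
# neural parameters are linear in the standardized scores plus noise, so
# every downstream group analysis has recoverable ground truth. The truth
# table is returned separately and is never read by the analysis path.

#' Cohort configuration
#'
#' Defaults emulate the adolescent study population: 128 subjects (78
#' male), right-skewed AUDIT (range 0-34, mean ~3.4, SD ~5.5) and CUDIT
#' (range 0-32, mean ~9.1, SD ~9.4) correlated ~0.49, females scoring
#' higher on AUDIT, and negative planted effects of AUDIT on choice
#' precision and on neural RPE scaling (stronger on explore trials), plus
#' a negative CUDIT-by-novelty-propensity interaction on explore-trial RPE
#' scaling.
#'
#' @param n_subjects Number of subjects.
#' @param n_male Number of males (sex coded 1 = male, 0 = female).
#' @param audit_shape,audit_scale,cudit_shape,cudit_scale Gamma marginal
#'   parameters for the latent (pre-rounding) scores.
#' @param audit_max,cudit_max Instrument maxima used for clipping.
#' @param latent_rho Copula correlation; 0.60 calibrates the post-rounding
#'   Pearson correlation of the realized scores to ~0.49 under the default
#'   marginals (skew and rounding attenuate the latent correlation).
#' @param sex_audit_shift Latent-normal shift added for females (positive =
#'   females score higher on AUDIT).
#' @param alpha_mean,alpha_sd Generating learning-rate distribution
#'   (truncated to (0.05, 1)); group mean 0.692.
#' @param beta_mean,beta_sd Inverse-temperature distribution before the
#'   AUDIT effect; floored at 0.5.
#' @param audit_beta_slope Planted slope of standardized AUDIT on beta (in
#'   beta units per SD; negative = higher symptoms, noisier choice).
#' @param ev_init_mean,ev_init_sd Subject novelty prior (initial EV of
#'   novel stimuli), truncated to (0, 0.30); its standardized value is the
#'   ground-truth novelty-propensity trait.
#' @param gamma_base Baseline neural RPE scaling (percent-signal-change
#'   units per dollar of RPE).
#' @param audit_gamma_explore,audit_gamma_nonexplore Planted standardized
#'   slopes of AUDIT on RPE scaling for explore / non-explore feedback.
#' @param cudit_np_gamma_explore Planted standardized CUDIT-by-NP
#'   interaction slope on explore RPE scaling.
#' @param gamma_noise_sd Subject-level noise SD of the RPE scalings, on the
#'   same standardized scale as the slopes.
#' @param gamma_scale Multiplies the standardized gamma model into BOLD
#'   units.
#' @param bold_noise_sd White-noise SD of the synthetic BOLD (raw signal
#'   units around a baseline of 100).
#' @param n_voxels Voxels per region of interest.
#' @param tr Repetition time (s).
#' @param motion_walk_sd Per-volume SD of the motion random walk (mm).
#' @param motion_spike_rate_shape1,motion_spike_rate_shape2 Beta
#'   distribution of each subject's volume-wise spike probability; the
#'   defaults give a median near 2% with a tail of high movers so the >15%
#'   exclusion rule has bite.
#' @param task Task configuration ([task_config()]).
#' @return List of class `nb_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 128L,
                          n_male = 78L,
                          audit_shape = 0.386, audit_scale = 8.8,
                          audit_max = 34,
                          cudit_shape = 0.943, cudit_scale = 9.65,
                          cudit_max = 32,
                          latent_rho = 0.60,
                          sex_audit_shift = 0.35,
                          alpha_mean = 0.692, alpha_sd = 0.06,
                          beta_mean = 8, beta_sd = 1.5,
                          audit_beta_slope = -1.5,
                          ev_init_mean = 0.216, ev_init_sd = 0.04,
                          gamma_base = 0.5,
                          audit_gamma_explore = -0.3,
                          audit_gamma_nonexplore = -0.1,
                          cudit_np_gamma_explore = -0.3,
                          gamma_noise_sd = 0.9,
                          gamma_scale = 0.5,
                          bold_noise_sd = 1,
                          n_voxels = 4L,
                          tr = 2,
                          motion_walk_sd = 0.03,
                          motion_spike_rate_shape1 = 0.6,
                          motion_spike_rate_shape2 = 20,
                          task = task_config()) {
  if (n_subjects < 10L) abort("`n_subjects` must be >= 10.")
  if (n_male > n_subjects) abort("`n_male` cannot exceed `n_subjects`.")
  cfg <- as.list(environment())
  structure(cfg, class = "nb_cohort_config")
}

#' Zero out every planted effect in a cohort configuration
#'
#' Convenience for calibration/null studies: removes the AUDIT effects on
#' beta and on RPE scaling, the CUDIT-by-NP interaction, and the sex shift.
#'
#' @param config An [cohort_config()].
#' @return The configuration with all effect-map slopes set to zero.
#' @export
null_effects <- function(config = cohort_config()) {
  config$audit_beta_slope <- 0
  config$audit_gamma_explore <- 0
  config$audit_gamma_nonexplore <- 0
  config$cudit_np_gamma_explore <- 0
  config$sex_audit_shift <- 0
  config
}

# correlated skewed clinical scores via a Gaussian copula
draw_clinical <- function(config, seed) {
  set.seed(seed)
  n <- config$n_subjects
  sex <- c(rep(1L, config$n_male), rep(0L, n - config$n_male))
  z1 <- rnorm(n)
  z2 <- config$latent_rho * z1 + sqrt(1 - config$latent_rho^2) * rnorm(n)
  z1 <- z1 + config$sex_audit_shift * (sex == 0L)
  audit <- round(qgamma(pnorm(z1, mean = mean(z1), sd = sd(z1)),
                        shape = config$audit_shape, scale = config$audit_scale))
  cudit <- round(qgamma(pnorm(z2),
                        shape = config$cudit_shape, scale = config$cudit_scale))
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    sex = sex,
    age = round(runif(n, 14, 18) + rnorm(n, 0, 0.1), 1),
    smoking = pmin(4L, stats::rpois(n, lambda = 0.8 + 0.15 * pmin(audit, 8))),
    audit_raw = pmin(audit, config$audit_max),
    cudit_raw = pmin(cudit, config$cudit_max)
  )
}

#' Generate a full synthetic cohort
#'
#' Draws clinical scores, subject agent parameters and neural RPE scalings
#' from the planted effect map, simulates each subject's choices on their
#' own task schedule, and (optionally) generates event tables, motion
#' traces and ROI BOLD time series.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed; all per-subject randomness derives from it.
#' @param neuro `"bold"` (full synthetic BOLD + motion per subject),
#'   `"betas"` (skip BOLD; emit ROI coefficients directly from the effect
#'   map — fast path for power/calibration studies of the group-level
#'   statistics), or `"none"`.
#' @return List of class `nb_cohort`:
#'   * `clinical`: subject-level tibble (ids, sex, age, smoking, raw
#'     scores);
#'   * `choices`: all subjects' choice data in one tibble;
#'   * `schedules`: named list of `nb_schedule`s;
#'   * `neuro`: for `"bold"`, a named list per subject with `events`,
#'     `motion`, `bold`, `n_volumes`; for `"betas"`, a tibble of ROI
#'     coefficients; otherwise NULL;
#'   * `truth`: the generating per-subject parameters (never read by the
#'     analysis path);
#'   * `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L,
                            neuro = c("bold", "betas", "none")) {
  neuro <- match.arg(neuro)
  if (!inherits(config, "nb_cohort_config")) abort("`config` must be a cohort_config().")
  seeds <- child_seeds(seed, 4L)
  clinical <- draw_clinical(config, seeds[1L])
  n <- config$n_subjects

  # planted subject parameters from standardized scores
  set.seed(seeds[2L])
  audit_z <- zscore(rankit_transform(clinical$audit_raw))
  cudit_z <- zscore(clinical$cudit_raw)
  alpha <- pmin(0.99, pmax(0.05, rnorm(n, config$alpha_mean, config$alpha_sd)))
  beta <- pmax(0.5, config$beta_mean + config$audit_beta_slope * audit_z +
                 rnorm(n, 0, config$beta_sd))
  ev_init <- pmin(0.30, pmax(0.01, rnorm(n, config$ev_init_mean,
                                         config$ev_init_sd)))
  np_true_z <- zscore(ev_init)
  g_expl <- config$audit_gamma_explore * audit_z +
    config$cudit_np_gamma_explore * cudit_z * np_true_z +
    rnorm(n, 0, config$gamma_noise_sd)
  g_nonexpl <- config$audit_gamma_nonexplore * audit_z +
    rnorm(n, 0, config$gamma_noise_sd)
  gamma_explore <- config$gamma_base + config$gamma_scale * g_expl
  gamma_nonexplore <- config$gamma_base + config$gamma_scale * g_nonexpl
  spike_rate <- stats::rbeta(n, config$motion_spike_rate_shape1,
                             config$motion_spike_rate_shape2)

  truth <- tibble::tibble(
    subject_id = clinical$subject_id,
    alpha = alpha, beta = beta, ev_init_novel = ev_init,
    np_true_z = np_true_z,
    gamma_explore = gamma_explore, gamma_nonexplore = gamma_nonexplore,
    motion_spike_rate = spike_rate
  )

  # simulate choices on per-subject schedules
  sub_seeds <- child_seeds(seeds[3L], 3L * n)
  schedules <- list()
  choices <- vector("list", n)
  for (i in seq_len(n)) {
    sched <- generate_schedule(config$task, seed = sub_seeds[i])
    schedules[[clinical$subject_id[i]]] <- sched
    choices[[i]] <- simulate_agent(
      sched,
      agent_params(alpha[i], beta[i], ev_init_novel = ev_init[i]),
      seed = sub_seeds[n + i],
      subject_id = clinical$subject_id[i]
    )
  }
  choices <- dplyr::bind_rows(choices)

  neuro_out <- NULL
  if (neuro == "betas") {
    neuro_out <- tibble::tibble(
      subject_id = clinical$subject_id,
      roi_beta_explore = gamma_explore,
      roi_beta_nonexplore = gamma_nonexplore
    )
  } else if (neuro == "bold") {
    neuro_out <- purrr::map(seq_len(n), function(i) {
      simulate_subject_bold(
        choices[choices$subject_id == clinical$subject_id[i], ],
        alpha = alpha[i], ev_init = ev_init[i],
        gamma_explore = gamma_explore[i],
        gamma_nonexplore = gamma_nonexplore[i],
        spike_rate = spike_rate[i],
        config = config, seed = sub_seeds[2L * n + i]
      )
    })
    names(neuro_out) <- clinical$subject_id
  }

  structure(
    list(clinical = clinical, choices = choices, schedules = schedules,
         neuro = neuro_out, truth = truth, config = config, seed = seed),
    class = "nb_cohort"
  )
}

#' @export
print.nb_cohort <- function(x, ...) {
  cat(sprintf("<nb_cohort> %d subjects, %d trials, neuro = %s (seed %s)\n",
              nrow(x$clinical), nrow(x$choices),
              if (is.null(x$neuro)) "none" else
                if (is.data.frame(x$neuro)) "betas" else "bold",
              format(x$seed)))
  invisible(x)
}

# one subject's event table, motion trace, and ROI BOLD.
# BOLD = 100 + sum of unmodulated responses + gamma-scaled RPE-modulated
# responses (+ EV-modulated cue responses) + white noise, per voxel.
simulate_subject_bold <- function(sub_choices, alpha, ev_init, gamma_explore,
                                  gamma_nonexplore, spike_rate, config, seed) {
  seeds <- child_seeds(seed, 3L)
  tr_tab <- derive_trajectory(sub_choices, alpha = alpha, ev_init = ev_init)
  events <- make_event_table(tr_tab, seed = seeds[1L])
  runs <- sort(unique(events$run))
  n_volumes <- vapply(runs, function(r) {
    e <- events[events$run == r, ]
    as.integer(ceiling((max(e$onset + e$duration) + 12) / config$tr))
  }, 0L)
  design <- build_design(events, tr = config$tr, n_volumes = n_volumes)

  set.seed(seeds[2L])
  nv_total <- sum(n_volumes)
  motion <- apply(matrix(rnorm(nv_total * 6L, 0, config$motion_walk_sd),
                         nv_total, 6L), 2L, cumsum)
  spikes <- runif(nv_total) < spike_rate
  motion[spikes, 1L] <- motion[spikes, 1L] + runif(sum(spikes), 0.5, 1.5)

  set.seed(seeds[3L])
  amp <- setNames(rep(0.2, nrow(design$columns)), design$columns$name)
  amp[grep("^feedback_explore_mod$", names(amp))] <- gamma_explore
  amp[grep("^feedback_nonexplore_mod$", names(amp))] <- gamma_nonexplore
  amp[grep("^cue_(non)?explore_mod$", names(amp))] <- 0.1
  amp[design$columns$kind == "drift"] <- 0
  signal <- design$X %*% amp[colnames(design$X)]
  bold <- matrix(100, nv_total, config$n_voxels) +
    matrix(signal, nv_total, config$n_voxels) +
    matrix(rnorm(nv_total * config$n_voxels, 0, config$bold_noise_sd),
           nv_total, config$n_voxels)
  list(events = events, motion = motion, bold = bold, n_volumes = n_volumes)
}

#' Fast beta-level ANCOVA cohort
#'
#' Generates only what [group_ancova()] consumes — standardized clinical
#' scores, NP, sex, and explore/non-explore ROI coefficients drawn directly
#' from the effect map — bypassing choice and BOLD simulation. Used for
#' type-I-error calibration and power studies of the group-level
#' statistics at many seeds.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, `sex`, `audit_rankit_z`, `cudit_z`,
#'   `np_z`, `roi_beta_explore`, `roi_beta_nonexplore`.
#' @export
simulate_ancova_cohort <- function(config = cohort_config(), seed = 1L) {
  seeds <- child_seeds(seed, 2L)
  clinical <- draw_clinical(config, seeds[1L])
  set.seed(seeds[2L])
  n <- config$n_subjects
  audit_z <- zscore(rankit_transform(clinical$audit_raw))
  cudit_z <- zscore(clinical$cudit_raw)
  np_z <- zscore(rnorm(n, config$ev_init_mean, config$ev_init_sd))
  g_expl <- config$audit_gamma_explore * audit_z +
    config$cudit_np_gamma_explore * cudit_z * np_z +
    rnorm(n, 0, config$gamma_noise_sd)
  g_nonexpl <- config$audit_gamma_nonexplore * audit_z +
    rnorm(n, 0, config$gamma_noise_sd)
  tibble::tibble(
    subject_id = clinical$subject_id,
    sex = clinical$sex,
    audit_rankit_z = audit_z,
    cudit_z = cudit_z,
    np_z = np_z,
    roi_beta_explore = config$gamma_base + config$gamma_scale * g_expl,
    roi_beta_nonexplore = config$gamma_base + config$gamma_scale * g_nonexpl
  )
}
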