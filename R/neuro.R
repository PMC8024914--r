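# RPE/EV-modulated fMRI design construction, motion censoring, and the
# per-voxel OLS GLM on (synthetic) BOLD.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities, `dgamma(t, peak, 1) -
#' dgamma(t, undershoot, 1) / ratio_inv`, scaled to unit peak. The default
#' (peak shape 6, undershoot shape 16, undershoot ratio 1/6) peaks about
#' 5 s after onset.
#'
#' @param t Time in seconds (vector).
#' @param peak,undershoot Gamma shape parameters (rate 1).
#' @param ratio_inv Undershoot amplitude divisor.
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio_inv = 6) {
  h <- dgamma(t, shape = peak, rate = 1) -
    dgamma(t, shape = undershoot, rate = 1) / ratio_inv
  tg <- seq(0, 32, by = 0.01)
  hg <- dgamma(tg, shape = peak, rate = 1) -
    dgamma(tg, shape = undershoot, rate = 1) / ratio_inv
  h / max(hg)
}

#' Build a BIDS-style event table from a labelled trajectory
#'
#' Assigns each trial a cue and a feedback event with nominal timings
#' (choice window, jittered delay, feedback window, jittered inter-trial
#' interval) and classifies events by decision type: explore / non-explore
#' for responded trials (modulated by decision-time EV at cue and by RPE at
#' feedback) and a no-response class with no modulator.
#'
#' @param trajectory An `nb_trajectory` with `explore` labels.
#' @param cue_duration,feedback_duration Event durations (s).
#' @param delay_range,iti_range Uniform jitter ranges (s) between cue and
#'   feedback, and between feedback and the next cue.
#' @param seed Seed for the jitters.
#' @return Tibble of class `nb_events`: `run`, `onset`, `duration`,
#'   `trial_type`, `modulator`, `trial`.
#' @export
make_event_table <- function(trajectory, cue_duration = 1.5,
                             feedback_duration = 1.5,
                             delay_range = c(1, 2), iti_range = c(1, 2),
                             seed = 1L) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- purrr::map_dfr(split(trajectory, trajectory$run), function(tr) {
    n <- nrow(tr)
    delay <- runif(n, delay_range[1], delay_range[2])
    iti <- runif(n, iti_range[1], iti_range[2])
    trial_len <- cue_duration + delay + feedback_duration + iti
    cue_on <- cumsum(c(0, head(trial_len, -1L)))
    fb_on <- cue_on + cue_duration + delay
    cls <- ifelse(!tr$responded, "noresponse",
                  ifelse(tr$explore, "explore", "nonexplore"))
    tibble::tibble(
      run = rep(tr$run, 2L),
      onset = c(cue_on, fb_on),
      duration = rep(c(cue_duration, feedback_duration), each = n),
      trial_type = c(paste0("cue_", cls), paste0("feedback_", cls)),
      modulator = c(ifelse(tr$responded, tr$ev_chosen, NA_real_),
                    ifelse(tr$responded, tr$rpe_chosen, NA_real_)),
      trial = rep(tr$trial, 2L)
    ) |>
      dplyr::arrange(.data$onset)
  })
  class(out) <- c("nb_events", class(out))
  out
}

#' Build the modulated fMRI design matrix
#'
#' One unmodulated regressor per event class present (boxcar at the events
#' convolved with the double-gamma HRF on an oversampled grid, sampled at
#' volume acquisition times), plus, for each modulated class, a companion
#' regressor whose event amplitudes are the run-mean-centered modulator
#' values. Centering makes the modulated column orthogonal-in-expectation
#' to its unmodulated companion and guarantees a constant modulator yields
#' an all-zero (dropped) column. Six motion columns and per-run
#' intercept + linear drift are appended. Event classes with zero events
#' are dropped and recorded.
#'
#' @param events An `nb_events` table (or BIDS-style tibble with `run`,
#'   `onset`, `duration`, `trial_type`, `modulator`).
#' @param tr Repetition time (s).
#' @param n_volumes Number of volumes per run; integer vector with one
#'   entry per run (in sorted run order) or a single count shared by all.
#' @param motion Optional (total volumes) x 6 motion-parameter matrix.
#' @param oversample Oversampling factor of the convolution grid.
#' @param hrf Function of time in seconds giving the HRF.
#' @param modulated_classes Event classes that get a modulated companion.
#' @return Object of class `nb_design`: list with `X` (volumes x
#'   regressors), `columns` (tibble: `name`, `class`, `modulated`, `kind`),
#'   `tr`, `run` (per-volume run index), `dropped` (classes with no
#'   events).
#' @export
build_design <- function(events, tr, n_volumes, motion = NULL,
                         oversample = 16L, hrf = hrf_double_gamma,
                         modulated_classes = c("cue_nonexplore", "cue_explore",
                                               "feedback_nonexplore",
                                               "feedback_explore")) {
  runs <- sort(unique(events$run))
  if (length(n_volumes) == 1L) n_volumes <- rep(n_volumes, length(runs))
  if (length(n_volumes) != length(runs)) {
    abort("`n_volumes` must have one entry per run.")
  }
  classes <- sort(unique(events$trial_type))
  dt <- tr / oversample
  kern <- hrf(seq(0, 32, by = dt))

  per_run <- purrr::map2(runs, n_volumes, function(r, nv) {
    ev <- events[events$run == r, ]
    if (any(ev$onset + ev$duration > nv * tr)) {
      abort(sprintf("run %s has events beyond the scan duration.", r))
    }
    ngrid <- nv * oversample + length(kern)
    vol_idx <- 1L + (seq_len(nv) - 1L) * oversample  # sample at volume onsets
    cols <- list()
    for (cl in classes) {
      e <- ev[ev$trial_type == cl, ]
      if (nrow(e) == 0L) next
      cols[[cl]] <- convolve_events(e$onset, e$duration, rep(1, nrow(e)),
                                    dt, ngrid, kern)[vol_idx]
      if (cl %in% modulated_classes) {
        m <- e$modulator
        if (anyNA(m)) abort(sprintf("class %s has missing modulators.", cl))
        cols[[paste0(cl, "_mod")]] <-
          convolve_events(e$onset, e$duration, m - mean(m),
                          dt, ngrid, kern)[vol_idx]
      }
    }
    cols
  })

  names_all <- unique(unlist(lapply(per_run, names)))
  task <- do.call(rbind, purrr::map2(per_run, n_volumes, function(cols, nv) {
    sapply(names_all, function(nm) cols[[nm]] %||% rep(0, nv))
  }))
  # drop columns that are identically zero (e.g. constant modulator)
  keep <- apply(abs(task), 2L, max) > 1e-12
  dropped <- setdiff(
    c(classes, paste0(intersect(classes, modulated_classes), "_mod")),
    names_all[keep]
  )
  task <- task[, keep, drop = FALSE]

  run_idx <- rep(runs, n_volumes)
  drift <- do.call(cbind, unlist(lapply(seq_along(runs), function(i) {
    ind <- run_idx == runs[i]
    base <- numeric(length(run_idx))
    lin <- numeric(length(run_idx))
    base[ind] <- 1
    lin[ind] <- seq(-1, 1, length.out = sum(ind))
    list(base, lin)
  }), recursive = FALSE))
  colnames(drift) <- as.vector(rbind(paste0("intercept_run", runs),
                                     paste0("drift_run", runs)))

  X <- cbind(task, drift)
  col_info <- tibble::tibble(
    name = colnames(task),
    class = sub("_mod$", "", colnames(task)),
    modulated = grepl("_mod$", colnames(task)),
    kind = "task"
  )
  col_info <- dplyr::bind_rows(
    col_info,
    tibble::tibble(name = colnames(drift), class = NA_character_,
                   modulated = FALSE, kind = "drift")
  )
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L) abort("`motion` must have 6 columns.")
    if (nrow(motion) != nrow(X)) abort("`motion` row count must match volumes.")
    colnames(motion) <- paste0("motion", 1:6)
    X <- cbind(X, motion)
    col_info <- dplyr::bind_rows(
      col_info,
      tibble::tibble(name = colnames(motion), class = NA_character_,
                     modulated = FALSE, kind = "motion")
    )
  }
  structure(
    list(X = X, columns = col_info, tr = tr, run = run_idx, dropped = dropped),
    class = "nb_design"
  )
}

# place amplitude-weighted boxcars on the oversampled grid and convolve
convolve_events <- function(onset, duration, amplitude, dt, ngrid, kern) {
  stick <- numeric(ngrid)
  for (i in seq_along(onset)) {
    a <- 1L + round(onset[i] / dt)
    b <- max(a, a + round(duration[i] / dt) - 1L)
    stick[a:b] <- stick[a:b] + amplitude[i]
  }
  full <- stats::convolve(stick, rev(kern), type = "open")
  full[seq_len(ngrid)] * dt
}

#' @export
print.nb_design <- function(x, ...) {
  cat(sprintf("<nb_design> %d volumes x %d regressors (TR = %gs, %d run(s))\n",
              nrow(x$X), ncol(x$X), x$tr, length(unique(x$run))))
  if (length(x$dropped)) {
    cat("  dropped empty/constant columns:", paste(x$dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Motion censor mask
#'
#' Computes the Euclidean norm of the backward difference of the six motion
#' parameters per volume and censors every volume whose norm exceeds the
#' threshold together with its predecessor.
#'
#' @param motion (volumes x 6) motion-parameter matrix (rotations already in
#'   mm-equivalent units).
#' @param threshold_mm Censoring threshold (default 0.5 mm).
#' @return Tibble of class `nb_censor`: `volume`, `enorm`, `censored`;
#'   attribute `fraction_censored`.
#' @export
censor_mask <- function(motion, threshold_mm = 0.5) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) abort("format error: motion must have 6 columns.")
  if (nrow(motion) < 2L) abort("need >= 2 volumes.")
  d <- diff(motion)
  enorm <- c(0, sqrt(rowSums(d^2)))
  trigger <- enorm > threshold_mm
  censored <- trigger | c(trigger[-1L], FALSE)
  out <- tibble::tibble(
    volume = seq_len(nrow(motion)),
    enorm = enorm,
    censored = censored
  )
  attr(out, "fraction_censored") <- mean(censored)
  class(out) <- c("nb_censor", class(out))
  out
}

#' Movement-based subject inclusion decision
#'
#' Excludes a subject when strictly more than `max_fraction` of volumes are
#' censored (a subject at exactly the threshold is retained).
#'
#' @param mask An `nb_censor` mask.
#' @param max_fraction Exclusion threshold (default 0.15).
#' @return One-row tibble: `fraction_censored`, `include`.
#' @export
subject_qc <- function(mask, max_fraction = 0.15) {
  f <- attr(mask, "fraction_censored") %||% mean(mask$censored)
  tibble::tibble(fraction_censored = f, include = f <= max_fraction)
}

#' Percent signal change normalization
#'
#' Rescales each voxel time series to `100 * (y - mean) / mean`, the mean
#' taken over uncensored volumes, so GLM coefficients read as percent
#' signal change from baseline.
#'
#' @param bold (volumes x voxels) matrix.
#' @param mask Optional `nb_censor` mask; censored volumes are excluded
#'   from the mean (but still returned, rescaled).
#' @return Matrix of the same shape; voxels with zero mean are set to NA
#'   with a warning.
#' @export
percent_signal_change <- function(bold, mask = NULL) {
  bold <- as.matrix(bold)
  keep <- if (is.null(mask)) rep(TRUE, nrow(bold)) else !mask$censored
  mu <- colMeans(bold[keep, , drop = FALSE])
  bad <- abs(mu) < .Machine$double.eps^0.5
  if (any(bad)) {
    warn(sprintf("%d voxel(s) with zero mean set to NA.", sum(bad)))
    mu[bad] <- NA_real_
  }
  sweep(sweep(bold, 2L, mu, "-"), 2L, mu, "/") * 100
}

#' Per-voxel OLS GLM
#'
#' Ordinary least squares of each voxel's time series on the design matrix
#' after deleting censored volumes. The modulated task coefficients are the
#' downstream quantities of interest.
#'
#' @param bold (volumes x voxels) matrix (typically percent signal change).
#' @param design An `nb_design`.
#' @param mask Optional `nb_censor` mask.
#' @return Object of class `nb_glm`: list with `betas` and `tstats`
#'   (regressors x voxels), `df_residual`, `columns` (design column info),
#'   `n_volumes_used`.
#' @export
fit_glm <- function(bold, design, mask = NULL) {
  X <- design$X
  Y <- as.matrix(bold)
  if (nrow(Y) != nrow(X)) abort("BOLD and design volume counts differ.")
  keep <- if (is.null(mask)) rep(TRUE, nrow(X)) else !mask$censored
  X <- X[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  if (nrow(X) <= ncol(X)) abort("fewer kept volumes than regressors.")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    abort(sprintf("rank-deficient design; collinear columns: %s",
                  paste(bad, collapse = ", ")))
  }
  betas <- qr.coef(qx, Y)
  res <- Y - X %*% betas
  dfres <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dfres
  xtxi <- chol2inv(qr.R(qx))
  o <- order(qx$pivot)
  xtxi <- xtxi[o, o, drop = FALSE]
  se <- sqrt(outer(diag(xtxi), sigma2))
  structure(
    list(betas = betas, tstats = betas / se, df_residual = dfres,
         columns = design$columns, n_volumes_used = nrow(X)),
    class = "nb_glm"
  )
}

#' @export
#' @method tidy nb_glm
tidy.nb_glm <- function(x, ...) {
  b <- x$betas
  voxels <- colnames(b) %||% paste0("voxel", seq_len(ncol(b)))
  out <- tibble::tibble(
    regressor = rep(rownames(b), times = ncol(b)),
    voxel = rep(voxels, each = nrow(b)),
    estimate = as.vector(b),
    statistic = as.vector(x$tstats)
  )
  dplyr::left_join(out, x$columns,
                   by = c(regressor = "name"))
}

#' @export
print.nb_glm <- function(x, ...) {
  cat(sprintf("<nb_glm> %d regressors x %d voxels, %d volumes, df = %d\n",
              nrow(x$betas), ncol(x$betas), x$n_volumes_used, x$df_residual))
  invisible(x)
}
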