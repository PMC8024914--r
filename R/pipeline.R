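# End-to-end analysis of a (synthetic) cohort: group learning rate,
# trajectories, novelty propensity, behavioral metrics, subject GLMs with
# motion QC, and the group-level clinical statistics.

#' Run the full analysis pipeline on a cohort
#'
#' Stages: (1) pooled maximum-likelihood fit of the shared group learning
#' rate; (2) per-subject EV/RPE trajectories at the fixed group rate; (3)
#' explore labels, novelty propensity, behavioral metrics; (4) per-subject
#' design/GLM on ROI BOLD with motion censoring and movement-based
#' exclusion (when BOLD is present; ROI coefficients are taken directly
#' when the cohort carries the beta-level fast path); (5) group ANCOVA on
#' explore / non-explore RPE coefficients, behavioral partial correlations,
#' CUDIT-by-NP moderation with Johnson-Neyman regions, and motion-symptom
#' correlations; (6) a recovery report comparing estimates with the
#' generating truth.
#'
#' @param cohort An `nb_cohort` from [generate_cohort()].
#' @param refit_alpha If TRUE (default) the group learning rate is
#'   estimated by pooled MLE; otherwise `alpha_fixed` is used directly.
#' @param alpha_fixed Learning rate used when `refit_alpha = FALSE`
#'   (default 0.692, the established group value).
#' @param qc_max_fraction Movement-exclusion threshold on the censored
#'   fraction.
#' @return List of class `nb_pipeline`: `group_alpha`, `cohort_table`
#'   (one row per included subject), `ancova`, `behavioral`, `moderation`,
#'   `motion_cor`, `excluded` (subject ids failing QC), `recovery`.
#' @export
run_pipeline <- function(cohort, refit_alpha = TRUE, alpha_fixed = 0.692,
                         qc_max_fraction = 0.15) {
  if (!inherits(cohort, "nb_cohort")) abort("`cohort` must be an nb_cohort.")
  ids <- cohort$clinical$subject_id
  chs <- split(cohort$choices, cohort$choices$subject_id)[ids]

  group_alpha <- if (refit_alpha) {
    fit_pooled(chs, share = "alpha")$alpha_hat
  } else {
    alpha_fixed
  }

  per_sub <- purrr::map(ids, function(id) {
    trj <- derive_trajectory(chs[[id]], alpha = group_alpha)
    fit_b <- fit_subject(chs[[id]], fixed = list(alpha = group_alpha))
    pb <- prop_best_nonnovel(trj)
    pred <- predicted_choice_props(trj, beta = fit_b$beta_hat)
    np <- tryCatch(estimate_np(trj), error = function(e) {
      tibble::tibble(np_value = NA_real_, identifiable = FALSE)
    })
    list(trajectory = trj, beta_hat = fit_b$beta_hat,
         metrics = tibble::tibble(
           subject_id = id,
           beta_hat = fit_b$beta_hat,
           prop_best_nonnovel = pb$prop,
           prop_best_pred = pred$prop_best_pred,
           np_value = np$np_value,
           np_identifiable = np$identifiable,
           n_explore = sum(trj$explore),
           n_trials = sum(trj$responded),
           winnings = total_winnings(chs[[id]])$winnings
         ))
  })
  names(per_sub) <- ids
  metrics <- purrr::map_dfr(per_sub, "metrics")

  # stage 4: ROI coefficients
  excluded <- character(0)
  motion_tab <- NULL
  if (is.data.frame(cohort$neuro)) {
    betas <- cohort$neuro
  } else if (is.list(cohort$neuro) && length(cohort$neuro)) {
    rois <- purrr::map_dfr(ids, function(id) {
      nd <- cohort$neuro[[id]]
      mask <- censor_mask(nd$motion)
      qc <- subject_qc(mask, max_fraction = qc_max_fraction)
      row <- tibble::tibble(
        subject_id = id,
        fraction_censored = qc$fraction_censored,
        n_censored = sum(mask$censored),
        mean_enorm = mean(mask$enorm),
        max_enorm = max(mask$enorm),
        include = qc$include,
        roi_beta_explore = NA_real_,
        roi_beta_nonexplore = NA_real_
      )
      if (!qc$include) return(row)
      design <- build_design(nd$events, tr = cohort$config$tr,
                             n_volumes = nd$n_volumes)
      psc <- percent_signal_change(nd$bold, mask)
      glm_fit <- fit_glm(psc, design, mask)
      b <- glm_fit$betas
      pick <- function(nm) {
        if (nm %in% rownames(b)) mean(b[nm, ]) else NA_real_
      }
      row$roi_beta_explore <- pick("feedback_explore_mod")
      row$roi_beta_nonexplore <- pick("feedback_nonexplore_mod")
      row
    })
    excluded <- rois$subject_id[!rois$include]
    motion_tab <- rois[, c("subject_id", "fraction_censored", "n_censored",
                           "mean_enorm", "max_enorm")]
    betas <- rois[rois$include, c("subject_id", "roi_beta_explore",
                                  "roi_beta_nonexplore")]
  } else {
    betas <- NULL
  }

  cohort_table <- cohort$clinical |>
    standardize_clinical() |>
    dplyr::left_join(metrics, by = "subject_id") |>
    dplyr::mutate(np_z = zscore(.data$np_value))
  if (!is.null(betas)) {
    cohort_table <- dplyr::inner_join(cohort_table, betas, by = "subject_id")
  }

  ancova <- NULL
  moderation <- NULL
  if (!is.null(betas)) {
    ancova <- group_ancova(cohort_table)
    moderation <- moderation_jn(
      cohort_table,
      outcome = "roi_beta_explore", x = "cudit_z", moderator = "np_z",
      covariates = c("audit_rankit_z", "sex")
    )
  }
  behavioral <- behavioral_correlations(cohort_table)

  motion_cor <- NULL
  if (!is.null(motion_tab)) {
    mc <- standardize_clinical(dplyr::left_join(
      motion_tab, cohort$clinical, by = "subject_id"))
    motion_cor <- tidyr::expand_grid(
      score = c("audit_rankit_z", "cudit_z"),
      metric = c("n_censored", "mean_enorm", "max_enorm")
    ) |>
      purrr::pmap_dfr(function(score, metric) {
        ct <- stats::cor.test(mc[[score]], mc[[metric]])
        tibble::tibble(score = score, metric = metric,
                       r = unname(ct$estimate), p_value = ct$p.value)
      })
  }

  recovery <- recovery_report(cohort, cohort_table, group_alpha)

  structure(
    list(group_alpha = group_alpha, cohort_table = cohort_table,
         ancova = ancova, behavioral = behavioral, moderation = moderation,
         motion_cor = motion_cor, excluded = excluded, recovery = recovery),
    class = "nb_pipeline"
  )
}

# compare pipeline estimates against the generating truth
recovery_report <- function(cohort, cohort_table, group_alpha) {
  tr <- dplyr::inner_join(cohort$truth, cohort_table, by = "subject_id")
  rows <- list(
    tibble::tibble(
      quantity = "group_alpha",
      truth = mean(cohort$truth$alpha),
      estimate = group_alpha,
      cor_truth_estimate = NA_real_
    ),
    tibble::tibble(
      quantity = "beta",
      truth = mean(tr$beta),
      estimate = mean(tr$beta_hat, na.rm = TRUE),
      cor_truth_estimate = cor(tr$beta, tr$beta_hat,
                               use = "complete.obs")
    ),
    tibble::tibble(
      quantity = "np",
      truth = mean(tr$ev_init_novel),
      estimate = mean(tr$np_value, na.rm = TRUE),
      cor_truth_estimate = cor(tr$ev_init_novel, tr$np_value,
                               use = "complete.obs")
    )
  )
  if ("roi_beta_explore" %in% names(tr)) {
    rows <- c(rows, list(
      tibble::tibble(
        quantity = "gamma_explore",
        truth = mean(tr$gamma_explore),
        estimate = mean(tr$roi_beta_explore, na.rm = TRUE),
        cor_truth_estimate = cor(tr$gamma_explore, tr$roi_beta_explore,
                                 use = "complete.obs")
      ),
      tibble::tibble(
        quantity = "gamma_nonexplore",
        truth = mean(tr$gamma_nonexplore),
        estimate = mean(tr$roi_beta_nonexplore, na.rm = TRUE),
        cor_truth_estimate = cor(tr$gamma_nonexplore, tr$roi_beta_nonexplore,
                                 use = "complete.obs")
      )
    ))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.nb_pipeline <- function(x, ...) {
  cat(sprintf("<nb_pipeline> group alpha = %.4f, %d subjects in cohort table",
              x$group_alpha, nrow(x$cohort_table)))
  if (length(x$excluded)) {
    cat(sprintf(" (%d excluded for motion)", length(x$excluded)))
  }
  cat("\n")
  invisible(x)
}

#' @export
#' @method glance nb_pipeline
glance.nb_pipeline <- function(x, ...) {
  tibble::tibble(
    group_alpha = x$group_alpha,
    n_subjects = nrow(x$cohort_table),
    n_excluded = length(x$excluded),
    has_neuro = !is.null(x$ancova)
  )
}
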