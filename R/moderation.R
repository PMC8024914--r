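# Moderation analysis with Johnson-Neyman regions, and the mixed-design
# ANCOVA on region-of-interest coefficients.

#' Moderation analysis with Johnson-Neyman regions of significance
#'
#' Fits `outcome ~ x * moderator + covariates` by OLS and solves for the
#' moderator values at which the simple slope of `x`,
#' `b_x + b_int * m`, is exactly at the two-sided critical t. The
#' Johnson-Neyman boundaries are the real roots of
#' `(b_x + b_int m)^2 = t_crit^2 * Var(b_x + b_int m)`; there may be 0, 1,
#' or 2. With no real root the slope is significant either everywhere or
#' nowhere in the moderator's range, and the result says which.
#'
#' @param data Data frame.
#' @param outcome,x,moderator Column names.
#' @param covariates Character vector of covariate column names.
#' @param alpha_level Two-sided significance level (default 0.05).
#' @return An object of class `nb_moderation`: list with `model` (the lm),
#'   `coefficients` tibble, `jn` tibble (`boundary`, plus whether each is
#'   inside the observed moderator range), `regions` tibble giving, for each
#'   interval between boundaries, whether the simple slope is significant,
#'   and `simple_slope(m)` / `slope_p(m)` functions.
#' @export
moderation_jn <- function(data, outcome, x, moderator,
                          covariates = character(), alpha_level = 0.05) {
  keep <- complete.cases(data[, c(outcome, x, moderator, covariates)])
  d <- as.data.frame(data[keep, ])
  n <- nrow(d)
  if (n <= length(covariates) + 4L) abort("need n > covariates + 4.")
  fml <- stats::reformulate(
    c(x, moderator, sprintf("%s:%s", x, moderator), covariates),
    response = outcome
  )
  fit <- lm(fml, data = d)
  b <- coef(fit)
  V <- vcov(fit)
  int_term <- sprintf("%s:%s", x, moderator)
  if (!int_term %in% names(b)) int_term <- sprintf("%s:%s", moderator, x)
  b1 <- b[[x]]
  b3 <- b[[int_term]]
  v11 <- V[x, x]
  v13 <- V[x, int_term]
  v33 <- V[int_term, int_term]
  dfres <- fit$df.residual
  tc2 <- qt(1 - alpha_level / 2, dfres)^2

  # (b1 + b3 m)^2 - tc2 (v11 + 2 v13 m + v33 m^2) = 0
  A <- b3^2 - tc2 * v33
  B <- 2 * (b1 * b3 - tc2 * v13)
  C <- b1^2 - tc2 * v11
  disc <- B^2 - 4 * A * C
  roots <- numeric(0)
  if (abs(A) < 1e-300) {
    if (abs(B) > 0) roots <- -C / B
  } else if (disc >= 0) {
    roots <- sort(((-B) + c(-1, 1) * sqrt(disc)) / (2 * A))
    if (disc == 0) roots <- roots[1L]
  }

  slope <- function(m) b1 + b3 * m
  slope_se <- function(m) sqrt(v11 + 2 * v13 * m + v33 * m^2)
  slope_p <- function(m) 2 * pt(-abs(slope(m) / slope_se(m)), dfres)

  mrange <- range(d[[moderator]])
  edges <- c(-Inf, roots, Inf)
  mids <- vapply(seq_len(length(edges) - 1L), function(i) {
    lo <- max(edges[i], mrange[1] - 10 * diff(mrange) - 1)
    hi <- min(edges[i + 1L], mrange[2] + 10 * diff(mrange) + 1)
    (lo + hi) / 2
  }, 0)
  regions <- tibble::tibble(
    lower = edges[-length(edges)],
    upper = edges[-1L],
    significant = slope_p(mids) < alpha_level
  )

  co <- summary(fit)$coefficients
  structure(
    list(
      model = fit,
      coefficients = tibble::tibble(
        term = rownames(co), estimate = co[, 1L], std_error = co[, 2L],
        statistic = co[, 3L], p_value = co[, 4L]
      ),
      jn = tibble::tibble(
        boundary = roots,
        in_range = roots >= mrange[1] & roots <= mrange[2]
      ),
      regions = regions,
      simple_slope = slope,
      slope_se = slope_se,
      slope_p = slope_p,
      alpha_level = alpha_level,
      moderator_range = mrange,
      vars = c(outcome = outcome, x = x, moderator = moderator)
    ),
    class = "nb_moderation"
  )
}

#' @export
print.nb_moderation <- function(x, ...) {
  v <- x$vars
  cat(sprintf("<nb_moderation> %s ~ %s * %s\n", v["outcome"], v["x"],
              v["moderator"]))
  if (nrow(x$jn) == 0L) {
    allsig <- x$regions$significant[1L]
    cat(sprintf("  no finite Johnson-Neyman boundary: simple slope %s over the whole range\n",
                if (allsig) "significant" else "not significant"))
  } else {
    cat(sprintf("  Johnson-Neyman boundaries at moderator = %s\n",
                paste(sprintf("%.4f", x$jn$boundary), collapse = ", ")))
  }
  invisible(x)
}

#' @export
#' @method tidy nb_moderation
tidy.nb_moderation <- function(x, ...) x$coefficients

#' @export
#' @method glance nb_moderation
glance.nb_moderation <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(
    r_squared = s$r.squared,
    df_residual = x$model$df.residual,
    n_jn_boundaries = nrow(x$jn),
    alpha_level = x$alpha_level
  )
}

#' Mixed-design ANCOVA on explore / non-explore ROI coefficients
#'
#' Tests the between-subject covariates and their interactions with the
#' two-level within-subject Decision factor (explore vs. non-explore) on
#' subject-level RPE-modulated coefficients. With a two-level within factor
#' the mixed-design ANCOVA decomposes exactly into two OLS models: the
#' subject mean `(explore + nonexplore) / 2` carries the between-subject
#' effects, and the difference `explore - nonexplore` carries the Decision
#' main effect (its intercept) and every covariate-by-Decision interaction.
#' All terms are single-degree-of-freedom, so each F is the squared t of
#' the corresponding OLS coefficient.
#'
#' @param cohort Data frame with `roi_beta_explore`, `roi_beta_nonexplore`,
#'   and the covariate columns.
#' @param covariates Between-subject model terms; `:` denotes an
#'   interaction. Default matches the AUDIT/CUDIT design:
#'   AUDIT, CUDIT, NP, sex, AUDIT-by-NP, CUDIT-by-NP.
#' @return A tibble of class `nb_ancova`: `term`, `within` (`"between"` or
#'   `"x Decision"`), `estimate`, `F`, `df1`, `df2`, `partial_eta_sq`,
#'   `p_value`. Subjects with a missing coefficient are dropped listwise
#'   (count in attribute `n_excluded`).
#' @export
group_ancova <- function(cohort,
                         covariates = c("audit_rankit_z", "cudit_z", "np_z",
                                        "sex", "audit_rankit_z:np_z",
                                        "cudit_z:np_z")) {
  base_cols <- unique(unlist(strsplit(covariates, ":", fixed = TRUE)))
  keep <- complete.cases(
    cohort[, c("roi_beta_explore", "roi_beta_nonexplore", base_cols)]
  )
  n_excluded <- sum(!keep)
  d <- as.data.frame(cohort[keep, ])
  d$.mean_beta <- (d$roi_beta_explore + d$roi_beta_nonexplore) / 2
  d$.diff_beta <- d$roi_beta_explore - d$roi_beta_nonexplore

  fit_b <- lm(stats::reformulate(covariates, response = ".mean_beta"), data = d)
  fit_w <- lm(stats::reformulate(covariates, response = ".diff_beta"), data = d)

  out <- dplyr::bind_rows(
    ancova_terms(fit_b, within = FALSE),
    ancova_terms(fit_w, within = TRUE)
  )
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_used") <- nrow(d)
  class(out) <- c("nb_ancova", class(out))
  out
}

# one-df F tests (squared t) with partial eta^2 from an OLS fit
ancova_terms <- function(fit, within) {
  s <- summary(fit)$coefficients
  dfres <- fit$df.residual
  terms <- rownames(s)
  est <- s[, 1L]
  Fv <- s[, 3L]^2
  if (within) {
    terms[terms == "(Intercept)"] <- "Decision"
    terms[terms != "Decision"] <- paste(terms[terms != "Decision"], "x Decision")
  } else {
    keep <- terms != "(Intercept)"
    terms <- terms[keep]
    est <- est[keep]
    Fv <- Fv[keep]
  }
  tibble::tibble(
    term = terms,
    within = within,
    estimate = unname(est),
    F = unname(Fv),
    df1 = 1L,
    df2 = dfres,
    partial_eta_sq = unname(Fv / (Fv + dfres)),
    p_value = stats::pf(unname(Fv), 1L, dfres, lower.tail = FALSE)
  )
}
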