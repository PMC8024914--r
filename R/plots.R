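# ggplot2 displays for the main result types.

#' @export
#' @method autoplot nb_lag_curve
autoplot.nb_lag_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$prop_chosen)) +
    ggplot2::geom_hline(yintercept = 1 / 3, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_offers), alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 4) +
    ggplot2::labs(
      x = "Trials since stimulus introduction (lag)",
      y = "Proportion of offers chosen",
      size = "Offers",
      title = "Novel-stimulus choice by lag"
    ) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot nb_moderation
autoplot.nb_moderation <- function(object, n = 200, ...) {
  mr <- object$moderator_range
  m <- seq(mr[1], mr[2], length.out = n)
  ci <- qt(1 - object$alpha_level / 2, object$model$df.residual)
  d <- tibble::tibble(
    moderator = m,
    slope = object$simple_slope(m),
    lo = object$simple_slope(m) - ci * object$slope_se(m),
    hi = object$simple_slope(m) + ci * object$slope_se(m)
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$moderator, y = .data$slope)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("Moderator (%s)", object$vars["moderator"]),
      y = sprintf("Simple slope of %s", object$vars["x"]),
      title = "Simple slope with Johnson-Neyman boundaries"
    ) +
    ggplot2::theme_minimal()
  jn <- object$jn$boundary[object$jn$in_range]
  if (length(jn)) {
    p <- p + ggplot2::geom_vline(xintercept = jn, colour = "firebrick",
                                 linetype = "dotted")
  }
  p
}

#' @export
#' @method autoplot nb_design
autoplot.nb_design <- function(object, classes = NULL, ...) {
  X <- object$X
  info <- object$columns[object$columns$kind == "task", ]
  if (!is.null(classes)) info <- info[info$class %in% classes, ]
  d <- tibble::tibble(
    volume = rep(seq_len(nrow(X)), times = nrow(info)),
    value = as.vector(X[, info$name]),
    regressor = rep(info$name, each = nrow(X))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$volume, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~regressor, scales = "free_y") +
    ggplot2::labs(x = "Volume", y = "Regressor value",
                  title = "Task regressors") +
    ggplot2::theme_minimal()
}

#' Scatter of a clinical score against a behavioral metric
#'
#' @param cohort_table Subject-level tibble (e.g. from [run_pipeline()]).
#' @param score,metric Column names.
#' @return A ggplot.
#' @export
plot_score_metric <- function(cohort_table, score = "audit_rankit_z",
                              metric = "prop_best_nonnovel") {
  ggplot2::ggplot(cohort_table,
                  ggplot2::aes(x = .data[[score]], y = .data[[metric]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "firebrick") +
    ggplot2::labs(x = score, y = metric) +
    ggplot2::theme_minimal()
}
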