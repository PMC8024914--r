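# Clinical statistics: rank-based normalization, partial correlation,
# dependent-correlation comparison, collinearity diagnostics.

#' Rankit (normal-scores) transformation
#'
#' Maps each value to the normal quantile of its fractional rank,
#' `qnorm((rank - 0.5) / n)`, with tie-averaged ranks. Used to de-skew
#' right-skewed clinical sum scores (e.g. AUDIT) before z-scoring.
#' Order-preserving and antisymmetric; missing values pass through.
#'
#' @param x Numeric vector.
#' @param offset,denominator The classical Rankit uses `(r - 0.5) / n`;
#'   Blom (`(r - 3/8) / (n + 1/4)`) and Tukey (`(r - 1/3) / (n + 1/3)`)
#'   variants are available via these knobs.
#' @return Numeric vector of normal scores (same length, NAs preserved).
#' @export
#' @examples
#' rankit_transform(c(0, 0, 1, 3, 10, 25))
rankit_transform <- function(x, offset = 0.5, denominator = 0) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0L) return(out)
  if (length(unique(x[ok])) == 1L) {
    warn("rankit_transform(): input is constant; returning zeros.")
    out[ok] <- 0
    return(out)
  }
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - offset) / (n + denominator))
  out
}

#' Partial correlation
#'
#' Pearson correlation of the residuals of `x` and `y` after regressing each
#' on the covariates (with intercept); two-sided p-value from the t
#' transform on `n - 2 - k` degrees of freedom.
#'
#' @param data Data frame.
#' @param x,y Column names of the two focal variables.
#' @param covariates Character vector of covariate column names (may be
#'   empty, giving the zero-order correlation).
#' @return One-row tibble: `r`, `df`, `p_value`.
#' @export
partial_correlation <- function(data, x, y, covariates = character()) {
  keep <- complete.cases(data[, c(x, y, covariates)])
  d <- data[keep, ]
  n <- nrow(d)
  k <- length(covariates)
  if (n <= k + 2L) abort("need n > k + 2 observations.")
  if (k > 0L) {
    Z <- cbind(1, as.matrix(d[, covariates, drop = FALSE]))
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      drop_idx <- qrz$pivot[seq.int(qrz$rank + 1L, ncol(Z))] - 1L
      abort(sprintf("collinear covariates: %s",
                    paste(covariates[pmax(drop_idx, 1L)], collapse = ", ")))
    }
    rx <- qr.resid(qrz, d[[x]])
    ry <- qr.resid(qrz, d[[y]])
  } else {
    rx <- d[[x]] - mean(d[[x]])
    ry <- d[[y]] - mean(d[[y]])
  }
  r <- cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  tibble::tibble(r = r, df = df, p_value = 2 * pt(-abs(tval), df))
}

#' Steiger's z-test for two dependent correlations sharing one variable
#'
#' Compares `cor(1,2)` with `cor(1,3)` measured on the same sample, using
#' Steiger's (1980) modification of Williams's test on Fisher-transformed
#' correlations with the dependence between them accounted for through
#' `cor(2,3)`.
#'
#' @param r12,r13 The two correlations being compared (shared variable 1).
#' @param r23 Correlation between variables 2 and 3.
#' @param n Sample size (> 3).
#' @return One-row tibble: `z`, `p_value` (two-sided).
#' @export
#' @examples
#' steiger_z(0.51, 0.56, 0.49, n = 128)
steiger_z <- function(r12, r13, r23, n) {
  if (any(abs(c(r12, r13, r23)) >= 1)) {
    abort("degenerate input: correlations must satisfy |r| < 1.")
  }
  if (n <= 3) abort("need n > 3.")
  z12 <- atanh(r12)
  z13 <- atanh(r13)
  rbar <- (r12 + r13) / 2
  # covariance of the two Fisher z's (Steiger 1980, using rbar)
  num <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  s <- num / (1 - rbar^2)^2
  z <- (z12 - z13) * sqrt((n - 3) / (2 - 2 * s))
  tibble::tibble(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing design column `j` on the
#' remaining columns (with intercept). Perfectly collinear columns get an
#' infinite VIF.
#'
#' @param data Data frame or matrix of design columns (>= 2 columns).
#' @return Tibble: `column`, `vif`.
#' @export
#' @examples
#' # two predictors correlated at r have VIF 1 / (1 - r^2)
vif <- function(data) {
  X <- as.matrix(data)
  if (ncol(X) < 2L) abort("need >= 2 columns.")
  if (nrow(X) <= ncol(X)) abort("need more rows than columns.")
  nm <- colnames(X) %||% paste0("V", seq_len(ncol(X)))
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- lm(X[, j] ~ X[, -j, drop = FALSE])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  tibble::tibble(column = nm, vif = out)
}

#' Standardize the clinical score columns of a cohort table
#'
#' Adds `audit_rankit_z` (z-scored Rankit-transformed AUDIT, the transform
#' used because raw AUDIT sum scores are strongly right-skewed) and
#' `cudit_z` (z-scored raw CUDIT) columns.
#'
#' @param cohort Data frame with `audit_raw` and `cudit_raw`.
#' @return The cohort with the two standardized columns added.
#' @export
standardize_clinical <- function(cohort) {
  cohort$audit_rankit_z <- zscore(rankit_transform(cohort$audit_raw))
  cohort$cudit_z <- zscore(cohort$cudit_raw)
  cohort
}
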