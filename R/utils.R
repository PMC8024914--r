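# internal helpers shared across modules

#' Z-score a numeric vector
#'
#' Centers and scales to unit standard deviation, ignoring missing values,
#' which are passed through unchanged.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
zscore <- function(x) {
  ok <- !is.na(x)
  s <- stats::sd(x[ok])
  if (!isTRUE(s > 0)) {
    warn("zscore(): input is constant; returning zeros.")
    out <- x
    out[ok] <- 0
    return(out)
  }
  (x - mean(x[ok])) / s
}

# numerically stable log(sum(exp(x))) along rows of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

stopifnot_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lo), format(hi)))
  }
  invisible(x)
}

# derive a stream of child seeds from a single master seed, staying well
# inside 32-bit integer range
child_seeds <- function(seed, n) {
  stopifnot_scalar_number(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}
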