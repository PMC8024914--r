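test_that("rankit transform matches the normal-quantile oracle and its symmetries", {
  x <- c(3, 9, 1, 5)
  got <- rankit_transform(x)
  want <- qnorm((rank(x) - 0.5) / 4)
  expect_equal(got, want)
  expect_equal(sort(got), qnorm(c(1, 3, 5, 7) / 8))

  # antisymmetry: reversing the order negates the scores
  y <- c(0, 0, 1, 3, 10, 25)
  expect_equal(rankit_transform(y), -rev(rankit_transform(rev(-y))),
               tolerance = 1e-12)
  # order preservation
  expect_equal(order(rankit_transform(y)), order(y))
  # tie-averaged ranks sum to n(n+1)/2
  expect_equal(sum(rank(y, ties.method = "average")), 6 * 7 / 2)
  # ties map to equal scores
  ry <- rankit_transform(y)
  expect_equal(ry[1], ry[2])

  expect_warning(r1 <- rankit_transform(7), "constant")
  expect_equal(r1, 0)
  # missing values pass through
  z <- rankit_transform(c(1, NA, 3))
  expect_true(is.na(z[2]) && !is.na(z[1]))
  # Blom variant knob
  expect_equal(rankit_transform(x, offset = 3 / 8, denominator = 1 / 4),
               qnorm((rank(x) - 3 / 8) / (4 + 1 / 4)))
})

test_that("partial correlation matches the closed-form 3x3 formula", {
  set.seed(11)
  n <- 200
  z <- rnorm(n)
  x <- 0.6 * z + rnorm(n)
  y <- -0.4 * z + 0.3 * x + rnorm(n)
  d <- tibble::tibble(x = x, y = y, z = z)
  got <- partial_correlation(d, "x", "y", "z")
  R <- cor(cbind(x, y, z))
  want <- (R[1, 2] - R[1, 3] * R[2, 3]) /
    sqrt((1 - R[1, 3]^2) * (1 - R[2, 3]^2))
  expect_equal(got$r, want, tolerance = 1e-10)
  expect_equal(got$df, n - 3L)

  # orthogonal covariate: equals the zero-order correlation
  w <- resid(lm(rnorm(n) ~ x + y))
  d$w <- w
  expect_equal(partial_correlation(d, "x", "y", "w")$r, cor(x, y),
               tolerance = 1e-10)
  # y = x gives r = 1
  d$y2 <- d$x
  expect_equal(partial_correlation(d, "x", "y2", "z")$r, 1, tolerance = 1e-10)
  # collinear covariates are named
  d$z2 <- d$z
  expect_error(partial_correlation(d, "x", "y", c("z", "z2")), "collinear")
})

test_that("Steiger's z has the right symmetries and agrees with a bootstrap oracle", {
  expect_equal(steiger_z(0.4, 0.4, 0.2, 100)$z, 0)
  expect_equal(steiger_z(0.4, 0.4, 0.2, 100)$p_value, 1)
  a <- steiger_z(0.51, 0.56, 0.49, 128)
  b <- steiger_z(0.56, 0.51, 0.49, 128)
  expect_equal(a$z, -b$z)
  # the comparison of two similar dependent correlations is not significant
  expect_lt(abs(a$z), 1.96)

  # bootstrap oracle: resample trivariate normals with this correlation
  # structure; the CI of r12 - r13 should cover 0 iff |z| is small
  set.seed(13)
  S <- matrix(c(1, 0.51, 0.56, 0.51, 1, 0.49, 0.56, 0.49, 1), 3, 3)
  L <- chol(S)
  diffs <- vapply(1:400, function(i) {
    X <- matrix(rnorm(128 * 3), 128, 3) %*% L
    cor(X[, 1], X[, 2]) - cor(X[, 1], X[, 3])
  }, 0)
  ci <- quantile(diffs + (0.51 - 0.56) - mean(diffs), c(0.025, 0.975))
  expect_true(ci[1] < 0 && ci[2] > 0)

  expect_error(steiger_z(1, 0.5, 0.2, 50), "degenerate")
  expect_error(steiger_z(0.5, 0.4, 0.2, 3), "n > 3")
})

test_that("VIF follows the closed form", {
  set.seed(17)
  n <- 300
  # orthogonal, mean-centred columns: VIF 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  v <- vif(as.data.frame(q))
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-10)
  # two columns at correlation r: VIF = 1 / (1 - r^2)
  r <- 0.49
  x1 <- rnorm(n)
  x2 <- r * x1 + sqrt(1 - r^2) * rnorm(n)
  rr <- cor(x1, x2)
  v2 <- vif(cbind(x1, x2))
  expect_equal(v2$vif, rep(1 / (1 - rr^2), 2), tolerance = 1e-10)
  expect_equal(1 / (1 - 0.49^2), 1.316, tolerance = 1e-3)
  # perfect collinearity reported as infinite
  v3 <- vif(cbind(a = x1, b = 2 * x1, c = x2))
  expect_true(any(is.infinite(v3$vif)))
})

test_that("moderation: no interaction means no finite JN boundary", {
  set.seed(19)
  n <- 200
  d <- tibble::tibble(m = rnorm(n), x = rnorm(n))
  d$y <- 0.5 * d$x + 0.2 * d$m + rnorm(n)
  res <- moderation_jn(d, "y", "x", "m")
  # slope significant across the observed moderator range: any boundary
  # lies outside it (where the slope's standard error balloons)
  expect_true(all(!res$jn$in_range) || nrow(res$jn) == 0)
  probe <- seq(min(d$m), max(d$m), length.out = 25)
  expect_true(all(res$slope_p(probe) < 0.05))
})

test_that("JN boundaries match a dense grid scan and rescale exactly", {
  set.seed(23)
  n <- 128
  m <- rnorm(n)
  x <- rnorm(n)
  y <- 0.5 * x * m + rnorm(n)  # crossover: slope -b at m=-1, +b at m=+1
  d <- tibble::tibble(y = y, x = x, m = m)
  res <- moderation_jn(d, "y", "x", "m")
  expect_equal(nrow(res$jn), 2L)

  # dense grid scan oracle: p-value of the simple slope via re-centred lm
  grid <- seq(min(m), max(m), by = 0.001)
  pvals <- vapply(grid, function(m0) {
    fit <- lm(y ~ x * I(m - m0), data = d)
    summary(fit)$coefficients["x", 4]
  }, 0)
  sig <- pvals < 0.05
  crossings <- grid[which(diff(sig) != 0)]
  expect_equal(length(crossings), 2L)
  expect_lt(max(abs(sort(res$jn$boundary) - sort(crossings))), 0.01)

  # boundary verification: just inside vs just outside
  for (bd in res$jn$boundary) {
    inside <- res$slope_p(bd + c(-1e-4, 1e-4))
    expect_true(any(inside < 0.05) && any(inside >= 0.05))
  }

  # rescaling the moderator by 2 rescales boundaries by 2
  d2 <- dplyr::mutate(d, m = 2 * m)
  res2 <- moderation_jn(d2, "y", "x", "m")
  expect_equal(sort(res2$jn$boundary), 2 * sort(res$jn$boundary),
               tolerance = 1e-8)
})

test_that("group ANCOVA: null cohorts rarely show Decision interactions", {
  rejections <- vapply(1:60, function(s) {
    coh <- simulate_ancova_cohort(null_effects(cohort_config()), seed = s)
    a <- group_ancova(coh)
    a$p_value[a$term == "audit_rankit_z x Decision"] < 0.05
  }, NA)
  expect_lt(mean(rejections), 0.15)
})

test_that("group ANCOVA F statistics match an independent nested-model oracle", {
  coh <- simulate_ancova_cohort(cohort_config(), seed = 99)
  a <- group_ancova(coh)
  d <- as.data.frame(coh)
  d$mean_beta <- (d$roi_beta_explore + d$roi_beta_nonexplore) / 2
  d$diff_beta <- d$roi_beta_explore - d$roi_beta_nonexplore
  full <- lm(mean_beta ~ audit_rankit_z + cudit_z + np_z + sex +
               audit_rankit_z:np_z + cudit_z:np_z, data = d)
  red <- update(full, . ~ . - audit_rankit_z)
  F_or <- anova(red, full)$F[2]
  expect_equal(a$F[a$term == "audit_rankit_z" & !a$within], F_or,
               tolerance = 1e-8)
  fullw <- lm(diff_beta ~ audit_rankit_z + cudit_z + np_z + sex +
                audit_rankit_z:np_z + cudit_z:np_z, data = d)
  redw <- update(fullw, . ~ . - cudit_z:np_z)
  F_w <- anova(redw, fullw)$F[2]
  expect_equal(a$F[a$term == "cudit_z:np_z x Decision"], F_w,
               tolerance = 1e-8)

  # duplicating every subject changes F by the known df algebra,
  # matched against the same independent route
  d2 <- rbind(d, d)
  full2 <- lm(mean_beta ~ audit_rankit_z + cudit_z + np_z + sex +
                audit_rankit_z:np_z + cudit_z:np_z, data = d2)
  red2 <- update(full2, . ~ . - audit_rankit_z)
  coh2 <- dplyr::bind_rows(coh, coh)
  a2 <- group_ancova(coh2)
  expect_equal(a2$F[a2$term == "audit_rankit_z" & !a2$within],
               anova(red2, full2)$F[2], tolerance = 1e-8)
  expect_equal(a2$df2[1], 2L * nrow(coh) - 7L)
})

test_that("identical betas across conditions null out Decision interactions", {
  coh <- simulate_ancova_cohort(cohort_config(), seed = 101)
  coh$roi_beta_nonexplore <- coh$roi_beta_explore
  a <- group_ancova(coh)
  w <- a[a$within, ]
  expect_true(all(abs(w$estimate) < 1e-12))
})
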