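test_that("suvr divides lesion by reference and rejects bad references", {
  expect_equal(suvr(5.68, 2.87), 1.979, tolerance = 1e-3)
  expect_equal(suvr(3.3, 3.3), 1.0)
  expect_error(suvr(2, 0), "positive")
})

test_that("deauville_score implements the threshold rule with inclusive boundaries", {
  expect_equal(deauville_score(0.9, 0.7), 2L)
  expect_equal(deauville_score(1.2, 0.96), 3L)
  expect_equal(deauville_score(1.2, 1.3), 4L)
  expect_equal(deauville_score(1.0, 1.0), 2L)   # boundary maps to lower score
  expect_equal(deauville_score(1.2, 1.0), 3L)
  # liver clause precedence when suvr_aorta <= 1 but suvr_liver > 1
  expect_equal(deauville_score(0.9, 1.1), 4L)
  expect_error(deauville_score(-1, 0.5), "positive")

  # monotonicity: increasing either ratio never decreases the score
  grid <- expand.grid(a = seq(0.5, 2, by = 0.25), l = seq(0.5, 2, by = 0.25))
  sc <- deauville_score(grid$a, grid$l)
  for (eps in c(0.1, 0.5)) {
    expect_true(all(deauville_score(grid$a + eps, grid$l) >= sc))
    expect_true(all(deauville_score(grid$a, grid$l + eps) >= sc))
  }
  expect_true(all(sc %in% 2:4))
})

test_that("fit_suvr_regression matches the closed-form OLS oracle", {
  # identity data
  idf <- fit_suvr_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(idf$a, 0)
  expect_equal(idf$b, 1)
  expect_equal(idf$s, 0)

  x <- c(1, 2, 3); y <- c(1.1, 2.0, 3.0)
  fit <- fit_suvr_regression(x, y)
  expect_equal(fit$b, 0.95, tolerance = 1e-12)
  expect_equal(fit$a, 0.13333, tolerance = 1e-4)
  expect_equal(fit$s, 0.0408, tolerance = 1e-3)
  oracle <- ols_oracle(x, y)
  expect_equal(fit$a, oracle$a)
  expect_equal(fit$b, oracle$b)
  expect_equal(fit$s, oracle$s)

  set.seed(5)
  xr <- rlnorm(40); yr <- 0.2 + 0.9 * xr + rnorm(40, sd = 0.1)
  fr <- fit_suvr_regression(xr, yr)
  or <- ols_oracle(xr, yr)
  expect_equal(fr$a, or$a); expect_equal(fr$b, or$b); expect_equal(fr$s, or$s)

  expect_error(fit_suvr_regression(c(2, 2, 2), c(1, 2, 3)), "constant predictor")
  expect_error(fit_suvr_regression(1:2, 1:2), "n >= 3")
})

test_that("prediction_distribution has the prediction-interval form", {
  idfit <- fit_suvr_regression(c(1, 2, 3), c(1, 2, 3))
  pd <- prediction_distribution(idfit, 1)
  expect_equal(pd$mean, 1)
  expect_equal(pd$sd, 0)

  set.seed(6)
  x <- rnorm(25, 2); y <- 0.1 + 0.95 * x + rnorm(25, sd = 0.2)
  fit <- fit_suvr_regression(x, y)
  at_xbar <- prediction_distribution(fit, fit$x_bar)
  expect_equal(at_xbar$sd, fit$s * sqrt(1 + 1 / fit$n)) # formula minimum
  # sd strictly increasing in |r - x_bar|
  r <- fit$x_bar + seq(0, 3, by = 0.1)
  expect_true(all(diff(prediction_distribution(fit, r)$sd) > 0))
  rl <- fit$x_bar - seq(0, 3, by = 0.1)
  expect_true(all(diff(prediction_distribution(fit, rl)$sd) > 0))
  # confidence band is narrower than prediction band
  expect_lt(prediction_distribution(fit, 2, "confidence")$sd,
            prediction_distribution(fit, 2, "prediction")$sd)
})

# build a fit whose predictive mean at r = 1 is exactly 1 + k * predictive sd,
# by exploiting a zero-residual line plus an inflated s via scaling
fit_with_boundary_gap <- function(k) {
  # a symmetric design centered at 1 so x_bar = 1; identity line, then shift
  x <- c(0.5, 0.75, 1, 1.25, 1.5)
  y <- x # perfect line: a = 0, b = 1, s = 0
  fit <- fit_suvr_regression(x, y)
  # manually set a residual SD and intercept so mean(1) = 1 + k * sd(1)
  fit$s <- 0.05
  sd1 <- fit$s * sqrt(1 + 1 / fit$n + (1 - fit$x_bar)^2 / fit$s_xx)
  fit$a <- k * sd1
  fit
}

test_that("misclassification_probability reproduces the boundary structure", {
  # symmetric fit: mean(1) = 1 -> P -> 0.5 as r -> 1+
  sym <- fit_with_boundary_gap(0)
  expect_equal(misclassification_probability(sym, 1 + 1e-9), 0.5, tolerance = 1e-6)

  # mean(1) = 1 + 1.96 sd: false upgrade 2.5% just above, downgrade 97.5% just below
  fit <- fit_with_boundary_gap(1.96)
  p_up <- misclassification_probability(fit, 1 + 1e-9)
  p_down <- misclassification_probability(fit, 1 - 1e-9)
  expect_equal(p_up, 0.025, tolerance = 1e-3)
  expect_equal(p_down, 0.975, tolerance = 1e-3)
  # complementarity at the threshold under one fit
  expect_equal(p_up + p_down, 1, tolerance = 1e-6)

  # monotonicity with b > 0: upgrade P non-increasing above, downgrade
  # non-decreasing below
  ru <- seq(1.001, 2, by = 0.01)
  expect_true(all(diff(misclassification_probability(fit, ru)) <= 1e-12))
  rd <- seq(0.5, 0.999, by = 0.01)
  expect_true(all(diff(misclassification_probability(fit, rd)) >= -1e-12))

  # degenerate fit: deterministic 0/1
  idfit <- fit_suvr_regression(c(1, 2, 3), c(1, 2, 3))
  expect_equal(misclassification_probability(idfit, 1.5), 0) # mean 1.5 > 1, r > 1
  expect_equal(misclassification_probability(idfit, 0.5), 0)
  expect_error(misclassification_probability(idfit, 1), "differ from the threshold")
})

test_that("misclassification probability agrees with Monte-Carlo sampling", {
  set.seed(8)
  x <- runif(40, 0.5, 3)
  y <- 0.15 + 0.9 * x + rnorm(40, sd = 0.15)
  fit <- fit_suvr_regression(x, y)
  for (r in c(0.8, 0.95, 1.05, 1.3)) {
    pd <- prediction_distribution(fit, r)
    draws <- rnorm(1e5, pd$mean, pd$sd)
    mc <- if (r > 1) mean(draws <= 1) else mean(draws > 1)
    expect_lt(abs(misclassification_probability(fit, r) - mc), 0.005)
  }
})

test_that("risk_flag thresholds the probability at alpha", {
  fit <- fit_with_boundary_gap(1.96)
  expect_false(risk_flag(fit, 1 + 1e-9))          # 2.5% < 5%
  expect_true(risk_flag(fit, 1 - 1e-9))           # 97.5% > 5%
  liver_like <- fit_with_boundary_gap(qnorm(1 - 0.16))
  expect_true(risk_flag(liver_like, 1 + 1e-9))    # 16% > 5%
  expect_false(risk_flag(fit, 1.5, alpha = 1))    # alpha = 1: never flagged
  cv <- risk_curve(fit, seq(0.9, 1.1, by = 0.01))
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))
  expect_false(1 %in% cv$r)
})

test_that("regression parameters are recovered from simulated data", {
  a0 <- 0.1; b0 <- 0.95; s0 <- 0.12
  set.seed(9)
  ok <- replicate(10, {
    x <- runif(200, 0.5, 4)
    y <- a0 + b0 * x + rnorm(200, sd = s0)
    fit <- fit_suvr_regression(x, y)
    se_b <- s0 / sqrt(sum((x - mean(x))^2))
    abs(fit$b - b0) < 4 * se_b && abs(fit$s - s0) < 0.05
  })
  expect_gte(mean(ok), 0.9)
})

test_that("score_change_table cross-tabulates per-lesion scores", {
  tab <- data.frame(
    lesion_id = rep(c("L1", "L2", "L3"), each = 2),
    recon = rep(c("AC", "CE"), 3),
    suvr_aorta = c(0.98, 1.02, 2.0, 1.9, 0.5, 0.5),
    suvr_liver = c(0.80, 0.85, 1.5, 1.4, 0.4, 0.4)
  )
  res <- score_change_table(tab)
  expect_equal(res$n_upgraded, 1L)   # L1: the boundary-crossing scenario, 2 -> 3
  expect_equal(res$n_downgraded, 0L)
  expect_equal(res$changes$lesion_id, "L1")
  expect_equal(res$changes$direction, "upgrade")
  expect_equal(sum(res$table), 3)

  # identical ratios -> no changes
  same <- tab
  same$suvr_aorta <- rep(c(1.5, 1.5), 3); same$suvr_liver <- rep(c(0.9, 0.9), 3)
  expect_equal(nrow(score_change_table(same)$changes), 0L)

  # all CE ratios scaled down: changes only in the downgrade direction
  set.seed(10)
  n <- 30
  ac_a <- rlnorm(n, log(1.05), 0.3); ac_l <- ac_a * 0.8
  down <- data.frame(
    lesion_id = rep(sprintf("L%02d", 1:n), each = 2),
    recon = rep(c("AC", "CE"), n),
    suvr_aorta = as.vector(rbind(ac_a, ac_a * 0.85)),
    suvr_liver = as.vector(rbind(ac_l, ac_l * 0.85))
  )
  resd <- score_change_table(down)
  expect_equal(resd$n_upgraded, 0L)
  expect_gt(resd$n_downgraded, 0L)

  expect_error(score_change_table(tab[-1, ]), "both an AC and a CE")
})
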